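# Internal helpers shared across the package.

# Probability clamp keeping log-densities finite; applied to rho, m_k, u_k
# after every M-step and to user-supplied parameters.
.FS_EPS <- 1e-6

clamp_unit <- function(p, eps = .FS_EPS) pmin(pmax(p, eps), 1 - eps)

# TRUE where a probability sits on the clamp boundary (a degenerate EM
# solution for field-selection purposes).
at_clamp <- function(p, eps = .FS_EPS) p <= eps | p >= 1 - eps

`%||%` <- function(x, y) if (is.null(x)) y else x

# Canonical pair key. Dedup pairs are stored with record_a before record_b in
# file order, but external gold standards may list them either way, so the
# unordered key sorts the two ids.
pair_key <- function(a, b, unordered = TRUE) {
  if (unordered) paste(pmin(a, b), pmax(a, b), sep = "\x1f")
  else paste(a, b, sep = "\x1f")
}

# Draw independent sub-seeds from the current RNG state so each stochastic
# component of a generator has its own stream.
spawn_seeds <- function(k) sample.int(.Machine$integer.max - 1L, k)
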