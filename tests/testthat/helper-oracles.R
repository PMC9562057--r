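# Independent oracles: deliberately naive implementations used to check the
# package's vectorized code paths.

# O(n^2) all-pairs scan: pairs agreeing (both non-missing, equal) on every
# blocking variable.
brute_force_block_count <- function(records, vars) {
  n <- nrow(records)
  cnt <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- TRUE
    for (v in vars) {
      a <- records[[v]][i]; b <- records[[v]][j]
      if (is.na(a) || is.na(b) || a != b) { ok <- FALSE; break }
    }
    if (ok) cnt <- cnt + 1L
  }
  cnt
}

# Term-by-term conditional density of one agreement vector.
oracle_class_density <- function(y, p, treatment = "mar") {
  out <- 1
  for (k in seq_along(y)) {
    if (is.na(y[k])) {
      if (treatment == "mad") stop("missing under MAD")
      next
    }
    out <- out * if (y[k] == 1) p[k] else (1 - p[k])
  }
  out
}

# Direct per-pair mixture/marginal log-likelihood summation.
oracle_marginal_loglik <- function(x, rho, m, u) {
  s <- 0
  for (i in seq_len(nrow(x))) {
    y <- x[i, ]
    s <- s + log(rho * oracle_class_density(y, m) +
                 (1 - rho) * oracle_class_density(y, u))
  }
  s
}

oracle_complete_loglik <- function(x, delta, rho, m, u) {
  s <- 0
  for (i in seq_len(nrow(x))) {
    y <- x[i, ]
    s <- s + if (delta[i] == 1) log(rho) + log(oracle_class_density(y, m))
             else log(1 - rho) + log(oracle_class_density(y, u))
  }
  s
}

# Exhaustive grid search for the K = 2 complete-data marginal likelihood,
# over (rho, m1, m2, u1, u2): a full coarse grid (step `coarse`, with the
# orientation representative m1 >= u1 -- the mixture is invariant under
# swapping classes) followed by a full fine grid (step `fine`) in the box
# around the coarse optimum. Returns the best grid log-likelihood and the
# likelihood drop of a one-fine-step perturbation at the optimum.
grid_search_fs2 <- function(x, coarse = 0.025, fine = 0.01) {
  stopifnot(ncol(x) == 2, !anyNA(x))
  cnt <- tabulate(x[, 1] * 2 + x[, 2] + 1, 4)  # patterns 00,01,10,11

  ll_of <- function(rho, m1, m2, u1, u2) {
    q <- function(y1, y2) {
      a <- (m1^y1 * (1 - m1)^(1 - y1)) * (m2^y2 * (1 - m2)^(1 - y2))
      b <- (u1^y1 * (1 - u1)^(1 - y1)) * (u2^y2 * (1 - u2)^(1 - y2))
      rho * a + (1 - rho) * b
    }
    cnt[1] * log(q(0, 0)) + cnt[2] * log(q(0, 1)) +
      cnt[3] * log(q(1, 0)) + cnt[4] * log(q(1, 1))
  }

  vals <- seq(coarse, 1 - coarse, by = coarse)
  combos <- expand.grid(p1 = vals, p2 = vals)
  pp <- cbind((1 - combos$p1) * (1 - combos$p2), (1 - combos$p1) * combos$p2,
              combos$p1 * (1 - combos$p2), combos$p1 * combos$p2)
  nc <- nrow(combos)
  ones <- rep(1, nc)
  orient_ok <- outer(combos$p1, combos$p1, `>=`)  # m1 >= u1
  best <- -Inf; best_par <- NULL
  for (rho in vals) {
    ll <- matrix(0, nc, nc)
    for (p in 1:4)
      ll <- ll + cnt[p] * log(outer(rho * pp[, p], ones) +
                              outer(ones, (1 - rho) * pp[, p]))
    ll[!orient_ok] <- -Inf
    i <- which.max(ll)
    if (ll[i] > best) {
      best <- ll[i]
      r <- (i - 1) %% nc + 1; cc <- (i - 1) %/% nc + 1
      best_par <- c(rho = rho, m1 = combos$p1[r], m2 = combos$p2[r],
                    u1 = combos$p1[cc], u2 = combos$p2[cc])
    }
  }

  fine_vals <- function(center) {
    v <- seq(fine, 1 - fine, by = fine)
    v[abs(v - center) <= coarse + 1e-12]
  }
  g <- expand.grid(rho = fine_vals(best_par["rho"]),
                   m1 = fine_vals(best_par["m1"]), m2 = fine_vals(best_par["m2"]),
                   u1 = fine_vals(best_par["u1"]), u2 = fine_vals(best_par["u2"]))
  ll_fine <- ll_of(g$rho, g$m1, g$m2, g$u1, g$u2)
  i <- which.max(ll_fine)
  opt <- as.numeric(g[i, ])
  ll_best <- max(best, ll_fine[i])

  # one-grid-step likelihood drop at the optimum (largest over coordinates)
  step_drop <- 0
  for (d in 1:5) for (s in c(-fine, fine)) {
    pert <- opt; pert[d] <- pert[d] + s
    if (all(pert > 0 & pert < 1))
      step_drop <- max(step_drop, ll_best - do.call(ll_of, as.list(pert)))
  }
  list(loglik = ll_best, par = opt, step_drop = step_drop)
}
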