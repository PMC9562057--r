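#' Fellegi-Sunter parameter set
#'
#' Bundles the three parameter groups of the latent-class model: the match
#' prevalence `rho` = P(pair is a true match) among the candidate pairs, and
#' per-field agreement probabilities `m[k]` = P(field k agrees | match) and
#' `u[k]` = P(field k agrees | nonmatch). All entries are clamped to
#' (1e-6, 1 - 1e-6) so log-densities stay finite.
#'
#' @param rho Match prevalence in (0, 1).
#' @param m,u Numeric vectors of equal length K with entries in (0, 1).
#' @return An object of class `fs_params`.
#' @export
fs_params <- function(rho, m, u) {
  stopifnot(length(rho) == 1L, is.numeric(rho), is.numeric(m), is.numeric(u),
            length(m) == length(u), length(m) >= 1L)
  if (rho <= 0 || rho >= 1 || any(m <= 0 | m >= 1) || any(u <= 0 | u >= 1))
    stop("rho, m and u must lie strictly inside (0, 1)")
  structure(list(rho = clamp_unit(rho), m = clamp_unit(m), u = clamp_unit(u)),
            class = "fs_params")
}

as_fs_params <- function(object) {
  if (inherits(object, "fs_fit")) return(object$params)
  if (inherits(object, "fs_params")) return(object)
  if (is.list(object) && all(c("rho", "m", "u") %in% names(object)))
    return(fs_params(object$rho, object$m, object$u))
  stop("expected an fs_fit, fs_params, or list(rho, m, u)")
}

check_treatment <- function(x, treatment) {
  if (treatment == "mad" && anyNA(x))
    stop("contract violation: MAD requires a missing-free agreement matrix; ",
         "apply zero_fill() first")
  invisible(TRUE)
}

# Per-pair log conditional density under one class. y: matrix with NA -> 0;
# obsd: 0/1 double mask of observed cells; p: length-K probability vector.
# Missing components contribute factor 1 (the MAR full-information
# likelihood); under MAD the mask is all ones.
.row_loglik <- function(y, obsd, p) {
  n <- nrow(y); K <- length(p)
  lp <- matrix(log(p), n, K, byrow = TRUE)
  lq <- matrix(log1p(-p), n, K, byrow = TRUE)
  rowSums(obsd * (y * lp + (1 - y) * lq))
}

.split_matrix <- function(x) {
  obs <- !is.na(x)
  y <- x; y[!obs] <- 0L
  storage.mode(y) <- "double"
  obsd <- obs + 0
  list(y = y, obsd = obsd)
}

#' Class-conditional density of an agreement vector
#'
#' Probability of the observed agreement pattern under one latent class,
#' assuming conditional independence of the K field comparisons given the
#' class. Under MAR the product runs over observed fields only; under MAD the
#' vector must be missing-free.
#'
#' @param x Agreement vector (length K, values 0/1/NA) or n x K matrix.
#' @param object [fs_params()], `fs_fit`, or `list(rho, m, u)`.
#' @param class `"match"` (uses `m`) or `"nonmatch"` (uses `u`).
#' @param treatment `"mar"` or `"mad"`.
#' @param log Return log-density?
#' @return Numeric vector of per-pair (log-)densities.
#' @export
class_density <- function(x, object, class = c("match", "nonmatch"),
                          treatment = c("mar", "mad"), log = FALSE) {
  class <- match.arg(class); treatment <- match.arg(treatment)
  p <- as_fs_params(object)
  x <- as_agreement_matrix(x)
  check_treatment(x, treatment)
  s <- .split_matrix(x)
  ll <- .row_loglik(s$y, s$obsd, if (class == "match") p$m else p$u)
  if (log) ll else exp(ll)
}

#' Marginal log-likelihood of an agreement matrix
#'
#' Sum over pairs of the log two-class mixture density
#' `log(rho * f(y | match) + (1 - rho) * f(y | nonmatch))`. This is the
#' objective the EM algorithm ascends; parameter clamping keeps it finite.
#'
#' @inheritParams class_density
#' @return A single number.
#' @export
marginal_loglik <- function(x, object, treatment = c("mar", "mad")) {
  treatment <- match.arg(treatment)
  p <- as_fs_params(object)
  x <- as_agreement_matrix(x)
  if (nrow(x) == 0L) stop("usage error: empty agreement matrix")
  check_treatment(x, treatment)
  s <- .split_matrix(x)
  la <- log(p$rho) + .row_loglik(s$y, s$obsd, p$m)
  lb <- log1p(-p$rho) + .row_loglik(s$y, s$obsd, p$u)
  mx <- pmax(la, lb)
  sum(mx + log(exp(la - mx) + exp(lb - mx)))
}

#' Complete-data log-likelihood
#'
#' Log-likelihood when the latent match labels are known:
#' `sum_i delta_i (log rho + log f(y_i | match)) +
#'  (1 - delta_i) (log(1 - rho) + log f(y_i | nonmatch))`.
#' With known labels the maximizing `rho` is `mean(delta)`.
#'
#' @inheritParams marginal_loglik
#' @param labels Per-pair 0/1 match labels (length n).
#' @return A single number.
#' @export
complete_data_loglik <- function(x, labels, object, treatment = c("mar", "mad")) {
  treatment <- match.arg(treatment)
  p <- as_fs_params(object)
  x <- as_agreement_matrix(x)
  if (length(labels) != nrow(x)) stop("labels must have one entry per pair")
  if (!all(labels %in% c(0, 1)))
    stop("usage error: labels must be 0 (nonmatch) or 1 (match)")
  check_treatment(x, treatment)
  s <- .split_matrix(x)
  lm_ <- .row_loglik(s$y, s$obsd, p$m)
  lu_ <- .row_loglik(s$y, s$obsd, p$u)
  sum(labels * (log(p$rho) + lm_) + (1 - labels) * (log1p(-p$rho) + lu_))
}

#' Posterior probability that a pair is a match
#'
#' Bayes rule on the two-class mixture:
#' `rho f(y|match) / (rho f(y|match) + (1-rho) f(y|nonmatch))`. Under MAR a
#' pair with every field missing carries no evidence and returns the prior
#' `rho`.
#'
#' @inheritParams marginal_loglik
#' @return Numeric vector of posterior probabilities in \[0, 1\].
#' @export
posterior_match_prob <- function(x, object, treatment = c("mar", "mad")) {
  treatment <- match.arg(treatment)
  p <- as_fs_params(object)
  x <- as_agreement_matrix(x)
  check_treatment(x, treatment)
  s <- .split_matrix(x)
  la <- log(p$rho) + .row_loglik(s$y, s$obsd, p$m)
  lb <- log1p(-p$rho) + .row_loglik(s$y, s$obsd, p$u)
  1 / (1 + exp(lb - la))
}

#' Fit the Fellegi-Sunter latent class model by EM
#'
#' Maximum-likelihood estimation of `(rho, m, u)` from the agreement matrix
#' alone -- no training labels. The E-step computes each pair's posterior
#' match probability; the M-step sets `rho` to the mean posterior and each
#' `m_k` / `u_k` to the posterior-weighted agreement rate of field k. Under
#' the `"mar"` treatment both weighted means run over the pairs with field k
#' observed (the full-information likelihood); under `"mad"` the matrix must
#' already be zero-filled (see [zero_fill()]) and the two treatments coincide
#' on complete data. Iteration stops when the relative change in the marginal
#' log-likelihood falls below `tol`. Latent-class label switching is resolved
#' by [orient_classes()] so that "match" is the class favouring agreement.
#'
#' @param x Agreement matrix (n x K, values 0/1/NA), e.g. from
#'   [build_agreement_matrix()] or [simulate_agreement()].
#' @param treatment `"mar"` (default) or `"mad"`.
#' @param init Optional [fs_params()] starting point. Default:
#'   `rho = 0.1`, `m_k = 0.8`, `u_k = 0.2`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @param n_starts Number of EM starts; starts beyond the first use random
#'   initial values (jittered, seeded by `seed`) and the best final
#'   log-likelihood wins. A guard against local optima of the mixture
#'   likelihood.
#' @param seed Optional seed for the extra starts.
#' @return An object of class `fs_fit`: `params` ([fs_params()]),
#'   `posteriors`, `loglik`, `loglik_trace`, `n_iter`, `converged`,
#'   `boundary` (any probability pinned at the clamp), `treatment`, `n`, `K`,
#'   `fields`, and the training `data`.
#' @examples
#' sim <- simulate_agreement(2000, rho = 0.3, m = rep(0.9, 4), u = rep(0.1, 4),
#'                           missingness = miss_mcar(0.2), seed = 1)
#' fit <- fs_fit(sim$matrix, treatment = "mar")
#' coef(fit)
#' @export
fs_fit <- function(x, treatment = c("mar", "mad"), init = NULL, tol = 1e-8,
                   max_iter = 1000L, n_starts = 1L, seed = NULL) {
  treatment <- match.arg(treatment)
  x <- as_agreement_matrix(x)
  n <- nrow(x); K <- ncol(x)
  if (n < 2L || K < 1L)
    stop("usage error: need at least 2 pairs and 1 field to fit")
  check_treatment(x, treatment)
  s <- .split_matrix(x)
  n_obs <- colSums(s$obsd)
  if (any(n_obs == 0L))
    stop("contract violation: field(s) observed in zero pairs: ",
         paste(colnames(x)[n_obs == 0L], collapse = ", "),
         " (screen fields before fitting)")

  run_em <- function(rho, m, u) {
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      la <- log(rho) + .row_loglik(s$y, s$obsd, m)
      lb <- log1p(-rho) + .row_loglik(s$y, s$obsd, u)
      mx <- pmax(la, lb)
      ll <- sum(mx + log(exp(la - mx) + exp(lb - mx)))
      trace[it] <- ll
      if (it > 1L &&
          abs(ll - ll_prev) < tol * (abs(ll_prev) + .Machine$double.eps)) {
        converged <- TRUE
        break
      }
      if (it >= max_iter) break
      ll_prev <- ll
      w <- 1 / (1 + exp(lb - la))            # E-step posteriors
      rho <- clamp_unit(mean(w))             # M-step
      ow <- s$obsd * w
      m <- clamp_unit(colSums(ow * s$y) / colSums(ow))
      ou <- s$obsd * (1 - w)
      u <- clamp_unit(colSums(ou * s$y) / colSums(ou))
    }
    list(rho = rho, m = m, u = u, trace = trace, n_iter = it,
         converged = converged, loglik = trace[it])
  }

  starts <- list(list(rho = 0.1, m = rep(0.8, K), u = rep(0.2, K)))
  if (!is.null(init)) {
    p0 <- as_fs_params(init)
    stopifnot(length(p0$m) == K)
    starts[[1]] <- list(rho = p0$rho, m = p0$m, u = p0$u)
  }
  if (n_starts > 1L) {
    if (!is.null(seed)) set.seed(seed)
    for (i in seq_len(n_starts - 1L))
      starts[[i + 1L]] <- list(rho = stats::runif(1, 0.02, 0.5),
                               m = stats::runif(K, 0.55, 0.95),
                               u = stats::runif(K, 0.05, 0.45))
  }
  best <- NULL
  for (st in starts) {
    res <- run_em(st$rho, st$m, st$u)
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }

  fit <- structure(list(
    params = fs_params(best$rho, best$m, best$u),
    posteriors = NULL,
    loglik = best$loglik,
    loglik_trace = best$trace,
    n_iter = best$n_iter,
    converged = best$converged,
    boundary = any(at_clamp(c(best$rho, best$m, best$u))),
    treatment = treatment,
    n = n, K = K, fields = colnames(x),
    n_observed = n_obs,
    data = x,
    call = match.call()
  ), class = "fs_fit")
  fit <- orient_classes(fit)
  fit$posteriors <- posterior_match_prob(x, fit$params, treatment)
  names(fit$params$m) <- names(fit$params$u) <- colnames(x)
  fit
}

#' Resolve latent-class label switching
#'
#' The mixture likelihood is invariant under swapping the two classes
#' (`rho, m, u` vs `1 - rho, u, m`); this picks the representative in which
#' agreement is overall more likely under the "match" class: if
#' `sum_k [log(m_k) - log(u_k)] < 0` the classes are swapped, `rho` is
#' replaced by `1 - rho` and posteriors by their complements. Idempotent.
#'
#' @param object An `fs_fit` or [fs_params()].
#' @return Object of the same class, oriented.
#' @export
orient_classes <- function(object) {
  if (inherits(object, "fs_params")) {
    if (sum(log(object$m) - log(object$u)) < 0)
      return(fs_params(1 - object$rho, object$u, object$m))
    return(object)
  }
  stopifnot(inherits(object, "fs_fit"))
  p <- object$params
  if (sum(log(p$m) - log(p$u)) < 0) {
    object$params <- fs_params(1 - p$rho, p$u, p$m)
    names(object$params$m) <- names(object$params$u) <- names(p$m)
    if (!is.null(object$posteriors)) object$posteriors <- 1 - object$posteriors
  }
  object
}

#' Did the EM fit converge cleanly?
#'
#' The working definition of a usable fit, as consumed by the data-driven
#' field-selection loop: the relative-likelihood stopping rule was met before
#' the iteration cap, no estimated probability is pinned at the clamping
#' boundary, and the estimated prevalence is not degenerate
#' (`rho_hat >= 10 / n`). These are the observable failure modes of EM on an
#' over-parameterized or uninformative field set.
#'
#' @param fit An `fs_fit`.
#' @return `TRUE` or `FALSE`.
#' @export
fs_fit_ok <- function(fit) {
  stopifnot(inherits(fit, "fs_fit"))
  isTRUE(fit$converged) && !isTRUE(fit$boundary) &&
    fit$params$rho >= 10 / fit$n
}
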