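# S3 methods for fitted Fellegi-Sunter models.

#' @export
print.fs_fit <- function(x, digits = 4, ...) {
  cat("Fellegi-Sunter latent class model fit\n")
  cat(sprintf("  treatment: %s   pairs: %d   fields: %d\n",
              toupper(x$treatment), x$n, x$K))
  cat(sprintf("  match prevalence (rho): %.*f\n", digits, x$params$rho))
  cat(sprintf("  log-likelihood: %.*f after %d EM iterations (%s)\n",
              digits, x$loglik, x$n_iter,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' Summarize a Fellegi-Sunter fit
#'
#' Tabulates the per-field m- and u-probability estimates together with the
#' agreement and disagreement log-weights `log(m/u)` and
#' `log((1-m)/(1-u))` that drive the match score, plus the share of pairs
#' with the field observed.
#'
#' @param object An `fs_fit`.
#' @param ... Unused.
#' @return An object of class `summary.fs_fit`.
#' @export
summary.fs_fit <- function(object, ...) {
  p <- object$params
  tab <- data.frame(field = object$fields,
                    m = unname(p$m), u = unname(p$u),
                    w_agree = unname(log(p$m) - log(p$u)),
                    w_disagree = unname(log1p(-p$m) - log1p(-p$u)),
                    prop_observed = unname(object$n_observed / object$n),
                    stringsAsFactors = FALSE)
  structure(list(fit = object, table = tab), class = "summary.fs_fit")
}

#' @export
print.summary.fs_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nField parameters:\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fs_fit <- function(object, ...) {
  p <- object$params
  c(rho = p$rho,
    stats::setNames(p$m, paste0("m.", object$fields)),
    stats::setNames(p$u, paste0("u.", object$fields)))
}

#' @export
logLik.fs_fit <- function(object, ...) {
  structure(object$loglik, df = 2L * object$K + 1L, nobs = object$n,
            class = "logLik")
}

#' Predict from a fitted Fellegi-Sunter model
#'
#' @param object An `fs_fit`.
#' @param newdata Agreement matrix; defaults to the training matrix.
#' @param type `"posterior"` (match probability), `"score"` (log
#'   likelihood-ratio), or `"class"` (logical match labels from the
#'   prevalence-quantile rule applied to the `newdata` scores).
#' @param ... Unused.
#' @return Numeric or logical vector, one value per pair.
#' @export
predict.fs_fit <- function(object, newdata = NULL,
                           type = c("posterior", "score", "class"), ...) {
  type <- match.arg(type)
  x <- newdata %||% object$data
  switch(type,
         posterior = posterior_match_prob(x, object$params, object$treatment),
         score = match_score(x, object$params, object$treatment),
         class = {
           sc <- match_score(x, object$params, object$treatment)
           sc > threshold_from_prevalence(sc, object$params$rho)$threshold
         })
}

#' @export
fitted.fs_fit <- function(object, ...) object$posteriors

#' Residuals of a Fellegi-Sunter fit
#'
#' Pearson residuals of the observed field agreements against the fitted
#' per-pair mixture probability `w_i * m_k + (1 - w_i) * u_k`, where `w_i`
#' is the posterior match probability. Missing comparisons give `NA`.
#'
#' @param object An `fs_fit`.
#' @param ... Unused.
#' @return An n x K matrix of residuals.
#' @export
residuals.fs_fit <- function(object, ...) {
  w <- object$posteriors
  p <- outer(w, object$params$m) + outer(1 - w, object$params$u)
  r <- (object$data - p) / sqrt(p * (1 - p))
  dimnames(r) <- list(NULL, object$fields)
  r
}

#' Diagnostic plots for a Fellegi-Sunter fit
#'
#' Left: the EM log-likelihood trace (monotone ascent). Right: histogram of
#' the training match scores with the prevalence-quantile threshold.
#'
#' @param x An `fs_fit`.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.fs_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b", pch = 16,
       cex = 0.6, xlab = "EM iteration", ylab = "marginal log-likelihood",
       main = "EM ascent")
  sc <- match_score(x$data, x$params, x$treatment)
  thr <- threshold_from_prevalence(sc, x$params$rho)$threshold
  graphics::hist(sc, breaks = 40, xlab = "match score",
                 main = "score distribution", ...)
  graphics::abline(v = thr, col = "red", lwd = 2)
  invisible(x)
}

#' Simulate agreement data from a fitted model
#'
#' Parametric simulation at the fitted `(rho, m, u)`; each field is masked
#' MCAR at its observed missingness rate, so simulated data share the fit's
#' missing-data footprint.
#'
#' @param object An `fs_fit`.
#' @param nsim Number of replicate data sets.
#' @param seed Optional root seed.
#' @param n_pairs Pairs per replicate (default: training size).
#' @param ... Unused.
#' @return List of `nsim` [simulate_agreement()] results.
#' @export
simulate.fs_fit <- function(object, nsim = 1, seed = NULL,
                            n_pairs = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  sub <- spawn_seeds(nsim)
  miss_rates <- 1 - object$n_observed / object$n
  mechs <- lapply(miss_rates, function(r)
    if (r > 0) miss_mcar(r) else miss_none())
  lapply(seq_len(nsim), function(i)
    simulate_agreement(n_pairs, object$params$rho, object$params$m,
                       object$params$u, missingness = mechs, seed = sub[i]))
}
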