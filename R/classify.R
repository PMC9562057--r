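#' Log likelihood-ratio match score
#'
#' Per-pair sum over fields of the log likelihood ratio of the observed
#' comparison outcome: `log(m_k / u_k)` on agreement,
#' `log((1 - m_k) / (1 - u_k))` on disagreement. Under MAR missing fields
#' contribute nothing (an all-missing pair scores exactly 0); under MAD the
#' matrix must be zero-filled first, so former missings score as
#' disagreements. The score is monotone in the posterior: it equals the
#' log posterior odds minus the log prior odds.
#'
#' @inheritParams marginal_loglik
#' @return Numeric vector of scores, one per pair.
#' @examples
#' match_score(c(1, 1, 0), fs_params(0.3, rep(0.9, 3), rep(0.1, 3)))
#' @export
match_score <- function(x, object, treatment = c("mar", "mad")) {
  treatment <- match.arg(treatment)
  p <- as_fs_params(object)
  x <- as_agreement_matrix(x)
  check_treatment(x, treatment)
  s <- .split_matrix(x)
  n <- nrow(x); K <- ncol(x)
  wa <- matrix(log(p$m) - log(p$u), n, K, byrow = TRUE)
  wd <- matrix(log1p(-p$m) - log1p(-p$u), n, K, byrow = TRUE)
  rowSums(s$obsd * (s$y * wa + (1 - s$y) * wd))
}

#' Prevalence-quantile classification threshold
#'
#' Sets the decision threshold at the upper-`rho` quantile of the empirical
#' score distribution, i.e. the `ceiling(n * (1 - rho))`-th ascending order
#' statistic, so that (up to ties) a fraction `rho` of the pairs is declared
#' a match. A pair is a match iff its score is strictly greater than the
#' threshold; ties at the threshold are nonmatches.
#'
#' @param scores Numeric vector of match scores (non-empty).
#' @param rho Match prevalence in (0, 1), normally the EM estimate for the
#'   same block.
#' @return An object of class `fs_rule`: `threshold`, `rho`.
#' @examples
#' threshold_from_prevalence(1:10, 0.3)  # threshold 7: matches are 8, 9, 10
#' @export
threshold_from_prevalence <- function(scores, rho) {
  if (!length(scores)) stop("usage error: empty score vector")
  stopifnot(rho > 0, rho < 1)
  ord <- sort(scores)
  thr <- ord[ceiling(length(scores) * (1 - rho))]
  structure(list(threshold = thr, rho = rho), class = "fs_rule")
}

#' @export
print.fs_rule <- function(x, ...) {
  cat(sprintf("Classification rule: score > %.6g (upper %.4f-quantile)\n",
              x$threshold, x$rho))
  invisible(x)
}

#' Classify the pairs of one block
#'
#' Scores every pair with the block's fitted parameters, derives the
#' threshold from the block-specific prevalence estimate via
#' [threshold_from_prevalence()], and labels each pair.
#'
#' @param x The agreement matrix the fit was produced from (zero-filled for
#'   MAD).
#' @param fit The block's `fs_fit`.
#' @param pairs Optional `record_a`/`record_b` data frame; defaults to the
#'   `pairs` attribute of `x` if present.
#' @return Data frame with (when pair ids are available) `record_a`,
#'   `record_b`, then `score`, `posterior`, `match`; attributes `rule` and
#'   `scheme`.
#' @export
classify_block <- function(x, fit, pairs = NULL) {
  stopifnot(inherits(fit, "fs_fit"))
  pairs <- pairs %||% attr(x, "pairs")
  x <- as_agreement_matrix(x)
  scores <- match_score(x, fit$params, fit$treatment)
  rule <- threshold_from_prevalence(scores, fit$params$rho)
  out <- data.frame(score = scores,
                    posterior = posterior_match_prob(x, fit$params, fit$treatment),
                    match = scores > rule$threshold)
  if (!is.null(pairs))
    out <- cbind(pairs[, c("record_a", "record_b")], out)
  attr(out, "rule") <- rule
  out
}

#' Union of matches over blocks
#'
#' A pair is a final match iff at least one block labels it a match; pairs
#' surfacing in several blocks are deduplicated and keep the provenance of
#' every block that matched them.
#'
#' @param blocks Named list of [classify_block()] results (names used as
#'   block labels) containing `record_a`, `record_b`, `match`.
#' @return Data frame of unique matched pairs: `record_a`, `record_b`,
#'   `blocks` (comma-separated provenance).
#' @export
union_matches <- function(blocks) {
  if (is.null(names(blocks))) names(blocks) <- sprintf("block%d", seq_along(blocks))
  rows <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    if (!all(c("record_a", "record_b", "match") %in% names(b)))
      stop("each block must carry record_a, record_b and match columns")
    m <- b[b$match, c("record_a", "record_b"), drop = FALSE]
    if (nrow(m)) m$block <- nm
    m
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || !nrow(all))
    return(data.frame(record_a = character(0), record_b = character(0),
                      blocks = character(0), stringsAsFactors = FALSE))
  k <- paste(all$record_a, all$record_b, sep = "\x1f")
  prov <- tapply(all$block, k, function(s) paste(sort(unique(s)), collapse = ","))
  first <- !duplicated(k)
  out <- all[first, c("record_a", "record_b"), drop = FALSE]
  out$blocks <- as.character(prov[k[first]])
  rownames(out) <- NULL
  out
}
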