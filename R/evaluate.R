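#' Confusion counts against a gold standard
#'
#' Cross-tabulates predicted match labels with human-reviewed true statuses.
#' Two input forms are supported: two aligned logical vectors
#' (`pred`, `truth`), or a data frame of predicted matched pairs plus a gold
#' standard data frame `record_a, record_b, label` with labels `"match"` /
#' `"nonmatch"` — any gold pair absent from the predicted match set counts as
#' a predicted nonmatch (pairs never generated by any block are nonmatches by
#' construction).
#'
#' @param pred Logical vector of predictions, or a data frame of predicted
#'   matches with `record_a`, `record_b` (e.g. from [union_matches()]).
#' @param truth Logical vector of true statuses, or a gold-standard data
#'   frame `record_a`, `record_b`, `label`.
#' @param unordered Treat pair keys as unordered (dedup semantics)? Default
#'   `TRUE`.
#' @return An object of class `fs_confusion`: integer vector
#'   `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(pred, truth, unordered = TRUE) {
  if (is.data.frame(truth)) {
    if (!all(c("record_a", "record_b", "label") %in% names(truth)))
      stop("gold standard must have columns record_a, record_b, label")
    bad <- setdiff(unique(truth$label), c("match", "nonmatch"))
    if (length(bad))
      stop("data error: gold labels must be 'match' or 'nonmatch'; found: ",
           paste(bad, collapse = ", "))
    gk <- pair_key(as.character(truth$record_a), as.character(truth$record_b),
                   unordered)
    if (anyDuplicated(gk)) stop("data error: duplicate gold-standard pairs")
    pk <- if (is.data.frame(pred))
      pair_key(as.character(pred$record_a), as.character(pred$record_b), unordered)
    else stop("with a gold-standard data frame, pred must be a data frame of matched pairs")
    pred <- gk %in% pk
    truth <- truth$label == "match"
  }
  stopifnot(is.logical(pred), is.logical(truth), length(pred) == length(truth))
  as_confusion(tp = sum(pred & truth), fp = sum(pred & !truth),
               tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' Build confusion counts directly
#'
#' @param tp,fp,tn,fn Non-negative cell counts.
#' @return An `fs_confusion` object.
#' @export
as_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp = as.integer(tp), fp = as.integer(fp),
              tn = as.integer(tn), fn = as.integer(fn))
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(counts, class = "fs_confusion")
}

#' @export
print.fs_confusion <- function(x, ...) {
  cat("Confusion counts (vs gold standard):\n")
  tbl <- matrix(c(x["tp"], x["fn"], x["fp"], x["tn"]), 2, 2,
                dimnames = list(c("pred match", "pred nonmatch"),
                                c("true match", "true nonmatch")))
  print(tbl)
  invisible(x)
}

#' Linkage accuracy metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`,
#' NPV `TN/(TN+FN)`, and the F1-score (harmonic mean of PPV and sensitivity,
#' equivalently `2TP/(2TP+FP+FN)`). A metric with a zero denominator is
#' undefined and reported as `NA`, never as 0.
#'
#' @param counts An `fs_confusion` from [confusion_counts()] /
#'   [as_confusion()].
#' @return Named numeric vector
#'   `c(sensitivity, specificity, ppv, npv, f1)`.
#' @examples
#' linkage_metrics(as_confusion(tp = 4647, fp = 52, tn = 10498, fn = 1303))
#' @export
linkage_metrics <- function(counts) {
  stopifnot(inherits(counts, "fs_confusion"))
  .metrics_from_cells(counts["tp"], counts["fp"], counts["tn"], counts["fn"])
}

.metrics_from_cells <- function(tp, fp, tn, fn) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  c(sensitivity = unname(safe_div(tp, tp + fn)),
    specificity = unname(safe_div(tn, tn + fp)),
    ppv = unname(safe_div(tp, tp + fp)),
    npv = unname(safe_div(tn, tn + fn)),
    f1 = unname(safe_div(2 * tp, 2 * tp + fp + fn)))
}

#' Bootstrap confidence intervals for linkage metrics
#'
#' Resamples the gold-standard pairs with replacement `B` times and reports
#' percentile confidence intervals for each metric. Because every metric
#' depends on the gold rows only through the 2x2 confusion table, resampling
#' n pairs is realized exactly as a multinomial draw over the four cells,
#' which keeps 999 replicates cheap at any n. Deterministic given `seed`.
#'
#' @param counts An `fs_confusion`.
#' @param B Number of bootstrap resamples (default 999).
#' @param seed RNG seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `metric_report`: data frame with columns
#'   `metric`, `estimate`, `lower`, `upper`; attributes `B`, `seed`, `conf`,
#'   `counts`.
#' @examples
#' cc <- as_confusion(tp = 4647, fp = 52, tn = 10498, fn = 1303)
#' bootstrap_metrics(cc, B = 999, seed = 42)
#' @export
bootstrap_metrics <- function(counts, B = 999L, seed = NULL, conf = 0.95) {
  stopifnot(inherits(counts, "fs_confusion"), B >= 1L)
  n <- sum(counts)
  if (n == 0L) stop("empty gold standard")
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rmultinom(B, size = n, prob = as.numeric(counts) / n)
  rownames(draws) <- names(counts)
  boot <- .metrics_from_cells(draws["tp", ], draws["fp", ],
                              draws["tn", ], draws["fn", ])
  boot <- matrix(boot, nrow = B,
                 dimnames = list(NULL, c("sensitivity", "specificity",
                                         "ppv", "npv", "f1")))
  alpha <- (1 - conf) / 2
  point <- linkage_metrics(counts)
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  out <- data.frame(metric = colnames(boot),
                    estimate = unname(point[colnames(boot)]),
                    lower = unname(ci[1, ]),
                    upper = unname(ci[2, ]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("metric_report", "data.frame"),
            B = B, seed = seed, conf = conf, counts = counts)
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(sprintf("Linkage metrics with %.0f%% percentile bootstrap CIs (B = %d):\n",
              100 * attr(x, "conf"), attr(x, "B")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-11s %s (%s-%s)\n", x$metric[i],
                format(round(x$estimate[i], digits), nsmall = digits),
                format(round(x$lower[i], digits), nsmall = digits),
                format(round(x$upper[i], digits), nsmall = digits)))
  invisible(x)
}

#' Read a gold-standard CSV
#'
#' Expected columns: `record_a`, `record_b`, `label` with labels `match` /
#' `nonmatch`.
#'
#' @param path CSV path.
#' @return Data frame with character columns.
#' @export
read_gold_standard <- function(path) {
  g <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                       stringsAsFactors = FALSE)
  need <- c("record_a", "record_b", "label")
  if (!all(need %in% names(g)))
    stop("gold standard must have columns record_a, record_b, label")
  g[need]
}
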