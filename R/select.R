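#' Screen candidate matching fields for one block
#'
#' Removes, in order and with recorded reasons: (i) the block's own blocking
#' variables (within the block they agree by construction, so they carry no
#' information there and are excluded from the agreement matrix — reason
#' `blocking_variable`); (ii) fields whose comparisons are 100% missing in
#' the block (`all_missing`); (iii) fields with no variability among the
#' observed comparisons, i.e. all-agree or all-disagree (`no_variability`).
#' Both expert and data-driven field selection apply this screen.
#'
#' @param x Agreement matrix whose columns are the candidate fields.
#' @param blocking_vars Character vector of the block's blocking variables.
#' @param candidates Candidate field names (default: all columns of `x`).
#' @return An object of class `field_set`: `fields` (survivors, in candidate
#'   order) and `dropped` (data frame `field`, `reason`).
#' @export
screen_fields <- function(x, blocking_vars = character(),
                          candidates = colnames(x)) {
  stopifnot(is.matrix(x) || is.data.frame(x))
  dropped <- data.frame(field = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  note <- function(f, why) rbind(dropped,
    data.frame(field = f, reason = rep(why, length(f)), stringsAsFactors = FALSE))

  keep <- candidates
  bv <- intersect(keep, blocking_vars)
  if (length(bv)) { dropped <- note(bv, "blocking_variable"); keep <- setdiff(keep, bv) }

  unknown <- setdiff(keep, colnames(x))
  if (length(unknown))
    stop("config error: candidate field(s) absent from agreement matrix: ",
         paste(unknown, collapse = ", "))

  am <- keep[vapply(keep, function(f) all(is.na(x[, f])), logical(1))]
  if (length(am)) { dropped <- note(am, "all_missing"); keep <- setdiff(keep, am) }

  nv <- keep[vapply(keep, function(f) {
    v <- x[, f][!is.na(x[, f])]
    all(v == v[1])
  }, logical(1))]
  if (length(nv)) { dropped <- note(nv, "no_variability"); keep <- setdiff(keep, nv) }

  if (!length(keep))
    stop("selection error: no usable matching fields survive screening")
  structure(list(fields = keep, dropped = dropped, mode = "screen"),
            class = "field_set")
}

#' Variability of a comparison column
#'
#' `min(p, 1 - p)` where `p` is the agreement proportion among non-missing
#' comparisons: 0 for a constant column, 0.5 for a perfectly balanced one.
#' Used to rank fields for dropping — the least variable field goes first —
#' when the data-driven selection loop must shrink the field set.
#'
#' @param column Ternary comparison vector (0/1/NA) with at least one
#'   observed state.
#' @return A number in \[0, 0.5\].
#' @export
field_variability <- function(column) {
  obs <- column[!is.na(column)]
  if (!length(obs)) stop("variability is undefined for an all-missing column")
  p <- mean(obs == 1)
  min(p, 1 - p)
}

#' Select matching fields for one block
#'
#' Expert mode screens the expert-specified list via [screen_fields()] and
#' returns it. Data-driven mode starts from the largest screened candidate
#' set and repeatedly: fits the FS model on the current set; stops if the fit
#' is clean per [fs_fit_ok()]; otherwise drops the single field with the
#' lowest [field_variability()] (ties broken lexicographically by field name,
#' for determinism) and refits. Exhausting the fields without a clean fit is
#' a selection error.
#'
#' @param x Agreement matrix over all candidate fields (ternary; the MAD
#'   zero-fill is applied internally to each fitted subset).
#' @param blocking_vars The block's blocking variables.
#' @param candidates Candidate fields (default all columns).
#' @param mode `"data_driven"` or `"expert"`.
#' @param expert_fields Character vector, required in expert mode.
#' @param treatment `"mar"` or `"mad"` — passed to [fs_fit()].
#' @param ... Further arguments to [fs_fit()] (`tol`, `max_iter`,
#'   `n_starts`, `seed`).
#' @return A `field_set`: `fields`, `dropped` (reasons partition the dropped
#'   fields), `mode`, and for data-driven mode the final `fit`.
#' @export
select_fields <- function(x, blocking_vars = character(),
                          candidates = colnames(x),
                          mode = c("data_driven", "expert"),
                          expert_fields = NULL,
                          treatment = c("mar", "mad"), ...) {
  mode <- match.arg(mode); treatment <- match.arg(treatment)
  if (mode == "expert") {
    if (is.null(expert_fields)) stop("expert mode requires expert_fields")
    fs <- screen_fields(x, blocking_vars, intersect(expert_fields, candidates))
    fs$mode <- "expert"
    return(fs)
  }
  fs <- screen_fields(x, blocking_vars, candidates)
  fields <- fs$fields
  dropped <- fs$dropped
  fit <- NULL
  repeat {
    xf <- x[, fields, drop = FALSE]
    if (treatment == "mad") xf <- zero_fill(xf)
    fit <- fs_fit(xf, treatment = treatment, ...)
    if (fs_fit_ok(fit)) break
    if (length(fields) <= 1L)
      stop("selection error: fields exhausted without a converged FS fit ",
           sprintf("(last fit: converged=%s, boundary=%s, rho=%.3g)",
                   fit$converged, fit$boundary, fit$params$rho))
    v <- vapply(fields, function(f) field_variability(x[, f]), numeric(1))
    worst <- fields[order(v, fields)][1L]
    dropped <- rbind(dropped, data.frame(field = worst,
                                         reason = "dropped_for_convergence",
                                         stringsAsFactors = FALSE))
    fields <- setdiff(fields, worst)
  }
  structure(list(fields = fields, dropped = dropped, mode = "data_driven",
                 fit = fit), class = "field_set")
}

#' @export
print.field_set <- function(x, ...) {
  cat(sprintf("Field set (%s): %s\n", x$mode, paste(x$fields, collapse = ", ")))
  if (nrow(x$dropped)) {
    cat("Dropped:\n")
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("  %s (%s)\n", x$dropped$field[i], x$dropped$reason[i]))
  }
  invisible(x)
}
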