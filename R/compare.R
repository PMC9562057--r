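#' Compare two canonical values on one field
#'
#' The ternary comparison underlying the whole model: `1` if both values are
#' non-missing and equal, `0` if both are non-missing and unequal, and `NA`
#' if either is missing (including both missing). Symmetric in its arguments.
#'
#' @param va,vb Character vectors of canonical values (`NA` = missing).
#' @return Integer vector in `{0L, 1L, NA}`.
#' @export
compare_values <- function(va, vb) {
  ifelse(is.na(va) | is.na(vb), NA_integer_, as.integer(va == vb))
}

#' Compare a record pair on one field
#'
#' @param rec_a,rec_b Single rows of `fs_records` data frames.
#' @param field Field name present in both.
#' @return `1L`, `0L`, or `NA` as in [compare_values()].
#' @export
compare_pair <- function(rec_a, rec_b, field) {
  if (!(field %in% names(rec_a)) || !(field %in% names(rec_b)))
    stop("field not present in both record sets: ", field)
  compare_values(rec_a[[field]], rec_b[[field]])
}

#' Build the agreement matrix for a candidate pair set
#'
#' Compares every candidate pair field by field, yielding one ternary
#' agreement vector per pair (row order follows the pair set). The resulting
#' n x K matrix of values in `{0, 1, NA}` is the observed data of the
#' Fellegi-Sunter model; with K complete fields each row is one of the 2^K
#' agreement patterns.
#'
#' @param pairs A `pair_set` data frame from [block_pairs()] /
#'   [union_pairsets()].
#' @param a Record set the `record_a` ids refer to.
#' @param b Record set for `record_b` ids; defaults to `a` (deduplication).
#' @param fields Character vector of matching-field names (non-empty).
#' @return Integer matrix with one column per field and attribute `pairs`
#'   (the `record_a`/`record_b` columns of `pairs`).
#' @export
build_agreement_matrix <- function(pairs, a, b = NULL, fields) {
  if (!length(fields)) stop("fields must be non-empty")
  bb <- b %||% a
  ia <- match(pairs$record_a, a$record_id)
  ib <- match(pairs$record_b, bb$record_id)
  if (anyNA(ia) || anyNA(ib))
    stop("pair set references record ids absent from the record sets")
  m <- matrix(NA_integer_, nrow(pairs), length(fields),
              dimnames = list(NULL, fields))
  for (f in fields) m[, f] <- compare_values(a[[f]][ia], bb[[f]][ib])
  attr(m, "pairs") <- data.frame(record_a = pairs$record_a,
                                 record_b = pairs$record_b,
                                 stringsAsFactors = FALSE)
  m
}

#' Recode missing comparisons as disagreement (MAD)
#'
#' The missing-as-disagreement treatment replaces every missing (`NA`)
#' comparison by `0` before model fitting; observed comparisons are left
#' untouched and the input is not modified. Idempotent, and the identity on
#' complete data.
#'
#' @param x Agreement matrix (values in `{0, 1, NA}`).
#' @return The zero-filled matrix (attributes preserved).
#' @export
zero_fill <- function(x) {
  x[is.na(x)] <- 0L
  x
}

# Validate/coerce a user-supplied agreement matrix: numeric matrix or data
# frame with entries in {0, 1, NA}. Ternary state is NA, never a numeric
# sentinel.
as_agreement_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && !is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(x) || !(is.numeric(x) || is.logical(x)))
    stop("agreement data must be a numeric matrix with entries 0, 1 or NA")
  if (!all(x %in% c(0, 1) | is.na(x)))
    stop("agreement data must contain only 0, 1 or NA")
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%d", seq_len(ncol(x)))
  x
}
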