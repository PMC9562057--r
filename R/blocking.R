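#' Define a blocking scheme
#'
#' A blocking scheme names an ordered set of blocking variables. Candidate
#' record pairs are those agreeing exactly (both non-missing and canonically
#' equal) on every blocking variable; all other pairs are never compared,
#' which reduces the quadratic all-pairs space to the union of within-block
#' pairs. Several schemes are typically run and their pair sets unioned,
#' because any single scheme misses true matches whose blocking values are
#' missing or erroneous.
#'
#' @param name Scheme label, e.g. `"DB-MB-YB-ZIP"`.
#' @param variables Character vector of field names (non-empty).
#' @return An object of class `blocking_scheme`.
#' @export
blocking_scheme <- function(name, variables) {
  variables <- as.character(variables)
  if (!length(variables)) stop("blocking scheme needs at least one variable")
  structure(list(name = name, variables = variables), class = "blocking_scheme")
}

# Concatenated canonical blocking key; NA if any blocking value is missing
# (exact agreement is impossible against a missing value, so such records
# fall out of this scheme entirely).
block_key <- function(records, vars) {
  key <- do.call(paste, c(unname(records[vars]), sep = "\x1f"))
  any_na <- Reduce(`|`, lapply(records[vars], is.na))
  key[any_na] <- NA_character_
  key
}

# All unordered index pairs within one block, in file order.
pairs_in_group <- function(g) {
  s <- length(g)
  i <- rep.int(seq_len(s - 1L), rev(seq_len(s - 1L)))
  j <- sequence(rev(seq_len(s - 1L)), from = 2:s)
  cbind(g[i], g[j])
}

#' Enumerate candidate pairs by exact-agreement blocking
#'
#' Hash-groups records on the concatenated canonical blocking key and emits
#' every within-block pair. With one record file (deduplication) each
#' unordered pair is emitted once, `record_a` preceding `record_b` in file
#' order and self-pairs excluded; with two files (linkage) the pairs are the
#' cross product of the two files' blocks. Records missing any blocking
#' variable appear in no pair of the scheme.
#'
#' @param a An `fs_records` data frame (see [read_records()]).
#' @param b Optional second `fs_records` data frame for cross-file linkage;
#'   `NULL` (default) deduplicates `a` against itself.
#' @param scheme A [blocking_scheme()] or character vector of variable names.
#' @param cap Optional per-block size cap; blocks larger than `cap` records
#'   trigger a warning (never an error) and are kept.
#' @return A `pair_set` data frame with columns `record_a`, `record_b`,
#'   `scheme`; attribute `mode` is `"dedup"` or `"linkage"`.
#' @examples
#' recs <- as_records(data.frame(record_id = 1:4,
#'                               zip = c("46202", "46202", "46202", NA)),
#'                    record_schema("zip"))
#' block_pairs(recs, scheme = "zip")
#' @export
block_pairs <- function(a, b = NULL, scheme, cap = Inf) {
  if (!inherits(scheme, "blocking_scheme"))
    scheme <- blocking_scheme(paste(scheme, collapse = "-"), scheme)
  vars <- scheme$variables
  unknown <- setdiff(vars, names(a))
  if (!is.null(b)) unknown <- union(unknown, setdiff(vars, names(b)))
  if (length(unknown))
    stop("config error: unknown blocking variable(s): ",
         paste(unknown, collapse = ", "))

  key_a <- block_key(a, vars)
  if (is.null(b)) {
    idx <- which(!is.na(key_a))
    grp <- split(idx, key_a[idx])
    grp <- grp[lengths(grp) >= 2L]
    oversize <- lengths(grp) > cap
    if (any(oversize))
      warning(sprintf("scheme %s: %d block(s) exceed the size cap of %d records",
                      scheme$name, sum(oversize), cap))
    ij <- if (length(grp)) do.call(rbind, lapply(grp, pairs_in_group))
          else matrix(integer(0), 0, 2)
    out <- data.frame(record_a = a$record_id[ij[, 1]],
                      record_b = a$record_id[ij[, 2]],
                      stringsAsFactors = FALSE)
    mode <- "dedup"
  } else {
    key_b <- block_key(b, vars)
    ia <- which(!is.na(key_a)); ib <- which(!is.na(key_b))
    ga <- split(ia, key_a[ia]); gb <- split(ib, key_b[ib])
    common <- intersect(names(ga), names(gb))
    oversize <- vapply(common, function(k) length(ga[[k]]) > cap || length(gb[[k]]) > cap,
                       logical(1))
    if (any(oversize))
      warning(sprintf("scheme %s: %d block(s) exceed the size cap of %d records",
                      scheme$name, sum(oversize), cap))
    ij <- if (length(common))
      do.call(rbind, lapply(common, function(k)
        as.matrix(expand.grid(ga[[k]], gb[[k]], KEEP.OUT.ATTRS = FALSE))))
    else matrix(integer(0), 0, 2)
    out <- data.frame(record_a = a$record_id[ij[, 1]],
                      record_b = b$record_id[ij[, 2]],
                      stringsAsFactors = FALSE)
    mode <- "linkage"
  }
  rownames(out) <- NULL
  out$scheme <- rep(scheme$name, nrow(out))
  attr(out, "mode") <- mode
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Union candidate pair sets across blocking schemes
#'
#' Deduplicates pairs produced by several schemes; each surviving pair
#' remembers every scheme that produced it (comma-separated in `scheme`).
#'
#' @param sets List of `pair_set` data frames sharing a mode.
#' @return A `pair_set` data frame with unique pairs.
#' @export
union_pairsets <- function(sets) {
  sets <- Filter(Negate(is.null), sets)
  if (!length(sets)) stop("no pair sets to union")
  modes <- unique(vapply(sets, function(s) attr(s, "mode") %||% "dedup", ""))
  if (length(modes) != 1L)
    stop("usage error: cannot union pair sets with mixed modes: ",
         paste(modes, collapse = ", "))
  all <- do.call(rbind, lapply(sets, as.data.frame))
  k <- paste(all$record_a, all$record_b, sep = "\x1f")
  sch <- tapply(all$scheme, k, function(s) paste(sort(unique(s)), collapse = ","))
  first <- !duplicated(k)
  out <- all[first, c("record_a", "record_b"), drop = FALSE]
  out$scheme <- as.character(sch[k[first]])
  rownames(out) <- NULL
  attr(out, "mode") <- modes
  class(out) <- c("pair_set", "data.frame")
  out
}
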