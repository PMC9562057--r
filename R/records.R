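#' Describe one identifier field of a record file
#'
#' A field specification names an identifier column (for example a name part,
#' a birth-date component, SSN, zip code) and fixes how raw cell values are
#' canonicalized before any comparison: which tokens denote a missing value
#' and whether values are case-folded and trimmed. Exact agreement between two
#' records is always judged on the canonical values.
#'
#' @param name Column name in the input CSV.
#' @param normalizer `"casefold_trim"` (lower-case and strip surrounding
#'   whitespace; the default, since exact agreement should not hinge on case
#'   or padding) or `"verbatim"`.
#' @param missing_tokens Character vector of tokens treated as missing,
#'   matched case-insensitively after trimming. The empty string is always a
#'   missing token. Clinical sources frequently code absent values as
#'   `"unknown"`, hence the defaults.
#' @param pad_width Optional integer; purely numeric values are zero-padded to
#'   this width so that, e.g., day-of-birth "7" and "07" agree.
#' @return An object of class `field_spec`.
#' @examples
#' field_spec("zip")
#' field_spec("db", pad_width = 2)
#' @export
field_spec <- function(name, normalizer = c("casefold_trim", "verbatim"),
                       missing_tokens = c("", "NA", "N/A", "UNKNOWN", "UNK"),
                       pad_width = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  normalizer <- match.arg(normalizer)
  missing_tokens <- unique(c("", tolower(trimws(as.character(missing_tokens)))))
  if (!is.null(pad_width)) pad_width <- as.integer(pad_width)
  structure(list(name = name, normalizer = normalizer,
                 missing_tokens = missing_tokens, pad_width = pad_width),
            class = "field_spec")
}

#' Assemble a record schema
#'
#' A schema is a named list of [field_spec()] objects, one per identifier
#' field. Bare character names are promoted to default field specs.
#'
#' @param ... `field_spec` objects and/or character field names.
#' @return Named list of `field_spec` objects (class `record_schema`).
#' @examples
#' record_schema("fn", "ln", field_spec("db", pad_width = 2))
#' @export
record_schema <- function(...) {
  specs <- lapply(list(...), function(f) {
    if (inherits(f, "field_spec")) f
    else if (is.character(f) && length(f) == 1L) field_spec(f)
    else stop("schema entries must be field_spec objects or field names")
  })
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate field name(s) in schema: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(specs) <- nm
  structure(specs, class = "record_schema")
}

#' Canonicalize raw field values
#'
#' Applies the field's normalizer, zero-pads numeric values when requested,
#' and maps missing tokens to `NA`. Normalization is idempotent:
#' `normalize_value(normalize_value(x, s), s)` equals `normalize_value(x, s)`.
#'
#' @param x Character vector of raw values (`NA` allowed).
#' @param spec A [field_spec()].
#' @return Character vector of canonical values with `NA` for missing.
#' @examples
#' normalize_value(c(" Smith ", "SMITH", "", "unknown"), field_spec("ln"))
#' @export
normalize_value <- function(x, spec) {
  stopifnot(inherits(spec, "field_spec"))
  x <- as.character(x)
  canon <- if (spec$normalizer == "casefold_trim") tolower(trimws(x)) else x
  miss <- is.na(x) | tolower(trimws(x)) %in% spec$missing_tokens
  if (!is.null(spec$pad_width)) {
    i <- which(!miss & grepl("^[0-9]+$", canon))
    if (length(i))
      canon[i] <- sprintf(paste0("%0", spec$pad_width, "d"), as.integer(canon[i]))
  }
  canon[miss] <- NA_character_
  canon
}

#' Read a record file
#'
#' Reads a CSV (header row required) and normalizes every schema field via
#' [normalize_value()]. Values matching a field's missing tokens are stored as
#' `NA`. A record-ID column is used when present and synthesized from the row
#' index otherwise; duplicate IDs are an integrity error.
#'
#' @param path Path to a CSV file.
#' @param schema A [record_schema()] (or list of [field_spec()]).
#' @param id_col Name of the record-ID column (default `"record_id"`).
#' @return A data frame of class `fs_records`: column `record_id` (character)
#'   followed by one canonical character column per schema field; attribute
#'   `schema` carries the schema.
#' @seealso [write_records()] for the inverse; the round trip preserves the
#'   record set exactly (missing values as empty cells).
#' @export
read_records <- function(path, schema, id_col = "record_id") {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(0), stringsAsFactors = FALSE)
  as_records(df, schema, id_col = id_col)
}

#' Normalize an in-memory data frame into a record set
#'
#' @param df Data frame with one row per record.
#' @inheritParams read_records
#' @return An `fs_records` data frame; see [read_records()].
#' @export
as_records <- function(df, schema, id_col = "record_id") {
  if (!inherits(schema, "record_schema")) schema <- do.call(record_schema, as.list(schema))
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols))
    stop("schema error: column(s) absent from input: ",
         paste(missing_cols, collapse = ", "))
  ids <- if (id_col %in% names(df)) as.character(df[[id_col]])
         else as.character(seq_len(nrow(df)))
  if (anyDuplicated(ids))
    stop("integrity error: duplicate record_id value(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- data.frame(record_id = ids, stringsAsFactors = FALSE)
  for (f in names(schema)) out[[f]] <- normalize_value(df[[f]], schema[[f]])
  attr(out, "schema") <- schema
  class(out) <- c("fs_records", "data.frame")
  out
}

#' Write a record set to CSV
#'
#' Missing values are written as empty cells, so re-reading with the same
#' schema reproduces the record set.
#'
#' @param x An `fs_records` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.fs_records <- function(x, ...) {
  cat(sprintf("Record set: %d records, %d identifier fields\n",
              nrow(x), ncol(x) - 1L))
  cat("Fields:", paste(setdiff(names(x), "record_id"), collapse = ", "), "\n")
  invisible(x)
}
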