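# End-to-end orchestration: block -> compare -> select fields -> fit ->
# classify -> union -> evaluate.

.norm_schemes <- function(schemes) {
  if (inherits(schemes, "blocking_scheme")) schemes <- list(schemes)
  out <- lapply(seq_along(schemes), function(i) {
    s <- schemes[[i]]
    if (inherits(s, "blocking_scheme")) s
    else blocking_scheme(names(schemes)[i] %||% paste(s, collapse = "-"), s)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

.norm_em_control <- function(em_control) {
  utils::modifyList(list(tol = 1e-8, max_iter = 1000L, n_starts = 1L), em_control)
}

# Shared blocking + comparison artifacts, computed once per scheme so a
# factorial run does not repeat them per cell.
prepare_blocks <- function(records, records_b = NULL, schemes,
                           candidates = NULL, cap = Inf) {
  schemes <- .norm_schemes(schemes)
  candidates <- candidates %||% setdiff(names(records), "record_id")
  lapply(schemes, function(sch) {
    pairs <- block_pairs(records, records_b, sch, cap = cap)
    amat <- if (nrow(pairs) > 0)
      build_agreement_matrix(pairs, records, records_b, candidates)
    else NULL
    list(scheme = sch, pairs = pairs, amat = amat)
  })
}

.run_cell <- function(blocks, mode, treatment, field_mode, expert_fields,
                      em_control, seed) {
  em <- .norm_em_control(em_control)
  sel_mode <- if (field_mode == "expert") "expert" else "data_driven"
  block_out <- list()
  classified <- list()
  for (nm in names(blocks)) {
    blk <- blocks[[nm]]
    if (is.null(blk$amat) || nrow(blk$amat) < 2L) {
      block_out[[nm]] <- list(scheme = nm, n_pairs = nrow(blk$pairs),
                              error = "too few candidate pairs")
      next
    }
    ef <- if (is.list(expert_fields)) expert_fields[[nm]] else expert_fields
    res <- tryCatch({
      sel <- select_fields(blk$amat, blocking_vars = blk$scheme$variables,
                           mode = sel_mode, expert_fields = ef,
                           treatment = treatment, tol = em$tol,
                           max_iter = em$max_iter, n_starts = em$n_starts,
                           seed = seed)
      xf <- blk$amat[, sel$fields, drop = FALSE]
      if (treatment == "mad") xf <- zero_fill(xf)
      fit <- sel$fit %||% fs_fit(xf, treatment = treatment, tol = em$tol,
                                 max_iter = em$max_iter,
                                 n_starts = em$n_starts, seed = seed)
      cls <- classify_block(xf, fit, pairs = blk$pairs)
      list(sel = sel, fit = fit, cls = cls)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      block_out[[nm]] <- list(scheme = nm, n_pairs = nrow(blk$pairs),
                              error = conditionMessage(res))
      next
    }
    classified[[nm]] <- res$cls
    block_out[[nm]] <- list(
      scheme = nm,
      n_pairs = nrow(blk$pairs),
      fields = res$sel$fields,
      dropped = res$sel$dropped,
      rho = res$fit$params$rho,
      m = res$fit$params$m,
      u = res$fit$params$u,
      loglik = res$fit$loglik,
      n_iter = res$fit$n_iter,
      converged = res$fit$converged,
      threshold = attr(res$cls, "rule")$threshold,
      n_matches = sum(res$cls$match))
  }
  matches <- if (length(classified)) union_matches(classified)
             else data.frame(record_a = character(0), record_b = character(0),
                             blocks = character(0))
  list(blocks = block_out, matches = matches)
}

#' Run the full record-linkage pipeline
#'
#' Blocks the input record set(s) under every scheme, builds agreement
#' matrices, selects matching fields per block (expert list or data-driven),
#' fits the FS model per block under the chosen missing-data treatment,
#' classifies each block's pairs with its block-specific prevalence
#' threshold, unions the per-block matches, and (when a gold standard is
#' supplied) evaluates the result with bootstrap confidence intervals. Fully
#' deterministic given `seed`.
#'
#' @param records,records_b Record set(s) from [read_records()] /
#'   [as_records()]; `records_b = NULL` means deduplication.
#' @param schemes Named list of blocking schemes (character vectors of
#'   variables, or [blocking_scheme()] objects).
#' @param candidates Candidate matching fields (default: every field).
#' @param treatment `"mar"` or `"mad"`.
#' @param field_mode `"auto"` (data-driven selection) or `"expert"`.
#' @param expert_fields Expert field list: character vector, or named list
#'   keyed by scheme name.
#' @param gold Optional gold-standard data frame (`record_a`, `record_b`,
#'   `label`) or CSV path.
#' @param bootstrap Bootstrap replicates for evaluation CIs (default 999).
#' @param seed Integer seed driving every random element.
#' @param em_control List overriding EM settings: `tol`, `max_iter`,
#'   `n_starts`.
#' @param cap Per-block size cap passed to [block_pairs()].
#' @param outdir Optional directory; when given, the JSON report and the
#'   matched-pairs CSV are written there.
#' @return An object of class `fs_run`: per-block summaries, the matched
#'   pairs, evaluation metrics (if `gold` given), and a config echo.
#' @export
run_linkage <- function(records, records_b = NULL, schemes, candidates = NULL,
                        treatment = c("mar", "mad"),
                        field_mode = c("auto", "expert"),
                        expert_fields = NULL, gold = NULL, bootstrap = 999L,
                        seed = 1L, em_control = list(), cap = Inf,
                        outdir = NULL) {
  treatment <- match.arg(treatment)
  field_mode <- match.arg(field_mode)
  t0 <- proc.time()[["elapsed"]]
  blocks <- prepare_blocks(records, records_b, schemes, candidates, cap = cap)
  report <- .finish_run(blocks, records_b, treatment, field_mode,
                        expert_fields, gold, bootstrap, seed, em_control, t0)
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

.finish_run <- function(blocks, records_b, treatment, field_mode,
                        expert_fields, gold, bootstrap, seed, em_control, t0) {
  mode <- if (is.null(records_b)) "dedup" else "linkage"
  cell <- .run_cell(blocks, mode, treatment, field_mode, expert_fields,
                    em_control, seed)
  evaluation <- NULL
  if (!is.null(gold)) {
    if (is.character(gold)) gold <- read_gold_standard(gold)
    counts <- confusion_counts(cell$matches, gold, unordered = mode == "dedup")
    evaluation <- bootstrap_metrics(counts, B = bootstrap, seed = seed)
  }
  structure(list(
    mode = mode, treatment = treatment, field_mode = field_mode,
    blocks = cell$blocks, matches = cell$matches,
    n_matches = nrow(cell$matches), evaluation = evaluation,
    config = list(treatment = treatment, field_mode = field_mode,
                  bootstrap = bootstrap, seed = seed,
                  em_control = .norm_em_control(em_control)),
    version = as.character(utils::packageVersion("fslink")),
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "fs_run")
}

#' Run the 2-by-2 factorial design
#'
#' Evaluates every combination of missing-data treatment and field-selection
#' mode on the same inputs. Blocking and field comparison are performed once
#' and shared across cells, so all cells classify the identical pair
#' universe.
#'
#' @inheritParams run_linkage
#' @param treatments Treatments to cross (default `c("mad", "mar")`).
#' @param field_modes Field modes to cross (default `c("expert", "auto")`).
#' @return Named list of `fs_run` objects, keys like `"mar.auto"`.
#' @export
run_factorial <- function(records, records_b = NULL, schemes,
                          candidates = NULL,
                          treatments = c("mad", "mar"),
                          field_modes = c("expert", "auto"),
                          expert_fields = NULL, gold = NULL, bootstrap = 999L,
                          seed = 1L, em_control = list(), cap = Inf) {
  stopifnot(length(treatments) >= 1, length(field_modes) >= 1)
  t0 <- proc.time()[["elapsed"]]
  blocks <- prepare_blocks(records, records_b, schemes, candidates, cap = cap)
  if (is.character(gold)) gold <- read_gold_standard(gold)
  out <- list()
  for (tr in treatments) for (fm in field_modes) {
    out[[paste(tr, fm, sep = ".")]] <-
      .finish_run(blocks, records_b, tr, fm, expert_fields, gold, bootstrap,
                  seed, em_control, t0)
  }
  out
}

#' @export
print.fs_run <- function(x, ...) {
  cat(sprintf("FS linkage run (%s, %s treatment, %s fields)\n",
              x$mode, toupper(x$treatment), x$field_mode))
  for (b in x$blocks) {
    if (!is.null(b$error))
      cat(sprintf("  block %-16s %8d pairs  [skipped: %s]\n",
                  b$scheme, b$n_pairs, b$error))
    else
      cat(sprintf("  block %-16s %8d pairs  rho=%.4f  %d matches (%s)\n",
                  b$scheme, b$n_pairs, b$rho, b$n_matches,
                  paste(b$fields, collapse = ",")))
  }
  cat(sprintf("  union of matches: %d pairs\n", x$n_matches))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}

#' Write a machine-readable run report
#'
#' Writes `report.json` (full precision; rounding is presentation-only) and
#' `matches.csv` to `outdir`.
#'
#' @param report An `fs_run`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    mode = report$mode, treatment = report$treatment,
    field_mode = report$field_mode,
    blocks = lapply(report$blocks, function(b) {
      b$dropped <- if (!is.null(b$dropped) && nrow(b$dropped)) b$dropped else NULL
      b
    }),
    n_matches = report$n_matches,
    evaluation = if (!is.null(report$evaluation))
      as.data.frame(report$evaluation) else NULL,
    config = report$config, version = report$version,
    elapsed = report$elapsed)
  jsonlite::write_json(payload, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.csv(report$matches, file.path(outdir, "matches.csv"),
                   row.names = FALSE)
  invisible(outdir)
}

#' Read a run configuration file
#'
#' YAML (or JSON) configuration describing one pipeline run; see the package
#' vignette for the schema. Returns the parsed list with a `record_schema`
#' built from the `schema` section.
#'
#' @param path Path to a YAML/JSON config file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$schema)) {
    specs <- lapply(cfg$schema, function(s) {
      if (is.character(s)) return(field_spec(s))
      field_spec(s$name,
                 normalizer = s$normalizer %||% "casefold_trim",
                 missing_tokens = s$missing_tokens %||%
                   c("", "NA", "N/A", "UNKNOWN", "UNK"),
                 pad_width = s$pad_width)
    })
    cfg$schema <- do.call(record_schema, specs)
  }
  cfg
}

#' Execute a pipeline run from a configuration list
#'
#' Convenience wrapper used by the command-line entry point: reads the
#' record file(s) and optional gold standard named in the config and calls
#' [run_linkage()] or, when `factorial: true`, [run_factorial()].
#'
#' @param cfg List from [read_run_config()].
#' @return An `fs_run`, or a named list of them for factorial runs.
#' @export
run_from_config <- function(cfg) {
  stopifnot(!is.null(cfg$records), !is.null(cfg$schema), !is.null(cfg$schemes))
  a <- read_records(cfg$records, cfg$schema, id_col = cfg$id_col %||% "record_id")
  b <- if (!is.null(cfg$records_b))
    read_records(cfg$records_b, cfg$schema, id_col = cfg$id_col %||% "record_id")
  args <- list(records = a, records_b = b, schemes = cfg$schemes,
               candidates = cfg$candidates,
               expert_fields = cfg$expert_fields, gold = cfg$gold,
               bootstrap = cfg$bootstrap %||% 999L, seed = cfg$seed %||% 1L,
               em_control = cfg$em_control %||% list(),
               cap = cfg$cap %||% Inf)
  if (isTRUE(cfg$factorial)) {
    args$treatments <- cfg$treatments %||% c("mad", "mar")
    args$field_modes <- cfg$field_modes %||% c("expert", "auto")
    do.call(run_factorial, args)
  } else {
    args$treatment <- cfg$treatment %||% "mar"
    args$field_mode <- cfg$field_mode %||% "auto"
    args$outdir <- cfg$outdir
    do.call(run_linkage, args)
  }
}
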