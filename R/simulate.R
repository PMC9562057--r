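#' Missingness mechanisms for the agreement-vector generator
#'
#' Constructors describing how comparison outcomes are masked after the
#' complete agreement data are drawn:
#' * `miss_none()` — no masking.
#' * `miss_mcar(rate)` — missing completely at random: every cell is masked
#'   with the same probability, independent of everything.
#' * `miss_mar_class(rate_match, rate_nonmatch)` — missing at random
#'   conditional on the true match status: the masking rate depends only on
#'   the pair's latent class. Estimable by the full-information MAR
#'   likelihood.
#' * `miss_mnar_value(rate_agree, rate_disagree)` — missing not at random:
#'   the masking rate depends on the (to-be-hidden) comparison outcome
#'   itself. Included as a stressor; no estimator in this package targets it.
#'
#' @param rate,rate_match,rate_nonmatch,rate_agree,rate_disagree Masking
#'   probabilities in \[0, 1\].
#' @return An object of class `fs_missingness`.
#' @name missingness
NULL

#' @rdname missingness
#' @export
miss_none <- function() structure(list(type = "none"), class = "fs_missingness")

#' @rdname missingness
#' @export
miss_mcar <- function(rate) {
  stopifnot(rate >= 0, rate <= 1)
  structure(list(type = "mcar", rate = rate), class = "fs_missingness")
}

#' @rdname missingness
#' @export
miss_mar_class <- function(rate_match, rate_nonmatch) {
  stopifnot(rate_match >= 0, rate_match <= 1, rate_nonmatch >= 0, rate_nonmatch <= 1)
  structure(list(type = "mar_class", rate_match = rate_match,
                 rate_nonmatch = rate_nonmatch), class = "fs_missingness")
}

#' @rdname missingness
#' @export
miss_mnar_value <- function(rate_agree, rate_disagree) {
  stopifnot(rate_agree >= 0, rate_agree <= 1, rate_disagree >= 0, rate_disagree <= 1)
  structure(list(type = "mnar_value", rate_agree = rate_agree,
                 rate_disagree = rate_disagree), class = "fs_missingness")
}

.mask_rate <- function(mech, delta, y_col) {
  switch(mech$type,
         none = rep(0, length(delta)),
         mcar = rep(mech$rate, length(delta)),
         mar_class = ifelse(delta == 1, mech$rate_match, mech$rate_nonmatch),
         mnar_value = ifelse(y_col == 1, mech$rate_agree, mech$rate_disagree),
         stop("unknown missingness mechanism: ", mech$type))
}

#' Simulate agreement vectors from the generative model
#'
#' Draws data exactly as the latent-class model assumes: latent match status
#' `delta_i ~ Bernoulli(rho)`, then conditionally independent field
#' agreements `Y_ik ~ Bernoulli(m_k)` for matches and `Bernoulli(u_k)` for
#' nonmatches, then per-field masking by the chosen missingness mechanism.
#' The root seed spawns an independent sub-seed per stochastic component
#' (labels, agreements, masking), so outputs are byte-reproducible and
#' changing one mechanism does not shift the other draws.
#'
#' @param n_pairs Number of record pairs.
#' @param rho True match prevalence in (0, 1).
#' @param m,u Length-K true agreement probability vectors.
#' @param missingness One [missingness] mechanism applied to every field, or
#'   a list of K mechanisms (one per field).
#' @param seed Optional integer root seed.
#' @return An object of class `fs_sim`: `matrix` (observed, with `NA`),
#'   `complete` (pre-masking), `truth` (the latent 0/1 labels), and the
#'   generating `params`.
#' @examples
#' sim <- simulate_agreement(1000, 0.3, rep(0.9, 5), rep(0.1, 5),
#'                           missingness = miss_mcar(0.2), seed = 7)
#' mean(sim$truth)
#' @export
simulate_agreement <- function(n_pairs, rho, m, u, missingness = miss_none(),
                               seed = NULL) {
  K <- length(m)
  stopifnot(n_pairs >= 1, length(u) == K, rho > 0, rho < 1,
            all(m > 0 & m < 1), all(u > 0 & u < 1))
  mechs <- if (inherits(missingness, "fs_missingness"))
    rep(list(missingness), K)
  else {
    stopifnot(is.list(missingness), length(missingness) == K)
    missingness
  }
  if (!is.null(seed)) set.seed(seed)
  streams <- spawn_seeds(3L)

  set.seed(streams[1])
  delta <- stats::rbinom(n_pairs, 1L, rho)

  set.seed(streams[2])
  prob <- outer(delta, m) + outer(1 - delta, u)
  y <- matrix(stats::rbinom(n_pairs * K, 1L, prob), n_pairs, K)

  set.seed(streams[3])
  x <- y
  for (k in seq_len(K)) {
    r <- .mask_rate(mechs[[k]], delta, y[, k])
    hide <- stats::rbinom(n_pairs, 1L, r) == 1L
    x[hide, k] <- NA_integer_
  }
  colnames(x) <- colnames(y) <- sprintf("f%d", seq_len(K))
  structure(list(matrix = x, complete = y, truth = delta,
                 params = fs_params(rho, m, u), missingness = mechs,
                 seed = seed),
            class = "fs_sim")
}

#' Default synthetic identifier value pools
#'
#' Deterministic pools of synthetic field values sized to mimic the
#' discriminating power of typical patient identifiers: near-unique SSN and
#' telephone, moderately discriminating names and zip, weak sex and
#' birth-date components.
#'
#' @return Named list of character pools.
#' @export
default_field_pools <- function() {
  list(fn  = sprintf("fn%03d", 1:250),
       ln  = sprintf("ln%03d", 1:400),
       mi  = letters,
       sex = c("f", "m"),
       db  = sprintf("%02d", 1:28),
       mb  = sprintf("%02d", 1:12),
       yb  = as.character(1940:2009),
       zip = sprintf("%05d", seq(10000L, 98900L, by = 250L)),
       ssn = sprintf("%09.0f", seq(100000007, 999999999, length.out = 50000L)),
       tel = sprintf("%010.0f", seq(3170000000, 3179999999, length.out = 50000L)))
}

#' Simulate record files with planted duplicates
#'
#' End-to-end fixture generator: entities draw each field uniformly from its
#' value pool; a fraction of entities receives a duplicate record in which
#' each field is independently perturbed (swapped for a random pool value)
#' with its error rate; finally each cell of every record is masked with its
#' missing rate. Ground-truth match pairs are emitted alongside. In `dedup`
#' mode originals and duplicates are shuffled into one file; in `linkage`
#' mode file A holds the originals and file B the duplicates plus an equal
#' number of novel entities.
#'
#' @param n_entities Number of distinct entities.
#' @param duplication_rate Fraction of entities that get a duplicate record.
#' @param pools Named list of value pools (default [default_field_pools()]).
#' @param error_rate Per-field perturbation probability for duplicates;
#'   scalar or named vector.
#' @param missing_rate Per-field masking probability for every record;
#'   scalar or named vector.
#' @param mode `"dedup"` or `"linkage"`.
#' @param seed Optional integer root seed.
#' @return An object of class `fs_simrecords`: `records` (an `fs_records`
#'   data frame), `records_b` (`NULL` in dedup mode), `truth`
#'   (`record_a`, `record_b` of true match pairs), `schema`, `mode`.
#' @export
simulate_records <- function(n_entities, duplication_rate = 0.2,
                             pools = default_field_pools(),
                             error_rate = 0.05, missing_rate = 0.1,
                             mode = c("dedup", "linkage"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_entities >= 1, duplication_rate >= 0, duplication_rate <= 1,
            length(pools) >= 1, all(lengths(pools) > 0))
  fields <- names(pools)
  expand_rate <- function(r) {
    if (length(r) == 1L) stats::setNames(rep(r, length(fields)), fields)
    else { stopifnot(all(fields %in% names(r))); r[fields] }
  }
  err <- expand_rate(error_rate)
  mis <- expand_rate(missing_rate)

  if (!is.null(seed)) set.seed(seed)
  streams <- spawn_seeds(4L)

  set.seed(streams[1])
  ent <- as.data.frame(lapply(pools, function(p)
    sample(p, n_entities, replace = TRUE)), stringsAsFactors = FALSE)
  n_dup <- round(n_entities * duplication_rate)
  dup_of <- if (n_dup > 0) sort(sample.int(n_entities, n_dup)) else integer(0)

  set.seed(streams[2])
  dup <- ent[dup_of, , drop = FALSE]
  for (f in fields) {
    flip <- stats::runif(n_dup) < err[f]
    if (any(flip)) dup[[f]][flip] <- sample(pools[[f]], sum(flip), replace = TRUE)
  }

  novel <- NULL
  if (mode == "linkage") {
    set.seed(streams[4])
    novel <- as.data.frame(lapply(pools, function(p)
      sample(p, n_dup, replace = TRUE)), stringsAsFactors = FALSE)
  }

  mask_cells <- function(df) {
    for (f in fields) {
      hide <- stats::runif(nrow(df)) < mis[f]
      df[[f]][hide] <- NA_character_
    }
    df
  }

  schema <- do.call(record_schema,
                    lapply(fields, function(f) field_spec(f, normalizer = "verbatim")))

  set.seed(streams[3])
  if (mode == "dedup") {
    ids <- sprintf("r%06d", seq_len(n_entities + n_dup))
    all <- rbind(ent, dup)
    all <- mask_cells(all)
    all$record_id <- ids
    truth <- data.frame(record_a = ids[seq_len(n_entities)][dup_of],
                        record_b = ids[n_entities + seq_len(n_dup)],
                        stringsAsFactors = FALSE)
    all <- all[sample.int(nrow(all)), , drop = FALSE]
    recs <- as_records(all, schema)
    out <- list(records = recs, records_b = NULL, truth = truth)
  } else {
    ids_a <- sprintf("a%06d", seq_len(n_entities))
    ids_b <- sprintf("b%06d", seq_len(n_dup + nrow(novel)))
    fa <- mask_cells(ent); fa$record_id <- ids_a
    fb <- rbind(dup, novel)
    fb <- mask_cells(fb)
    fb$record_id <- ids_b
    truth <- data.frame(record_a = ids_a[dup_of],
                        record_b = ids_b[seq_len(n_dup)],
                        stringsAsFactors = FALSE)
    fb <- fb[sample.int(nrow(fb)), , drop = FALSE]
    out <- list(records = as_records(fa, schema),
                records_b = as_records(fb, schema), truth = truth)
  }
  out$schema <- schema
  out$mode <- mode
  out$config <- list(n_entities = n_entities, duplication_rate = duplication_rate,
                     error_rate = err, missing_rate = mis, seed = seed)
  class(out) <- "fs_simrecords"
  out
}
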