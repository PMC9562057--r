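# Small fixture builders used across test files.

tiny_records <- function(df, fields = setdiff(names(df), "record_id")) {
  as_records(df, do.call(record_schema, as.list(fields)))
}

# F1 of a pipeline run against known truth pairs (unordered keys).
run_f1 <- function(run, truth) {
  pk <- paste(pmin(run$matches$record_a, run$matches$record_b),
              pmax(run$matches$record_a, run$matches$record_b))
  tk <- paste(pmin(truth$record_a, truth$record_b),
              pmax(truth$record_a, truth$record_b))
  tp <- sum(pk %in% tk)
  2 * tp / (2 * tp + (length(pk) - tp) + (length(tk) - tp))
}

# Random ternary agreement matrix for property tests.
random_matrix <- function(n, K, miss = 0.2) {
  x <- matrix(rbinom(n * K, 1L, runif(K, 0.2, 0.8)[rep(1:K, each = n)]), n, K)
  if (miss > 0) x[matrix(runif(n * K) < miss, n, K)] <- NA_integer_
  colnames(x) <- sprintf("f%d", 1:K)
  x
}

random_params <- function(K) {
  fs_params(runif(1, 0.1, 0.9), runif(K, 0.55, 0.95), runif(K, 0.05, 0.45))
}
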