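test_that("the vector-tier generator follows its generative model", {
  sim <- simulate_agreement(1000, 0.4, rep(0.8, 3), rep(0.2, 3), seed = 61)
  expect_identical(sim$matrix, sim$complete)        # no masking by default
  expect_false(anyNA(sim$matrix))

  # empirical prevalence within 3 SE of rho
  big <- simulate_agreement(100000, 0.4, rep(0.8, 2), rep(0.2, 2), seed = 62)
  se <- sqrt(0.4 * 0.6 / 100000)
  expect_lt(abs(mean(big$truth) - 0.4), 3 * se)

  # observed cells always equal the complete data where non-missing
  mc <- simulate_agreement(5000, 0.3, rep(0.9, 3), rep(0.1, 3),
                           miss_mcar(0.3), seed = 63)
  obs <- !is.na(mc$matrix)
  expect_identical(mc$matrix[obs], mc$complete[obs])
})

test_that("MCAR masking hits its rate independently of match status", {
  sim <- simulate_agreement(50000, 0.3, rep(0.9, 3), rep(0.1, 3),
                            miss_mcar(0.3), seed = 64)
  for (k in 1:3) {
    frac <- mean(is.na(sim$matrix[, k]))
    expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 50000))
    p <- chisq.test(table(missing = is.na(sim$matrix[, k]),
                          delta = sim$truth))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("class- and value-dependent mechanisms condition on the right thing", {
  sim <- simulate_agreement(40000, 0.4, rep(0.8, 2), rep(0.2, 2),
                            miss_mar_class(0.5, 0.1), seed = 65)
  miss_m <- mean(is.na(sim$matrix[sim$truth == 1, 1]))
  miss_u <- mean(is.na(sim$matrix[sim$truth == 0, 1]))
  expect_lt(abs(miss_m - 0.5), 0.02)
  expect_lt(abs(miss_u - 0.1), 0.02)

  sim2 <- simulate_agreement(40000, 0.4, rep(0.8, 2), rep(0.2, 2),
                             miss_mnar_value(0.5, 0.1), seed = 66)
  miss_agree <- mean(is.na(sim2$matrix[sim2$complete[, 1] == 1, 1]))
  miss_dis <- mean(is.na(sim2$matrix[sim2$complete[, 1] == 0, 1]))
  expect_lt(abs(miss_agree - 0.5), 0.02)
  expect_lt(abs(miss_dis - 0.1), 0.02)
})

test_that("complete data are conditionally independent within class", {
  sim <- simulate_agreement(100000, 0.5, rep(0.7, 4), rep(0.3, 4), seed = 67)
  for (cl in 0:1) {
    y <- sim$complete[sim$truth == cl, ]
    cors <- cor(y)
    expect_lt(max(abs(cors[upper.tri(cors)])), 0.02)
  }
})

test_that("generation is byte-identical under a repeated seed", {
  a <- simulate_agreement(500, 0.3, rep(0.9, 3), rep(0.1, 3),
                          miss_mar_class(0.4, 0.1), seed = 68)
  b <- simulate_agreement(500, 0.3, rep(0.9, 3), rep(0.1, 3),
                          miss_mar_class(0.4, 0.1), seed = 68)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  r1 <- simulate_records(200, seed = 69)
  r2 <- simulate_records(200, seed = 69)
  expect_identical(as.data.frame(r1$records), as.data.frame(r2$records))
  expect_identical(r1$truth, r2$truth)
})

test_that("MAR fitting is biased under value-dependent (MNAR) masking", {
  # same draw sizes; the full-information likelihood is consistent under
  # MCAR but not when missingness depends on the hidden outcome itself
  mcar <- simulate_agreement(30000, 0.3, rep(0.9, 4), rep(0.1, 4),
                             miss_mcar(0.3), seed = 70)
  mnar <- simulate_agreement(30000, 0.3, rep(0.9, 4), rep(0.1, 4),
                             miss_mnar_value(0.5, 0.1), seed = 70)
  bias <- function(s) {
    f <- fs_fit(s$matrix, "mar")$params
    max(abs(f$rho - 0.3), abs(f$m - 0.9), abs(f$u - 0.1))
  }
  expect_lt(bias(mcar), 0.02)
  expect_gt(bias(mnar), bias(mcar) + 0.02)
})

test_that("record-tier generator plants duplicates as configured", {
  clean <- simulate_records(300, duplication_rate = 0.2, error_rate = 0,
                            missing_rate = 0, seed = 71)
  amat <- build_agreement_matrix(clean$truth, clean$records,
                                 fields = names(default_field_pools()))
  expect_true(all(amat == 1L))            # error-free duplicates agree everywhere

  none <- simulate_records(300, duplication_rate = 0, seed = 72)
  expect_equal(nrow(none$truth), 0L)

  lk <- simulate_records(300, duplication_rate = 0.2, mode = "linkage", seed = 73)
  expect_false(is.null(lk$records_b))
  expect_true(all(lk$truth$record_a %in% lk$records$record_id))
  expect_true(all(lk$truth$record_b %in% lk$records_b$record_id))
})

test_that("blocking, fitting and classifying recover planted duplicates", {
  sim <- simulate_records(5000, duplication_rate = 0.2, error_rate = 0.05,
                          missing_rate = 0.15, seed = 1)
  run <- run_linkage(sim$records,
                     schemes = list(SSN = "ssn", "LN-FN" = c("ln", "fn"),
                                    "DB-MB-YB" = c("db", "mb", "yb"),
                                    ZIP = "zip", TEL = "tel"),
                     treatment = "mar", field_mode = "auto", seed = 1)
  expect_gte(run_f1(run, sim$truth), 0.95)
})
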