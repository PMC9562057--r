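test_that("class densities factorize over observed fields", {
  p <- fs_params(0.5, c(0.9, 0.8), c(0.1, 0.2))
  expect_equal(class_density(c(1), fs_params(0.5, 0.9, 0.1), "match"), 0.9)
  expect_equal(class_density(c(1, NA), p, "match", "mar"), 0.9)
  expect_error(class_density(c(1, NA), p, "match", "mad"), "MAD")

  set.seed(11)
  for (r in 1:20) {
    y <- sample(c(0L, 1L, NA), 3, replace = TRUE)
    pp <- random_params(3)
    expect_equal(class_density(y, pp, "match"),
                 oracle_class_density(y, pp$m), tolerance = 1e-12)
    expect_equal(class_density(y, pp, "nonmatch"),
                 oracle_class_density(y, pp$u), tolerance = 1e-12)
  }
})

test_that("marginal and complete-data log-likelihoods match hand expansion", {
  p1 <- fs_params(0.5, 0.5, 0.5)
  expect_equal(marginal_loglik(matrix(1L, 1, 1), p1), log(0.5))
  expect_error(marginal_loglik(matrix(integer(0), 0, 1), p1), "empty")

  # 2x2 hand-expanded mixture
  x <- matrix(c(1L, 0L, NA, 1L), 2, 2, byrow = TRUE)
  p <- fs_params(0.3, c(0.9, 0.8), c(0.1, 0.2))
  hand <- log(0.3 * (0.9 * (1 - 0.8)) + 0.7 * (0.1 * (1 - 0.2))) +
          log(0.3 * 0.8 + 0.7 * 0.2)
  expect_equal(marginal_loglik(x, p), hand, tolerance = 1e-12)

  expect_equal(complete_data_loglik(matrix(1L, 1, 1), 1,
                                    fs_params(0.3, 0.9, 0.1)),
               log(0.3) + log(0.9), tolerance = 1e-12)
  expect_error(complete_data_loglik(x, c(1, 2), p), "labels")

  set.seed(12)
  for (r in 1:10) {
    xr <- random_matrix(15, 3)
    pr <- random_params(3)
    dr <- rbinom(15, 1, 0.5)
    expect_equal(marginal_loglik(xr, pr),
                 oracle_marginal_loglik(xr, pr$rho, pr$m, pr$u),
                 tolerance = 1e-10)
    expect_equal(complete_data_loglik(xr, dr, pr),
                 oracle_complete_loglik(xr, dr, pr$rho, pr$m, pr$u),
                 tolerance = 1e-10)
  }
})

test_that("with known labels the prevalence MLE is the label mean", {
  set.seed(13)
  x <- random_matrix(40, 2, miss = 0)
  delta <- rbinom(40, 1, 0.4)
  m <- c(0.8, 0.7); u <- c(0.2, 0.3)
  f <- function(r) complete_data_loglik(x, delta, fs_params(r, m, u))
  opt <- optimize(f, c(0.001, 0.999), maximum = TRUE)
  expect_equal(opt$maximum, mean(delta), tolerance = 1e-4)
})

test_that("posterior match probability follows Bayes rule", {
  # uninformative fields return the prior
  p_flat <- fs_params(0.37, c(0.5, 0.5), c(0.5, 0.5))
  set.seed(14)
  for (y in list(c(1L, 1L), c(0L, 1L), c(NA, 0L)))
    expect_equal(posterior_match_prob(y, p_flat), 0.37, tolerance = 1e-12)
  # all fields missing: empty evidence returns the prior under MAR
  p <- fs_params(0.25, c(0.9, 0.8), c(0.1, 0.2))
  expect_equal(posterior_match_prob(c(NA, NA), p, "mar"), 0.25)
  # fixed K = 2 case against an enumerated Bayes computation
  y <- c(1L, 0L)
  num <- 0.25 * 0.9 * (1 - 0.8)
  den <- num + 0.75 * 0.1 * (1 - 0.2)
  expect_equal(posterior_match_prob(y, p), num / den, tolerance = 1e-12)
})

test_that("EM ascends the likelihood and lands on its fixed point", {
  set.seed(15)
  for (r in 1:15) {
    x <- random_matrix(80, 3, miss = if (r %% 2) 0.25 else 0)
    for (tr in c("mar", "mad")) {
      xt <- if (tr == "mad") zero_fill(x) else x
      fit <- fs_fit(xt, tr, max_iter = 200)
      expect_true(all(diff(fit$loglik_trace) >= -1e-9))
      if (fit$converged)
        expect_equal(mean(fit$posteriors), fit$params$rho, tolerance = 1e-4)
      expect_true(all(fit$posteriors >= 0 & fit$posteriors <= 1))
    }
  }
})

test_that("the mixture likelihood is class-swap symmetric and orientation resolves it", {
  set.seed(16)
  x <- random_matrix(60, 3)
  p <- random_params(3)
  swapped <- fs_params(1 - p$rho, p$u, p$m)
  expect_equal(marginal_loglik(x, p), marginal_loglik(x, swapped),
               tolerance = 1e-10)

  up <- orient_classes(fs_params(0.7, c(0.1, 0.1), c(0.9, 0.9)))
  expect_equal(up$rho, 0.3)
  expect_equal(unname(up$m), c(0.9, 0.9))
  keep <- orient_classes(fs_params(0.3, c(0.9, 0.9), c(0.1, 0.1)))
  expect_equal(unname(keep$m), c(0.9, 0.9))
  for (r in 1:10) {
    pr <- fs_params(runif(1, 0.05, 0.95), runif(3, 0.05, 0.95),
                    runif(3, 0.05, 0.95))
    once <- orient_classes(pr)
    expect_identical(orient_classes(once), once)  # idempotent
  }
})

test_that("MAD and MAR produce identical fits on complete data", {
  sim <- simulate_agreement(3000, 0.35, c(0.9, 0.85, 0.8), c(0.1, 0.15, 0.2),
                            seed = 17)
  f1 <- fs_fit(sim$matrix, "mad")
  f2 <- fs_fit(sim$matrix, "mar")
  expect_identical(f1$loglik_trace, f2$loglik_trace)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$posteriors, f2$posteriors)
})

test_that("MAR estimation is consistent under MCAR missingness", {
  for (n in c(5000, 50000)) {
    sim <- simulate_agreement(n, 0.3, rep(0.9, 5), rep(0.1, 5),
                              miss_mcar(0.2), seed = 18)
    fit <- fs_fit(sim$matrix, "mar")
    tol_rho <- if (n == 5000) 0.03 else 0.01
    tol_m <- if (n == 5000) 0.04 else 0.015
    expect_lt(abs(fit$params$rho - 0.3), tol_rho)
    expect_lt(max(abs(fit$params$m - 0.9)), tol_m)
    expect_lt(max(abs(fit$params$u - 0.1)), tol_m)
  }
})

test_that("EM refuses malformed inputs and flags degenerate fits", {
  expect_error(fs_fit(matrix(1L, 1, 2)), "at least 2 pairs")
  expect_error(fs_fit(matrix(c(1L, NA, 0L, NA), 2, 2), "mad"), "zero_fill")
  x <- matrix(c(1L, 0L, NA, NA), 2, 2)
  expect_error(fs_fit(x, "mar"), "observed in zero pairs")
  expect_error(fs_fit(matrix(c(2L, 0L), 2, 1)), "0, 1 or NA")
})
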