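test_that("match scores are summed log likelihood ratios", {
  expect_equal(match_score(1L, fs_params(0.5, 0.9, 0.1)), log(9))
  p <- fs_params(0.3, c(0.9, 0.8), c(0.1, 0.2))
  expect_equal(match_score(c(NA, NA), p, "mar"), 0)   # empty sum
  expect_equal(match_score(c(1L, 0L), p),
               log(0.9 / 0.1) + log(0.2 / 0.8), tolerance = 1e-12)
  # a field with m = u contributes nothing either way
  p3 <- fs_params(0.3, c(0.9, 0.5), c(0.1, 0.5))
  expect_equal(match_score(c(1L, 1L), p3), match_score(c(1L, 0L), p3))
})

test_that("score equals log posterior odds minus log prior odds", {
  set.seed(21)
  for (r in 1:25) {
    K <- sample(2:5, 1)
    y <- sample(c(0L, 1L, NA), K, replace = TRUE)
    p <- random_params(K)
    sc <- match_score(y, p, "mar")
    post <- posterior_match_prob(y, p, "mar")
    expect_equal(exp(sc), (post / (1 - post)) * ((1 - p$rho) / p$rho),
                 tolerance = 1e-10)
  }
})

test_that("the prevalence-quantile threshold behaves as an order statistic", {
  rule <- threshold_from_prevalence(1:10, 0.3)
  expect_equal(rule$threshold, 7)
  expect_identical(which(1:10 > rule$threshold), 8:10)
  # ties at the threshold are nonmatches
  expect_equal(sum(rep(5, 8) > threshold_from_prevalence(rep(5, 8), 0.4)$threshold), 0)
  expect_error(threshold_from_prevalence(numeric(0), 0.3), "empty")
  # distinct scores: exactly round(n * rho) matches within 1
  set.seed(22)
  for (r in 1:20) {
    n <- sample(50:400, 1); rho <- runif(1, 0.05, 0.6)
    sc <- rnorm(n)
    got <- sum(sc > threshold_from_prevalence(sc, rho)$threshold)
    expect_lte(abs(got - n * rho), 1)
  }
})

test_that("posterior is strictly increasing in score at fixed parameters", {
  set.seed(23)
  sim <- simulate_agreement(500, 0.3, rep(0.85, 4), rep(0.15, 4),
                            miss_mcar(0.2), seed = 3)
  p <- fs_params(0.3, rep(0.85, 4), rep(0.15, 4))
  sc <- match_score(sim$matrix, p)
  post <- posterior_match_prob(sim$matrix, p)
  o <- order(sc)
  expect_true(all(diff(post[o]) >= -1e-12))
  # equal scores carry equal posteriors, so the score-quantile rule is a
  # posterior-quantile rule
  expect_true(all(abs(diff(post[o])[abs(diff(sc[o])) < 1e-12]) < 1e-12))
})

test_that("block classification matches an independent recount", {
  sim <- simulate_agreement(4000, 0.3, rep(0.9, 5), rep(0.1, 5),
                            miss_mcar(0.15), seed = 24)
  fit <- fs_fit(sim$matrix, "mar")
  cls <- classify_block(sim$matrix, fit)
  # fraction matched is rho_hat up to threshold ties
  expect_lte(abs(mean(cls$match) - fit$params$rho), 0.01)
  cc <- confusion_counts(cls$match, sim$truth == 1)
  expect_equal(unname(cc["tp"]), sum(cls$match & sim$truth == 1))
  expect_equal(unname(cc["tn"]), sum(!cls$match & sim$truth == 0))
  expect_equal(sum(cc), 4000)
})

test_that("final matches are the union over blocks", {
  b1 <- data.frame(record_a = c("1", "3"), record_b = c("2", "4"),
                   match = c(TRUE, FALSE))
  b2 <- data.frame(record_a = c("1", "5"), record_b = c("2", "6"),
                   match = c(FALSE, TRUE))
  u <- union_matches(list(A = b1, B = b2))
  k <- sprintf("%s-%s", u$record_a, u$record_b)
  expect_setequal(k, c("1-2", "5-6"))       # matched in >= 1 block wins
  expect_identical(u$blocks[k == "1-2"], "A")
  # concatenate-filter-dedup oracle over several random blocks
  set.seed(25)
  blocks <- lapply(1:5, function(i) {
    n <- 30
    data.frame(record_a = as.character(sample(20, n, TRUE)),
               record_b = as.character(sample(21:40, n, TRUE)),
               match = runif(n) < 0.3)
  })
  u2 <- union_matches(blocks)
  oracle <- unique(unlist(lapply(blocks, function(b)
    paste(b$record_a[b$match], b$record_b[b$match]))))
  expect_setequal(paste(u2$record_a, u2$record_b), oracle)
})
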