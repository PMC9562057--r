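test_that("dedup blocking forms the complete graph per block and skips missing", {
  recs <- tiny_records(data.frame(
    record_id = as.character(1:4),
    ssn = c("123456789", "123456789", "123456789", NA)))
  ps <- block_pairs(recs, scheme = "ssn")
  expect_identical(attr(ps, "mode"), "dedup")
  got <- sprintf("%s-%s", ps$record_a, ps$record_b)
  expect_setequal(got, c("1-2", "1-3", "2-3"))
})

test_that("linkage blocking is the within-block cross product", {
  a <- tiny_records(data.frame(record_id = c("a1", "a2"), zip = "46202"))
  b <- tiny_records(data.frame(record_id = c("b1", "b2", "b3"), zip = "46202"))
  ps <- block_pairs(a, b, scheme = "zip")
  expect_identical(attr(ps, "mode"), "linkage")
  expect_equal(nrow(ps), 6L)
  expect_setequal(ps$record_a, c("a1", "a2"))
  expect_error(block_pairs(a, b, scheme = "tel"), "unknown blocking variable")
})

test_that("pair counts on planted-duplicate data agree with an all-pairs scan", {
  sim <- simulate_records(250, duplication_rate = 0.3, error_rate = 0.05,
                          missing_rate = 0.2, seed = 31)
  for (vars in list("ssn", c("ln", "fn"), c("db", "mb", "yb"))) {
    ps <- block_pairs(sim$records, scheme = vars)
    expect_equal(nrow(ps), brute_force_block_count(sim$records, vars))
    # no pair disagrees (both observed, unequal) on any blocking variable
    ia <- match(ps$record_a, sim$records$record_id)
    ib <- match(ps$record_b, sim$records$record_id)
    for (v in vars) {
      va <- sim$records[[v]][ia]; vb <- sim$records[[v]][ib]
      expect_false(any(is.na(va)) || any(is.na(vb)) || any(va != vb))
    }
  }
})

test_that("blocking is invariant to input record order", {
  sim <- simulate_records(120, duplication_rate = 0.3, seed = 8)
  recs <- sim$records
  shuf <- recs[sample.int(nrow(recs)), , drop = FALSE]
  attr(shuf, "schema") <- attr(recs, "schema")
  k1 <- with(block_pairs(recs, scheme = c("ln", "fn")),
             paste(pmin(record_a, record_b), pmax(record_a, record_b)))
  k2 <- with(block_pairs(shuf, scheme = c("ln", "fn")),
             paste(pmin(record_a, record_b), pmax(record_a, record_b)))
  expect_setequal(k1, k2)
})

test_that("union of pair sets deduplicates and keeps scheme provenance", {
  recs <- tiny_records(data.frame(
    record_id = as.character(1:5),
    ssn = c("1", "1", "2", "2", NA),
    zip = c("9", "9", "9", "8", "8")))
  s1 <- block_pairs(recs, scheme = blocking_scheme("SSN", "ssn"))
  s2 <- block_pairs(recs, scheme = blocking_scheme("ZIP", "zip"))
  u <- union_pairsets(list(s1, s2))
  k <- sprintf("%s-%s", u$record_a, u$record_b)
  expect_setequal(k, c("1-2", "3-4", "1-3", "2-3", "4-5"))
  expect_identical(u$scheme[k == "1-2"], "SSN,ZIP")
  expect_identical(u$scheme[k == "3-4"], "SSN")
  expect_identical(u$scheme[k == "4-5"], "ZIP")
  # identity and oracle count on many schemes
  expect_equal(nrow(union_pairsets(list(s1))), nrow(s1))
  sim <- simulate_records(150, duplication_rate = 0.3, seed = 9)
  sets <- lapply(list(SSN = "ssn", LNFN = c("ln", "fn"), ZIP = "zip",
                      TEL = "tel", DOB = c("db", "mb", "yb")),
                 function(v) block_pairs(sim$records, scheme = v))
  u2 <- union_pairsets(sets)
  allk <- unlist(lapply(sets, function(s) paste(s$record_a, s$record_b)))
  expect_equal(nrow(u2), length(unique(allk)))
  # mixed modes refuse to union
  a <- tiny_records(data.frame(record_id = "a1", zip = "1"))
  b <- tiny_records(data.frame(record_id = "b1", zip = "1"))
  expect_error(union_pairsets(list(s1, block_pairs(a, b, scheme = "zip"))),
               "mixed modes")
})
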