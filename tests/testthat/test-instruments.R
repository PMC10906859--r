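test_that("MHC-SF scoring applies the flourishing/languishing counting rules", {
  hi <- score_mhcsf(rep(5, 14))
  expect_equal(hi$total, 70)
  expect_equal(hi$category, "flourishing")
  expect_equal(hi$collapsed, "flourishing")

  lo <- score_mhcsf(rep(0, 14))
  expect_equal(lo$total, 0)
  expect_equal(lo$category, "languishing")
  expect_equal(lo$collapsed, "moderate_to_low")

  # emotional criterion met but functioning top-band count 0 -> moderate
  mid <- score_mhcsf(c(5, 0, 0, rep(3, 11)))
  expect_equal(mid$functioning_high_count, 0L)
  expect_equal(mid$category, "moderate")
  expect_equal(mid$collapsed, "moderate_to_low")

  # exactly at the functioning boundary: 6 of 11 items in the top band
  at6 <- score_mhcsf(c(4, 0, 0, rep(5, 6), rep(3, 5)))
  expect_equal(at6$category, "flourishing")
  at5 <- score_mhcsf(c(4, 0, 0, rep(5, 5), rep(3, 6)))
  expect_equal(at5$category, "moderate")
})

test_that("MHC-SF missing-item policies differ as documented", {
  items <- c(5, NA, 5, rep(5, 6), rep(NA, 5))
  tol <- score_mhcsf(items)                     # answered-items-only counts
  expect_true(is.na(tol$total))
  expect_equal(tol$category, "flourishing")     # 6 functioning top-band hits
  strict <- score_mhcsf(items, missing_policy = "strict")
  expect_true(is.na(strict$category))

  # unanswered items qualify for neither band: drifts toward moderate
  few <- score_mhcsf(c(5, NA, NA, 5, 5, rep(NA, 9)))
  expect_equal(few$category, "moderate")
})

test_that("MHC-SF rejects malformed input", {
  expect_error(score_mhcsf(rep(3, 13)), "14")
  expect_error(score_mhcsf(c(rep(3, 13), 6)), "out of range")
  expect_error(score_mhcsf(c(rep(3, 13), 2.5)), "out of range")
})

test_that("flourishing and languishing are mutually exclusive by construction", {
  # 6 + 6 > 11 functioning items: property over random item vectors
  set.seed(71)
  for (i in 1:2000) {
    s <- score_mhcsf(sample(0:5, 14, replace = TRUE))
    expect_false(s$emotional_high_count >= 1 && s$functioning_high_count >= 6 &&
                   s$emotional_low_count >= 1 && s$functioning_low_count >= 6)
  }
})

test_that("raising an MHC item never demotes a flourishing respondent", {
  set.seed(72)
  for (i in 1:300) {
    items <- sample(0:5, 14, replace = TRUE)
    if (score_mhcsf(items)$category != "flourishing") next
    idx <- which(items < 5)
    if (!length(idx)) next
    j <- idx[sample.int(length(idx), 1)]
    bumped <- items; bumped[j] <- bumped[j] + 1L
    expect_equal(score_mhcsf(bumped)$category, "flourishing")
  }
})

test_that("SDQ scoring reverse-codes the five positive difficulty items", {
  z <- score_sdq(rep(0, 25))
  expect_equal(z$total_difficulties, 10)   # the 5 reverse items give 2 each
  expect_false(z$caseness)

  ones <- score_sdq(rep(1, 25))
  expect_equal(ones$total_difficulties, 20)
  expect_true(ones$caseness)               # >= 20 is caseness, boundary included

  twos <- score_sdq(rep(2, 25))
  expect_equal(twos$total_difficulties, 30)  # reverse items contribute 0
  expect_equal(twos$prosocial, 10)
})

test_that("SDQ caseness boundary is strict at the cutoff", {
  # construct total 19: all difficulty items at their scored value 1
  # except one scored 0
  items <- rep(1, 25)
  items[3] <- 0                       # emotional item scored 0
  s <- score_sdq(items)
  expect_equal(s$total_difficulties, 19)
  expect_false(s$caseness)
})

test_that("SDQ total is invariant to prosocial responses", {
  set.seed(73)
  pro <- c(1, 4, 9, 17, 20)
  for (i in 1:200) {
    items <- sample(0:2, 25, replace = TRUE)
    perturbed <- items
    perturbed[pro] <- sample(0:2, 5, replace = TRUE)
    expect_equal(score_sdq(items)$total_difficulties,
                 score_sdq(perturbed)$total_difficulties)
  }
})

test_that("SDQ missing-item policy: complete-case default, prorating optional", {
  items <- rep(1, 25); items[3] <- NA      # one emotional item missing
  expect_true(is.na(score_sdq(items)$emotional))
  expect_true(is.na(score_sdq(items)$total_difficulties))
  pro <- score_sdq(items, prorate = TRUE)  # 4/5 answered -> mean * 5 rounded
  expect_equal(pro$emotional, 5)
  expect_equal(pro$total_difficulties, 20)
})

test_that("CYRM-12 total spans 12-60 and propagates missingness", {
  expect_equal(score_cyrm(rep(5, 12)), 60)
  expect_equal(score_cyrm(rep(1, 12)), 12)
  expect_true(is.na(score_cyrm(c(rep(3, 11), NA))))
  expect_error(score_cyrm(rep(0, 12)), "out of range")
})

test_that("Cronbach's alpha matches the closed form and its edge cases", {
  # hand-evaluated: items (0,1,2,3) and (0,2,1,3); item vars 5/3 each,
  # total var 6 -> alpha = 2 * (1 - (10/3)/6) = 8/9
  m <- cbind(c(0, 1, 2, 3), c(0, 2, 1, 3))
  expect_equal(cronbach_alpha(m)$alpha, 8 / 9, tolerance = 1e-12)

  # k identical copies of a non-constant item -> exactly 1
  x <- c(2, 5, 3, 1, 4)
  expect_equal(cronbach_alpha(cbind(x, x, x))$alpha, 1.0, tolerance = 1e-12)

  expect_error(cronbach_alpha(cbind(x)), "at least 2 items")
  expect_error(cronbach_alpha(matrix(c(1, NA, NA, 2, 3, NA), 3, 2)),
               "complete rows")
  expect_error(cronbach_alpha(cbind(c(1, 1), c(2, 2))), "zero variance")
})
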