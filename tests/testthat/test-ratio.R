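test_that("worked examples of the polyadenylation ratio hold", {
  # WT (f1=100, f5=50) vs mut (f1=100, f5=25), alpha = 0 -> log2(2) = 1
  # (library totals equalized so size factors are all 1)
  x <- make_counts(c(100L, 100L), c(50L, 150L), c(50L, 150L),
                   c(100L, 100L), c(25L, 175L), c(25L, 175L))
  r <- polya_ratio(normalize_counts(x, "total"), k = 5, pseudocount = 0)
  expect_equal(unname(r["T01"]), 1)
  # WT identical to mut -> all ratios zero
  y <- make_counts(c(7L, 30L), c(3L, 10L), c(9L, 40L),
                   c(7L, 30L), c(3L, 10L), c(9L, 40L))
  expect_equal(unname(polya_ratio(normalize_counts(y, "total"), 5, 0.5)),
               c(0, 0))
  expect_equal(unname(polya_ratio(normalize_counts(y, "total"), 6, 0.5)),
               c(0, 0))
  # symmetric zeros with a pseudocount -> zero, and alpha = 0 -> NaN, no crash
  z <- make_counts(c(10L, 10L), c(0L, 5L), c(1L, 5L),
                   c(10L, 10L), c(0L, 5L), c(1L, 5L))
  expect_equal(unname(polya_ratio(normalize_counts(z, "total"), 5, 0.5)),
               c(0, 0))
  r0 <- polya_ratio(normalize_counts(z, "total"), 5, 0)
  expect_true(is.nan(r0[["T01"]]))
  expect_equal(r0[["T02"]], 0)
})

test_that("log2 ratios match the brute-force oracle on random matrices", {
  set.seed(101)
  for (i in 1:100) {
    cnt <- matrix(rpois(30, 60) + 1L, 5, 6)
    x <- make_counts(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4], cnt[, 5], cnt[, 6])
    alpha <- sample(c(0, 0.5, 1), 1)
    r <- polya_ratio(normalize_counts(x, "total"), k = 5, pseudocount = alpha)
    expect_equal(unname(r), unname(oracle_ratio(x$counts, alpha)),
                 tolerance = 1e-12)
  }
})

test_that("swapping condition labels negates every ratio exactly", {
  sim <- simulate_fractionation(small_config(), sequences = FALSE)
  x <- sim$counts
  nc <- normalize_counts(x, "spikein")
  swapped <- x
  swapped$samples$condition <- ifelse(swapped$samples$condition == "WT",
                                      "mut", "WT")
  nc2 <- normalize_counts(swapped, "spikein")
  for (k in c(5, 6))
    expect_identical(polya_ratio(nc, k, 0.5), -polya_ratio(nc2, k, 0.5))
})

test_that("rescaling one library leaves all ratios unchanged", {
  sim <- simulate_fractionation(small_config(), sequences = FALSE)
  x <- sim$counts
  nc <- normalize_counts(x, "spikein")
  r <- polya_ratio(nc, 5, 0.5)
  # scale up a non-anchor library (the median library defines the scale,
  # so it is the one library whose own rescaling must move the factors)
  lib <- names(which.max(nc$size_factors))
  x2 <- sim$counts
  x2$counts[, lib] <- x2$counts[, lib] * 3L
  r2 <- polya_ratio(normalize_counts(x2, "spikein"), 5, 0.5)
  expect_equal(r2, r, tolerance = 1e-9)
})

test_that("robust null fit recovers normal moments and resists contamination", {
  set.seed(7)
  x <- rnorm(1e4)
  nl <- fit_null(x)
  expect_equal(nl$mu, 0, tolerance = 0.05)
  expect_equal(nl$sigma, 1, tolerance = 0.05)
  expect_equal(nl$n_used, 1e4)
  # 5% right-tail contamination at +5: the contaminated median sits at
  # qnorm(0.5/0.95) ~ 0.066, and the robust fit stays near it while the
  # naive mean/sd are dragged far off
  xc <- c(rnorm(9500), rnorm(500, 5, 0.3))
  nlc <- fit_null(xc)
  expect_lt(abs(nlc$mu - qnorm(0.5 / 0.95)), 0.05)
  expect_equal(nlc$sigma, 1, tolerance = 0.06)
  expect_lt(abs(nlc$mu), abs(mean(xc)))
  expect_lt(abs(nlc$sigma - 1), abs(sd(xc) - 1))
  # the fit always equals the data's robust moments
  expect_identical(nl$mu, median(x))
  expect_identical(nl$sigma, mad(x))
})

test_that("degenerate null inputs error", {
  expect_error(fit_null(rep(3, 10)), "degenerate")
  expect_error(fit_null(c(1, 2)), "at least 3")
  expect_error(fit_null(c(1, 2, NA, Inf)), "at least 3")
})
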