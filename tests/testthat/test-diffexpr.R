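# Independent oracle for the Audic-Claverie tails: conditional on x, the
# second count is negative binomial with size x+1 and prob n1/(n1+n2).
ac_oracle <- function(x, y, n1, n2) {
  pr <- n1 / (n1 + n2)
  lo <- pnbinom(y, size = x + 1, prob = pr)
  up <- pnbinom(y, size = x + 1, prob = pr, lower.tail = FALSE)
  min(1, 2 * min(lo, up))
}

test_that("rpm is exact arithmetic and validates inputs", {
  expect_identical(rpm(0, 1e7), 0)
  expect_identical(rpm(12345, 12345), 1e6)
  expect_equal(rpm(1011, N1_PUB), 1011 / N1_PUB * 1e6, tolerance = 1e-12)
  expect_error(rpm(1, 0), "positive")
  expect_error(rpm(-1, 10), "non-negative")
})

test_that("log2 fold change reproduces printed values and symmetries", {
  expect_equal(log2_fold_change(41719, 85216, N1_PUB, N2_PUB), 0.9888,
               tolerance = 1e-4)
  expect_identical(log2_fold_change(7, 7, 1000, 1000), 0)
  expect_equal(log2_fold_change(30, 90, 1e6, 2e6),
               -log2_fold_change(90, 30, 2e6, 1e6), tolerance = 1e-12)
  # zero substitution: rpm 0 becomes 0.01
  expect_equal(log2_fold_change(0, 50, 1e6, 1e6), log2(50 / 0.01),
               tolerance = 1e-12)
  expect_error(log2_fold_change(0, 0, 1e6, 1e6), "both")
})

test_that("ac_pvalue reproduces the published Table-2 value", {
  p <- ac_pvalue(25, 84, N1_PUB, N2_PUB)
  expect_equal(p, 1.86e-8, tolerance = 0.01)
})

test_that("near-null counts give a large p-value", {
  expect_gte(ac_pvalue(10, 10, 1e6, 1e6), 0.4)
})

test_that("ac_pvalue matches the exact dyadic-rational tail at r = 1", {
  # r = 1: p(y'|x=2) = (y'+2)(y'+1)/2 / 2^(y'+3); every term is a dyadic
  # rational held exactly in doubles
  terms <- function(yp) (yp + 2) * (yp + 1) / 2 / 2^(yp + 3)
  exact <- 2 * sum(terms(9:200))      # strict upper tail from y+1 = 9
  expect_equal(ac_pvalue(2, 8, 1000, 1000), exact, tolerance = 1e-12)
})

test_that("ac_pvalue agrees with the negative-binomial oracle", {
  set.seed(19)
  for (i in 1:50) {
    n1 <- sample(1e5:1e7, 1)
    n2 <- sample(1e5:1e7, 1)
    x <- rpois(1, 10^runif(1, 0, 4))
    y <- rpois(1, 10^runif(1, 0, 4))
    expect_equal(ac_pvalue(x, y, n1, n2), ac_oracle(x, y, n1, n2),
                 tolerance = 1e-10)
  }
})

test_that("ac_pvalue is symmetric under library swap", {
  set.seed(23)
  for (i in 1:25) {
    x <- rpois(1, 200); y <- rpois(1, 400)
    n1 <- 2e6; n2 <- 3e6
    expect_equal(ac_pvalue(x, y, n1, n2), ac_pvalue(y, x, n2, n1),
                 tolerance = 1e-9)
  }
})

test_that("p decreases as y moves away from the null expectation", {
  ys <- 30:80
  ps <- ac_pvalue(rep(20L, length(ys)), ys, 1e6, 1e6)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("BH q-values match the hand-applied step-up formula", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.02, 0.5)),
               c(0.004, 0.02, 0.02 * 4 / 3, 0.5), tolerance = 1e-12)
  expect_identical(bh_fdr(0.037), 0.037)
  expect_identical(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # manual step-up oracle on random p-values
  set.seed(41)
  p <- runif(40)
  o <- order(p)
  m <- length(p)
  q_ranked <- rev(cummin(rev(p[o] * m / seq_len(m))))
  oracle <- pmin(q_ranked, 1)[match(seq_len(m), o)]
  expect_equal(bh_fdr(p), oracle, tolerance = 1e-12)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("differential calls honour the published row and gates", {
  # the published up-regulated row (x=25, y=84); the expression columns of
  # the published table are raw counts, so gate on counts
  row <- score_expression("miR-310-3p", 25, 84, N1_PUB, N2_PUB)
  called <- call_differential(row, expr_on = "count")
  expect_identical(called$call, "up")
  expect_equal(called$fc, 1.71, tolerance = 1e-2)
  # exclusion: rpm < 1 in both libraries
  low <- score_expression("low", 5, 8, 1e7, 1e7)
  expect_identical(call_differential(low)$call, "excluded")
})

test_that("a constructed table yields exactly the planted calls", {
  # 3 planted up (m1-m3), 2 planted down (m4, m5); m6/m10 have strong
  # ratios but fail the expression gate, m7-m9 are null
  n1 <- n2 <- 1e6
  x <- c(100, 50, 30, 2000, 500, 3, 5000, 300, 40, 8)
  y <- c(420, 240, 150, 510, 120, 9, 5200, 310, 40, 2)
  rows <- score_expression(sprintf("m%02d", 1:10), x, y, n1, n2)
  called <- call_differential(rows)
  s <- attr(called, "summary")
  expect_identical(unname(s["up"]), 3L)
  expect_identical(unname(s["down"]), 2L)
  expect_identical(called$call[called$id == "m04"], "down")
  expect_identical(called$call[called$id == "m06"], "ns")
  expect_identical(called$call[called$id == "m09"], "ns")
})

test_that("platform intersection requires concordant significance", {
  seq_rows <- data.frame(id = c("a", "b", "c"), fc = c(1.5, -1.2, 2.0),
                         call = c("up", "down", "up"),
                         stringsAsFactors = FALSE)
  arr <- data.frame(id = c("a", "b", "d"),
                    signal_na = c(600, 700, 900),
                    signal_da = c(1200, 300, 1500),
                    fc = c(1.2, 1.4, 2.0), q = c(1e-4, 1e-4, 1e-5),
                    stringsAsFactors = FALSE)
  got <- intersect_platforms(seq_rows, arr)
  # b is discordant (down by sequencing, up by array); d absent from
  # sequencing; c absent from array
  expect_identical(got$id, "a")
  expect_identical(got$direction, "up")
  expect_identical(nrow(intersect_platforms(seq_rows, arr[0, ])), 0L)
})
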