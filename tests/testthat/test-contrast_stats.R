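# Pooled contrasts, JZS Bayes factors, evidence classification.
#
# Reference values checked against published group summaries carry the
# quantisation of inputs printed to two decimals; tolerances reflect that
# propagation (about 0.006 on t, 0.02 on BF01), not looseness in the code.

test_that("pooled t reproduces published contrasts from group summaries", {
  r1 <- pooled_t(49.94, 12.82, 54, 52.83, 12.88, 54,
                 tails = "one", direction = "A<B")
  expect_lt(abs(r1$t_abs - 1.17), 0.01)
  expect_lt(abs(r1$d - 0.22), 0.01)
  expect_lt(abs(r1$p - 0.123), 0.002)
  expect_equal(r1$df, 106)
  expect_gt(r1$t_signed, 0)   # observed direction matches prediction

  r2 <- pooled_t(13.65, 8.90, 54, 7.35, 5.16, 54, tails = "two")
  expect_lt(abs(r2$t_abs - 4.50), 0.01)
  expect_lt(abs(r2$d - 0.87), 0.01)
  expect_lt(r2$p, 0.001)

  # opposite-to-prediction data: one-tailed p in the upper half
  r3 <- pooled_t(13.65, 8.90, 54, 9.71, 6.46, 54,
                 tails = "one", direction = "A<B")
  expect_lt(r3$t_signed, 0)
  expect_lt(abs(r3$p - 0.995), 0.002)

  r0 <- pooled_t(10, 2, 20, 10, 2, 20, tails = "two")
  expect_equal(r0$t_signed, 0)
  expect_equal(r0$d, 0)
  expect_equal(r0$p, 1)
})

test_that("swapping groups negates t and preserves d, p and BF01", {
  a <- pooled_t(12.3, 3.1, 30, 10.9, 2.7, 25, tails = "two")
  b <- pooled_t(10.9, 2.7, 25, 12.3, 3.1, 30, tails = "two")
  expect_equal(a$t_signed, -b$t_signed, tolerance = 1e-12)
  expect_equal(a$d, b$d, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(jzs_bf01(a$t_signed, 30, 25, "two"),
               jzs_bf01(b$t_signed, 25, 30, "two"), tolerance = 1e-6)
})

test_that("directional p values of opposite orientations sum to one", {
  set.seed(50)
  for (i in 1:6) {
    ma <- rnorm(1, 10); mb <- rnorm(1, 10)
    p1 <- pooled_t(ma, 2, 31, mb, 2.4, 28, tails = "one", direction = "A<B")$p
    p2 <- pooled_t(ma, 2, 31, mb, 2.4, 28, tails = "one", direction = "A>B")$p
    expect_equal(p1 + p2, 1, tolerance = 1e-12)
  }
})

test_that("JZS BF01 reproduces published values at the printed t", {
  # one-sided, observed in predicted direction, near-unity case
  expect_lt(abs(jzs_bf01(1.17, 54, 54, "one") - 1.55), 0.02)
  # one-sided with data opposite to the prediction
  expect_lt(abs(jzs_bf01(-2.63, 54, 54, "one") - 16.77), 0.05)
  # two-sided near-unity case
  expect_lt(abs(jzs_bf01(1.75, 54, 54, "two") - 1.25), 0.02)
  # strongly significant two-sided case
  expect_lt(jzs_bf01(4.50, 54, 54, "two"), 0.01)
  # smaller-sample design
  expect_lt(abs(jzs_bf01(2.01, 38, 38, "one") - 0.39), 0.01)
})

test_that("quadrature BF matches a Monte-Carlo marginal-likelihood oracle", {
  mc_bf01 <- function(t, n1, n2, side, ndraws = 1e6) {
    set.seed(99)
    neff <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2
    delta <- rcauchy(ndraws, 0, sqrt(2) / 2)
    if (side == "positive") delta <- abs(delta)  # truncated symmetric prior
    m1 <- mean(suppressWarnings(dt(t, df, ncp = delta * sqrt(neff))))
    dt(t, df) / m1
  }
  for (case in list(list(t = 0, side = "two"),
                    list(t = 1.17, side = "positive"),
                    list(t = -2.63, side = "positive"))) {
    tails <- if (case$side == "two") "two" else "one"
    got <- jzs_bf01(case$t, 54, 54, tails)
    oracle <- mc_bf01(case$t, 54, 54, case$side)
    expect_lt(abs(got - oracle) / oracle, 0.01)
  }
})

test_that("one-sided marginals average to the two-sided Bayes factor", {
  # mixture identity under the symmetric prior:
  # BF10_two = (BF10_positive + BF10_negative) / 2
  set.seed(51)
  for (t in runif(6, -3, 3)) {
    bf10_two <- 1 / jzs_bf01(t, 40, 35, "two")
    bf10_pos <- 1 / jzs_bf01(t, 40, 35, "one")
    bf10_neg <- 1 / jzs_bf01(-t, 35, 40, "one")  # mirrored orientation
    expect_equal(bf10_two, (bf10_pos + bf10_neg) / 2, tolerance = 1e-5)
  }
})

test_that("two-sided BF01 peaks at t = 0 and decreases in |t|", {
  grid <- seq(0, 5, by = 0.5)
  vals <- vapply(grid, jzs_bf01, numeric(1), n_a = 54, n_b = 54,
                 tails = "two")
  expect_true(all(diff(vals) < 0))
  expect_equal(which.max(vals), 1)
})

test_that("evidence classification bands reproduce the printed symbols", {
  expect_equal(classify_evidence(1.25)$symbol, "○")   # inconclusive
  expect_equal(classify_evidence(1.36)$symbol, "○")
  w <- classify_evidence(1.55)
  expect_equal(w$strength, "weak"); expect_equal(w$direction, "against_h1")
  expect_equal(w$symbol, "-")
  expect_equal(classify_evidence(4.92)$symbol, "- -")
  expect_equal(classify_evidence(16.77)$symbol, "- - -")
  expect_equal(classify_evidence(0.35)$symbol, "+")        # 1/0.35 ~ 2.9
  expect_equal(classify_evidence(0.13)$symbol, "+ +")      # moderate for H1
  expect_equal(classify_evidence(0.05)$symbol, "+ + +")    # strong for H1
  expect_equal(classify_evidence(0.02)$symbol, "+ + + +")  # very strong
  expect_equal(classify_evidence(0.0009)$symbol, "+ + + + +")
  expect_equal(classify_evidence(250)$strength, "extreme")
  expect_error(classify_evidence(0), "> 0")
})

test_that("the batch driver resolves groups and formats display columns", {
  summaries <- data.frame(measure = "m",
                          group = c("a", "b"),
                          mean = c(10.95, 10.95), sd = c(8.42, 8.47),
                          n = 54)
  plan <- data.frame(measure = "m", group_a = "a", group_b = "b",
                     tails = "one", direction = "A>B")
  tab <- contrast_table(summaries, plan)
  expect_equal(tab$t_disp, "< 0.01")
  expect_equal(tab$d_disp, "< 0.01")
  expect_equal(tab$df, 106)
  bad <- plan; bad$group_b <- "zzz"
  expect_error(contrast_table(summaries, bad), "unknown group")
  empty <- contrast_table(summaries, plan[0, ])
  expect_equal(nrow(empty), 0)
})
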