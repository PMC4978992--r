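test_that("area test returns 100 for a constant gap and 200 for a doubling", {
  age <- seq(100, 0, by = -5)
  clade <- 10 + 0.5 * (100 - age)             # arbitrary base curve
  # constant gap g = 4 on both sides of the shift
  at <- area_test(age, clade + 4, clade, shift_age = 50)
  expect_false(at$undefined)
  expect_equal(at$ratio_pct, 100, tolerance = 1e-10)
  # gap grows linearly 0 -> 4 before the shift (mean 2), constant 4 after
  gap <- ifelse(age >= 50, 4 * (100 - age) / 50, 4)
  at2 <- area_test(age, clade + gap, clade, shift_age = 50)
  expect_equal(at2$ratio_pct, 200, tolerance = 1e-10)
  # identical curves before the shift: undefined, flagged, not infinite
  gap3 <- ifelse(age >= 50, 0, 50 - age)
  at3 <- area_test(age, clade + gap3, clade, shift_age = 50)
  expect_true(at3$undefined)
  expect_true(is.na(at3$ratio_pct))
  expect_error(area_test(age, clade, clade, shift_age = 100), "inside")
})

test_that("area test is exactly 100 on random constant-gap instances", {
  set.seed(14)
  for (rep in 1:10) {
    age <- sort(runif(12, 0, 80), decreasing = TRUE)
    base <- cumsum(runif(12, 0, 5))
    g <- runif(1, 0.5, 10)
    shift <- runif(1, age[10] + 1, age[3] - 1)
    at <- area_test(age, base + g, base, shift)
    expect_equal(at$ratio_pct, 100, tolerance = 1e-9)
  }
})

test_that("slope test recovers a perfect decline and a flat null", {
  # values (3, 2, 1) at forward times (1, 2, 3)
  st <- slope_test(age = c(39, 38, 37), avg = c(3, 2, 1), shift_age = 39.5,
                   origin_age = 40)
  expect_equal(st$slope, -1, tolerance = 1e-10)
  expect_lt(st$p, 1e-6)
  flat <- slope_test(age = c(30, 20, 10, 5), avg = rep(2.5, 4),
                     shift_age = 35, origin_age = 40)
  expect_equal(flat$slope, 0)
  expect_equal(flat$p, 1)
  # fewer than 3 post-shift bins: not applicable, as in printed-table NAs
  na <- slope_test(age = c(30, 20), avg = c(1, 2), shift_age = 35)
  expect_false(na$applicable)
  expect_true(is.na(na$p))
})

test_that("slope test type-I error is nominal on white noise", {
  set.seed(123)
  hits <- 0
  for (r in 1:1000) {
    age <- seq(50, 5, by = -5)
    st <- slope_test(age, rnorm(10), shift_age = 55, origin_age = 60)
    if (st$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 1000, 0.03)
  expect_lt(hits / 1000, 0.07)
})

test_that("the one-sided Wilcoxon matches enumeration and closed forms", {
  # complete separation, m = n = 3: p = 1 / choose(6, 3)
  p <- net_rate_wilcoxon(c(0.5, 0.4, 0.6), c(-0.2, -0.1, -0.3))
  expect_equal(p, 1 / 20)
  # wrong direction: after stochastically larger
  expect_gt(net_rate_wilcoxon(c(-0.2, -0.1, -0.3), c(0.5, 0.4, 0.6)), 0.5)
  # all tied values: p = 1 with a warning
  expect_warning(p1 <- net_rate_wilcoxon(rep(1, 3), rep(1, 4)), "tied")
  expect_equal(p1, 1)
  # exact p equals brute-force enumeration over all C(17, 8) partitions
  set.seed(77)
  before <- rnorm(8); after <- rnorm(9) - 0.5
  got <- net_rate_wilcoxon(before, after)
  pool <- c(before, after)
  rk <- rank(pool)
  u_obs <- sum(rk[9:17]) - 9 * 10 / 2         # U statistic of "after"
  combos <- utils::combn(17, 9)
  u_all <- colSums(matrix(rk[combos], nrow = 9)) - 9 * 10 / 2
  expect_equal(got, mean(u_all <= u_obs))
})

test_that("normal-approximation Wilcoxon p is close to exact for m,n ~ 10", {
  set.seed(31)
  for (rep in 1:5) {
    m <- sample(8:12, 1); n <- sample(8:12, 1)
    before <- rnorm(m); after <- rnorm(n, -0.3)
    exact <- suppressWarnings(stats::wilcox.test(
      after, before, alternative = "less", exact = TRUE)$p.value)
    approx <- suppressWarnings(stats::wilcox.test(
      after, before, alternative = "less", exact = FALSE,
      correct = TRUE)$p.value)
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("binomial summaries are exact one-sided tails", {
  expect_equal(binomial_summary(3, 3)$binomial_p, 0.125)
  expect_equal(binomial_summary(0, 5)$binomial_p, 1)
  # independent combinatorial summation for 20 of 30
  expect_equal(binomial_summary(20, 30)$binomial_p,
               sum(choose(30, 20:30)) / 2^30, tolerance = 1e-12)
  # strictly decreasing in the success count
  for (k in 0:9)
    expect_lt(binomial_summary(k + 1, 10)$binomial_p,
              binomial_summary(k, 10)$binomial_p)
  expect_equal(binomial_summary(2, 4)$pct, 50)
})

test_that("the printed shift-level counts are reproduced from the fixture", {
  tbl <- read.csv(system.file("extdata", "table2_fixture.csv",
                              package = "waxwane"))
  rep <- summarize_report(tbl, alpha = 0.05, area_rule = "lt100")
  s <- rep$summary
  g <- function(test, level) s[s$test == test & s$level == level, ]
  expect_equal(g("p_dist", "shift")$n_success, 20)   # coincident shifts
  expect_equal(g("p_dist", "shift")$n_trials, 30)
  expect_equal(g("area", "shift")$n_success, 28)     # sympatry increases
  expect_equal(g("net", "shift")$n_success, 28)      # net-rate declines
  expect_equal(g("slope_sig", "shift")$n_success, 15)
  expect_equal(g("slope_neg", "shift")$n_success, 12)
  # clade-level rollups (a clade complies when any shift does); under the
  # strict alpha = 0.05 rule the coincidence count is 15 of 21
  expect_equal(g("p_dist", "clade")$n_success, 15)
  expect_equal(g("p_dist", "clade")$n_trials, 21)
  expect_equal(g("area", "clade")$n_success, 20)
  expect_equal(round(g("area", "clade")$pct, 2), 95.24)
  expect_equal(g("net", "clade")$n_success, 21)
})

test_that("covariate correlation counts are reproduced from the fixture", {
  tbl <- read.csv(system.file("extdata", "table4_fixture.csv",
                              package = "waxwane"))
  cc <- summarize_covariate(tbl)
  expect_equal(cc$n_clades, 21)
  expect_equal(cc$lambda_negative, 13)   # speciation depressed by sympatry
  expect_equal(cc$mu_positive, 12)       # extinction raised by sympatry
  expect_equal(cc$either, 16)
})
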