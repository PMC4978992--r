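test_that("preservation log-likelihood matches Poisson closed forms", {
  # q = 1, duration 2, k = 2, unconditioned: log(e^-2 * 2^2 / 2!) = log 2 - 2
  expect_equal(preservation_loglik(1, ts = 2, te = 0, k = 2,
                                   conditioned = FALSE), log(2) - 2)
  # random draws against the Poisson pmf
  set.seed(5)
  for (rep in 1:20) {
    q <- runif(1, 0.2, 5); d <- runif(1, 0.5, 20); k <- rpois(1, q * d) + 1
    expect_equal(preservation_loglik(q, d, 0, k, conditioned = FALSE),
                 dpois(k, q * d, log = TRUE), tolerance = 1e-12)
    expect_equal(preservation_loglik(q, d, 0, k, conditioned = TRUE),
                 dpois(k, q * d, log = TRUE) - log(1 - exp(-q * d)),
                 tolerance = 1e-12)
  }
  # unconditioned MLE is k / duration
  k <- 7; d <- 3.5
  opt <- optimize(function(q) preservation_loglik(q, d, 0, k,
                                                  conditioned = FALSE),
                  c(0.01, 20), maximum = TRUE)
  expect_equal(opt$maximum, k / d, tolerance = 1e-4)
  expect_error(preservation_loglik(1, 1, 2, 3), "exceed")
})

test_that("lineage-time MCMC is seed-deterministic and hugs dense records", {
  # single species, dense record, high preservation: ts sits just above the
  # oldest occurrence
  set.seed(8)
  occ <- data.frame(species = "a", age = runif(120, 10, 30))
  r1 <- sample_lineage_times(occ, iterations = 6000, burnin = 1000,
                             thin = 10, seed = 3)
  r2 <- sample_lineage_times(occ, iterations = 6000, burnin = 1000,
                             thin = 10, seed = 3)
  expect_identical(r1$samples, r2$samples)
  expect_lt(r1$times$ts - max(occ$age), 1)    # gap shrinks like 1/q, q ~ 6
  expect_gt(r1$times$ts, max(occ$age))
  expect_lt(r1$times$te, min(occ$age))
})

test_that("the preservation rate is recovered within 20%", {
  set.seed(21)
  n_sp <- 50
  q_true <- 3
  occ <- do.call(rbind, lapply(seq_len(n_sp), function(i) {
    repeat {
      ts <- runif(1, 20, 60); d <- rexp(1, 0.15); te <- max(ts - d, 0)
      k <- rpois(1, q_true * (ts - te))
      if (k >= 1) break
    }
    data.frame(species = sprintf("sp%02d", i), age = runif(k, te, ts))
  }))
  fit <- sample_lineage_times(occ, iterations = 20000, burnin = 4000,
                              thin = 20, seed = 9)
  expect_gt(fit$q_mean, 2.4)
  expect_lt(fit$q_mean, 3.6)
})

test_that("the rate timeline divides events by lineage-Myr exposure", {
  # founder A on [1, 3]; B originates at 2.5 and lives to 1.5
  times <- data.frame(ts = c(3, 2.5), te = c(1, 1.5))
  tl <- rates_timeline(times)
  # cell (3,2]: exposure 1 (A) + 0.5 (B), one origination event
  expect_equal(tl$lambda[tl$age == 2.5], 1 / 1.5)
  # cell (2,1]: exposure 1 (A) + 0.5 (B), one extinction event (B)
  expect_equal(tl$mu[tl$age == 1.5], 1 / 1.5)
  expect_equal(tl$net, tl$lambda - tl$mu)
  # no extinctions anywhere: mu is identically zero where defined
  alive <- data.frame(ts = c(5, 4, 3), te = c(0, 0, 0))
  tl2 <- rates_timeline(alive)
  expect_true(all(tl2$mu == 0, na.rm = TRUE))
  expect_equal(tl2$net, tl2$lambda)
})

test_that("origination events are conserved across the timeline", {
  cov <- rising_covariate(60)
  tm <- simulate_bd_times(0.35, 0.25, 0, 0, cov, t_origin = 60, seed = 11,
                          min_species = 40)
  tl <- rates_timeline(tm)
  # total births recovered from per-cell rates x exposures = N - 1
  edges_hi <- tl$age + 0.5; edges_lo <- tl$age - 0.5
  expo <- vapply(seq_along(tl$age), function(i)
    sum(pmax(pmin(tm$ts, edges_hi[i]) - pmax(tm$te, edges_lo[i]), 0)),
    numeric(1))
  births <- sum(tl$lambda * expo, na.rm = TRUE)
  expect_equal(births, nrow(tm) - 1, tolerance = 1e-9)
  # time-averaged constant-rate estimates are near the truth
  lam_hat <- (nrow(tm) - 1) / sum(tm$ts - tm$te)
  expect_lt(abs(lam_hat - 0.35) / 0.35, 0.25)
})

test_that("the covariate likelihood collapses to the constant-rate form", {
  set.seed(17)
  cov <- rising_covariate(60)
  for (rep in 1:5) {
    tm <- simulate_bd_times(0.3, 0.2, 0, 0, cov, t_origin = 60, seed = rep,
                            min_species = 20)
    l0 <- runif(1, 0.1, 1); m0 <- runif(1, 0.1, 1)
    got <- covariate_bd_loglik(l0, m0, 0, 0, cov, tm)
    B <- nrow(tm) - 1
    D <- sum(tm$te > 0)
    closed <- B * log(l0) + D * log(m0) - (l0 + m0) * sum(tm$ts - tm$te)
    expect_equal(got, closed, tolerance = 1e-10)
  }
})

test_that("the covariate likelihood matches a hand-worked two-lineage case", {
  # lineages: founder [4, 2.2], child [2.9, 1.2]
  tm <- data.frame(ts = c(4, 2.9), te = c(2.2, 1.2))
  cov <- data.frame(age = c(3.5, 2.5, 1.5, 0.5), value = c(1, 2, 3, 4))
  z <- (cov$value - 2.5) / sd(cov$value)
  l0 <- 0.4; m0 <- 0.3; gl <- 0.7; gm <- -0.5
  # events: one birth at 2.9 (z2), deaths at 2.2 (z2) and 1.2 (z3)
  ev <- log(l0) + gl * z[2] + 2 * log(m0) + gm * (z[2] + z[3])
  # integration cells (4,3], (3,2], (2,1]: exposures 1, 1.7, 0.8
  E <- c(1, 1.7, 0.8)
  integ <- sum(E * (l0 * exp(gl * z[1:3]) + m0 * exp(gm * z[1:3])))
  expect_equal(covariate_bd_loglik(l0, m0, gl, gm, cov, tm), ev - integ,
               tolerance = 1e-10)
  # affine rescaling of the covariate leaves the likelihood unchanged
  cov2 <- transform(cov, value = 2 * value + 5)
  expect_equal(covariate_bd_loglik(l0, m0, gl, gm, cov2, tm),
               covariate_bd_loglik(l0, m0, gl, gm, cov, tm),
               tolerance = 1e-12)
  # a covariate that stops far short of the lifespan is a coverage error
  expect_error(covariate_bd_loglik(l0, m0, gl, gm,
                                   data.frame(age = c(1, 0.5),
                                              value = c(1, 2)), tm),
               "cover")
})

test_that("covariate MCMC is deterministic under a fixed seed", {
  cov <- rising_covariate(60)
  tm <- simulate_bd_times(0.3, 0.2, 0, 1.5, cov, t_origin = 60, seed = 2,
                          min_species = 40)
  p1 <- covariate_bd_mcmc(tm, cov, iterations = 2000, thin = 10,
                          burnin_samples = 50, seed = 4)
  p2 <- covariate_bd_mcmc(tm, cov, iterations = 2000, thin = 10,
                          burnin_samples = 50, seed = 4)
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$summary, p2$summary)
})

test_that("null covariate effects are flagged in at most 10% of replicates", {
  cov <- rising_covariate(60)
  flags <- logical(50)
  for (r in 1:50) {
    tm <- simulate_bd_times(0.3, 0.25, 0, 0, cov, t_origin = 60,
                            seed = 100 + r, min_species = 40,
                            max_species = 600)
    post <- covariate_bd_mcmc(tm, cov, iterations = 6000, thin = 15,
                              burnin_samples = 100, seed = r)
    flags[r] <- post$summary$significant[
      post$summary$parameter == "gamma_lambda"]
  }
  expect_gte(sum(!flags), 45)                 # >= 90% correctly unflagged
})

test_that("a strong extinction covariate effect is detected with power", {
  cov <- rising_covariate(60)
  hit <- 0
  for (r in 1:50) {
    tm <- simulate_bd_times(0.3, 0.15, 0, 2, cov, t_origin = 60,
                            seed = 200 + r, min_species = 100,
                            max_species = 1500)
    post <- covariate_bd_mcmc(tm, cov, iterations = 6000, thin = 15,
                              burnin_samples = 100, seed = r)
    row <- post$summary[post$summary$parameter == "gamma_mu", ]
    if (row$mean > 0 && isTRUE(row$significant)) hit <- hit + 1
  }
  expect_gte(hit, 40)                         # >= 80% power at gamma_mu = 2
})

test_that("credible intervals cover the generating gammas", {
  # a fluctuating covariate keeps clade growth bounded while leaving the
  # gammas well identified (rates swing around their baselines many times)
  age <- seq(59.5, 0.5, by = -1)
  cov <- data.frame(age = age, value = sin(age / 3))
  cover_l <- cover_m <- 0
  n_rep <- 25
  for (r in 1:n_rep) {
    gl <- -0.75; gm <- 0.75
    tm <- simulate_bd_times(0.3, 0.28, gl, gm, cov, t_origin = 60,
                            seed = 300 + r, min_species = 60,
                            max_species = 1200, max_attempts = 2000)
    post <- covariate_bd_mcmc(tm, cov, iterations = 6000, thin = 15,
                              burnin_samples = 100, seed = r)
    s <- post$summary
    gl_row <- s[s$parameter == "gamma_lambda", ]
    gm_row <- s[s$parameter == "gamma_mu", ]
    if (gl_row$ci_low <= gl && gl <= gl_row$ci_high) cover_l <- cover_l + 1
    if (gm_row$ci_low <= gm && gm <= gm_row$ci_high) cover_m <- cover_m + 1
  }
  expect_gte(cover_l / n_rep, 0.8)
  expect_gte(cover_m / n_rep, 0.8)
})
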