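# simulate a chronosequence-shaped mixed-model dataset: 8 stages x 6 plots
sim_mixed_data <- function(seed, beta = c(PD = 1, PSR = 0, PSE = 0,
                                          NRI = 0, NTI = 0),
                           sd_stage = 0.5, sd_resid = 0.5) {
  set.seed(seed)
  stages <- rep(c(0, 10, 20, 40, 70, 120, 135, 150), each = 6)
  n <- length(stages)
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("PD", "PSR", "PSE", "NRI", "NTI")))
  u <- rnorm(8, 0, sd_stage)
  y <- drop(X %*% beta) + u[match(stages, unique(stages))] +
    rnorm(n, 0, sd_resid)
  data.frame(total_agb = y, X, stage_years = stages)
}

test_that("mixed model recovers a strong PD effect and ignores noise", {
  hits_pd <- 0; false_others <- 0
  for (seed in 1:25) {
    fm <- fit_mixed(sim_mixed_data(seed))
    tv <- fm$coefficients
    if (abs(tv$t[tv$predictor == "PD"]) > 2) hits_pd <- hits_pd + 1
    false_others <- false_others +
      sum(abs(tv$t[tv$predictor %in% c("PSR", "PSE", "NRI", "NTI")]) > 2)
  }
  expect_gte(hits_pd / 25, 0.9)
  expect_lte(false_others / (25 * 4), 0.15)
})

test_that("pure-noise responses rarely show significant predictors", {
  quiet <- 0
  for (seed in 1:15) {
    fm <- fit_mixed(sim_mixed_data(seed + 100, beta = rep(0, 5),
                                   sd_stage = 0))
    if (all(abs(fm$coefficients$t[-1]) < 2)) quiet <- quiet + 1
  }
  expect_gte(quiet / 15, 0.6)
})

test_that("R2m/R2c behave as the variance decomposition dictates", {
  # no stage variance: marginal and conditional R2 coincide (up to the
  # small spurious variance a boundary fit can pick up)
  gaps <- vapply(1:8, function(seed) {
    fm0 <- fit_mixed(sim_mixed_data(seed, sd_stage = 0))
    expect_gte(fm0$r2_conditional, fm0$r2_marginal)
    fm0$r2_conditional - fm0$r2_marginal
  }, numeric(1))
  expect_lt(mean(gaps), 0.05)
  # known variance shares 0.4 / 0.4 / 0.2 -> (R2m, R2c) ~ (0.4, 0.8)
  r2m <- c(); r2c <- c()
  for (seed in 1:10) {
    fm <- fit_mixed(sim_mixed_data(seed + 300,
                                   beta = c(PD = sqrt(0.4), PSR = 0,
                                            PSE = 0, NRI = 0, NTI = 0),
                                   sd_stage = sqrt(0.4),
                                   sd_resid = sqrt(0.2)))
    r2m <- c(r2m, fm$r2_marginal); r2c <- c(r2c, fm$r2_conditional)
  }
  expect_lt(abs(mean(r2m) - 0.4), 0.1)
  expect_lt(abs(mean(r2c) - 0.8), 0.1)
  expect_true(all(r2c >= r2m))
})

test_that("mixed-model coefficient estimates are unbiased for PD", {
  ests <- vapply(1:40, function(seed) {
    fm <- fit_mixed(sim_mixed_data(seed + 600))
    cf <- fm$coefficients
    cf$estimate[cf$predictor == "PD"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 1), 0.05)
})

test_that("AIC penalizes a superfluous noise predictor most of the time", {
  wins <- 0
  for (seed in 1:30) {
    d <- sim_mixed_data(seed + 900)
    d$noise <- rnorm(nrow(d))
    a_true <- fit_mixed(d, predictors = c("PD"))$AIC
    a_extra <- fit_mixed(d, predictors = c("PD", "noise"))$AIC
    if (a_true < a_extra) wins <- wins + 1
  }
  expect_gte(wins / 30, 0.7)
})

test_that("variance partition satisfies its algebraic identity", {
  set.seed(8)
  for (rep_i in 1:10) {
    n <- 60
    s1 <- data.frame(a = rnorm(n), b = rnorm(n))
    s2 <- data.frame(c = rnorm(n) + 0.5 * s1$a)
    y <- s1$a + 0.5 * s2$c + rnorm(n)
    vp <- variance_partition(y, s1, s2)
    expect_equal(vp$unique1 + vp$unique2 + vp$shared, vp$adj_r2_full,
                 tolerance = 1e-8)
    expect_equal(vp$residual, 1 - vp$adj_r2_full, tolerance = 1e-12)
  }
})

test_that("variance partition attributes orthogonal and null structure", {
  set.seed(17)
  n <- 200
  x1 <- rnorm(n)
  x2 <- rnorm(n)            # independent of x1 and of y
  y <- x1 + rnorm(n, 0, 0.5)
  vp <- variance_partition(y, data.frame(x1), data.frame(x2))
  expect_lt(abs(vp$unique2), 0.05)
  expect_lt(abs(vp$shared), 0.05)
  expect_gt(vp$unique1, 0.5)
  # pure noise response: every fraction near zero
  vp0 <- variance_partition(rnorm(n), data.frame(x1), data.frame(x2))
  expect_lt(abs(vp0$unique1), 0.05)
  expect_lt(abs(vp0$unique2), 0.05)
  expect_lt(abs(vp0$shared), 0.05)
  # correlated predictors share explained variance
  x3 <- 0.7 * x1 + sqrt(1 - 0.49) * rnorm(n)
  y2 <- x1 + x3 + rnorm(n, 0, 0.5)
  vp2 <- variance_partition(y2, data.frame(x1), data.frame(x3))
  expect_gt(vp2$shared, 0)
  expect_error(variance_partition(y, data.frame(x1, x1b = x1),
                                  data.frame(x2)), "collinear")
})

test_that("PLS-PM with single-indicator blocks equals OLS path analysis", {
  d <- simulate_path_data(n = 80, seed = 5)
  lat <- c("TVR", "WPD", "WPS", "AGB")
  paths <- matrix(0, 4, 4, dimnames = list(lat, lat))
  paths["TVR", "WPD"] <- paths["TVR", "WPS"] <- 1
  paths["WPD", "AGB"] <- paths["WPS", "AGB"] <- 1
  fit <- fit_plspm(d, blocks = list(TVR = "tvr", WPD = "PD", WPS = "NRI",
                                    AGB = "agb"),
                   paths = paths, n_boot = 0)
  z <- scale(d)
  ref_wpd <- coef(lm(z[, "PD"] ~ z[, "tvr"]))[2]
  ref_wps <- coef(lm(z[, "NRI"] ~ z[, "tvr"]))[2]
  ref_agb <- coef(lm(z[, "agb"] ~ z[, "PD"] + z[, "NRI"]))[2:3]
  pc <- fit$path_coefficients
  expect_equal(pc$estimate[pc$from == "TVR" & pc$to == "WPD"],
               unname(ref_wpd), tolerance = 1e-6)
  expect_equal(pc$estimate[pc$from == "TVR" & pc$to == "WPS"],
               unname(ref_wps), tolerance = 1e-6)
  expect_equal(pc$estimate[pc$from == "WPD" & pc$to == "AGB"],
               unname(ref_agb[1]), tolerance = 1e-6)
  expect_equal(pc$estimate[pc$from == "WPS" & pc$to == "AGB"],
               unname(ref_agb[2]), tolerance = 1e-6)
  # single-indicator blocks have communality 1
  expect_equal(unname(fit$communality), rep(1, 4), tolerance = 1e-9)
  expect_true(all(abs(pc$estimate) <= 1 + 1e-9))
})

test_that("GOF formula and recovery of known path coefficients", {
  expect_equal(plspm_gof(1, 0.49), 0.7, tolerance = 1e-12)
  expect_equal(plspm_gof(c(1, 1, 1), c(0.49, 0.49)), 0.7, tolerance = 1e-12)
  truth <- c(TVR_WPD = 0.6, TVR_WPS = -0.4, WPD_AGB = 0.6, WPS_AGB = -0.3)
  lat <- c("TVR", "WPD", "WPS", "AGB")
  paths <- matrix(0, 4, 4, dimnames = list(lat, lat))
  paths["TVR", "WPD"] <- paths["TVR", "WPS"] <- 1
  paths["WPD", "AGB"] <- paths["WPS", "AGB"] <- 1
  ok <- 0
  for (seed in 1:20) {
    d <- simulate_path_data(n = 48, coefs = truth, seed = seed)
    fit <- fit_plspm(d, blocks = list(TVR = "tvr", WPD = c("PD", "PSE"),
                                      WPS = "NRI", AGB = "agb"),
                     paths = paths, n_boot = 0)
    pc <- fit$path_coefficients
    est <- setNames(pc$estimate, paste(pc$from, pc$to, sep = "_"))
    # mean absolute path error: at n = 48 a single path estimate carries
    # sampling error ~ (1 - r^2)/sqrt(n) ~ 0.12, so the averaged error is
    # the stable recovery measure
    if (mean(abs(est[names(truth)] - truth)) < 0.15) ok <- ok + 1
    expect_gt(fit$r2["AGB"], 0)
  }
  expect_gte(ok / 20, 0.8)
})

test_that("bootstrap significance flags strong paths", {
  d <- simulate_path_data(n = 100, seed = 31)
  lat <- c("TVR", "WPD", "WPS", "AGB")
  paths <- matrix(0, 4, 4, dimnames = list(lat, lat))
  paths["TVR", "WPD"] <- paths["TVR", "WPS"] <- 1
  paths["WPD", "AGB"] <- paths["WPS", "AGB"] <- 1
  fit <- fit_plspm(d, blocks = list(TVR = "tvr", WPD = c("PD", "PSE"),
                                    WPS = "NRI", AGB = "agb"),
                   paths = paths, n_boot = 199, seed = 2)
  pc <- fit$path_coefficients
  expect_lt(pc$p[pc$from == "TVR" & pc$to == "WPD"], 0.05)
  expect_lt(pc$p[pc$from == "WPD" & pc$to == "AGB"], 0.05)
  # rerun with same seed: identical bootstrap SEs
  fit2 <- fit_plspm(d, blocks = list(TVR = "tvr", WPD = c("PD", "PSE"),
                                     WPS = "NRI", AGB = "agb"),
                    paths = paths, n_boot = 199, seed = 2)
  expect_equal(fit$path_coefficients$boot_se, fit2$path_coefficients$boot_se)
})
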