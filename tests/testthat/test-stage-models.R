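# a metric-table-shaped frame from the regression fixture, so model-layer
# tests run without the full pipeline
fixture_metrics <- function(beta, n_groups = 20, n_per_group = 100,
                            group_sd = 0.4, noise_sd = 1, seed = 1,
                            response = "nri", scale = 5, stage = "all") {
  dat <- simulate_regression_dataset(beta, noise_sd = noise_sd,
                                     n_groups = n_groups, group_sd = group_sd,
                                     n_per_group = n_per_group, seed = seed)
  out <- data.frame(scale = scale, stage = stage, quadrat = seq_len(nrow(dat)) - 1L)
  out[c("ci", "elevation", "aspect", "slope", "tpi", "tri", "flowdir", "sr")] <-
    dat[c("ci", "elevation", "aspect", "slope", "tpi", "tri", "flowdir", "sr")]
  out[[response]] <- dat$y   # after the predictors: "sr" may be the response
  out$dominant_species <- sprintf("g%02d", as.integer(dat$group))
  out$block <- as.integer(dat$group)
  out
}

test_that("designs carry the documented predictor sets and z-scored columns", {
  m_sr <- fixture_metrics(c(0, 0.5, rep(0, 7)), response = "sr")
  d_sr <- build_design(m_sr, "SR", 5, "all")
  expect_equal(length(d_sr$predictors), 7L)   # SR/PD model: 7 fixed predictors
  expect_false("sr" %in% d_sr$predictors)

  m_nri <- fixture_metrics(c(0, 0.5, rep(0, 7)), response = "nri")
  d_nri <- build_design(m_nri, "NRI", 5, "all")
  expect_equal(length(d_nri$predictors), 8L)  # NRI/NTI model adds SR
  expect_true("sr" %in% d_nri$predictors)

  for (p in d_nri$predictors) {
    expect_equal(mean(d_nri$data[[p]]), 0, tolerance = 1e-6)
    expect_equal(sd(d_nri$data[[p]]), 1, tolerance = 1e-6)
  }

  # roughness can be appended as an extra covariate
  m_nri$roughness <- rnorm(nrow(m_nri))
  d_r <- build_design(m_nri, "NRI", 5, "all", extra_predictors = "roughness")
  expect_true("roughness" %in% d_r$predictors)

  # undefined responses are dropped and counted; surviving rows unchanged
  m2 <- m_nri
  m2$nri[1:25] <- NA
  d2 <- build_design(m2, "NRI", 5, "all")
  expect_equal(d2$n_dropped, 25L)
  expect_equal(nrow(d2$data), nrow(m2) - 25L)
  d3 <- build_design(m2, "NRI", 5, "all")
  expect_equal(d2$data, d3$data)   # idempotent filter

  # refuses designs with fewer than 10 rows per predictor
  small <- m_nri[1:50, ]
  expect_error(build_design(small, "NRI", 5, "all"), "usable quadrats")
})

test_that("the mixed model recovers known coefficients within 3 SE", {
  beta <- c(0.2, 0.5, -0.3, 0, 0, 0.15, 0, 0, -0.25)
  m <- fixture_metrics(beta, n_groups = 25, n_per_group = 80, seed = 31)
  fit <- fit_lmm(build_design(m, "NRI", 5, "all"))
  expect_equal(fit$method, "lmm")
  expect_true(fit$converged)
  expect_equal(nrow(fit$coefficients), 9L)
  ok <- abs(fit$coefficients$estimate - beta) <= 3 * fit$coefficients$se
  expect_true(all(ok))
  expect_true(all(fit$coefficients$se > 0))
})

test_that("zero group variance falls back to OLS and matches it", {
  m <- fixture_metrics(c(0, 0.5, rep(0, 7)), group_sd = 0, seed = 32)
  des <- build_design(m, "NRI", 5, "all")
  expect_warning(fit <- fit_lmm(des), "boundary|singular")
  expect_equal(fit$method, "ols")
  expect_lt(fit$group_var, 0.05)
  ols <- lm(y ~ ci + elevation + aspect + slope + tpi + tri + flowdir + sr,
            data = des$data)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-10)
})

test_that("fits are invariant to row order and reject collinear designs", {
  m <- fixture_metrics(c(0.1, 0.4, rep(0, 7)), seed = 33)
  des <- build_design(m, "NRI", 5, "all")
  f1 <- fit_lmm(des)
  des2 <- des
  perm <- withr::with_seed(34, sample(nrow(des2$data)))
  des2$data <- des2$data[perm, ]
  f2 <- fit_lmm(des2)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f1$coefficients$se, f2$coefficients$se, tolerance = 1e-6)

  des3 <- des
  des3$data$tri <- des3$data$ci   # duplicate predictor
  expect_error(fit_lmm(des3), "collinear.*(tri|ci)")
})

test_that("coefficient grids tier p-values as a/b/c and tabulate fits", {
  expect_equal(significance_tier(c(0.2, 0.04, 0.004, 0.0004, NA)),
               c("ns", "a", "b", "c", NA))

  m <- fixture_metrics(c(0, 0.5, rep(0, 7)), seed = 35)
  fit <- fit_lmm(build_design(m, "NRI", 5, "all"))
  grid <- coefficient_grid(list(fit, fit))
  expect_equal(nrow(grid), 18L)
  expect_true(all(c("response", "scale", "stage", "term", "estimate", "se",
                    "p", "tier") %in% names(grid)))
  expect_equal(grid$tier[grid$term == "ci"][1], "c")  # 0.5 slope at n=2000
})

test_that("coefficient estimates are unbiased with near-nominal CI coverage", {
  beta <- c(0.1, 0.5, -0.3, 0.2, 0, 0, 0.15, 0, -0.25)
  n_rep <- 50
  est <- matrix(NA_real_, n_rep, 9)
  cover <- matrix(NA, n_rep, 9)
  for (r in seq_len(n_rep)) {
    m <- fixture_metrics(beta, n_groups = 20, n_per_group = 100,
                         group_sd = 0.4, seed = 1000 + r)
    fit <- suppressWarnings(fit_lmm(build_design(m, "NRI", 5, "all")))
    est[r, ] <- fit$coefficients$estimate
    hw <- qt(0.975, fit$coefficients$df) * fit$coefficients$se
    cover[r, ] <- abs(fit$coefficients$estimate - beta) <= hw
  }
  bias <- colMeans(est) - beta
  expect_lt(max(abs(bias)), 0.02)
  coverage <- mean(cover)
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.98)
})
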