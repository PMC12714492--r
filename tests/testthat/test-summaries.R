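# Posterior summary tables, derived probabilities and use maps.

# build a deterministic occufit shell for summary arithmetic
fake_fit <- function(chains) {
  structure(list(draws = chains,
                 iterations = seq_len(nrow(chains[[1]])),
                 latent = NULL, control = occu_control(seed = 1),
                 fixed = FALSE, elapsed = 0), class = "occufit")
}

mk_draws <- function(values_by_param, n) {
  m <- matrix(0, n, length(occuhier:::.PAR_NAMES),
              dimnames = list(NULL, occuhier:::.PAR_NAMES))
  for (pp in names(values_by_param)) m[, pp] <- values_by_param[[pp]]
  m
}

test_that("summary uses pooled means and interpolation quantiles", {
  # constant draws collapse to a point interval
  f <- fake_fit(list(mk_draws(list(b0 = 2), 200)))
  sm <- summary(f)
  expect_equal(sm$mean[sm$parameter == "b0"], 2)
  expect_equal(sm$lower[sm$parameter == "b0"], 2)
  expect_equal(sm$upper[sm$parameter == "b0"], 2)

  # draws 1..1000: the type-7 quantile convention
  f2 <- fake_fit(list(mk_draws(list(b1 = 1:1000), 1000)))
  sm2 <- summary(f2)
  expect_equal(sm2$lower[sm2$parameter == "b1"], 25.975)
  expect_equal(sm2$upper[sm2$parameter == "b1"], 975.025)

  # symmetric draws about zero do not exclude zero
  f3 <- fake_fit(list(mk_draws(list(b2 = c(-(1:100), 1:100)), 200)))
  sm3 <- summary(f3)
  expect_false(sm3$excludes_zero[sm3$parameter == "b2"])
  expect_true(sm3$excludes_zero[sm3$parameter == "b0"] == FALSE)
  # strictly positive draws do
  f4 <- fake_fit(list(mk_draws(list(b3 = 1:200 / 10), 200)))
  sm4 <- summary(f4)
  expect_true(sm4$excludes_zero[sm4$parameter == "b3"])

  # pooling across chains
  f5 <- fake_fit(list(mk_draws(list(b0 = rep(1, 100)), 100),
                      mk_draws(list(b0 = rep(3, 100)), 100)))
  expect_equal(summary(f5)$mean[1], 2)
  expect_equal(unname(coef(f5)["b0"]), 2)

  expect_error(summary(fake_fit(list(mk_draws(list(), 50)))),
               "at least 100")
})

test_that("derived probabilities at mean covariates are intercept links", {
  n <- 150
  f <- fake_fit(list(mk_draws(list(b0 = stats::qlogis(0.9),
                                   beta0x = stats::qlogis(0.8),
                                   beta0y = -0.2, beta1y = 0.6,
                                   d0y = stats::qlogis(0.342)), n)))
  occ <- at_mean_covariates(f, "grid_occupancy")
  expect_equal(occ$mean, 0.9, tolerance = 1e-12)
  det <- at_mean_covariates(f, "tiger_detection")
  expect_equal(det$mean, 0.342, tolerance = 1e-12)
  use <- at_mean_covariates(f, "tiger_use")
  expect_equal(nrow(use), 2)    # reported at prey use present and absent
  expect_equal(use$mean[1], stats::plogis(-0.2 + 0.6), tolerance = 1e-12)
  expect_equal(use$mean[2], stats::plogis(-0.2), tolerance = 1e-12)
  # monotone in the intercept draw
  f2 <- fake_fit(list(mk_draws(list(b0 = stats::qlogis(0.9) + 0.5), n)))
  expect_gt(at_mean_covariates(f2, "grid_occupancy")$mean, occ$mean)
  expect_error(at_mean_covariates(f, "nope"))
})

test_that("posterior prediction averages the link over the draws", {
  n <- 120
  f <- fake_fit(list(mk_draws(list(b0 = stats::qlogis(0.9), b1 = 1.42),
                              n)))
  nd <- data.frame(prey_km = c(0, 1), ndvi = 0, hpd = 0, elev = 0)
  pr <- predict(f, nd, "grid_occupancy")
  expect_equal(pr$mean, stats::plogis(stats::qlogis(0.9) + 1.42 * c(0, 1)),
               tolerance = 1e-12)
  expect_equal(pr$lower, pr$upper)   # constant draws, point interval
  # tiger use requires the prey-use indicator
  expect_error(predict(f, data.frame(ndvi = 0, hpd = 0, elev = 0),
                       "tiger_use"), "prey_use")
  # with genuine posterior spread, intervals bracket the mean
  f2 <- fake_fit(list(mk_draws(list(d0y = rnorm(n, -0.65, 0.1)), n)))
  pr2 <- predict(f2, data.frame(ndvi = 0, elev = 0), "tiger_detection")
  expect_lt(pr2$lower, pr2$mean)
  expect_gt(pr2$upper, pr2$mean)
})

test_that("use maps are posterior latent frequencies with forced cells", {
  d <- standardize_covariates(tiny_survey(),
                              grid_fields = c("prey_km", "ndvi"),
                              subgrid_fields = c("ndvi", "hpd"))
  ctl <- occu_control(iterations = 600, chains = 2, thin = 2,
                      burn_in = 100, seed = 12)
  fit <- occu_fit(d, ctl)
  map <- use_map(fit)
  expect_true(all(map$subgrids$p_tiger_use >= 0 &
                    map$subgrids$p_tiger_use <= 1))
  expect_true(all(map$grids$p_occupancy >= 0 & map$grids$p_occupancy <= 1))
  # subgrid s1 has a tiger detection: use probability exactly 1, and its
  # grid is certainly occupied
  expect_equal(map$subgrids$p_tiger_use[map$subgrids$subgrid_id == "s1"], 1)
  expect_equal(map$grids$p_occupancy[map$grids$grid_id == "A"], 1)
  # prey detections force prey use
  expect_equal(map$subgrids$p_prey_use[map$subgrids$subgrid_id == "s1"], 1)
  expect_equal(map$subgrids$p_prey_use[map$subgrids$subgrid_id == "s3"], 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_use_map(map, f)
  back <- utils::read.csv(f)
  expect_equal(back$p_tiger_use, map$subgrids$p_tiger_use,
               tolerance = 1e-12)
})

test_that("zero-effort cells revert to the prior under fixed params", {
  # intercept-only model, no data: posterior use equals the prior link
  g <- data.frame(grid_id = "A", prey_km = 0, ndvi = 0, hpd = 0, elev = 0,
                  surveyed = TRUE)
  s <- data.frame(subgrid_id = c("u1", "u2"), grid_id = "A",
                  effort = 0L, tiger_det = 0L, prey_det = 0L,
                  ndvi = 0, hpd = 0, elev = 0)
  d <- survey_data(g, s)
  p <- occu_params(b0 = 3, beta0y = -0.4, beta0x = 0.6)
  ctl <- occu_control(iterations = 4000, chains = 2, thin = 2,
                      burn_in = 500, seed = 7)
  fit <- occu_fit(d, ctl, fixed_params = p, check_standardized = FALSE)
  map <- use_map(fit)
  post <- enumerate_latent_posterior(p, d)
  mc_se <- 3 / sqrt(nrow(fit$draws[[1]]))   # generous MC allowance
  expect_lt(max(abs(map$subgrids$p_tiger_use - post$zy)), mc_se)
  expect_lt(max(abs(map$subgrids$p_prey_use - post$zx)), mc_se)
})

test_that("pooled and per-chain latent means agree on converged fits", {
  d <- standardize_covariates(tiny_survey(),
                              grid_fields = c("prey_km", "ndvi"),
                              subgrid_fields = c("ndvi", "hpd"))
  ctl <- occu_control(iterations = 3000, chains = 3, thin = 3,
                      burn_in = 500, seed = 9)
  fit <- occu_fit(d, ctl, fixed_params = tiny_params(),
                  check_standardized = FALSE)
  # compare the pooled posterior mean of Z with the enumeration posterior
  post <- enumerate_latent_posterior(tiny_params(), d)
  expect_lt(max(abs(fit$latent$Z - post$Z)), 0.05)
})
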