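# Link functions, complete-data likelihood and the enumeration oracle.

test_that("inverse logit is exact, saturating and self-complementary", {
  expect_equal(inv_logit(0), 0.5)
  expect_lt(inv_logit(-50), 1e-20)
  expect_equal(inv_logit(-50), exp(-50), tolerance = 1e-10)
  expect_equal(inv_logit(1.42), 1 / (1 + exp(-1.42)), tolerance = 1e-15)
  expect_equal(round(inv_logit(1.42), 4), 0.8053)
  x <- seq(-30, 30, length.out = 101)
  expect_equal(inv_logit(-x), 1 - inv_logit(x), tolerance = 1e-12)
  expect_true(all(inv_logit(x) > 0 & inv_logit(x) < 1))
  expect_error(inv_logit(Inf), "finite")
})

test_that("linear predictors follow the two-scale model structure", {
  g <- data.frame(prey_km = 1, ndvi = 0, hpd = 0, elev = 0)
  expect_equal(grid_occupancy_prob(occu_params(), g), 0.5)
  expect_equal(grid_occupancy_prob(occu_params(b1 = 1.42), g),
               inv_logit(1.42))
  # covariates at the scale mean reduce the predictor to its intercept
  g0 <- data.frame(prey_km = 0, ndvi = 0, hpd = 0, elev = 0)
  expect_equal(grid_occupancy_prob(occu_params(b0 = 1.3, b1 = 9), g0),
               inv_logit(1.3))

  s <- data.frame(ndvi = 0, hpd = 0, elev = 0)
  p <- occu_params(beta1y = 0.570)
  expect_equal(subgrid_use_prob(p, s, "tiger", prey_use = 1),
               inv_logit(0.570))
  expect_equal(subgrid_use_prob(p, s, "tiger", prey_use = 0), 0.5)
  expect_error(subgrid_use_prob(p, s, "tiger"), "prey_use")
  # prey use never sees the prey-use indicator
  expect_equal(subgrid_use_prob(p, s, "prey"),
               subgrid_use_prob(occu_params(beta1y = -3), s, "prey"))

  # detection responds to NDVI and elevation in the reported directions
  sv <- data.frame(ndvi = c(-1, 0, 1), hpd = 0, elev = 0)
  pt <- detection_prob(occu_params(d1y = 0.15), sv, "tiger")
  expect_true(all(diff(pt) > 0))
  se <- data.frame(ndvi = 0, hpd = 0, elev = c(-1, 0, 1))
  pp <- detection_prob(occu_params(d2x = -0.65), se, "prey")
  expect_true(all(diff(pp) < 0))
  # effort never enters the detection predictor
  expect_equal(detection_prob(occu_params(d0y = 0.3),
                              cbind(se, effort = c(0, 5, 400)), "tiger"),
               rep(inv_logit(0.3), 3))
})

test_that("parameter vectors are validated and serialize losslessly", {
  expect_error(occu_params(nosuch = 1), "unknown coefficient")
  expect_error(occu_params(b0 = Inf), "finite")
  p <- default_true_params()
  f <- withr::local_tempfile(fileext = ".txt")
  write_params(p, f)
  expect_equal(unclass(read_params(f)), unclass(p), tolerance = 1e-15)
})

test_that("complete-data log likelihood matches hand computation", {
  # one grid, one subgrid, all coefficients 0, all latent on, n=2, y=1, x=0:
  # three Bernoulli(0.5) latent masses, Binom(1; 2, 0.5) and Binom(0; 2, 0.5)
  d <- one_cell_survey(effort = 2L, tiger_det = 1L, prey_det = 0L)
  lat <- latent_state(Z = 1, zx = 1, zy = 1)
  ll <- complete_data_loglik(occu_params(), lat, d)
  expect_equal(ll, 3 * log(0.5) + log(2 * 0.25) + log(0.25),
               tolerance = 1e-12)

  # impossible observation under a closed gate
  lat0 <- latent_state(Z = 1, zx = 1, zy = 0)
  expect_identical(complete_data_loglik(occu_params(), lat0, d), -Inf)
  # under tiger gating, Z=0 also forbids the tiger detection
  latz <- latent_state(Z = 0, zx = 1, zy = 1)
  expect_identical(complete_data_loglik(occu_params(), latz, d,
                                        "tiger_gated"), -Inf)
  # ... but under the printed layout Z gates prey, and x=0 is possible
  expect_true(is.finite(complete_data_loglik(occu_params(), latz, d,
                                             "as_printed")))

  # empty dataset
  e <- survey_data(
    data.frame(grid_id = character(0), prey_km = numeric(0),
               ndvi = numeric(0), hpd = numeric(0), elev = numeric(0),
               surveyed = logical(0)),
    data.frame(subgrid_id = character(0), grid_id = character(0),
               effort = integer(0), tiger_det = integer(0),
               prey_det = integer(0), ndvi = numeric(0), hpd = numeric(0),
               elev = numeric(0)))
  expect_identical(
    complete_data_loglik(occu_params(),
                         latent_state(integer(0), integer(0), integer(0)),
                         e), 0)
  expect_error(complete_data_loglik(occu_params(),
                                    latent_state(1, c(1, 0), c(1, 1)), d),
               "dimensions")
})

test_that("gating modes swap which species grid occupancy silences", {
  d <- one_cell_survey(effort = 3L, tiger_det = 0L, prey_det = 2L)
  lat <- latent_state(Z = 0, zx = 1, zy = 1)
  # prey detections possible when Z only gates the tiger side
  expect_true(is.finite(complete_data_loglik(occu_params(), lat, d,
                                             "tiger_gated")))
  expect_identical(complete_data_loglik(occu_params(), lat, d,
                                        "as_printed"), -Inf)
  expect_identical(complete_data_loglik(occu_params(), lat, d,
                                        "both_gated"), -Inf)
})

test_that("brute-force marginal equals the explicit latent sum", {
  d <- tiny_survey()
  p <- tiny_params()
  for (gt in c("tiger_gated", "as_printed", "both_gated")) {
    # independent direct sum over all 2^10 configurations
    total <- -Inf
    for (code in 0:(2^10 - 1)) {
      bits <- as.integer(intToBits(code))[1:10]
      lat <- latent_state(Z = bits[1:2], zx = bits[3:6], zy = bits[7:10])
      ll <- complete_data_loglik(p, lat, d, gt)
      if (is.finite(ll)) {
        m <- max(total, ll)
        total <- m + log(exp(total - m) + exp(ll - m))
      }
    }
    expect_equal(marginal_loglik_bruteforce(p, d, gt), total,
                 tolerance = 1e-10)
  }
  # likelihood rises when detections agree with a high detection rate
  d1 <- one_cell_survey(effort = 4L, tiger_det = 1L)
  d3 <- one_cell_survey(effort = 4L, tiger_det = 3L)
  hi <- occu_params(b0 = 2, beta0y = 2, d0y = 2)
  expect_gt(marginal_loglik_bruteforce(hi, d3),
            marginal_loglik_bruteforce(hi, d1))
  # instance guard
  des <- sim_design(n_grids = 4, subgrids_per_grid = 5, seed = 1)
  big <- simulate_survey(des)$data
  expect_error(marginal_loglik_bruteforce(tiny_params(), big),
               "enumeration guard")
})

test_that("forced latent states collapse the marginal to one term", {
  # strong detections force Z = zx = zy = 1; only one configuration is
  # possible and the marginal equals its complete-data likelihood
  d <- one_cell_survey(effort = 5L, tiger_det = 2L, prey_det = 3L)
  p <- tiny_params()
  lat <- latent_state(1, 1, 1)
  expect_equal(marginal_loglik_bruteforce(p, d),
               complete_data_loglik(p, lat, d), tolerance = 1e-12)
  post <- enumerate_latent_posterior(p, d)
  expect_equal(post$Z, 1)
  expect_equal(post$zx, 1)
  expect_equal(post$zy, 1)
})
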