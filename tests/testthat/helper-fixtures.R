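# Shared fixtures, built in code.

# minimal valid two-grid survey on the model (standardized) scale
tiny_survey <- function() {
  g <- data.frame(grid_id = c("A", "B"), prey_km = c(0.5, -0.5),
                  ndvi = c(0.2, -0.2), hpd = c(0.1, -0.1),
                  elev = c(0.3, -0.3), surveyed = TRUE)
  s <- data.frame(subgrid_id = paste0("s", 1:4),
                  grid_id = rep(c("A", "B"), each = 2),
                  effort = c(3L, 2L, 4L, 0L), tiger_det = c(1L, 0L, 0L, 0L),
                  prey_det = c(2L, 0L, 1L, 0L),
                  ndvi = c(0.1, -0.3, 0.5, 0), hpd = c(0, 0.2, -0.1, 0),
                  elev = c(0.3, 0, -0.2, 0))
  survey_data(g, s)
}

# a single grid with one subgrid; everything at the covariate mean
one_cell_survey <- function(effort = 2L, tiger_det = 1L, prey_det = 0L) {
  g <- data.frame(grid_id = "A", prey_km = 0, ndvi = 0, hpd = 0, elev = 0,
                  surveyed = TRUE)
  s <- data.frame(subgrid_id = "A_1", grid_id = "A", effort = effort,
                  tiger_det = tiger_det, prey_det = prey_det,
                  ndvi = 0, hpd = 0, elev = 0)
  survey_data(g, s)
}

# non-trivial parameter vector used across sampler tests
tiny_params <- function() {
  occu_params(b0 = 0.5, b1 = 1, beta0x = 0.3, beta3x = -0.5,
              beta0y = -0.2, beta1y = 0.6, d0y = -0.5, d1y = 0.2,
              d0x = 0.2, d2x = -0.3)
}

# the shipped buffer-zone contingency tables
fixture_tables <- function() rescue_tables()
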