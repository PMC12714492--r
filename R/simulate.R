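# Synthetic survey generator for simulation-based validation.
#
# Emulates the motivating study design: 62 grids of 10 x 10 km, each split
# into 25 subgrids of 2 x 2 km, standard-normal covariates, covariate-driven
# latent occupancy and use, and binomial sign detections on a number of
# 100-m segments drawn from an empirical-style effort distribution capped at
# 40 km of trail per grid.

#' Plausible coefficient preset
#'
#' Coefficients in the regime the model is intended for: grid occupancy
#' ~0.90, prey use ~0.80 and predator use ~0.46 at covariate means,
#' per-segment detection ~0.34 (predator) and ~0.62 (prey), a strong
#' positive prey effect on grid occupancy and negative human-population and
#' elevation effects on subgrid use.
#'
#' @return an [occu_params()] vector.
#' @export
default_true_params <- function() {
  occu_params(
    b0 = stats::qlogis(0.90), b1 = 1.42, b2 = -0.852, b3 = -0.841,
    b4 = -0.784,
    beta0x = stats::qlogis(0.80), beta2x = 0.1, beta3x = -0.5,
    beta4x = -0.6,
    beta0y = stats::qlogis(0.46), beta1y = 0.570, beta2y = 0.583,
    beta3y = -0.664, beta4y = -1.264,
    d0y = stats::qlogis(0.342), d1y = 0.15, d2y = 0.42,
    d0x = stats::qlogis(0.62), d1x = 0.43, d2x = -0.65)
}

#' Default per-subgrid effort distribution
#'
#' Discrete distribution of the number of 100-m segments surveyed in one
#' subgrid: point mass at 0 (subgrids the teams never reached) and a
#' geometrically decaying spread over 1-16 segments. The support cap of 16
#' guarantees a 25-subgrid grid never exceeds the 400-segment (40 km) trail
#' budget.
#'
#' @param p_zero probability of an unvisited subgrid.
#' @param decay geometric decay rate of the positive part.
#' @param max_segments largest per-subgrid effort.
#' @return data.frame with columns `segments`, `prob`.
#' @export
default_effort_dist <- function(p_zero = 0.25, decay = 1 / 8,
                                max_segments = 16L) {
  k <- seq_len(max_segments)
  w <- exp(-decay * k)
  data.frame(segments = c(0L, k),
             prob = c(p_zero, (1 - p_zero) * w / sum(w)))
}

#' Simulation design
#'
#' @param n_grids number of large grids.
#' @param subgrids_per_grid subgrids per grid (<= 25).
#' @param true_params generating [occu_params()] vector.
#' @param effort_dist data.frame `segments`/`prob` (see
#'   [default_effort_dist()]).
#' @param frac_unsurveyed expected fraction of grids never visited (effort
#'   0, prey covariate missing; mirrors 5 unvisited grids out of 62).
#' @param rho_ndvi_hpd correlation induced between subgrid NDVI and HPD
#'   (0 = independent covariates).
#' @param gating a [gating_mode()].
#' @param seed integer seed.
#' @return a classed design list.
#' @export
sim_design <- function(n_grids = 62L, subgrids_per_grid = 25L,
                       true_params = default_true_params(),
                       effort_dist = default_effort_dist(),
                       frac_unsurveyed = 5 / 62, rho_ndvi_hpd = 0,
                       gating = gating_mode(), seed = 1L) {
  stopifnot(n_grids >= 1, subgrids_per_grid >= 1, subgrids_per_grid <= 25,
            all(effort_dist$prob >= 0), sum(effort_dist$prob) > 0,
            frac_unsurveyed >= 0, frac_unsurveyed < 1,
            abs(rho_ndvi_hpd) < 1)
  if (max(effort_dist$segments) * subgrids_per_grid > 400)
    stop("effort distribution can exceed the 400-segment per-grid budget")
  structure(list(n_grids = as.integer(n_grids),
                 subgrids_per_grid = as.integer(subgrids_per_grid),
                 true_params = .as_params(true_params),
                 effort_dist = effort_dist,
                 frac_unsurveyed = frac_unsurveyed,
                 rho_ndvi_hpd = rho_ndvi_hpd,
                 gating = gating_mode(gating), seed = as.integer(seed)),
            class = "sim_design")
}

# queen (8-neighbour) adjacency of grids laid on a near-square lattice
.lattice_adjacency <- function(grid_ids) {
  n <- length(grid_ids)
  ncol <- ceiling(sqrt(n))
  row <- (seq_len(n) - 1L) %/% ncol
  col <- (seq_len(n) - 1L) %% ncol
  pairs <- NULL
  for (i in seq_len(n)) {
    nb <- which(abs(row - row[i]) <= 1 & abs(col - col[i]) <= 1 &
                  seq_len(n) != i)
    if (length(nb))
      pairs <- rbind(pairs, data.frame(grid_id = grid_ids[i],
                                       neighbor_id = grid_ids[nb]))
  }
  pairs
}

#' Generate standard-normal covariate tables
#'
#' Independent standard-normal NDVI, HPD and elevation at the subgrid scale
#' (optionally with an induced NDVI-HPD correlation); grid covariates are
#' the means of their member subgrids; the grid prey covariate is standard
#' normal. Values are on the model (standardized) scale by construction and
#' are re-standardized exactly during simulation.
#'
#' @param design a [sim_design()] (its `seed` drives the draw).
#' @return list with raw `grids` and `subgrids` data.frames.
#' @export
generate_covariates <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  G <- design$n_grids; spg <- design$subgrids_per_grid; S <- G * spg
  gid <- sprintf("G%03d", seq_len(G))
  sgid <- sprintf("%s_S%02d", rep(gid, each = spg), rep(seq_len(spg), G))
  ndvi <- stats::rnorm(S)
  rho <- design$rho_ndvi_hpd
  hpd <- rho * ndvi + sqrt(1 - rho^2) * stats::rnorm(S)
  elev <- stats::rnorm(S)
  subgrids <- data.frame(subgrid_id = sgid, grid_id = rep(gid, each = spg),
                         ndvi = ndvi, hpd = hpd, elev = elev)
  agg <- function(v) as.numeric(tapply(v, rep(seq_len(G), each = spg),
                                       mean))
  grids <- data.frame(grid_id = gid, prey_km = stats::rnorm(G),
                      ndvi = agg(ndvi), hpd = agg(hpd), elev = agg(elev))
  list(grids = grids, subgrids = subgrids)
}

#' Simulate a two-scale sign survey
#'
#' Draws covariates, latent occupancy/use states and binomial detections
#' under the generating coefficients, samples per-subgrid effort from the
#' design's effort distribution, and marks a random subset of grids
#' unsurveyed (all efforts 0, prey covariate missing — to be filled by
#' [impute_prey()] with the returned lattice adjacency). Identical seeds
#' give identical datasets.
#'
#' @param design a [sim_design()].
#' @param seed overrides `design$seed` when given.
#' @return object of class `occu_sim`: list with the standardized
#'   [survey_data()] (`$data`), the true [latent_state()] (`$latent`), the
#'   generating parameters (`$params`), the queen `$adjacency` table and
#'   the design echo.
#' @export
simulate_survey <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) design$seed <- as.integer(seed)
  cov <- generate_covariates(design)       # seeds the stream
  G <- design$n_grids; spg <- design$subgrids_per_grid; S <- G * spg
  p <- design$true_params
  gating <- design$gating

  grids <- cov$grids
  subgrids <- cov$subgrids
  subgrids$effort <- 0L
  subgrids$tiger_det <- 0L
  subgrids$prey_det <- 0L
  subgrids$in_buffer <- FALSE
  grids$surveyed <- TRUE
  data <- survey_data(grids, subgrids)
  data <- standardize_covariates(data)

  # latent truth from the standardized covariates
  psi <- grid_occupancy_prob(p, data$grids)
  Z <- stats::rbinom(G, 1, psi)
  psix <- subgrid_use_prob(p, data$subgrids, "prey")
  zx <- stats::rbinom(S, 1, psix)
  psiy <- subgrid_use_prob(p, data$subgrids, "tiger", prey_use = zx)
  zy <- stats::rbinom(S, 1, psiy)

  # effort, with a subset of grids never visited
  n_un <- round(design$frac_unsurveyed * G)
  unsurveyed <- if (n_un > 0) sample(seq_len(G), n_un) else integer(0)
  eff <- sample(design$effort_dist$segments, S, replace = TRUE,
                prob = design$effort_dist$prob)
  eff[data$subgrids$grid_id %in% data$grids$grid_id[unsurveyed]] <- 0L
  data$subgrids$effort <- as.integer(eff)
  data$grids$surveyed[unsurveyed] <- FALSE
  data$grids$prey_km[unsurveyed] <- NA_real_

  gi <- match(data$subgrids$grid_id, data$grids$grid_id)
  ga <- .gates(Z[gi], zx, zy, gating)
  px <- detection_prob(p, data$subgrids, "prey")
  py <- detection_prob(p, data$subgrids, "tiger")
  data$subgrids$prey_det <- as.integer(stats::rbinom(S, eff, px * ga$x))
  data$subgrids$tiger_det <- as.integer(stats::rbinom(S, eff, py * ga$y))

  structure(list(data = data, latent = latent_state(Z, zx, zy),
                 params = p, adjacency = .lattice_adjacency(grids$grid_id),
                 design = design), class = "occu_sim")
}

#' @export
print.occu_sim <- function(x, ...) {
  cat("Simulated two-scale survey (seed ", x$design$seed, ")\n", sep = "")
  cat("  occupied grids:", sum(x$latent$Z), "/", length(x$latent$Z),
      " prey-use subgrids:", sum(x$latent$zx),
      " tiger-use subgrids:", sum(x$latent$zy), "\n")
  print(x$data)
  invisible(x)
}

#' Write a simulated survey with its truth sidecar
#'
#' Emits the standard survey/grid/adjacency CSV schemas plus a truth
#' sidecar (latent states per cell) and the generating coefficients, so a
#' simulation can be re-analyzed from files alone.
#'
#' @param sim an `occu_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "occu_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("subgrids.csv", "grids.csv", "adjacency.csv",
                        "truth_latent.csv", "truth_params.txt"))
  write_survey(sim$data, f[1], f[2])
  utils::write.csv(sim$adjacency, f[3], row.names = FALSE)
  truth <- data.frame(subgrid_id = sim$data$subgrids$subgrid_id,
                      z_prey = sim$latent$zx, z_tiger = sim$latent$zy)
  truth$Z_grid <- sim$latent$Z[match(sim$data$subgrids$grid_id,
                                     sim$data$grids$grid_id)]
  utils::write.csv(truth, f[4], row.names = FALSE)
  write_params(sim$params, f[5])
  invisible(f)
}

#' Parameter-recovery experiment
#'
#' The model's own validation loop: repeatedly simulate a survey from known
#' coefficients, fit it, and record per-coefficient posterior mean, 95%
#' credible interval coverage of the truth, and convergence. Mirrors the
#' simulate-then-refit check used to validate the original analysis.
#'
#' @param design a [sim_design()].
#' @param control an [occu_control()] for the fits.
#' @param replicates number of simulate/fit cycles.
#' @param seed base seed; replicate `r` simulates with `seed + r - 1`.
#' @return a `recovery_report`: data.frame per coefficient with `truth`,
#'   `bias`, `rmse`, `coverage`; per-replicate convergence in attribute
#'   `"replicates"`.
#' @export
recovery_experiment <- function(design, control = occu_control(),
                                replicates = 20L, seed = 1L) {
  stopifnot(replicates >= 1)
  if (control$iterations <= control$burn_in)
    stop("sampler configuration retains no draws")
  truth <- design$true_params
  cover <- bias <- matrix(NA_real_, replicates, length(.PAR_NAMES),
                          dimnames = list(NULL, .PAR_NAMES))
  reps <- data.frame(replicate = seq_len(replicates), max_rhat = NA_real_,
                     converged = NA)
  for (r in seq_len(replicates)) {
    sim <- tryCatch(simulate_survey(design, seed = seed + r - 1L),
                    error = function(e)
                      stop("replicate ", r, " failed in simulation: ",
                           conditionMessage(e)))
    dat <- impute_prey(sim$data, sim$adjacency)
    ctl <- control
    ctl$seed <- as.integer(seed + 1000L * r)
    fit <- tryCatch(occu_fit(dat, ctl),
                    error = function(e)
                      stop("replicate ", r, " failed in fitting: ",
                           conditionMessage(e)))
    sm <- summary(fit)
    cover[r, ] <- truth >= sm$lower & truth <= sm$upper
    bias[r, ] <- sm$mean - truth
    if (!is.null(fit$rhat)) {
      reps$max_rhat[r] <- max(fit$rhat$rhat)
      reps$converged[r] <- attr(fit$rhat, "converged")
    }
  }
  out <- data.frame(parameter = .PAR_NAMES, truth = unname(truth),
                    bias = colMeans(bias), rmse = sqrt(colMeans(bias^2)),
                    coverage = colMeans(cover), row.names = NULL)
  attr(out, "replicates") <- reps
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' @export
print.recovery_report <- function(x, digits = 3, ...) {
  cat("Parameter recovery over", nrow(attr(x, "replicates")),
      "replicates\n")
  y <- x
  for (cc in c("truth", "bias", "rmse", "coverage"))
    y[[cc]] <- round(y[[cc]], digits)
  print.data.frame(y, row.names = FALSE)
  r <- attr(x, "replicates")
  if (!all(is.na(r$converged)))
    cat("converged replicates:", sum(r$converged, na.rm = TRUE), "/",
        nrow(r), "\n")
  invisible(x)
}
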