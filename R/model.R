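# The two-scale occupancy model.
#
# Latent structure: grid occupancy Z_i ~ Bern(psi_i); prey subgrid use
# z_x_ij ~ Bern(psix_ij); predator subgrid use z_y_ij ~ Bern(psiy_ij), where
# psiy depends on z_x_ij. Detections on n_ij segments are binomial with a
# success probability gated by the latent indicators. All four linear
# predictors are on the logit scale with standardized covariates.

.PAR_NAMES <- c("b0", "b1", "b2", "b3", "b4",
                "beta0x", "beta2x", "beta3x", "beta4x",
                "beta0y", "beta1y", "beta2y", "beta3y", "beta4y",
                "d0y", "d1y", "d2y",
                "d0x", "d1x", "d2x")

.PAR_BLOCKS <- list(
  grid_occupancy = c("b0", "b1", "b2", "b3", "b4"),
  prey_use = c("beta0x", "beta2x", "beta3x", "beta4x"),
  tiger_use = c("beta0y", "beta1y", "beta2y", "beta3y", "beta4y"),
  tiger_detection = c("d0y", "d1y", "d2y"),
  prey_detection = c("d0x", "d1x", "d2x"))

#' Model coefficient vector
#'
#' Builds the full named coefficient vector of the four logistic linear
#' predictors: grid occupancy (`b0` intercept, `b1` prey, `b2` NDVI, `b3`
#' HPD, `b4` elevation), prey subgrid use (`beta0x`, `beta2x` NDVI, `beta3x`
#' HPD, `beta4x` elevation), predator subgrid use (`beta0y`, `beta1y`
#' prey-use indicator, `beta2y` NDVI, `beta3y` HPD, `beta4y` elevation), and
#' the two detection predictors (`d0y`,`d1y`,`d2y` and `d0x`,`d1x`,`d2x`:
#' intercept, NDVI, elevation). Unspecified coefficients are 0.
#'
#' @param ... named coefficients from the list above.
#' @return named numeric vector of length 20, class `occu_params`.
#' @export
occu_params <- function(...) {
  p <- stats::setNames(numeric(length(.PAR_NAMES)), .PAR_NAMES)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .PAR_NAMES)
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown coefficient name(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- unlist(dots)
  }
  if (any(!is.finite(p))) stop("coefficients must be finite")
  class(p) <- "occu_params"
  p
}

.as_params <- function(params) {
  if (inherits(params, "occu_params")) return(unclass(params))
  p <- unclass(params)
  if (is.null(names(p)) || !all(.PAR_NAMES %in% names(p)))
    stop("params must be an occu_params vector or carry all coefficient names")
  p[.PAR_NAMES]
}

#' Gating modes for the detection layer
#'
#' Controls which latent indicators multiply each species' detection
#' probability. Under `tiger_gated` (default) predator detections require
#' both grid occupancy and predator subgrid use (`p * Z * z_y`) while prey
#' detections require prey use only (`p * z_x`): grid occupancy is a
#' predator-level state, so it gates the predator's detections. Under
#' `as_printed` the roles swap (`p * Z * z_x` for prey, `p * z_y` for the
#' predator), matching the equation layout some model statements use.
#' `both_gated` multiplies both species' detections by `Z` for sensitivity
#' analysis.
#'
#' @param mode one of `"tiger_gated"`, `"as_printed"`, `"both_gated"`.
#' @return the validated mode string.
#' @export
gating_mode <- function(mode = c("tiger_gated", "as_printed", "both_gated")) {
  match.arg(mode)
}

# gate multipliers per subgrid, given grid occupancy mapped to subgrids
.gates <- function(Zsub, zx, zy, gating) {
  switch(gating,
         tiger_gated = list(x = zx, y = Zsub * zy),
         as_printed = list(x = Zsub * zx, y = zy),
         both_gated = list(x = Zsub * zx, y = Zsub * zy))
}

#' Numerically safe inverse logit
#'
#' @param x real vector.
#' @return `1/(1 + exp(-x))`, computed without overflow for large `|x|`.
#' @export
inv_logit <- function(x) {
  if (any(!is.finite(x))) stop("inv_logit requires finite input")
  stats::plogis(x)
}

# Design matrices and observation vectors, precomputed once per fit.
# Grid order follows data$grids; subgrids carry an integer grid index.
.model_frames <- function(data) {
  g <- data$grids
  s <- data$subgrids
  gi <- match(s$grid_id, g$grid_id)
  list(
    Xg = cbind(1, g$prey_km, g$ndvi, g$hpd, g$elev),
    Xu = cbind(1, s$ndvi, s$hpd, s$elev),          # prey use
    Xd = cbind(1, s$ndvi, s$elev),                 # both detection layers
    n = as.numeric(s$effort),
    y = as.numeric(s$tiger_det),
    x = as.numeric(s$prey_det),
    gi = gi, G = nrow(g), S = nrow(s))
}

# linear predictors given a parameter vector; zx needed for the tiger-use
# layer. Returns probabilities.
.link_probs <- function(p, fr, zx = NULL) {
  out <- list(
    psi = stats::plogis(drop(fr$Xg %*% p[.PAR_BLOCKS$grid_occupancy])),
    psix = stats::plogis(drop(fr$Xu %*% p[.PAR_BLOCKS$prey_use])),
    py = stats::plogis(drop(fr$Xd %*% p[.PAR_BLOCKS$tiger_detection])),
    px = stats::plogis(drop(fr$Xd %*% p[.PAR_BLOCKS$prey_detection])))
  if (!is.null(zx)) {
    eta <- p["beta0y"] + p["beta1y"] * zx + p["beta2y"] * fr$Xu[, 2] +
      p["beta3y"] * fr$Xu[, 3] + p["beta4y"] * fr$Xu[, 4]
    out$psiy <- stats::plogis(eta)
  }
  out
}

#' Grid occupancy probability
#'
#' Inverse-logit of the grid-scale linear predictor
#' `b0 + b1*prey + b2*ndvi + b3*hpd + b4*elev` (vectorized over grids).
#'
#' @param params [occu_params()] vector.
#' @param grids grid data.frame with standardized `prey_km`, `ndvi`, `hpd`,
#'   `elev`.
#' @return occupancy probabilities, one per grid.
#' @export
grid_occupancy_prob <- function(params, grids) {
  p <- .as_params(params)
  v <- cbind(1, grids$prey_km, grids$ndvi, grids$hpd, grids$elev)
  if (any(!is.finite(v))) stop("non-finite grid covariate")
  stats::plogis(drop(v %*% p[.PAR_BLOCKS$grid_occupancy]))
}

#' Subgrid use probability
#'
#' Prey use depends on subgrid NDVI, HPD and elevation only; predator use
#' additionally shifts by `beta1y` when the subgrid's prey-use indicator is
#' 1.
#'
#' @param params [occu_params()] vector.
#' @param subgrids subgrid data.frame with standardized covariates.
#' @param species `"prey"` or `"tiger"`.
#' @param prey_use binary prey-use indicator(s), required for
#'   `species = "tiger"` and ignored for prey.
#' @return use probabilities, one per subgrid.
#' @export
subgrid_use_prob <- function(params, subgrids, species = c("prey", "tiger"),
                             prey_use = NULL) {
  p <- .as_params(params)
  species <- match.arg(species)
  if (species == "prey") {
    eta <- p["beta0x"] + p["beta2x"] * subgrids$ndvi +
      p["beta3x"] * subgrids$hpd + p["beta4x"] * subgrids$elev
  } else {
    if (is.null(prey_use))
      stop("prey_use indicator is required for the tiger-use predictor")
    eta <- p["beta0y"] + p["beta1y"] * prey_use +
      p["beta2y"] * subgrids$ndvi + p["beta3y"] * subgrids$hpd +
      p["beta4y"] * subgrids$elev
  }
  stats::plogis(unname(eta))
}

#' Per-segment detection probability
#'
#' Inverse-logit of `d0 + d1*ndvi + d2*elev` for the requested species.
#' Effort does not enter the predictor; it is the binomial size of the
#' detection count.
#'
#' @param params [occu_params()] vector.
#' @param subgrids subgrid data.frame with standardized covariates.
#' @param species `"tiger"` or `"prey"`.
#' @return detection probabilities, one per subgrid.
#' @export
detection_prob <- function(params, subgrids, species = c("tiger", "prey")) {
  p <- .as_params(params)
  species <- match.arg(species)
  k <- if (species == "tiger") .PAR_BLOCKS$tiger_detection
       else .PAR_BLOCKS$prey_detection
  eta <- p[k[1]] + p[k[2]] * subgrids$ndvi + p[k[3]] * subgrids$elev
  stats::plogis(unname(eta))
}

#' Latent state container
#'
#' @param Z binary vector, one entry per grid (occupancy).
#' @param zx,zy binary vectors, one entry per subgrid (prey and predator
#'   use).
#' @return a classed list.
#' @export
latent_state <- function(Z, zx, zy) {
  stopifnot(all(Z %in% 0:1), all(zx %in% 0:1), all(zy %in% 0:1),
            length(zx) == length(zy))
  structure(list(Z = as.integer(Z), zx = as.integer(zx),
                 zy = as.integer(zy)), class = "latent_state")
}

#' Complete-data log likelihood
#'
#' Sum of the Bernoulli log-masses of all latent indicators plus the
#' binomial log-masses of both species' detection counts with gated success
#' probabilities. Returns `-Inf` (never `NaN`) when an observed detection is
#' impossible under the latent state.
#'
#' @param params [occu_params()] vector.
#' @param latent [latent_state()] matching the dataset's dimensions.
#' @param data standardized [survey_data()].
#' @param gating a [gating_mode()].
#' @return scalar log likelihood (0 for an empty dataset).
#' @export
complete_data_loglik <- function(params, latent, data,
                                 gating = gating_mode()) {
  p <- .as_params(params)
  gating <- gating_mode(gating)
  fr <- .model_frames(data)
  if (length(latent$Z) != fr$G || length(latent$zx) != fr$S)
    stop("latent state dimensions do not match the dataset")
  if (fr$G == 0) return(0)
  pr <- .link_probs(p, fr, zx = latent$zx)
  ll <- sum(stats::dbinom(latent$Z, 1, pr$psi, log = TRUE))
  if (fr$S) {
    ga <- .gates(latent$Z[fr$gi], latent$zx, latent$zy, gating)
    ll <- ll +
      sum(stats::dbinom(latent$zx, 1, pr$psix, log = TRUE)) +
      sum(stats::dbinom(latent$zy, 1, pr$psiy, log = TRUE)) +
      sum(stats::dbinom(fr$x, fr$n, pr$px * ga$x, log = TRUE)) +
      sum(stats::dbinom(fr$y, fr$n, pr$py * ga$y, log = TRUE))
  }
  if (is.nan(ll)) ll <- -Inf
  ll
}

# iterate over all 2^k latent configurations of a small instance,
# calling f(latent, loglik). Guarded to k <= max_bits.
.enumerate_latents <- function(params, data, gating, f, max_bits = 20L) {
  fr <- .model_frames(data)
  k <- fr$G + 2L * fr$S
  if (k > max_bits)
    stop("latent dimension ", k, " exceeds the enumeration guard (",
         max_bits, " bits)")
  for (code in 0:(2^k - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(k)]
    lat <- latent_state(Z = bits[seq_len(fr$G)],
                        zx = bits[fr$G + seq_len(fr$S)],
                        zy = bits[fr$G + fr$S + seq_len(fr$S)])
    f(lat, complete_data_loglik(params, lat, data, gating))
  }
  invisible(NULL)
}

#' Marginal log likelihood by exhaustive enumeration
#'
#' Sums the complete-data likelihood over all `2^k` latent configurations
#' (k = grids + 2*subgrids). An independent oracle for validating the
#' sampler on tiny instances; guarded to `k <= 20`.
#'
#' @inheritParams complete_data_loglik
#' @return scalar log marginal likelihood of the observed detections.
#' @export
marginal_loglik_bruteforce <- function(params, data,
                                       gating = gating_mode()) {
  gating <- gating_mode(gating)
  terms <- c()
  .enumerate_latents(params, data, gating,
                     function(lat, ll) terms <<- c(terms, ll))
  m <- max(terms)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(terms - m)))
}

#' Exact posterior of the latent states by enumeration
#'
#' Brute-force posterior marginal probabilities `P(Z_i = 1 | data)`,
#' `P(z_x_ij = 1 | data)` and `P(z_y_ij = 1 | data)` at fixed coefficients,
#' for instances within the enumeration guard. The reference oracle for the
#' Gibbs sampler.
#'
#' @inheritParams complete_data_loglik
#' @return list with elements `Z`, `zx`, `zy` of posterior marginals.
#' @export
enumerate_latent_posterior <- function(params, data,
                                       gating = gating_mode()) {
  gating <- gating_mode(gating)
  fr <- .model_frames(data)
  wZ <- numeric(fr$G); wx <- numeric(fr$S); wy <- numeric(fr$S)
  lls <- c(); lats <- list()
  .enumerate_latents(params, data, gating, function(lat, ll) {
    lls <<- c(lls, ll); lats[[length(lats) + 1L]] <<- lat
  })
  m <- max(lls)
  if (!is.finite(m)) stop("all latent configurations have zero likelihood")
  w <- exp(lls - m); w <- w / sum(w)
  for (i in seq_along(w)) {
    wZ <- wZ + w[i] * lats[[i]]$Z
    wx <- wx + w[i] * lats[[i]]$zx
    wy <- wy + w[i] * lats[[i]]$zy
  }
  list(Z = wZ, zx = wx, zy = wy)
}

#' Serialize model coefficients to a flat key-value file
#'
#' @param params [occu_params()] vector.
#' @param file output path; one `name = value` line per coefficient.
#' @export
write_params <- function(params, file) {
  p <- .as_params(params)
  writeLines(sprintf("%s = %.17g", names(p), p), file)
  invisible(file)
}

#' Read model coefficients from a flat key-value file
#'
#' @param file path written by [write_params()].
#' @return [occu_params()] vector.
#' @export
read_params <- function(file) {
  ln <- readLines(file)
  ln <- ln[nzchar(trimws(ln))]
  kv <- strsplit(ln, "=", fixed = TRUE)
  nm <- trimws(vapply(kv, `[`, "", 1L))
  val <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  do.call(occu_params, as.list(stats::setNames(val, nm)))
}
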