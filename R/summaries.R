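# Posterior summaries, methods for occufit objects, and draw persistence.

.pooled_draws <- function(fit) {
  do.call(rbind, fit$draws)
}

#' @export
print.occufit <- function(x, ...) {
  cat("Two-scale occupancy model fit (Metropolis-within-Gibbs)\n")
  cat("  chains:", x$control$chains, " retained draws/chain:",
      nrow(x$draws[[1]]), " gating:", x$control$gating, "\n")
  if (x$fixed)
    cat("  coefficients held fixed; latent states sampled only\n")
  if (!is.null(x$rhat))
    cat("  max R-hat:", round(max(x$rhat$rhat), 4),
        if (attr(x$rhat, "converged")) "(converged)" else "(NOT converged)",
        "\n")
  cat("  elapsed:", round(x$elapsed, 1), "s\n")
  invisible(x)
}

#' @export
coef.occufit <- function(object, ...) {
  colMeans(.pooled_draws(object))
}

#' Posterior summary table
#'
#' Posterior means and equal-tailed 95% credible intervals (empirical 2.5%
#' and 97.5% quantiles of the chains pooled after burn-in and thinning),
#' plus a flag for intervals that exclude zero.
#'
#' @param object an `occufit`.
#' @param prob interval mass (0.95 default).
#' @param ... unused.
#' @return data.frame with columns `parameter`, `mean`, `lower`, `upper`,
#'   `excludes_zero`; class `summary.occufit`.
#' @export
summary.occufit <- function(object, prob = 0.95, ...) {
  d <- .pooled_draws(object)
  if (nrow(d) < 100)
    stop("need at least 100 retained draws to summarize (have ",
         nrow(d), ")")
  a <- (1 - prob) / 2
  q <- apply(d, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  out <- data.frame(parameter = colnames(d), mean = colMeans(d),
                    lower = q[1, ], upper = q[2, ], row.names = NULL)
  out$excludes_zero <- out$lower > 0 | out$upper < 0
  class(out) <- c("summary.occufit", "data.frame")
  attr(out, "prob") <- prob
  out
}

#' @export
print.summary.occufit <- function(x, digits = 3, ...) {
  cat("Posterior summary (", attr(x, "prob") * 100,
      "% equal-tailed credible intervals)\n", sep = "")
  y <- x
  for (cc in c("mean", "lower", "upper")) y[[cc]] <- round(y[[cc]], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Occupancy, use and detection at mean covariates
#'
#' Evaluates a derived probability at the covariate means: with
#' standardized covariates the linear predictors reduce to their
#' intercepts, so the quantity is the inverse logit of the intercept draw
#' (per retained draw), then summarized. Predator use depends on the
#' prey-use indicator, so it is reported at both `z_x = 1` and `z_x = 0`.
#'
#' @param fit an `occufit`.
#' @param quantity one of `"grid_occupancy"`, `"tiger_use"`, `"prey_use"`,
#'   `"tiger_detection"`, `"prey_detection"`.
#' @param prob credible-interval mass.
#' @return data.frame with `mean`, `lower`, `upper` (one row, or two rows
#'   for `tiger_use`: at prey use present / absent).
#' @export
at_mean_covariates <- function(fit, quantity = c("grid_occupancy",
                                                 "tiger_use", "prey_use",
                                                 "tiger_detection",
                                                 "prey_detection"),
                               prob = 0.95) {
  stopifnot(inherits(fit, "occufit"))
  quantity <- match.arg(quantity)
  d <- .pooled_draws(fit)
  a <- (1 - prob) / 2
  smry <- function(v, label) {
    q <- stats::quantile(v, c(a, 1 - a), names = FALSE)
    data.frame(quantity = label, mean = mean(v), lower = q[1], upper = q[2])
  }
  if (quantity == "tiger_use") {
    rbind(smry(stats::plogis(d[, "beta0y"] + d[, "beta1y"]),
               "tiger_use | prey used"),
          smry(stats::plogis(d[, "beta0y"]), "tiger_use | prey unused"))
  } else {
    ic <- switch(quantity, grid_occupancy = "b0", prey_use = "beta0x",
                 tiger_detection = "d0y", prey_detection = "d0x")
    smry(stats::plogis(d[, ic]), quantity)
  }
}

#' Posterior predictive probabilities for new cells
#'
#' Evaluates a linear predictor over the pooled posterior draws for each
#' row of `newdata` and summarizes the resulting probability draws
#' (posterior mean and equal-tailed interval). `newdata` covariates must
#' be on the model (standardized) scale.
#'
#' @param object an `occufit`.
#' @param newdata data.frame of covariates: `prey_km`, `ndvi`, `hpd`,
#'   `elev` for `type = "grid_occupancy"`; `ndvi`, `hpd`, `elev` (plus
#'   `prey_use` for tiger use) otherwise.
#' @param type which probability to predict.
#' @param prob credible mass of the interval.
#' @param ... unused.
#' @return data.frame with `mean`, `lower`, `upper`, one row per row of
#'   `newdata`.
#' @export
predict.occufit <- function(object, newdata,
                            type = c("grid_occupancy", "tiger_use",
                                     "prey_use", "tiger_detection",
                                     "prey_detection"),
                            prob = 0.95, ...) {
  type <- match.arg(type)
  d <- .pooled_draws(object)
  newdata <- as.data.frame(newdata)
  X <- switch(type,
    grid_occupancy = cbind(1, newdata$prey_km, newdata$ndvi, newdata$hpd,
                           newdata$elev),
    prey_use = cbind(1, newdata$ndvi, newdata$hpd, newdata$elev),
    tiger_use = {
      if (is.null(newdata$prey_use))
        stop("newdata needs a prey_use column for tiger-use predictions")
      cbind(1, newdata$prey_use, newdata$ndvi, newdata$hpd, newdata$elev)
    },
    cbind(1, newdata$ndvi, newdata$elev))
  if (any(!is.finite(X))) stop("non-finite covariate in newdata")
  blk <- switch(type, grid_occupancy = "grid_occupancy",
                prey_use = "prey_use", tiger_use = "tiger_use",
                tiger_detection = "tiger_detection",
                prey_detection = "prey_detection")
  pp <- stats::plogis(X %*% t(d[, .PAR_BLOCKS[[blk]], drop = FALSE]))
  a <- (1 - prob) / 2
  q <- apply(pp, 1, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(mean = rowMeans(pp), lower = q[1, ], upper = q[2, ])
}

#' Posterior use map
#'
#' Posterior probabilities of predator use and prey use per subgrid and of
#' occupancy per grid: means of the retained latent indicators across all
#' chains. Subgrids whose gated detections are positive have probability
#' exactly 1.
#'
#' @param fit an `occufit` (latent frequencies are always retained).
#' @return list of class `use_map` with data.frames `subgrids`
#'   (`subgrid_id`, `p_tiger_use`, `p_prey_use`) and `grids` (`grid_id`,
#'   `p_occupancy`).
#' @export
use_map <- function(fit) {
  stopifnot(inherits(fit, "occufit"))
  if (is.null(fit$latent))
    stop("no latent-state frequencies in this fit; re-run occu_fit()")
  structure(list(
    subgrids = data.frame(subgrid_id = fit$subgrid_id,
                          p_tiger_use = fit$latent$zy,
                          p_prey_use = fit$latent$zx),
    grids = data.frame(grid_id = fit$grid_id,
                       p_occupancy = fit$latent$Z)), class = "use_map")
}

#' @export
print.use_map <- function(x, ...) {
  cat("Posterior use map:", nrow(x$subgrids), "subgrids,",
      nrow(x$grids), "grids\n")
  cat("  mean P(tiger use):", round(mean(x$subgrids$p_tiger_use), 3),
      " mean P(prey use):", round(mean(x$subgrids$p_prey_use), 3),
      " mean P(occupancy):", round(mean(x$grids$p_occupancy), 3), "\n")
  invisible(x)
}

#' Write a use map to CSV
#'
#' @param map a [use_map()].
#' @param subgrid_file,grid_file output paths (grid file optional).
#' @export
write_use_map <- function(map, subgrid_file, grid_file = NULL) {
  stopifnot(inherits(map, "use_map"))
  utils::write.csv(map$subgrids, subgrid_file, row.names = FALSE)
  if (!is.null(grid_file))
    utils::write.csv(map$grids, grid_file, row.names = FALSE)
  invisible(subgrid_file)
}

#' Trace plots of posterior draws
#'
#' @param x an `occufit`.
#' @param parameters coefficients to plot (default: the four intercepts).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.occufit <- function(x, parameters = c("b0", "beta0y", "d0y", "d0x"),
                         ...) {
  old <- graphics::par(mfrow = c(length(parameters), 1),
                       mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (pp in parameters) {
    tr <- sapply(x$draws, function(d) d[, pp])
    graphics::matplot(x$iterations, tr, type = "l", lty = 1,
                      xlab = "", ylab = pp, ...)
  }
  invisible(x)
}

#' Persist posterior draws to CSV
#'
#' One row per retained draw with its chain and iteration; reloads
#' losslessly with [read_draws()].
#'
#' @param fit an `occufit`.
#' @param file output path.
#' @export
write_draws <- function(fit, file) {
  stopifnot(inherits(fit, "occufit"))
  tab <- do.call(rbind, lapply(seq_along(fit$draws), function(cc) {
    cbind(data.frame(chain = cc, iteration = fit$iterations),
          as.data.frame(fit$draws[[cc]]))
  }))
  utils::write.csv(format(tab, digits = 17, scientific = TRUE, trim = TRUE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Reload posterior draws written by [write_draws()]
#'
#' @param file CSV path.
#' @return list of per-chain draw matrices with attribute `"iterations"`.
#' @export
read_draws <- function(file) {
  tab <- utils::read.csv(file)
  out <- lapply(split(tab, tab$chain), function(d) {
    m <- as.matrix(d[, setdiff(names(d), c("chain", "iteration"))])
    rownames(m) <- NULL
    m
  })
  attr(out, "iterations") <- unique(tab$iteration)
  names(out) <- NULL
  out
}

#' Write a JSON run manifest
#'
#' Records the sampler configuration, seed, acceptance rates and
#' convergence state of a fit, for reproducibility audits.
#'
#' @param fit an `occufit`.
#' @param file output path.
#' @export
write_run_manifest <- function(fit, file) {
  stopifnot(inherits(fit, "occufit"))
  man <- list(
    package = "occuhier",
    control = unclass(fit$control),
    acceptance_rates = as.list(as.data.frame(fit$accept)),
    retained_draws_per_chain = nrow(fit$draws[[1]]),
    max_rhat = if (!is.null(fit$rhat)) max(fit$rhat$rhat) else NULL,
    converged = if (!is.null(fit$rhat)) attr(fit$rhat, "converged")
                else NULL,
    elapsed_seconds = fit$elapsed)
  jsonlite::write_json(man, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}
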