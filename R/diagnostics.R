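# Convergence diagnostics.

#' Split-chain Gelman-Rubin diagnostic
#'
#' Classic potential scale reduction factor computed on split chains: each
#' chain is halved, the between- and within-half variances are combined as
#' `sqrt(((n-1)/n * W + B/n) / W)`. Parameters with zero total variance
#' (e.g. held fixed) report 1.
#'
#' @param draws an `occufit` object or a list of per-chain draw matrices
#'   with identical column names.
#' @param threshold convergence is declared when every R-hat is below this
#'   value (1.1 by default).
#' @return a `convergence_report`: data.frame of per-parameter R-hat with
#'   attributes `converged` and `threshold`.
#' @export
gelman_rubin <- function(draws, threshold = 1.1) {
  if (inherits(draws, "occufit")) draws <- draws$draws
  stopifnot(is.list(draws), length(draws) >= 1)
  if (length(draws) < 2)
    stop("R-hat needs at least 2 chains")
  n0 <- nrow(draws[[1]])
  if (n0 < 10) stop("R-hat needs at least 10 retained draws per chain")
  n <- floor(n0 / 2)
  halves <- list()
  for (ch in draws) {
    halves <- c(halves, list(ch[seq_len(n), , drop = FALSE],
                             ch[(n0 - n + 1):n0, , drop = FALSE]))
  }
  m <- length(halves)
  params <- colnames(draws[[1]])
  rhat <- vapply(params, function(pp) {
    x <- sapply(halves, function(h) h[, pp])     # n x m
    mu <- colMeans(x)
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(mu)
    vplus <- (n - 1) / n * W + B / n
    if (vplus <= .Machine$double.eps) return(1)
    if (W <= .Machine$double.eps) return(Inf)
    sqrt(vplus / W)
  }, numeric(1))
  out <- data.frame(parameter = params, rhat = unname(rhat),
                    row.names = NULL)
  attr(out, "threshold") <- threshold
  attr(out, "converged") <- all(rhat < threshold)
  class(out) <- c("convergence_report", "data.frame")
  out
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Split-chain Gelman-Rubin diagnostic (threshold ",
      attr(x, "threshold"), ")\n", sep = "")
  print.data.frame(data.frame(parameter = x$parameter,
                              rhat = round(x$rhat, 4)), row.names = FALSE)
  cat(if (isTRUE(attr(x, "converged"))) "All chains converged.\n"
      else "NOT converged: some R-hat at or above the threshold.\n")
  invisible(x)
}
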