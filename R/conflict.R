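# Rescue-conflict association analysis.
#
# Subgrids of the buffer zone are classified high/low on posterior tiger
# use, prey use and log human population density; 2x2 tables of rescue
# presence against each classification are tested with one-sided Z-tests of
# the log odds ratio, and stratified tables with odds-ratio homogeneity
# tests (Woolf by default, Breslow-Day as an option).

#' 2x2 contingency table of events by exposure
#'
#' Cell layout follows the exposed/unexposed by event/no-event convention:
#' `a` exposed with event, `b` unexposed with event, `c` exposed without,
#' `d` unexposed without; the odds ratio is `a*d / (b*c)`.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return an object of class `two_by_two` (a 2x2 matrix).
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("empty table")
  m <- matrix(c(a, c, b, d), 2, 2,
              dimnames = list(event = c("yes", "no"),
                              exposure = c("high", "low")))
  class(m) <- c("two_by_two", class(m))
  m
}

.cells <- function(tbl) {
  if (inherits(tbl, "two_by_two"))
    return(c(a = tbl[1, 1], b = tbl[1, 2], c = tbl[2, 1], d = tbl[2, 2]))
  if (is.numeric(tbl) && length(tbl) == 4)
    return(stats::setNames(as.numeric(tbl), c("a", "b", "c", "d")))
  stop("expected a two_by_two table or a length-4 numeric (a,b,c,d)")
}

#' Count cells into a 2x2 table
#'
#' Cross-tabulates binary exposure labels against event presence per cell.
#' Events are coded as presence (a cell with several rescues counts once),
#' so `a+b+c+d` equals the number of analyzed cells.
#'
#' @param exposure logical vector, one entry per cell (TRUE = high).
#' @param events logical vector (TRUE = at least one event in the cell).
#' @return a [two_by_two()].
#' @export
build_table <- function(exposure, events) {
  stopifnot(length(exposure) == length(events))
  exposure <- as.logical(exposure); events <- as.logical(events)
  two_by_two(a = sum(exposure & events), b = sum(!exposure & events),
             c = sum(exposure & !events), d = sum(!exposure & !events))
}

#' Odds ratio of a 2x2 table
#'
#' @param tbl a [two_by_two()] or numeric `(a, b, c, d)`.
#' @param continuity add 0.5 to every cell (required when a cell is zero).
#' @return the cross-product ratio `a*d / (b*c)`.
#' @export
odds_ratio <- function(tbl, continuity = FALSE) {
  ce <- .cells(tbl)
  if (continuity) ce <- ce + 0.5
  if (any(ce == 0))
    stop("zero cell; use continuity = TRUE for a corrected estimate")
  unname(ce["a"] * ce["d"] / (ce["b"] * ce["c"]))
}

#' Z-test for the log odds ratio
#'
#' Large-sample test of association in a 2x2 table:
#' `logOR = log(ad/bc)`, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`,
#' `Z = logOR / SE`, with a one- or two-sided normal p-value.
#'
#' @param tbl a [two_by_two()] or numeric `(a, b, c, d)`; all cells must be
#'   positive (or use `continuity`).
#' @param alternative `"greater"` (OR > 1), `"less"`, or `"two.sided"`.
#' @param continuity add 0.5 to every cell first.
#' @return an object of class `htest` with the odds ratio, log odds ratio,
#'   its standard error, the Z statistic and p-value.
#' @export
log_or_test <- function(tbl, alternative = c("greater", "less",
                                             "two.sided"),
                        continuity = FALSE) {
  alternative <- match.arg(alternative)
  ce <- .cells(tbl)
  if (continuity) ce <- ce + 0.5
  if (any(ce == 0))
    stop("zero cell; use continuity = TRUE")
  lor <- log(ce["a"] * ce["d"] / (ce["b"] * ce["c"]))
  se <- sqrt(sum(1 / ce))
  z <- lor / se
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  structure(list(statistic = c(Z = unname(z)),
                 estimate = c(`odds ratio` = unname(exp(lor)),
                              `log odds ratio` = unname(lor),
                              SE = unname(se)),
                 p.value = unname(p), alternative = alternative,
                 method = "Z-test for the log odds ratio",
                 data.name = paste(ce, collapse = "/")),
            class = "htest")
}

#' Homogeneity of odds ratios across strata
#'
#' Tests whether a common odds ratio holds across stratified 2x2 tables.
#' `"woolf"` (default) weights stratum log odds ratios by their inverse
#' variances `w_k = 1/(1/a+1/b+1/c+1/d)` and sums
#' `w_k (logOR_k - pooled)^2` against chi-square with `K - 1` df.
#' `"breslow-day"` compares each stratum's `a` cell with its expectation
#' under the Mantel-Haenszel common odds ratio.
#'
#' @param strata list of [two_by_two()] tables (>= 2), optionally named.
#' @param method `"woolf"` or `"breslow-day"`.
#' @param continuity add 0.5 to all cells of every stratum.
#' @return an `htest` with the chi-square statistic, df, p-value and the
#'   per-stratum odds ratios in `$estimate`.
#' @export
or_homogeneity_test <- function(strata, method = c("woolf", "breslow-day"),
                                continuity = FALSE) {
  method <- match.arg(method)
  if (!is.list(strata) || length(strata) < 2)
    stop("need at least 2 strata")
  ce <- lapply(strata, .cells)
  if (continuity) ce <- lapply(ce, `+`, 0.5)
  if (any(vapply(ce, function(x) any(x == 0), TRUE)))
    stop("zero cell in a stratum; use continuity = TRUE")
  ors <- vapply(ce, function(x) unname(x["a"] * x["d"] / (x["b"] * x["c"])),
                numeric(1))
  K <- length(ce)
  if (method == "woolf") {
    lor <- log(ors)
    w <- vapply(ce, function(x) 1 / sum(1 / x), numeric(1))
    pooled <- sum(w * lor) / sum(w)
    chi2 <- sum(w * (lor - pooled)^2)
    meth <- "Woolf test of homogeneity of odds ratios"
    common <- exp(pooled)
  } else {
    # Mantel-Haenszel common OR
    num <- sum(vapply(ce, function(x) x["a"] * x["d"] /
                        sum(x), numeric(1)))
    den <- sum(vapply(ce, function(x) x["b"] * x["c"] /
                        sum(x), numeric(1)))
    psi <- num / den
    chi2 <- 0
    for (x in ce) {
      n1 <- x["a"] + x["c"]; n2 <- x["b"] + x["d"]; m1 <- x["a"] + x["b"]
      # E[a] solves a quadratic under OR psi with fixed margins
      A <- psi - 1
      B <- -((m1 + n1) * psi + (n2 - m1))
      C <- psi * m1 * n1
      ea <- if (abs(A) < 1e-12) -C / B
            else (-B - sqrt(B^2 - 4 * A * C)) / (2 * A)
      va <- 1 / (1 / ea + 1 / (m1 - ea) + 1 / (n1 - ea) +
                   1 / (n2 - m1 + ea))
      chi2 <- chi2 + (x["a"] - ea)^2 / va
    }
    chi2 <- unname(chi2)
    meth <- "Breslow-Day test of homogeneity of odds ratios"
    common <- psi
  }
  df <- K - 1
  nm <- if (!is.null(names(strata))) names(strata)
        else paste0("stratum", seq_len(K))
  structure(list(statistic = c(`X-squared` = chi2),
                 parameter = c(df = df),
                 p.value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 estimate = stats::setNames(c(ors, unname(common)),
                                            c(paste0("OR ", nm),
                                              "common OR")),
                 method = meth,
                 data.name = paste(K, "strata")), class = "htest")
}

#' Marginal exposure-by-stratum association
#'
#' Collapses the event dimension of stratified tables to ask how exposure
#' itself distributes across the (binary) stratifying variable: cell counts
#' are the per-stratum totals of exposed and unexposed cells, arranged as an
#' exposure-by-stratum 2x2 table (first stratum in the `a`/`c` column).
#'
#' @param strata list of exactly 2 [two_by_two()] tables.
#' @return list with the collapsed `table` and its odds ratio `or`.
#' @export
marginal_association <- function(strata) {
  if (!is.list(strata) || length(strata) != 2)
    stop("marginal association needs exactly 2 strata")
  ce <- lapply(strata, .cells)
  if (any(vapply(ce, sum, numeric(1)) == 0)) stop("empty stratum")
  tab <- two_by_two(a = ce[[1]]["a"] + ce[[1]]["c"],
                    b = ce[[2]]["a"] + ce[[2]]["c"],
                    c = ce[[1]]["b"] + ce[[1]]["d"],
                    d = ce[[2]]["b"] + ce[[2]]["d"])
  list(table = tab, or = odds_ratio(tab))
}

#' Naive occupancy
#'
#' Fraction of surveyed units with at least one detection, uncorrected for
#' imperfect detection.
#'
#' @param detected number of units with detections.
#' @param surveyed number of surveyed units (> 0).
#' @return `detected / surveyed`.
#' @export
naive_occupancy <- function(detected, surveyed) {
  if (surveyed <= 0) stop("no surveyed units")
  if (detected > surveyed) stop("detected cannot exceed surveyed")
  detected / surveyed
}

#' Classification thresholds for the conflict analysis
#'
#' Defaults are the buffer-zone means of the motivating analysis: tiger-use
#' probability 0.54, prey-use probability 0.80, and 141 persons/km2 for
#' human population density. Classification is strict: a cell is "high"
#' only when its value exceeds the threshold.
#'
#' @param tiger_use,prey_use probabilities in (0,1).
#' @param population persons/km2 (> 0), compared on the raw density scale.
#' @return a classed list.
#' @export
conflict_thresholds <- function(tiger_use = 0.54, prey_use = 0.80,
                                population = 141) {
  stopifnot(tiger_use > 0, tiger_use < 1, prey_use > 0, prey_use < 1,
            population > 0)
  structure(list(tiger_use = tiger_use, prey_use = prey_use,
                 population = population), class = "conflict_thresholds")
}

#' Classify subgrids as high/low use and population
#'
#' @param map a [use_map()] (or its `$subgrids` data.frame).
#' @param population data.frame with `subgrid_id` and `density`
#'   (persons/km2).
#' @param thresholds a [conflict_thresholds()]; alternatively set
#'   `recompute = TRUE` to use the means of the supplied cells.
#' @param buffer optional character vector of subgrid ids forming the
#'   buffer zone; other cells are dropped.
#' @param recompute replace the thresholds by the means over the analyzed
#'   cells.
#' @return data.frame with `subgrid_id` and logical `tiger_high`,
#'   `prey_high`, `pop_high`.
#' @export
classify_subgrids <- function(map, population,
                              thresholds = conflict_thresholds(),
                              buffer = NULL, recompute = FALSE) {
  sub <- if (inherits(map, "use_map")) map$subgrids else as.data.frame(map)
  population <- as.data.frame(population)
  stopifnot(all(c("subgrid_id", "density") %in% names(population)))
  extra <- setdiff(sub$subgrid_id, population$subgrid_id)
  miss <- setdiff(population$subgrid_id, sub$subgrid_id)
  if (length(extra) || length(miss))
    stop("use map and population cover different cells; only in map: ",
         paste(utils::head(extra, 5), collapse = ", "),
         "; only in population: ",
         paste(utils::head(miss, 5), collapse = ", "))
  d <- merge(sub, population, by = "subgrid_id")
  if (!is.null(buffer)) d <- d[d$subgrid_id %in% buffer, ]
  th <- thresholds
  if (recompute)
    th <- conflict_thresholds(tiger_use = mean(d$p_tiger_use),
                              prey_use = mean(d$p_prey_use),
                              population = mean(d$density))
  data.frame(subgrid_id = d$subgrid_id,
             tiger_high = d$p_tiger_use > th$tiger_use,
             prey_high = d$p_prey_use > th$prey_use,
             pop_high = d$density > th$population)
}

#' Packaged rescue contingency fixture
#'
#' Loads the shipped buffer-zone contingency tables of tiger rescues
#' against high/low tiger use, prey use and log human population density,
#' including the prey-use tables stratified by population density and the
#' rescued-animal age/sex tally.
#'
#' @return list with `overall` (named list of [two_by_two()] per
#'   classification), `prey_by_population` (named list of two
#'   [two_by_two()] strata), `age_sex` (data.frame) and scalar survey
#'   counts `grids_surveyed`, `grids_with_detections`.
#' @export
rescue_tables <- function() {
  path <- system.file("extdata", "cpc_rescue_tables.csv",
                      package = "occuhier", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  mk <- function(rows) two_by_two(rows$a, rows$b, rows$c, rows$d)
  ov <- raw[raw$section == "overall", ]
  st <- raw[raw$section == "prey_by_population", ]
  overall <- lapply(split(ov, ov$comparison), mk)   # named by comparison
  strata <- lapply(split(st, st$comparison), mk)
  # keep the (low, high) population order regardless of file order
  strata <- strata[c("low_population", "high_population")]
  age <- utils::read.csv(system.file("extdata", "cpc_rescue_age_sex.csv",
                                     package = "occuhier",
                                     mustWork = TRUE))
  list(overall = overall, prey_by_population = strata, age_sex = age,
       grids_surveyed = 57L, grids_with_detections = 36L)
}

#' Full conflict-association report
#'
#' Runs the standard battery on the overall and stratified tables: per
#' comparison the odds ratio, log odds ratio, SE, Z and one-sided p-value;
#' for the stratified tables the per-stratum odds ratios and the
#' homogeneity test.
#'
#' @param overall named list of [two_by_two()] tables.
#' @param strata optional named list of stratified [two_by_two()] tables.
#' @param method homogeneity method, see [or_homogeneity_test()].
#' @return list with data.frame `associations` and, when strata are given,
#'   `homogeneity` (an `htest`) and `marginal` (see
#'   [marginal_association()]).
#' @export
conflict_report <- function(overall, strata = NULL,
                            method = c("woolf", "breslow-day")) {
  method <- match.arg(method)
  row1 <- function(nm, tbl) {
    ht <- log_or_test(tbl, "greater")
    data.frame(comparison = nm, or = unname(ht$estimate["odds ratio"]),
               log_or = unname(ht$estimate["log odds ratio"]),
               se = unname(ht$estimate["SE"]),
               z = unname(ht$statistic), p = ht$p.value)
  }
  assoc <- do.call(rbind, Map(row1, names(overall), overall))
  rownames(assoc) <- NULL
  out <- list(associations = assoc)
  if (!is.null(strata)) {
    out$stratum_or <- vapply(strata, odds_ratio, numeric(1))
    out$homogeneity <- or_homogeneity_test(strata, method = method)
    if (length(strata) == 2) out$marginal <- marginal_association(strata)
  }
  out
}
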