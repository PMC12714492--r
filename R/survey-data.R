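# Survey containers and covariate preparation.
#
# A survey consists of large grid cells (10 x 10 km in the motivating design)
# partitioned into subgrid cells (2 x 2 km, at most 25 per grid). Detections
# are counts of sign-positive 100-m segments out of `effort` segments walked
# in a subgrid. Covariates live at both scales and are standardized before
# modelling; the scaling record keeps standardization invertible.

#' Construct a two-scale survey dataset
#'
#' Bundles the grid-level and subgrid-level tables of a sign survey and
#' validates their joint invariants: detections never exceed effort, every
#' subgrid belongs to exactly one grid, no grid holds more than
#' `max_subgrids` subgrids, and total per-grid effort respects the trail
#' budget (400 segments = 40 km at 100-m spacing, by default).
#'
#' @param grids data.frame with columns `grid_id`, `prey_km`, `ndvi`, `hpd`,
#'   `elev`, `surveyed`. `prey_km` may be `NA` for unsurveyed grids until
#'   [impute_prey()] fills it.
#' @param subgrids data.frame with columns `subgrid_id`, `grid_id`, `effort`,
#'   `tiger_det`, `prey_det`, `ndvi`, `hpd`, `elev`, and optionally
#'   `in_buffer` (defaults to `FALSE`).
#' @param scaling optional scaling record as produced by
#'   [standardize_covariates()]; `NULL` means covariates are on their raw
#'   scale.
#' @param max_subgrids,max_effort structural bounds per grid.
#' @return an object of class `survey_data`.
#' @export
survey_data <- function(grids, subgrids, scaling = NULL,
                        max_subgrids = 25L, max_effort = 400L) {
  grids <- as.data.frame(grids)
  subgrids <- as.data.frame(subgrids)
  need_g <- c("grid_id", "prey_km", "ndvi", "hpd", "elev", "surveyed")
  need_s <- c("subgrid_id", "grid_id", "effort", "tiger_det", "prey_det",
              "ndvi", "hpd", "elev")
  miss <- setdiff(need_g, names(grids))
  if (length(miss))
    stop("grid table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_s, names(subgrids))
  if (length(miss))
    stop("subgrid table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"in_buffer" %in% names(subgrids))
    subgrids$in_buffer <- logical(nrow(subgrids))

  grids$grid_id <- as.character(grids$grid_id)
  subgrids$grid_id <- as.character(subgrids$grid_id)
  subgrids$subgrid_id <- as.character(subgrids$subgrid_id)
  if (anyDuplicated(grids$grid_id))
    stop("duplicated grid_id in grid table")
  if (anyDuplicated(subgrids$subgrid_id))
    stop("duplicated subgrid_id: each subgrid maps to exactly one grid")

  bad <- which(!subgrids$grid_id %in% grids$grid_id)
  if (length(bad))
    stop("subgrid rows reference unknown grids (rows ",
         paste(utils::head(bad, 10L), collapse = ", "), ")")
  bad <- which(subgrids$effort < 0 | subgrids$tiger_det < 0 |
                 subgrids$prey_det < 0)
  if (length(bad))
    stop("negative effort or detection counts (rows ",
         paste(utils::head(bad, 10L), collapse = ", "), ")")
  bad <- which(subgrids$tiger_det > subgrids$effort)
  if (length(bad))
    stop("tiger detections exceed effort in subgrid(s): ",
         paste(utils::head(subgrids$subgrid_id[bad], 10L), collapse = ", "),
         " (rows ", paste(utils::head(bad, 10L), collapse = ", "), ")")
  bad <- which(subgrids$prey_det > subgrids$effort)
  if (length(bad))
    stop("prey detections exceed effort in subgrid(s): ",
         paste(utils::head(subgrids$subgrid_id[bad], 10L), collapse = ", "),
         " (rows ", paste(utils::head(bad, 10L), collapse = ", "), ")")

  n_per <- table(subgrids$grid_id)
  if (any(n_per > max_subgrids))
    stop("grid(s) with more than ", max_subgrids, " subgrids: ",
         paste(names(n_per)[n_per > max_subgrids], collapse = ", "))
  eff <- tapply(subgrids$effort, subgrids$grid_id, sum)
  if (any(eff > max_effort))
    stop("grid(s) exceed the per-grid effort budget of ", max_effort,
         " segments: ", paste(names(eff)[eff > max_effort], collapse = ", "))

  structure(list(grids = grids, subgrids = subgrids, scaling = scaling),
            class = "survey_data")
}

#' @export
print.survey_data <- function(x, ...) {
  cat("Two-scale survey dataset\n")
  cat("  grids:   ", nrow(x$grids), " (", sum(x$grids$surveyed),
      " surveyed)\n", sep = "")
  cat("  subgrids:", nrow(x$subgrids), "\n")
  cat("  effort:  ", sum(x$subgrids$effort), "segments;",
      sum(x$subgrids$tiger_det), "tiger and",
      sum(x$subgrids$prey_det), "prey sign detections\n")
  cat("  covariates", if (is.null(x$scaling)) "raw" else "standardized", "\n")
  invisible(x)
}

#' Read a two-scale survey from CSV files
#'
#' @param subgrid_file CSV with columns `grid_id, subgrid_id, effort,
#'   tiger_det, prey_det, ndvi, hpd, elev, in_buffer`.
#' @param grid_file CSV with columns `grid_id, prey_km, ndvi, hpd, elev,
#'   surveyed`.
#' @param schema optional named character vector mapping the canonical column
#'   names above to the names used in the files.
#' @return a validated [survey_data()] object.
#' @export
read_survey <- function(subgrid_file, grid_file, schema = NULL) {
  sg <- utils::read.csv(subgrid_file, stringsAsFactors = FALSE)
  g <- utils::read.csv(grid_file, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    rename <- function(df) {
      for (canon in names(schema)) {
        if (schema[[canon]] %in% names(df))
          names(df)[names(df) == schema[[canon]]] <- canon
      }
      df
    }
    sg <- rename(sg)
    g <- rename(g)
  }
  g$surveyed <- as.logical(g$surveyed)
  if ("in_buffer" %in% names(sg)) sg$in_buffer <- as.logical(sg$in_buffer)
  survey_data(g, sg)
}

#' Write a survey dataset to CSV files
#'
#' Inverse of [read_survey()]; the round trip preserves ids and integer
#' fields exactly and real fields to full printed precision.
#'
#' @param data a [survey_data()] object.
#' @param subgrid_file,grid_file output paths.
#' @export
write_survey <- function(data, subgrid_file, grid_file) {
  stopifnot(inherits(data, "survey_data"))
  utils::write.csv(data$subgrids, subgrid_file, row.names = FALSE)
  utils::write.csv(data$grids, grid_file, row.names = FALSE)
  invisible(c(subgrid = subgrid_file, grid = grid_file))
}

#' Floor and log-transform a population density
#'
#' Zero (or near-zero) densities inside park cores are floored to the
#' minimum nonzero density observed across the study wards (11 persons/km2
#' by default) before the log10 transform, so the log scale is defined
#' everywhere.
#'
#' @param raw_density non-negative density in persons/km2 (vectorized).
#' @param floor positive flooring density.
#' @return log10(pmax(raw_density, floor)).
#' @export
floor_log_pop <- function(raw_density, floor = 11) {
  if (any(raw_density < 0, na.rm = TRUE))
    stop("population density must be non-negative")
  if (floor <= 0) stop("floor must be positive")
  log10(pmax(raw_density, floor))
}

.zscore <- function(v, field, scale_name) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("covariate '", field, "' is constant at the ", scale_name,
         " scale; cannot standardize")
  c(mean = mean(v), sd = s)
}

#' Standardize covariates at both scales
#'
#' Centres and scales each named covariate to mean 0 and sample (n-1)
#' standard deviation 1, separately at the grid and subgrid scale, and
#' stores the per-field means and standard deviations so the operation is
#' invertible with [unstandardize()]. Fields with missing values (e.g.
#' prey before imputation) are standardized on their observed part.
#'
#' @param data a [survey_data()] object.
#' @param grid_fields,subgrid_fields covariate columns to standardize at each
#'   scale.
#' @return the dataset with standardized covariates and a scaling record.
#' @export
standardize_covariates <- function(data,
                                   grid_fields = c("prey_km", "ndvi",
                                                   "hpd", "elev"),
                                   subgrid_fields = c("ndvi", "hpd",
                                                      "elev")) {
  stopifnot(inherits(data, "survey_data"))
  sc <- list(grid = list(), subgrid = list())
  for (f in grid_fields) {
    v <- data$grids[[f]]
    ms <- .zscore(v[!is.na(v)], f, "grid")
    data$grids[[f]] <- (v - ms["mean"]) / ms["sd"]
    sc$grid[[f]] <- ms
  }
  for (f in subgrid_fields) {
    v <- data$subgrids[[f]]
    ms <- .zscore(v[!is.na(v)], f, "subgrid")
    data$subgrids[[f]] <- (v - ms["mean"]) / ms["sd"]
    sc$subgrid[[f]] <- ms
  }
  data$scaling <- sc
  data
}

#' Undo covariate standardization
#'
#' @param data a standardized [survey_data()] object carrying a scaling
#'   record.
#' @return the dataset on the original covariate scale, scaling record
#'   removed.
#' @export
unstandardize <- function(data) {
  stopifnot(inherits(data, "survey_data"))
  if (is.null(data$scaling))
    stop("dataset carries no scaling record; nothing to invert")
  for (f in names(data$scaling$grid)) {
    ms <- data$scaling$grid[[f]]
    data$grids[[f]] <- data$grids[[f]] * ms["sd"] + ms["mean"]
  }
  for (f in names(data$scaling$subgrid)) {
    ms <- data$scaling$subgrid[[f]]
    data$subgrids[[f]] <- data$subgrids[[f]] * ms["sd"] + ms["mean"]
  }
  data$scaling <- NULL
  data
}

#' Impute prey for unsurveyed grids from adjacent grids
#'
#' Grids that could not be visited have unknown prey; their `prey_km` is set
#' to the arithmetic mean of `prey_km` over adjacent surveyed grids.
#' Surveyed grids are never altered. The adjacency relation is supplied
#' explicitly (queen/8-neighbour adjacency in the shipped generator) so the
#' package stays free of geometry.
#'
#' @param data a [survey_data()] object, or a grid data.frame.
#' @param adjacency data.frame with columns `grid_id`, `neighbor_id`
#'   (undirected pairs; either orientation or both may be listed).
#' @return the input with imputed `prey_km`; the imputation log (grid id and
#'   imputed value) is attached as attribute `"imputed"`.
#' @export
impute_prey <- function(data, adjacency) {
  is_sd <- inherits(data, "survey_data")
  grids <- if (is_sd) data$grids else as.data.frame(data)
  adjacency <- as.data.frame(adjacency)
  stopifnot(all(c("grid_id", "neighbor_id") %in% names(adjacency)))
  # symmetrize once so lookups work from either column
  adj <- unique(rbind(
    data.frame(a = as.character(adjacency$grid_id),
               b = as.character(adjacency$neighbor_id)),
    data.frame(a = as.character(adjacency$neighbor_id),
               b = as.character(adjacency$grid_id))))

  todo <- which(!grids$surveyed | is.na(grids$prey_km))
  log <- data.frame(grid_id = character(0), prey_km = numeric(0))
  for (i in todo) {
    id <- grids$grid_id[i]
    nb <- adj$b[adj$a == id]
    donors <- grids$prey_km[grids$grid_id %in% nb & grids$surveyed &
                              !is.na(grids$prey_km)]
    if (!length(donors))
      stop("unsurveyed grid '", id,
           "' has no surveyed neighbour to impute prey from")
    grids$prey_km[i] <- mean(donors)
    log <- rbind(log, data.frame(grid_id = id, prey_km = mean(donors)))
  }
  out <- if (is_sd) { data$grids <- grids; data } else grids
  attr(out, "imputed") <- log
  out
}

#' Pearson correlations between covariates at one scale
#'
#' Report-only screen of covariate collinearity; nothing is dropped
#' automatically.
#'
#' @param data a [survey_data()] object.
#' @param scale `"grid"` or `"subgrid"`.
#' @param fields covariate columns; defaults to prey, NDVI, HPD and
#'   elevation at the grid scale and NDVI, HPD, elevation at the subgrid
#'   scale.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
covariate_correlation <- function(data, scale = c("grid", "subgrid"),
                                  fields = NULL) {
  stopifnot(inherits(data, "survey_data"))
  scale <- match.arg(scale)
  tab <- if (scale == "grid") data$grids else data$subgrids
  if (is.null(fields))
    fields <- if (scale == "grid") c("prey_km", "ndvi", "hpd", "elev")
              else c("ndvi", "hpd", "elev")
  if (nrow(tab) < 3)
    stop("need at least 3 cells at the ", scale,
         " scale to estimate correlations")
  stats::cor(tab[, fields], use = "complete.obs")
}
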