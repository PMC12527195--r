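#' @keywords internal
"_PACKAGE"

## Closed vocabularies for the survey design: four management treatments
## (unarmored "Protect" vs armored "Restore", crossed with high/low potential
## sediment-supply benefit) sampled in five geographic regions of Puget Sound.

#' Treatment and region vocabularies
#'
#' The survey design crosses four shoreline-management treatments with five
#' geographic regions, one site per treatment within each region (20 sites).
#'
#' @return Character vector of the closed vocabulary.
#' @export
bb_treatments <- function() {
  c("ProtectHigh", "ProtectLow", "RestoreHigh", "RestoreLow")
}

#' @rdname bb_treatments
#' @export
bb_regions <- function() {
  c("PennCove", "DabobBay", "AgatePass", "VashonIsland", "HarstineIsland")
}

#' Names of the 30 site metrics
#'
#' The fixed, ordered set of metric names used throughout the package: wrack
#' (4), logs (4), fish (4), vegetation (4), supratidal invertebrates (2),
#' low-shore biota (2), geomorphology and waves (6), sediment (4).
#'
#' @return Character vector of length 30.
#' @export
bb_metric_names <- function() {
  c("% Wrack Cover",
    "% Terrestrial Wrack",
    "Wrack Depth (cm)",
    "Wrack Width (m)",
    "Log Count",
    "Width of Log Line (m)",
    "Count Partially Buried Logs",
    "Fallen Tree Count",
    "Total Fish Density (100m-2)",
    "Juvenile Salmon Density (100m-2)",
    "Forage Fish Density (100m-2)",
    "Juv. Salmon Feeding Observations (%)",
    "% Overhanging Vegetation",
    "% Supratidal Vegetation",
    "Dunegrass Patch Width (m)",
    "Native Vegetation Taxa Richness",
    "Fallout Trap Taxa Richness",
    "Fallout Trap Density (m-2)",
    "Biota Taxa Richness",
    "% Eelgrass",
    "Beach Slope (m/m) Toe-MSL",
    "Beach Width (m) Toe-MLLW",
    "Bluff Height (m)",
    "Bluff Exposure (m2)",
    "Relative Encroachment (m)",
    "Wave Height (m)",
    "% Sand MHHW",
    "% Sand MLLW",
    "Normalized Sorting MHHW",
    "Normalized Sorting MLLW")
}

#' Metric definitions: orientation of each metric for scoring
#'
#' Each metric is scored so that a higher scaled value indicates greater beach
#' function. Metrics for which a LOWER raw value indicates greater function are
#' inverted during min-max scaling. By default only Relative Encroachment is
#' inverted: positive encroachment means the bluff/armor toe sits below MHHW,
#' truncating the upper beach. Every orientation is overridable because the
#' appropriate direction for some metrics (e.g. beach slope, fallout-trap
#' density dominated by non-insect taxa) is a judgement call; the headline
#' treatment ratios are robust to the slope choice (see the methods vignette).
#'
#' @param overrides Named character vector, values `"higher_is_better"` or
#'   `"lower_is_better"`, names drawn from [bb_metric_names()].
#' @return Data frame with columns `metric` and `orientation`, one row per
#'   metric, in canonical order.
#' @examples
#' defs <- metric_definitions()
#' table(defs$orientation)
#' @export
metric_definitions <- function(overrides = NULL) {
  nm <- bb_metric_names()
  orientation <- rep("higher_is_better", length(nm))
  names(orientation) <- nm
  orientation["Relative Encroachment (m)"] <- "lower_is_better"
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("orientation overrides must be a named vector")
    bad <- setdiff(names(overrides), nm)
    if (length(bad))
      stop("unknown metric in overrides: ", paste(bad, collapse = ", "))
    if (!all(overrides %in% c("higher_is_better", "lower_is_better")))
      stop("orientation must be 'higher_is_better' or 'lower_is_better'")
    orientation[names(overrides)] <- overrides
  }
  data.frame(metric = nm, orientation = unname(orientation),
             stringsAsFactors = FALSE)
}

#' Reference treatment means from the Puget Sound feeder-bluff field study
#'
#' The canonical 4 treatment x 30 metric table of field-measured averages that
#' the synthetic generator targets and the scale bar is demonstrated on. Values
#' are unweighted treatment means across the five regions.
#'
#' @return Data frame with column `metric` plus one numeric column per
#'   treatment, 30 rows in canonical metric order.
#' @examples
#' ref <- reference_treatment_means()
#' ref[ref$metric == "% Wrack Cover", ]
#' @export
reference_treatment_means <- function() {
  path <- system.file("extdata", "puget_treatment_means.csv",
                      package = "bluffbeach", mustWork = TRUE)
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(identical(x$metric, bb_metric_names()),
            identical(names(x), c("metric", bb_treatments())))
  x
}

## internal: treatment-mean matrix (metrics x treatments) from the fixture or
## a compatible data frame
.tm_matrix <- function(tm) {
  m <- as.matrix(tm[, bb_treatments(), drop = FALSE])
  rownames(m) <- tm$metric
  storage.mode(m) <- "double"
  m
}
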