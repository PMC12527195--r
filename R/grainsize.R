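## Folk & Ward grain-size statistics from percent-by-class data
## (logarithmic / phi-scale graphical method, as popularised by Gradistat).

#' Grain-size distribution over a sieve-class ladder
#'
#' Classes are defined by a strictly decreasing ladder of sieve diameters in
#' mm; `percent_by_class` holds the percent of sediment in each class between
#' consecutive bounds (length `length(class_bounds) - 1`). If
#' `percent_by_class` has `length(class_bounds) + 1` entries the first and
#' last are open-ended extreme classes; these are closed one phi unit beyond
#' the outer bounds.
#'
#' @param class_bounds Strictly decreasing sieve diameters, mm.
#' @param percent_by_class Percents, non-negative, summing to 100 (+-0.5).
#' @param station `"MHHW"` or `"MLLW"`.
#' @param layer `"surface"` or `"subsurface"`.
#' @return List of class `grain_size_distribution` with elements
#'   `bounds_mm`, `percent`, `phi` (ascending phi at the bounds), `station`,
#'   `layer`.
#' @examples
#' g <- grain_size_distribution(c(2, 1), 100)
#' percentile_phi(g, 50)  # midway between phi(2mm) and phi(1mm)
#' @export
grain_size_distribution <- function(class_bounds, percent_by_class,
                                    station = c("MHHW", "MLLW"),
                                    layer = c("surface", "subsurface")) {
  station <- match.arg(station)
  layer <- match.arg(layer)
  b <- as.numeric(class_bounds)
  p <- as.numeric(percent_by_class)
  if (any(b <= 0)) stop("class bounds must be positive diameters (mm)")
  if (length(b) >= 2 && any(diff(b) >= 0))
    stop("class bounds must be strictly decreasing")
  if (length(p) == length(b) + 1) {
    # open-ended extreme classes: close one phi unit beyond each end
    b <- c(b[1] * 2, b, b[length(b)] / 2)
  } else if (length(p) != length(b) - 1) {
    stop("percent_by_class must have length(class_bounds) - 1 entries ",
         "(or + 1 with open-ended extremes)")
  }
  if (any(p < 0)) stop("percents must be non-negative")
  if (abs(sum(p) - 100) > 0.5)
    stop("percents must sum to 100 (+-0.5); got ", round(sum(p), 3))
  p <- p / sum(p) * 100
  structure(list(bounds_mm = b, percent = p, phi = -log2(b),
                 station = station, layer = layer),
            class = "grain_size_distribution")
}

#' Phi percentile of a grain-size distribution
#'
#' Builds the cumulative percent-coarser curve at the class bounds and
#' interpolates linearly in phi (`phi = -log2(diameter mm)`).
#'
#' @param dist A [grain_size_distribution()].
#' @param p Percentile in (0, 100), percent coarser.
#' @return Phi value.
#' @export
percentile_phi <- function(dist, p) {
  stopifnot(inherits(dist, "grain_size_distribution"))
  if (any(p <= 0 | p >= 100)) stop("p must be strictly inside (0, 100)")
  cum <- c(0, cumsum(dist$percent))      # percent coarser at each bound
  phi <- dist$phi                        # ascending (coarse -> fine)
  keep <- !duplicated(cum)               # flat (empty-class) segments: first phi
  stats::approx(cum[keep], phi[keep], xout = p, ties = "ordered")$y
}

#' Folk & Ward statistics (logarithmic method)
#'
#' Graphical percentile statistics on the phi scale: mean
#' `(phi16 + phi50 + phi84)/3`, inclusive sorting
#' `sigma_I = (phi84 - phi16)/4 + (phi95 - phi5)/6.6`, inclusive skewness and
#' graphical kurtosis, geometric sorting `sigma_G = 2^sigma_I` (unitless,
#' >= 1, 1 = perfectly sorted), and median diameter `d50 = 2^(-phi50)` mm.
#'
#' @param dist A [grain_size_distribution()].
#' @return List of class `grain_size_stats`: `d50_mm`, `mean_phi`,
#'   `sorting_phi`, `sorting_geometric`, `skewness`, `kurtosis`,
#'   `percent_sand`.
#' @export
folk_ward <- function(dist) {
  q <- vapply(c(5, 16, 25, 50, 75, 84, 95),
              function(p) percentile_phi(dist, p), 0)
  names(q) <- c("p5", "p16", "p25", "p50", "p75", "p84", "p95")
  mean_phi <- (q["p16"] + q["p50"] + q["p84"]) / 3
  sorting <- (q["p84"] - q["p16"]) / 4 + (q["p95"] - q["p5"]) / 6.6
  if (sorting == 0) {
    warning("degenerate distribution: zero spread, sorting = 0")
    skew <- 0
    kurt <- 1
  } else {
    skew <- (q["p16"] + q["p84"] - 2 * q["p50"]) /
      (2 * (q["p84"] - q["p16"])) +
      (q["p5"] + q["p95"] - 2 * q["p50"]) / (2 * (q["p95"] - q["p5"]))
    iqr <- q["p75"] - q["p25"]
    kurt <- if (iqr > 0) (q["p95"] - q["p5"]) / (2.44 * iqr) else NA_real_
  }
  structure(list(d50_mm = unname(2^(-q["p50"])),
                 mean_phi = unname(mean_phi),
                 sorting_phi = unname(sorting),
                 sorting_geometric = unname(2^sorting),
                 skewness = unname(skew),
                 kurtosis = unname(kurt),
                 percent_sand = percent_sand(dist)),
            class = "grain_size_stats")
}

#' Percent sand of a grain-size distribution
#'
#' Summed percent of classes within the Wentworth sand window 0.0625-2 mm;
#' classes straddling a window boundary contribute pro-rata by their
#' phi-linear fraction inside the window.
#'
#' @param dist A [grain_size_distribution()].
#' @return Percent in [0, 100].
#' @export
percent_sand <- function(dist) {
  stopifnot(inherits(dist, "grain_size_distribution"))
  lo <- -log2(2)       # phi of 2 mm     = -1
  hi <- -log2(0.0625)  # phi of 0.0625 mm = 4
  phi <- dist$phi
  frac <- vapply(seq_along(dist$percent), function(j) {
    a <- phi[j]; b <- phi[j + 1]
    max(0, min(b, hi) - max(a, lo)) / (b - a)
  }, 0)
  sum(dist$percent * frac)
}
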