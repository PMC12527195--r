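## The headline computation: orient metrics, average by treatment, min-max
## scale each metric across the four treatments to [0, 1], and average the
## scaled values into a per-treatment beach-function score with SE.

#' Treatment means of the site metric table
#'
#' Unweighted mean per metric across each treatment's sites; missing values
#' are excluded pairwise (never imputed as zero).
#'
#' @param table A `site_metric_table` (see [build_site_metric_table()]), or
#'   any data frame with a `treatment` column plus metric columns.
#' @return Data frame: `metric` column plus one column per treatment, metrics
#'   in canonical order.
#' @export
treatment_means <- function(table) {
  trs <- bb_treatments()
  present <- intersect(trs, unique(table$treatment))
  absent <- setdiff(trs, present)
  if (length(absent))
    stop("treatment with zero sites: ", paste(absent, collapse = ", "))
  metrics <- intersect(bb_metric_names(), names(table))
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (tr in trs) {
    sub <- table[table$treatment == tr, metrics, drop = FALSE]
    out[[tr]] <- vapply(metrics, function(m)
      mean(sub[[m]], na.rm = TRUE), 0)
  }
  out
}

#' Min-max scale one metric's four treatment means
#'
#' `s = (x - min) / (max - min)`, then `s <- 1 - s` for metrics where lower
#' raw values indicate greater function. If all four values are equal the
#' metric is neutral and every treatment scores 0.5, keeping the metric in
#' the denominator rather than dropping it.
#'
#' @param values Numeric vector of 4 finite treatment means.
#' @param orientation `"higher_is_better"` or `"lower_is_better"`.
#' @return Numeric vector of 4 scaled values in [0, 1].
#' @examples
#' minmax_scale(c(43.2, 41.7, 13.7, 24.0))
#' minmax_scale(c(-0.51, -0.12, 0.27, 0.41), "lower_is_better")
#' @export
minmax_scale <- function(values, orientation = "higher_is_better") {
  if (any(!is.finite(values))) stop("values must be finite")
  orientation <- match.arg(orientation,
                           c("higher_is_better", "lower_is_better"))
  rng <- max(values) - min(values)
  s <- if (rng == 0) rep(0.5, length(values))
       else (values - min(values)) / rng
  if (orientation == "lower_is_better") s <- 1 - s
  s
}

#' Beach-function scale bar
#'
#' Computes the composite 0-1 beach-function score per treatment: each
#' metric's treatment means are min-max scaled (with orientation applied),
#' and the scaled values are averaged across metrics. The standard error is
#' taken across the scaled metric values within each treatment (the single
#' error bar per treatment).
#'
#' @param x A `site_metric_table` of per-site values (averaged to treatment
#'   means internally), or a pre-averaged treatment-mean table with a
#'   `metric` column plus one column per treatment.
#' @param definitions Metric definitions from [metric_definitions()]; every
#'   metric present in `x` must have one.
#' @return Object of class `scale_bar`: list with `scores` (named per
#'   treatment), `se`, `n_metrics`, `scaled` (metrics x treatments matrix).
#' @examples
#' sb <- scale_bar(reference_treatment_means())
#' sb$scores
#' @export
scale_bar <- function(x, definitions = metric_definitions()) {
  tm <- if ("metric" %in% names(x) && !("treatment" %in% names(x))) x
        else treatment_means(x)
  metrics <- tm$metric
  if (length(metrics) < 2) stop("scale bar needs >= 2 metrics")
  miss <- setdiff(metrics, definitions$metric)
  if (length(miss))
    stop("metric without a definition: ", miss[1])
  ori <- definitions$orientation[match(metrics, definitions$metric)]
  vals <- .tm_matrix(tm)
  scaled <- t(vapply(seq_along(metrics), function(i)
    minmax_scale(vals[i, ], ori[i]), numeric(ncol(vals))))
  dimnames(scaled) <- dimnames(vals)
  scores <- colMeans(scaled)
  se <- apply(scaled, 2, stats::sd) / sqrt(nrow(scaled))
  structure(list(scores = scores, se = se, n_metrics = nrow(scaled),
                 scaled = scaled), class = "scale_bar")
}

#' @export
print.scale_bar <- function(x, ...) {
  cat("Beach-function scale bar (", x$n_metrics, " metrics)\n\n", sep = "")
  out <- data.frame(treatment = names(x$scores),
                    score = round(unname(x$scores), 3),
                    se = round(unname(x$se), 3))
  print(out, row.names = FALSE)
  prot <- mean(x$scores[c("ProtectHigh", "ProtectLow")])
  rest <- mean(x$scores[c("RestoreHigh", "RestoreLow")])
  cat("\nProtect / Restore ratio:", round(prot / rest, 2), "\n")
  invisible(x)
}

#' @export
summary.scale_bar <- function(object, ...) {
  cat("Per-metric scaled values (rows = metrics, cols = treatments):\n")
  print(round(object$scaled, 3))
  invisible(object$scaled)
}

#' @export
plot.scale_bar <- function(x, ...) {
  mid <- graphics::barplot(x$scores, ylim = c(0, 1),
                           ylab = "Beach function (0-1)",
                           names.arg = names(x$scores), las = 2, ...)
  graphics::arrows(mid, x$scores - x$se, mid, x$scores + x$se,
                   angle = 90, code = 3, length = 0.06)
  invisible(mid)
}
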