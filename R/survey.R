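## Survey record validation and aggregation of raw records into site metrics.
##
## Records are plain data frames (one CSV per record type); validators check
## the schema invariants and return the frame invisibly classed by record
## type. Assemblage-bearing records (fallout traps, low-shore quadrats) are
## wide: identifier columns followed by one column per taxon.

.id_cols <- list(
  registry  = c("site_id", "treatment", "region", "facing_degrees",
                "bluff_height_m", "bluff_exposure_m2", "toe_index"),
  wrack     = c("site_id", "percent_cover_total", "percent_algae",
                "percent_eelgrass", "percent_terrestrial",
                "wrack_width_m", "wrack_depth_cm"),
  loglines  = c("site_id", "log_count", "buried_count", "log_line_width_m",
                "fallen_trees_site_total"),
  snorkel   = c("site_id", "season", "transect_length_m", "visibility_m",
                "total_fish", "juv_salmon", "forage_fish", "other_fish",
                "feeding_observed", "salmon_observation_events"),
  fallout   = c("site_id", "trap_id", "trap_area_m2", "deploy_hours"),
  mllw      = c("site_id", "quadrat_id", "quadrat_area_m2")
)

.check_cols <- function(x, cols, what) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(what, ": missing columns ", paste(miss, collapse = ", "))
  invisible(x)
}

.check_percent <- function(x, col, what) {
  v <- x[[col]]
  bad <- which(!is.na(v) & (v < 0 | v > 100))
  if (length(bad))
    stop(what, ": column '", col, "' outside [0,100] at row ",
         bad[1])
  invisible(x)
}

.check_nonneg <- function(x, col, what) {
  v <- x[[col]]
  bad <- which(!is.na(v) & v < 0)
  if (length(bad))
    stop(what, ": column '", col, "' negative at row ", bad[1])
  invisible(x)
}

#' Validate a site registry
#'
#' One row per site: identifier, treatment, region, shoreline facing
#' (degrees true), and the two pass-through bluff characteristics estimated
#' from imagery (height and exposed-face area).
#'
#' @param x Data frame with columns `site_id`, `treatment`, `region`,
#'   `facing_degrees`, `bluff_height_m`, `bluff_exposure_m2`, `toe_index`.
#' @return The validated data frame, invisibly.
#' @export
validate_registry <- function(x) {
  .check_cols(x, .id_cols$registry, "registry")
  if (anyDuplicated(x$site_id))
    stop("registry: duplicate site_id '",
         x$site_id[duplicated(x$site_id)][1], "'")
  bad <- setdiff(unique(x$treatment), bb_treatments())
  if (length(bad)) stop("registry: unknown treatment '", bad[1], "'")
  bad <- setdiff(unique(x$region), bb_regions())
  if (length(bad)) stop("registry: unknown region '", bad[1], "'")
  if (any(x$facing_degrees < 0 | x$facing_degrees >= 360))
    stop("registry: facing_degrees outside [0,360)")
  .check_nonneg(x, "bluff_height_m", "registry")
  .check_nonneg(x, "bluff_exposure_m2", "registry")
  invisible(x)
}

#' Validate wrack quadrat records
#'
#' @param x Data frame of per-quadrat wrack measurements (percent covers,
#'   width in m, depth in cm).
#' @return The validated data frame, invisibly.
#' @export
validate_wrack <- function(x) {
  .check_cols(x, .id_cols$wrack, "wrack")
  for (p in c("percent_cover_total", "percent_algae", "percent_eelgrass",
              "percent_terrestrial"))
    .check_percent(x, p, "wrack")
  comp <- x$percent_algae + x$percent_eelgrass + x$percent_terrestrial
  bad <- which(comp > x$percent_cover_total + 1e-8)
  if (length(bad))
    stop("wrack: component covers exceed total cover at row ", bad[1])
  .check_nonneg(x, "wrack_width_m", "wrack")
  .check_nonneg(x, "wrack_depth_cm", "wrack")
  invisible(x)
}

#' Validate log-line records
#'
#' @param x Data frame of per-point log-line measurements plus the site-level
#'   fallen-tree total (repeated on each of the site's rows).
#' @return The validated data frame, invisibly.
#' @export
validate_loglines <- function(x) {
  .check_cols(x, .id_cols$loglines, "loglines")
  for (p in c("log_count", "buried_count", "fallen_trees_site_total"))
    .check_nonneg(x, p, "loglines")
  if (any(x$buried_count > x$log_count))
    stop("loglines: buried_count exceeds log_count")
  tot <- tapply(x$fallen_trees_site_total, x$site_id,
                function(v) length(unique(v)))
  if (any(tot > 1))
    stop("loglines: fallen_trees_site_total inconsistent within a site")
  invisible(x)
}

#' Validate snorkel transect records
#'
#' @param x Data frame of per-transect fish counts, with transect length and
#'   horizontal Secchi visibility used for density conversion, and juvenile
#'   salmon feeding observations.
#' @return The validated data frame, invisibly.
#' @export
validate_snorkel <- function(x) {
  .check_cols(x, .id_cols$snorkel, "snorkel")
  if (!all(x$season %in% c("spring", "summer")))
    stop("snorkel: season must be 'spring' or 'summer'")
  if (any(x$transect_length_m <= 0)) stop("snorkel: transect_length_m <= 0")
  if (any(x$visibility_m <= 0)) stop("snorkel: visibility_m <= 0")
  for (p in c("total_fish", "juv_salmon", "forage_fish", "other_fish",
              "feeding_observed", "salmon_observation_events"))
    .check_nonneg(x, p, "snorkel")
  if (any(x$feeding_observed > x$salmon_observation_events))
    stop("snorkel: feeding_observed exceeds salmon_observation_events")
  invisible(x)
}

#' Validate fallout trap records
#'
#' @param x Wide data frame: `site_id`, `trap_id`, `trap_area_m2`,
#'   `deploy_hours`, then one non-negative count column per taxon.
#' @return The validated data frame, invisibly.
#' @export
validate_fallout <- function(x) {
  .check_cols(x, .id_cols$fallout, "fallout")
  if (any(x$trap_area_m2 <= 0)) stop("fallout: trap_area_m2 <= 0")
  taxa <- setdiff(names(x), .id_cols$fallout)
  if (!length(taxa)) stop("fallout: no taxon columns")
  for (p in taxa) .check_nonneg(x, p, "fallout")
  invisible(x)
}

#' Validate low-shore (MLLW) quadrat records
#'
#' @param x Wide data frame: `site_id`, `quadrat_id`, `quadrat_area_m2`, then
#'   one percent-cover column per taxon (eelgrass among them as `eelgrass`).
#' @return The validated data frame, invisibly.
#' @export
validate_mllw <- function(x) {
  .check_cols(x, .id_cols$mllw, "mllw")
  if (any(x$quadrat_area_m2 <= 0)) stop("mllw: quadrat_area_m2 <= 0")
  taxa <- setdiff(names(x), .id_cols$mllw)
  if (!length(taxa)) stop("mllw: no taxon columns")
  for (p in taxa) .check_percent(x, p, "mllw")
  invisible(x)
}

#' Validate vegetation transect records
#'
#' Vegetation is carried as four frames: the per-site transect (`transects`),
#' overhang intervals (`overhangs`: `site_id`, `start_m`, `end_m`), dunegrass
#' patch widths (`patches`: `site_id`, `patch_width_m`), and the species list
#' (`species`: `site_id`, `species`, `status` in native/introduced/cryptic).
#'
#' @param transects,overhangs,patches,species The four vegetation frames.
#' @return The list of validated frames, invisibly.
#' @export
validate_vegetation <- function(transects, overhangs, patches, species) {
  .check_cols(transects, c("site_id", "transect_length_m",
                           "supratidal_percent"), "vegetation")
  if (any(transects$transect_length_m <= 0))
    stop("vegetation: transect_length_m <= 0")
  .check_percent(transects, "supratidal_percent", "vegetation")
  .check_cols(overhangs, c("site_id", "start_m", "end_m"), "overhangs")
  if (any(overhangs$start_m > overhangs$end_m))
    stop("overhangs: start_m > end_m")
  len <- transects$transect_length_m[match(overhangs$site_id,
                                           transects$site_id)]
  if (any(is.na(len)))
    stop("overhangs: site_id not in vegetation transects")
  if (any(overhangs$start_m < 0 | overhangs$end_m > len + 1e-9))
    stop("overhangs: interval outside transect")
  .check_cols(patches, c("site_id", "patch_width_m"), "patches")
  .check_nonneg(patches, "patch_width_m", "patches")
  .check_cols(species, c("site_id", "species", "status"), "species")
  if (!all(species$status %in% c("native", "introduced", "cryptic")))
    stop("species: status must be native, introduced or cryptic")
  invisible(list(transects = transects, overhangs = overhangs,
                 patches = patches, species = species))
}

## ---- aggregation operations -------------------------------------------

#' Aggregate wrack quadrats for one site
#'
#' Arithmetic means over quadrats of total cover, terrestrial cover, depth
#' and width.
#'
#' @param quadrats Data frame of wrack quadrats for a single site.
#' @return Named numeric vector: `% Wrack Cover`, `% Terrestrial Wrack`,
#'   `Wrack Depth (cm)`, `Wrack Width (m)`.
#' @examples
#' q <- data.frame(site_id = "s", percent_cover_total = c(40, 20),
#'                 percent_algae = 0, percent_eelgrass = 0,
#'                 percent_terrestrial = c(10, 0),
#'                 wrack_width_m = c(4, 2), wrack_depth_cm = c(2, 1))
#' aggregate_wrack(q)
#' @export
aggregate_wrack <- function(quadrats) {
  if (is.null(quadrats) || nrow(quadrats) == 0)
    stop("no quadrats for site")
  c("% Wrack Cover"      = mean(quadrats$percent_cover_total),
    "% Terrestrial Wrack" = mean(quadrats$percent_terrestrial),
    "Wrack Depth (cm)"   = mean(quadrats$wrack_depth_cm),
    "Wrack Width (m)"    = mean(quadrats$wrack_width_m))
}

#' Convert a transect fish count to a density per 100 m2
#'
#' The surveyed water volume is approximated by transect length times
#' horizontal Secchi visibility; counts are scaled to a standard 100 m2.
#'
#' @param count Non-negative count.
#' @param transect_length Transect length, m (> 0).
#' @param visibility Horizontal visibility, m (> 0).
#' @return Density per 100 m2.
#' @examples
#' fish_density(10, 50, 2)   # area 100 m2 -> 10
#' fish_density(13, 50, 1)   # area 50 m2  -> 26
#' @export
fish_density <- function(count, transect_length, visibility) {
  if (any(transect_length <= 0)) stop("transect_length must be > 0")
  if (any(visibility <= 0)) stop("visibility must be > 0")
  count / (transect_length * visibility) * 100
}

#' Fallout-trap density and taxa richness
#'
#' @param counts Named non-negative counts by taxon for one trap.
#' @param trap_area Trap opening area, m2 (> 0; the standard bin is 0.10 m2).
#' @return List with `density` (individuals per m2) and `richness`
#'   (number of taxa with count > 0).
#' @examples
#' fallout_density(c(acari = 5, diptera = 4, araneae = 1), 0.10)
#' @export
fallout_density <- function(counts, trap_area = 0.10) {
  if (trap_area <= 0) stop("trap_area must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  list(density = sum(counts) / trap_area,
       richness = sum(counts > 0))
}

#' Percent of a transect overhung by vegetation
#'
#' Computes the union length of the (possibly overlapping) overhang intervals
#' as a percentage of the transect.
#'
#' @param intervals Two-column matrix or data frame of (start, end) in m.
#' @param transect_length Transect length, m.
#' @return Percent in [0, 100].
#' @examples
#' overhang_percent(rbind(c(0, 10), c(5, 20)), 50)  # union 20 m -> 40
#' @export
overhang_percent <- function(intervals, transect_length) {
  if (transect_length <= 0) stop("transect_length must be > 0")
  iv <- as.matrix(intervals)
  if (is.null(dim(iv)) || nrow(iv) == 0) return(0)
  if (ncol(iv) != 2) stop("intervals must have two columns (start, end)")
  if (any(iv[, 1] > iv[, 2])) stop("interval start exceeds end")
  if (any(iv[, 1] < 0) || any(iv[, 2] > transect_length + 1e-9))
    stop("interval outside transect")
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  total <- 0
  cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= cur_e) {
        cur_e <- max(cur_e, iv[i, 2])
      } else {
        total <- total + (cur_e - cur_s)
        cur_s <- iv[i, 1]; cur_e <- iv[i, 2]
      }
    }
  }
  total <- total + (cur_e - cur_s)
  min(100, total / transect_length * 100)
}

#' Juvenile-salmon feeding contingency table by treatment
#'
#' Sums feeding and non-feeding salmon observation events per treatment into
#' a 2 x 4 contingency table (rows `feeding`, `not_feeding`).
#'
#' @param snorkel Snorkel transect data frame (see [validate_snorkel()]).
#' @param registry Site registry mapping `site_id` to `treatment`.
#' @return Integer matrix 2 x 4 with treatment columns in canonical order.
#' @export
feeding_contingency <- function(snorkel, registry) {
  tr <- registry$treatment[match(snorkel$site_id, registry$site_id)]
  if (any(is.na(tr)))
    stop("snorkel site_id not present in registry")
  bad <- setdiff(unique(tr), bb_treatments())
  if (length(bad)) stop("unknown treatment label '", bad[1], "'")
  missing_tr <- setdiff(bb_treatments(), unique(tr))
  if (length(missing_tr))
    stop("treatment absent from input: ", paste(missing_tr, collapse = ", "))
  feed <- tapply(snorkel$feeding_observed, tr, sum)[bb_treatments()]
  evts <- tapply(snorkel$salmon_observation_events, tr, sum)[bb_treatments()]
  tab <- rbind(feeding = feed, not_feeding = evts - feed)
  colnames(tab) <- bb_treatments()
  storage.mode(tab) <- "integer"
  tab
}

#' Assemble the site metric table
#'
#' Joins per-site metric values onto the registry, checks for duplicates and
#' unknown metrics, fills unreported metrics with `NA` (missing, never zero),
#' and orders columns canonically.
#'
#' @param registry Validated site registry.
#' @param metric_values Data frame with `site_id` plus one column per metric
#'   (any subset of [bb_metric_names()]).
#' @return Data frame of class `site_metric_table`: `site_id`, `treatment`,
#'   `region`, then the 30 metric columns.
#' @export
build_site_metric_table <- function(registry, metric_values) {
  validate_registry(registry)
  if (anyDuplicated(metric_values$site_id))
    stop("duplicate site ids in metric values")
  unknown <- setdiff(setdiff(names(metric_values), "site_id"),
                     bb_metric_names())
  if (length(unknown))
    stop("unknown metric column: ", unknown[1])
  out <- data.frame(site_id = registry$site_id,
                    treatment = registry$treatment,
                    region = registry$region,
                    stringsAsFactors = FALSE, check.names = FALSE)
  idx <- match(registry$site_id, metric_values$site_id)
  for (m in bb_metric_names()) {
    out[[m]] <- if (m %in% names(metric_values))
      as.numeric(metric_values[[m]][idx]) else NA_real_
  }
  class(out) <- c("site_metric_table", "data.frame")
  out
}

#' Aggregate a full record set into the 30-metric site table
#'
#' Runs every per-record-type aggregation (wrack, logs, fish, vegetation,
#' fallout traps, low-shore quadrats), the geomorphic derivations from
#' elevation profiles, the wave hindcast from wind/fetch specifications, and
#' the grain-size statistics, and assembles them with
#' [build_site_metric_table()]. Fish metrics are computed per season and the
#' two seasonal site values averaged; raw seasonal records are retained for
#' the community statistics.
#'
#' @param records List with elements `registry`, `wrack`, `loglines`,
#'   `snorkel`, `fallout`, `mllw`, `vegetation` (list of four frames),
#'   `profiles` (named list of [elevation_profile()]s), `datums`
#'   ([tidal_datums()]), `windfetch` (data frame `site_id`, `facing_degrees`,
#'   `fetch_m`, `shoreline_angle_deg`), `grainsize` (named list of
#'   [grain_size_distribution()]s keyed `<site_id>|<station>`), as produced
#'   by [simulate_sites()] or read from a survey directory.
#' @return A `site_metric_table` data frame.
#' @export
site_metric_table <- function(records) {
  reg <- validate_registry(records$registry)
  validate_wrack(records$wrack)
  validate_loglines(records$loglines)
  validate_snorkel(records$snorkel)
  validate_fallout(records$fallout)
  validate_mllw(records$mllw)
  veg <- records$vegetation
  validate_vegetation(veg$transects, veg$overhangs, veg$patches, veg$species)

  sites <- reg$site_id
  mv <- data.frame(site_id = sites, stringsAsFactors = FALSE,
                   check.names = FALSE)
  n <- length(sites)
  for (m in bb_metric_names()) mv[[m]] <- NA_real_

  fallout_taxa <- setdiff(names(records$fallout), .id_cols$fallout)
  mllw_taxa <- setdiff(names(records$mllw), .id_cols$mllw)

  for (i in seq_len(n)) {
    s <- sites[i]

    w <- records$wrack[records$wrack$site_id == s, , drop = FALSE]
    if (nrow(w)) mv[i, names(aggregate_wrack(w))] <- aggregate_wrack(w)

    l <- records$loglines[records$loglines$site_id == s, , drop = FALSE]
    if (nrow(l)) {
      mv[i, "Log Count"] <- mean(l$log_count)
      mv[i, "Width of Log Line (m)"] <- mean(l$log_line_width_m)
      mv[i, "Count Partially Buried Logs"] <- mean(l$buried_count)
      mv[i, "Fallen Tree Count"] <- l$fallen_trees_site_total[1]
    }

    sn <- records$snorkel[records$snorkel$site_id == s, , drop = FALSE]
    if (nrow(sn)) {
      dens <- function(col) {
        d <- fish_density(sn[[col]], sn$transect_length_m, sn$visibility_m)
        mean(tapply(d, sn$season, mean))   # season means, then their mean
      }
      mv[i, "Total Fish Density (100m-2)"] <- dens("total_fish")
      mv[i, "Juvenile Salmon Density (100m-2)"] <- dens("juv_salmon")
      mv[i, "Forage Fish Density (100m-2)"] <- dens("forage_fish")
      ev <- sum(sn$salmon_observation_events)
      mv[i, "Juv. Salmon Feeding Observations (%)"] <-
        if (ev > 0) 100 * sum(sn$feeding_observed) / ev else NA_real_
    }

    f <- records$fallout[records$fallout$site_id == s, , drop = FALSE]
    if (nrow(f)) {
      per_trap <- lapply(seq_len(nrow(f)), function(k)
        fallout_density(unlist(f[k, fallout_taxa]), f$trap_area_m2[k]))
      mv[i, "Fallout Trap Density (m-2)"] <-
        mean(vapply(per_trap, `[[`, 0, "density"))
      mv[i, "Fallout Trap Taxa Richness"] <-
        mean(vapply(per_trap, `[[`, 0, "richness"))
    }

    q <- records$mllw[records$mllw$site_id == s, , drop = FALSE]
    if (nrow(q)) {
      cov <- as.matrix(q[, mllw_taxa, drop = FALSE])
      mv[i, "Biota Taxa Richness"] <- mean(rowSums(cov > 0))
      mv[i, "% Eelgrass"] <-
        if ("eelgrass" %in% mllw_taxa) mean(q$eelgrass) else NA_real_
    }

    vt <- veg$transects[veg$transects$site_id == s, , drop = FALSE]
    if (nrow(vt)) {
      ov <- veg$overhangs[veg$overhangs$site_id == s,
                          c("start_m", "end_m"), drop = FALSE]
      mv[i, "% Overhanging Vegetation"] <-
        overhang_percent(ov, vt$transect_length_m[1])
      mv[i, "% Supratidal Vegetation"] <- vt$supratidal_percent[1]
      pw <- veg$patches$patch_width_m[veg$patches$site_id == s]
      mv[i, "Dunegrass Patch Width (m)"] <-
        if (length(pw)) mean(pw) else 0
      sp <- veg$species[veg$species$site_id == s, , drop = FALSE]
      mv[i, "Native Vegetation Taxa Richness"] <-
        length(unique(sp$species[sp$status == "native"]))
    }

    prof <- records$profiles[[s]]
    if (!is.null(prof)) {
      gm <- geomorph_metrics(prof, records$datums)
      mv[i, "Relative Encroachment (m)"] <- gm$relative_encroachment
      mv[i, "Beach Slope (m/m) Toe-MSL"] <- gm$slope_toe_msl
      mv[i, "Beach Width (m) Toe-MLLW"] <- gm$width_toe_mllw
    }
    mv[i, "Bluff Height (m)"] <- reg$bluff_height_m[i]
    mv[i, "Bluff Exposure (m2)"] <- reg$bluff_exposure_m2[i]

    wf <- records$windfetch[records$windfetch$site_id == s, , drop = FALSE]
    if (nrow(wf)) {
      sc <- assign_wind(wf$facing_degrees[1])
      wv <- smb_wave(sc, fetch_spec(wf$fetch_m[1], wf$facing_degrees[1],
                                    wf$shoreline_angle_deg[1]))
      mv[i, "Wave Height (m)"] <- wv$hs
    }

    for (st in c("MHHW", "MLLW")) {
      g <- records$grainsize[[paste(s, st, sep = "|")]]
      if (!is.null(g)) {
        fw <- folk_ward(g)
        mv[i, paste("% Sand", st)] <- percent_sand(g)
        mv[i, paste("Normalized Sorting", st)] <- fw$sorting_geometric
      }
    }
  }
  build_site_metric_table(reg, mv)
}
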