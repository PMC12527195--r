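## CSV readers/writers for every record type, directory-level validation,
## and the end-to-end pipeline: simulate -> validate -> aggregate -> score
## -> statistics, with a JSON run report.

.survey_files <- c("registry.csv", "wrack.csv", "loglines.csv",
                   "snorkel.csv", "fallout.csv", "mllw.csv",
                   "vegetation.csv", "overhangs.csv",
                   "dunegrass_patches.csv", "vegetation_species.csv",
                   "windfetch.csv", "profiles.csv", "datums.csv",
                   "grainsize.csv")

#' Write a simulated (or assembled) record set to a survey directory
#'
#' One CSV per record type; elevation profiles are written long
#' (`site_id`, `distance_m`, `elevation_m`), grain-size tables wide with
#' class bounds encoded in the headers (`pct_<coarse>_<fine>mm`).
#'
#' @param records Record list as produced by [simulate_sites()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_survey_dir <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f)
    utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  wcsv(records$registry, "registry.csv")
  wcsv(records$wrack, "wrack.csv")
  wcsv(records$loglines, "loglines.csv")
  wcsv(records$snorkel, "snorkel.csv")
  wcsv(records$fallout, "fallout.csv")
  wcsv(records$mllw, "mllw.csv")
  wcsv(records$vegetation$transects, "vegetation.csv")
  wcsv(records$vegetation$overhangs, "overhangs.csv")
  wcsv(records$vegetation$patches, "dunegrass_patches.csv")
  wcsv(records$vegetation$species, "vegetation_species.csv")
  wcsv(records$windfetch, "windfetch.csv")
  prof <- do.call(rbind, lapply(names(records$profiles), function(s) {
    p <- records$profiles[[s]]
    data.frame(site_id = s, distance_m = p$distance,
               elevation_m = p$elevation, stringsAsFactors = FALSE)
  }))
  wcsv(prof, "profiles.csv")
  d <- records$datums
  wcsv(data.frame(mhhw = d$mhhw, msl = d$msl, mllw = d$mllw), "datums.csv")
  gs <- do.call(rbind, lapply(names(records$grainsize), function(key) {
    g <- records$grainsize[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    b <- g$bounds_mm
    cols <- sprintf("pct_%g_%gmm", b[-length(b)], b[-1])
    row <- as.data.frame(as.list(g$percent), col.names = cols,
                         check.names = FALSE)
    cbind(data.frame(site_id = parts[1], station = parts[2],
                     layer = g$layer, stringsAsFactors = FALSE), row)
  }))
  wcsv(gs, "grainsize.csv")
  invisible(dir)
}

#' Read a survey directory back into a record set
#'
#' @param dir Directory written by [write_survey_dir()] (or assembled by
#'   hand in the same layout).
#' @return Record list suitable for [site_metric_table()].
#' @export
read_survey_dir <- function(dir) {
  rcsv <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing mandatory file: ", f)
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  registry <- rcsv("registry.csv")
  prof_df <- rcsv("profiles.csv")
  profiles <- lapply(split(prof_df, prof_df$site_id), function(p)
    elevation_profile(p$distance_m, p$elevation_m, 1L))
  profiles <- profiles[registry$site_id]
  dd <- rcsv("datums.csv")
  gs <- rcsv("grainsize.csv")
  pct_cols <- grep("^pct_", names(gs), value = TRUE)
  bounds <- as.numeric(sub("^pct_([0-9.eE+-]+)_.*", "\\1", pct_cols))
  last <- as.numeric(sub("^pct_[0-9.eE+-]+_([0-9.eE+-]+)mm$", "\\1",
                         pct_cols[length(pct_cols)]))
  bounds <- c(bounds, last)
  grains <- list()
  for (r in seq_len(nrow(gs))) {
    grains[[paste(gs$site_id[r], gs$station[r], sep = "|")]] <-
      grain_size_distribution(bounds, as.numeric(gs[r, pct_cols]),
                              station = gs$station[r], layer = gs$layer[r])
  }
  list(registry = registry, wrack = rcsv("wrack.csv"),
       loglines = rcsv("loglines.csv"), snorkel = rcsv("snorkel.csv"),
       fallout = rcsv("fallout.csv"), mllw = rcsv("mllw.csv"),
       vegetation = list(transects = rcsv("vegetation.csv"),
                         overhangs = rcsv("overhangs.csv"),
                         patches = rcsv("dunegrass_patches.csv"),
                         species = rcsv("vegetation_species.csv")),
       profiles = profiles,
       datums = tidal_datums(dd$mhhw[1], dd$msl[1], dd$mllw[1]),
       windfetch = rcsv("windfetch.csv"),
       grainsize = grains)
}

#' Validate every CSV in a survey directory against its schema
#'
#' Runs all record validators and collects violations instead of stopping
#' at the first one. A missing mandatory file is a fatal error.
#'
#' @param dir Survey directory.
#' @return Data frame with columns `component` and `message`; zero rows
#'   means the directory is clean.
#' @export
validate_survey_dir <- function(dir) {
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  missing <- .survey_files[!file.exists(file.path(dir, .survey_files))]
  if (length(missing))
    stop("missing mandatory file: ", paste(missing, collapse = ", "))
  rec <- read_survey_dir(dir)
  checks <- list(
    registry = function() validate_registry(rec$registry),
    wrack = function() validate_wrack(rec$wrack),
    loglines = function() validate_loglines(rec$loglines),
    snorkel = function() validate_snorkel(rec$snorkel),
    fallout = function() validate_fallout(rec$fallout),
    mllw = function() validate_mllw(rec$mllw),
    vegetation = function()
      validate_vegetation(rec$vegetation$transects,
                          rec$vegetation$overhangs,
                          rec$vegetation$patches, rec$vegetation$species))
  out <- data.frame(component = character(), message = character(),
                    stringsAsFactors = FALSE)
  for (nm in names(checks)) {
    msg <- tryCatch({ checks[[nm]](); NA_character_ },
                    error = function(e) conditionMessage(e))
    if (!is.na(msg))
      out <- rbind(out, data.frame(component = nm, message = msg,
                                   stringsAsFactors = FALSE))
  }
  out
}

## site-level assemblage matrix from a wide trap/quadrat frame
.site_assemblage <- function(x, id_cols) {
  taxa <- setdiff(names(x), id_cols)
  agg <- stats::aggregate(x[taxa], by = list(site_id = x$site_id), FUN = sum)
  m <- as.matrix(agg[, taxa, drop = FALSE])
  rownames(m) <- agg$site_id
  m
}

#' Run the full pipeline on simulated (or provided) records
#'
#' Chains simulate -> write -> read -> validate -> aggregate -> score ->
#' statistics and writes every product plus a JSON run report to
#' `out_dir`. Identical inputs and seed produce identical outputs.
#'
#' @param cfg A [simulation_config()]; ignored when `records` is supplied.
#' @param out_dir Output directory.
#' @param records Optional pre-built record list (skips simulation).
#' @param n_perm Permutations for the community statistics.
#' @return List of class `bluffbeach_run`: `table`, `scale_bar`,
#'   `permanova` (fallout and low-shore assemblages), `feeding_chisq`,
#'   `report`.
#' @export
run_pipeline <- function(cfg = simulation_config(), out_dir,
                         records = NULL, n_perm = 999) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(records)) records <- simulate_sites(cfg)
  raw_dir <- file.path(out_dir, "survey")
  write_survey_dir(records, raw_dir)
  rec <- read_survey_dir(raw_dir)
  viol <- validate_survey_dir(raw_dir)
  if (nrow(viol))
    stop("validation failed: ", viol$component[1], ": ", viol$message[1])

  tab <- site_metric_table(rec)
  utils::write.csv(tab, file.path(out_dir, "site_metric_table.csv"),
                   row.names = FALSE)
  sb <- scale_bar(tab)
  utils::write.csv(data.frame(treatment = names(sb$scores),
                              score = unname(sb$scores),
                              se = unname(sb$se)),
                   file.path(out_dir, "scale_bar.csv"), row.names = FALSE)

  reg <- rec$registry
  strata <- reg$region
  groups <- reg$treatment

  fo <- .site_assemblage(rec$fallout, .id_cols$fallout)[reg$site_id, ,
                                                        drop = FALSE]
  fo <- transform_abundance(rare_taxa_filter(fo), "log1")
  pv_fo <- permanova(bray_curtis(fo), groups, n_perm = n_perm,
                     strata = strata, seed = cfg$seed)

  ml <- .site_assemblage(rec$mllw, .id_cols$mllw)[reg$site_id, ,
                                                  drop = FALSE]
  ml <- transform_abundance(rare_taxa_filter(ml), "sqrt")
  pv_ml <- permanova(bray_curtis(ml), groups, n_perm = n_perm,
                     strata = strata, seed = cfg$seed + 1L)

  feeding <- feeding_contingency(rec$snorkel, reg)
  chi <- chi_square_independence(feeding)

  stats_out <- list(
    fallout_permanova = list(pseudo_F = pv_fo$pseudo_F,
                             p_value = pv_fo$p_value),
    mllw_permanova = list(pseudo_F = pv_ml$pseudo_F,
                          p_value = pv_ml$p_value),
    feeding_chisq = list(statistic = chi$statistic, df = chi$df,
                         p_value = chi$p_value))
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- list.files(raw_dir, full.names = TRUE)
  report <- list(
    seed = cfg$seed,
    n_sites = nrow(reg),
    record_counts = list(wrack = nrow(rec$wrack),
                         loglines = nrow(rec$loglines),
                         snorkel = nrow(rec$snorkel),
                         fallout = nrow(rec$fallout),
                         mllw = nrow(rec$mllw)),
    inputs_digest = unname(tools::md5sum(sort(files))),
    outputs = c("site_metric_table.csv", "scale_bar.csv", "stats.json",
                "run_report.json"),
    scores = as.list(sb$scores))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(table = tab, scale_bar = sb,
                 permanova = list(fallout = pv_fo, mllw = pv_ml),
                 feeding_chisq = chi, report = report),
            class = "bluffbeach_run")
}

#' @export
print.bluffbeach_run <- function(x, ...) {
  cat("bluffbeach pipeline run:", x$report$n_sites, "sites\n\n")
  print(x$scale_bar)
  cat(sprintf("\nFallout assemblage PERMANOVA: F = %.2f, p = %.4g\n",
              x$permanova$fallout$pseudo_F, x$permanova$fallout$p_value))
  cat(sprintf("Low-shore assemblage PERMANOVA: F = %.2f, p = %.4g\n",
              x$permanova$mllw$pseudo_F, x$permanova$mllw$p_value))
  cat(sprintf("Feeding chi-squared: X2 = %.2f (df %d), p = %.4g\n",
              x$feeding_chisq$statistic, x$feeding_chisq$df,
              x$feeding_chisq$p_value))
  invisible(x)
}
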