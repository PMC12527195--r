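## Hierarchical synthetic survey generator. Site-level expected metric values
## are treatment means plus mean-zero normal region effects; replicate-level
## records are drawn around the site expectation with distribution families
## mirroring the field data: logit-normal for bounded percentages,
## negative-binomial for counts, truncated normal for continuous positive
## quantities, multinomial assemblage composition. At zero noise every draw
## collapses to a deterministic expected-value allocation (integer counts
## summing to round(n * mu)), which is what makes exact parameter-recovery
## checks possible with integer-valued records.

.pct_metrics <- function() {
  c("% Wrack Cover", "% Terrestrial Wrack", "% Overhanging Vegetation",
    "% Supratidal Vegetation", "% Eelgrass", "% Sand MHHW", "% Sand MLLW",
    "Juv. Salmon Feeding Observations (%)")
}

.default_fallout_taxa <- function() {
  flying <- c(diptera = 0.30, hymenoptera = 0.20, hemiptera = 0.15,
              coleoptera = 0.10)
  base <- c(flying, acari = 0.10, collembola = 0.10, araneae = 0.05)
  rl <- c(acari = 0.55, collembola = 0.36, diptera = 0.04, hemiptera = 0.02,
          hymenoptera = 0.02, coleoptera = 0.00, araneae = 0.01)
  list(ProtectHigh = base / sum(base),
       ProtectLow = base / sum(base),
       RestoreHigh = base / sum(base),
       RestoreLow = rl[names(base)] / sum(rl))
}

.default_mllw_taxa <- function() {
  base <- c(eelgrass = 0.08, ulvoid_algae = 0.22, barnacle = 0.18,
            littorina = 0.14, shore_crab = 0.10, oyster = 0.08,
            mussel = 0.08, limpet = 0.06, fucus = 0.04, polychaete = 0.02)
  rl <- c(eelgrass = 0.30, ulvoid_algae = 0.25, barnacle = 0.10,
          littorina = 0.10, shore_crab = 0.06, oyster = 0.06,
          mussel = 0.05, limpet = 0.04, fucus = 0.02, polychaete = 0.02)
  list(ProtectHigh = base / sum(base), ProtectLow = base / sum(base),
       RestoreHigh = base / sum(base), RestoreLow = rl / sum(rl))
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: the 4 x 30 target
#' treatment-mean table (default: the reference field means), region
#' random-effect scale, count overdispersion, replicate counts per record
#' type (defaults match the field protocol: 10 wrack quadrats, 5 log points,
#' 7 fallout traps, 10 low-shore quadrats, 4 snorkel transects in each of 2
#' seasons), per-treatment assemblage composition profiles, tidal datums and
#' wind/fetch placement.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param treatment_means Data frame like [reference_treatment_means()].
#' @param region_sd Region random-effect SD as a fraction of each metric's
#'   mean magnitude (default 0.12; 0 disables region effects).
#' @param dispersion Negative-binomial overdispersion coefficient for counts
#'   (variance `mu + dispersion * mu^2`); 0 switches to deterministic
#'   expected-count allocation.
#' @param cv Coefficient of variation for continuous positive replicate
#'   draws (0 = exact).
#' @param logit_sd Logit-scale SD for percentage replicate draws (0 = exact).
#' @param replicates Named list: `wrack`, `loglines`, `fallout`, `mllw`,
#'   `snorkel` (transects per season).
#' @param events_per_transect Named per-treatment mean number of juvenile
#'   salmon observation events per snorkel transect.
#' @param fallout_composition,mllw_composition Per-treatment taxon
#'   probability vectors (must sum to 1).
#' @param datums A [tidal_datums()] object (default MHHW 3.3, MSL 2.0,
#'   MLLW 0.0 m, a typical Puget Sound tidal frame).
#' @param facing_degrees Shoreline facing used for wind assignment
#'   (default 190, southerly).
#' @param profile_noise SD of vertical jitter on profile interior points, m.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              treatment_means = reference_treatment_means(),
                              region_sd = 0.12,
                              dispersion = 0.5,
                              cv = 0.25,
                              logit_sd = 0.4,
                              replicates = list(wrack = 10, loglines = 5,
                                                fallout = 7, mllw = 10,
                                                snorkel = 4),
                              events_per_transect = c(ProtectHigh = 0.4,
                                                      ProtectLow = 0.175,
                                                      RestoreHigh = 0.25,
                                                      RestoreLow = 0.3),
                              fallout_composition = .default_fallout_taxa(),
                              mllw_composition = .default_mllw_taxa(),
                              datums = tidal_datums(3.3, 2.0, 0.0),
                              facing_degrees = 190,
                              profile_noise = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  tm <- .tm_matrix(treatment_means)
  if (!all(is.finite(tm))) stop("treatment means must be finite")
  for (comp in list(fallout_composition, mllw_composition)) {
    stopifnot(identical(sort(names(comp)), sort(bb_treatments())))
    for (p in comp) {
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("composition profiles must be non-negative and sum to 1")
    }
  }
  stopifnot(all(c("wrack", "loglines", "fallout", "mllw", "snorkel") %in%
                  names(replicates)))
  structure(list(seed = as.integer(seed), tm = tm,
                 region_sd = region_sd, dispersion = dispersion, cv = cv,
                 logit_sd = logit_sd, replicates = replicates,
                 events_per_transect = events_per_transect,
                 fallout_composition = fallout_composition,
                 mllw_composition = mllw_composition,
                 datums = datums, facing_degrees = facing_degrees,
                 profile_noise = profile_noise),
            class = "simulation_config")
}

## ---- elementary draws --------------------------------------------------

## n counts with mean mu: NB for dispersion > 0, else deterministic integers
## summing to round(n * mu)
.count_draw <- function(mu, n, dispersion) {
  if (mu <= 0) return(integer(n))
  if (dispersion > 0)
    return(stats::rnbinom(n, mu = mu, size = 1 / dispersion))
  tot <- round(mu * n)
  base <- tot %/% n
  out <- rep.int(base, n)
  rem <- tot - base * n
  if (rem > 0) out[seq_len(rem)] <- out[seq_len(rem)] + 1L
  as.integer(out)
}

## n percentages in [0,100] around p (logit-normal, median-parameterised)
.pct_draw <- function(p, n, logit_sd) {
  if (p <= 0) return(numeric(n))
  if (p >= 100) return(rep(100, n))
  if (logit_sd <= 0) return(rep(p, n))
  100 * stats::plogis(stats::rnorm(n, stats::qlogis(p / 100), logit_sd))
}

## n non-negative continuous values around mu
.pos_draw <- function(mu, n, cv) {
  if (mu <= 0) return(numeric(n))
  if (cv <= 0) return(rep(mu, n))
  pmax(0, stats::rnorm(n, mu, cv * mu))
}

## distribute `total` units over n slots capped elementwise by `cap`
.capped_alloc <- function(total, cap) {
  out <- integer(length(cap))
  total <- min(total, sum(cap))
  while (total > 0) {
    open <- which(out < cap)
    take <- open[seq_len(min(length(open), total))]
    out[take] <- out[take] + 1L
    total <- total - length(take)
  }
  out
}

## site-level expected metric values: treatment mean + region effect
.expected_metrics <- function(cfg, registry) {
  metrics <- bb_metric_names()
  tm <- cfg$tm
  e <- matrix(NA_real_, nrow(registry), length(metrics),
              dimnames = list(registry$site_id, metrics))
  scale_m <- rowMeans(abs(tm))
  for (m in metrics) {
    delta <- if (cfg$region_sd > 0 && scale_m[m] > 0)
      stats::rnorm(length(bb_regions()), 0, cfg$region_sd * scale_m[m])
    else rep(0, length(bb_regions()))
    names(delta) <- bb_regions()
    v <- tm[m, registry$treatment] + delta[registry$region]
    if (m != "Relative Encroachment (m)") v <- pmax(v, 0)
    if (m %in% .pct_metrics()) v <- pmin(v, 100)
    # zero treatment means stay exactly zero (structural zeros)
    v[tm[m, registry$treatment] == 0] <- 0
    e[, m] <- v
  }
  # terrestrial wrack cannot exceed total wrack cover
  e[, "% Terrestrial Wrack"] <- pmin(e[, "% Terrestrial Wrack"],
                                     e[, "% Wrack Cover"])
  # wave targets must stay hindcastable for the design wind event
  sc <- assign_wind(cfg$facing_degrees)
  u <- sc$speed_kmh / 3.6
  ua <- 0.71 * u^1.23
  hs_max <- min(0.2433 * ua^2 / 9.81,
                .smb_hs(ua, (sc$duration_h * 3600 * 9.81 /
                               (68.8 * ua))^1.5 * ua^2 / 9.81))
  e[, "Wave Height (m)"] <- pmin(pmax(e[, "Wave Height (m)"], 0.05),
                                 0.98 * hs_max)
  e
}

## ---- profile and grain-size generators --------------------------------

.profile_for <- function(encroachment, slope, width, datums, noise = 0) {
  toe <- datums$mhhw - encroachment
  if (toe <= datums$mllw)
    stop("infeasible geometry: toe elevation at or below MLLW")
  if (toe <= datums$msl)
    stop("infeasible geometry: toe elevation at or below MSL")
  if (slope <= 0) stop("infeasible geometry: non-positive slope")
  x_msl <- (toe - datums$msl) / slope
  if (width <= x_msl)
    stop("infeasible geometry: width places MLLW landward of MSL")
  xm1 <- x_msl / 2
  em1 <- toe - slope * xm1
  xm2 <- (x_msl + width) / 2
  em2 <- (datums$msl + datums$mllw) / 2
  if (noise > 0) {
    em1 <- min(max(em1 + stats::rnorm(1, 0, noise), datums$msl + 1e-3),
               toe - 1e-3)
    em2 <- min(max(em2 + stats::rnorm(1, 0, noise), datums$mllw + 1e-3),
               datums$msl - 1e-3)
  }
  elevation_profile(
    distance = c(0, xm1, x_msl, xm2, width, width + 5),
    elevation = c(toe, em1, datums$msl, em2, datums$mllw,
                  datums$mllw - 0.3),
    toe_index = 1L)
}

#' Simulate cross-shore profiles and tidal datums
#'
#' Builds, for each site, a piecewise-linear profile whose toe elevation
#' reproduces the site's expected relative encroachment and whose toe-to-MSL
#' slope and toe-to-MLLW width equal the expected metric values (optionally
#' with small seeded vertical noise on interior points).
#'
#' @param cfg A [simulation_config()].
#' @param registry Optional site registry (default: the standard 20-site
#'   design).
#' @return List with `profiles` (named by site_id), `datums`, and the
#'   expected-metric matrix used.
#' @export
simulate_profiles <- function(cfg, registry = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  if (is.null(registry)) registry <- .default_registry(cfg)
  e <- .expected_metrics(cfg, registry)
  profiles <- lapply(seq_len(nrow(registry)), function(i)
    .profile_for(e[i, "Relative Encroachment (m)"],
                 e[i, "Beach Slope (m/m) Toe-MSL"],
                 e[i, "Beach Width (m) Toe-MLLW"],
                 cfg$datums, cfg$profile_noise))
  names(profiles) <- registry$site_id
  list(profiles = profiles, datums = cfg$datums, expected = e)
}

.default_grain_ladder <- function() 2^seq(8, -4, by = -0.5)  # 256 .. 0.0625 mm

.discretize_phinormal <- function(mu, sigma, ladder_mm) {
  phi <- -log2(ladder_mm)
  cdf <- stats::pnorm(phi, mu, sigma)
  p <- diff(cdf)
  p / sum(p) * 100
}

#' Simulate a grain-size distribution matching sorting and sand targets
#'
#' Tunes a normal distribution on the phi scale, discretized to the class
#' ladder, so that [folk_ward()] recovers the target geometric sorting and
#' [percent_sand()] the target percent sand. Errors with a diagnostic when
#' the target is unattainable on the given ladder (tolerance: 10% on
#' sorting, 5 percentage points on sand).
#'
#' @param target_sorting Target geometric sorting, >= 1.
#' @param target_sand Target percent sand in [0, 100].
#' @param ladder_mm Descending class-bound ladder (default half-phi steps,
#'   256 to 0.0625 mm).
#' @param station,layer Passed to [grain_size_distribution()].
#' @return A `grain_size_distribution`.
#' @export
simulate_grainsize_one <- function(target_sorting, target_sand,
                                   ladder_mm = .default_grain_ladder(),
                                   station = "MHHW", layer = "surface") {
  # percentile interpolation across finite-width classes imposes a sorting
  # floor of about 1.2 on a half-phi ladder; clamp targets to what the
  # ladder can express
  target_sorting <- max(target_sorting, 1.25)
  sigma0 <- max(log2(target_sorting), 0.05)
  # cap the sand target at what a phi-normal of this spread can reach
  max_sand <- 100 * (2 * stats::pnorm(2.5 / sigma0) - 1)
  target_sand <- min(max(target_sand, 0), 0.98 * max_sand)
  obj <- function(par) {
    p <- .discretize_phinormal(par[1], exp(par[2]), ladder_mm)
    g <- grain_size_distribution(ladder_mm, p, station, layer)
    fw <- folk_ward(g)
    (log(fw$sorting_geometric / target_sorting) / 0.02)^2 +
      ((percent_sand(g) - target_sand) / 1)^2
  }
  # analytic start: place the phi-normal on the coarse side of the sand
  # window so its sand fraction matches the target, then refine on the
  # discretized ladder
  sand_of <- function(mu) 100 * (stats::pnorm((4 - mu) / sigma0) -
                                   stats::pnorm((-1 - mu) / sigma0))
  mu0 <- if (sand_of(1.5) <= target_sand) 1.5
         else stats::uniroot(function(mu) sand_of(mu) - target_sand,
                             c(-9, 1.5), tol = 1e-8)$root
  fit <- stats::optim(c(mu0, log(sigma0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  p <- .discretize_phinormal(fit$par[1], exp(fit$par[2]), ladder_mm)
  g <- grain_size_distribution(ladder_mm, p, station, layer)
  fw <- folk_ward(g)
  if (abs(fw$sorting_geometric / target_sorting - 1) > 0.10 ||
      abs(percent_sand(g) - target_sand) > 5)
    stop(sprintf(paste0("unattainable grain-size target on this ladder: ",
                        "wanted sorting %.2f / sand %.1f, reached ",
                        "%.2f / %.1f"),
                 target_sorting, target_sand,
                 fw$sorting_geometric, percent_sand(g)))
  g
}

#' Simulate grain-size distributions for every site and station
#'
#' @inheritParams simulate_profiles
#' @return Named list of `grain_size_distribution`s keyed
#'   `<site_id>|<station>`.
#' @export
simulate_grainsize <- function(cfg, registry = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  if (is.null(registry)) registry <- .default_registry(cfg)
  e <- .expected_metrics(cfg, registry)
  out <- list()
  for (i in seq_len(nrow(registry))) {
    s <- registry$site_id[i]
    out[[paste(s, "MHHW", sep = "|")]] <-
      simulate_grainsize_one(e[i, "Normalized Sorting MHHW"],
                             e[i, "% Sand MHHW"], station = "MHHW")
    out[[paste(s, "MLLW", sep = "|")]] <-
      simulate_grainsize_one(e[i, "Normalized Sorting MLLW"],
                             e[i, "% Sand MLLW"], station = "MLLW")
  }
  out
}

## standard 20-site design: one site per treatment x region
.default_registry <- function(cfg) {
  grid <- expand.grid(treatment = bb_treatments(), region = bb_regions(),
                      stringsAsFactors = FALSE)
  data.frame(site_id = paste(grid$region, grid$treatment, sep = "_"),
             treatment = grid$treatment, region = grid$region,
             facing_degrees = cfg$facing_degrees,
             bluff_height_m = 0, bluff_exposure_m2 = 0, toe_index = 1L,
             stringsAsFactors = FALSE)
}

#' Simulate a complete survey record set
#'
#' Generates every raw input the aggregation pipeline consumes for the
#' standard 20-site design (4 treatments x 5 regions): site registry, wrack
#' quadrats, log-line points, seasonal snorkel transects, fallout traps,
#' low-shore quadrats, vegetation transects, elevation profiles, wind/fetch
#' specifications and grain-size tables. Deterministic for a fixed seed.
#'
#' @param cfg A [simulation_config()].
#' @return List of records (see [site_metric_table()]) plus `expected`
#'   (the site-level expected metric matrix) and `config`.
#' @examples
#' rec <- simulate_sites(simulation_config(seed = 42))
#' tab <- site_metric_table(rec)
#' @export
simulate_sites <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  registry <- .default_registry(cfg)
  e <- .expected_metrics(cfg, registry)
  n_sites <- nrow(registry)
  disp <- cfg$dispersion

  registry$bluff_height_m <- e[, "Bluff Height (m)"]
  registry$bluff_exposure_m2 <- e[, "Bluff Exposure (m2)"]

  ## site-level counts allocated across each treatment's sites so treatment
  ## means recover exactly at zero dispersion
  site_count <- function(metric) {
    out <- numeric(n_sites)
    for (tr in bb_treatments()) {
      w <- which(registry$treatment == tr)
      mus <- e[w, metric]
      if (disp > 0) {
        out[w] <- stats::rnbinom(length(w), mu = mus, size = 1 / disp)
      } else {
        out[w] <- .count_draw(mean(mus), length(w), 0)
      }
    }
    out
  }
  fallen_trees <- site_count("Fallen Tree Count")
  native_rich <- site_count("Native Vegetation Taxa Richness")

  wrack_l <- list(); log_l <- list(); sn_l <- list(); fo_l <- list()
  ml_l <- list(); vt_l <- list(); ovh_l <- list(); pat_l <- list()
  spp_l <- list(); wf_l <- list()

  fo_taxa <- names(cfg$fallout_composition[[1]])
  ml_taxa <- names(cfg$mllw_composition[[1]])

  for (i in seq_len(n_sites)) {
    s <- registry$site_id[i]
    tr <- registry$treatment[i]

    ## wrack quadrats
    nw <- cfg$replicates$wrack
    tot <- .pct_draw(e[i, "% Wrack Cover"], nw, cfg$logit_sd)
    f_ter <- if (e[i, "% Wrack Cover"] > 0)
      e[i, "% Terrestrial Wrack"] / e[i, "% Wrack Cover"] else 0
    ter <- tot * f_ter
    rest <- tot - ter
    wrack_l[[s]] <- data.frame(
      site_id = s, percent_cover_total = tot,
      percent_algae = 0.7 * rest, percent_eelgrass = 0.3 * rest,
      percent_terrestrial = ter,
      wrack_width_m = .pos_draw(e[i, "Wrack Width (m)"], nw, cfg$cv),
      wrack_depth_cm = .pos_draw(e[i, "Wrack Depth (cm)"], nw, cfg$cv),
      stringsAsFactors = FALSE)

    ## log lines
    nl <- cfg$replicates$loglines
    lc <- .count_draw(e[i, "Log Count"], nl, disp)
    mu_b <- min(e[i, "Count Partially Buried Logs"], e[i, "Log Count"])
    if (disp > 0) {
      pb <- if (e[i, "Log Count"] > 0) mu_b / e[i, "Log Count"] else 0
      bc <- stats::rbinom(nl, lc, min(pb, 1))
    } else {
      bc <- .capped_alloc(round(mu_b * nl), lc)
    }
    log_l[[s]] <- data.frame(
      site_id = s, log_count = lc, buried_count = bc,
      log_line_width_m = .pos_draw(e[i, "Width of Log Line (m)"], nl,
                                   cfg$cv),
      fallen_trees_site_total = fallen_trees[i], stringsAsFactors = FALSE)

    ## snorkel transects (two seasons)
    nt <- cfg$replicates$snorkel * 2L
    season <- rep(c("spring", "summer"), each = cfg$replicates$snorkel)
    mu_ev <- cfg$events_per_transect[[tr]]
    ev <- .count_draw(mu_ev, nt, disp)
    p_feed <- e[i, "Juv. Salmon Feeding Observations (%)"] / 100
    if (disp > 0) {
      fe <- stats::rbinom(nt, ev, min(p_feed, 1))
    } else {
      fe <- .capped_alloc(round(p_feed * sum(ev)), ev)
    }
    sn_l[[s]] <- data.frame(
      site_id = s, season = season, transect_length_m = 50,
      visibility_m = 2,
      total_fish = .count_draw(e[i, "Total Fish Density (100m-2)"], nt,
                               disp),
      juv_salmon = .count_draw(e[i, "Juvenile Salmon Density (100m-2)"],
                               nt, disp),
      forage_fish = .count_draw(e[i, "Forage Fish Density (100m-2)"], nt,
                                disp),
      other_fish = .count_draw(1, nt, disp),
      feeding_observed = fe, salmon_observation_events = ev,
      stringsAsFactors = FALSE)

    ## fallout traps
    nf <- cfg$replicates$fallout
    prob <- cfg$fallout_composition[[tr]]
    mu_tot <- e[i, "Fallout Trap Density (m-2)"] * 0.10
    pos_taxa <- fo_taxa[prob > 0]
    rich <- pmin(pmax(.count_draw(e[i, "Fallout Trap Taxa Richness"], nf,
                                  disp), 0L), length(pos_taxa))
    tot_n <- pmax(.count_draw(mu_tot, nf, disp), rich)
    counts <- matrix(0L, nf, length(fo_taxa),
                     dimnames = list(NULL, fo_taxa))
    for (k in seq_len(nf)) {
      r <- rich[k]
      if (r == 0) next
      chosen <- if (disp > 0)
        sample(pos_taxa, r, prob = prob[pos_taxa])
      else names(sort(prob, decreasing = TRUE))[seq_len(r)]
      pc <- prob[chosen] / sum(prob[chosen])
      alloc <- rep(1L, r)
      extra <- tot_n[k] - r
      if (extra > 0) {
        if (disp > 0) {
          add <- stats::rmultinom(1, extra, pc)[, 1]
        } else {
          add <- floor(extra * pc)
          left <- extra - sum(add)
          if (left > 0) {
            o <- order(extra * pc - add, decreasing = TRUE)
            add[o[seq_len(left)]] <- add[o[seq_len(left)]] + 1
          }
        }
        alloc <- alloc + as.integer(add)
      }
      counts[k, chosen] <- alloc
    }
    fo_l[[s]] <- data.frame(site_id = s, trap_id = seq_len(nf),
                            trap_area_m2 = 0.10, deploy_hours = 2,
                            counts, stringsAsFactors = FALSE,
                            check.names = FALSE)

    ## low-shore quadrats
    nq <- cfg$replicates$mllw
    probm <- cfg$mllw_composition[[tr]]
    eg <- .pct_draw(e[i, "% Eelgrass"], nq, cfg$logit_sd)
    richq <- pmin(pmax(.count_draw(e[i, "Biota Taxa Richness"], nq, disp),
                       0L), length(ml_taxa))
    cov <- matrix(0, nq, length(ml_taxa), dimnames = list(NULL, ml_taxa))
    others <- setdiff(ml_taxa, "eelgrass")
    prob_o <- probm[others] / sum(probm[others])
    for (k in seq_len(nq)) {
      r <- richq[k]
      has_eg <- eg[k] > 0
      r_other <- max(r - as.integer(has_eg), 0L)
      r_other <- min(r_other, length(others))
      chosen <- if (disp > 0 && r_other > 0)
        sample(others, r_other, prob = prob_o)
      else names(sort(prob_o, decreasing = TRUE))[seq_len(r_other)]
      if (has_eg) cov[k, "eelgrass"] <- eg[k]
      if (r_other > 0) {
        base_cov <- 60 * prob_o[chosen] / max(prob_o[chosen])
        if (cfg$logit_sd > 0)
          base_cov <- base_cov *
            exp(stats::rnorm(r_other, 0, cfg$logit_sd / 2))
        cov[k, chosen] <- pmin(base_cov, 100)
      }
    }
    ml_l[[s]] <- data.frame(site_id = s, quadrat_id = seq_len(nq),
                            quadrat_area_m2 = 0.25, cov,
                            stringsAsFactors = FALSE, check.names = FALSE)

    ## vegetation
    len <- 50
    ov_len <- e[i, "% Overhanging Vegetation"] / 100 * len
    if (cfg$logit_sd > 0 && e[i, "% Overhanging Vegetation"] > 0)
      ov_len <- .pct_draw(e[i, "% Overhanging Vegetation"], 1,
                          cfg$logit_sd) / 100 * len
    vt_l[[s]] <- data.frame(
      site_id = s, transect_length_m = len,
      supratidal_percent = .pct_draw(e[i, "% Supratidal Vegetation"], 1,
                                     cfg$logit_sd),
      stringsAsFactors = FALSE)
    if (ov_len > 0)
      ovh_l[[s]] <- data.frame(site_id = s, start_m = 0,
                               end_m = min(ov_len, len),
                               stringsAsFactors = FALSE)
    if (e[i, "Dunegrass Patch Width (m)"] > 0)
      pat_l[[s]] <- data.frame(
        site_id = s,
        patch_width_m = .pos_draw(e[i, "Dunegrass Patch Width (m)"], 3,
                                  cfg$cv),
        stringsAsFactors = FALSE)
    k_nat <- native_rich[i]
    spp <- data.frame(
      site_id = s,
      species = c(if (k_nat > 0) paste0("native_sp", seq_len(k_nat)),
                  "blackberry", "ivy"),
      status = c(rep("native", k_nat), "introduced", "introduced"),
      stringsAsFactors = FALSE)
    spp_l[[s]] <- spp

    ## wind / fetch placed so the hindcast reproduces the wave target
    sc <- assign_wind(registry$facing_degrees[i])
    wf_l[[s]] <- data.frame(
      site_id = s, facing_degrees = registry$facing_degrees[i],
      fetch_m = solve_fetch(e[i, "Wave Height (m)"], sc),
      shoreline_angle_deg = 90, stringsAsFactors = FALSE)
  }

  profiles <- lapply(seq_len(n_sites), function(i)
    .profile_for(e[i, "Relative Encroachment (m)"],
                 e[i, "Beach Slope (m/m) Toe-MSL"],
                 e[i, "Beach Width (m) Toe-MLLW"],
                 cfg$datums, cfg$profile_noise))
  names(profiles) <- registry$site_id

  grains <- list()
  for (i in seq_len(n_sites)) {
    s <- registry$site_id[i]
    grains[[paste(s, "MHHW", sep = "|")]] <-
      simulate_grainsize_one(e[i, "Normalized Sorting MHHW"],
                             e[i, "% Sand MHHW"], station = "MHHW")
    grains[[paste(s, "MLLW", sep = "|")]] <-
      simulate_grainsize_one(e[i, "Normalized Sorting MLLW"],
                             e[i, "% Sand MLLW"], station = "MLLW")
  }

  list(registry = registry,
       wrack = do.call(rbind, c(wrack_l, make.row.names = FALSE)),
       loglines = do.call(rbind, c(log_l, make.row.names = FALSE)),
       snorkel = do.call(rbind, c(sn_l, make.row.names = FALSE)),
       fallout = do.call(rbind, c(fo_l, make.row.names = FALSE)),
       mllw = do.call(rbind, c(ml_l, make.row.names = FALSE)),
       vegetation = list(
         transects = do.call(rbind, c(vt_l, make.row.names = FALSE)),
         overhangs = do.call(rbind, c(ovh_l, make.row.names = FALSE)),
         patches = if (length(pat_l))
           do.call(rbind, c(pat_l, make.row.names = FALSE))
         else data.frame(site_id = character(), patch_width_m = numeric()),
         species = do.call(rbind, c(spp_l, make.row.names = FALSE))),
       profiles = profiles,
       datums = cfg$datums,
       windfetch = do.call(rbind, c(wf_l, make.row.names = FALSE)),
       grainsize = grains,
       expected = e,
       config = cfg)
}
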