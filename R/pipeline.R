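#' Pipeline configuration
#'
#' Collects the thresholds and constants the stages share: the kappa gate
#' (0.4), the minimum modellable record count (8), the bootstrap/CV cut
#' (30), the threshold percentile (10), the background size (10,000), the
#' spatial resolution cut (2 km), the studentized-residual outlier cut (3),
#' the scenario midpoint years (2025/2055/2085 for the 2020s/2050s/2080s)
#' and the present reference year (1975).
#'
#' @param kappa_gate,min_records,replicate_cut,percentile,background_n
#'   numeric thresholds (see description).
#' @param resolution_cut_km,outlier_resid numeric thresholds.
#' @param scenario_years named vector of projection years per future period.
#' @param present_year reference year for dispersal elapsed time.
#' @param current_buffer_years dispersal-years buffering the current-period
#'   clip region (default 1).
#' @param beta_reg regularization multiplier for the suitability fits.
#' @param seed integer master seed.
#' @return named list.
#' @export
pipelineConfig <- function(kappa_gate = 0.4, min_records = 8L,
                           replicate_cut = 30L, percentile = 10,
                           background_n = 10000L, resolution_cut_km = 2,
                           outlier_resid = 3,
                           scenario_years = c(f2020s = 2025, f2050s = 2055,
                                              f2080s = 2085),
                           present_year = 1975, current_buffer_years = 1,
                           beta_reg = 1, seed = 1L) {
  stopifnot(kappa_gate > 0, min_records > 0, replicate_cut > 0,
            percentile > 0, background_n > 0, resolution_cut_km > 0,
            outlier_resid > 0, all(diff(scenario_years) > 0))
  as.list(environment())
}

# Suitability scores at SWD rows under a variant: habitat-restricted
# variants zero the score wherever the land-cover class is unoccupied.
variantScores <- function(scores, swd, restricted, landcover, grid,
                          occupied) {
  if (!restricted) return(scores)
  ci <- cellIndex(grid, swd$lon, swd$lat)
  cls <- rep(NA_integer_, nrow(swd))
  ok <- !is.na(ci[, 1L])
  cls[ok] <- landcover[cbind(ci[ok, 1L], ci[ok, 2L])]
  scores[!is.na(cls) & !(cls %in% occupied)] <- 0
  scores
}

# Replicate-averaged kappa for one variant, scored on all input records.
evaluateVariant <- function(reps, presence, background, percentile,
                            restricted = FALSE, landcover = NULL,
                            grid = NULL, occupied = NULL) {
  acc <- NULL; nrep <- 0L
  for (r in seq_along(reps@models)) {
    test_idx <- seq_len(nrow(presence))
    m <- reps@models[[r]]
    adj <- function(sc, swd) variantScores(sc, swd, restricted, landcover,
                                           grid, occupied)
    train <- adj(predictPB(m, presence), presence)
    thr <- threshold10ptp(train, percentile)
    sp <- adj(predictPB(m, presence[test_idx, , drop = FALSE]),
              presence[test_idx, , drop = FALSE])
    sb <- adj(predictPB(m, background), background)
    met <- computeMetrics(confusionCounts(sp >= thr, sb >= thr), sp, sb)
    met$degenerate <- NULL
    acc <- if (is.null(acc)) met else Map(`+`, acc, met)
    nrep <- nrep + 1L
  }
  lapply(acc, `/`, nrep)
}

#' Run the full modelling pipeline on a synthetic world
#'
#' Executes the stages in order for every species: occurrence QC,
#' period-matched SWD extraction, temporally stratified target-group
#' background sampling, replicate suitability fits on the four input/habitat
#' variants, kappa evaluation and the joint expert/Kappa gate (expert
#' ratings emulated from truth overlap), dispersal-buffered MCP clipping,
#' projection to the past and the three future periods, change metrics, and
#' the comparative stage (GLS group trends and PGLS trait regressions with
#' AICc model averaging) on the modellable species. Unmodellable species
#' are still projected, flagged for reference only, and their cells mask
#' the richness-change raster as uncertain.
#'
#' @param world a world object from [genWorld()].
#' @param out_dir output directory; created if needed. CSV outputs
#'   (decisions, metrics, change summaries, comparative tables, QC report)
#'   and a JSON manifest are written there.
#' @param config a [pipelineConfig()] list.
#' @return invisibly, a list with the per-species decisions, change
#'   summaries, comparative results and the richness-change matrix.
#' @export
runPipeline <- function(world, out_dir, config = pipelineConfig()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stacks <- world$stacks
  grid <- stacks$current
  sw <- list(pre1950 = stacks$past, post1950 = stacks$current)
  base_vars <- names(stacks$current@layers)
  spnames <- world$species$species

  ## occurrence QC
  qc <- list(); clean <- list()
  for (sp in spnames) {
    res <- qcSpecies(world$records[world$records$species == sp, ],
                     accepted_names = spnames, grid = grid,
                     max_precision_km = config$resolution_cut_km)
    clean[[sp]] <- res$records
    qc[[sp]] <- cbind(species = sp, res$report)
  }
  all_clean <- do.call(rbind, clean)
  qc_report <- do.call(rbind, qc)

  ## target-group background cells (global, reused across species)
  eligible <- targetGroupCells(all_clean, grid)

  decisions <- list(); metrics_rows <- list(); change_rows <- list()
  period_rows <- list(); binary_past <- list(); binary_2080 <- list()
  modellable <- character()
  for (si in seq_along(spnames)) {
    sp <- spnames[si]
    rec <- clean[[sp]]
    scheme <- chooseReplication(nrow(rec), config$min_records,
                                config$replicate_cut)
    if (scheme == "insufficient") {
      decisions[[sp]] <- data.frame(species = sp, n_records = nrow(rec),
                                    scheme = scheme, variant = NA,
                                    kappa = NA_real_, rating = NA,
                                    decision = "unmodellable_by_data")
      next
    }
    pres <- extractSWD(rec, sw)
    bg <- suppressWarnings(
      sampleBackground(eligible, periodCounts(rec), sw,
                       n_points = config$background_n,
                       seed = config$seed + si))
    occ_ci <- cellIndex(grid, rec$lon, rec$lat)
    occ_cls <- world$landcover[occ_ci[!is.na(occ_ci[, 1L]), , drop = FALSE]]
    occupied <- sort(unique(occ_cls[!is.na(occ_cls)]))

    ## four variants: i/ii use pre+post data, iii/iv post-only;
    ## ii/iv are habitat-restricted
    pres_post <- pres[pres$period == "post1950", , drop = FALSE]
    reps_all <- fitReplicates(scheme, pres, bg, base_vars,
                              config$beta_reg, seed = config$seed + si)
    scheme_post <- chooseReplication(nrow(pres_post), config$min_records,
                                    config$replicate_cut)
    reps_post <- if (scheme_post == "insufficient") NULL
    else fitReplicates(scheme_post, pres_post, bg, base_vars,
                       config$beta_reg, seed = config$seed + si)
    variant_defs <- list(
      i = list(reps = reps_all, pres = pres, restricted = FALSE),
      ii = list(reps = reps_all, pres = pres, restricted = TRUE),
      iii = list(reps = reps_post, pres = pres_post, restricted = FALSE),
      iv = list(reps = reps_post, pres = pres_post, restricted = TRUE))
    variant_defs <- Filter(function(v) !is.null(v$reps), variant_defs)
    kap <- numeric(); met_by_var <- list()
    for (v in names(variant_defs)) {
      vd <- variant_defs[[v]]
      met <- evaluateVariant(vd$reps, vd$pres, bg, config$percentile,
                             vd$restricted, world$landcover, grid, occupied)
      kap[v] <- met$kappa
      met_by_var[[v]] <- met
      metrics_rows[[paste(sp, v)]] <-
        data.frame(species = sp, variant = v,
                   as.data.frame(met[c("auc", "omission_rate", "sensitivity",
                                       "specificity", "proportion_correct",
                                       "kappa", "tss")]))
    }

    ## expert rating emulated from truth overlap of the best-kappa variant
    best <- selectVariant(kap)
    vd <- variant_defs[[best]]
    mean_scores <- predictRows(vd$reps, vd$pres)
    tau <- threshold10ptp(mean_scores, config$percentile)
    pred_cur <- predictMap(vd$reps, stacks$current)
    if (vd$restricted)
      pred_cur <- landClassMask(pred_cur, world$landcover, occupied)
    truth_bin <- ifelse(world$truth[[sp]]$truth >= 0.5, 1L, 0L)
    rating <- rateByOverlap(truth_bin, binarizeMap(pred_cur, tau))
    variant <- selectVariant(kap, expert_choice = best)
    gate <- validationGate(kap[[variant]], rating, config$kappa_gate)
    decisions[[sp]] <- data.frame(species = sp, n_records = nrow(rec),
                                  scheme = scheme, variant = variant,
                                  kappa = kap[[variant]], rating = rating,
                                  decision = gate$decision)

    ## projections (unmodellable species projected for reference only)
    disp <- world$dispersal$annual_km[world$dispersal$species == sp]
    clip_cur <- clipRegion(rec, disp * config$current_buffer_years)
    maps <- list()
    for (p in c("past", "current", names(config$scenario_years))) {
      m <- predictMap(vd$reps, stacks[[p]])
      if (vd$restricted)
        m <- landClassMask(m, world$landcover, occupied)
      b <- binarizeMap(m, tau)
      clip <- if (p %in% c("past", "current")) clip_cur
      else clipRegion(rec, futureBufferDistance(
        disp, config$scenario_years[[p]], config$present_year))
      maps[[p]] <- clipMap(b, grid, clip)
    }
    per_period <- do.call(rbind, lapply(names(maps), function(p)
      cbind(species = sp,
            rangeMetrics(maps[[p]], grid, world$elevation, period = p))))
    period_rows[[sp]] <- per_period
    m0 <- per_period[per_period$period == "past", ]
    m1 <- per_period[per_period$period == "f2080s", ]
    if (!m0$extinct)
      change_rows[[sp]] <- cbind(species = sp,
                                 changeSummary(m0, m1, hemisphere = "N"),
                                 reference_only =
                                   gate$decision != "modellable")
    if (gate$decision == "modellable") {
      modellable <- c(modellable, sp)
      binary_past[[sp]] <- maps$past
      binary_2080[[sp]] <- maps$f2080s
    } else {
      binary_past[[paste0(".ref.", sp)]] <- maps$past
    }
  }

  decisions <- do.call(rbind, decisions)
  rownames(decisions) <- NULL
  metrics <- do.call(rbind, metrics_rows)
  rownames(metrics) <- NULL
  change <- do.call(rbind, change_rows)
  rownames(change) <- NULL
  period_metrics <- do.call(rbind, period_rows)
  rownames(period_metrics) <- NULL

  ## richness change, uncertain where only unmodellable species occur
  rich <- NULL
  if (length(modellable) >= 1L) {
    rp <- richnessMap(binary_past[modellable])
    rf <- richnessMap(binary_2080[modellable])
    ref_maps <- binary_past[grep("^\\.ref\\.", names(binary_past))]
    uncertain <- if (length(ref_maps))
      richnessMap(ref_maps) > 0 & rp == 0 else NULL
    rich <- richnessChange(rp, rf, uncertain)
  }

  ## comparative stage on exactly the modellable species
  comparative <- NULL
  ok_change <- change[change$species %in% modellable & !change$extinct, ]
  # the 2-term PGLS carries k = 5 parameters, so AICc needs n > 6
  if (nrow(ok_change) >= 8L) {
    cdat <- merge(ok_change, world$traits, by = "species")
    cdat$log_body_mass <- log(cdat$body_mass_g)
    keep_tree <- ape::keep.tip(world$tree,
                               intersect(world$tree$tip.label,
                                         cdat$species))
    cdat <- cdat[match(keep_tree$tip.label, cdat$species), ]
    fits <- list()
    for (resp in c("range_change_pct", "poleward_deg",
                   "mean_elev_change_m")) {
      f <- stats::as.formula(paste(resp,
                                   "~ log_body_mass + litters_per_year"))
      dd <- dredgePGLS(f, cdat, keep_tree)
      fits[[resp]] <- list(dredge = dd$table, average = modelAverage(dd),
                           full = dd$fits[[which(dd$table$model ==
                             "log_body_mass + litters_per_year")]])
    }
    ## temporal trends by group with AR(1) errors
    trend_dat <- merge(period_metrics[period_metrics$species %in%
                                        modellable, ],
                       world$species[c("species", "group")], by = "species")
    trend_dat <- trend_dat[trend_dat$period != "past" &
                             !is.na(trend_dat$mean_latitude), ]
    trend_dat$period <- match(trend_dat$period,
                              c("current", "f2020s", "f2050s", "f2080s"))
    trend_dat$y <- trend_dat$mean_latitude
    trend <- if (length(unique(trend_dat$period)) >= 2L)
      glsTrend(trend_dat, "y") else NULL
    comparative <- list(pgls = fits, trend = trend)
  }

  ## outputs
  wr <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(out_dir, f), row.names = FALSE,
                     quote = FALSE)
  wr(qc_report, "qc_report.csv")
  wr(decisions, "decisions.csv")
  wr(metrics, "metrics.csv")
  wr(period_metrics, "period_metrics.csv")
  wr(change, "change_summary.csv")
  if (!is.null(comparative)) {
    avg <- do.call(rbind, lapply(names(comparative$pgls), function(r)
      cbind(response = r, comparative$pgls[[r]]$average)))
    wr(avg, "comparative_averaged.csv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("lagoshift")),
    seed = config$seed,
    n_species = length(spnames),
    n_modellable = length(modellable),
    n_records_clean = nrow(all_clean),
    stages = c("occurrence_qc", "env_stack", "background", "sdm_core",
               "evaluation", "range_geometry", "projections",
               "change_metrics", "comparative_stats"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(decisions = decisions, metrics = metrics,
                 period_metrics = period_metrics, change = change,
                 richness_change = rich, comparative = comparative,
                 modellable = modellable, qc_report = qc_report))
}
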