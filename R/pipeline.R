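#' End-to-end analysis pipeline
#'
#' Orchestrates the full chain: obtain petal spectra (simulated or from
#' CSV), resample to the 1-nm working grid, compute pigment and peak
#' indices, map petals into the requested pollinator colour spaces, score
#' perceptibility against a control treatment, run the statistical battery
#' (PERMANOVA on transformed spectra, planned contrasts, random-intercept
#' AIC choice), summarize petal-area effects, and write tidy CSV outputs
#' plus a JSON run manifest echoing every threshold and seed used.
#'
#' @param config Named list:
#'   \describe{
#'     \item{sim}{optional list with `config` ([sim_config()]), `params`,
#'       `effects`; if absent, `spectra_csv` / `metadata_csv` are read.}
#'     \item{spectra_csv, metadata_csv}{input paths (long/wide spectra CSV
#'       and petal metadata CSV) when not simulating.}
#'     \item{guilds}{character subset of bee/fly/butterfly (default all).}
#'     \item{control}{control treatment for perceptibility (default CFA).}
#'     \item{perceptibility_mode}{"centroid" (default) or "strict".}
#'     \item{butterfly_axis}{axis for the butterfly rule; defaults to "u"
#'       (logged when falling back).}
#'     \item{n_perm}{PERMANOVA permutations (default 999).}
#'     \item{seed}{integer seed, required.}
#'     \item{out_dir}{output directory, created if missing.}
#'   }
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results (`indices`,
#'   `loci`, `perceptibility`, `stats`, `areas`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  guilds <- config$guilds %||% c("bee", "fly", "butterfly")
  control <- config$control %||% "CFA"
  mode <- config$perceptibility_mode %||% "centroid"
  axis <- config$butterfly_axis
  if (is.null(axis)) {
    axis <- "u"
    say("butterfly axis not set; using default axis 'u'")
  }
  n_perm <- config$n_perm %||% 999

  # --- data stage ---------------------------------------------------------
  stage <- "data"
  res <- tryCatch({
    if (!is.null(config$sim)) {
      simcfg <- config$sim$config %||% sim_config(seed = config$seed)
      simcfg$seed <- as.integer(config$seed)
      sim <- simulate_dataset(simcfg,
                              config$sim$params %||% spectrum_model_params(),
                              config$sim$effects %||% treatment_effects())
      list(set = sim$set, areas = sim$areas)
    } else {
      set <- read_spectra_csv(config$spectra_csv,
                              metadata = config$metadata_csv,
                              percent = isTRUE(config$percent))
      list(set = set, areas = attr(set, "areas"))
    }
  }, error = function(e) stop(sprintf("stage '%s': %s", stage,
                                      conditionMessage(e)), call. = FALSE))
  set <- res$set
  areas <- res$areas
  say("data: %d petals", length(set))

  # --- preprocessing: common 1-nm grid ------------------------------------
  stage <- "preprocess"
  grid1 <- seq(min(set$grid_nm), max(set$grid_nm), by = 1)
  set1 <- spectrum_set(lapply(set$spectra, resample, grid = grid1))

  # --- indices ------------------------------------------------------------
  stage <- "indices"
  indices <- pigment_index_table(set1)
  if (!is.null(areas)) {
    indices <- merge(indices, areas[, c("petal_id", "area_cm2")],
                     by = "petal_id", sort = FALSE)
  }
  utils::write.csv(indices, file.path(out_dir, "indices.csv"),
                   row.names = FALSE)

  # --- vision + perceptibility --------------------------------------------
  loci_out <- list()
  perc_out <- list()
  for (g in guilds) {
    stage <- paste0("vision:", g)
    sys <- visual_system(g)
    cl <- colour_loci(set1, sys)
    loci_out[[g]] <- cl$table
    utils::write.csv(cl$table,
                     file.path(out_dir, sprintf("loci_%s.csv", g)),
                     row.names = FALSE)
    treatments <- cl$table$treatment
    if (g == "fly") {
      perc <- category_fractions(cl$loci, treatments)
      tab <- as.data.frame(perc$percent)
      utils::write.csv(tab, file.path(out_dir, "fly_category_percent.csv"),
                       row.names = FALSE)
      perc_out[[g]] <- perc
    } else {
      rule <- if (g == "butterfly") {
        perceptibility_rule("butterfly", axis = axis)
      } else {
        perceptibility_rule("bee")
      }
      ctl_idx <- which(treatments == control)
      if (length(ctl_idx)) {
        rows <- list()
        for (tr in setdiff(unique(treatments), control)) {
          tr_idx <- which(treatments == tr)
          s <- cross_treatment_perceptibility(cl$loci[ctl_idx],
                                              cl$loci[tr_idx], rule,
                                              mode = mode)
          rows[[tr]] <- data.frame(guild = g, control = control,
                                   treatment = tr, n = s$n_compared,
                                   n_perceptible = s$n_perceptible,
                                   percent = s$percent, mode = s$mode,
                                   stringsAsFactors = FALSE)
        }
        ptab <- do.call(rbind, rows)
        utils::write.csv(ptab,
                         file.path(out_dir,
                                   sprintf("perceptibility_%s.csv", g)),
                         row.names = FALSE)
        perc_out[[g]] <- ptab
      }
    }
  }

  # --- statistics ---------------------------------------------------------
  stage <- "stats"
  stats_out <- tryCatch({
    ozone_idx <- indices[indices$treatment %in% c("CFA", "NFA", "FU+"), ]
    lev <- c("CFA", "NFA", "FU+")
    rows <- list()
    if (all(lev %in% ozone_idx$treatment)) {
      ct_peak <- contrast_test(ozone_idx$peak_height, ozone_idx$treatment,
                               contrast_spec(lev, name = "linear_increase"))
      ct_ari <- contrast_test(log(ozone_idx$ari), ozone_idx$treatment,
                              contrast_spec(lev, name = "nfa_vs_rest"))
      rows$peak <- data.frame(analysis = "peak_height_linear_increase",
                              statistic = ct_peak$F, df1 = 1,
                              df2 = ct_peak$df2, p = ct_peak$p)
      rows$ari <- data.frame(analysis = "log_ari_nfa_vs_rest",
                             statistic = ct_ari$F, df1 = 1,
                             df2 = ct_ari$df2, p = ct_ari$p)
      if (!is.null(areas)) {
        oz_areas <- areas[areas$treatment %in% lev, ]
        ct_area <- contrast_test(oz_areas$area_cm2, oz_areas$treatment,
                                 contrast_spec(lev, name = "control_vs_rest"))
        ri <- fit_random_intercept(oz_areas$area_cm2, oz_areas$treatment,
                                   oz_areas$plant_id)
        rows$area <- data.frame(analysis = "area_control_vs_rest",
                                statistic = ct_area$F, df1 = 1,
                                df2 = ct_area$df2, p = ct_area$p)
        rows$ri <- data.frame(analysis = "area_mixed_treatment_lrt",
                              statistic = ri$treatment_chisq,
                              df1 = ri$treatment_df, df2 = NA_real_,
                              p = ri$treatment_p)
      }
      spm <- t(vapply(set1$spectra, function(s) s$reflectance,
                      numeric(length(set1$grid_nm))))
      rownames(spm) <- vapply(set1$spectra, function(s) s$meta$petal_id,
                              character(1))
      treat_all <- vapply(set1$spectra, function(s) s$meta$treatment,
                          character(1))
      keep <- treat_all %in% lev
      pm <- permanova(bray_curtis(spm[keep, , drop = FALSE]),
                      treat_all[keep], n_perm = n_perm, seed = config$seed)
      rows$perm <- data.frame(analysis = "permanova_spectra",
                              statistic = pm$pseudo_F, df1 = pm$df_between,
                              df2 = pm$df_within, p = pm$p_perm)
    }
    do.call(rbind, rows)
  }, error = function(e) stop(sprintf("stage '%s': %s", stage,
                                      conditionMessage(e)), call. = FALSE))
  if (!is.null(stats_out)) {
    utils::write.csv(stats_out, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
  }

  # --- petal-area effects --------------------------------------------------
  reductions <- NULL
  if (!is.null(areas) && control %in% areas$treatment) {
    reductions <- estimate_area_reductions(areas, control = control)
    utils::write.csv(reductions, file.path(out_dir, "area_reductions.csv"),
                     row.names = FALSE)
  }

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "petalvision",
    version = as.character(utils::packageVersion("petalvision")),
    seed = as.integer(config$seed),
    n_petals = length(set),
    guilds = guilds,
    control = control,
    perceptibility_mode = mode,
    thresholds = list(bee_hexagon_distance = 0.09,
                      butterfly_axis_distance = 0.03,
                      butterfly_axis = axis,
                      aot40_threshold_nl_l = 40,
                      daylight_window_h = c(7, 15)),
    n_perm = n_perm,
    config_hash = config_hash(config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline complete: outputs in %s", out_dir)
  invisible(list(indices = indices, loci = loci_out,
                 perceptibility = perc_out, stats = stats_out,
                 areas = areas, reductions = reductions,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hash of the analysis-relevant configuration (output location excluded,
# so the same analysis written elsewhere hashes identically)
config_hash <- function(config) {
  config$out_dir <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}
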