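# End-to-end orchestration: simulate (or ingest) -> range change ->
# protection -> covariates -> matching -> boosted -> regressions -> report.
# Every stage writes plain-text artifacts (ASCII grids, GeoJSON, CSV, JSON)
# into the output directory and is recorded in a run manifest sufficient to
# re-run identically.

write_csv_stable <- function(df, path) {
  utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

effect_row <- function(cmp, res) {
  e <- res$effect
  data.frame(comparison = cmp, label = res$label, estimate = e$estimate,
             ci_lower = e$ci_lower, ci_upper = e$ci_upper,
             mean_treated = e$mean_treated, mean_control = e$mean_control,
             n_pairs = e$n_pairs, naive_diff = res$naive_diff,
             stringsAsFactors = FALSE)
}

#' Summarize matched comparisons as report tables
#'
#' One balance table per completed comparison (before/after SMD per
#' covariate, the propensity score labelled `distance`, and the averaged
#' bioanthrome indicators) and one effect table (estimate, 95% CI, pair
#' count, naive unmatched difference). When a generative truth is supplied,
#' the effect table gains the true ATT and a CI-coverage flag per
#' comparison.
#'
#' @param comparisons A `comparison_set` from [run_comparisons()].
#' @param truth Optional truth list (field `att` named a-d), as produced by
#'   the synthetic-world generator.
#' @return List with `effects` (data.frame) and `balance` (named list of
#'   `balance_report`s).
#' @export
pipeline_report <- function(comparisons, truth = NULL) {
  cmps <- names(comparisons)
  effects <- do.call(rbind, lapply(cmps, function(cmp)
    effect_row(cmp, comparisons[[cmp]])))
  if (!is.null(truth)) {
    effects$true_att <- as.numeric(truth$att[effects$comparison])
    effects$ci_covers_truth <- effects$true_att >= effects$ci_lower &
      effects$true_att <= effects$ci_upper
  }
  balance <- lapply(comparisons, function(res) res$balance)
  list(effects = effects, balance = balance)
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Simulates a world from `config`, computes range change, richness and
#' extinction-rate layers, classifies protection, assembles the pixel
#' table, runs the four matched comparisons, the boosted multilevel model,
#' and the species- and landscape-level regressions, writing every artifact
#' under `out_dir` and returning a manifest that identifies the run.
#'
#' @param config A [world_config()].
#' @param out_dir Output directory (created if missing).
#' @param boosted_cfg A [boosted_config()]; the default uses a desk-scale
#'   tree grid.
#' @param write_rasters Also write per-species presence grids and covariate
#'   grids (many files on large worlds); summary tables are always written.
#' @return The run manifest (list), invisibly also written as
#'   `manifest.json`.
#' @export
run_world_pipeline <- function(config = world_config(), out_dir,
                               boosted_cfg = boosted_config(
                                 n_trees_grid = c(200, 500, 1000),
                                 seed = config$seed),
                               write_rasters = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  note <- function(stage, ...) {
    stages[[stage]] <<- list(...)
  }

  # -- stage 1: simulate
  world <- gen_world(config)
  cfg_path <- file.path(out_dir, "config_resolved.json")
  cfg_out <- unclass(world$config)
  cfg_out$beta_cov <- as.list(cfg_out$beta_cov)
  cfg_out$delta <- as.list(cfg_out$delta)
  jsonlite::write_json(cfg_out, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_pa_geojson(world$pa_records, file.path(out_dir, "pa_records.geojson"))
  jsonlite::write_json(
    list(realized_category_means =
           as.list(world$truth$realized_category_means),
         att = as.list(world$truth$att)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  note("simulate", n_species = config$n_species,
       n_pas = length(world$pa_records),
       outputs = c("config_resolved.json", "pa_records.geojson",
                   "truth.json"))

  # -- stage 2: range change
  summaries <- vector("list", config$n_species)
  changes <- vector("list", config$n_species)
  for (s in seq_along(world$species$past)) {
    ch <- classify_range_change(world$species$past[[s]],
                                world$species$recent[[s]])
    changes[[s]] <- ch
    summaries[[s]] <- species_change_summary(ch, sprintf("SP%03d", s))
  }
  change_tab <- do.call(rbind, summaries)
  write_csv_stable(change_tab, file.path(out_dir, "species_change.csv"))
  note("rangechange", n_species = nrow(change_tab),
       outputs = "species_change.csv")

  # -- stage 3: protection summaries
  prot_sum <- do.call(rbind, lapply(seq_along(changes), function(s)
    species_protection_summary(world$species$past[[s]],
                               world$species$recent[[s]], world$pmap,
                               sprintf("SP%03d", s))))
  loss_dec <- do.call(rbind, lapply(changes, loss_by_protection,
                                    pmap = world$pmap))
  loss_dec <- cbind(species_id = change_tab$species_id, loss_dec)
  write_csv_stable(prot_sum, file.path(out_dir, "species_protection.csv"))
  write_csv_stable(loss_dec, file.path(out_dir, "loss_by_protection.csv"))
  if (write_rasters)
    write_ascii_raster(structure(unclass(world$pmap),
                                 grid = world$grid),
                       file.path(out_dir, "protection.asc"))
  note("protection", n_species = nrow(prot_sum),
       outputs = c("species_protection.csv", "loss_by_protection.csv"))

  # -- stage 4: covariates / pixel table
  tab <- world_pixel_table(world)
  write_csv_stable(as.data.frame(tab), file.path(out_dir, "pixel_table.csv"))
  note("covariates", n_rows = nrow(tab),
       n_dropped = attr(tab, "drop_log")$n_dropped_missing,
       outputs = "pixel_table.csv")

  # -- stage 5: matching
  comparisons <- run_comparisons(tab)
  rep_tabs <- pipeline_report(comparisons, world$truth)
  write_csv_stable(rep_tabs$effects, file.path(out_dir, "effects.csv"))
  for (cmp in names(rep_tabs$balance))
    write_csv_stable(rep_tabs$balance[[cmp]],
                     file.path(out_dir, sprintf("balance_%s.csv", cmp)))
  note("matching", n_comparisons = length(comparisons),
       skipped = nrow(attr(comparisons, "skipped")),
       outputs = c("effects.csv",
                   sprintf("balance_%s.csv", names(rep_tabs$balance))))

  # -- stage 6: boosted
  bm <- fit_boosted(tab, boosted_cfg)
  me <- marginal_effects(bm, tab)
  write_csv_stable(data.frame(protection = names(me),
                              pd_pct_lost = as.numeric(me)),
                   file.path(out_dir, "marginal_effects.csv"))
  ri <- relative_influence(bm)
  write_csv_stable(data.frame(covariate = names(ri),
                              influence_pct = as.numeric(ri)),
                   file.path(out_dir, "influence.csv"))
  write_csv_stable(bm$cv_curve, file.path(out_dir, "cv_curve.csv"))
  note("boosted", best_iteration = bm$best_iteration,
       outputs = c("marginal_effects.csv", "influence.csv", "cv_curve.csv"))

  # -- stage 7: regressions
  species_tab <- merge(change_tab, prot_sum, by = "species_id")
  species_tab$pct_range_lost <- species_tab$pct_lost
  ba_sum <- bioanthrome_summary(attr(tab, "past_rich"),
                                attr(tab, "lost_rich"), world$pmap,
                                attr(tab, "bioanthromes"))
  fits <- list(
    coverage_change = fit_loss_vs_coverage_change(species_tab),
    extent_since_past = fit_loss_vs_protected_extent(species_tab,
                                                     "since_past"),
    extent_recent_only = fit_loss_vs_protected_extent(species_tab,
                                                      "recent_only"),
    extirpation_area = fit_extirpation_vs_coverage(ba_sum, "identity"),
    extirpation_log_area = fit_extirpation_vs_coverage(ba_sum, "log"))
  coef_tab <- do.call(rbind, lapply(names(fits), function(nm) {
    cbind(model = nm, fits[[nm]]$coefficients,
          r_squared = fits[[nm]]$r_squared, n = fits[[nm]]$n)
  }))
  write_csv_stable(coef_tab, file.path(out_dir, "regressions.csv"))
  write_csv_stable(ba_sum, file.path(out_dir, "bioanthrome_summary.csv"))
  note("regress", n_models = length(fits),
       outputs = c("regressions.csv", "bioanthrome_summary.csv"))

  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$results <- list(world = world, pixel_table = tab,
                           comparisons = comparisons, boosted = bm,
                           marginal_effects = me, regressions = fits,
                           report = rep_tabs, species_table = species_tab,
                           bioanthrome_summary = ba_sum)
  invisible(manifest)
}
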