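#' Configuration for an end-to-end synthetic run
#'
#' Bundles every stage's parameters under one seed. The defaults run a
#' compact two-group comparison (a low-signal and a high-signal condition,
#' 4x apart in dot count) through both quantification pipelines, the
#' statistics layer and the C-terminal decomposition.
#'
#' @param out_dir output directory.
#' @param seed master seed; all per-image seeds derive from it.
#' @param n_images_per_group images per group (>= 1; >= 2 to reach the
#'   statistics stage).
#' @param spec_low,spec_high [scene_spec()]s for the two conditions.
#' @param group_labels length-2 group labels.
#' @param rout_q ROUT FDR level (NULL skips outlier removal).
#' @param r_flapp,r_cterm fold changes fed to the decomposition stage.
#' @param sigma_nucleus,sigma_pla,min_size_nucleus,min_size_pla
#'   nucleus-normalized pipeline parameters.
#' @param sigma_organelle organelle pipeline blur.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("plaq_run_"), seed = 1L,
                       n_images_per_group = 4L,
                       spec_low = scene_spec(shape = c(21L, 96L, 96L),
                                             n_nuclei = 1L,
                                             nucleus_radii = c(4, 14, 14),
                                             n_pla_dots = 8L,
                                             n_organelles = 8L),
                       spec_high = scene_spec(shape = c(21L, 96L, 96L),
                                              n_nuclei = 1L,
                                              nucleus_radii = c(4, 14, 14),
                                              n_pla_dots = 32L,
                                              n_organelles = 8L),
                       group_labels = c("NPC", "neuron"), rout_q = 0.001,
                       r_flapp = 1.63, r_cterm = 0.21,
                       sigma_nucleus = 3, sigma_pla = 1,
                       min_size_nucleus = 500L, min_size_pla = 4L,
                       sigma_organelle = 1) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_images_per_group = as.integer(n_images_per_group),
              spec_low = spec_low, spec_high = spec_high,
              group_labels = group_labels, rout_q = rout_q,
              r_flapp = r_flapp, r_cterm = r_cterm,
              sigma_nucleus = sigma_nucleus, sigma_pla = sigma_pla,
              min_size_nucleus = as.integer(min_size_nucleus),
              min_size_pla = as.integer(min_size_pla),
              sigma_organelle = sigma_organelle)
  if (cfg$n_images_per_group < 1L)
    stop("validation error: n_images_per_group must be >= 1")
  stopifnot(inherits(spec_low, "scene_spec"), inherits(spec_high, "scene_spec"))
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic pipeline end to end
#'
#' Generates a two-group synthetic experiment on disk, quantifies the
#' nucleus-normalized PLA score and the organelle occupancy for every
#' image, compares the groups (ROUT + Student's t + fold change), computes
#' the C-terminal decomposition bounds, and writes: the resolved
#' configuration (`config.json`), per-image results CSVs with full
#' provenance (thresholds and focus planes), a statistics CSV, the
#' sensitivity table, and a plain-text `report.txt` with sections pla,
#' organelle, stats and ctf. Two runs with the same config produce
#' identical CSVs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the output directory and all stage
#'   results.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_images_per_group < 2L)
    stop("validation error: need >= 2 images per group for the statistics stage")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_json <- config
  class(cfg_json) <- NULL
  cfg_json$spec_low <- unclass(cfg_json$spec_low)
  cfg_json$spec_high <- unclass(cfg_json$spec_high)
  jsonlite::write_json(cfg_json, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  exp_dir <- file.path(config$out_dir, "images")
  expmt <- .stage("simulate", generate_group_experiment(
    config$spec_low, config$spec_high,
    n_images_per_group = config$n_images_per_group,
    base_seed = config$seed, dir = exp_dir,
    group_labels = config$group_labels, primary = "nucleus"))
  manifest <- read_manifest(expmt$manifest_path)

  pairs <- .stage("read", lapply(seq_len(nrow(manifest)), function(i)
    read_stack_pair(manifest[i, ])))
  pla <- .stage("quantify-pla", quantify_pla_set(
    pairs, sigma_nucleus = config$sigma_nucleus, sigma_pla = config$sigma_pla,
    min_size_nucleus = config$min_size_nucleus,
    min_size_pla = config$min_size_pla))
  if (length(pla$results) == 0L) stop("[stage quantify-pla] no usable images")
  pla_df <- results_table(pla$results)
  write_results_table(pla_df, file.path(config$out_dir, "pla_results.csv"))

  # organelle pipeline on scenes regenerated with the same per-image seeds,
  # organelle channel as primary
  org_results <- .stage("quantify-organelle", {
    res <- list()
    img <- 0L
    for (g in 1:2) {
      spec_g <- if (g == 1L) config$spec_low else config$spec_high
      for (i in seq_len(config$n_images_per_group)) {
        img <- img + 1L
        spec_i <- spec_g
        spec_i$seed <- .derive_seed(config$seed, img)
        scene <- generate_scene(spec_i)
        pair <- as_stack_pair(scene, "organelle",
                              image_id = sprintf("img%03d_%s", img,
                                                 config$group_labels[g]),
                              group_label = config$group_labels[g],
                              organelle_kind = "Rab5a")
        res[[img]] <- quantify_organelle_image(pair, sigma = config$sigma_organelle)
      }
    }
    res
  })
  org_df <- results_table(org_results)
  write_results_table(org_df, file.path(config$out_dir, "organelle_results.csv"))
  org_summary <- summarize_by_organelle(org_df)

  stats <- .stage("compare", {
    a <- pla_df$ratio[pla_df$group_label == config$group_labels[1]]
    b <- pla_df$ratio[pla_df$group_label == config$group_labels[2]]
    compare_groups(a, b, rout_q = config$rout_q)
  })
  stats_df <- data.frame(
    group_a = config$group_labels[1], group_b = config$group_labels[2],
    n_a = stats$n_a, n_b = stats$n_b,
    mean_a = stats$mean_a, sem_a = stats$sem_a,
    mean_b = stats$mean_b, sem_b = stats$sem_b,
    fold_change_b_vs_a = stats$fold_change_b_vs_a,
    t_statistic = stats$t_statistic, df = stats$df, p_value = stats$p_value)
  write_results_table(stats_df, file.path(config$out_dir, "stats.csv"))

  ctf <- .stage("ctf-bounds",
                decompose_cterm_signal(config$r_flapp, config$r_cterm))
  sens <- sensitivity_table(config$r_flapp)
  write_results_table(sens, file.path(config$out_dir, "ctf_sensitivity.csv"))

  report <- file.path(config$out_dir, "report.txt")
  .stage("report", {
    con <- file(report, "w"); on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("== pla =="); w("images quantified: %d (excluded: %d)",
                      nrow(pla_df), nrow(pla$excluded))
    for (i in seq_len(nrow(pla_df)))
      w("  %s [%s] ratio %.5f (focus nuc z%d / pla z%d, thr li %.3f / tri %.3f)",
        pla_df$image_id[i], pla_df$group_label[i], pla_df$ratio[i],
        pla_df$best_focus_nucleus[i], pla_df$best_focus_pla[i],
        pla_df$threshold_nucleus[i], pla_df$threshold_pla[i])
    w(""); w("== organelle ==")
    for (i in seq_len(nrow(org_summary)))
      w("  %s / %s: %.3f +/- %.3f %% occupied (n = %d)",
        org_summary$organelle_kind[i], org_summary$group_label[i],
        org_summary$mean_percent[i], org_summary$sem_percent[i],
        org_summary$n[i])
    w(""); w("== stats ==")
    w("  %s vs %s: fold change %.4g, t = %.4f, df = %g, p = %.4g",
      config$group_labels[2], config$group_labels[1],
      stats$fold_change_b_vs_a, stats$t_statistic, stats$df, stats$p_value)
    w(""); w("== ctf ==")
    w("  r_flapp = %g, r_cterm = %g", ctf$r_flapp, ctf$r_cterm)
    w("  min NPC:neuron CTF contribution ratio: %.4f",
      ctf$min_npc_to_neuron_ctf_ratio)
    w("  min CTF:flAPP contribution ratio (first state): %.4f",
      ctf$min_ctf_to_flapp_npc)
  })

  invisible(list(out_dir = config$out_dir, manifest = manifest,
                 pla = pla, pla_table = pla_df,
                 organelle = org_results, organelle_summary = org_summary,
                 stats = stats, ctf = ctf, sensitivity = sens,
                 report = report))
}
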