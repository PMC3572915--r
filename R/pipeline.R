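## End-to-end orchestration: spectral -> inverse -> group ICA ->
## network scores -> moderation statistics, per frequency band.

#' Build and validate a pipeline run configuration
#'
#' Input is either a fixture directory (EDF recordings + questionnaire
#' TSV + manifest, as written by [write_fixture_set]) or a cohort
#' configuration to simulate on the fly (one subject at a time, so full
#' cohorts never need to be held in memory).
#'
#' @param fixture_dir Fixture directory, or `NULL` to simulate.
#' @param cohort A `dmn_cohort_config` used when `fixture_dir` is NULL.
#' @param bands Character vector of band names to analyse (default all
#'   five; alpha is the band of the headline analysis).
#' @param epoch_len_s,overlap_frac Epoching parameters (1.7 s, 0.5).
#' @param amp_thresh_uv Artifact rejection threshold (100 uV).
#' @param alpha_frac sLORETA regularization fraction (1/100).
#' @param n_components Group-ICA order: a count, or `"mdl"` to use the
#'   minimum-description-length estimate (default 20).
#' @param q,min_cluster FDR threshold and minimum cluster size (0.05, 8).
#' @param threshold_sd Subgroup threshold in SD units (0.5).
#' @param outcome,moderator Column names in the questionnaire table
#'   (defaults `"item01"`, `"assertiveness"`).
#' @param restrict_to_significant Restrict intensity summation to the
#'   FDR-surviving mask (default FALSE: whole map).
#' @param seed Seed for the ICA stage.
#' @param out_dir Output directory for artifacts and the JSON report.
#' @return A validated `dmn_run_config`.
#' @export
run_config <- function(fixture_dir = NULL, cohort = NULL,
                       bands = names(dmn_constants$bands),
                       epoch_len_s = 1.7, overlap_frac = 0.5,
                       amp_thresh_uv = 100, alpha_frac = 1 / 100,
                       n_components = 20, q = 0.05, min_cluster = 8,
                       threshold_sd = 0.5, outcome = "item01",
                       moderator = "assertiveness",
                       restrict_to_significant = FALSE, seed = 1,
                       out_dir = tempfile("dmnrun")) {
  cfg <- as.list(environment())
  if (is.null(fixture_dir) && is.null(cohort))
    stop("either fixture_dir or a cohort config is required")
  if (!is.null(fixture_dir)) {
    man <- file.path(fixture_dir, "manifest.json")
    if (!file.exists(man)) stop("missing manifest: ", man)
    mf <- jsonlite::read_json(man)
    qf <- file.path(fixture_dir, mf$questionnaire)
    if (!file.exists(qf)) stop("missing questionnaire file: ", qf)
    for (f in mf$eeg_files)
      if (!file.exists(file.path(fixture_dir, f)))
        stop("missing EEG file: ", f)
    cfg$manifest <- mf
  } else {
    stopifnot(inherits(cohort, "dmn_cohort_config"))
  }
  if (!all(bands %in% names(dmn_constants$bands)))
    stop("unknown band(s): ",
         paste(setdiff(bands, names(dmn_constants$bands)), collapse = ","))
  stopifnot(epoch_len_s > 0, overlap_frac >= 0, overlap_frac < 1,
            amp_thresh_uv > 0, alpha_frac >= 0, q > 0, q < 1,
            min_cluster >= 1, threshold_sd > 0)
  if (!identical(n_components, "mdl"))
    stopifnot(is.numeric(n_components), n_components >= 2)
  class(cfg) <- "dmn_run_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes epoching, artifact rejection, per-epoch sLORETA imaging,
#' group spatial ICA with back-reconstruction, significance mapping,
#' DMN template matching, per-subject intensity scoring and the
#' moderation analysis, separately for every configured band.  All
#' intermediate artifacts are written under `cfg$out_dir`; the per-band
#' interaction test and subgroup correlations go into
#' `report.json`.
#'
#' @param cfg A `dmn_run_config`.
#' @param progress Print stage progress (default FALSE).
#' @return The run report (list), invisibly the same as
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "dmn_run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (progress) message(...)
  simulate_mode <- is.null(cfg$fixture_dir)
  chash <- if (simulate_mode) config_hash(cfg$cohort)
           else cfg$manifest$config_hash
  ## ---- geometry and inverse operator -------------------------------
  geom <- .stage("forward", {
    if (simulate_mode) cohort_geometry(cfg$cohort)
    else {
      f1 <- file.path(cfg$fixture_dir, cfg$manifest$eeg_files[[1]])
      nch <- nrow(read_edf(f1)$samples)
      mon <- build_montage(nch,
                           dmn_constants$head_model$radii_mm[["scalp"]])
      sp <- build_source_space(15)
      list(montage = mon, space = sp,
           lead_field = compute_lead_field(mon, sp))
    }
  })
  op <- .stage("inverse", build_sloreta_operator(geom$lead_field,
                                                 cfg$alpha_frac))
  ## ---- questionnaire ----------------------------------------------
  qtab <- .stage("questionnaire", {
    if (simulate_mode) {
      bundle <- simulate_cohort(cfg$cohort, keep_recordings = FALSE,
                                geometry = geom)
      bundle$questionnaire
    } else {
      utils::read.delim(file.path(cfg$fixture_dir,
                                  cfg$manifest$questionnaire))
    }
  })
  for (col in c(cfg$outcome, cfg$moderator))
    if (!col %in% names(qtab))
      stop("[stage questionnaire] missing column: ", col)
  item_cols <- grep("^item[0-9]+$", names(qtab), value = TRUE)
  scale_set <- if (length(item_cols) >= 8)
    .stage("scales", construct_scales(as.matrix(qtab[, item_cols])))
  else NULL
  ## ---- per-subject spectral + inverse imaging ----------------------
  bands <- dmn_constants$bands[cfg$bands]
  subj_ids <- if (simulate_mode) bundle$truth$subject
              else names(cfg$manifest$eeg_files)
  ns <- length(subj_ids)
  images <- lapply(cfg$bands, function(b) vector("list", ns))
  names(images) <- cfg$bands
  epochs_used <- integer(ns)
  for (i in seq_len(ns)) {
    rec <- .stage("io", {
      if (simulate_mode)
        simulate_subject_recording(cfg$cohort, i,
                                   bundle$subject_seeds[i],
                                   bundle$truth$a_A[i],
                                   bundle$truth$a_P[i], geom)
      else read_edf(file.path(cfg$fixture_dir,
                              cfg$manifest$eeg_files[[i]]))
    })
    es <- .stage("spectral", {
      es <- segment_epochs(rec, cfg$epoch_len_s, cfg$overlap_frac)
      reject_artifact_epochs(es, cfg$amp_thresh_uv)
    })
    epochs_used[i] <- dim(es$epochs)[1]
    imgs <- .stage("imaging", source_band_power_epochs(op, es, bands))
    for (b in cfg$bands) images[[b]][[i]] <- imgs[[b]]
    say("subject ", i, "/", ns, ": ", epochs_used[i], " epochs")
  }
  templates <- .stage("templates", build_dmn_templates(geom$space))
  ## ---- per-band group ICA + scores + moderation --------------------
  band_results <- list()
  for (b in cfg$bands) {
    say("band ", b)
    res <- .stage(paste0("groupica:", b), {
      names(images[[b]]) <- subj_ids
      stack <- new_image_stack(images[[b]], band = b)
      nc <- if (identical(cfg$n_components, "mdl")) {
        k <- estimate_order_mdl(stack)
        max(2L, min(k, 20L, nrow(stack$X) - 1L))
      } else min(cfg$n_components, nrow(stack$X) - 1L)
      dec <- fit_group_ica(stack, n_components = nc, seed = cfg$seed)
      dec <- back_reconstruct(dec, stack)
      list(stack = stack, dec = dec)
    })
    dec <- res$dec
    sig <- .stage(paste0("significance:", b), lapply(
      seq_len(dec$n_components), function(k)
        component_significance(dec, geom$space, q = cfg$q,
                               min_cluster = cfg$min_cluster,
                               component = k)))
    eligible <- which(vapply(sig, function(s) any(s$surviving_mask),
                             TRUE))
    if (!length(eligible)) {
      warning("band ", b, ": no component significant; using all")
      eligible <- seq_len(dec$n_components)
    }
    scores <- .stage(paste0("netscore:", b), {
      mA <- match_components(dec, templates$ADMN, eligible = eligible)
      mP <- match_components(dec, templates$PDMN, eligible = eligible)
      maskA <- if (cfg$restrict_to_significant)
        sig[[mA$selected_component]]$surviving_mask else NULL
      maskP <- if (cfg$restrict_to_significant)
        sig[[mP$selected_component]]$surviving_mask else NULL
      tab <- combined_score(intensity_scores(dec, mA, maskA),
                            intensity_scores(dec, mP, maskP),
                            band = b, subject_ids = subj_ids)
      list(match_A = mA, match_P = mP, table = tab)
    })
    stat <- .stage(paste0("stats:", b), {
      y <- qtab[[cfg$outcome]]
      m <- qtab[[cfg$moderator]]
      mod <- hierarchical_moderation(y, scores$table$P_ADMN, m)
      ss <- simple_slopes(mod, c(cfg$threshold_sd, -cfg$threshold_sd))
      sg <- subgroup_correlations(y, m,
                                  list(PDMN = scores$table$z_PDMN,
                                       ADMN = scores$table$z_ADMN),
                                  cfg$threshold_sd)
      list(moderation = mod, simple_slopes = ss, subgroups = sg)
    })
    ## persist artifacts
    bdir <- file.path(cfg$out_dir, b)
    dir.create(bdir, showWarnings = FALSE)
    write_score_table(scores$table, file.path(bdir, "scores.tsv"))
    utils::write.table(stat$simple_slopes,
                       file.path(bdir, "simple_slopes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stat$subgroups,
                       file.path(bdir, "subgroup_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_source_nifti(dec$group_maps[scores$match_A$selected_component, ],
                       geom$space, file.path(bdir, "ADMN_component.nii.gz"))
    write_source_nifti(dec$group_maps[scores$match_P$selected_component, ],
                       geom$space, file.path(bdir, "PDMN_component.nii.gz"))
    jsonlite::write_json(
      list(config_hash = chash, band = b, seed = cfg$seed,
           n_components = dec$n_components,
           ica_iterations = dec$ica_iterations,
           explained_variance = dec$explained_variance,
           eligible_components = eligible),
      file.path(bdir, "decomposition.json"),
      auto_unbox = TRUE, digits = NA)
    i2 <- stat$moderation$step2
    band_results[[b]] <- list(
      n_components = dec$n_components,
      admn_component = scores$match_A$selected_component,
      pdmn_component = scores$match_P$selected_component,
      admn_match_r = scores$match_A$ranking$correlation[1],
      pdmn_match_r = scores$match_P$ranking$correlation[1],
      interaction = as.list(i2[i2$term == "x_m",
                               c("B", "SE", "T", "df", "p")]),
      delta_r2 = stat$moderation$delta_r2,
      simple_slopes = stat$simple_slopes,
      subgroup_correlations = stat$subgroups)
  }
  report <- list(config_hash = chash, seed = cfg$seed,
                 n_subjects = ns, bands = cfg$bands,
                 epochs_used = epochs_used,
                 n_voxels = n_voxels(geom$space),
                 scale_alphas = if (!is.null(scale_set))
                   lapply(scale_set$scales, function(s) s$alpha)
                 else NULL,
                 band_results = band_results)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Render a human-readable summary of a completed run
#'
#' Writes `report.md` with per-band coefficient tables, and per band a
#' PNG thumbnail of the selected anterior and posterior component maps
#' (mid-axial slice).  Plot data for the simple-slopes figure and the
#' subgroup scatter are already persisted as TSV by [run_pipeline].
#'
#' @param run_dir Output directory of a completed [run_pipeline] run.
#' @return Path to `report.md`, invisibly.
#' @export
make_report <- function(run_dir) {
  rj <- file.path(run_dir, "report.json")
  if (!file.exists(rj)) stop("incomplete run directory: missing report.json")
  rep_ <- jsonlite::read_json(rj)
  missing <- character(0)
  lines <- c("# Pipeline run report", "",
             paste0("Subjects: ", rep_$n_subjects,
                    "; voxels: ", rep_$n_voxels,
                    "; config hash: ", rep_$config_hash), "")
  for (b in names(rep_$band_results)) {
    br <- rep_$band_results[[b]]
    lines <- c(lines, paste0("## Band: ", b), "",
               sprintf("Interaction: B = %.3f, SE = %.3f, T(%d) = %.2f, p = %.4g",
                       br$interaction$B, br$interaction$SE,
                       br$interaction$df, br$interaction$T,
                       br$interaction$p),
               sprintf("Template matches: ADMN r = %.3f (component %d), PDMN r = %.3f (component %d)",
                       br$admn_match_r, br$admn_component,
                       br$pdmn_match_r, br$pdmn_component), "")
    for (f in c("scores.tsv", "simple_slopes.tsv",
                "subgroup_correlations.tsv")) {
      fp <- file.path(run_dir, b, f)
      if (!file.exists(fp)) missing <- c(missing, file.path(b, f))
    }
    sgf <- file.path(run_dir, b, "subgroup_correlations.tsv")
    if (file.exists(sgf)) {
      sg <- utils::read.delim(sgf)
      lines <- c(lines, "Subgroup correlations:",
                 utils::capture.output(print(sg, row.names = FALSE)),
                 "")
    }
    for (comp in c("ADMN", "PDMN")) {
      nf <- file.path(run_dir, b, paste0(comp, "_component.nii.gz"))
      if (file.exists(nf)) {
        vol <- RNifti::readNifti(nf)
        png_path <- file.path(run_dir, b, paste0(comp, "_thumb.png"))
        grDevices::png(png_path, width = 240, height = 240)
        graphics::image(vol[, , ceiling(dim(vol)[3] / 2)],
                        col = grDevices::hcl.colors(32),
                        axes = FALSE, main = paste(comp, b))
        grDevices::dev.off()
      } else missing <- c(missing, file.path(b, basename(nf)))
    }
  }
  if (length(missing))
    lines <- c(lines, "## Missing artifacts", paste("-", missing))
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
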