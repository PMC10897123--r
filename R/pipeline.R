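# Cohort-level orchestration: read a cohort tree (or take an in-memory
# phantom cohort), run every analysis stage, and write TSV tables, NIfTI
# maps and a plain-text run log. All outputs are deterministic given the
# configuration and cohort.

#' Pipeline run configuration
#'
#' Defaults mirror the analysis conventions the package implements: 2 mm
#' background erosion, CE-T1w as the reference sequence, alpha 0.05,
#' ICC(2,1), pooled uncorrected post hoc t-tests.
#'
#' @param cohort_dir Cohort root (one directory per subject); may be NULL
#'   when an in-memory cohort is passed to [run_pipeline()].
#' @param output_dir Where tables, maps and the log are written.
#' @param sequences Sequence names expected per subject.
#' @param reference Reference sequence (must be in `sequences`).
#' @param raters Rater ids; the first is the primary rater used for the
#'   sequence-comparison analyses.
#' @param erosion_radius_mm Background-ROI erosion radius, mm.
#' @param axis_map Named integer vector mapping anatomical axis labels to
#'   voxel axes (template grids are assumed axis-aligned).
#' @param profile_axes Axes for slice error profiles (axial-wise "z",
#'   coronal-wise "y").
#' @param icc_variant "ICC2_1" or "ICC3_1".
#' @param var_equal,paired,correction Options forwarded to the t-test
#'   battery.
#' @param alpha Significance level.
#' @param seed Integer seed recorded in the log (the analysis itself is
#'   deterministic; the seed feeds cohort simulation).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort_dir = NULL, output_dir = tempfile("chpqc_out"),
                       sequences = c("T1w", "FLAIR", "CE-T1w"),
                       reference = "CE-T1w", raters = c("r1", "r2"),
                       erosion_radius_mm = 2,
                       axis_map = c(x = 1L, y = 2L, z = 3L),
                       profile_axes = c("z", "y"),
                       icc_variant = "ICC2_1", var_equal = TRUE,
                       paired = FALSE, correction = "none",
                       alpha = 0.05, seed = 1L) {
  cfg <- list(cohort_dir = cohort_dir, output_dir = output_dir,
              sequences = sequences, reference = reference, raters = raters,
              erosion_radius_mm = erosion_radius_mm, axis_map = axis_map,
              profile_axes = profile_axes, icc_variant = icc_variant,
              var_equal = var_equal, paired = paired,
              correction = correction, alpha = alpha,
              seed = as.integer(seed))
  if (!cfg$reference %in% cfg$sequences)
    stop("reference sequence '", cfg$reference, "' not among sequences")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep the [run_config()] defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$axis_map)) vals$axis_map <- unlist(vals$axis_map)
  do.call(run_config, vals)
}

#' Read a cohort directory tree into subject bundles
#'
#' Expects the layout written by [write_cohort()]: one directory per
#' subject with `<sequence>.nii.gz`, `<sequence>_chp_<rater>.nii.gz` and
#' `ventricles.nii.gz` (plus optional `chp_truth.nii.gz`).
#'
#' @param dir Cohort root.
#' @param sequences,raters Expected members per subject.
#' @return List of [subject_bundle]s.
#' @export
read_cohort <- function(dir, sequences = c("T1w", "FLAIR", "CE-T1w"),
                        raters = c("r1", "r2")) {
  subs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(subs) == 0L) stop("no subject directories under ", dir)
  lapply(subs, function(sd_) read_subject_dir(sd_, sequences, raters))
}

read_subject_dir <- function(sd_, sequences, raters) {
  find1 <- function(base) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- file.path(sd_, paste0(base, ext))
      if (file.exists(p)) return(p)
    }
    stop("missing ", base, ".nii[.gz] for subject ", basename(sd_))
  }
  intensities <- lapply(stats::setNames(sequences, sequences),
                        function(sq) read_volume(find1(sq)))
  chp_masks <- lapply(stats::setNames(sequences, sequences), function(sq) {
    lapply(stats::setNames(raters, raters), function(r)
      read_mask(find1(paste0(sq, "_chp_", r))))
  })
  vent <- read_mask(find1("ventricles"))
  tp <- file.path(sd_, "chp_truth.nii.gz")
  truth <- if (file.exists(tp)) read_mask(tp) else NULL
  subject_bundle(basename(sd_), intensities, chp_masks, vent,
                 truth_mask = truth)
}

#' Simulate a phantom cohort tree
#'
#' Generates a cohort from a [phantom_spec()] (or a YAML file whose keys
#' are `phantom_spec` arguments) and writes it where [run_pipeline()] can
#' consume it, including the ground-truth record.
#'
#' @param spec A `phantom_spec` or path to a YAML spec file.
#' @param dir Output cohort directory.
#' @return `dir`, invisibly.
#' @export
simulate_cohort <- function(spec, dir) {
  if (is.character(spec)) {
    vals <- yaml::read_yaml(spec)
    if (!is.null(vals$sequences))
      vals$sequences <- as.data.frame(lapply(vals$sequences, unlist),
                                      stringsAsFactors = FALSE)
    spec <- do.call(phantom_spec, vals)
  }
  write_cohort(generate_cohort(spec), dir)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

summarize_num <- function(x) c(mean = mean(x), sd = stats::sd(x))

#' Run the full comparison pipeline over a cohort
#'
#' Stages: per-subject background ROI + SNR/CNR; per-subject overlap and
#' volume metrics of every non-reference sequence against the reference;
#' inter-rater Dice and volumes; cohort summary (mean +/- SD per metric per
#' sequence, Pearson r, ICC); the statistical battery; slice-wise error
#' profiles along the configured axes; frequency maps per sequence and
#' difference maps against the reference. Per-subject failures are logged
#' and the subject skipped; the report records them.
#'
#' @param config A [run_config()] (or path to a YAML config file).
#' @param cohort Optional in-memory cohort: a `phantom_cohort` or list of
#'   [subject_bundle]s. When NULL, `config$cohort_dir` is read.
#' @return Invisibly, a list of all result tables plus `failed_subjects`;
#'   files are written under `config$output_dir`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  read_failures <- character(0)
  if (is.null(cohort)) {
    if (is.null(config$cohort_dir)) stop("no cohort and no cohort_dir")
    subs <- sort(list.dirs(config$cohort_dir, recursive = FALSE))
    if (length(subs) == 0L)
      stop("no subject directories under ", config$cohort_dir)
    cohort <- list()
    for (sd_ in subs) {
      b <- tryCatch(read_subject_dir(sd_, config$sequences, config$raters),
                    error = function(e) e)
      if (inherits(b, "error"))
        read_failures <- c(read_failures,
                           paste0(basename(sd_), ": ", conditionMessage(b)))
      else cohort <- c(cohort, list(b))
    }
    if (length(cohort) == 0L) stop("no readable subject in cohort")
  }
  bundles <- if (inherits(cohort, "phantom_cohort")) cohort$subjects
             else cohort
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("chpqc run log",
                 paste0("package version: ",
                        as.character(utils::packageVersion("chpqc"))),
                 paste0("R version: ", R.version.string),
                 paste0("n subjects: ", length(bundles)),
                 paste0("sequences: ", paste(config$sequences, collapse = ", ")),
                 paste0("reference: ", config$reference),
                 paste0("raters: ", paste(config$raters, collapse = ", ")),
                 paste0("erosion_radius_mm: ", config$erosion_radius_mm),
                 paste0("icc_variant: ", config$icc_variant),
                 paste0("t-test pooled var: ", config$var_equal,
                        "; paired: ", config$paired,
                        "; correction: ", config$correction),
                 paste0("alpha: ", config$alpha),
                 paste0("seed: ", config$seed),
                 "SD convention: sample SD (n-1) throughout")
  primary <- config$raters[1]
  ref <- config$reference
  nonref <- setdiff(config$sequences, ref)
  failed <- character(0)
  for (rf in read_failures) {
    failed <- c(failed, sub(":.*$", "", rf))
    log_lines <- c(log_lines, paste0("SKIPPED subject ", rf))
  }

  contrast_rows <- list()
  overlap_rows <- list()
  inter_rows <- list()
  ok_bundles <- list()
  for (b in bundles) {
    res <- tryCatch({
      ct <- contrast_table(b, rater = primary,
                           erosion_radius_mm = config$erosion_radius_mm)
      ov <- do.call(rbind, lapply(nonref, function(sq)
        overlap_row(b$chp_masks[[sq]][[primary]],
                    b$chp_masks[[ref]][[primary]],
                    subject_id = b$subject_id,
                    seg_label = sq, ref_label = ref)))
      ir <- NULL
      if (length(config$raters) >= 2L) {
        ir <- do.call(rbind, lapply(config$sequences, function(sq) {
          do.call(rbind, lapply(config$raters[-1], function(r)
            overlap_row(b$chp_masks[[sq]][[r]],
                        b$chp_masks[[sq]][[primary]],
                        subject_id = b$subject_id,
                        seg_label = paste0(sq, ":", r),
                        ref_label = paste0(sq, ":", primary))))
        }))
      }
      list(ct = ct, ov = ov, ir = ir)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, b$subject_id)
      log_lines <- c(log_lines, paste0("SKIPPED subject ", b$subject_id,
                                       ": ", conditionMessage(res)))
      next
    }
    contrast_rows[[b$subject_id]] <- res$ct
    overlap_rows[[b$subject_id]] <- res$ov
    inter_rows[[b$subject_id]] <- res$ir
    ok_bundles[[b$subject_id]] <- b
  }
  if (length(ok_bundles) == 0L) stop("no subject could be processed")
  contrast <- do.call(rbind, unname(contrast_rows))
  overlap <- do.call(rbind, unname(overlap_rows))
  interrater <- do.call(rbind, unname(inter_rows))
  write_tsv(contrast, file.path(config$output_dir, "contrast.tsv"))
  write_tsv(overlap, file.path(config$output_dir, "overlap.tsv"))
  if (!is.null(interrater))
    write_tsv(interrater, file.path(config$output_dir, "interrater.tsv"))

  n_ok <- length(ok_bundles)
  # cohort summary: mean +/- SD per sequence for every metric
  summary_rows <- list()
  for (sq in config$sequences) {
    cs <- contrast[contrast$sequence == sq, ]
    vols <- vapply(ok_bundles, function(b)
      volume_ml(b$chp_masks[[sq]][[primary]]), numeric(1))
    row <- data.frame(sequence = sq,
                      snr_mean = mean(cs$snr), snr_sd = stats::sd(cs$snr),
                      cnr_mean = mean(cs$cnr), cnr_sd = stats::sd(cs$cnr),
                      vol_ml_mean = mean(vols), vol_ml_sd = stats::sd(vols),
                      dsc_mean = NA_real_, dsc_sd = NA_real_,
                      dvol_pct_mean = NA_real_, dvol_pct_sd = NA_real_,
                      abs_dvol_pct_mean = NA_real_,
                      abs_dvol_pct_sd = NA_real_,
                      pearson_r = NA_real_, icc = NA_real_,
                      stringsAsFactors = FALSE)
    if (sq %in% nonref) {
      os <- overlap[overlap$seg_label == sq, ]
      row$dsc_mean <- mean(os$dsc); row$dsc_sd <- stats::sd(os$dsc)
      row$dvol_pct_mean <- mean(os$dvol_pct)
      row$dvol_pct_sd <- stats::sd(os$dvol_pct)
      row$abs_dvol_pct_mean <- mean(os$abs_dvol_pct)
      row$abs_dvol_pct_sd <- stats::sd(os$abs_dvol_pct)
      if (n_ok >= 3L)
        row$pearson_r <- pearson_volume_correlation(os$vol_seg_ml,
                                                    os$vol_ref_ml)
    }
    if (length(config$raters) >= 2L && n_ok >= 2L) {
      ratings <- vapply(config$raters, function(r)
        vapply(ok_bundles, function(b)
          volume_ml(b$chp_masks[[sq]][[r]]), numeric(1)),
        numeric(n_ok))
      row$icc <- icc_absolute_volume(ratings, variant = config$icc_variant)
    }
    summary_rows[[sq]] <- row
  }
  cohort_summary <- do.call(rbind, unname(summary_rows))
  if (n_ok < 3L)
    log_lines <- c(log_lines,
                   "insufficient n for Pearson correlation (needs >= 3)")
  if (n_ok < 2L)
    log_lines <- c(log_lines, "insufficient n for ICC (needs >= 2)")
  write_tsv(cohort_summary, file.path(config$output_dir,
                                      "cohort_summary.tsv"))

  # statistical battery
  stats_rows <- list()
  if (n_ok >= 2L) {
    vol_groups <- lapply(stats::setNames(config$sequences, config$sequences),
      function(sq) vapply(ok_bundles, function(b)
        volume_ml(b$chp_masks[[sq]][[primary]]), numeric(1)))
    snr_groups <- lapply(stats::setNames(config$sequences, config$sequences),
      function(sq) contrast$snr[contrast$sequence == sq])
    cnr_groups <- lapply(stats::setNames(config$sequences, config$sequences),
      function(sq) contrast$cnr[contrast$sequence == sq])
    for (metric in c("volume_ml", "snr", "cnr")) {
      g <- switch(metric, volume_ml = vol_groups, snr = snr_groups,
                  cnr = cnr_groups)
      an <- tryCatch(one_way_anova(g, alpha = config$alpha),
                     error = function(e) NULL)
      if (!is.null(an)) {
        an$metric <- metric
        ph <- posthoc_pairwise_t(g, alpha = config$alpha,
                                 var_equal = config$var_equal,
                                 paired = config$paired,
                                 correction = config$correction)
        ph$metric <- metric
        stats_rows <- c(stats_rows, list(an, ph))
      }
    }
    for (sq in nonref) {
      dv <- overlap$dvol_pct[overlap$seg_label == sq]
      ts <- tryCatch(t_test(dv, mode = "one-sample", mu0 = 0,
                            alpha = config$alpha, label = sq),
                     error = function(e) NULL)
      if (!is.null(ts)) {
        ts$metric <- "dvol_pct"
        stats_rows <- c(stats_rows, list(ts))
      }
    }
    if (length(nonref) >= 2L) {
      for (metric in c("dvol_pct", "abs_dvol_pct")) {
        a <- overlap[[metric]][overlap$seg_label == nonref[1]]
        b2 <- overlap[[metric]][overlap$seg_label == nonref[2]]
        ts <- tryCatch(t_test(a, b2,
                              mode = if (config$paired) "paired"
                                     else "two-sample",
                              var_equal = config$var_equal,
                              alpha = config$alpha,
                              label = paste(nonref[1], nonref[2],
                                            sep = "|")),
                       error = function(e) NULL)
        if (!is.null(ts)) {
          ts$metric <- metric
          stats_rows <- c(stats_rows, list(ts))
        }
      }
    }
    if (!is.null(interrater) && length(config$raters) >= 2L) {
      dsc_groups <- lapply(
        stats::setNames(config$sequences, config$sequences),
        function(sq) interrater$dsc[startsWith(interrater$seg_label,
                                               paste0(sq, ":"))])
      an <- tryCatch(one_way_anova(dsc_groups, alpha = config$alpha),
                     error = function(e) NULL)
      if (!is.null(an)) {
        an$metric <- "interrater_dsc"
        stats_rows <- c(stats_rows, list(an))
      }
    }
  } else {
    log_lines <- c(log_lines, "insufficient n for statistical tests")
  }
  stats_tbl <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL
  if (!is.null(stats_tbl))
    write_tsv(stats_tbl, file.path(config$output_dir, "stats.tsv"))

  # slice error profiles (non-reference sequences vs reference)
  ref_masks <- lapply(ok_bundles, function(b) b$chp_masks[[ref]][[primary]])
  profile_rows <- list()
  for (sq in nonref) {
    seg_masks <- lapply(ok_bundles, function(b) b$chp_masks[[sq]][[primary]])
    for (ax in config$profile_axes) {
      pr <- slice_error_profile(seg_masks, ref_masks, axis = ax,
                                axis_map = config$axis_map)
      pr$sequence <- sq
      attr(pr, "per_subject") <- NULL
      profile_rows <- c(profile_rows, list(as.data.frame(pr)))
    }
  }
  profiles <- if (length(profile_rows)) do.call(rbind, profile_rows) else NULL
  if (!is.null(profiles))
    write_tsv(profiles, file.path(config$output_dir, "slice_profiles.tsv"))

  # frequency maps and differences against the reference
  fmaps <- list()
  for (sq in config$sequences) {
    fm <- frequency_map(lapply(ok_bundles, function(b)
      b$chp_masks[[sq]][[primary]]), label = sq)
    fmaps[[sq]] <- fm
    write_volume(fm, file.path(config$output_dir,
                               paste0("freq_", sq, ".nii.gz")))
  }
  for (sq in nonref) {
    dm <- frequency_difference_map(fmaps[[sq]], fmaps[[ref]])
    write_volume(dm, file.path(config$output_dir,
                               paste0("freqdiff_", sq, "_vs_", ref,
                                      ".nii.gz")))
  }

  if (length(failed))
    log_lines <- c(log_lines, paste0("FAILED subjects: ",
                                     paste(failed, collapse = ", ")))
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  invisible(list(contrast = contrast, overlap = overlap,
                 interrater = interrater, cohort_summary = cohort_summary,
                 stats = stats_tbl, slice_profiles = profiles,
                 frequency_maps = fmaps, failed_subjects = failed,
                 output_dir = config$output_dir))
}
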