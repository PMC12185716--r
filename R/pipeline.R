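#' Run the clustered de novo mutation pipeline end to end
#'
#' Orchestrates simulate -> emit fixtures -> read joint VCF -> score and
#' filter DNM candidates -> assemble clusters -> target masks -> phasing
#' -> window sensitivity scan -> age matching -> descriptive and
#' regression statistics -> PPV thinning simulation -> report. Every
#' stage's outputs are persisted under `out_dir` so stages can be
#' inspected in isolation, and a manifest records seeds and per-stage
#' counts. Re-running with the same config and seed reproduces all
#' tables byte-identically.
#'
#' @param config A `sim_config` (or path to a YAML config).
#' @param out_dir Output directory.
#' @param seed Integer seed; defaults to the config's.
#' @param window_bp Cluster window for the main analysis.
#' @param ppv Positive predictive value used for adjusted descriptives
#'   and the thinning simulation.
#' @param ppv_reps Replicates of the thinning simulation (0 disables).
#' @param ref_cohort Reference (control) cohort for contrasts.
#' @param match_ratio Partners per reference offspring in age matching.
#' @param m_tests Bonferroni multiplier.
#' @return A list of class `cdnm_bundle` with the stage results
#'   (`meta`, `truth`, `callset`, `clusters`, `counts`, `phases`,
#'   `sensitivity`, `matching`, `descriptives`, `fits`, `ppv_sim`,
#'   `manifest`, `paths`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, window_bp = NULL,
                         ppv = 0.23, ppv_reps = 50L, ref_cohort = "inova",
                         match_ratio = 1L, m_tests = 9) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(window_bp)) window_bp <- config$window_bp
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, window_bp = window_bp, ppv = ppv)

  # stage 1: simulate cohort + fixtures
  meta <- simulate_metadata(config)
  truth <- simulate_mutations(meta, config)
  fx <- emit_fixtures(truth, config, file.path(out_dir, "fixtures"))
  manifest$n_offspring <- nrow(meta)
  manifest$n_vcf_records <- fx$n_records

  # stage 2: DNM detection from the joint VCF
  ped <- read_pedigree(fx$ped)
  records <- read_joint_vcf(fx$vcf, ped, carriers_only = TRUE)
  callset <- apply_dnm_filters(records, filter_config())
  manifest$dnm_audit <- as.list(callset$audit)
  write_tables(callset$calls, prefix = file.path(out_dir, "dnm"))

  # stage 3: clustering + masks
  clusters <- assemble_clusters(callset$calls, window_bp = window_bp)
  rep_mask <- read_mask(fx$repeat_bed, label = "repeat")
  map_mask <- read_mask(fx$mapability_bed, label = "low_mapability")
  clusters <- apply_target_mask(clusters, rep_mask, map_mask)

  # stage 4: phasing
  evidence <- read_evidence_table(fx$evidence)
  phases <- if (nrow(evidence) > 0L) phase_dnm(evidence) else NULL
  if (!is.null(phases)) clusters <- phase_clusters(clusters, phases)

  # attach validation labels from the truth set (stand-in for wet-lab
  # validation of called clusters)
  tc <- truth$clusters
  if (nrow(clusters$clusters) > 0L && nrow(tc) > 0L) {
    key_called <- paste(clusters$clusters$sample_id, clusters$clusters$chrom,
                        clusters$clusters$start)
    key_truth <- paste(tc$sample_id, tc$chrom, tc$start)
    hit <- base::match(key_called, key_truth)
    lab <- tc$validation[hit]
    clusters$clusters$validation <- ifelse(is.na(lab), "untested", lab)
  }
  write_tables(callset$calls, clusters, prefix = file.path(out_dir, "cdnm"))
  manifest$n_clusters <- nrow(clusters$clusters)
  manifest$n_clustered_dnms <- nrow(clusters$members)
  manifest$n_unclustered_dnms <- nrow(callset$calls) - nrow(clusters$members)

  # stage 5: per-sample counts + sensitivity scan
  counts <- per_sample_counts(callset$calls, clusters, meta)
  sens <- sensitivity_scan(callset$calls, meta)
  utils::write.table(counts, file.path(out_dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sens, file.path(out_dir, "sensitivity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # stage 6: age matching of the other cohorts to the reference-smallest
  cohorts <- unique(meta$cohort)
  smallest <- names(which.min(table(meta$cohort)))
  matching <- list()
  for (co in setdiff(cohorts, smallest)) {
    ref_m <- meta[meta$cohort == smallest, ]
    oth_m <- meta[meta$cohort == co, ]
    if (nrow(oth_m) >= match_ratio * nrow(ref_m)) {
      matching[[co]] <- age_match(ref_m, oth_m, ratio = match_ratio)
    }
  }
  if (length(matching) > 0L) {
    pairs <- do.call(rbind, lapply(names(matching), function(co) {
      cbind(cohort = co, matching[[co]]$pairs)
    }))
    utils::write.table(pairs, file.path(out_dir, "matched.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # stage 7: statistics
  descriptives <- list(
    dnm = descriptive_stats(counts$n_dnm, counts$cohort, ppv = 1),
    cdnm = descriptive_stats(counts$n_cdnm, counts$cohort, ppv = ppv)
  )
  fits <- list()
  fits$age_effect <- tryCatch(
    fit_nb_glm(n_dnm ~ father_age, counts), error = function(e) e)
  if (inherits(fits$age_effect, "cdnm_fit")) {
    fits$age_effect_summary <- paternal_age_effect(
      fits$age_effect, ref_count = mean(counts$n_dnm))
  }
  fits$cohort_contrast <- tryCatch(
    cohort_contrast_model(counts, response = "n_cdnm", ref_level = ref_cohort,
                          m_tests = m_tests),
    error = function(e) e)
  fits$dose_response <- tryCatch(
    dose_response_model(counts), error = function(e) e)
  fits$inverse_dose <- tryCatch(
    inverse_dose_model(counts), error = function(e) e)

  phase_tab <- NULL
  if (!is.null(phases)) {
    ph <- phases[phases$origin %in% c("paternal", "maternal"), , drop = FALSE]
    ph$cohort <- meta$cohort[base::match(ph$sample_id, meta$sample_id)]
    phase_tab <- table(ph$cohort, ph$origin)
    fits$origin_ratio <- tryCatch(
      origin_ratio_test(phase_tab[, c("paternal", "maternal"), drop = FALSE]),
      error = function(e) e)
  }

  ok_fits <- Filter(function(f) inherits(f, c("cdnm_fit", "cohort_contrast",
                                              "dose_response")), fits)
  write_tables(callset$calls[0, ], fits = ok_fits,
               prefix = file.path(out_dir, "model"))

  # stage 8: PPV thinning robustness
  ppv_sim <- NULL
  if (ppv_reps > 0L && inherits(fits$cohort_contrast, "cohort_contrast")) {
    ppv_sim <- tryCatch(
      ppv_thinning_simulation(counts, response = "n_cdnm",
                              ref_level = ref_cohort, ppv = ppv,
                              reps = ppv_reps, m_tests = m_tests,
                              seed = config$seed + 3L),
      error = function(e) e)
  }

  bundle <- structure(list(
    meta = meta, truth = truth, callset = callset, clusters = clusters,
    counts = counts, phases = phases, phase_table = phase_tab,
    sensitivity = sens, matching = matching, descriptives = descriptives,
    fits = fits, ppv_sim = ppv_sim, manifest = manifest,
    paths = c(fx, out_dir = out_dir)
  ), class = "cdnm_bundle")

  report <- make_report(bundle)
  writeLines(report, file.path(out_dir, "report.md"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle
}

#' @export
print.cdnm_bundle <- function(x, ...) {
  cat("cDNM pipeline bundle:", nrow(x$meta), "offspring,",
      nrow(x$callset$calls), "DNM calls,", nrow(x$clusters$clusters),
      "clusters\n")
  cat("outputs under:", x$paths[["out_dir"]], "\n")
  invisible(x)
}

.fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)

#' Render a human-readable pipeline report
#'
#' @param bundle A `cdnm_bundle` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "cdnm_bundle"))
  L <- c("# Clustered de novo mutation analysis report", "")
  L <- c(L, paste0("Seed: ", bundle$manifest$seed,
                   "; window: ", bundle$manifest$window_bp, " bp; PPV: ",
                   bundle$manifest$ppv), "")
  au <- bundle$manifest$dnm_audit
  L <- c(L, "## Detection",
         paste0("- candidates: ", au$candidates, "; retained: ", au$retained,
                " (score/depth/parental/AC/extra rejections: ",
                au$fail_score, "/", au$fail_depth, "/", au$fail_parental_reads,
                "/", au$fail_ac, "/", au$fail_extra, ")"), "")
  L <- c(L, "## Per-cohort counts", "",
         "cohort | n | DNM mean (sd, median) | cDNM mean (sd, median) | ppv-adj cDNM mean",
         "--- | --- | --- | --- | ---")
  dd <- bundle$descriptives$dnm
  dc <- bundle$descriptives$cdnm
  for (i in seq_len(nrow(dd))) {
    L <- c(L, paste0(dd$group[i], " | ", dd$n[i], " | ",
                     .fmt(dd$mean[i]), " (", .fmt(dd$sd[i]), ", ", dd$median[i],
                     ") | ", .fmt(dc$mean[i]), " (", .fmt(dc$sd[i]), ", ",
                     dc$median[i], ") | ", .fmt(dc$ppv_adjusted_mean[i])))
  }
  L <- c(L, "")
  f <- bundle$fits
  L <- c(L, "## Paternal age effect")
  if (inherits(f$age_effect, "cdnm_fit")) {
    ae <- f$age_effect_summary
    L <- c(L, paste0("- ", .fmt(ae$percent_per_year), "% per year (95% CI ",
                     .fmt(ae$percent_ci_lo), " to ", .fmt(ae$percent_ci_hi),
                     "), ~", .fmt(ae$dnms_per_year, 1),
                     " additional DNMs/year at the cohort mean"))
  } else L <- c(L, "- unavailable: model did not fit")
  L <- c(L, "", "## Cohort contrasts (cDNM counts)")
  if (inherits(f$cohort_contrast, "cohort_contrast")) {
    cc <- f$cohort_contrast$contrasts
    for (i in seq_len(nrow(cc))) {
      L <- c(L, paste0("- ", cc$group[i], " vs ", f$cohort_contrast$reference,
                       ": rate ratio ", .fmt(cc$rate_ratio[i]),
                       " (95% CI ", .fmt(cc$ci_lo[i]), "-", .fmt(cc$ci_hi[i]),
                       "), p_nom = ", signif(cc$p_nom[i], 3),
                       ", p_adj = ", signif(cc$p_adj[i], 3)))
    }
  } else L <- c(L, "- unavailable: model did not fit")
  L <- c(L, "", "## Dose response (exposed subgroup)")
  if (inherits(f$dose_response, "dose_response")) {
    dr <- f$dose_response
    L <- c(L, paste0("- f(n) = ", .fmt(dr$baseline$estimate),
                     " * exp(", signif(dr$beta$estimate, 3), " * n) per mGy; beta 95% CI (",
                     signif(dr$beta$ci_lo, 3), ", ", signif(dr$beta$ci_hi, 3),
                     "), p = ", signif(dr$beta$p_value, 3), ", n = ", dr$n))
  } else L <- c(L, "- unavailable: too few exposed offspring or model failure")
  L <- c(L, "", "## Phasing")
  if (!is.null(bundle$phase_table)) {
    pt <- bundle$phase_table
    for (co in rownames(pt)) {
      L <- c(L, paste0("- ", co, ": paternal ", pt[co, "paternal"],
                       ", maternal ", pt[co, "maternal"]))
    }
    if (!is.null(f$origin_ratio) && !inherits(f$origin_ratio, "error")) {
      L <- c(L, paste0("- homogeneity chi-squared = ",
                       signif(f$origin_ratio$statistic, 4), " (df ",
                       f$origin_ratio$df, "), p = ",
                       signif(f$origin_ratio$p_value, 3)))
    }
  } else L <- c(L, "- unavailable: no phaseable evidence")
  L <- c(L, "", "## Window sensitivity (clusters per window, cohort totals)")
  sens <- bundle$sensitivity
  sens$cohort <- bundle$meta$cohort[base::match(sens$sample_id,
                                                bundle$meta$sample_id)]
  wcols <- grep("^w[0-9]+$", names(sens), value = TRUE)
  for (co in unique(sens$cohort)) {
    tot <- vapply(wcols, function(cn) sum(sens[[cn]][sens$cohort == co]), 0)
    L <- c(L, paste0("- ", co, ": ",
                     paste(sub("^w", "", wcols), "bp:", tot, collapse = "; ")))
  }
  L <- c(L, "", "## PPV robustness")
  if (inherits(bundle$ppv_sim, "ppv_simulation")) {
    s <- bundle$ppv_sim
    L <- c(L, paste0("- thinning at PPV ", s$ppv, ", ", s$reps,
                     " reps: significant fraction (alpha ", s$alpha, ") = ",
                     .fmt(s$significant_fraction), "; failed refits: ",
                     s$n_failed))
  } else L <- c(L, "- not run")
  L
}
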