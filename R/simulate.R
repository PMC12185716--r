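#' Simulation configuration for a synthetic trio-cohort study
#'
#' Defines three cohorts mirroring the statistical structure of a
#' radiation trio-WGS study: a large unexposed control cohort with older
#' parents, and two case cohorts with paternal dose distributions that
#' mix a point mass at 0 mGy with an exponential tail. Per-offspring
#' isolated DNM counts follow a negative binomial with a paternal-age
#' effect on the log scale; true cluster counts follow a negative
#' binomial with a dose effect; artifact (false positive) clusters are
#' Poisson and sized so that the fraction of true clusters among all
#' emitted clusters matches the target positive predictive value.
#'
#' @param cohorts Named list of per-cohort parameter lists; see
#'   [cohort_params()] for the fields. Defaults describe a control cohort
#'   (`inova`-like) and two exposed cohorts (`radar`-like, `cru`-like) at
#'   reduced sample sizes suitable for interactive use; pass
#'   `n_offspring` per cohort to scale.
#' @param genome Named integer vector of chromosome lengths (bp).
#' @param window_bp Generating cluster window (consecutive member gaps are
#'   drawn strictly below this). Default 20.
#' @param min_event_spacing Minimum distance in bp between distinct
#'   mutation events of one offspring, so isolated DNMs stay isolated and
#'   clusters do not merge at the generating window.
#' @param paternal_fraction Probability that a mutation event is of
#'   paternal origin (population ratio unknown; 2:1 is a configurable
#'   guess).
#' @param cluster_extra_mean Poisson mean of extra members beyond 2 per
#'   cluster.
#' @param artifact_in_repeat Probability that an artifact cluster is
#'   placed inside a repeat-mask interval.
#' @param seed Default seed carried in the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(cohorts = default_cohorts(),
                       genome = stats::setNames(rep(50e6, 22), paste0("chr", 1:22)),
                       window_bp = 20L,
                       min_event_spacing = 200L,
                       paternal_fraction = 2 / 3,
                       cluster_extra_mean = 0.25,
                       artifact_in_repeat = 0.6,
                       seed = 1L) {
  stopifnot(length(cohorts) >= 1L, !is.null(names(cohorts)),
            window_bp >= 2, all(genome > 0),
            paternal_fraction >= 0, paternal_fraction <= 1)
  for (nm in names(cohorts)) {
    p <- cohorts[[nm]]
    stopifnot(p$n_offspring >= 1,
              p$parent_age_correlation >= -1, p$parent_age_correlation <= 1,
              p$dose_zero_fraction >= 0, p$dose_zero_fraction <= 1,
              p$dnm_rate_at_ref_age >= 0, p$cdnm_base_mean >= 0,
              p$fp_cluster_rate >= 0, p$dnm_dispersion > 0,
              p$cdnm_dispersion > 0)
  }
  structure(list(cohorts = cohorts, genome = genome, window_bp = window_bp,
                 min_event_spacing = min_event_spacing,
                 paternal_fraction = paternal_fraction,
                 cluster_extra_mean = cluster_extra_mean,
                 artifact_in_repeat = artifact_in_repeat, seed = seed),
            class = "sim_config")
}

#' Per-cohort simulation parameters
#'
#' @param n_offspring Number of offspring trios.
#' @param father_age_mean,father_age_sd Paternal age at conception, years.
#' @param mother_age_mean,mother_age_sd Maternal age at conception, years.
#' @param parent_age_correlation Target Pearson correlation between
#'   parental ages (bivariate normal).
#' @param dose_zero_fraction Probability of 0 mGy paternal dose.
#' @param dose_positive_mean Mean of the exponential dose tail, mGy.
#' @param dose_missing_fraction Probability the dose estimate is missing.
#' @param dnm_rate_at_ref_age Expected isolated DNMs per generation at
#'   `ref_age`.
#' @param paternal_age_log_slope Log-linear paternal age effect per year
#'   (default `log(1.02)`, i.e. ~2%/yr).
#' @param ref_age Reference paternal age, years.
#' @param cdnm_base_mean Expected TRUE clusters per offspring at dose 0.
#' @param cdnm_dose_log_slope Log-linear dose effect per mGy on true
#'   clusters.
#' @param fp_cluster_rate Poisson mean of artifact (false positive)
#'   clusters per offspring.
#' @param dnm_dispersion,cdnm_dispersion NB2 dispersion theta for the two
#'   count families (Poisson limit as theta grows).
#' @param read_length Sequencing read length in bp; bounds the
#'   DNM-to-informative-site distance that read-backed phasing can
#'   bridge.
#' @return A parameter list.
#' @export
cohort_params <- function(n_offspring = 100L,
                          father_age_mean = 30, father_age_sd = 5,
                          mother_age_mean = 27.5, mother_age_sd = 4.5,
                          parent_age_correlation = 0.71,
                          dose_zero_fraction = 1, dose_positive_mean = 0,
                          dose_missing_fraction = 0,
                          dnm_rate_at_ref_age = 70,
                          paternal_age_log_slope = log(1.02),
                          ref_age = 30,
                          cdnm_base_mean = 0.20,
                          cdnm_dose_log_slope = 0,
                          fp_cluster_rate = 0.68,
                          dnm_dispersion = 20, cdnm_dispersion = 1.5,
                          read_length = 150L) {
  as.list(environment())
}

#' Default three-cohort study layout
#'
#' Cohort means and shapes follow the published study design: control
#' parents ~5 (fathers) and ~5.5 (mothers) years older; parental-age
#' correlation 0.71; the radar-like cohort with 70% unexposed fathers
#' and a 34 mGy exponential tail; the CRU-like cohort with a 365 mGy
#' tail; raw called-cluster means of roughly 0.88 / 1.48 / 2.65 per
#' offspring split 23% true / 77% artifact (PPV 0.23); a 2%/yr paternal
#' age effect around 70 isolated DNMs per generation.
#'
#' @param n_inova,n_radar,n_cru Offspring counts per cohort (defaults are
#'   desk-scale; the source cohorts had 1275/110/130).
#' @return Named list of cohort parameter lists.
#' @export
default_cohorts <- function(n_inova = 120L, n_radar = 60L, n_cru = 60L) {
  list(
    inova = cohort_params(
      n_offspring = n_inova,
      father_age_mean = 35, father_age_sd = 5.5,
      mother_age_mean = 33, mother_age_sd = 5,
      dose_zero_fraction = 1, dose_positive_mean = 0,
      cdnm_base_mean = 0.23 * 0.88, fp_cluster_rate = 0.77 * 0.88,
      read_length = 100L
    ),
    radar = cohort_params(
      n_offspring = n_radar,
      father_age_mean = 30, father_age_sd = 5,
      mother_age_mean = 27.5, mother_age_sd = 4.5,
      dose_zero_fraction = 0.7, dose_positive_mean = 34.35,
      dose_missing_fraction = 0.027,
      cdnm_base_mean = 0.23 * 1.48 / 1.005, cdnm_dose_log_slope = 5e-4,
      fp_cluster_rate = 0.77 * 1.48,
      read_length = 150L
    ),
    cru = cohort_params(
      n_offspring = n_cru,
      father_age_mean = 30, father_age_sd = 5,
      mother_age_mean = 27.5, mother_age_sd = 4.5,
      dose_zero_fraction = 0.1, dose_positive_mean = 365.42,
      cdnm_base_mean = 0.23 * 2.65 / 1.201, cdnm_dose_log_slope = 5e-4,
      fp_cluster_rate = 0.77 * 2.65,
      read_length = 150L
    )
  )
}

#' Read a simulation config from YAML
#'
#' Any key present in the file overrides the corresponding
#' [sim_config()] / [cohort_params()] default; cohorts are listed under a
#' `cohorts:` mapping.
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohorts <- default_cohorts()
  for (nm in names(y$cohorts)) {
    base <- if (nm %in% names(cohorts)) cohorts[[nm]] else cohort_params()
    cohorts[[nm]] <- utils::modifyList(base, y$cohorts[[nm]])
  }
  top <- y[setdiff(names(y), "cohorts")]
  args <- utils::modifyList(list(cohorts = cohorts), top)
  if (!is.null(args$genome)) args$genome <- unlist(args$genome)
  do.call(sim_config, args)
}

#' Simulate per-offspring sample metadata
#'
#' Parental ages are drawn from a bivariate normal with the configured
#' means, standard deviations and correlation; paternal doses from the
#' configured zero-inflated exponential; a configurable fraction of dose
#' estimates is set missing.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (defaults to the config's).
#' @return Data frame: `sample_id`, `family_id`, `cohort`, `father_age`,
#'   `mother_age`, `dose` (mGy, `NA` when missing), `exposure_group`
#'   (`Exposed`/`Unexposed`/`NA`), `read_length`.
#' @export
simulate_metadata <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  out <- lapply(names(config$cohorts), function(nm) {
    p <- config$cohorts[[nm]]
    n <- p$n_offspring
    zf <- stats::rnorm(n)
    zm <- stats::rnorm(n)
    rho <- p$parent_age_correlation
    father_age <- p$father_age_mean + p$father_age_sd * zf
    mother_age <- p$mother_age_mean +
      p$mother_age_sd * (rho * zf + sqrt(1 - rho^2) * zm)
    dose <- ifelse(stats::runif(n) < p$dose_zero_fraction, 0,
                   stats::rexp(n, rate = 1 / max(p$dose_positive_mean, 1e-12)))
    if (p$dose_positive_mean <= 0) dose <- rep(0, n)
    dose[stats::runif(n) < p$dose_missing_fraction] <- NA_real_
    id <- sprintf("%s_%04d", nm, seq_len(n))
    data.frame(sample_id = id, family_id = paste0("fam_", id), cohort = nm,
               father_age = father_age, mother_age = mother_age, dose = dose,
               exposure_group = ifelse(is.na(dose), NA_character_,
                                       ifelse(dose > 0, "Exposed", "Unexposed")),
               read_length = p$read_length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# place n event anchors on the genome for one offspring, pairwise spaced
# by at least `spacing` bp within a chromosome
.place_anchors <- function(n, genome, spacing, max_tries = 100L) {
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  chroms <- sample(names(genome), n, replace = TRUE,
                   prob = genome / sum(genome))
  pos <- floor(stats::runif(n, min = spacing,
                            max = genome[chroms] - spacing)) + 1L
  for (i in seq_len(max_tries)) {
    ord <- order(chroms, pos)
    bad_sorted <- c(FALSE, chroms[ord][-1L] == chroms[ord][-n] &
                      diff(pos[ord]) < spacing)
    bad <- logical(n)
    bad[ord] <- bad_sorted
    if (!any(bad)) {
      return(data.frame(chrom = chroms, pos = as.integer(pos),
                        stringsAsFactors = FALSE))
    }
    k <- sum(bad)
    chroms[bad] <- sample(names(genome), k, replace = TRUE,
                          prob = genome / sum(genome))
    pos[bad] <- floor(stats::runif(k, min = spacing,
                                   max = genome[chroms[bad]] - spacing)) + 1L
  }
  stop("could not place mutation events without collisions after ",
       max_tries, " retries")
}

.random_snv <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

#' Simulate the mutation truth set for a cohort study
#'
#' Draws, per offspring: isolated DNM counts (negative binomial, mean
#' `dnm_rate_at_ref_age * exp(slope * (father_age - ref_age))`); true
#' cluster counts (negative binomial, mean
#' `cdnm_base_mean * exp(dose_slope * dose)`, missing dose treated as 0);
#' artifact cluster counts (Poisson, `fp_cluster_rate`). Cluster members
#' are placed with consecutive gaps uniform on `[1, window_bp - 1]`;
#' distinct events of one offspring are spaced by at least
#' `min_event_spacing`. Origins are paternal with probability
#' `paternal_fraction`. Artifact clusters carry validation label
#' `false_positive`, true clusters `true_positive`.
#'
#' @param meta Metadata from [simulate_metadata()].
#' @param config The `sim_config` used to generate `meta`.
#' @param seed Integer seed.
#' @return A list of class `truth_set`: `dnms` (all individual mutations
#'   with `sample_id`, `chrom`, `pos`, `ref`, `alt`, `origin`,
#'   `cluster_id` (`NA` for isolated), `is_artifact`, `validation`),
#'   `clusters` (per cluster: id, sample, chrom, start, end, n_members,
#'   origin, is_artifact, validation), plus `meta`, `window_bp`, `genome`.
#' @export
simulate_mutations <- function(meta, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  w <- config$window_bp
  per_sample <- lapply(seq_len(nrow(meta)), function(i) {
    p <- config$cohorts[[meta$cohort[i]]]
    mu_dnm <- p$dnm_rate_at_ref_age *
      exp(p$paternal_age_log_slope * (meta$father_age[i] - p$ref_age))
    n_iso <- stats::rnbinom(1L, mu = mu_dnm, size = p$dnm_dispersion)
    dose <- if (is.na(meta$dose[i])) 0 else meta$dose[i]
    mu_cl <- p$cdnm_base_mean * exp(p$cdnm_dose_log_slope * dose)
    n_true_cl <- stats::rnbinom(1L, mu = mu_cl, size = p$cdnm_dispersion)
    n_fp_cl <- stats::rpois(1L, p$fp_cluster_rate)
    n_cl <- n_true_cl + n_fp_cl
    anchors <- .place_anchors(n_iso + n_cl, config$genome,
                              config$min_event_spacing)
    origin <- ifelse(stats::runif(n_iso + n_cl) < config$paternal_fraction,
                     "paternal", "maternal")
    sid <- meta$sample_id[i]
    iso <- if (n_iso > 0L) {
      data.frame(sample_id = sid, chrom = anchors$chrom[seq_len(n_iso)],
                 pos = anchors$pos[seq_len(n_iso)],
                 origin = origin[seq_len(n_iso)],
                 cluster_id = NA_character_, is_artifact = FALSE,
                 stringsAsFactors = FALSE)
    } else NULL
    cl_rows <- NULL
    cl_members <- NULL
    if (n_cl > 0L) {
      sizes <- 2L + stats::rpois(n_cl, config$cluster_extra_mean)
      is_art <- c(rep(FALSE, n_true_cl), rep(TRUE, n_fp_cl))
      a <- anchors[n_iso + seq_len(n_cl), , drop = FALSE]
      ids <- paste0("t_", sid, "_", a$chrom, "_", a$pos)
      member_pos <- lapply(seq_len(n_cl), function(k) {
        gaps <- sample.int(w - 1L, sizes[k] - 1L, replace = TRUE)
        a$pos[k] + cumsum(c(0L, gaps))
      })
      cl_members <- data.frame(
        sample_id = sid,
        chrom = rep(a$chrom, sizes),
        pos = unlist(member_pos),
        origin = rep(origin[n_iso + seq_len(n_cl)], sizes),
        cluster_id = rep(ids, sizes),
        is_artifact = rep(is_art, sizes),
        stringsAsFactors = FALSE
      )
      cl_rows <- data.frame(
        cluster_id = ids, sample_id = sid, chrom = a$chrom,
        start = vapply(member_pos, min, 0),
        end = vapply(member_pos, max, 0),
        n_members = sizes,
        origin = origin[n_iso + seq_len(n_cl)],
        is_artifact = is_art,
        validation = ifelse(is_art, "false_positive", "true_positive"),
        stringsAsFactors = FALSE
      )
    }
    list(dnms = rbind(iso, cl_members), clusters = cl_rows)
  })
  dnms <- do.call(rbind, lapply(per_sample, `[[`, "dnms"))
  clusters <- do.call(rbind, lapply(per_sample, `[[`, "clusters"))
  if (is.null(dnms)) {
    dnms <- data.frame(sample_id = character(), chrom = character(),
                       pos = integer(), origin = character(),
                       cluster_id = character(), is_artifact = logical(),
                       stringsAsFactors = FALSE)
  }
  if (is.null(clusters)) {
    clusters <- data.frame(cluster_id = character(), sample_id = character(),
                           chrom = character(), start = integer(),
                           end = integer(), n_members = integer(),
                           origin = character(), is_artifact = logical(),
                           validation = character(), stringsAsFactors = FALSE)
  }
  # resolve cross-sample position collisions (same site in two genomes
  # would inflate the joint AC)
  key <- paste(dnms$chrom, dnms$pos)
  tries <- 0L
  while (anyDuplicated(key) && tries < 100L) {
    dup <- duplicated(key) & is.na(dnms$cluster_id)
    if (!any(dup)) break
    shift <- sample(c(-1L, 1L), sum(dup), replace = TRUE) *
      sample(1000:2000, sum(dup), replace = TRUE)
    dnms$pos[dup] <- dnms$pos[dup] + shift
    key <- paste(dnms$chrom, dnms$pos)
    tries <- tries + 1L
  }
  al <- .random_snv(nrow(dnms))
  dnms$ref <- al$ref
  dnms$alt <- al$alt
  dnms$validation <- ifelse(is.na(dnms$cluster_id), "untested",
                            ifelse(dnms$is_artifact, "false_positive",
                                   "true_positive"))
  dnms <- dnms[order(dnms$sample_id, dnms$chrom, dnms$pos),
               c("sample_id", "chrom", "pos", "ref", "alt", "origin",
                 "cluster_id", "is_artifact", "validation")]
  rownames(dnms) <- NULL
  if (nrow(clusters) > 0L) {
    clusters <- clusters[order(clusters$sample_id, clusters$chrom,
                               clusters$start), , drop = FALSE]
    rownames(clusters) <- NULL
  }
  structure(list(dnms = dnms, clusters = clusters, meta = meta,
                 window_bp = w, genome = config$genome),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Truth set:", nrow(x$meta), "offspring,", nrow(x$dnms), "de novo mutations,",
      nrow(x$clusters), "clusters (",
      sum(x$clusters$is_artifact), "artifact )\n")
  invisible(x)
}
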