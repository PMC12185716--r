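tiny_config <- function(seed = 5L, ...) {
  sim_config(cohorts = default_cohorts(n_inova = 8L, n_radar = 6L, n_cru = 6L),
             seed = seed, ...)
}

test_that("metadata simulation is deterministic and matches the config", {
  cfg <- tiny_config()
  m1 <- simulate_metadata(cfg)
  m2 <- simulate_metadata(cfg)
  expect_identical(m1, m2)
  m3 <- simulate_metadata(cfg, seed = 99L)
  expect_false(identical(m1, m3))
  expect_equal(nrow(m1), 20L)
  # all-zero dose when the zero fraction is 1
  expect_true(all(m1$dose[m1$cohort == "inova"] == 0))
  expect_equal(unique(m1$exposure_group[m1$cohort == "inova"]), "Unexposed")
})

test_that("parental age correlation is recovered at n = 1000", {
  cfg <- sim_config(cohorts = list(
    x = cohort_params(n_offspring = 1000L, parent_age_correlation = 0.71)),
    seed = 10L)
  m <- simulate_metadata(cfg)
  expect_lt(abs(cor(m$father_age, m$mother_age) - 0.71), 0.05)
})

test_that("truth sets respect the window rule and label artifacts", {
  cfg <- tiny_config(seed = 17L)
  meta <- simulate_metadata(cfg)
  truth <- simulate_mutations(meta, cfg)
  expect_identical(truth$dnms,
                   simulate_mutations(meta, cfg)$dnms)  # deterministic
  cl <- truth$clusters
  for (i in seq_len(nrow(cl))) {
    p <- sort(truth$dnms$pos[!is.na(truth$dnms$cluster_id) &
                               truth$dnms$cluster_id == cl$cluster_id[i]])
    expect_true(all(diff(p) < cfg$window_bp))
    expect_gte(length(p), 2L)
  }
  expect_true(all(cl$validation[cl$is_artifact] == "false_positive"))
  expect_true(all(cl$validation[!cl$is_artifact] == "true_positive"))
  # events of one offspring never chain across truth clusters at the window
  called <- assemble_clusters(truth$dnms, cfg$window_bp)
  expect_equal(nrow(called$clusters), nrow(cl))
})

test_that("no artifacts means every cluster is a true positive", {
  cohorts <- default_cohorts(4L, 4L, 4L)
  for (nm in names(cohorts)) cohorts[[nm]]$fp_cluster_rate <- 0
  cfg <- sim_config(cohorts = cohorts, seed = 3L)
  truth <- simulate_mutations(simulate_metadata(cfg), cfg)
  expect_true(all(!truth$clusters$is_artifact))
  expect_true(all(truth$clusters$validation == "true_positive"))
})

test_that("fixtures are byte-identical under a fixed seed and conserve records", {
  cfg <- tiny_config(seed = 23L)
  meta <- simulate_metadata(cfg)
  truth <- simulate_mutations(meta, cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- emit_fixtures(truth, cfg, d1)
  fx2 <- emit_fixtures(truth, cfg, d2)
  for (f in c("vcf", "ped", "evidence", "repeat_bed", "mapability_bed")) {
    expect_identical(readLines(fx1[[f]]), readLines(fx2[[f]]))
  }
  # conservation: one clean het VCF record per simulated mutation
  ped <- read_pedigree(fx1$ped)
  rec <- read_joint_vcf(fx1$vcf, ped, carriers_only = TRUE)
  calls <- apply_dnm_filters(rec)$calls
  per_kid_truth <- table(factor(truth$dnms$sample_id, levels = meta$sample_id))
  per_kid_called <- table(factor(calls$sample_id, levels = meta$sample_id))
  expect_equal(as.integer(per_kid_called), as.integer(per_kid_truth))
})

test_that("clean fixtures give 100% recall and no surviving inherited variant", {
  cfg <- tiny_config(seed = 29L)
  meta <- simulate_metadata(cfg)
  truth <- simulate_mutations(meta, cfg)
  fx <- emit_fixtures(truth, cfg, withr::local_tempdir())
  ped <- read_pedigree(fx$ped)
  rec <- read_joint_vcf(fx$vcf, ped, carriers_only = TRUE)
  cs <- apply_dnm_filters(rec)
  truth_key <- paste(truth$dnms$sample_id, truth$dnms$chrom, truth$dnms$pos)
  call_key <- paste(cs$calls$sample_id, cs$calls$chrom, cs$calls$pos)
  expect_setequal(call_key, truth_key)       # perfect recall, no extras
  expect_true(all(cs$calls$ac == 1L))        # nothing inherited survives
  # spiked negatives exercised each filter at least once
  expect_gt(cs$audit[["fail_score"]], 0L)
  expect_gt(cs$audit[["fail_depth"]], 0L)
  expect_gt(cs$audit[["fail_parental_reads"]], 0L)
  expect_gt(cs$audit[["fail_ac"]], 0L)
})

test_that("cluster count means track cohort and dose parameters", {
  cohorts <- list(
    lo = cohort_params(n_offspring = 600L, cdnm_base_mean = 0.5,
                       fp_cluster_rate = 0),
    hi = cohort_params(n_offspring = 600L, cdnm_base_mean = 2.0,
                       fp_cluster_rate = 0)
  )
  cfg <- sim_config(cohorts = cohorts, seed = 31L)
  meta <- simulate_metadata(cfg)
  truth <- simulate_mutations(meta, cfg)
  per_kid <- table(factor(truth$clusters$sample_id, levels = meta$sample_id))
  m_lo <- mean(per_kid[meta$cohort == "lo"])
  m_hi <- mean(per_kid[meta$cohort == "hi"])
  expect_lt(abs(m_lo - 0.5), 0.15)
  expect_lt(abs(m_hi - 2.0), 0.3)
})

test_that("true-cluster fraction converges to the target PPV", {
  cohorts <- list(x = cohort_params(n_offspring = 800L,
                                    cdnm_base_mean = 0.23 * 1.48,
                                    fp_cluster_rate = 0.77 * 1.48))
  cfg <- sim_config(cohorts = cohorts, seed = 37L)
  truth <- simulate_mutations(simulate_metadata(cfg), cfg)
  ppv_hat <- mean(!truth$clusters$is_artifact)
  expect_lt(abs(ppv_hat - 0.23), 0.05)
})

test_that("YAML configs override defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 42",
    "window_bp: 30",
    "cohorts:",
    "  inova:",
    "    n_offspring: 5",
    "  radar:",
    "    n_offspring: 4",
    "    dose_positive_mean: 50"
  ), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$seed, 42)
  expect_equal(cfg$window_bp, 30)
  expect_equal(cfg$cohorts$inova$n_offspring, 5)
  expect_equal(cfg$cohorts$radar$dose_positive_mean, 50)
  expect_equal(cfg$cohorts$cru$n_offspring, default_cohorts()$cru$n_offspring)
})
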