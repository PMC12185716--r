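make_evidence <- function(n_pat = 0L, n_mat = 0L, n_noninf = 0L,
                          sample_id = "s1", pos = 100L) {
  rows <- function(n, f_gt, m_gt) {
    if (n == 0L) return(NULL)
    data.frame(sample_id = sample_id, chrom = "chr1", pos = pos, alt = "T",
               read_id = paste0("r", seq_len(n)), dnm_allele = "alt",
               inf_chrom = "chr1", inf_pos = pos + 50L,
               informative_allele = "alt", father_gt = f_gt, mother_gt = m_gt,
               stringsAsFactors = FALSE)
  }
  rbind(rows(n_pat, "0/1", "0/0"), rows(n_mat, "0/0", "0/1"),
        rows(n_noninf, "0/1", "0/1"))
}

test_that("DNM phasing requires unanimous alt-read votes", {
  p <- phase_dnm(make_evidence(n_pat = 3L))
  expect_equal(p$origin, "paternal")
  expect_equal(p$support, 3L)
  expect_equal(p$conflict, 0L)

  m <- phase_dnm(make_evidence(n_mat = 2L))
  expect_equal(m$origin, "maternal")

  mixed <- phase_dnm(make_evidence(n_pat = 2L, n_mat = 1L))
  expect_equal(mixed$origin, "unknown")
  expect_equal(mixed$support, 2L)
  expect_equal(mixed$conflict, 1L)

  # non-discriminating informative sites are ignored but counted
  ni <- phase_dnm(make_evidence(n_pat = 1L, n_noninf = 2L))
  expect_equal(ni$origin, "paternal")
  expect_equal(ni$non_informative, 2L)
  only_ni <- phase_dnm(make_evidence(n_noninf = 2L))
  expect_equal(only_ni$origin, "unknown")

  # reads carrying the ref allele at the DNM never vote
  ev <- make_evidence(n_pat = 1L)
  ev$dnm_allele <- "ref"
  expect_equal(phase_dnm(ev)$origin, "unknown")

  expect_error(phase_dnm(make_evidence(n_pat = 1L)[, -1]), "missing column")
})

test_that("phasing through a hom-alt parent uses transmissible alleles", {
  # informative allele ref; father 1/1 cannot transmit ref, mother 0/1 can
  ev <- make_evidence(n_pat = 2L)
  ev$informative_allele <- "ref"
  ev$father_gt <- "1/1"
  ev$mother_gt <- "0/1"
  expect_equal(phase_dnm(ev)$origin, "maternal")
})

test_that("cluster origin follows the at-least-one-lesion rule", {
  expect_equal(cluster_origin(c("paternal", "unknown")), "paternal")
  expect_equal(cluster_origin(c("unknown", "maternal")), "maternal")
  expect_equal(cluster_origin(c("paternal", "maternal")), "contradictory")
  expect_equal(cluster_origin(c("unknown", "unknown")), "unknown")
  # symmetric under reordering
  set.seed(3)
  for (i in 1:20) {
    v <- sample(c("paternal", "maternal", "unknown"), 4, replace = TRUE)
    expect_equal(cluster_origin(v), cluster_origin(sample(v)))
  }
})

test_that("cluster phases lift member assignments and flag contradictions", {
  d <- rbind(dnm_table(c(100L, 110L), sample_id = "s1"),
             dnm_table(c(500L, 510L), sample_id = "s1"))
  cl <- assemble_clusters(d, 20L)
  phases <- rbind(
    phase_dnm(make_evidence(n_pat = 2L, pos = 100L)),
    phase_dnm(make_evidence(n_pat = 1L, pos = 500L)),
    phase_dnm(make_evidence(n_mat = 1L, pos = 510L))
  )
  out <- phase_clusters(cl, phases)
  origins <- out$clusters$origin[order(out$clusters$start)]
  # 110 unphased: at-least-one rule gives paternal; 500/510 disagree
  expect_equal(origins, c("paternal", "contradictory"))
  expect_true(!any(out$clusters$origin %in% c("paternal", "maternal") &
                     vapply(out$clusters$cluster_id, function(id) {
                       ph <- out$members$phase[out$members$cluster_id == id]
                       any(ph == "paternal") && any(ph == "maternal")
                     }, logical(1))))
})

test_that("origin ratio homogeneity test reproduces hand-computed values", {
  # identical ratios: no heterogeneity
  r <- origin_ratio_test(rbind(c(10, 5), c(20, 10)))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  expect_equal(r$df, 1)

  # fully separated table: Pearson statistic equals N
  r2 <- origin_ratio_test(rbind(c(10, 0), c(0, 10)))
  expect_equal(r2$statistic, 20, tolerance = 1e-12)
  expect_equal(r2$df, 1)

  r3 <- origin_ratio_test(rbind(c(3, 1), c(1, 3)))
  expect_false(r3$low_expected)
  expect_error(origin_ratio_test(rbind(c(10, 5))), "two groups")
  expect_error(origin_ratio_test(rbind(c(0, 0), c(1, 2))), "at least one")
})

test_that("phaseable fraction grows with read length on synthetic evidence", {
  cfg_short <- sim_config(cohorts = list(
    x = cohort_params(n_offspring = 12L, read_length = 100L)), seed = 21L)
  cfg_long <- sim_config(cohorts = list(
    x = cohort_params(n_offspring = 12L, read_length = 150L)), seed = 21L)
  frac <- function(cfg) {
    meta <- simulate_metadata(cfg)
    truth <- simulate_mutations(meta, cfg)
    fx <- emit_fixtures(truth, cfg, withr::local_tempdir())
    ev <- read_evidence_table(fx$evidence)
    length(unique(paste(ev$sample_id, ev$pos))) / nrow(truth$dnms)
  }
  expect_gt(frac(cfg_long), frac(cfg_short))
})
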