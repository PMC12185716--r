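test_that("window rule worked examples", {
  # gap 15 joins, gap 25 does not
  cl <- assemble_clusters(dnm_table(c(100L, 115L, 140L)), window_bp = 20L)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(sort(cl$members$pos), c(100L, 115L))

  # chains of sub-window gaps may span more than the window
  cl2 <- assemble_clusters(dnm_table(c(100L, 119L, 138L)), window_bp = 20L)
  expect_equal(cl2$clusters$n_members, 3L)
  expect_equal(cl2$clusters$span_bp, 38L)

  # strict inequality at the boundary
  cl3 <- assemble_clusters(dnm_table(c(100L, 120L)), window_bp = 20L)
  expect_equal(nrow(cl3$clusters), 0L)

  # chromosomes never chain
  cl4 <- assemble_clusters(dnm_table(c(100L, 100L + 5L), chrom = c("chr1", "chr2")),
                           window_bp = 20L)
  expect_equal(nrow(cl4$clusters), 0L)

  # samples never chain
  cl5 <- assemble_clusters(dnm_table(c(100L, 105L), sample_id = c("a", "b")),
                           window_bp = 20L)
  expect_equal(nrow(cl5$clusters), 0L)

  expect_error(assemble_clusters(dnm_table(c(100L, 100L))), "duplicate")
})

test_that("clustering agrees with the brute-force oracle on random inputs", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(2:15, 1)
    d <- dnm_table(sample(1:120, n), chrom = sample(c("chr1", "chr2"), n, TRUE),
                   sample_id = sample(c("s1", "s2"), n, TRUE))
    d <- d[!duplicated(paste(d$sample_id, d$chrom, d$pos)), ]
    w <- sample(2:30, 1)
    got <- assemble_clusters(d, window_bp = w)
    expect_equal(cluster_signature(got), oracle_signature(oracle_clusters(d, w)))
    # every consecutive member gap is below the window
    for (cid in unique(got$members$cluster_id)) {
      p <- sort(got$members$pos[got$members$cluster_id == cid])
      expect_true(all(diff(p) < w))
    }
  }
})

test_that("clustering is permutation invariant and idempotent", {
  set.seed(77)
  d <- dnm_table(sample(1:500, 40), chrom = sample(paste0("chr", 1:3), 40, TRUE),
                 sample_id = sample(c("s1", "s2"), 40, TRUE))
  d <- d[!duplicated(paste(d$sample_id, d$chrom, d$pos)), ]
  base <- assemble_clusters(d, 20L)
  for (i in 1:5) {
    shuffled <- d[sample(nrow(d)), ]
    expect_equal(cluster_signature(assemble_clusters(shuffled, 20L)),
                 cluster_signature(base))
  }
  members_only <- base$members[names(d)]
  again <- assemble_clusters(members_only, 20L)
  expect_equal(cluster_signature(again), cluster_signature(base))
})

test_that("clustered-DNM membership grows monotonically with the window", {
  set.seed(13)
  for (i in 1:30) {
    d <- dnm_table(sample(1:400, 25), sample_id = sample(c("a", "b"), 25, TRUE))
    d <- d[!duplicated(paste(d$sample_id, d$pos)), ]
    member_set <- function(w) {
      m <- assemble_clusters(d, w)$members
      paste(m$sample_id, m$pos)
    }
    sets <- lapply(c(5L, 10L, 20L, 50L, 200L), member_set)
    for (k in seq_along(sets)[-1]) {
      expect_true(all(sets[[k - 1]] %in% sets[[k]]))
    }
  }
})

test_that("per-sample counts conserve totals and keep zero-cluster offspring", {
  meta <- small_meta(c(30, 31, 32), c(28, 29, 30))
  d <- rbind(dnm_table(c(100L, 110L, 500L), sample_id = meta$sample_id[1]),
             dnm_table(c(900L), sample_id = meta$sample_id[2]))
  cl <- assemble_clusters(d, 20L)
  counts <- per_sample_counts(d, cl, meta)
  expect_equal(counts$n_cdnm, c(1L, 0L, 0L))
  expect_equal(sum(counts$n_cdnm), nrow(cl$clusters))
  expect_equal(counts$n_dnm, c(1L, 1L, 0L))      # isolated only
  expect_equal(counts$n_dnm_total, c(3L, 1L, 0L))
  expect_equal(sum(counts$n_dnm) + nrow(cl$members), sum(counts$n_dnm_total))

  d_bad <- dnm_table(c(5L, 8L), sample_id = "ghost")
  cl_bad <- assemble_clusters(d_bad, 20L)
  expect_error(per_sample_counts(d_bad, cl_bad, meta), "ghost")
})

test_that("target masks flag clusters by member overlap, half-open", {
  d <- dnm_table(c(100L, 110L, 300L, 308L), sample_id = "s1")
  cl <- assemble_clusters(d, 20L)
  rep_mask <- genome_mask(data.frame(chrom = "chr1", start = 99L, end = 105L))
  map_mask <- genome_mask(data.frame(chrom = "chr1", start = 0L, end = 0L + 1L))
  flagged <- apply_target_mask(cl, rep_mask, map_mask)
  flags <- flagged$clusters$in_target[order(flagged$clusters$start)]
  expect_equal(flags, c(FALSE, TRUE))

  # member at 1-based 21 against [10,20): outside (half-open)
  d2 <- dnm_table(c(21L, 25L), sample_id = "s1")
  cl2 <- assemble_clusters(d2, 20L)
  m2 <- genome_mask(data.frame(chrom = "chr1", start = 10L, end = 20L))
  cl2 <- apply_target_mask(cl2, m2, genome_mask())
  expect_true(cl2$clusters$in_target)
  # member at 20 (1-based) is the last covered base
  d3 <- dnm_table(c(20L, 24L), sample_id = "s1")
  cl3 <- apply_target_mask(assemble_clusters(d3, 20L), m2, genome_mask())
  expect_false(cl3$clusters$in_target)
})

test_that("sensitivity scan recomputes per window with monotone totals", {
  meta <- small_meta(30, 28)
  d <- dnm_table(c(100L, 115L, 400L, 5000L), sample_id = meta$sample_id)
  sc <- sensitivity_scan(d, meta, windows = c(10L, 20L, 10000L))
  expect_equal(sc$w10, 0L)
  expect_equal(sc$w20, 1L)
  expect_equal(sc$w10000, 1L)          # all four chain into one run
  expect_equal(sc$w10000_dnms, 4L)
  # clustered-DNM totals are non-decreasing in the window
  expect_true(all(diff(c(sc$w10_dnms, sc$w20_dnms, sc$w10000_dnms)) >= 0))
})

test_that("cluster size distribution sums to the cluster count", {
  d <- rbind(dnm_table(c(10L, 15L), sample_id = "a"),
             dnm_table(c(100L, 105L, 110L), sample_id = "b"),
             dnm_table(c(300L, 310L), sample_id = "c"))
  cl <- assemble_clusters(d, 20L)
  dist <- cluster_size_distribution(cl)
  expect_equal(dist$histogram, c("2" = 2L, "3" = 1L))
  expect_equal(dist$max_size, 3L)
  expect_equal(sum(dist$histogram), nrow(cl$clusters))
  empty <- assemble_clusters(dnm_table(100L), 20L)
  expect_equal(cluster_size_distribution(empty)$max_size, 0L)
})
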