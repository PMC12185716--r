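# Independent oracles and tiny fixture builders shared across tests.

# Exhaustive 9-configuration enumeration of the trio de novo posterior,
# written directly from the model definition (independent of the package's
# vectorized implementation).
oracle_denovo <- function(cpl, fpl, mpl, prior) {
  lk <- function(pl) {
    l <- 10^(-pl / 10)
    l / sum(l)
  }
  lc <- lk(cpl)
  lf <- lk(fpl)
  lm <- lk(mpl)
  num <- lc[2] * lf[1] * lm[1] * prior
  comp <- 0
  for (gf in 1:3) {
    for (gm in 1:3) {
      if (!(gf == 1 && gm == 1)) comp <- comp + lf[gf] * lm[gm]
    }
  }
  num / (num + lc[2] * comp * (1 - prior) / 8)
}

# one-row trio record data frame with configurable PLs/depths
trio_record <- function(sample_id = "s1", chrom = "chr1", pos = 100L,
                        ref = "A", alt = "T", ac = 1L,
                        child_nalt = 1L, child_ad = c(15L, 15L), child_dp = 30L,
                        child_pl = c(60, 0, 60),
                        father_nalt = 0L, father_ad = c(30L, 0L), father_dp = 30L,
                        father_pl = c(0, 60, 120),
                        mother_nalt = 0L, mother_ad = c(30L, 0L), mother_dp = 30L,
                        mother_pl = c(0, 60, 120)) {
  data.frame(
    sample_id = sample_id, father_id = paste0(sample_id, "_fa"),
    mother_id = paste0(sample_id, "_mo"),
    chrom = chrom, pos = pos, ref = ref, alt = alt, ac = ac,
    child_nalt = child_nalt, child_ad_ref = child_ad[1], child_ad_alt = child_ad[2],
    child_dp = child_dp, child_pl_rr = child_pl[1], child_pl_het = child_pl[2],
    child_pl_aa = child_pl[3],
    father_nalt = father_nalt, father_ad_ref = father_ad[1],
    father_ad_alt = father_ad[2], father_dp = father_dp,
    father_pl_rr = father_pl[1], father_pl_het = father_pl[2],
    father_pl_aa = father_pl[3],
    mother_nalt = mother_nalt, mother_ad_ref = mother_ad[1],
    mother_ad_alt = mother_ad[2], mother_dp = mother_dp,
    mother_pl_rr = mother_pl[1], mother_pl_het = mother_pl[2],
    mother_pl_aa = mother_pl[3],
    stringsAsFactors = FALSE
  )
}

# minimal DNM call table
dnm_table <- function(pos, chrom = "chr1", sample_id = "s1", alt = "T") {
  n <- max(length(pos), length(chrom), length(sample_id))
  data.frame(sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
             pos = pos, ref = "A", alt = rep_len(alt, n),
             stringsAsFactors = FALSE)
}

# brute-force clustering oracle: maximal runs under the strict
# predecessor-distance predicate, found by direct scanning per
# (sample, chrom) group of the sorted positions
oracle_clusters <- function(dnms, window_bp) {
  out <- list()
  for (g in split(dnms, paste(dnms$sample_id, dnms$chrom))) {
    p <- sort(g$pos)
    if (length(p) < 2) next
    run <- c(1)
    for (i in seq_along(p)[-1]) {
      if (p[i] - p[i - 1] < window_bp) {
        run <- c(run, i)
      } else {
        if (length(run) >= 2) out[[length(out) + 1]] <-
            list(sample_id = g$sample_id[1], chrom = g$chrom[1], pos = p[run])
        run <- c(i)
      }
    }
    if (length(run) >= 2) out[[length(out) + 1]] <-
        list(sample_id = g$sample_id[1], chrom = g$chrom[1], pos = p[run])
  }
  out
}

# canonical signature of a cluster set for comparisons
cluster_signature <- function(clusters) {
  m <- clusters$members
  sig <- vapply(split(m$pos, m$cluster_id), function(p) {
    paste(sort(p), collapse = ",")
  }, "")
  sort(unname(paste(
    clusters$clusters$sample_id[match(names(sig), clusters$clusters$cluster_id)],
    clusters$clusters$chrom[match(names(sig), clusters$clusters$cluster_id)],
    sig)))
}

oracle_signature <- function(oc) {
  sort(vapply(oc, function(x) paste(x$sample_id, x$chrom,
                                    paste(sort(x$pos), collapse = ",")), ""))
}

# exhaustive minimum-cost assignment over all injective maps of the
# (replicated) reference slots into the candidate set
oracle_min_cost <- function(cost) {
  n_left <- nrow(cost)
  n_right <- ncol(cost)
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i], k - 1)) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n_right), n_left)) {
    tc <- sum(cost[cbind(seq_len(n_left), p)])
    if (tc < best) best <- tc
  }
  best
}

small_meta <- function(father_age, mother_age, ids = NULL, cohort = "x") {
  n <- length(father_age)
  data.frame(sample_id = if (is.null(ids)) sprintf("%s_%03d", cohort, seq_len(n)) else ids,
             cohort = cohort, father_age = father_age, mother_age = mother_age,
             dose = 0, stringsAsFactors = FALSE)
}
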