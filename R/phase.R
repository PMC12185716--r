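#' Phase DNMs to a parental haplotype from read evidence
#'
#' Evidence rows link reads that carry a DNM to a nearby informative
#' inherited variant. A read that carries the DNM alt allele votes for the
#' parent that is uniquely able to transmit the informative allele seen on
#' that read (the allele occurs in exactly one parent's genotype). Rows
#' whose informative site does not discriminate — both parents or neither
#' parent could transmit the observed allele — are ignored and counted.
#' A DNM is assigned an origin only when all votes agree and there is at
#' least one vote; any conflict yields `unknown` with the vote counts
#' retained.
#'
#' @param evidence Data frame with columns `sample_id`, `chrom`, `pos`,
#'   `alt` (the DNM key), `read_id`, `dnm_allele` (`"ref"`/`"alt"`),
#'   `inf_chrom`, `inf_pos`, `informative_allele` (`"ref"`/`"alt"` at the
#'   informative site), `father_gt`, `mother_gt` (genotype strings such as
#'   `"0/1"` at the informative site). Positions are 1-based.
#' @return Data frame with one row per distinct DNM key present in
#'   `evidence`: `sample_id`, `chrom`, `pos`, `alt`, `origin`
#'   (`paternal`/`maternal`/`unknown`), `support`, `conflict`,
#'   `non_informative`.
#' @export
phase_dnm <- function(evidence) {
  need <- c("sample_id", "chrom", "pos", "alt", "read_id", "dnm_allele",
            "informative_allele", "father_gt", "mother_gt")
  missing_cols <- setdiff(need, names(evidence))
  if (length(missing_cols) > 0L) {
    stop("evidence table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- paste(evidence$sample_id, evidence$chrom, evidence$pos, evidence$alt,
               sep = "\r")
  carries <- function(gt, allele) {
    a <- strsplit(gt, "[/|]")
    code <- ifelse(allele == "alt", "1", "0")
    mapply(function(al, cd) cd %in% al, a, code)
  }
  alt_read <- evidence$dnm_allele == "alt"
  f_can <- carries(evidence$father_gt, evidence$informative_allele)
  m_can <- carries(evidence$mother_gt, evidence$informative_allele)
  vote <- ifelse(!alt_read, "none",
          ifelse(f_can & !m_can, "paternal",
          ifelse(m_can & !f_can, "maternal", "non_informative")))
  res <- lapply(split(seq_along(key), key), function(idx) {
    v <- vote[idx]
    np <- sum(v == "paternal")
    nm <- sum(v == "maternal")
    ni <- sum(v == "non_informative")
    if (np > 0L && nm == 0L) {
      origin <- "paternal"; support <- np; conflict <- 0L
    } else if (nm > 0L && np == 0L) {
      origin <- "maternal"; support <- nm; conflict <- 0L
    } else if (np > 0L && nm > 0L) {
      origin <- "unknown"; support <- max(np, nm); conflict <- min(np, nm)
    } else {
      origin <- "unknown"; support <- 0L; conflict <- 0L
    }
    i <- idx[1L]
    data.frame(sample_id = evidence$sample_id[i], chrom = evidence$chrom[i],
               pos = evidence$pos[i], alt = evidence$alt[i],
               origin = origin, support = support, conflict = conflict,
               non_informative = ni, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lift DNM-level origins to clusters
#'
#' A cluster inherits the origin suggested by at least one phased member;
#' members with both paternal and maternal assignments make the cluster
#' `contradictory`; clusters with no phased member stay `unknown`.
#'
#' @param clusters A `cdnm_clusters` object.
#' @param phases DNM-level phase table from [phase_dnm()].
#' @return The `cdnm_clusters` object with the `origin` column filled in,
#'   and member phases merged into `members$phase`.
#' @export
phase_clusters <- function(clusters, phases) {
  stopifnot(inherits(clusters, "cdnm_clusters"))
  m <- clusters$members
  if (nrow(m) == 0L) return(clusters)
  mk <- paste(m$sample_id, m$chrom, m$pos, m$alt, sep = "\r")
  pk <- paste(phases$sample_id, phases$chrom, phases$pos, phases$alt, sep = "\r")
  m$phase <- phases$origin[match(mk, pk)]
  m$phase[is.na(m$phase)] <- "unknown"
  origin_of <- vapply(split(m$phase, m$cluster_id), cluster_origin,
                      character(1L))
  clusters$members <- m
  clusters$clusters$origin <- unname(origin_of[clusters$clusters$cluster_id])
  clusters
}

#' Combine member origins into a cluster origin
#'
#' At-least-one-lesion rule: any phased member determines the cluster
#' origin; disagreeing members make it contradictory; none phased leaves
#' it unknown. Symmetric under member reordering.
#'
#' @param member_origins Character vector of member-level origins
#'   (`paternal`/`maternal`/`unknown`).
#' @return One of `"paternal"`, `"maternal"`, `"contradictory"`,
#'   `"unknown"`.
#' @export
cluster_origin <- function(member_origins) {
  has_p <- any(member_origins == "paternal")
  has_m <- any(member_origins == "maternal")
  if (has_p && has_m) "contradictory"
  else if (has_p) "paternal"
  else if (has_m) "maternal"
  else "unknown"
}

#' Chi-squared homogeneity test of parental-origin ratios across groups
#'
#' Pearson chi-squared test (no continuity correction) on the k x 2 table
#' of paternal/maternal counts per group; unknown origins must be
#' excluded by the caller.
#'
#' @param counts Matrix or data frame with k rows (groups) and two columns
#'   (paternal, maternal counts).
#' @return List with `statistic`, `df`, `p_value`, `expected`, and
#'   `low_expected` flag (any expected cell below 1).
#' @export
origin_ratio_test <- function(counts) {
  tab <- as.matrix(counts)
  if (nrow(tab) < 2L) stop("need at least two groups for a homogeneity test")
  if (ncol(tab) != 2L) stop("counts must have two columns (paternal, maternal)")
  if (any(rowSums(tab) < 1)) stop("every group needs at least one phased DNM")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected,
       low_expected = any(ct$expected < 1))
}
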