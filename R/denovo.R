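#' Posterior probability that a child heterozygote is de novo
#'
#' Trio genotype-likelihood model for a candidate site: the de novo
#' hypothesis is (child het, father hom-ref, mother hom-ref) with prior
#' `prior`; the competing hypothesis is that at least one parent carries
#' the alternate allele, with the remaining prior mass spread uniformly
#' over the 8 parental genotype configurations other than
#' (hom-ref, hom-ref). Per-member likelihoods are `10^(-PL/10)`,
#' normalized within member.
#'
#' \deqn{score = \frac{L_c(het) L_f(RR) L_m(RR) \pi}
#'   {L_c(het) L_f(RR) L_m(RR) \pi + \frac{1-\pi}{8} L_c(het)
#'    \sum_{(g_f,g_m) \ne (RR,RR)} L_f(g_f) L_m(g_m)}}
#'
#' Children whose genotype call is not heterozygous for the focal alt get
#' score 0 (they are not candidates).
#'
#' @param records A `trio_records` data frame (see [read_joint_vcf()]) or
#'   any data frame with the `*_nalt` and `*_pl_*` columns.
#' @param prior Per-site prior probability of a true de novo mutation.
#' @return Numeric vector of scores in `[0, 1]`, one per record row.
#' @export
denovo_posterior <- function(records, prior = 1e-5) {
  stopifnot(prior > 0, prior < 1)
  pls <- c("pl_rr", "pl_het", "pl_aa")
  for (m in c("child", "father", "mother")) {
    if (any(is.na(records[paste0(m, "_", pls)]))) {
      stop("missing PL values; records with absent likelihoods cannot be scored")
    }
  }
  lik <- function(member) {
    l <- 10^(-as.matrix(records[paste0(member, "_", pls)]) / 10)
    l / rowSums(l)
  }
  lc <- lik("child")
  lf <- lik("father")
  lm <- lik("mother")
  # sum over all 9 parental configurations minus (hom-ref, hom-ref)
  competing <- rowSums(lf) * rowSums(lm) - lf[, 1L] * lm[, 1L]
  num <- lc[, 2L] * lf[, 1L] * lm[, 1L] * prior
  den <- num + lc[, 2L] * competing * (1 - prior) / 8
  score <- ifelse(den > 0, num / den, 0)
  score[records$child_nalt != 1L] <- 0
  as.numeric(score)
}

#' Filter configuration for de novo calling
#'
#' Thresholds follow the inequality conventions of the published heuristic
#' stack: de novo score strictly greater than `score_min`, child depth
#' strictly greater than `depth_min`, each parent's alt-supporting reads
#' strictly fewer than `parental_alt_reads_max`, and joint allele count at
#' most `ac_max` (the AC = 1 filter that removes inherited variants).
#'
#' @param score_min Minimum de novo posterior (exclusive). Default 0.85.
#' @param depth_min Minimum child sequencing depth (exclusive). Default 10.
#' @param parental_alt_reads_max Upper bound (exclusive) on alt reads per
#'   parent. Default 2, i.e. fewer than 2 alt reads in each parent.
#' @param ac_max Maximum joint allele count (inclusive). Default 1.
#' @param de_novo_prior Prior for [denovo_posterior()].
#' @param gq_min Optional genotype-quality floor for the child (difference
#'   between second-smallest and smallest PL); `NULL` disables.
#' @param allele_balance Optional length-2 numeric window for the child alt
#'   allele fraction; `NULL` disables.
#' @param autosomes_only Drop records on non-autosomal chromosomes.
#' @return A `filter_config` list.
#' @export
filter_config <- function(score_min = 0.85, depth_min = 10,
                          parental_alt_reads_max = 2, ac_max = 1,
                          de_novo_prior = 1e-5, gq_min = NULL,
                          allele_balance = NULL, autosomes_only = TRUE) {
  stopifnot(is.finite(score_min), is.finite(depth_min),
            is.finite(parental_alt_reads_max), is.finite(ac_max),
            de_novo_prior > 0, de_novo_prior < 1)
  structure(list(score_min = score_min, depth_min = depth_min,
                 parental_alt_reads_max = parental_alt_reads_max,
                 ac_max = ac_max, de_novo_prior = de_novo_prior,
                 gq_min = gq_min, allele_balance = allele_balance,
                 autosomes_only = autosomes_only),
            class = "filter_config")
}

.autosome <- function(chrom) {
  grepl("^(chr)?([0-9]+)$", chrom)
}

#' Apply the de novo filter stack to trio records
#'
#' Scores every candidate (child het) record and applies the filters in a
#' fixed order — score, depth, parental alt reads, allele count, then any
#' extra predicates — producing mutually exclusive per-filter rejection
#' counts: a record is charged to the first filter it fails.
#'
#' @param records A `trio_records` data frame.
#' @param cfg A [filter_config()].
#' @return A list of class `dnm_callset` with elements `calls` (data frame
#'   of surviving calls: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `score`, `child_dp`, `father_alt_reads`, `mother_alt_reads`, `ac`,
#'   `phase`, `validation`) and `audit` (named integer vector of counts:
#'   candidates, retained, and per-filter rejections).
#' @export
apply_dnm_filters <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (cfg$autosomes_only) records <- records[.autosome(records$chrom), , drop = FALSE]
  cand <- records[!is.na(records$child_nalt) & records$child_nalt == 1L, , drop = FALSE]
  n_cand <- nrow(cand)
  if (n_cand == 0L) {
    calls <- data.frame(sample_id = character(), chrom = character(),
                        pos = integer(), ref = character(), alt = character(),
                        score = numeric(), child_dp = integer(),
                        father_alt_reads = integer(), mother_alt_reads = integer(),
                        ac = integer(), phase = character(), validation = character(),
                        stringsAsFactors = FALSE)
    audit <- c(candidates = 0L, retained = 0L, fail_score = 0L, fail_depth = 0L,
               fail_parental_reads = 0L, fail_ac = 0L, fail_extra = 0L)
    return(structure(list(calls = calls, audit = audit), class = "dnm_callset"))
  }
  score <- denovo_posterior(cand, prior = cfg$de_novo_prior)
  pass_score <- score > cfg$score_min
  pass_depth <- cand$child_dp > cfg$depth_min
  pass_par <- cand$father_ad_alt < cfg$parental_alt_reads_max &
    cand$mother_ad_alt < cfg$parental_alt_reads_max
  pass_ac <- cand$ac <= cfg$ac_max
  pass_extra <- rep(TRUE, n_cand)
  if (!is.null(cfg$gq_min)) {
    pl <- as.matrix(cand[c("child_pl_rr", "child_pl_het", "child_pl_aa")])
    gq <- apply(pl, 1L, function(x) sort(x)[2L] - min(x))
    pass_extra <- pass_extra & gq >= cfg$gq_min
  }
  if (!is.null(cfg$allele_balance)) {
    ab <- cand$child_ad_alt / pmax(cand$child_ad_ref + cand$child_ad_alt, 1L)
    pass_extra <- pass_extra & ab >= cfg$allele_balance[1L] & ab <= cfg$allele_balance[2L]
  }
  keep <- pass_score & pass_depth & pass_par & pass_ac & pass_extra
  first_fail <- ifelse(!pass_score, "fail_score",
                ifelse(!pass_depth, "fail_depth",
                ifelse(!pass_par, "fail_parental_reads",
                ifelse(!pass_ac, "fail_ac",
                ifelse(!pass_extra, "fail_extra", "retained")))))
  audit <- c(candidates = n_cand,
             retained = sum(keep),
             fail_score = sum(first_fail == "fail_score"),
             fail_depth = sum(first_fail == "fail_depth"),
             fail_parental_reads = sum(first_fail == "fail_parental_reads"),
             fail_ac = sum(first_fail == "fail_ac"),
             fail_extra = sum(first_fail == "fail_extra"))
  calls <- data.frame(
    sample_id = cand$sample_id[keep], chrom = cand$chrom[keep],
    pos = cand$pos[keep], ref = cand$ref[keep], alt = cand$alt[keep],
    score = score[keep], child_dp = cand$child_dp[keep],
    father_alt_reads = as.integer(cand$father_ad_alt[keep]),
    mother_alt_reads = as.integer(cand$mother_ad_alt[keep]),
    ac = cand$ac[keep],
    phase = rep("unknown", sum(keep)), validation = rep("untested", sum(keep)),
    stringsAsFactors = FALSE
  )
  calls <- calls[order(calls$sample_id, calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(calls = calls, audit = audit), class = "dnm_callset")
}

#' @export
print.dnm_callset <- function(x, ...) {
  cat("DNM callset:", nrow(x$calls), "calls from", x$audit[["candidates"]],
      "candidates\n")
  print(x$audit)
  invisible(x)
}

#' Concordance between two DNM call sets
#'
#' Fraction of calls in `calls_a` that are also present in `calls_b`,
#' matching on (sample, chrom, pos, alt); the symmetric Jaccard index is
#' reported alongside.
#'
#' @param calls_a,calls_b DNM call data frames (as in `dnm_callset$calls`).
#' @return List with `concordance` (|a ∩ b| / |a|), `jaccard`, `n_a`,
#'   `n_b`, `n_shared`.
#' @export
callset_concordance <- function(calls_a, calls_b) {
  if (length(intersect(unique(calls_a$sample_id), unique(calls_b$sample_id))) == 0L &&
      (nrow(calls_a) > 0L && nrow(calls_b) > 0L)) {
    stop("call sets share no samples; concordance is undefined")
  }
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$alt, sep = "\r")
  ka <- key(calls_a)
  kb <- key(calls_b)
  shared <- sum(ka %in% kb)
  list(concordance = if (length(ka) > 0L) shared / length(ka) else NA_real_,
       jaccard = if (length(union(ka, kb)) > 0L) {
         length(intersect(ka, kb)) / length(union(ka, kb))
       } else NA_real_,
       n_a = length(ka), n_b = length(kb), n_shared = shared)
}
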