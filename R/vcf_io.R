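#' Read a joint multi-sample VCF into per-trio variant records
#'
#' Produces one row per (trio, biallelic alternate allele). Multiallelic
#' sites are decomposed into per-alt records: allele depths, the relevant
#' phred-scaled genotype likelihood triple (hom-ref, het, hom-alt) and the
#' per-alt joint allele count `AC` are extracted for each alternate allele
#' separately. Positions are 1-based VCF `POS`.
#'
#' Sites where a trio member is missing a required FORMAT field (GT, AD,
#' DP or PL) are skipped for that trio and counted; the per-field skip
#' counts are attached as the `skipped` attribute. Samples named in the
#' pedigree but absent from the VCF are a hard error.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param pedigree A `cdnm_pedigree`; all complete trios are extracted.
#' @param carriers_only If `TRUE`, keep only records where the child
#'   genotype carries the alternate allele (de novo candidates and
#'   inherited carriers); the default `FALSE` returns every (trio, alt)
#'   pair.
#' @return A data frame of class `trio_records` with columns `sample_id`,
#'   `father_id`, `mother_id`, `chrom`, `pos`, `ref`, `alt`, `ac` and, for
#'   each of `child`/`father`/`mother`, `*_nalt` (alt alleles in the
#'   genotype call), `*_ad_ref`, `*_ad_alt`, `*_dp`, `*_pl_rr`, `*_pl_het`,
#'   `*_pl_aa`.
#' @export
read_joint_vcf <- function(path, pedigree, carriers_only = FALSE) {
  stopifnot(inherits(pedigree, "cdnm_pedigree"))
  tr <- trios(pedigree)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1L]
  need <- unique(c(tr$child, tr$father, tr$mother))
  absent <- setdiff(need, samples)
  if (length(absent) > 0L) {
    stop("pedigree sample(s) absent from VCF: ", paste(absent, collapse = ", "))
  }

  fix <- v@fix
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_field <- fix[, "ALT"]
  info <- fix[, "INFO"]
  ac_str <- sub(".*(^|;)AC=([^;]*).*", "\\2", paste0(";", info))
  alt_list <- strsplit(alt_field, ",", fixed = TRUE)
  ac_list <- strsplit(ac_str, ",", fixed = TRUE)

  n_alt_per_site <- lengths(alt_list)
  site_idx <- rep(seq_along(pos), n_alt_per_site)
  a_idx <- unlist(lapply(n_alt_per_site, seq_len))
  alt_vec <- unlist(alt_list)
  ac_vec <- suppressWarnings(as.integer(unlist(lapply(seq_along(ac_list), function(i) {
    a <- ac_list[[i]]
    if (length(a) < n_alt_per_site[i]) rep(NA_character_, n_alt_per_site[i]) else a
  }))))

  gt_m <- vcfR::extract.gt(v, "GT")
  ad_m <- vcfR::extract.gt(v, "AD")
  dp_m <- vcfR::extract.gt(v, "DP")
  pl_m <- vcfR::extract.gt(v, "PL")

  # per-alt PL indices within the diploid ordering: genotype (j,k) sits at
  # k(k+1)/2 + j (0-based)
  pl_idx_het <- (a_idx * (a_idx + 1L)) %/% 2L + 1L   # (0,a), 1-based index
  pl_idx_aa <- (a_idx * (a_idx + 1L)) %/% 2L + a_idx + 1L

  member_block <- function(sample, prefix) {
    gt <- gt_m[site_idx, sample]
    ad <- strsplit(ad_m[site_idx, sample], ",", fixed = TRUE)
    dp <- suppressWarnings(as.integer(dp_m[site_idx, sample]))
    pl <- strsplit(pl_m[site_idx, sample], ",", fixed = TRUE)
    alleles <- strsplit(gt, "[/|]")
    nalt <- mapply(function(al, a) sum(al == as.character(a)), alleles, a_idx)
    nalt[gt %in% c(".", "./.", ".|.") | is.na(gt)] <- NA_integer_
    pick <- function(lst, idx) {
      suppressWarnings(as.numeric(mapply(function(x, i) {
        if (length(x) >= i) x[i] else NA_character_
      }, lst, idx)))
    }
    out <- data.frame(
      nalt = as.integer(nalt),
      ad_ref = pick(ad, rep(1L, length(site_idx))),
      ad_alt = pick(ad, a_idx + 1L),
      dp = dp,
      pl_rr = pick(pl, rep(1L, length(site_idx))),
      pl_het = pick(pl, pl_idx_het),
      pl_aa = pick(pl, pl_idx_aa)
    )
    names(out) <- paste0(prefix, "_", names(out))
    out
  }

  skipped <- c(missing_gt = 0L, missing_ad = 0L, missing_dp = 0L, missing_pl = 0L)
  per_trio <- vector("list", nrow(tr))
  for (k in seq_len(nrow(tr))) {
    base <- data.frame(
      sample_id = tr$child[k], father_id = tr$father[k], mother_id = tr$mother[k],
      chrom = chrom[site_idx], pos = pos[site_idx], ref = ref[site_idx],
      alt = alt_vec, ac = ac_vec, stringsAsFactors = FALSE
    )
    rec <- cbind(base,
                 member_block(tr$child[k], "child"),
                 member_block(tr$father[k], "father"),
                 member_block(tr$mother[k], "mother"))
    miss_gt <- is.na(rec$child_nalt) | is.na(rec$father_nalt) | is.na(rec$mother_nalt)
    miss_ad <- is.na(rec$child_ad_alt) | is.na(rec$father_ad_alt) | is.na(rec$mother_ad_alt)
    miss_dp <- is.na(rec$child_dp) | is.na(rec$father_dp) | is.na(rec$mother_dp)
    miss_pl <- is.na(rec$child_pl_het) | is.na(rec$father_pl_het) | is.na(rec$mother_pl_het)
    drop <- miss_gt | miss_ad | miss_dp | miss_pl
    skipped <- skipped + c(sum(miss_gt), sum(miss_ad & !miss_gt),
                           sum(miss_dp & !miss_gt & !miss_ad),
                           sum(miss_pl & !miss_gt & !miss_ad & !miss_dp))
    rec <- rec[!drop, , drop = FALSE]
    if (carriers_only) rec <- rec[rec$child_nalt >= 1L, , drop = FALSE]
    per_trio[[k]] <- rec
  }
  out <- do.call(rbind, per_trio)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("trio_records", "data.frame")
  out
}
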