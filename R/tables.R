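#' Write DNM, cluster and fit artifacts to disk
#'
#' Emits deterministic, documented TSVs: `<prefix>.dnm.tsv`,
#' `<prefix>.clusters.tsv`, `<prefix>.cluster_members.tsv`, a BED version
#' of the clusters (`<prefix>.clusters.bed`; 0-based half-open, span from
#' first to last member) and, when fits are supplied, `<prefix>.fits.json`.
#'
#' @param dnms DNM call data frame (may be empty).
#' @param clusters A `cdnm_clusters` object, or `NULL`.
#' @param fits Named list of `cdnm_fit` / contrast objects, or `NULL`.
#' @param prefix Output path prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_tables <- function(dnms, clusters = NULL, fits = NULL, prefix) {
  out <- c()
  dnm_path <- paste0(prefix, ".dnm.tsv")
  utils::write.table(dnms, dnm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- c(dnms = dnm_path)
  if (!is.null(clusters)) {
    stopifnot(inherits(clusters, "cdnm_clusters"))
    cl_path <- paste0(prefix, ".clusters.tsv")
    mem_path <- paste0(prefix, ".cluster_members.tsv")
    bed_path <- paste0(prefix, ".clusters.bed")
    utils::write.table(clusters$clusters, cl_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(clusters$members, mem_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cl <- clusters$clusters
    bed <- data.frame(chrom = cl$chrom, start = cl$start - 1L, end = cl$end,
                      name = cl$cluster_id)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    out <- c(out, clusters = cl_path, members = mem_path, bed = bed_path)
  }
  if (!is.null(fits)) {
    fit_path <- paste0(prefix, ".fits.json")
    serializable <- lapply(fits, function(f) {
      if (inherits(f, "cdnm_fit")) {
        f[c("coefficients", "theta", "loglik", "converged", "n", "family")]
      } else if (inherits(f, "cohort_contrast")) {
        list(contrasts = f$contrasts, reference = f$reference,
             alpha_adjusted = f$alpha_adjusted)
      } else if (inherits(f, "dose_response")) {
        f[c("beta", "baseline", "n")]
      } else f
    })
    jsonlite::write_json(serializable, fit_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out <- c(out, fits = fit_path)
  }
  invisible(out)
}

# TSVs may hold allele columns ("T") or ids that read.table would guess as
# logical/numeric; force the known identifier columns back to character
.read_tsv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  chr_cols <- c("sample_id", "family_id", "chrom", "ref", "alt", "cluster_id",
                "phase", "validation", "origin", "cohort", "exposure_group",
                "inf_chrom", "read_id", "dnm_allele", "informative_allele",
                "father_gt", "mother_gt")
  cc <- ifelse(hdr %in% chr_cols, "character", NA)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = cc)
}

#' Read back a DNM table written by [write_tables()]
#'
#' @param path TSV path.
#' @return DNM call data frame.
#' @export
read_dnm_table <- function(path) {
  .read_tsv(path)
}

#' Read back cluster tables written by [write_tables()]
#'
#' @param prefix The path prefix used when writing.
#' @return A `cdnm_clusters` object.
#' @export
read_cluster_tables <- function(prefix) {
  structure(list(clusters = .read_tsv(paste0(prefix, ".clusters.tsv")),
                 members = .read_tsv(paste0(prefix, ".cluster_members.tsv"))),
            class = "cdnm_clusters")
}

#' Read a sample metadata table
#'
#' @param path TSV with at least `sample_id`; typically also `cohort`,
#'   `father_age`, `mother_age`, `dose`.
#' @return Data frame.
#' @export
read_meta_table <- function(path) {
  .read_tsv(path)
}

#' Read a read-evidence table for phasing
#'
#' @param path TSV with the [phase_dnm()] schema (1-based positions).
#' @return Data frame.
#' @export
read_evidence_table <- function(path) {
  .read_tsv(path)
}
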