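#' Read a 6-column PED pedigree file
#'
#' Parses a whitespace-delimited pedigree file with the classic columns
#' family id, sample id, father id, mother id, sex, phenotype. Missing
#' parents are encoded as `"0"` (or `"."`). Sex codes 1/2 map to
#' male/female; anything else is `unknown`.
#'
#' @param path Path to a PED file.
#' @return A data frame of class `cdnm_pedigree` with columns `family_id`,
#'   `sample_id`, `father_id`, `mother_id` (`NA` when missing) and `sex`.
#' @examples
#' ped <- tempfile(fileext = ".ped")
#' writeLines(c("F1 FA 0 0 1 0", "F1 MO 0 0 2 0", "F1 CH FA MO 1 0"), ped)
#' trios(read_pedigree(ped))
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    ped <- data.frame(family_id = character(), sample_id = character(),
                      father_id = character(), mother_id = character(),
                      sex = character(), stringsAsFactors = FALSE)
    class(ped) <- c("cdnm_pedigree", "data.frame")
    return(ped)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- which(nf < 6L)[1L]
    stop("malformed PED line ", bad, ": expected 6 whitespace-delimited columns, got ",
         nf[bad])
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  miss <- function(x) ifelse(x %in% c("0", ".", ""), NA_character_, x)
  ped <- data.frame(
    family_id = m[, 1L],
    sample_id = m[, 2L],
    father_id = miss(m[, 3L]),
    mother_id = miss(m[, 4L]),
    sex = c("1" = "male", "2" = "female")[m[, 5L]],
    stringsAsFactors = FALSE
  )
  ped$sex[is.na(ped$sex)] <- "unknown"
  dup <- ped$sample_id[duplicated(ped$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample id(s) in pedigree: ", paste(unique(dup), collapse = ", "))
  }
  parents <- c(ped$father_id, ped$mother_id)
  dangling <- setdiff(parents[!is.na(parents)], ped$sample_id)
  if (length(dangling) > 0L) {
    stop("parent id(s) not present in pedigree: ", paste(dangling, collapse = ", "))
  }
  rownames(ped) <- NULL
  class(ped) <- c("cdnm_pedigree", "data.frame")
  ped
}

#' Enumerate complete trios in a pedigree
#'
#' @param ped A `cdnm_pedigree`.
#' @return Data frame with one row per child whose father and mother both
#'   resolve, columns `family_id`, `child`, `father`, `mother`, ordered by
#'   child sample id.
#' @export
trios <- function(ped) {
  stopifnot(inherits(ped, "cdnm_pedigree"))
  ok <- !is.na(ped$father_id) & !is.na(ped$mother_id)
  out <- data.frame(
    family_id = ped$family_id[ok],
    child = ped$sample_id[ok],
    father = ped$father_id[ok],
    mother = ped$mother_id[ok],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$child), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.cdnm_pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "samples,", nrow(trios(x)), "complete trios\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
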