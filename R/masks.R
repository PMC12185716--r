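#' Read a BED interval mask
#'
#' Loads a 3+ column BED file (0-based, half-open) into a genome mask.
#' Overlapping or book-ended intervals on the same chromosome are merged,
#' and intervals are sorted, so membership queries are unambiguous.
#'
#' @param path Path to a BED file (at least chrom, start, end).
#' @param label Mask label, e.g. `"repeat"` or `"low_mapability"`.
#' @return A `genome_mask`: data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and attribute `label`.
#' @export
read_mask <- function(path, label = "repeat") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)|^\\s*$", lines)]
  if (length(lines) == 0L) {
    bed <- data.frame(chrom = character(), start = integer(), end = integer())
  } else {
    fields <- strsplit(trimws(lines), "\\s+")
    bed <- data.frame(
      chrom = vapply(fields, `[`, "", 1L),
      start = as.integer(vapply(fields, `[`, "", 2L)),
      end = as.integer(vapply(fields, `[`, "", 3L)),
      stringsAsFactors = FALSE
    )
  }
  genome_mask(bed, label = label)
}

#' Construct a genome mask from intervals
#'
#' @param bed Data frame with `chrom`, `start`, `end` in 0-based half-open
#'   coordinates.
#' @param label Mask label.
#' @return A merged, sorted `genome_mask`.
#' @export
genome_mask <- function(bed = NULL, label = "repeat") {
  if (is.null(bed) || nrow(bed) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "label") <- label
    class(out) <- c("genome_mask", "data.frame")
    return(out)
  }
  if (any(is.na(bed$start)) || any(is.na(bed$end))) {
    stop("mask intervals contain non-numeric start/end")
  }
  if (any(bed$start < 0L)) stop("mask intervals must have start >= 0")
  if (any(bed$start >= bed$end)) {
    bad <- which(bed$start >= bed$end)[1L]
    stop("mask interval with start >= end at line ", bad, " (",
         bed$chrom[bad], ":", bed$start[bad], "-", bed$end[bad], ")")
  }
  merged <- lapply(split(bed, bed$chrom), function(d) {
    # IRanges is 1-based closed; shift BED starts by +1 for the merge
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1L],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- c("genome_mask", "data.frame")
  out
}

#' Test whether 1-based positions fall inside a mask
#'
#' A 1-based point position `p` is inside a 0-based half-open interval
#' `[start, end)` iff `p - 1 >= start` and `p - 1 < end`, i.e.
#' `start < p <= end`.
#'
#' @param mask A `genome_mask`.
#' @param chrom Character vector of chromosomes.
#' @param pos Integer vector of 1-based positions (recycled against `chrom`).
#' @return Logical vector.
#' @export
mask_covers <- function(mask, chrom, pos) {
  stopifnot(inherits(mask, "genome_mask"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  if (nrow(mask) == 0L) return(rep(FALSE, n))
  out <- logical(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    iv <- mask[mask$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0L) next
    q <- IRanges::IRanges(start = pos[sel], width = 1L)
    s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    out[sel] <- IRanges::overlapsAny(q, s)
  }
  out
}

#' @export
print.genome_mask <- function(x, ...) {
  cat("Genome mask [", attr(x, "label"), "]: ", nrow(x), " merged intervals, ",
      sum(x$end - x$start), " bp\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}

#' Write a genome mask back to BED
#'
#' @param mask A `genome_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "genome_mask"))
  utils::write.table(as.data.frame(mask)[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
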