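#' Assemble clustered de novo mutations under a window rule
#'
#' Within each offspring, DNMs are sorted by (chrom, pos) and chained: a
#' DNM joins the open cluster iff the distance to its direct predecessor
#' on the same chromosome is strictly less than `window_bp`. Runs of
#' length 1 are discarded. A cluster with more than two members can span
#' more than `window_bp` in total, as long as every consecutive gap is
#' below the window.
#'
#' @param dnms DNM call data frame (`sample_id`, `chrom`, `pos`, `alt`,
#'   further columns carried through to the member table).
#' @param window_bp Cluster window in bp (strict upper bound on
#'   consecutive-member distance). Default 20.
#' @return A `cdnm_clusters` list with `clusters` (one row per cluster:
#'   `cluster_id`, `sample_id`, `chrom`, `start`, `end` (1-based member
#'   positions), `n_members`, `span_bp`, `window_bp`, `origin`,
#'   `in_target`, `validation`) and `members` (one row per member DNM with
#'   its `cluster_id`). Cluster ids are deterministic:
#'   `<sample>_<chrom>_<first pos>`.
#' @export
assemble_clusters <- function(dnms, window_bp = 20L) {
  stopifnot(window_bp >= 2)
  key <- paste(dnms$sample_id, dnms$chrom, dnms$pos, dnms$alt, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate DNM (sample, chrom, pos, alt) in input")
  }
  ord <- order(dnms$sample_id, dnms$chrom, dnms$pos)
  d <- dnms[ord, , drop = FALSE]
  new_run <- c(TRUE, d$sample_id[-1L] != d$sample_id[-nrow(d)] |
                 d$chrom[-1L] != d$chrom[-nrow(d)] |
                 diff(d$pos) >= window_bp)
  if (nrow(d) == 0L) new_run <- logical(0)
  run_id <- cumsum(new_run)
  run_sizes <- tabulate(run_id)
  keep <- run_sizes[run_id] >= 2L
  members <- d[keep, , drop = FALSE]
  mrun <- run_id[keep]
  if (nrow(members) == 0L) {
    clusters <- data.frame(cluster_id = character(), sample_id = character(),
                           chrom = character(), start = integer(), end = integer(),
                           n_members = integer(), span_bp = integer(),
                           window_bp = integer(), origin = character(),
                           in_target = logical(), validation = character(),
                           stringsAsFactors = FALSE)
    members$cluster_id <- character(0)
    return(structure(list(clusters = clusters, members = members),
                     class = "cdnm_clusters"))
  }
  first <- !duplicated(mrun)
  starts <- members$pos[first]
  cluster_id_map <- paste(members$sample_id[first], members$chrom[first],
                          starts, sep = "_")
  members$cluster_id <- cluster_id_map[match(mrun, mrun[first])]
  agg_start <- tapply(members$pos, members$cluster_id, min)
  agg_end <- tapply(members$pos, members$cluster_id, max)
  agg_n <- tapply(members$pos, members$cluster_id, length)
  ids <- unique(members$cluster_id)
  clusters <- data.frame(
    cluster_id = ids,
    sample_id = members$sample_id[first][match(ids, cluster_id_map)],
    chrom = members$chrom[first][match(ids, cluster_id_map)],
    start = as.integer(agg_start[ids]),
    end = as.integer(agg_end[ids]),
    n_members = as.integer(agg_n[ids]),
    span_bp = as.integer(agg_end[ids] - agg_start[ids]),
    window_bp = as.integer(window_bp),
    origin = "unknown",
    in_target = NA,
    validation = "untested",
    stringsAsFactors = FALSE
  )
  clusters <- clusters[order(clusters$sample_id, clusters$chrom, clusters$start), ,
                       drop = FALSE]
  rownames(clusters) <- NULL
  rownames(members) <- NULL
  structure(list(clusters = clusters, members = members), class = "cdnm_clusters")
}

#' @export
print.cdnm_clusters <- function(x, ...) {
  cat("cDNM clusters:", nrow(x$clusters), "clusters,", nrow(x$members),
      "member DNMs (window", if (nrow(x$clusters)) x$clusters$window_bp[1L] else NA,
      "bp)\n")
  print.data.frame(utils::head(x$clusters, 10L), ...)
  invisible(x)
}

#' Per-offspring DNM and cluster counts joined to covariates
#'
#' @param dnms DNM call data frame.
#' @param clusters A `cdnm_clusters` object.
#' @param meta Sample metadata with `sample_id` and covariates (cohort,
#'   parental ages, dose); offspring with no calls appear with count 0.
#' @param in_target_only Count only clusters flagged `in_target`.
#' @return Data frame: `meta` plus `n_dnm` (isolated DNMs, i.e. calls not
#'   in any cluster), `n_dnm_total` and `n_cdnm` (clusters).
#' @export
per_sample_counts <- function(dnms, clusters, meta, in_target_only = FALSE) {
  stopifnot(inherits(clusters, "cdnm_clusters"))
  cl <- clusters$clusters
  if (in_target_only) cl <- cl[!is.na(cl$in_target) & cl$in_target, , drop = FALSE]
  extra <- setdiff(unique(cl$sample_id), meta$sample_id)
  if (length(extra) > 0L) {
    stop("cluster sample(s) missing from metadata: ", paste(extra, collapse = ", "))
  }
  clustered_key <- paste(clusters$members$sample_id, clusters$members$chrom,
                         clusters$members$pos, clusters$members$alt, sep = "\r")
  dnm_key <- paste(dnms$sample_id, dnms$chrom, dnms$pos, dnms$alt, sep = "\r")
  isolated <- dnms[!(dnm_key %in% clustered_key), , drop = FALSE]
  out <- meta
  out$n_dnm <- as.integer(table(factor(isolated$sample_id, levels = meta$sample_id)))
  out$n_dnm_total <- as.integer(table(factor(dnms$sample_id, levels = meta$sample_id)))
  out$n_cdnm <- as.integer(table(factor(cl$sample_id, levels = meta$sample_id)))
  out
}

#' Flag clusters against repeat and mapability target masks
#'
#' A cluster is in-target iff none of its member positions falls inside
#' the repeat mask nor inside the low-mapability mask (the latter encodes
#' regions whose 36-mer alignability is below 1.0). The cluster set is
#' preserved; only the `in_target` flag changes. Overlap is tested per
#' member position, not per cluster span.
#'
#' @param clusters A `cdnm_clusters` object.
#' @param repeat_mask,mapability_mask `genome_mask` objects.
#' @param by Either `"member"` (default) or `"span"`: test each member
#'   position, or every base of the cluster span.
#' @return The `cdnm_clusters` object with `in_target` filled in.
#' @export
apply_target_mask <- function(clusters, repeat_mask, mapability_mask,
                              by = c("member", "span")) {
  stopifnot(inherits(clusters, "cdnm_clusters"))
  by <- match.arg(by)
  cl <- clusters$clusters
  if (nrow(cl) == 0L) return(clusters)
  if (by == "member") {
    m <- clusters$members
    hit <- mask_covers(repeat_mask, m$chrom, m$pos) |
      mask_covers(mapability_mask, m$chrom, m$pos)
    bad <- unique(m$cluster_id[hit])
  } else {
    bad <- cl$cluster_id[vapply(seq_len(nrow(cl)), function(i) {
      p <- cl$start[i]:cl$end[i]
      any(mask_covers(repeat_mask, cl$chrom[i], p)) ||
        any(mask_covers(mapability_mask, cl$chrom[i], p))
    }, logical(1L))]
  }
  clusters$clusters$in_target <- !(cl$cluster_id %in% bad)
  clusters
}

#' Window sensitivity scan
#'
#' Recomputes cluster membership from scratch at each window size and
#' tabulates per-sample cluster counts.
#'
#' @param dnms DNM call data frame.
#' @param meta Sample metadata (`sample_id` at minimum).
#' @param windows Integer vector of window sizes in bp.
#' @return Data frame with one row per sample, one `w<window>` column per
#'   window holding the cluster count, plus `w<window>_dnms` columns with
#'   the number of clustered DNMs.
#' @export
sensitivity_scan <- function(dnms, meta,
                             windows = c(10L, 20L, 30L, 10000L, 47000L)) {
  stopifnot(all(windows > 0))
  out <- data.frame(sample_id = meta$sample_id, stringsAsFactors = FALSE)
  for (w in windows) {
    cl <- assemble_clusters(dnms, window_bp = w)
    out[[paste0("w", w)]] <-
      as.integer(table(factor(cl$clusters$sample_id, levels = meta$sample_id)))
    out[[paste0("w", w, "_dnms")]] <-
      as.integer(table(factor(cl$members$sample_id, levels = meta$sample_id)))
  }
  out
}

#' Cluster size distribution
#'
#' @param clusters A `cdnm_clusters` object.
#' @return List with `histogram` (named integer vector: member count ->
#'   number of clusters) and `max_size`.
#' @export
cluster_size_distribution <- function(clusters) {
  stopifnot(inherits(clusters, "cdnm_clusters"))
  n <- clusters$clusters$n_members
  if (length(n) == 0L) {
    return(list(histogram = integer(0), max_size = 0L))
  }
  h <- table(n)
  list(histogram = stats::setNames(as.integer(h), names(h)),
       max_size = max(n))
}
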