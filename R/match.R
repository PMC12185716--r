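#' Age-match a reference cohort against another cohort
#'
#' Finds the assignment of `ratio` partners from `other_meta` to every
#' offspring in `ref_meta` that minimizes the total parental-age cost
#' \eqn{\sum |father_{ref} - father_{other}| + |mother_{ref} -
#' mother_{other}|}, via minimum-weight bipartite matching. 1:n matching
#' is reduced to standard assignment by replicating each reference node
#' `ratio` times. The optimum is global, not greedy.
#'
#' @param ref_meta,other_meta Sample metadata data frames with
#'   `sample_id`, `father_age`, `mother_age`.
#' @param ratio Number of partners per reference offspring (integer >= 1).
#' @return A list of class `match_result`: `pairs` (data frame `ref_id`,
#'   `other_id`, `cost`), `total_cost`, `ratio`.
#' @export
age_match <- function(ref_meta, other_meta, ratio = 1L) {
  ratio <- as.integer(ratio)
  stopifnot(ratio >= 1L)
  for (d in list(ref_meta, other_meta)) {
    bad <- d$sample_id[is.na(d$father_age) | is.na(d$mother_age)]
    if (length(bad) > 0L) {
      stop("missing parental age(s) for sample(s): ", paste(bad, collapse = ", "))
    }
  }
  n_ref <- nrow(ref_meta)
  n_other <- nrow(other_meta)
  if (n_other < ratio * n_ref) {
    stop("infeasible matching: need at least ", ratio * n_ref,
         " candidates, have ", n_other)
  }
  ref_meta <- ref_meta[order(ref_meta$sample_id), , drop = FALSE]
  other_meta <- other_meta[order(other_meta$sample_id), , drop = FALSE]
  # cost matrix with reference nodes replicated `ratio` times
  rep_ref <- rep(seq_len(n_ref), each = ratio)
  cost <- outer(rep_ref, seq_len(n_other), function(i, j) {
    abs(ref_meta$father_age[i] - other_meta$father_age[j]) +
      abs(ref_meta$mother_age[i] - other_meta$mother_age[j])
  })
  n_left <- length(rep_ref)
  # min-cost perfect (on the left) assignment as max-weight bipartite
  # matching: weight = Cmax - cost + 1 > 0, so larger matchings always win
  # and among them the minimum-cost one has maximum weight
  w <- max(cost) - cost + 1
  edges <- rbind(rep(seq_len(n_left), n_other),
                 n_left + rep(seq_len(n_other), each = n_left))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, n_left), rep(TRUE, n_other)),
                                    edges = as.vector(edges))
  igraph::E(g)$weight <- as.vector(w)  # column-major matches edge order
  mm <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  partner <- mm$matching[seq_len(n_left)] - n_left
  if (any(is.na(partner)) || anyDuplicated(partner)) {
    stop("matching failed to assign every reference slot")  # nocov
  }
  pairs <- data.frame(
    ref_id = ref_meta$sample_id[rep_ref],
    other_id = other_meta$sample_id[partner],
    cost = cost[cbind(seq_len(n_left), partner)],
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$ref_id, pairs$other_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, total_cost = sum(pairs$cost), ratio = ratio),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("Age matching: ", nrow(x$pairs), " pairs (ratio ", x$ratio,
      "), total cost ", format(x$total_cost), " years\n", sep = "")
  print.data.frame(utils::head(x$pairs, 10L), ...)
  invisible(x)
}

#' Extract the matched subcohort
#'
#' @param match A `match_result` from [age_match()].
#' @param other_meta The candidate cohort metadata the match was made
#'   against.
#' @return The rows of `other_meta` selected by the matching, in pair
#'   order.
#' @export
matched_subcohort <- function(match, other_meta) {
  stopifnot(inherits(match, "match_result"))
  out <- other_meta[base::match(match$pairs$other_id, other_meta$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
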