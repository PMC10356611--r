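# Recurrent-motif queries over connectome synapse tables: thresholded
# edges, reciprocal pairs, cross-hemisphere single-intermediary loops.

#' Aggregate and threshold a synapse table
#'
#' Duplicate (pre, post) rows are summed first, then edges with fewer
#' than `min_synapses` synapses are dropped (the ten-synapse threshold
#' by default).
#'
#' @param table Synapse data frame: `pre_id, post_id, pre_class,
#'   post_class, pre_side, post_side, n_synapses`.
#' @param min_synapses Minimum synapse count per aggregated edge.
#' @return Edge data frame in the same schema, one row per (pre, post).
#' @export
filter_edges <- function(table, min_synapses = 10) {
  stopifnot(all(c("pre_id", "post_id", "n_synapses") %in% names(table)))
  if (any(table$n_synapses < 1)) stop("n_synapses must be >= 1")
  key <- paste(table$pre_id, table$post_id, sep = "\r")
  tot <- tapply(table$n_synapses, key, sum)
  first <- table[!duplicated(key), , drop = FALSE]
  first$n_synapses <- as.numeric(tot[paste(first$pre_id, first$post_id,
                                           sep = "\r")])
  out <- first[first$n_synapses >= min_synapses, , drop = FALSE]
  out <- out[order(out$pre_id, out$post_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutually connected cell pairs
#'
#' Unordered pairs (a, b) with both a->b and b->a present in the
#' thresholded edge set; optionally restricted to pairs with at least
#' one member in `class_filter`.
#'
#' @param edges Thresholded edge data frame (see [filter_edges()]).
#' @param class_filter Optional character vector of cell classes.
#' @return Data frame `cell_a, cell_b, class_a, class_b, w_ab, w_ba`.
#' @export
reciprocal_pairs <- function(edges, class_filter = NULL) {
  key <- paste(edges$pre_id, edges$post_id, sep = "\r")
  rev_key <- paste(edges$post_id, edges$pre_id, sep = "\r")
  has_rev <- rev_key %in% key
  out <- list()
  seen <- character(0)
  for (i in which(has_rev)) {
    a <- edges$pre_id[i]; b <- edges$post_id[i]
    pk <- paste(sort(c(a, b)), collapse = "\r")
    if (pk %in% seen || a == b) next
    seen <- c(seen, pk)
    j <- which(key == paste(b, a, sep = "\r"))[1]
    out[[length(out) + 1L]] <- data.frame(
      cell_a = a, cell_b = b,
      class_a = edges$pre_class[i], class_b = edges$post_class[i],
      w_ab = edges$n_synapses[i], w_ba = edges$n_synapses[j],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_a = character(0), cell_b = character(0),
               class_a = character(0), class_b = character(0),
               w_ab = numeric(0), w_ba = numeric(0),
               stringsAsFactors = FALSE)
  if (!is.null(class_filter) && nrow(res))
    res <- res[res$class_a %in% class_filter |
                 res$class_b %in% class_filter, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Single-intermediary cross-hemisphere recurrent loops
#'
#' Finds every cell x (of any class outside the seed class) that
#' interconnects the seed class across hemispheres in both directions
#' through itself: there must be thresholded edges from a left-side
#' seed cell into x and from x onto a right-side seed cell, and from a
#' right-side seed cell into x and from x onto a left-side seed cell.
#' The seed cells on the two legs need not be the same individuals.
#' With `require_both_directions = FALSE` one of the two directions
#' suffices.
#'
#' @param edges Thresholded edge data frame (see [filter_edges()]).
#' @param seed_class Seed cell class (e.g. the oviposition-circuit
#'   input-neuron class).
#' @param require_both_directions Demand both cross-hemisphere
#'   directions (the default, matching the recurrence criterion).
#' @return Data frame `intermediary, class` with the supporting edges
#'   for each intermediary in attribute `"evidence"` (a named list of
#'   edge data frames).
#' @export
single_intermediary_loops <- function(edges, seed_class,
                                      require_both_directions = TRUE) {
  cls <- c(stats::setNames(edges$pre_class, edges$pre_id),
           stats::setNames(edges$post_class, edges$post_id))
  cls <- cls[!duplicated(names(cls))]
  if (!any(cls == seed_class)) stop("seed class absent: ", seed_class)
  sides <- c(stats::setNames(edges$pre_side, edges$pre_id),
             stats::setNames(edges$post_side, edges$post_id))
  sides <- sides[!duplicated(names(sides))]
  seed_pre <- edges$pre_class == seed_class
  seed_post <- edges$post_class == seed_class
  candidates <- setdiff(unique(c(edges$post_id[seed_pre],
                                 edges$pre_id[seed_post])),
                        names(cls)[cls == seed_class])
  out <- list(); evidence <- list()
  for (x in candidates) {
    inc <- edges[seed_pre & edges$post_id == x, , drop = FALSE]
    outg <- edges[seed_post & edges$pre_id == x, , drop = FALSE]
    lr <- any(inc$pre_side == "L") && any(outg$post_side == "R")
    rl <- any(inc$pre_side == "R") && any(outg$post_side == "L")
    hit <- if (require_both_directions) lr && rl else lr || rl
    if (!hit) next
    out[[length(out) + 1L]] <- data.frame(
      intermediary = x, class = unname(cls[x]), stringsAsFactors = FALSE)
    evidence[[x]] <- rbind(inc, outg)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(intermediary = character(0), class = character(0),
               stringsAsFactors = FALSE)
  res <- res[order(res$intermediary), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "evidence") <- evidence
  res
}
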