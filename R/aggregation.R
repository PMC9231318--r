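# Peptide clustering by the centre-of-mass distance rule: two chains belong
# to the same cluster iff their minimum-image COM distance is strictly below
# the cutoff (default 1.5 nm), closed transitively (single linkage).

#' Centre of mass of one peptide chain
#'
#' Chains are assumed stored whole; if `unwrap = TRUE` a minimum-image
#' chaining pass along the bonded sequence rebuilds wrapped chains first.
#'
#' @param fr an `mp_frame`.
#' @param top an `mp_topology`.
#' @param chain_id chain to evaluate.
#' @param weighting `"mass"` (default) or `"geometric"`.
#' @param unwrap rebuild the chain across periodic boundaries first.
#' @return numeric length-3 COM (nm).
#' @export
chain_com <- function(fr, top, chain_id, weighting = c("mass", "geometric"),
                      unwrap = TRUE) {
  weighting <- match.arg(weighting)
  idx <- chain_particles(top, chain_id)
  xyz <- fr$coords[idx, , drop = FALSE]
  if (unwrap) xyz <- unwrap_chain(xyz, fr$box)
  w <- if (weighting == "mass") top$particles$mass[idx] else rep(1, length(idx))
  colSums(xyz * w) / sum(w)
}

#' Centres of mass of all peptide chains
#'
#' @inheritParams chain_com
#' @return matrix with one row per chain; rownames are chain ids.
#' @export
chain_coms <- function(fr, top, weighting = c("mass", "geometric"),
                       unwrap = TRUE) {
  weighting <- match.arg(weighting)
  ids <- chain_ids(top)
  out <- t(vapply(ids, function(id)
    chain_com(fr, top, id, weighting, unwrap), numeric(3)))
  rownames(out) <- ids
  out
}

#' Cluster the peptide chains of one frame
#'
#' Single-linkage partition under periodic boundaries: chains i and j are
#' in the same cluster iff they are connected by a path of chain pairs
#' whose minimum-image COM distance is strictly less than `cutoff`.
#'
#' @inheritParams chain_com
#' @param cutoff COM distance cutoff (nm); must be below half the smallest
#'   box edge for the minimum-image rule to be well defined.
#' @return an object of class `mp_clusters`: list with `time`, `clusters`
#'   (list of integer chain-id vectors), `membership` (named integer),
#'   `largest_cluster_id`.
#' @export
cluster_frame <- function(fr, top, cutoff = 1.5,
                          weighting = c("mass", "geometric"), unwrap = TRUE) {
  stopifnot(cutoff > 0)
  if (cutoff >= min(fr$box) / 2)
    stop("cutoff must be below half the smallest box edge (minimum image)")
  coms <- chain_coms(fr, top, match.arg(weighting), unwrap)
  ids <- as.integer(rownames(coms))
  n <- nrow(coms)
  dmat <- min_image_dist_matrix(coms, fr$box)
  adj <- dmat < cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- lapply(seq_len(comp$no), function(k) ids[comp$membership == k])
  membership <- stats::setNames(comp$membership, ids)
  sizes <- lengths(clusters)
  obj <- list(time = fr$time, clusters = clusters, membership = membership,
              largest_cluster_id = which.max(sizes))
  class(obj) <- "mp_clusters"
  obj
}

#' @export
print.mp_clusters <- function(x, ...) {
  cat(sprintf("Cluster assignment at t = %g ns: %d clusters, largest has %d chains\n",
              x$time, length(x$clusters),
              length(x$clusters[[x$largest_cluster_id]])))
  invisible(x)
}

#' Cluster-count time series
#'
#' Applies [cluster_frame()] to every frame and reports, per frame, the
#' number of clusters and the size and members of the largest cluster (the
#' observable of the aggregation kinetics).
#'
#' @param traj an `mp_trajectory`.
#' @inheritParams cluster_frame
#' @return a data.frame with columns `time_ns`, `n_clusters`,
#'   `largest_cluster_size`, `largest_cluster_members` (semicolon-joined
#'   ids); the per-frame `mp_clusters` objects are attached as attribute
#'   `"assignments"`.
#' @export
cluster_count_series <- function(traj, cutoff = 1.5,
                                 weighting = c("mass", "geometric"),
                                 unwrap = TRUE) {
  stopifnot(inherits(traj, "mp_trajectory"), length(traj$frames) >= 1L)
  weighting <- match.arg(weighting)
  asg <- lapply(traj$frames, cluster_frame, top = traj$topology,
                cutoff = cutoff, weighting = weighting, unwrap = unwrap)
  out <- data.frame(
    time_ns = vapply(asg, `[[`, numeric(1), "time"),
    n_clusters = vapply(asg, function(a) length(a$clusters), integer(1)),
    largest_cluster_size = vapply(asg, function(a)
      length(a$clusters[[a$largest_cluster_id]]), integer(1)),
    largest_cluster_members = vapply(asg, function(a)
      paste(sort(a$clusters[[a$largest_cluster_id]]), collapse = ";"),
      character(1))
  )
  attr(out, "assignments") <- asg
  out
}
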