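#' Belonging coefficients of nodes to edge clusters
#'
#' Given a partition of the edges of `g` into k clusters, the belonging
#' coefficient of node i to cluster c is the fraction of i's incident edges
#' assigned to c. Rows therefore sum to exactly 1 for every node of positive
#' degree (in a connected graph, every node).
#'
#' @param g an [lpam_graph][from_edge_list].
#' @param edge_labels integer vector of length `n_edges(g)`: cluster (in
#'   `1..k`) of each edge, in canonical edge order.
#' @param k number of clusters.
#' @return numeric matrix F of dimension `n_nodes(g) x k`, rownames = node
#'   labels; `F[i, c]` in \[0, 1\].
#' @export
belonging_fractions <- function(g, edge_labels, k) {
  m <- n_edges(g)
  if (length(edge_labels) != m || anyNA(edge_labels))
    stop("every edge must carry a cluster label")
  edge_labels <- as.integer(edge_labels)
  if (any(edge_labels < 1L) || any(edge_labels > k))
    stop(sprintf("edge labels must lie in 1..%d", k))
  n <- n_nodes(g)
  F <- matrix(0, n, k, dimnames = list(g$nodes, NULL))
  for (side in 1:2) {
    tab <- table(factor(g$edges[, side], levels = seq_len(n)),
                 factor(edge_labels, levels = seq_len(k)))
    F <- F + as.matrix(unclass(tab))
  }
  deg <- node_degrees(g)
  F[deg > 0, ] <- F[deg > 0, , drop = FALSE] / deg[deg > 0]
  dimnames(F) <- list(g$nodes, NULL)
  F
}

# Belonging fractions from the medoid-distance indicator itself: an edge
# whose distance to several medoids is minimal (within a relative tolerance)
# counts toward each of those clusters.  On tie-free instances this equals
# belonging_fractions() of the single assignment; on symmetric graphs (the
# regular lattice) the tied boundary edges are what lets both neighbouring
# communities claim a node, so row sums may exceed 1 there.
belonging_tie_aware <- function(g, D, medoids, rel_tol = 1e-9) {
  sub <- D[, medoids, drop = FALSE]
  mins <- do.call(pmin, lapply(seq_along(medoids), function(j) sub[, j]))
  X <- sub <= mins + rel_tol * (1 + abs(mins))   # m x k tie-aware indicator
  n <- n_nodes(g)
  F <- matrix(0, n, length(medoids), dimnames = list(g$nodes, NULL))
  for (side in 1:2) {
    idx <- g$edges[, side]
    for (c in seq_along(medoids)) {
      cnt <- tabulate(idx[X[, c]], nbins = n)
      F[, c] <- F[, c] + cnt
    }
  }
  deg <- node_degrees(g)
  F[deg > 0, ] <- F[deg > 0, , drop = FALSE] / deg[deg > 0]
  F
}

#' Threshold a belonging matrix into an overlapping cover
#'
#' Node i joins community c iff `F[i, c] >= theta` (inclusive). Nodes can
#' land in zero, one, or several communities; those reaching the threshold
#' nowhere are reported as `unassigned`, never force-assigned. Raising
#' `theta` never adds a membership.
#'
#' @param F belonging matrix as returned by [belonging_fractions()]
#'   (rownames = node labels).
#' @param theta threshold in \[0, 1\].
#' @return an [lpam_cover()] with one (possibly empty) community per column
#'   of `F`.
#' @export
threshold_cover <- function(F, theta = 0.5) {
  if (length(theta) != 1L || is.na(theta) || theta < 0 || theta > 1)
    stop("`theta` must be a single value in [0, 1]")
  member <- F >= theta
  communities <- lapply(seq_len(ncol(F)), function(c) rownames(F)[member[, c]])
  lpam_cover(communities, unassigned = rownames(F)[rowSums(member) == 0L])
}

#' Link Partitioning Around Medoids (LPAM)
#'
#' Full pipeline for detecting `k` overlapping communities in a connected,
#' simple, unweighted graph:
#' 1. build the line graph L(G) (vertices = edges of G, adjacency = shared
#'    endpoint);
#' 2. compute the commute (`"cm"`) or amplified commute (`"acm"`) distance
#'    matrix on L(G);
#' 3. solve the k-median problem on that matrix, exactly or with the CLARANS
#'    heuristic, giving k medoid edges and a disjoint edge clustering;
#' 4. compute per-node belonging fractions and threshold them at `theta`
#'    into an overlapping node cover.
#'
#' The belonging fraction of node i to cluster c is the fraction of i's
#' incident edges whose nearest-medoid set contains c. An edge exactly
#' equidistant (within a relative tolerance of 1e-9) to several medoids
#' counts toward each of them, so on highly symmetric graphs row sums of the
#' belonging matrix can exceed 1; on generic (tie-free) inputs every row
#' sums to exactly 1 and the matrix equals
#' `belonging_fractions(g, edge_labels, k)`.
#'
#' Communities are index-aligned with the sorted medoid line-graph vertices,
#' so output is stable for diffing; with the exact solver (or the heuristic
#' plus a fixed seed) the whole result is deterministic.
#'
#' @param g a connected [lpam_graph][from_edge_list] with at least `k` edges.
#' @param k number of communities.
#' @param distance `"cm"` (commute) or `"acm"` (amplified commute).
#' @param solver `"exact"` or `"clarans"`.
#' @param theta belonging threshold in \[0, 1\]; default 0.5, which in
#'   practice recovers known covers best because few real nodes straddle
#'   more than two communities.
#' @param seed integer seed for the heuristic solver (ignored by the exact
#'   solver).
#' @param tol eigenvalue cutoff passed to the distance computation.
#' @param budget candidate-set budget passed to [solve_exact()].
#' @param numlocal,maxneighbor CLARANS parameters, see [solve_clarans()].
#' @return an object of class `lpam_result`: `cover` ([lpam_cover()]),
#'   `belonging` (node x cluster fraction matrix), `medoid_edges` (k x 2
#'   character matrix of medoid edge endpoints), `edge_labels` (cluster per
#'   edge of `g`, canonical order), `objective` (k-median objective) and
#'   `settings` (distance, solver, theta, k, seed).
#' @examples
#' tri <- from_edge_list(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
#' res <- run_lpam(tri, k = 1)
#' res$cover$communities[[1]]  # all three nodes
#' @export
run_lpam <- function(g, k, distance = c("cm", "acm"),
                     solver = c("exact", "clarans"), theta = 0.5,
                     seed = NULL, tol = 1e-9, budget = 1e7,
                     numlocal = 4, maxneighbor = NULL) {
  distance <- match.arg(distance)
  solver <- match.arg(solver)
  if (!inherits(g, "lpam_graph")) stop("`g` must be an lpam_graph (unweighted simple graph)")
  m <- n_edges(g)
  if (length(k) != 1L || k < 1L || k != round(k)) stop("`k` must be a positive integer")
  if (k > m) stop(sprintf("k = %d exceeds the number of edges (%d)", k, m))
  stop_if_disconnected(g, what = "input graph")

  lg <- line_graph(g)
  D <- if (m == 1L) {
    matrix(0, 1L, 1L, dimnames = list(lg$graph$nodes, lg$graph$nodes))
  } else if (distance == "cm") {
    commute_matrix(lg$graph, tol = tol)
  } else {
    amplified_commute_matrix(lg$graph, tol = tol)
  }

  km <- if (solver == "exact") solve_exact(D, k, budget = budget)
        else solve_clarans(D, k, numlocal = numlocal,
                           maxneighbor = maxneighbor, seed = seed)

  # clusters numbered by sorted medoid line-vertex index
  edge_labels <- match(km$labels, km$medoids)
  F <- belonging_tie_aware(g, D, km$medoids)
  cover <- threshold_cover(F, theta)

  structure(list(cover = cover,
                 belonging = F,
                 medoid_edges = lg$index_to_edge[km$medoids, , drop = FALSE],
                 edge_labels = edge_labels,
                 objective = km$objective,
                 settings = list(distance = distance, solver = solver,
                                 theta = theta, k = as.integer(k),
                                 seed = seed)),
            class = "lpam_result")
}

#' @export
print.lpam_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf("LPAM result: k = %d, distance = %s, solver = %s, theta = %g\n",
              s$k, s$distance, s$solver, s$theta))
  cat(sprintf("k-median objective: %.6g\n", x$objective))
  sizes <- vapply(x$cover$communities, length, 1L)
  cat(sprintf("community sizes: %s\n", paste(sizes, collapse = ", ")))
  if (length(x$cover$unassigned) > 0L)
    cat(sprintf("unassigned nodes: %s\n", paste(x$cover$unassigned, collapse = " ")))
  cat("medoid edges:", paste(x$medoid_edges[, 1L], x$medoid_edges[, 2L],
                             sep = "--", collapse = " "), "\n")
  invisible(x)
}
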