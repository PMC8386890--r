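#' Resistance, commute and amplified commute distance matrices
#'
#' The resistance (effective-resistance) distance between nodes i and j is
#' `Lp[i,i] + Lp[j,j] - 2*Lp[i,j]`, where `Lp` is the Moore-Penrose
#' pseudoinverse of the graph Laplacian `L = D - A`. The commute distance is
#' `vol(G)` times the resistance distance, i.e. the expected number of steps
#' of a random walk from i to j and back. The amplified commute distance
#' subtracts the degree-driven terms that dominate the commute distance on
#' large graphs:
#' `d_amp(i,j) = d_cm(i,j)/vol(G) - 1/d_i - 1/d_j + 2*a_ij/(d_i*d_j)`,
#' with `a_ij` the 0/1 adjacency indicator (self-weight terms vanish on a
#' simple graph). Its diagonal is set to 0 by convention; off-diagonal
#' entries are kept exactly as the formula yields them, so on small graphs
#' they may be 0 or even negative for distinct nodes (the k-median solvers
#' accept that).
#'
#' All three require a connected graph with at least 2 nodes; resistance
#' across components is infinite, so disconnected input is an error naming
#' the components.
#'
#' @param g a connected [lpam_graph][from_edge_list] with >= 2 nodes.
#' @param tol relative eigenvalue cutoff for the pseudoinverse: eigenvalues
#'   below `tol * max(eigenvalue)` are treated as zero.
#' @return a symmetric numeric matrix with zero diagonal, dimnames = node
#'   labels.
#' @examples
#' p3 <- from_edge_list(rbind(c("a", "b"), c("b", "c")))
#' resistance_matrix(p3)["a", "c"]        # 2 (series resistors)
#' commute_matrix(p3)["a", "c"]           # vol = 4, so 8
#' amplified_commute_matrix(p3)["a", "c"] # 0
#' @export
resistance_matrix <- function(g, tol = 1e-9) {
  if (n_nodes(g) < 2L) stop("resistance distance needs at least 2 nodes")
  stop_if_disconnected(g)
  Lp <- laplacian_pseudoinverse(g, tol = tol)
  dg <- diag(Lp)
  R <- outer(dg, dg, "+") - 2 * Lp
  R <- (R + t(R)) / 2
  diag(R) <- 0
  R[R < 0] <- 0  # clip eigen-roundoff; true resistances are nonnegative
  dimnames(R) <- list(g$nodes, g$nodes)
  R
}

#' @rdname resistance_matrix
#' @export
commute_matrix <- function(g, tol = 1e-9) {
  graph_volume(g) * resistance_matrix(g, tol = tol)
}

#' @rdname resistance_matrix
#' @export
amplified_commute_matrix <- function(g, tol = 1e-9) {
  R <- resistance_matrix(g, tol = tol)
  d <- node_degrees(g)
  A <- adjacency_matrix(g)
  inv <- 1 / d
  Damp <- R - outer(inv, inv, "+") + 2 * A / outer(d, d)
  diag(Damp) <- 0
  Damp <- (Damp + t(Damp)) / 2
  dimnames(Damp) <- list(g$nodes, g$nodes)
  Damp
}

# dense 0/1 adjacency matrix in node order
adjacency_matrix <- function(g) {
  n <- n_nodes(g)
  A <- matrix(0, n, n)
  A[g$edges] <- 1
  A[g$edges[, c(2L, 1L), drop = FALSE]] <- 1
  dimnames(A) <- list(g$nodes, g$nodes)
  A
}

# Moore-Penrose pseudoinverse of the graph Laplacian via symmetric eigen
# decomposition; for a connected graph exactly one eigenvalue is (numerically)
# zero and is dropped by the relative cutoff.
laplacian_pseudoinverse <- function(g, tol = 1e-9) {
  A <- adjacency_matrix(g)
  L <- diag(node_degrees(g)) - A
  e <- eigen(L, symmetric = TRUE)
  cutoff <- tol * max(e$values, 0)
  keep <- e$values > cutoff
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}
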