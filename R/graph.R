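#' Simple undirected graphs with stable node ordering
#'
#' `lpam_graph` objects hold an unweighted, undirected simple graph: a vector
#' of opaque node labels (order = order of first appearance) plus an integer
#' edge matrix in canonical form. Canonical form means each edge is stored
#' with its lexicographically smaller label first, and edges are ordered
#' lexicographically by their label pairs (byte order, locale-independent).
#' This ordering is what makes medoid indices and tie-breaking deterministic
#' downstream.
#'
#' @param pairs edges as a two-column matrix/data.frame of labels, or a list
#'   of length-2 vectors.
#' @param isolated_nodes optional labels of degree-0 nodes to register after
#'   the nodes appearing in `pairs`.
#' @return An object of class `lpam_graph` with elements `nodes` (character
#'   vector) and `edges` (m x 2 integer matrix of node indices, canonical
#'   order).
#' @details Duplicate edges are collapsed with a warning; self-loops are an
#'   error (the method is defined for simple unweighted graphs only).
#' @examples
#' g <- from_edge_list(rbind(c("a", "b"), c("b", "c")))
#' n_nodes(g)
#' n_edges(g)
#' @export
from_edge_list <- function(pairs, isolated_nodes = NULL) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.list(pairs) && !is.matrix(pairs)) {
    if (length(pairs) == 0L) {
      pairs <- matrix(character(), ncol = 2L)
    } else {
      if (any(lengths(pairs) != 2L)) stop("each edge must have exactly two endpoints")
      pairs <- do.call(rbind, lapply(pairs, as.character))
    }
  }
  if (!is.matrix(pairs) || (nrow(pairs) > 0L && ncol(pairs) != 2L))
    stop("`pairs` must be a two-column matrix of node labels")
  storage.mode(pairs) <- "character"
  loops <- which(pairs[, 1L] == pairs[, 2L])
  if (length(loops) > 0L)
    stop(sprintf("self-loop not allowed: (%s, %s)",
                 pairs[loops[1L], 1L], pairs[loops[1L], 2L]))
  nodes <- unique(c(as.vector(t(pairs)), as.character(isolated_nodes)))
  a <- pmin(pairs[, 1L], pairs[, 2L])
  b <- pmax(pairs[, 1L], pairs[, 2L])
  key <- paste0(a, "\r", b)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
    a <- a[!dup]; b <- b[!dup]
  }
  o <- byte_order(a, b)
  a <- a[o]; b <- b[o]
  edges <- cbind(match(a, nodes), match(b, nodes))
  storage.mode(edges) <- "integer"
  new_lpam_graph(nodes, edges)
}

new_lpam_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "lpam_graph")
}

#' @export
print.lpam_graph <- function(x, ...) {
  cat(sprintf("lpam_graph: %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Basic graph accessors
#'
#' @param g an [lpam_graph][from_edge_list].
#' @return `n_nodes`/`n_edges`: integer counts. `node_degrees`: named integer
#'   vector of degrees in node order. `graph_volume`: sum of degrees
#'   (`2 * n_edges`). `edge_labels_of`: character vector `"u--v"` naming each
#'   edge in canonical order.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' @rdname n_nodes
#' @export
node_degrees <- function(g) {
  d <- tabulate(g$edges, nbins = n_nodes(g))
  names(d) <- g$nodes
  d
}

#' @rdname n_nodes
#' @export
graph_volume <- function(g) 2L * n_edges(g)

#' @rdname n_nodes
#' @export
edge_labels_of <- function(g) {
  paste0(g$nodes[g$edges[, 1L]], "--", g$nodes[g$edges[, 2L]])
}

#' Convert to an igraph object
#'
#' Vertex order and edge order are preserved; vertices are named with the
#' node labels.
#'
#' @param g an [lpam_graph][from_edge_list].
#' @return an [igraph::igraph] object.
#' @export
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = n_nodes(g), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes)
  igraph::add_edges(ig, as.vector(t(g$edges)))
}

is_connected_graph <- function(g) {
  if (n_nodes(g) == 0L) return(TRUE)
  igraph::is_connected(as_igraph(g))
}

# components as a list of label vectors; used in error messages
graph_components <- function(g) {
  comp <- igraph::components(as_igraph(g))
  split(g$nodes, comp$membership)
}

stop_if_disconnected <- function(g, what = "graph") {
  if (!is_connected_graph(g)) {
    comps <- graph_components(g)
    desc <- vapply(head(comps, 4L), function(x)
      paste0("{", paste(head(x, 6L), collapse = ","),
             if (length(x) > 6L) ",..." else "", "}"), character(1L))
    stop(sprintf("%s is disconnected (%d components: %s%s); distances are undefined across components",
                 what, length(comps), paste(desc, collapse = " "),
                 if (length(comps) > 4L) " ..." else ""))
  }
  invisible(g)
}

#' Global clustering coefficient (transitivity)
#'
#' Ratio of closed triplets to all connected triplets, computed via igraph.
#' Returns 0 for triangle-free graphs with at least one connected triple.
#'
#' @param g an [lpam_graph][from_edge_list].
#' @return a number in \[0, 1\] (0 when undefined).
#' @export
global_clustering <- function(g) {
  v <- igraph::transitivity(as_igraph(g), type = "global")
  if (is.nan(v)) 0 else v
}

#' Line graph of a simple graph
#'
#' The line graph L(G) has one vertex per edge of `g`; two vertices of L(G)
#' are adjacent iff the corresponding edges of `g` share an endpoint. Vertex
#' i of the returned graph corresponds to edge i of `g` in canonical edge
#' order, so the edge-to-line-vertex map is returned explicitly.
#'
#' @param g an [lpam_graph][from_edge_list] with at least one edge.
#' @return a list with `graph` (the line graph, an `lpam_graph` whose node
#'   labels are `"u--v"` edge names), `edge_to_index` (named integer vector:
#'   edge name -> line-graph vertex index) and `index_to_edge` (m x 2
#'   character matrix of endpoint labels, row i = edge i).
#' @examples
#' g <- grid_graph(3, 3)
#' lg <- line_graph(g)
#' n_nodes(lg$graph)  # == n_edges(g)
#' @export
line_graph <- function(g) {
  m <- n_edges(g)
  if (m < 1L) stop("line graph requires a graph with at least one edge")
  labs <- edge_labels_of(g)
  # incident edge indices per node; all unordered pairs of edges sharing the
  # node become edges of L(G).  In a simple graph two edges share at most one
  # endpoint, so each pair is generated exactly once.
  inc <- split(rep(seq_len(m), 2L), c(g$edges[, 1L], g$edges[, 2L]))
  pair_list <- lapply(inc, function(ix) {
    if (length(ix) < 2L) return(NULL)
    t(combn(sort(ix), 2L))
  })
  prs <- do.call(rbind, pair_list)
  if (is.null(prs)) {
    ledges <- matrix(integer(), ncol = 2L)
  } else {
    ledges <- prs[order(prs[, 1L], prs[, 2L]), , drop = FALSE]
    storage.mode(ledges) <- "integer"
  }
  lg <- new_lpam_graph(labs, ledges)
  idx <- seq_len(m)
  names(idx) <- labs
  list(graph = lg,
       edge_to_index = idx,
       index_to_edge = cbind(g$nodes[g$edges[, 1L]], g$nodes[g$edges[, 2L]]))
}

#' Rectangular grid (lattice) graph
#'
#' Non-periodic 4-neighbour lattice with `rows * cols` nodes and
#' `rows*(cols-1) + cols*(rows-1)` edges. Node labels are `"r<i>c<j>"`,
#' zero-padded so lexicographic order equals row-major order.
#'
#' @param rows,cols positive integers, `rows * cols >= 2`.
#' @return an [lpam_graph][from_edge_list].
#' @examples
#' g <- grid_graph(8, 8)
#' n_edges(g)  # 112
#' @export
grid_graph <- function(rows, cols) {
  if (length(rows) != 1L || length(cols) != 1L ||
      rows < 1L || cols < 1L || rows != round(rows) || cols != round(cols))
    stop("`rows` and `cols` must be positive integers")
  if (rows * cols < 2L) stop("grid must have at least 2 nodes")
  wr <- nchar(as.character(rows)); wc <- nchar(as.character(cols))
  lab <- function(i, j) sprintf(paste0("r%0", wr, "dc%0", wc, "d"), i, j)
  hor <- ver <- NULL
  ij <- expand.grid(j = seq_len(cols), i = seq_len(rows))
  if (cols > 1L) {
    s <- ij[ij$j < cols, ]
    hor <- cbind(lab(s$i, s$j), lab(s$i, s$j + 1L))
  }
  if (rows > 1L) {
    s <- ij[ij$i < rows, ]
    ver <- cbind(lab(s$i, s$j), lab(s$i + 1L, s$j))
  }
  all_nodes <- lab(ij$i, ij$j)
  from_edge_list(rbind(hor, ver), isolated_nodes = all_nodes)
}

#' Ground-truth covers
#'
#' A cover is a family of node-label sets (communities) that may overlap and
#' need not include every node. `lpam_cover` objects also track the nodes
#' assigned to no community.
#'
#' @param communities list of character vectors of node labels.
#' @param unassigned character vector of labels in no community.
#' @return an object of class `lpam_cover`.
#' @export
lpam_cover <- function(communities, unassigned = character()) {
  communities <- unname(lapply(communities, function(x) unique(as.character(x))))
  structure(list(communities = communities,
                 unassigned = unique(as.character(unassigned))),
            class = "lpam_cover")
}

#' @export
print.lpam_cover <- function(x, ...) {
  cat(sprintf("lpam_cover: %d communities (sizes %s)%s\n",
              length(x$communities),
              paste(vapply(x$communities, length, 1L), collapse = ", "),
              if (length(x$unassigned) > 0L)
                sprintf(", %d unassigned", length(x$unassigned)) else ""))
  invisible(x)
}

# accept either an lpam_cover or a bare list of label vectors
as_cover <- function(x) {
  if (inherits(x, "lpam_cover")) return(x)
  if (is.list(x)) return(lpam_cover(x))
  stop("expected an lpam_cover or a list of node-label vectors")
}

#' Planted-partition benchmark graph
#'
#' `l` groups of `g` nodes each; every within-group pair is an edge with
#' probability `p_in`, every between-group pair with probability `p_out`,
#' all draws independent. The ground truth is the `l` disjoint groups.
#' A special case of [sbm_graph()].
#'
#' @param l number of groups (>= 1).
#' @param g nodes per group (>= 1).
#' @param p_in,p_out edge probabilities; `p_out <= p_in` is expected for a
#'   community structure (violations warn, they are not errors).
#' @param seed integer seed; identical seeds replay identical graphs.
#' @return list with `graph` (an `lpam_graph` over all `l*g` nodes, isolated
#'   nodes included) and `truth` (an [lpam_cover()]).
#' @examples
#' pp <- planted_partition(2, 3, 1, 0, seed = 1)
#' n_edges(pp$graph)  # two disjoint triangles: 6 edges
#' @export
planted_partition <- function(l, g, p_in, p_out, seed = NULL) {
  if (l < 1L || g < 1L) stop("`l` and `g` must be at least 1")
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1)
    stop("edge probabilities must lie in [0, 1]")
  if (p_out > p_in)
    warning("p_out > p_in: between-group pairs are denser than within-group pairs")
  probs <- matrix(p_out, l, l)
  diag(probs) <- p_in
  sbm_graph(rep(g, l), probs, seed = seed)
}

#' Stochastic-block-model benchmark graph
#'
#' Independent Bernoulli edges: a pair of nodes in blocks (r, s) is an edge
#' with probability `probs[r, s]`. Ground truth = the blocks. Node labels are
#' `"b<block>n<index>"`, zero-padded.
#'
#' @param sizes positive integer vector of block sizes.
#' @param probs symmetric matrix of probabilities, one row/column per block.
#' @param seed integer seed for reproducible sampling.
#' @return list with `graph` and `truth`, as in [planted_partition()].
#' @export
sbm_graph <- function(sizes, probs, seed = NULL) {
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("block sizes must be positive")
  nb <- length(sizes)
  probs <- as.matrix(probs)
  if (nrow(probs) != nb || ncol(probs) != nb)
    stop(sprintf("`probs` must be %d x %d to match %d blocks", nb, nb, nb))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (max(abs(probs - t(probs))) > 1e-12)
    warning("`probs` is not symmetric; the upper triangle is used")
  n <- sum(sizes)
  wn <- nchar(as.character(n)); wb <- nchar(as.character(nb))
  block <- rep(seq_len(nb), sizes)
  labels <- sprintf(paste0("b%0", wb, "dn%0", wn, "d"), block, seq_len(n))
  # upper-triangle pairs in fixed (row-major) order so seeds replay exactly
  if (n >= 2L) {
    iu <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    ju <- sequence((n - 1L):1L, from = 2L:n)
    p <- probs[cbind(pmin(block[iu], block[ju]), pmax(block[iu], block[ju]))]
    keep <- with_seed(seed, runif(length(p)) < p)
    pairs <- cbind(labels[iu[keep]], labels[ju[keep]])
  } else {
    pairs <- matrix(character(), ncol = 2L)
  }
  graph <- from_edge_list(pairs, isolated_nodes = labels)
  truth <- lpam_cover(split(labels, block))
  list(graph = graph, truth = truth)
}
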