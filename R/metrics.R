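#' Overlapping normalized mutual information (ONMI)
#'
#' Compares two overlapping covers over a common node universe. Each
#' community is treated as a binary membership variable over the universe.
#' For a community X_k of one cover, the conditional entropy against a
#' community Y_l of the other is computed from the 2x2 joint membership
#' counts, but accepted only under the validity constraint
#' `h(n11) + h(n00) >= h(n01) + h(n10)` (otherwise the unconditional H(X_k)
#' is used); H(X_k|Y) is the minimum over l of the accepted values.
#'
#' * `variant = "lfk"` (default): each community's conditional entropy is
#'   normalized by H(X_k) and averaged;
#'   score = 1 - (mean_k H(X_k|Y)/H(X_k) + mean_l H(Y_l|X)/H(Y_l)) / 2.
#' * `variant = "max"`: the max-normalization
#'   I(X;Y) / max(H(X), H(Y)), with H(X) = sum_k H(X_k) and
#'   I(X;Y) = ((H(X) - H(X|Y)) + (H(Y) - H(Y|X))) / 2.
#'
#' Both variants are symmetric in their arguments, equal 1 on identical
#' covers, and lie in \[0, 1\]; the two normalizations are not comparable
#' with each other. Empty communities are dropped; a community covering the
#' whole universe has zero entropy and contributes a zero normalized term.
#'
#' @param a,b covers: [lpam_cover()] objects or lists of node-label vectors.
#' @param universe character vector of all node labels both covers live on;
#'   defaults to the union of all community members.
#' @param variant `"lfk"` or `"max"`.
#' @return a single number in \[0, 1\].
#' @export
onmi <- function(a, b, universe = NULL, variant = c("lfk", "max")) {
  variant <- match.arg(variant)
  a <- as_cover(a); b <- as_cover(b)
  universe <- resolve_universe(a, b, universe)
  A <- membership_matrix(a, universe)
  B <- membership_matrix(b, universe)
  if (ncol(A) == 0L || ncol(B) == 0L)
    stop("both covers must contain at least one nonempty community")

  N <- length(universe)
  HA <- apply(A, 2L, binary_entropy, N = N)
  HB <- apply(B, 2L, binary_entropy, N = N)
  HA_given_B <- cond_entropy_profile(A, B, N)  # H(X_k | Y), length ncol(A)
  HB_given_A <- cond_entropy_profile(B, A, N)

  if (variant == "lfk") {
    na <- ifelse(HA > 0, HA_given_B / HA, 0)
    nb <- ifelse(HB > 0, HB_given_A / HB, 0)
    1 - (mean(na) + mean(nb)) / 2
  } else {
    I <- ((sum(HA) - sum(HA_given_B)) + (sum(HB) - sum(HB_given_A))) / 2
    denom <- max(sum(HA), sum(HB))
    if (denom == 0) 1 else I / denom
  }
}

# h(w) = -(w/N) log2(w/N), h(0) = 0
hfun <- function(w, N) {
  p <- w / N
  ifelse(w > 0, -p * log2(p), 0)
}

binary_entropy <- function(x, N) {
  n1 <- sum(x)
  hfun(n1, N) + hfun(N - n1, N)
}

# For each column X_k of A: min over columns Y_l of B of H(X_k | Y_l),
# subject to the LFK validity constraint, falling back to H(X_k).
cond_entropy_profile <- function(A, B, N) {
  n11 <- crossprod(A, B)              # both members
  ca <- colSums(A); cb <- colSums(B)
  n10 <- outer(ca, cb, function(x, y) x) - n11   # in X_k only
  n01 <- outer(ca, cb, function(x, y) y) - n11   # in Y_l only
  n00 <- N - n11 - n10 - n01
  joint <- hfun(n11, N) + hfun(n10, N) + hfun(n01, N) + hfun(n00, N)
  HY <- matrix(hfun(cb, N) + hfun(N - cb, N),
               nrow = ncol(A), ncol = ncol(B), byrow = TRUE)
  cond <- joint - HY
  valid <- hfun(n11, N) + hfun(n00, N) >= hfun(n01, N) + hfun(n10, N)
  HX <- hfun(ca, N) + hfun(N - ca, N)
  cond[!valid] <- NA
  out <- apply(cond, 1L, function(row) if (all(is.na(row))) NA else min(row, na.rm = TRUE))
  ifelse(is.na(out), HX, pmin(out, HX))
}

#' Omega index of two covers
#'
#' Chance-corrected agreement of pairwise co-membership multiplicities: for
#' every unordered node pair, count in how many communities of each cover
#' both endpoints sit together; observed agreement is the fraction of pairs
#' with identical counts, expected agreement follows from the marginal count
#' distributions, and omega = (obs - exp) / (1 - exp). Identical covers give
#' 1 (also when obs = exp = 1); the index can be negative.
#'
#' @inheritParams onmi
#' @return a single number <= 1.
#' @export
omega_index <- function(a, b, universe = NULL) {
  a <- as_cover(a); b <- as_cover(b)
  universe <- resolve_universe(a, b, universe)
  N <- length(universe)
  if (N < 2L) stop("omega index needs a universe of at least 2 nodes")
  ta <- pair_comembership_counts(a, universe)
  tb <- pair_comembership_counts(b, universe)
  M <- N * (N - 1) / 2
  obs <- sum(ta == tb) / M
  levels_all <- 0:max(ta, tb)
  ca <- tabulate(ta + 1L, nbins = length(levels_all))
  cb <- tabulate(tb + 1L, nbins = length(levels_all))
  expd <- sum(as.numeric(ca) * as.numeric(cb)) / M^2
  if (abs(1 - expd) < .Machine$double.eps^0.5)
    return(if (abs(obs - 1) < .Machine$double.eps^0.5) 1 else 0)
  (obs - expd) / (1 - expd)
}

# vector over unordered node pairs (i < j in universe order) of the number
# of communities containing both endpoints
pair_comembership_counts <- function(cover, universe) {
  Mm <- membership_matrix(cover, universe, drop_empty = FALSE)
  co <- tcrossprod(Mm)  # co[i, j] = communities containing both i and j
  co[upper.tri(co)]
}

#' Symmetrized best-match F1 between covers
#'
#' For each community of `a`, take the maximum F1 score (harmonic mean of
#' precision and recall of the node sets) against any community of `b`;
#' average over `a`'s communities; do the same in the other direction and
#' average the two means. Identical covers score 1.
#'
#' @inheritParams onmi
#' @return a single number in \[0, 1\].
#' @export
f1_best_match <- function(a, b) {
  a <- as_cover(a); b <- as_cover(b)
  ca <- drop_empty(a$communities)
  cb <- drop_empty(b$communities)
  if (length(ca) == 0L || length(cb) == 0L)
    stop("both covers must contain at least one nonempty community")
  best <- function(from, to) {
    vapply(from, function(x) {
      max(vapply(to, function(y) {
        inter <- length(intersect(x, y))
        if (inter == 0L) return(0)
        2 * inter / (length(x) + length(y))
      }, numeric(1L)))
    }, numeric(1L))
  }
  (mean(best(ca, cb)) + mean(best(cb, ca))) / 2
}

#' Per-cover graph statistics
#'
#' `avg_internal_degree` is the mean over communities of `2 * m_s / n_s`
#' (m_s = edges with both endpoints in the community, n_s = community size).
#' `normalized_cut` is the mean over communities of
#' `cut(S)/vol(S) + cut(S)/(vol(G) - vol(S))`, where `cut(S)` counts edges
#' with exactly one endpoint in S and `vol(S)` is the total degree of S. A
#' community with `vol(S) = 0` or `vol(S) = vol(G)` contributes a zero
#' normalized-cut term (logged via `message`).
#'
#' @param g an [lpam_graph][from_edge_list].
#' @param cover an [lpam_cover()] or list of node-label vectors; empty
#'   communities are dropped with a message.
#' @return list with `avg_internal_degree` and `normalized_cut`.
#' @examples
#' g <- grid_graph(8, 8)
#' quads <- split(g$nodes, list(rep(rep(1:2, each = 4), 8), rep(1:2, each = 32)))
#' cover_stats(g, quads)  # avg internal degree 3, normalized cut ~0.19
#' @export
cover_stats <- function(g, cover) {
  cover <- as_cover(cover)
  comms <- cover$communities
  if (any(lengths(comms) == 0L)) {
    message("dropping ", sum(lengths(comms) == 0L), " empty community(ies)")
    comms <- drop_empty(comms)
  }
  if (length(comms) == 0L) stop("cover has no nonempty communities")
  unknown <- setdiff(unique(unlist(comms)), g$nodes)
  if (length(unknown) > 0L)
    stop("cover members not in graph: ", paste(head(unknown, 5L), collapse = ", "))
  deg <- node_degrees(g)
  volG <- graph_volume(g)
  e1 <- g$nodes[g$edges[, 1L]]
  e2 <- g$nodes[g$edges[, 2L]]
  aid <- ncut <- numeric(length(comms))
  for (i in seq_along(comms)) {
    S <- comms[[i]]
    in1 <- e1 %in% S; in2 <- e2 %in% S
    ms <- sum(in1 & in2)
    cut <- sum(xor(in1, in2))
    volS <- sum(deg[S])
    aid[i] <- 2 * ms / length(S)
    if (volS == 0 || volS == volG) {
      message(sprintf("community %d has vol(S) = %g (vol(G) = %d); its normalized-cut term is defined as 0",
                      i, volS, volG))
      ncut[i] <- 0
    } else {
      ncut[i] <- cut / volS + cut / (volG - volS)
    }
  }
  list(avg_internal_degree = mean(aid), normalized_cut = mean(ncut))
}

drop_empty <- function(comms) comms[lengths(comms) > 0L]

resolve_universe <- function(a, b, universe) {
  if (is.null(universe))
    universe <- union(unlist(a$communities), unlist(b$communities))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("node universe is empty")
  extra <- setdiff(c(unlist(a$communities), unlist(b$communities)), universe)
  if (length(extra) > 0L)
    stop("cover members outside the universe: ", paste(head(extra, 5L), collapse = ", "))
  universe
}

# nodes x communities 0/1 matrix
membership_matrix <- function(cover, universe, drop_empty = TRUE) {
  comms <- cover$communities
  if (drop_empty) comms <- comms[lengths(comms) > 0L]
  M <- matrix(0, length(universe), length(comms))
  rownames(M) <- universe
  for (j in seq_along(comms)) M[match(comms[[j]], universe), j] <- 1
  M
}
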