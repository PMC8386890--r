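# Small graphs used across the suite, built in code.

path3 <- function() from_edge_list(rbind(c("a", "b"), c("b", "c")))
triangle <- function() from_edge_list(rbind(c("a", "b"), c("b", "c"), c("a", "c")))

karate_path <- function() {
  system.file("extdata", "karate.edgelist", package = "lpam", mustWork = TRUE)
}

# random connected simple graph on n nodes (labels x01, x02, ...): a uniform
# random spanning tree plus Bernoulli(p) extra edges
random_connected_graph <- function(n, p = 0.3) {
  stopifnot(n >= 2)
  w <- nchar(as.character(n))
  labels <- sprintf(paste0("x%0", w, "d"), seq_len(n))
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  extra <- t(combn(n, 2L))
  intree <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  keyall <- paste(extra[, 1], extra[, 2])
  extra <- extra[!(keyall %in% intree) & runif(nrow(extra)) < p, , drop = FALSE]
  all_e <- rbind(edges, extra)
  from_edge_list(cbind(labels[all_e[, 1]], labels[all_e[, 2]]))
}

# random symmetric distance-like matrix (zero diagonal); optionally with some
# negative off-diagonal entries, which the solvers must tolerate
random_distance_matrix <- function(m, negatives = FALSE) {
  M <- matrix(runif(m * m, 0.1, 10), m, m)
  if (negatives) {
    mask <- matrix(runif(m * m) < 0.1, m, m)
    M[mask] <- -runif(sum(mask), 0, 0.5)
  }
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

# random cover over a universe: each of k communities is a random nonempty
# subset
random_cover <- function(universe, k) {
  repeat {
    comms <- lapply(seq_len(k), function(i) {
      s <- universe[runif(length(universe)) < 0.5]
      if (length(s) == 0L) universe[sample.int(length(universe), 1L)] else s
    })
    return(lpam_cover(comms))
  }
}
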