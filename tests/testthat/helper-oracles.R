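# Independent slow oracles, written directly from the defining formulas and
# kept free of the package's computational paths.

# Effective resistance as a ratio of Kirchhoff-matrix minors: the determinant
# of the Laplacian with rows/columns {i, j} deleted over the determinant with
# row/column i deleted (= number of spanning trees).
resistance_minor_oracle <- function(g) {
  n <- n_nodes(g)
  A <- matrix(0, n, n)
  A[g$edges] <- 1
  A[g$edges[, c(2, 1), drop = FALSE]] <- 1
  L <- diag(rowSums(A)) - A
  trees <- det(L[-1, -1, drop = FALSE])
  R <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    R[i, j] <- R[j, i] <- det(L[-c(i, j), -c(i, j), drop = FALSE]) / trees
  }
  dimnames(R) <- list(g$nodes, g$nodes)
  R
}

# brute-force k-median: enumerate every k-subset, recompute the assignment
# cost naively, keep the first (lexicographically smallest) optimum
brute_kmedian <- function(D, k, tol = 1e-9) {
  m <- nrow(D)
  sets <- combn(m, k)
  best <- Inf
  best_set <- NULL
  for (s in seq_len(ncol(sets))) {
    meds <- sets[, s]
    cost <- 0
    for (i in seq_len(m)) cost <- cost + min(D[i, meds])
    if (cost < best - tol * (1 + abs(cost))) {
      best <- cost
      best_set <- meds
    }
  }
  list(medoids = best_set, objective = best)
}

# literal-formula ONMI (LFK), computed with explicit loops over community
# pairs and 2x2 contingency tables
onmi_lfk_oracle <- function(a, b, universe) {
  ca <- Filter(length, a$communities)
  cb <- Filter(length, b$communities)
  N <- length(universe)
  h <- function(w) if (w <= 0) 0 else -(w / N) * log2(w / N)
  Hcomm <- function(x) h(length(x)) + h(N - length(x))
  cond_norm <- function(from, to) {
    vals <- numeric(length(from))
    for (k in seq_along(from)) {
      X <- from[[k]]
      HX <- Hcomm(X)
      cands <- c()
      for (l in seq_along(to)) {
        Y <- to[[l]]
        n11 <- length(intersect(X, Y))
        n10 <- length(X) - n11
        n01 <- length(Y) - n11
        n00 <- N - n11 - n10 - n01
        if (h(n11) + h(n00) >= h(n01) + h(n10)) {
          HXY <- h(n11) + h(n10) + h(n01) + h(n00)
          HY <- h(length(Y)) + h(N - length(Y))
          cands <- c(cands, HXY - HY)
        }
      }
      HXgY <- if (length(cands) == 0) HX else min(min(cands), HX)
      vals[k] <- if (HX > 0) HXgY / HX else 0
    }
    mean(vals)
  }
  1 - (cond_norm(ca, cb) + cond_norm(cb, ca)) / 2
}

# literal omega index by explicit enumeration of node pairs
omega_oracle <- function(a, b, universe) {
  N <- length(universe)
  count_pair <- function(cover, u, v) {
    sum(vapply(cover$communities, function(s) (u %in% s) && (v %in% s), TRUE))
  }
  ta <- tb <- c()
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    ta <- c(ta, count_pair(a, universe[i], universe[j]))
    tb <- c(tb, count_pair(b, universe[i], universe[j]))
  }
  M <- length(ta)
  obs <- mean(ta == tb)
  expd <- 0
  for (v in 0:max(ta, tb)) expd <- expd + sum(ta == v) * sum(tb == v) / M^2
  if (abs(1 - expd) < 1e-12) return(if (abs(obs - 1) < 1e-12) 1 else 0)
  (obs - expd) / (1 - expd)
}

# literal best-match F1 with explicit precision/recall
f1_oracle <- function(a, b) {
  ca <- Filter(length, a$communities)
  cb <- Filter(length, b$communities)
  dir <- function(from, to) {
    mean(vapply(from, function(x) {
      max(vapply(to, function(y) {
        tp <- length(intersect(x, y))
        if (tp == 0) return(0)
        prec <- tp / length(y)
        rec <- tp / length(x)
        2 * prec * rec / (prec + rec)
      }, 0))
    }, 0))
  }
  (dir(ca, cb) + dir(cb, ca)) / 2
}
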