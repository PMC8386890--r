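#' Nearest-medoid assignment and k-median objective
#'
#' `assign_to_medoids` maps every point to its nearest medoid, breaking
#' distance ties toward the medoid with the smallest index; a medoid is
#' always assigned to itself (zero self-distance). `kmedian_objective` is the
#' k-median cost: the sum over points of the distance to the assigned medoid.
#'
#' @param D square symmetric distance matrix (zero diagonal; negative
#'   off-diagonal entries are tolerated).
#' @param medoids nonempty vector of point indices.
#' @return `assign_to_medoids`: integer vector of length `nrow(D)` whose i-th
#'   entry is the medoid index point i is assigned to. `kmedian_objective`:
#'   a single number.
#' @export
assign_to_medoids <- function(D, medoids) {
  medoids <- check_medoids(D, medoids)
  sub <- D[, medoids, drop = FALSE]
  # max.col(ties.method = "first") picks the leftmost minimum; columns are in
  # increasing medoid order, so ties break toward the smallest medoid index
  medoids[max.col(-sub, ties.method = "first")]
}

#' @rdname assign_to_medoids
#' @export
kmedian_objective <- function(D, medoids) {
  medoids <- check_medoids(D, medoids)
  sum(do.call(pmin, lapply(medoids, function(j) D[, j])))
}

check_medoids <- function(D, medoids) {
  if (length(medoids) == 0L) stop("medoid set must be nonempty")
  medoids <- as.integer(medoids)
  if (anyNA(medoids) || any(medoids < 1L) || any(medoids > nrow(D)))
    stop("medoid indices out of range")
  sort(unique(medoids))
}

new_kmedian_result <- function(D, medoids, solver_tag, seed = NULL) {
  medoids <- sort(as.integer(medoids))
  labels <- assign_to_medoids(D, medoids)
  structure(list(medoids = medoids,
                 labels = labels,
                 objective = kmedian_objective(D, medoids),
                 solver_tag = solver_tag,
                 seed = seed),
            class = "kmedian_result")
}

#' @export
print.kmedian_result <- function(x, ...) {
  cat(sprintf("kmedian_result (%s): k = %d, objective = %.6g\n",
              x$solver_tag, length(x$medoids), x$objective))
  cat("medoids:", paste(x$medoids, collapse = " "), "\n")
  invisible(x)
}

#' Exact k-median solver
#'
#' Finds a globally optimal set of k medoids minimizing the sum of
#' point-to-nearest-medoid distances, by pruned exhaustive enumeration of all
#' `choose(m, k)` candidate sets (lexicographic order, greedy upper bound,
#' per-point suffix-minimum lower bound). Among optimal sets the
#' lexicographically smallest sorted index tuple is returned. Instances with
#' `choose(m, k)` beyond `budget` candidate evaluations are refused with an
#' explicit error: no integer-programming backend is configured, and an
#' unpruned search of that size would not certify optimality in reasonable
#' time.
#'
#' @inheritParams assign_to_medoids
#' @param k number of medoids, `1 <= k <= nrow(D)`.
#' @param budget maximum number of candidate medoid sets the enumeration may
#'   have to visit (default 1e7).
#' @return an object of class `kmedian_result`: `medoids` (sorted indices),
#'   `labels` (per-point assigned medoid), `objective`, `solver_tag`,
#'   `seed` (NULL for the exact solver).
#' @examples
#' D <- as.matrix(dist(c(0, 1, 2)))
#' solve_exact(D, 1)$medoids   # 2 (the middle point)
#' solve_exact(D, 2)$objective # 1
#' @export
solve_exact <- function(D, k, budget = 1e7) {
  D <- check_distance_matrix(D)
  m <- nrow(D)
  if (k < 1L || k > m) stop(sprintf("k must be in [1, %d], got %s", m, format(k)))
  ncand <- choose(m, k)
  if (ncand > budget)
    stop(sprintf(paste0("exact solver refused: choose(%d, %d) = %.3g candidate sets ",
                        "exceeds the enumeration budget (%.3g) and no ILP backend ",
                        "is available; use solve_clarans() or raise `budget`"),
                 m, k, ncand, budget))
  res <- kmedian_enumerate_cpp(D, as.integer(k))
  new_kmedian_result(D, res$medoids, solver_tag = "exact")
}

#' CLARANS heuristic k-median solver
#'
#' Randomized local search over single-medoid swaps (Ng & Han's CLARANS):
#' from a random initial medoid set, repeatedly sample a random
#' (medoid, non-medoid) swap; accept it on first improvement and reset the
#' neighbour counter; declare a local optimum after `maxneighbor` consecutive
#' non-improving samples. `numlocal` independent restarts are performed and
#' the best local optimum is returned. Fully reproducible from `seed`.
#'
#' @inheritParams solve_exact
#' @param numlocal number of restarts (default 4).
#' @param maxneighbor neighbour samples before declaring a local optimum;
#'   default `max(250, ceiling(0.0125 * k * (m - k)))`.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a `kmedian_result` with `solver_tag = "clarans"`.
#' @export
solve_clarans <- function(D, k, numlocal = 4, maxneighbor = NULL, seed = NULL) {
  D <- check_distance_matrix(D)
  m <- nrow(D)
  if (k < 1L || k > m) stop(sprintf("k must be in [1, %d], got %s", m, format(k)))
  if (is.null(maxneighbor)) maxneighbor <- max(250, ceiling(0.0125 * k * (m - k)))
  if (k == m) return(new_kmedian_result(D, seq_len(m), "clarans", seed = seed))

  best_set <- NULL
  best_obj <- Inf
  with_seed(seed, {
    for (rs in seq_len(numlocal)) {
      cur <- sort(sample.int(m, k))
      cur_obj <- kmedian_objective(D, cur)
      fails <- 0L
      while (fails < maxneighbor) {
        out_pos <- sample.int(k, 1L)
        nonmed <- setdiff(seq_len(m), cur)
        cand_in <- nonmed[sample.int(length(nonmed), 1L)]
        cand <- cur
        cand[out_pos] <- cand_in
        cand_obj <- kmedian_objective(D, cand)
        if (cand_obj < cur_obj - 1e-12 * (1 + abs(cur_obj))) {
          cur <- sort(cand)
          cur_obj <- cand_obj
          fails <- 0L
        } else {
          fails <- fails + 1L
        }
      }
      better <- cur_obj < best_obj - 1e-12 * (1 + abs(best_obj))
      tie <- abs(cur_obj - best_obj) <= 1e-12 * (1 + abs(best_obj))
      if (better || (tie && lex_less(cur, best_set))) {
        best_set <- cur
        best_obj <- cur_obj
      }
    }
  })
  new_kmedian_result(D, best_set, "clarans", seed = seed)
}

# TRUE if sorted integer tuple a precedes b lexicographically
lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  d <- a - b
  nz <- which(d != 0L)
  length(nz) > 0L && d[nz[1L]] < 0L
}

check_distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(!is.finite(D))) stop("distance matrix must be finite")
  D
}
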