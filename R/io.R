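#' Read a graph from an edge-list file
#'
#' One edge per line: two whitespace-separated node labels. Blank lines and
#' lines starting with `#` are ignored. Self-loops and lines with a token
#' count other than two are rejected with the offending line number.
#'
#' @param path path to a UTF-8 edge-list text file.
#' @param isolated_nodes optional extra degree-0 node labels to register.
#' @return an [lpam_graph][from_edge_list].
#' @export
read_edge_list <- function(path, isolated_nodes = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0L) {
    lineno <- which(keep)[bad[1L]]
    stop(sprintf("malformed edge at line %d of %s: expected two tokens, got %d",
                 lineno, path, lengths(toks)[bad[1L]]))
  }
  if (length(toks) == 0L) stop("no edges found in ", path)
  from_edge_list(do.call(rbind, toks), isolated_nodes = isolated_nodes)
}

#' Write a graph as an edge-list file
#'
#' @param g an [lpam_graph][from_edge_list].
#' @param path output path.
#' @return `path`, invisibly. Isolated nodes (if any) are recorded on a
#'   `#nodes:` comment line so the file round-trips.
#' @export
write_edge_list <- function(g, path) {
  lines <- paste(g$nodes[g$edges[, 1L]], g$nodes[g$edges[, 2L]])
  iso <- g$nodes[node_degrees(g) == 0L]
  if (length(iso) > 0L)
    lines <- c(lines, paste("#nodes:", paste(iso, collapse = " ")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read and write covers in community-file format
#'
#' One community per line, space-separated node labels (the common dialect
#' of overlapping-NMI tools). Empty lines inside the community block are
#' kept as empty communities so files round-trip; a trailing
#' `#unassigned: ...` line records nodes in no community; other `#` lines
#' are comments.
#'
#' @param path path to the community file.
#' @return `read_cover`: an [lpam_cover()]. `write_cover`: `path`,
#'   invisibly.
#' @export
read_cover <- function(path) {
  if (!file.exists(path)) stop("community file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  un <- character()
  is_unassigned <- grepl("^#unassigned:", lines)
  if (any(is_unassigned)) {
    payload <- trimws(sub("^#unassigned:", "", lines[is_unassigned]))
    un <- unlist(strsplit(payload[payload != ""], "\\s+"))
  }
  lines <- lines[!is_unassigned & !grepl("^\\s*#", lines)]
  comms <- lapply(lines, function(x) {
    x <- trimws(x)
    if (x == "") character() else strsplit(x, "\\s+")[[1L]]
  })
  lpam_cover(comms, unassigned = un)
}

#' @rdname read_cover
#' @param cover an [lpam_cover()] or list of node-label vectors.
#' @export
write_cover <- function(cover, path) {
  cover <- as_cover(cover)
  lines <- vapply(cover$communities, paste, character(1L), collapse = " ")
  if (length(cover$unassigned) > 0L)
    lines <- c(lines, paste("#unassigned:", paste(cover$unassigned, collapse = " ")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
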