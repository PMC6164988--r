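#' Areal adjacency structure
#'
#' A \code{region_graph} stores the neighborhood structure of a set of
#' areal units: ordered region labels, symmetric irreflexive neighbor sets
#' \eqn{\Omega_i}, and the neighbor cardinalities \eqn{n_{\delta i}} that
#' scale the conditional variance of the intrinsic CAR prior.
#'
#' @param edges a two-column matrix or data frame of region labels, one
#'   undirected edge per row.  One-directional duplicates are merged;
#'   self-loops are an error.
#' @param region_ids optional character vector fixing the region ordering
#'   (and allowing isolated regions); defaults to the sorted labels present
#'   in \code{edges}.
#' @return an object of class \code{region_graph} with components
#'   \code{region_ids}, \code{neighbors} (list of integer index vectors),
#'   \code{n_neighbors}, \code{edge_mat} (two-column integer matrix, each
#'   undirected edge once), \code{n_regions} and \code{connected}.
#' @examples
#' g <- region_graph(rbind(c("A", "B"), c("B", "C")))
#' g$n_neighbors   # 1, 2, 1
#' @export
region_graph <- function(edges, region_ids = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("'edges' must have two columns", call. = FALSE)
  mode(edges) <- "character"
  if (is.null(region_ids)) {
    region_ids <- sort(unique(as.vector(edges)))
  } else {
    region_ids <- as.character(region_ids)
    if (anyDuplicated(region_ids)) stop("duplicate region ids", call. = FALSE)
    unknown <- setdiff(unique(as.vector(edges)), region_ids)
    if (length(unknown))
      stop("edge references unknown region(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- length(region_ids)
  i <- match(edges[, 1], region_ids)
  j <- match(edges[, 2], region_ids)
  if (any(i == j))
    stop("self-loop(s) on region(s): ",
         paste(unique(edges[i == j, 1]), collapse = ", "), call. = FALSE)
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi))
  edge_mat <- cbind(lo, hi)[keep, , drop = FALSE]
  neighbors <- vector("list", n)
  for (k in seq_len(n)) neighbors[[k]] <- integer(0)
  if (nrow(edge_mat)) {
    for (k in seq_len(nrow(edge_mat))) {
      a <- edge_mat[k, 1]; b <- edge_mat[k, 2]
      neighbors[[a]] <- c(neighbors[[a]], b)
      neighbors[[b]] <- c(neighbors[[b]], a)
    }
    neighbors <- lapply(neighbors, sort)
  }
  g <- structure(list(region_ids = region_ids,
                      neighbors = neighbors,
                      n_neighbors = vapply(neighbors, length, integer(1)),
                      edge_mat = edge_mat,
                      n_regions = n),
                 class = "region_graph")
  g$connected <- graph_is_connected(g)
  g
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph:", x$n_regions, "regions,", nrow(x$edge_mat), "edges,",
      if (x$connected) "connected" else "NOT connected", "\n")
  invisible(x)
}

# Breadth-first search from region 1; a graph with no regions is vacuously
# connected, an isolated region makes fitting impossible under ICAR.
graph_is_connected <- function(graph) {
  n <- graph$n_regions
  if (n <= 1) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nb <- graph$neighbors[[cur]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

stop_if_disconnected <- function(graph) {
  if (!graph$connected)
    stop("the region graph is not connected; the intrinsic CAR prior is ",
         "only defined here for connected graphs (split islands into ",
         "separate analyses or amend the adjacency)", call. = FALSE)
  invisible(TRUE)
}

#' Rook-adjacency lattice graph
#'
#' Builds a \code{rows x cols} rectangular lattice with rook (4-neighbor)
#' adjacency.  Used throughout as a desk-scale stand-in for a real county
#' adjacency map (e.g. the 46 counties of a US state): connected, irregular
#' neighbor counts at edges and corners, and arbitrary size.
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @return a \code{\link{region_graph}} with region ids \code{"r<i>c<j>"}
#'   in row-major order.
#' @export
lattice_graph <- function(rows, cols) {
  if (rows < 1 || cols < 1) stop("'rows' and 'cols' must be >= 1", call. = FALSE)
  id <- function(r, c) paste0("r", r, "c", c)
  ids <- as.vector(t(outer(seq_len(rows), seq_len(cols), id)))
  edges <- NULL
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) edges <- rbind(edges, c(id(r, c), id(r, c + 1)))
    if (r < rows) edges <- rbind(edges, c(id(r, c), id(r + 1, c)))
  }
  if (is.null(edges)) {
    structure(list(region_ids = ids, neighbors = list(integer(0)),
                   n_neighbors = 0L,
                   edge_mat = matrix(integer(0), 0, 2),
                   n_regions = 1L, connected = TRUE),
              class = "region_graph")
  } else region_graph(edges, region_ids = ids)
}

# n x n binary adjacency matrix (dense; areal maps are small).
adjacency_matrix <- function(graph) {
  n <- graph$n_regions
  W <- matrix(0, n, n)
  if (nrow(graph$edge_mat)) {
    W[graph$edge_mat] <- 1
    W[graph$edge_mat[, 2:1, drop = FALSE]] <- 1
  }
  W
}

# Graph Laplacian Q = D - W; the ICAR precision is Q / sigma_u^2.
graph_laplacian <- function(graph) {
  diag(graph$n_neighbors) - adjacency_matrix(graph)
}

# Moore-Penrose pseudo-inverse of a symmetric PSD matrix; the constrained
# ICAR covariance is sigma_u^2 * pinv(Laplacian).
pinv_sym <- function(M) {
  eg <- eigen(M, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  V <- eg$vectors[, pos, drop = FALSE]
  V %*% (t(V) / eg$values[pos])
}

# Greedy proper coloring; regions in one color class share no edge, so the
# sampler can propose Metropolis updates for a whole class at once.
graph_coloring <- function(graph) {
  n <- graph$n_regions
  color <- integer(n)
  for (i in order(graph$n_neighbors, decreasing = TRUE)) {
    used <- color[graph$neighbors[[i]]]
    color[i] <- setdiff(seq_len(n), used)[1]
  }
  split(seq_len(n), color)
}

#' Read an adjacency file
#'
#' Reads either a whitespace-delimited edge list (two region labels per
#' line, \code{#} comments allowed) or a GAL-style neighbor file (a header
#' line whose last field is the region count, then alternating
#' \code{id n_neighbors} / neighbor-list lines).  The format is detected
#' from the file structure.  One-directional edges are symmetrized with a
#' warning; self-loops and references to unknown regions are errors.
#'
#' @param path path to the adjacency file.
#' @param format \code{"auto"} (default), \code{"edgelist"} or \code{"gal"}.
#' @return a \code{\link{region_graph}}.
#' @export
read_adjacency <- function(path, format = c("auto", "edgelist", "gal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("adjacency file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("adjacency file is empty: ", path, call. = FALSE)
  toks <- strsplit(lines, "[[:space:]]+")
  if (format == "auto") {
    # GAL headers are numeric and the file is not a plain two-token-per-line
    # edge list; a two-region GAL file still parses identically either way.
    first_n <- suppressWarnings(as.numeric(toks[[1]][length(toks[[1]])]))
    format <- if (!is.na(first_n) && length(toks) > 1 &&
                  any(lengths(toks) != 2)) "gal" else "edgelist"
    if (!is.na(first_n) && length(toks) == 2 * first_n + 1) format <- "gal"
  }
  if (format == "edgelist") {
    if (any(lengths(toks) != 2))
      stop("edge list lines must contain exactly two region labels", call. = FALSE)
    region_graph(do.call(rbind, toks))
  } else {
    n <- as.integer(toks[[1]][length(toks[[1]])])
    if (is.na(n) || length(toks) < n + 1)
      stop("malformed GAL file: header count does not match body", call. = FALSE)
    ids <- character(n); nb <- vector("list", n)
    k <- 2
    for (r in seq_len(n)) {
      hdr <- toks[[k]]
      if (length(hdr) != 2)
        stop("malformed GAL record at line ", k, call. = FALSE)
      ids[r] <- hdr[1]
      deg <- as.integer(hdr[2])
      if (deg > 0) {
        nb[[r]] <- toks[[k + 1]]
        if (length(nb[[r]]) != deg)
          stop("GAL record for region ", ids[r], " promises ", deg,
               " neighbors but lists ", length(nb[[r]]), call. = FALSE)
        k <- k + 2
      } else {
        # blank neighbor lines were stripped above, so a zero-degree record
        # occupies a single line
        nb[[r]] <- character(0)
        k <- k + 1
      }
    }
    edges <- NULL
    for (r in seq_len(n)) if (length(nb[[r]]))
      edges <- rbind(edges, cbind(ids[r], nb[[r]]))
    if (is.null(edges)) stop("GAL file lists no edges", call. = FALSE)
    # detect one-directional listings before region_graph merges them
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (any(table(key) == 1))
      warning("one-directional neighbor listings were symmetrized", call. = FALSE)
    region_graph(edges, region_ids = ids)
  }
}

#' Write a region graph as an edge list
#'
#' @param graph a \code{\link{region_graph}}.
#' @param path output file path.
#' @export
write_adjacency <- function(graph, path) {
  ids <- graph$region_ids
  writeLines(paste(ids[graph$edge_mat[, 1]], ids[graph$edge_mat[, 2]]), path)
  invisible(path)
}
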