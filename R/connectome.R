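#' Connectome container
#'
#' Bundles a symmetric anatomical connection probability (ACP) matrix, the
#' corresponding inter-region fiber lengths (mm) and region metadata into a
#' validated `connectome` object. ACP values quantify the evidence for a
#' white-matter connection between two gray-matter regions; self-connections
#' are fixed at 1 and fiber lengths on the diagonal at 0.
#'
#' @param acp N x N numeric matrix of connection probabilities in \[0, 1\].
#'   Must be symmetric up to 1e-9 (it is symmetrized by averaging) and have
#'   unit diagonal.
#' @param fiber_length N x N numeric matrix of connection path lengths in mm
#'   (0 where there is no connection). Symmetric, non-negative, zero diagonal.
#' @param labels character vector of N unique region names. Defaults to
#'   `"R1".."RN"`.
#' @param coords optional N x 3 matrix of region centroid coordinates (mm).
#' @return An object of class `connectome`: a list with elements `acp`,
#'   `fiber_length`, `labels` and `coords`.
#' @export
connectome <- function(acp, fiber_length, labels = NULL, coords = NULL) {
  acp <- as.matrix(acp)
  fiber_length <- as.matrix(fiber_length)
  if (!is.numeric(acp) || !is.numeric(fiber_length)) {
    stop("acp and fiber_length must be numeric matrices")
  }
  n <- nrow(acp)
  if (ncol(acp) != n) stop("acp must be square")
  if (any(dim(fiber_length) != c(n, n))) {
    stop("dimension mismatch between acp and fiber_length")
  }
  if (anyNA(acp) || anyNA(fiber_length)) stop("non-numeric or missing cells")
  if (any(acp < 0 | acp > 1)) stop("acp value out of range [0, 1]")
  if (any(fiber_length < 0)) stop("fiber_length must be non-negative")
  acp <- symmetrize(acp, "acp")
  fiber_length <- symmetrize(fiber_length, "fiber_length")
  diag(acp) <- 1
  diag(fiber_length) <- 0
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have one entry per region")
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3) {
      stop("coords must be an N x 3 matrix")
    }
  }
  dimnames(acp) <- dimnames(fiber_length) <- list(labels, labels)
  structure(list(acp = acp, fiber_length = fiber_length,
                 labels = labels, coords = coords),
            class = "connectome")
}

symmetrize <- function(m, what) {
  asym <- max(abs(m - t(m)))
  if (asym > 1e-9) stop(sprintf("%s matrix is asymmetric (max |m - t(m)| = %g)",
                                what, asym))
  (m + t(m)) / 2
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$labels)
  ne <- sum(x$acp[upper.tri(x$acp)] > 0)
  cat(sprintf("connectome: %d regions, %d connections, mean off-diagonal ACP %.3f\n",
              n, ne, mean(x$acp[upper.tri(x$acp)][x$acp[upper.tri(x$acp)] > 0])))
  invisible(x)
}

#' Number of regions in a connectome
#' @param conn a `connectome` object.
#' @return integer region count.
#' @export
n_regions <- function(conn) length(conn$labels)

#' Read a connectome from delimited text files
#'
#' ACP and fiber-length matrices are plain numeric TSV (no header); labels
#' one region name per line. The ACP matrix is validated (values in \[0,1\],
#' symmetry up to 1e-9 with symmetrization by averaging, unit diagonal).
#'
#' @param path path to the ACP matrix TSV.
#' @param lengths_path path to the fiber-length matrix TSV (mm).
#' @param labels_path optional path to a region-label file (one per line).
#' @return a validated [connectome()] object.
#' @export
read_connectome <- function(path, lengths_path, labels_path = NULL) {
  acp <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  len <- as.matrix(read.table(lengths_path, sep = "\t", header = FALSE))
  if (!is.numeric(acp) || !is.numeric(len)) stop("non-numeric cells in matrix file")
  labels <- NULL
  if (!is.null(labels_path)) labels <- readLines(labels_path)
  connectome(acp, len, labels = labels)
}

#' Write a connectome to delimited text files
#'
#' @param conn a `connectome` object.
#' @param path,lengths_path,labels_path destination files (TSV matrices,
#'   one label per line).
#' @return invisibly, `conn`.
#' @export
write_connectome <- function(conn, path, lengths_path, labels_path = NULL) {
  write.table(conn$acp, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  write.table(conn$fiber_length, lengths_path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  if (!is.null(labels_path)) writeLines(conn$labels, labels_path)
  invisible(conn)
}

#' Edge length for effective-distance paths
#'
#' Converts a connection probability into a path-edge length. The default
#' `"log"` convention, `1 - log(p)`, makes a certain connection (p = 1) one
#' unit long and rare connections long, reproducing the effective-distance
#' semantics used for epidemic arrival times on networks. Alternatives:
#' `"inv"` = `1/p`, `"neglog"` = `-log(p)`.
#'
#' @param p connection probabilities in (0, 1].
#' @param transform one of `"log"`, `"inv"`, `"neglog"`.
#' @return numeric edge lengths.
#' @export
acp_edge_length <- function(p, transform = c("log", "inv", "neglog")) {
  transform <- match.arg(transform)
  switch(transform,
         log = 1 - log(p),
         inv = 1 / p,
         neglog = -log(p))
}

#' Effective anatomical distance to an outbreak set
#'
#' Shortest-path distance from every region to the nearest source region,
#' with each connection of probability p contributing an edge length given by
#' [acp_edge_length()] (default `1 - log(p)`). Self-loops are excluded;
#' sources have distance 0; unreachable regions get `Inf`.
#'
#' @param conn a `connectome`.
#' @param sources non-empty integer vector of source (outbreak) region indices.
#' @param transform edge-length convention, see [acp_edge_length()].
#' @return numeric vector of N non-negative distances.
#' @export
effective_distance <- function(conn, sources, transform = c("log", "inv", "neglog")) {
  n <- n_regions(conn)
  sources <- as.integer(sources)
  if (length(sources) == 0) stop("sources must be non-empty")
  if (any(sources < 1 | sources > n)) stop("source index out of range")
  transform <- match.arg(transform)
  offdiag <- conn$acp
  diag(offdiag) <- 0 # self-loops never enter paths
  idx <- which(upper.tri(offdiag) & offdiag > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, t(idx))
    igraph::E(g)$weight <- acp_edge_length(offdiag[idx], transform)
  }
  d <- igraph::distances(g, v = sources, weights = igraph::E(g)$weight)
  apply(d, 2, min)
}

#' Weighted connectivity degree
#'
#' Sum of off-diagonal ACP values per region (self-connections excluded),
#' the "hubness" measure used when relating connectivity to arrival times.
#'
#' @param conn a `connectome`.
#' @return numeric vector of N non-negative degrees.
#' @export
weighted_degree <- function(conn) {
  rowSums(conn$acp) - diag(conn$acp)
}

#' Degree-preserving connectome randomization
#'
#' Null model that rewires the binarized topology with Maslov-Sneppen
#' double-edge swaps (preserving the binary degree sequence exactly), then
#' reassigns the original multiset of edge weights to the new edges by rank:
#' the largest weights go to the edges whose endpoints had the largest
#' original strengths, so node strengths are approximately preserved. Fiber
#' lengths travel with their paired weight. The diagonal stays at 1.
#'
#' @param conn a `connectome`.
#' @param rng_seed integer seed; the same seed reproduces the same rewiring.
#' @param n_swaps number of attempted double-edge swaps (default 10 per edge).
#' @return a rewired `connectome`.
#' @export
randomize_connectome <- function(conn, rng_seed, n_swaps = NULL) {
  n <- n_regions(conn)
  a <- conn$acp
  diag(a) <- 0
  ut <- upper.tri(a)
  idx <- which(ut & a > 0, arr.ind = TRUE)
  ne <- nrow(idx)
  if (ne < 2) stop("graph too small/dense to swap (need at least 2 edges)")
  if (is.null(n_swaps)) n_swaps <- 10L * ne
  if (n_swaps < 1) stop("n_swaps must be >= 1")
  sel <- ut & a > 0
  weights <- a[sel]
  lengths <- conn$fiber_length[sel]
  strength <- rowSums(a)

  g <- igraph::graph_from_edgelist(as.matrix(idx), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  newg <- with_rng_seed(rng_seed, {
    igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
  })
  el <- igraph::as_edgelist(newg, names = FALSE)
  el <- t(apply(el, 1, sort))

  # rank-match: heaviest weights on edges with largest combined endpoint
  # strength in the original network
  score <- strength[el[, 1]] + strength[el[, 2]]
  ord_edges <- order(score, decreasing = TRUE)
  ord_w <- order(weights, decreasing = TRUE)
  new_acp <- matrix(0, n, n)
  new_len <- matrix(0, n, n)
  for (k in seq_len(ne)) {
    e <- el[ord_edges[k], ]
    w <- weights[ord_w[k]]
    l <- lengths[ord_w[k]]
    new_acp[e[1], e[2]] <- new_acp[e[2], e[1]] <- w
    new_len[e[1], e[2]] <- new_len[e[2], e[1]] <- l
  }
  diag(new_acp) <- 1
  connectome(new_acp, new_len, labels = conn$labels, coords = conn$coords)
}
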