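#' Construct a region adjacency structure
#'
#' Binary, symmetric, zero-diagonal contiguity matrix used both for the
#' intrinsic CAR / MCAR priors and as the spatial weights of Moran's I.
#'
#' @param regions character vector of region labels.
#' @param W binary symmetric matrix with zero diagonal (or an object
#'   coercible to one), rows/columns in the order of \code{regions}.
#' @return An object of class \code{adjacency}: list with \code{regions},
#'   \code{W} (0/1 matrix), \code{edges} (two-column matrix of pair indices,
#'   a < b), and \code{connected} (logical).
#' @export
adjacency <- function(regions, W) {
  regions <- as.character(regions)
  N <- length(regions)
  W <- matrix(as.numeric(W), N, N)
  if (any(W != 0 & W != 1)) stop("W must be binary 0/1")
  if (any(diag(W) != 0)) stop("self-loop: diagonal of W must be zero")
  if (!isTRUE(all.equal(W, t(W)))) stop("W must be symmetric")
  dimnames(W) <- list(regions, regions)
  edges <- which(upper.tri(W) & W == 1, arr.ind = TRUE)
  colnames(edges) <- c("a", "b")
  structure(list(regions = regions, W = W, edges = edges,
                 connected = is_connected(W)),
            class = "adjacency")
}

# breadth-first search connectivity; isolated vertices count as disconnected
is_connected <- function(W) {
  N <- nrow(W)
  if (N == 1L) return(TRUE)
  seen <- logical(N); seen[1L] <- TRUE; frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(W[frontier, , drop = FALSE] == 1) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %d regions, %d edges, %sconnected\n",
              length(x$regions), nrow(x$edges), if (x$connected) "" else "NOT "))
  invisible(x)
}

#' Read an adjacency structure from a GAL file or CSV edge list
#'
#' GAL is the standard plain-text spatial-weights format: a header line whose
#' last-but-? field is the region count, then for each region a line
#' \code{label degree} followed by a line listing its neighbours. CSV edge
#' lists have columns \code{region_a,region_b}, one undirected edge per row;
#' a one-directional edge list is symmetrized with a warning.
#'
#' @param path file path; format chosen by extension (".gal" vs anything else
#'   = CSV edge list).
#' @param regions declared region set; labels in the file outside this set
#'   are errors. Defaults to the labels found in the file.
#' @return An \code{\link{adjacency}}.
#' @export
read_adjacency <- function(path, regions = NULL) {
  if (grepl("\\.gal$", path, ignore.case = TRUE)) {
    adj <- read_gal(path)
  } else {
    adj <- read_edge_csv(path)
  }
  if (!is.null(regions)) {
    unknown <- setdiff(adj$regions, regions)
    if (length(unknown))
      stop("adjacency refers to unknown region(s): ", paste(unknown, collapse = ", "))
    # re-index onto the declared set (regions absent from the file get no edges)
    N <- length(regions)
    W <- matrix(0, N, N, dimnames = list(regions, regions))
    W[adj$regions, adj$regions] <- adj$W
    adj <- adjacency(regions, W)
  }
  adj
}

read_gal <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  hdr <- strsplit(lines[1L], "[[:space:]]+")[[1L]]
  # GeoDa headers are "0 N shapefile key"; plain GAL is just "N"
  N <- as.integer(if (length(hdr) >= 2L) hdr[2L] else hdr[1L])
  labels <- character(N)
  nbrs <- vector("list", N)
  at <- 2L
  for (i in seq_len(N)) {
    head_i <- strsplit(lines[at], "[[:space:]]+")[[1L]]
    labels[i] <- head_i[1L]
    deg <- as.integer(head_i[length(head_i)])
    nbrs[[i]] <- if (deg > 0L) strsplit(lines[at + 1L], "[[:space:]]+")[[1L]] else character(0)
    if (length(nbrs[[i]]) != deg)
      stop(sprintf("GAL: region %s declares degree %d but lists %d neighbours",
                   labels[i], deg, length(nbrs[[i]])))
    at <- at + 2L
  }
  W <- matrix(0, N, N, dimnames = list(labels, labels))
  for (i in seq_len(N)) {
    unknown <- setdiff(nbrs[[i]], labels)
    if (length(unknown)) stop("GAL: unknown neighbour label(s): ",
                              paste(unknown, collapse = ", "))
    W[labels[i], nbrs[[i]]] <- 1
  }
  if (any(diag(W) != 0)) stop("GAL: self-loop found")
  if (!isTRUE(all.equal(W, t(W)))) {
    warning("asymmetric neighbour lists; symmetrizing")
    W <- pmax(W, t(W))
  }
  adjacency(labels, W)
}

read_edge_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("region_a", "region_b") %in% names(d)))
    stop("edge list needs columns region_a,region_b")
  if (any(d$region_a == d$region_b)) stop("self-loop in edge list")
  labels <- unique(c(d$region_a, d$region_b))
  N <- length(labels)
  W <- matrix(0, N, N, dimnames = list(labels, labels))
  W[cbind(d$region_a, d$region_b)] <- 1
  if (!isTRUE(all.equal(W, t(W), check.attributes = FALSE))) {
    W <- pmax(W, t(W))
  }
  adjacency(labels, W)
}

#' Default contiguity for the seven-province study design
#'
#' First-order land contiguity among Jiangsu, Shandong, Henan, Hubei, Hunan,
#' Guangxi and Guizhou: a connected graph with 7 edges (mean degree 2).
#'
#' @return An \code{\link{adjacency}} over the seven provinces.
#' @export
default_adjacency <- function() {
  prov <- c("Jiangsu", "Shandong", "Henan", "Hubei", "Hunan", "Guangxi", "Guizhou")
  edges <- rbind(c("Jiangsu", "Shandong"), c("Shandong", "Henan"),
                 c("Henan", "Hubei"), c("Hubei", "Hunan"),
                 c("Hunan", "Guangxi"), c("Hunan", "Guizhou"),
                 c("Guangxi", "Guizhou"))
  W <- matrix(0, 7, 7, dimnames = list(prov, prov))
  W[edges] <- 1
  W <- pmax(W, t(W))
  adjacency(prov, W)
}
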