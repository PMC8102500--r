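#' Connected-component labeling in 2D and 3D
#'
#' Labels the foreground (non-zero) voxels of a binary 2D matrix or 3D
#' array into connected components. Default connectivity is 8-neighbor in
#' 2D and 26-neighbor in 3D; 4-neighbor (2D) and 6-neighbor (3D) are also
#' supported. Components are numbered 1..n in order of first appearance in
#' column-major raster order, so labeling is deterministic.
#'
#' Adjacency is resolved as a graph problem: foreground voxels are
#' vertices, neighboring foreground pairs are edges, and components are
#' read off the graph.
#'
#' @param mask logical or numeric matrix / 3D array; non-zero = foreground.
#' @param connectivity 4 or 8 for 2D input, 6 or 26 for 3D input. `NULL`
#'   picks the default for the dimensionality.
#' @return integer array of the same shape; 0 background, 1..n components.
#' @examples
#' m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
#' max(label_components(m))               # 1: diagonal touch, 8-connected
#' max(label_components(m, connectivity = 4))  # 2
#' @export
label_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  nd <- length(d)
  if (!nd %in% c(2, 3)) stop("mask must be 2D or 3D", call. = FALSE)
  if (is.null(connectivity)) connectivity <- if (nd == 2) 8 else 26
  offsets <- neighbor_offsets(nd, connectivity)

  fg <- which(mask != 0)
  labels <- array(0L, dim = d)
  if (length(fg) == 0) return(labels)

  idx <- array(0L, dim = d)
  idx[fg] <- seq_along(fg)
  coords <- arrayInd(fg, d)

  edges <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    off <- offsets[k, ]
    nc <- sweep(coords, 2, off, `+`)
    ok <- rep(TRUE, nrow(nc))
    for (j in seq_len(nd)) ok <- ok & nc[, j] >= 1 & nc[, j] <= d[j]
    if (!any(ok)) next
    lin <- nc[ok, 1]
    mult <- 1
    for (j in 2:nd) {
      mult <- mult * d[j - 1]
      lin <- lin + (nc[ok, j] - 1) * mult
    }
    nb <- idx[lin]
    keep <- nb > 0L
    if (!any(keep)) next
    edges[[k]] <- cbind(idx[fg[ok]][keep], nb[keep])
  }
  edges <- do.call(rbind, edges)

  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  membership <- igraph::components(g)$membership
  labels[fg] <- match(membership, unique(membership))
  labels
}

# Half-neighborhood offsets (lexicographically positive), sufficient for
# undirected adjacency.
neighbor_offsets <- function(nd, connectivity) {
  if (nd == 2) {
    if (connectivity == 4) return(rbind(c(1, 0), c(0, 1)))
    if (connectivity == 8) return(rbind(c(1, 0), c(0, 1), c(1, 1), c(-1, 1)))
    stop("2D connectivity must be 4 or 8", call. = FALSE)
  }
  if (connectivity == 6) {
    return(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  }
  if (connectivity == 26) {
    all <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    colnames(all) <- NULL
    keep <- apply(all, 1, function(v) {
      nz <- which(v != 0)
      length(nz) > 0 && v[nz[length(nz)]] > 0  # lexicographically positive half
    })
    half <- all[keep, , drop = FALSE]
    # half must contain exactly 13 of the 26 neighbors
    stopifnot(nrow(half) == 13)
    return(half)
  }
  stop("3D connectivity must be 6 or 26", call. = FALSE)
}

#' Per-label sizes of a label array
#'
#' @param labels integer array from [label_components] or [segment_objects].
#' @return named integer vector, names = label ids, values = voxel counts.
#' @export
label_sizes <- function(labels) {
  tab <- table(labels[labels > 0])
  stats::setNames(as.integer(tab), names(tab))
}
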