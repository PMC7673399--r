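#' @include AllClasses.R
NULL

#' Build a spatial skeleton graph
#'
#' @param edges integer `2 x E` matrix (or E x 2) of 1-based undirected
#'   edges; self-edges and duplicates are rejected.
#' @param V number of nodes.
#' @param centerIndex 1-based index of the body-center joint used for the
#'   centripetal/centrifugal ordering (default 1 = SpineBase).
#' @return a [SkeletonGraph-class].
#' @export
#' @examples
#' g <- buildSkeletonGraph(kinectEdges(), 25, 1)
buildSkeletonGraph <- function(edges, V, centerIndex = 1L) {
  edges <- as.matrix(edges)
  if (nrow(edges) != 2L && ncol(edges) == 2L) edges <- t(edges)
  storage.mode(edges) <- "integer"
  methods::new("SkeletonGraph", V = as.integer(V), edges = edges,
               centerIndex = as.integer(centerIndex))
}

#' Binary adjacency matrix of a skeleton graph
#'
#' @param graph a [SkeletonGraph-class].
#' @return symmetric `V x V` 0/1 matrix with zero diagonal.
#' @export
adjacencyMatrix <- function(graph) {
  a <- matrix(0, graph@V, graph@V)
  e <- graph@edges
  if (ncol(e) > 0) {
    a[cbind(e[1L, ], e[2L, ])] <- 1
    a[cbind(e[2L, ], e[1L, ])] <- 1
  }
  a
}

# Breadth-first hop distances from `from`; unreachable nodes get Inf.
bfsDistances <- function(graph, from = graph@centerIndex) {
  a <- adjacencyMatrix(graph)
  d <- rep(Inf, graph@V)
  d[from] <- 0
  frontier <- from
  level <- 0
  while (length(frontier) > 0) {
    level <- level + 1
    nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 & !is.finite(d))
    d[nxt] <- level
    frontier <- nxt
  }
  d
}

#' Induced key-point subgraph with bridging
#'
#' Takes the induced subgraph on a joint subset (keeping only bones with
#' both endpoints in the subset) and adds the configured bridge edges so
#' that chains whose intermediate joints were filtered out stay connected.
#' Node indices are remapped to `1..|subset|` in ascending original order.
#'
#' @param graph a [SkeletonGraph-class] on the full joint set.
#' @param subset integer vector of retained 1-based joint indices.
#' @param bridges integer `2 x B` matrix of extra edges in the original
#'   indexing (default [defaultJointBridges()]); bridges whose endpoints are
#'   not both retained are ignored.
#' @return a [SkeletonGraph-class] on the remapped subset.
#' @export
inducedSkeletonGraph <- function(graph, subset = defaultJointSubset(),
                                 bridges = defaultJointBridges()) {
  subset <- sort(unique(as.integer(subset)))
  if (any(subset < 1L | subset > graph@V)) stop("subset indices out of range")
  keepEdge <- function(e) e[1L, ] %in% subset & e[2L, ] %in% subset
  e <- graph@edges[, keepEdge(graph@edges), drop = FALSE]
  if (!is.null(bridges) && length(bridges)) {
    bridges <- as.matrix(bridges)
    if (nrow(bridges) != 2L) bridges <- t(bridges)
    b <- bridges[, keepEdge(bridges), drop = FALSE]
    if (ncol(b)) e <- cbind(e, b)
  }
  remap <- match(e, subset)
  dim(remap) <- dim(e)
  center <- match(graph@centerIndex, subset)
  if (is.na(center)) center <- 1L
  buildSkeletonGraph(remap, length(subset), center)
}

#' Symmetric degree normalization of an adjacency mask
#'
#' Returns `Lambda^{-1/2} %*% mask %*% Lambda^{-1/2}` where `Lambda` is the
#' diagonal degree matrix. For the spatial-configuration partition the
#' degrees are computed once from the full `A + I` and shared by all three
#' subset masks; when `degrees` is omitted they default to the row sums of
#' `mask` itself. Zero-degree rows are guarded and yield zero rows.
#'
#' @param mask nonnegative square matrix.
#' @param degrees optional degree vector (row sums of the full `A + I`).
#' @return normalized matrix of the same shape.
#' @export
#' @examples
#' normalizeAdjacency(matrix(1, 2, 2))  # all entries 0.5
normalizeAdjacency <- function(mask, degrees = NULL) {
  stopifnot(is.matrix(mask), nrow(mask) == ncol(mask), all(mask >= 0))
  if (is.null(degrees)) degrees <- rowSums(mask)
  s <- ifelse(degrees > 0, 1 / sqrt(degrees), 0)
  mask * outer(s, s)
}

#' Spatial-configuration partition of the skeleton graph
#'
#' Splits each node's neighbourhood (including the node itself through the
#' self-connection matrix I) into three subsets: the root node itself; the
#' centripetal group, nodes graph-closer to the body center than the root;
#' and the centrifugal group, nodes farther from the center. Neighbours at
#' equal distance are assigned to the centripetal subset (deterministic tie
#' rule). Distances are hop counts to the center joint on the template
#' skeleton, making the partition static across frames. Each binary mask is
#' then degree-normalized with the degree matrix of the full `A + I`.
#'
#' @param graph a connected [SkeletonGraph-class].
#' @return a [PartitionedAdjacency-class].
#' @export
partitionSpatialConfiguration <- function(graph) {
  v <- graph@V
  a <- adjacencyMatrix(graph)
  d <- bfsDistances(graph)
  if (any(!is.finite(d)))
    stop("graph is disconnected; nodes unreachable from center: ",
         paste(which(!is.finite(d)), collapse = ", "))
  masks <- array(0, c(v, v, 3L))
  masks[, , 1L] <- diag(v)
  # mask[i, j]: neighbour j of root node i
  dj <- matrix(d, v, v, byrow = TRUE)   # distance of the neighbour j
  di <- matrix(d, v, v)                 # distance of the root i
  masks[, , 2L] <- a * (dj <= di)       # centripetal (ties included)
  masks[, , 3L] <- a * (dj > di)        # centrifugal
  degrees <- rowSums(a) + 1             # degrees of A + I
  normalized <- lapply(1:3, function(k)
    normalizeAdjacency(matrix(masks[, , k], v, v), degrees))
  methods::new("PartitionedAdjacency", masks = masks,
               normalized = normalized, degrees = degrees,
               centerIndex = graph@centerIndex)
}
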