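## Icosphere hierarchy: construction, one-ring topology, pooling maps.

## Base icosahedron with the canonical vertex/face ordering used throughout.
## Faces are counter-clockwise as seen from outside the sphere.
baseIcosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12,  6), c(1,  6,  2), c(1,  2,  8), c(1,  8, 11), c(1, 11, 12),
    c(2,  6, 10), c(6, 12,  5), c(12, 11, 3), c(11, 8,  7), c(8,  2,  9),
    c(4, 10,  5), c(4,  5,  3), c(4,  3,  7), c(4,  7,  9), c(4,  9, 10),
    c(5, 10,  6), c(3,  5, 12), c(7,  3, 11), c(9,  7,  8), c(10, 9,  2))
  storage.mode(f) <- "integer"
  ## enforce outward CCW orientation
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    n <- crossProd3(b - a, c3 - a)
    if (sum(n * (a + b + c3)) < 0) f[i, ] <- f[i, c(1L, 3L, 2L)]
  }
  list(vertices = v, faces = f)
}

crossProd3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Unique undirected edges of a face matrix, sorted lexicographically by
## (min index, max index) -- the canonical midpoint order of a subdivision.
sortedEdges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

## One 1-to-4 subdivision step; midpoints are appended after the parent
## vertices in sorted parent-edge order, then projected to the unit sphere.
subdivideOnce <- function(vertices, faces) {
  V <- nrow(vertices)
  edges <- sortedEdges(faces)
  mid <- vertices[edges[, 1], ] + vertices[edges[, 2], ]
  mid <- mid / sqrt(rowSums(mid^2))
  ## midpoint index lookup by edge key
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  midIndex <- structure(V + seq_len(nrow(edges)), names = key(edges[, 1], edges[, 2]))
  v1 <- faces[, 1]; v2 <- faces[, 2]; v3 <- faces[, 3]
  m12 <- midIndex[key(v1, v2)]
  m23 <- midIndex[key(v2, v3)]
  m31 <- midIndex[key(v3, v1)]
  newFaces <- rbind(
    cbind(v1, m12, m31),
    cbind(v2, m23, m12),
    cbind(v3, m31, m23),
    cbind(m12, m23, m31))
  dimnames(newFaces) <- NULL
  storage.mode(newFaces) <- "integer"
  list(vertices = rbind(vertices, mid), faces = newFaces)
}

## CCW one-ring: order neighbors by angle in the tangent plane at each
## vertex, with a right-handed frame whose normal points outward; start at
## the lowest-index neighbor so the ordering is canonical.
buildOneRing <- function(vertices, faces) {
  V <- nrow(vertices)
  nbr <- vector("list", V)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)],
             faces[, c(2, 1)], faces[, c(3, 2)], faces[, c(1, 3)])
  sp <- split(e[, 2], e[, 1])
  for (v in seq_len(V)) {
    u <- sort(unique(sp[[as.character(v)]]))
    p <- vertices[v, ]
    ## tangent frame (right-handed with outward normal p)
    ref <- if (abs(p[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- crossProd3(ref, p); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- crossProd3(p, e1)
    d <- vertices[u, , drop = FALSE] - matrix(p, length(u), 3, byrow = TRUE)
    ang <- atan2(d %*% e2, d %*% e1)
    ord <- order(ang)
    u <- u[ord]
    k <- which.min(u)
    nbr[[v]] <- as.integer(u[c(seq(k, length(u)), seq_len(k - 1))])
  }
  nbr
}

.meshCache <- new.env(parent = emptyenv())

#' Build an icosphere mesh
#'
#' Constructs the subdivided icosahedron at the requested level with the
#' canonical vertex ordering: the 12 base vertices first, then the edge
#' midpoints of each successive subdivision appended in sorted parent-edge
#' order. This makes every coarser mesh an index prefix of every finer one.
#' Meshes are memoised in-session by level, and rebuilding is bit-identical.
#'
#' @param level non-negative integer subdivision level. Levels above 7
#'   (163,842 vertices) are rejected as impractical.
#' @return a \linkS4class{SphereMesh}.
#' @examples
#' m <- buildIcosphere(2)
#' nVertices(m)  # 10 * 4^2 + 2 = 162
#' @export
buildIcosphere <- function(level) {
  if (length(level) != 1L || is.na(level) || level < 0 || level != round(level))
    stopf("level must be a single non-negative integer")
  if (level > 7) stopf("level %d exceeds the practical cap of 7", as.integer(level))
  level <- as.integer(level)
  key <- as.character(level)
  if (!is.null(.meshCache[[key]])) return(.meshCache[[key]])
  if (level == 0L) {
    base <- baseIcosahedron()
    g <- base
  } else {
    parent <- buildIcosphere(level - 1L)
    g <- subdivideOnce(parent@vertices, parent@faces)
  }
  mesh <- new("SphereMesh", level = level, vertices = g$vertices,
              faces = g$faces, oneRing = buildOneRing(g$vertices, g$faces),
              coarserCount = if (level == 0L) 0L
                             else as.integer(10 * 4^(level - 1) + 2))
  .meshCache[[key]] <- mesh
  mesh
}

#' Edges of a mesh
#'
#' @param mesh a \linkS4class{SphereMesh}.
#' @return E x 2 integer matrix of undirected edges, lexicographically sorted.
#' @export
meshEdges <- function(mesh) sortedEdges(mesh@faces)

#' Pooling map between two consecutive icosphere levels
#'
#' The coarse vertices are the index prefix of the fine mesh; each fine-only
#' vertex is the midpoint of exactly one coarse edge and maps to that edge's
#' two endpoints. Midpoint order follows the canonical sorted-edge order, so
#' the map is recomputable from the coarse mesh alone.
#'
#' @param fine,coarse \linkS4class{SphereMesh} objects with
#'   \code{meshLevel(fine) == meshLevel(coarse) + 1}.
#' @return a \linkS4class{PoolingMap} with sparse \code{up} (copy coarse,
#'   average the two parents at midpoints) and \code{down} (prefix
#'   restriction) matrices.
#' @export
poolingMap <- function(fine, coarse) {
  if (meshLevel(fine) != meshLevel(coarse) + 1L)
    stopf("fine level (%d) must be coarse level (%d) + 1",
          meshLevel(fine), meshLevel(coarse))
  Vc <- nVertices(coarse)
  Vf <- nVertices(fine)
  parents <- sortedEdges(coarse@faces)       # midpoint k <=> k-th sorted edge
  stopifnot(nrow(parents) == Vf - Vc)
  up <- Matrix::sparseMatrix(
    i = c(seq_len(Vc), rep(Vc + seq_len(Vf - Vc), 2L)),
    j = c(seq_len(Vc), parents[, 1], parents[, 2]),
    x = c(rep(1, Vc), rep(0.5, 2L * (Vf - Vc))),
    dims = c(Vf, Vc))
  down <- Matrix::sparseMatrix(i = seq_len(Vc), j = seq_len(Vc), x = 1,
                               dims = c(Vc, Vf))
  new("PoolingMap", fineLevel = meshLevel(fine), coarseLevel = meshLevel(coarse),
      midpointParents = parents, up = up, down = down)
}

#' Restrict a fine-level field to the coarse level
#'
#' @param x V_fine x K matrix (or vector).
#' @param pool a \linkS4class{PoolingMap}.
#' @return V_coarse x K matrix: the coarse index prefix of \code{x}.
#' @export
restrictField <- function(x, pool) {
  x <- as.matrix(x)
  Vc <- 10L * 4L^pool@coarseLevel + 2L
  x[seq_len(Vc), , drop = FALSE]
}

#' Prolong a coarse-level field to the fine level
#'
#' Coarse values are copied; each midpoint receives the mean of its two
#' parent vertices.
#'
#' @param x V_coarse x K matrix (or vector).
#' @param pool a \linkS4class{PoolingMap}.
#' @return V_fine x K matrix.
#' @export
prolongField <- function(x, pool) {
  as.matrix(pool@up %*% as.matrix(x))
}
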