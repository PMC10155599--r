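## Differential operators on the icosphere: the basis of the spherical
## convolution kernel. Each first-order operator is a per-vertex
## least-squares estimate of a tangential directional derivative from the
## one-ring; the Laplacian is a graph Laplacian with zero row sums.

## Tangential frame at a vertex p = (x, y, z) on the unit sphere:
##  east  = direction of increasing longitude phi,
##  ns    = direction of increasing polar angle theta (north pole -> south),
## so that D_ns applied to f(v) = z reproduces the analytic -sin(theta).
tangentFrame <- function(p) {
  rho2 <- p[1]^2 + p[2]^2
  if (rho2 < 1e-12) return(NULL)                   # pole: degenerate frame
  rho <- sqrt(rho2)
  east <- c(-p[2], p[1], 0) / rho
  ns <- c(p[1] * p[3], p[2] * p[3], -rho2) / rho
  rbind(east, ns)
}

#' Assemble differential operators for a mesh
#'
#' For every vertex the one-ring offsets are projected into the local
#' (east, north-south) tangent frame and a linear function is fit by least
#' squares; its two slope components define rows of the east-west and
#' north-south derivative operators. At the (at most two) vertices where
#' the tangent frame is degenerate the frame of the nearest non-degenerate
#' neighbor is reused. The Laplacian is either the uniform normalized graph
#' Laplacian (mean of neighbors minus center; default, exactly reproducible)
#' or a cotangent-weighted variant. All operators have zero row sums and row
#' support restricted to the one-ring plus the vertex itself.
#'
#' @param mesh a \linkS4class{SphereMesh}.
#' @param laplacian "uniform" (default) or "cotangent".
#' @return a \linkS4class{DiffOperators}.
#' @export
assembleDiffOps <- function(mesh, laplacian = c("uniform", "cotangent")) {
  laplacian <- match.arg(laplacian)
  V <- nVertices(mesh)
  vs <- mesh@vertices
  ring <- mesh@oneRing
  jjL <- vector("list", V)
  xewL <- vector("list", V)
  xnsL <- vector("list", V)
  for (v in seq_len(V)) {
    p <- vs[v, ]
    fr <- tangentFrame(p)
    if (is.null(fr)) {
      ## nearest non-degenerate neighbor's frame (pole handling)
      cand <- ring[[v]]
      fr <- NULL
      for (u in cand[order(greatCircleDist(matrix(p, 1), vs[cand, , drop = FALSE]))]) {
        fr <- tangentFrame(vs[u, ])
        if (!is.null(fr)) break
      }
      if (is.null(fr)) stopf("degenerate ring geometry at vertex %d", v)
    }
    u <- ring[[v]]
    d <- vs[u, , drop = FALSE] - matrix(p, length(u), 3, byrow = TRUE)
    A <- d %*% t(fr)                               # ring x 2 tangent coords
    G <- tryCatch(solve(crossprod(A), t(A)),
                  error = function(e) stopf("degenerate ring geometry at vertex %d", v))
    ## rows of G: coefficients on (f(u) - f(v))
    jjL[[v]] <- c(u, v)
    xewL[[v]] <- c(G[1, ], -sum(G[1, ]))
    xnsL[[v]] <- c(G[2, ], -sum(G[2, ]))
  }
  ii <- rep(seq_len(V), lengths(jjL))
  jj <- unlist(jjL, use.names = FALSE)
  Dew <- Matrix::sparseMatrix(i = ii, j = jj, x = unlist(xewL, use.names = FALSE),
                              dims = c(V, V))
  Dns <- Matrix::sparseMatrix(i = ii, j = jj, x = unlist(xnsL, use.names = FALSE),
                              dims = c(V, V))
  Lap <- switch(laplacian,
    uniform = uniformLaplacian(mesh),
    cotangent = cotangentLaplacian(mesh))
  new("DiffOperators", level = meshLevel(mesh),
      Dew = Dew, Dns = Dns, Lap = Lap,
      DewT = Matrix::t(Dew), DnsT = Matrix::t(Dns), LapT = Matrix::t(Lap))
}

## mean over the ring minus the center value; zero row sums by construction.
uniformLaplacian <- function(mesh) {
  V <- nVertices(mesh)
  ring <- mesh@oneRing
  deg <- lengths(ring)
  ii <- rep(seq_len(V), deg + 1L)
  jj <- unlist(lapply(seq_len(V), function(v) c(ring[[v]], v)), use.names = FALSE)
  xx <- unlist(lapply(seq_len(V), function(v)
    c(rep(1 / deg[v], deg[v]), -1)), use.names = FALSE)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(V, V))
}

## cotangent weights, normalized per row to a weighted mean minus center.
cotangentLaplacian <- function(mesh) {
  V <- nVertices(mesh)
  vs <- mesh@vertices
  f <- mesh@faces
  w <- new.env(parent = emptyenv())
  addW <- function(a, b, val) {
    k <- paste(min(a, b), max(a, b))
    w[[k]] <- (if (is.null(w[[k]])) 0 else w[[k]]) + val
  }
  for (i in seq_len(nrow(f))) {
    tri <- f[i, ]
    for (k in 1:3) {
      o <- tri[k]; a <- tri[(k %% 3) + 1]; b <- tri[((k + 1) %% 3) + 1]
      u <- vs[a, ] - vs[o, ]; vv <- vs[b, ] - vs[o, ]
      cosA <- sum(u * vv)
      sinA <- sqrt(max(sum(crossProd3(u, vv)^2), 1e-300))
      addW(a, b, cosA / sinA / 2)
    }
  }
  keys <- ls(w)
  kk <- do.call(rbind, strsplit(keys, " "))
  a <- as.integer(kk[, 1]); b <- as.integer(kk[, 2])
  val <- vapply(keys, function(k) w[[k]], 1)
  ii <- c(a, b); jj <- c(b, a); xx <- c(val, val)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(V, V))
  rs <- Matrix::rowSums(W)
  Matrix::Diagonal(x = 1 / rs) %*% W - Matrix::Diagonal(V)
}

#' Apply the spherical convolution kernel
#'
#' A parameterized-differential-operator convolution: each output channel is
#' a learned mixture of the identity, the two tangential derivatives and the
#' Laplacian of every input channel, plus a bias.
#' \code{out_c = sum_k w[c,k,1] f_k + w[c,k,2] Dew f_k + w[c,k,3] Dns f_k +
#' w[c,k,4] Lap f_k + b_c}.
#'
#' @param features V x Cin numeric matrix.
#' @param ops \linkS4class{DiffOperators} for the same mesh.
#' @param weights array of dim (Cout, Cin, 4).
#' @param bias length-Cout numeric.
#' @return V x Cout matrix.
#' @export
meshConv <- function(features, ops, weights, bias) {
  features <- as.matrix(features)
  dm <- dim(weights)
  if (length(dm) != 3L || dm[3] != 4L || dm[2] != ncol(features))
    stopf("weights must have dim (Cout, Cin, 4) with Cin = %d", ncol(features))
  if (length(bias) != dm[1]) stopf("bias length must equal Cout")
  wk <- function(k) t(matrix(weights[, , k], dm[1], dm[2]))  # Cin x Cout
  out <- features %*% wk(1) +
    as.matrix(ops@Dew %*% features) %*% wk(2) +
    as.matrix(ops@Dns %*% features) %*% wk(3) +
    as.matrix(ops@Lap %*% features) %*% wk(4)
  sweep(out, 2, bias, "+")
}
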