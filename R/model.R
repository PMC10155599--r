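## Surface U-Net built from parameterized-differential-operator convolutions,
## with hand-written backpropagation (the training loop in train.R drives it
## with analytic loss gradients).

#' Create a model specification
#'
#' Topology follows a U-Net: an encoder of \code{depth} convolution+pool
#' stages, a bottleneck, a decoder of unpool+convolution stages with
#' optional skip connections, and a final per-vertex linear head projecting
#' to one channel per task contrast. Widths, depth, normalization and
#' nonlinearity are configuration, not fixed by the method.
#'
#' @param inputLevel icosphere level of the input/output fields.
#' @param depth number of down/up stages; must not exceed \code{inputLevel}.
#' @param widths integer vector of length \code{depth + 1} (finest stage
#'   first); default doubles from 64.
#' @param inChannels number of connectome input channels.
#' @param outChannels number of task-contrast output channels.
#' @param skip use skip connections (default TRUE).
#' @param normalization "instance" (default) or "none".
#' @param negativeSlope leaky-ReLU negative slope (default 0.01).
#' @param seed initialization seed.
#' @return a \linkS4class{ModelSpec}.
#' @export
modelSpec <- function(inputLevel, depth, inChannels, outChannels,
                      widths = 64L * 2L^(0:depth), skip = TRUE,
                      normalization = "instance", negativeSlope = 0.01,
                      seed = 1L) {
  new("ModelSpec", inputLevel = as.integer(inputLevel),
      depth = as.integer(depth), widths = as.integer(widths),
      inChannels = as.integer(inChannels),
      outChannels = as.integer(outChannels), skip = as.logical(skip),
      normalization = normalization, negativeSlope = negativeSlope,
      seed = as.integer(seed))
}

convInChannels <- function(spec) {
  d <- spec@depth
  enc <- c(spec@inChannels, spec@widths[seq_len(d)])
  dec <- if (d > 0)
    spec@widths[seq_len(d) + 1L] + if (spec@skip) spec@widths[seq_len(d)] else 0L
  else integer(0)
  list(enc = enc, dec = dec)
}

initConv <- function(cin, cout) {
  sd <- sqrt(2 / (cin * 4))
  array(stats::rnorm(cout * cin * 4, sd = sd), dim = c(cout, cin, 4))
}

#' Build a surface convolutional network
#'
#' Allocates and seeds all parameters and caches the mesh hierarchy,
#' differential operators and pooling maps the forward/backward passes use.
#' The same seed always yields bit-identical initial parameters.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param laplacian Laplacian variant passed to \code{\link{assembleDiffOps}}.
#' @return a \linkS4class{SurfModel} with both partitions trainable.
#' @export
buildModel <- function(spec, laplacian = "uniform") {
  validObject(spec)
  L <- spec@inputLevel
  d <- spec@depth
  meshes <- lapply(L:(L - d), buildIcosphere)
  names(meshes) <- as.character(L:(L - d))
  ops <- lapply(meshes, assembleDiffOps, laplacian = laplacian)
  pools <- if (d > 0)
    lapply(seq_len(d), function(s)
      poolingMap(meshes[[as.character(L - s + 1L)]],
                 meshes[[as.character(L - s)]]))
  else list()
  ci <- convInChannels(spec)
  params <- list()
  set.seed(spec@seed)
  for (s in seq_len(d + 1L)) {
    params[[sprintf("enc%d.W", s)]] <- initConv(ci$enc[s], spec@widths[s])
    params[[sprintf("enc%d.b", s)]] <- numeric(spec@widths[s])
    if (spec@normalization == "instance") {
      params[[sprintf("enc%d.g", s)]] <- rep(1, spec@widths[s])
      params[[sprintf("enc%d.bt", s)]] <- numeric(spec@widths[s])
    }
  }
  for (s in rev(seq_len(d))) {
    params[[sprintf("dec%d.W", s)]] <- initConv(ci$dec[s], spec@widths[s])
    params[[sprintf("dec%d.b", s)]] <- numeric(spec@widths[s])
    if (spec@normalization == "instance") {
      params[[sprintf("dec%d.g", s)]] <- rep(1, spec@widths[s])
      params[[sprintf("dec%d.bt", s)]] <- numeric(spec@widths[s])
    }
  }
  params[["head.W"]] <- matrix(stats::rnorm(spec@widths[1] * spec@outChannels,
                                            sd = sqrt(1 / spec@widths[1])),
                               spec@widths[1], spec@outChannels)
  params[["head.b"]] <- numeric(spec@outChannels)
  new("SurfModel", spec = spec, params = params, meshes = meshes, ops = ops,
      pools = pools, trainable = c("backbone", "head"), normStats = list(),
      history = data.frame())
}

## ---- layer primitives -------------------------------------------------

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)

instNormFwd <- function(h, g, bt, eps = 1e-5) {
  mu <- colMeans(h)
  hc <- sweep(h, 2, mu)
  inv <- 1 / sqrt(colMeans(hc^2) + eps)
  xhat <- sweep(hc, 2, inv, "*")
  list(y = sweep(sweep(xhat, 2, g, "*"), 2, bt, "+"), xhat = xhat, inv = inv)
}

instNormBwd <- function(dy, cacheN, g) {
  xhat <- cacheN$xhat
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*")
  dx <- sweep(dx, 2, cacheN$inv, "*")
  list(dx = dx, dg = colSums(dy * xhat), dbt = colSums(dy))
}

convFwd <- function(x, ops, W, b) {
  dm <- dim(W)
  gx <- list(x, as.matrix(ops@Dew %*% x), as.matrix(ops@Dns %*% x),
             as.matrix(ops@Lap %*% x))
  out <- matrix(rep(b, each = nrow(x)), nrow(x))
  for (k in 1:4)
    out <- out + gx[[k]] %*% t(matrix(W[, , k], dm[1], dm[2]))
  list(y = out, gx = gx)
}

convBwd <- function(dy, gx, ops, W) {
  dm <- dim(W)
  dW <- array(0, dm)
  for (k in 1:4) dW[, , k] <- crossprod(dy, gx[[k]])
  db <- colSums(dy)
  dx <- matrix(0, nrow(dy), dm[2])
  opT <- list(NULL, ops@DewT, ops@DnsT, ops@LapT)
  for (k in 1:4) {
    dg <- dy %*% matrix(W[, , k], dm[1], dm[2])
    dx <- dx + if (k == 1) dg else as.matrix(opT[[k]] %*% dg)
  }
  list(dW = dW, db = db, dx = dx)
}

blockFwd <- function(x, ops, params, prefix, spec) {
  cv <- convFwd(x, ops, params[[paste0(prefix, ".W")]],
                params[[paste0(prefix, ".b")]])
  if (spec@normalization == "instance") {
    nm <- instNormFwd(cv$y, params[[paste0(prefix, ".g")]],
                      params[[paste0(prefix, ".bt")]])
    pre <- nm$y
  } else {
    nm <- NULL
    pre <- cv$y
  }
  list(a = lrelu(pre, spec@negativeSlope),
       cache = list(gx = cv$gx, norm = nm, pre = pre))
}

blockBwd <- function(da, cache, ops, params, prefix, spec, grads) {
  dpre <- da * ifelse(cache$pre > 0, 1, spec@negativeSlope)
  if (spec@normalization == "instance") {
    nb <- instNormBwd(dpre, cache$norm, params[[paste0(prefix, ".g")]])
    grads[[paste0(prefix, ".g")]] <- nb$dg
    grads[[paste0(prefix, ".bt")]] <- nb$dbt
    dpre <- nb$dx
  }
  cb <- convBwd(dpre, cache$gx, ops, params[[paste0(prefix, ".W")]])
  grads[[paste0(prefix, ".W")]] <- cb$dW
  grads[[paste0(prefix, ".b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

## ---- full forward / backward -----------------------------------------

## Forward pass for one sample (V x Cin matrix). Returns the V x C output
## and, when cache = TRUE, everything backward needs.
modelForward <- function(model, x, cache = FALSE) {
  spec <- model@spec
  L <- spec@inputLevel
  d <- spec@depth
  opsAt <- function(lev) model@ops[[as.character(lev)]]
  caches <- list(enc = vector("list", d + 1L), dec = vector("list", d),
                 skipWidth = integer(d))
  skips <- vector("list", d)
  a <- x
  for (s in seq_len(d + 1L)) {
    lev <- L - s + 1L
    bl <- blockFwd(a, opsAt(lev), model@params, sprintf("enc%d", s), spec)
    if (cache) caches$enc[[s]] <- bl$cache
    if (s <= d) {
      skips[[s]] <- bl$a
      a <- restrictField(bl$a, model@pools[[s]])
    } else a <- bl$a
  }
  for (s in rev(seq_len(d))) {
    u <- prolongField(a, model@pools[[s]])
    if (spec@skip) {
      caches$skipWidth[s] <- ncol(u)
      u <- cbind(u, skips[[s]])
    }
    bl <- blockFwd(u, opsAt(L - s + 1L), model@params, sprintf("dec%d", s), spec)
    if (cache) caches$dec[[s]] <- bl$cache
    a <- bl$a
  }
  out <- sweep(a %*% model@params[["head.W"]], 2, model@params[["head.b"]], "+")
  if (!cache) return(out)
  caches$headIn <- a
  list(out = out, caches = caches)
}

## Backward pass for one sample given dLoss/dOut; returns named gradient list.
modelBackward <- function(model, fw, dOut) {
  spec <- model@spec
  L <- spec@inputLevel
  d <- spec@depth
  opsAt <- function(lev) model@ops[[as.character(lev)]]
  grads <- list()
  grads[["head.W"]] <- crossprod(fw$caches$headIn, dOut)
  grads[["head.b"]] <- colSums(dOut)
  da <- dOut %*% t(model@params[["head.W"]])
  dskip <- vector("list", d)
  for (s in seq_len(d)) {
    bb <- blockBwd(da, fw$caches$dec[[s]], opsAt(L - s + 1L), model@params,
                   sprintf("dec%d", s), spec, grads)
    grads <- bb$grads
    du <- bb$dx
    if (spec@skip) {
      wUp <- fw$caches$skipWidth[s]
      dskip[[s]] <- du[, -seq_len(wUp), drop = FALSE]
      du <- du[, seq_len(wUp), drop = FALSE]
    }
    ## through prolongation into the coarser stage
    da <- as.matrix(Matrix::crossprod(model@pools[[s]]@up, du))
  }
  for (s in rev(seq_len(d + 1L))) {
    lev <- L - s + 1L
    if (s <= d) {
      ## through restriction: pad gradient to fine size, add skip gradient
      Vf <- nVertices(model@meshes[[as.character(lev)]])
      daPad <- matrix(0, Vf, ncol(da))
      daPad[seq_len(nrow(da)), ] <- da
      if (spec@skip && !is.null(dskip[[s]])) daPad <- daPad + dskip[[s]]
      da <- daPad
    }
    bb <- blockBwd(da, fw$caches$enc[[s]], opsAt(lev), model@params,
                   sprintf("enc%d", s), spec, grads)
    grads <- bb$grads
    da <- bb$dx
  }
  grads
}

#' Predict contrast maps from a connectome
#'
#' Runs the forward pass. If the model carries input normalization
#' statistics (from training), they are applied first. Evaluation is
#' deterministic: no stochastic layers are active.
#'
#' @param model a \linkS4class{SurfModel}.
#' @param connectome a \linkS4class{Connectome} (or bare V x Cin matrix).
#' @param contrastNames optional output channel names.
#' @return a \linkS4class{ContrastMaps}.
#' @export
predictContrasts <- function(model, connectome, contrastNames = NULL) {
  x <- if (is(connectome, "Connectome")) connectome@data else as.matrix(connectome)
  if (ncol(x) != model@spec@inChannels)
    stopf("connectome has %d channels; model expects %d", ncol(x),
          model@spec@inChannels)
  if (length(model@normStats))
    x <- applyChannelStats(x, model@normStats)
  out <- modelForward(model, x)
  if (is.null(contrastNames))
    contrastNames <- sprintf("contrast%02d", seq_len(ncol(out)))
  mask <- if (is(connectome, "Connectome")) connectome@vertexMask
          else rep(TRUE, nrow(out))
  subj <- if (is(connectome, "Connectome")) connectome@subject else "unknown"
  new("ContrastMaps", data = out, vertexMask = mask, subject = subj,
      contrastNames = contrastNames)
}

#' Replace the model head
#'
#' Transfer-learning surgery: keeps every backbone parameter bit-exactly
#' and re-initializes the final per-vertex projection with \code{cNew}
#' output channels from the given seed.
#'
#' @param model a \linkS4class{SurfModel}.
#' @param cNew new output channel count (>= 1).
#' @param seed seed for the new head initialization.
#' @return the modified \linkS4class{SurfModel}.
#' @export
replaceHead <- function(model, cNew, seed) {
  if (cNew < 1) stopf("cNew must be >= 1")
  w1 <- model@spec@widths[1]
  set.seed(as.integer(seed))
  model@params[["head.W"]] <- matrix(stats::rnorm(w1 * cNew, sd = sqrt(1 / w1)),
                                     w1, as.integer(cNew))
  model@params[["head.b"]] <- numeric(as.integer(cNew))
  model@spec@outChannels <- as.integer(cNew)
  model
}

#' Select trainable parameter partitions
#'
#' @param model a \linkS4class{SurfModel}.
#' @param parts non-empty subset of \code{c("backbone", "head")}; frozen
#'   partitions receive no gradient updates and stay bit-identical under
#'   training.
#' @return the modified \linkS4class{SurfModel}.
#' @export
setTrainable <- function(model, parts) {
  if (length(parts) == 0L) stopf("at least one of 'backbone', 'head' must be trainable")
  if (!all(parts %in% c("backbone", "head")))
    stopf("parts must be a subset of c('backbone', 'head')")
  model@trainable <- unique(parts)
  model
}

isHeadParam <- function(name) startsWith(name, "head.")

trainableNames <- function(model) {
  nm <- names(model@params)
  keep <- (isHeadParam(nm) & "head" %in% model@trainable) |
          (!isHeadParam(nm) & "backbone" %in% model@trainable)
  nm[keep]
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the parameter arrays,
#' spec, normalization statistics and history, with a JSON provenance
#' sidecar (spec summary, trainable partitions, package version).
#'
#' @param model a \linkS4class{SurfModel}.
#' @param path file path for the checkpoint (".rds" recommended).
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(spec = model@spec, params = model@params,
               trainable = model@trainable, normStats = model@normStats,
               history = model@history), path)
  prov <- list(
    class = "SurfModel",
    inputLevel = model@spec@inputLevel, depth = model@spec@depth,
    widths = model@spec@widths, inChannels = model@spec@inChannels,
    outChannels = model@spec@outChannels, skip = model@spec@skip,
    seed = model@spec@seed, trainable = model@trainable,
    package = pkgVersionString())
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  model <- buildModel(x$spec)
  model@params <- x$params
  model@trainable <- x$trainable
  model@normStats <- x$normStats
  model@history <- x$history
  model
}
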