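## Internal helpers shared across modules.

## Great-circle (angular) distance between unit vectors; rows of `a` against
## rows of `b`. Returns length(a-rows) x length(b-rows) matrix of radians.
greatCircleDist <- function(a, b) {
  d <- tcrossprod(a, b)
  d[d > 1] <- 1
  d[d < -1] <- -1
  acos(d)
}

## Minimum-norm least squares via SVD with a relative singular value cutoff.
pinvSolve <- function(X, y, rtol = 1e-10) {
  s <- svd(X)
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(X), NCOL(y)))
  s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], as.matrix(y))) / s$d[keep])
}

## Composite trapezoid on (x, y).
trapezoid <- function(x, y) pracma::trapz(x, y)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Draw a fresh 32-bit sub-seed from the current RNG stream.
subSeed <- function() sample.int(.Machine$integer.max, 1L)

## package version, tolerant of a not-yet-installed source tree
pkgVersionString <- function() {
  tryCatch(as.character(utils::packageVersion("surftask")),
           error = function(e) "0.0.0")
}
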