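## References: ensembled parcel-wise linear regression and group average.

#' Fit the ensembled parcel-wise linear baseline
#'
#' For every training subject and every parcel, a no-intercept linear model
#' maps the parcel's connectome features (n_k vertices x M channels) to the
#' parcel's activation pattern, solved with the minimum-norm pseudoinverse
#' (relative singular-value cutoff 1e-10). The per-subject regressors are
#' then averaged across subjects to a single predictive model per parcel.
#' All contrasts are fit (each with its own solve, sharing the features).
#'
#' @param connectomes list of per-subject \linkS4class{Connectome} features
#'   (same layout as the network input).
#' @param targets list of per-subject \linkS4class{ContrastMaps}.
#' @param parc a \linkS4class{ParcellationLabels}.
#' @param intercept include an intercept column (default FALSE, matching
#'   the no-intercept formulation).
#' @return a \linkS4class{ParcelLinearModel}.
#' @export
fitParcelLinear <- function(connectomes, targets, parc, intercept = FALSE) {
  N <- length(connectomes)
  stopifnot(N == length(targets), N >= 1L)
  lab <- parc@labels
  members <- lapply(seq_len(parc@M), function(k) which(lab == k))
  if (any(lengths(members) == 0L))
    stopf("parcel %d has no member vertices", which(lengths(members) == 0L)[1])
  C <- ncol(targets[[1]]@data)
  Mfeat <- ncol(connectomes[[1]]@data) + as.integer(intercept)
  betaSum <- lapply(seq_len(parc@M), function(k) matrix(0, Mfeat, C))
  for (i in seq_len(N)) {
    X <- connectomes[[i]]@data
    Y <- targets[[i]]@data
    for (k in seq_len(parc@M)) {
      Xk <- X[members[[k]], , drop = FALSE]
      if (intercept) Xk <- cbind(Xk, 1)
      betaSum[[k]] <- betaSum[[k]] + pinvSolve(Xk, Y[members[[k]], , drop = FALSE])
    }
  }
  new("ParcelLinearModel",
      beta = lapply(betaSum, function(b) b / N),
      labels = lab, M = parc@M, nTrain = as.integer(N),
      contrastNames = targets[[1]]@contrastNames)
}

#' Predict from the parcel-wise linear baseline
#'
#' Applies each parcel's averaged regressor to the test subject's features
#' and assembles the full map. By linearity this equals the average of the
#' per-training-subject predictions.
#'
#' @param fit a \linkS4class{ParcelLinearModel}.
#' @param connectome test-subject \linkS4class{Connectome} with the same
#'   feature layout as training.
#' @return a \linkS4class{ContrastMaps}.
#' @export
predictParcelLinear <- function(fit, connectome) {
  X <- connectome@data
  intercept <- nrow(fit@beta[[1]]) == ncol(X) + 1L
  if (!intercept && nrow(fit@beta[[1]]) != ncol(X))
    stopf("feature count mismatch: model has %d, connectome has %d",
          nrow(fit@beta[[1]]), ncol(X))
  C <- ncol(fit@beta[[1]])
  out <- matrix(0, nrow(X), C)
  for (k in seq_len(fit@M)) {
    idx <- which(fit@labels == k)
    Xk <- X[idx, , drop = FALSE]
    if (intercept) Xk <- cbind(Xk, 1)
    out[idx, ] <- Xk %*% fit@beta[[k]]
  }
  new("ContrastMaps", data = out, vertexMask = connectome@vertexMask,
      subject = connectome@subject, contrastNames = fit@contrastNames)
}

#' Group-average reference maps
#'
#' Vertex-wise mean over training subjects, per contrast; the naive
#' reference any individualized prediction should beat.
#'
#' @param targets non-empty list of per-subject \linkS4class{ContrastMaps}.
#' @return a \linkS4class{ContrastMaps} with subject id "group_average".
#' @export
groupAverage <- function(targets) {
  if (length(targets) == 0L) stopf("empty target set")
  avg <- Reduce(`+`, lapply(targets, function(x) x@data)) / length(targets)
  new("ContrastMaps", data = avg, vertexMask = targets[[1]]@vertexMask,
      subject = "group_average", contrastNames = targets[[1]]@contrastNames)
}
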