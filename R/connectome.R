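## Vertex-to-ROI functional connectomes: winner-take-all parcellation, ROI
## mean timeseries, Pearson correlation channels, hemisphere concatenation,
## contiguous-segment augmentation and channel normalization.

#' Winner-take-all parcel assignment
#'
#' Assigns every vertex to the component with the highest z-score at that
#' location. Ties break to the lowest component index; masked-out vertices
#' receive NA. Assignment happens even when all z-scores are negative
#' unless a z-floor is supplied.
#'
#' @param zmaps V x M numeric matrix of component z-score maps.
#' @param mask optional logical length-V inclusion mask (default all TRUE).
#' @param zFloor optional minimum winning z-score; vertices whose best
#'   z-score falls below it stay unassigned (default \code{-Inf}, off).
#' @return a \linkS4class{ParcellationLabels}.
#' @export
winnerTakeAll <- function(zmaps, mask = NULL, zFloor = -Inf) {
  zmaps <- as.matrix(zmaps)
  if (any(!is.finite(zmaps))) stopf("z-score maps must be finite")
  if (ncol(zmaps) < 1L) stopf("need at least one component map")
  if (is.null(mask)) mask <- rep(TRUE, nrow(zmaps))
  lab <- max.col(zmaps, ties.method = "first")
  best <- zmaps[cbind(seq_len(nrow(zmaps)), lab)]
  lab[best < zFloor] <- NA_integer_
  lab[!mask] <- NA_integer_
  new("ParcellationLabels", labels = as.integer(lab),
      M = ncol(zmaps), zmaps = zmaps)
}

#' ROI mean timeseries
#'
#' Row j is the unweighted mean of the timeseries of all (unmasked)
#' vertices assigned to ROI j.
#'
#' @param ts a \linkS4class{SurfaceTimeseries}.
#' @param parc a \linkS4class{ParcellationLabels} on the same mesh.
#' @return M x T numeric matrix.
#' @export
roiMeanTimeseries <- function(ts, parc) {
  if (length(parc@labels) != nVertices(ts))
    stopf("parcellation and timeseries are on different meshes")
  lab <- parc@labels
  lab[!ts@vertexMask] <- NA_integer_
  out <- matrix(NA_real_, parc@M, ncol(ts@data))
  for (j in seq_len(parc@M)) {
    idx <- which(lab == j)
    if (length(idx) == 0L) stopf("ROI %d has no member vertices", j)
    out[j, ] <- colMeans(ts@data[idx, , drop = FALSE])
  }
  out
}

#' Vertex-to-ROI functional connectivity
#'
#' Entry (i, j) is the Pearson correlation between vertex i's resting
#' timeseries and ROI j's mean timeseries. A zero-variance vertex or ROI
#' series yields 0 in the affected entries (counted in a warning) rather
#' than NaN, keeping downstream tensors finite.
#'
#' @param ts a \linkS4class{SurfaceTimeseries}.
#' @param roiTs M x T matrix from \code{\link{roiMeanTimeseries}}.
#' @param subject subject identifier attached to the result.
#' @param channelNames optional ROI channel names.
#' @return a \linkS4class{Connectome}.
#' @export
vertexToRoiFC <- function(ts, roiTs, subject = "subject",
                          channelNames = NULL) {
  Tn <- ncol(ts@data)
  if (ncol(roiTs) != Tn)
    stopf("timepoint mismatch: vertices have %d, ROIs have %d", Tn, ncol(roiTs))
  if (Tn < 3L) stopf("need at least 3 timepoints for correlation")
  vt <- ts@data - rowMeans(ts@data)
  rt <- roiTs - rowMeans(roiTs)
  vsd <- sqrt(rowSums(vt^2))
  rsd <- sqrt(rowSums(rt^2))
  nzV <- vsd > 0
  nzR <- rsd > 0
  r <- matrix(0, nrow(vt), nrow(rt))
  if (any(nzV) && any(nzR)) {
    r[nzV, nzR] <- (vt[nzV, , drop = FALSE] %*% t(rt[nzR, , drop = FALSE])) /
      (vsd[nzV] %o% rsd[nzR])
  }
  nDegen <- sum(!nzV) * nrow(rt) + sum(!nzR) * sum(nzV)
  if (nDegen > 0)
    warnf("%d degenerate (constant-series) correlation entries set to 0", nDegen)
  r[r > 1] <- 1
  r[r < -1] <- -1
  if (is.null(channelNames))
    channelNames <- sprintf("roi%02d", seq_len(nrow(rt)))
  new("Connectome", data = r, vertexMask = ts@vertexMask,
      subject = subject, channelNames = channelNames)
}

#' Build a connectome from a timeseries and a parcellation
#'
#' Convenience wrapper: ROI mean timeseries then vertex-to-ROI correlation.
#'
#' @inheritParams roiMeanTimeseries
#' @inheritParams vertexToRoiFC
#' @return a \linkS4class{Connectome}.
#' @export
buildConnectome <- function(ts, parc, subject = "subject") {
  vertexToRoiFC(ts, roiMeanTimeseries(ts, parc), subject = subject)
}

#' Concatenate hemisphere connectomes
#'
#' Produces the bilateral layout: one mesh, 2M channels, left block first,
#' channel names suffixed "_L"/"_R". Assumes the template convention that
#' identical vertex indices are contralateral homologs.
#'
#' @param left,right \linkS4class{Connectome} objects with identical vertex
#'   count and ROI count.
#' @return a \linkS4class{Connectome} with 2M channels.
#' @export
concatHemispheres <- function(left, right) {
  if (nVertices(left) != nVertices(right))
    stopf("vertex count mismatch between hemispheres")
  if (ncol(left@data) != ncol(right@data))
    stopf("ROI count mismatch between hemispheres")
  new("Connectome",
      data = cbind(left@data, right@data),
      vertexMask = left@vertexMask & right@vertexMask,
      subject = left@subject,
      channelNames = c(paste0(left@channelNames, "_L"),
                       paste0(right@channelNames, "_R")))
}

#' Split resting runs into contiguous segments
#'
#' Augmentation: \code{scheme = "halves"} yields the two contiguous halves
#' of every run (2R segments); \code{"fixed"} yields floor(T / length)
#' non-overlapping contiguous segments per run; \code{"random"} yields
#' seeded random contiguous windows.
#'
#' @param runs list of \linkS4class{SurfaceTimeseries} runs of one subject.
#' @param scheme "halves", "fixed" or "random".
#' @param length segment length (schemes "fixed" and "random").
#' @param count windows per run (scheme "random").
#' @param seed seed (scheme "random").
#' @return flat list of \linkS4class{SurfaceTimeseries} segments.
#' @export
splitSegments <- function(runs, scheme = c("halves", "fixed", "random"),
                          length = NULL, count = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  if (is(runs, "SurfaceTimeseries")) runs <- list(runs)
  segs <- list()
  if (scheme == "random") {
    if (is.null(length) || is.null(count) || is.null(seed))
      stopf("scheme 'random' requires length, count and seed")
    set.seed(as.integer(seed))
  }
  cut1 <- function(run, from, to) {
    new("SurfaceTimeseries", data = run@data[, from:to, drop = FALSE],
        vertexMask = run@vertexMask, hemisphere = run@hemisphere, tr = run@tr)
  }
  for (run in runs) {
    Tn <- ncol(run@data)
    starts <- switch(scheme,
      halves = {
        half <- Tn %/% 2L
        segs <- c(segs, list(cut1(run, 1L, half),
                             cut1(run, half + 1L, half + half)))
        NULL
      },
      fixed = {
        if (length > Tn) stopf("segment length %d exceeds run length %d", length, Tn)
        k <- Tn %/% length
        for (i in seq_len(k))
          segs <- c(segs, list(cut1(run, (i - 1L) * length + 1L, i * length)))
        NULL
      },
      random = {
        if (length > Tn) stopf("segment length %d exceeds run length %d", length, Tn)
        for (i in seq_len(count)) {
          s <- sample.int(Tn - length + 1L, 1L)
          segs <- c(segs, list(cut1(run, s, s + length - 1L)))
        }
        NULL
      })
  }
  segs
}

#' Per-channel z-scoring of connectomes
#'
#' Training mode (\code{stats = NULL}) computes per-channel mean and sd
#' over all supplied connectomes and returns them with the scaled data;
#' evaluation mode applies the provided training statistics. Zero-sd
#' channels are left unscaled with a warning.
#'
#' @param connectomes list of \linkS4class{Connectome} (or a single one).
#' @param stats list(mean, sd) from a previous training-mode call, or NULL.
#' @return list with elements \code{connectomes} (same shape as input,
#'   note scaled values leave the [-1,1] range so plain matrices are
#'   returned in the \code{data} slots) and \code{stats}.
#' @export
normalizeChannels <- function(connectomes, stats = NULL) {
  single <- is(connectomes, "Connectome")
  if (single) connectomes <- list(connectomes)
  if (is.null(stats)) {
    all <- do.call(rbind, lapply(connectomes, function(cc) cc@data))
    mu <- colMeans(all)
    sd <- apply(all, 2, stats::sd)
    zero <- sd == 0
    if (any(zero)) {
      warnf("%d zero-sd channels left unscaled", sum(zero))
      sd[zero] <- 1
      mu[zero] <- 0
    }
    stats <- list(mean = mu, sd = sd)
  }
  out <- lapply(connectomes, function(cc) {
    x <- applyChannelStats(cc@data, stats)
    list(data = x, subject = cc@subject, vertexMask = cc@vertexMask,
         channelNames = cc@channelNames)
  })
  list(connectomes = if (single) out[[1]] else out, stats = stats)
}

applyChannelStats <- function(x, stats) {
  sweep(sweep(x, 2, stats$mean), 2, stats$sd, "/")
}

invertChannelStats <- function(x, stats) {
  sweep(sweep(x, 2, stats$sd, "*"), 2, stats$mean, "+")
}
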