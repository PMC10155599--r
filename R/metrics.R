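## Evaluation: thresholded Dice and Dice AUC, whole-brain R^2, subject
## identification, reliability screening, and a tidy evaluation report.

#' Top-fraction activation set
#'
#' The k = max(1, round(x * V_masked)) unmasked vertices with the largest
#' values ("most activated"). Rounding is round-half-even; ties break to
#' the lower vertex index. Modes: "signed" ranks raw values (default),
#' "absolute" ranks |value|, "deactivated" ranks -value.
#'
#' @param map length-V numeric activation map.
#' @param x fraction in (0, 1].
#' @param mask logical inclusion mask (default all).
#' @param mode "signed", "absolute" or "deactivated".
#' @return integer vector of selected vertex indices (1-based, unsorted by
#'   rank but returned sorted for set arithmetic).
#' @export
topFracSet <- function(map, x, mask = NULL,
                       mode = c("signed", "absolute", "deactivated")) {
  mode <- match.arg(mode)
  if (x <= 0 || x > 1) stopf("fraction x must lie in (0, 1]")
  if (is.null(mask)) mask <- rep(TRUE, length(map))
  idx <- which(mask)
  if (length(idx) == 0L) stopf("empty vertex mask")
  v <- switch(mode, signed = map[idx], absolute = abs(map[idx]),
              deactivated = -map[idx])
  k <- max(1L, round(x * length(idx)))
  ord <- order(v, decreasing = TRUE)  # stable: ties keep lower index first
  sort(idx[ord[seq_len(k)]])
}

#' Dice overlap at one threshold
#'
#' \code{2 |A intersect B| / (|A| + |B|)} where A and B are the
#' top-fraction sets of the two maps. Symmetric whenever both maps use the
#' same fraction and mask (equal set sizes).
#'
#' @param pred,target length-V numeric maps on the same mesh.
#' @param x threshold fraction in (0, 1].
#' @param mask logical inclusion mask.
#' @param mode passed to \code{\link{topFracSet}}.
#' @return Dice score in [0, 1].
#' @export
diceAt <- function(pred, target, x, mask = NULL, mode = "signed") {
  if (length(pred) != length(target))
    stopf("maps live on different meshes (%d vs %d vertices)",
          length(pred), length(target))
  A <- topFracSet(pred, x, mask, mode)
  B <- topFracSet(target, x, mask, mode)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

#' Dice curve and area under it
#'
#' Dice overlap at the 10 fractions 0.05, 0.10, ..., 0.50 of most activated
#' vertices, integrated over the fraction axis with the composite
#' trapezoidal rule. Identical maps give AUC = 0.45 (width of the axis).
#'
#' @inheritParams diceAt
#' @param thresholds fraction grid (default \code{seq(0.05, 0.5, 0.05)}).
#' @return a \linkS4class{DiceCurve}.
#' @export
diceAUC <- function(pred, target, mask = NULL, mode = "signed",
                    thresholds = seq(0.05, 0.50, by = 0.05)) {
  pred <- as.numeric(pred)
  target <- as.numeric(target)
  d <- vapply(thresholds, function(x) diceAt(pred, target, x, mask, mode), 1)
  new("DiceCurve", thresholds = thresholds, dice = d,
      auc = trapezoid(thresholds, d))
}

#' Whole-brain R^2
#'
#' Per contrast, \code{1 - SS_res / SS_tot} over masked vertices where
#' SS_tot centers the target at its own mean; the across-contrast mean is
#' returned as the summary when maps are multi-channel. A zero-variance
#' target yields NA for that contrast (flagged sentinel).
#'
#' @param pred,target numeric vectors or V x C matrices on the same mesh.
#' @param mask logical vertex mask.
#' @return list(r2: per-contrast values, mean: across-contrast mean).
#' @export
wholeBrainR2 <- function(pred, target, mask = NULL) {
  pred <- as.matrix(asMapMatrix(pred))
  target <- as.matrix(asMapMatrix(target))
  if (!all(dim(pred) == dim(target))) stopf("prediction/target shape mismatch")
  if (is.null(mask)) mask <- rep(TRUE, nrow(target))
  r2 <- vapply(seq_len(ncol(target)), function(c) {
    y <- target[mask, c]
    p <- pred[mask, c]
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((y - p)^2) / sst
  }, 1)
  list(r2 = r2, mean = mean(r2, na.rm = TRUE))
}

#' Subject identification matrix
#'
#' Entry (i, j) is the Dice AUC between subject j's prediction and subject
#' i's target for one contrast. A subject is identified when its column's
#' strict maximum sits on the diagonal (ties count as failure); accuracy is
#' the identified fraction.
#'
#' @param preds,targets lists of per-subject maps (numeric vectors,
#'   \linkS4class{ContrastMaps} columns are extracted via \code{contrast}).
#' @param contrast contrast index or name when maps are multi-channel.
#' @param mask logical vertex mask.
#' @param mode passed to \code{\link{topFracSet}}.
#' @return an \linkS4class{IdentMatrix}.
#' @export
identificationMatrix <- function(preds, targets, contrast = 1L, mask = NULL,
                                 mode = "signed") {
  N <- length(preds)
  if (N < 2L) stopf("identification needs at least 2 subjects")
  if (N != length(targets)) stopf("prediction/target subject lists differ")
  getMap <- function(x) {
    if (is(x, "ContrastMaps")) {
      ci <- if (is.character(contrast)) match(contrast, x@contrastNames)
            else contrast
      x@data[, ci]
    } else as.numeric(x)
  }
  Pm <- lapply(preds, getMap)
  Tm <- lapply(targets, getMap)
  if (is.null(mask) && is(targets[[1]], "ContrastMaps"))
    mask <- targets[[1]]@vertexMask
  A <- matrix(NA_real_, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    A[i, j] <- diceAUC(Pm[[j]], Tm[[i]], mask, mode)@auc
  acc <- identAccuracy(A)
  new("IdentMatrix", aucMatrix = A, accuracy = acc)
}

## strict-diagonal-maximum column counting
identAccuracy <- function(A) {
  N <- ncol(A)
  hits <- vapply(seq_len(N), function(j) {
    col <- A[, j]
    col[j] > max(col[-j])
  }, TRUE)
  mean(hits)
}

#' Reliability screening of contrasts
#'
#' A contrast is individual-level reliable when the mean (over subjects)
#' target-vs-repeat Dice AUC exceeds the mean target-vs-group-average Dice
#' AUC.
#'
#' @param targets,repeats lists of per-subject \linkS4class{ContrastMaps}
#'   (first and repeat visit).
#' @param groupAvg group-average \linkS4class{ContrastMaps}.
#' @param mask logical vertex mask.
#' @param mode passed to \code{\link{topFracSet}}.
#' @return data.frame with per-contrast mean repeat AUC, mean group AUC and
#'   the reliability flag.
#' @export
reliabilityScreen <- function(targets, repeats, groupAvg, mask = NULL,
                              mode = "signed") {
  if (length(targets) != length(repeats))
    stopf("every test subject needs a repeat visit")
  C <- ncol(targets[[1]]@data)
  if (is.null(mask)) mask <- targets[[1]]@vertexMask
  res <- lapply(seq_len(C), function(c) {
    repAuc <- mean(vapply(seq_along(targets), function(i)
      diceAUC(repeats[[i]]@data[, c], targets[[i]]@data[, c], mask, mode)@auc, 1))
    grpAuc <- mean(vapply(seq_along(targets), function(i)
      diceAUC(groupAvg@data[, c], targets[[i]]@data[, c], mask, mode)@auc, 1))
    data.frame(contrast = targets[[1]]@contrastNames[c],
               repeatAUC = repAuc, groupAUC = grpAuc,
               reliable = repAuc > grpAuc)
  })
  do.call(rbind, res)
}

#' Tidy evaluation report
#'
#' One row per subject x contrast x comparator with the 10 Dice values,
#' the Dice AUC and the whole-brain R^2; writable as CSV.
#'
#' @param preds named list of comparator prediction lists (each a list of
#'   per-subject \linkS4class{ContrastMaps}), e.g.
#'   \code{list(prediction = ..., group_avg = ..., linear = ...)}.
#' @param targets list of per-subject target \linkS4class{ContrastMaps}.
#' @param mask logical vertex mask.
#' @param file optional CSV path to write.
#' @return data.frame (invisibly written to \code{file} when given).
#' @export
evaluationReport <- function(preds, targets, mask = NULL, file = NULL) {
  thr <- seq(0.05, 0.50, by = 0.05)
  rows <- list()
  C <- ncol(targets[[1]]@data)
  if (is.null(mask)) mask <- targets[[1]]@vertexMask
  for (cmp in names(preds)) {
    plist <- preds[[cmp]]
    for (i in seq_along(targets)) {
      p <- if (is(plist, "ContrastMaps")) plist else plist[[i]]
      for (c in seq_len(C)) {
        dc <- diceAUC(p@data[, c], targets[[i]]@data[, c], mask)
        r2 <- wholeBrainR2(p@data[, c, drop = FALSE],
                           targets[[i]]@data[, c, drop = FALSE], mask)$mean
        row <- data.frame(subject = targets[[i]]@subject,
                          contrast = targets[[i]]@contrastNames[c],
                          comparator = cmp, auc = dc@auc, r2 = r2)
        dice <- as.data.frame(as.list(stats::setNames(dc@dice,
                 sprintf("dice_%02d", round(100 * thr)))))
        rows[[length(rows) + 1L]] <- cbind(row, dice)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
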