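## Training: MSE and reconstructive-contrastive objectives, margin
## initialization and schedule, Adam, two-phase schedules, finetuning
## modes with channel masking, and test-time ensembling.

#' Loss configuration
#'
#' @param alpha same-subject (reconstructive) margin, >= 0.
#' @param gamma across-subject (contrastive) margin, >= 0.
#' @param channelMask logical per-contrast mask; TRUE channels contribute
#'   to the divergence, FALSE channels are held out of loss and gradient.
#' @return a \linkS4class{LossConfig}.
#' @export
lossConfig <- function(alpha = 0, gamma = 0, channelMask = logical(0)) {
  new("LossConfig", alpha = alpha, gamma = gamma,
      channelMask = as.logical(channelMask))
}

## mean squared divergence over unmasked vertices x unmasked channels
divergence <- function(a, b, vmask, cmask) {
  d <- (a - b)[vmask, cmask, drop = FALSE]
  mean(d * d)
}

asMapMatrix <- function(x) if (is(x, "SurfaceData")) x@data else as.matrix(x)

#' Reconstructive-contrastive loss
#'
#' \code{L_R} is the batch mean of the same-subject divergence
#' \code{d(pred_i, target_i)}; \code{L_C} averages the cross divergence
#' \code{d(pred_i, target_j)} over the (N^2 - N)/2 unordered cross pairs
#' (each pair's two directions are averaged, which equals the ordered-pair
#' mean). The combined hinge loss is
#' \code{L_RC = max(L_R - alpha, 0) + max(L_R - L_C + gamma, 0)}.
#' With a single-subject batch the contrastive term is undefined and the
#' loss falls back to the hinge on \code{L_R} alone (with a message).
#'
#' @param preds,targets lists of \linkS4class{ContrastMaps} (or V x C
#'   matrices), one per batch subject, in matching order.
#' @param cfg a \linkS4class{LossConfig}.
#' @param vertexMask optional logical vertex inclusion mask (defaults to
#'   the first target's mask, or all vertices).
#' @return a \linkS4class{LossReport}.
#' @export
rcLoss <- function(preds, targets, cfg = lossConfig(), vertexMask = NULL) {
  rcLossCore(preds, targets, cfg, vertexMask, wantGrad = FALSE)$report
}

rcLossCore <- function(preds, targets, cfg, vertexMask = NULL,
                       wantGrad = FALSE) {
  if (is(preds, "SurfaceData") || is.matrix(preds)) preds <- list(preds)
  if (is(targets, "SurfaceData") || is.matrix(targets)) targets <- list(targets)
  N <- length(preds)
  stopifnot(N == length(targets), N >= 1L)
  P <- lapply(preds, asMapMatrix)
  Tm <- lapply(targets, asMapMatrix)
  C <- ncol(P[[1]])
  cmask <- if (length(cfg@channelMask)) cfg@channelMask else rep(TRUE, C)
  if (length(cmask) != C) stopf("channel mask length %d != %d channels",
                                length(cmask), C)
  if (!any(cmask)) stopf("channel mask removes all channels")
  vmask <- if (!is.null(vertexMask)) vertexMask
           else if (is(targets[[1]], "SurfaceData")) targets[[1]]@vertexMask
           else rep(TRUE, nrow(P[[1]]))
  nel <- sum(vmask) * sum(cmask)
  lR <- mean(vapply(seq_len(N), function(i)
    divergence(P[[i]], Tm[[i]], vmask, cmask), 1))
  nPairs <- as.integer((N^2 - N) / 2)
  if (N >= 2L) {
    cross <- 0
    for (i in seq_len(N)) for (j in seq_len(N)) if (i != j)
      cross <- cross + divergence(P[[i]], Tm[[j]], vmask, cmask)
    lC <- cross / (N^2 - N)
    lRC <- max(lR - cfg@alpha, 0) + max(lR - lC + cfg@gamma, 0)
  } else {
    message("single-subject batch: contrastive term undefined, using hinge on L_R only")
    lC <- NA_real_
    lRC <- max(lR - cfg@alpha, 0)
  }
  report <- new("LossReport", lR = lR, lC = if (is.na(lC)) 0 else lC,
                lRC = lRC, n = N, nPairs = nPairs)
  if (is.na(lC)) report@lC <- NA_real_
  if (!wantGrad) return(list(report = report))
  ## analytic gradient of L_RC w.r.t. each prediction
  h1 <- as.numeric(lR > cfg@alpha)                       # d/dL_R of hinge 1
  h2 <- if (N >= 2L) as.numeric(lR - lC + cfg@gamma > 0) else 0
  grads <- vector("list", N)
  sel <- outer(vmask, cmask)
  for (i in seq_len(N)) {
    g <- matrix(0, nrow(P[[i]]), C)
    coefR <- (h1 + h2) * 2 / (N * nel)
    if (coefR != 0) g <- g + coefR * (P[[i]] - Tm[[i]])
    if (h2 != 0 && N >= 2L) {
      coefC <- -h2 * 2 / ((N^2 - N) * nel)
      for (j in seq_len(N)) if (j != i) g <- g + coefC * (P[[i]] - Tm[[j]])
    }
    g[!sel] <- 0
    grads[[i]] <- g
  }
  list(report = report, grads = grads)
}

## plain MSE objective (reconstructive only): loss and per-subject gradient
mseLossCore <- function(P, Tm, vmask, cmask) {
  N <- length(P)
  nel <- sum(vmask) * sum(cmask)
  sel <- outer(vmask, cmask)
  lR <- mean(vapply(seq_len(N), function(i)
    divergence(P[[i]], Tm[[i]], vmask, cmask), 1))
  grads <- lapply(seq_len(N), function(i) {
    g <- 2 / (N * nel) * (P[[i]] - Tm[[i]])
    g[!sel] <- 0
    g
  })
  list(lR = lR, grads = grads)
}

#' Initialize R-C margins from a converged model
#'
#' Computes the average reconstructive loss \code{L_R} and contrastive loss
#' \code{L_C} over all training subjects (first connectome sample of each)
#' and derives initial margins: \code{alpha0 = L_R}; by the default "gap"
#' rule \code{gamma0 = max(L_C - L_R, 0)}, by the alternative "full" rule
#' \code{gamma0 = L_C}. Deterministic for a fixed model and data.
#'
#' @param model a trained \linkS4class{SurfModel} (phase-1 checkpoint).
#' @param connectomes list (per subject) of connectome samples, or a list
#'   of single \linkS4class{Connectome} objects.
#' @param targets list of per-subject \linkS4class{ContrastMaps}.
#' @param cfg \linkS4class{LossConfig} carrying the channel mask.
#' @param rule "gap" (default) or "full".
#' @return list(alpha0, gamma0, lR, lC).
#' @export
initMargins <- function(model, connectomes, targets, cfg = lossConfig(),
                        rule = c("gap", "full")) {
  rule <- match.arg(rule)
  if (length(targets) < 2L) stopf("margin initialization needs >= 2 subjects")
  first <- lapply(connectomes, function(x) if (is.list(x)) x[[1]] else x)
  preds <- lapply(first, function(cc) modelForward(model, prepInput(model, cc)))
  rep0 <- rcLoss(preds, targets, lossConfig(0, 0, cfg@channelMask))
  alpha0 <- rep0@lR
  gamma0 <- switch(rule, gap = max(rep0@lC - rep0@lR, 0), full = rep0@lC)
  list(alpha0 = alpha0, gamma0 = gamma0, lR = rep0@lR, lC = rep0@lC)
}

#' Margin schedule
#'
#' Within the R-C phase the same-subject margin is halved and the
#' across-subject margin doubled every \code{period} epochs:
#' \code{alpha = alpha0 / 2^floor(epoch/period)},
#' \code{gamma = gamma0 * 2^floor(epoch/period)}.
#'
#' @param alpha0,gamma0 initial margins.
#' @param epoch 0-based epoch within the phase.
#' @param period epochs between margin updates (default 20).
#' @return list(alpha, gamma).
#' @export
marginSchedule <- function(alpha0, gamma0, epoch, period = 20L) {
  if (epoch < 0) stopf("epoch must be >= 0")
  k <- floor(epoch / period)
  list(alpha = alpha0 / 2^k, gamma = gamma0 * 2^k)
}

#' Describe one training phase
#'
#' @param objective "mse" or "rc".
#' @param epochs number of epochs.
#' @param batchSize minibatch size (>= 2 for "rc").
#' @param lr Adam learning rate.
#' @param alpha0,gamma0 optional fixed initial margins for "rc"; when NULL
#'   they are computed with \code{\link{initMargins}} at phase start.
#' @param marginPeriod epochs between margin updates.
#' @param marginRule "gap" or "full" (see \code{\link{initMargins}}).
#' @return a phase description list for \code{\link{trainModel}}.
#' @export
phaseSpec <- function(objective = c("mse", "rc"), epochs, batchSize = 2L,
                      lr = 1e-3, alpha0 = NULL, gamma0 = NULL,
                      marginPeriod = 20L, marginRule = "gap") {
  objective <- match.arg(objective)
  if (objective == "rc" && batchSize < 2L)
    stopf("the R-C objective needs batch size >= 2")
  list(objective = objective, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), lr = lr, alpha0 = alpha0,
       gamma0 = gamma0, marginPeriod = as.integer(marginPeriod),
       marginRule = marginRule)
}

prepInput <- function(model, connectome) {
  x <- asMapMatrix(connectome)
  if (length(model@normStats)) x <- applyChannelStats(x, model@normStats)
  x
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       v = lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       t = 0L)
}

adamStep <- function(params, grads, state, names, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## accumulate named gradient lists
addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

#' Train a surface network
#'
#' Runs a phase plan over a cohort. Each epoch shuffles the subjects and
#' samples one connectome per subject (contiguous-segment augmentation);
#' all randomness (shuffling, sampling) is governed by \code{seed}.
#' "mse" phases minimize the reconstructive loss; "rc" phases minimize the
#' reconstructive-contrastive hinge loss with margins initialized from the
#' converged model at phase start and rescheduled every
#' \code{marginPeriod} epochs. When a validation set is supplied the
#' best-validation parameters are restored after the final phase.
#'
#' @param model a \linkS4class{SurfModel}.
#' @param subjects list, one element per training subject:
#'   \code{list(connectomes = list of Connectome, target = ContrastMaps)}.
#' @param phases list of phases from \code{\link{phaseSpec}}.
#' @param valSubjects optional validation list shaped like \code{subjects}.
#' @param seed integer seed for shuffling/sampling.
#' @param channelMask optional logical per-contrast loss mask.
#' @param normalize compute (or reuse) per-channel input z-scoring stats
#'   from the training connectomes (default TRUE).
#' @return the trained \linkS4class{SurfModel} with a populated
#'   \code{history} (per-epoch losses and margins).
#' @export
trainModel <- function(model, subjects, phases, valSubjects = NULL,
                       seed = 1L, channelMask = NULL, normalize = TRUE) {
  if (length(subjects) == 0L) stopf("empty training cohort")
  C <- model@spec@outChannels
  cmask <- if (is.null(channelMask)) rep(TRUE, C) else as.logical(channelMask)
  if (length(cmask) != C) stopf("channel mask must have length %d", C)
  if (!any(cmask)) stopf("channel mask removes all channels")
  if (normalize && !length(model@normStats)) {
    allConn <- unlist(lapply(subjects, `[[`, "connectomes"), recursive = FALSE)
    model@normStats <- normalizeChannels(allConn)$stats
  }
  inputs <- lapply(subjects, function(s)
    lapply(s$connectomes, function(cc) prepInput(model, cc)))
  targets <- lapply(subjects, function(s) asMapMatrix(s$target))
  vmask <- if (is(subjects[[1]]$target, "SurfaceData"))
    subjects[[1]]$target@vertexMask else rep(TRUE, nrow(targets[[1]]))
  valIn <- if (!is.null(valSubjects))
    lapply(valSubjects, function(s) prepInput(model, s$connectomes[[1]]))
  valTg <- if (!is.null(valSubjects))
    lapply(valSubjects, function(s) asMapMatrix(s$target))
  n <- length(subjects)
  adam <- adamInit(model@params)
  hist <- list()
  bestVal <- Inf
  bestParams <- NULL
  set.seed(as.integer(seed))
  for (ph in seq_along(phases)) {
    phase <- phases[[ph]]
    alpha0 <- phase$alpha0
    gamma0 <- phase$gamma0
    if (phase$objective == "rc" && (is.null(alpha0) || is.null(gamma0))) {
      conns1 <- lapply(subjects, `[[`, "connectomes")
      mi <- initMargins(model, conns1, lapply(subjects, `[[`, "target"),
                        lossConfig(0, 0, cmask), rule = phase$marginRule)
      if (is.null(alpha0)) alpha0 <- mi$alpha0
      if (is.null(gamma0)) gamma0 <- mi$gamma0
    }
    for (ep in seq_len(phase$epochs) - 1L) {
      marg <- if (phase$objective == "rc")
        marginSchedule(alpha0, gamma0, ep, phase$marginPeriod)
      else list(alpha = NA_real_, gamma = NA_real_)
      ord <- sample.int(n)
      pick <- vapply(seq_len(n), function(i)
        sample.int(length(inputs[[i]]), 1L), 1L)
      epLoss <- epLR <- epLC <- 0
      nb <- 0L
      b0 <- 1L
      while (b0 <= n) {
        idx <- ord[b0:min(b0 + phase$batchSize - 1L, n)]
        b0 <- b0 + phase$batchSize
        fws <- lapply(idx, function(i)
          modelForward(model, inputs[[i]][[pick[i]]], cache = TRUE))
        P <- lapply(fws, `[[`, "out")
        Tm <- targets[idx]
        if (phase$objective == "mse") {
          lo <- mseLossCore(P, Tm, vmask, cmask)
          loss <- lo$lR; lR <- lo$lR; lC <- NA_real_
          dpred <- lo$grads
        } else {
          lo <- rcLossCore(P, Tm,
                           new("LossConfig", alpha = marg$alpha,
                               gamma = marg$gamma, channelMask = cmask),
                           vertexMask = vmask, wantGrad = TRUE)
          loss <- lo$report@lRC; lR <- lo$report@lR; lC <- lo$report@lC
          dpred <- lo$grads
        }
        grads <- NULL
        for (k in seq_along(idx))
          grads <- addGrads(grads, modelBackward(model, fws[[k]], dpred[[k]]))
        st <- adamStep(model@params, grads, adam, trainableNames(model),
                       phase$lr)
        model@params <- st$params
        adam <- st$state
        epLoss <- epLoss + loss
        epLR <- epLR + lR
        epLC <- epLC + if (is.na(lC)) 0 else lC
        nb <- nb + 1L
      }
      valLoss <- NA_real_
      if (!is.null(valSubjects)) {
        vp <- lapply(valIn, function(x) modelForward(model, x))
        valLoss <- mseLossCore(vp, valTg, vmask, cmask)$lR
        if (valLoss < bestVal) {
          bestVal <- valLoss
          bestParams <- model@params
        }
      }
      hist[[length(hist) + 1L]] <- data.frame(
        phase = ph, epoch = ep, objective = phase$objective,
        loss = epLoss / nb, lR = epLR / nb,
        lC = if (phase$objective == "rc") epLC / nb else NA_real_,
        alpha = marg$alpha, gamma = marg$gamma, val = valLoss)
    }
  }
  if (!is.null(bestParams)) model@params <- bestParams
  model@history <- do.call(rbind, hist)
  model
}

#' Finetune a pretrained model
#'
#' Transfer-learning modes:
#' \itemize{
#'   \item \code{"denovo"}: ignore the pretrained weights; build a fresh
#'     model from the same spec (re-seeded) and train it.
#'   \item \code{"full_with_new_head"}: replace the head (optionally with a
#'     new output channel count), then finetune all layers.
#'   \item \code{"backbone_only"}: freeze the head and finetune the
#'     backbone with the loss restricted to the unmasked channels; held-out
#'     channels contribute no gradient.
#' }
#' Finetuning uses the MSE objective (the contrastive term is disabled by
#' default on small datasets).
#'
#' @param model pretrained \linkS4class{SurfModel}.
#' @param subjects training list as in \code{\link{trainModel}}.
#' @param mode one of "denovo", "full_with_new_head", "backbone_only".
#' @param epochs,batchSize,lr training budget.
#' @param seed seed for sampling (and fresh init under "denovo").
#' @param channelMask logical per-contrast mask for "backbone_only" (FALSE
#'   = held-out); a mask with no held-out channel triggers a warning.
#' @param cNew output channels for the new head (default: keep).
#' @param headSeed seed for the new head ("full_with_new_head").
#' @param valSubjects optional validation list.
#' @return the finetuned \linkS4class{SurfModel}.
#' @export
finetuneModel <- function(model, subjects,
                          mode = c("denovo", "full_with_new_head",
                                   "backbone_only"),
                          epochs = 20L, batchSize = 2L, lr = 1e-3,
                          seed = 1L, channelMask = NULL, cNew = NULL,
                          headSeed = seed, valSubjects = NULL) {
  mode <- match.arg(mode)
  phases <- list(phaseSpec("mse", epochs = epochs, batchSize = batchSize,
                           lr = lr))
  if (mode == "denovo") {
    spec <- model@spec
    if (!is.null(cNew)) spec@outChannels <- as.integer(cNew)
    spec@seed <- as.integer(seed)
    fresh <- buildModel(spec)
    return(trainModel(fresh, subjects, phases, valSubjects = valSubjects,
                      seed = seed))
  }
  if (mode == "full_with_new_head") {
    model <- replaceHead(model, if (is.null(cNew)) model@spec@outChannels
                                else cNew, headSeed)
    model <- setTrainable(model, c("backbone", "head"))
    ## input statistics belong to the new domain
    model@normStats <- list()
    return(trainModel(model, subjects, phases, valSubjects = valSubjects,
                      seed = seed))
  }
  ## backbone_only
  C <- model@spec@outChannels
  if (is.null(channelMask)) channelMask <- rep(TRUE, C)
  if (all(channelMask))
    warnf("backbone_only finetuning without a held-out channel")
  model <- setTrainable(model, "backbone")
  model@normStats <- list()
  trainModel(model, subjects, phases, valSubjects = valSubjects,
             seed = seed, channelMask = channelMask)
}

#' Test-time ensembled prediction
#'
#' Averages the forward passes over every connectome sample of a subject
#' (one per run segment) vertex-wise.
#'
#' @param model a \linkS4class{SurfModel}.
#' @param connectomes non-empty list of \linkS4class{Connectome} samples of
#'   one subject (a single Connectome is accepted).
#' @param contrastNames optional output channel names.
#' @return a \linkS4class{ContrastMaps}.
#' @export
ensemblePredict <- function(model, connectomes, contrastNames = NULL) {
  if (is(connectomes, "Connectome")) connectomes <- list(connectomes)
  if (length(connectomes) == 0L) stopf("empty connectome list")
  preds <- lapply(connectomes, function(cc)
    modelForward(model, prepInput(model, cc)))
  avg <- Reduce(`+`, preds) / length(preds)
  if (is.null(contrastNames))
    contrastNames <- sprintf("contrast%02d", seq_len(ncol(avg)))
  new("ContrastMaps", data = avg,
      vertexMask = connectomes[[1]]@vertexMask,
      subject = connectomes[[1]]@subject, contrastNames = contrastNames)
}
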