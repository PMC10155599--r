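## End-to-end scaled experiments on synthetic cohorts: the package's own
## self-contained counterpart of the benchmark workflow (train with MSE,
## continue with the R-C objective, compare against group-average and
## parcel-linear references, quantify identification), plus the transfer
## workflow (finetune vs denovo, backbone-only leave-one-task-out).

meanTestAUC <- function(predList, targets, mask) {
  mean(vapply(seq_along(targets), function(i) {
    p <- if (is(predList, "ContrastMaps")) predList else predList[[i]]
    mean(vapply(seq_len(ncol(p@data)), function(c)
      diceAUC(p@data[, c], targets[[i]]@data[, c], mask)@auc, 1))
  }, 1))
}

meanIdentAccuracy <- function(preds, targets, mask) {
  C <- ncol(targets[[1]]@data)
  mean(vapply(seq_len(C), function(c)
    identificationMatrix(preds, targets, contrast = c, mask = mask)@accuracy, 1))
}

## across-segment mean connectome of one subject (linear baseline features)
meanConnectome <- function(conns) {
  avg <- Reduce(`+`, lapply(conns, function(x) x@data)) / length(conns)
  new("Connectome", data = avg, vertexMask = conns[[1]]@vertexMask,
      subject = conns[[1]]@subject, channelNames = conns[[1]]@channelNames)
}

#' Run the scaled synthetic benchmark experiment
#'
#' Generates a seeded cohort, trains the surface network in two phases
#' (MSE, then reconstructive-contrastive with scheduled margins), fits the
#' group-average and ensembled parcel-linear references on the same
#' training subjects, and evaluates everything on held-out test subjects
#' with test-time connectome ensembling.
#'
#' @param seed master seed; cohort, initialization and sampling seeds are
#'   derived from it.
#' @param nTrain,nTest training and test subject counts.
#' @param level,M,C,link cohort geometry and rest-to-task coupling.
#' @param mseEpochs,rcEpochs epochs of the two phases.
#' @param depth,widths network topology.
#' @param lr,batchSize optimizer settings; \code{rcLr} is the phase-2
#'   learning rate (smaller so the hinge boundary is tracked closely).
#' @param rcLr learning rate of the R-C phase.
#' @param cohort optional pre-built cohort (overrides generation).
#' @param mseModel optional phase-1 model to resume from (skips phase 1).
#' @return list of summary quantities: mean test Dice AUCs (model after
#'   each phase, group average, linear baseline, repeat scan, oracle),
#'   identification accuracies after each phase, whole-brain R^2, final
#'   \code{L_R} and margin \code{alpha}, the trained model and the cohort.
#' @export
runSyntheticExperiment <- function(seed, nTrain = 40L, nTest = 10L,
                                   level = 3L, M = 10L, C = 6L,
                                   link = "nonlinear", mseEpochs = 30L,
                                   rcEpochs = 20L, depth = 2L,
                                   widths = c(32L, 48L, 64L), lr = 3e-3,
                                   rcLr = 1e-3, batchSize = 2L,
                                   cohort = NULL, mseModel = NULL) {
  set.seed(as.integer(seed))
  cohortSeed <- subSeed(); initSeed <- subSeed()
  trainSeed <- subSeed(); rcSeed <- subSeed()
  if (is.null(cohort))
    cohort <- makeCohort(cohortConfig(nSubjects = nTrain + nTest, level = level,
                                      M = M, C = C, link = link,
                                      seed = cohortSeed))
  conns <- cohortConnectomes(cohort)
  trIdx <- seq_len(nTrain)
  teIdx <- nTrain + seq_len(nTest)
  trainData <- cohortTrainingData(cohort, conns, indices = trIdx)
  targetsTe <- lapply(cohort$subjects[teIdx], function(s) s$visits[[1]])
  repeatsTe <- lapply(cohort$subjects[teIdx], function(s) s$visits[[2]])
  mask <- targetsTe[[1]]@vertexMask
  cNames <- targetsTe[[1]]@contrastNames

  if (is.null(mseModel)) {
    spec <- modelSpec(level, depth, inChannels = ncol(conns[[1]][[1]]@data),
                      outChannels = C, widths = widths, seed = initSeed)
    model <- buildModel(spec)
    model <- trainModel(model, trainData,
                        list(phaseSpec("mse", epochs = mseEpochs, lr = lr,
                                       batchSize = batchSize)),
                        seed = trainSeed)
  } else model <- mseModel
  predPhase1 <- lapply(teIdx, function(i)
    ensemblePredict(model, conns[[i]], contrastNames = cNames))
  histMse <- model@history
  msePhaseModel <- model
  model <- trainModel(model, trainData,
                      list(phaseSpec("rc", epochs = rcEpochs, lr = rcLr,
                                     batchSize = batchSize)),
                      seed = rcSeed)
  predPhase2 <- lapply(teIdx, function(i)
    ensemblePredict(model, conns[[i]], contrastNames = cNames))

  ## references
  targetsTr <- lapply(cohort$subjects[trIdx], function(s) s$visits[[1]])
  ga <- groupAverage(targetsTr)
  linFit <- fitParcelLinear(lapply(trIdx, function(i) meanConnectome(conns[[i]])),
                            targetsTr, cohort$parcellation)
  linPred <- lapply(teIdx, function(i)
    predictParcelLinear(linFit, meanConnectome(conns[[i]])))
  oracle <- lapply(teIdx, function(i) oraclePredictor(cohort$groundTruth, i))

  hist2 <- model@history
  lastRc <- hist2[hist2$objective == "rc", ]
  lastRc <- lastRc[nrow(lastRc), ]
  list(
    aucModel = meanTestAUC(predPhase2, targetsTe, mask),
    aucModelMse = meanTestAUC(predPhase1, targetsTe, mask),
    aucGroup = meanTestAUC(ga, targetsTe, mask),
    aucLinear = meanTestAUC(linPred, targetsTe, mask),
    aucRepeat = meanTestAUC(repeatsTe, targetsTe, mask),
    aucOracle = meanTestAUC(oracle, targetsTe, mask),
    identRc = meanIdentAccuracy(predPhase2, targetsTe, mask),
    identMse = meanIdentAccuracy(predPhase1, targetsTe, mask),
    r2Model = mean(vapply(seq_along(teIdx), function(i)
      wholeBrainR2(predPhase2[[i]], targetsTe[[i]], mask)$mean, 1)),
    r2Linear = mean(vapply(seq_along(teIdx), function(i)
      wholeBrainR2(linPred[[i]], targetsTe[[i]], mask)$mean, 1)),
    finalLR = lastRc$lR, finalAlpha = lastRc$alpha,
    history = rbind(histMse, hist2),
    model = model, msePhaseModel = msePhaseModel,
    cohort = cohort, connectomes = conns,
    predictions = predPhase2, testIdx = teIdx)
}

#' Run the scaled transfer-learning experiment
#'
#' From a pretrained model and its base cohort, generates a small cohort in
#' a shifted domain (same tasks, shifted group templates, new subjects) and
#' compares, at matched budget: (1) full finetuning of the pretrained model
#' with a re-initialized head versus training from scratch; (2)
#' backbone-only finetuning with one contrast held out of the loss versus
#' the non-finetuned pretrained model, on that held-out contrast.
#'
#' @param seed master seed.
#' @param pretrained trained \linkS4class{SurfModel} from the base domain.
#' @param baseCohort the cohort the model was pretrained on.
#' @param nTrain,nTest transfer-domain subject counts.
#' @param epochs,lr,batchSize matched finetuning budget.
#' @param templateShift,loadingShift magnitude of the output-side
#'   (template) and input-side (connectivity loading) domain shifts.
#' @param heldOut index of the contrast excluded in backbone-only mode.
#' @return list with mean test Dice AUCs of the finetuned, denovo and
#'   pretrained models, and the held-out-contrast AUCs before/after
#'   backbone-only finetuning.
#' @export
runTransferExperiment <- function(seed, pretrained, baseCohort,
                                  nTrain = 12L, nTest = 6L, epochs = 12L,
                                  lr = 1e-3, batchSize = 2L,
                                  templateShift = 0.3, loadingShift = 0.6,
                                  heldOut = 1L) {
  set.seed(as.integer(seed))
  cohortSeed <- subSeed(); ftSeed <- subSeed(); dnSeed <- subSeed()
  boSeed <- subSeed()
  cfg0 <- baseCohort$config
  ## transfer domain: shorter rest scans, noisier and slower timeseries --
  ## an acquisition shift the backbone can adapt to
  cfg <- cohortConfig(nSubjects = nTrain + nTest, level = cfg0@level,
                      M = cfg0@M, K = cfg0@K, C = cfg0@C, T = 600L, R = 2L,
                      sigmaTs = 0.7, arCoef = 0.45, globalSignal = 0.6,
                      link = cfg0@link, seed = cohortSeed)
  cohort <- makeCohort(cfg, groundTruth = baseCohort$groundTruth,
                       templateShift = templateShift,
                       loadingShift = loadingShift)
  conns <- cohortConnectomes(cohort)
  trIdx <- seq_len(nTrain)
  teIdx <- nTrain + seq_len(nTest)
  trainData <- cohortTrainingData(cohort, conns, indices = trIdx)
  targetsTe <- lapply(cohort$subjects[teIdx], function(s) s$visits[[1]])
  mask <- targetsTe[[1]]@vertexMask
  cNames <- targetsTe[[1]]@contrastNames
  C <- cfg0@C

  finetuned <- finetuneModel(pretrained, trainData, "full_with_new_head",
                             epochs = epochs, batchSize = batchSize, lr = lr,
                             seed = ftSeed, headSeed = ftSeed)
  denovo <- finetuneModel(pretrained, trainData, "denovo", epochs = epochs,
                          batchSize = batchSize, lr = lr, seed = dnSeed)
  cmask <- rep(TRUE, C); cmask[heldOut] <- FALSE
  backboneOnly <- finetuneModel(pretrained, trainData, "backbone_only",
                                epochs = epochs, batchSize = batchSize,
                                lr = lr, seed = boSeed, channelMask = cmask)

  predOf <- function(m) lapply(teIdx, function(i)
    ensemblePredict(m, conns[[i]], contrastNames = cNames))
  heldOutAUC <- function(preds) mean(vapply(seq_along(targetsTe), function(i)
    diceAUC(preds[[i]]@data[, heldOut], targetsTe[[i]]@data[, heldOut],
            mask)@auc, 1))
  pFt <- predOf(finetuned); pDn <- predOf(denovo)
  pBo <- predOf(backboneOnly); pPre <- predOf(pretrained)
  list(
    aucFinetuned = meanTestAUC(pFt, targetsTe, mask),
    aucDenovo = meanTestAUC(pDn, targetsTe, mask),
    aucPretrained = meanTestAUC(pPre, targetsTe, mask),
    heldOutFinetuned = heldOutAUC(pBo),
    heldOutPretrained = heldOutAUC(pPre),
    heldOut = heldOut, cohort = cohort)
}
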