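#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- SphereMesh

#' Icosphere mesh
#'
#' A recursively subdivided icosahedron projected onto the unit sphere.
#' Level L has 10*4^L + 2 vertices and 20*4^L faces. Vertices of level L-1
#' form the index prefix of level L (index-preserving nesting), which makes
#' pooling between levels a simple index restriction.
#'
#' @slot level non-negative integer subdivision level.
#' @slot vertices V x 3 numeric matrix of unit vectors.
#' @slot faces F x 3 integer matrix (1-based), counter-clockwise from outside.
#' @slot oneRing list of per-vertex neighbor index vectors, CCW ordered.
#' @slot coarserCount number of vertices shared with level-1 (0 at level 0).
#' @export
setClass("SphereMesh",
  representation(level = "integer", vertices = "matrix", faces = "matrix",
                 oneRing = "list", coarserCount = "integer"))

setValidity("SphereMesh", function(object) {
  L <- object@level
  V <- 10L * 4L^L + 2L
  msg <- character()
  if (L < 0L) msg <- c(msg, "level must be >= 0")
  if (nrow(object@vertices) != V)
    msg <- c(msg, sprintf("expected %d vertices at level %d", V, L))
  if (nrow(object@faces) != 20L * 4L^L)
    msg <- c(msg, sprintf("expected %d faces at level %d", 20L * 4L^L, L))
  nrm <- sqrt(rowSums(object@vertices^2))
  if (any(abs(nrm - 1) > 1e-9))
    msg <- c(msg, "vertices must have unit norm (tol 1e-9)")
  if (length(object@oneRing) != V)
    msg <- c(msg, "oneRing must have one entry per vertex")
  if (length(msg)) msg else TRUE
})

#' @describeIn SphereMesh vertex count
#' @export
setMethod("nVertices", "SphereMesh", function(x) nrow(x@vertices))

#' @describeIn SphereMesh face count
#' @export
setMethod("nFaces", "SphereMesh", function(x) nrow(x@faces))

#' @describeIn SphereMesh subdivision level
#' @export
setMethod("meshLevel", "SphereMesh", function(x) x@level)

#' @describeIn SphereMesh one-ring neighbor lists
#' @export
setMethod("oneRing", "SphereMesh", function(x) x@oneRing)

setMethod("show", "SphereMesh", function(object) {
  cat(sprintf("SphereMesh level %d: %d vertices, %d faces, %d edges\n",
              object@level, nVertices(object), nFaces(object),
              30L * 4L^object@level))
})

## ---------------------------------------------------------------- PoolingMap

#' Pooling map between consecutive icosphere levels
#'
#' Records, for every fine-only vertex (an edge midpoint introduced by one
#' subdivision), the two coarse-level endpoint indices of the bisected edge.
#' Restriction (downsampling) keeps the coarse index prefix; prolongation
#' (upsampling) copies coarse values and averages the two parents at each
#' midpoint. Both are exposed as sparse matrices.
#'
#' @slot fineLevel,coarseLevel integer levels, fine = coarse + 1.
#' @slot midpointParents (Vf - Vc) x 2 integer matrix of parent indices.
#' @slot up sparse Vf x Vc prolongation matrix.
#' @slot down sparse Vc x Vf restriction matrix.
#' @export
setClass("PoolingMap",
  representation(fineLevel = "integer", coarseLevel = "integer",
                 midpointParents = "matrix", up = "Matrix", down = "Matrix"))

setValidity("PoolingMap", function(object) {
  msg <- character()
  if (object@fineLevel != object@coarseLevel + 1L)
    msg <- c(msg, "fine level must be coarse level + 1")
  Vc <- 10L * 4L^object@coarseLevel + 2L
  Vf <- 10L * 4L^object@fineLevel + 2L
  if (nrow(object@midpointParents) != Vf - Vc || ncol(object@midpointParents) != 2L)
    msg <- c(msg, "midpointParents must be (Vf - Vc) x 2")
  if (any(object@midpointParents < 1L) || any(object@midpointParents > Vc))
    msg <- c(msg, "parent indices must lie in the coarse vertex range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PoolingMap", function(object) {
  cat(sprintf("PoolingMap level %d -> %d: %d shared vertices, %d midpoints\n",
              object@fineLevel, object@coarseLevel,
              10L * 4L^object@coarseLevel + 2L, nrow(object@midpointParents)))
})

## ------------------------------------------------------------- surface data

#' Virtual parent of vertex-attached data
#'
#' @slot data numeric V x K matrix.
#' @slot vertexMask logical length-V inclusion mask.
#' @export
setClass("SurfaceData", representation("VIRTUAL",
  data = "matrix", vertexMask = "logical"))

setValidity("SurfaceData", function(object) {
  msg <- character()
  if (length(object@vertexMask) != nrow(object@data))
    msg <- c(msg, "vertexMask length must equal number of vertices")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn SurfaceData vertex count
#' @export
setMethod("nVertices", "SurfaceData", function(x) nrow(x@data))

#' @describeIn SurfaceData inclusion mask
#' @export
setMethod("vertexMask", "SurfaceData", function(x) x@vertexMask)

#' @describeIn SurfaceData data matrix
#' @export
setMethod("values", "SurfaceData", function(x) x@data)

#' Surface-mapped fMRI timeseries
#'
#' Vertex x timepoint matrix for one run (or run segment) of one hemisphere
#' (or a single synthetic sphere).
#'
#' @slot hemisphere "L", "R" or "single".
#' @slot tr repetition time in seconds.
#' @export
setClass("SurfaceTimeseries", contains = "SurfaceData",
  representation(hemisphere = "character", tr = "numeric"))

setValidity("SurfaceTimeseries", function(object) {
  msg <- character()
  if (!object@hemisphere %in% c("L", "R", "single"))
    msg <- c(msg, "hemisphere must be 'L', 'R' or 'single'")
  if (ncol(object@data) < 2L) msg <- c(msg, "need at least 2 timepoints")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SurfaceTimeseries", function(object) {
  cat(sprintf("SurfaceTimeseries (%s): %d vertices x %d timepoints, TR %.3gs, %d masked out\n",
              object@hemisphere, nrow(object@data), ncol(object@data),
              object@tr, sum(!object@vertexMask)))
})

#' Per-subject task contrast maps
#'
#' One channel per task contrast; the prediction target and output type.
#'
#' @slot subject subject identifier.
#' @slot contrastNames unique channel names, one per contrast.
#' @export
setClass("ContrastMaps", contains = "SurfaceData",
  representation(subject = "character", contrastNames = "character"))

setValidity("ContrastMaps", function(object) {
  msg <- character()
  if (ncol(object@data) < 1L) msg <- c(msg, "need at least one contrast")
  if (length(object@contrastNames) != ncol(object@data))
    msg <- c(msg, "one name per contrast channel required")
  if (anyDuplicated(object@contrastNames))
    msg <- c(msg, "contrast names must be unique")
  if (length(msg)) msg else TRUE
})

#' @describeIn ContrastMaps subject identifier
#' @export
setMethod("subjectId", "ContrastMaps", function(x) x@subject)

#' @describeIn ContrastMaps contrast channel names
#' @export
setMethod("contrastNames", "ContrastMaps", function(x) x@contrastNames)

setMethod("show", "ContrastMaps", function(object) {
  cat(sprintf("ContrastMaps [%s]: %d vertices x %d contrasts (%s%s)\n",
              object@subject, nrow(object@data), ncol(object@data),
              paste(utils::head(object@contrastNames, 3), collapse = ", "),
              if (ncol(object@data) > 3) ", ..." else ""))
})

#' Vertex-to-ROI functional connectome
#'
#' Channel j holds the Pearson correlation between each vertex's resting
#' timeseries and the mean timeseries of ROI j; values lie in [-1, 1].
#'
#' @slot subject subject identifier.
#' @slot channelNames ROI channel names (suffixed _L/_R in bilateral mode).
#' @export
setClass("Connectome", contains = "SurfaceData",
  representation(subject = "character", channelNames = "character"))

setValidity("Connectome", function(object) {
  msg <- character()
  if (length(object@channelNames) != ncol(object@data))
    msg <- c(msg, "one name per channel required")
  if (any(object@data < -1 - 1e-8) || any(object@data > 1 + 1e-8))
    msg <- c(msg, "connectome values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn Connectome subject identifier
#' @export
setMethod("subjectId", "Connectome", function(x) x@subject)

#' @describeIn Connectome ROI channel names
#' @export
setMethod("channelNames", "Connectome", function(x) x@channelNames)

setMethod("show", "Connectome", function(object) {
  cat(sprintf("Connectome [%s]: %d vertices x %d ROI channels, range [%.3f, %.3f]\n",
              object@subject, nrow(object@data), ncol(object@data),
              min(object@data), max(object@data)))
})

## ------------------------------------------------------------- parcellation

#' Winner-take-all parcellation labels
#'
#' Parcels may be empty (a component that wins nowhere); operations that
#' need member vertices (ROI averaging, parcel regression) raise an error
#' naming the empty parcel.
#'
#' @slot labels length-V integer labels in 1..M, NA for unassigned vertices.
#' @slot M number of ROIs.
#' @slot zmaps optional V x M source z-score maps (empty matrix if absent).
#' @export
setClass("ParcellationLabels",
  representation(labels = "integer", M = "integer", zmaps = "matrix"))

setValidity("ParcellationLabels", function(object) {
  msg <- character()
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && (min(lab) < 1L || max(lab) > object@M))
    msg <- c(msg, "assigned labels must lie in 1..M")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ParcellationLabels", function(object) {
  cat(sprintf("ParcellationLabels: %d vertices, %d ROIs, %d unassigned\n",
              length(object@labels), object@M, sum(is.na(object@labels))))
})

## ------------------------------------------------------------ diff operators

#' Differential operators on an icosphere
#'
#' Sparse V x V east-west derivative, north-south derivative and Laplacian
#' used as the basis of the spherical convolution kernel. All three
#' annihilate constant fields (zero row sums); row support is the one-ring
#' plus the vertex itself.
#'
#' @slot level mesh level the operators act on.
#' @slot Dew,Dns,Lap sparse V x V operators.
#' @slot DewT,DnsT,LapT cached transposes (backpropagation).
#' @export
setClass("DiffOperators",
  representation(level = "integer", Dew = "Matrix", Dns = "Matrix",
                 Lap = "Matrix", DewT = "Matrix", DnsT = "Matrix",
                 LapT = "Matrix"))

setValidity("DiffOperators", function(object) {
  msg <- character()
  for (nm in c("Dew", "Dns", "Lap")) {
    rs <- Matrix::rowSums(slot(object, nm))
    if (max(abs(rs)) > 1e-8)
      msg <- c(msg, sprintf("%s must annihilate constants (row sums ~ 0)", nm))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiffOperators", function(object) {
  cat(sprintf("DiffOperators at level %d (%d vertices): Dew, Dns, Lap\n",
              object@level, nrow(object@Dew)))
})

## -------------------------------------------------------------------- model

#' Surface U-Net specification
#'
#' @slot inputLevel icosphere level of input/output fields.
#' @slot depth number of down/up stages (0 = plain convolutional stack).
#' @slot widths channel widths, length depth + 1 (finest to bottleneck).
#' @slot inChannels input channel count (connectome channels).
#' @slot outChannels output channel count (task contrasts).
#' @slot skip logical, concatenating encoder features into the decoder.
#' @slot normalization "instance" or "none".
#' @slot negativeSlope leaky-ReLU slope.
#' @slot seed integer initialization seed.
#' @export
setClass("ModelSpec",
  representation(inputLevel = "integer", depth = "integer",
                 widths = "integer", inChannels = "integer",
                 outChannels = "integer", skip = "logical",
                 normalization = "character", negativeSlope = "numeric",
                 seed = "integer"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (object@depth > object@inputLevel)
    msg <- c(msg, "depth must not exceed the input mesh level")
  if (length(object@widths) != object@depth + 1L)
    msg <- c(msg, "widths must have length depth + 1")
  if (any(object@widths < 1L)) msg <- c(msg, "widths must be positive")
  if (object@outChannels < 1L) msg <- c(msg, "need at least one output channel")
  if (!object@normalization %in% c("instance", "none"))
    msg <- c(msg, "normalization must be 'instance' or 'none'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: level %d, depth %d, widths %s, %d -> %d channels, skip=%s, norm=%s\n",
              object@inputLevel, object@depth,
              paste(object@widths, collapse = "/"),
              object@inChannels, object@outChannels, object@skip,
              object@normalization))
})

#' Surface convolutional network
#'
#' Parameters are partitioned into a backbone (all convolutional stages)
#' and a head (the final per-vertex projection to contrast channels);
#' transfer learning replaces or freezes the head.
#'
#' @slot spec a \linkS4class{ModelSpec}.
#' @slot params named list of parameter arrays ("head." prefix = head).
#' @slot meshes,ops,pools cached geometry per level.
#' @slot trainable character subset of c("backbone", "head").
#' @slot normStats input channel normalization statistics (list or empty).
#' @slot history training history data.frame.
#' @export
setClass("SurfModel",
  representation(spec = "ModelSpec", params = "list", meshes = "list",
                 ops = "list", pools = "list", trainable = "character",
                 normStats = "list", history = "data.frame"))

setMethod("show", "SurfModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("SurfModel: %s  %d parameters (%d head), trainable: %s\n",
              sprintf("level %d depth %d", object@spec@inputLevel,
                      object@spec@depth),
              np,
              sum(vapply(object@params[startsWith(names(object@params), "head.")],
                         length, 1L)),
              paste(object@trainable, collapse = "+")))
})

## ------------------------------------------------------------------- losses

#' Reconstructive-contrastive loss configuration
#'
#' @slot alpha same-subject (reconstructive) margin, >= 0.
#' @slot gamma across-subject (contrastive) margin, >= 0.
#' @slot channelMask logical per-contrast mask (TRUE = contributes).
#' @export
setClass("LossConfig",
  representation(alpha = "numeric", gamma = "numeric",
                 channelMask = "logical"))

setValidity("LossConfig", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@gamma < 0)
    msg <- c(msg, "margins must be non-negative")
  if (length(object@channelMask) && !any(object@channelMask))
    msg <- c(msg, "channel mask must leave at least one channel")
  if (length(msg)) msg else TRUE
})

#' Loss report
#'
#' @slot lR,lC,lRC reconstructive, contrastive and combined hinge losses.
#' @slot n batch size; \code{nPairs} = (n^2 - n) / 2 cross pairs.
#' @slot nPairs number of unordered cross-subject pairs.
#' @export
setClass("LossReport",
  representation(lR = "numeric", lC = "numeric", lRC = "numeric",
                 n = "integer", nPairs = "integer"))

setMethod("show", "LossReport", function(object) {
  cat(sprintf("LossReport: L_R=%.6g L_C=%.6g L_RC=%.6g (N=%d, %d pairs)\n",
              object@lR, object@lC, object@lRC, object@n, object@nPairs))
})

## ------------------------------------------------------------------ metrics

#' Thresholded Dice curve with area under the curve
#'
#' Dice overlap of top-x\% activation sets at fractions 0.05..0.50, plus the
#' composite-trapezoid AUC over the fraction axis (perfect agreement: 0.45).
#'
#' @slot thresholds fraction thresholds.
#' @slot dice per-threshold Dice values in [0, 1].
#' @slot auc composite trapezoid of dice over thresholds.
#' @export
setClass("DiceCurve",
  representation(thresholds = "numeric", dice = "numeric", auc = "numeric"))

setValidity("DiceCurve", function(object) {
  msg <- character()
  if (length(object@dice) != length(object@thresholds))
    msg <- c(msg, "one dice value per threshold")
  if (any(object@dice < -1e-12) || any(object@dice > 1 + 1e-12))
    msg <- c(msg, "dice values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiceCurve", function(object) {
  cat(sprintf("DiceCurve: %d thresholds [%.2f..%.2f], AUC = %.4f\n",
              length(object@thresholds), min(object@thresholds),
              max(object@thresholds), object@auc))
})

#' Subject identification matrix
#'
#' Entry (i, j) is the Dice AUC between subject j's predicted map and
#' subject i's target map; a subject is identified when the diagonal entry
#' is the strict maximum of its column.
#'
#' @slot aucMatrix N x N Dice-AUC matrix (rows targets, columns predictions).
#' @slot accuracy fraction of identified subjects.
#' @export
setClass("IdentMatrix",
  representation(aucMatrix = "matrix", accuracy = "numeric"))

setMethod("show", "IdentMatrix", function(object) {
  cat(sprintf("IdentMatrix: %d subjects, identification accuracy %.3f\n",
              nrow(object@aucMatrix), object@accuracy))
})

## ---------------------------------------------------------------- baselines

#' Ensembled parcel-wise linear model
#'
#' Per parcel, the across-training-subject average of per-subject
#' least-squares regressors mapping connectome features to activation.
#'
#' @slot beta list (one per parcel) of M-feature x C-contrast matrices.
#' @slot labels parcel labels the model was fit on.
#' @slot M number of parcels.
#' @slot nTrain number of training subjects averaged.
#' @slot contrastNames fitted contrast names.
#' @export
setClass("ParcelLinearModel",
  representation(beta = "list", labels = "integer", M = "integer",
                 nTrain = "integer", contrastNames = "character"))

setMethod("show", "ParcelLinearModel", function(object) {
  cat(sprintf("ParcelLinearModel: %d parcels, %d features, %d contrasts, averaged over %d subjects\n",
              object@M, if (length(object@beta)) nrow(object@beta[[1]]) else 0L,
              length(object@contrastNames), object@nTrain))
})

## -------------------------------------------------------------- synthcohort

#' Synthetic cohort configuration
#'
#' Defaults define the standing study conditions of the package's
#' synthetic experiments (see the methods vignette for rationale).
#'
#' @slot level icosphere level of the cohort surface.
#' @slot nSubjects number of subjects.
#' @slot M number of ROIs; \code{K} latent fingerprint dimensions (K <= M).
#' @slot K latent dimensionality of the subject fingerprint.
#' @slot C number of task contrasts.
#' @slot T timepoints per run; \code{R} runs; \code{visits} task visits.
#' @slot R number of resting runs.
#' @slot visits number of task visits (>= 1; 2 gives a repeat scan).
#' @slot beta fingerprint scale (sd of latent entries).
#' @slot sigmaTs resting timeseries noise sd.
#' @slot globalSignal sd of a global (shared across vertices) nuisance
#'   timeseries added to every vertex -- site/scanner-like contamination.
#' @slot sigmaScan task-map scan noise sd.
#' @slot smoothIter spatial smoothing iterations (one-ring averaging).
#' @slot devScale sd of the fingerprint-coupled contrast deviation.
#' @slot link "linear" or "nonlinear" rest-to-task coupling.
#' @slot arCoef AR(1) coefficient of latent ROI signals.
#' @slot seed integer cohort seed.
#' @export
setClass("CohortConfig",
  representation(level = "integer", nSubjects = "integer", M = "integer",
                 K = "integer", C = "integer", T = "integer", R = "integer",
                 visits = "integer", beta = "numeric", sigmaTs = "numeric",
                 globalSignal = "numeric", sigmaScan = "numeric",
                 smoothIter = "integer",
                 devScale = "numeric", link = "character", arCoef = "numeric",
                 seed = "integer"),
  prototype(level = 3L, nSubjects = 20L, M = 10L, K = 3L, C = 6L, T = 1200L,
            R = 4L, visits = 2L, beta = 1, sigmaTs = 0.5, globalSignal = 0,
            sigmaScan = 0.25,
            smoothIter = 2L, devScale = 0.6, link = "linear", arCoef = 0.3,
            seed = 1L))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@K > object@M) msg <- c(msg, "K must not exceed M")
  if (object@visits < 1L) msg <- c(msg, "need at least one visit")
  for (nm in c("nSubjects", "M", "K", "C", "T", "R"))
    if (slot(object, nm) < 1L) msg <- c(msg, sprintf("%s must be positive", nm))
  if (!object@link %in% c("linear", "nonlinear"))
    msg <- c(msg, "link must be 'linear' or 'nonlinear'")
  if (object@beta <= 0) msg <- c(msg, "beta must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: level %d, n=%d, M=%d, K=%d, C=%d, T=%d x %d runs, %d visits, link=%s, seed=%d\n",
              object@level, object@nSubjects, object@M, object@K, object@C,
              object@T, object@R, object@visits, object@link, object@seed))
})
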