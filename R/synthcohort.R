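## Seeded generator of coupled rest/task cohorts on an icosphere with known
## ground truth: a low-dimensional subject fingerprint drives both the
## resting vertex-to-ROI correlation structure and the subject-specific
## deviation of the task contrast maps from a smooth group template.

#' Cohort configuration
#'
#' Constructor for \linkS4class{CohortConfig}; see that class for the
#' meaning and defaults of every field.
#'
#' @param ... slots to override, e.g. \code{nSubjects = 50, seed = 7}.
#' @return a validated \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(...) {
  args <- list(...)
  intSlots <- c("level", "nSubjects", "M", "K", "C", "T", "R", "visits",
                "smoothIter", "seed")
  for (nm in intSlots) if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  ## named Class= avoids partial matching of slots like C against Class
  do.call(new, c(list(Class = "CohortConfig"), args))
}

## row-normalized (ring + self) smoothing operator; s applications
smoothingMatrix <- function(mesh) {
  ring <- mesh@oneRing
  V <- nVertices(mesh)
  deg <- lengths(ring)
  ii <- rep(seq_len(V), deg + 1L)
  jj <- unlist(lapply(seq_len(V), function(v) c(ring[[v]], v)), use.names = FALSE)
  xx <- rep(1 / (deg + 1), deg + 1L)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(V, V))
}

smoothField <- function(S, x, iter) {
  x <- as.matrix(x)
  for (i in seq_len(iter)) x <- as.matrix(S %*% x)
  x
}

## seeded farthest-point sampling of M seed vertices
farthestPointSeeds <- function(mesh, M) {
  V <- nVertices(mesh)
  seeds <- sample.int(V, 1L)
  dmin <- greatCircleDist(mesh@vertices, mesh@vertices[seeds, , drop = FALSE])[, 1]
  while (length(seeds) < M) {
    nxt <- which.max(dmin)              # ties: lowest index
    seeds <- c(seeds, nxt)
    dmin <- pmin(dmin, greatCircleDist(mesh@vertices,
                                       mesh@vertices[nxt, , drop = FALSE])[, 1])
  }
  seeds
}

## normalized nonlinear feature map of the latent fingerprint
latentFeatures <- function(z, beta, link) {
  u <- z / beta
  if (link == "linear") return(u)
  K <- length(z)
  sq <- (z^2 - beta^2) / (sqrt(2) * beta^2)
  int <- if (K >= 2) {
    pairs <- utils::combn(K, 2)
    z[pairs[1, ]] * z[pairs[2, ]] / beta^2
  } else numeric(0)
  c(u, sq, int)
}

nLatentFeatures <- function(K, link) {
  if (link == "linear") K else K + K + K * (K - 1) / 2
}

#' Generate a synthetic rest/task cohort
#'
#' Construction (all draws from \code{cfg@seed}; bit-reproducible):
#' \enumerate{
#'   \item M ROI seed vertices by seeded farthest-point sampling; labels by
#'     nearest seed; synthetic z-score maps as distance-decay bumps so
#'     winner-take-all recovers the labels.
#'   \item Per subject and run, latent ROI signals: AR(1) series with unit
#'     marginal variance, iid across ROIs.
#'   \item Subject loadings \code{W_i = base + sum_k z_ik B_k} with
#'     fingerprints \code{z_i ~ N(0, beta^2 I_K)} and fixed smooth basis
#'     fields B; vertex timeseries = \code{W_i \%*\% signals} + Gaussian
#'     noise (sd \code{sigmaTs}).
#'   \item Task contrasts per visit: group template plus a
#'     fingerprint-coupled deviation (linear in z, or with additional
#'     quadratic/interaction features under \code{link = "nonlinear"}),
#'     plus spatially smoothed scan noise (sd \code{sigmaScan} before
#'     smoothing). Visits share the signal and differ only in noise.
#' }
#'
#' A transfer-domain cohort is generated by passing the \code{groundTruth}
#' of an existing cohort: ROI seeds, parcellation, base loadings, basis and
#' coupling fields are reused (the tasks stay the same) while the group
#' templates are shifted by \code{templateShift} times a fresh smooth
#' unit-sd field and all subjects, fingerprints and noise are redrawn --
#' emulating a new dataset with the same task battery.
#'
#' @param cfg a \linkS4class{CohortConfig}.
#' @param groundTruth optional \code{groundTruth} of a base cohort to
#'   transfer from (dimensions must match \code{cfg}).
#' @param templateShift magnitude of the template shift in template-sd
#'   units (only with \code{groundTruth}; default 0.5).
#' @param loadingShift magnitude of a group-level shift of the base
#'   connectivity loadings (population / registration difference; only
#'   with \code{groundTruth}; default 0.25).
#' @return list with \code{mesh}, \code{config}, \code{parcellation}
#'   (\linkS4class{ParcellationLabels} from winner-take-all on the z-maps),
#'   \code{subjects} (per subject: \code{id}, \code{runs} -- list of
#'   \linkS4class{SurfaceTimeseries}, \code{visits} -- list of
#'   \linkS4class{ContrastMaps}) and \code{groundTruth} (latents, template,
#'   coupling fields, seeds, labels; never consumed by the pipeline).
#' @export
makeCohort <- function(cfg, groundTruth = NULL, templateShift = 0.5,
                       loadingShift = 0.25) {
  validObject(cfg)
  set.seed(cfg@seed)
  mesh <- buildIcosphere(cfg@level)
  V <- nVertices(mesh)
  S <- smoothingMatrix(mesh)
  contrasts <- sprintf("contrast%02d", seq_len(cfg@C))

  if (is.null(groundTruth)) {
    ## 1. parcellation
    seeds <- farthestPointSeeds(mesh, cfg@M)
    dm <- greatCircleDist(mesh@vertices, mesh@vertices[seeds, , drop = FALSE])
    zmaps <- 3 * exp(-(dm / 0.4)^2)
    trueLabels <- max.col(-dm, ties.method = "first")

    ## 2. group-level fields
    base <- 0.9 * exp(-(dm / 0.5)^2)
    B <- lapply(seq_len(cfg@K), function(k) {
      f <- smoothField(S, matrix(stats::rnorm(V * cfg@M), V), cfg@smoothIter)
      0.25 * f / stats::sd(f)
    })
    templates <- vapply(seq_len(cfg@C), function(c) {
      f <- smoothField(S, stats::rnorm(V), cfg@smoothIter)
      as.numeric(scale(f))
    }, numeric(V))
    nf <- nLatentFeatures(cfg@K, cfg@link)
    fieldSd <- if (cfg@link == "linear") rep(cfg@devScale / sqrt(cfg@K), cfg@K)
               else c(rep(cfg@devScale * sqrt(0.5 / cfg@K), cfg@K),
                      rep(cfg@devScale * sqrt(0.5 / (nf - cfg@K)), nf - cfg@K))
    D <- lapply(seq_len(cfg@C), function(c) {
      f <- smoothField(S, matrix(stats::rnorm(V * nf), V), cfg@smoothIter)
      f <- scale(f)        # unit sd per column
      sweep(f, 2, fieldSd, "*")
    })
  } else {
    gt0 <- groundTruth
    if (nrow(gt0$templates) != V || ncol(gt0$templates) != cfg@C ||
        ncol(gt0$base) != cfg@M || gt0$link != cfg@link)
      stopf("base ground truth dimensions do not match the transfer config")
    seeds <- gt0$seeds
    dm <- greatCircleDist(mesh@vertices, mesh@vertices[seeds, , drop = FALSE])
    zmaps <- 3 * exp(-(dm / 0.4)^2)
    trueLabels <- gt0$labels
    ## group-level loading shift: the same fingerprint is expressed on a
    ## systematically different connectivity topography in the new domain
    base <- gt0$base + loadingShift *
      smoothField(S, matrix(stats::rnorm(V * cfg@M), V), cfg@smoothIter)
    B <- gt0$basis
    D <- gt0$D
    ## domain shift: dominated by a smooth field shared across contrasts
    ## (scanner/preprocessing effects hit all tasks alike), plus a smaller
    ## contrast-specific component
    shared <- as.numeric(scale(smoothField(S, stats::rnorm(V), cfg@smoothIter)))
    own <- vapply(seq_len(cfg@C), function(c)
      as.numeric(scale(smoothField(S, stats::rnorm(V), cfg@smoothIter))),
      numeric(V))
    templates <- gt0$templates +
      templateShift * (sqrt(0.8) * shared + sqrt(0.2) * own)
  }
  parc <- winnerTakeAll(zmaps)

  ## 3. subjects
  z <- matrix(stats::rnorm(cfg@nSubjects * cfg@K, sd = cfg@beta),
              cfg@nSubjects, cfg@K)
  subjects <- vector("list", cfg@nSubjects)
  for (i in seq_len(cfg@nSubjects)) {
    id <- sprintf("sub%03d", i)
    W <- base
    for (k in seq_len(cfg@K)) W <- W + z[i, k] * B[[k]]
    runs <- lapply(seq_len(cfg@R), function(r) {
      sig <- arSignals(cfg@M, cfg@T, cfg@arCoef)
      ts <- W %*% sig + cfg@sigmaTs * matrix(stats::rnorm(V * cfg@T), V)
      if (cfg@globalSignal > 0)
        ts <- ts + cfg@globalSignal *
          matrix(arSignals(1L, cfg@T, cfg@arCoef), V, cfg@T, byrow = TRUE)
      new("SurfaceTimeseries", data = ts, vertexMask = rep(TRUE, V),
          hemisphere = "single", tr = 1)
    })
    feat <- latentFeatures(z[i, ], cfg@beta, cfg@link)
    signal <- templates
    for (c in seq_len(cfg@C))
      signal[, c] <- signal[, c] + as.numeric(D[[c]] %*% feat)
    visits <- lapply(seq_len(cfg@visits), function(v) {
      noise <- smoothField(S, matrix(stats::rnorm(V * cfg@C), V) * cfg@sigmaScan,
                           cfg@smoothIter)
      new("ContrastMaps", data = signal + noise, vertexMask = rep(TRUE, V),
          subject = id, contrastNames = contrasts)
    })
    subjects[[i]] <- list(id = id, runs = runs, visits = visits)
  }
  gt <- structure(list(z = z, templates = templates, D = D, basis = B,
                       base = base, seeds = seeds, labels = trueLabels,
                       link = cfg@link, beta = cfg@beta,
                       contrastNames = contrasts, mask = rep(TRUE, V)),
                  class = "GroundTruth")
  list(mesh = mesh, config = cfg, parcellation = parc, zmaps = zmaps,
       subjects = subjects, groundTruth = gt)
}

## AR(1) signals, unit marginal variance, iid across ROIs (rows)
arSignals <- function(M, Tn, rho) {
  e <- matrix(stats::rnorm(M * Tn), M, Tn)
  s <- matrix(0, M, Tn)
  s[, 1] <- e[, 1]
  sc <- sqrt(1 - rho^2)
  for (t in 2:Tn) s[, t] <- rho * s[, t - 1] + sc * e[, t]
  s
}

#' Noise-free oracle prediction
#'
#' The generative contrast maps of a subject without scan noise: the group
#' template plus the subject's fingerprint-coupled deviation. Defines the
#' cohort's performance ceiling.
#'
#' @param gt \code{groundTruth} element of \code{\link{makeCohort}} output.
#' @param subject subject index (row of the latent matrix), or a latent
#'   vector via \code{z}.
#' @param z optional explicit latent vector overriding \code{subject}.
#' @return a \linkS4class{ContrastMaps}.
#' @export
oraclePredictor <- function(gt, subject = 1L, z = NULL) {
  if (is.null(z)) z <- gt$z[subject, ]
  feat <- latentFeatures(z, gt$beta, gt$link)
  out <- gt$templates
  for (c in seq_along(gt$D)) out[, c] <- out[, c] + as.numeric(gt$D[[c]] %*% feat)
  new("ContrastMaps", data = out, vertexMask = gt$mask,
      subject = if (is.null(z)) sprintf("sub%03d", subject) else "oracle",
      contrastNames = gt$contrastNames)
}

#' Connectome samples for every cohort subject
#'
#' Splits each subject's runs into contiguous segments and computes one
#' vertex-to-ROI connectome per segment using the cohort's winner-take-all
#' parcellation -- the augmentation scheme used for training and test-time
#' ensembling.
#'
#' @param cohort output of \code{\link{makeCohort}}.
#' @param scheme,length,count,seed passed to \code{\link{splitSegments}}.
#' @return list (per subject) of lists of \linkS4class{Connectome}.
#' @export
cohortConnectomes <- function(cohort, scheme = "halves", length = NULL,
                              count = NULL, seed = NULL) {
  lapply(cohort$subjects, function(s) {
    segs <- splitSegments(s$runs, scheme, length = length, count = count,
                          seed = seed)
    lapply(segs, function(seg)
      buildConnectome(seg, cohort$parcellation, subject = s$id))
  })
}

#' Assemble per-subject training data
#'
#' Pairs each subject's connectome samples with a target visit in the
#' shape \code{\link{trainModel}} expects.
#'
#' @param cohort output of \code{\link{makeCohort}}.
#' @param connectomes output of \code{\link{cohortConnectomes}}.
#' @param visit target visit index (default 1).
#' @param indices subject subset (default all).
#' @return list of \code{list(connectomes, target)} per subject.
#' @export
cohortTrainingData <- function(cohort, connectomes, visit = 1L,
                               indices = seq_along(cohort$subjects)) {
  lapply(indices, function(i)
    list(connectomes = connectomes[[i]],
         target = cohort$subjects[[i]]$visits[[visit]]))
}
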