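# Shared fixtures, generated in code. Kept tiny: level-2 spheres (162
# vertices) and short runs unless a check needs the scale of the full
# benchmark experiment.

tinyCohort <- function(seed = 42L, n = 10L, ...) {
  makeCohort(cohortConfig(nSubjects = n, level = 2L, T = 200L, R = 2L,
                          M = 6L, K = 2L, C = 3L, seed = seed, ...))
}

randomTimeseries <- function(V = 162L, Tn = 30L, seed = 1L) {
  set.seed(seed)
  new("SurfaceTimeseries", data = matrix(rnorm(V * Tn), V),
      vertexMask = rep(TRUE, V), hemisphere = "single", tr = 1)
}

randomMaps <- function(V = 162L, C = 3L, seed = 1L, subject = "s01") {
  set.seed(seed)
  new("ContrastMaps", data = matrix(rnorm(V * C), V),
      vertexMask = rep(TRUE, V), subject = subject,
      contrastNames = sprintf("c%02d", seq_len(C)))
}

# single-vertex-per-map divergence: d(a, b) = (a - b)^2 for scalar "maps",
# convenient for exact loss arithmetic
scalarMap <- function(x) matrix(x, 1, 1)
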