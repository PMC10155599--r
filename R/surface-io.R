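## Surface data I/O: GIFTI functional/shape and CIFTI-2 dtseries/dscalar
## readers and writers, nearest-neighbor resampling onto internal
## icospheres, and the on-disk cohort container.

formatOf <- function(path) {
  if (grepl("\\.(func|shape)\\.gii$", path)) "gifti"
  else if (grepl("\\.surf\\.gii$", path)) "gifti_surf"
  else if (grepl("\\.dtseries\\.nii$", path)) "dtseries"
  else if (grepl("\\.dscalar\\.nii$", path)) "dscalar"
  else stopf("unknown surface data format: '%s'", path)
}

#' Write surface-mapped data
#'
#' \linkS4class{SurfaceTimeseries} go to \code{.func.gii} (one 2D
#' time-series array) or \code{.dtseries.nii}; \linkS4class{ContrastMaps}
#' (and \linkS4class{Connectome}) go to \code{.func.gii}/\code{.shape.gii}
#' (one named array per channel) or \code{.dscalar.nii}. The format is
#' chosen from the file extension. CIFTI files persist the vertex mask via
#' the brain-model vertex list; GIFTI files store the full field.
#'
#' @param x a \linkS4class{SurfaceTimeseries}, \linkS4class{ContrastMaps}
#'   or \linkS4class{Connectome}.
#' @param path output path; the extension selects the format.
#' @return the path, invisibly.
#' @export
writeSurfaceData <- function(x, path) {
  fmt <- formatOf(path)
  if (is(x, "SurfaceTimeseries")) {
    switch(fmt,
      gifti = giftiWrite(list(list(data = x@data,
                                   intent = "NIFTI_INTENT_TIME_SERIES")), path),
      dtseries = ciftiWrite(x, path, "dtseries"),
      stopf("a timeseries cannot be written to '%s'", path))
  } else if (is(x, "ContrastMaps") || is(x, "Connectome")) {
    nm <- if (is(x, "ContrastMaps")) x@contrastNames else x@channelNames
    switch(fmt,
      gifti = giftiWrite(lapply(seq_len(ncol(x@data)), function(c)
        list(data = x@data[, c, drop = FALSE], intent = "NIFTI_INTENT_NONE",
             name = nm[c])), path),
      dscalar = {
        y <- if (is(x, "Connectome"))
          new("ContrastMaps", data = x@data, vertexMask = x@vertexMask,
              subject = x@subject, contrastNames = nm)
        else x
        ciftiWrite(y, path, "dscalar")
      },
      stopf("multi-channel maps cannot be written to '%s'", path))
  } else stopf("unsupported object of class %s", class(x))
  invisible(path)
}

#' Read surface-mapped data
#'
#' Reads GIFTI functional/shape or CIFTI-2 dtseries/dscalar files into the
#' package's containers. CIFTI brain-model indexing is expanded to
#' full-surface indexing with the mask FALSE where the file stores no
#' data. Files containing non-finite values are rejected with the
#' offending map named.
#'
#' @param path input file.
#' @param kind "timeseries" or "contrasts"; the default infers it from the
#'   file (dtseries / time-series intent = timeseries).
#' @param mesh optional \linkS4class{SphereMesh}; when given, the vertex
#'   count is checked against it.
#' @param tr repetition time override for GIFTI timeseries (default 1).
#' @return a \linkS4class{SurfaceTimeseries} or \linkS4class{ContrastMaps}.
#' @export
readSurfaceData <- function(path, kind = c("auto", "timeseries", "contrasts"),
                            mesh = NULL, tr = 1) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  fmt <- formatOf(path)
  checkV <- function(V) {
    if (!is.null(mesh) && V != nVertices(mesh))
      stopf("'%s' has %d vertices but the declared mesh has %d",
            path, V, nVertices(mesh))
  }
  checkFinite <- function(m, names) {
    bad <- which(vapply(seq_len(ncol(m)), function(c)
      any(!is.finite(m[, c])), TRUE))
    if (length(bad))
      stopf("'%s' contains non-finite values in map(s): %s", path,
            paste(names[bad], collapse = ", "))
  }
  if (fmt %in% c("dtseries", "dscalar")) {
    x <- ciftiRead(path)
    checkV(nrow(x$data))
    checkFinite(x$data, as.character(seq_len(ncol(x$data))))
    if (x$kind == "dtseries") {
      if (kind == "contrasts") stopf("'%s' is a timeseries file", path)
      return(new("SurfaceTimeseries", data = x$data, vertexMask = x$mask,
                 hemisphere = if (x$hemi %in% c("L", "R", "single")) x$hemi
                              else "single",
                 tr = x$tr))
    }
    if (kind == "timeseries") stopf("'%s' is a scalar-maps file", path)
    nm <- if (length(x$names)) x$names
          else sprintf("map%02d", seq_len(ncol(x$data)))
    return(new("ContrastMaps", data = x$data, vertexMask = x$mask,
               subject = x$subject, contrastNames = nm))
  }
  if (fmt == "gifti_surf") stopf("'%s' is a surface geometry file; use readMeshGIFTI", path)
  arrays <- giftiRead(path)
  isTs <- length(arrays) == 1L &&
    arrays[[1]]$intent == "NIFTI_INTENT_TIME_SERIES"
  if (kind == "timeseries" || (kind == "auto" && isTs)) {
    m <- arrays[[1]]$data
    checkV(nrow(m))
    checkFinite(m, "timeseries")
    return(new("SurfaceTimeseries", data = m,
               vertexMask = rep(TRUE, nrow(m)), hemisphere = "single",
               tr = tr))
  }
  nm <- vapply(seq_along(arrays), function(i) {
    if (is.na(arrays[[i]]$name)) sprintf("map%02d", i) else arrays[[i]]$name
  }, "")
  m <- do.call(cbind, lapply(arrays, `[[`, "data"))
  checkV(nrow(m))
  checkFinite(m, nm)
  new("ContrastMaps", data = m, vertexMask = rep(TRUE, nrow(m)),
      subject = "unknown", contrastNames = nm)
}

#' Nearest-neighbor resampling onto an icosphere
#'
#' Each target vertex takes the value of its nearest source vertex by
#' great-circle distance; ties break to the lowest source index, so the
#' operation is deterministic and idempotent. This is the adapter that
#' carries external template meshes (whose vertex counts are not icosphere
#' counts) onto the internal exact hierarchy.
#'
#' @param data V_src x K matrix (or vector) of source values.
#' @param sourceVertices V_src x 3 matrix of unit vectors.
#' @param target a \linkS4class{SphereMesh}.
#' @return V_target x K matrix.
#' @export
resampleNearest <- function(data, sourceVertices, target) {
  data <- as.matrix(data)
  if (nrow(sourceVertices) == 0L) stopf("empty source vertex set")
  if (nrow(data) != nrow(sourceVertices))
    stopf("data rows (%d) must match source vertices (%d)", nrow(data),
          nrow(sourceVertices))
  ## nearest by maximal dot product; which.max takes the lowest index on ties
  sim <- tcrossprod(target@vertices, sourceVertices)
  nn <- apply(sim, 1, which.max)
  data[nn, , drop = FALSE]
}
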