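## Minimal CIFTI-2 adapter: dense timeseries (.dtseries.nii) and dense
## scalar (.dscalar.nii) files in the NIfTI-2 container with the CIFTI XML
## extension. Only single-surface brain models are produced; files store
## FLOAT64 so round trips are lossless (FLOAT32 accepted on read).

writeInt64 <- function(con, v) {
  ## values here are far below 2^31; low word then zero high word
  for (x in v) writeBin(c(as.integer(x), 0L), con, size = 4, endian = "little")
}

readInt64 <- function(raw, offset, n) {
  ## offset in bytes (0-based); returns doubles
  lo <- readBin(raw[(offset + 1):(offset + 8 * n)], "integer", 2 * n,
                size = 4, endian = "little")
  lo[seq(1, 2 * n, 2)] + lo[seq(2, 2 * n, 2)] * 2^32
}

padTo <- function(raw, mult) {
  r <- length(raw) %% mult
  if (r == 0) raw else c(raw, raw(mult - r))
}

ciftiXml <- function(x, kind) {
  mask <- x@vertexMask
  V <- length(mask)
  idx0 <- which(mask) - 1L
  doc <- xml2::xml_new_root("CIFTI", Version = "2.0")
  mat <- xml2::xml_add_child(doc, "Matrix")
  md <- xml2::xml_add_child(mat, "MetaData")
  addMD <- function(name, value) {
    e <- xml2::xml_add_child(md, "MD")
    xml2::xml_add_child(e, "Name", name)
    xml2::xml_add_child(e, "Value", value)
  }
  if (kind == "dtseries") {
    addMD("surftask_hemisphere", x@hemisphere)
    xml2::xml_add_child(mat, "MatrixIndicesMap",
      AppliesToMatrixDimension = "0",
      IndicesMapToDataType = "CIFTI_INDEX_TYPE_SERIES",
      NumberOfSeriesPoints = as.character(ncol(x@data)),
      SeriesExponent = "0", SeriesStart = "0",
      SeriesStep = as.character(x@tr), SeriesUnit = "SECOND")
    structure <- switch(x@hemisphere, R = "CIFTI_STRUCTURE_CORTEX_RIGHT",
                        "CIFTI_STRUCTURE_CORTEX_LEFT")
  } else {
    addMD("surftask_subject", x@subject)
    mim <- xml2::xml_add_child(mat, "MatrixIndicesMap",
      AppliesToMatrixDimension = "0",
      IndicesMapToDataType = "CIFTI_INDEX_TYPE_SCALARS")
    for (nm in x@contrastNames) {
      nmap <- xml2::xml_add_child(mim, "NamedMap")
      xml2::xml_add_child(nmap, "MapName", nm)
    }
    structure <- "CIFTI_STRUCTURE_CORTEX_LEFT"
  }
  mim2 <- xml2::xml_add_child(mat, "MatrixIndicesMap",
    AppliesToMatrixDimension = "1",
    IndicesMapToDataType = "CIFTI_INDEX_TYPE_BRAIN_MODELS")
  bm <- xml2::xml_add_child(mim2, "BrainModel",
    IndexOffset = "0", IndexCount = as.character(length(idx0)),
    ModelType = "CIFTI_MODEL_TYPE_SURFACE", BrainStructure = structure,
    SurfaceNumberOfVertices = as.character(V))
  xml2::xml_add_child(bm, "VertexIndices", paste(idx0, collapse = " "))
  charToRaw(as.character(doc))
}

ciftiWrite <- function(x, path, kind) {
  xml <- ciftiXml(x, kind)
  body <- padTo(xml, 16L)
  esize <- 8L + length(body)
  nMaps <- ncol(x@data)             # time points or named maps
  B <- sum(x@vertexMask)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(540L, con, size = 4, endian = "little")
  writeBin(c(charToRaw("n+2"), as.raw(c(0x00, 0x0D, 0x0A, 0x1A, 0x0A))), con)
  writeBin(c(64L, 64L), con, size = 2, endian = "little")      # datatype, bitpix
  writeInt64(con, c(6, 1, 1, 1, 1, nMaps, B, 1))               # dim[8]
  writeBin(rep(0, 3), con, size = 8, endian = "little")        # intent_p1..3
  writeBin(rep(1, 8), con, size = 8, endian = "little")        # pixdim
  writeInt64(con, 544 + esize)                                 # vox_offset
  writeBin(rep(0, 6), con, size = 8, endian = "little")  # scl/cal/slice_dur/toffset
  writeInt64(con, c(0, 0))                                     # slice_start/end
  writeBin(raw(80 + 24), con)                                  # descrip, aux_file
  writeBin(c(0L, 0L), con, size = 4, endian = "little")        # q/sform_code
  writeBin(rep(0, 6), con, size = 8, endian = "little")        # quatern/qoffset
  writeBin(rep(0, 12), con, size = 8, endian = "little")       # srow
  writeBin(c(0L, 0L), con, size = 4, endian = "little")        # slice_code, xyzt
  writeBin(if (kind == "dtseries") 3002L else 3006L, con, size = 4,
           endian = "little")                                  # intent_code
  inm <- if (kind == "dtseries") "ConnDenseSeries" else "ConnDenseScalar"
  writeBin(c(charToRaw(inm), raw(16 - nchar(inm))), con)       # intent_name
  writeBin(raw(16), con)                                       # dim_info+unused
  writeBin(as.raw(c(1, 0, 0, 0)), con)                         # extender
  writeBin(c(esize, 32L), con, size = 4, endian = "little")
  writeBin(body, con)
  ## data: fastest-varying dimension is the map/series axis
  m <- t(x@data[x@vertexMask, , drop = FALSE])                 # nMaps x B
  writeBin(as.vector(m), con, size = 8, endian = "little")
  invisible(path)
}

ciftiRead <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (readBin(raw[1:4], "integer", 1, size = 4, endian = "little") != 540L)
    stopf("'%s' is not a NIfTI-2 / CIFTI-2 file", path)
  if (rawToChar(raw[5:7]) != "n+2")
    stopf("'%s' has an invalid NIfTI-2 magic", path)
  datatype <- readBin(raw[13:14], "integer", 1, size = 2, endian = "little")
  dims <- readInt64(raw, 16, 8)
  nMaps <- dims[6]; B <- dims[7]
  voxOffset <- readInt64(raw, 168, 1)
  intentCode <- readBin(raw[505:508], "integer", 1, size = 4, endian = "little")
  ## extension
  if (raw[541] != as.raw(1)) stopf("'%s' carries no CIFTI extension", path)
  esize <- readBin(raw[545:548], "integer", 1, size = 4, endian = "little")
  xmlRaw <- raw[553:(544 + esize)]
  xmlRaw <- xmlRaw[xmlRaw != as.raw(0)]
  doc <- xml2::read_xml(rawToChar(xmlRaw))
  nVal <- nMaps * B
  bytes <- if (datatype == 64L) 8L else 4L
  vec <- readBin(raw[(voxOffset + 1):(voxOffset + nVal * bytes)], "numeric",
                 nVal, size = bytes, endian = "little")
  m <- matrix(vec, nMaps, B)       # row t fastest in file
  bmNode <- xml2::xml_find_first(doc, ".//BrainModel")
  V <- as.integer(xml2::xml_attr(bmNode, "SurfaceNumberOfVertices"))
  idx0 <- as.integer(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(bmNode, "./VertexIndices"))), "[[:space:]]+")[[1]])
  mask <- rep(FALSE, V)
  mask[idx0 + 1L] <- TRUE
  full <- matrix(0, V, nMaps)
  full[mask, ] <- t(m)
  getMD <- function(name) {
    node <- xml2::xml_find_first(doc,
      sprintf(".//Matrix/MetaData/MD[Name='%s']/Value", name))
    if (inherits(node, "xml_missing")) NA_character_ else xml2::xml_text(node)
  }
  if (intentCode == 3002L) {
    step <- as.numeric(xml2::xml_attr(
      xml2::xml_find_first(doc, ".//MatrixIndicesMap[@AppliesToMatrixDimension='0']"),
      "SeriesStep"))
    hemi <- getMD("surftask_hemisphere")
    if (is.na(hemi)) {
      hemi <- if (grepl("RIGHT", xml2::xml_attr(bmNode, "BrainStructure")))
        "R" else "L"
    }
    list(kind = "dtseries", data = full, mask = mask, tr = step, hemi = hemi)
  } else {
    names <- xml2::xml_text(xml2::xml_find_all(doc, ".//NamedMap/MapName"))
    subj <- getMD("surftask_subject")
    list(kind = "dscalar", data = full, mask = mask, names = names,
         subject = if (is.na(subj)) "unknown" else subj)
  }
}
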