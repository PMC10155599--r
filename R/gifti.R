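## Minimal GIFTI (XML) adapter: functional / shape data arrays and surface
## (pointset + triangle) files, GZipBase64Binary encoding, little endian.
## Data are stored as FLOAT64 so the round trip is lossless; FLOAT32 and
## INT32 arrays are accepted on read.

giftiEncode <- function(raw) jsonlite::base64_enc(memCompress(raw, "gzip"))

giftiDecode <- function(txt, encoding) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
  switch(encoding,
    GZipBase64Binary = memDecompress(raw, "gzip"),
    Base64Binary = raw,
    stopf("unsupported GIFTI encoding '%s'", encoding))
}

giftiDataArrayNode <- function(doc, mat, intent, name = NULL,
                               dataType = "NIFTI_TYPE_FLOAT64") {
  da <- xml2::xml_add_child(doc, "DataArray",
    Intent = intent, DataType = dataType,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dim(mat))),
    Encoding = "GZipBase64Binary", Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  dims <- dim(mat)
  for (i in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", i - 1L), as.character(dims[i]))
  if (!is.null(name)) {
    md <- xml2::xml_add_child(da, "MetaData")
    e <- xml2::xml_add_child(md, "MD")
    xml2::xml_add_child(e, "Name", "Name")
    xml2::xml_add_child(e, "Value", name)
  }
  ## row-major serialization
  vec <- as.vector(t(mat))
  raw <- if (dataType == "NIFTI_TYPE_INT32")
    writeBin(as.integer(vec), raw(), size = 4, endian = "little")
  else writeBin(as.numeric(vec), raw(), size = 8, endian = "little")
  xml2::xml_add_child(da, "Data", giftiEncode(raw))
  da
}

giftiWrite <- function(arrays, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(length(arrays)))
  xml2::xml_add_child(doc, "MetaData")
  xml2::xml_add_child(doc, "LabelTable")
  for (a in arrays)
    giftiDataArrayNode(doc, a$data, a$intent, name = a$name,
                       dataType = if (isTRUE(a$int)) "NIFTI_TYPE_INT32"
                                  else "NIFTI_TYPE_FLOAT64")
  xml2::write_xml(doc, path)
  invisible(path)
}

giftiRead <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "GIFTI") stopf("'%s' is not a GIFTI file", path)
  das <- xml2::xml_find_all(doc, "./DataArray")
  lapply(das, function(da) {
    ndim <- as.integer(xml2::xml_attr(da, "Dimensionality"))
    dims <- vapply(seq_len(ndim) - 1L, function(i)
      as.integer(xml2::xml_attr(da, paste0("Dim", i))), 1L)
    dt <- xml2::xml_attr(da, "DataType")
    enc <- xml2::xml_attr(da, "Encoding")
    order <- xml2::xml_attr(da, "ArrayIndexingOrder")
    raw <- giftiDecode(xml2::xml_text(xml2::xml_find_first(da, "./Data")), enc)
    vec <- switch(dt,
      NIFTI_TYPE_FLOAT64 = readBin(raw, "numeric", prod(dims), size = 8,
                                   endian = "little"),
      NIFTI_TYPE_FLOAT32 = readBin(raw, "numeric", prod(dims), size = 4,
                                   endian = "little"),
      NIFTI_TYPE_INT32 = readBin(raw, "integer", prod(dims), size = 4,
                                 endian = "little"),
      stopf("unsupported GIFTI data type '%s' in %s", dt, path))
    m <- if (ndim == 2L) {
      if (identical(order, "ColumnMajorOrder")) matrix(vec, dims[1], dims[2])
      else t(matrix(vec, dims[2], dims[1]))
    } else matrix(vec, dims[1], 1L)
    nameNode <- xml2::xml_find_first(da,
      "./MetaData/MD[Name='Name']/Value")
    list(data = m,
         intent = xml2::xml_attr(da, "Intent"),
         name = if (inherits(nameNode, "xml_missing")) NA_character_
                else xml2::xml_text(nameNode))
  })
}

#' Export a mesh as a GIFTI surface file
#'
#' Writes the pointset (vertex coordinates) and triangle (0-based face
#' indices) arrays of a \code{.surf.gii} file.
#'
#' @param mesh a \linkS4class{SphereMesh}.
#' @param path output path (conventionally \code{*.surf.gii}).
#' @return the path, invisibly.
#' @export
writeMeshGIFTI <- function(mesh, path) {
  giftiWrite(list(
    list(data = mesh@vertices, intent = "NIFTI_INTENT_POINTSET"),
    list(data = mesh@faces - 1L, intent = "NIFTI_INTENT_TRIANGLE",
         int = TRUE)), path)
}

#' Read a GIFTI surface file
#'
#' @param path a \code{.surf.gii} file written by \code{\link{writeMeshGIFTI}}
#'   (or any GIFTI surface with pointset + triangle arrays).
#' @return list with \code{vertices} (V x 3) and \code{faces} (F x 3,
#'   1-based).
#' @export
readMeshGIFTI <- function(path) {
  arrays <- giftiRead(path)
  pt <- Filter(function(a) a$intent == "NIFTI_INTENT_POINTSET", arrays)
  tr <- Filter(function(a) a$intent == "NIFTI_INTENT_TRIANGLE", arrays)
  if (!length(pt) || !length(tr))
    stopf("'%s' lacks pointset/triangle arrays", path)
  list(vertices = pt[[1]]$data,
       faces = matrix(as.integer(tr[[1]]$data), nrow(tr[[1]]$data)) + 1L)
}
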