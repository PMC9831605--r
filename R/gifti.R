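# Minimal GIfTI (.gii) I/O with ASCII data encoding.  Covers the three array
# kinds the pipeline emits: surface geometry (.surf.gii), per-vertex scalars
# (.shape.gii) and per-vertex labels (.label.gii).

gifti_data_array <- function(doc_root, intent, datatype, mat) {
  mat <- as.matrix(mat)
  da <- xml2::xml_add_child(doc_root, "DataArray",
    Intent = intent, DataType = datatype,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(if (ncol(mat) > 1) 2L else 1L),
    Dim0 = as.character(nrow(mat)),
    Encoding = "ASCII", Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  if (ncol(mat) > 1) xml2::xml_set_attr(da, "Dim1", as.character(ncol(mat)))
  # row-major: interleave rows
  vals <- as.vector(t(mat))
  txt <- paste(format(vals, trim = TRUE, digits = 9, scientific = FALSE),
               collapse = " ")
  xml2::xml_add_child(da, "Data", txt)
  invisible(da)
}

gifti_new_doc <- function(n_arrays) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(n_arrays))
  xml2::xml_add_child(doc, "MetaData")
  doc
}

#' Write a surface mesh as GIfTI
#'
#' Emits a two-array `.surf.gii`: a float32 POINTSET (vertices, mm) and an
#' int32 TRIANGLE array (0-based indices), ASCII-encoded.
#'
#' @param mesh a [surface_mesh()]
#' @param path output file path
#' @export
write_gifti_surface <- function(mesh, path) {
  doc <- gifti_new_doc(2)
  gifti_data_array(doc, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                   mesh$vertices)
  gifti_data_array(doc, "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                   mesh$triangles - 1L)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a per-vertex metric as GIfTI
#'
#' @param values numeric vector (length = vertex count) or a [metric_map()]
#' @param path output file path
#' @export
write_gifti_metric <- function(values, path) {
  if (inherits(values, "metric_map")) values <- values$values
  doc <- gifti_new_doc(1)
  gifti_data_array(doc, "NIFTI_INTENT_SHAPE", "NIFTI_TYPE_FLOAT32",
                   matrix(values, ncol = 1))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write per-vertex labels as GIfTI
#'
#' @param labels integer vector of label values per vertex
#' @param label_names named integer vector mapping names to values
#' @param path output file path
#' @export
write_gifti_labels <- function(labels, label_names, path) {
  doc <- gifti_new_doc(1)
  lt <- xml2::xml_add_child(doc, "LabelTable")
  for (i in seq_along(label_names)) {
    xml2::xml_add_child(lt, "Label", names(label_names)[i],
                        Key = as.character(label_names[i]),
                        Red = "0", Green = "0", Blue = "0", Alpha = "1")
  }
  gifti_data_array(doc, "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32",
                   matrix(as.integer(labels), ncol = 1))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GIfTI file written by this package
#'
#' Supports ASCII-encoded data arrays.  Returns the arrays with their intents;
#' for surfaces, triangle indices are converted back to 1-based.
#'
#' @param path `.gii` file path
#' @return a list with elements `arrays` (list of matrices), `intents`
#'   (character), and `labels` (named integer vector or NULL)
#' @export
read_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  arrays <- list(); intents <- character(0)
  for (da in das) {
    intent <- xml2::xml_attr(da, "Intent")
    if (xml2::xml_attr(da, "Encoding") != "ASCII")
      stop("only ASCII-encoded GIfTI supported")
    dim0 <- as.integer(xml2::xml_attr(da, "Dim0"))
    dim1 <- xml2::xml_attr(da, "Dim1")
    dim1 <- if (is.na(dim1)) 1L else as.integer(dim1)
    txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
    vals <- as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    m <- matrix(vals, nrow = dim0, ncol = dim1, byrow = TRUE)
    if (intent == "NIFTI_INTENT_TRIANGLE") m <- matrix(as.integer(m) + 1L, nrow = dim0)
    if (intent == "NIFTI_INTENT_LABEL") m <- matrix(as.integer(m), nrow = dim0)
    arrays[[length(arrays) + 1L]] <- m
    intents <- c(intents, intent)
  }
  labs <- NULL
  lab_nodes <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  if (length(lab_nodes)) {
    labs <- as.integer(xml2::xml_attr(lab_nodes, "Key"))
    names(labs) <- xml2::xml_text(lab_nodes)
  }
  list(arrays = arrays, intents = intents, labels = labs)
}
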