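#' SearchHandle: an immutable result set on the history server
#'
#' Identifies a fixed set of PMCIDs matching a query or an explicit ID
#' list. When the result set lives on the Entrez history server the
#' handle carries the (WebEnv, query_key) pair; re-fetching the same
#' handle always yields the same IDs.
#'
#' @slot query the query string, or "" for an ID list
#' @slot ids explicit PMCIDs when the handle was built from an ID list
#' @slot resultCount number of matching articles
#' @slot webenv,queryKey opaque history-server keys ("" when absent)
#' @slot createdAt POSIXct creation time
#' @export
setClass("SearchHandle", representation(
  query = "character", ids = "character", resultCount = "integer",
  webenv = "character", queryKey = "character", createdAt = "POSIXct"
))

setValidity("SearchHandle", function(object) {
  if (length(object@resultCount) != 1L || object@resultCount < 0L)
    return("resultCount must be a single non-negative integer")
  if (object@resultCount > 0L && length(object@ids) == 0L &&
      (!nzchar(object@webenv) || !nzchar(object@queryKey)))
    return("history keys required when resultCount > 0 and no explicit IDs")
  TRUE
})

#' DownloadState: planned and executed batches for one result set
#'
#' @slot handle the [SearchHandle-class] being downloaded
#' @slot batchSize articles per E-Fetch request (default 500)
#' @slot batches data.frame with columns index, status
#'   (pending/done/failed), path
#' @export
setClass("DownloadState", representation(
  handle = "SearchHandle", batchSize = "integer", batches = "data.frame"
))

setValidity("DownloadState", function(object) {
  b <- object@batches
  n <- object@handle@resultCount
  expected <- as.integer(ceiling(n / object@batchSize))
  if (nrow(b) != expected)
    return(sprintf("expected %d batches for %d results", expected, n))
  if (nrow(b) > 0L) {
    if (!identical(b$index, seq_len(nrow(b)) - 1L))
      return("batch indices must be contiguous from 0")
    if (!all(b$status %in% c("pending", "done", "failed")))
      return("invalid batch status")
  }
  TRUE
})

#' NormalizedTable: dialect-independent rectangular table
#'
#' One article table after span expansion: every row has the same number
#' of cells, and a cell spanning several rows or columns has its value
#' duplicated into each covered position so downstream column matching
#' sees dense columns.
#'
#' @slot tableId identifier of the table within its article
#' @slot label,caption table label/caption text ("" when absent)
#' @slot nHeaderRows number of leading header rows
#' @slot cells character matrix of cell values
#' @slot footnotes character vector of footnote texts
#' @slot sourceDialect "xhtml" or "oasis"
#' @export
setClass("NormalizedTable", representation(
  tableId = "character", label = "character", caption = "character",
  nHeaderRows = "integer", cells = "matrix", footnotes = "character",
  sourceDialect = "character"
))

setValidity("NormalizedTable", function(object) {
  if (!is.character(object@cells)) return("cells must be a character matrix")
  if (object@nHeaderRows > nrow(object@cells))
    return("nHeaderRows exceeds number of rows")
  if (!object@sourceDialect %in% c("xhtml", "oasis"))
    return("sourceDialect must be 'xhtml' or 'oasis'")
  TRUE
})

setMethod("show", "NormalizedTable", function(object) {
  cat(sprintf("NormalizedTable '%s' (%s dialect): %d x %d, %d header row(s)\n",
              object@tableId, object@sourceDialect, nrow(object@cells),
              ncol(object@cells), object@nHeaderRows))
})

#' DocTermMatrix: articles x vocabulary TF-IDF weights
#'
#' Raw term counts and their TF-IDF weights (smoothed idf, L2-normalized
#' rows) over a fixed vocabulary.
#'
#' @slot pmcids row identifiers, one per article
#' @slot terms the vocabulary, lowercase, unique
#' @slot weights sparse articles x terms TF-IDF matrix
#' @slot rawCounts sparse articles x terms count matrix
#' @slot idf per-term inverse document frequency used for the weights
#' @export
setClass("DocTermMatrix", representation(
  pmcids = "character", terms = "character", weights = "Matrix",
  rawCounts = "Matrix", idf = "numeric"
))

setValidity("DocTermMatrix", function(object) {
  if (any(duplicated(object@terms))) return("terms must be unique")
  if (!identical(dim(object@weights), dim(object@rawCounts)))
    return("weights and rawCounts must have identical dimensions")
  if (nrow(object@weights) != length(object@pmcids))
    return("one row per pmcid required")
  if (ncol(object@weights) != length(object@terms))
    return("one column per term required")
  if (any(object@weights@x < 0)) return("weights must be non-negative")
  nrm <- sqrt(Matrix::rowSums(object@weights^2))
  nz <- nrm > 0
  if (any(abs(nrm[nz] - 1) > 1e-9))
    return("nonzero weight rows must have unit L2 norm")
  TRUE
})

setMethod("show", "DocTermMatrix", function(object) {
  cat(sprintf("DocTermMatrix: %d articles x %d terms (%d nonzero weights)\n",
              length(object@pmcids), length(object@terms),
              length(object@weights@x)))
})

#' BrainGrid: the spatial support of voxel maps
#'
#' An axis-aligned isotropic voxel grid in millimetre (RAS) world
#' coordinates. `origin` is the world coordinate of the center of voxel
#' (0, 0, 0).
#'
#' @slot shape integer (nx, ny, nz)
#' @slot voxelSize isotropic voxel size in mm
#' @slot origin mm coordinates of the first voxel center
#' @export
setClass("BrainGrid", representation(
  shape = "integer", voxelSize = "numeric", origin = "numeric"
))

setValidity("BrainGrid", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be three positive integers")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

setMethod("show", "BrainGrid", function(object) {
  cat(sprintf("BrainGrid: %s voxels at %g mm, origin (%s) mm\n",
              paste(object@shape, collapse = " x "), object@voxelSize,
              paste(object@origin, collapse = ", ")))
})

#' StudyMaps: per-study voxel maps built from reported peaks
#'
#' @slot grid the [BrainGrid-class]
#' @slot pmcids study identifiers, one per row
#' @slot binary sparse studies x voxels pattern matrix (peak within radius)
#' @slot density sparse studies x voxels Gaussian-smoothed peak maps
#' @export
setClass("StudyMaps", representation(
  grid = "BrainGrid", pmcids = "character", binary = "Matrix",
  density = "Matrix"
))

setValidity("StudyMaps", function(object) {
  nv <- prod(object@grid@shape)
  if (ncol(object@binary) != nv || ncol(object@density) != nv)
    return("map columns must match grid voxel count")
  if (nrow(object@binary) != length(object@pmcids) ||
      nrow(object@density) != length(object@pmcids))
    return("one row per study required")
  TRUE
})

setMethod("show", "StudyMaps", function(object) {
  cat(sprintf("StudyMaps: %d studies on a %s grid\n", length(object@pmcids),
              paste(object@grid@shape, collapse = " x ")))
})

#' MetaResult: voxelwise association maps for one term
#'
#' @slot term the term tested
#' @slot chi2,p,z voxel maps (chi-square statistic, two-sided p, signed z)
#' @slot qThreshold FDR level used for `significant`
#' @slot significant logical voxel map after Benjamini-Hochberg control
#' @slot grid the [BrainGrid-class]
#' @export
setClass("MetaResult", representation(
  term = "character", chi2 = "numeric", p = "numeric", z = "numeric",
  qThreshold = "numeric", significant = "logical", grid = "BrainGrid"
))

setValidity("MetaResult", function(object) {
  n <- prod(object@grid@shape)
  if (length(object@chi2) != n || length(object@p) != n ||
      length(object@z) != n || length(object@significant) != n)
    return("map lengths must match grid voxel count")
  if (any(object@p < 0 | object@p > 1)) return("p values must lie in [0, 1]")
  TRUE
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("MetaResult '%s': %d/%d voxels significant at q = %g\n",
              object@term, sum(object@significant),
              length(object@significant), object@qThreshold))
})

# ---- accessors ----

#' @describeIn SearchHandle-class number of matching articles
#' @param handle a SearchHandle
#' @export
resultCount <- function(handle) handle@resultCount

#' @describeIn NormalizedTable-class the rectangular cell grid
#' @param table a NormalizedTable
#' @export
tableCells <- function(table) table@cells

#' @describeIn NormalizedTable-class number of header rows
#' @export
headerRows <- function(table) table@nHeaderRows

#' @describeIn DocTermMatrix-class the TF-IDF weight matrix
#' @param dtm a DocTermMatrix
#' @export
tfidfWeights <- function(dtm) dtm@weights

#' @describeIn DocTermMatrix-class the vocabulary terms, in column order
#' @export
vocabularyTerms <- function(dtm) dtm@terms

#' @describeIn BrainGrid-class total number of voxels
#' @param grid a BrainGrid
#' @export
voxelCount <- function(grid) prod(grid@shape)
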