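#' Construct a brain grid
#'
#' The default is an MNI-like bounding box, x in [-90, 90], y in
#' [-126, 90], z in [-72, 108] mm, sampled at 4 mm (2 mm available via
#' `voxelSize`): large enough to hold every plausible peak while small
#' enough for interactive work.
#'
#' @param voxelSize isotropic voxel size in mm
#' @param xlim,ylim,zlim world-coordinate bounds in mm
#' @return a [BrainGrid-class]
#' @export
defaultGrid <- function(voxelSize = 4, xlim = c(-90, 90),
                        ylim = c(-126, 90), zlim = c(-72, 108)) {
  shape <- as.integer(c(diff(xlim), diff(ylim), diff(zlim)) / voxelSize + 1L)
  new("BrainGrid", shape = shape, voxelSize = as.numeric(voxelSize),
      origin = c(xlim[1], ylim[1], zlim[1]))
}

# 0-based voxel indices of world coordinates (nearest voxel center).
worldToVoxel <- function(grid, xyz) {
  round(sweep(xyz, 2, grid@origin) / grid@voxelSize)
}

voxelToWorld <- function(grid, ijk) {
  sweep(ijk * grid@voxelSize, 2, grid@origin, `+`)
}

inGrid <- function(grid, ijk) {
  ijk[, 1] >= 0 & ijk[, 1] < grid@shape[1] &
    ijk[, 2] >= 0 & ijk[, 2] < grid@shape[2] &
    ijk[, 3] >= 0 & ijk[, 3] < grid@shape[3]
}

linearIndex <- function(grid, ijk) {
  1L + ijk[, 1] + grid@shape[1] * (ijk[, 2] + grid@shape[2] * ijk[, 3])
}

#' Binarize peaks onto a grid
#'
#' A voxel is true iff its center lies within `radius` mm of any peak.
#' Out-of-grid peaks are ignored (their count is reported as an
#' attribute).
#'
#' @param peaks data.frame with x, y, z columns (mm)
#' @param grid a [BrainGrid-class]
#' @param radius sphere radius in mm (default 10)
#' @return logical vector over voxels (column-major), attribute
#'   `nOutOfGrid`
#' @export
peaksToBinary <- function(peaks, grid, radius = 10) {
  stopifnot(radius >= 0)
  out <- logical(voxelCount(grid))
  nOut <- 0L
  if (nrow(peaks) > 0L) {
    vs <- grid@voxelSize
    r <- ceiling(radius / vs)
    offsets <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
    for (i in seq_len(nrow(peaks))) {
      p <- c(peaks$x[i], peaks$y[i], peaks$z[i])
      center <- round((p - grid@origin) / vs)
      if (any(center < 0 | center >= grid@shape)) {
        nOut <- nOut + 1L
        next
      }
      ijk <- sweep(offsets, 2, center, `+`)
      keep <- inGrid(grid, ijk)
      ijk <- ijk[keep, , drop = FALSE]
      centers <- voxelToWorld(grid, ijk)
      d2 <- rowSums(sweep(centers, 2, p)^2)
      hit <- d2 <= radius^2 + 1e-9
      out[linearIndex(grid, ijk[hit, , drop = FALSE])] <- TRUE
    }
  }
  attr(out, "nOutOfGrid") <- nOut
  out
}

#' Gaussian-smoothed peak map
#'
#' Sum of isotropic Gaussian kernels centred at the peaks, evaluated at
#' voxel centers, each kernel normalized to unit sum over an unbounded
#' grid (so total in-grid mass approximately equals the number of peaks
#' when peaks sit away from the boundary). Kernels are truncated at
#' 6 sigma (truncation error below 1e-8).
#'
#' @param peaks data.frame with x, y, z columns (mm)
#' @param grid a [BrainGrid-class]
#' @param sigma kernel standard deviation in mm (default 3.82,
#'   equivalent to a 9 mm FWHM)
#' @return numeric vector over voxels (column-major)
#' @export
peaksToDensity <- function(peaks, grid, sigma = 3.82) {
  stopifnot(sigma > 0)
  out <- numeric(voxelCount(grid))
  if (nrow(peaks) == 0L) return(out)
  vs <- grid@voxelSize
  r <- ceiling(6 * sigma / vs)
  rWide <- max(r, ceiling(9 * sigma / vs))
  for (i in seq_len(nrow(peaks))) {
    p <- c(peaks$x[i], peaks$y[i], peaks$z[i])
    center <- round((p - grid@origin) / vs)
    # separable 1D kernels; per-axis normalization over a wide window
    # stands in for the unbounded-grid sum
    k1 <- vector("list", 3L)
    for (ax in 1:3) {
      offs <- (-rWide):rWide
      pos <- (center[ax] + offs) * vs + grid@origin[ax]
      w <- exp(-(pos - p[ax])^2 / (2 * sigma^2))
      w <- w / sum(w)
      keepIdx <- abs(offs) <= r
      k1[[ax]] <- list(idx = center[ax] + offs[keepIdx], w = w[keepIdx])
    }
    ijk <- as.matrix(expand.grid(x = k1[[1]]$idx, y = k1[[2]]$idx,
                                 z = k1[[3]]$idx))
    wts <- as.vector(outer(outer(k1[[1]]$w, k1[[2]]$w), k1[[3]]$w))
    keep <- inGrid(grid, ijk)
    idx <- linearIndex(grid, ijk[keep, , drop = FALSE])
    out[idx] <- out[idx] + wts[keep]
  }
  out
}

#' Build per-study binary and density maps
#'
#' @param coords coordinate records (pmcid, x, y, z) as produced by
#'   [corpusCoordinates()]; UNKNOWN-space records are included as-is
#' @param grid a [BrainGrid-class]
#' @param radius sphere radius in mm for the binary maps
#' @param sigma Gaussian sd in mm for the density maps
#' @param pmcids study order; defaults to order of appearance
#' @return a [StudyMaps-class] with sparse maps
#' @export
buildStudyMaps <- function(coords, grid, radius = 10, sigma = 3.82,
                           pmcids = unique(coords$pmcid)) {
  nv <- voxelCount(grid)
  bi <- bj <- integer()
  di <- dj <- integer()
  dx <- numeric()
  for (s in seq_along(pmcids)) {
    peaks <- coords[coords$pmcid == pmcids[s], , drop = FALSE]
    b <- peaksToBinary(peaks, grid, radius)
    idx <- which(b)
    bi <- c(bi, rep.int(s, length(idx)))
    bj <- c(bj, idx)
    d <- peaksToDensity(peaks, grid, sigma)
    idx <- which(d > 0)
    di <- c(di, rep.int(s, length(idx)))
    dj <- c(dj, idx)
    dx <- c(dx, d[idx])
  }
  new("StudyMaps", grid = grid, pmcids = pmcids,
      binary = Matrix::sparseMatrix(i = bi, j = bj, x = TRUE,
                                    dims = c(length(pmcids), nv)),
      density = Matrix::sparseMatrix(i = di, j = dj, x = dx,
                                     dims = c(length(pmcids), nv)))
}

#' Benjamini-Hochberg rejections
#'
#' Standard step-up FDR procedure at level `q` (computed through
#' `p.adjust`).
#'
#' @param p vector of p-values in [0, 1]
#' @param q FDR level in (0, 1)
#' @return logical rejection vector
#' @export
bhFdr <- function(p, q) {
  if (length(p) == 0L) return(logical())
  p.adjust(p, method = "BH") <= q
}

#' Voxelwise chi-square association test
#'
#' For every voxel, builds the 2x2 contingency of (term present/absent)
#' x (voxel active/inactive) over studies and computes the Pearson
#' chi-square statistic without continuity correction; p-values come
#' from the chi-square distribution with 1 df, the z map is the
#' two-sided normal transform signed by whether P(active | term) exceeds
#' P(active | no term), and Benjamini-Hochberg control at `qThreshold`
#' defines the significant map. A voxel with a zero margin (e.g. active
#' in every study) gets chi2 = 0, p = 1.
#'
#' @param binary studies x voxels logical/sparse matrix
#'   (`StudyMaps@binary`)
#' @param termPresent logical study vector
#' @param term label stored in the result
#' @param grid the [BrainGrid-class] of the maps
#' @param qThreshold FDR level (default 0.01)
#' @return a [MetaResult-class]
#' @export
chiSquareMap <- function(binary, termPresent, term = "term",
                         grid, qThreshold = 0.01) {
  stopifnot(sum(termPresent) >= 2L, sum(!termPresent) >= 2L)
  n <- nrow(binary)
  nT <- sum(termPresent)
  nF <- n - nT
  a <- Matrix::colSums(binary[termPresent, , drop = FALSE])   # term & active
  cc <- Matrix::colSums(binary[!termPresent, , drop = FALSE]) # no-term & active
  b <- nT - a
  d <- nF - cc
  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi2 <- ifelse(denom > 0, n * (a * d - b * cc)^2 / denom, 0)
  p <- ifelse(denom > 0, pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  sgn <- sign(a / nT - cc / nF)
  z <- sgn * qnorm(pmax(p, .Machine$double.xmin) / 2, lower.tail = FALSE)
  new("MetaResult", term = term, chi2 = as.numeric(chi2),
      p = as.numeric(p), z = as.numeric(z), qThreshold = qThreshold,
      significant = bhFdr(p, qThreshold), grid = grid)
}

#' Ridge model from TF-IDF features to smoothed peak maps
#'
#' Per-voxel ridge regression of the density maps on the TF-IDF
#' features, solved in closed form from the normal equations with the
#' penalty applied to all coefficients. This is a deliberately simple
#' one-stage linear model: text features in, brain maps out.
#'
#' @param dtm a [DocTermMatrix-class]; rows align with `density` rows
#' @param density studies x voxels density matrix
#'   (`StudyMaps@density`)
#' @param ridgePenalty non-negative penalty; 0 requires a non-singular
#'   feature Gram matrix
#' @param grid the [BrainGrid-class] of the maps
#' @return object of class `TermModel`: list(coefficients
#'   [terms x voxels], terms, idf, grid)
#' @export
fitTermModel <- function(dtm, density, ridgePenalty = 0.1, grid) {
  stopifnot(nrow(dtm@weights) == nrow(density), ridgePenalty >= 0)
  X <- as.matrix(dtm@weights)
  G <- crossprod(X) + ridgePenalty * diag(ncol(X))
  rhs <- as.matrix(Matrix::crossprod(Matrix::Matrix(X), density))
  coef <- tryCatch(solve(G, rhs), error = function(e) e)
  if (inherits(coef, "error")) {
    if (ridgePenalty == 0)
      stop("singular feature Gram matrix; use a positive ridgePenalty",
           call. = FALSE)
    stop(coef)
  }
  rownames(coef) <- dtm@terms
  structure(list(coefficients = coef, terms = dtm@terms, idf = dtm@idf,
                 grid = grid),
            class = "TermModel")
}

#' Predict a brain map from a free-text query
#'
#' Tokenizes the query, builds its TF-IDF row using the training idf,
#' and returns the feature-weighted sum of coefficient maps.
#'
#' @param model a `TermModel` from [fitTermModel()]
#' @param query free text
#' @return numeric voxel map; all-zero (with a warning) when no query
#'   token is in the vocabulary
#' @export
predictMap <- function(model, query) {
  counts <- countTerms(query, model$terms)
  w <- counts * model$idf
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) {
    warning("no query term is in the vocabulary; returning a zero map")
    return(numeric(ncol(model$coefficients)))
  }
  as.numeric((w / nrm) %*% model$coefficients)
}

#' Affine of a grid (voxel indices to mm, RAS)
#'
#' @param grid a [BrainGrid-class]
#' @return 4x4 affine matrix
#' @export
gridAffine <- function(grid) {
  aff <- diag(c(rep(grid@voxelSize, 3), 1))
  aff[1:3, 4] <- grid@origin
  aff
}

#' Write a voxel map as a NIfTI-1 volume
#'
#' @param map numeric voxel vector or array matching the grid shape
#' @param grid a [BrainGrid-class]
#' @param path output file (".nii" or ".nii.gz")
#' @return the path, invisibly
#' @export
writeVolume <- function(map, grid, path) {
  if (length(map) != voxelCount(grid))
    stop("map length does not match grid shape")
  arr <- array(as.numeric(map), dim = grid@shape)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(gridAffine(grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume back as a voxel vector
#'
#' @param path a NIfTI file
#' @return numeric vector (column-major), attribute `affine`
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.numeric(img)
  attr(out, "affine") <- unclass(RNifti::xform(img))
  out
}
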