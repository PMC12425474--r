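test_that("peak binarization respects radius and grid bounds", {
  grid <- defaultGrid()
  # a peak exactly at a voxel center with radius 0 marks that voxel only
  b0 <- peaksToBinary(data.frame(x = 2, y = -18, z = 44), grid, radius = 0)
  expect_identical(sum(b0), 1L)
  expect_true(b0[voxelIndexOf(grid, c(2, -18, 44))])

  # radius = voxel size marks the 7-voxel face-neighbour cross
  b1 <- peaksToBinary(data.frame(x = 2, y = -18, z = 44), grid,
                      radius = grid@voxelSize)
  expect_identical(sum(b1), 7L)

  # an out-of-grid peak yields an all-false map
  b2 <- peaksToBinary(data.frame(x = 500, y = 0, z = 0), grid, radius = 10)
  expect_false(any(b2))
  expect_identical(attr(b2, "nOutOfGrid"), 1L)
})

test_that("density maps are unit-mass kernels, linear in peaks", {
  grid <- defaultGrid()
  one <- peaksToDensity(data.frame(x = 2, y = -18, z = 44), grid, sigma = 3.82)
  expect_identical(which.max(one), voxelIndexOf(grid, c(2, -18, 44)))
  expect_equal(sum(one), 1, tolerance = 1e-6)

  two <- peaksToDensity(data.frame(x = c(2, 2), y = c(-18, -18),
                                   z = c(44, 44)), grid, sigma = 3.82)
  expect_equal(two, 2 * one, tolerance = 1e-12)

  # total mass approximately equals the number of interior peaks
  pk <- data.frame(x = c(10, -30, 22), y = c(0, -40, 30), z = c(10, 0, -20))
  expect_equal(sum(peaksToDensity(pk, grid, sigma = 3.82)), 3,
               tolerance = 1e-6)
})

test_that("the chi-square map matches the textbook contingency formula", {
  # spec'd worked example: table [[20,10],[5,25]] => chi2 = 15.428571...
  term <- rep(c(TRUE, FALSE), c(30, 30))
  active <- c(rep(TRUE, 20), rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 25))
  res <- chiSquareMap(matrix(active, ncol = 1), term,
                      grid = new("BrainGrid", shape = c(1L, 1L, 1L),
                                 voxelSize = 1, origin = c(0, 0, 0)))
  expect_equal(res@chi2, 60 * (20 * 25 - 10 * 5)^2 / (30 * 30 * 25 * 35),
               tolerance = 1e-9)
  expect_gt(res@z, 0)  # P(active | term) > P(active | no term)

  # oracle equivalence on random corpora: 20 studies x 100 voxels
  grid100 <- new("BrainGrid", shape = c(10L, 10L, 1L), voxelSize = 1,
                 origin = c(0, 0, 0))
  for (s in 1:10) {
    set.seed(s)
    binary <- matrix(runif(20 * 100) < 0.3, 20, 100)
    term <- c(rep(TRUE, 10), rep(FALSE, 10))
    res <- chiSquareMap(binary, term, grid = grid100)
    oracle <- bruteChiSquare(binary, term)
    expect_lt(max(abs(res@chi2 - oracle[, 1])), 1e-9)
    expect_lt(max(abs(res@p - oracle[, 2])), 1e-9)
  }
})

test_that("degenerate margins give chi2 = 0 and p = 1", {
  grid1 <- new("BrainGrid", shape = c(1L, 1L, 1L), voxelSize = 1,
               origin = c(0, 0, 0))
  allActive <- matrix(TRUE, 10, 1)
  res <- chiSquareMap(allActive, rep(c(TRUE, FALSE), 5), grid = grid1)
  expect_identical(res@chi2, 0)
  expect_identical(res@p, 1)
})

test_that("Benjamini-Hochberg matches a brute-force step-up exactly", {
  expect_identical(bhFdr(c(0.01, 0.02, 0.04), 0.05), rep(TRUE, 3))
  expect_identical(bhFdr(c(0.5, 0.9), 0.05), rep(FALSE, 2))
  expect_true(bhFdr(0.04, 0.05))
  expect_identical(bhFdr(numeric(), 0.05), logical())
  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:200, 1))
    expect_identical(bhFdr(p, 0.05), bruteBh(p, 0.05))
  }
})

test_that("the ridge model reduces to OLS for orthonormal features and shrinks to zero", {
  grid1 <- new("BrainGrid", shape = c(2L, 2L, 1L), voxelSize = 1,
               origin = c(0, 0, 0))
  X <- diag(4)  # orthonormal features, one per study
  dtm <- tfidfMatrix(X, paste0("PMC", 1:4), paste0("t", 1:4))
  Y <- matrix(rnorm(16), 4, 4)
  m0 <- fitTermModel(dtm, Y, ridgePenalty = 0, grid = grid1)
  W <- as.matrix(tfidfWeights(dtm))
  expect_equal(m0$coefficients, solve(crossprod(W)) %*% crossprod(W, Y),
               tolerance = 1e-9, ignore_attr = TRUE)

  mBig <- fitTermModel(dtm, Y, ridgePenalty = 1e12, grid = grid1)
  expect_lt(max(abs(mBig$coefficients)), 1e-9)

  # singular design with zero penalty advises a positive one
  Xs <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  dtms <- tfidfMatrix(Xs, paste0("PMC", 1:4), c("a", "b"))
  expect_error(fitTermModel(dtms, Y, ridgePenalty = 0, grid = grid1),
               "positive ridgePenalty")
})

test_that("query prediction is linear in terms and warns out of vocabulary", {
  grid1 <- new("BrainGrid", shape = c(2L, 2L, 1L), voxelSize = 1,
               origin = c(0, 0, 0))
  set.seed(1)
  dtm <- tfidfMatrix(matrix(rpois(12, 2), 4, 3), paste0("PMC", 1:4),
                     c("pain", "fear", "memory"))
  model <- fitTermModel(dtm, matrix(rnorm(16), 4, 4), 0.1, grid1)
  single <- predictMap(model, "pain")
  # single-term query: the term's coefficient map up to positive scale
  expect_equal(single, as.numeric(model$coefficients["pain", ]),
               tolerance = 1e-9)
  pairMap <- predictMap(model, "pain fear")
  w <- c(model$idf[1:2], 0)
  w <- w / sqrt(sum(w^2))
  expect_equal(pairMap, as.numeric(w %*% model$coefficients),
               tolerance = 1e-12)
  expect_warning(z <- predictMap(model, "qwertyuiop"), "vocabulary")
  expect_identical(z, numeric(4))
})

test_that("volumes round-trip through NIfTI with the grid affine", {
  grid <- defaultGrid()
  set.seed(3)
  map <- rnorm(voxelCount(grid))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(map, grid, f)
  back <- readVolume(f)
  expect_lt(max(abs(back - map)), max(abs(map)) * 1e-6)  # float32 scale
  aff <- attr(back, "affine")
  expect_equal(unname(diag(aff)[1:3]), rep(4, 3))
  expect_equal(unname(aff[1:3, 4]), c(-90, -126, -72))
  expect_error(writeVolume(map[-1], grid, f), "shape")
  # zero map round-trips to all zeros
  writeVolume(numeric(voxelCount(grid)), grid, f)
  expect_identical(max(abs(readVolume(f))), 0)
})
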