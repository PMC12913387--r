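test_that("low-signal threshold separates two well-separated intensity modes", {
  set.seed(1)
  x <- array(c(rnorm(5000, 100, 2), rnorm(5000, 1000, 2)), dim = c(100, 100, 1))
  thr <- lowSignalThreshold(x)
  expect_gt(thr, 110)
  expect_lt(thr, 990)
})

test_that("threshold equals the grid-scan density-minimum oracle on a bimodal mixture", {
  set.seed(42)
  n <- 1e5
  x <- c(rnorm(0.4 * n, 20, 5), rnorm(0.6 * n, 80, 5))
  thr <- lowSignalThreshold(array(x, dim = c(n, 1, 1)))
  ## oracle: evaluate the same Gaussian KDE on a 0.1-step grid between the
  ## two mode locations and take the argmin
  bw <- bw.nrd0(x)
  grid <- seq(20, 80, by = 0.1)
  dens <- vapply(grid, function(t) sum(dnorm((t - x) / bw)), numeric(1))
  oracle <- grid[which.min(dens)]
  expect_lt(abs(thr - oracle), 0.5)
})

test_that("constant image raises an explicit unimodal-histogram error", {
  expect_error(lowSignalThreshold(array(7, dim = c(4, 4, 2))), "unimodal")
})

test_that("flattening averages valid voxels over slices", {
  vol <- new("SpecimenVolume", data = array(7, dim = c(3, 3, 4)),
             voxelSize = c(1, 1, 1), specimenID = "t", diagnosis = 0L)
  flat <- flattenVolume(vol, array(TRUE, dim = c(3, 3, 4)))
  expect_true(all(flat@intensity == 7))
  ## column (10, 20, dropout) -> mean of valid entries = 15
  dat <- array(0, dim = c(1, 1, 3)); dat[1, 1, ] <- c(10, 20, 5)
  v <- array(c(TRUE, TRUE, FALSE), dim = c(1, 1, 3))
  vol2 <- new("SpecimenVolume", data = dat, voxelSize = c(1, 1, 1),
              specimenID = "t", diagnosis = 0L)
  expect_equal(flattenVolume(vol2, v)@intensity[1, 1], 15)
  ## fully-invalid column flagged as low-signal
  flat3 <- flattenVolume(vol2, array(FALSE, dim = c(1, 1, 3)))
  expect_equal(flat3@validity[1, 1], 1L)
})

test_that("flattened phantom equals a brute-force masked slice average", {
  cohort <- generateCohort(phantomConfig(seed = 6))
  sp <- cohort$specimens[[2]]
  thr <- lowSignalThreshold(sp$volume)
  valid3d <- sp$volume@data >= thr
  flat <- flattenVolume(sp$volume, valid3d)
  d <- dim(valid3d)
  for (i in sample(d[1], 10)) for (j in sample(d[2], 10)) {
    sel <- valid3d[i, j, ]
    if (any(sel))
      expect_equal(flat@intensity[i, j], mean(sp$volume@data[i, j, sel]))
  }
})

test_that("CNR follows its defining formula", {
  intens <- matrix(c(500, 550, 1000), 1, 3)
  flat <- computeCNR(flatImage(intens), matrix(c(TRUE, TRUE, FALSE), 1, 3))
  ## reference mode of (500, 550) by KDE lies between the two values;
  ## an exactly-constant reference gives CNR 0 at the reference
  flat2 <- computeCNR(flatImage(matrix(c(800, 800, 880), 1, 3)),
                      matrix(c(TRUE, TRUE, FALSE), 1, 3))
  expect_equal(flat2@referenceMode, 800)
  expect_equal(flat2@cnr[1, 1], 0)
  expect_equal(flat2@cnr[1, 3], 0.10)  # 1.1 x mode: the SN-voxel threshold
  expect_error(computeCNR(flatImage(intens), matrix(FALSE, 1, 3)), "empty")
})

test_that("reference mode equals the grid-scan KDE argmax oracle", {
  set.seed(7)
  vals <- rnorm(2000, 1000, 20)
  intens <- matrix(vals, 40, 50)
  flat <- computeCNR(flatImage(intens), matrix(TRUE, 40, 50))
  bw <- bw.nrd0(vals)
  grid <- seq(900, 1100, by = 0.1)
  dens <- vapply(grid, function(t) sum(dnorm((t - vals) / bw)), numeric(1))
  expect_lt(abs(flat@referenceMode - grid[which.max(dens)]), 0.5)
})

test_that("unconditional border removal strips perimeter plus two dilations", {
  validity <- matrix(1L, 16, 16)
  validity[4:13, 4:13] <- 0L  # 10 x 10 valid square
  flat <- flatImage(matrix(1000, 16, 16), validity = validity)
  out <- removeEdgeArtifacts(flat, matrix(FALSE, 16, 16))
  inner <- out@validity == 2L
  depth <- bruteDepth(validity == 0L)
  expect_identical(inner, validity == 0L & depth <= 3)
  ## the surviving core is the inner 4 x 4 block
  expect_equal(sum(out@validity == 0L), 16)
  expect_true(all(out@validity[7:10, 7:10] == 0L))
})

test_that("border-band removal respects the CNR cutoff and spares SN sections", {
  validity <- matrix(1L, 20, 20)
  validity[3:18, 3:18] <- 0L
  cnr <- matrix(NA_real_, 20, 20)
  cnr[validity == 0L] <- 0.05
  depth <- bruteDepth(validity == 0L)
  band <- validity == 0L & depth >= 4 & depth <= 8
  hot <- which(band, arr.ind = TRUE)[1:2, , drop = FALSE]
  cnr[hot] <- 0.50
  snMask <- matrix(FALSE, 20, 20)
  snMask[hot[2, 1], hot[2, 2]] <- TRUE  # second hot voxel is in an SN section
  flat <- flatImage(matrix(1000, 20, 20), validity = validity, cnr = cnr,
                    referenceMode = 1000)
  out <- removeEdgeArtifacts(flat, snMask)
  expect_equal(out@validity[hot[1, 1], hot[1, 2]], 3L)  # removed
  expect_equal(out@validity[hot[2, 1], hot[2, 2]], 0L)  # spared in SN
})

test_that("edge-removal sets match the brute-force distance-transform oracle", {
  set.seed(13)
  for (rep in 1:5) {
    mask <- matrix(runif(400) < 0.7, 20, 20)
    expect_identical(cityblockDepth(mask), 1 * bruteDepth(mask))
    validity <- matrix(ifelse(mask, 0L, 1L), 20, 20)
    cnr <- matrix(NA_real_, 20, 20); cnr[mask] <- 0
    flat <- flatImage(matrix(1000, 20, 20), validity = validity, cnr = cnr,
                      referenceMode = 1000)
    out <- removeEdgeArtifacts(flat, matrix(FALSE, 20, 20))
    d <- bruteDepth(mask)
    expect_identical(out@validity == 2L, mask & d <= 3)
  }
})

test_that("Cook's filter flags only genuine outliers", {
  expect_length(cooksOutlierFilter(rep(2.5, 10))$flagged, 0)
  x <- c(1, 1, 1, 1, 10)
  res <- cooksOutlierFilter(x)
  loo <- cooksLOO(x)
  expect_identical(res$flagged, which(loo > 4 / 5))
  expect_equal(res$kept, x[-res$flagged])
  expect_warning(cooksOutlierFilter(c(1, 2)), "fewer than 3")
})

test_that("hat-matrix Cook's distance equals the leave-one-out oracle", {
  set.seed(99)
  for (rep in 1:100) {
    x <- rnorm(sample(5:40, 1))
    expect_equal(cooksDistanceConstant(x), cooksLOO(x), tolerance = 1e-10)
  }
})

test_that("the cleaning chain is deterministic and scale invariant", {
  cohort <- generateCohort(phantomConfig(seed = 8))
  sp <- cohort$specimens[[3]]
  a <- cleanVolume(sp$volume, sp$layout, sp$masks$reference)
  b <- cleanVolume(sp$volume, sp$layout, sp$masks$reference)
  expect_identical(a$flat@validity, b$flat@validity)
  ## global intensity rescaling leaves every CNR value unchanged
  scaled <- sp$volume
  scaled@data <- scaled@data * 3.7
  cs <- cleanVolume(scaled, sp$layout, sp$masks$reference)
  expect_identical(a$flat@validity, cs$flat@validity)
  expect_equal(a$flat@cnr, cs$flat@cnr, tolerance = 1e-12)
})

test_that("noise-free phantoms lose no voxels beyond the unconditional border", {
  cohort <- generateCohort(noiselessConfig(seed = 2))
  for (sp in cohort$specimens[1:3]) {
    cl <- cleanVolume(sp$volume, sp$layout, sp$masks$reference)
    expect_equal(cl$removed[["border_cnr"]], 0L)
    expect_equal(cl$removed[["cooks_outlier"]], 0L)
  }
})
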