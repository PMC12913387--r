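test_that("zero-SD configuration reproduces the region x group concentration table", {
  cfg <- phantomConfig(regionParams = zeroSDParams(), seed = 3)
  truth <- generateConcentrations(cfg)
  snAD <- truth[truth$region == "SN" & truth$diagnosis == 0, ]
  expect_true(all(snAD$nm_conc == 0.57))
  expect_true(all(snAD$fe_conc == 69))
  pagPD <- truth[truth$region == "PAG" & truth$diagnosis == 1, ]
  expect_true(all(pagPD$nm_conc == 0.31))
  expect_true(all(pagPD$fe_conc == 33))
})

test_that("generation is reproducible under a fixed seed and varies across seeds", {
  cfg <- phantomConfig(seed = 11)
  t1 <- generateSectionCNR(generateConcentrations(cfg), cfg)
  t2 <- generateSectionCNR(generateConcentrations(cfg), cfg)
  expect_identical(t1, t2)
  t3 <- generateConcentrations(phantomConfig(seed = 12))
  expect_false(isTRUE(all.equal(t1$nm_conc, t3$nm_conc)))
})

test_that("default cohort has the published section structure", {
  truth <- generateConcentrations(phantomConfig(seed = 1))
  expect_equal(nrow(truth), 221L)
  perSpec <- table(truth$specimen_id)
  expect_true(all(perSpec >= 13 & perSpec <= 36))
  usable <- truth[truth$is_valid, ]
  expect_equal(sum(!usable$is_posterior), 163L)
  expect_equal(sum(usable$is_posterior), 56L)
  ## region counts among usable central-anterior sections
  expect_equal(as.integer(table(usable$region)[c("SN", "RN", "CC", "SC", "PAG")]),
               c(60L, 22L, 35L, 17L, 18L))
  ## diagnosis constant within specimen
  expect_true(all(tapply(truth$diagnosis, truth$specimen_id,
                         function(x) length(unique(x))) == 1))
  ## concentrations are nonnegative
  expect_true(all(truth$nm_conc >= 0 & truth$fe_conc >= 0))
})

test_that("linear CNR model evaluates the stated linear form exactly", {
  cfg <- phantomConfig(cnrModel = "linear", residualSD = 0,
                       subjectInterceptSD = 0, seed = 5)
  truth <- data.frame(specimen_id = "AD1", diagnosis = 0L, section_id = 1L,
                      grid_row = 0L, grid_col = 0L, region = "SN",
                      is_sn = TRUE, is_posterior = FALSE, is_valid = TRUE,
                      nm_conc = 0.1, fe_conc = 10)
  out <- generateSectionCNR(truth, cfg)
  expect_equal(100 * out$true_cnr, 7.37 * 0.1 + 0.050 * 10)  # = 1.237
  cfg0 <- phantomConfig(cnrModel = "linear", residualSD = 0,
                        subjectInterceptSD = 0,
                        signalCoeffs = c(beta0 = 0, beta1 = 0, beta2 = 0,
                                         beta3 = 0), seed = 5)
  out0 <- generateSectionCNR(truth, cfg0)
  expect_equal(out0$true_cnr, 0)
})

test_that("regression on a generated cohort recovers the linear-model slopes (OLS oracle)", {
  cfg <- phantomConfig(cnrModel = "linear", subjectInterceptSD = 0, seed = 7)
  truth <- generateSectionCNR(generateConcentrations(cfg), cfg)
  ca <- truth[!truth$is_posterior & truth$is_valid, ]
  expect_gt(nrow(ca), 150)
  ols <- lm(I(100 * true_cnr) ~ nm_conc + fe_conc + diagnosis, data = ca)
  se <- sqrt(diag(vcov(ols)))
  ## estimates within 4 standard errors of the generating coefficients
  expect_lt(abs(coef(ols)["nm_conc"] - 7.37), 4 * se["nm_conc"])
  expect_lt(abs(coef(ols)["fe_conc"] - 0.050), 4 * se["fe_conc"])
})

test_that("region x group sample moments converge to the configured parameters", {
  ## 50x the cohort size by stacking allocation rows
  a <- defaultAllocation()
  big <- a[rep(seq_len(nrow(a)), each = 50), ]
  rownames(big) <- c(paste0("AD", seq_len(350)), paste0("PD", seq_len(200)))
  cfg <- phantomConfig(nSpecimensAD = 350, nSpecimensPD = 200,
                       allocation = big, seed = 21)
  truth <- generateSectionCNR(generateConcentrations(cfg), cfg)
  rp <- defaultRegionParams()
  ## closed-form moments of the truncated-at-zero normal
  tmean <- function(m, s) if (s == 0) m else m + s * dnorm(m / s) / pnorm(m / s)
  tsd <- function(m, s) {
    if (s == 0) return(0)
    z <- m / s; lam <- dnorm(z) / pnorm(z)
    s * sqrt(1 - z * lam - lam^2)
  }
  gam <- phantomConfig()@condSlopes
  for (i in seq_len(nrow(rp))) {
    sel <- truth$region == rp$region[i] &
      truth$diagnosis == as.integer(rp$group[i] == "PD")
    expect_equal(mean(truth$nm_conc[sel]), tmean(rp$nm_mean[i], rp$nm_sd[i]),
                 tolerance = 0.03, ignore_attr = TRUE)
    expect_equal(sd(truth$nm_conc[sel]), tsd(rp$nm_mean[i], rp$nm_sd[i]),
                 tolerance = 0.08)
    expect_equal(mean(truth$fe_conc[sel]), tmean(rp$fe_mean[i], rp$fe_sd[i]),
                 tolerance = 0.04)
    expect_equal(sd(truth$fe_conc[sel]), tsd(rp$fe_mean[i], rp$fe_sd[i]),
                 tolerance = 0.10)
    ## anchored CNR means sit at the region x group NM-MRI anchor, shifted
    ## by the conditional slopes times the truncation offsets
    expCnr <- rp$cnr_mean[i]
    if (rp$region[i] != "posterior")
      expCnr <- expCnr +
        (gam[["gamma1"]] * (tmean(rp$nm_mean[i], rp$nm_sd[i]) - rp$nm_mean[i]) +
         gam[["gamma2"]] * (tmean(rp$fe_mean[i], rp$fe_sd[i]) - rp$fe_mean[i])) / 100
    expect_lt(abs(mean(truth$true_cnr[sel]) - expCnr), 0.006)
  }
})

test_that("rendered volumes encode section CNR and artifacts as documented", {
  cfg <- noiselessConfig(seed = 4)
  cohort <- generateCohort(cfg)
  sp <- cohort$specimens[[1]]
  tr <- cohort$truth[cohort$truth$specimen_id == sp$volume@specimenID, ]
  ip <- cfg@imageParams
  ## noise-free: per-section voxel intensities equal tissue * (1 + true CNR)
  for (k in sample(nrow(tr), 5)) {
    vox <- sp$masks$sectionMap == tr$section_id[k] & !is.na(sp$masks$sectionMap)
    vals <- sp$volume@data[, , 1][vox]
    expect_equal(vals, rep(ip$tissue * (1 + tr$true_cnr[k]), sum(vox)),
                 tolerance = 1e-12)
  }
  ## bimodal separation: threshold strictly between background and tissue
  thr <- lowSignalThreshold(sp$volume)
  expect_gt(thr, ip$background)
  expect_lt(thr, ip$tissue * 0.95)
})

test_that("dropout probability is honored (checked against the generator's own mask)", {
  cfg <- phantomConfig(seed = 9, imageParams = list(dropout_prob = 0.05))
  cohort <- generateCohort(cfg)
  fracs <- vapply(cohort$specimens, function(sp) {
    inSpec <- rep(sp$masks$specimen, dim(sp$volume@data)[3])
    sum(sp$masks$dropout) / sum(inSpec)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.005)
  ## dropout voxels fall below the tissue level
  sp <- cohort$specimens[[1]]
  expect_true(all(sp$volume@data[sp$masks$dropout] <
                    cfg@imageParams$tissue / 2))
})

test_that("configuration invariants are enforced", {
  rp <- defaultRegionParams()
  rp$nm_sd[1] <- -0.1
  expect_error(phantomConfig(regionParams = rp), "SD")
  a <- defaultAllocation()
  a[1, "posterior"] <- 30L
  expect_error(phantomConfig(allocation = a), "13")
  expect_error(phantomConfig(imageParams = list(background = 2000)),
               "background")
})
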