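## shared fixtures: all built in code at test time

## region parameters with every SD forced to zero (deterministic draws)
zeroSDParams <- function() {
  rp <- defaultRegionParams()
  rp[, c("cnr_sd", "nm_sd", "fe_sd")] <- 0
  rp
}

## noise-free phantom configuration (clean imaging, no stochastic CNR terms)
noiselessConfig <- function(seed = 1L, ...) {
  phantomConfig(seed = seed, subjectInterceptSD = 0, residualSD = 0,
                imageParams = list(edge_amplitude = 0, dropout_prob = 0),
                ...)
}

## section table taken straight from ground truth (no imaging stage)
truthSections <- function(cfg) {
  cohort <- generateCohort(cfg, render = FALSE)
  s <- cohort$truth[cohort$truth$is_valid, ]
  s$mean_cnr <- s$true_cnr
  s
}

## minimal CleanFlatImage built by hand
flatImage <- function(intensity, validity = NULL, cnr = NULL,
                      referenceMode = NA_real_) {
  if (is.null(validity))
    validity <- matrix(0L, nrow(intensity), ncol(intensity))
  if (is.null(cnr))
    cnr <- matrix(NA_real_, nrow(intensity), ncol(intensity))
  new("CleanFlatImage", intensity = intensity, validity = validity,
      cnr = cnr, referenceMode = referenceMode)
}

## brute-force city-block distance from each TRUE cell to the nearest FALSE
## cell or image edge (quadratic-time oracle)
bruteDepth <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  inv <- which(!mask, arr.ind = TRUE)
  d <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    edge <- min(i, j, nr + 1L - i, nc + 1L - j)
    cell <- if (nrow(inv)) min(abs(inv[, 1] - i) + abs(inv[, 2] - j)) else Inf
    d[i, j] <- min(edge, cell)
  }
  d
}

## leave-one-out Cook's distance oracle for the intercept-only regression
cooksLOO <- function(x) {
  n <- length(x)
  s2 <- sum((x - mean(x))^2) / (n - 1)
  vapply(seq_len(n), function(i) {
    mi <- mean(x[-i])
    sum((mean(x) - mi)^2 * n) / (1 * s2)
  }, numeric(1))
}
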