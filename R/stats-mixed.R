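## Profiled maximum-likelihood fit of a Gaussian random-intercept model
## y = X beta + u[g] + e,  u ~ N(0, lambda sigma2), e ~ N(0, sigma2).
## One random intercept makes the covariance V = sigma2 (I + lambda Z Z')
## block-diagonal, so GLS quantities reduce to per-group sums and the
## likelihood profiles to a 1D search over lambda.
lmmProfileML <- function(y, X, g, tol = 1e-10) {
  g <- as.integer(factor(g))
  n <- length(y)
  ns <- tabulate(g)
  gls <- function(lambda) {
    cs <- lambda / (1 + ns * lambda)
    Sx <- rowsum(X, g)
    Sy <- as.vector(rowsum(y, g))
    XtVX <- crossprod(X) - crossprod(Sx * sqrt(cs))
    XtVy <- crossprod(X, y) - crossprod(Sx, cs * Sy)
    beta <- solve(XtVX, XtVy)
    r <- as.vector(y - X %*% beta)
    Sr <- as.vector(rowsum(r, g))
    q <- sum(r^2) - sum(cs * Sr^2)       # r' (I + lambda ZZ')^-1 r
    sigma2 <- max(q / n, 1e-300)         # guard the log for noise-free data
    m2l <- n * log(2 * pi * sigma2) + sum(log1p(ns * lambda)) + n
    list(beta = as.vector(beta), XtVX = XtVX, sigma2 = sigma2, m2l = m2l)
  }
  opt <- optimize(function(l) gls(exp(l))$m2l, c(-15, 10), tol = tol)
  lambda <- exp(opt$minimum)
  if (gls(0)$m2l <= opt$objective + 1e-12) lambda <- 0  # boundary solution
  f <- gls(lambda)
  vcov <- solve(f$XtVX) * f$sigma2
  list(beta = f$beta, vcov = vcov, sigma2e = f$sigma2,
       sigma2b = lambda * f$sigma2, lambda = lambda, logLik = -f$m2l / 2)
}

#' Fit the random-intercept mixed model of section CNR
#'
#' Fits \deqn{\bar{CNR}_{gs} = \beta_0 + \beta_1 [\bar{NM}]_{gs} +
#' \beta_2 [\bar{Fe}]_{gs} + \beta_3 \, diagnosis_s + b_{0s} +
#' \epsilon_{gs}} by profiled maximum likelihood, with random intercepts
#' per specimen but no random slopes. The CNR response is expressed in
#' percent, so the NM slope has units of percent CNR per (ug NM/mg tissue)
#' and the Fe slope percent CNR per (ng Fe/mg tissue). Wald t statistics
#' use df = n - 4 (the number of fixed effects), and both R-squared
#' conventions for the fixed-effect predictions are reported.
#'
#' @param sections section table (see \code{\link{aggregateSections}}).
#' @param subset which sections to analyze: \code{"central_anterior"}
#'   (the primary analysis; excludes posterior-midbrain sections, where the
#'   NM-MRI signal is unrelated to NM content) or \code{"posterior"}.
#' @return a \code{\linkS4class{MixedModelFit}}.
#' @section Errors:
#' Requires at least 2 specimens and 10 sections; rows with missing
#' \code{mean_cnr} are dropped with a warning; a rank-deficient design
#' raises an error naming the collinear columns.
#' @examples
#' cohort <- generateCohort(phantomConfig(seed = 1), render = FALSE)
#' sections <- cohort$truth[cohort$truth$is_valid, ]
#' sections$mean_cnr <- sections$true_cnr
#' fitMixedModel(sections)
#' @export
fitMixedModel <- function(sections,
                          subset = c("central_anterior", "posterior")) {
  subset <- match.arg(subset)
  d <- sections[if (subset == "posterior") sections$is_posterior
                else !sections$is_posterior, , drop = FALSE]
  if (any(is.na(d$mean_cnr))) {
    warning(sum(is.na(d$mean_cnr)), " row(s) with missing mean_cnr dropped")
    d <- d[!is.na(d$mean_cnr), , drop = FALSE]
  }
  nspec <- length(unique(d$specimen_id))
  if (nspec < 2L) stop("need at least 2 specimens")
  if (nrow(d) < 10L) stop("need at least 10 sections")
  y <- 100 * d$mean_cnr
  X <- cbind(`(Intercept)` = 1, nm_conc = d$nm_conc, fe_conc = d$fe_conc,
             diagnosis = d$diagnosis)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  f <- lmmProfileML(y, X, d$specimen_id)
  n <- nrow(d)
  df <- n - 4L
  se <- sqrt(diag(f$vcov))
  tstat <- f$beta / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  tc <- qt(0.975, df)
  pred <- as.vector(X %*% f$beta)
  rss <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  nm <- colnames(X)
  new("MixedModelFit",
      beta = setNames(f$beta, nm), se = setNames(se, nm),
      ci95 = matrix(c(f$beta - tc * se, f$beta + tc * se), ncol = 2,
                    dimnames = list(nm, c("2.5 %", "97.5 %"))),
      tstat = setNames(tstat, nm), df = df, p = setNames(p, nm),
      sigma2e = f$sigma2e, sigma2b = f$sigma2b,
      r2 = c(corr = unname(cor(pred, y)^2), rss = 1 - rss / tss),
      nSections = n, nSpecimens = as.integer(nspec), subset = subset)
}
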