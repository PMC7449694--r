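.CRIT <- 1.96  # 95% normal quantile as printed in the field's tables

#' Assemble an MREstimate
#'
#' Low-level constructor filling in the normal-approximation 95 percent
#' confidence interval (beta +/- `crit` * se) and two-sided p-value. Mostly
#' for internal use and for wrapping externally published estimates.
#'
#' @param method estimator tag.
#' @param beta,se point estimate and standard error.
#' @param nSnps number of variants behind the estimate.
#' @param scale `"linear"` or `"logodds"`.
#' @param Q,Qdf heterogeneity statistic and df, where defined.
#' @param eggerIntercept,eggerInterceptSE,eggerInterceptP intercept test.
#' @param p override for the p-value (default: normal two-sided from beta/se).
#' @param crit critical value for the CI (default 1.96).
#' @return an [MREstimate-class] object.
#' @export
mrEstimate <- function(method, beta, se, nSnps, scale = "linear",
                       Q = NA_real_, Qdf = NA_real_,
                       eggerIntercept = NA_real_, eggerInterceptSE = NA_real_,
                       eggerInterceptP = NA_real_, p = NULL, crit = .CRIT) {
  if (is.null(p))
    p <- if (se > 0) 2 * stats::pnorm(-abs(beta) / se) else as.numeric(beta == 0)
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - crit * se, ciHigh = beta + crit * se, p = p,
      nSnps = as.integer(nSnps), Q = Q, Qdf = Qdf,
      eggerIntercept = eggerIntercept, eggerInterceptSE = eggerInterceptSE,
      eggerInterceptP = eggerInterceptP, scale = scale)
}

#' Wald ratio for a single-SNP instrument
#'
#' The SNP-outcome association divided by the SNP-exposure association, with
#' the first-order delta-method standard error seY / |betaX| (the
#' second-order form additionally propagates the exposure SE).
#'
#' @param h a [HarmonizedSet-class] restricted to one SNP.
#' @param secondOrder use the second-order delta-method SE.
#' @return an [MREstimate-class] with method `"wald"`.
#' @export
waldRatio <- function(h, secondOrder = FALSE) {
  stopifnot(is(h, "HarmonizedSet"))
  if (length(h@snps) != 1L)
    stop("waldRatio needs exactly one SNP; got ", length(h@snps))
  bx <- h@betaX; by <- h@betaY; sy <- h@seY; sx <- h@seX
  if (bx == 0) stop("undefined ratio: SNP-exposure association is zero")
  beta <- by / bx
  se <- if (secondOrder) sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
        else sy / abs(bx)
  mrEstimate("wald", beta, se, 1L, scale = h@outcomeScale)
}

.ivwCore <- function(bx, by, sy, randomEffects) {
  w <- 1 / sy^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  seFE <- 1 / sqrt(sum(w * bx^2))
  J <- length(bx)
  Q <- sum(w * (by - theta * bx)^2)
  scaleUp <- if (randomEffects == "multiplicative" && J > 1)
    max(1, sqrt(Q / (J - 1))) else 1
  list(theta = theta, se = seFE * scaleUp, seFE = seFE, Q = Q, J = J)
}

#' Inverse-variance weighted estimate for uncorrelated instruments
#'
#' Combines SNP-specific Wald estimates by weighted zero-intercept regression
#' of the SNP-outcome on the SNP-exposure associations with weights
#' 1 / seY^2. With multiplicative random effects (the default) the standard
#' error is inflated by max(1, sqrt(Q / (J - 1))), where Q is Cochran's
#' heterogeneity statistic; the floor at 1 stops heterogeneity below its
#' expectation from shrinking the SE. With J = 1 the result coincides with
#' the Wald ratio.
#'
#' @param h a [HarmonizedSet-class]; its LD slot, if any, is ignored (use
#'   [mrIVWCorrelated()] for correlated instruments).
#' @param randomEffects `"multiplicative"` (default) or `"fixed"`.
#' @return an [MREstimate-class] with method `"ivw_mre"` or `"ivw_fe"`.
#' @export
#' @examples
#' h <- new("HarmonizedSet", snps = c("rs1", "rs2", "rs3"),
#'   betaX = c(.2, .3, .25), seX = rep(.01, 3),
#'   betaY = c(.1, .15, .12), seY = rep(.02, 3),
#'   flips = rep(FALSE, 3), log = data.frame(), outcomeScale = "linear")
#' mrIVW(h)
mrIVW <- function(h, randomEffects = c("multiplicative", "fixed")) {
  stopifnot(is(h, "HarmonizedSet"))
  randomEffects <- match.arg(randomEffects)
  if (any(h@betaX == 0))
    stop("zero SNP-exposure association; drop the SNP first")
  fit <- .ivwCore(h@betaX, h@betaY, h@seY, randomEffects)
  mrEstimate(if (randomEffects == "multiplicative") "ivw_mre" else "ivw_fe",
             fit$theta, fit$se, fit$J, scale = h@outcomeScale,
             Q = fit$Q, Qdf = max(fit$J - 1, 0))
}

#' IVW for correlated instruments (generalized least squares)
#'
#' For instruments in linkage disequilibrium the weighting matrix becomes
#' Omega = diag(seY) %*% rho %*% diag(seY):
#' theta = (bx' Omega^-1 bx)^-1 bx' Omega^-1 by, with SE
#' (bx' Omega^-1 bx)^-1/2 and the same multiplicative random-effects scaling
#' as [mrIVW()], using the generalized residual Q. With an identity rho this
#' reduces exactly to [mrIVW()].
#'
#' @param h a [HarmonizedSet-class] with an aligned LD matrix
#'   (see [alignLD()]).
#' @param randomEffects `"multiplicative"` (default) or `"fixed"`.
#' @param ridge small non-negative value added to the diagonal of rho to
#'   stabilise near-singular correlation structures (default 0).
#' @param conditionMax maximum acceptable condition number of Omega; above
#'   it an error advises pruning or the ridge option.
#' @return an [MREstimate-class] with method `"ivw_correlated"`.
#' @export
mrIVWCorrelated <- function(h, randomEffects = c("multiplicative", "fixed"),
                            ridge = 0, conditionMax = 1e12) {
  stopifnot(is(h, "HarmonizedSet"))
  randomEffects <- match.arg(randomEffects)
  if (is.null(h@ld))
    stop("no LD matrix attached; use alignLD() first")
  rho <- h@ld@rho
  if (ridge > 0) rho <- rho + diag(ridge, nrow(rho))
  omega <- rho * tcrossprod(h@seY)
  kappa <- kappa(omega, exact = TRUE)
  if (!is.finite(kappa) || kappa > conditionMax)
    stop(sprintf(paste0(
      "Omega condition number %.3g exceeds %.3g; prune correlated SNPs ",
      "or set a small ridge"), kappa, conditionMax))
  oi <- solve(omega)
  bx <- h@betaX; by <- h@betaY
  denom <- drop(crossprod(bx, oi %*% bx))
  theta <- drop(crossprod(bx, oi %*% by)) / denom
  seFE <- 1 / sqrt(denom)
  J <- length(bx)
  res <- by - theta * bx
  Q <- drop(crossprod(res, oi %*% res))
  scaleUp <- if (randomEffects == "multiplicative" && J > 1)
    max(1, sqrt(Q / (J - 1))) else 1
  mrEstimate("ivw_correlated", theta, seFE * scaleUp, J,
             scale = h@outcomeScale, Q = Q, Qdf = max(J - 1, 0))
}

.weightedMedian <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  # mid-cumulative positions; linear interpolation at probability one half
  pos <- cumsum(w) - w / 2
  stats::approx(pos, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Orders the per-SNP Wald ratios and takes the weighted 50th percentile
#' (weights (betaX / seY)^2, normalized; linear interpolation between the
#' mid-cumulative weight positions of adjacent ratios). Consistent when more
#' than half of the weight comes from valid instruments. The SE comes from a
#' seeded parametric bootstrap resampling betaX and betaY from their normal
#' sampling distributions. Refuses correlated instruments: with LD attached
#' the estimator's validity share is not interpretable.
#'
#' @param h a [HarmonizedSet-class] without LD, J >= 3.
#' @param nBoot bootstrap draws (default 10000).
#' @param seed integer seed for the bootstrap (required: reproducibility).
#' @return an [MREstimate-class] with method `"weighted_median"`.
#' @export
mrWeightedMedian <- function(h, nBoot = 10000, seed) {
  stopifnot(is(h, "HarmonizedSet"))
  if (!is.null(h@ld))
    stop("policy error: weighted median is not reported for correlated SNPs")
  J <- length(h@snps)
  if (J < 3) stop("weighted median needs at least 3 SNPs; got ", J)
  if (missing(seed)) stop("a bootstrap seed is required")
  w <- (h@betaX / h@seY)^2
  beta <- .weightedMedian(h@betaY / h@betaX, w)
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  draws <- vapply(seq_len(nBoot), function(i) {
    bx <- stats::rnorm(J, h@betaX, h@seX)
    by <- stats::rnorm(J, h@betaY, h@seY)
    .weightedMedian(by / bx, (bx / h@seY)^2)
  }, numeric(1))
  .restore_seed(old)
  se <- stats::sd(draws)
  mrEstimate("weighted_median", beta, se, J, scale = h@outcomeScale)
}

# preserve the caller's RNG state around internally seeded draws
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.wlsFit <- function(X, y, w, scaleDfAdjust) {
  # weighted least squares via normal equations; multiplicative SE scaling
  XtW <- t(X * w)
  XtWXinv <- solve(XtW %*% X)
  coef <- drop(XtWXinv %*% (XtW %*% y))
  res <- y - drop(X %*% coef)
  Q <- sum(w * res^2)
  df <- nrow(X) - ncol(X)
  scaleUp <- if (df > 0) max(1, sqrt(Q / df)) else 1
  se <- sqrt(diag(XtWXinv)) * scaleUp
  list(coef = coef, se = se, Q = Q, df = df, cov = XtWXinv * scaleUp^2)
}

#' MR-Egger regression
#'
#' Orients every SNP so its exposure association is non-negative (negating
#' both betas where needed — estimates are invariant to the original allele
#' labelling), then fits the weighted regression betaY = b0 + theta * betaX
#' with weights 1 / seY^2. The slope is the causal estimate; the intercept
#' estimates average directional pleiotropy, with its SE and p reported.
#' Standard errors carry the multiplicative scaling max(1, sqrt(Q/(J - 2))).
#' Refuses correlated instruments (same policy as [mrWeightedMedian()]).
#'
#' @param h a [HarmonizedSet-class] without LD, J >= 3.
#' @param refDist `"normal"` (default) or `"t"` reference distribution for
#'   slope and intercept p-values (t uses J - 2 df).
#' @return an [MREstimate-class] with method `"egger"` and the intercept in
#'   its dedicated slots.
#' @export
mrEgger <- function(h, refDist = c("normal", "t")) {
  stopifnot(is(h, "HarmonizedSet"))
  refDist <- match.arg(refDist)
  if (!is.null(h@ld))
    stop("policy error: MR-Egger is not reported for correlated SNPs")
  J <- length(h@snps)
  if (J < 3) stop("MR-Egger needs at least 3 SNPs; got ", J)
  s <- ifelse(h@betaX < 0, -1, 1)
  x <- s * h@betaX
  y <- s * h@betaY
  fit <- .wlsFit(cbind(1, x), y, 1 / h@seY^2, TRUE)
  pfun <- if (refDist == "normal")
    function(z) 2 * stats::pnorm(-abs(z))
  else
    function(z) 2 * stats::pt(-abs(z), df = J - 2)
  co <- unname(fit$coef); ses <- unname(fit$se)
  mrEstimate("egger", co[2L], ses[2L], J, scale = h@outcomeScale,
             Q = fit$Q, Qdf = J - 2,
             eggerIntercept = co[1L], eggerInterceptSE = ses[1L],
             eggerInterceptP = pfun(co[1L] / ses[1L]),
             p = pfun(co[2L] / ses[2L]))
}

#' Steiger filtering: directionality between exposure and outcome
#'
#' Per SNP, the variance explained in a trait is approximated from the
#' association z-statistic as r2 = t^2 / (t^2 + n - 2) with t = beta / se.
#' For a log-odds outcome the same transform is applied to the logistic
#' z-statistic (an observed-scale approximation, recorded in the result's
#' note). The declared direction is exposure-to-outcome when the summed
#' exposure r2 exceeds the summed outcome r2, with per-SNP flags marking
#' variants whose individual ordering disagrees.
#'
#' @param h a [HarmonizedSet-class].
#' @param nExposure,nOutcome GWAS sample sizes behind the exposure and
#'   outcome associations.
#' @param caseFraction case fraction of a binary outcome (metadata only).
#' @param tol relative tolerance under which the comparison is declared
#'   inconclusive.
#' @return a [SteigerResult-class] object.
#' @export
steigerFilter <- function(h, nExposure, nOutcome, caseFraction = NA_real_,
                          tol = 1e-6) {
  stopifnot(is(h, "HarmonizedSet"))
  if (missing(nExposure) || missing(nOutcome) ||
      is.na(nExposure) || is.na(nOutcome) ||
      nExposure <= 0 || nOutcome <= 0)
    stop("positive exposure and outcome sample sizes are required")
  r2of <- function(beta, se, n) {
    t2 <- (beta / se)^2
    t2 / (t2 + n - 2)
  }
  r2x <- r2of(h@betaX, h@seX, nExposure)
  r2y <- r2of(h@betaY, h@seY, nOutcome)
  sx <- sum(r2x); sy <- sum(r2y)
  direction <- if (abs(sx - sy) <= tol * max(sx, sy, .Machine$double.eps))
    "inconclusive"
  else if (sx > sy) "exposure_to_outcome" else "outcome_to_exposure"
  flags <- if (direction == "exposure_to_outcome") r2y > r2x
           else if (direction == "outcome_to_exposure") r2x > r2y
           else rep(FALSE, length(r2x))
  note <- if (h@outcomeScale == "logodds")
    sprintf(paste0("outcome r2 uses the observed-scale approximation ",
                   "t^2/(t^2+n-2) on the logistic z-statistic%s"),
            if (!is.na(caseFraction))
              sprintf(" (case fraction %.3g)", caseFraction) else "")
  else NA_character_
  new("SteigerResult", r2Exposure = r2x, r2Outcome = r2y,
      direction = direction, snpFlags = flags, note = note)
}
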