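.mvmrDesign <- function(h) {
  if (!length(h@betaX2))
    stop("multivariable MR needs a second exposure (harmonize with exposure2)")
  X <- cbind(h@betaX, h@betaX2)
  colnames(X) <- c(
    if (is.na(h@exposureName)) "exposure1" else h@exposureName,
    if (is.na(h@exposure2Name)) "exposure2" else h@exposure2Name)
  X
}

.glsFit <- function(X, y, Oi, floorScale = TRUE) {
  XtO <- crossprod(X, Oi)
  XtOXinv <- solve(XtO %*% X)
  coef <- drop(XtOXinv %*% (XtO %*% y))
  res <- y - drop(X %*% coef)
  Q <- drop(crossprod(res, Oi %*% res))
  df <- nrow(X) - ncol(X)
  scaleUp <- if (df > 0 && floorScale) max(1, sqrt(Q / df)) else 1
  list(coef = coef, se = sqrt(diag(XtOXinv)) * scaleUp, Q = Q, df = df)
}

.mvmrFit <- function(h, intercept, randomEffects) {
  X <- .mvmrDesign(h)
  y <- h@betaY
  expoNames <- colnames(X)
  # drop exposures with no instrument signal at all (exact reduction to the
  # univariable model); their coefficients are reported as NA
  active <- colSums(X != 0) > 0
  if (!any(active)) stop("both exposure association vectors are zero")
  Xa <- X[, active, drop = FALSE]
  if (intercept) Xa <- cbind(`(intercept)` = 1, Xa)
  w <- 1 / h@seY^2
  cond <- kappa(sqrt(w) * Xa, exact = TRUE)
  if (cond > 1e10)
    stop(sprintf(
      "collinear exposure vectors (condition number %.3g); the direct effects are not separable", cond))
  if (is.null(h@ld)) {
    fit <- .wlsFit(Xa, y, w, TRUE)
  } else {
    omega <- h@ld@rho * tcrossprod(h@seY)
    fit <- .glsFit(Xa, y, solve(omega))
  }
  if (randomEffects == "fixed") {
    # undo the multiplicative scaling
    df <- fit$df
    sc <- if (df > 0) max(1, sqrt(fit$Q / df)) else 1
    fit$se <- fit$se / sc
  }
  k <- as.integer(intercept)
  coef <- se <- rep(NA_real_, length(expoNames))
  coef[active] <- fit$coef[(k + 1):length(fit$coef)]
  se[active] <- fit$se[(k + 1):length(fit$se)]
  list(expoNames = expoNames, coef = unname(coef), se = unname(se),
       active = active,
       intercept = if (intercept) unname(fit$coef[1L]) else NA_real_,
       interceptSE = if (intercept) unname(fit$se[1L]) else NA_real_,
       Qres = fit$Q, dfres = fit$df)
}

.mvmrResult <- function(h, fit, method, crit = 1.96) {
  est <- data.frame(exposure = fit$expoNames, beta = fit$coef, se = fit$se,
                    stringsAsFactors = FALSE)
  est$ciLow <- est$beta - crit * est$se
  est$ciHigh <- est$beta + crit * est$se
  est$p <- 2 * stats::pnorm(-abs(est$beta / est$se))
  theta <- ifelse(is.na(fit$coef), 0, fit$coef)
  qv <- mvmrQ(h, theta)
  cf <- tryCatch(conditionalF(h), error = function(e)
    stats::setNames(rep(NA_real_, length(fit$expoNames)), fit$expoNames))
  ip <- if (is.na(fit$intercept)) NA_real_ else
    2 * stats::pnorm(-abs(fit$intercept / fit$interceptSE))
  new("MVMRResult", estimates = est, method = method,
      eggerIntercept = fit$intercept, eggerInterceptSE = fit$interceptSE,
      eggerInterceptP = unname(ip), Q = qv[["Q"]], Qdf = qv[["df"]],
      Qp = qv[["p"]],
      conditionalF = cf, J = length(h@snps), L = 2L,
      scale = h@outcomeScale)
}

#' Multivariable IVW: direct effects of two exposures
#'
#' Weighted zero-intercept multiple regression of the SNP-outcome
#' associations on the SNP associations with both exposures, weights
#' 1 / seY^2 (generalized least squares with
#' Omega = diag(seY) rho diag(seY) when an LD matrix is attached). Each
#' coefficient is the direct effect of its exposure conditional on the
#' other. Standard errors carry the multiplicative scaling
#' max(1, sqrt(Q_residual / (J - L))). If one exposure's association vector
#' is identically zero it is dropped from the design (its coefficient is
#' reported NA) and the fit reduces exactly to the univariable model.
#'
#' @param h a [HarmonizedSet-class] with a second exposure
#'   (`harmonize(..., exposure2 = )`) and, optionally, aligned LD.
#' @param randomEffects `"multiplicative"` (default) or `"fixed"`.
#' @return an [MVMRResult-class] including the instrument-validity Q
#'   ([mvmrQ()]) and the per-exposure conditional F ([conditionalF()]).
#' @export
mvmrIVW <- function(h, randomEffects = c("multiplicative", "fixed")) {
  stopifnot(is(h, "HarmonizedSet"))
  randomEffects <- match.arg(randomEffects)
  J <- length(h@snps)
  if (J <= 2) stop("multivariable IVW needs J > L = 2 SNPs; got ", J)
  fit <- .mvmrFit(h, intercept = FALSE, randomEffects = randomEffects)
  .mvmrResult(h, fit, "mvmr_ivw")
}

#' Multivariable MR-Egger
#'
#' As [mvmrIVW()] but with a free intercept estimating average directional
#' pleiotropy. SNPs are first oriented so the chosen exposure's associations
#' are non-negative (both exposures and the outcome are negated together, so
#' estimates are invariant to the original allele labelling). Used as the
#' primary model when the instrument-validity Q and the intercept are both
#' significant.
#'
#' @param h a [HarmonizedSet-class] with a second exposure.
#' @param orientTo which exposure (1 or 2) defines the orientation
#'   (default 1, the drug-mimicking exposure by pipeline convention).
#' @param randomEffects `"multiplicative"` (default) or `"fixed"`.
#' @return an [MVMRResult-class] with the intercept test filled in.
#' @export
mvmrEgger <- function(h, orientTo = 1L,
                      randomEffects = c("multiplicative", "fixed")) {
  stopifnot(is(h, "HarmonizedSet"))
  randomEffects <- match.arg(randomEffects)
  J <- length(h@snps)
  if (J <= 3) stop("multivariable MR-Egger needs J > L + 1 = 3 SNPs; got ", J)
  ref <- if (orientTo == 1L) h@betaX else h@betaX2
  s <- ifelse(ref < 0, -1, 1)
  h2 <- h
  h2@betaX <- s * h@betaX
  h2@betaX2 <- s * h@betaX2
  h2@betaY <- s * h@betaY
  if (!is.null(h@ld))
    h2@ld <- LDMatrix(h@snps, h@ld@rho * tcrossprod(s))
  fit <- .mvmrFit(h2, intercept = TRUE, randomEffects = randomEffects)
  .mvmrResult(h2, fit, "mvmr_egger")
}

#' Instrument-validity Q statistic for multivariable MR
#'
#' Q_a = sum_j (betaY_j - theta1 betaX1_j - theta2 betaX2_j)^2 /
#' (seY_j^2 + theta1^2 seX1_j^2 + theta2^2 seX2_j^2), on J - L degrees of
#' freedom, compared against the chi-squared distribution. Large values
#' signal horizontal pleiotropy not captured by the fitted exposures.
#'
#' @param h a [HarmonizedSet-class] with a second exposure.
#' @param theta length-2 fitted effect pair (from [mvmrIVW()]).
#' @param accountExposureSE include the theta^2 * seX^2 terms in the
#'   denominator (default TRUE); FALSE gives the plain weighted residual Q.
#' @return named numeric `c(Q, df, p)`.
#' @export
mvmrQ <- function(h, theta, accountExposureSE = TRUE) {
  stopifnot(is(h, "HarmonizedSet"), length(theta) == 2L)
  if (!length(h@betaX2)) stop("mvmrQ needs a second exposure")
  theta <- ifelse(is.na(theta), 0, theta)
  res <- h@betaY - theta[1L] * h@betaX - theta[2L] * h@betaX2
  denom <- h@seY^2
  if (accountExposureSE)
    denom <- denom + theta[1L]^2 * h@seX^2 + theta[2L]^2 * h@seX2^2
  Q <- sum(res^2 / denom)
  df <- length(h@snps) - 2L
  c(Q = Q, df = df,
    p = stats::pchisq(Q, df = max(df, 1L), lower.tail = FALSE))
}

.conditionalQdelta <- function(a, sa, b, sb) {
  # nuisance regression of exposure k's SNP associations (a) on the other
  # exposure's (b), with weights updated from the current slope:
  #   delta solves  sum w(delta) b (a - delta b) = 0,
  #   w(delta) = 1 / (sa^2 + delta^2 sb^2),
  # iterated to its fixed point. The conditional Q is Q(delta-hat) =
  # sum w (a - delta b)^2. Note the regression direction matters: this is
  # what makes the per-exposure statistics asymmetric (fully minimizing Q
  # over delta instead would give both exposures the same value, since
  # delta -> 1/delta exchanges the roles).
  Qfun <- function(d) sum((a - d * b)^2 / (sa^2 + d^2 * sb^2))
  if (all(b == 0))
    return(list(delta = 0, Q = sum((a / sa)^2)))
  d <- sum(b * a / sa^2) / sum(b^2 / sa^2)
  for (i in 1:200) {
    w <- 1 / (sa^2 + d^2 * sb^2)
    dNew <- sum(w * b * a) / sum(w * b^2)
    if (abs(dNew - d) < 1e-13 * (abs(d) + 1)) { d <- dNew; break }
    d <- dNew
  }
  list(delta = d, Q = Qfun(d))
}

#' @describeIn conditionalF Sanderson-Windmeijer conditional F-statistics
#'
#' Instrument strength for each exposure conditional on the other: the
#' heterogeneity Q_k of the iteratively reweighted regression of exposure
#' k's SNP associations on the other exposure's, with weights
#' 1 / (seXk^2 + delta^2 seXl^2), divided by J - 1 (the published
#' two-exposure convention; `denominator = "J-L"` switches to J - 2). When
#' the other exposure's associations are identically zero the statistic
#' reduces to the mean univariable chi-squared, sum((betaXk/seXk)^2)/(J-1).
#'
#' @param x a [HarmonizedSet-class] with a second exposure.
#' @param denominator `"J-1"` (default) or `"J-L"`.
#' @param ... unused.
#' @return named numeric, one conditional F per exposure.
#' @export
setMethod("conditionalF", "HarmonizedSet",
  function(x, denominator = c("J-1", "J-L"), ...) {
    denominator <- match.arg(denominator)
    if (!length(x@betaX2))
      stop("conditional F needs a second exposure")
    if (any(x@seX <= 0) || any(x@seX2 <= 0))
      stop("degenerate exposure standard errors")
    J <- length(x@snps)
    if (J <= 2) stop("conditional F needs J > L = 2 SNPs")
    df <- if (denominator == "J-1") J - 1 else J - 2
    f1 <- .conditionalQdelta(x@betaX, x@seX, x@betaX2, x@seX2)$Q / df
    f2 <- .conditionalQdelta(x@betaX2, x@seX2, x@betaX, x@seX)$Q / df
    nm <- c(if (is.na(x@exposureName)) "exposure1" else x@exposureName,
            if (is.na(x@exposure2Name)) "exposure2" else x@exposure2Name)
    stats::setNames(c(f1, f2), nm)
  })
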