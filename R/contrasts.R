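#' Convert an odds ratio with 95 percent CI to log-odds beta and SE
#'
#' beta = log(OR); se = (log(ciHigh) - log(ciLow)) / (2 * 1.96). The inverse
#' of the OR view printed in the field's tables; needed to pool or contrast
#' published estimates. A degenerate CI (both bounds equal to the OR) yields
#' se = 0 with a warning.
#'
#' @param or odds ratio(s), positive.
#' @param ciLow,ciHigh 95 percent bounds with `ciLow <= or <= ciHigh`.
#' @param crit critical value the CI was built with (default 1.96).
#' @return data.frame with columns `beta` and `se`.
#' @export
#' @examples
#' orCiToBetaSe(0.55, 0.38, 0.79)   # men's one-SNP drug-mimic disease row
orCiToBetaSe <- function(or, ciLow, ciHigh, crit = 1.96) {
  if (any(ciLow <= 0))
    stop("bound violation: ciLow must be positive")
  if (any(!(ciLow <= or & or <= ciHigh)))
    stop("bound violation: need 0 < ciLow <= or <= ciHigh")
  se <- (log(ciHigh) - log(ciLow)) / (2 * crit)
  if (any(se == 0))
    warning("degenerate CI: se = 0")
  data.frame(beta = log(or), se = se)
}

#' @rdname orCiToBetaSe
#' @param beta,se log-odds estimate and SE.
#' @return `betaSeToOrCi()`: data.frame with `or`, `ciLow`, `ciHigh`.
#' @export
betaSeToOrCi <- function(beta, se, crit = 1.96) {
  data.frame(or = exp(beta), ciLow = exp(beta - crit * se),
             ciHigh = exp(beta + crit * se))
}

#' Fixed-effect inverse-variance meta-analysis of MR estimates
#'
#' Pools estimates on a common scale with weights 1 / se^2:
#' pooled beta = sum(w * beta) / sum(w), se = sum(w)^(-1/2). Fixed effect is
#' the appropriate model for pooling the two sex strata of one study.
#'
#' @param estimates list of [MREstimate-class] objects (>= 2) sharing a scale.
#' @return a pooled [MREstimate-class] with method `"meta_fixed"`.
#' @export
#' @examples
#' men <- with(orCiToBetaSe(0.73, 0.48, 1.11),
#'   mrEstimate("mvmr_egger", beta, se, 1L, scale = "logodds"))
#' women <- with(orCiToBetaSe(0.72, 0.55, 0.94),
#'   mrEstimate("mvmr_egger", beta, se, 254L, scale = "logodds"))
#' oddsRatio(fixedEffectMeta(list(men, women)))  # pooled OR 0.72
fixedEffectMeta <- function(estimates) {
  stopifnot(is.list(estimates), length(estimates) >= 2L)
  ok <- vapply(estimates, is, logical(1), "MREstimate")
  if (!all(ok)) stop("all inputs must be MREstimate objects")
  scales <- vapply(estimates, function(e) e@scale, character(1))
  if (length(unique(scales)) != 1L)
    stop("mixed scales: refusing to pool linear with log-odds estimates")
  b <- vapply(estimates, function(e) e@beta, numeric(1))
  s <- vapply(estimates, function(e) e@se, numeric(1))
  if (any(s <= 0)) stop("all estimates need positive SEs to be pooled")
  w <- 1 / s^2
  mrEstimate("meta_fixed", sum(w * b) / sum(w), 1 / sqrt(sum(w)),
             sum(vapply(estimates, function(e) e@nSnps, integer(1))),
             scale = scales[1L])
}

#' Sex-difference z-test between two estimates
#'
#' z = (beta_m - beta_w) / sqrt(se_m^2 + se_w^2), with the two-sided normal
#' p-value.
#'
#' @param estM,estW [MREstimate-class] objects on a common scale
#'   (conventionally men and women).
#' @return named numeric `c(z, p)`.
#' @export
sexDifferenceZ <- function(estM, estW) {
  stopifnot(is(estM, "MREstimate"), is(estW, "MREstimate"))
  if (estM@scale != estW@scale)
    stop("estimates must share a scale")
  z <- (estM@beta - estW@beta) / sqrt(estM@se^2 + estW@se^2)
  c(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Mediation by attenuation
#'
#' Compares the univariable (total) and multivariable (direct) estimates for
#' the same exposure and outcome: proportion attenuated =
#' 1 - multi_beta / uni_beta on the beta (log-odds for disease outcomes)
#' scale. Caveat flags are raised when the two estimates disagree in sign
#' (attenuation above 100 percent is not a proportion mediated) and when the
#' univariable estimate is weak (|beta| < 2 se), where the ratio is
#' unstable.
#'
#' @param uni,multi [MREstimate-class] objects for the same exposure-outcome
#'   pair on the same scale.
#' @param label free-text description.
#' @return a [Contrast-class] with the `attenuation` slot filled.
#' @export
mediationAttenuation <- function(uni, multi, label = "attenuation") {
  stopifnot(is(uni, "MREstimate"), is(multi, "MREstimate"))
  if (uni@scale != multi@scale)
    stop("estimates must share a scale")
  caveat <- character(0)
  if (uni@beta == 0) {
    prop <- NA_real_
    caveat <- c(caveat, "univariable beta is zero: attenuation undefined")
  } else {
    prop <- 1 - multi@beta / uni@beta
    if (sign(multi@beta) != sign(uni@beta) && multi@beta != 0)
      caveat <- c(caveat,
                  "sign reversal: attenuation exceeds 100%, not a proportion mediated")
    if (abs(uni@beta) < 2 * uni@se)
      caveat <- c(caveat, "weak univariable estimate (|beta| < 2 se)")
  }
  new("Contrast", label = label, inputs = list(uni = uni, multi = multi),
      pooled = NULL, z = NA_real_, p = NA_real_,
      attenuation = c(uni_beta = uni@beta, multi_beta = multi@beta,
                      proportion_attenuated = prop),
      caveat = caveat)
}
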