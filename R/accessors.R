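#' Variant identifiers and LD access
#'
#' `snpIds()` returns the rsIDs carried by an object; `ldRho()` the signed
#' correlation matrix of an [LDMatrix].
#'
#' @param x a package object holding variants.
#' @return `snpIds()`: character vector; `ldRho()`: numeric matrix with
#'   rsID dimnames.
#' @name snpIds
#' @aliases ldRho
#' @examples
#' ld <- LDMatrix(c("rs1", "rs2"), matrix(c(1, .3, .3, 1), 2))
#' snpIds(ld)
NULL

#' @rdname snpIds
setMethod("snpIds", "SummaryStats", function(x) x@records$snp)
#' @rdname snpIds
setMethod("snpIds", "LDMatrix", function(x) x@snps)
#' @rdname snpIds
setMethod("snpIds", "HarmonizedSet", function(x) x@snps)
#' @rdname snpIds
setMethod("snpIds", "InstrumentSet", function(x) x@snps)
#' @rdname snpIds
setMethod("snpIds", "Cohort", function(x) colnames(x@genotypes))

#' @rdname snpIds
setMethod("ldRho", "LDMatrix", function(x) {
  r <- x@rho
  dimnames(r) <- list(x@snps, x@snps)
  r
})

#' Estimate accessors
#'
#' Point estimate, standard error, p-value, number of variants, confidence
#' interval and heterogeneity Q of an [MREstimate]; the same accessors return
#' per-exposure vectors for an [MVMRResult].
#'
#' @param x an [MREstimate] or [MVMRResult].
#' @return numeric scalar/vector; `confInt()` returns a two-column matrix.
#' @name estimate
#' @aliases stdError pValue nSnps confInt heterogeneityQ
#' @examples
#' est <- fixedEffectMeta(list(
#'   mrEstimate("wald", beta = 0.1, se = 0.05, nSnps = 1L),
#'   mrEstimate("wald", beta = 0.2, se = 0.05, nSnps = 1L)))
#' estimate(est); stdError(est); confInt(est)
NULL

#' @rdname estimate
setMethod("estimate", "MREstimate", function(x) x@beta)
#' @rdname estimate
setMethod("stdError", "MREstimate", function(x) x@se)
#' @rdname estimate
setMethod("pValue", "MREstimate", function(x) x@p)
#' @rdname estimate
setMethod("nSnps", "MREstimate", function(x) x@nSnps)
#' @rdname estimate
setMethod("confInt", "MREstimate", function(x)
  cbind(low = x@ciLow, high = x@ciHigh))
#' @rdname estimate
setMethod("heterogeneityQ", "MREstimate", function(x)
  c(Q = x@Q, df = x@Qdf))

#' @rdname estimate
setMethod("estimate", "MVMRResult", function(x)
  stats::setNames(x@estimates$beta, x@estimates$exposure))
#' @rdname estimate
setMethod("stdError", "MVMRResult", function(x)
  stats::setNames(x@estimates$se, x@estimates$exposure))
#' @rdname estimate
setMethod("pValue", "MVMRResult", function(x)
  stats::setNames(x@estimates$p, x@estimates$exposure))
#' @rdname estimate
setMethod("nSnps", "MVMRResult", function(x) x@J)
#' @rdname estimate
setMethod("confInt", "MVMRResult", function(x) {
  m <- cbind(low = x@estimates$ciLow, high = x@estimates$ciHigh)
  rownames(m) <- x@estimates$exposure
  m
})
#' @rdname estimate
setMethod("heterogeneityQ", "MVMRResult", function(x)
  c(Q = x@Q, df = x@Qdf, p = x@Qp))

#' Odds-ratio view of a log-odds estimate
#'
#' @param x an [MREstimate] or [MVMRResult] on the log-odds scale.
#' @return named numeric `c(or, ciLow, ciHigh)` (a matrix for MVMR).
#' @name oddsRatio
#' @examples
#' est <- mrEstimate("wald", beta = log(0.55), se = 0.18, nSnps = 1L,
#'                   scale = "logodds")
#' oddsRatio(est)
NULL

#' @rdname oddsRatio
setMethod("oddsRatio", "MREstimate", function(x) {
  if (x@scale != "logodds")
    stop("oddsRatio is only defined for estimates on the log-odds scale")
  c(or = exp(x@beta), ciLow = exp(x@ciLow), ciHigh = exp(x@ciHigh))
})
#' @rdname oddsRatio
setMethod("oddsRatio", "MVMRResult", function(x) {
  if (x@scale != "logodds")
    stop("oddsRatio is only defined for estimates on the log-odds scale")
  m <- exp(cbind(or = x@estimates$beta, ciLow = x@estimates$ciLow,
                 ciHigh = x@estimates$ciHigh))
  rownames(m) <- x@estimates$exposure
  m
})

#' Selection / harmonization audit logs
#'
#' @param x an [InstrumentSet], [HarmonizedSet] or [SummaryStats] carrying a
#'   log of row-level decisions.
#' @return data.frame with columns `snp`, `action`, `detail`.
#' @name selectionLog
NULL

#' @rdname selectionLog
setMethod("selectionLog", "InstrumentSet", function(x) x@log)
#' @rdname selectionLog
setMethod("selectionLog", "HarmonizedSet", function(x) x@log)

#' @describeIn snpIds coerce SummaryStats to its record data.frame
#' @param row.names,optional,... passed through (unused).
#' @export
as.data.frame.SummaryStats <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  x@records
}

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats: %d SNP(s), trait '%s' (%s, %s scale)\n",
              nrow(object@records), object@trait, object@sex, object@scale))
  print(utils::head(object@records, 5))
  if (nrow(object@records) > 5)
    cat(sprintf("... and %d more row(s)\n", nrow(object@records) - 5L))
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d SNP(s)\n", length(object@snps)))
  print(utils::head(ldRho(object), c(4, 4)))
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf(
    "HarmonizedSet: %d SNP(s), exposure '%s'%s -> outcome '%s' (%s)\n",
    length(object@snps), object@exposureName,
    if (length(object@betaX2)) sprintf(" + '%s'", object@exposure2Name) else "",
    object@outcomeName, object@outcomeScale))
  cat(sprintf("  %d outcome flip(s), %d SNP(s) dropped, LD %s\n",
              sum(object@flips),
              sum(object@log$action %in%
                    c("dropped_mismatch", "dropped_palindromic")),
              if (is.null(object@ld)) "absent" else "aligned"))
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s], %d SNP(s), %s scale\n",
              object@method, object@nSnps, object@scale))
  cat(sprintf("  beta %.4g (se %.4g), 95%% CI %.4g to %.4g, p %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh, object@p))
  if (object@scale == "logodds") {
    orv <- oddsRatio(object)
    cat(sprintf("  OR %.3f, 95%% CI %.3f to %.3f\n",
                orv["or"], orv["ciLow"], orv["ciHigh"]))
  }
  if (!is.na(object@Q))
    cat(sprintf("  Q %.3f on %g df\n", object@Q, object@Qdf))
  if (!is.na(object@eggerIntercept))
    cat(sprintf("  Egger intercept %.4g (se %.4g), p %.3g\n",
                object@eggerIntercept, object@eggerInterceptSE,
                object@eggerInterceptP))
})

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf(
    "SteigerResult: direction %s (sum r2 exposure %.4g vs outcome %.4g)\n",
    object@direction, sum(object@r2Exposure), sum(object@r2Outcome)))
  cat(sprintf("  %d of %d SNP(s) flagged against the declared direction\n",
              sum(object@snpFlags), length(object@snpFlags)))
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet for '%s': %d SNP(s) kept\n",
              object@trait, length(object@snps)))
  acts <- table(object@log$action)
  cat(sprintf("  log: %s\n",
              paste(sprintf("%s=%d", names(acts), acts), collapse = ", ")))
})

setMethod("show", "MVMRResult", function(object) {
  cat(sprintf("MVMRResult [%s]: %d SNP(s), %d exposure(s), %s scale\n",
              object@method, object@J, object@L, object@scale))
  print(object@estimates, digits = 4)
  if (!is.na(object@Q))
    cat(sprintf("  instrument-validity Q %.2f on %g df (p %.3g)\n",
                object@Q, object@Qdf, object@Qp))
  if (length(object@conditionalF))
    cat(sprintf("  conditional F: %s\n",
                paste(sprintf("%s=%.2f", names(object@conditionalF),
                              object@conditionalF), collapse = ", ")))
  if (!is.na(object@eggerIntercept))
    cat(sprintf("  Egger intercept %.4g (p %.3g)\n",
                object@eggerIntercept, object@eggerInterceptP))
})

setMethod("show", "Contrast", function(object) {
  cat(sprintf("Contrast: %s\n", object@label))
  if (!is.null(object@pooled)) {
    cat("  pooled: ")
    show(object@pooled)
  }
  if (!is.na(object@z))
    cat(sprintf("  z %.3f, p %.3g\n", object@z, object@p))
  if (length(object@attenuation))
    cat(sprintf("  attenuation: uni %.4g -> multi %.4g (%.1f%% attenuated)\n",
                object@attenuation["uni_beta"],
                object@attenuation["multi_beta"],
                100 * object@attenuation["proportion_attenuated"]))
  if (length(object@caveat))
    cat(sprintf("  caveat: %s\n", paste(object@caveat, collapse = "; ")))
})

setMethod("show", "SimScenario", function(object) {
  cat(sprintf(
    "SimScenario: %d men / %d women, %d SNP(s), seed %d\n",
    object@nMale, object@nFemale, nrow(object@snpSpec), object@seed))
  cat(sprintf("  roles: %s\n", paste(sprintf(
    "%s=%d", names(table(object@snpSpec$role)),
    table(object@snpSpec$role)), collapse = ", ")))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort (%s): %d individuals x %d SNP(s), %d case(s)\n",
              object@sex, nrow(object@genotypes), ncol(object@genotypes),
              sum(object@phenotypes$ihd)))
})
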