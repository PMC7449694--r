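#' @import methods
NULL

.SEX_LEVELS <- c("male", "female", "combined")
.SCALE_LEVELS <- c("linear", "logodds")

#' SummaryStats: per-SNP GWAS association records for one trait in one sex
#'
#' Container for the summary statistics Mendelian randomization consumes:
#' one row per variant with effect and other allele, effect-allele frequency,
#' association beta (trait units: effect sizes for continuous traits,
#' log-odds for binary disease outcomes), its standard error, p-value and
#' sample size. Construct with [SummaryStats()] or [readSumstats()].
#'
#' @slot records data.frame with columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#' @slot trait character, trait name (e.g. `"ldl"`, `"testosterone"`).
#' @slot sex one of `"male"`, `"female"`, `"combined"`.
#' @slot scale `"linear"` (continuous trait) or `"logodds"` (binary).
#' @aliases SummaryStats-class
#' @exportClass SummaryStats
setClass("SummaryStats",
  representation(records = "data.frame", trait = "character",
                 sex = "character", scale = "character"),
  prototype(records = data.frame(), trait = NA_character_,
            sex = "combined", scale = "linear"))

.validSummaryStats <- function(object) {
  msgs <- character()
  rec <- object@records
  req <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "p", "n")
  miss <- setdiff(req, names(rec))
  if (length(miss))
    return(sprintf("records is missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(rec$snp))
    msgs <- c(msgs, sprintf("duplicated snp id(s): %s",
      paste(unique(rec$snp[duplicated(rec$snp)]), collapse = ", ")))
  bad_se <- which(!is.na(rec$se) & rec$se <= 0)
  if (length(bad_se))
    msgs <- c(msgs, sprintf("non-positive se at row(s): %s",
                            paste(bad_se, collapse = ", ")))
  bad_eaf <- which(!is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1))
  if (length(bad_eaf))
    msgs <- c(msgs, sprintf("eaf outside [0,1] at row(s): %s",
                            paste(bad_eaf, collapse = ", ")))
  bad_p <- which(!is.na(rec$p) & (rec$p < 0 | rec$p > 1))
  if (length(bad_p))
    msgs <- c(msgs, sprintf("p outside [0,1] at row(s): %s",
                            paste(bad_p, collapse = ", ")))
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  bad_al <- which(!ok_allele(rec$effect_allele) | !ok_allele(rec$other_allele) |
                    rec$effect_allele == rec$other_allele)
  if (length(bad_al))
    msgs <- c(msgs, sprintf("invalid allele pair at row(s): %s",
                            paste(bad_al, collapse = ", ")))
  if (!object@sex %in% .SEX_LEVELS)
    msgs <- c(msgs, "sex must be one of male, female, combined")
  if (!object@scale %in% .SCALE_LEVELS)
    msgs <- c(msgs, "scale must be linear or logodds")
  if (length(msgs)) msgs else TRUE
}
setValidity("SummaryStats", .validSummaryStats)

#' LDMatrix: signed linkage-disequilibrium correlation matrix
#'
#' Square matrix of signed correlations (r, not r squared) between variants,
#' keyed by rsID. Signs refer to the effect alleles stated in the file the
#' matrix came from; [alignLD()] handles reorientation after harmonization.
#'
#' @slot snps character vector of rsIDs, in matrix order.
#' @slot rho numeric matrix of signed correlations, symmetric, unit diagonal,
#'   positive semi-definite within numerical tolerance.
#' @aliases LDMatrix-class
#' @exportClass LDMatrix
setClass("LDMatrix",
  representation(snps = "character", rho = "matrix"))

setValidity("LDMatrix", function(object) {
  msgs <- character()
  r <- object@rho
  J <- length(object@snps)
  if (!is.numeric(r) || nrow(r) != J || ncol(r) != J)
    return("rho must be a square numeric matrix matching snps")
  if (any(abs(r) > 1 + 1e-10))
    msgs <- c(msgs, "correlations must lie in [-1, 1]")
  if (max(abs(r - t(r))) > 1e-10)
    msgs <- c(msgs, "rho must be symmetric within 1e-10")
  if (any(diag(r) != 1))
    msgs <- c(msgs, "rho must have unit diagonal")
  if (J > 0) {
    ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      msgs <- c(msgs, sprintf(
        "rho is not positive semi-definite (min eigenvalue %.3g)", ev))
  }
  if (length(msgs)) msgs else TRUE
})

#' HarmonizedSet: exposure and outcome associations on a common effect allele
#'
#' Result of [harmonize()]: per-SNP exposure and outcome betas and SEs with
#' effect alleles aligned, an optional second exposure (for multivariable MR),
#' an optional aligned [LDMatrix], the per-SNP outcome flip flags, and the
#' harmonization log.
#'
#' @slot snps character rsIDs (length J).
#' @slot betaX,seX numeric, SNP-exposure association and SE.
#' @slot betaY,seY numeric, SNP-outcome association and SE.
#' @slot betaX2,seX2 numeric, optional second exposure (length 0 when absent).
#' @slot seX2n placeholder kept for forward compatibility.
#' @slot ld `LDMatrix` aligned to `snps`, or `NULL`.
#' @slot flips logical, TRUE where the outcome beta was negated.
#' @slot log data.frame of flips/drops (`snp`, `action`, `detail`).
#' @slot outcomeScale `"linear"` or `"logodds"`.
#' @slot exposureName,exposure2Name,outcomeName trait labels.
#' @aliases HarmonizedSet-class
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
  representation(snps = "character",
                 betaX = "numeric", seX = "numeric",
                 betaY = "numeric", seY = "numeric",
                 betaX2 = "numeric", seX2 = "numeric",
                 ld = "ANY", flips = "logical", log = "data.frame",
                 outcomeScale = "character",
                 exposureName = "character", exposure2Name = "character",
                 outcomeName = "character"),
  prototype(betaX2 = numeric(0), seX2 = numeric(0), ld = NULL,
            outcomeScale = "linear", exposureName = NA_character_,
            exposure2Name = NA_character_, outcomeName = NA_character_))

setValidity("HarmonizedSet", function(object) {
  msgs <- character()
  J <- length(object@snps)
  if (J < 1) msgs <- c(msgs, "at least one SNP required")
  lens <- c(length(object@betaX), length(object@seX),
            length(object@betaY), length(object@seY), length(object@flips))
  if (any(lens != J))
    msgs <- c(msgs, "betaX/seX/betaY/seY/flips must all have length J")
  if (length(object@betaX2) && length(object@betaX2) != J)
    msgs <- c(msgs, "betaX2/seX2 must have length J when present")
  if (length(object@betaX2) != length(object@seX2))
    msgs <- c(msgs, "betaX2 and seX2 must have equal length")
  if (any(object@seX <= 0) || any(object@seY <= 0))
    msgs <- c(msgs, "standard errors must be positive")
  if (!is.null(object@ld)) {
    if (!is(object@ld, "LDMatrix"))
      msgs <- c(msgs, "ld must be an LDMatrix or NULL")
    else if (!identical(object@ld@snps, object@snps))
      msgs <- c(msgs, "ld must be ordered identically to snps (use alignLD)")
  }
  if (!object@outcomeScale %in% .SCALE_LEVELS)
    msgs <- c(msgs, "outcomeScale must be linear or logodds")
  if (length(msgs)) msgs else TRUE
})

#' MREstimate: a causal effect estimate with its diagnostics
#'
#' @slot method estimator tag: one of `wald`, `ivw_mre`, `ivw_fe`,
#'   `ivw_correlated`, `weighted_median`, `egger`, `mvmr_ivw`, `mvmr_egger`,
#'   `meta_fixed`.
#' @slot beta,se point estimate (outcome units per exposure unit) and SE.
#' @slot ciLow,ciHigh 95 percent normal-approximation confidence bounds.
#' @slot p two-sided p-value.
#' @slot nSnps number of variants used.
#' @slot Q Cochran heterogeneity statistic (NA where undefined).
#' @slot Qdf degrees of freedom of Q.
#' @slot eggerIntercept,eggerInterceptSE,eggerInterceptP MR-Egger intercept
#'   estimate, SE and p (NA for other methods).
#' @slot scale `"linear"` or `"logodds"`; when log-odds, [oddsRatio()] gives
#'   the exponentiated view.
#' @aliases MREstimate-class
#' @exportClass MREstimate
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", p = "numeric",
                 nSnps = "integer", Q = "numeric", Qdf = "numeric",
                 eggerIntercept = "numeric", eggerInterceptSE = "numeric",
                 eggerInterceptP = "numeric", scale = "character"),
  prototype(Q = NA_real_, Qdf = NA_real_, eggerIntercept = NA_real_,
            eggerInterceptSE = NA_real_, eggerInterceptP = NA_real_,
            scale = "linear"))

setValidity("MREstimate", function(object) {
  msgs <- character()
  if (object@se < 0) msgs <- c(msgs, "se must be non-negative")
  if (!(object@ciLow <= object@beta && object@beta <= object@ciHigh))
    msgs <- c(msgs, "ci must bracket beta")
  if (abs(object@ciLow - (object@beta - 1.96 * object@se)) > 1e-9 ||
      abs(object@ciHigh - (object@beta + 1.96 * object@se)) > 1e-9)
    msgs <- c(msgs, "ci bounds must equal beta +/- 1.96*se within 1e-9")
  if (!object@scale %in% .SCALE_LEVELS)
    msgs <- c(msgs, "scale must be linear or logodds")
  if (length(msgs)) msgs else TRUE
})

#' SteigerResult: per-SNP directionality diagnostics
#'
#' @slot r2Exposure,r2Outcome per-SNP variance explained in exposure/outcome.
#' @slot direction `"exposure_to_outcome"`, `"outcome_to_exposure"` or
#'   `"inconclusive"`.
#' @slot snpFlags logical; TRUE for SNPs whose individual r2 ordering runs
#'   against the declared direction.
#' @slot note provenance of the binary-outcome r2 approximation, if used.
#' @aliases SteigerResult-class
#' @exportClass SteigerResult
setClass("SteigerResult",
  representation(r2Exposure = "numeric", r2Outcome = "numeric",
                 direction = "character", snpFlags = "logical",
                 note = "character"),
  prototype(note = NA_character_))

setValidity("SteigerResult", function(object) {
  if (any(object@r2Exposure < 0 | object@r2Exposure > 1, na.rm = TRUE) ||
      any(object@r2Outcome < 0 | object@r2Outcome > 1, na.rm = TRUE))
    return("r2 values must lie in [0,1]")
  TRUE
})

#' InstrumentSet: the outcome of instrument selection, with its audit trail
#'
#' @slot snps rsIDs retained as instruments.
#' @slot trait source trait the instruments predict.
#' @slot log data.frame (`snp`, `action`, `detail`); `action` is one of
#'   `kept`, `pruned_ld`, `dropped_weak_F`, `proxied`, `lead_selected`.
#' @aliases InstrumentSet-class
#' @exportClass InstrumentSet
setClass("InstrumentSet",
  representation(snps = "character", trait = "character", log = "data.frame"))

#' MVMRResult: multivariable MR estimates and instrument diagnostics
#'
#' @slot estimates data.frame, one row per exposure: `exposure`, `beta`,
#'   `se`, `ciLow`, `ciHigh`, `p`.
#' @slot method `"mvmr_ivw"` or `"mvmr_egger"`.
#' @slot eggerIntercept,eggerInterceptSE,eggerInterceptP intercept test
#'   (mvmr_egger only).
#' @slot Q,Qdf,Qp instrument-validity heterogeneity statistic.
#' @slot conditionalF named per-exposure Sanderson-Windmeijer conditional F.
#' @slot J,L number of variants and exposures.
#' @slot scale outcome scale.
#' @aliases MVMRResult-class
#' @exportClass MVMRResult
setClass("MVMRResult",
  representation(estimates = "data.frame", method = "character",
                 eggerIntercept = "numeric", eggerInterceptSE = "numeric",
                 eggerInterceptP = "numeric", Q = "numeric", Qdf = "numeric",
                 Qp = "numeric", conditionalF = "numeric", J = "integer",
                 L = "integer", scale = "character"),
  prototype(eggerIntercept = NA_real_, eggerInterceptSE = NA_real_,
            eggerInterceptP = NA_real_, Q = NA_real_, Qdf = NA_real_,
            Qp = NA_real_, conditionalF = numeric(0), scale = "linear"))

setValidity("MVMRResult", function(object) {
  msgs <- character()
  if (length(object@conditionalF) &&
      any(object@conditionalF < 0, na.rm = TRUE))
    msgs <- c(msgs, "conditional F must be non-negative")
  if (!is.na(object@Q) && object@Q < 0)
    msgs <- c(msgs, "Q must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Contrast: a cross-estimate comparison
#'
#' Holds either a fixed-effect pooled estimate, a difference z-test, or a
#' mediation-by-attenuation summary for a pair of [MREstimate] objects.
#'
#' @slot label free-text description.
#' @slot inputs list of the MREstimate inputs.
#' @slot pooled pooled [MREstimate] (meta-analysis contrasts) or NULL.
#' @slot z,p difference z statistic and two-sided p (NA where not applicable).
#' @slot attenuation named numeric: `uni_beta`, `multi_beta`,
#'   `proportion_attenuated` (mediation contrasts).
#' @slot caveat character flags (e.g. sign reversal, weak univariable signal).
#' @aliases Contrast-class
#' @exportClass Contrast
setClass("Contrast",
  representation(label = "character", inputs = "list", pooled = "ANY",
                 z = "numeric", p = "numeric", attenuation = "numeric",
                 caveat = "character"),
  prototype(pooled = NULL, z = NA_real_, p = NA_real_,
            attenuation = numeric(0), caveat = character(0)))

#' SimScenario: generative parameters of a synthetic sex-stratified cohort
#'
#' Defines the causal structure the generator emulates: a drug-target locus
#' whose variants shift a biomarker (labelled `ldl`), variants for
#' testosterone, optional direct-to-disease (pleiotropic) effects, and
#' sex-specific mediation drug locus -> testosterone -> disease.
#'
#' @slot nMale,nFemale cohort sizes.
#' @slot snpSpec data.frame: `snp`, `maf` in (0, 0.5], `block` (0 =
#'   unlinked), `role` in drug_locus/testosterone_locus/null/pleiotropic,
#'   `effectScale` per-SNP multiplier of the role effect.
#' @slot ldWithinBlock target within-block genotype correlation r.
#' @slot effects named list: `gammaLdl` (drug locus -> biomarker per allele),
#'   `alphaTMale`, `alphaTFemale` (drug locus -> testosterone per allele),
#'   `tau` (testosterone locus -> testosterone per allele), `thetaL`
#'   (biomarker -> disease log-odds per effect size), `thetaTMale`,
#'   `thetaTFemale` (testosterone -> disease log-odds).
#' @slot pleiotropyMean,pleiotropySd direct SNP -> disease log-odds effects
#'   for pleiotropic-role SNPs, drawn once per run.
#' @slot prevalenceMale,prevalenceFemale target disease prevalences.
#' @slot seed integer seed; the whole run is deterministic given it.
#' @aliases SimScenario-class
#' @exportClass SimScenario
setClass("SimScenario",
  representation(nMale = "integer", nFemale = "integer",
                 snpSpec = "data.frame", ldWithinBlock = "numeric",
                 effects = "list", pleiotropyMean = "numeric",
                 pleiotropySd = "numeric", prevalenceMale = "numeric",
                 prevalenceFemale = "numeric", seed = "integer"),
  prototype(pleiotropyMean = 0, pleiotropySd = 0))

.SNP_ROLES <- c("drug_locus", "testosterone_locus", "null", "pleiotropic")

setValidity("SimScenario", function(object) {
  msgs <- character()
  sp <- object@snpSpec
  req <- c("snp", "maf", "block", "role", "effectScale")
  if (!all(req %in% names(sp)))
    return(sprintf("snpSpec needs columns: %s", paste(req, collapse = ", ")))
  if (any(sp$maf <= 0 | sp$maf > 0.5))
    msgs <- c(msgs, "maf must lie in (0, 0.5]")
  if (!all(sp$role %in% .SNP_ROLES))
    msgs <- c(msgs, sprintf("role must be one of: %s",
                            paste(.SNP_ROLES, collapse = ", ")))
  if (object@prevalenceMale <= 0 || object@prevalenceMale >= 1 ||
      object@prevalenceFemale <= 0 || object@prevalenceFemale >= 1)
    msgs <- c(msgs, "prevalences must lie in (0,1)")
  if (abs(object@ldWithinBlock) >= 1)
    msgs <- c(msgs, "ldWithinBlock must lie in (-1, 1)")
  eff <- object@effects
  reqE <- c("gammaLdl", "alphaTMale", "alphaTFemale", "tau", "thetaL",
            "thetaTMale", "thetaTFemale")
  if (!all(reqE %in% names(eff)))
    msgs <- c(msgs, sprintf("effects needs entries: %s",
                            paste(reqE, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Cohort: simulated individual-level data for one sex
#'
#' @slot genotypes integer dosage matrix (individuals x SNPs, 0/1/2).
#' @slot phenotypes data.frame with `ldl`, `testosterone` (continuous,
#'   effect-size standardized) and `ihd` (0/1).
#' @slot sex `"male"` or `"female"`.
#' @slot maf effect-allele population frequencies used.
#' @slot realizedLD realized genotype correlation matrix.
#' @aliases Cohort-class
#' @exportClass Cohort
setClass("Cohort",
  representation(genotypes = "matrix", phenotypes = "data.frame",
                 sex = "character", maf = "numeric", realizedLD = "matrix"))

setValidity("Cohort", function(object) {
  if (!all(object@genotypes %in% 0:2))
    return("genotype dosages must be 0, 1 or 2")
  if (nrow(object@genotypes) != nrow(object@phenotypes))
    return("genotypes and phenotypes must describe the same individuals")
  TRUE
})
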