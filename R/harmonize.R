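.isPalindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Align exposure and outcome summary statistics to a common effect allele
#'
#' Intersects the SNPs of the exposure and outcome (and optionally a second
#' exposure, for multivariable MR), takes the exposure file's effect allele
#' as the reference, and at every SNP where another file reports the swapped
#' allele pair negates that file's beta (and reflects its frequency). SNPs
#' whose allele pairs neither match nor swap are dropped and logged.
#' Palindromic SNPs (A/T or C/G) are dropped when the minor-allele frequency
#' on either side exceeds `dropPalindromicMaf` — near 0.5 the strand cannot
#' be resolved from frequency — or when a frequency needed for the check is
#' missing.
#'
#' @param exposure,outcome [SummaryStats-class] objects sharing SNPs.
#' @param exposure2 optional second exposure for multivariable MR.
#' @param dropPalindromicMaf threshold in `[0, 0.5]`; palindromic SNPs with
#'   `min(eaf, 1 - eaf)` above it are dropped (default 0.42).
#' @return a [HarmonizedSet-class]; `selectionLog()` lists flips and drops.
#' @export
#' @examples
#' exp <- SummaryStats(data.frame(snp = "rs1", effect_allele = "A",
#'   other_allele = "G", beta = 0.2, se = 0.01), trait = "ldl")
#' out <- SummaryStats(data.frame(snp = "rs1", effect_allele = "G",
#'   other_allele = "A", beta = 0.1, se = 0.02), trait = "ihd",
#'   scale = "logodds")
#' h <- harmonize(exp, out)
#' h@betaY  # -0.1: outcome flipped onto the exposure's effect allele
harmonize <- function(exposure, outcome, exposure2 = NULL,
                      dropPalindromicMaf = 0.42) {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"))
  stopifnot(dropPalindromicMaf >= 0, dropPalindromicMaf <= 0.5)
  ex <- exposure@records
  ou <- outcome@records
  common <- intersect(ex$snp, ou$snp)
  if (!is.null(exposure2)) {
    stopifnot(is(exposure2, "SummaryStats"))
    common <- intersect(common, exposure2@records$snp)
  }
  if (!length(common))
    stop("exposure and outcome share no SNPs")
  ex <- ex[match(common, ex$snp), ]
  ou <- ou[match(common, ou$snp), ]

  log <- data.frame(snp = character(0), action = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  addLog <- function(snp, action, detail)
    log <<- rbind(log, data.frame(snp = snp, action = action, detail = detail,
                                  stringsAsFactors = FALSE))

  alignOne <- function(ref, other) {
    # returns +1 (match), -1 (swap) or NA (mismatch) per SNP
    same <- other$effect_allele == ref$effect_allele &
      other$other_allele == ref$other_allele
    swap <- other$effect_allele == ref$other_allele &
      other$other_allele == ref$effect_allele
    ifelse(same, 1, ifelse(swap, -1, NA))
  }

  sgn <- alignOne(ex, ou)
  drop <- is.na(sgn)
  if (any(drop))
    addLog(ex$snp[drop], "dropped_mismatch",
           sprintf("exposure %s/%s vs outcome %s/%s",
                   ex$effect_allele[drop], ex$other_allele[drop],
                   ou$effect_allele[drop], ou$other_allele[drop]))

  pal <- .isPalindromic(ex$effect_allele, ex$other_allele)
  if (any(pal & !drop)) {
    maf <- function(f) pmin(f, 1 - f)
    ambiguous <- pal & !drop &
      (is.na(ex$eaf) | is.na(ou$eaf) |
         maf(ex$eaf) > dropPalindromicMaf | maf(ou$eaf) > dropPalindromicMaf)
    if (any(ambiguous)) {
      addLog(ex$snp[ambiguous], "dropped_palindromic",
             ifelse(is.na(ex$eaf[ambiguous]) | is.na(ou$eaf[ambiguous]),
                    "palindromic with missing eaf",
                    sprintf("palindromic, maf > %g", dropPalindromicMaf)))
      drop <- drop | ambiguous
    }
  }

  e2 <- NULL
  if (!is.null(exposure2)) {
    e2 <- exposure2@records[match(common, exposure2@records$snp), ]
    sgn2 <- alignOne(ex, e2)
    m2 <- is.na(sgn2) & !drop
    if (any(m2))
      addLog(ex$snp[m2], "dropped_mismatch",
             sprintf("exposure %s/%s vs exposure2 %s/%s",
                     ex$effect_allele[m2], ex$other_allele[m2],
                     e2$effect_allele[m2], e2$other_allele[m2]))
    drop <- drop | is.na(sgn2)
  }

  keep <- !drop
  if (!any(keep))
    stop("no SNPs survived harmonization; see the log for reasons")

  flips <- sgn[keep] == -1
  if (any(flips))
    addLog(ex$snp[keep][flips], "flipped",
           "outcome beta negated to match the exposure effect allele")

  h <- new("HarmonizedSet",
           snps = ex$snp[keep],
           betaX = ex$beta[keep], seX = ex$se[keep],
           betaY = ou$beta[keep] * sgn[keep], seY = ou$se[keep],
           betaX2 = if (is.null(e2)) numeric(0)
                    else e2$beta[keep] * sgn2[keep],
           seX2 = if (is.null(e2)) numeric(0) else e2$se[keep],
           ld = NULL, flips = flips, log = log,
           outcomeScale = outcome@scale,
           exposureName = exposure@trait,
           exposure2Name = if (is.null(exposure2)) NA_character_
                           else exposure2@trait,
           outcomeName = outcome@trait)
  validObject(h)
  h
}

#' Attach an LD matrix to a harmonized set
#'
#' Permutes `ld` to the SNP order of `h`. The input correlations are signed
#' with respect to the effect alleles stated in the file they came from; when
#' that file shares the orientation of the original *outcome* records
#' (`signedBy = "outcome"`), SNPs whose outcome beta was flipped during
#' harmonization have their off-diagonal row and column negated so the signs
#' refer to the harmonized effect alleles. With the default
#' (`signedBy = "exposure"`) the matrix is assumed already oriented to the
#' exposure's (i.e. the harmonized) effect alleles.
#'
#' @param h a [HarmonizedSet-class].
#' @param ld an [LDMatrix-class] covering all SNPs of `h`.
#' @param signedBy which file's stated effect alleles the input signs follow.
#' @return `h` with an aligned `LDMatrix` in its `ld` slot.
#' @export
alignLD <- function(h, ld, signedBy = c("exposure", "outcome")) {
  stopifnot(is(h, "HarmonizedSet"), is(ld, "LDMatrix"))
  signedBy <- match.arg(signedBy)
  missing <- setdiff(h@snps, ld@snps)
  if (length(missing))
    stop("SNP(s) absent from the LD matrix: ", paste(missing, collapse = ", "))
  idx <- match(h@snps, ld@snps)
  r <- ld@rho[idx, idx, drop = FALSE]
  if (signedBy == "outcome" && any(h@flips)) {
    s <- ifelse(h@flips, -1, 1)
    r <- r * tcrossprod(s)   # preserves the unit diagonal
  }
  h@ld <- LDMatrix(h@snps, r)
  validObject(h)
  h
}
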