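#' Approximate per-SNP F-statistic for instrument strength
#'
#' The square of the SNP-exposure association divided by the square of its
#' standard error. For a vector of SNPs the per-SNP values are returned;
#' [meanF()] gives the set-level summary (their arithmetic mean). A
#' conventional adequacy threshold is 10.
#'
#' @param beta SNP-exposure association(s).
#' @param se standard error(s), positive.
#' @return non-negative numeric, same length as `beta`.
#' @export
#' @examples
#' fStatistic(0.1, 0.01)   # 100
fStatistic <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0))
    stop("validation error: se must be positive")
  (beta / se)^2
}

#' @rdname fStatistic
#' @param x a [SummaryStats-class] or [HarmonizedSet-class] object.
#' @export
meanF <- function(x) {
  if (is(x, "SummaryStats"))
    mean(fStatistic(x@records$beta, x@records$se))
  else if (is(x, "HarmonizedSet"))
    mean(fStatistic(x@betaX, x@seX))
  else stop("meanF needs a SummaryStats or HarmonizedSet")
}

#' Drop weak instruments by F-statistic
#'
#' Removes SNPs whose F-statistic for the exposure falls below `threshold`
#' (default 10) and logs each removal. An empty survivor set is allowed but
#' flagged with a warning so a silently vanished exposure cannot pass
#' unnoticed.
#'
#' @param stats a [SummaryStats-class] object for the exposure.
#' @param threshold minimum F (default 10).
#' @return list with elements `stats` (filtered [SummaryStats-class]) and
#'   `log` (data.frame `snp`, `action`, `detail`).
#' @export
filterByF <- function(stats, threshold = 10) {
  stopifnot(is(stats, "SummaryStats"))
  f <- fStatistic(stats@records$beta, stats@records$se)
  weak <- f < threshold
  log <- data.frame(
    snp = stats@records$snp,
    action = ifelse(weak, "dropped_weak_F", "kept"),
    detail = sprintf("F = %.4g", f),
    stringsAsFactors = FALSE)
  out <- stats
  out@records <- stats@records[!weak, , drop = FALSE]
  rownames(out@records) <- NULL
  if (nrow(out@records) == 0L)
    warning(sprintf("all %d SNP(s) of '%s' dropped (F < %g)",
                    length(weak), stats@trait, threshold))
  list(stats = out, log = log)
}

.rankOrder <- function(rec, rankBy = c("p", "abs_beta_over_se")) {
  rankBy <- match.arg(rankBy)
  z <- abs(rec$beta / rec$se)
  p <- rec$p
  # missing p falls back on the normal two-sided p from |beta/se|
  p[is.na(p)] <- 2 * stats::pnorm(-z[is.na(p)])
  if (rankBy == "p")
    order(p, -z, rec$snp)
  else
    order(-z, p, rec$snp)
}

#' Greedy LD pruning to an independent instrument set
#'
#' Repeatedly keeps the highest-ranked remaining SNP (smallest p by default;
#' ties broken by larger |beta/se|, then lexicographic rsID) and removes all
#' SNPs correlated with it at r squared above `r2Threshold`. The result is
#' deterministic and invariant to the input row order.
#'
#' @param stats [SummaryStats-class] for the ranking trait.
#' @param ld [LDMatrix-class] covering all SNPs of `stats`.
#' @param r2Threshold maximum pairwise r squared among kept SNPs
#'   (default 0.05).
#' @param rankBy `"p"` (default) or `"abs_beta_over_se"`.
#' @return an [InstrumentSet-class]; `selectionLog()` records every decision.
#' @export
ldPrune <- function(stats, ld, r2Threshold = 0.05,
                    rankBy = c("p", "abs_beta_over_se")) {
  stopifnot(is(stats, "SummaryStats"), is(ld, "LDMatrix"))
  rec <- stats@records
  missing <- setdiff(rec$snp, ld@snps)
  if (length(missing))
    stop("SNP(s) missing from the LD matrix: ",
         paste(missing, collapse = ", "))
  ord <- .rankOrder(rec, rankBy)
  rec <- rec[ord, , drop = FALSE]
  r2 <- ld@rho[match(rec$snp, ld@snps), match(rec$snp, ld@snps),
               drop = FALSE]^2
  n <- nrow(rec)
  status <- rep(NA_character_, n)
  detail <- rep("", n)
  for (i in seq_len(n)) {
    if (!is.na(status[i])) next
    status[i] <- "kept"
    detail[i] <- sprintf("rank %d", sum(status == "kept", na.rm = TRUE))
    victims <- which(is.na(status) & r2[i, ] > r2Threshold)
    status[victims] <- "pruned_ld"
    detail[victims] <- sprintf("r2 = %.4g with %s", r2[i, victims], rec$snp[i])
  }
  new("InstrumentSet",
      snps = rec$snp[status == "kept"], trait = stats@trait,
      log = data.frame(snp = rec$snp, action = status, detail = detail,
                       stringsAsFactors = FALSE))
}

#' Pick the lead SNP of an association set
#'
#' The SNP with the smallest p-value; ties broken by larger |beta/se|, then
#' by lexicographic rsID. SNPs without a p-value are ranked by the normal
#' two-sided p implied by |beta/se|.
#'
#' @param stats a nonempty [SummaryStats-class] object.
#' @return the rsID of the lead SNP.
#' @export
selectLead <- function(stats) {
  stopifnot(is(stats, "SummaryStats"), nrow(stats@records) > 0L)
  stats@records$snp[.rankOrder(stats@records)[1L]]
}

#' Find an LD proxy for a missing variant
#'
#' Looks up, among the candidates present in the LD matrix, the variant most
#' strongly correlated with `snp` at r squared of at least `minR2`
#' (default 0.8; ties broken lexicographically). The proxy inherits its own
#' association record — substitution only changes which rsID is carried
#' forward, and should be logged as action `"proxied"`.
#'
#' @param snp rsID to be proxied.
#' @param ld [LDMatrix-class] containing `snp`.
#' @param minR2 minimum acceptable r squared.
#' @param candidates optional restriction of the proxy search.
#' @return list with `snp` (the proxy rsID) and `r2`, or NULL when no
#'   candidate reaches `minR2`.
#' @export
findProxy <- function(snp, ld, minR2 = 0.8, candidates = NULL) {
  stopifnot(is(ld, "LDMatrix"))
  if (!snp %in% ld@snps)
    stop("SNP absent from the LD matrix: ", snp)
  pool <- setdiff(if (is.null(candidates)) ld@snps else candidates, snp)
  pool <- intersect(pool, ld@snps)
  if (!length(pool)) return(NULL)
  r2 <- ld@rho[match(snp, ld@snps), match(pool, ld@snps)]^2
  ord <- order(-r2, pool)
  if (r2[ord[1L]] < minR2) return(NULL)
  list(snp = pool[ord[1L]], r2 = unname(r2[ord[1L]]))
}

#' Restrict summary statistics to a set of SNPs
#'
#' @param stats a [SummaryStats-class] object.
#' @param snps rsIDs to keep, in the order given.
#' @return the subsetted [SummaryStats-class] object.
#' @export
subsetSnps <- function(stats, snps) {
  stopifnot(is(stats, "SummaryStats"))
  idx <- match(snps, stats@records$snp)
  if (anyNA(idx))
    stop("SNP(s) not present: ", paste(snps[is.na(idx)], collapse = ", "))
  stats@records <- stats@records[idx, , drop = FALSE]
  rownames(stats@records) <- NULL
  stats
}
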