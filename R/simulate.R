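#' Construct a simulation scenario
#'
#' See [SimScenario-class] for the meaning of every field. The causal
#' structure is: drug-locus variants shift a biomarker (slot `ldl`) by
#' `gammaLdl` per allele and testosterone by the sex-specific `alphaT*`;
#' testosterone-locus variants shift testosterone by `tau`; disease risk is
#' Bernoulli(inverse-logit(c_sex + thetaL * biomarker + thetaT_sex *
#' testosterone + direct pleiotropic effects)), with c_sex calibrated to the
#' target prevalence by root finding.
#'
#' @param nMale,nFemale cohort sizes.
#' @param snpSpec data.frame (`snp`, `maf`, `block`, `role`, `effectScale`);
#'   `effectScale` defaults to 1 when absent.
#' @param ldWithinBlock target within-block genotype correlation r.
#' @param effects named list of effect sizes (see [SimScenario-class]).
#' @param pleiotropyMean,pleiotropySd direct SNP-disease effect distribution
#'   for pleiotropic-role SNPs.
#' @param prevalenceMale,prevalenceFemale target case fractions.
#' @param seed integer seed.
#' @return a validated [SimScenario-class] object.
#' @export
simScenario <- function(nMale, nFemale, snpSpec, ldWithinBlock = 0,
                        effects, pleiotropyMean = 0, pleiotropySd = 0,
                        prevalenceMale, prevalenceFemale, seed) {
  if (is.null(snpSpec$effectScale)) snpSpec$effectScale <- 1
  snpSpec$snp <- as.character(snpSpec$snp)
  rownames(snpSpec) <- NULL
  new("SimScenario", nMale = as.integer(nMale), nFemale = as.integer(nFemale),
      snpSpec = snpSpec, ldWithinBlock = ldWithinBlock, effects = effects,
      pleiotropyMean = pleiotropyMean, pleiotropySd = pleiotropySd,
      prevalenceMale = prevalenceMale, prevalenceFemale = prevalenceFemale,
      seed = as.integer(seed))
}

# P(Z1 < q1, Z2 < q2) for standard bivariate normal with correlation a
.binorm <- function(q1, q2, a) {
  if (abs(a) < 1e-12) return(stats::pnorm(q1) * stats::pnorm(q2))
  f <- function(z) stats::pnorm((q2 - a * z) / sqrt(1 - a^2)) * stats::dnorm(z)
  stats::integrate(f, -Inf, q1, rel.tol = 1e-10)$value
}

# latent correlation yielding a target correlation between allele indicators
.latentCorr <- function(maf1, maf2, targetR) {
  if (abs(targetR) < 1e-12) return(0)
  q1 <- stats::qnorm(maf1); q2 <- stats::qnorm(maf2)
  f <- function(a) {
    p11 <- .binorm(q1, q2, a)
    (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2)) - targetR
  }
  lo <- -0.9999; hi <- 0.9999
  if (f(lo) * f(hi) > 0)
    stop(sprintf("unattainable (maf, r) combination: maf %.3g/%.3g, r %.3g",
                 maf1, maf2, targetR))
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

.directEffects <- function(scenario, sex, pleio) {
  sp <- scenario@snpSpec
  eff <- scenario@effects
  alphaT <- if (sex == "male") eff$alphaTMale else eff$alphaTFemale
  dLdl <- ifelse(sp$role == "drug_locus", eff$gammaLdl * sp$effectScale, 0)
  dT <- ifelse(sp$role == "drug_locus", alphaT * sp$effectScale,
        ifelse(sp$role %in% c("testosterone_locus", "pleiotropic"),
               eff$tau * sp$effectScale, 0))
  list(ldl = dLdl, testo = dT, pleio = pleio)
}

.drawGenotypes <- function(n, scenario) {
  sp <- scenario@snpSpec
  J <- nrow(sp)
  G <- matrix(0L, n, J, dimnames = list(NULL, sp$snp))
  for (b in unique(sp$block)) {
    idx <- which(sp$block == b)
    k <- length(idx)
    q <- stats::qnorm(sp$maf[idx])
    if (b == 0 || k == 1L) {
      # unlinked variants
      for (j in idx)
        G[, j] <- (stats::rnorm(n) < stats::qnorm(sp$maf[j])) +
                  (stats::rnorm(n) < stats::qnorm(sp$maf[j]))
    } else {
      # a single latent correlation serves the whole block (calibrated at
      # the mean frequency), but the target must be attainable for every
      # pair: indicator correlations are bounded well below 1 when
      # frequencies differ
      r <- scenario@ldWithinBlock
      for (j1 in seq_len(k - 1)) for (j2 in (j1 + 1):k) {
        m1 <- sp$maf[idx[j1]]; m2 <- sp$maf[idx[j2]]
        maxR <- (.binorm(stats::qnorm(m1), stats::qnorm(m2), 0.9999) -
                   m1 * m2) / sqrt(m1 * (1 - m1) * m2 * (1 - m2))
        if (abs(r) > maxR)
          stop(sprintf(
            "unattainable (maf, r) combination in block %s: maf %.3g/%.3g supports |r| <= %.3g, requested %.3g",
            b, m1, m2, maxR, r))
      }
      a <- .latentCorr(mean(sp$maf[idx]), mean(sp$maf[idx]), r)
      A <- matrix(a, k, k); diag(A) <- 1
      U <- chol(A)
      hap <- function() {
        Z <- matrix(stats::rnorm(n * k), n, k) %*% U
        sweep(Z, 2, q, "<") + 0L
      }
      G[, idx] <- hap() + hap()
    }
  }
  storage.mode(G) <- "integer"
  G
}

.simulateSex <- function(scenario, sex, n, prevalence, pleio) {
  eff <- scenario@effects
  d <- .directEffects(scenario, sex, pleio)
  G <- .drawGenotypes(n, scenario)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  mkTrait <- function(dvec) {
    gen <- drop(Gc %*% dvec)
    residSd <- sqrt(max(0.05, 1 - stats::var(gen)))
    gen + stats::rnorm(n, 0, residSd)
  }
  ldl <- mkTrait(d$ldl)
  thetaT <- if (sex == "male") eff$thetaTMale else eff$thetaTFemale
  testo <- mkTrait(d$testo)
  lp <- eff$thetaL * ldl + thetaT * testo + drop(Gc %*% d$pleio)
  cSex <- stats::uniroot(function(c0) mean(stats::plogis(c0 + lp)) - prevalence,
                         c(-30, 30), tol = 1e-10)$root
  ihd <- stats::rbinom(n, 1L, stats::plogis(cSex + lp))
  ld <- suppressWarnings(stats::cor(G))
  ld[!is.finite(ld)] <- 0
  diag(ld) <- 1
  new("Cohort", genotypes = G,
      phenotypes = data.frame(ldl = ldl, testosterone = testo, ihd = ihd),
      sex = sex, maf = stats::setNames(scenario@snpSpec$maf,
                                       scenario@snpSpec$snp),
      realizedLD = ld)
}

#' Simulate sex-stratified cohorts from a scenario
#'
#' Genotypes are drawn per LD block through a latent-Gaussian threshold
#' construction: two haplotype draws of correlated standard normals are
#' thresholded at qnorm(maf), with the latent correlation calibrated by root
#' finding so the allele indicators hit the block's target correlation.
#' Direct pleiotropic disease effects are drawn once (shared by the sexes),
#' phenotypes are built per sex with the sex-specific effects, and the
#' disease intercept is calibrated to the target prevalence by root finding
#' on the realized linear predictors. Deterministic given the scenario seed.
#'
#' @param scenario a [SimScenario-class] object.
#' @return list with elements `male` and `female`, each a [Cohort-class];
#'   the realized within-block genotype correlations sit in `realizedLD`.
#' @export
simulateCohort <- function(scenario) {
  stopifnot(is(scenario, "SimScenario"))
  old <- .Random.seed_exists()
  set.seed(scenario@seed)
  sp <- scenario@snpSpec
  pleio <- ifelse(sp$role == "pleiotropic",
                  stats::rnorm(nrow(sp), scenario@pleiotropyMean,
                               scenario@pleiotropySd), 0)
  male <- .simulateSex(scenario, "male", scenario@nMale,
                       scenario@prevalenceMale, pleio)
  female <- .simulateSex(scenario, "female", scenario@nFemale,
                         scenario@prevalenceFemale, pleio)
  .restore_seed(old)
  list(male = male, female = female)
}

#' Per-SNP GWAS summary statistics from a simulated cohort
#'
#' Continuous traits: per-SNP simple linear regression in closed form
#' (slope, SE from the residual variance, t-based p). Binary disease:
#' per-SNP logistic regression (intercept + dosage) fitted by iteratively
#' reweighted least squares, Wald SE and normal p. Monomorphic SNPs cannot
#' be tested: they are excluded from the records and listed in
#' `attr(x, "flagged")`. Synthetic alleles are reported as effect A / other
#' G throughout.
#'
#' @param cohort a [Cohort-class] object.
#' @param trait `"ldl"`, `"testosterone"` or `"ihd"`.
#' @return a [SummaryStats-class] object (`scale = "logodds"` for `ihd`).
#' @export
computeSumstats <- function(cohort, trait = c("ldl", "testosterone", "ihd")) {
  stopifnot(is(cohort, "Cohort"))
  trait <- match.arg(trait)
  G <- cohort@genotypes
  y <- cohort@phenotypes[[trait]]
  n <- nrow(G)
  mono <- apply(G, 2, function(g) length(unique(g)) == 1L)
  res <- if (trait == "ihd") .logisticScan(G[, !mono, drop = FALSE], y)
         else .linearScan(G[, !mono, drop = FALSE], y)
  rec <- data.frame(snp = colnames(G)[!mono],
                    effect_allele = "A", other_allele = "G",
                    eaf = colMeans(G[, !mono, drop = FALSE]) / 2,
                    beta = res$beta, se = res$se, p = res$p, n = n,
                    stringsAsFactors = FALSE)
  out <- SummaryStats(rec, trait = trait, sex = cohort@sex,
                      scale = if (trait == "ihd") "logodds" else "linear")
  if (any(mono))
    attr(out, "flagged") <- data.frame(snp = colnames(G)[mono],
                                       reason = "monomorphic",
                                       stringsAsFactors = FALSE)
  out
}

.linearScan <- function(G, y) {
  n <- length(y)
  gc <- scale(G, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  beta <- colSums(gc * yc) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  t <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pt(-abs(t), df = n - 2))
}

.logisticScan <- function(G, y) {
  J <- ncol(G)
  beta <- se <- numeric(J)
  for (j in seq_len(J)) {
    X <- cbind(1, G[, j])
    fit <- stats::glm.fit(X, y, family = stats::binomial())
    mu <- fit$fitted.values
    info <- crossprod(X * (mu * (1 - mu)), X)
    beta[j] <- fit$coefficients[2L]
    se[j] <- sqrt(solve(info)[2L, 2L])
  }
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Fast asymptotic summary statistics (no individual-level simulation)
#'
#' Draws per-SNP betas directly from normal sampling distributions centered
#' on the theoretical marginal associations implied by the scenario
#' (marginal beta_j = (Sigma_G d)_j / Var(G_j), with the within-block
#' genotype covariance approximated by the target r), with SEs
#' 1/sqrt(n Var(G_j)) for continuous traits and
#' 1/sqrt(n Var(G_j) p (1 - p)) on the log-odds scale. Useful for large-J
#' tests where individual-level cohorts would be wasteful; logistic-scale
#' non-collapsibility is not reproduced in this mode.
#'
#' @param scenario a [SimScenario-class] object.
#' @param sex `"male"` or `"female"`.
#' @param seed seed for the draws (default: the scenario seed).
#' @return list of [SummaryStats-class] objects: `ldl`, `testosterone`,
#'   `ihd`.
#' @export
asymptoticSumstats <- function(scenario, sex = c("male", "female"),
                               seed = scenario@seed) {
  stopifnot(is(scenario, "SimScenario"))
  sex <- match.arg(sex)
  sp <- scenario@snpSpec
  eff <- scenario@effects
  n <- if (sex == "male") scenario@nMale else scenario@nFemale
  prev <- if (sex == "male") scenario@prevalenceMale
          else scenario@prevalenceFemale
  old <- .Random.seed_exists()
  set.seed(as.integer(seed) + (sex == "female"))
  pleio <- ifelse(sp$role == "pleiotropic",
                  stats::rnorm(nrow(sp), scenario@pleiotropyMean,
                               scenario@pleiotropySd), 0)
  d <- .directEffects(scenario, sex, pleio)
  v <- 2 * sp$maf * (1 - sp$maf)
  SigmaG <- diag(v, nrow(sp))
  for (b in setdiff(unique(sp$block), 0)) {
    idx <- which(sp$block == b)
    for (j in idx) for (k in idx) if (j != k)
      SigmaG[j, k] <- scenario@ldWithinBlock * sqrt(v[j] * v[k])
  }
  thetaT <- if (sex == "male") eff$thetaTMale else eff$thetaTFemale
  dIhd <- eff$thetaL * d$ldl + thetaT * d$testo + d$pleio
  marginal <- function(dvec) drop(SigmaG %*% dvec) / v
  draw <- function(dvec, seVec, trait, scale) {
    beta <- stats::rnorm(nrow(sp), marginal(dvec), seVec)
    SummaryStats(data.frame(
      snp = sp$snp, effect_allele = "A", other_allele = "G", eaf = sp$maf,
      beta = beta, se = seVec, p = 2 * stats::pnorm(-abs(beta / seVec)),
      n = n, stringsAsFactors = FALSE), trait = trait, sex = sex,
      scale = scale)
  }
  out <- list(
    ldl = draw(d$ldl, 1 / sqrt(n * v), "ldl", "linear"),
    testosterone = draw(d$testo, 1 / sqrt(n * v), "testosterone", "linear"),
    ihd = draw(dIhd, 1 / sqrt(n * v * prev * (1 - prev)), "ihd", "logodds"))
  .restore_seed(old)
  out
}

#' Realized LD matrix of a simulated cohort
#'
#' @param cohort a [Cohort-class] object.
#' @param snps optional subset of rsIDs.
#' @return an [LDMatrix-class] of realized genotype correlations.
#' @export
realizedLDMatrix <- function(cohort, snps = NULL) {
  stopifnot(is(cohort, "Cohort"))
  r <- cohort@realizedLD
  ids <- colnames(cohort@genotypes)
  if (!is.null(snps)) {
    idx <- match(snps, ids)
    if (anyNA(idx)) stop("SNP(s) not in cohort: ",
                         paste(snps[is.na(idx)], collapse = ", "))
    r <- r[idx, idx, drop = FALSE]
    ids <- snps
  }
  LDMatrix(ids, r)
}

.presetCatalog <- function() c("statin_mediation", "anakinra_reverse",
                               "null", "pleiotropic")

#' Named catalog of simulation scenarios
#'
#' Ships the study patterns the package is exercised against, at desk scale
#' (20,000 individuals per sex by default):
#' \describe{
#'   \item{statin_mediation}{six correlated drug-locus variants whose lead
#'     explains the biomarker strongly, ten independent testosterone
#'     variants, four null variants; male-only drug-locus effect on
#'     testosterone (IVW estimand -0.15 per biomarker effect size), disease
#'     log-odds log(0.55) per biomarker effect size and log(1.11) per
#'     testosterone effect size in men, null testosterone pathway in women.}
#'   \item{anakinra_reverse}{two independent drug-locus variants; male-only
#'     *positive* effect on testosterone and a harmful disease effect — the
#'     mirror image of the statin pattern.}
#'   \item{null}{the statin_mediation genetic architecture with every
#'     downstream effect set to zero (type-I error checks).}
#'   \item{pleiotropic}{twenty independent testosterone variants with
#'     spread instrument strengths and directional direct disease effects
#'     (mean 0.08, SD 0.02 log-odds per allele), sized for the Egger
#'     intercept to be detectable.}
#' }
#'
#' @param name preset name; NULL lists the catalog.
#' @param ... overrides passed to the scenario (e.g. `seed`, `nMale`).
#' @return a [SimScenario-class], or the catalog names when `name` is NULL.
#' @export
#' @examples
#' scenarioPresets()
#' scenarioPresets("statin_mediation", seed = 7)
scenarioPresets <- function(name = NULL, ...) {
  if (is.null(name)) return(.presetCatalog())
  if (!name %in% .presetCatalog())
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(.presetCatalog(), collapse = ", ")))
  snpRow <- function(snp, maf, block, role, effectScale = 1)
    data.frame(snp = snp, maf = maf, block = block, role = role,
               effectScale = effectScale, stringsAsFactors = FALSE)
  drugBlock <- snpRow(sprintf("rs%d", 101:106), 0.3, 1L, "drug_locus",
                      c(1, rep(0.6, 5)))
  # a spread of instrument strengths, as in real testosterone GWAS hits
  testoSnps <- snpRow(sprintf("rs%d", 201:210), 0.3, 0L, "testosterone_locus",
                      seq(0.6, 1.6, length.out = 10))
  nullSnps <- snpRow(sprintf("rs%d", 301:304), 0.3, 0L, "null")
  base <- list(nMale = 20000L, nFemale = 20000L, ldWithinBlock = 0.55,
               prevalenceMale = 25410 / 179918,
               prevalenceFemale = 12511 / 212080, seed = 42L)
  args <- switch(name,
    statin_mediation = c(base, list(
      snpSpec = rbind(drugBlock, testoSnps, nullSnps),
      effects = list(gammaLdl = 0.25, alphaTMale = -0.15 * 0.25,
                     alphaTFemale = 0, tau = 0.1, thetaL = log(0.55),
                     thetaTMale = log(1.11), thetaTFemale = 0))),
    null = c(base, list(
      snpSpec = rbind(drugBlock, testoSnps, nullSnps),
      effects = list(gammaLdl = 0.25, alphaTMale = 0, alphaTFemale = 0,
                     tau = 0.1, thetaL = 0, thetaTMale = 0,
                     thetaTFemale = 0))),
    anakinra_reverse = c(base, list(
      snpSpec = rbind(
        snpRow(sprintf("rs%d", 111:112), 0.3, 0L, "drug_locus"),
        testoSnps, nullSnps),
      effects = list(gammaLdl = 0.3, alphaTMale = 0.15 * 0.3,
                     alphaTFemale = 0, tau = 0.1, thetaL = log(1.25),
                     thetaTMale = log(1.11), thetaTFemale = 0))),
    pleiotropic = c(base, list(
      snpSpec = snpRow(sprintf("rs%d", 401:420), 0.3, 0L, "pleiotropic",
                       seq(0.5, 2.5, length.out = 20)),
      effects = list(gammaLdl = 0, alphaTMale = 0, alphaTFemale = 0,
                     tau = 0.1, thetaL = 0, thetaTMale = log(1.11),
                     thetaTFemale = 0),
      pleiotropyMean = 0.08, pleiotropySd = 0.02)))
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(simScenario, args)
}
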