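smallScenario <- function(snpSpec, effects = NULL, n = 4000, seed = 1, ...) {
  base <- list(gammaLdl = 0, alphaTMale = 0, alphaTFemale = 0, tau = 0,
               thetaL = 0, thetaTMale = 0, thetaTFemale = 0)
  if (!is.null(effects)) base[names(effects)] <- effects
  simScenario(nMale = n, nFemale = n, snpSpec = snpSpec, effects = base,
              prevalenceMale = 0.14, prevalenceFemale = 0.06, seed = seed,
              ...)
}

snpSpec <- function(n, role = "null", maf = 0.3, block = 0L,
                    effectScale = 1)
  data.frame(snp = sprintf("rs%d", seq_len(n)), maf = maf, block = block,
             role = role, effectScale = effectScale,
             stringsAsFactors = FALSE)

test_that("the generator is deterministic given its seed", {
  sc <- scenarioPresets("statin_mediation", seed = 9,
                        nMale = 500L, nFemale = 500L)
  a <- simulateCohort(sc)
  b <- simulateCohort(sc)
  expect_identical(a$male@genotypes, b$male@genotypes)
  expect_identical(a$male@phenotypes, b$male@phenotypes)
  expect_identical(a$female@phenotypes, b$female@phenotypes)
  c2 <- simulateCohort(scenarioPresets("statin_mediation", seed = 10,
                                       nMale = 500L, nFemale = 500L))
  expect_false(identical(a$male@phenotypes$ldl, c2$male@phenotypes$ldl))
})

test_that("phenotypes are standardized and null effects give null signal", {
  sc <- smallScenario(snpSpec(10), n = 6000, seed = 4)
  co <- simulateCohort(sc)$male
  expect_equal(mean(co@phenotypes$ldl), 0, tolerance = 0.05)
  expect_equal(sd(co@phenotypes$ldl), 1, tolerance = 0.05)
  expect_equal(sd(co@phenotypes$testosterone), 1, tolerance = 0.05)
  cors <- cor(co@genotypes, co@phenotypes$ldl)
  expect_lt(max(abs(cors)), 4 / sqrt(6000))
})

test_that("within-block LD calibration hits the target correlation", {
  spec <- snpSpec(4, block = 1L)
  sc <- smallScenario(spec, n = 20000, seed = 6, ldWithinBlock = 0.55)
  co <- simulateCohort(sc)$male
  off <- co@realizedLD[upper.tri(co@realizedLD)]
  expect_equal(mean(off), 0.55, tolerance = 0.03)
  # an unattainable frequency/correlation pair errors out
  specBad <- snpSpec(2, block = 1L)
  specBad$maf <- c(0.01, 0.49)
  expect_error(simulateCohort(smallScenario(specBad, n = 100,
                                            ldWithinBlock = 0.97)),
               "unattainable")
})

test_that("disease prevalence is calibrated to its target", {
  spec <- snpSpec(3, role = "drug_locus")
  sc <- smallScenario(spec, effects = list(gammaLdl = 0.2,
                                           thetaL = log(0.55)),
                      n = 50000, seed = 12)
  sc@prevalenceMale <- 25410 / 179918  # 0.1412
  co <- simulateCohort(sc)$male
  expect_lt(abs(mean(co@phenotypes$ihd) - 25410 / 179918), 0.005)
})

test_that("per-SNP regression recovers a planted effect", {
  spec <- snpSpec(1, role = "drug_locus")
  sc <- smallScenario(spec, effects = list(gammaLdl = 0.3), n = 20000,
                      seed = 21)
  co <- simulateCohort(sc)$male
  s <- computeSumstats(co, "ldl")
  expect_lt(abs(s@records$beta - 0.3), 3 * s@records$se)
  expect_equal(s@records$n, 20000)
  expect_equal(s@records$eaf, 0.3, tolerance = 0.02)
})

test_that("null associations give uniform p-values", {
  spec <- snpSpec(200)
  sc <- smallScenario(spec, n = 2000, seed = 31)
  co <- simulateCohort(sc)$male
  # permuting the phenotype severs any residual structure
  set.seed(99)
  co@phenotypes$ldl <- sample(co@phenotypes$ldl)
  s <- computeSumstats(co, "ldl")
  ks <- suppressWarnings(ks.test(s@records$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("logistic scan equals the contingency-table log odds ratio", {
  set.seed(41)
  g <- rbinom(5000, 1, 0.3)   # binary-coded variant
  y <- rbinom(5000, 1, plogis(-2 + 0.5 * g))
  co <- new("Cohort",
            genotypes = matrix(as.integer(g), ncol = 1,
                               dimnames = list(NULL, "rs1")),
            phenotypes = data.frame(ldl = rnorm(5000),
                                    testosterone = rnorm(5000), ihd = y),
            sex = "male", maf = c(rs1 = 0.3),
            realizedLD = matrix(1, 1, 1))
  s <- computeSumstats(co, "ihd")
  tab <- table(g, y)
  logOR <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  expect_equal(s@records$beta, logOR, tolerance = 1e-6)
  seOracle <- sqrt(sum(1 / tab))
  expect_equal(s@records$se, seOracle, tolerance = 1e-4)
})

test_that("monomorphic variants are flagged and excluded", {
  co <- new("Cohort",
            genotypes = cbind(rs1 = rep(2L, 100),
                              rs2 = rbinom(100, 2, 0.4)),
            phenotypes = data.frame(ldl = rnorm(100),
                                    testosterone = rnorm(100),
                                    ihd = rbinom(100, 1, 0.2)),
            sex = "female", maf = c(rs1 = 1, rs2 = 0.4),
            realizedLD = diag(2))
  s <- computeSumstats(co, "ldl")
  expect_identical(snpIds(s), "rs2")
  expect_identical(attr(s, "flagged")$snp, "rs1")
})

test_that("the preset catalog is complete and errors helpfully", {
  expect_setequal(scenarioPresets(),
                  c("statin_mediation", "anakinra_reverse", "null",
                    "pleiotropic"))
  expect_error(scenarioPresets("nonsense"), "statin_mediation")
  for (nm in scenarioPresets())
    expect_s4_class(scenarioPresets(nm), "SimScenario")
  # named defaults encode the sex-specific pattern
  sc <- scenarioPresets("statin_mediation")
  expect_lt(sc@effects$alphaTMale, 0)
  expect_identical(sc@effects$alphaTFemale, 0)
  expect_identical(sc@effects$thetaTFemale, 0)
  expect_gt(sc@effects$thetaTMale, 0)
})

test_that("statin_mediation reproduces the qualitative sex pattern", {
  sc <- scenarioPresets("statin_mediation", seed = 101)
  co <- simulateCohort(sc)
  for (sex in c("male", "female")) {
    ldl <- computeSumstats(co[[sex]], "ldl")
    testo <- computeSumstats(co[[sex]], "testosterone")
    lead <- selectLead(subsetSnps(ldl, sprintf("rs%d", 101:106)))
    h <- harmonize(subsetSnps(ldl, lead), subsetSnps(testo, lead))
    est <- mrIVW(h)
    if (sex == "male") {
      expect_lt(estimate(est), 0)
      expect_lt(pValue(est), 0.05)
    } else {
      expect_gt(pValue(est), 0.001)   # no planted female pathway
      expect_lt(abs(estimate(est)), 0.15)
    }
  }
})

test_that("anakinra_reverse mirrors the statin pattern with opposite signs", {
  sc <- scenarioPresets("anakinra_reverse", seed = 103)
  co <- simulateCohort(sc)
  ldl <- computeSumstats(co$male, "ldl")        # drug biomarker
  testo <- computeSumstats(co$male, "testosterone")
  ihd <- computeSumstats(co$male, "ihd")
  drug <- sprintf("rs%d", 111:112)
  hT <- harmonize(subsetSnps(ldl, drug), subsetSnps(testo, drug))
  hD <- harmonize(subsetSnps(ldl, drug), subsetSnps(ihd, drug))
  expect_gt(estimate(mrIVW(hT)), 0)
  expect_lt(pValue(mrIVW(hT)), 0.05)
  expect_gt(unname(oddsRatio(mrIVW(hD))["or"]), 1)
})

test_that("asymptotic summary statistics center on the marginal effects", {
  sc <- scenarioPresets("statin_mediation", seed = 51,
                        nMale = 10000000L, nFemale = 10000000L)
  ss <- asymptoticSumstats(sc, "male")
  v <- 2 * 0.3 * 0.7
  # lead drug SNP: own effect plus LD leak-through from its block
  gamma <- sc@effects$gammaLdl
  scales <- sc@snpSpec$effectScale[1:6]
  marg <- gamma * (scales[1] + 0.55 * sum(scales[-1]))
  expect_equal(ss$ldl@records$beta[1], marg, tolerance = 0.02)
  # unlinked null SNP: zero
  expect_equal(ss$ldl@records$beta[20], 0, tolerance = 0.005)
  # determinism
  ss2 <- asymptoticSumstats(sc, "male")
  expect_identical(ss$ihd@records$beta, ss2$ihd@records$beta)
})

test_that("the null preset keeps the type-I error near its nominal level", {
  falsePos <- 0L
  for (r in 1:200) {
    sc <- scenarioPresets("null", seed = 6000 + r)
    ss <- asymptoticSumstats(sc, "male")
    lead <- selectLead(subsetSnps(ss$ldl, sprintf("rs%d", 101:106)))
    h <- harmonize(subsetSnps(ss$ldl, lead),
                   subsetSnps(ss$testosterone, lead))
    falsePos <- falsePos + (pValue(mrIVW(h)) < 0.05)
  }
  expect_lt(falsePos / 200, 0.11)
})

test_that("the pleiotropic preset gives the Egger intercept real power", {
  hits <- 0L
  for (r in 1:100) {
    sc <- scenarioPresets("pleiotropic", seed = 7000 + r)
    ss <- asymptoticSumstats(sc, "male")
    h <- harmonize(ss$testosterone, ss$ihd)
    est <- mrEgger(h)
    hits <- hits + (est@eggerInterceptP < 0.05)
  }
  expect_gte(hits / 100, 0.8)
})
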