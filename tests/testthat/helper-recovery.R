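# one replicate of the parameter-recovery experiment under the
# statin_mediation preset: simulate both sexes at the preset's scale,
# run the lead-SNP analyses, and report
#   cover  - does the drug->disease IVW CI cover the planted biomarker
#            effect log(0.55)?
#   power  - is the men's drug->testosterone estimate negative and p < 0.05?
#   betaF  - the women's drug->testosterone estimate (should center on 0)
recoveryReplicate <- function(seed) {
  sc <- scenarioPresets("statin_mediation", seed = seed)
  co <- simulateCohort(sc)
  drug <- sprintf("rs%d", 101:106)

  leadOf <- function(cohort) {
    ldl <- computeSumstats(cohort, "ldl")
    list(ldl = ldl, lead = selectLead(subsetSnps(ldl, drug)))
  }

  m <- leadOf(co$male)
  # disease scan restricted to the lead variant (logistic fits are the
  # expensive step)
  ihdCo <- co$male
  ihdCo@genotypes <- co$male@genotypes[, m$lead, drop = FALSE]
  ihdCo@realizedLD <- matrix(1, 1, 1)
  ihd <- computeSumstats(ihdCo, "ihd")
  hD <- harmonize(subsetSnps(m$ldl, m$lead), ihd)
  estD <- mrIVW(hD)
  ci <- confInt(estD)
  cover <- ci[1, "low"] <= log(0.55) && log(0.55) <= ci[1, "high"]

  testoM <- computeSumstats(co$male, "testosterone")
  estT <- mrIVW(harmonize(subsetSnps(m$ldl, m$lead),
                          subsetSnps(testoM, m$lead)))
  power <- estimate(estT) < 0 && pValue(estT) < 0.05

  f <- leadOf(co$female)
  testoF <- computeSumstats(co$female, "testosterone")
  estF <- mrIVW(harmonize(subsetSnps(f$ldl, f$lead),
                          subsetSnps(testoF, f$lead)))

  c(cover = cover, power = power, betaF = estimate(estF))
}

runRecoveryStudy <- function(nReps, baseSeed) {
  out <- vapply(seq_len(nReps),
                function(r) recoveryReplicate(baseSeed + r), numeric(3))
  list(coverage = mean(out["cover", ]),
       power = mean(out["power", ]),
       womenCenterRatio = abs(mean(out["betaF", ])) / sd(out["betaF", ]),
       womenMean = mean(out["betaF", ]),
       womenSD = sd(out["betaF", ]))
}

publishedEstimates <- function() {
  path <- system.file("extdata", "published_estimates.tsv",
                      package = "drugTargetMR")
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
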