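# shared builders for summary-statistic and harmonized fixtures

makeStats <- function(snp, beta, se, eaf = NA_real_, p = NA_real_,
                      n = NA_real_, ea = "A", oa = "G",
                      trait = "ldl", sex = "male", scale = "linear") {
  SummaryStats(data.frame(snp = snp, effect_allele = ea, other_allele = oa,
                          eaf = eaf, beta = beta, se = se, p = p, n = n,
                          stringsAsFactors = FALSE),
               trait = trait, sex = sex, scale = scale)
}

makeHarm <- function(betaX, seX, betaY, seY, betaX2 = numeric(0),
                     seX2 = numeric(0), ld = NULL, scale = "linear",
                     snps = sprintf("rs%d", seq_along(betaX))) {
  h <- new("HarmonizedSet", snps = snps,
           betaX = betaX, seX = seX, betaY = betaY, seY = seY,
           betaX2 = betaX2, seX2 = seX2, ld = NULL,
           flips = rep(FALSE, length(betaX)),
           log = data.frame(snp = character(0), action = character(0),
                            detail = character(0)),
           outcomeScale = scale, exposureName = "exposure1",
           exposure2Name = if (length(betaX2)) "exposure2" else NA_character_,
           outcomeName = "outcome")
  if (!is.null(ld)) h <- alignLD(h, ld)
  h
}

# a reproducible random harmonized fixture (uncorrelated instruments)
randHarm <- function(seed, J, theta = 0.4, noise = 0.02) {
  set.seed(seed)
  bx <- runif(J, 0.05, 0.3)
  sx <- runif(J, 0.005, 0.02)
  sy <- runif(J, 0.01, 0.05)
  by <- theta * bx + rnorm(J, 0, noise)
  makeHarm(bx, sx, by, sy)
}

# equicorrelated LD matrix fixture
equiLD <- function(snps, r) {
  k <- length(snps)
  m <- matrix(r, k, k); diag(m) <- 1
  LDMatrix(snps, m)
}
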