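# two-exposure harmonized fixture builder
mvHarm <- function(seed, J, theta1 = 0.3, theta2 = 0.1, noise = 0.01,
                   bx2 = NULL, scale = "linear") {
  set.seed(seed)
  bx1 <- runif(J, 0.05, 0.3)
  if (is.null(bx2)) bx2 <- runif(J, -0.2, 0.3)
  sy <- runif(J, 0.01, 0.04)
  by <- theta1 * bx1 + theta2 * bx2 + rnorm(J, 0, noise)
  makeHarm(bx1, runif(J, 0.005, 0.02), by, sy,
           betaX2 = bx2, seX2 = runif(J, 0.005, 0.02), scale = scale)
}

test_that("a zero second exposure reduces MVMR-IVW to univariable IVW", {
  h <- mvHarm(1, 8, theta2 = 0, bx2 = rep(0, 8))
  fit <- mvmrIVW(h)
  uni <- mrIVW(makeHarm(h@betaX, h@seX, h@betaY, h@seY),
               randomEffects = "fixed")
  expect_equal(unname(estimate(fit)[1]), estimate(uni), tolerance = 1e-12)
  expect_true(is.na(estimate(fit)[2]))
})

test_that("MVMR-IVW matches the two-column normal-equations oracle", {
  h <- mvHarm(5, 9)
  fit <- mvmrIVW(h)
  X <- cbind(h@betaX, h@betaX2)
  w <- 1 / h@seY^2
  XtWXi <- solve(t(X * w) %*% X)
  coefO <- drop(XtWXi %*% (t(X * w) %*% h@betaY))
  Qres <- sum(w * (h@betaY - X %*% coefO)^2)
  seO <- sqrt(diag(XtWXi)) * max(1, sqrt(Qres / (9 - 2)))
  expect_equal(unname(estimate(fit)), coefO, tolerance = 1e-10)
  expect_equal(unname(stdError(fit)), seO, tolerance = 1e-10)
})

test_that("MVMR-IVW with block LD matches the explicit GLS oracle", {
  set.seed(8)
  J <- 8
  rho <- diag(J)
  rho[1:4, 1:4] <- 0.4; rho[5:8, 5:8] <- 0.25; diag(rho) <- 1
  h <- mvHarm(8, J)
  h@ld <- LDMatrix(h@snps, rho)
  fit <- mvmrIVW(h)
  X <- cbind(h@betaX, h@betaX2)
  omega <- diag(h@seY) %*% rho %*% diag(h@seY)
  oi <- solve(omega)
  XtOXi <- solve(t(X) %*% oi %*% X)
  coefO <- drop(XtOXi %*% (t(X) %*% oi %*% h@betaY))
  res <- h@betaY - X %*% coefO
  Qres <- drop(t(res) %*% oi %*% res)
  seO <- sqrt(diag(XtOXi)) * max(1, sqrt(Qres / (J - 2)))
  expect_equal(unname(estimate(fit)), coefO, tolerance = 1e-10)
  expect_equal(unname(stdError(fit)), seO, tolerance = 1e-10)
})

test_that("MVMR estimates are invariant to exchanging the exposures", {
  h <- mvHarm(12, 10)
  a <- estimate(mvmrIVW(h))
  hSwap <- h
  hSwap@betaX <- h@betaX2; hSwap@seX <- h@seX2
  hSwap@betaX2 <- h@betaX; hSwap@seX2 <- h@seX
  hSwap@exposureName <- "exposure2"; hSwap@exposure2Name <- "exposure1"
  b <- estimate(mvmrIVW(hSwap))
  expect_equal(unname(a), unname(rev(b)), tolerance = 1e-12)
})

test_that("collinear exposure vectors are rejected with a diagnostic", {
  set.seed(3)
  bx <- runif(6, 0.1, 0.3)
  h <- makeHarm(bx, rep(0.01, 6), 0.2 * bx, rep(0.02, 6),
                betaX2 = 2 * bx, seX2 = rep(0.01, 6))
  expect_error(mvmrIVW(h), "collinear")
})

test_that("MVMR-Egger: exact fit, IVW agreement, orientation invariance", {
  # exact-fit construction at J = L + 2
  bx1 <- c(0.1, 0.2, 0.3, 0.15)
  bx2 <- c(0.2, -0.1, 0.05, 0.25)
  by <- 0.03 + 0.5 * bx1 - 0.2 * bx2
  h <- makeHarm(bx1, rep(0.01, 4), by, rep(0.02, 4),
                betaX2 = bx2, seX2 = rep(0.01, 4))
  fit <- mvmrEgger(h)
  expect_equal(unname(estimate(fit)), c(0.5, -0.2), tolerance = 1e-9)
  expect_equal(fit@eggerIntercept, 0.03, tolerance = 1e-9)

  # zero-intercept generative data: slopes agree with MVMR-IVW within
  # simulation tolerance
  h0 <- mvHarm(21, 40, noise = 0.005)
  expect_equal(unname(estimate(mvmrEgger(h0))),
               unname(estimate(mvmrIVW(h0))), tolerance = 0.05)

  # flipping one SNP leaves estimates unchanged (orientation step)
  h1 <- mvHarm(23, 8)
  ref <- mvmrEgger(h1)
  for (j in c(2, 5)) {
    h2 <- h1
    h2@betaX[j] <- -h2@betaX[j]
    h2@betaX2[j] <- -h2@betaX2[j]
    h2@betaY[j] <- -h2@betaY[j]
    got <- mvmrEgger(h2)
    expect_equal(unname(estimate(got)), unname(estimate(ref)),
                 tolerance = 1e-12)
    expect_equal(got@eggerIntercept, ref@eggerIntercept, tolerance = 1e-12)
  }

  expect_error(mvmrEgger(mvHarm(1, 3)), "J > L \\+ 1")
})

test_that("conditional F: reductions and the root-finding oracle", {
  # other exposure identically zero: mean univariable chi-squared
  h <- mvHarm(31, 10, bx2 = rep(0, 10))
  cf <- conditionalF(h)
  expect_equal(unname(cf[1]), sum((h@betaX / h@seX)^2) / 9,
               tolerance = 1e-10)

  # exposure k nearly proportional to exposure l: conditionally weak
  set.seed(33)
  bx2 <- runif(8, 0.1, 0.3)
  bx1 <- 0.7 * bx2 + rnorm(8, 0, 1e-5)
  hW <- makeHarm(bx1, rep(0.01, 8), 0.2 * bx1, rep(0.02, 8),
                 betaX2 = bx2, seX2 = rep(0.01, 8))
  expect_lt(unname(conditionalF(hW)[1]), 0.1)

  # independent oracle: solve the weighted-regression estimating equation
  # for delta by root finding, then assemble Q(delta)/(J-1)
  h2 <- mvHarm(35, 9)
  condOracle <- function(a, sa, b, sb, df) {
    g <- function(d) {
      w <- 1 / (sa^2 + d^2 * sb^2)
      sum(w * b * (a - d * b))
    }
    lo <- -1e3; hi <- 1e3
    d <- uniroot(g, c(lo, hi), tol = 1e-14)$root
    sum((a - d * b)^2 / (sa^2 + d^2 * sb^2)) / df
  }
  got <- conditionalF(h2)
  expect_equal(unname(got[1]),
               condOracle(h2@betaX, h2@seX, h2@betaX2, h2@seX2, 8),
               tolerance = 1e-8)
  expect_equal(unname(got[2]),
               condOracle(h2@betaX2, h2@seX2, h2@betaX, h2@seX, 8),
               tolerance = 1e-8)
  # the two statistics are genuinely asymmetric
  expect_false(isTRUE(all.equal(unname(got[1]), unname(got[2]))))

  # denominator convention switch
  gotJL <- conditionalF(h2, denominator = "J-L")
  expect_equal(unname(gotJL[1]), unname(got[1]) * 8 / 7, tolerance = 1e-12)
})

test_that("the instrument-validity Q behaves as specified", {
  # perfectly linear noiseless fixture
  h0 <- mvHarm(41, 6, noise = 0)
  fit <- mvmrIVW(h0)
  expect_lt(unname(heterogeneityQ(fit)["Q"]), 1e-10)

  # hand-computed four-SNP example, term by term
  h <- mvHarm(43, 4)
  theta <- c(0.25, -0.1)
  qv <- mvmrQ(h, theta)
  manual <- 0
  for (j in 1:4) {
    num <- (h@betaY[j] - theta[1] * h@betaX[j] - theta[2] * h@betaX2[j])^2
    den <- h@seY[j]^2 + theta[1]^2 * h@seX[j]^2 + theta[2]^2 * h@seX2[j]^2
    manual <- manual + num / den
  }
  expect_equal(unname(qv["Q"]), manual, tolerance = 1e-12)
  expect_identical(unname(qv["df"]), 2)

  # dropping the exposure-SE terms gives the plain weighted residual sum
  qv0 <- mvmrQ(h, theta, accountExposureSE = FALSE)
  residQ <- sum((h@betaY - theta[1] * h@betaX - theta[2] * h@betaX2)^2 /
                  h@seY^2)
  expect_equal(unname(qv0["Q"]), residQ, tolerance = 1e-12)

  # invariance to SNP ordering
  perm <- c(3, 1, 4, 2)
  hP <- h
  for (slot in c("betaX", "seX", "betaY", "seY", "betaX2", "seX2"))
    slot(hP, slot) <- slot(h, slot)[perm]
  hP@snps <- h@snps[perm]; hP@flips <- h@flips[perm]
  expect_equal(unname(mvmrQ(hP, theta)["Q"]), unname(qv["Q"]),
               tolerance = 1e-12)
})

test_that("Q detects injected pleiotropy with high power", {
  set.seed(55)
  J <- 20
  rejections <- 0L
  for (r in 1:500) {
    bx1 <- runif(J, 0.1, 0.3)
    bx2 <- runif(J, 0.1, 0.3)
    sy <- rep(0.02, J)
    direct <- ifelse(seq_len(J) <= 6, rnorm(6, 0, 0.08), 0)  # 30% of SNPs
    by <- 0.3 * bx1 + 0.1 * bx2 + direct + rnorm(J, 0, sy)
    h <- makeHarm(bx1, rep(1e-3, J), by, sy,
                  betaX2 = bx2, seX2 = rep(1e-3, J))
    fit <- mvmrIVW(h)
    qv <- heterogeneityQ(fit)
    rejections <- rejections +
      (qv[["Q"]] > qchisq(0.95, df = qv[["df"]]))
  }
  expect_gte(rejections / 500, 0.9)
})
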