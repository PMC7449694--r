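test_that("the Wald ratio and its delta-method SE are correct", {
  h <- makeHarm(0.2, 0.01, 0.04, 0.01)
  est <- waldRatio(h)
  expect_equal(estimate(est), 0.2)
  expect_equal(stdError(est), 0.05)
  expect_equal(unname(confInt(est)[1, ]), c(0.2 - 1.96 * 0.05,
                                            0.2 + 1.96 * 0.05))

  # simulation oracle for the first-order SE: sd of ratio draws with the
  # exposure held fixed
  set.seed(1)
  draws <- rnorm(2e5, 0.04, 0.01) / 0.2
  expect_equal(stdError(est), sd(draws), tolerance = 0.02)

  expect_equal(estimate(waldRatio(makeHarm(0.2, 0.01, 0, 0.01))), 0)
  expect_equal(estimate(waldRatio(makeHarm(-0.2, 0.01, 0.04, 0.01))), -0.2)
  expect_error(waldRatio(makeHarm(0, 0.01, 0.04, 0.01)), "zero")

  est2 <- waldRatio(makeHarm(0.2, 0.05, 0.04, 0.01), secondOrder = TRUE)
  expect_equal(stdError(est2),
               sqrt(0.01^2 / 0.2^2 + 0.04^2 * 0.05^2 / 0.2^4))
})

test_that("IVW reduces to the Wald ratio at J = 1 and has zero Q when exact", {
  h1 <- makeHarm(0.25, 0.01, 0.1, 0.03)
  expect_equal(estimate(mrIVW(h1)), estimate(waldRatio(h1)))
  expect_equal(stdError(mrIVW(h1)), stdError(waldRatio(h1)))

  h3 <- makeHarm(c(0.1, 0.2, 0.3), rep(0.01, 3),
                 0.5 * c(0.1, 0.2, 0.3), rep(0.02, 3))
  mre <- mrIVW(h3)
  fe <- mrIVW(h3, randomEffects = "fixed")
  expect_equal(estimate(mre), 0.5)
  expect_equal(unname(heterogeneityQ(mre)["Q"]), 0)
  expect_equal(stdError(mre), stdError(fe))
})

test_that("IVW matches the weighted normal-equations oracle", {
  h <- randHarm(3, 5)
  w <- 1 / h@seY^2
  thetaOracle <- sum(w * h@betaX * h@betaY) / sum(w * h@betaX^2)
  seFE <- 1 / sqrt(sum(w * h@betaX^2))
  Q <- sum(w * (h@betaY - thetaOracle * h@betaX)^2)
  est <- mrIVW(h)
  expect_equal(estimate(est), thetaOracle, tolerance = 1e-12)
  expect_equal(unname(heterogeneityQ(est)["Q"]), Q, tolerance = 1e-12)
  expect_equal(stdError(est), seFE * max(1, sqrt(Q / 4)), tolerance = 1e-12)
  # independent route: weighted regression through the origin
  fit <- lm(h@betaY ~ 0 + h@betaX, weights = w)
  expect_equal(estimate(est), unname(coef(fit)), tolerance = 1e-12)
})

test_that("multiplicative random effects never deflate the SE", {
  for (seed in 1:10) {
    h <- randHarm(seed, 6, noise = ifelse(seed %% 2, 0.05, 1e-4))
    mre <- mrIVW(h)
    fe <- mrIVW(h, randomEffects = "fixed")
    expect_gte(stdError(mre), stdError(fe))
    Q <- unname(heterogeneityQ(mre)["Q"])
    if (Q <= 5) expect_equal(stdError(mre), stdError(fe))
    else expect_gt(stdError(mre), stdError(fe))
  }
})

test_that("rescaling the exposure rescales the estimate inversely", {
  h <- randHarm(9, 5)
  ref <- mrIVW(h)
  for (c0 in c(2, -0.5, 10)) {
    h2 <- h
    h2@betaX <- c0 * h@betaX
    h2@seX <- abs(c0) * h@seX
    expect_equal(estimate(mrIVW(h2)), estimate(ref) / c0, tolerance = 1e-12)
    expect_equal(stdError(mrIVW(h2)), stdError(ref) / abs(c0),
                 tolerance = 1e-12)
  }
})

test_that("correlated-instrument IVW reduces to IVW under identity LD", {
  h <- randHarm(13, 6)
  hLD <- alignLD(h, LDMatrix(h@snps, diag(6)))
  a <- mrIVWCorrelated(hLD)
  b <- mrIVW(h)
  expect_equal(estimate(a), estimate(b), tolerance = 1e-12)
  expect_equal(stdError(a), stdError(b), tolerance = 1e-12)
})

test_that("duplicated instruments collapse to the single-SNP estimate", {
  h <- makeHarm(c(0.2, 0.2), c(0.01, 0.01), c(0.08, 0.08), c(0.02, 0.02))
  rho <- matrix(c(1, 1, 1, 1), 2)
  h@ld <- LDMatrix(h@snps, rho)
  est <- mrIVWCorrelated(h, ridge = 1e-8)
  single <- waldRatio(makeHarm(0.2, 0.01, 0.08, 0.02))
  expect_equal(estimate(est), estimate(single), tolerance = 1e-4)
  expect_equal(stdError(est), stdError(single), tolerance = 1e-3)
})

test_that("correlated-instrument IVW matches the explicit GLS oracle", {
  set.seed(21)
  J <- 6
  rho <- diag(6)
  rho[1:3, 1:3] <- 0.5; rho[4:6, 4:6] <- 0.3; diag(rho) <- 1
  bx <- runif(J, 0.05, 0.3); sy <- runif(J, 0.01, 0.05)
  by <- 0.3 * bx + rnorm(J, 0, 0.01)
  h <- makeHarm(bx, rep(0.01, J), by, sy)
  h@ld <- LDMatrix(h@snps, rho)
  est <- mrIVWCorrelated(h)
  omega <- diag(sy) %*% rho %*% diag(sy)
  oi <- solve(omega)
  thetaO <- drop(t(bx) %*% oi %*% by) / drop(t(bx) %*% oi %*% bx)
  seO <- 1 / sqrt(drop(t(bx) %*% oi %*% bx))
  resid <- by - thetaO * bx
  Qo <- drop(t(resid) %*% oi %*% resid)
  expect_equal(estimate(est), thetaO, tolerance = 1e-10)
  expect_equal(stdError(est), seO * max(1, sqrt(Qo / (J - 1))),
               tolerance = 1e-10)
  expect_error(mrIVWCorrelated(h, conditionMax = 1), "condition number")
})

test_that("the weighted median interpolates the mid-cumulative weights", {
  h <- makeHarm(c(0.1, 0.1, 0.1), rep(0.01, 3),
                c(0.1, 0.2, 0.3), rep(0.02, 3))
  est <- mrWeightedMedian(h, nBoot = 200, seed = 1)
  expect_equal(estimate(est), 2)   # equal weights, ratios 1,2,3

  # a SNP with 60% of the weight flanked by 20% below: the estimate sits on
  # its ratio whatever the upper ratios are
  for (upper in list(c(1.0, 2.0), c(0.9, 5.0))) {
    bx <- c(0.1, sqrt(3) * 0.1, 0.1 / sqrt(2), 0.1 / sqrt(2))
    sy <- rep(0.02, 4)
    ratios <- c(0.3, 0.7, upper)
    h2 <- makeHarm(bx, rep(0.01, 4), ratios * bx, sy)
    w <- (bx / sy)^2
    expect_equal(w[2] / sum(w), 0.6, tolerance = 1e-12)
    expect_equal(estimate(mrWeightedMedian(h2, nBoot = 100, seed = 1)), 0.7)
  }
})

test_that("the weighted median matches a cumulative-sum oracle, SE stable", {
  h <- randHarm(31, 10, noise = 0.03)
  est <- mrWeightedMedian(h, nBoot = 10000, seed = 99)
  theta <- h@betaY / h@betaX
  w <- (h@betaX / h@seY)^2
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord] / sum(w)
  pos <- cumsum(w) - w / 2
  i <- max(which(pos < 0.5))
  oracle <- theta[i] + (theta[i + 1] - theta[i]) *
    (0.5 - pos[i]) / (pos[i + 1] - pos[i])
  expect_equal(estimate(est), oracle, tolerance = 1e-12)

  est2 <- mrWeightedMedian(h, nBoot = 10000, seed = 1234)
  expect_equal(stdError(est), stdError(est2), tolerance = 0.1)
  # determinism at a fixed seed
  expect_equal(stdError(mrWeightedMedian(h, nBoot = 1000, seed = 99)),
               stdError(mrWeightedMedian(h, nBoot = 1000, seed = 99)))
})

test_that("weighted median and Egger refuse correlated instruments", {
  h <- randHarm(17, 5)
  h@ld <- LDMatrix(h@snps, diag(5))
  expect_error(mrWeightedMedian(h, seed = 1), "policy")
  expect_error(mrEgger(h), "policy")
  expect_error(mrWeightedMedian(makeHarm(c(.1, .2), c(.01, .01),
                                         c(.1, .1), c(.02, .02)), seed = 1),
               "at least 3")
  expect_error(mrEgger(makeHarm(c(.1, .2), c(.01, .01),
                                c(.1, .1), c(.02, .02))), "at least 3")
})

test_that("MR-Egger recovers slope and intercept; orientation-invariant", {
  # exact-fit construction: three collinear points
  bx <- c(0.1, 0.2, 0.3)
  by <- 0.05 + 0.4 * bx
  h <- makeHarm(bx, rep(0.01, 3), by, c(0.02, 0.03, 0.04))
  est <- mrEgger(h)
  expect_equal(estimate(est), 0.4, tolerance = 1e-10)
  expect_equal(est@eggerIntercept, 0.05, tolerance = 1e-10)
  expect_equal(unname(heterogeneityQ(est)["Q"]), 0, tolerance = 1e-16)

  # under a zero intercept the slope equals the IVW fixed-effect estimate
  # on a balanced (exactly proportional) fixture
  h0 <- makeHarm(c(0.1, 0.15, 0.2, 0.3), rep(0.01, 4),
                 0.25 * c(0.1, 0.15, 0.2, 0.3), rep(0.02, 4))
  expect_equal(estimate(mrEgger(h0)),
               estimate(mrIVW(h0, randomEffects = "fixed")),
               tolerance = 1e-6)

  # flipping any one SNP's alleles leaves slope and intercept unchanged
  h1 <- randHarm(41, 6, noise = 0.03)
  ref <- mrEgger(h1)
  for (j in 1:6) {
    h2 <- h1
    h2@betaX[j] <- -h2@betaX[j]
    h2@betaY[j] <- -h2@betaY[j]
    got <- mrEgger(h2)
    expect_equal(estimate(got), estimate(ref), tolerance = 1e-12)
    expect_equal(got@eggerIntercept, ref@eggerIntercept, tolerance = 1e-12)
  }

  # the t reference widens the p-values relative to normal
  expect_gte(mrEgger(h1, refDist = "t")@p, mrEgger(h1)@p)
})

test_that("Egger matches an explicit weighted-regression oracle", {
  h <- randHarm(43, 8, noise = 0.05)
  est <- mrEgger(h)
  s <- ifelse(h@betaX < 0, -1, 1)
  x <- s * h@betaX; y <- s * h@betaY
  w <- 1 / h@seY^2
  X <- cbind(1, x)
  XtWXi <- solve(t(X * w) %*% X)
  coefO <- unname(drop(XtWXi %*% (t(X * w) %*% y)))
  Qo <- sum(w * (y - X %*% coefO)^2)
  seO <- unname(sqrt(diag(XtWXi))) * max(1, sqrt(Qo / 6))
  expect_equal(estimate(est), coefO[2], tolerance = 1e-10)
  expect_equal(est@eggerIntercept, coefO[1], tolerance = 1e-10)
  expect_equal(stdError(est), seO[2], tolerance = 1e-10)
  expect_equal(est@eggerInterceptSE, seO[1], tolerance = 1e-10)
})

test_that("Steiger filtering compares variance explained and flags SNPs", {
  # r2_exposure 0.04 vs r2_outcome about 0.0005: exposure drives outcome
  h <- makeHarm(0.2, 0.0098, 0.022, 0.0098, scale = "linear")
  st <- steigerFilter(h, nExposure = 10000, nOutcome = 10000)
  expect_gt(sum(st@r2Exposure), 0.03)
  expect_lt(sum(st@r2Outcome), 0.001)
  expect_identical(st@direction, "exposure_to_outcome")
  expect_false(any(st@snpFlags))

  same <- steigerFilter(makeHarm(0.2, 0.01, 0.2, 0.01), 5000, 5000)
  expect_identical(same@direction, "inconclusive")

  expect_error(steigerFilter(h, NA, 1000), "sample sizes")
  logodds <- steigerFilter(makeHarm(0.2, 0.01, 0.05, 0.03,
                                    scale = "logodds"),
                           10000, 10000, caseFraction = 0.14)
  expect_match(logodds@note, "observed-scale")
})

test_that("Steiger declares the generative direction in most replicates", {
  # X -> Y chain with theta = 0.3: per-SNP variance explained in Y is
  # theta^2 * r2_X, so the exposure side must win
  set.seed(77)
  n <- 5000
  hits <- 0L
  for (r in 1:500) {
    bx <- rnorm(5, 0.2, 0.01 * sqrt(5000 / n))
    bxHat <- rnorm(5, bx, 1 / sqrt(n * 0.42))
    byHat <- rnorm(5, 0.3 * bx, 1 / sqrt(n * 0.42))
    h <- makeHarm(bxHat, rep(1 / sqrt(n * 0.42), 5),
                  byHat, rep(1 / sqrt(n * 0.42), 5))
    st <- steigerFilter(h, n, n)
    hits <- hits + (st@direction == "exposure_to_outcome")
  }
  expect_gte(hits / 500, 0.95)
})
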