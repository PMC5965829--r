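test_that("extinction Jacobian is the printed diagonal matrix", {
  p <- kineticParameters(0.5, 100, c(0.01, 0.02, 0.03, 0.04, 0.05))
  J <- jacobianExtinction(p)
  expect_equal(J, diag(c(1.5, 1, 1, 1, 1)))
  ev <- sort(eigen(J, only.values = TRUE)$values)
  expect_equal(ev, c(1, 1, 1, 1, 1.5))
  expect_equal(J, numericalJacobian(numeric(5), p), tolerance = 1e-7)
})

test_that("coexistence Jacobian has the printed sparsity and entries", {
  p <- baseParams()
  J <- jacobianCoexistence(p)
  M1s <- speciesAbundances(coexistenceEquilibrium(p))[1]
  K <- rateConstants(p)
  expect_equal(J[1, 1], 1 - M1s * (1 + 2 * 100 * K[1]) / (100 * 2))
  expect_equal(J[1, 3], -M1s * K[3] / 2)
  expect_equal(J[4, 3], K[3] * M1s / (1 + K[4] * M1s))
  # strict zero pattern away from row 1, the diagonal and sub-diagonal
  for (i in 2:5) for (j in 1:5)
    if (j > i || j < i - 1) expect_identical(J[i, j], 0)
  # diagonal entries of the chain rows lie in (0, 1)
  expect_true(all(diag(J)[-1] > 0 & diag(J)[-1] < 1))
})

test_that("analytic Jacobians match finite differences over random draws", {
  for (i in 1:100) {
    p <- randomParameters(seed = 5000 + i, n = sample(c(4L, 6L, 7L), 1))
    Je <- jacobianExtinction(p)
    k <- aggregationNumber(p) - 1L
    expect_lt(max(abs(Je - numericalJacobian(numeric(k), p))), 1e-6)
    Jc <- jacobianCoexistence(p)
    Jn <- numericalJacobian(coexistenceEquilibrium(p), p)
    expect_lt(max(abs(Jc - Jn) / pmax(1, abs(Jc))), 1e-6)
  }
})

test_that("numerical Jacobian recovers the Beverton-Holt derivative", {
  # one-species interpretation: d/dM of (delta+1)*gamma*M/(gamma+delta*M)
  # is (delta+1)*gamma^2/(gamma+delta*M)^2
  p <- baseParams()
  delta <- netGrowthRate(p); gamma <- carryingCapacity(p)
  f <- function(M) bevertonHoltStep(M, p)
  for (M in c(10, 100, 400)) {
    num <- (f(M + 1e-6 * max(1, M)) - f(M - 1e-6 * max(1, M))) /
      (2e-6 * max(1, M))
    expect_equal(num, (delta + 1) * gamma^2 / (gamma + delta * M)^2,
                 tolerance = 1e-6)
  }
})

test_that("Gershgorin disks are row summaries and contain the spectrum", {
  expect_equal(gershgorinDisks(diag(5)),
               data.frame(center = as.complex(rep(1, 5)),
                          radius = rep(0, 5)))
  d <- gershgorinDisks(diag(c(1.5, 1, 1, 1, 1)))
  expect_equal(Re(d$center), c(1.5, 1, 1, 1, 1))
  expect_equal(d$radius, rep(0, 5))
  expect_error(gershgorinDisks(matrix(1, 2, 3)), "square")
  set.seed(17)
  for (i in 1:1000) {
    m <- matrix(rnorm(25), 5, 5)
    d <- gershgorinDisks(m)
    ev <- eigen(m, only.values = TRUE)$values
    for (lam in ev) {
      inside <- min(Mod(lam - d$center) - d$radius)
      expect_lte(inside, 1e-12)
    }
  }
})

test_that("extinction point is classified unstable for every positive delta", {
  for (i in 1:50) {
    p <- randomParameters(seed = 6000 + i)
    rep <- classifyEquilibrium(p, "extinction")
    expect_identical(classification(rep), "unstable")
    ev <- sort(Mod(rep@eigenvalues))
    expect_equal(ev, c(rep(1, 4), netGrowthRate(p) + 1))
    expect_false(gershgorinCertified(rep))
  }
})

test_that("theorem conditions and classification behave on worked cases", {
  # sum condition and monotone K hold -> certificate and spectral stability
  p1 <- kineticParameters(10, 1, c(0.1, 0.1, 0.1, 0.1, 0.1) +
                            c(0, 1e-3, 2e-3, 3e-3, 4e-3))
  r1 <- classifyEquilibrium(p1, "coexistence")
  expect_true(r1@sumConditionHolds)
  expect_true(r1@monotoneKHolds)
  expect_true(gershgorinCertified(r1))
  expect_lt(spectralRadius(r1), 1)
  expect_identical(classification(r1), "stable")

  # baseline parameters: sum condition fails, no certificate, but the
  # eigenvalues still say stable
  r2 <- classifyEquilibrium(baseParams(), "coexistence")
  expect_false(r2@sumConditionHolds)
  expect_equal(r2@sumConditionMargin, 0.03 - 0.14)
  expect_false(gershgorinCertified(r2))
  expect_identical(classification(r2), "stable")

  # equal adjacent constants put a disk tangent to the unit circle
  p3 <- kineticParameters(10, 1, rep(0.1, 5))
  r3 <- classifyEquilibrium(p3, "coexistence")
  expect_true(r3@monotoneKHolds)
  expect_true(r3@monotoneKBoundary)
  expect_false(gershgorinCertified(r3))
})

test_that("certificate is sound: certified draws have spectral radius < 1", {
  for (i in 1:1000) {
    p <- randomParameters(seed = 7000 + i, condition = "certified_stable")
    rep <- classifyEquilibrium(p, "coexistence")
    expect_true(gershgorinCertified(rep))
    expect_lt(spectralRadius(rep), 1 + 1e-9)
    # eigenvalues inside the disk union for this Jacobian too
    d <- rep@disks
    for (lam in rep@eigenvalues)
      expect_lte(min(Mod(lam - d$center) - d$radius), 1e-12)
  }
})

test_that("the always-true intermediate inequality holds", {
  for (i in 1:500) {
    p <- randomParameters(seed = 8000 + i, n = sample(3:8, 1))
    delta <- netGrowthRate(p); gamma <- carryingCapacity(p)
    K1 <- rateConstants(p)[1]; n <- aggregationNumber(p)
    q <- delta * (delta + 2 * gamma * K1) /
      ((delta + 1) * (delta + n * gamma * K1))
    expect_lt(q, 1)
  }
})

test_that("destabilization criterion is the strict mirrored inequality", {
  p <- kineticParameters(0.01, 100, c(0.0001, 0.01, 0.01, 0.01, 0.01))
  dc <- destabilizationCriterion(p)
  expect_true(dc$met)
  expect_equal(dc$margin, 0.04 - (0.01 + 2 * 100 * 1e-4) / 100)
  # parameters satisfying the theorem strictly can never meet it
  ps <- randomParameters(seed = 99, condition = "certified_stable")
  expect_false(destabilizationCriterion(ps)$met)
  # exact boundary: criterion false with zero margin
  gamma <- 100; Ktail <- c(0.02, 0.03, 0.04, 0.05)
  K1 <- (gamma * sum(Ktail) - 1) / (2 * gamma)  # sum condition with equality
  pb <- kineticParameters(1, gamma, c(K1, Ktail))
  dcb <- destabilizationCriterion(pb)
  expect_false(dcb$met)
  expect_equal(dcb$margin, 0, tolerance = 1e-15)
})
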