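test_that("source term matches the logistic-bracket formula", {
  p <- baseParams()
  expect_identical(sourceTerm(0, 17, p), 0)
  expect_identical(sourceTerm(42, 100, p), 0)  # bracket vanishes at capacity
  expect_equal(sourceTerm(10, 20, p), 8)       # 1 * 10 * (1 - 0.2)
  expect_error(sourceTerm(-1, 0, p), "must be >= 0")
})

test_that("Beverton-Holt step has its fixed points and closed-form value", {
  p <- baseParams()
  expect_identical(bevertonHoltStep(0, p), 0)
  expect_equal(bevertonHoltStep(100, p), 100)   # carrying capacity fixed
  expect_equal(bevertonHoltStep(10, p), 2000 / 110)
})

test_that("step fixes the zero state and matches the implicit-form oracle", {
  p <- baseParams()
  z <- aggregateState(numeric(5))
  sz <- stepState(z, p)
  expect_identical(speciesAbundances(sz), numeric(5))
  expect_identical(oligomerPool(sz), 0)

  s0 <- aggregateState(c(10, 0, 0, 0, 0))
  closed <- speciesAbundances(stepState(s0, p))
  oracle <- implicitStepOracle(c(10, 0, 0, 0, 0), p)
  expect_lt(max(abs(closed - oracle) / pmax(1, abs(oracle))), 1e-10)

  # and from a generic interior state
  set.seed(7)
  M <- runif(5, 0, 50)
  closed <- speciesAbundances(stepState(aggregateState(M), p))
  oracle <- implicitStepOracle(M, p)
  expect_lt(max(abs(closed - oracle) / pmax(1, abs(oracle))), 1e-10)
})

test_that("step preserves the coexistence equilibrium", {
  p <- baseParams()
  Ms <- speciesAbundances(coexistenceEquilibrium(p))
  out <- speciesAbundances(stepState(aggregateState(Ms), p))
  expect_lt(max(abs(out - Ms) / pmax(1, abs(Ms))), 1e-10)
})

test_that("step signals dimension mismatches", {
  p <- baseParams()
  expect_error(stepState(aggregateState(c(1, 2, 3)), p), "species")
  expect_error(simulateTrajectory(p, aggregateState(c(1, 2, 3)), 5),
               "species")
})

test_that("step output stays nonnegative over randomized cases", {
  set.seed(11)
  for (i in 1:250) {
    p <- randomParameters(seed = 1000 + i,
                          n = sample(c(4L, 5L, 6L, 8L), 1))
    for (j in 1:4) {
      s <- randomState(p, scale = 3 * carryingCapacity(p))
      nx <- stepState(s, p)
      expect_true(all(speciesAbundances(nx) >= 0))
      expect_gte(oligomerPool(nx), oligomerPool(s))
    }
  }
})

test_that("closed form always zeroes the increment residuals", {
  set.seed(13)
  for (i in 1:50) {
    p <- randomParameters(seed = 2000 + i)
    s <- randomState(p)
    nx <- stepState(s, p)
    r <- incrementResiduals(s, nx, p)
    expect_lt(max(abs(r)) / max(1, max(abs(speciesAbundances(nx)))), 1e-10)
  }
})

test_that("increment residuals detect non-steps and scale with perturbation", {
  p <- baseParams()
  s <- aggregateState(c(10, 1, 1, 1, 1))
  # a constant (non-equilibrium) pair cannot satisfy the balance
  same <- aggregateState(speciesAbundances(s), t = 1L)
  expect_gt(max(abs(incrementResiduals(s, same, p))), 1e-6)
  # perturbing one component of a true step leaves a residual of that order
  nx <- stepState(s, p)
  M <- speciesAbundances(nx)
  M[3] <- M[3] + 1e-3
  pert <- aggregateState(M, O = oligomerPool(nx), t = timeIndex(nx))
  r <- incrementResiduals(s, pert, p)
  expect_gt(abs(r[3]), 1e-4)
  expect_lt(abs(r[3]), 1e-2)
  # non-consecutive time indices are rejected
  expect_error(incrementResiduals(s, aggregateState(M, t = 2L), p),
               "consecutive")
})

test_that("simulation length, consecutiveness and monotone O", {
  p <- baseParams()
  s0 <- aggregateState(c(10, 0, 0, 0, 0))
  expect_equal(length(simulateTrajectory(p, s0, 0)), 1L)
  tr <- simulateTrajectory(p, s0, 50)
  expect_equal(length(tr), 51L)
  expect_identical(timeIndex(tr), 0:50)
  expect_true(all(diff(oligomerPool(tr)) >= 0))
  # consecutive rows related by step
  M <- speciesAbundances(tr)
  mid <- stepState(aggregateState(M[10, ], t = 9L), p)
  expect_equal(M[11, ], speciesAbundances(mid))
})

test_that("no-interaction mode reduces exactly to Beverton-Holt", {
  p <- baseParams()
  s0 <- aggregateState(c(10, 1, 2, 3, 4))
  # 30 steps: long enough to pass |M1 - gamma| < 1e-6, short enough that
  # the iterates have not yet saturated at double precision
  tr <- simulateTrajectory(p, s0, 30, mode = "no_interaction")
  M1 <- speciesAbundances(tr)[, 1]
  x <- 10
  for (i in 1:30) {
    x <- bevertonHoltStep(x, p)
    expect_identical(M1[i + 1], x)
  }
  # other species and the accumulator are frozen
  expect_true(all(speciesAbundances(tr)[, 2] == 1))
  expect_true(all(oligomerPool(tr) == 0))
  # monotone approach to carrying capacity
  expect_true(all(diff(M1) > 0))
  expect_lt(abs(M1[31] - 100), 1e-6)
  # growth ratio decreases from delta + 1 toward 1
  ratio <- M1[-1] / M1[-31]
  expect_true(all(diff(ratio) < 0))
  expect_lt(ratio[1], netGrowthRate(p) + 1)
  expect_gt(ratio[30], 1)
})

test_that("long-run trajectory converges to the coexistence equilibrium", {
  p <- baseParams()
  tr <- simulateTrajectory(p, aggregateState(c(10, 0, 0, 0, 0)), 200)
  Ms <- speciesAbundances(coexistenceEquilibrium(p))
  fin <- speciesAbundances(finalState(tr))
  expect_lt(max(abs(fin - Ms) / pmax(1, abs(Ms))), 1e-6)
})

test_that("mass audit exposes the scheme's booking drift", {
  p <- baseParams()
  tr <- simulateTrajectory(p, aggregateState(c(10, 0, 0, 0, 0)), 50)
  audit <- massAudit(tr)
  expect_equal(nrow(audit), 51L)
  # mixed time indexing means the drift is genuinely nonzero...
  expect_gt(max(abs(audit$drift)), 1e-6)
  # ...but in no-interaction mode nothing is lost at all
  tr0 <- simulateTrajectory(p, aggregateState(c(10, 0, 0, 0, 0)), 50,
                            mode = "no_interaction")
  expect_true(all(abs(massAudit(tr0)$drift) < 1e-9))
})

test_that("parameter and state validity is enforced", {
  expect_error(kineticParameters(0, 100, rep(0.01, 5)), "delta")
  expect_error(kineticParameters(1, -1, rep(0.01, 5)), "gamma")
  expect_error(kineticParameters(1, 100, c(0.01, -0.02, 0.03, 0.04, 0.05)),
               "K")
  expect_error(kineticParameters(1, 100, 0.01, n = 2), "n")
  expect_error(kineticParameters(1, 100, rep(0.01, 3), n = 6), "length")
  expect_error(aggregateState(c(-1, 0)), "M")
  expect_error(aggregateState(c(1, 0), O = -2), "O")
})
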