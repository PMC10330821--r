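test_that("Nernst potential reproduces the 150/30 mM bilayer values", {
  expect_equal(nernstPotential(-1, 150, 30), -41.2, tolerance = 0.005)
  expect_equal(nernstPotential(+1, 150, 30), +41.2, tolerance = 0.005)
  expect_equal(nernstPotential(+1, 80, 80), 0)
  expect_equal(nernstPotential(-2, 10, 10, 310), 0)
  expect_error(nernstPotential(0, 150, 30), "valence")
  expect_error(nernstPotential(-1, 0, 30), "positive")
  expect_error(nernstPotential(-1, 150, -5), "positive")
})

test_that("GHK reversal reduces to Nernst for a single permeant species and
           vanishes in symmetric solutions", {
  set.seed(11)
  for (i in 1:200) {
    z <- sample(c(-1, 1), 2, replace = TRUE)
    conc <- matrix(runif(4, 1, 300), 2)
    which1 <- sample(2, 1)
    perm <- c(0, 0); perm[which1] <- runif(1, 0.1, 10)
    cond <- recordingCondition(
      ionSpecies("A", z[1], conc[1, 1], conc[1, 2], perm[1]),
      ionSpecies("B", z[2], conc[2, 1], conc[2, 2], perm[2]),
      temperatureK = runif(1, 273, 310))
    expect_equal(ghkReversal(cond),
                 nernstPotential(z[which1], conc[which1, 1], conc[which1, 2],
                                 cond@temperatureK),
                 tolerance = 1e-12)
  }
  sym <- recordingCondition(ionSpecies("K", 1, 150, 150, 1),
                            ionSpecies("Cl", -1, 150, 150, 7))
  expect_equal(ghkReversal(sym), 0)
})

test_that("GHK reversal at P_Cl/P_K = 130 matches direct evaluation and
           swapping sides negates it", {
  expect_equal(ghkReversal(kclCondition(pCl = 130)), -40.278, tolerance = 1e-3)
  swapped <- recordingCondition(ionSpecies("K", +1, 30, 150, 1),
                                ionSpecies("Cl", -1, 30, 150, 130))
  expect_equal(ghkReversal(swapped), -ghkReversal(kclCondition(pCl = 130)))
  expect_error(ghkReversal(recordingCondition(
    ionSpecies("Ca", +2, 2, 2, 1))), "monovalent")
  expect_error(ghkReversal(kclCondition(pCl = 0, pK = 0)), "permeability")
})

test_that("permeability-ratio solver inverts the GHK relation", {
  ## round trip over randomized monovalent conditions
  set.seed(21)
  for (i in 1:100) {
    r <- 10^runif(1, -2, 2.5)
    cc <- runif(2, 5, 300)
    tmpl <- recordingCondition(
      ionSpecies("K", +1, cc[1], cc[2], 1),
      ionSpecies("Cl", -1, cc[1], cc[2], 1))
    withPerm <- tmpl
    withPerm@species$relPermeability[2] <- r
    target <- ghkReversal(withPerm)
    solved <- solvePermeabilityRatio(target, tmpl, "Cl", "K")
    expect_equal(solved, r, tolerance = 1e-6)
  }
  ## the -40.5 mV measurement implies strong anion selectivity
  expect_gt(solvePermeabilityRatio(-40.5, kclCondition(), "Cl", "K"), 100)
  ## monotone growth toward the Nernst limit
  rs <- vapply(c(-39, -40, -40.5, -41), function(e)
    solvePermeabilityRatio(e, kclCondition(), "Cl", "K"), numeric(1))
  expect_true(all(diff(rs) > 0))
  ## degenerate/out-of-range inputs
  expect_error(solvePermeabilityRatio(-45, kclCondition(), "Cl", "K"),
               "Nernst limits")
  sym <- recordingCondition(ionSpecies("K", +1, 100, 100, 1),
                            ionSpecies("Cl", -1, 100, 100, 1))
  expect_error(solvePermeabilityRatio(0, sym, "Cl", "K"))
})

test_that("GHK current shares: chloride carries nearly all current in the
           whole-cell composition, shares normalize, reversal balances", {
  fig1 <- recordingCondition(ionSpecies("Na", +1, 140, 0, 1),
                             ionSpecies("Cl", -1, 152.4, 6, 25))
  sh <- ghkCurrentShares(fig1, 80)
  expect_gt(sh$share[sh$name == "Cl"], 0.95)
  expect_equal(sum(sh$share), 1)
  expect_true(all(sh$share >= 0 & sh$share <= 1))
  ## single permeant species carries everything
  one <- recordingCondition(ionSpecies("Cl", -1, 150, 30, 1))
  expect_equal(ghkCurrentShares(one, 25)$share, 1)
  ## at the reversal potential per-ion currents cancel exactly
  cond <- kclCondition(pCl = 130)
  er <- ghkReversal(cond)
  sh0 <- ghkCurrentShares(cond, er)
  expect_equal(sum(sh0$current), 0, tolerance = 1e-9)
  expect_equal(sh0$current[1], -sh0$current[2], tolerance = 1e-9)
  ## net current changes sign exactly at the reversal potential
  below <- sum(ghkCurrentShares(cond, er - 1)$current)
  above <- sum(ghkCurrentShares(cond, er + 1)$current)
  expect_lt(below * above, 0)
  expect_error(ghkCurrentShares(recordingCondition(
    ionSpecies("K", 1, 100, 10, 0)), 10), "permeant")
})

test_that("exocytosis charge-balance estimates", {
  n <- ionsInVolume(10e-6, 40e-15)
  expect_equal(n, 6.02214076e23 * 10e-6 * 40e-15)
  expect_equal(n, 2.41e5, tolerance = 0.002)
  expect_equal(ionsInVolume(0, 1e-12), 0)
  v <- diskChargingPotential(n, 2, 4)
  expect_equal(v, 0.614, tolerance = 0.001)
  expect_equal(diskChargingPotential(0, 2, 4), 0)
  expect_equal(diskChargingPotential(n, 2, 8), v / 4)
})
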