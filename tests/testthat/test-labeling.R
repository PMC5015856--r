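test_that("clinical cutoffs follow the Cmax formulas", {
  cp <- clinicalCutoffs(1.0, clampFloor = NULL)
  expect_equal(resistantCutoff(cp), 6 - log10(1.5))
  expect_equal(sensitiveCutoff(cp), 6 + log10(1.5))
  expect_equal(resistantCutoff(cp), 5.8239, tolerance = 1e-4)
  expect_equal(sensitiveCutoff(cp), 6.1761, tolerance = 1e-4)
  expect_error(clinicalCutoffs(0), "positive")
  expect_error(clinicalCutoffs(-2), "positive")
})

test_that("unclamped clinical pairs always differ by 2*log10(1.5)", {
  set.seed(31)
  for (cmax in 10^runif(20, -3, 2)) {
    cp <- clinicalCutoffs(cmax, clampFloor = NULL)
    expect_equal(sensitiveCutoff(cp) - resistantCutoff(cp), 2 * log10(1.5),
                 tolerance = 1e-9)
  }
})

test_that("the clamp floor raises each cutoff to at least 5", {
  # Cmax = 20 uM: raw cutoffs 4.523 / 4.875, both below the floor
  cp <- clinicalCutoffs(20)
  expect_equal(resistantCutoff(cp), 5)
  expect_equal(sensitiveCutoff(cp), 5)
  # Cmax = 8 uM: raw resistant 4.921 clamps, raw sensitive 5.273 does not
  cp2 <- clinicalCutoffs(8)
  expect_equal(resistantCutoff(cp2), 5)
  expect_equal(sensitiveCutoff(cp2), 6 - log10(8 / 1.5))
})

test_that("statistical cutoffs match hand arithmetic for both SD conventions", {
  ec <- c(1, 1, 3, 3)  # mean 2, sample SD 2/sqrt(3), population SD 1
  cp <- statisticalCutoffs(ec)
  expect_equal(resistantCutoff(cp), -log10((2 + 0.3 * 2 / sqrt(3)) * 1e-6))
  expect_equal(resistantCutoff(cp), 5.62960, tolerance = 1e-5)
  expect_equal(sensitiveCutoff(cp), 5.78158, tolerance = 1e-5)
  cpPop <- statisticalCutoffs(ec, sdType = "population")
  expect_equal(resistantCutoff(cpPop), -log10(2.3e-6))
  expect_equal(sensitiveCutoff(cpPop), -log10(1.7e-6))
  expect_equal(resistantCutoff(cpPop), 5.63827, tolerance = 1e-5)
  expect_equal(sensitiveCutoff(cpPop), 5.76955, tolerance = 1e-5)
})

test_that("degenerate and invalid EC50 distributions are handled", {
  cp <- statisticalCutoffs(c(1, 1, 1))  # sigma = 0
  expect_equal(resistantCutoff(cp), 6)
  expect_equal(sensitiveCutoff(cp), 6)
  # sigma > 0 implies a strict gap
  set.seed(8)
  for (i in 1:10) {
    ec <- runif(6, 0.9, 1.1)
    cp <- statisticalCutoffs(ec)
    expect_lt(resistantCutoff(cp), sensitiveCutoff(cp))
  }
  # heavily skewed EC50s: 0.3*sigma exceeds the mean, cutoff undefined
  expect_error(statisticalCutoffs(c(rep(0.001, 20), 100)), "undefined")
  expect_error(statisticalCutoffs(1), "at least 2")
})

test_that("statistical cutoffs are scale-equivariant in -log10 units", {
  ec <- c(0.5, 1, 2, 4)
  base <- statisticalCutoffs(ec)
  for (k in c(0.1, 3, 100)) {
    shifted <- statisticalCutoffs(ec * k)
    expect_equal(resistantCutoff(shifted), resistantCutoff(base) - log10(k),
                 tolerance = 1e-9)
    expect_equal(sensitiveCutoff(shifted), sensitiveCutoff(base) - log10(k),
                 tolerance = 1e-9)
  }
})

test_that("label assignment partitions samples with strict boundaries", {
  cp <- new("CutoffPair", resistant = 5.562, sensitive = 5.915,
            source = "clinical", cmaxUM = numeric(), muUM = numeric(),
            sigmaUM = numeric())
  # 0.1 uM -> score 7 -> sensitive; 10 uM -> score 5 -> resistant;
  # 2 uM -> score 5.70, inside the (5.562, 5.915) zone -> ambiguous
  lab <- assignLabels(c(a = 0.1, b = 10, c = 2), cp)
  expect_identical(as.character(lab),
                   c("sensitive", "resistant", "ambiguous"))
  # exact boundary scores are ambiguous (cutoffs built by the same
  # -log10 arithmetic the scorer uses, so equality is exact)
  cpExact <- new("CutoffPair", resistant = -log10(10 * 1e-6),
                 sensitive = -log10(0.5 * 1e-6), source = "clinical",
                 cmaxUM = numeric(), muUM = numeric(), sigmaUM = numeric())
  expect_true(all(assignLabels(c(10, 0.5), cpExact) == "ambiguous"))
  # every sample gets exactly one label
  set.seed(9)
  lab2 <- assignLabels(10^runif(200, -3, 3), cp)
  expect_false(anyNA(lab2))
  expect_equal(length(lab2), 200)
})

test_that("ambiguous cell lines are dropped with a count", {
  expr <- randomExpr(4, 6, seed = 10)
  lab <- factor(c("resistant", "ambiguous", "sensitive", "resistant",
                  "ambiguous", "sensitive"),
                levels = c("resistant", "ambiguous", "sensitive"))
  ds <- dropAmbiguous(expr, lab)
  expect_equal(ds$droppedAmbiguous, 2)
  expect_equal(ncol(ds$expr), 4)
  expect_identical(levels(ds$labels), c("resistant", "sensitive"))
})

test_that("drug retention requires both classes and is monotone in the minimum", {
  mk <- function(r, s) factor(rep(c("resistant", "sensitive"), c(r, s)),
                              levels = c("resistant", "ambiguous", "sensitive"))
  sets <- list(biased = mk(30, 0), balanced = mk(30, 30), small = mk(7, 7))
  expect_identical(filterBalancedDrugs(sets, 5), c("balanced", "small"))
  expect_identical(filterBalancedDrugs(sets, 10), "balanced")
  expect_true(all(filterBalancedDrugs(sets, 10) %in%
                    filterBalancedDrugs(sets, 5)))
})
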