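test_that("identity matrix returns the input as MDV", {
  z <- c(0.5, 0.3, 0.2)
  res <- correctFam(z, diag(3), method = "NRE")
  expect_equal(mdv(res), z, tolerance = 1e-12)
  expect_equal(residualNorm(res), 0, tolerance = 1e-12)
})

test_that("noise-free forward models are recovered to solver precision", {
  set.seed(42)
  cfg <- tracerConfig("15N", 0.99)
  C <- totalMatrixNre(glnFormula, cfg)
  for (rep in 1:20) {
    x <- stats::runif(3); x <- x / sum(x)
    z <- forwardFam(C, x)
    res <- correctFam(z, C)
    expect_equal(mdv(res), x, tolerance = 1e-10)
  }
})

test_that("correction is invariant to the scale of input and matrix", {
  cfg <- tracerConfig("15N", 0.99)
  C <- totalMatrixNre(glnFormula, cfg)
  z <- forwardFam(C, c(0.64, 0.32, 0.04))
  r1 <- correctFam(z, C)
  r2 <- correctFam(17.3 * z, C)
  expect_equal(mdv(r1), mdv(r2), tolerance = 1e-12)
  Cs <- entries(C) * 0.8
  r3 <- correctFam(z, Cs, method = "NRE")
  expect_equal(mdv(r1), mdv(r3), tolerance = 1e-10)
  expect_equal(enrichment(r1), enrichment(r3), tolerance = 1e-10)
})

test_that("enrichment is the Nt-normalized weighted channel sum", {
  expect_equal(enrichment(c(0.64, 0.32, 0.04), nTracer = 2), 0.20)
  expect_equal(enrichment(c(1, 0, 0, 0)), 0)
  expect_equal(enrichment(c(0, 0, 0, 1)), 1)
  # un-normalized option returns the bare weighted sum
  expect_equal(enrichment(c(0.64, 0.32, 0.04), nTracer = 2,
                          normalized = FALSE), 0.40)
  expect_error(enrichment(0.5, nTracer = 0), "positive")
})

test_that("degenerate inputs are rejected", {
  expect_error(correctFam(c(0, 0, 0), diag(3)), "all-zero")
  expect_error(correctFam(c(0.2, 0.2, 0.2, 0.4), diag(3)), "refusing")
  expect_error(correctFam(c(-0.1, 1.1), diag(2)), "non-negative")
  # short inputs are zero-padded
  res <- correctFam(c(1), diag(3), method = "FAM")
  expect_equal(mdv(res), c(1, 0, 0))
})

test_that("an ill-conditioned matrix warns but still returns", {
  C <- diag(3); C[1, 1] <- 1e-12
  expect_warning(res <- correctFam(c(0.5, 0.3, 0.2), C, method = "NRE"),
                 "ill-conditioned")
  expect_s4_class(res, "CorrectionResult")
})

test_that("simulated glutamine is recovered at the stated enrichment", {
  cfg <- tracerConfig("15N", 0.99)
  z <- simulateFam(glnFormula, cfg, spec140k, e = 0.2)
  res <- correctFam(z, totalMatrixMdt(glnFormula, cfg, spec140k))
  expect_equal(enrichment(res), 0.200, tolerance = 1e-2)
  expect_equal(mdv(res), labelingMixture(2, 0.2), tolerance = 1e-8)
})

test_that("batch correction orders methods as expected and never aborts", {
  cfg <- tracerConfig("15N", 0.99)
  fs <- metaboliteFormulas("15N")[c("glutamine", "serine", "glutathione")]
  study <- simulateStudy(fs, cfg, spec140k, e = 0.2)
  runs <- lapply(c("FAM", "NRE", "MDT", "ULS"), function(m)
    runCorrection(study$labeled, cfg, spec140k,
                  unlabeled = study$unlabeled, method = m))
  names(runs) <- c("FAM", "NRE", "MDT", "ULS")
  rmse <- vapply(runs, function(r)
    sqrt(mean((enrichment(r) - 0.2)^2)), numeric(1))
  expect_lt(rmse[["MDT"]], rmse[["NRE"]])
  expect_lt(rmse[["ULS"]], rmse[["NRE"]])
  expect_lt(rmse[["MDT"]], rmse[["FAM"]])
  # every MDV is a probability vector
  for (r in runs) for (res in runResults(r)) {
    expect_true(all(mdv(res) >= -1e-12))
    expect_equal(sum(mdv(res)), 1, tolerance = 1e-9)
  }
})

test_that("auto method selection uses ULS only where unlabeled data exist", {
  cfg <- tracerConfig("15N", 0.99)
  fs <- metaboliteFormulas("15N")[c("glutamine", "serine")]
  study <- simulateStudy(fs, cfg, spec140k, e = 0.2)
  # drop serine from the unlabeled table
  u <- study$unlabeled
  keep <- u@compound == "glutamine"
  u <- new("IsotopologTable", compound = u@compound[keep],
           formula = u@formula[keep], channel = u@channel[keep],
           values = u@values[keep, , drop = FALSE])
  run <- runCorrection(study$labeled, cfg, spec140k, unlabeled = u,
                       method = "auto")
  meths <- vapply(runResults(run), function(r) r@method, character(1))
  cps <- vapply(runResults(run), function(r) r@compound, character(1))
  expect_equal(unname(meths[cps == "glutamine"]), "ULS")
  expect_equal(unname(meths[cps == "serine"]), "MDT")
})

test_that("a compound with a broken formula is reported, not fatal", {
  cfg <- tracerConfig("15N", 0.99)
  tab <- new("IsotopologTable",
             compound = c("good", "good", "good", "bad", "bad"),
             formula = c(rep("C5H10N2O3", 3), rep("C2H4", 2)),
             channel = c(0:2, 0:1),
             values = matrix(c(0.9, 0.08, 0.02, 0.95, 0.05), ncol = 1,
                             dimnames = list(NULL, "s1")))
  run <- runCorrection(tab, cfg, spec140k, method = "MDT")
  expect_equal(length(runResults(run)), 1L)
  expect_equal(runErrors(run)$compound, "bad")
  expect_match(runErrors(run)$message, "tracer element")
})

test_that("ULS without an unlabeled table is a usage error", {
  cfg <- tracerConfig("15N", 0.99)
  tab <- new("IsotopologTable", compound = rep("x", 3),
             formula = rep("C5H10N2O3", 3), channel = 0:2,
             values = matrix(c(1, 0, 0), ncol = 1,
                             dimnames = list(NULL, "s1")))
  expect_error(runCorrection(tab, cfg, spec140k, method = "ULS"),
               "unlabeled")
})
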