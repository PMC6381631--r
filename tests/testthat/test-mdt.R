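test_that("resolvability limit reproduces the analyzer formulas", {
  M <- monoisotopicMass(glnFormula)
  expect_equal(minResolvableDm(M, spec100k), 2.07e-3, tolerance = 5e-3)
  # the orbitrap and fticr formulas coincide at M = MR
  expect_equal(minResolvableDm(200, resolutionSpec("orbitrap", 1e5)),
               1.66 * 200 / 1e5, tolerance = 1e-12)
  expect_equal(minResolvableDm(400, resolutionSpec("fticr", 1e5)),
               1.66 * 400 / 1e5, tolerance = 1e-12)
  # fticr decays faster with mass than orbitrap
  expect_gt(minResolvableDm(800, resolutionSpec("fticr", 1e5)),
            minResolvableDm(800, resolutionSpec("orbitrap", 1e5, MR = 400)))
})

test_that("per-atom mass differences match the tabulated isotope masses", {
  expect_equal(perAtomMassDifference("O", 17, "13C"), 8.62e-4,
               tolerance = 5e-3)
  expect_equal(abs(perAtomMassDifference("N", 15, "13C")), 6.32e-3,
               tolerance = 5e-3)
  expect_equal(perAtomMassDifference("H", 2, "13C"), 2.92e-3,
               tolerance = 5e-3)
  # +2 isotope against two tracer atoms
  expect_equal(abs(perAtomMassDifference("O", 18, "13C")), 2.46e-3,
               tolerance = 5e-3)
  expect_error(perAtomMassDifference("O", 19, "13C"), "not in")
})

test_that("correction limits floor the ratio and cap at the atom count", {
  expect_equal(correctionLimit("O", 17, glnFormula, spec100k, "13C"), 2L)
  expect_equal(correctionLimit("N", 15, glnFormula, spec100k, "13C"), 0L)
  expect_equal(correctionLimit("H", 2, glnFormula, spec100k, "13C"), 0L)
  expect_equal(correctionLimit("O", 18, glnFormula, spec100k, "13C"), 0L)
  # at negligible resolving power everything is unresolved: cap applies
  specLow <- resolutionSpec("orbitrap", 1e-6)
  expect_equal(correctionLimit("O", 17, glnFormula, specLow, "13C"), 3L)
  expect_equal(correctionLimit("H", 2, glnFormula, specLow, "13C"), 10L)
})

test_that("combined-mode enumeration admits sign-canceling combinations", {
  combos <- enumerateUnresolvedCombinations(glnFormula, "13C", 4, spec100k,
                                            mode = "combined")
  expect_true("17O2.18O1" %in% combos$label)
  i <- match("17O2.18O1", combos$label)
  expect_equal(abs(combos$netMassDifference[i]), 7.39e-4, tolerance = 5e-3)
  orig <- enumerateUnresolvedCombinations(glnFormula, "13C", 4, spec100k,
                                          mode = "original")
  expect_false("17O2.18O1" %in% orig$label)
  # every combination that distinguishes the modes cancels signs
  dmMin <- minResolvableDm(monoisotopicMass(glnFormula), spec100k)
  for (s in 1:5) {
    cmb <- enumerateUnresolvedCombinations(glnFormula, "13C", s, spec100k,
                                           "combined")
    org <- enumerateUnresolvedCombinations(glnFormula, "13C", s, spec100k,
                                           "original")
    expect_true(all(org$label %in% cmb$label), info = paste("shift", s))
    extra <- setdiff(cmb$label, org$label)
    for (lab in extra) {
      # a combination beyond the per-isotope limits can only stay
      # unresolvable by mixing isotopes of opposite-signed differences
      parts <- strsplit(lab, ".", fixed = TRUE)[[1]]
      signs <- vapply(parts, function(p) {
        m <- regmatches(p, regexec("^([0-9]+)([A-Za-z]+)[0-9]+$", p))[[1]]
        sign(perAtomMassDifference(m[3], as.integer(m[2]), "13C"))
      }, numeric(1))
      expect_true(all(c(-1, 1) %in% signs) ||
                    any(vapply(parts, function(p)
                      grepl("^13C", p), logical(1))),
                  info = lab)
    }
  }
})

test_that("extreme resolving powers collapse the enumeration", {
  # R -> infinity: only the tracer-pure combination survives at each shift
  specHi <- resolutionSpec("orbitrap", 1e15)
  for (s in 1:3) {
    cmb <- enumerateUnresolvedCombinations(glnFormula, "13C", s, specHi,
                                           "combined")
    expect_equal(cmb$label, paste0("13C", s))
    expect_equal(cmb$netMassDifference, 0)
  }
  # off-ladder shifts under a +2 tracer have no channel
  expect_equal(nrow(enumerateUnresolvedCombinations("C3H7NO2S", "34S", 1,
                                                    spec140k)), 0)
})

test_that("MDT matrix keeps only unresolved combinations", {
  cfg <- tracerConfig("13C", 0.99)
  C_mdt <- entries(totalMatrixMdt(glnFormula, cfg, spec100k))
  C_nre <- entries(totalMatrixNre(glnFormula, cfg))
  expect_true(all(C_mdt <= C_nre + 1e-12))
  expect_true(all(colSums(C_mdt) <= colSums(C_nre) + 1e-12))
  # column 0 entries equal the summed probabilities of the enumerated
  # combinations at each shift (cross-check of the two code paths)
  for (s in 1:3) {
    cmb <- enumerateUnresolvedCombinations(glnFormula, "13C", s, spec100k,
                                           "combined")
    beta0 <- tracerConfig("13C", 1)
    C0 <- entries(totalMatrixMdt(glnFormula, beta0, spec100k))
    expect_equal(C0[s + 1, 1], sum(cmb$probability), tolerance = 1e-9,
                 info = paste("shift", s))
  }
})

test_that("MDT matrix entries are non-increasing in resolving power", {
  cfg <- tracerConfig("13C", 0.99)
  Rs <- c(1e3, 3e4, 1e5, 5e5, 1e7)
  mats <- lapply(Rs, function(R)
    entries(totalMatrixMdt(glnFormula, cfg, resolutionSpec("orbitrap", R))))
  for (i in seq_along(Rs)[-1])
    expect_true(all(mats[[i]] <= mats[[i - 1]] + 1e-12),
                info = paste("R =", Rs[i]))
})

test_that("MDT limits recover the NRE matrix and the pure-tracer matrix", {
  cfg <- tracerConfig("15N", 0.99)
  # R -> 0: nothing is resolvable, the matrix equals NRE
  expect_equal(entries(totalMatrixMdt(glnFormula, cfg,
                                      resolutionSpec("orbitrap", 1e-6))),
               entries(totalMatrixNre(glnFormula, cfg)), tolerance = 1e-12)
  # R -> infinity: everything but the tracer ladder is resolved, leaving
  # the all-light probability of the non-tracer elements as a scalar factor
  specHi <- resolutionSpec("orbitrap", 1e15)
  u0 <- elementPattern("C", 5, 0) * elementPattern("H", 10, 0) *
    elementPattern("O", 3, 0)
  expect_equal(entries(totalMatrixMdt(glnFormula, cfg, specHi)),
               u0 * entries(buildTracerMatrix("15N", 2)) %*%
                 entries(buildImpurityMatrix(2, 0.01)), tolerance = 1e-12)
  # single-isotope non-tracer elements: MDT equals C2 C3 at any R
  cfgC <- tracerConfig("13C", 0.98)
  expect_equal(entries(totalMatrixMdt("C3P2", cfgC, spec140k)),
               entries(buildTracerMatrix("13C", 3)) %*%
                 entries(buildImpurityMatrix(3, 0.02)), tolerance = 1e-12)
})

test_that("original and combined MDT matrices differ for glutamine at 100k", {
  cfg <- tracerConfig("13C", 1)
  Cc <- entries(totalMatrixMdt(glnFormula, cfg, spec100k, "combined"))
  Co <- entries(totalMatrixMdt(glnFormula, cfg, spec100k, "original"))
  expect_gt(max(abs(Cc - Co)), 0)
  # combined admits at least as much probability mass in every entry
  expect_true(all(Cc >= Co - 1e-15))
})

test_that("the labeled-mass convention is exposed as a switch", {
  M <- monoisotopicMass(glnFormula)
  limDefault <- correctionLimit("O", 17, glnFormula, spec100k, "13C")
  # with the labeled-isotopolog mass the threshold grows slightly
  expect_gte(correctionLimit("O", 17, glnFormula, spec100k, "13C",
                             useLabeledMass = TRUE), limDefault)
  cfg <- tracerConfig("13C", 1)
  dm1 <- minResolvableDm(M, spec100k)
  dm2 <- minResolvableDm(M + 5 * 1.003355, spec100k)
  expect_gt(dm2, dm1)
})
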