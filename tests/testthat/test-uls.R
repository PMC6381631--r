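test_that("deconvolution inverts a binomial factorization", {
  a <- 0.0107
  v <- deconvolveOnce(c((1 - a)^2, 2 * a * (1 - a), a^2), c(1 - a, a))
  expect_equal(as.numeric(v), c(1 - a, a, 0), tolerance = 1e-14)
  expect_equal(attr(v, "residual"), 0, tolerance = 1e-14)
  # dividing by a point mass is the identity
  v2 <- deconvolveOnce(c(0.2, 0.5, 0.3), c(1, 0))
  expect_equal(as.numeric(v2), c(0.2, 0.5, 0.3))
  expect_error(deconvolveOnce(c(1, 0), c(0, 1)), "leading")
})

test_that("deconvolving the tracer from an unlabeled pattern leaves the rest", {
  # glutamine, 15N tracer: two divisions remove the nitrogen contribution
  cfg <- tracerConfig("15N", 1)
  specLow <- resolutionSpec("orbitrap", 1e-6)
  ufam <- simulateFam(glnFormula, cfg, specLow, e = 0, normalize = FALSE)
  a <- isotopeTable("N")$abundance[2]
  v <- deconvolveOnce(deconvolveOnce(ufam, c(1 - a, a)), c(1 - a, a))
  rest <- convolve(convolve(elementPattern("C", 5, 2),
                            rev(elementPattern("H", 10, 2)),
                            type = "open")[1:3],
                   rev(elementPattern("O", 3, 2)), type = "open")[1:3]
  expect_equal(as.numeric(v), rest, tolerance = 1e-9)
})

test_that("ULS matrix from an exact NRE column recovers the NRE matrix", {
  cfg <- tracerConfig("15N", 0.99)
  na_part <- entries(buildNontracerMatrix("C", 5, 2)) %*%
    entries(buildNontracerMatrix("H", 10, 2)) %*%
    entries(buildNontracerMatrix("O", 3, 2)) %*%
    entries(buildTracerMatrix("15N", 2))
  ufam <- na_part[, 1]
  got <- entries(ulsCorrectionMatrix(ufam, 2, cfg, normalize = FALSE))
  want <- na_part %*% entries(buildImpurityMatrix(2, 0.01))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("ULS matrix equals the MDT matrix for simulated unlabeled data", {
  for (case in list(list(f = glnFormula, tr = "15N", R = 1.4e5),
                    list(f = "C10H17N3O6S", tr = "15N", R = 1.4e5),
                    list(f = "C6H12N2O4S2", tr = "34S", R = 1.4e5),
                    list(f = "C23H38N7O17P3S", tr = "13C", R = 2.8e5))) {
    cfg <- tracerConfig(case$tr, 0.99)
    spec <- resolutionSpec("orbitrap", case$R)
    f <- parseFormula(case$f)
    nt <- f[[tracerElement(cfg)]]
    ufam <- simulateFam(f, cfg, spec, e = 0, normalize = FALSE)
    got <- entries(ulsCorrectionMatrix(ufam, nt, cfg, spec = spec,
                                       mass = monoisotopicMass(f),
                                       normalize = FALSE))
    want <- entries(totalMatrixMdt(f, cfg, spec))
    expect_equal(got, want, tolerance = 1e-9,
                 info = paste(case$f, case$tr))
  }
})

test_that("a heavy-free unlabeled vector gives a near-identity ladder", {
  cfg <- tracerConfig("15N", 0.99)
  a <- isotopeTable("N")$abundance[2]
  C3 <- entries(buildImpurityMatrix(3, 0.01))
  got <- entries(ulsCorrectionMatrix(c(1, 0, 0, 0), 3, cfg))
  # dividing a point mass by the (1-a, a) ladder inflates the diagonal by
  # (1-a)^-j and leaves only O(a^2) off-diagonal residue after clamping
  na <- got %*% solve(C3)
  expect_equal(diag(na), (1 - a)^-(0:3), tolerance = 1e-4)
  expect_lt(max(abs(na - diag(diag(na)))), 1e-4)
  # the single-vector variant is exactly the impurity factor
  expect_equal(entries(naiveUlsMatrix(c(1, 0, 0, 0), 3, cfg)), C3,
               tolerance = 1e-12)
})

test_that("re-convolution of column j reproduces column 0", {
  cfg <- tracerConfig("15N", 0.99)
  ufam <- simulateFam(glnFormula, cfg, spec140k, e = 0, normalize = FALSE)
  C <- entries(ulsCorrectionMatrix(ufam, 2, tracerConfig("15N", 1),
                                   spec = spec140k,
                                   mass = monoisotopicMass(glnFormula),
                                   normalize = FALSE))
  a <- isotopeTable("N")$abundance[2]
  d <- c(1 - a, a)
  col <- C[, 3][3:3]          # un-shift column 2
  for (k in 1:2) col <- convolve(col, rev(d), type = "open")
  expect_equal(col[1:3], C[, 1], tolerance = 1e-9)
})

test_that("naive and deconvolved ULS matrices differ on the diagonal", {
  cfg <- tracerConfig("13C", 1)
  spec <- resolutionSpec("orbitrap", 2.8e5)
  f <- parseFormula("C23H38N7O17P3S")   # acetyl-CoA
  nt <- f[["C"]]
  ufam <- simulateFam(f, cfg, spec, e = 0)
  dec <- diag(entries(ulsCorrectionMatrix(ufam, nt, cfg, spec = spec,
                                          mass = monoisotopicMass(f))))
  nai <- diag(entries(naiveUlsMatrix(ufam, nt, cfg)))
  expect_gt(max(abs(dec - nai)), 1e-3)
  # division by a leading term below one raises the deconvolved diagonal
  expect_true(all(dec >= nai - 1e-12))
})

test_that("degenerate unlabeled input is rejected with advice", {
  cfg <- tracerConfig("15N", 0.99)
  expect_error(ulsCorrectionMatrix(c(0, 0, 0), 2, cfg), "MDT")
  expect_error(ulsCorrectionMatrix(c(0.2, 0.3, 0.1, 0.4), 2, cfg),
               "channels")
})

test_that("a large deconvolution residual triggers a low-signal warning", {
  # a heavy-tailed tracer ladder makes an inconsistent unlabeled vector
  # produce substantial negative mass on division
  tab <- isotopeTable()
  tab$abundance[tab$element == "C"] <- c(0.7, 0.3)
  setIsotopeTable(tab)
  on.exit(setIsotopeTable(NULL))
  cfg <- tracerConfig("13C", 1)
  ws <- capture_warnings(ulsCorrectionMatrix(c(1, 0, 0), 2, cfg,
                                             compound = "glutathione"))
  expect_true(any(grepl("glutathione", ws)))
})
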