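#' Binomial labeling mixture
#'
#' Theoretical MDV of a compound whose tracer atoms are labeled
#' independently with probability `e` (independent incorporation):
#' `x[i] = C(n, i) (1 - e)^(n - i) e^i`.
#'
#' @param nTracer Number of tracer atom positions.
#' @param e Isotopic enrichment in [0, 1].
#' @return Numeric vector of length `nTracer + 1`.
#' @export
#' @examples
#' labelingMixture(2, 0.20)  # 0.64 0.32 0.04
labelingMixture <- function(nTracer, e) {
  stopifnot(nTracer >= 0, e >= 0, e <= 1)
  stats::dbinom(0:nTracer, nTracer, e)
}

#' Simulate a measured FAM by isotope fine-structure enumeration
#'
#' Generates the theoretical measured isotopolog fractional abundances of a
#' compound at a stated enrichment, tracer purity and instrument
#' resolution.  The labeled-atom count is drawn from the binomial labeling
#' mixture; each nominally labeled atom reverts to the light isotope with
#' probability `beta = 1 - purity`; every atom not carrying the label is
#' assigned isotopes per natural abundance (non-tracer elements by exact
#' joint enumeration on a nominal-shift x mass-defect grid, unlabeled
#' tracer atoms per atom on the channel ladder).  Each fine-structure peak
#' is assigned to the isotopolog channel sharing its nominal mass when its
#' exact mass lies within the smallest resolvable mass difference of the
#' channel reference mass `M0 + i * excess(tracer)`; peaks resolvable from
#' every channel are separate observable peaks and are dropped.  Channel
#' probabilities are finally renormalized to sum 1 (measured FAM are
#' fractions of the integrated channel signals).
#'
#' @param formula Compound formula (string or atom-count vector) containing
#'   the tracer element.
#' @param config Tracer configuration ([TracerConfig-class] or label).
#' @param spec A [ResolutionSpec-class].
#' @param e Isotopic enrichment in [0, 1].
#' @param noiseSd Optional relative standard deviation of multiplicative
#'   Gaussian channel noise (truncated at 0); default 0 (noise-free).
#' @param seed Optional integer seed for the noise draw.
#' @param normalize Renormalize the channel vector to sum 1 (default
#'   `TRUE`).  With `FALSE` the vector sums to the retained-mass fraction,
#'   exposing how much signal the resolution removed.
#' @param useLabeledMass See [correctionLimit()].
#' @return Numeric vector of length `Nt + 1` over channels M+0 .. M+Nt.
#' @export
#' @examples
#' simulateFam("C5H10N2O3", tracerConfig("15N", 0.99),
#'             resolutionSpec("orbitrap", 1.4e5), e = 0.2)
simulateFam <- function(formula, config, spec, e, noiseSd = 0, seed = NULL,
                        normalize = TRUE, useLabeledMass = FALSE) {
  if (is.character(config)) config <- tracerConfig(config)
  formula <- .as_formula(formula)
  if (!config@element %in% names(formula))
    stop("tracer element '", config@element, "' absent from formula '",
         formulaString(formula), "'")
  stopifnot(e >= 0, e <= 1)
  nt <- formula[[config@element]]
  sigma <- .tracer_shift(config)
  dT <- .tracer_excess(config)
  dmMin <- minResolvableDm(.mdt_mass(formula, config, useLabeledMass), spec)
  # labeled-atom count after impurity: mixture of binomials
  xj <- labelingMixture(nt, e)
  beta <- impurity(config)
  pa <- numeric(nt + 1L)
  for (j in 0:nt)
    pa[1:(j + 1L)] <- pa[1:(j + 1L)] + xj[j + 1L] *
      stats::dbinom(0:j, j, 1 - beta)
  # joint fine structure of all non-tracer elements (exact masses)
  peaks <- .formula_peaks(formula, nt * sigma, exclude = config@element)
  # per-atom channel-ladder fine structure of one unlabeled tracer atom:
  # (channel offset, mass excess, prob) for each isotope on the ladder
  single <- .single_atom(config@element)
  tr <- single[single$shift %% sigma == 0L, , drop = FALSE]
  channels <- numeric(nt + 1L)
  for (a in 0:nt) {
    if (pa[a + 1L] == 0) next
    # unlabeled tracer atoms: (nt - a)-fold convolution of the ladder atoms
    tpk <- .peak_unit()
    rem <- nt - a
    if (rem > 0L) {
      atom <- data.frame(shift = tr$shift, mass = tr$excess,
                         prob = tr$prob)
      for (r in seq_len(rem))
        tpk <- .peak_conv(tpk, atom, (nt - a) * sigma)
    }
    all <- .peak_conv(peaks, tpk, (nt - a) * sigma)
    s <- all$shift + a * sigma           # total nominal shift
    onladder <- s %% sigma == 0L
    k <- s %/% sigma                     # candidate channel
    m <- all$mass + a * dT               # exact-mass excess over M0
    net <- m - k * dT                    # distance to channel reference
    keep <- onladder & k <= nt & .unresolved(net, dmMin)
    if (any(keep)) {
      kk <- k[keep]
      pp <- all$prob[keep] * pa[a + 1L]
      for (i in seq_along(kk))
        channels[kk[i] + 1L] <- channels[kk[i] + 1L] + pp[i]
    }
  }
  if (sum(channels) <= 0)
    stop("no fine-structure peak falls into any channel; resolution ",
         "specification is degenerate")
  if (noiseSd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    channels <- pmax(channels * (1 + rnorm(length(channels), 0, noiseSd)),
                     0)
  }
  if (normalize) channels <- channels / sum(channels)
  channels
}

#' Simulate a full labeled + unlabeled study table
#'
#' Convenience fixture generator: simulates FAM for a set of compounds at
#' one or more enrichments and returns labeled and unlabeled
#' [IsotopologTable-class]s in the package's standard layout.
#'
#' @param formulas Named character vector of formula strings (names are
#'   compound identifiers).
#' @param config,spec Tracer configuration and resolution.
#' @param e Enrichment(s); one sample column is produced per value.
#' @param noiseSd,seed Passed to [simulateFam()]; with a seed, each
#'   compound x sample cell uses a distinct deterministic sub-seed.
#' @return List with elements `labeled` and `unlabeled`.
#' @export
simulateStudy <- function(formulas, config, spec, e = 0.2, noiseSd = 0,
                          seed = NULL) {
  if (is.character(config)) config <- tracerConfig(config)
  stopifnot(length(formulas) >= 1, !is.null(names(formulas)))
  mk <- function(enr, tag) {
    rows <- list()
    for (i in seq_along(formulas)) {
      f <- .as_formula(formulas[[i]])
      nt <- f[[config@element]]
      vals <- vapply(seq_along(enr), function(s) {
        sub <- if (is.null(seed)) NULL else
          (seed + 7919L * i + 104729L * s) %% .Machine$integer.max
        simulateFam(f, config, spec, enr[s], noiseSd = noiseSd, seed = sub)
      }, numeric(nt + 1L))
      rows[[i]] <- list(compound = rep(names(formulas)[i], nt + 1L),
                        formula = rep(formulaString(f), nt + 1L),
                        channel = 0:nt,
                        values = matrix(vals, nrow = nt + 1L))
    }
    vals <- do.call(rbind, lapply(rows, `[[`, "values"))
    colnames(vals) <- paste0(tag, seq_along(enr))
    new("IsotopologTable",
        compound = unlist(lapply(rows, `[[`, "compound")),
        formula = unlist(lapply(rows, `[[`, "formula")),
        channel = unlist(lapply(rows, `[[`, "channel")),
        values = vals)
  }
  list(labeled = mk(e, "labeled_"), unlabeled = mk(0, "unlabeled_"))
}
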