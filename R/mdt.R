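# Tie tolerance: a mass difference within this of the resolvability
# threshold is treated as resolved (the criterion is "resolved if >=").
.TIE_TOL <- 1e-12

# Exact isobars (zero mass difference) can never be resolved, whatever the
# resolving power; everything else uses the strict-inequality criterion.
.unresolved <- function(net, dmMin) net == 0 | abs(net) < dmMin - .TIE_TOL

#' Smallest resolvable mass difference
#'
#' Mass-dependent peak-separation limit of the analyzer:
#' `1.66 * M^1.5 / (R * sqrt(MR))` for Orbitrap and
#' `1.66 * M^2 / (R * MR)` for FT-ICR, where `R` is the nominal resolving
#' power defined at reference m/z `MR`.  Two ions closer in mass than this
#' value coalesce into one peak.
#'
#' @param M Ion mass (Da); by convention the monoisotopic neutral mass of
#'   the unlabeled compound (see [totalMatrixMdt()]'s `useLabeledMass`).
#' @param spec A [ResolutionSpec-class].
#' @return Mass difference in Da.
#' @export
#' @examples
#' minResolvableDm(monoisotopicMass("C5H10N2O3"),
#'                 resolutionSpec("orbitrap", 1e5))  # ~2.07e-3
minResolvableDm <- function(M, spec) {
  stopifnot(is(spec, "ResolutionSpec"), all(M > 0))
  if (spec@analyzer == "orbitrap")
    1.66 * M^1.5 / (spec@R * sqrt(spec@MR))
  else
    1.66 * M^2 / (spec@R * spec@MR)
}

#' Per-atom mass difference between a heavy isotope and tracer labeling
#'
#' Signed mass difference between one heavy-isotope substitution of a
#' non-tracer element and the nominally equivalent amount of tracer
#' labeling: `excess(heavy) - (s / s_t) * excess(tracer heavy)`, where `s`
#' is the isotope's nominal shift and `s_t` the tracer's.  A value of zero
#' means the species is exactly isobaric with tracer labeling.
#'
#' @param element Element symbol of the contaminating isotope.
#' @param heavyIsotope Mass number of the heavy isotope (e.g. `17` for 17O).
#' @param config Tracer configuration ([TracerConfig-class] or label).
#' @return Signed mass difference in Da.
#' @export
#' @examples
#' perAtomMassDifference("O", 17, "13C")  # ~8.62e-4
perAtomMassDifference <- function(element, heavyIsotope, config) {
  if (is.character(config)) config <- tracerConfig(config)
  tab <- isotopeTable(element)
  if (!heavyIsotope %in% tab$mass_number)
    stop("isotope ", heavyIsotope, element, " not in the isotope table")
  pr <- .principal(element)
  s <- heavyIsotope - pr$mass_number
  if (s < 1) stop("isotope ", heavyIsotope, element,
                  " has no positive nominal shift")
  excess <- tab$exact_mass[tab$mass_number == heavyIsotope] - pr$exact_mass
  excess - (s / .tracer_shift(config)) * .tracer_excess(config)
}

#' Correction limit of a heavy isotope
#'
#' Largest number of atoms of a given non-tracer heavy isotope whose summed
#' mass difference from equivalent tracer labeling stays below the smallest
#' resolvable mass difference:
#' `floor(minResolvableDm / |perAtomMassDifference|)`, capped at the
#' formula's atom count for that element.  Zero means a single substitution
#' is already resolvable and the isotope drops out of the correction.
#'
#' @param element,heavyIsotope Contaminating isotope, as in
#'   [perAtomMassDifference()].
#' @param formula Compound formula (string or atom-count vector).
#' @param spec A [ResolutionSpec-class].
#' @param config Tracer configuration.
#' @param useLabeledMass Use the tracer-labeled isotopolog mass instead of
#'   the unlabeled monoisotopic mass in the resolvability formula.  Default
#'   `FALSE` (the convention that reproduces the theory's worked values).
#' @return Integer limit.
#' @export
#' @examples
#' correctionLimit("O", 17, "C5H10N2O3",
#'                 resolutionSpec("orbitrap", 1e5), "13C")  # 2
correctionLimit <- function(element, heavyIsotope, formula, spec, config,
                            useLabeledMass = FALSE) {
  if (is.character(config)) config <- tracerConfig(config)
  formula <- .as_formula(formula)
  d <- perAtomMassDifference(element, heavyIsotope, config)
  if (abs(d) < .TIE_TOL)
    return(if (element %in% names(formula)) formula[[element]] else 0L)
  dm <- minResolvableDm(.mdt_mass(formula, config, useLabeledMass), spec)
  lim <- floor(dm / abs(d) + .TIE_TOL)
  cap <- if (element %in% names(formula)) formula[[element]] else 0L
  as.integer(min(lim, cap))
}

# Mass entering the resolvability formula.
.mdt_mass <- function(formula, config, useLabeledMass = FALSE) {
  M <- monoisotopicMass(formula)
  if (useLabeledMass)
    M <- M + formula[[config@element]] * .tracer_excess(config)
  M
}

# Heavy-isotope inventory of a formula relative to a tracer: one row per
# (element, heavy isotope) with its nominal shift, per-atom signed mass
# difference and maximum count.  The tracer's own labeling isotope is
# listed with dm = 0.
.heavy_inventory <- function(formula, config) {
  formula <- .as_formula(formula)
  sigma <- .tracer_shift(config)
  rows <- list()
  for (el in names(formula)) {
    single <- .single_atom(el)
    heavy <- single[single$shift > 0, , drop = FALSE]
    if (nrow(heavy) == 0L) next
    for (h in seq_len(nrow(heavy))) {
      rows[[length(rows) + 1L]] <- data.frame(
        element = el,
        mass_number = .principal(el)$mass_number + heavy$shift[h],
        shift = heavy$shift[h],
        excess = heavy$excess[h],
        dm = heavy$excess[h] - (heavy$shift[h] / sigma) *
          .tracer_excess(config),
        maxCount = formula[[el]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Enumerate isotope combinations unresolvable from tracer labeling
#'
#' Lists the heavy-isotope combinations of a compound whose total nominal
#' mass shift equals `shift` and which are included in the correction
#' matrix at the stated resolution.  In `mode = "original"` a combination
#' is included when every heavy isotope occurs no more often than its
#' individual [correctionLimit()] (isotopes with limit 0 are excluded
#' entirely).  In `mode = "combined"` a combination is included when the
#' absolute sum of its signed per-atom mass differences is below the
#' smallest resolvable mass difference, which admits sign-canceling
#' combinations the per-isotope limits reject.  The tracer's own labeling
#' isotope (mass difference zero) may always participate.
#'
#' @param formula Compound formula (string or atom-count vector).
#' @param config Tracer configuration ([TracerConfig-class] or label).
#' @param shift Total nominal mass shift (1 .. Nt * tracer shift); must be
#'   a multiple of the tracer's nominal shift to correspond to a measured
#'   channel.
#' @param spec A [ResolutionSpec-class].
#' @param mode `"combined"` (default) or `"original"`.
#' @param useLabeledMass See [correctionLimit()].
#' @return data.frame with one row per included combination: `label` (e.g.
#'   `"17O2.18O1"`), `nominalShift`, `netMassDifference` (Da) and
#'   `probability` (multinomial probability of the isotope assignment given
#'   the formula's atom counts).
#' @export
enumerateUnresolvedCombinations <- function(formula, config, shift, spec,
                                            mode = c("combined", "original"),
                                            useLabeledMass = FALSE) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- tracerConfig(config)
  formula <- .as_formula(formula)
  if (!config@element %in% names(formula))
    stop("tracer element '", config@element, "' absent from formula")
  sigma <- .tracer_shift(config)
  nt <- formula[[config@element]]
  shift <- as.integer(shift)
  stopifnot(shift >= 1, shift <= nt * sigma)
  empty <- data.frame(label = character(0), nominalShift = integer(0),
                      netMassDifference = numeric(0),
                      probability = numeric(0))
  if (shift %% sigma != 0L) return(empty)  # off the channel ladder
  inv <- .heavy_inventory(formula, config)
  if (!is.null(inv)) {
    # the tracer element contributes only its labeling isotope here; its
    # minor isotopes follow the per-atom channel-vector model (see
    # totalMatrixMdt) rather than combination enumeration
    inv <- inv[inv$element != config@element |
                 inv$mass_number == config@heavyMassNumber, , drop = FALSE]
  }
  if (is.null(inv) || nrow(inv) == 0L) return(empty)
  dmMin <- minResolvableDm(.mdt_mass(formula, config, useLabeledMass), spec)
  if (mode == "original") {
    lim <- integer(nrow(inv))
    for (i in seq_len(nrow(inv)))
      lim[i] <- correctionLimit(inv$element[i], inv$mass_number[i], formula,
                                spec, config, useLabeledMass)
    # the labeling isotope itself is never limited
    tracerRow <- inv$element == config@element &
      inv$mass_number == config@heavyMassNumber
    lim[tracerRow] <- inv$maxCount[tracerRow]
  } else lim <- inv$maxCount
  caps <- pmin(lim, inv$maxCount, shift %/% inv$shift)
  grid <- expand.grid(lapply(caps, function(k) 0:k))
  tot <- as.integer(as.matrix(grid) %*% inv$shift)
  keep <- tot == shift
  # respect per-element atom counts across isotopes of the same element
  for (el in unique(inv$element)) {
    cols <- which(inv$element == el)
    keep <- keep & rowSums(grid[, cols, drop = FALSE]) <= inv$maxCount[cols[1]]
  }
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L) return(empty)
  net <- as.numeric(as.matrix(grid) %*% inv$dm)
  included <- if (mode == "combined") .unresolved(net, dmMin) else
    rep(TRUE, nrow(grid))
  grid <- grid[included, , drop = FALSE]
  net <- net[included]
  if (nrow(grid) == 0L) return(empty)
  lab <- apply(grid, 1L, function(cnt) {
    nz <- which(cnt > 0)
    paste0(inv$mass_number[nz], inv$element[nz], cnt[nz], collapse = ".")
  })
  prob <- vapply(seq_len(nrow(grid)), function(i) {
    p <- 1
    for (el in unique(inv$element)) {
      cols <- which(inv$element == el)
      single <- .single_atom(el)
      pr0 <- single$prob[single$shift == 0]
      cnts <- as.integer(grid[i, cols])
      nat <- mapply(function(mn) {
        tab <- isotopeTable(el)
        tab$abundance[tab$mass_number == mn]
      }, inv$mass_number[cols])
      nAt <- inv$maxCount[cols[1]]
      rest <- nAt - sum(cnts)
      p <- p * exp(lgamma(nAt + 1) - sum(lgamma(cnts + 1)) -
                     lgamma(rest + 1) + sum(cnts * log(nat)) +
                     rest * log(pr0))
    }
    p
  }, numeric(1))
  out <- data.frame(label = lab, nominalShift = shift,
                    netMassDifference = net, probability = prob,
                    stringsAsFactors = FALSE)
  out[order(-out$probability), , drop = FALSE]
}

# Channel-mapped, resolvability-pruned distribution of the NON-tracer
# elements ("combined" mode: peaks kept when the summed mass difference
# from the channel reference is unresolvable).  Returns a vector over
# channel offsets 0..nt.
.nontracer_channel_dist <- function(formula, config, spec, mode,
                                    dmMin, prune = TRUE) {
  sigma <- .tracer_shift(config)
  nt <- formula[[config@element]]
  dT <- .tracer_excess(config)
  out <- numeric(nt + 1L)
  if (mode == "original") {
    # capped shift-only convolution: per-isotope counts bounded by their
    # correction limits; no combined-mass test
    pat <- numeric(nt * sigma + 1L); pat[1L] <- 1
    for (el in setdiff(names(formula), config@element)) {
      elpat <- .capped_element_pattern(el, formula[[el]], nt * sigma,
                                       formula, config, spec)
      pat <- .conv_trunc(pat, elpat, nt * sigma + 1L)
      length(pat) <- nt * sigma + 1L
      pat[is.na(pat)] <- 0
    }
    idx <- seq(1L, by = sigma, length.out = nt + 1L)
    out <- pat[idx]
    out[is.na(out)] <- 0
  } else {
    peaks <- .formula_peaks(formula, nt * sigma,
                            exclude = config@element)
    onladder <- peaks$shift %% sigma == 0L
    peaks <- peaks[onladder, , drop = FALSE]
    k <- peaks$shift %/% sigma
    net <- peaks$mass - k * dT
    keep <- if (prune) .unresolved(net, dmMin) else rep(TRUE, nrow(peaks))
    peaks <- peaks[keep & k <= nt, , drop = FALSE]
    k <- k[keep & k <= nt]
    for (i in seq_along(k))
      out[k[i] + 1L] <- out[k[i] + 1L] + peaks$prob[i]
  }
  out
}

# Shift-only pattern of one element with each heavy isotope's count capped
# at its correction limit (isotopes with limit 0 excluded) — original-MDT
# semantics.
.capped_element_pattern <- function(element, nAtoms, maxShift, formula,
                                    config, spec) {
  single <- .single_atom(element)
  heavy <- single[single$shift > 0, , drop = FALSE]
  p0 <- single$prob[single$shift == 0]
  out <- numeric(maxShift + 1L)
  if (nrow(heavy) == 0L) { out[1L] <- p0^nAtoms; return(out) }
  lims <- vapply(seq_len(nrow(heavy)), function(h)
    correctionLimit(element, .principal(element)$mass_number +
                      heavy$shift[h], formula, spec, config),
    integer(1))
  caps <- pmin(lims, nAtoms, maxShift %/% heavy$shift)
  grid <- expand.grid(lapply(caps, function(k) 0:k))
  tshift <- as.integer(as.matrix(grid) %*% heavy$shift)
  tot <- rowSums(grid)
  keep <- tshift <= maxShift & tot <= nAtoms
  grid <- grid[keep, , drop = FALSE]
  tshift <- tshift[keep]; tot <- tot[keep]
  lp0 <- if (p0 > 0) log(p0) else -Inf
  lg <- lgamma(nAtoms + 1) - lgamma(nAtoms - tot + 1) + (nAtoms - tot) * lp0
  for (h in seq_len(nrow(heavy)))
    lg <- lg - lgamma(grid[[h]] + 1) +
      grid[[h]] * ifelse(heavy$prob[h] > 0, log(heavy$prob[h]), -Inf)
  prob <- exp(lg); prob[!is.finite(prob)] <- 0
  for (i in seq_along(tshift))
    out[tshift[i] + 1L] <- out[tshift[i] + 1L] + prob[i]
  out
}

# Resolvability-pruned single-atom channel vector of the tracer element:
# each unlabeled tracer atom contributes its channel-mapped single-atom
# abundance vector, a minor isotope being retained only when its own mass
# difference from equivalent labeling is unresolvable.  Off-ladder isotopes
# (odd shifts under a +2 tracer) are dropped.  Length nt + 1.
.tracer_atom_vector <- function(config, nt, dmMin = Inf) {
  sigma <- .tracer_shift(config)
  dT <- .tracer_excess(config)
  single <- .single_atom(config@element)
  out <- numeric(nt + 1L)
  for (i in seq_len(nrow(single))) {
    s <- single$shift[i]
    if (s %% sigma != 0L) next
    k <- s %/% sigma
    if (k > nt) next
    net <- single$excess[i] - k * dT
    if (.unresolved(net, dmMin))
      out[k + 1L] <- out[k + 1L] + single$prob[i]
  }
  out
}

#' Total MDT correction matrix
#'
#' Resolution-dependent correction matrix built by mass difference theory:
#' the natural-abundance part keeps only isotope combinations that are
#' unresolvable from tracer labeling at the stated resolution (resolved
#' probability mass is excluded, not redistributed), and is then multiplied
#' by the impurity factor.  Non-tracer elements are pruned by the summed
#' signed mass difference of each combination (`mode = "combined"`) or by
#' per-isotope correction limits (`mode = "original"`); unlabeled tracer
#' atoms contribute their channel-mapped single-atom abundance vector with
#' per-atom pruning of minor isotopes.
#'
#' @param formula Compound formula (string or atom-count vector); must
#'   contain the tracer element.
#' @param config Tracer configuration ([TracerConfig-class] or label).
#' @param spec A [ResolutionSpec-class].
#' @param mode `"combined"` (default) or `"original"`.
#' @param useLabeledMass See [correctionLimit()].
#' @return A [CorrectionMatrix-class] with role `"total"`, method `"MDT"`.
#' @export
#' @examples
#' totalMatrixMdt("C5H10N2O3", tracerConfig("13C", 0.99),
#'                resolutionSpec("orbitrap", 1e5))
totalMatrixMdt <- function(formula, config, spec,
                           mode = c("combined", "original"),
                           useLabeledMass = FALSE) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- tracerConfig(config)
  formula <- .as_formula(formula)
  if (!config@element %in% names(formula))
    stop("tracer element '", config@element, "' absent from formula '",
         formulaString(formula), "'")
  nt <- formula[[config@element]]
  dmMin <- minResolvableDm(.mdt_mass(formula, config, useLabeledMass), spec)
  u <- .nontracer_channel_dist(formula, config, spec, mode, dmMin)
  d <- .tracer_atom_vector(config, nt, dmMin)
  n <- nt + 1L
  na <- matrix(0, n, n)
  for (j in 0:nt) {
    col <- u
    if (nt - j > 0L) {
      for (r in seq_len(nt - j)) {
        col <- .conv_trunc(col, d, n)
        length(col) <- n; col[is.na(col)] <- 0
      }
    }
    na[(j + 1L):n, j + 1L] <- col[seq_len(n - j)]
  }
  total <- na %*% entries(buildImpurityMatrix(nt, impurity(config)))
  .cm(total, "total", "MDT")
}
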