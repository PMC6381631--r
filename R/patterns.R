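# Discrete convolution of two shift-indexed probability vectors (index 0
# at position 1), truncated at maxLen entries.
.conv_trunc <- function(a, b, maxLen) {
  na <- length(a); nb <- length(b)
  out <- numeric(min(na + nb - 1L, maxLen))
  for (i in seq_len(na)) {
    if (a[i] == 0) next
    jmax <- min(nb, maxLen - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Isotope pattern of n atoms of one element
#'
#' Probability of a total nominal mass shift s (0, 1, ..., `maxShift`) for
#' `nAtoms` atoms of `element`, obtained by convolving the single-atom shift
#' distribution `nAtoms` times.  Each isotope contributes a shift equal to
#' its mass number minus the principal (most abundant) isotope's mass
#' number.  Truncation only removes probability mass beyond `maxShift`;
#' nothing is renormalized, so the untruncated pattern sums to 1.
#'
#' @param element Element symbol present in the isotope table.
#' @param nAtoms Number of atoms (>= 0; 0 gives a point mass at shift 0).
#' @param maxShift Largest shift retained.
#' @return Numeric vector of length `maxShift + 1`; element `s + 1` is the
#'   probability of shift `s`.
#' @export
#' @examples
#' elementPattern("C", 2, 2)  # (1-a)^2, 2a(1-a), a^2 with a = 13C abundance
elementPattern <- function(element, nAtoms, maxShift) {
  stopifnot(nAtoms >= 0, maxShift >= 0)
  single <- .single_atom(element)   # errors if element unknown
  base <- numeric(maxShift + 1L)
  keep <- single$shift <= maxShift
  base[single$shift[keep] + 1L] <- single$prob[keep]
  out <- numeric(maxShift + 1L); out[1L] <- 1
  n <- as.integer(nAtoms)
  # binary exponentiation of the single-atom polynomial
  sq <- base
  while (n > 0L) {
    if (n %% 2L == 1L) {
      out <- .conv_trunc(out, sq, maxShift + 1L)
      length(out) <- maxShift + 1L
      out[is.na(out)] <- 0
    }
    n <- n %/% 2L
    if (n > 0L) {
      sq <- .conv_trunc(sq, sq, maxShift + 1L)
      length(sq) <- maxShift + 1L
      sq[is.na(sq)] <- 0
    }
  }
  out
}

## ---- fine-structure peak grids ------------------------------------------
## A "peak set" is a data.frame(shift = integer nominal shift, mass = summed
## exact-mass excess over the all-principal species, prob).  Peaks with the
## same shift and mass within mergeTol are merged; merging never changes any
## downstream decision because resolvability depends on mass only.

.peak_unit <- function() data.frame(shift = 0L, mass = 0, prob = 1)

.peak_merge <- function(p, mergeTol = 1e-9, pruneTol = 0) {
  if (nrow(p) <= 1L) return(p)
  key <- paste(p$shift, round(p$mass / mergeTol))
  shift <- tapply(p$shift, key, `[`, 1L)
  mass <- tapply(p$mass, key, `[`, 1L)
  prob <- tapply(p$prob, key, sum)
  out <- data.frame(shift = as.integer(shift), mass = as.numeric(mass),
                    prob = as.numeric(prob))
  if (pruneTol > 0) out <- out[out$prob > pruneTol, , drop = FALSE]
  out[order(out$shift, out$mass), , drop = FALSE]
}

.peak_conv <- function(a, b, maxShift, mergeTol = 1e-9, pruneTol = 1e-18) {
  ia <- rep(seq_len(nrow(a)), times = nrow(b))
  ib <- rep(seq_len(nrow(b)), each = nrow(a))
  out <- data.frame(shift = a$shift[ia] + b$shift[ib],
                    mass = a$mass[ia] + b$mass[ib],
                    prob = a$prob[ia] * b$prob[ib])
  out <- out[out$shift <= maxShift, , drop = FALSE]
  .peak_merge(out, mergeTol, pruneTol)
}

# Fine-structure peak set for nAtoms atoms of one element, exact multinomial
# over isotope count vectors, truncated at maxShift total shift.
.element_peaks <- function(element, nAtoms, maxShift,
                           mergeTol = 1e-9, pruneTol = 1e-18) {
  single <- .single_atom(element)
  nAtoms <- as.integer(nAtoms)
  if (nAtoms == 0L) return(.peak_unit())
  heavy <- single[single$shift > 0, , drop = FALSE]
  p0 <- single$prob[single$shift == 0]
  if (nrow(heavy) == 0L)
    return(data.frame(shift = 0L, mass = 0, prob = p0^nAtoms))
  # enumerate heavy-isotope count vectors with total shift <= maxShift
  counts <- list(0L)
  for (h in seq_len(nrow(heavy))) {
    cmax <- min(nAtoms, maxShift %/% heavy$shift[h])
    counts[[h]] <- 0:cmax
  }
  grid <- expand.grid(counts)
  tshift <- as.integer(as.matrix(grid) %*% heavy$shift)
  tot <- rowSums(grid)
  keep <- tshift <= maxShift & tot <= nAtoms
  grid <- grid[keep, , drop = FALSE]
  tshift <- tshift[keep]; tot <- tot[keep]
  # multinomial probability of each count vector
  lp0 <- if (p0 > 0) log(p0) else -Inf
  lph <- ifelse(heavy$prob > 0, log(heavy$prob), -Inf)
  lg <- lgamma(nAtoms + 1) - lgamma(nAtoms - tot + 1) + (nAtoms - tot) * lp0
  for (h in seq_len(nrow(heavy)))
    lg <- lg - lgamma(grid[[h]] + 1) + grid[[h]] * lph[h]
  prob <- exp(lg)
  prob[!is.finite(prob)] <- 0
  mass <- as.numeric(as.matrix(grid) %*% heavy$excess)
  out <- data.frame(shift = tshift, mass = mass, prob = prob)
  .peak_merge(out, mergeTol, pruneTol)
}

# Joint fine-structure peak set of a whole formula (subset of elements),
# truncated at maxShift.
.formula_peaks <- function(formula, maxShift, exclude = character(0),
                           mergeTol = 1e-9, pruneTol = 1e-18) {
  formula <- .as_formula(formula)
  els <- setdiff(names(formula), exclude)
  out <- .peak_unit()
  for (el in els)
    out <- .peak_conv(out, .element_peaks(el, formula[[el]], maxShift,
                                          mergeTol, pruneTol),
                      maxShift, mergeTol, pruneTol)
  out
}
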