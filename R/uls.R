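#' Deconvolve one tracer atom from an abundance column
#'
#' Polynomial long division: returns the vector `v` (same length as
#' `column`) such that `v` convolved with `divisor` reproduces `column` up
#' to the truncation tail.  Neighboring columns of the natural-abundance
#' correction matrix differ by exactly one convolution of the tracer
#' element's single-atom abundance vector, so repeated division walks the
#' matrix columns.
#'
#' @param column Numeric vector (channel 0 first).
#' @param divisor Single-atom abundance vector on the channel ladder;
#'   `divisor[1]` must be positive.
#' @return Numeric vector with attribute `"residual"` (L2 norm of
#'   `column - v * divisor` over the retained channels; 0 for exact
#'   division).
#' @export
#' @examples
#' a <- 0.0107
#' deconvolveOnce(c((1 - a)^2, 2 * a * (1 - a), a^2), c(1 - a, a))
deconvolveOnce <- function(column, divisor) {
  stopifnot(is.numeric(column), is.numeric(divisor), length(divisor) >= 1)
  if (divisor[1] <= 0)
    stop("leading coefficient of the divisor must be positive")
  n <- length(column)
  v <- numeric(n)
  for (k in seq_len(n)) {
    acc <- column[k]
    jmax <- min(k - 1L, length(divisor) - 1L)
    if (jmax >= 1L)
      acc <- acc - sum(divisor[1L + seq_len(jmax)] * v[k - seq_len(jmax)])
    v[k] <- acc / divisor[1]
  }
  recon <- .conv_trunc(v, divisor, n)
  length(recon) <- n; recon[is.na(recon)] <- 0
  attr(v, "residual") <- sqrt(sum((column - recon)^2))
  v
}

# Divisor used by the ULS ladder: the tracer element's single-atom
# abundance vector on the channel ladder.  With a ResolutionSpec and a
# compound mass, minor tracer isotopes are pruned per atom exactly as in
# the MDT construction; otherwise the full natural vector is used.
.uls_divisor <- function(config, nt, spec = NULL, mass = NULL) {
  dmMin <- if (!is.null(spec) && !is.null(mass))
    minResolvableDm(mass, spec) else Inf
  d <- .tracer_atom_vector(config, nt, dmMin)
  # keep only the leading channels that can be non-zero for one atom
  d[seq_len(min(length(d), max(which(d > 0))))]
}

#' Semi-empirical (ULS) correction matrix from an unlabeled sample
#'
#' The measured FAM of an unlabeled sample is, up to scale, the first
#' column of the natural-abundance correction matrix.  Column j is obtained
#' by deconvolving the tracer element's single-atom abundance vector j
#' times from it and shifting down j rows; negative intermediate values
#' (noise artifacts) are clamped to zero after each pass and columns are
#' not renormalized.  The result is multiplied by the impurity factor,
#' which cannot be inferred from unlabeled data and is always constructed
#' theoretically.
#'
#' @param ufam Numeric vector: measured fractional abundances of the
#'   unlabeled sample over channels M+0 .. M+Nt (shorter vectors are
#'   zero-padded).
#' @param nTracer Number of tracer atoms Nt.
#' @param config Tracer configuration ([TracerConfig-class] or label).
#' @param spec Optional [ResolutionSpec-class]; together with `mass` it
#'   prunes resolvable minor isotopes of multi-isotope tracer elements from
#'   the divisor, making the construction consistent with
#'   [totalMatrixMdt()].
#' @param mass Optional compound monoisotopic mass (Da), used with `spec`.
#' @param normalize Normalize `ufam` to sum 1 on ingest (default `TRUE`;
#'   measured FAM sum to 1 by definition).  Note the overall scale of the
#'   matrix never affects corrected MDVs or enrichments.
#' @param compound Compound name used in warnings.
#' @param residualTol Warn (naming the compound) when a deconvolution pass
#'   leaves a residual above this fraction of the column norm, which
#'   indicates an unlabeled measurement near the limit of detection.
#' @return A [CorrectionMatrix-class] with role `"total"`, method `"ULS"`.
#' @export
ulsCorrectionMatrix <- function(ufam, nTracer, config, spec = NULL,
                                mass = NULL, normalize = TRUE,
                                compound = "compound",
                                residualTol = 0.1) {
  if (is.character(config)) config <- tracerConfig(config)
  stopifnot(nTracer >= 1)
  n <- nTracer + 1L
  if (length(ufam) > n)
    stop("unlabeled FAM for '", compound, "' has ", length(ufam),
         " channels but the formula allows only ", n)
  ufam <- c(ufam, numeric(n - length(ufam)))
  if (any(ufam < 0)) stop("unlabeled FAM must be non-negative")
  if (sum(ufam) <= 0)
    stop("unlabeled FAM for '", compound,
         "' carries no signal; fall back to MDT for this compound")
  if (normalize) ufam <- ufam / sum(ufam)
  d <- .uls_divisor(config, nTracer, spec, mass)
  na <- matrix(0, n, n)
  na[, 1L] <- ufam
  col <- ufam
  for (j in seq_len(nTracer)) {
    col <- as.numeric(deconvolveOnce(col, d))
    # exact long division reconstructs the retained channels, so the
    # deconvolution artifact is the non-physical negative mass it produces
    res <- sqrt(sum(pmin(col, 0)^2))
    col <- pmax(col, 0)
    if (res > residualTol * sqrt(sum(col^2)))
      warning("ULS deconvolution residual for '", compound, "' is ",
              signif(res, 3), "; unlabeled measurement may be near the ",
              "limit of detection", call. = FALSE)
    na[(j + 1L):n, j + 1L] <- col[seq_len(n - j)]
  }
  total <- na %*% entries(buildImpurityMatrix(nTracer, impurity(config)))
  .cm(total, "total", "ULS")
}

#' Naive single-vector ULS matrix (defect comparison mode)
#'
#' Reproduces the defective construction in which every column of the
#' correction matrix is the unmodified unlabeled FAM, merely shifted down.
#' Because each column should describe one fewer tracer atom's worth of
#' natural abundance, this overweights the heavy channels and underweights
#' the diagonal; it is provided only to quantify that defect.
#'
#' @inheritParams ulsCorrectionMatrix
#' @return A [CorrectionMatrix-class] with role `"total"`, method `"ULS"`.
#' @export
naiveUlsMatrix <- function(ufam, nTracer, config, normalize = TRUE,
                           compound = "compound") {
  if (is.character(config)) config <- tracerConfig(config)
  stopifnot(nTracer >= 1)
  n <- nTracer + 1L
  if (length(ufam) > n)
    stop("unlabeled FAM for '", compound, "' has ", length(ufam),
         " channels but the formula allows only ", n)
  ufam <- c(ufam, numeric(n - length(ufam)))
  if (any(ufam < 0)) stop("unlabeled FAM must be non-negative")
  if (sum(ufam) <= 0)
    stop("unlabeled FAM for '", compound,
         "' carries no signal; fall back to MDT for this compound")
  if (normalize) ufam <- ufam / sum(ufam)
  na <- matrix(0, n, n)
  for (j in 0:nTracer)
    na[(j + 1L):n, j + 1L] <- ufam[seq_len(n - j)]
  total <- na %*% entries(buildImpurityMatrix(nTracer, impurity(config)))
  .cm(total, "total", "ULS")
}
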