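#' Non-tracer natural-abundance correction factor
#'
#' Lower-triangular Toeplitz factor for one non-tracer element Q: column
#' entries are the isotopolog natural abundances of Q's atoms, truncated to
#' `nTracer + 1` rows/columns (mass beyond the last retained channel is
#' dropped, never renormalized).  For +2 tracers the channel ladder is
#' spaced two nominal mass units apart (`channelStep = 2`) and only shifts
#' on the ladder contribute; off-ladder shifts correspond to distinct
#' nominal masses outside the measured channels.
#'
#' @param element Non-tracer element symbol.
#' @param nAtoms Number of atoms of the element (>= 1).
#' @param nTracer Number of tracer atoms Nt (>= 1); the matrix is
#'   `(nTracer+1) x (nTracer+1)`.
#' @param channelStep Nominal mass spacing of the isotopolog channels
#'   (1 for 13C/2H/15N tracers, 2 for 18O/34S).
#' @param tracer Optional tracer element symbol; passing the same element as
#'   `element` is an error (use [buildTracerMatrix()]).
#' @return A [CorrectionMatrix-class] with role `"nontracer"`.
#' @export
buildNontracerMatrix <- function(element, nAtoms, nTracer, channelStep = 1L,
                                 tracer = NULL) {
  stopifnot(nAtoms >= 1, nTracer >= 1, channelStep >= 1)
  if (!is.null(tracer) && identical(element, tracer))
    stop("element '", element, "' is the tracer element; ",
         "use buildTracerMatrix()")
  pat <- elementPattern(element, nAtoms, nTracer * channelStep)
  q <- pat[seq(1L, by = as.integer(channelStep), length.out = nTracer + 1L)]
  n <- nTracer + 1L
  m <- matrix(0, n, n)
  for (j in seq_len(n))
    m[j:n, j] <- q[seq_len(n - j + 1L)]
  .cm(m, "nontracer")
}

#' Tracer-element natural-abundance correction factor
#'
#' Column j (0-based) holds the natural-abundance shift distribution of the
#' `nTracer - j` tracer atoms not yet labeled.  For a two-isotope tracer
#' this is the binomial \eqn{p_{i,j} = C(j,i) (1-\alpha)^{j-i} \alpha^i};
#' for tracer elements with more than two stable isotopes the pattern is
#' computed by iterative convolution over all isotopes and mapped onto the
#' channel ladder (off-ladder nominal shifts are dropped).
#'
#' @param config A [TracerConfig-class] (or tracer label string).
#' @param nTracer Number of tracer atoms Nt (>= 1).
#' @param alphaOverride Optional replacement for the natural abundance of
#'   the labeling isotope (two-isotope tracers only).
#' @return A [CorrectionMatrix-class] with role `"tracer"`.
#' @export
buildTracerMatrix <- function(config, nTracer, alphaOverride = NULL) {
  if (is.character(config)) config <- tracerConfig(config)
  stopifnot(is(config, "TracerConfig"), nTracer >= 1)
  sigma <- .tracer_shift(config)
  n <- nTracer + 1L
  tab <- isotopeTable(config@element)
  m <- matrix(0, n, n)
  if (!is.null(alphaOverride)) {
    if (nrow(tab) > 2L)
      stop("alphaOverride only applies to two-isotope tracer elements")
    a <- alphaOverride
    for (j in 0:nTracer) {
      rem <- nTracer - j
      p <- stats::dbinom(0:rem, rem, a)
      m[(j + 1L):(j + rem + 1L), j + 1L] <- p
    }
  } else {
    for (j in 0:nTracer) {
      rem <- nTracer - j
      pat <- elementPattern(config@element, rem, (nTracer - j) * sigma)
      p <- pat[seq(1L, by = sigma, length.out = rem + 1L)]
      p[is.na(p)] <- 0
      m[(j + 1L):(j + rem + 1L), j + 1L] <- p
    }
  }
  .cm(m, "tracer")
}

#' Tracer isotopic-impurity correction factor
#'
#' Upper-triangular binomial factor
#' \eqn{r_{i,j} = C(j,i) \beta^{j-i} (1-\beta)^i} for `j >= i`, where
#' \eqn{\beta} is the atomic impurity of the tracer (an impure position
#' reverts to the principal light isotope, i.e. moves down one full
#' channel).  Columns sum to 1 exactly (no truncation occurs).
#'
#' @param nTracer Number of tracer atoms Nt (>= 1).
#' @param beta Impurity fraction in [0, 1).
#' @return A [CorrectionMatrix-class] with role `"impurity"`.
#' @export
#' @examples
#' buildImpurityMatrix(1, 0.01)  # [[1, 0.01], [0, 0.99]]
buildImpurityMatrix <- function(nTracer, beta) {
  stopifnot(nTracer >= 1)
  if (beta < 0 || beta >= 1) stop("beta must lie in [0, 1)")
  n <- nTracer + 1L
  m <- matrix(0, n, n)
  for (j in 0:nTracer)
    m[seq_len(j + 1L), j + 1L] <- stats::dbinom(0:j, j, 1 - beta)
  .cm(m, "impurity")
}

#' Total resolution-naive (NRE) correction matrix
#'
#' Ordered product of all non-tracer natural-abundance factors, then the
#' tracer natural-abundance factor, then the impurity factor:
#' `C = C1 C1' ... C2 C3`.  The order is fixed; each factor is built
#' directly at `(Nt+1) x (Nt+1)` (truncate-then-multiply).  This is the
#' correction used by resolution-unaware tools and serves as the baseline
#' against the resolution-dependent constructions.
#'
#' @param formula Formula string or named atom-count vector; must contain
#'   the tracer element.
#' @param config A [TracerConfig-class] (or tracer label string).
#' @return A [CorrectionMatrix-class] with role `"total"`, method `"NRE"`.
#' @export
#' @examples
#' totalMatrixNre("C5H10N2O3", tracerConfig("15N", purity = 0.99))
totalMatrixNre <- function(formula, config) {
  if (is.character(config)) config <- tracerConfig(config)
  formula <- .as_formula(formula)
  if (!config@element %in% names(formula))
    stop("tracer element '", config@element, "' absent from formula '",
         formulaString(formula), "'")
  nt <- formula[[config@element]]
  sigma <- .tracer_shift(config)
  total <- diag(nt + 1)
  for (el in setdiff(names(formula), config@element))
    total <- total %*% entries(buildNontracerMatrix(el, formula[[el]], nt,
                                                    channelStep = sigma))
  total <- total %*% entries(buildTracerMatrix(config, nt))
  total <- total %*% entries(buildImpurityMatrix(nt, impurity(config)))
  .cm(total, "total", "NRE")
}
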