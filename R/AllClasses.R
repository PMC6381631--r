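#' @import methods
NULL

.known_tracers <- c("13C" = "C", "2H" = "H", "15N" = "N",
                    "18O" = "O", "34S" = "S")

#' TracerConfig: tracer element and isotopic purity
#'
#' Describes the isotopic tracer used in the labeling experiment: the tracer
#' element, the mass number of its heavy (labeling) isotope, and the atomic
#' isotopic purity of the nutrient.  The impurity \eqn{\beta} (probability
#' that a nominally labeled position carries the light isotope) is
#' `1 - purity`; purities are reported at the atomic level.
#'
#' @slot element Tracer element symbol (e.g. `"N"`).
#' @slot heavyMassNumber Mass number of the labeling isotope (e.g. `15L`).
#' @slot purity Atomic isotopic purity in (0, 1].
#' @export
setClass("TracerConfig",
         representation(element = "character",
                        heavyMassNumber = "integer",
                        purity = "numeric"))

setValidity("TracerConfig", function(object) {
  msgs <- character(0)
  tab <- try(isotopeTable(object@element), silent = TRUE)
  if (inherits(tab, "try-error"))
    msgs <- c(msgs, paste0("tracer element '", object@element,
                           "' not in the isotope table"))
  else if (!object@heavyMassNumber %in% tab$mass_number)
    msgs <- c(msgs, paste0("isotope ", object@heavyMassNumber, object@element,
                           " not in the isotope table"))
  if (object@purity <= 0 || object@purity > 1)
    msgs <- c(msgs, "purity must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TracerConfig
#'
#' @param tracer Tracer label such as `"13C"`, `"2H"`, `"15N"`, `"18O"` or
#'   `"34S"` (mass number followed by element symbol).
#' @param purity Atomic isotopic purity of the nutrient, in (0, 1].
#'   Default 1 (pure tracer).
#' @return A [TracerConfig-class] object.
#' @export
#' @examples
#' tracerConfig("15N", purity = 0.99)
tracerConfig <- function(tracer, purity = 1) {
  stopifnot(is.character(tracer), length(tracer) == 1L)
  m <- regmatches(tracer, regexec("^([0-9]+)([A-Z][a-z]?)$", tracer))[[1]]
  if (length(m) != 3L)
    stop("cannot parse tracer label '", tracer,
         "' (expected e.g. \"13C\", \"15N\", \"34S\")")
  new("TracerConfig", element = m[3], heavyMassNumber = as.integer(m[2]),
      purity = as.numeric(purity))
}

#' @describeIn TracerConfig-class Tracer impurity beta = 1 - purity.
#' @param object A `TracerConfig`.
#' @export
setGeneric("impurity", function(object) standardGeneric("impurity"))

#' @export
setMethod("impurity", "TracerConfig", function(object) 1 - object@purity)

#' @describeIn TracerConfig-class Element symbol of the tracer.
#' @export
setGeneric("tracerElement", function(object) standardGeneric("tracerElement"))

#' @export
setMethod("tracerElement", "TracerConfig", function(object) object@element)

# Nominal mass shift of one labeled atom (1 for 13C/2H/15N, 2 for 18O/34S).
.tracer_shift <- function(config) {
  pr <- .principal(config@element)
  as.integer(config@heavyMassNumber - pr$mass_number)
}

# Exact mass excess of the labeling isotope over the principal isotope.
.tracer_excess <- function(config) {
  tab <- isotopeTable(config@element)
  pr <- .principal(config@element)
  tab$exact_mass[tab$mass_number == config@heavyMassNumber] - pr$exact_mass
}

# Natural abundance of the labeling isotope (alpha for two-isotope tracers).
.tracer_alpha <- function(config) {
  tab <- isotopeTable(config@element)
  tab$abundance[tab$mass_number == config@heavyMassNumber]
}

setMethod("show", "TracerConfig", function(object) {
  cat(sprintf("TracerConfig: %d%s tracer, atomic purity %.4g (impurity %.4g)\n",
              object@heavyMassNumber, object@element, object@purity,
              1 - object@purity))
})

#' ResolutionSpec: analyzer resolving power model
#'
#' Nominal resolving power `R` of a Fourier-transform mass analyzer, defined
#' at reference m/z `MR` (classically 200 for Orbitrap and 400 for FT-ICR).
#' Resolution decays with mass as M^1.5 (Orbitrap) or M^2 (FT-ICR).
#'
#' @slot analyzer `"orbitrap"` or `"fticr"`.
#' @slot R Nominal resolving power (dimensionless, > 0).
#' @slot MR Reference m/z where `R` is defined (Da).
#' @export
setClass("ResolutionSpec",
         representation(analyzer = "character", R = "numeric",
                        MR = "numeric"))

setValidity("ResolutionSpec", function(object) {
  msgs <- character(0)
  if (!object@analyzer %in% c("orbitrap", "fticr"))
    msgs <- c(msgs, "analyzer must be 'orbitrap' or 'fticr'")
  if (object@R <= 0) msgs <- c(msgs, "R must be > 0")
  if (object@MR <= 0) msgs <- c(msgs, "MR must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ResolutionSpec
#'
#' @param analyzer `"orbitrap"` or `"fticr"`.
#' @param R Nominal resolving power.
#' @param MR Reference m/z; defaults to 200 (orbitrap) or 400 (fticr).
#' @return A [ResolutionSpec-class] object.
#' @export
#' @examples
#' resolutionSpec("orbitrap", 1e5)
resolutionSpec <- function(analyzer = c("orbitrap", "fticr"), R,
                           MR = NULL) {
  analyzer <- match.arg(analyzer)
  if (is.null(MR)) MR <- if (analyzer == "orbitrap") 200 else 400
  new("ResolutionSpec", analyzer = analyzer, R = as.numeric(R),
      MR = as.numeric(MR))
}

setMethod("show", "ResolutionSpec", function(object) {
  cat(sprintf("ResolutionSpec: %s, R = %g at m/z %g\n", object@analyzer,
              object@R, object@MR))
})

#' CorrectionMatrix: FAM-from-MDV linear model
#'
#' Square `(Nt+1) x (Nt+1)` matrix `C` mapping a mass distribution vector
#' (MDV, labeled-atom counts 0..Nt) to measured fractional abundances (FAM)
#' via `C x' = z`.  `role` records which factor or total it is.
#'
#' @slot entries Numeric matrix.
#' @slot role One of `"nontracer"`, `"tracer"`, `"impurity"`, `"total"`.
#' @slot method Construction method for totals (`"NRE"`, `"MDT"`, `"ULS"`,
#'   or `""` for single factors).
#' @export
setClass("CorrectionMatrix",
         representation(entries = "matrix", role = "character",
                        method = "character"))

setValidity("CorrectionMatrix", function(object) {
  e <- object@entries
  msgs <- character(0)
  if (nrow(e) != ncol(e)) msgs <- c(msgs, "matrix must be square")
  if (any(e < -1e-12)) msgs <- c(msgs, "entries must be non-negative")
  if (!object@role %in% c("nontracer", "tracer", "impurity", "total"))
    msgs <- c(msgs, "invalid role")
  if (object@role %in% c("nontracer", "tracer") &&
      any(abs(e[upper.tri(e)]) > 1e-12))
    msgs <- c(msgs, "natural-abundance factors must be lower-triangular")
  if (object@role == "impurity" && any(abs(e[lower.tri(e)]) > 1e-12))
    msgs <- c(msgs, "impurity factor must be upper-triangular")
  # theoretical constructions conserve or lose mass, never create it; the
  # semi-empirical ULS matrix carries the (arbitrary) scale of the
  # normalized measurement, which downstream correction is invariant to
  if (object@method != "ULS") {
    if (any(e > 1 + 1e-9))
      msgs <- c(msgs, "entries must lie in [0, 1]")
    if (any(colSums(e) > 1 + 1e-9))
      msgs <- c(msgs,
                "column sums must not exceed 1 (truncation only removes mass)")
  }
  if (length(msgs)) msgs else TRUE
})

.cm <- function(entries, role, method = "") {
  new("CorrectionMatrix", entries = unname(entries), role = role,
      method = method)
}

#' @describeIn CorrectionMatrix-class The numeric matrix of entries.
#' @param object A `CorrectionMatrix`.
#' @export
setGeneric("entries", function(object) standardGeneric("entries"))

#' @export
setMethod("entries", "CorrectionMatrix", function(object) object@entries)

#' @describeIn CorrectionMatrix-class Role of the factor
#'   (`"nontracer"`, `"tracer"`, `"impurity"` or `"total"`).
#' @export
setGeneric("matrixRole", function(object) standardGeneric("matrixRole"))

#' @export
setMethod("matrixRole", "CorrectionMatrix", function(object) object@role)

setMethod("show", "CorrectionMatrix", function(object) {
  cat(sprintf("CorrectionMatrix (%s%s), %d x %d, column sums %.6g..%.6g\n",
              object@role,
              if (nzchar(object@method)) paste0(", ", object@method) else "",
              nrow(object@entries), ncol(object@entries),
              min(colSums(object@entries)), max(colSums(object@entries))))
  print(signif(object@entries, 6))
})

#' CorrectionResult: corrected MDV for one compound in one sample
#'
#' @slot compound Compound identifier.
#' @slot sample Sample identifier.
#' @slot mdv Normalized mass distribution vector `x` (sums to 1).
#' @slot rawSolution Non-negative raw regression solution `x'`.
#' @slot residualNorm L2 norm of the regression residual `C x' - z`.
#' @slot enrichment Isotopic enrichment in [0, 1].
#' @slot method `"FAM"`, `"NRE"`, `"MDT"` or `"ULS"`.
#' @export
setClass("CorrectionResult",
         representation(compound = "character", sample = "character",
                        mdv = "numeric", rawSolution = "numeric",
                        residualNorm = "numeric", enrichment = "numeric",
                        method = "character"))

setValidity("CorrectionResult", function(object) {
  msgs <- character(0)
  if (any(object@mdv < -1e-12))
    msgs <- c(msgs, "MDV must be non-negative")
  if (abs(sum(object@mdv) - 1) > 1e-9)
    msgs <- c(msgs, "MDV must sum to 1")
  if (object@enrichment < -1e-12 || object@enrichment > 1 + 1e-12)
    msgs <- c(msgs, "enrichment must lie in [0, 1]")
  if (!object@method %in% c("FAM", "NRE", "MDT", "ULS"))
    msgs <- c(msgs, "invalid method")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CorrectionResult-class The normalized MDV.
#' @param object A `CorrectionResult`.
#' @export
setGeneric("mdv", function(object) standardGeneric("mdv"))

#' @export
setMethod("mdv", "CorrectionResult", function(object) object@mdv)

#' @describeIn CorrectionResult-class The raw non-negative solution x'.
#' @export
setGeneric("rawSolution", function(object) standardGeneric("rawSolution"))

#' @export
setMethod("rawSolution", "CorrectionResult", function(object)
  object@rawSolution)

#' @describeIn CorrectionResult-class L2 residual of the regression.
#' @export
setGeneric("residualNorm", function(object) standardGeneric("residualNorm"))

#' @export
setMethod("residualNorm", "CorrectionResult", function(object)
  object@residualNorm)

setMethod("show", "CorrectionResult", function(object) {
  cat(sprintf("CorrectionResult [%s] %s / %s: enrichment %.4f\n",
              object@method, object@compound, object@sample,
              object@enrichment))
  cat("  MDV:", paste(sprintf("%.4f", object@mdv), collapse = " "), "\n")
})

#' IsotopologTable: per-compound isotopolog intensities or fractions
#'
#' One row per compound x isotopolog channel (M+0 ... M+N, counting labeled
#' atoms), one column per sample.  Channels per compound must be consecutive
#' from M+0 and values non-negative.
#'
#' @slot compound Character vector, one entry per row.
#' @slot formula Character vector of formula strings (`NA` when unknown).
#' @slot channel Integer vector of labeled-atom counts (0, 1, ...).
#' @slot values Numeric matrix, rows matching `compound`, columns = samples.
#' @export
setClass("IsotopologTable",
         representation(compound = "character", formula = "character",
                        channel = "integer", values = "matrix"))

setValidity("IsotopologTable", function(object) {
  msgs <- character(0)
  n <- length(object@compound)
  if (length(object@formula) != n || length(object@channel) != n ||
      nrow(object@values) != n)
    msgs <- c(msgs, "slot lengths disagree")
  if (any(object@values < 0, na.rm = TRUE))
    msgs <- c(msgs, "values must be non-negative")
  if (anyDuplicated(paste(object@compound, object@channel)))
    msgs <- c(msgs, "duplicate (compound, channel) rows")
  for (cp in unique(object@compound)) {
    ch <- sort(object@channel[object@compound == cp])
    if (!identical(ch, seq(0L, length(ch) - 1L))) {
      missing <- setdiff(seq(0L, max(ch)), ch)
      msgs <- c(msgs, paste0("compound '", cp,
                             "' has a gap in its channel ladder (missing M+",
                             paste(missing, collapse = ", M+"), ")"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn IsotopologTable-class Compound identifiers (unique, in order
#'   of first appearance).
#' @param object An `IsotopologTable`.
#' @export
setGeneric("compounds", function(object) standardGeneric("compounds"))

#' @export
setMethod("compounds", "IsotopologTable", function(object)
  unique(object@compound))

#' @describeIn IsotopologTable-class Sample names.
#' @export
setGeneric("sampleNames", function(object) standardGeneric("sampleNames"))

#' @export
setMethod("sampleNames", "IsotopologTable", function(object)
  colnames(object@values))

setMethod("show", "IsotopologTable", function(object) {
  cat(sprintf("IsotopologTable: %d compounds, %d rows, %d samples\n",
              length(unique(object@compound)), length(object@compound),
              ncol(object@values)))
})

#' CorrectionRun: batch correction results
#'
#' Collects per-compound, per-sample [CorrectionResult-class] objects plus
#' any per-compound failures (a batch never aborts on one bad compound).
#'
#' @slot results List of `CorrectionResult` objects.
#' @slot errors data.frame with columns `compound`, `message`.
#' @slot method Requested method.
#' @export
setClass("CorrectionRun",
         representation(results = "list", errors = "data.frame",
                        method = "character"))

setMethod("show", "CorrectionRun", function(object) {
  cat(sprintf("CorrectionRun (%s): %d results, %d compound errors\n",
              object@method, length(object@results), nrow(object@errors)))
  if (nrow(object@errors))
    for (i in seq_len(nrow(object@errors)))
      cat("  !", object@errors$compound[i], ":", object@errors$message[i],
          "\n")
})

#' @describeIn CorrectionRun-class Per-compound error records.
#' @param object A `CorrectionRun`.
#' @export
setGeneric("runErrors", function(object) standardGeneric("runErrors"))

#' @export
setMethod("runErrors", "CorrectionRun", function(object) object@errors)

#' @describeIn CorrectionRun-class List of CorrectionResult objects.
#' @export
setGeneric("runResults", function(object) standardGeneric("runResults"))

#' @export
setMethod("runResults", "CorrectionRun", function(object) object@results)

#' Enrichment accessor / calculator
#'
#' For a numeric MDV, computes the isotopic enrichment
#' \eqn{\sum_i i x_i / N_t}; for a [CorrectionResult-class] or
#' [CorrectionRun-class], returns the stored value(s).
#'
#' @param object MDV vector, `CorrectionResult`, or `CorrectionRun`.
#' @param ... Passed on (`nTracer`, `normalized` for the numeric method).
#' @export
setGeneric("enrichment", function(object, ...) standardGeneric("enrichment"))

#' @export
setMethod("enrichment", "CorrectionResult", function(object, ...)
  object@enrichment)

#' @export
setMethod("enrichment", "CorrectionRun", function(object, ...) {
  vapply(object@results, function(r) r@enrichment, numeric(1))
})
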