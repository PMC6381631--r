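#' Correct a measured FAM vector to an MDV
#'
#' Solves the constrained regression `C x' = z` by non-negative least
#' squares (Lawson-Hanson active set) and normalizes the solution to the
#' mass distribution vector `x = x' / |x'|_1`.  The input is renormalized
#' to sum 1 on entry (measured FAM sum to 1 by definition), so the result
#' is invariant to the scale of both `z` and `C`.
#'
#' @param z Non-negative measured abundance vector (length must match `C`;
#'   shorter vectors are zero-padded).
#' @param C A [CorrectionMatrix-class] or plain numeric matrix.
#' @param compound,sample Identifiers stored in the result.
#' @param method Method label stored in the result (defaults to the
#'   matrix's construction method).
#' @return A [CorrectionResult-class].
#' @export
#' @examples
#' C <- totalMatrixNre("C5H10N2O3", tracerConfig("15N", 0.99))
#' correctFam(c(0.6, 0.3, 0.1), C)
correctFam <- function(z, C, compound = "compound", sample = "sample",
                       method = NULL) {
  if (is(C, "CorrectionMatrix")) {
    if (is.null(method))
      method <- if (nzchar(C@method)) C@method else "NRE"
    C <- entries(C)
  } else if (is.null(method)) method <- "NRE"
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  n <- nrow(C)
  if (length(z) > n)
    stop("input for '", compound, "' has ", length(z),
         " channels but the correction matrix allows only ", n,
         "; refusing to truncate")
  z <- c(z, numeric(n - length(z)))
  if (any(z < 0)) stop("measured abundances must be non-negative")
  if (sum(z) <= 0) stop("all-zero measured vector for '", compound, "'")
  z <- z / sum(z)
  kap <- kappa(C, exact = FALSE)
  if (!is.finite(kap) || kap > 1e10)
    warning("correction matrix for '", compound,
            "' is ill-conditioned (condition estimate ", signif(kap, 3),
            "); result may be unstable", call. = FALSE)
  fit <- pracma::lsqnonneg(C, z)
  xprime <- as.numeric(fit$x)
  if (sum(xprime) <= 0)
    stop("non-negative regression returned the zero vector for '",
         compound, "'")
  x <- xprime / sum(xprime)
  new("CorrectionResult", compound = compound, sample = sample,
      mdv = x, rawSolution = xprime,
      residualNorm = sqrt(sum((C %*% xprime - z)^2)),
      enrichment = enrichment(x, nTracer = n - 1L),
      method = method)
}

#' @describeIn enrichment Enrichment of a numeric MDV:
#'   `sum(i * x[i]) / nTracer` (set `normalized = FALSE` for the bare
#'   weighted sum of labeled-atom counts).
#' @param nTracer Number of tracer atom positions Nt (> 0).
#' @param normalized Divide by `nTracer` so a fully labeled compound has
#'   enrichment 1 (default `TRUE`).
#' @export
setMethod("enrichment", "numeric", function(object, nTracer = NULL,
                                            normalized = TRUE, ...) {
  if (is.null(nTracer)) nTracer <- length(object) - 1L
  if (nTracer == 0) stop("nTracer must be positive")
  if (any(object < -1e-9)) stop("MDV must be non-negative")
  x <- object / sum(object)
  s <- sum(seq_along(x[-1]) * x[-1])
  if (normalized) s / nTracer else s
})

# FAM passthrough: measured vector taken as the MDV (uncorrected baseline).
.fam_result <- function(z, nt, compound, sample) {
  z <- c(z, numeric(nt + 1L - length(z)))
  z <- z / sum(z)
  new("CorrectionResult", compound = compound, sample = sample,
      mdv = z, rawSolution = z, residualNorm = 0,
      enrichment = enrichment(z, nTracer = nt), method = "FAM")
}

# Extract one compound's channel-ladder block from an IsotopologTable.
.table_block <- function(tab, cp) {
  idx <- which(tab@compound == cp)
  idx <- idx[order(tab@channel[idx])]
  list(values = tab@values[idx, , drop = FALSE],
       formula = tab@formula[idx[1]],
       channels = tab@channel[idx])
}

#' Run a batch correction over a sample table
#'
#' Applies the selected correction method compound by compound and sample
#' by sample.  `method = "auto"` uses ULS where the compound has unlabeled
#' data (matched by identifier, case-insensitively) and MDT otherwise.
#' Per-compound failures are collected in the returned object; a batch
#' never aborts on one bad compound.
#'
#' @param labeled [IsotopologTable-class] of labeled-sample measurements.
#' @param config Tracer configuration ([TracerConfig-class] or label).
#' @param spec [ResolutionSpec-class] (required for MDT/ULS/auto).
#' @param unlabeled Optional [IsotopologTable-class] from unlabeled samples
#'   (required for `method = "ULS"`); multiple unlabeled samples are
#'   averaged.
#' @param method `"auto"` (default), `"FAM"`, `"NRE"`, `"MDT"` or `"ULS"`.
#' @param mdtMode `"combined"` (default) or `"original"`, see
#'   [totalMatrixMdt()].
#' @return A [CorrectionRun-class].
#' @export
runCorrection <- function(labeled, config, spec = NULL, unlabeled = NULL,
                          method = c("auto", "FAM", "NRE", "MDT", "ULS"),
                          mdtMode = c("combined", "original")) {
  method <- match.arg(method)
  mdtMode <- match.arg(mdtMode)
  stopifnot(is(labeled, "IsotopologTable"))
  if (is.character(config)) config <- tracerConfig(config)
  if (method %in% c("auto", "MDT", "ULS") && is.null(spec))
    stop("method '", method, "' needs a ResolutionSpec")
  if (method == "ULS" && is.null(unlabeled))
    stop("method 'ULS' requires an unlabeled sample table")
  ukey <- if (!is.null(unlabeled))
    tolower(trimws(unique(unlabeled@compound))) else character(0)
  results <- list()
  errs <- data.frame(compound = character(0), message = character(0),
                     stringsAsFactors = FALSE)
  for (cp in compounds(labeled)) {
    blk <- .table_block(labeled, cp)
    res <- try({
      hasU <- tolower(trimws(cp)) %in% ukey
      meth <- method
      if (method == "auto") meth <- if (hasU) "ULS" else "MDT"
      if (meth == "ULS" && !hasU) {
        warning("no unlabeled data for '", cp, "'; falling back to MDT",
                call. = FALSE)
        meth <- "MDT"
      }
      needFormula <- meth != "FAM"
      formula <- NULL
      nt <- NA_integer_
      if (!is.na(blk$formula) && nzchar(blk$formula)) {
        formula <- parseFormula(blk$formula)
        if (config@element %in% names(formula))
          nt <- formula[[config@element]]
      }
      if (meth == "FAM") {
        nt0 <- if (!is.na(nt)) nt else max(blk$channels)
        lapply(seq_len(ncol(blk$values)), function(s)
          .fam_result(blk$values[, s], nt0, cp,
                      colnames(blk$values)[s]))
      } else {
        if (is.null(formula) && meth != "ULS")
          stop("compound '", cp, "' has no chemical formula")
        if (is.na(nt)) {
          if (meth == "ULS") nt <- max(blk$channels)
          else stop("tracer element '", config@element,
                    "' absent from formula of '", cp, "'")
        }
        C <- switch(meth,
          NRE = totalMatrixNre(formula, config),
          MDT = totalMatrixMdt(formula, config, spec, mode = mdtMode),
          ULS = {
            ub <- .table_block(unlabeled,
                               unique(unlabeled@compound)[
                                 match(tolower(trimws(cp)),
                                       tolower(trimws(unique(
                                         unlabeled@compound))))])
            ufam <- rowMeans(ub$values)
            mass <- if (!is.null(formula)) monoisotopicMass(formula)
                    else NULL
            ulsCorrectionMatrix(ufam, nt, config, spec = spec,
                                mass = mass, compound = cp)
          })
        lapply(seq_len(ncol(blk$values)), function(s)
          correctFam(blk$values[, s], C, compound = cp,
                     sample = colnames(blk$values)[s]))
      }
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      errs <- rbind(errs, data.frame(
        compound = cp,
        message = conditionMessage(attr(res, "condition")),
        stringsAsFactors = FALSE))
    } else results <- c(results, res)
  }
  new("CorrectionRun", results = results, errors = errs, method = method)
}

#' Tidy tables from a correction run
#'
#' @param run A [CorrectionRun-class].
#' @return `enrichmentTable`: data.frame compound x sample of enrichments.
#'   `mdvTable`: long data.frame with one row per compound, channel and
#'   sample.
#' @export
enrichmentTable <- function(run) {
  stopifnot(is(run, "CorrectionRun"))
  if (!length(run@results))
    return(data.frame(compound = character(0)))
  cps <- vapply(run@results, function(r) r@compound, character(1))
  smp <- vapply(run@results, function(r) r@sample, character(1))
  enr <- vapply(run@results, function(r) r@enrichment, numeric(1))
  out <- data.frame(compound = unique(cps), stringsAsFactors = FALSE)
  for (s in unique(smp))
    out[[s]] <- enr[match(paste(out$compound, s), paste(cps, smp))]
  out
}

#' @rdname enrichmentTable
#' @export
mdvTable <- function(run) {
  stopifnot(is(run, "CorrectionRun"))
  do.call(rbind, lapply(run@results, function(r)
    data.frame(compound = r@compound, sample = r@sample,
               channel = seq_along(r@mdv) - 1L, mdv = r@mdv,
               method = r@method, stringsAsFactors = FALSE)))
}
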