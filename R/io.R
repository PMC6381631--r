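#' Read a sample table
#'
#' Reads a CSV/TSV table with header columns `compound`, `formula`
#' (optional), `isotopolog` (labels `M+0`, `M+1`, ...; for +2 tracers the
#' label counts labeled atoms, not nominal mass units) followed by one
#' column per sample.  Channel ladders must be consecutive from M+0;
#' negative values, gaps and duplicate (compound, channel) rows are
#' rejected with the offending compound named.
#'
#' @param path File path.
#' @param dialect `"csv"` (default) or `"tsv"`; guessed from the file
#'   extension when missing.
#' @return An [IsotopologTable-class].
#' @export
readSampleTable <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
      "tsv" else "csv"
  if (!dialect %in% c("csv", "tsv"))
    stop("unknown dialect '", dialect, "' (use \"csv\" or \"tsv\")")
  sep <- if (dialect == "csv") "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  names(df)[1:min(3, ncol(df))] <- tolower(names(df)[1:min(3, ncol(df))])
  if (!"compound" %in% names(df))
    stop("malformed header in ", path, " (line 1): need a 'compound' column")
  hasFormula <- "formula" %in% names(df)
  isoCol <- intersect(c("isotopolog", "isotopologue", "channel"), names(df))
  if (!length(isoCol))
    stop("malformed header in ", path,
         " (line 1): need an 'isotopolog' column")
  lab <- as.character(df[[isoCol[1]]])
  m <- regmatches(lab, regexec("^M\\+?([0-9]+)$", lab))
  ch <- vapply(m, function(x) if (length(x) == 2L) as.integer(x[2]) else
    NA_integer_, integer(1))
  bad <- which(is.na(ch))
  if (length(bad))
    stop("unparseable isotopolog label '", lab[bad[1]], "' (row ",
         bad[1] + 1L, ") — expected M+k")
  meta <- c("compound", if (hasFormula) "formula", isoCol[1])
  sampleCols <- setdiff(names(df), meta)
  if (!length(sampleCols)) stop("no sample columns found in ", path)
  vals <- as.matrix(df[sampleCols])
  if (!is.numeric(vals)) stop("non-numeric sample values in ", path)
  new("IsotopologTable",
      compound = as.character(df$compound),
      formula = if (hasFormula) as.character(df$formula) else
        rep(NA_character_, nrow(df)),
      channel = ch, values = vals)
}

#' Write a sample table
#'
#' @param tab An [IsotopologTable-class].
#' @param path Output path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @export
writeSampleTable <- function(tab, path, dialect = "csv") {
  stopifnot(is(tab, "IsotopologTable"))
  df <- data.frame(compound = tab@compound, formula = tab@formula,
                   isotopolog = paste0("M+", tab@channel),
                   stringsAsFactors = FALSE, check.names = FALSE)
  vals <- tab@values
  for (j in seq_len(ncol(vals)))
    df[[colnames(vals)[j]]] <- .sig12(vals[, j])
  write.table(df, path, sep = if (dialect == "csv") "," else "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

.sig12 <- function(x) formatC(x, digits = 12, format = "g")

#' Write correction results
#'
#' Serializes a [CorrectionRun-class] to three output tables: corrected
#' MDVs, normalized input FAMs (the raw solutions before impurity scaling
#' are not written), and a compound x sample enrichment table.  Numbers are
#' written with 12 significant digits.
#'
#' @param run A [CorrectionRun-class].
#' @param path Output path stem; `_mdv.csv`, `_fam.csv` (omitted — only
#'   MDV and enrichment surfaces are written unless `fam` is supplied) and
#'   `_enrichment.csv` are appended.
#' @param fam Optional [IsotopologTable-class] of the (normalized) input,
#'   written alongside as `_fam.csv`.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return Character vector of the files written, invisibly.
#' @export
writeResults <- function(run, path, fam = NULL, dialect = "csv") {
  stopifnot(is(run, "CorrectionRun"))
  if (!length(run@results)) stop("no results to write")
  ext <- if (dialect == "csv") ".csv" else ".tsv"
  sep <- if (dialect == "csv") "," else "\t"
  files <- character(0)
  mdv <- mdvTable(run)
  # one row per (compound, channel), one column per sample
  key <- paste(mdv$compound, mdv$channel)
  wide <- data.frame(compound = mdv$compound[!duplicated(key)],
                     isotopolog = paste0("M+", mdv$channel[!duplicated(key)]),
                     stringsAsFactors = FALSE)
  for (s in unique(mdv$sample)) {
    sub <- mdv[mdv$sample == s, ]
    wide[[s]] <- .sig12(sub$mdv[match(paste(wide$compound,
                                            sub("M\\+", "", wide$isotopolog)),
                                      paste(sub$compound, sub$channel))])
  }
  f <- paste0(path, "_mdv", ext)
  write.table(wide, f, sep = sep, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  enr <- enrichmentTable(run)
  for (j in seq_along(enr)[-1]) enr[[j]] <- .sig12(enr[[j]])
  f <- paste0(path, "_enrichment", ext)
  write.table(enr, f, sep = sep, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  if (!is.null(fam)) {
    f <- paste0(path, "_fam", ext)
    writeSampleTable(.normalize_table(fam), f, dialect)
    files <- c(files, f)
  }
  invisible(files)
}

# Normalize each compound's channel block to sum 1 per sample.
.normalize_table <- function(tab) {
  vals <- tab@values
  for (cp in unique(tab@compound)) {
    idx <- which(tab@compound == cp)
    for (j in seq_len(ncol(vals))) {
      s <- sum(vals[idx, j])
      if (s > 0) vals[idx, j] <- vals[idx, j] / s
    }
  }
  new("IsotopologTable", compound = tab@compound, formula = tab@formula,
      channel = tab@channel, values = vals)
}

#' Built-in metabolite formula catalog
#'
#' Standard neutral chemical formulas for the small-metabolite and
#' coenzyme-A panels used in the package's validation studies: 24
#' nitrogen-containing small metabolites, 10 sulfur-containing metabolites,
#' and 4 coenzyme A species.
#'
#' @param panel `"15N"`, `"34S"`, `"CoA"`, or `"all"` (default).
#' @return Named character vector of formula strings.
#' @export
#' @examples
#' metaboliteFormulas("34S")
metaboliteFormulas <- function(panel = c("all", "15N", "34S", "CoA")) {
  panel <- match.arg(panel)
  path <- system.file("extdata", "metabolite_formulas.csv",
                      package = "isoresolve", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (panel != "all") df <- df[df$panel == panel, , drop = FALSE]
  stats::setNames(df$formula, df$compound)
}
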