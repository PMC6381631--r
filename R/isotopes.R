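#' @importFrom methods new validObject is setValidity show slot
#' @importFrom stats rnorm
#' @importFrom utils read.csv write.csv read.table
NULL

# Embedded natural isotope constants (standard reference compilation).
# One row per stable isotope: exact mass in Da, abundance as atomic fraction.
.default_isotopes <- data.frame(
  element     = c("H","H",  "C","C",  "N","N",  "O","O","O",
                  "P",      "S","S","S","S"),
  mass_number = c(1L, 2L,   12L, 13L, 14L, 15L, 16L, 17L, 18L,
                  31L,      32L, 33L, 34L, 36L),
  exact_mass  = c(1.00782503207, 2.01410177785,
                  12.0000000, 13.0033548378,
                  14.0030740048, 15.0001088982,
                  15.9949146196, 16.9991317, 17.9991610,
                  30.97376163,
                  31.97207100, 32.97145876, 33.96786690, 35.96708076),
  abundance   = c(0.999885, 0.000115,
                  0.9893, 0.0107,
                  0.99636, 0.00364,
                  0.99757, 0.00038, 0.00205,
                  1.0,
                  0.9499, 0.0075, 0.0425, 0.0001),
  stringsAsFactors = FALSE
)

.isotope_env <- new.env(parent = emptyenv())
.isotope_env$table <- .default_isotopes

.validate_isotope_table <- function(tab) {
  need <- c("element", "mass_number", "exact_mass", "abundance")
  if (!all(need %in% names(tab)))
    stop("isotope table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$exact_mass <= 0)) stop("isotope exact masses must be positive")
  if (any(tab$abundance < 0 | tab$abundance > 1))
    stop("isotope abundances must lie in [0, 1]")
  for (el in unique(tab$element)) {
    sub <- tab[tab$element == el, ]
    if (abs(sum(sub$abundance) - 1) > 1e-6)
      stop("abundances of element ", el, " sum to ", sum(sub$abundance),
           ", not 1 (tolerance 1e-6)")
    if (any(diff(sub$mass_number[order(sub$mass_number)]) <= 0) ||
        is.unsorted(sub$mass_number, strictly = TRUE))
      stop("isotopes of element ", el,
           " must be listed with strictly increasing mass numbers")
  }
  tab
}

#' Natural isotope table
#'
#' Returns the active table of stable isotopes (element symbol, mass number,
#' exact mass in Da, natural abundance as an atomic fraction).  The built-in
#' table covers H, C, N, O, P and S with standard reference values; it can be
#' replaced at run time with [setIsotopeTable()] or [readIsotopeTable()].
#'
#' @param element Optional element symbol; if given, only that element's
#'   isotopes are returned (sorted by mass number).
#' @return A `data.frame` with columns `element`, `mass_number`,
#'   `exact_mass`, `abundance`.
#' @export
#' @examples
#' isotopeTable("C")
isotopeTable <- function(element = NULL) {
  tab <- .isotope_env$table
  if (is.null(element)) return(tab)
  sub <- tab[tab$element == element, , drop = FALSE]
  if (nrow(sub) == 0L) stop("element '", element, "' not in the isotope table")
  sub[order(sub$mass_number), , drop = FALSE]
}

#' Override the isotope table
#'
#' @param tab A data.frame with columns `element`, `mass_number`,
#'   `exact_mass`, `abundance`; abundances of each element must sum to 1
#'   within 1e-6.  Pass `NULL` to restore the built-in table.
#' @return The previous table, invisibly.
#' @export
setIsotopeTable <- function(tab = NULL) {
  old <- .isotope_env$table
  if (is.null(tab)) tab <- .default_isotopes
  .isotope_env$table <- .validate_isotope_table(tab)
  invisible(old)
}

#' Read an isotope table from a plain-text config file
#'
#' Each non-comment line holds `element mass_number exact_mass abundance`
#' (whitespace separated; `#` starts a comment).
#'
#' @param path File path.
#' @param activate If `TRUE` (default) the table replaces the active one.
#' @return The parsed table (invisibly when activated).
#' @export
readIsotopeTable <- function(path, activate = TRUE) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("element", "mass_number", "exact_mass",
                                  "abundance"),
                    colClasses = c("character", "integer", "numeric",
                                   "numeric"))
  tab <- .validate_isotope_table(tab)
  if (activate) {
    setIsotopeTable(tab)
    invisible(tab)
  } else tab
}

# Principal (most abundant) isotope row of an element.
.principal <- function(element) {
  sub <- isotopeTable(element)
  sub[which.max(sub$abundance), , drop = FALSE]
}

# Per-element single-atom shift distribution with exact-mass excesses.
# Shift = mass_number - principal mass_number; excess = exact_mass -
# principal exact_mass.  Returned sorted by shift; shift 0 is the principal.
.single_atom <- function(element) {
  sub <- isotopeTable(element)
  pr <- sub[which.max(sub$abundance), ]
  data.frame(shift = sub$mass_number - pr$mass_number,
             excess = sub$exact_mass - pr$exact_mass,
             prob = sub$abundance)[order(sub$mass_number - pr$mass_number), ]
}

#' Parse a chemical formula
#'
#' Parses a Hill-style element-count string (e.g. `"C5H10N2O3"`) into a named
#' integer vector of atom counts.  A missing count means one atom.  Only
#' elements present in the active isotope table are accepted.
#'
#' @param text Formula string.
#' @return Named integer vector of atom counts (class `"ChemicalFormula"`).
#' @export
#' @examples
#' parseFormula("C5H10N2O3")
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (text == "") {
    out <- integer(0)
    class(out) <- "ChemicalFormula"
    return(out)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || length(toks) == 0L)
    stop("cannot parse formula '", text, "'")
  known <- unique(isotopeTable()$element)
  counts <- integer(0)
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    nstr <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(nstr)) as.integer(nstr) else 1L
    if (!el %in% known)
      stop("unknown element symbol '", el, "' in formula '", text, "'")
    if (n <= 0L)
      stop("non-positive atom count for element '", el, "' in '", text, "'")
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  class(counts) <- "ChemicalFormula"
  counts
}

#' Canonical formula string
#'
#' Serializes an atom-count vector back to Hill notation (C first, then H,
#' then other elements alphabetically); inverse of [parseFormula()].
#'
#' @param formula Named integer vector of atom counts.
#' @return Character scalar.
#' @export
formulaString <- function(formula) {
  formula <- .as_formula(formula)
  if (length(formula) == 0L) return("")
  els <- names(formula)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(el) {
    n <- formula[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

.as_formula <- function(formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  stopifnot(is.numeric(formula))
  if (length(formula)) {
    if (is.null(names(formula)) || any(!nzchar(names(formula))))
      stop("formula must be a named atom-count vector")
    if (any(formula < 1)) stop("all atom counts must be >= 1")
    known <- unique(isotopeTable()$element)
    bad <- setdiff(names(formula), known)
    if (length(bad))
      stop("unknown element symbol '", bad[1], "'")
  }
  storage.mode(formula) <- "integer"
  formula
}

#' Monoisotopic mass
#'
#' Sum over elements of atom count times the exact mass of the most abundant
#' isotope.  The empty formula has mass 0.
#'
#' @param formula Formula string or named atom-count vector.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopicMass("C5H10N2O3")  # glutamine, ~146.0691
monoisotopicMass <- function(formula) {
  formula <- .as_formula(formula)
  if (length(formula) == 0L) return(0)
  sum(vapply(names(formula), function(el) .principal(el)$exact_mass,
             numeric(1)) * as.numeric(formula))
}
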