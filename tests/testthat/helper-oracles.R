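# Brute-force isotope-assignment oracle: enumerates every assignment of an
# isotope to each of n atoms (m^n tuples) and accumulates the probability
# of each total nominal shift.  Independent of the package's convolution /
# multinomial code paths.
bruteElementPattern <- function(element, n, maxShift) {
  tab <- isotopeTable(element)
  pr <- which.max(tab$abundance)
  shifts <- tab$mass_number - tab$mass_number[pr]
  probs <- tab$abundance
  m <- nrow(tab)
  out <- numeric(maxShift + 1L)
  if (n == 0L) { out[1L] <- 1; return(out) }
  idx <- 0:(m^n - 1)
  p <- rep(1, m^n); s <- integer(m^n)
  for (a in seq_len(n)) {
    d <- idx %% m
    idx <- idx %/% m
    p <- p * probs[d + 1L]
    s <- s + shifts[d + 1L]
  }
  for (k in 0:maxShift) out[k + 1L] <- sum(p[s == k])
  out
}

# Cache of brute-force patterns, keyed by element and atom count.
.brute_cache <- new.env(parent = emptyenv())
brutePattern <- function(element, n, maxShift) {
  key <- paste(element, n, maxShift)
  if (is.null(.brute_cache[[key]]))
    .brute_cache[[key]] <- bruteElementPattern(element, n, maxShift)
  .brute_cache[[key]]
}

# Small helper: forward-model FAM from a matrix and an MDV.
forwardFam <- function(C, x) as.numeric(entries(C) %*% x)

`%||%` <- function(a, b) if (is.null(a)) b else a

glnFormula <- "C5H10N2O3"
spec100k <- resolutionSpec("orbitrap", 1e5)
spec140k <- resolutionSpec("orbitrap", 1.4e5)
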