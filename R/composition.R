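#' Membrane composition
#'
#' A membrane composition maps lipid species names to mole fractions.
#' Fractions must lie in \[0, 1\] and sum to 1 (tolerance 1e-9).
#'
#' @param ... named mole fractions, e.g. `PG = 0.75, DAG = 0.25`, or a
#'   single named numeric vector.
#' @return an object of class `membrane_composition` (a named numeric
#'   vector).
#' @examples
#' membrane_composition(PG = 0.75, DAG = 0.25)
#' @export
membrane_composition <- function(...) {
  x <- c(...)
  if (length(x) == 1L && is.list(..1)) x <- unlist(..1)
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all mole fractions must be named by species")
  if (anyDuplicated(names(x)))
    stop("duplicated species names in composition")
  if (any(x < 0) || any(x > 1))
    stop("mole fractions must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-9)
    stop("mole fractions must sum to 1 (got ", format(sum(x), digits = 12), ")")
  structure(as.numeric(x), names = names(x), class = "membrane_composition")
}

#' Reference bilayer compositions M1-M4
#'
#' The four chloroplast-mimicking model membranes used throughout the
#' package documentation and tests: M1 is a PG/DAG bilayer; M2-M4 add the
#' galactolipids MGDG and DGDG at inner-envelope-like proportions.
#'
#' @param model one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return a [membrane_composition].
#' @examples
#' composition_preset("M1")
#' @export
composition_preset <- function(model = c("M1", "M2", "M3", "M4")) {
  model <- match.arg(model)
  switch(model,
    M1 = membrane_composition(PG = 0.75, DAG = 0.25),
    M2 = membrane_composition(MGDG = 0.50, DGDG = 0.30, PG = 0.10, DAG = 0.10),
    M3 = membrane_composition(MGDG = 0.50, DGDG = 0.30, PG = 0.15, DAG = 0.05),
    M4 = membrane_composition(MGDG = 0.40, DGDG = 0.30, PG = 0.25, DAG = 0.05)
  )
}

#' @export
print.membrane_composition <- function(x, ...) {
  cat("Membrane composition (mole fractions):\n")
  for (s in names(x)) cat(sprintf("  %-6s %.4f\n", s, x[[s]]))
  invisible(x)
}

#' Largest-remainder apportionment of counts to a composition
#'
#' Rounds `n * fractions` to integers summing exactly to `n`, assigning
#' leftover units to the species with the largest fractional remainders
#' (ties broken by species order).
#'
#' @param composition a [membrane_composition].
#' @param n total count to apportion.
#' @return named integer vector of per-species counts summing to `n`.
#' @export
species_counts <- function(composition, n) {
  stopifnot(inherits(composition, "membrane_composition"), n >= 1)
  exact <- composition * n
  base <- floor(exact)
  rem <- exact - base
  short <- n - sum(base)
  if (short > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  storage.mode(base) <- "integer"
  stats::setNames(base, names(composition))
}
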