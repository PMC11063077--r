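# Element data used across the package.
#
# Covalent radii follow Pyykko & Atsumi, Chem. Eur. J. 2009 (single-bond
# values); van der Waals radii follow Bondi 1964 with Alvarez 2013 values
# filling gaps.  "M" is a generic surrogate metal for toy systems (not a
# real element); it is assigned an even electron count so that neutral
# singlet toy complexes are parity-consistent.

.element_table <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
             "Ti", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Br",
             "Zr", "Rh", "Pd", "Ag", "I", "Ir", "Pt", "Au", "M"),
  number = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L,
             11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L,
             22L, 24L, 25L, 26L, 27L, 28L, 29L, 30L, 31L, 35L,
             40L, 45L, 46L, 47L, 53L, 77L, 78L, 79L, 40L),
  r_cov = c(0.32, 0.46, 1.33, 1.02, 0.85, 0.75, 0.71, 0.63, 0.64, 0.67,
            1.55, 1.39, 1.26, 1.16, 1.11, 1.03, 0.99, 0.96, 1.96, 1.71,
            1.36, 1.22, 1.19, 1.16, 1.11, 1.10, 1.12, 1.18, 1.24, 1.14,
            1.54, 1.25, 1.20, 1.28, 1.33, 1.22, 1.23, 1.24, 1.40),
  r_vdw = c(1.20, 1.40, 1.81, 1.53, 1.92, 1.70, 1.55, 1.52, 1.47, 1.54,
            2.27, 1.73, 1.84, 2.10, 1.80, 1.80, 1.75, 1.88, 2.75, 2.31,
            2.15, 2.06, 2.05, 2.04, 2.00, 1.97, 1.96, 2.01, 1.87, 1.85,
            2.52, 2.10, 2.10, 2.11, 1.98, 2.13, 2.13, 2.14, 2.00),
  stringsAsFactors = FALSE
)

element_index <- function(symbols) {
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Look up element properties
#'
#' Atomic numbers and covalent / van der Waals radii for the elements known
#' to the package (common main-group elements, a selection of transition
#' metals, and the generic surrogate metal `"M"`).
#'
#' @param symbols Character vector of element symbols.
#' @return `atomic_number()` returns an integer vector; `covalent_radius()`
#'   and `vdw_radius()` return numeric vectors in Angstrom.
#' @examples
#' covalent_radius(c("H", "C"))
#' @export
atomic_number <- function(symbols) {
  .element_table$number[element_index(symbols)]
}

#' @rdname atomic_number
#' @export
covalent_radius <- function(symbols) {
  .element_table$r_cov[element_index(symbols)]
}

#' @rdname atomic_number
#' @export
vdw_radius <- function(symbols) {
  .element_table$r_vdw[element_index(symbols)]
}
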