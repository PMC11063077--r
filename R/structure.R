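#' Molecular structures
#'
#' A `crn_structure` is one three-dimensional molecular geometry together
#' with its total charge `q` (elementary charges) and spin multiplicity
#' `M_s` (2S+1).  It is the atomic unit of a reaction network: compounds
#' and flasks aggregate structures that share charge, multiplicity and
#' molecular graph.
#'
#' The electron count implied by the elements and the charge must have a
#' parity consistent with the multiplicity: an even number of electrons
#' requires odd multiplicity (singlet, triplet, ...) and vice versa.
#'
#' @param symbols Character vector of element symbols.
#' @param coords Numeric matrix (n x 3) of Cartesian positions in Angstrom.
#' @param charge Integer total charge.
#' @param multiplicity Positive integer spin multiplicity.
#' @param label Free-text label.
#' @param energy Optional electronic energy in kJ/mol.
#' @param model Model tag for `energy` (e.g. `"toy"`).
#' @return An object of class `crn_structure`.
#' @examples
#' h2 <- structure_new(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' n_atoms(h2)
#' @export
structure_new <- function(symbols, coords, charge = 0L, multiplicity = 1L,
                          label = "", energy = NULL, model = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(symbols) == nrow(coords))
  if (!all(is.finite(coords))) stop("non-finite atomic positions")
  charge <- as.integer(charge)
  multiplicity <- as.integer(multiplicity)
  if (multiplicity < 1L) stop("multiplicity must be >= 1")
  n_el <- sum(atomic_number(symbols)) - charge
  if (n_el < 0L) stop("charge exceeds available electrons")
  # even electron count <=> odd multiplicity
  if ((n_el %% 2L) != ((multiplicity - 1L) %% 2L)) {
    stop(sprintf(
      "electron count %d is inconsistent with multiplicity %d",
      n_el, multiplicity))
  }
  s <- list(symbols = as.character(symbols), coords = coords,
            charge = charge, multiplicity = multiplicity,
            label = as.character(label), energy = energy, model = model)
  class(s) <- "crn_structure"
  s
}

#' @rdname structure_new
#' @param x A `crn_structure`.
#' @export
n_atoms <- function(x) length(x$symbols)

#' @export
print.crn_structure <- function(x, ...) {
  cat(sprintf("<crn_structure> %d atoms [%s] q=%d m=%d%s%s\n",
              n_atoms(x), paste(unique(x$symbols), collapse = ","),
              x$charge, x$multiplicity,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              if (!is.null(x$energy))
                sprintf(" E=%.3f kJ/mol", x$energy) else ""))
  invisible(x)
}

#' Pairwise interatomic distances
#'
#' @param s A `crn_structure`.
#' @return A symmetric n x n matrix of distances in Angstrom.
#' @export
distance_matrix <- function(s) {
  as.matrix(stats::dist(s$coords))
}

#' Read and write XYZ files
#'
#' Standard XYZ format: an atom-count line, a comment line, then one
#' `element x y z` line per atom.  Charge and multiplicity are carried in
#' the comment line as `q=<int> m=<int>`; absent tags default to a neutral
#' singlet.  `read_xyz()` reads all frames of a (possibly multi-frame)
#' file; `write_xyz()` writes one structure or a list of structures.
#'
#' @param path File path.
#' @return `read_xyz()` returns a list of `crn_structure` objects.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i)
    comment <- lines[i + 1L]
    q <- 0L; m <- 1L
    qm <- regmatches(comment, regexec("q=(-?[0-9]+)", comment))[[1]]
    if (length(qm) == 2L) q <- as.integer(qm[2])
    mm <- regmatches(comment, regexec("m=([0-9]+)", comment))[[1]]
    if (length(mm) == 2L) m <- as.integer(mm[2])
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[[:space:]]+")
    sym <- vapply(rows, `[`, "", 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    lbl <- trimws(sub("q=-?[0-9]+", "", sub("m=[0-9]+", "", comment)))
    out[[length(out) + 1L]] <-
      structure_new(sym, xyz, charge = q, multiplicity = m, label = lbl)
    i <- i + 2L + n
  }
  out
}

#' @rdname read_xyz
#' @param structures A `crn_structure` or a list of them.
#' @export
write_xyz <- function(structures, path) {
  if (inherits(structures, "crn_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    writeLines(sprintf("%d", n_atoms(s)), con)
    writeLines(sprintf("%s q=%d m=%d", s$label, s$charge, s$multiplicity),
               con)
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f",
                       s$symbols, s$coords[, 1], s$coords[, 2],
                       s$coords[, 3]), con)
  }
  invisible(path)
}
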