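#' Toy pairwise-Morse potential
#'
#' The surrogate chemistry engine evaluates a sum of pairwise Morse terms
#' \deqn{V(d) = D [ (1 - e^{-\beta (d - r_0)})^2 - 1 ]}
#' over all atom pairs whose element pair carries a well depth `D > 0`,
#' plus a pure exponential core repulsion `A exp(-b d)` for pairs tabled
#' with `D = 0`, plus an additive whole-structure offset keyed by
#' (empirical formula, charge, multiplicity).  The offset fallback is
#' `k_q q^2 + k_m (M - 1)`, which makes charge separation and spin
#' excitation cost energy so that the dissociation screen's enumeration
#' over charge/multiplicity combinations has a well-defined optimum.
#'
#' The form is smooth in the coordinates, size-consistent (all pair terms
#' vanish at large separation) and supports bond making and breaking along
#' forced scans — the minimum physics the single-ended trial machinery
#' needs.  It is a stand-in toy model, not an electronic-structure method.
#'
#' @param pairs Data frame with columns `a`, `b` (element symbols), `D`
#'   (well depth, kJ/mol, `>= 0`), `beta` (1/Angstrom), `r0` (Angstrom).
#' @param offsets Optional data frame with columns `formula`, `charge`,
#'   `multiplicity`, `offset` (kJ/mol) overriding the generic fallback.
#' @param k_charge,k_mult Fallback offset coefficients (kJ/mol).
#' @param repulsion_A,repulsion_b Core repulsion amplitude (kJ/mol) and
#'   decay (1/Angstrom) for `D = 0` pairs.
#' @param bo_width Pauling bond-order width `b` in
#'   `n(d) = exp((r0 - d)/b)` (Angstrom).
#' @return An object of class `crn_toy_potential`.
#' @seealso [toy_calculator()], [default_toy_potential()]
#' @export
toy_potential <- function(pairs, offsets = NULL,
                          k_charge = 150, k_mult = 80,
                          repulsion_A = 1000, repulsion_b = 3.0,
                          bo_width = 0.35) {
  stopifnot(all(c("a", "b", "D", "beta", "r0") %in% names(pairs)))
  if (any(pairs$D < 0)) stop("well depths must be >= 0")
  if (any(pairs$r0 <= 0)) stop("equilibrium distances must be > 0")
  key <- pair_key(pairs$a, pairs$b)
  if (anyDuplicated(key)) stop("duplicate element pair in table")
  pot <- list(pairs = pairs, pair_key = key, offsets = offsets,
              k_charge = k_charge, k_mult = k_mult,
              repulsion_A = repulsion_A, repulsion_b = repulsion_b,
              bo_width = bo_width)
  class(pot) <- "crn_toy_potential"
  pot
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

# Per-pair parameter lookup for a structure; errors on missing pairs.
pot_params <- function(pot, symbols) {
  n <- length(symbols)
  if (n < 2L) {
    return(list(i = integer(0), j = integer(0), D = numeric(0),
                beta = numeric(0), r0 = numeric(0)))
  }
  ij <- utils::combn(n, 2L)
  key <- pair_key(symbols[ij[1, ]], symbols[ij[2, ]])
  row <- match(key, pot$pair_key)
  if (anyNA(row)) {
    stop("element pair(s) missing from potential table: ",
         paste(unique(key[is.na(row)]), collapse = ", "))
  }
  list(i = ij[1, ], j = ij[2, ], D = pot$pairs$D[row],
       beta = pot$pairs$beta[row], r0 = pot$pairs$r0[row])
}

pot_offset <- function(pot, structure) {
  if (!is.null(pot$offsets)) {
    f <- structure_formula(structure$symbols)
    hit <- which(pot$offsets$formula == f &
                   pot$offsets$charge == structure$charge &
                   pot$offsets$multiplicity == structure$multiplicity)
    if (length(hit)) return(pot$offsets$offset[hit[1]])
  }
  pot$k_charge * structure$charge^2 +
    pot$k_mult * (structure$multiplicity - 1)
}

pot_energy_coords <- function(pot, par, coords) {
  if (!length(par$i)) return(0)
  dx <- coords[par$i, , drop = FALSE] - coords[par$j, , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  e <- numeric(length(d))
  m <- par$D > 0
  if (any(m)) {
    x <- 1 - exp(-par$beta[m] * (d[m] - par$r0[m]))
    e[m] <- par$D[m] * (x^2 - 1)
  }
  if (any(!m)) {
    e[!m] <- pot$repulsion_A * exp(-pot$repulsion_b * d[!m])
  }
  sum(e)
}

pot_gradient_coords <- function(pot, par, coords) {
  g <- matrix(0, nrow(coords), 3L)
  if (!length(par$i)) return(g)
  dx <- coords[par$i, , drop = FALSE] - coords[par$j, , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  dVdd <- numeric(length(d))
  m <- par$D > 0
  if (any(m)) {
    ex <- exp(-par$beta[m] * (d[m] - par$r0[m]))
    dVdd[m] <- 2 * par$D[m] * par$beta[m] * ex * (1 - ex)
  }
  if (any(!m)) {
    dVdd[!m] <- -pot$repulsion_A * pot$repulsion_b *
      exp(-pot$repulsion_b * d[!m])
  }
  u <- dx / d
  for (k in seq_along(d)) {
    g[par$i[k], ] <- g[par$i[k], ] + dVdd[k] * u[k, ]
    g[par$j[k], ] <- g[par$j[k], ] - dVdd[k] * u[k, ]
  }
  g
}

pot_bond_orders <- function(pot, par, symbols, coords) {
  n <- length(symbols)
  bo <- matrix(0, n, n)
  if (!length(par$i)) return(bo)
  dx <- coords[par$i, , drop = FALSE] - coords[par$j, , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  ord <- ifelse(par$D > 0,
                pmin(exp((par$r0 - d) / pot$bo_width), 4), 0)
  for (k in seq_along(d)) {
    bo[par$i[k], par$j[k]] <- ord[k]
    bo[par$j[k], par$i[k]] <- ord[k]
  }
  bo
}

#' Default surrogate potential table
#'
#' Covers H, C, O and the generic metal `"M"` with qualitatively sensible
#' well depths, widths and equilibrium distances for a toy model.
#'
#' @return A `crn_toy_potential`.
#' @export
default_toy_potential <- function() {
  pairs <- data.frame(
    a = c("H", "H", "H", "H", "C", "C", "C", "O", "O", "M"),
    b = c("H", "C", "O", "M", "C", "O", "M", "O", "M", "M"),
    D = c(436, 410, 460, 250, 350, 360, 280, 300, 300, 100),
    beta = c(1.9, 1.9, 2.2, 1.6, 1.9, 2.2, 1.6, 2.3, 1.7, 1.3),
    r0 = c(0.74, 1.09, 0.96, 1.60, 1.54, 1.43, 2.00, 1.21, 1.90, 2.60))
  toy_potential(pairs)
}

#' Read / write a potential table
#'
#' Structured-text (YAML) serialization of a [toy_potential()].
#'
#' @param pot A `crn_toy_potential`.
#' @param path File path.
#' @export
write_potential <- function(pot, path) {
  obj <- list(pairs = lapply(seq_len(nrow(pot$pairs)), function(i) {
    as.list(pot$pairs[i, c("a", "b", "D", "beta", "r0")])
  }),
  k_charge = pot$k_charge, k_mult = pot$k_mult,
  repulsion_A = pot$repulsion_A, repulsion_b = pot$repulsion_b,
  bo_width = pot$bo_width)
  if (!is.null(pot$offsets)) {
    obj$offsets <- lapply(seq_len(nrow(pot$offsets)), function(i) {
      as.list(pot$offsets[i, ])
    })
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  obj <- yaml::read_yaml(path)
  pairs <- do.call(rbind, lapply(obj$pairs, as.data.frame))
  offsets <- if (!is.null(obj$offsets)) {
    do.call(rbind, lapply(obj$offsets, as.data.frame))
  }
  toy_potential(pairs, offsets = offsets, k_charge = obj$k_charge,
                k_mult = obj$k_mult, repulsion_A = obj$repulsion_A,
                repulsion_b = obj$repulsion_b, bo_width = obj$bo_width)
}

#' Surrogate calculator
#'
#' Wraps a [toy_potential()] in the calculator contract: a deterministic
#' object exposing `energy`, `gradient`, `bond_orders`,
#' `optimize_minimum` and `constrained_relax`.  Any engine honouring the
#' same contract (same capability names and determinism guarantee) can be
#' slotted in behind the exploration machinery.
#'
#' @param potential A `crn_toy_potential`.
#' @param model Model tag recorded on energies.
#' @param gtol Gradient-infinity-norm convergence tolerance
#'   (kJ/mol/Angstrom).
#' @param maxit Maximum optimizer iterations.
#' @return An object of class `crn_calculator`.
#' @examples
#' calc <- toy_calculator()
#' h2 <- structure_new(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' calc$energy(h2)
#' @export
toy_calculator <- function(potential = default_toy_potential(),
                           model = "toy", gtol = 1e-6, maxit = 500L) {
  pot <- potential
  calc <- list(
    model = model,
    capabilities = c("energy", "gradient", "bond_orders",
                     "optimize_minimum", "constrained_relax"),
    settings = list(gtol = gtol, maxit = maxit),
    potential = pot)
  calc$energy <- function(structure) {
    par <- pot_params(pot, structure$symbols)
    pot_energy_coords(pot, par, structure$coords) +
      pot_offset(pot, structure)
  }
  calc$gradient <- function(structure) {
    par <- pot_params(pot, structure$symbols)
    pot_gradient_coords(pot, par, structure$coords)
  }
  calc$bond_orders <- function(structure) {
    par <- pot_params(pot, structure$symbols)
    pot_bond_orders(pot, par, structure$symbols, structure$coords)
  }
  calc$optimize_minimum <- function(structure) {
    optimize_minimum(structure, calc)
  }
  calc$constrained_relax <- function(structure, pairs, targets) {
    constrained_relax(structure, calc, pairs, targets)
  }
  class(calc) <- "crn_calculator"
  calc
}

#' Geometry optimization to a local minimum
#'
#' Quasi-Newton (L-BFGS-B) minimization with analytic gradients; declares
#' convergence when the gradient infinity norm drops below the
#' calculator's `gtol`.  Deterministic from a fixed start.
#'
#' @param structure Starting `crn_structure`.
#' @param calculator A `crn_calculator` with energy and gradient.
#' @return The optimized structure with `$energy`, `$model` and
#'   `$converged` set; non-convergence sets `$converged = FALSE`.
#' @export
optimize_minimum <- function(structure, calculator) {
  pot <- calculator$potential
  par <- pot_params(pot, structure$symbols)
  off <- pot_offset(pot, structure)
  fn <- function(x) {
    pot_energy_coords(pot, par, matrix(x, ncol = 3L)) + off
  }
  gr <- function(x) {
    as.numeric(pot_gradient_coords(pot, par, matrix(x, ncol = 3L)))
  }
  gtol <- calculator$settings$gtol
  x <- as.numeric(structure$coords)
  converged <- max(abs(gr(x))) <= gtol
  tries <- 0L
  while (!converged && tries < 3L) {
    res <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = calculator$settings$maxit,
                                       factr = 1, pgtol = gtol / 10))
    x <- res$par
    converged <- max(abs(gr(x))) <= gtol
    tries <- tries + 1L
  }
  out <- structure
  out$coords <- matrix(x, ncol = 3L)
  out$energy <- fn(x)
  out$model <- calculator$model
  out$converged <- converged
  out$graph <- NULL
  out$bond_orders <- NULL
  out
}

#' Constrained relaxation
#'
#' Relaxes a structure while holding chosen interatomic distances at
#' target values: an escalating quadratic-penalty minimization is followed
#' by exact projection of the constrained pairs onto their targets and a
#' final relaxation of the unconstrained atoms.  Constrained distances end
#' within 1e-3 Angstrom of their targets; the returned energy is the plain
#' (penalty-free) energy at the final geometry.
#'
#' @param structure A `crn_structure`.
#' @param calculator A `crn_calculator`.
#' @param pairs Integer matrix (k x 2) of atom-index pairs.
#' @param targets Numeric vector of k target distances (Angstrom, > 0).
#' @return The relaxed structure with `$energy` set.
#' @export
constrained_relax <- function(structure, calculator, pairs, targets) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(optimize_minimum(structure, calculator))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  stopifnot(length(targets) == nrow(pairs), all(targets > 0))
  pk <- paste(pmin(pairs[, 1], pairs[, 2]),
              pmax(pairs[, 1], pairs[, 2]))
  if (anyDuplicated(pk)) {
    dup <- duplicated(pk) | duplicated(pk, fromLast = TRUE)
    if (any(abs(tapply(targets, pk, max) -
                  tapply(targets, pk, min)) > 1e-9)) {
      stop("conflicting targets for the same atom pair")
    }
    pairs <- pairs[!duplicated(pk), , drop = FALSE]
    targets <- targets[!duplicated(pk)]
  }
  pot <- calculator$potential
  par <- pot_params(pot, structure$symbols)
  off <- pot_offset(pot, structure)
  n <- n_atoms(structure)
  pair_d <- function(coords) {
    sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                    coords[pairs[, 2], , drop = FALSE])^2))
  }
  x <- as.numeric(structure$coords)
  for (k_pen in c(1e4, 1e6)) {
    fn <- function(x) {
      cm <- matrix(x, ncol = 3L)
      pot_energy_coords(pot, par, cm) +
        k_pen * sum((pair_d(cm) - targets)^2)
    }
    gr <- function(x) {
      cm <- matrix(x, ncol = 3L)
      g <- pot_gradient_coords(pot, par, cm)
      d <- pair_d(cm)
      for (q in seq_len(nrow(pairs))) {
        i <- pairs[q, 1]; j <- pairs[q, 2]
        u <- (cm[i, ] - cm[j, ]) / d[q]
        f <- 2 * k_pen * (d[q] - targets[q])
        g[i, ] <- g[i, ] + f * u
        g[j, ] <- g[j, ] - f * u
      }
      as.numeric(g)
    }
    res <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = calculator$settings$maxit,
                                       factr = 1, pgtol = 1e-8))
    x <- res$par
  }
  cm <- matrix(x, ncol = 3L)
  # exact projection of constrained pairs (iterated for shared atoms)
  for (sweep in seq_len(25L)) {
    d <- pair_d(cm)
    if (max(abs(d - targets)) < 1e-9) break
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      v <- cm[i, ] - cm[j, ]
      dq <- sqrt(sum(v^2))
      shift <- (targets[q] - dq) / 2
      u <- v / dq
      cm[i, ] <- cm[i, ] + shift * u
      cm[j, ] <- cm[j, ] - shift * u
    }
  }
  # final relaxation of atoms not touched by any constraint
  free <- setdiff(seq_len(n), unique(as.integer(pairs)))
  if (length(free)) {
    fixed <- cm
    fn <- function(xf) {
      fixed[free, ] <- matrix(xf, ncol = 3L)
      pot_energy_coords(pot, par, fixed)
    }
    gr <- function(xf) {
      fixed[free, ] <- matrix(xf, ncol = 3L)
      as.numeric(pot_gradient_coords(pot, par, fixed)[free, ,
                                                      drop = FALSE])
    }
    res <- stats::optim(as.numeric(cm[free, , drop = FALSE]), fn, gr,
                        method = "L-BFGS-B",
                        control = list(maxit = calculator$settings$maxit,
                                       factr = 1, pgtol = 1e-8))
    cm[free, ] <- matrix(res$par, ncol = 3L)
  }
  if (max(abs(pair_d(cm) - targets)) > 1e-3) {
    stop("constrained relaxation failed to satisfy targets")
  }
  out <- structure
  out$coords <- cm
  out$energy <- pot_energy_coords(pot, par, cm) + off
  out$model <- calculator$model
  out$converged <- TRUE
  out$graph <- NULL
  out$bond_orders <- NULL
  out
}
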