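#' Reaction coordinates
#'
#' A reaction coordinate is a list of atom-index pairs, each tagged
#' associative (to be pushed together) or dissociative (to be pulled
#' apart), with a per-pair force scale used by the forced-scan driver.
#'
#' @param pairs Integer matrix (k x 2) of atom indices.
#' @param kinds Character vector, `"associative"` or `"dissociative"`
#'   per pair (recycled).
#' @param scales Per-pair force scales (default 1).
#' @return A data frame of class `crn_coordinate` with columns
#'   `i`, `j`, `kind`, `scale`.
#' @export
reaction_coordinate <- function(pairs, kinds = "associative",
                                scales = 1) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) < 1L) stop("a coordinate needs at least one pair")
  if (any(pairs[, 1] == pairs[, 2])) stop("pair indices must differ")
  kinds <- rep_len(as.character(kinds), nrow(pairs))
  if (!all(kinds %in% c("associative", "dissociative"))) {
    stop("pair kinds must be 'associative' or 'dissociative'")
  }
  key <- paste(pmin(pairs[, 1], pairs[, 2]),
               pmax(pairs[, 1], pairs[, 2]))
  if (anyDuplicated(key)) stop("duplicate pairs in coordinate")
  out <- data.frame(i = pairs[, 1], j = pairs[, 2], kind = kinds,
                    scale = rep_len(scales, nrow(pairs)))
  class(out) <- c("crn_coordinate", "data.frame")
  out
}

#' Build a reactive complex
#'
#' For a bimolecular trial, fragment B is rigidly placed so that the
#' first paired reactive sites face each other at the start separation
#' (default: the sum of the two sites' van der Waals radii), with B's
#' bulk pointing away from A.  Orientations are sampled deterministically
#' from a seed until no inter-fragment clash remains.  For a unimolecular
#' trial the structure is copied unchanged and the internal coordinate
#' attached.
#'
#' @param structA Lowest-energy member structure of the first aggregate.
#' @param structB Optional second structure (bimolecular trials).
#' @param sitesA,sitesB Integer vectors of reactive-site atom indices
#'   (paired elementwise for bimolecular trials).
#' @param coordinate Optional explicit `crn_coordinate` (unimolecular
#'   trials; indices refer to `structA`).
#' @param start_sep Start separation in Angstrom (bimolecular).
#' @param seed Integer seed for orientation sampling.
#' @param max_attempts Orientation attempts before giving up.
#' @return A list of class `crn_complex`: `structure`, `coordinate`,
#'   `n_atoms_A`.
#' @export
build_reactive_complex <- function(structA, structB = NULL,
                                   sitesA = NULL, sitesB = NULL,
                                   coordinate = NULL, start_sep = NULL,
                                   seed = 1L, max_attempts = 36L) {
  if (is.null(structB)) {
    if (is.null(coordinate)) {
      if (is.null(sitesA) || length(sitesA) < 2L) {
        stop("unimolecular trials need a coordinate or >= 2 sites")
      }
      coordinate <- reaction_coordinate(matrix(sitesA[1:2], ncol = 2L))
    }
    stopifnot(all(c(coordinate$i, coordinate$j) <= n_atoms(structA)))
    out <- list(structure = structA, coordinate = coordinate,
                n_atoms_A = n_atoms(structA))
    class(out) <- "crn_complex"
    return(out)
  }
  stopifnot(length(sitesA) == length(sitesB), length(sitesA) >= 1L)
  nA <- n_atoms(structA)
  a_site <- sitesA[1]
  b_site <- sitesB[1]
  if (is.null(start_sep)) {
    start_sep <- vdw_radius(structA$symbols[a_site]) +
      vdw_radius(structB$symbols[b_site])
  }
  A <- structA$coords
  B0 <- structB$coords
  # outward direction through A's primary site
  cA <- colMeans(A)
  u <- A[a_site, ] - cA
  if (sqrt(sum(u^2)) < 1e-8) u <- c(1, 0, 0)
  u <- u / sqrt(sum(u^2))
  # orient B so its bulk points away from A along u
  cB <- colMeans(B0)
  w <- cB - B0[b_site, ]
  R0 <- if (sqrt(sum(w^2)) < 1e-8) diag(3) else rotation_between(w, u)
  target <- A[a_site, ] + start_sep * u
  rcA <- covalent_radius(structA$symbols)
  rcB <- covalent_radius(structB$symbols)
  clash_lim <- 0.8 * outer(rcA, rcB, `+`)
  golden <- pi * (3 - sqrt(5))
  placed <- NULL
  for (attempt in seq_len(max_attempts)) {
    theta <- (seed %% 997) * 1e-3 + (attempt - 1L) * golden
    Rspin <- rotation_about(u, theta)
    B <- sweep(B0, 2, B0[b_site, ]) %*% t(R0) %*% t(Rspin)
    B <- sweep(B, 2, target, `+`)
    cross <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), `+`) -
                         2 * A %*% t(B), 0))
    if (all(cross >= clash_lim)) {
      placed <- B
      break
    }
  }
  if (is.null(placed)) {
    stop("clashing placement after ", max_attempts,
         " orientation attempts")
  }
  combined <- structure_new(
    c(structA$symbols, structB$symbols), rbind(A, placed),
    charge = structA$charge + structB$charge,
    multiplicity = combine_multiplicity(structA, structB),
    label = paste0(structA$label, "+", structB$label))
  coordinate <- reaction_coordinate(cbind(sitesA, sitesB + nA),
                                    "associative")
  out <- list(structure = combined, coordinate = coordinate,
              n_atoms_A = nA)
  class(out) <- "crn_complex"
  out
}

# Lowest parity-consistent multiplicity for the combined system.
combine_multiplicity <- function(a, b) {
  n_el <- sum(atomic_number(a$symbols)) + sum(atomic_number(b$symbols)) -
    a$charge - b$charge
  if (n_el %% 2L == 0L) 1L else 2L
}

#' Run a single-ended forced scan
#'
#' Per macro-iteration each coordinate pair's distance is moved by its
#' force scale times the step size (associative pairs shrink,
#' dissociative pairs grow) and the remaining degrees of freedom are
#' relaxed under the distance constraints.  Each frame records the
#' penalty-free energy and the calculator bond orders.  The scan stops
#' when the target bond-order change is reached, at the step limit, or on
#' a calculator failure (truncated but still analyzable).
#'
#' @param complex A `crn_complex`.
#' @param calculator A `crn_calculator` supporting `constrained_relax`
#'   and `bond_orders`.
#' @param step_size Macro-iteration distance increment (Angstrom).
#' @param max_steps Maximum number of macro-iterations.
#' @param bo_threshold Bond-order change threshold (formation: rise
#'   above; cleavage: fall below).
#' @param min_distance Floor for associative targets (Angstrom).
#' @return A list of class `crn_trajectory`: `frames` (each with
#'   `structure`, `energy`, `bond_orders`), `energies`, `pair_orders`
#'   (frames x pairs), `coordinate`, `reason`.
#' @export
run_scan <- function(complex, calculator, step_size = 0.1,
                     max_steps = 200L, bo_threshold = 0.5,
                     min_distance = 0.5) {
  coord <- complex$coordinate
  pairs <- cbind(coord$i, coord$j)
  s <- complex$structure
  frames <- list()
  reason <- "max-steps"
  record <- function(st) {
    bo <- calculator$bond_orders(st)
    if (is.null(st$energy)) st$energy <- calculator$energy(st)
    frames[[length(frames) + 1L]] <<- list(structure = st,
                                           energy = st$energy,
                                           bond_orders = bo)
  }
  record(s)
  pair_order <- function(frame) {
    vapply(seq_len(nrow(pairs)), function(q) {
      frame$bond_orders[pairs[q, 1], pairs[q, 2]]
    }, 0)
  }
  change_hit <- function(frame) {
    ord <- pair_order(frame)
    all(ifelse(coord$kind == "associative", ord > bo_threshold,
               ord < bo_threshold))
  }
  if (change_hit(frames[[1]])) reason <- "target-change-reached"
  step <- 0L
  while (reason == "max-steps" && step < max_steps) {
    step <- step + 1L
    cur <- frames[[length(frames)]]$structure
    d <- sqrt(rowSums((cur$coords[pairs[, 1], , drop = FALSE] -
                         cur$coords[pairs[, 2], , drop = FALSE])^2))
    targets <- ifelse(coord$kind == "associative",
                      pmax(d - coord$scale * step_size, min_distance),
                      d + coord$scale * step_size)
    nxt <- tryCatch(
      constrained_relax(cur, calculator, pairs, targets),
      error = function(e) e)
    if (inherits(nxt, "error")) {
      reason <- "calculation-failure"
      break
    }
    record(nxt)
    if (change_hit(frames[[length(frames)]])) {
      reason <- "target-change-reached"
    }
  }
  po <- t(vapply(frames, pair_order, numeric(nrow(pairs))))
  po <- matrix(po, nrow = length(frames))
  out <- list(frames = frames,
              energies = vapply(frames, `[[`, 0, "energy"),
              pair_orders = po, coordinate = coord, reason = reason)
  class(out) <- "crn_trajectory"
  out
}

#' Detect the bond-order change event
#'
#' Returns the first frame (1-based) at which every associative pair's
#' bond order has risen above the threshold and every dissociative
#' pair's has fallen below it, or `NA` if no such frame exists.  On
#' monotone order profiles this equals the maximum over per-pair first
#' crossings.
#'
#' @param trajectory A `crn_trajectory` (frames carry bond orders).
#' @param threshold Bond-order threshold (default 0.5).
#' @return Integer frame index or `NA`.
#' @export
detect_bond_change <- function(trajectory, threshold = 0.5) {
  po <- trajectory$pair_orders
  kind <- trajectory$coordinate$kind
  ok <- vapply(seq_len(nrow(po)), function(t) {
    all(ifelse(kind == "associative", po[t, ] > threshold,
               po[t, ] < threshold))
  }, TRUE)
  if (!any(ok)) return(NA_integer_)
  which(ok)[1]
}

# Interior local maxima of a series, plateaus collapsed to their first
# frame; endpoints are never maxima.
local_maxima <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  hits <- which(seq_len(k) > 1L & seq_len(k) < k &
                  r$values > c(Inf, r$values[-k]) &
                  r$values > c(r$values[-1], Inf))
  starts[hits]
}

smooth_profile <- function(e, window = 5L, poly_order = 2L) {
  n <- length(e)
  w <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (w < poly_order + 2L) return(e)
  as.numeric(signal::sgolayfilt(e, p = poly_order, n = w))
}

#' Select a transition-state-guess frame
#'
#' Implements the rule cascade for single-ended scans.  If the desired
#' bond-order change occurred at `change_frame`, the last local energy
#' maximum before the event is selected; whether a maximum was observed
#' before the event is decided on the profile smoothed with a
#' Savitzky-Golay filter (window `window`, order `poly_order`).  If the
#' smoothed screen finds no prior maximum, the first local maximum after
#' the event is selected instead.  Without a change event the highest
#' local maximum is selected.  Only interior frames qualify; a profile
#' with no interior maximum yields `NA` (trial unsuccessful).
#'
#' @param trajectory A `crn_trajectory` or a numeric energy profile.
#' @param change_frame Event frame from [detect_bond_change()] (or
#'   `NA`/`NULL` when no change was observed).
#' @param window,poly_order Savitzky-Golay smoothing parameters.
#' @return Integer frame index (1-based) or `NA`, with attribute
#'   `"rule"` naming the branch taken.
#' @export
select_ts_guess <- function(trajectory, change_frame = NULL,
                            window = 5L, poly_order = 2L) {
  e <- if (inherits(trajectory, "crn_trajectory")) {
    trajectory$energies
  } else {
    as.numeric(trajectory)
  }
  if (length(e) < 3L) stop("trajectory must have >= 3 frames")
  raw_max <- local_maxima(e)
  if (is.null(change_frame) || is.na(change_frame)) {
    if (!length(raw_max)) {
      return(structure(NA_integer_, rule = "no-guess"))
    }
    pick <- raw_max[which.max(e[raw_max])]
    return(structure(pick, rule = "highest-maximum"))
  }
  smooth_max <- local_maxima(smooth_profile(e, window, poly_order))
  before <- raw_max[raw_max < change_frame]
  after <- raw_max[raw_max >= change_frame]
  screen_found <- any(smooth_max < change_frame)
  if (screen_found && length(before)) {
    return(structure(max(before), rule = "last-before-event"))
  }
  if (length(after)) {
    return(structure(min(after), rule = "first-after-event"))
  }
  if (length(before)) {
    return(structure(max(before), rule = "last-before-event"))
  }
  structure(NA_integer_, rule = "no-guess")
}

#' Scale forces for haptic coordinates
#'
#' Haptic (eta-n) bond formation or breaking applies several coordinate
#' pairs to what is chemically a single bond; adding their forces would
#' overpower other concerted coordinates.  Pairs of the same kind form a
#' haptic group when they share a nucleus, or when their endpoints sit on
#' the same contiguous bonded fragment (adjacency taken from the supplied
#' bond orders).  Each pair in a k-pair group gets scale 1/k, so the
#' total force per group equals a single pair's force; ungrouped pairs
#' keep scale 1.
#'
#' @param coordinate A `crn_coordinate`.
#' @param bond_orders Bond-order matrix (or `crn_bond_orders`) of the
#'   current geometry.
#' @param threshold Bond detection threshold for adjacency.
#' @return The coordinate with updated `scale` column.
#' @export
scale_haptic_forces <- function(coordinate, bond_orders,
                                threshold = 0.30) {
  bo <- if (inherits(bond_orders, "crn_bond_orders")) {
    bond_orders$orders
  } else {
    bond_orders
  }
  adj <- bo >= threshold
  n <- nrow(coordinate)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  linked <- function(p, q) {
    ap <- c(coordinate$i[p], coordinate$j[p])
    aq <- c(coordinate$i[q], coordinate$j[q])
    if (length(intersect(ap, aq))) return(TRUE)
    # contiguous-fragment rule: one endpoint pair adjacent, the other
    # endpoint pair shared or adjacent
    for (a in ap) {
      for (b in aq) {
        if (adj[a, b]) {
          a2 <- setdiff(ap, a)
          b2 <- setdiff(aq, b)
          if (a2 == b2 || adj[a2, b2]) return(TRUE)
        }
      }
    }
    FALSE
  }
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (q <= p) next
      if (coordinate$kind[p] != coordinate$kind[q]) next
      if (linked(p, q)) parent[find(q)] <- find(p)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  sizes <- table(roots)
  coordinate$scale <- 1 / as.integer(sizes[as.character(roots)])
  coordinate
}

#' Validate a transition-state guess into an elementary step
#'
#' The guess frame is refined by one-dimensional energy maximization
#' along the local trajectory direction; downhill relaxations from both
#' displaced sides must reach two structures with different molecular
#' graphs.  An accepted step carries both optimized endpoints and the
#' refined TS energy (which must be at least as high as both endpoints);
#' anything else is a rejection with a reason.
#'
#' @param trajectory A `crn_trajectory`.
#' @param ts_frame Interior frame index of the TS guess.
#' @param calculator A `crn_calculator`.
#' @param displacement Side displacement along the trajectory direction
#'   (fraction of the local frame spacing).
#' @return A list: `accepted` plus either `reactant`, `product`,
#'   `ts_structure`, `ts_energy` or `reason`.
#' @export
validate_step <- function(trajectory, ts_frame, calculator,
                          displacement = 0.5) {
  nf <- length(trajectory$frames)
  if (is.na(ts_frame) || ts_frame <= 1L || ts_frame >= nf) {
    return(list(accepted = FALSE, reason = "no interior TS guess"))
  }
  x_prev <- trajectory$frames[[ts_frame - 1L]]$structure$coords
  x_ts <- trajectory$frames[[ts_frame]]$structure$coords
  x_next <- trajectory$frames[[ts_frame + 1L]]$structure$coords
  d <- x_next - x_prev
  nd <- sqrt(sum(d^2))
  if (nd < 1e-10) {
    return(list(accepted = FALSE, reason = "degenerate direction"))
  }
  d <- d / nd
  base <- trajectory$frames[[ts_frame]]$structure
  probe <- function(t) {
    s <- base
    s$coords <- x_ts + t * d
    calculator$energy(s)
  }
  half <- nd / 2
  opt <- stats::optimize(probe, c(-half, half), maximum = TRUE,
                         tol = 1e-8)
  ts_structure <- base
  ts_structure$coords <- x_ts + opt$maximum * d
  ts_structure$energy <- opt$objective
  ts_structure$graph <- NULL
  step_out <- displacement * half
  side <- function(sgn) {
    s <- base
    s$coords <- ts_structure$coords + sgn * step_out * d
    s$energy <- NULL
    optimize_minimum(s, calculator)
  }
  lo <- side(-1)
  hi <- side(+1)
  if (!isTRUE(lo$converged) || !isTRUE(hi$converged)) {
    return(list(accepted = FALSE, reason = "side relaxation failed"))
  }
  lo <- with_graph(lo, calculator)
  hi <- with_graph(hi, calculator)
  if (same_aggregate(lo, hi)) {
    return(list(accepted = FALSE, reason = "no reaction"))
  }
  if (ts_structure$energy < max(lo$energy, hi$energy) - 1e-9) {
    return(list(accepted = FALSE, reason = "not a saddle"))
  }
  # orient: the side matching the scan's starting graph is the reactant
  start <- with_graph(trajectory$frames[[1]]$structure, calculator)
  if (!same_aggregate(lo, start) && same_aggregate(hi, start)) {
    tmp <- lo; lo <- hi; hi <- tmp
  }
  list(accepted = TRUE, reactant = lo, product = hi,
       ts_structure = ts_structure, ts_energy = ts_structure$energy)
}

# Parity-consistent multiplicities for a fragment: all values in
# [1, parent_M + 1] whose parity matches the fragment electron count.
fragment_multiplicities <- function(symbols, charge, parent_mult) {
  n_el <- sum(atomic_number(symbols)) - charge
  if (n_el < 0L) return(integer(0))
  cand <- seq_len(parent_mult + 1L)
  cand[(cand - 1L) %% 2L == n_el %% 2L]
}

#' Enumerate dissociation charge/multiplicity combinations
#'
#' All integer charge splits of the parent charge with each fragment
#' charge within `charge_window` of zero (shifted toward the parent
#' charge), crossed with all parity-consistent fragment multiplicities
#' up to `parent multiplicity + 1`.  Exported so the enumeration can be
#' inspected and tested independently of the screen itself.
#'
#' @param fragment_symbols List of element-symbol vectors, one per
#'   fragment.
#' @param parent_charge,parent_mult Parent charge and multiplicity.
#' @param charge_window Per-fragment charge window (default 1).
#' @return Data frame with one row per combination: `q1..qk`, `m1..mk`.
#' @export
dissociation_combinations <- function(fragment_symbols, parent_charge,
                                      parent_mult, charge_window = 1L) {
  k <- length(fragment_symbols)
  lo <- min(0L, parent_charge) - charge_window
  hi <- max(0L, parent_charge) + charge_window
  qs <- do.call(expand.grid, rep(list(lo:hi), k))
  qs <- qs[rowSums(qs) == parent_charge, , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(qs))) {
    mult_lists <- lapply(seq_len(k), function(f) {
      fragment_multiplicities(fragment_symbols[[f]], qs[r, f],
                              parent_mult)
    })
    if (any(!lengths(mult_lists))) next
    ms <- do.call(expand.grid, mult_lists)
    for (s in seq_len(nrow(ms))) {
      rows[[length(rows) + 1L]] <-
        c(as.integer(qs[r, ]), as.integer(ms[s, ]))
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(paste0("q", seq_len(k)), paste0("m", seq_len(k)))
  out
}

#' Fast dissociation screen
#'
#' Deletes the cut bonds, splits the structure into fragments, and
#' optimizes every fragment separately for all enumerated charge splits
#' (homo- and heterolytic) and parity-consistent spin multiplicities.
#' The combination with the lowest summed fragment energy is retained;
#' the dissociation energy is that sum minus the optimized parent energy
#' on the same surface.
#'
#' @param structure Parent `crn_structure`.
#' @param cut_bonds Integer matrix (k x 2) of bonds to delete; they must
#'   exist in the perceived graph and their removal must disconnect it.
#' @param calculator A `crn_calculator`.
#' @param charge_window Per-fragment charge window.
#' @return A list of class `crn_dissociation`: `cut_bonds`,
#'   `combinations` (with summed energies), `best` (row index),
#'   `fragments` (optimized structures of the best combination),
#'   `dissociation_energy`, `parent` (optimized), `barrierless`
#'   (`FALSE`; set by [barrierless_probe()]).
#' @export
dissociation_screen <- function(structure, cut_bonds, calculator,
                                charge_window = 1L) {
  parent <- optimize_minimum(structure, calculator)
  parent <- with_graph(parent, calculator)
  g <- parent$graph
  cut_bonds <- matrix(as.integer(cut_bonds), ncol = 2L)
  for (b in seq_len(nrow(cut_bonds))) {
    if (!g$adj[cut_bonds[b, 1], cut_bonds[b, 2]]) {
      stop("cut bond ", cut_bonds[b, 1], "-", cut_bonds[b, 2],
           " is not an edge of the molecular graph")
    }
  }
  adj <- g$adj
  for (b in seq_len(nrow(cut_bonds))) {
    adj[cut_bonds[b, 1], cut_bonds[b, 2]] <- FALSE
    adj[cut_bonds[b, 2], cut_bonds[b, 1]] <- FALSE
  }
  comp <- graph_components(adj)
  if (max(comp) < 2L) {
    stop("removing the cut bonds does not disconnect the graph")
  }
  frag_atoms <- lapply(seq_len(max(comp)), function(kk) which(comp == kk))
  frag_symbols <- lapply(frag_atoms, function(a) parent$symbols[a])
  combos <- dissociation_combinations(frag_symbols, parent$charge,
                                      parent$multiplicity, charge_window)
  k <- length(frag_atoms)
  cache <- new.env(parent = emptyenv())
  opt_frag <- function(f, q, m) {
    key <- paste(f, q, m, sep = "/")
    if (!is.null(cache[[key]])) return(cache[[key]])
    frag <- substructure(parent, frag_atoms[[f]], charge = q,
                         multiplicity = m)
    res <- tryCatch(optimize_minimum(frag, calculator),
                    error = function(e) NULL)
    if (!is.null(res) && !isTRUE(res$converged)) res <- NULL
    cache[[key]] <- list(res)
    list(res)
  }
  energies <- rep(NA_real_, nrow(combos))
  frag_sets <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    frags <- lapply(seq_len(k), function(f) {
      opt_frag(f, combos[r, f], combos[r, k + f])[[1]]
    })
    if (any(vapply(frags, is.null, TRUE))) next
    energies[r] <- sum(vapply(frags, `[[`, 0, "energy"))
    frag_sets[[r]] <- frags
  }
  combos$energy <- energies
  if (all(is.na(energies))) {
    out <- list(cut_bonds = cut_bonds, combinations = combos,
                best = NA_integer_, fragments = NULL,
                dissociation_energy = NA_real_, parent = parent,
                fragment_atoms = frag_atoms, barrierless = FALSE,
                failed = TRUE)
    class(out) <- "crn_dissociation"
    return(out)
  }
  best <- which.min(energies)
  out <- list(cut_bonds = cut_bonds, combinations = combos, best = best,
              fragments = frag_sets[[best]],
              dissociation_energy = energies[best] - parent$energy,
              parent = parent, fragment_atoms = frag_atoms,
              barrierless = FALSE, failed = FALSE)
  class(out) <- "crn_dissociation"
  out
}

#' Probe a dissociation for a barrierless step
#'
#' The optimized fragments of the best combination are aligned back onto
#' their parent positions and placed along the first cut bond's
#' direction with the reactive-site separation elongated to the sum of
#' the two sites' van der Waals radii.  If optimizing this super-system
#' recovers the parent's aggregate key (identical molecular graph,
#' charge and multiplicity), a barrierless elementary step between the
#' dissociated arrangement and the parent exists and a candidate is
#' returned; otherwise `NULL`.
#'
#' @param dissociation A `crn_dissociation` (two fragments).
#' @param calculator A `crn_calculator`.
#' @param far_separation Extra site separation used to build the
#'   dissociated endpoint structure (Angstrom).
#' @return `NULL`, or a list with `type = "barrierless"`,
#'   `dissociated` (flask-like endpoint structure), `parent` (optimized
#'   parent) and `supersystem` (the optimized probe geometry).
#' @export
barrierless_probe <- function(dissociation, calculator,
                              far_separation = 25) {
  if (isTRUE(dissociation$failed)) return(NULL)
  if (length(dissociation$fragments) != 2L) {
    stop("barrierless probe expects exactly two fragments")
  }
  parent <- dissociation$parent
  i <- dissociation$cut_bonds[1, 1]
  j <- dissociation$cut_bonds[1, 2]
  atoms <- dissociation$fragment_atoms
  fi <- which(vapply(atoms, function(a) i %in% a, TRUE))
  fj <- which(vapply(atoms, function(a) j %in% a, TRUE))
  if (fi == fj) stop("cut bond does not straddle the two fragments")
  place <- function(extra) {
    coords <- parent$coords
    for (f in seq_along(atoms)) {
      coords[atoms[[f]], ] <-
        kabsch_transform(parent$coords[atoms[[f]], , drop = FALSE],
                         dissociation$fragments[[f]]$coords)
    }
    u <- coords[j, ] - coords[i, ]
    u <- u / sqrt(sum(u^2))
    sep <- vdw_radius(parent$symbols[i]) +
      vdw_radius(parent$symbols[j]) + extra
    shift <- coords[i, ] + sep * u - coords[j, ]
    coords[atoms[[fj]], ] <- sweep(coords[atoms[[fj]], , drop = FALSE],
                                   2, shift, `+`)
    s <- parent
    s$coords <- coords
    s$energy <- NULL
    s$graph <- NULL
    s$bond_orders <- NULL
    s
  }
  probe <- tryCatch(optimize_minimum(place(0), calculator),
                    error = function(e) NULL)
  if (is.null(probe) || !isTRUE(probe$converged)) return(NULL)
  probe <- with_graph(probe, calculator)
  if (!same_aggregate(probe, parent)) return(NULL)
  dissociated <- place(far_separation)
  dissociated$energy <- calculator$energy(dissociated)
  dissociated <- with_graph(dissociated, calculator)
  list(type = "barrierless", dissociated = dissociated,
       parent = parent, supersystem = probe)
}

#' Follow-up queue for screened dissociations
#'
#' After a screening pass, exactly the dissociations with a reaction
#' energy below the threshold (200 kJ/mol by default) are queued for
#' scan-based sampling with the conventional forced-scan algorithm.
#'
#' @param results List of `crn_dissociation` objects.
#' @param threshold Reaction-energy threshold in kJ/mol.
#' @return Integer indices into `results` selected for follow-up.
#' @export
followup_queue <- function(results, threshold = 200) {
  de <- vapply(results, function(r) {
    if (isTRUE(r$failed)) Inf else r$dissociation_energy
  }, 0)
  which(de < threshold)
}

#' Export a trajectory
#'
#' Writes a multi-frame XYZ file plus a tab-separated table with one row
#' per frame (frame index, energy, per-pair bond order).
#'
#' @param trajectory A `crn_trajectory`.
#' @param xyz_path,table_path Output file paths.
#' @export
write_trajectory <- function(trajectory, xyz_path, table_path) {
  write_xyz(lapply(trajectory$frames, `[[`, "structure"), xyz_path)
  po <- trajectory$pair_orders
  tab <- data.frame(frame = seq_along(trajectory$energies),
                    energy = trajectory$energies)
  for (q in seq_len(ncol(po))) tab[[paste0("order_", q)]] <- po[, q]
  utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(xyz_path)
}
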