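#' Bond perception
#'
#' Builds a symmetric bond-order matrix for a structure.  If a calculator
#' with the `bond_orders` capability is supplied, its (Mayer-style) orders
#' are used; otherwise a covalent-radius distance heuristic assigns order 1
#' to pairs with `d <= tol * (r_cov(A) + r_cov(B))` and 0 otherwise.
#'
#' @param structure A `crn_structure`.
#' @param calculator Optional calculator (see [toy_calculator()]).
#' @param tol Distance tolerance factor for the heuristic
#'   (default 1.25).
#' @return A list of class `crn_bond_orders` with elements `orders`
#'   (matrix) and `source` (`"heuristic"` or `"calculator"`).
#' @examples
#' h2 <- structure_new(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
#' perceive_bonds(h2)$orders
#' @export
perceive_bonds <- function(structure, calculator = NULL, tol = 1.25) {
  n <- n_atoms(structure)
  d <- distance_matrix(structure)
  if (n > 1L && min(d[upper.tri(d)]) < 0.1) {
    stop("degenerate geometry: atoms closer than 0.1 Angstrom")
  }
  if (!is.null(calculator)) {
    if (!("bond_orders" %in% calculator$capabilities)) {
      stop("calculator does not supply bond orders")
    }
    bo <- calculator$bond_orders(structure)
    src <- "calculator"
  } else {
    r <- covalent_radius(structure$symbols)
    lim <- tol * outer(r, r, `+`)
    bo <- matrix(0, n, n)
    bo[d <= lim] <- 1
    diag(bo) <- 0
    src <- "heuristic"
  }
  stopifnot(nrow(bo) == n, ncol(bo) == n)
  bo <- (bo + t(bo)) / 2
  diag(bo) <- 0
  out <- list(orders = bo, source = src)
  class(out) <- "crn_bond_orders"
  out
}

#' Molecular graph from a bond-order matrix
#'
#' Applies a detection threshold: an edge exists iff the bond order is at
#' least `threshold`.  The default 0.30 classifies weak contacts (such as
#' a Mayer order of 0.22) as non-bonded.
#'
#' @param structure The originating `crn_structure`.
#' @param bond_orders A `crn_bond_orders` object or a plain matrix.
#' @param threshold Bond detection threshold (> 0).
#' @return An object of class `crn_graph` with fields `symbols`, `adj`
#'   (logical adjacency matrix) and `component` (integer membership).
#' @export
graph_from_bond_orders <- function(structure, bond_orders,
                                   threshold = 0.30) {
  bo <- if (inherits(bond_orders, "crn_bond_orders")) {
    bond_orders$orders
  } else {
    bond_orders
  }
  stopifnot(threshold > 0)
  n <- n_atoms(structure)
  if (nrow(bo) != n || ncol(bo) != n) {
    stop("bond-order matrix dimension does not match atom count")
  }
  adj <- bo >= threshold
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  g <- list(symbols = structure$symbols, adj = adj,
            component = graph_components(adj))
  class(g) <- "crn_graph"
  g
}

# Connected-component labels (1-based, in order of first atom) by BFS.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    k <- k + 1L
    queue <- start
    comp[start] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Perceive and attach a molecular graph
#'
#' Convenience wrapper: perceives bonds (heuristic or calculator) and
#' attaches the thresholded graph to the structure as `$graph`.
#'
#' @inheritParams perceive_bonds
#' @inheritParams graph_from_bond_orders
#' @return The structure with `$graph` (and `$bond_orders`) set.
#' @export
with_graph <- function(structure, calculator = NULL, threshold = 0.30) {
  bo <- perceive_bonds(structure, calculator)
  structure$bond_orders <- bo
  structure$graph <- graph_from_bond_orders(structure, bo, threshold)
  structure
}

structure_graph <- function(structure, calculator = NULL) {
  if (!is.null(structure$graph)) return(structure$graph)
  graph_from_bond_orders(structure, perceive_bonds(structure, calculator))
}

#' Canonical graph certificate
#'
#' Iterative colour refinement (Weisfeiler–Lehman style) starting from
#' element labels.  Equal certificates are necessary for isomorphism; the
#' exact VF2 check in [same_aggregate()] resolves certificate collisions.
#'
#' @param graph A `crn_graph`.
#' @return A single character string.
#' @export
graph_certificate <- function(graph) {
  n <- length(graph$symbols)
  if (n == 0L) return("empty")
  colours <- graph$symbols
  for (iter in seq_len(max(1L, n))) {
    new <- vapply(seq_len(n), function(i) {
      nb <- sort(colours[graph$adj[i, ]])
      paste0(colours[i], "|", paste(nb, collapse = ","))
    }, "")
    relabel <- paste0("c", match(new, sort(unique(new))), ".",
                      graph$symbols)
    stable <- length(unique(relabel)) == length(unique(colours))
    colours <- relabel
    if (stable) break
  }
  paste(sort(colours), collapse = ";")
}

graph_to_igraph <- function(graph) {
  g <- igraph::graph_from_adjacency_matrix(graph$adj, mode = "undirected")
  igraph::V(g)$color <- match(graph$symbols,
                              sort(unique(graph$symbols)))
  g
}

#' Exact element-respecting graph isomorphism
#'
#' @param g1,g2 `crn_graph` objects.
#' @return Logical.
#' @export
graphs_isomorphic <- function(g1, g2) {
  if (length(g1$symbols) != length(g2$symbols)) return(FALSE)
  if (!identical(sort(g1$symbols), sort(g2$symbols))) return(FALSE)
  if (sum(g1$adj) != sum(g2$adj)) return(FALSE)
  # colours must be aligned across the two graphs
  lev <- sort(unique(c(g1$symbols, g2$symbols)))
  ig1 <- igraph::graph_from_adjacency_matrix(g1$adj, mode = "undirected")
  igraph::V(ig1)$color <- match(g1$symbols, lev)
  ig2 <- igraph::graph_from_adjacency_matrix(g2$adj, mode = "undirected")
  igraph::V(ig2)$color <- match(g2$symbols, lev)
  igraph::isomorphic(ig1, ig2, method = "vf2")
}

#' Aggregate identity key
#'
#' Two structures belong to the same aggregate (compound or flask) iff
#' their charges and spin multiplicities are equal and their molecular
#' graphs are isomorphic respecting element labels.  The key combines
#' charge, multiplicity, molecule count and the canonical certificate.
#'
#' @param structure A `crn_structure` (graph perceived on demand).
#' @return A list of class `crn_aggregate_key` with a `$hash` string.
#' @export
aggregate_key <- function(structure) {
  g <- structure_graph(structure)
  key <- list(charge = structure$charge,
              multiplicity = structure$multiplicity,
              n_molecules = max(g$component),
              certificate = graph_certificate(g))
  key$hash <- sprintf("q%+d.m%d.n%d.%s", key$charge, key$multiplicity,
                      key$n_molecules, key$certificate)
  class(key) <- "crn_aggregate_key"
  key
}

#' Aggregate identity test
#'
#' @param a,b `crn_structure` objects with perceivable graphs.
#' @return `TRUE` iff charge, multiplicity equal and graphs isomorphic.
#' @export
same_aggregate <- function(a, b) {
  if (a$charge != b$charge || a$multiplicity != b$multiplicity) {
    return(FALSE)
  }
  ga <- structure_graph(a)
  gb <- structure_graph(b)
  # cheap certificate pre-filter, exact VF2 on agreement
  if (!identical(graph_certificate(ga), graph_certificate(gb))) {
    return(FALSE)
  }
  graphs_isomorphic(ga, gb)
}

#' Split a graph into molecules
#'
#' Returns the connected components in a deterministic order: sorted by
#' canonical certificate, ties broken by the lowest original atom index.
#'
#' @param graph A `crn_graph`.
#' @return A list with one entry per component, each a list with
#'   `graph` (the component subgraph) and `atoms` (original atom indices).
#' @export
split_molecules <- function(graph) {
  comp <- graph$component
  pieces <- lapply(seq_len(max(comp)), function(k) {
    idx <- which(comp == k)
    sub <- list(symbols = graph$symbols[idx],
                adj = graph$adj[idx, idx, drop = FALSE],
                component = rep(1L, length(idx)))
    class(sub) <- "crn_graph"
    list(graph = sub, atoms = idx, certificate = graph_certificate(sub))
  })
  ord <- order(vapply(pieces, `[[`, "", "certificate"),
               vapply(pieces, function(p) min(p$atoms), 0L))
  lapply(pieces[ord], function(p) p[c("graph", "atoms")])
}

#' Extract one molecule as a structure
#'
#' Helper for fragment workflows: carves the atoms of one component out of
#' a parent structure.  Charge and multiplicity must be supplied (a
#' fragment's charge split is not derivable from geometry); the default is
#' a neutral fragment with the lowest parity-consistent multiplicity.
#'
#' @param structure Parent `crn_structure`.
#' @param atoms Integer atom indices.
#' @param charge,multiplicity Fragment charge and multiplicity;
#'   `multiplicity = NA` picks 1 or 2 by electron parity.
#' @return A `crn_structure`.
#' @export
substructure <- function(structure, atoms, charge = 0L,
                         multiplicity = NA_integer_) {
  sym <- structure$symbols[atoms]
  if (is.na(multiplicity)) {
    n_el <- sum(atomic_number(sym)) - as.integer(charge)
    multiplicity <- if (n_el %% 2L == 0L) 1L else 2L
  }
  structure_new(sym, structure$coords[atoms, , drop = FALSE],
                charge = charge, multiplicity = multiplicity,
                label = structure$label)
}

# Empirical molecular formula, e.g. "C2H6" (Hill-ish: sorted symbols).
structure_formula <- function(symbols) {
  tab <- table(symbols)
  paste0(names(tab), ifelse(tab > 1L, as.integer(tab), ""), collapse = "")
}
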