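# Reaction energetics helpers ----------------------------------------

# Orientation-resolved activation / reaction energy of one reaction.
# direction "forward" follows the stored canonical direction.
reaction_energetics <- function(store, rid, direction = "forward") {
  rx <- store$reactions[[rid]]
  if (is.null(rx)) stop("unknown reaction id: ", rid)
  best <- NULL
  for (eid in rx$steps) {
    st <- store$elementary_steps[[eid]]
    r_agg <- sort(unname(vapply(st$reactants, function(s) {
      store$structures[[s]]$aggregate_id
    }, "")))
    fwd_as_stored <- identical(r_agg, rx$reactants)
    e_r <- if (fwd_as_stored) st$energy_reactants else {
      st$energy_products
    }
    e_p <- if (fwd_as_stored) st$energy_products else {
      st$energy_reactants
    }
    if (direction == "backward") {
      tmp <- e_r; e_r <- e_p; e_p <- tmp
    }
    ea <- if (st$type == "barrierless") 0 else st$ts_energy - e_r
    cand <- list(ea = ea, dE = e_p - e_r,
                 barrierless = st$type == "barrierless", step = eid)
    if (is.null(best) || cand$ea < best$ea) best <- cand
  }
  best
}

#' Build the bipartite compound/reaction path graph
#'
#' Aggregate nodes and one reaction node per reaction direction, with
#' directed edges reactant-aggregate -> reaction -> product-aggregate.
#' The cost of entering a reaction is its activation energy in that
#' direction (zero for barrierless reactions) plus the acquisition cost
#' of any required co-reactants: aggregates a reaction needs beyond the
#' incoming one are charged their cheapest acquisition cost from the
#' start set, computed recursively (memoized fixpoint) — a simplified
#' compound-cost scheme.
#'
#' @param store A `crn_store` with reactions carrying activation
#'   energies.
#' @param start Character vector of start aggregate ids (cost 0).
#' @return An object of class `crn_pathgraph`: `graph` (igraph),
#'   `acquisition` (named costs), `store`.
#' @export
build_graph <- function(store, start) {
  rids <- names(store$reactions)
  missing <- Filter(function(rid) {
    rx <- store$reactions[[rid]]
    is.null(rx$ea_forward) || is.na(rx$ea_forward) ||
      is.null(rx$ea_backward) || is.na(rx$ea_backward)
  }, rids)
  if (length(missing)) {
    stop("reactions without activation energies: ",
         paste(missing, collapse = ", "))
  }
  aggs <- aggregate_ids(store)
  stopifnot(all(start %in% aggs))
  # acquisition-cost fixpoint (Bellman-Ford over reaction directions)
  acq <- stats::setNames(rep(Inf, length(aggs)), aggs)
  acq[start] <- 0
  for (iter in seq_len(length(rids) + 2L)) {
    changed <- FALSE
    for (rid in rids) {
      rx <- store$reactions[[rid]]
      for (dir in c("forward", "backward")) {
        from <- if (dir == "forward") rx$reactants else rx$products
        to <- if (dir == "forward") rx$products else rx$reactants
        ea <- max(0, if (dir == "forward") rx$ea_forward else {
          rx$ea_backward
        })
        if (any(!is.finite(acq[from]))) next
        cost <- ea + sum(acq[from])
        upd <- to[acq[to] > cost + 1e-12]
        if (length(upd)) {
          acq[upd] <- cost
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  edges <- character(0)
  weights <- numeric(0)
  rnode_info <- list()
  for (rid in rids) {
    rx <- store$reactions[[rid]]
    for (dir in c("forward", "backward")) {
      from <- if (dir == "forward") rx$reactants else rx$products
      to <- if (dir == "forward") rx$products else rx$reactants
      ea <- max(0, if (dir == "forward") rx$ea_forward else {
        rx$ea_backward
      })
      rnode <- paste0(rid, if (dir == "forward") ">" else "<")
      rnode_info[[rnode]] <- list(reaction = rid, direction = dir,
                                  reactants = from, products = to)
      for (x in unique(from)) {
        co <- from[-match(x, from)]  # multiset: drop one copy of x
        co_cost <- if (length(co)) sum(acq[co]) else 0
        if (!is.finite(co_cost)) next
        edges <- c(edges, x, rnode)
        weights <- c(weights, ea + co_cost)
      }
      for (y in to) {
        edges <- c(edges, rnode, y)
        weights <- c(weights, 0)
      }
    }
  }
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(aggs), name = aggs,
                            kind = "aggregate")
  rnames <- names(rnode_info)
  g <- igraph::add_vertices(g, length(rnames), name = rnames,
                            kind = "reaction")
  if (length(edges)) {
    g <- igraph::add_edges(g, edges, weight = weights)
  }
  out <- list(graph = g, acquisition = acq, start = start,
              reaction_nodes = rnode_info, store = store)
  class(out) <- "crn_pathgraph"
  out
}

#' Find the energetically lowest paths
#'
#' Deviation-based (Yen) k-shortest loopless path search on the
#' bipartite graph, from any of the source aggregates to the target.
#' Paths are returned in nondecreasing total cost with deterministic
#' tie-breaking by node-id sequence; an unreachable target yields an
#' empty list.
#'
#' @param pathgraph A `crn_pathgraph` from [build_graph()].
#' @param sources Character vector of source aggregate ids.
#' @param target Target aggregate id.
#' @param k Number of paths requested.
#' @return List of path results, each with `nodes` (alternating
#'   aggregate/reaction-node sequence), `reactions` (data frame with
#'   per-reaction activation/reaction energies and barrierless flags)
#'   and `cost`.
#' @export
find_lowest_paths <- function(pathgraph, sources, target, k = 1L) {
  g <- pathgraph$graph
  vn <- igraph::V(g)$name
  stopifnot(all(sources %in% vn), target %in% vn)
  virt <- "..source.."
  g2 <- igraph::add_vertices(g, 1L, name = virt, kind = "virtual")
  g2 <- igraph::add_edges(g2, as.vector(rbind(virt, sources)),
                          weight = rep(0, length(sources)))
  res <- tryCatch(
    suppressWarnings(
      igraph::k_shortest_paths(g2, from = virt, to = target,
                               k = k + 8L,
                               weights = igraph::E(g2)$weight,
                               mode = "out")),
    error = function(e) NULL)
  if (is.null(res) || !length(res$vpaths)) return(list())
  paths <- lapply(res$vpaths, function(vp) {
    nodes <- igraph::V(g2)$name[vp]
    nodes[nodes != virt]
  })
  paths <- unique(paths)
  w <- stats::setNames(igraph::E(g2)$weight,
                       paste(as.integer(igraph::tail_of(g2,
                                                        igraph::E(g2))),
                             as.integer(igraph::head_of(g2,
                                                        igraph::E(g2)))))
  cost_of <- function(nodes) {
    ids <- match(nodes, igraph::V(g2)$name)
    sum(w[paste(ids[-length(ids)], ids[-1])])
  }
  costs <- vapply(paths, cost_of, 0)
  keys <- vapply(paths, paste, "", collapse = "|")
  ord <- order(costs, keys)
  paths <- paths[ord][seq_len(min(k, length(paths)))]
  costs <- costs[ord][seq_len(min(k, length(paths)))]
  lapply(seq_along(paths), function(p) {
    nodes <- paths[[p]]
    rnodes <- nodes[grepl("[<>]$", nodes)]
    rx_tab <- do.call(rbind, lapply(rnodes, function(rn) {
      info <- pathgraph$reaction_nodes[[rn]]
      en <- reaction_energetics(pathgraph$store, info$reaction,
                                info$direction)
      data.frame(reaction = info$reaction, direction = info$direction,
                 ea = en$ea, dE = en$dE, barrierless = en$barrierless,
                 stringsAsFactors = FALSE)
    }))
    out <- list(nodes = nodes,
                aggregates = nodes[!grepl("[<>]$", nodes)],
                reactions = rx_tab, cost = costs[p])
    class(out) <- "crn_path"
    out
  })
}

#' Export level-diagram data for a path
#'
#' Produces the ordered record table behind an energy level diagram:
#' one `minimum` record per aggregate along the path (cumulative
#' reaction energies, referenced to the first aggregate), one
#' `transition-state` record per reaction with a TS, and one
#' `barrierless-link` record per barrierless reaction.
#'
#' @param path A `crn_path` from [find_lowest_paths()].
#' @return Data frame with columns `species`, `energy` (relative
#'   kJ/mol) and `kind`.
#' @export
export_level_diagram <- function(path) {
  recs <- list()
  level <- 0
  recs[[1]] <- data.frame(species = path$aggregates[1], energy = 0,
                          kind = "minimum", stringsAsFactors = FALSE)
  for (r in seq_len(nrow(path$reactions))) {
    rx <- path$reactions[r, ]
    if (rx$barrierless) {
      recs[[length(recs) + 1L]] <-
        data.frame(species = rx$reaction, energy = NA_real_,
                   kind = "barrierless-link", stringsAsFactors = FALSE)
    } else {
      recs[[length(recs) + 1L]] <-
        data.frame(species = paste0(rx$reaction, ":TS"),
                   energy = level + rx$ea, kind = "transition-state",
                   stringsAsFactors = FALSE)
    }
    level <- level + rx$dE
    recs[[length(recs) + 1L]] <-
      data.frame(species = path$aggregates[r + 1L], energy = level,
                 kind = "minimum", stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' @rdname export_level_diagram
#' @param diagram Data frame from `export_level_diagram()`.
#' @param file Optional TSV output path.
#' @export
write_level_diagram <- function(diagram, file) {
  utils::write.table(diagram, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Plot a level diagram
#'
#' Base-graphics rendering of the level-diagram visual grammar: black
#' levels for minima, red levels for transition states, gray dotted
#' connectors for barrierless reactions.
#'
#' @param diagram Data frame from [export_level_diagram()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_level_diagram <- function(diagram, ...) {
  drawn <- diagram[diagram$kind != "barrierless-link", ]
  n <- nrow(drawn)
  x <- seq_len(n)
  graphics::plot(NULL, xlim = c(0.5, n + 0.5),
                 ylim = range(drawn$energy) + c(-10, 10),
                 xlab = "", ylab = "relative energy / kJ mol-1",
                 xaxt = "n", ...)
  half <- 0.3
  prev <- NULL
  link_barrierless <- FALSE
  i <- 0L
  for (r in seq_len(nrow(diagram))) {
    rec <- diagram[r, ]
    if (rec$kind == "barrierless-link") {
      link_barrierless <- TRUE
      next
    }
    i <- i + 1L
    col <- if (rec$kind == "transition-state") "red" else "black"
    graphics::segments(i - half, rec$energy, i + half, rec$energy,
                       col = col, lwd = 2)
    graphics::text(i, rec$energy, rec$species, pos = 1, cex = 0.6)
    if (!is.null(prev)) {
      lty <- if (link_barrierless) 3 else 1
      lcol <- if (link_barrierless) "gray" else "gray40"
      graphics::segments(i - 1 + half, prev, i - half, rec$energy,
                         lty = lty, col = lcol)
    }
    prev <- rec$energy
    link_barrierless <- FALSE
  }
  invisible(diagram)
}
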