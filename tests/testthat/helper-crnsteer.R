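# Shared fixtures and independent oracles for the test suite.

h2_structure <- function(d = 0.74) {
  structure_new(c("H", "H"), rbind(c(0, 0, 0), c(d, 0, 0)))
}

water_structure <- function(shift = c(0, 0, 0)) {
  structure_new(c("O", "H", "H"),
                rbind(c(0, 0, 0), c(0.76, 0.59, 0),
                      c(-0.76, 0.59, 0)) + rep(shift, each = 3))
}

co_structure <- function(shift = c(0, 0, 0)) {
  structure_new(c("C", "O"),
                rbind(c(0, 0, 0), c(1.2, 0, 0)) + rep(shift, each = 2))
}

# Random element-labelled graph as a crn_graph (no geometry involved).
random_graph <- function(n, p = 0.4, elements = c("C", "H", "O")) {
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    up <- which(upper.tri(adj))
    on <- up[stats::runif(length(up)) < p]
    adj[on] <- TRUE
    adj <- adj | t(adj)
  }
  g <- list(symbols = sample(elements, n, replace = TRUE), adj = adj,
            component = crnsteer:::graph_components(adj))
  class(g) <- "crn_graph"
  g
}

# Apply a node permutation to a crn_graph.
permute_graph <- function(g, perm) {
  out <- g
  out$symbols <- g$symbols[perm]
  out$adj <- g$adj[perm, perm, drop = FALSE]
  out$component <- crnsteer:::graph_components(out$adj)
  out
}

# Brute-force element-respecting isomorphism by exhaustive backtracking
# over element-class-constrained assignments (exact for small graphs).
brute_isomorphic <- function(g1, g2) {
  n <- length(g1$symbols)
  if (n != length(g2$symbols)) return(FALSE)
  if (!identical(sort(g1$symbols), sort(g2$symbols))) return(FALSE)
  assign_next <- function(mapping) {
    i <- length(mapping) + 1L
    if (i > n) return(TRUE)
    for (cand in which(g2$symbols == g1$symbols[i])) {
      if (cand %in% mapping) next
      ok <- TRUE
      for (j in seq_along(mapping)) {
        if (g1$adj[i, j] != g2$adj[cand, mapping[j]]) {
          ok <- FALSE
          break
        }
      }
      if (ok && assign_next(c(mapping, cand))) return(TRUE)
    }
    FALSE
  }
  assign_next(integer(0))
}

# Exhaustive simple-path enumeration on a weighted directed edge list
# (data frame from, to, w); returns paths sorted by (cost, node key).
enumerate_paths <- function(edges, sources, target) {
  out <- list()
  dfs <- function(node, visited, cost) {
    if (node == target) {
      out[[length(out) + 1L]] <<- list(nodes = visited, cost = cost)
      return()
    }
    nxt <- edges[edges$from == node, , drop = FALSE]
    for (r in seq_len(nrow(nxt))) {
      if (nxt$to[r] %in% visited) next
      dfs(nxt$to[r], c(visited, nxt$to[r]), cost + nxt$w[r])
    }
  }
  for (s in sources) dfs(s, s, 0)
  if (!length(out)) return(out)
  keys <- vapply(out, function(p) paste(p$nodes, collapse = "|"), "")
  costs <- vapply(out, `[[`, 0, "cost")
  out[order(costs, keys)]
}

# Random hand-energied reaction network store over n aggregates
# (hydrogen chains of distinct lengths; unimolecular reactions only).
random_network_store <- function(n_aggs, n_reactions) {
  store <- crn_store()
  sids <- character(n_aggs)
  labels <- paste0("L", seq_len(n_aggs))
  energies <- round(stats::runif(n_aggs, -100, 0), 2)
  for (i in seq_len(n_aggs)) {
    nn <- i + 1L
    s <- structure_new(rep("H", nn), cbind(0.74 * (seq_len(nn) - 1),
                                           0, 0),
                       multiplicity = if (nn %% 2L) 2L else 1L,
                       label = labels[i], energy = energies[i],
                       model = "assigned")
    sids[i] <- add_structure(store, s)$structure_id
  }
  for (r in seq_len(n_reactions)) {
    ft <- sample.int(n_aggs, 2L)
    ea <- round(stats::runif(1, 5, 80), 2)
    step <- elementary_step(sids[ft[1]], sids[ft[2]], type = "with-TS",
                            ts_energy = max(energies[ft]) + ea,
                            model = "assigned")
    add_elementary_step(store, step)
  }
  store
}

# Assert the store partition invariant: every structure in exactly one
# compound or flask; every elementary step in exactly one reaction.
expect_store_partition <- function(store) {
  member_of <- character(0)
  for (agg in c(store$compounds, store$flasks)) {
    expect_false(any(agg$members %in% member_of))
    member_of <- c(member_of, agg$members)
  }
  expect_setequal(member_of, names(store$structures) %||% character(0))
  for (sid in names(store$structures)) {
    aid <- store$structures[[sid]]$aggregate_id
    agg <- crnsteer:::get_aggregate(store, aid)
    expect_true(sid %in% agg$members)
  }
  step_of <- character(0)
  for (rx in store$reactions) {
    expect_false(any(rx$steps %in% step_of))
    step_of <- c(step_of, rx$steps)
  }
  expect_setequal(step_of,
                  names(store$elementary_steps) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
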