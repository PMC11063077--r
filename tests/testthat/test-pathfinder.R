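# All stores here carry hand-assigned electronic energies, so path
# costs are exactly checkable.

linear_store <- function(eas = c(10, 25), e0 = 0) {
  store <- crn_store()
  n_aggs <- length(eas) + 1L
  energies <- seq(e0, by = -5, length.out = n_aggs)
  sids <- character(n_aggs)
  for (i in seq_len(n_aggs)) {
    n <- i + 1L
    s <- structure_new(rep("H", n), cbind(0.74 * (seq_len(n) - 1), 0, 0),
                       multiplicity = if (n %% 2L) 2L else 1L,
                       energy = energies[i], model = "assigned")
    sids[i] <- add_structure(store, s)$structure_id
  }
  for (i in seq_along(eas)) {
    add_elementary_step(store, elementary_step(
      sids[i], sids[i + 1L], type = "with-TS",
      ts_energy = energies[i] + eas[i], model = "assigned"))
  }
  list(store = store, sids = sids)
}

test_that("the path graph is bipartite with activation-energy costs", {
  ls <- linear_store(eas = 10)
  aggs <- crnsteer:::aggregate_ids(ls$store)
  pg <- build_graph(ls$store, start = aggs[1])
  kinds <- igraph::V(pg$graph)$kind
  # one reaction gives 2 aggregate nodes + 2 direction nodes
  expect_equal(sum(kinds == "aggregate"), 2L)
  expect_equal(sum(kinds == "reaction"), 2L)
  # every edge joins an aggregate to a reaction node (bipartite)
  ends <- igraph::ends(pg$graph, igraph::E(pg$graph))
  k_of <- stats::setNames(kinds, igraph::V(pg$graph)$name)
  expect_true(all(k_of[ends[, 1]] != k_of[ends[, 2]]))
  expect_true(all(igraph::E(pg$graph)$weight >= 0))
})

test_that("lowest paths on chains equal summed activations", {
  ls <- linear_store(eas = c(10, 25))
  aggs <- unique(vapply(ls$sids, function(s) {
    ls$store$structures[[s]]$aggregate_id
  }, ""))
  pg <- build_graph(ls$store, start = aggs[1])
  paths <- find_lowest_paths(pg, sources = aggs[1], target = aggs[3],
                             k = 5)
  expect_length(paths, 1L)  # k beyond the path count returns all paths
  expect_equal(paths[[1]]$cost, 35)
  expect_equal(paths[[1]]$aggregates, aggs)
  expect_equal(paths[[1]]$reactions$ea, c(10, 25))

  # unreachable target
  iso <- structure_new(rep("H", 9), cbind(0.74 * (0:8), 0, 0),
                       multiplicity = 2L, energy = 0,
                       model = "assigned")
  iso_id <- add_structure(ls$store, iso)$aggregate_id
  pg2 <- build_graph(ls$store, start = aggs[1])
  expect_length(find_lowest_paths(pg2, aggs[1], iso_id, k = 3), 0L)
})

test_that("barrierless steps traverse at zero cost", {
  store <- crn_store()
  a <- structure_new(rep("H", 2), cbind(c(0, 0.74), 0, 0),
                     energy = 0, model = "assigned")
  b <- structure_new(rep("H", 3), cbind(0.74 * (0:2), 0, 0),
                     multiplicity = 2L, energy = -30,
                     model = "assigned")
  sa <- add_structure(store, a)$structure_id
  sb <- add_structure(store, b)$structure_id
  add_elementary_step(store, elementary_step(sa, sb,
                                             type = "barrierless"))
  aggs <- crnsteer:::aggregate_ids(store)
  pg <- build_graph(store, start = aggs[1])
  paths <- find_lowest_paths(pg, aggs[1], aggs[2], k = 1)
  expect_equal(paths[[1]]$cost, 0)
  expect_true(paths[[1]]$reactions$barrierless)
})

test_that("k-lowest paths match exhaustive enumeration on toy networks", {
  set.seed(17)
  for (rep in 1:6) {
    n_aggs <- sample(5:9, 1)
    store <- random_network_store(n_aggs, n_reactions = n_aggs + 3L)
    aggs <- crnsteer:::aggregate_ids(store)
    src <- aggs[1]
    tgt <- aggs[length(aggs)]
    pg <- build_graph(store, start = src)
    got <- find_lowest_paths(pg, src, tgt, k = 4)

    # independent oracle: exhaustive DFS over the same edge set
    ee <- igraph::ends(pg$graph, igraph::E(pg$graph))
    edges <- data.frame(from = ee[, 1], to = ee[, 2],
                        w = igraph::E(pg$graph)$weight,
                        stringsAsFactors = FALSE)
    want <- enumerate_paths(edges, src, tgt)
    expect_equal(length(got), min(4L, length(want)))
    for (i in seq_along(got)) {
      expect_equal(got[[i]]$cost, want[[i]]$cost, tolerance = 1e-9)
    }
  }
})

test_that("adding a reaction never raises the optimal cost", {
  set.seed(31)
  store <- random_network_store(6, n_reactions = 8)
  aggs <- crnsteer:::aggregate_ids(store)
  pg <- build_graph(store, start = aggs[1])
  before <- find_lowest_paths(pg, aggs[1], aggs[6], k = 1)
  # add a direct low-barrier shortcut
  s1 <- store$compounds[[aggs[1]]]$members[1]
  s6 <- store$compounds[[aggs[6]]]$members[1]
  e1 <- store$structures[[s1]]$structure$energy
  e6 <- store$structures[[s6]]$structure$energy
  add_elementary_step(store, elementary_step(
    s1, s6, type = "with-TS", ts_energy = max(e1, e6) + 1,
    model = "assigned"))
  pg2 <- build_graph(store, start = aggs[1])
  after <- find_lowest_paths(pg2, aggs[1], aggs[6], k = 1)
  if (length(before)) {
    expect_lte(after[[1]]$cost, before[[1]]$cost)
  } else {
    expect_length(after, 1L)
  }
})

test_that("co-reactants are charged their acquisition cost", {
  store <- crn_store()
  mk <- function(n, e) {
    s <- structure_new(rep("H", n), cbind(0.74 * (seq_len(n) - 1), 0, 0),
                       multiplicity = if (n %% 2L) 2L else 1L,
                       energy = e, model = "assigned")
    add_structure(store, s)
  }
  a <- mk(2L, 0)    # start
  w <- mk(3L, 0)    # start; precursor of the co-reactant
  x <- mk(4L, -5)   # co-reactant, made from W with ea 30
  b <- mk(5L, -20)  # target, from A + X with ea 12
  add_elementary_step(store, elementary_step(
    w$structure_id, x$structure_id, type = "with-TS", ts_energy = 30,
    model = "assigned"))
  add_elementary_step(store, elementary_step(
    c(a$structure_id, x$structure_id), b$structure_id,
    type = "with-TS", ts_energy = 7, model = "assigned"))
  start <- c(a$aggregate_id, w$aggregate_id)
  pg <- build_graph(store, start = start)
  expect_equal(unname(pg$acquisition[x$aggregate_id]), 30)
  paths <- find_lowest_paths(pg, sources = start,
                             target = b$aggregate_id, k = 1)
  # entering via A pays the bimolecular ea (7 - (0 + -5) = 12) plus
  # the acquisition of X (30)
  expect_equal(paths[[1]]$cost, 42)
})

test_that("level diagrams reference the first aggregate and shift-invariantly", {
  ls <- linear_store(eas = c(10, 25), e0 = 100)
  aggs <- unique(vapply(ls$sids, function(s) {
    ls$store$structures[[s]]$aggregate_id
  }, ""))
  pg <- build_graph(ls$store, start = aggs[1])
  path <- find_lowest_paths(pg, aggs[1], aggs[3], k = 1)[[1]]
  diag <- export_level_diagram(path)
  expect_equal(diag$energy[diag$kind == "minimum"], c(0, -5, -10))
  expect_equal(diag$energy[diag$kind == "transition-state"],
               c(10, -5 + 25))
  # record count: one row per aggregate plus one per reaction
  expect_equal(nrow(diag), 3L + 2L)

  # global energy shift leaves the diagram unchanged
  ls2 <- linear_store(eas = c(10, 25), e0 = -400)
  aggs2 <- crnsteer:::aggregate_ids(ls2$store)
  pg2 <- build_graph(ls2$store, start = aggs2[1])
  path2 <- find_lowest_paths(pg2, aggs2[1], aggs2[3], k = 1)[[1]]
  expect_equal(export_level_diagram(path2)$energy, diag$energy)

  # a single barrierless step: two minima, a link row, no TS row
  store <- crn_store()
  sa <- add_structure(store, structure_new(rep("H", 2),
                                           cbind(c(0, 0.74), 0, 0),
                                           energy = 0,
                                           model = "assigned"))
  sb <- add_structure(store, structure_new(rep("H", 4),
                                           cbind(0.74 * (0:3), 0, 0),
                                           energy = -15,
                                           model = "assigned"))
  add_elementary_step(store, elementary_step(sa$structure_id,
                                             sb$structure_id,
                                             type = "barrierless"))
  pgb <- build_graph(store, start = sa$aggregate_id)
  pb <- find_lowest_paths(pgb, sa$aggregate_id, sb$aggregate_id,
                          k = 1)[[1]]
  db <- export_level_diagram(pb)
  expect_equal(db$kind,
               c("minimum", "barrierless-link", "minimum"))
  expect_equal(db$energy[c(1, 3)], c(0, -15))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_level_diagram(db, tsv)
  expect_equal(nrow(read.delim(tsv)), 3L)
})
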