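calc <- toy_calculator()

test_that("published protocol lists parse verbatim", {
  wil <- parse_protocol(published_protocol("wilkinson"))
  expect_length(wil$steps, 14L)
  expect_equal(expansion_sequence(wil),
               c("Dissociation", "Association", "Association",
                 "Rearrangement", "Rearrangement", "Dissociation"))
  # with preparation steps retained the optimization reappears
  expect_equal(expansion_sequence(wil, drop_preparation = FALSE)[1],
               "Simple_Optimization")

  zn <- parse_protocol(published_protocol("ziegler_natta"))
  expect_length(expansion_sequence(zn), 7L)
  expect_equal(expansion_sequence(zn)[4], "Conformer_Creation")

  mon <- parse_protocol(published_protocol("monsanto"))
  expect_length(mon$steps, 7L)
  expect_true(all(vapply(mon$steps, `[[`, "", "type") == "expansion"))

  empty <- parse_protocol("[]")
  expect_length(empty$steps, 0L)

  expect_error(parse_protocol("[Association, Frobnicate_Step]"),
               "Frobnicate_Step")
  expect_error(parse_protocol("Association, Dissociation"),
               "malformed")
  # expansion-only lists violate strict alternation
  expect_error(parse_protocol(published_protocol("monsanto"),
                              strict = TRUE), "non-alternating")
  expect_silent(parse_protocol(published_protocol("wilkinson"),
                               strict = TRUE))
})

test_that("protocols serialize losslessly with settings and seed", {
  p <- protocol(list(
    "File_Input_Selection",
    list(name = "Association",
         settings = list(a_contains = "M", n_coordinates = 2L)),
    list(name = "Central_Metal_Selection",
         settings = list(metal = "M", vicinity = 1L)),
    "Dissociation"), model = "toy", seed = 42L)
  text <- serialize_protocol(p)
  back <- restore_protocol(text)
  expect_equal(back, p)
  expect_identical(protocol_hash(back), protocol_hash(p))

  wil <- parse_protocol(published_protocol("wilkinson"))
  expect_equal(restore_protocol(serialize_protocol(wil)), wil)

  bad <- sub("version: '1'", "version: '99'", text)
  expect_error(restore_protocol(bad), "version")
})

make_filled_store <- function() {
  store <- crn_store()
  add_structure(store, water_structure(), calc)
  add_structure(store, co_structure(), calc)
  mh <- structure_new(c("M", "H"), rbind(c(0, 0, 0), c(1.6, 0, 0)),
                      multiplicity = 2L, energy = -170, model = "toy")
  add_structure(store, mh, calc)
  mc <- structure_new(c("M", "C"), rbind(c(0, 0, 0), c(2.0, 0, 0)),
                      energy = -280, model = "toy")
  add_structure(store, mc, calc)
  h2 <- h2_structure()
  h2$energy <- -436
  h2$model <- "toy"
  add_structure(store, h2, calc)
  store
}

test_that("selection steps restrict aggregates and sites", {
  store <- make_filled_store()
  ctx <- list(calculator = calc)

  all_sel <- apply_selection("All_Compounds_Selection", store, ctx)
  expect_length(all_sel$aggregates, 5L)

  met <- apply_selection(list(name = "Central_Metal_Selection",
                              settings = list(metal = "M")),
                         store, ctx)
  expect_length(met$aggregates, 2L)
  mh <- lowest_structure(store, met$aggregates[1])
  sites <- met$site_filter(mh)
  # all atoms of a diatomic M complex are within 2 bonds of the metal
  expect_setequal(sites, 1:2)
  # vicinity zero keeps only the metal itself
  met0 <- apply_selection(list(name = "Central_Metal_Selection",
                               settings = list(metal = "M",
                                               vicinity = 0L)),
                          store, ctx)
  expect_equal(met0$site_filter(mh), which(mh$symbols == "M"))

  expect_error(apply_selection("Products_Selection", store, ctx),
               "preceding expansion")

  motif <- apply_selection(
    list(name = "Structural_Motif_Selection",
         settings = list(motif = list(symbols = c("O", "H"),
                                      edges = list(c(1L, 2L))))),
    store, ctx)
  # O-H bond occurs in water only
  expect_length(motif$aggregates, 1L)

  # n lowest conformers per aggregate
  w2 <- water_structure()
  w2$coords[2, ] <- w2$coords[2, ] + c(0.08, 0, 0)
  w2$energy <- -900
  w3 <- water_structure()
  w3$coords[2, ] <- w3$coords[2, ] + c(0.12, 0, 0)
  w3$energy <- -880
  add_structure(store, w2, calc)
  add_structure(store, w3, calc)
  low <- apply_selection(list(name = "Energy_Selection",
                              settings = list(n_lowest = 1L)),
                         store, ctx)
  w_agg <- store$structures[[low$structures[1]]]$aggregate_id
  members <- store$compounds[[w_agg]]$members
  picked <- intersect(low$structures, members)
  expect_length(picked, 1L)
  expect_equal(store$structures[[picked]]$structure$energy, -900)

  # conjunction never enlarges a selection
  joint <- intersect_selections(all_sel, met)
  expect_true(all(joint$aggregates %in% all_sel$aggregates))
  expect_lte(length(joint$aggregates), length(met$aggregates))
})

test_that("previews enumerate exactly what execution runs", {
  store <- make_filled_store()
  sel <- apply_selection("All_Compounds_Selection", store,
                         list(calculator = calc))
  assoc <- list(name = "Association",
                settings = list(a_contains = "M", b_excludes = "M",
                                site_elements_a = "M"))
  pv <- preview_expansion(sel, assoc, store, calc)
  expect_gt(pv$count, 0L)
  n_calc_before <- count_records(store)$calculations
  expect_equal(count_records(store)$calculations, n_calc_before)

  rep <- run_expansion(assoc, sel, store, calc, seed = 1L)
  expect_length(rep$calculations, pv$count)
  jobs <- vapply(rep$calculations, function(q) {
    store$calculations[[q]]$job
  }, "")
  expect_equal(sort(unname(jobs)),
               sort(vapply(pv$trials, `[[`, "", "kind")))

  # conjoining a site filter never increases the preview count
  met <- apply_selection(list(name = "Central_Metal_Selection",
                              settings = list(metal = "M")),
                         store, list(calculator = calc))
  pv2 <- preview_expansion(intersect_selections(sel, met), assoc,
                           store, calc)
  expect_lte(pv2$count, pv$count)
})

test_that("expansions classify results and report exact diffs", {
  store <- make_filled_store()
  before <- crnsteer:::snapshot_ids(store)
  sel <- apply_selection("All_Compounds_Selection", store,
                         list(calculator = calc))
  assoc <- list(name = "Association",
                settings = list(a_contains = "M", b_excludes = "M",
                                site_elements_a = "M",
                                site_elements_b = "O"))
  rep <- run_expansion(assoc, sel, store, calc, seed = 1L)
  expect_true(rep$complete)
  after <- crnsteer:::snapshot_ids(store)
  # the report's created ids equal the store snapshot diff
  expect_setequal(rep$created_structures,
                  setdiff(after$structures, before$structures))
  expect_setequal(rep$created_reactions,
                  setdiff(after$reactions, before$reactions))
  expect_gt(length(rep$created_aggregates), 0L)
  expect_store_partition(store)

  # all calculations finished (completion gating)
  statuses <- vapply(names(store$calculations), function(q) {
    store$calculations[[q]]$status
  }, "")
  expect_true(all(statuses %in% c("done", "failed")))

  # optimizing an already-optimized set creates no new aggregates
  opt_store <- crn_store()
  h2 <- optimize_minimum(h2_structure(0.74), calc)
  add_structure(opt_store, h2, calc)
  sel2 <- apply_selection("All_Compounds_Selection", opt_store,
                          list(calculator = calc))
  rep2 <- run_expansion(list(name = "Simple_Optimization",
                             settings = list()),
                        sel2, opt_store, calc)
  expect_length(rep2$created_aggregates, 0L)
})

test_that("protocol runs are ordered, gated and reproducible", {
  fx <- make_fixture("ligand-exchange", seed = 7)
  lcalc <- toy_calculator(fx$potential)
  res <- run_protocol(fx$protocol, calculator = lcalc,
                      input_structures = fx$structures)
  expect_equal(res$store$meta$completed_steps, length(fx$protocol$steps))
  expect_identical(res$store$meta$protocol_hash,
                   protocol_hash(fx$protocol))
  # every calculation is finished at the end of each step
  statuses <- vapply(names(res$store$calculations), function(q) {
    res$store$calculations[[q]]$status
  }, "")
  expect_false(any(statuses %in% c("pending", "running")))
  expect_store_partition(res$store)

  # determinism: identical reruns give identical record sets
  res2 <- run_protocol(fx$protocol, calculator = lcalc,
                       input_structures = fx$structures)
  expect_identical(count_records(res2$store), count_records(res$store))
  rx_sig <- function(store) {
    vapply(store$reactions, function(r) {
      paste(paste(r$reactants, collapse = "+"),
            paste(r$products, collapse = "+"), sep = ">")
    }, "")
  }
  expect_identical(rx_sig(res2$store), rx_sig(res$store))

  # the ledger outcome: an M-O compound exists and a barrierless
  # dissociation step was recorded
  formulas <- vapply(names(res$store$compounds), function(id) {
    crnsteer:::structure_formula(lowest_structure(res$store,
                                                  id)$symbols)
  }, "")
  expect_true(fx$ledger$expect_formula %in% formulas)
  types <- vapply(res$store$elementary_steps, `[[`, "", "type")
  expect_true("barrierless" %in% types)
})
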