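calc <- toy_calculator()

fake_trajectory <- function(orders, kinds, energies = NULL) {
  orders <- matrix(orders, nrow = length(orders) / length(kinds))
  if (is.null(energies)) energies <- seq_len(nrow(orders))
  out <- list(frames = vector("list", nrow(orders)),
              energies = energies, pair_orders = orders,
              coordinate = data.frame(kind = kinds),
              reason = "target-change-reached")
  class(out) <- "crn_trajectory"
  out
}

test_that("reaction coordinates validate their pairs", {
  rc <- reaction_coordinate(rbind(c(1L, 2L), c(3L, 4L)),
                            c("associative", "dissociative"))
  expect_equal(rc$scale, c(1, 1))
  expect_error(reaction_coordinate(matrix(integer(0), 0, 2)),
               "at least one")
  expect_error(reaction_coordinate(rbind(c(2L, 2L))), "differ")
  expect_error(reaction_coordinate(rbind(c(1L, 2L), c(2L, 1L))),
               "duplicate")
})

test_that("reactive complexes are placed deterministically", {
  w <- water_structure()
  co <- co_structure()
  # unimolecular: geometry untouched
  uni <- build_reactive_complex(w, coordinate =
                                  reaction_coordinate(rbind(c(1L, 2L)),
                                                      "dissociative"))
  expect_identical(uni$structure$coords, w$coords)

  # bimolecular: site pair faces at the start separation
  cx <- build_reactive_complex(w, co, sitesA = 1L, sitesB = 1L,
                               start_sep = 3.0, seed = 9)
  d <- sqrt(sum((cx$structure$coords[1, ] -
                   cx$structure$coords[4, ])^2))
  expect_equal(d, 3.0, tolerance = 1e-3)
  expect_equal(cx$coordinate$i, 1L)
  expect_equal(cx$coordinate$j, 4L)

  cx2 <- build_reactive_complex(w, co, sitesA = 1L, sitesB = 1L,
                                start_sep = 3.0, seed = 9)
  expect_identical(cx$structure$coords, cx2$structure$coords)

  # impossible placement clashes out
  expect_error(build_reactive_complex(w, co, sitesA = 1L, sitesB = 1L,
                                      start_sep = 0.2, seed = 1),
               "clashing placement")
})

test_that("forced scans move coordinates and stop on target change", {
  # dissociative scan on a bound diatomic: bond order falls below 0.5
  h2 <- optimize_minimum(h2_structure(0.74), calc)
  cx <- build_reactive_complex(h2, coordinate =
                                 reaction_coordinate(rbind(c(1L, 2L)),
                                                     "dissociative"))
  traj <- run_scan(cx, calc, step_size = 0.1, max_steps = 50)
  expect_equal(traj$reason, "target-change-reached")
  expect_true(nrow(traj$pair_orders) < 50)
  d_seq <- vapply(traj$frames, function(f) {
    as.numeric(dist(f$structure$coords))
  }, 0)
  expect_true(all(diff(d_seq) > 0))  # monotone distance sequence
  # energies reproduce the Morse closed form frame by frame
  morse <- function(d) 436 * ((1 - exp(-1.9 * (d - 0.74)))^2 - 1)
  expect_equal(traj$energies, morse(d_seq), tolerance = 1e-6)

  # zero allowed steps: single-frame trajectory, reason max-steps
  t0 <- run_scan(cx, calc, max_steps = 0)
  expect_length(t0$frames, 1L)
  expect_equal(t0$reason, "max-steps")
})

test_that("bond-change detection scans the order series", {
  t1 <- fake_trajectory(c(0.0, 0.2, 0.5, 0.9), "associative")
  expect_equal(detect_bond_change(t1, threshold = 0.3), 3L)

  t2 <- fake_trajectory(c(0.0, 0.1, 0.2, 0.25), "associative")
  expect_true(is.na(detect_bond_change(t2, threshold = 0.3)))

  # multi-pair coordinates: the change frame is the max over per-pair
  # first crossings (computed brute-force)
  set.seed(5)
  for (r in 1:20) {
    k <- sample(1:3, 1)
    nf <- sample(4:12, 1)
    kinds <- sample(c("associative", "dissociative"), k, replace = TRUE)
    po <- vapply(seq_len(k), function(q) {
      if (kinds[q] == "associative") sort(runif(nf)) else {
        sort(runif(nf), decreasing = TRUE)
      }
    }, numeric(nf))
    tt <- fake_trajectory(as.numeric(po), kinds)
    crossings <- vapply(seq_len(k), function(q) {
      hit <- if (kinds[q] == "associative") {
        which(po[, q] > 0.5)
      } else {
        which(po[, q] < 0.5)
      }
      if (length(hit)) hit[1] else NA_integer_
    }, 0L)
    expected <- if (anyNA(crossings)) NA_integer_ else {
      max(crossings)
    }
    expect_equal(detect_bond_change(tt), expected)
  }
})

test_that("TS-guess selection follows the rule cascade", {
  # event seen, maximum before it: pick the last prior maximum
  r <- select_ts_guess(c(0, 5, 2, 8, 1), change_frame = 4L)
  expect_equal(as.integer(r), 2L)
  expect_equal(attr(r, "rule"), "last-before-event")

  # event seen on a rising flank with no prior maximum: first after
  r <- select_ts_guess(c(0, 1, 2, 3, 4, 2), change_frame = 2L)
  expect_equal(as.integer(r), 5L)
  expect_equal(attr(r, "rule"), "first-after-event")

  # no event: highest local maximum
  r <- select_ts_guess(c(0, 3, 1, 6, 2))
  expect_equal(as.integer(r), 4L)

  # no interior maximum anywhere: unsuccessful trial
  expect_true(is.na(select_ts_guess(c(0, 1, 2, 3))))
  expect_error(select_ts_guess(c(1, 2)), ">= 3 frames")

  # plateaus resolve to their first frame
  expect_equal(as.integer(select_ts_guess(c(0, 4, 4, 1, 0))), 2L)
})

test_that("TS-guess selection matches the brute-force oracle", {
  suite <- make_fixture("profile-suite", seed = 23, n_profiles = 300)
  for (pr in suite$profiles) {
    got <- select_ts_guess(pr$energies, pr$change_frame)
    expect_identical(as.integer(got), as.integer(pr$expected))
  }
})

test_that("haptic groups share one pair's worth of force", {
  # eta-2 formation: two pairs from one metal onto adjacent carbons,
  # plus an independent pair elsewhere
  bo <- matrix(0, 6, 6)
  bo[2, 3] <- bo[3, 2] <- 1  # adjacent carbons
  coord <- reaction_coordinate(rbind(c(1L, 2L), c(1L, 3L), c(4L, 5L)),
                               "associative")
  scaled <- scale_haptic_forces(coord, bo)
  expect_equal(scaled$scale, c(0.5, 0.5, 1.0))
  expect_equal(scaled$i, coord$i)  # membership unchanged
  expect_equal(scaled$j, coord$j)

  # single pair untouched; disjoint singles untouched
  single <- scale_haptic_forces(reaction_coordinate(rbind(c(1L, 2L))),
                                bo)
  expect_equal(single$scale, 1)
  two <- scale_haptic_forces(
    reaction_coordinate(rbind(c(1L, 2L), c(4L, 5L))), matrix(0, 6, 6))
  expect_equal(two$scale, c(1, 1))

  # per-group total force equals a single pair's force
  grp <- scale_haptic_forces(
    reaction_coordinate(rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L))),
    matrix(0, 6, 6))
  expect_equal(sum(grp$scale), 1)
})

test_that("step validation accepts barriers and rejects non-reactions", {
  # association over a steric barrier: H approaches the carbon of a
  # bound O-C unit against the oxygen's long-range core repulsion,
  # giving a real saddle between the separated and chained minima
  pot <- toy_potential(
    data.frame(a = c("O", "C", "O", "C", "H", "O"),
               b = c("C", "H", "O", "C", "H", "H"),
               D = c(360, 150, 150, 350, 436, 0),
               beta = c(2.2, 3.5, 2.3, 1.9, 1.9, 1.9),
               r0 = c(1.43, 1.09, 1.21, 1.54, 0.74, 1.0)),
    repulsion_A = 2000, repulsion_b = 1.2)
  scalc <- toy_calculator(pot, gtol = 1e-5)
  s <- structure_new(c("O", "C", "H"),
                     rbind(c(0, 0, 0), c(1.43, 0, 0), c(3.93, 0, 0)),
                     multiplicity = 2L)
  cx <- build_reactive_complex(
    s, coordinate = reaction_coordinate(rbind(c(2L, 3L)),
                                        "associative"))
  traj <- run_scan(cx, scalc, step_size = 0.1, max_steps = 60)
  expect_equal(traj$reason, "target-change-reached")
  cf <- detect_bond_change(traj)
  ts <- select_ts_guess(traj, cf)
  expect_false(is.na(ts))
  expect_equal(attr(ts, "rule"), "last-before-event")
  v <- validate_step(traj, ts, scalc)
  expect_true(v$accepted)
  expect_false(same_aggregate(v$reactant, v$product))
  expect_gte(v$ts_energy, v$reactant$energy)
  expect_gte(v$ts_energy, v$product$energy)
  # reactant side is the separated pair, product the bonded chain
  expect_equal(max(structure_graph(v$reactant)$component), 2L)
  expect_equal(max(structure_graph(v$product)$component), 1L)
  expect_true(structure_graph(v$product)$adj[2, 3])

  # interior frame requirement
  expect_false(validate_step(traj, 1L, calc)$accepted)
  expect_false(validate_step(traj, NA_integer_, calc)$accepted)

  # a barrier-free downhill association has no saddle to validate:
  # both sides relax into the same basin ("no reaction")
  h <- structure_new("H", matrix(0, 1, 3), multiplicity = 2L)
  hcx <- build_reactive_complex(h, h, sitesA = 1L, sitesB = 1L,
                                seed = 4)
  htraj <- run_scan(hcx, calc, step_size = 0.1, max_steps = 40)
  mid <- max(2L, length(htraj$frames) %/% 2L)
  vv <- validate_step(htraj, mid, calc)
  expect_false(vv$accepted)
})

test_that("dissociation combinations match the combinatorial oracle", {
  frag <- list("H", "H")
  combos <- dissociation_combinations(frag, parent_charge = 0L,
                                      parent_mult = 1L,
                                      charge_window = 1L)
  # brute-force oracle: enumerate every (q1,q2,m1,m2) and keep the
  # legal ones
  legal <- 0L
  for (q1 in -1:1) {
    for (q2 in -1:1) {
      if (q1 + q2 != 0L) next
      for (m1 in 1:2) {
        for (m2 in 1:2) {
          ok1 <- ((1 - q1) %% 2L) == ((m1 - 1L) %% 2L)
          ok2 <- ((1 - q2) %% 2L) == ((m2 - 1L) %% 2L)
          if (ok1 && ok2) legal <- legal + 1L
        }
      }
    }
  }
  expect_equal(nrow(combos), legal)
  # all candidate splits conserve the parent charge
  expect_true(all(combos$q1 + combos$q2 == 0L))
})

test_that("the screen picks the lowest combination and probes barrierless", {
  h2 <- h2_structure(0.74)
  diss <- dissociation_screen(h2, rbind(c(1L, 2L)), calc)
  expect_false(diss$failed)
  # homolysis into two doublet H atoms wins under the default offsets
  best <- diss$combinations[diss$best, ]
  expect_equal(c(best$q1, best$q2), c(0L, 0L))
  expect_equal(c(best$m1, best$m2), c(2L, 2L))
  expect_equal(diss$dissociation_energy,
               2 * 80 - (-436), tolerance = 1e-4)

  # a strongly bound pair re-associates: barrierless step found
  probe <- barrierless_probe(diss, calc)
  expect_false(is.null(probe))
  expect_equal(probe$type, "barrierless")
  expect_true(same_aggregate(probe$supersystem, diss$parent))

  # rigged heterolytic offsets flip the best combination
  rigged <- toy_potential(default_toy_potential()$pairs,
                          offsets = data.frame(
                            formula = "H", charge = c(1L, -1L),
                            multiplicity = 1L, offset = -300))
  rcalc <- toy_calculator(rigged)
  rdiss <- dissociation_screen(h2, rbind(c(1L, 2L)), rcalc)
  rbest <- rdiss$combinations[rdiss$best, ]
  expect_setequal(c(rbest$q1, rbest$q2), c(-1L, 1L))

  # a failing supersystem optimization yields no barrierless step
  broken <- toy_calculator(toy_potential(
    data.frame(a = "C", b = "C", D = 350, beta = 1.9, r0 = 1.54)))
  expect_null(barrierless_probe(diss, broken))
})

test_that("the follow-up queue holds exactly sub-threshold dissociations", {
  mk_result <- function(de, failed = FALSE) {
    structure(list(dissociation_energy = de, failed = failed),
              class = "crn_dissociation")
  }
  results <- list(mk_result(150), mk_result(250), mk_result(199.9),
                  mk_result(NA, failed = TRUE), mk_result(0))
  expect_equal(followup_queue(results), c(1L, 3L, 5L))
  expect_equal(followup_queue(results, threshold = 100), 5L)
})

test_that("trajectories export as multi-frame XYZ plus a profile table", {
  h2 <- optimize_minimum(h2_structure(0.74), calc)
  cx <- build_reactive_complex(h2, coordinate =
                                 reaction_coordinate(rbind(c(1L, 2L)),
                                                     "dissociative"))
  traj <- run_scan(cx, calc, max_steps = 5)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  tab <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, xyz, tab)
  expect_length(read_xyz(xyz), length(traj$frames))
  profile <- read.delim(tab)
  expect_equal(nrow(profile), length(traj$frames))
  expect_equal(profile$energy, traj$energies, tolerance = 1e-9)
})
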