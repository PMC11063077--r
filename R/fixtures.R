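#' Published protocol fixtures
#'
#' The three homogeneous-catalysis steering protocols shipped with the
#' package as plain-text keyword lists: hydrogenation by a rhodium
#' phosphine catalyst (full alternating protocol), olefin
#' polymerization by a zirconocene catalyst (expansion-only list), and
#' methanol carbonylation by a rhodium iodide catalyst (expansion-only
#' list).
#'
#' @param name One of `"wilkinson"`, `"ziegler_natta"`, `"monsanto"`;
#'   `NULL` lists the available names.
#' @return The protocol text, or the available names.
#' @export
published_protocol <- function(name = NULL) {
  dir <- system.file("extdata", "protocols", package = "crnsteer")
  avail <- sub("\\.txt$", "", list.files(dir, pattern = "\\.txt$"))
  if (is.null(name)) return(avail)
  path <- file.path(dir, paste0(name, ".txt"))
  if (!file.exists(path)) {
    stop("unknown protocol fixture: ", name, " (available: ",
         paste(avail, collapse = ", "), ")")
  }
  paste(readLines(path), collapse = "\n")
}

# ---------------------------------------------------------------------
# independent TS-guess oracle (brute force; used by the profile-suite
# fixture labels and by the test suite)

# Quadratic local least-squares smoother: an independent implementation
# of Savitzky-Golay smoothing via explicit polynomial fits per window.
oracle_smooth <- function(e, window = 5L, poly_order = 2L) {
  n <- length(e)
  w <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (w < poly_order + 2L) return(e)
  half <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - half, n - w + 1L))
    idx <- lo:(lo + w - 1L)
    x <- idx - i
    X <- outer(x, 0:poly_order, `^`)
    beta <- qr.solve(X, e[idx])
    out[i] <- beta[1]
  }
  out
}

# Brute-force interior local maxima: walk to the previous and next
# distinct values; plateaus report their first frame.
oracle_maxima <- function(v) {
  n <- length(v)
  out <- integer(0)
  for (i in 2:(n - 1L)) {
    if (i > 1L && v[i - 1L] == v[i]) next  # not the plateau head
    l <- i - 1L
    while (l >= 1L && v[l] == v[i]) l <- l - 1L
    r <- i + 1L
    while (r <= n && v[r] == v[i]) r <- r + 1L
    if (l < 1L || r > n) next  # plateau touches an endpoint
    if (v[l] < v[i] && v[r] < v[i]) out <- c(out, i)
  }
  out
}

#' Brute-force TS-guess oracle
#'
#' Independent reference for the TS-guess selection cascade, built on
#' exhaustive maxima enumeration and an explicit per-window polynomial
#' smoother.  Used to label the `profile-suite` fixture and to verify
#' [select_ts_guess()].
#'
#' @param energies Numeric energy profile.
#' @param change_frame Event frame (1-based) or `NA`.
#' @param window,poly_order Smoothing parameters.
#' @return Integer frame or `NA`.
#' @export
ts_guess_oracle <- function(energies, change_frame = NA,
                            window = 5L, poly_order = 2L) {
  if (length(energies) < 3L) stop("profile must have >= 3 frames")
  raw <- oracle_maxima(energies)
  if (is.na(change_frame)) {
    if (!length(raw)) return(NA_integer_)
    best <- raw[1]
    for (m in raw) if (energies[m] > energies[best]) best <- m
    return(best)
  }
  smoothed <- oracle_smooth(energies, window, poly_order)
  screen <- any(oracle_maxima(smoothed) < change_frame)
  before <- raw[raw < change_frame]
  after <- raw[raw >= change_frame]
  if (screen && length(before)) return(max(before))
  if (length(after)) return(min(after))
  if (length(before)) return(max(before))
  NA_integer_
}

# ---------------------------------------------------------------------
# fixture registry

fixture_names <- c("diatomics", "ligand-exchange", "toy-polymerization",
                   "toy-monsanto-shape", "profile-suite")

#' Generate a registered toy fixture
#'
#' Deterministic generator of the toy chemical systems, surrogate
#' parameter tables and synthetic scan profiles that make every module
#' testable without downloads.  Output is a pure function of
#' `(name, seed)`.
#'
#' Registered fixtures:
#' * `diatomics` — three diatomics (H2, CO, M-H) with the default
#'   surrogate table; optimization-only protocol.
#' * `ligand-exchange` — an M-H complex and an oxygen ligand; protocol
#'   associates O at the metal and screens the M-H dissociation
#'   (exercising the barrierless probe).
#' * `toy-polymerization` — an M-C catalyst plus one-carbon monomer,
#'   with an Association/Rearrangement protocol that inserts one
#'   monomer per pair into the growing metal-bound chain.
#' * `toy-monsanto-shape` — a hand-energied network with two
#'   cost-distinct routes to one product diverging at one intermediate;
#'   see [build_fixture_store()].
#' * `profile-suite` — labeled synthetic energy/bond-change profiles
#'   with TS-guess answers from [ts_guess_oracle()].
#'
#' @param name Registered fixture name.
#' @param seed Integer seed.
#' @param n_profiles Number of profiles (profile-suite only).
#' @return A list with `name`, `seed`, and per-fixture fields:
#'   `structures`, `potential`, `protocol`, `ledger` (expected-outcome
#'   bookkeeping), or `profiles`.
#' @export
make_fixture <- function(name, seed = 1L, n_profiles = 1000L) {
  if (!name %in% fixture_names) {
    stop("unknown fixture name: ", name, " (registered: ",
         paste(fixture_names, collapse = ", "), ")")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  switch(name,
    "diatomics" = {
      structures <- list(
        structure_new(c("H", "H"), rbind(c(0, 0, 0), c(0.90, 0, 0)),
                      label = "h2"),
        structure_new(c("C", "O"), rbind(c(0, 0, 0), c(1.30, 0, 0)),
                      label = "co"),
        structure_new(c("M", "H"), rbind(c(0, 0, 0), c(1.80, 0, 0)),
                      multiplicity = 2L, label = "mh"))
      proto <- protocol(list("File_Input_Selection",
                             "Simple_Optimization"), seed = seed)
      list(name = name, seed = seed, structures = structures,
           potential = default_toy_potential(), protocol = proto,
           ledger = list(compounds = 3L, structures_min = 3L))
    },
    "ligand-exchange" = {
      structures <- list(
        structure_new(c("M", "H"), rbind(c(0, 0, 0), c(1.70, 0, 0)),
                      multiplicity = 2L, label = "mh"),
        structure_new("O", matrix(0, 1, 3), label = "o"))
      steps <- list(
        "File_Input_Selection",
        "Simple_Optimization",
        "All_Compounds_Selection",
        list(name = "Association",
             settings = list(a_contains = "M", b_excludes = "M",
                             site_elements_a = "M",
                             site_elements_b = "O")),
        "Products_Selection",
        list(name = "Dissociation",
             settings = list(bond_elements = c("M", "H"))))
      proto <- protocol(steps, seed = seed)
      list(name = name, seed = seed, structures = structures,
           potential = default_toy_potential(), protocol = proto,
           ledger = list(expect_formula = "HMO",
                         expect_barrierless = TRUE))
    },
    "toy-polymerization" = {
      structures <- list(
        structure_new(c("M", "C"), rbind(c(0, 0, 0), c(2.0, 0, 0)),
                      label = "cat"),
        structure_new("C", matrix(0, 1, 3), label = "monomer"))
      assoc <- list(name = "Association",
                    settings = list(a_contains = "M", b_excludes = "M",
                                    site_elements_a = "M",
                                    site_elements_b = "C"))
      rearr <- list(name = "Rearrangement",
                    settings = list(assoc_elements = c("C", "C"),
                                    dissoc_elements = c("M", "C"),
                                    n_coordinates = 2L))
      steps <- list("File_Input_Selection", "Simple_Optimization",
                    "All_Compounds_Selection", assoc,
                    "Products_Selection", rearr,
                    "All_Compounds_Selection", assoc,
                    "Products_Selection", rearr)
      proto <- protocol(steps, seed = seed)
      list(name = name, seed = seed, structures = structures,
           potential = default_toy_potential(), protocol = proto,
           ledger = list(seed_chain_carbons = 1L, growth_per_pair = 1L,
                         expect_chain_carbons = 3L))
    },
    "toy-monsanto-shape" = {
      # hand-energied network: two routes to P diverging at I1
      species <- data.frame(
        label = c("A", "I1", "I2a", "I2b", "P"),
        n_atoms = c(2L, 3L, 4L, 5L, 6L),
        energy = c(0, -10, -15, -5, -40))
      reactions <- data.frame(
        from = c("A", "I1", "I1", "I2a", "I2b"),
        to = c("I1", "I2a", "I2b", "P", "P"),
        ea = c(50, 30, 10, 20, 60))
      list(name = name, seed = seed, species = species,
           reactions = reactions,
           potential = default_toy_potential(),
           ledger = list(route_costs = c(100, 120),
                         diverge_at = "I1", n_routes = 2L))
    },
    "profile-suite" = {
      profiles <- vector("list", n_profiles)
      for (p in seq_len(n_profiles)) {
        len <- sample(6:40, 1L)
        e <- round(cumsum(stats::rnorm(len, 0, 2)), 1)
        if (stats::runif(1) < 0.5) {
          # inject a bump so maxima are common but not guaranteed
          at <- sample(2:(len - 1L), 1L)
          e[at] <- e[at] + stats::runif(1, 1, 8)
        }
        cf <- if (stats::runif(1) < 0.6) {
          sample(2:len, 1L)
        } else {
          NA_integer_
        }
        profiles[[p]] <- list(energies = e, change_frame = cf,
                              expected = ts_guess_oracle(e, cf))
      }
      list(name = name, seed = seed, profiles = profiles)
    })
}

#' Build the store of a network-shaped fixture
#'
#' Materializes the `toy-monsanto-shape` fixture into a CRN store:
#' each species is a hydrogen chain of distinct length with an assigned
#' electronic energy, each reaction a single with-TS elementary step
#' whose TS energy realizes the prescribed activation energy.
#'
#' @param fixture Output of `make_fixture("toy-monsanto-shape", seed)`.
#' @return List with `store` and `ids` (label -> aggregate id).
#' @export
build_fixture_store <- function(fixture) {
  stopifnot(identical(fixture$name, "toy-monsanto-shape"))
  store <- crn_store()
  ids <- character(0)
  sids <- character(0)
  for (r in seq_len(nrow(fixture$species))) {
    sp <- fixture$species[r, ]
    n <- sp$n_atoms
    coords <- cbind(0.74 * (seq_len(n) - 1), 0, 0)
    s <- structure_new(rep("H", n), coords,
                       multiplicity = if (n %% 2L) 2L else 1L,
                       label = sp$label, energy = sp$energy,
                       model = "assigned")
    res <- add_structure(store, s)
    ids[sp$label] <- res$aggregate_id
    sids[sp$label] <- res$structure_id
  }
  for (r in seq_len(nrow(fixture$reactions))) {
    rx <- fixture$reactions[r, ]
    e_from <- fixture$species$energy[fixture$species$label == rx$from]
    step <- elementary_step(sids[rx$from], sids[rx$to],
                            type = "with-TS",
                            ts_energy = e_from + rx$ea,
                            model = "assigned")
    add_elementary_step(store, step)
  }
  list(store = store, ids = ids)
}

#' Write a fixture to disk
#'
#' Writes the fixture's starting structures as XYZ files, the surrogate
#' table as structured text, and the ready-to-run protocol.
#'
#' @param fixture Output of [make_fixture()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(fixture$structures)) {
    for (s in fixture$structures) {
      write_xyz(s, file.path(dir, paste0(s$label, ".xyz")))
    }
  }
  if (!is.null(fixture$potential)) {
    write_potential(fixture$potential, file.path(dir, "potential.yaml"))
  }
  if (!is.null(fixture$protocol)) {
    writeLines(serialize_protocol(fixture$protocol),
               file.path(dir, "protocol.yaml"))
  }
  if (!is.null(fixture$profiles)) {
    # plain two-column text per profile: energy, change indicator
    pd <- file.path(dir, "profiles")
    dir.create(pd, showWarnings = FALSE)
    for (p in seq_along(fixture$profiles)) {
      pr <- fixture$profiles[[p]]
      ind <- as.integer(seq_along(pr$energies) >=
                          ifelse(is.na(pr$change_frame), Inf,
                                 pr$change_frame))
      utils::write.table(
        data.frame(energy = pr$energies, changed = ind),
        file.path(pd, sprintf("profile_%04d.txt", p)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
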