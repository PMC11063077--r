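#' Exploration protocols
#'
#' A steering protocol is an ordered list of exploration steps, each a
#' Selection Step (choosing aggregates, structures and reactive sites)
#' or a Network Expansion Step (adding calculations and their results to
#' the CRN), together with a global model tag and a random seed.  The
#' serialized protocol is the reproducibility artifact of an
#' exploration: publishing it (plus inputs and engine) makes the run
#' repeatable.
#'
#' @name exploration-protocols
NULL

.selection_keywords <- c(
  "File_Input_Selection", "All_Compounds_Selection",
  "Products_Selection", "Central_Metal_Selection",
  "Energy_Selection", "Structural_Motif_Selection")

.expansion_keywords <- c(
  "Dissociation", "Association", "Rearrangement",
  "Conformer_Creation", "Simple_Optimization")

.protocol_version <- "1"

step_type <- function(name) {
  if (name %in% .selection_keywords) return("selection")
  if (name %in% .expansion_keywords) return("expansion")
  stop("unknown exploration step keyword: ", name)
}

#' Construct a protocol
#'
#' @param steps List of steps; each either a keyword string or a list
#'   with `name` and optional `settings`.
#' @param model Global model tag.
#' @param seed Integer random seed.
#' @param strict Enforce Selection/Expansion alternation (after an
#'   optional leading input selection)?
#' @return An object of class `crn_protocol`.
#' @export
protocol <- function(steps = list(), model = "toy", seed = 1L,
                     strict = FALSE) {
  steps <- lapply(steps, function(s) {
    if (is.character(s)) s <- list(name = s)
    if (is.null(s$settings)) s$settings <- list()
    s$type <- step_type(s$name)
    s[c("name", "type", "settings")]
  })
  if (strict && length(steps) > 1L) {
    types <- vapply(steps, `[[`, "", "type")
    if (any(types[-1] == types[-length(types)])) {
      stop("non-alternating Selection/Expansion sequence")
    }
  }
  p <- list(version = .protocol_version, model = model,
            seed = as.integer(seed), steps = steps)
  class(p) <- "crn_protocol"
  p
}

#' @export
print.crn_protocol <- function(x, ...) {
  cat(sprintf("<crn_protocol> %d steps, model '%s', seed %d\n",
              length(x$steps), x$model, x$seed))
  for (s in x$steps) {
    cat(sprintf("  [%s] %s\n", substr(s$type, 1, 3), s$name))
  }
  invisible(x)
}

#' Parse a protocol from text
#'
#' Accepts the compact bracketed keyword list used in publications
#' (`"[File_Input_Selection, Dissociation, ...]"`, default settings) or
#' the structured YAML form written by [serialize_protocol()] (with
#' per-step settings, model and seed).  Unknown keywords raise an error
#' naming the offending token.  By default consecutive Expansion steps
#' are accepted (the prior selection is implicitly reused, matching
#' published expansion-only listings); `strict = TRUE` enforces
#' alternation.
#'
#' @param text Protocol text (single string or lines), or a file path
#'   ending in `.yml`/`.yaml`/`.txt`.
#' @param strict Enforce alternation.
#' @return A `crn_protocol`.
#' @export
parse_protocol <- function(text, strict = FALSE) {
  if (length(text) == 1L && grepl("\\.(ya?ml|txt)$", text) &&
      file.exists(text)) {
    text <- paste(readLines(text), collapse = "\n")
  }
  text <- paste(text, collapse = "\n")
  if (grepl("steps:", text)) {
    return(restore_protocol(text, strict = strict))
  }
  body <- trimws(text)
  if (!grepl("^\\[", body) || !grepl("\\]$", body)) {
    stop("malformed protocol list: expected [Keyword, Keyword, ...]")
  }
  body <- sub("^\\[", "", sub("\\]$", "", body))
  toks <- trimws(strsplit(body, ",")[[1]])
  toks <- toks[nzchar(toks)]
  protocol(as.list(toks), strict = strict)
}

#' Expansion sub-list of a protocol
#'
#' Returns the Network Expansion Step names, omitting Selection steps
#' and (by default) any leading structure-preparation optimizations, the
#' convention used when quoting a protocol's expansion list.
#'
#' @param p A `crn_protocol`.
#' @param drop_preparation Drop leading `Simple_Optimization` steps?
#' @return Character vector of expansion step names.
#' @export
expansion_sequence <- function(p, drop_preparation = TRUE) {
  nm <- vapply(p$steps, `[[`, "", "name")
  ty <- vapply(p$steps, `[[`, "", "type")
  exp <- nm[ty == "expansion"]
  if (drop_preparation) {
    while (length(exp) && exp[1] == "Simple_Optimization") {
      exp <- exp[-1]
    }
  }
  exp
}

#' Serialize / restore a protocol
#'
#' Round-trips a protocol through structured text (YAML) including all
#' per-step settings, the model tag and the seed.  A version mismatch on
#' restore is flagged as an error.
#'
#' @param p A `crn_protocol`.
#' @return `serialize_protocol()` returns a single YAML string;
#'   `restore_protocol()` returns a `crn_protocol`.
#' @export
serialize_protocol <- function(p) {
  obj <- list(version = p$version, model = p$model, seed = p$seed,
              steps = lapply(p$steps, function(s) {
                out <- list(name = s$name)
                if (length(s$settings)) out$settings <- s$settings
                out
              }))
  yaml::as.yaml(obj)
}

#' @rdname serialize_protocol
#' @param text YAML text.
#' @param strict Enforce alternation.
#' @export
restore_protocol <- function(text, strict = FALSE) {
  obj <- yaml::yaml.load(paste(text, collapse = "\n"))
  if (!identical(as.character(obj$version), .protocol_version)) {
    stop("unsupported protocol version: ", obj$version)
  }
  protocol(obj$steps, model = obj$model, seed = obj$seed,
           strict = strict)
}

protocol_step_hash <- function(step) {
  fnv1a(yaml::as.yaml(step[c("name", "settings")]))
}

#' Protocol hash
#'
#' @param p A `crn_protocol`.
#' @return Hash string of the serialized protocol.
#' @export
protocol_hash <- function(p) {
  fnv1a(serialize_protocol(p))
}

# ---------------------------------------------------------------------
# Selection Steps

new_selection <- function(aggregates, structures = NULL,
                          site_filter = NULL, kind = "selection") {
  sel <- list(aggregates = sort(unique(aggregates)),
              structures = structures, site_filter = site_filter,
              kind = kind)
  class(sel) <- "crn_selection"
  sel
}

#' Apply a Selection Step
#'
#' Produces the filter result that limits the next expansion: a set of
#' aggregates, optionally explicit structures, and an optional
#' reactive-site filter mapping a structure to its allowed atom indices.
#'
#' Implemented kinds: `File_Input_Selection` (explicit user structures,
#' added to the store), `All_Compounds_Selection` (every current
#' aggregate), `Products_Selection` (aggregates first created by the
#' preceding expansion), `Central_Metal_Selection` (aggregates holding
#' the configured metal, sites restricted to its graph vicinity),
#' `Energy_Selection` (n lowest-energy conformers, maximum-diversity
#' conformer subsets, or aggregates reachable within an
#' activation-energy cutoff), `Structural_Motif_Selection` (aggregates
#' whose graph contains a configured subgraph).
#'
#' @param step A protocol step (list with `name`, `settings`).
#' @param store A `crn_store`.
#' @param context List with optional `last_report` (the preceding
#'   [run_expansion()] report), `input_structures`, `calculator`.
#' @return A `crn_selection`.
#' @export
apply_selection <- function(step, store, context = list()) {
  if (is.character(step)) step <- list(name = step, settings = list())
  st <- step$settings
  calc <- context$calculator
  switch(step$name,
    File_Input_Selection = {
      inputs <- context$input_structures
      if (!is.null(st$files)) {
        inputs <- unlist(lapply(st$files, read_xyz), recursive = FALSE)
      }
      if (is.null(inputs) || !length(inputs)) {
        stop("File_Input_Selection without input structures")
      }
      added <- lapply(inputs, function(s) {
        add_structure(store, s, calc)
      })
      new_selection(vapply(added, `[[`, "", "aggregate_id"),
                    structures = vapply(added, `[[`, "",
                                        "structure_id"))
    },
    All_Compounds_Selection = new_selection(aggregate_ids(store)),
    Products_Selection = {
      rep <- context$last_report
      if (is.null(rep)) {
        stop("Products_Selection without a preceding expansion")
      }
      new_selection(rep$created_aggregates)
    },
    Central_Metal_Selection = {
      metal <- st$metal
      if (is.null(metal)) stop("Central_Metal_Selection needs a metal")
      vic <- if (is.null(st$vicinity)) 2L else as.integer(st$vicinity)
      ids <- Filter(function(id) {
        metal %in% lowest_structure(store, id)$symbols
      }, aggregate_ids(store))
      filt <- function(structure) {
        g <- structure_graph(structure)
        m <- which(structure$symbols == metal)
        if (!length(m)) return(integer(0))
        dists <- graph_distances(g$adj, m)
        which(dists <= vic)
      }
      new_selection(unlist(ids), site_filter = filt)
    },
    Energy_Selection = {
      if (!is.null(st$n_lowest)) {
        sids <- unlist(lapply(aggregate_ids(store), function(id) {
          agg <- get_aggregate(store, id)
          en <- vapply(agg$members, function(sid) {
            e <- store$structures[[sid]]$structure$energy
            if (is.null(e)) Inf else e
          }, 0)
          agg$members[order(en)][seq_len(min(st$n_lowest,
                                             length(en)))]
        }))
        aggs <- unique(vapply(sids, function(sid) {
          store$structures[[sid]]$aggregate_id
        }, ""))
        new_selection(aggs, structures = sids)
      } else if (!is.null(st$n_diverse)) {
        sids <- unlist(lapply(aggregate_ids(store), function(id) {
          diverse_members(store, id, st$n_diverse)
        }))
        aggs <- unique(vapply(sids, function(sid) {
          store$structures[[sid]]$aggregate_id
        }, ""))
        new_selection(aggs, structures = sids)
      } else if (!is.null(st$ea_cutoff)) {
        start <- st$from
        if (is.null(start)) stop("ea_cutoff selection needs 'from'")
        new_selection(reachable_aggregates(store, start, st$ea_cutoff))
      } else {
        stop("Energy_Selection needs n_lowest, n_diverse or ea_cutoff")
      }
    },
    Structural_Motif_Selection = {
      if (is.null(st$motif)) {
        stop("Structural_Motif_Selection needs a motif")
      }
      ids <- Filter(function(id) {
        graph_contains_motif(
          structure_graph(lowest_structure(store, id)), st$motif)
      }, aggregate_ids(store))
      new_selection(unlist(ids))
    },
    stop("unknown Selection Step: ", step$name))
}

# BFS hop distances from a set of source atoms over an adjacency matrix.
graph_distances <- function(adj, sources) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[sources] <- 0
  frontier <- sources
  hop <- 0
  while (length(frontier)) {
    hop <- hop + 1
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] & d == Inf)
      d[nb] <- hop
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  d
}

# Maximum-diversity member subset by farthest-point selection on
# best-fit RMSD, seeded with the lowest-energy member.
diverse_members <- function(store, agg_id, n) {
  agg <- get_aggregate(store, agg_id)
  members <- agg$members
  if (length(members) <= n) return(members)
  coords <- lapply(members, function(sid) {
    store$structures[[sid]]$structure$coords
  })
  en <- vapply(members, function(sid) {
    e <- store$structures[[sid]]$structure$energy
    if (is.null(e)) Inf else e
  }, 0)
  chosen <- which.min(en)
  while (length(chosen) < n) {
    rest <- setdiff(seq_along(members), chosen)
    mind <- vapply(rest, function(r) {
      min(vapply(chosen, function(c) {
        fit_rmsd(coords[[r]], coords[[c]])
      }, 0))
    }, 0)
    chosen <- c(chosen, rest[which.max(mind)])
  }
  members[sort(chosen)]
}

# Aggregates reachable from a start set through reactions whose
# direction-appropriate activation energy is within the cutoff.
reachable_aggregates <- function(store, start, ea_cutoff) {
  seen <- start
  repeat {
    grew <- FALSE
    for (rx in store$reactions) {
      fwd_ok <- all(rx$reactants %in% seen) &&
        rx$ea_forward <= ea_cutoff
      bwd_ok <- all(rx$products %in% seen) &&
        rx$ea_backward <= ea_cutoff
      new_ids <- c(if (fwd_ok) rx$products, if (bwd_ok) rx$reactants)
      new_ids <- setdiff(new_ids, seen)
      if (length(new_ids)) {
        seen <- c(seen, new_ids)
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  sort(seen)
}

graph_contains_motif <- function(graph, motif) {
  msym <- motif$symbols
  madj <- matrix(FALSE, length(msym), length(msym))
  for (e in motif$edges) {
    madj[e[1], e[2]] <- TRUE
    madj[e[2], e[1]] <- TRUE
  }
  lev <- sort(unique(c(graph$symbols, msym)))
  big <- igraph::graph_from_adjacency_matrix(graph$adj,
                                             mode = "undirected")
  igraph::V(big)$color <- match(graph$symbols, lev)
  pat <- igraph::graph_from_adjacency_matrix(madj, mode = "undirected")
  igraph::V(pat)$color <- match(msym, lev)
  igraph::subgraph_isomorphic(pat, big, method = "vf2")
}

#' Conjoin two selections
#'
#' Combining several Selection Steps into one restricts by filter
#' conjunction: the aggregate sets intersect and both site filters must
#' accept a site.
#'
#' @param a,b `crn_selection` objects.
#' @return A `crn_selection`.
#' @export
intersect_selections <- function(a, b) {
  sf <- if (is.null(a$site_filter)) b$site_filter else {
    if (is.null(b$site_filter)) a$site_filter else {
      function(structure) {
        intersect(a$site_filter(structure), b$site_filter(structure))
      }
    }
  }
  structures <- if (is.null(a$structures)) b$structures else {
    if (is.null(b$structures)) a$structures else {
      intersect(a$structures, b$structures)
    }
  }
  new_selection(intersect(a$aggregates, b$aggregates),
                structures = structures, site_filter = sf)
}

# ---------------------------------------------------------------------
# trial enumeration (shared by preview and execution)

selected_sites <- function(structure, selection, elements = NULL) {
  sites <- seq_len(n_atoms(structure))
  if (!is.null(selection$site_filter)) {
    sites <- intersect(sites, selection$site_filter(structure))
  }
  if (!is.null(elements)) {
    sites <- sites[structure$symbols[sites] %in% elements]
  }
  sites
}

agg_has <- function(store, id, contains = NULL, excludes = NULL) {
  sym <- lowest_structure(store, id)$symbols
  if (!is.null(contains) && !all(contains %in% sym)) return(FALSE)
  if (!is.null(excludes) && any(excludes %in% sym)) return(FALSE)
  TRUE
}

#' Enumerate the trials an expansion would run
#'
#' Deterministic enumeration of the reactive complexes and coordinates a
#' Network Expansion Step would create for a given selection, without
#' writing any calculations.  [preview_expansion()] wraps this;
#' [run_expansion()] executes exactly this list, so a preview count
#' always equals the subsequent setup count.
#'
#' @param expansion Protocol step (list with `name`, `settings`).
#' @param selection A `crn_selection`.
#' @param store A `crn_store`.
#' @param calculator A `crn_calculator`.
#' @return List of trial descriptors.
#' @export
enumerate_trials <- function(expansion, selection, store, calculator) {
  st <- expansion$settings
  n_coord <- if (is.null(st$n_coordinates)) 1L else {
    as.integer(st$n_coordinates)
  }
  aggs <- selection$aggregates
  trials <- list()
  add_trial <- function(t) trials[[length(trials) + 1L]] <<- t
  switch(expansion$name,
    Simple_Optimization = {
      sids <- selection$structures
      if (is.null(sids)) {
        sids <- unlist(lapply(aggs, function(id) {
          get_aggregate(store, id)$members
        }))
      }
      for (sid in sort(sids)) {
        add_trial(list(kind = "optimize", structure_id = sid))
      }
    },
    Association = {
      cand_a <- Filter(function(id) {
        agg_has(store, id, st$a_contains, st$a_excludes)
      }, aggs)
      cand_b <- Filter(function(id) {
        agg_has(store, id, st$b_contains, st$b_excludes)
      }, aggs)
      seen <- character(0)
      for (ia in cand_a) {
        for (ib in cand_b) {
          if (ia == ib && !isTRUE(st$self_pairs)) next
          pair_id <- paste(sort(c(ia, ib)), collapse = "+")
          if (!identical(st$a_contains, st$b_contains) ||
              !identical(st$a_excludes, st$b_excludes)) {
            pair_id <- paste(ia, ib, sep = "+")
          }
          if (pair_id %in% seen) next
          seen <- c(seen, pair_id)
          sa <- lowest_structure(store, ia)
          sb <- lowest_structure(store, ib)
          sites_a <- selected_sites(sa, selection, st$site_elements_a)
          sites_b <- selected_sites(sb, selection, st$site_elements_b)
          if (!length(sites_a) || !length(sites_b)) next
          combos <- expand.grid(a = sites_a, b = sites_b)
          combos <- combos[order(combos$a, combos$b), , drop = FALSE]
          for (r in seq_len(min(n_coord, nrow(combos)))) {
            add_trial(list(kind = "association",
                           aggregates = c(ia, ib),
                           site_a = combos$a[r], site_b = combos$b[r]))
          }
        }
      }
    },
    Dissociation = {
      for (id in aggs) {
        s <- lowest_structure(store, id)
        if (max(structure_graph(s)$component) > 1L) next
        g <- structure_graph(s)
        sites <- selected_sites(s, selection, NULL)
        edges <- which(g$adj & upper.tri(g$adj), arr.ind = TRUE)
        if (!nrow(edges)) next
        for (r in seq_len(nrow(edges))) {
          i <- edges[r, 1]; j <- edges[r, 2]
          if (!(i %in% sites) || !(j %in% sites)) next
          if (!is.null(st$bond_elements)) {
            pr <- sort(c(s$symbols[i], s$symbols[j]))
            if (!identical(pr, sort(st$bond_elements))) next
          }
          # only bonds whose removal splits the molecule
          adj <- g$adj
          adj[i, j] <- adj[j, i] <- FALSE
          if (max(graph_components(adj)) < 2L) next
          add_trial(list(kind = "dissociation", aggregates = id,
                         cut_bond = c(i, j)))
        }
      }
    },
    Rearrangement = {
      for (id in aggs) {
        s <- lowest_structure(store, id)
        g <- structure_graph(s)
        if (max(g$component) > 1L) next
        sites <- selected_sites(s, selection, NULL)
        hops <- NULL
        assoc_el <- st$assoc_elements
        cand <- utils::combn(n_atoms(s), 2L)
        made <- 0L
        for (r in seq_len(ncol(cand))) {
          if (made >= n_coord) break
          i <- cand[1, r]; j <- cand[2, r]
          if (g$adj[i, j]) next
          if (!(i %in% sites) || !(j %in% sites)) next
          if (!is.null(assoc_el)) {
            pr <- sort(c(s$symbols[i], s$symbols[j]))
            if (!identical(pr, sort(assoc_el))) next
          }
          if (is.null(st$dissoc_elements)) {
            add_trial(list(kind = "rearrangement", aggregates = id,
                           assoc = c(i, j), dissoc = NULL))
            made <- made + 1L
            next
          }
          # breakable bonds sharing an atom with the forming pair
          edges <- which(g$adj & upper.tri(g$adj), arr.ind = TRUE)
          for (e in seq_len(nrow(edges))) {
            if (made >= n_coord) break
            k <- edges[e, 1]; l <- edges[e, 2]
            pr <- sort(c(s$symbols[k], s$symbols[l]))
            if (!identical(pr, sort(st$dissoc_elements))) next
            if (!length(intersect(c(k, l), c(i, j)))) next
            add_trial(list(kind = "rearrangement", aggregates = id,
                           assoc = c(i, j), dissoc = c(k, l)))
            made <- made + 1L
          }
        }
      }
    },
    Conformer_Creation = {
      grid <- if (is.null(st$grid)) 3L else as.integer(st$grid)
      for (id in aggs) {
        s <- lowest_structure(store, id)
        rb <- rotatable_bonds(s)
        for (r in seq_len(nrow(rb))) {
          for (k in seq_len(grid - 1L)) {
            add_trial(list(kind = "conformer", aggregates = id,
                           bond = c(rb[r, 1], rb[r, 2]),
                           angle = 2 * pi * k / grid))
          }
        }
      }
    },
    stop("unknown Network Expansion Step: ", expansion$name))
  trials
}

# Acyclic single bonds with both atoms of degree >= 2: rotating about
# them changes a torsion without breaking the graph apart trivially.
rotatable_bonds <- function(s) {
  g <- structure_graph(s)
  deg <- rowSums(g$adj)
  edges <- which(g$adj & upper.tri(g$adj), arr.ind = TRUE)
  keep <- matrix(integer(0), 0, 2)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    if (deg[i] < 2L || deg[j] < 2L) next
    adj <- g$adj
    adj[i, j] <- adj[j, i] <- FALSE
    if (max(graph_components(adj)) < 2L) next  # ring bond
    keep <- rbind(keep, c(i, j))
  }
  keep
}

#' Preview a Network Expansion Step
#'
#' @param selection A `crn_selection`.
#' @param expansion Protocol step.
#' @param store A `crn_store`.
#' @param calculator A `crn_calculator`.
#' @return List with `count` and `trials` (the planned trial list); no
#'   calculations are written.
#' @export
preview_expansion <- function(selection, expansion, store, calculator) {
  trials <- enumerate_trials(expansion, selection, store, calculator)
  list(count = length(trials), trials = trials)
}

# ---------------------------------------------------------------------
# expansion execution

snapshot_ids <- function(store) {
  list(structures = names(store$structures),
       compounds = names(store$compounds),
       flasks = names(store$flasks),
       reactions = names(store$reactions))
}

#' Run a Network Expansion Step
#'
#' Enumerates the trials for the selection (identically to
#' [preview_expansion()]), writes one calculation record per trial,
#' executes them in order, classifies all results into the store, and
#' reports every created compound, flask, structure and reaction id.
#' The step is complete when no pending or running calculations remain;
#' trial failures are recorded on their calculation records and do not
#' abort the step.
#'
#' @param expansion Protocol step (list with `name`, `settings`).
#' @param selection A `crn_selection`.
#' @param store A `crn_store`.
#' @param calculator A `crn_calculator`.
#' @param seed Integer seed for orientation sampling.
#' @return A list of class `crn_expansion_report`.
#' @export
run_expansion <- function(expansion, selection, store, calculator,
                          seed = 1L) {
  st <- expansion$settings
  before <- snapshot_ids(store)
  trials <- enumerate_trials(expansion, selection, store, calculator)
  calc_ids <- character(0)
  for (t_idx in seq_along(trials)) {
    trial <- trials[[t_idx]]
    qid <- add_calculation(store, job = trial$kind,
                           inputs = if (!is.null(trial$structure_id)) {
                             trial$structure_id
                           } else character(0),
                           settings = st)
    calc_ids <- c(calc_ids, qid)
    set_calculation_status(store, qid, "running")
    res <- tryCatch(
      execute_trial(trial, store, calculator, st,
                    seed = seed + t_idx),
      error = function(e) list(ok = FALSE, reason = conditionMessage(e),
                               results = character(0)))
    if (isTRUE(res$ok)) {
      set_calculation_status(store, qid, "done", results = res$results)
    } else {
      set_calculation_status(store, qid, "failed")
    }
  }
  after <- snapshot_ids(store)
  created_compounds <- setdiff(after$compounds, before$compounds)
  created_flasks <- setdiff(after$flasks, before$flasks)
  rep <- list(step_name = expansion$name,
              created_structures = setdiff(after$structures,
                                           before$structures),
              created_compounds = created_compounds,
              created_flasks = created_flasks,
              created_aggregates = sort(c(created_compounds,
                                          created_flasks)),
              created_reactions = setdiff(after$reactions,
                                          before$reactions),
              calculations = calc_ids)
  statuses <- vapply(calc_ids, function(q) {
    store$calculations[[q]]$status
  }, "")
  rep$complete <- !any(statuses %in% c("pending", "running"))
  class(rep) <- "crn_expansion_report"
  rep
}

# Classify a finished scan trajectory into the store: validated with-TS
# step, or barrierless association when the profile is downhill, or
# failure.
classify_scan <- function(traj, store, calculator) {
  cf <- detect_bond_change(traj)
  ts <- select_ts_guess(traj, cf)
  if (!is.na(ts)) {
    v <- validate_step(traj, ts, calculator)
    if (isTRUE(v$accepted)) {
      rid <- add_structure(store, v$reactant, calculator)
      pid <- add_structure(store, v$product, calculator)
      step <- elementary_step(rid$structure_id, pid$structure_id,
                              type = "with-TS",
                              ts_energy = v$ts_energy,
                              ts_structure = v$ts_structure,
                              model = calculator$model)
      add_elementary_step(store, step)
      return(list(ok = TRUE,
                  results = c(rid$structure_id, pid$structure_id)))
    }
    return(list(ok = FALSE, reason = v$reason))
  }
  if (is.na(cf)) {
    return(list(ok = FALSE, reason = "no bond-order change observed"))
  }
  # change reached without an interior maximum: barrierless candidate
  start <- traj$frames[[1]]$structure
  start$energy <- traj$frames[[1]]$energy
  start <- with_graph(start, calculator)
  final <- optimize_minimum(traj$frames[[length(traj$frames)]]$structure,
                            calculator)
  if (!isTRUE(final$converged)) {
    return(list(ok = FALSE, reason = "product optimization failed"))
  }
  final <- with_graph(final, calculator)
  if (same_aggregate(start, final)) {
    return(list(ok = FALSE, reason = "no reaction"))
  }
  rid <- add_structure(store, start, calculator)
  pid <- add_structure(store, final, calculator)
  step <- elementary_step(rid$structure_id, pid$structure_id,
                          type = "barrierless",
                          model = calculator$model)
  add_elementary_step(store, step)
  list(ok = TRUE, results = c(rid$structure_id, pid$structure_id))
}

execute_trial <- function(trial, store, calculator, settings,
                          seed = 1L) {
  scan_steps <- if (is.null(settings$max_steps)) 120L else {
    as.integer(settings$max_steps)
  }
  step_size <- if (is.null(settings$step_size)) 0.1 else {
    settings$step_size
  }
  switch(trial$kind,
    optimize = {
      s <- store$structures[[trial$structure_id]]$structure
      opt <- optimize_minimum(s, calculator)
      if (!isTRUE(opt$converged)) {
        return(list(ok = FALSE, reason = "optimization not converged"))
      }
      res <- add_structure(store, with_graph(opt, calculator),
                           calculator)
      list(ok = TRUE, results = res$structure_id)
    },
    association = {
      sa <- lowest_structure(store, trial$aggregates[1])
      sb <- lowest_structure(store, trial$aggregates[2])
      cx <- build_reactive_complex(sa, sb, sitesA = trial$site_a,
                                   sitesB = trial$site_b, seed = seed)
      traj <- run_scan(cx, calculator, step_size = step_size,
                       max_steps = scan_steps)
      classify_scan(traj, store, calculator)
    },
    rearrangement = {
      s <- lowest_structure(store, trial$aggregates[1])
      pairs <- rbind(trial$assoc, trial$dissoc)
      kinds <- c("associative",
                 if (!is.null(trial$dissoc)) "dissociative")
      coord <- reaction_coordinate(pairs, kinds)
      bo <- calculator$bond_orders(s)
      coord <- scale_haptic_forces(coord, bo)
      cx <- build_reactive_complex(s, coordinate = coord)
      traj <- run_scan(cx, calculator, step_size = step_size,
                       max_steps = scan_steps)
      classify_scan(traj, store, calculator)
    },
    dissociation = {
      s <- lowest_structure(store, trial$aggregates[1])
      diss <- dissociation_screen(s, matrix(trial$cut_bond, ncol = 2L),
                                  calculator)
      if (isTRUE(diss$failed)) {
        return(list(ok = FALSE, reason = "no combination converged"))
      }
      threshold <- if (is.null(settings$followup_threshold)) 200 else {
        settings$followup_threshold
      }
      probe <- barrierless_probe(diss, calculator)
      if (!is.null(probe)) {
        par_id <- add_structure(store, probe$parent, calculator)
        flask_id <- add_structure(store, probe$dissociated, calculator)
        step <- elementary_step(par_id$structure_id,
                                flask_id$structure_id,
                                type = "barrierless",
                                model = calculator$model)
        add_elementary_step(store, step)
        return(list(ok = TRUE, results = c(par_id$structure_id,
                                           flask_id$structure_id)))
      }
      if (diss$dissociation_energy < threshold) {
        # follow-up: conventional forced scan along the cut bond
        coord <- reaction_coordinate(matrix(trial$cut_bond, ncol = 2L),
                                     "dissociative")
        cx <- build_reactive_complex(diss$parent, coordinate = coord)
        traj <- run_scan(cx, calculator, step_size = step_size,
                         max_steps = scan_steps)
        return(classify_scan(traj, store, calculator))
      }
      list(ok = FALSE, reason = "dissociation above follow-up threshold")
    },
    conformer = {
      s <- lowest_structure(store, trial$aggregates[1])
      rot <- rotate_torsion(s, trial$bond, trial$angle)
      opt <- optimize_minimum(rot, calculator)
      if (!isTRUE(opt$converged)) {
        return(list(ok = FALSE, reason = "optimization not converged"))
      }
      opt <- with_graph(opt, calculator)
      ref <- lowest_structure(store, trial$aggregates[1])
      agg <- get_aggregate(store, trial$aggregates[1])
      dup <- any(vapply(agg$members, function(sid) {
        old <- store$structures[[sid]]$structure
        length(old$symbols) == length(opt$symbols) &&
          fit_rmsd(old$coords, opt$coords) < 0.1
      }, TRUE))
      if (dup) {
        return(list(ok = TRUE, results = character(0)))
      }
      res <- add_structure(store, opt, calculator)
      list(ok = TRUE, results = res$structure_id)
    },
    stop("unknown trial kind: ", trial$kind))
}

# Rigid rotation of the smaller side of an acyclic bond about its axis.
rotate_torsion <- function(s, bond, angle) {
  g <- structure_graph(s)
  adj <- g$adj
  adj[bond[1], bond[2]] <- adj[bond[2], bond[1]] <- FALSE
  comp <- graph_components(adj)
  side <- which(comp == comp[bond[2]])
  if (length(side) > n_atoms(s) / 2) {
    side <- which(comp == comp[bond[1]])
    bond <- rev(bond)
  }
  axis <- s$coords[bond[2], ] - s$coords[bond[1], ]
  R <- rotation_about(axis, angle)
  out <- s
  pivot <- s$coords[bond[1], ]
  out$coords[side, ] <-
    sweep(sweep(s$coords[side, , drop = FALSE], 2, pivot) %*% t(R),
          2, pivot, `+`)
  out$graph <- NULL
  out$bond_orders <- NULL
  out$energy <- NULL
  out
}

# ---------------------------------------------------------------------
# protocol execution

#' Run a steering protocol
#'
#' Executes the protocol's steps strictly in order.  A step begins only
#' after the previous expansion is complete (no pending or running
#' calculations), which makes the exploration reproducible: with a fixed
#' seed the final store is identical across runs.  The store records the
#' hash of every completed step, so a run can be interrupted (via
#' `stop_after`) and resumed by calling `run_protocol()` again with the
#' same protocol on the saved store; resuming with a mutated protocol
#' prefix is rejected.  Extending a completed protocol with further
#' steps and resuming is allowed.
#'
#' @param p A `crn_protocol`.
#' @param store A `crn_store` (fresh by default).
#' @param calculator A `crn_calculator`.
#' @param input_structures List of `crn_structure` inputs consumed by
#'   `File_Input_Selection` steps without a `files` setting.
#' @param stop_after Stop (checkpoint) after this step index.
#' @return List with `store` and `reports` (one per executed step).
#' @export
run_protocol <- function(p, store = crn_store(), calculator,
                         input_structures = NULL, stop_after = NULL) {
  hashes <- vapply(p$steps, protocol_step_hash, "")
  done <- store$meta$completed_steps
  if (done > 0L) {
    prev <- store$meta$step_hashes
    if (length(prev) < done ||
        !identical(unlist(prev[seq_len(done)]), hashes[seq_len(done)])) {
      stop("store was produced by a different protocol prefix; refusing",
           " to resume")
    }
    if (done > length(p$steps)) {
      stop("protocol is shorter than the store's completed prefix")
    }
  } else {
    store$meta$seed <- p$seed
  }
  context <- list(calculator = calculator,
                  input_structures = input_structures,
                  last_report = NULL, selection = NULL)
  if (done > 0L) {
    if (!is.null(store$meta$last_created)) {
      context$last_report <-
        list(created_aggregates = unlist(store$meta$last_created))
    }
    # re-materialize the selection in force at the checkpoint: the most
    # recent selection step not followed by a completed expansion
    types <- vapply(p$steps, `[[`, "", "type")
    j <- done
    while (j >= 1L && types[j] == "selection") j <- j - 1L
    if (j < done) {
      for (jj in (j + 1L):done) {
        context$selection <- apply_selection(p$steps[[jj]], store,
                                             context)
      }
    }
  }
  reports <- list()
  upto <- if (is.null(stop_after)) length(p$steps) else {
    min(stop_after, length(p$steps))
  }
  i <- done
  while (i < upto) {
    i <- i + 1L
    step <- p$steps[[i]]
    step_seed <- (p$seed * 1009L + i * 7919L) %% 2147483399L
    set.seed(step_seed)
    if (step$type == "selection") {
      context$selection <- apply_selection(step, store, context)
    } else {
      sel <- context$selection
      if (is.null(sel)) {
        sel <- new_selection(aggregate_ids(store))
      }
      rep <- run_expansion(step, sel, store, calculator,
                           seed = step_seed %% 100000L)
      stopifnot(isTRUE(rep$complete))
      context$last_report <- rep
      reports[[length(reports) + 1L]] <- rep
    }
    store$meta$completed_steps <- i
    store$meta$step_hashes <- as.list(hashes[seq_len(i)])
    store$meta$protocol_hash <- protocol_hash(p)
    if (!is.null(context$last_report)) {
      store$meta$last_created <-
        as.list(context$last_report$created_aggregates)
    }
  }
  list(store = store, reports = reports)
}
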