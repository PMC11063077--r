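#' Create an empty CRN store
#'
#' The store is the persistent data model of an exploration: six
#' collections (structures, compounds, flasks, elementary steps,
#' reactions, calculations) plus run metadata.  Compounds aggregate all
#' structures sharing charge, spin multiplicity and molecular graph for a
#' single connected molecule; flasks are the analogous aggregate for
#' non-covalently bound multi-molecule complexes.  The store is a mutable
#' environment: `add_structure()` and friends modify it in place.
#'
#' @return An environment of class `crn_store`.
#' @examples
#' store <- crn_store()
#' count_records(store)
#' @export
crn_store <- function() {
  store <- new.env(parent = emptyenv())
  store$structures <- list()
  store$compounds <- list()
  store$flasks <- list()
  store$elementary_steps <- list()
  store$reactions <- list()
  store$calculations <- list()
  store$meta <- list(schema = "crnsteer-store-v1", completed_steps = 0L,
                     protocol_hash = NULL, seed = NULL)
  store$counters <- c(s = 0L, c = 0L, f = 0L, e = 0L, r = 0L, q = 0L)
  class(store) <- "crn_store"
  store
}

next_id <- function(store, prefix) {
  store$counters[prefix] <- store$counters[prefix] + 1L
  sprintf("%s%06d", prefix, store$counters[prefix])
}

#' @export
print.crn_store <- function(x, ...) {
  cts <- count_records(x)
  cat("<crn_store>",
      paste(names(cts), unlist(cts), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Collection cardinalities
#'
#' @param store A `crn_store`.
#' @return Named list with counts of structures, compounds, flasks,
#'   elementary steps, reactions and calculations.
#' @export
count_records <- function(store) {
  list(structures = length(store$structures),
       compounds = length(store$compounds),
       flasks = length(store$flasks),
       elementary_steps = length(store$elementary_steps),
       reactions = length(store$reactions),
       calculations = length(store$calculations))
}

# All aggregate ids (compounds then flasks), sorted.
aggregate_ids <- function(store) {
  sort(c(names(store$compounds), names(store$flasks)))
}

get_aggregate <- function(store, id) {
  if (!is.null(store$compounds[[id]])) return(store$compounds[[id]])
  if (!is.null(store$flasks[[id]])) return(store$flasks[[id]])
  stop("unknown aggregate id: ", id)
}

#' Lowest-energy member structure of an aggregate
#'
#' @param store A `crn_store`.
#' @param id Aggregate (compound or flask) id.
#' @return The member `crn_structure` with the lowest recorded energy
#'   (the first member if no energies are recorded).
#' @export
lowest_structure <- function(store, id) {
  agg <- get_aggregate(store, id)
  members <- agg$members
  en <- vapply(members, function(sid) {
    e <- store$structures[[sid]]$structure$energy
    if (is.null(e)) Inf else e
  }, 0)
  pick <- members[which.min(en)]
  store$structures[[pick]]$structure
}

#' Add a structure to the store
#'
#' The structure is attached to the existing aggregate with matching key
#' (charge, multiplicity, molecular-graph isomorphism, molecule count) or
#' a new compound (one molecule) / flask (two or more molecules) is
#' created.  A flask additionally references the compounds of its
#' constituent molecules, creating neutral parity-consistent compounds
#' for constituents not yet present.  Adding a bit-identical geometry
#' twice is idempotent.
#'
#' @param store A `crn_store`.
#' @param structure A `crn_structure`; its graph is perceived on demand.
#' @param calculator Optional calculator used for bond perception.
#' @return List with `aggregate_id`, `structure_id` and `is_new`
#'   (whether a new aggregate was created).
#' @export
add_structure <- function(store, structure, calculator = NULL) {
  # quantize at the persistence boundary so stored numerics survive
  # text serialization exactly (short decimals are print-parse stable)
  structure$coords <- round(structure$coords, 10)
  if (!is.null(structure$energy)) {
    structure$energy <- round(structure$energy, 8)
  }
  if (is.null(structure$graph)) {
    structure <- with_graph(structure, calculator)
  }
  key <- aggregate_key(structure)
  is_flask <- key$n_molecules >= 2L
  pool <- if (is_flask) store$flasks else store$compounds
  hit <- NULL
  for (agg in pool) {
    if (agg$key_hash != key$hash) next
    rep_sid <- agg$members[1]
    rep_graph <- store$structures[[rep_sid]]$structure$graph
    if (graphs_isomorphic(rep_graph, structure$graph)) {
      hit <- agg$id
      break
    }
  }
  if (!is.null(hit)) {
    agg <- get_aggregate(store, hit)
    for (sid in agg$members) {
      old <- store$structures[[sid]]$structure
      if (identical(old$symbols, structure$symbols) &&
          isTRUE(all.equal(old$coords, structure$coords,
                           tolerance = 1e-12))) {
        if (is.null(old$energy) && !is.null(structure$energy)) {
          rec <- store$structures[[sid]]
          rec$structure$energy <- structure$energy
          rec$structure$model <- structure$model
          store$structures[[sid]] <- rec
        }
        return(list(aggregate_id = hit, structure_id = sid,
                    is_new = FALSE))
      }
    }
    sid <- next_id(store, "s")
    store$structures[[sid]] <- list(id = sid, structure = structure,
                                    aggregate_id = hit)
    agg$members <- c(agg$members, sid)
    if (is_flask) store$flasks[[hit]] <- agg else {
      store$compounds[[hit]] <- agg
    }
    return(list(aggregate_id = hit, structure_id = sid, is_new = FALSE))
  }
  # new aggregate
  aid <- next_id(store, if (is_flask) "f" else "c")
  sid <- next_id(store, "s")
  store$structures[[sid]] <- list(id = sid, structure = structure,
                                  aggregate_id = aid)
  agg <- list(id = aid, key_hash = key$hash, charge = key$charge,
              multiplicity = key$multiplicity,
              n_molecules = key$n_molecules, members = sid)
  if (is_flask) {
    parts <- split_molecules(structure$graph)
    agg$compounds <- vapply(parts, function(p) {
      frag <- substructure(structure, p$atoms)
      frag <- with_graph(frag, calculator)
      add_structure(store, frag, calculator)$aggregate_id
    }, "")
    store$flasks[[aid]] <- agg
  } else {
    store$compounds[[aid]] <- agg
  }
  list(aggregate_id = aid, structure_id = sid, is_new = TRUE)
}

#' Construct an elementary step record
#'
#' A single transformation between stored structures, either through one
#' transition state (`type = "with-TS"`) or without one
#' (`type = "barrierless"`).  Endpoint energies are taken from the stored
#' structures; with-TS steps must supply a TS energy at least as high as
#' both endpoints on the same surface.
#'
#' @param reactants,products Character vectors of structure ids.
#' @param type `"with-TS"` or `"barrierless"`.
#' @param ts_energy TS electronic energy in kJ/mol (with-TS only).
#' @param ts_structure Optional TS `crn_structure` (with-TS only).
#' @param model Model tag of the energies.
#' @return A list of class `crn_elementary_step` (not yet stored).
#' @export
elementary_step <- function(reactants, products,
                            type = c("with-TS", "barrierless"),
                            ts_energy = NULL, ts_structure = NULL,
                            model = "toy") {
  type <- match.arg(type)
  if (type == "with-TS" && is.null(ts_energy)) {
    stop("with-TS steps need a TS energy")
  }
  if (type == "barrierless" && !is.null(ts_energy)) {
    stop("barrierless steps have no TS")
  }
  step <- list(reactants = as.character(reactants),
               products = as.character(products), type = type,
               ts_energy = ts_energy, ts_structure = ts_structure,
               model = model)
  class(step) <- "crn_elementary_step"
  step
}

side_energy <- function(store, sids) {
  sum(vapply(sids, function(sid) {
    e <- store$structures[[sid]]$structure$energy
    if (is.null(e)) stop("structure ", sid, " has no energy")
    e
  }, 0))
}

#' Add an elementary step, aggregating into a reaction
#'
#' The step is appended to the unique reaction connecting the same
#' unordered pair of aggregate sets (direction-normalized: the canonical
#' forward direction is the lexicographically smaller aggregate-id
#' tuple), creating the reaction if absent.  The reaction's minimal
#' forward/backward activation energies are updated; barrierless steps
#' contribute zero activation in both directions.
#'
#' @param store A `crn_store`.
#' @param step A `crn_elementary_step`; endpoint structures must already
#'   be stored.
#' @return The reaction id (invisibly also recorded on the step).
#' @export
add_elementary_step <- function(store, step) {
  all_sids <- c(step$reactants, step$products)
  missing <- all_sids[!(all_sids %in% names(store$structures))]
  if (length(missing)) {
    stop("endpoint structure(s) not in store: ",
         paste(missing, collapse = ", "))
  }
  r_agg <- sort(unname(vapply(step$reactants, function(s) {
    store$structures[[s]]$aggregate_id
  }, "")))
  p_agg <- sort(unname(vapply(step$products, function(s) {
    store$structures[[s]]$aggregate_id
  }, "")))
  e_r <- round(side_energy(store, step$reactants), 8)
  e_p <- round(side_energy(store, step$products), 8)
  if (step$type == "with-TS") {
    if (step$ts_energy < max(e_r, e_p) - 1e-9) {
      stop("TS energy below an endpoint energy")
    }
    step$ts_energy <- round(step$ts_energy, 8)
    ea_f <- round(step$ts_energy - e_r, 8)
    ea_b <- round(step$ts_energy - e_p, 8)
  } else {
    ea_f <- 0
    ea_b <- 0
  }
  # canonical direction: lexicographically smaller aggregate tuple first
  fwd_key <- paste(r_agg, collapse = "+")
  bwd_key <- paste(p_agg, collapse = "+")
  flipped <- bwd_key < fwd_key
  canon_r <- if (flipped) p_agg else r_agg
  canon_p <- if (flipped) r_agg else p_agg
  canon_ea_f <- if (flipped) ea_b else ea_f
  canon_ea_b <- if (flipped) ea_f else ea_b
  rid <- NULL
  for (rx in store$reactions) {
    if (identical(rx$reactants, canon_r) &&
        identical(rx$products, canon_p)) {
      rid <- rx$id
      break
    }
  }
  eid <- next_id(store, "e")
  step$id <- eid
  if (is.null(rid)) {
    rid <- next_id(store, "r")
    store$reactions[[rid]] <- list(id = rid, reactants = canon_r,
                                   products = canon_p, steps = eid,
                                   ea_forward = canon_ea_f,
                                   ea_backward = canon_ea_b)
  } else {
    rx <- store$reactions[[rid]]
    rx$steps <- c(rx$steps, eid)
    rx$ea_forward <- min(rx$ea_forward, canon_ea_f)
    rx$ea_backward <- min(rx$ea_backward, canon_ea_b)
    store$reactions[[rid]] <- rx
  }
  step$reaction_id <- rid
  step$energy_reactants <- e_r
  step$energy_products <- e_p
  store$elementary_steps[[eid]] <- step
  rid
}

#' Record a calculation
#'
#' Calculations follow a monotone lifecycle
#' pending -> running -> done/failed; `done` records reference results.
#'
#' @param store A `crn_store`.
#' @param job Job-type string.
#' @param inputs Character vector of input structure ids (may be empty
#'   for file-input jobs).
#' @param settings Settings snapshot (list).
#' @return The calculation id.
#' @export
add_calculation <- function(store, job, inputs = character(0),
                            settings = list()) {
  qid <- next_id(store, "q")
  store$calculations[[qid]] <- list(id = qid, job = job,
                                    inputs = as.character(inputs),
                                    settings = settings,
                                    status = "pending",
                                    results = character(0))
  qid
}

#' @rdname add_calculation
#' @param id Calculation id.
#' @param status New status.
#' @param results Result ids (for `status = "done"`).
#' @export
set_calculation_status <- function(store, id, status,
                                   results = NULL) {
  rec <- store$calculations[[id]]
  if (is.null(rec)) stop("unknown calculation id: ", id)
  order_of <- c(pending = 1L, running = 2L, done = 3L, failed = 3L)
  if (order_of[[status]] <= order_of[[rec$status]] &&
      !(rec$status == "pending" && status == "pending")) {
    stop("illegal status transition ", rec$status, " -> ", status)
  }
  rec$status <- status
  if (!is.null(results)) rec$results <- as.character(results)
  store$calculations[[id]] <- rec
  invisible(id)
}

# ---------------------------------------------------------------------
# persistence: directory of JSON-lines collections

graph_edges <- function(graph) {
  w <- which(graph$adj & upper.tri(graph$adj), arr.ind = TRUE)
  if (!nrow(w)) return(list())
  lapply(seq_len(nrow(w)), function(k) c(w[k, 1], w[k, 2]))
}

graph_from_edges <- function(symbols, edges) {
  n <- length(symbols)
  adj <- matrix(FALSE, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- TRUE
    adj[e[2], e[1]] <- TRUE
  }
  g <- list(symbols = symbols, adj = adj,
            component = graph_components(adj))
  class(g) <- "crn_graph"
  g
}

structure_record <- function(rec) {
  s <- rec$structure
  list(id = rec$id, aggregate_id = rec$aggregate_id,
       symbols = s$symbols,
       coords = apply(s$coords, 1, identity, simplify = FALSE),
       charge = s$charge, multiplicity = s$multiplicity,
       label = s$label,
       energy = s$energy,
       model = s$model,
       edges = graph_edges(s$graph))
}

write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                  null = "null"))
  }, "")
  writeLines(lines, path)
}

read_jsonl <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

#' Save / load a store
#'
#' Native persistence is a directory of JSON-lines collections
#' (`structures.jsonl`, `compounds.jsonl`, `flasks.jsonl`,
#' `elementary_steps.jsonl`, `reactions.jsonl`, `calculations.jsonl`)
#' plus `meta.json`.  Records are written in sorted-id order with fixed
#' field order, so identical stores export byte-identically.
#'
#' @param store A `crn_store`.
#' @param dir Directory path (created if needed).
#' @return `save_store()` returns `dir` invisibly; `load_store()`
#'   returns a `crn_store`.
#' @export
save_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(names(store$structures))
  write_jsonl(lapply(ids, function(i) {
    structure_record(store$structures[[i]])
  }), file.path(dir, "structures.jsonl"))
  ids <- sort(names(store$compounds))
  write_jsonl(lapply(ids, function(i) {
    a <- store$compounds[[i]]
    a[c("id", "key_hash", "charge", "multiplicity", "n_molecules",
        "members")]
  }), file.path(dir, "compounds.jsonl"))
  ids <- sort(names(store$flasks))
  write_jsonl(lapply(ids, function(i) {
    a <- store$flasks[[i]]
    a[c("id", "key_hash", "charge", "multiplicity", "n_molecules",
        "members", "compounds")]
  }), file.path(dir, "flasks.jsonl"))
  ids <- sort(names(store$elementary_steps))
  write_jsonl(lapply(ids, function(i) {
    st <- store$elementary_steps[[i]]
    list(id = st$id, reactants = st$reactants, products = st$products,
         type = st$type,
         ts_energy = st$ts_energy,
         energy_reactants = st$energy_reactants,
         energy_products = st$energy_products,
         model = st$model, reaction_id = st$reaction_id)
  }), file.path(dir, "elementary_steps.jsonl"))
  ids <- sort(names(store$reactions))
  write_jsonl(lapply(ids, function(i) {
    rx <- store$reactions[[i]]
    list(id = rx$id, reactants = rx$reactants, products = rx$products,
         steps = rx$steps, ea_forward = rx$ea_forward,
         ea_backward = rx$ea_backward)
  }), file.path(dir, "reactions.jsonl"))
  ids <- sort(names(store$calculations))
  write_jsonl(lapply(ids, function(i) {
    store$calculations[[i]][c("id", "job", "inputs", "settings",
                              "status", "results")]
  }), file.path(dir, "calculations.jsonl"))
  meta <- store$meta
  meta$counters <- as.list(store$counters)
  # force array form for fields that may hold a single element
  if (!is.null(meta$step_hashes)) {
    meta$step_hashes <- I(unlist(meta$step_hashes))
  }
  if (!is.null(meta$last_created)) {
    meta$last_created <- I(unlist(meta$last_created))
  }
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname save_store
#' @export
load_store <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json in ", dir)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema, "crnsteer-store-v1")) {
    stop("unsupported store schema: ", meta$schema)
  }
  store <- crn_store()
  for (rec in read_jsonl(file.path(dir, "structures.jsonl"))) {
    coords <- if (is.matrix(rec$coords)) rec$coords else {
      do.call(rbind, rec$coords)
    }
    s <- structure_new(rec$symbols, coords, charge = rec$charge,
                       multiplicity = rec$multiplicity,
                       label = if (is.null(rec$label)) "" else rec$label,
                       energy = rec$energy, model = rec$model)
    edges <- if (is.list(rec$edges)) rec$edges else {
      if (length(rec$edges)) {
        lapply(seq_len(nrow(rec$edges)), function(k) rec$edges[k, ])
      } else list()
    }
    s$graph <- graph_from_edges(s$symbols, edges)
    store$structures[[rec$id]] <- list(id = rec$id, structure = s,
                                       aggregate_id = rec$aggregate_id)
  }
  for (rec in read_jsonl(file.path(dir, "compounds.jsonl"))) {
    store$compounds[[rec$id]] <- rec
  }
  for (rec in read_jsonl(file.path(dir, "flasks.jsonl"))) {
    store$flasks[[rec$id]] <- rec
  }
  for (rec in read_jsonl(file.path(dir, "elementary_steps.jsonl"))) {
    rec$ts_structure <- NULL
    class(rec) <- "crn_elementary_step"
    store$elementary_steps[[rec$id]] <- rec
  }
  for (rec in read_jsonl(file.path(dir, "reactions.jsonl"))) {
    store$reactions[[rec$id]] <- rec
  }
  for (rec in read_jsonl(file.path(dir, "calculations.jsonl"))) {
    if (is.null(rec$settings)) rec$settings <- list()
    store$calculations[[rec$id]] <- rec
  }
  store$counters <- unlist(meta$counters)
  meta$counters <- NULL
  store$meta <- meta
  store
}

#' Import a deposited CRN dump
#'
#' Reads a directory holding the six CRN collections and returns a
#' read-only store view suitable for counting and path analysis.  Two
#' layouts are recognized: the native JSON-lines layout written by
#' [save_store()], and MongoDB-export JSON collections (one array of
#' documents per collection, ids under `_id.$oid`).  Any other layout
#' raises an unsupported-schema error.
#'
#' @param path Directory containing the dump.
#' @return A `crn_store`.
#' @export
import_deposit <- function(path) {
  if (!dir.exists(path)) stop("no such dump directory: ", path)
  if (file.exists(file.path(path, "meta.json"))) {
    return(load_store(path))
  }
  collections <- c("structures", "compounds", "flasks",
                   "elementary_steps", "reactions", "calculations")
  files <- file.path(path, paste0(collections, ".json"))
  if (!any(file.exists(files))) {
    stop("unsupported deposit schema: no recognized collection files in ",
         path)
  }
  store <- crn_store()
  doc_id <- function(doc, fallback) {
    if (!is.null(doc[["_id"]])) {
      oid <- doc[["_id"]]
      if (is.list(oid) && !is.null(oid[["$oid"]])) return(oid[["$oid"]])
      return(as.character(oid))
    }
    fallback
  }
  for (k in seq_along(collections)) {
    if (!file.exists(files[k])) next
    docs <- jsonlite::fromJSON(files[k], simplifyVector = FALSE)
    coll <- collections[k]
    recs <- list()
    for (i in seq_along(docs)) {
      id <- doc_id(docs[[i]], sprintf("%s%06d", substr(coll, 1, 1), i))
      recs[[id]] <- c(list(id = id), docs[[i]])
    }
    store[[coll]] <- recs
  }
  store$meta$schema <- "deposit-import"
  store$meta$read_only <- TRUE
  store
}
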