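
# Synthetic database releases with fully known ground truth.
#
# The generator emulates the redundancy structure of real compound-database
# dumps (exact duplicates, salt forms, charge states, isotope labels,
# tautomer re-drawings, stereo variants) and between-release curation events
# (records removed, stereo added to flat drawings, tautomers re-drawn, new
# records). Ground truth is computed by plan bookkeeping, never by running
# the analysis pipeline, so recovery tests are genuine two-route checks.
#
# Scaffolds come from a parameterized pool built around one master graph
# that provably carries every needed capability: a methyl ketone (tautomer
# site whose enol is non-stereogenic), a fluorinated quaternary-substituted
# stereocenter with no hydrogen (so no tautomer move can ever destroy it),
# a carboxylic acid (charge site), and a decorable alkyl arm (chain
# extension x terminal ring size) that makes every pool member a distinct
# skeleton. Capability-free "plain" scaffolds are simple alkanes.

.variant_types <- c("exact_duplicate", "salt", "charge", "isotope",
                    "tautomer", "stereo_invert", "stereo_strip")
.curation_types <- c("remove", "add_stereo", "redraw_tautomer")

.ring_sizes <- c(0L, 3L, 4L, 5L, 6L)

# master scaffold: CH3-C(=O)-CH2-C*(F)(arm)(COOH)
# arm = CH2 x (1+ext), optionally terminated by a carbocycle of `ring` atoms
master_scaffold <- function(combo, source_id, flat = FALSE) {
  ring <- .ring_sizes[(combo %% 5L) + 1L]
  ext <- combo %/% 5L
  elem <- c("C", "C", "O", "C", "C", "F", "C", "O", "O")
  x <- c(0, 0.87, 0.87, 1.73, 2.60, 2.60, 3.46, 3.46, 4.33)
  y <- c(0, 0.5, 1.5, 0, 0.5, -0.5, 0, -1.0, 0.5)
  bonds <- data.frame(
    a1 = c(1L, 2L, 2L, 4L, 5L, 5L, 7L, 7L, 5L),
    a2 = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L),
    order = c(1L, 2L, 1L, 1L, 1L, 1L, 2L, 1L, 1L),
    wedge = "none", stringsAsFactors = FALSE)
  # arm: atom 10 plus ext extra carbons
  arm <- 10L + seq_len(ext + 1L) - 1L
  for (j in seq_along(arm)) {
    elem <- c(elem, "C")
    x <- c(x, 2.60 + 0.3 * ((j - 1L) %% 2L))
    y <- c(y, 1.5 + 0.9 * (j - 1L))
    if (j > 1L)
      bonds <- rbind(bonds, data.frame(a1 = arm[j - 1L], a2 = arm[j],
                                       order = 1L, wedge = "none"))
  }
  if (ring > 0L) {
    tip <- arm[length(arm)]
    cx <- x[tip]; cy <- y[tip] + 1.6
    first <- length(elem) + 1L
    th <- 2 * pi * seq_len(ring) / ring - pi / 2
    elem <- c(elem, rep("C", ring))
    x <- c(x, cx + 0.8 * cos(th)); y <- c(y, cy + 0.8 * sin(th))
    bonds <- rbind(bonds, data.frame(a1 = tip, a2 = first, order = 1L,
                                     wedge = "none"))
    for (j in seq_len(ring)) {
      a <- first + j - 1L
      b <- if (j == ring) first else first + j
      bonds <- rbind(bonds, data.frame(a1 = a, a2 = b, order = 1L,
                                       wedge = "none"))
    }
  }
  if (!flat) bonds$wedge[bonds$a1 == 5L & bonds$a2 == 10L] <- "up"
  atoms <- data.frame(elem = elem, charge = 0L, isotope = NA_integer_,
                      hcount = NA_integer_, x = x, y = y,
                      stringsAsFactors = FALSE)
  complete_hydrogens(mol_record(source_id, atoms, bonds))
}

# plain alkane CH3-(CH2)-... with 4+len carbons: no stereo, no tautomers
plain_scaffold <- function(len, source_id) {
  n <- 4L + len
  atoms <- data.frame(elem = rep("C", n), charge = 0L, isotope = NA_integer_,
                      hcount = NA_integer_,
                      x = 0.87 * seq_len(n), y = 0.5 * (seq_len(n) %% 2L),
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = seq_len(n - 1L), a2 = seq_len(n - 1L) + 1L,
                      order = 1L, wedge = "none", stringsAsFactors = FALSE)
  complete_hydrogens(mol_record(source_id, atoms, bonds))
}

find_bond_row <- function(rec, u, v) {
  which((rec$bonds$a1 == u & rec$bonds$a2 == v) |
        (rec$bonds$a1 == v & rec$bonds$a2 == u))
}

# hand-coded record transforms; indices refer to the master scaffold layout
apply_variant <- function(rec, type, source_id) {
  rec$source_id <- source_id
  switch(type,
    exact_duplicate = rec,
    salt = {
      na <- data.frame(elem = "Na", charge = 1L, isotope = NA_integer_,
                       hcount = 0L, x = 8, y = 3, stringsAsFactors = FALSE)
      mol_record(source_id, rbind(rec$atoms, na), rec$bonds, rec$flags)
    },
    charge = {  # deprotonate the acid hydroxyl (atom 9)
      rec$atoms$charge[9L] <- -1L; rec$atoms$hcount[9L] <- 0L
      rec
    },
    isotope = { rec$atoms$isotope[1L] <- 13L; rec },
    tautomer = ,
    redraw_tautomer = {  # keto -> enol at the methyl ketone (atoms 1-2-3)
      rec$bonds$order[find_bond_row(rec, 2L, 3L)] <- 1L
      rec$bonds$order[find_bond_row(rec, 1L, 2L)] <- 2L
      rec$atoms$hcount[3L] <- rec$atoms$hcount[3L] + 1L
      rec$atoms$hcount[1L] <- rec$atoms$hcount[1L] - 1L
      rec
    },
    stereo_invert = {
      rec$bonds$wedge[find_bond_row(rec, 5L, 10L)] <- "down"; rec
    },
    stereo_strip = {
      rec$bonds$wedge[find_bond_row(rec, 5L, 10L)] <- "none"; rec
    },
    add_stereo = {
      rec$bonds$wedge[find_bond_row(rec, 5L, 10L)] <- "up"; rec
    },
    stop("unknown variant type: ", type)
  )
}

#' Specify a synthetic two-release compound library
#'
#' @param n_scaffolds number of scaffolds (distinct skeletons) in release 1
#' @param variant_plan character vector or list of character vectors
#'   (recycled over scaffolds); each a multiset over
#'   `exact_duplicate`, `salt`, `charge`, `isotope`, `tautomer`,
#'   `stereo_invert`, `stereo_strip`
#' @param curation list with counts `remove`, `add_stereo`,
#'   `redraw_tautomer`, `new_records` applied when deriving release 2;
#'   curation events target single-record scaffolds (those with an empty
#'   variant plan) so release-diff bookkeeping is exact
#' @param seed integer seed; identical spec+seed gives byte-identical output
#' @return object of class `library_spec`
#' @export
library_spec <- function(n_scaffolds, variant_plan = list(character()),
                         curation = list(), seed = 1L) {
  if (n_scaffolds < 1L) stop("n_scaffolds must be >= 1")
  if (is.character(variant_plan)) variant_plan <- list(variant_plan)
  plans <- rep(variant_plan, length.out = n_scaffolds)
  bad <- setdiff(unlist(plans), .variant_types)
  if (length(bad)) stop("unknown variant type(s): ", paste(bad, collapse = ", "))
  cur <- utils::modifyList(list(remove = 0L, add_stereo = 0L,
                                redraw_tautomer = 0L, new_records = 0L),
                           curation)
  n_empty <- sum(vapply(plans, length, integer(1)) == 0L)
  need <- cur$remove + cur$add_stereo + cur$redraw_tautomer
  if (need > n_empty)
    stop("curation plan needs ", need, " single-record scaffolds but only ",
         n_empty, " have empty variant plans")
  structure(list(n_scaffolds = as.integer(n_scaffolds), plans = plans,
                 curation = cur, seed = as.integer(seed)),
            class = "library_spec")
}

#' Generate a two-release synthetic library with ground truth
#'
#' Builds release-1 records from the scaffold pool per the variant plan,
#' derives release 2 by applying the curation plan, and returns both record
#' lists together with the bookkeeping-derived ground truth: per-level unique
#' counts, release-diff triples, skeleton-link counts, stereo-class counts
#' and the release-pair Venn cells. Atom orders are randomly permuted
#' (seeded) so identity must come from canonicalization, not input order.
#'
#' @param spec a [library_spec()]
#' @param out_dir optional directory; when given, writes `release1.sdf`,
#'   `release2.sdf` and `ground_truth.json` there
#' @return list with `release1`, `release2` (lists of [mol_record()]),
#'   `truth` (list), and `spec`
#' @export
generate_library <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "library_spec"))
  set.seed(spec$seed)
  K <- spec$n_scaffolds
  plans <- spec$plans
  cur <- spec$curation

  # assign curation events to empty-plan scaffolds in index order
  events <- rep("keep", K)
  empties <- which(vapply(plans, length, integer(1)) == 0L)
  todo <- c(rep("add_stereo", cur$add_stereo),
            rep("redraw_tautomer", cur$redraw_tautomer),
            rep("remove", cur$remove))
  events[empties[seq_along(todo)]] <- todo

  # scaffold types: master unless capability-free
  needs_master <- vapply(seq_len(K), function(k)
    length(plans[[k]]) > 0L || events[k] %in% c("add_stereo", "redraw_tautomer"),
    logical(1))
  combo <- cumsum(needs_master) - 1L          # master pool combo index
  plain_len <- cumsum(!needs_master)          # plain chain length index

  r1 <- list(); r2 <- list()
  stereo1 <- character(); stereo2 <- character()
  u_ficts1 <- 0L; u_ficus1 <- 0L
  for (k in seq_len(K)) {
    sid <- sprintf("S%03dR0", k)
    base <- if (needs_master[k]) {
      master_scaffold(combo[k], sid, flat = (events[k] == "add_stereo"))
    } else plain_scaffold(plain_len[k], sid)
    recs <- list(base)
    cls <- if (!needs_master[k]) "none"
           else if (events[k] == "add_stereo") "unspec" else "full"
    stereo_k <- cls
    for (j in seq_along(plans[[k]])) {
      ty <- plans[[k]][j]
      recs[[j + 1L]] <- apply_variant(base, ty, sprintf("S%03dR%d", k, j))
      stereo_k <- c(stereo_k, if (ty == "stereo_strip") "unspec" else cls)
    }
    types <- unique(setdiff(plans[[k]], "exact_duplicate"))
    u_ficts1 <- u_ficts1 + 1L + length(types)
    u_ficus1 <- u_ficus1 + 1L + length(setdiff(types, "tautomer"))
    r1 <- c(r1, recs)
    stereo1 <- c(stereo1, stereo_k)
    # release 2
    if (events[k] == "remove") next
    recs2 <- recs
    if (events[k] %in% c("add_stereo", "redraw_tautomer")) {
      recs2[[1]] <- apply_variant(base, events[k], sid)
      stereo_k[1] <- if (events[k] == "add_stereo") "full" else stereo_k[1]
    }
    r2 <- c(r2, recs2)
    stereo2 <- c(stereo2, stereo_k)
  }
  for (j in seq_len(cur$new_records)) {
    sid <- sprintf("N%03d", j)
    rec <- master_scaffold(max(combo) + j, sid)
    r2 <- c(r2, list(rec))
    stereo2 <- c(stereo2, "full")
  }
  r1 <- lapply(r1, function(r) permute_atoms(r))
  r2 <- lapply(r2, function(r) permute_atoms(r))

  n_mod <- cur$add_stereo + cur$redraw_tautomer
  truth <- list(
    n_records = c(r1 = length(r1), r2 = length(r2)),
    unique = list(
      r1 = c(ficts = u_ficts1, ficus = u_ficus1, uuuuu = K),
      r2 = c(ficts = u_ficts1 - cur$remove + cur$new_records,
             ficus = u_ficus1 - cur$remove + cur$new_records,
             uuuuu = K - cur$remove + cur$new_records)),
    diff = list(
      sensitive = c(maintained = u_ficts1 - cur$remove - n_mod,
                    removed = cur$remove + n_mod,
                    added = n_mod + cur$new_records),
      skeleton = c(maintained = K - cur$remove,
                   removed = cur$remove,
                   added = cur$new_records),
      skeleton_links = n_mod),
    venn_sensitive = c(both = u_ficts1 - cur$remove - n_mod,
                       old_only = cur$remove + n_mod,
                       new_only = n_mod + cur$new_records),
    stereo = list(
      r1 = stereo_class_counts(stereo1),
      r2 = stereo_class_counts(stereo2))
  )
  out <- list(release1 = r1, release2 = r2, truth = truth, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sdf(r1, file.path(out_dir, "release1.sdf"))
    write_sdf(r2, file.path(out_dir, "release2.sdf"))
    # named vectors as JSON objects, not arrays
    objify <- function(x) {
      if (is.list(x)) lapply(x, objify)
      else if (!is.null(names(x))) as.list(x)
      else x
    }
    jsonlite::write_json(objify(truth),
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

stereo_class_counts <- function(cls) {
  c(no_atom_stereo = sum(cls == "none"), full_atom_spec = sum(cls == "full"),
    unspec_atom = sum(cls == "unspec"),
    no_bond_stereo = length(cls), full_bond_spec = 0L, unspec_bond = 0L)
}

#' Plant 2-4 keyed sets with exact Venn cells
#'
#' Builds abstract key sets whose exclusive Venn partition is given, for
#' oracle-checking the set algebra.
#'
#' @param labels 2-4 source labels
#' @param cells named integer vector; names are `&`-joined label subsets
#'   (e.g. `"A&B"`), values the exclusive cell counts
#' @param level level tag stamped on the sets
#' @return list with `sets` (list of [keyed_set()]) and `truth` (the cells)
#' @export
plant_keyed_sets <- function(labels, cells, level = "ficts") {
  stopifnot(length(labels) >= 2L, length(labels) <= 4L)
  memb <- strsplit(names(cells), "&", fixed = TRUE)
  bad <- setdiff(unlist(memb), labels)
  if (length(bad)) stop("cell label(s) not among sources: ",
                        paste(bad, collapse = ", "))
  keys <- sprintf("K%06d", seq_len(sum(cells)))
  idx <- rep(seq_along(cells), cells)
  sets <- lapply(labels, function(lb) {
    in_cell <- vapply(memb, function(m) lb %in% m, logical(1))
    keyed_set(lb, keys[in_cell[idx]], level)
  })
  list(sets = sets, truth = cells)
}

#' Generate synthetic protein-ID inputs with ground truth
#'
#' Plants 2-4 accession sets with exact consensus (Venn) cells, a species
#' mix, a reviewed (Swiss-Prot) fraction and per-source GO category biases,
#' and emits the ID-list files and annotation TSV the comparison pipeline
#' consumes. Duplicated and malformed lines can be planted in the ID lists
#' to exercise loader hygiene.
#'
#' @param cells named integer vector of exclusive consensus cells (names are
#'   `&`-joined source labels, as in [plant_keyed_sets()])
#' @param target_fraction fraction of the accession universe assigned to the
#'   target species (deterministic count: `round(f * n)`)
#' @param target_species,other_species species labels
#' @param reviewed_fraction fraction of accessions reviewed (`"SP"`)
#' @param go_categories category labels; every annotated protein gets one by
#'   round-robin with per-source-independent global assignment
#' @param fork_fraction fraction of proteins assigned a second category
#' @param n_duplicates,n_malformed planted per ID list
#' @param out_dir optional output directory (one `<label>_ids.txt` per
#'   source plus `annotations.tsv`)
#' @param seed integer seed
#' @return list with `ids` (per-source accession character vectors, with
#'   plants), `annotations` (data.frame), `truth` (cells, per-source species
#'   splits, SP:TR counts, GO counts), and `files` when `out_dir` given
#' @export
generate_protein_inputs <- function(cells,
                                    target_fraction = 0.45,
                                    target_species = "human",
                                    other_species = c("mouse", "rat", "E.coli"),
                                    reviewed_fraction = 0.9,
                                    go_categories = c("receptor", "enzyme",
                                                      "ion channel",
                                                      "transporter"),
                                    fork_fraction = 0,
                                    n_duplicates = 0L, n_malformed = 0L,
                                    out_dir = NULL, seed = 1L) {
  set.seed(seed)
  memb <- strsplit(names(cells), "&", fixed = TRUE)
  labels <- sort(unique(unlist(memb)))
  stopifnot(length(labels) >= 2L, length(labels) <= 4L)
  n <- sum(cells)
  acc <- sprintf("P%05d", seq_len(n))
  # deterministic attribute assignment over the shuffled universe
  ord <- sample(n)
  n_target <- round(target_fraction * n)
  species <- character(n)
  species[ord[seq_len(n_target)]] <- target_species
  rest <- ord[setdiff(seq_len(n), seq_len(n_target))]
  species[rest] <- rep(other_species, length.out = length(rest))
  n_sp <- round(reviewed_fraction * n)
  reviewed <- character(n)
  ord2 <- sample(n)
  reviewed[ord2[seq_len(n_sp)]] <- "SP"
  reviewed[ord2[setdiff(seq_len(n), seq_len(n_sp))]] <- "TR"
  go1 <- rep(go_categories, length.out = n)[sample(n)]
  forked <- sample(n, round(fork_fraction * n))
  go <- go1
  if (length(forked)) {
    # second category guaranteed different from the first
    alt <- vapply(go1[forked], function(g)
      go_categories[match(g, go_categories) %% length(go_categories) + 1L],
      character(1))
    go[forked] <- paste0(go1[forked], ";", alt)
  }
  annotations <- data.frame(accession = acc, species = species,
                            reviewed = reviewed, go = go,
                            stringsAsFactors = FALSE)

  idx <- rep(seq_along(cells), cells)
  ids <- lapply(labels, function(lb) {
    in_cell <- vapply(memb, function(m) lb %in% m, logical(1))
    acc[in_cell[idx]]
  })
  names(ids) <- labels

  per_source <- lapply(labels, function(lb) {
    sub <- annotations[annotations$accession %in% ids[[lb]], ]
    list(total = nrow(sub),
         target = sum(sub$species == target_species),
         sp = sum(sub$reviewed == "SP"), tr = sum(sub$reviewed == "TR"),
         target_tr = sum(sub$species == target_species & sub$reviewed == "TR"),
         go_counts = as.list(table(unlist(strsplit(sub$go, ";", fixed = TRUE)))))
  })
  names(per_source) <- labels
  truth <- list(cells = cells, n_universe = n, per_source = per_source)

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list()
    for (lb in labels) {
      lines <- ids[[lb]]
      if (n_duplicates > 0L)
        lines <- c(lines, lines[seq_len(min(n_duplicates, length(lines)))])
      if (n_malformed > 0L)
        lines <- c(lines, sprintf("not_an_id_%d", seq_len(n_malformed)))
      lines <- lines[sample(length(lines))]
      f <- file.path(out_dir, paste0(lb, "_ids.txt"))
      writeLines(lines, f)
      files[[lb]] <- f
    }
    af <- file.path(out_dir, "annotations.tsv")
    utils::write.table(annotations, af, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files$annotations <- af
  }
  list(ids = ids, annotations = annotations, truth = truth, files = files)
}

#' Sample a log-normal molecular-weight mixture with closed-form truth
#'
#' Emulates the weight regimes of compound collections: a unimodal
#' "lead-like" distribution, or bi-/tri-modal patterns such as a metabolite
#' database taking up large lipid classes. Components are parameterized by
#' their median (Da) and log-scale sd.
#'
#' @param n sample size
#' @param medians component medians in Da
#' @param sdlog component log-scale standard deviations (recycled)
#' @param weights mixture weights (normalized internally)
#' @param seed integer seed
#' @return list with `samples` (numeric) and `truth`: component parameters,
#'   mixture `mean`, and for single-component mixtures the closed-form
#'   `q1`, `median`, `q3`; `modes` are the component medians
#' @export
sample_mw_mixture <- function(n, medians = 400, sdlog = 0.3,
                              weights = rep(1, length(medians)), seed = 1L) {
  set.seed(seed)
  k <- length(medians)
  sdlog <- rep(sdlog, length.out = k)
  w <- weights / sum(weights)
  comp <- sample.int(k, n, replace = TRUE, prob = w)
  mu <- log(medians)
  samples <- stats::rlnorm(n, meanlog = mu[comp], sdlog = sdlog[comp])
  truth <- list(medians = medians, sdlog = sdlog, weights = w,
                mean = sum(w * exp(mu + sdlog^2 / 2)),
                modes = medians)
  if (k == 1L) {
    z <- stats::qnorm(c(0.25, 0.5, 0.75))
    truth$q1 <- exp(mu + z[1] * sdlog)
    truth$median <- exp(mu)
    truth$q3 <- exp(mu + z[3] * sdlog)
    truth$sd <- sqrt((exp(sdlog^2) - 1) * exp(2 * mu + sdlog^2))
  }
  list(samples = samples, truth = truth)
}
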