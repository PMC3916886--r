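
# The graded normalization cascade behind the identity keys.
#
# Levels (least to most aggressive):
#   SENSITIVE  ("ficts") — normalize_base only: keeps fragments, charges,
#                          isotopes, the drawn tautomer and stereo.
#   TAUTOMER_INVARIANT ("ficus") — adds per-fragment canonical tautomer.
#   SKELETON   ("uuuuu") — parent fragment, neutralized, isotope-free,
#                          canonical tautomer, stereo stripped.
#
# The transform tables are this package's own documented rule set; they honor
# the *contracts* of the graded-identity levels (what each level disregards),
# not any proprietary toolkit's internal rules.

SENSITIVITY_LEVELS <- c("ficts", "ficus", "uuuuu")

valence_exact <- function(rec) {
  bos <- bond_order_sums(rec)
  a <- rec$atoms
  ok <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    v <- effective_valence(a$elem[i], a$charge[i])
    ok[i] <- !is.na(v) && bos[i] + a$hcount[i] == v
  }
  ok
}

# fold explicit, unlabelled H atoms into their neighbor's hcount
fold_explicit_h <- function(rec) {
  a <- rec$atoms; b <- rec$bonds
  h <- which(a$elem == "H" & is.na(a$isotope) & a$charge == 0L)
  fold <- integer()
  for (i in h) {
    k <- which((b$a1 == i | b$a2 == i))
    if (length(k) != 1L || b$order[k] != 1L) next
    nbr <- if (b$a1[k] == i) b$a2[k] else b$a1[k]
    if (a$elem[nbr] == "H") next
    a$hcount[nbr] <- a$hcount[nbr] + 1L
    fold <- c(fold, i)
  }
  if (!length(fold)) return(rec)
  keep <- setdiff(seq_len(nrow(a)), fold)
  remap <- integer(nrow(a)); remap[keep] <- seq_along(keep)
  b <- b[!(b$a1 %in% fold | b$a2 %in% fold), , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  mol_record(rec$source_id, a[keep, , drop = FALSE], b, rec$flags)
}

# --- functional-group transform table --------------------------------------
# Applied to fixpoint; each rule strictly reduces hypervalent/charge-separated
# drawings so iteration terminates and the result is idempotent.
#  R1 nitro:      R-N(=O)=O          -> R-[N+](=O)[O-]
#  R2 azide/diazo: X=N=N (central N hypervalent) -> X=[N+]=[N-]
#  R3 sulfoxide:  [S+]-[O-]          -> S=O
apply_group_transforms <- function(rec) {
  repeat {
    bos <- bond_order_sums(rec)
    a <- rec$atoms; b <- rec$bonds
    changed <- FALSE
    hyperN <- which(a$elem == "N" & a$charge == 0L & bos + a$hcount > 3L)
    for (i in hyperN) {
      ks <- which((b$a1 == i | b$a2 == i) & b$order == 2L)
      nb <- ifelse(b$a1[ks] == i, b$a2[ks], b$a1[ks])
      deg <- tabulate(c(b$a1, b$a2), nbins = nrow(a))
      tO <- ks[a$elem[nb] == "O" & a$charge[nb] == 0L & deg[nb] == 1L]
      tN <- ks[a$elem[nb] == "N" & a$charge[nb] == 0L & deg[nb] == 1L]
      if (length(tO)) {                      # nitro
        k <- tO[1]; o <- if (b$a1[k] == i) b$a2[k] else b$a1[k]
        b$order[k] <- 1L; a$charge[o] <- -1L; a$charge[i] <- 1L
        changed <- TRUE
      } else if (length(tN)) {               # azide / diazo
        k <- tN[1]; t <- if (b$a1[k] == i) b$a2[k] else b$a1[k]
        a$charge[i] <- 1L; a$charge[t] <- -1L
        changed <- TRUE
      }
      if (changed) break
    }
    if (!changed) {
      sp <- which(a$elem == "S" & a$charge == 1L)
      for (i in sp) {
        ks <- which((b$a1 == i | b$a2 == i) & b$order == 1L)
        for (k in ks) {
          o <- if (b$a1[k] == i) b$a2[k] else b$a1[k]
          deg <- tabulate(c(b$a1, b$a2), nbins = nrow(a))
          if (a$elem[o] == "O" && a$charge[o] == -1L && deg[o] == 1L &&
              a$hcount[o] == 0L) {
            b$order[k] <- 2L; a$charge[i] <- 0L; a$charge[o] <- 0L
            changed <- TRUE; break
          }
        }
        if (changed) break
      }
    }
    if (!changed) break
    rec$atoms <- a; rec$bonds <- b
  }
  rec
}

# --- charged-resonance canonicalization ------------------------------------
# Moves a unit charge along conjugated paths i-j=k / i=j-k (swapping the two
# bond orders) whenever both end atoms keep exact valence, enumerates the
# closure and keeps the form with the lexicographically smallest canonical
# serialization. No CIP machinery: canonicality comes from the same
# refinement used for hashing.
resonance_moves <- function(rec) {
  a <- rec$atoms; b <- rec$bonds
  out <- list()
  charged <- which(abs(a$charge) == 1L)
  if (!length(charged) || !nrow(b)) return(out)
  bkey <- function(u, v) which((b$a1 == u & b$a2 == v) | (b$a1 == v & b$a2 == u))
  adj <- adjacency(rec)
  for (i in charged) {
    for (j in adj[[i]]) {
      kij <- bkey(i, j)[1]
      for (k in setdiff(adj[[j]], i)) {
        kjk <- bkey(j, k)[1]
        o1 <- b$order[kij]; o2 <- b$order[kjk]
        if (!((o1 == 1L && o2 == 2L) || (o1 == 2L && o2 == 1L))) next
        if (a$charge[k] != 0L) next
        cand <- rec
        cand$bonds$order[kij] <- o2
        cand$bonds$order[kjk] <- o1
        cand$atoms$charge[k] <- a$charge[i]
        cand$atoms$charge[i] <- 0L
        # a double bond that moved loses any wedge annotation
        cand$bonds$wedge[c(kij, kjk)][cand$bonds$order[c(kij, kjk)] == 2L] <- "none"
        vi <- valence_exact(cand)
        if (vi[i] && vi[j] && vi[k]) out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

canonicalize_resonance <- function(rec, cap = 200L) {
  if (!any(abs(rec$atoms$charge) == 1L)) return(rec)
  seen <- character(); forms <- list()
  queue <- list(rec)
  while (length(queue) && length(forms) < cap) {
    cur <- queue[[1]]; queue <- queue[-1]
    ser <- canonical_serialization(cur)
    if (ser %in% seen) next
    seen <- c(seen, ser)
    forms[[length(forms) + 1L]] <- list(ser = ser, rec = cur)
    queue <- c(queue, resonance_moves(cur))
  }
  {
    sers <- vapply(forms, `[[`, character(1), "ser")
    forms[[which(sers == min(sers))[1]]]$rec
  }
}

#' Base normalization of a parsed record
#'
#' Applies, in fixed order: explicit-hydrogen folding, the functional-group
#' transform table (pentavalent nitro, azide/diazo, charge-separated
#' sulfoxide), and charged-resonance canonicalization. Idempotent. Records
#' with an uncorrectable valence are flagged `"rejected"`.
#'
#' @param rec a parsed [mol_record()]
#' @return the normalized record
#' @export
normalize_base <- function(rec) {
  if (n_atoms(rec) == 0L) return(add_flag(rec, "rejected"))
  rec <- fold_explicit_h(rec)
  rec <- apply_group_transforms(rec)
  rec <- canonicalize_resonance(rec)
  rec$flags <- setdiff(rec$flags, "valence")
  if (!all(valence_exact(rec))) rec <- add_flag(rec, "rejected")
  rec
}

#' Select the parent fragment of a multi-component record
#'
#' Keeps the connected component with the most heavy atoms; ties broken by
#' larger molecular weight, then by lexicographically smallest canonical
#' serialization (so true duplicates resolve deterministically).
#'
#' @param rec a normalized [mol_record()]
#' @return a single-fragment record
#' @export
select_parent <- function(rec) {
  if (n_atoms(rec) == 0L) stop("cannot select parent of an empty record")
  comp <- components_of(rec)
  if (max(comp) == 1L) return(rec)
  frags <- lapply(seq_len(max(comp)), extract_fragment, rec = rec, comp = comp)
  heavy <- vapply(frags, function(f) sum(f$atoms$elem != "H"), integer(1))
  mw <- vapply(frags, molecular_weight, numeric(1))
  ser <- vapply(frags, canonical_serialization, character(1))
  ord <- order(-heavy, -mw, ser)
  frags[[ord[1]]]
}

#' Neutralize formal charges where hydrogen arithmetic permits
#'
#' Anions gain implicit hydrogens, cations shed them; centers with no
#' hydrogen to remove (e.g. quaternary nitrogen) and bare metal ions retain
#' their charge. Idempotent.
#'
#' @param rec a normalized [mol_record()]
#' @return the neutralized record
#' @export
neutralize <- function(rec) {
  a <- rec$atoms
  protic <- a$elem %in% c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  for (i in seq_len(nrow(a))) {
    if (a$charge[i] == 0L || !protic[i]) next
    if (a$charge[i] < 0L) {
      a$hcount[i] <- a$hcount[i] - a$charge[i]
      a$charge[i] <- 0L
    } else if (a$hcount[i] >= a$charge[i]) {
      a$hcount[i] <- a$hcount[i] - a$charge[i]
      a$charge[i] <- 0L
    }
  }
  rec$atoms <- a
  rec
}

#' Clear isotope labels
#'
#' Unsets all mass numbers; explicit hydrogens that were retained only for
#' their label are folded back into implicit counts. Idempotent.
#'
#' @param rec a [mol_record()]
#' @return the label-free record
#' @export
clear_isotopes <- function(rec) {
  rec$atoms$isotope <- NA_integer_
  fold_explicit_h(rec)
}

#' Strip all stereochemistry
#'
#' Clears wedge/either annotations and zeroes 2D coordinates so that no
#' double-bond geometry remains derivable. Idempotent.
#'
#' @param rec a [mol_record()]
#' @return the stereo-free record
#' @export
strip_stereo <- function(rec) {
  if (nrow(rec$bonds)) rec$bonds$wedge <- "none"
  rec$atoms$x <- 0; rec$atoms$y <- 0
  rec
}

# --- canonical tautomer ----------------------------------------------------

# one-directional 1,3 H-shift: x(H)-a=b  ->  x=a-b(H), x in {O,N,S},
# a,b in {C,N}; enumerating ordered triples in both orientations makes the
# move set symmetric, so tautomer orbits are connected components.
tautomer_moves <- function(rec) {
  a <- rec$atoms; b <- rec$bonds
  out <- list()
  if (!nrow(b)) return(out)
  adj <- adjacency(rec)
  bkey <- function(u, v) which((b$a1 == u & b$a2 == v) | (b$a1 == v & b$a2 == u))
  # never erase curated stereo: moves that would rehybridize a specified
  # tetrahedral center or break a specified double-bond geometry are blocked
  # (the tautomer-invariant identity level keeps stereochemistry)
  cls <- symmetry_classes(rec)
  pos <- seq_len(n_atoms(rec))
  spec_atoms <- Filter(function(i) atom_parity(rec, i, pos) != 0L,
                       atom_stereocenters_idx(rec, cls))
  spec_bonds <- Filter(function(k) nzchar(bond_geometry(rec, k, pos)),
                       bond_stereocenters_idx(rec, cls))
  donors <- which(a$elem %in% c("O", "N", "S") & a$hcount >= 1L & a$charge == 0L)
  for (x in donors) {
    for (aa in adj[[x]]) {
      kxa <- bkey(x, aa)[1]
      if (b$order[kxa] != 1L || !a$elem[aa] %in% c("C", "N")) next
      for (bb in setdiff(adj[[aa]], x)) {
        kab <- bkey(aa, bb)[1]
        if (b$order[kab] != 2L || !a$elem[bb] %in% c("C", "N")) next
        if (a$charge[bb] != 0L) next
        if (x %in% spec_atoms || kab %in% spec_bonds) next
        cand <- rec
        cand$atoms$hcount[x] <- a$hcount[x] - 1L
        cand$atoms$hcount[bb] <- a$hcount[bb] + 1L
        cand$bonds$order[kxa] <- 2L
        cand$bonds$order[kab] <- 1L
        cand$bonds$wedge[kxa] <- "none"
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  # reverse direction: x=a-b(H) -> x(H)-a=b
  accept <- which(a$elem %in% c("O", "N", "S") & a$charge == 0L)
  for (x in accept) {
    for (aa in adj[[x]]) {
      kxa <- bkey(x, aa)[1]
      if (b$order[kxa] != 2L || !a$elem[aa] %in% c("C", "N")) next
      for (bb in setdiff(adj[[aa]], x)) {
        kab <- bkey(aa, bb)[1]
        if (b$order[kab] != 1L || !a$elem[bb] %in% c("C", "N")) next
        if (a$hcount[bb] < 1L || a$charge[bb] != 0L) next
        if (bb %in% spec_atoms || kxa %in% spec_bonds) next
        cand <- rec
        cand$atoms$hcount[x] <- a$hcount[x] + 1L
        cand$atoms$hcount[bb] <- a$hcount[bb] - 1L
        cand$bonds$order[kxa] <- 1L
        cand$bonds$order[kab] <- 2L
        cand$bonds$wedge[kab] <- "none"
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

#' Canonical tautomer of a record
#'
#' Enumerates the 1,3 hydrogen-shift orbit (keto/enol, amide/iminol and their
#' aza analogues) breadth-first to a hard cap of `cap` distinct forms and
#' returns the form with the lexicographically smallest canonical
#' serialization. Any two members of one orbit map to the same
#' representative. If the cap is hit the input form is returned with a
#' `"tautomer_cap"` flag (the key stays deterministic).
#'
#' @param rec a normalized [mol_record()] (applied per fragment by
#'   [compute_keys()])
#' @param cap maximum number of distinct forms to enumerate
#' @return the representative tautomer
#' @export
canonical_tautomer <- function(rec, cap = 1000L) {
  seen <- new.env(parent = emptyenv())
  forms <- list()
  queue <- list(rec)
  capped <- FALSE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    ser <- canonical_serialization(cur)
    if (!is.null(seen[[ser]])) next
    if (length(forms) >= cap) { capped <- TRUE; break }
    seen[[ser]] <- TRUE
    forms[[length(forms) + 1L]] <- list(ser = ser, rec = cur)
    queue <- c(queue, tautomer_moves(cur))
  }
  if (capped) return(add_flag(rec, "tautomer_cap"))
  {
    sers <- vapply(forms, `[[`, character(1), "ser")
    forms[[which(sers == min(sers))[1]]]$rec
  }
}

# canonical tautomer applied independently to every fragment
canonical_tautomer_per_fragment <- function(rec, cap = 1000L) {
  comp <- components_of(rec)
  if (max(comp) == 1L) return(canonical_tautomer(rec, cap))
  frags <- lapply(seq_len(max(comp)), function(ci)
    canonical_tautomer(extract_fragment(rec, ci, comp), cap))
  combine_fragments(frags, rec$source_id, rec$flags)
}

# --- identity keys ---------------------------------------------------------

#' Compute the identity-key bundle of a record
#'
#' Emits canonical keys at the three sensitivity levels, plus any keys from
#' external providers (e.g. a Standard InChIKey backend) attached verbatim.
#' Rejected records (uncorrectable valence) yield `NULL`.
#'
#' @param rec a parsed [mol_record()]
#' @param providers named list of functions `record -> key string` (e.g.
#'   `list(stdkey = fn)`); their results are attached under their names
#' @return a list with `source_id`, `keys` (named character vector with at
#'   least `ficts`, `ficus`, `uuuuu`) and `flags`, or `NULL` if rejected
#' @export
compute_keys <- function(rec, providers = NULL) {
  norm <- normalize_base(rec)
  if (has_flag(norm, "rejected")) return(NULL)
  ficts <- hash_key(canonical_serialization(norm))
  taut <- canonical_tautomer_per_fragment(norm)
  ficus <- hash_key(canonical_serialization(taut))
  # stereo is stripped before tautomer canonicalization: the skeleton level
  # disregards stereo entirely, so the tautomer orbit must not be constrained
  # by the stereo-protection rule
  skel <- canonical_tautomer(strip_stereo(clear_isotopes(neutralize(
    select_parent(norm)))))
  uuuuu <- hash_key(canonical_serialization(skel, with_stereo = FALSE))
  keys <- c(ficts = ficts, ficus = ficus, uuuuu = uuuuu)
  for (nm in names(providers)) {
    k <- providers[[nm]](rec)
    if (!is.null(k)) keys[nm] <- k
  }
  list(source_id = rec$source_id, keys = keys,
       flags = unique(c(norm$flags, taut$flags)))
}

#' Key table for a record collection
#'
#' @param records list of [mol_record()]
#' @param providers see [compute_keys()]
#' @return list with `keys` (data.frame: source_id, ficts, ficus, uuuuu, and
#'   one column per provider) and `rejected` (data.frame: source_id)
#' @export
key_table <- function(records, providers = NULL) {
  rows <- list(); rej <- character()
  for (rec in records) {
    bdl <- compute_keys(rec, providers)
    if (is.null(bdl)) { rej <- c(rej, rec$source_id); next }
    rows[[length(rows) + 1L]] <-
      c(source_id = bdl$source_id, as.list(bdl$keys))
  }
  cols <- c("source_id", SENSITIVITY_LEVELS, names(providers))
  keys <- if (length(rows)) {
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    for (cn in setdiff(cols, names(df))) df[[cn]] <- NA_character_
    df[, cols, drop = FALSE]
  } else {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df
  }
  list(keys = keys,
       rejected = data.frame(source_id = rej, stringsAsFactors = FALSE))
}

#' Export a key table and its rejected records as TSV
#' @param kt result of [key_table()]
#' @param path output path for keys; rejected rows go to
#'   `paste0(path, ".rejected.tsv")`
#' @export
write_key_table <- function(kt, path) {
  utils::write.table(kt$keys, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(kt$rejected, paste0(path, ".rejected.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
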