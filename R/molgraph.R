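
#' Construct a molecule record
#'
#' The package's internal molecular-graph model: a hydrogen-suppressed (after
#' normalization) colored graph. Atoms carry element symbol, formal charge,
#' optional isotope mass number, an explicit-H count and 2D coordinates in
#' dimensionless molfile units; bonds carry order and a wedge annotation.
#'
#' @param source_id record identifier string (e.g. a database accession)
#' @param atoms data.frame with columns `elem` (character), `charge`
#'   (integer), `isotope` (integer, `NA` = unlabelled), `hcount` (integer,
#'   implicit+explicit hydrogens attached), `x`, `y` (numeric)
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices),
#'   `order` (1, 2 or 3) and `wedge` (`"none"`, `"up"`, `"down"`, `"either"`;
#'   the wedge narrow end is at `a1`)
#' @param flags character vector of quality flags (e.g. `"rejected"`,
#'   `"tautomer_cap"`)
#' @return an object of class `mol_record`
#' @export
mol_record <- function(source_id, atoms, bonds = NULL, flags = character()) {
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        wedge = character(), stringsAsFactors = FALSE)
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$isotope)) atoms$isotope <- NA_integer_
  if (is.null(atoms$hcount)) atoms$hcount <- NA_integer_
  if (is.null(atoms$x)) atoms$x <- 0
  if (is.null(atoms$y)) atoms$y <- 0
  if (is.null(bonds$wedge)) bonds$wedge <- rep("none", nrow(bonds))
  atoms$charge <- as.integer(atoms$charge)
  atoms$isotope <- as.integer(atoms$isotope)
  bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
  bonds$order <- as.integer(bonds$order)
  rec <- structure(list(source_id = as.character(source_id),
                        atoms = atoms, bonds = bonds,
                        flags = unique(flags)),
                   class = "mol_record")
  n <- nrow(atoms)
  if (nrow(bonds) > 0L && (any(bonds$a1 < 1L | bonds$a1 > n) ||
                           any(bonds$a2 < 1L | bonds$a2 > n)))
    stop("bond references nonexistent atom", call. = FALSE)
  rec
}

#' @export
print.mol_record <- function(x, ...) {
  cat(sprintf("<mol_record %s: %d atoms, %d bonds, %d fragment(s)%s>\n",
              x$source_id, nrow(x$atoms), nrow(x$bonds), fragment_count(x),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

n_atoms <- function(rec) nrow(rec$atoms)

has_flag <- function(rec, flag) flag %in% rec$flags

add_flag <- function(rec, flag) {
  rec$flags <- unique(c(rec$flags, flag))
  rec
}

#' Adjacency list of a record
#' @keywords internal
adjacency <- function(rec) {
  n <- n_atoms(rec)
  adj <- vector("list", n)
  b <- rec$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  adj
}

#' Connected-component membership of each atom
#' @return integer vector, component ids 1..k in order of first atom
#' @keywords internal
components_of <- function(rec) {
  n <- n_atoms(rec)
  comp <- integer(n)
  adj <- adjacency(rec)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

#' Number of connected components (fragments) of a record
#' @param rec a [mol_record()]
#' @return positive integer
#' @export
fragment_count <- function(rec) {
  if (n_atoms(rec) == 0L) return(0L)
  max(components_of(rec))
}

#' Extract one fragment as a standalone record
#' @keywords internal
extract_fragment <- function(rec, comp_id, comp = components_of(rec)) {
  keep <- which(comp == comp_id)
  remap <- integer(n_atoms(rec)); remap[keep] <- seq_along(keep)
  b <- rec$bonds
  bk <- b[b$a1 %in% keep & b$a2 %in% keep, , drop = FALSE]
  bk$a1 <- remap[bk$a1]; bk$a2 <- remap[bk$a2]
  mol_record(rec$source_id, rec$atoms[keep, , drop = FALSE], bk, rec$flags)
}

#' Reassemble fragments into one record (atom blocks concatenated)
#' @keywords internal
combine_fragments <- function(frags, source_id, flags = character()) {
  atoms <- do.call(rbind, lapply(frags, function(f) f$atoms))
  off <- 0L
  blist <- list()
  for (f in frags) {
    b <- f$bonds
    if (nrow(b)) { b$a1 <- b$a1 + off; b$a2 <- b$a2 + off }
    blist[[length(blist) + 1L]] <- b
    off <- off + n_atoms(f)
  }
  mol_record(source_id, atoms, do.call(rbind, blist),
             unique(c(flags, unlist(lapply(frags, `[[`, "flags")))))
}

# Sum of bond orders incident to each atom ("either" wedges don't affect order).
bond_order_sums <- function(rec) {
  n <- n_atoms(rec)
  s <- integer(n)
  b <- rec$bonds
  for (k in seq_len(nrow(b))) {
    s[b$a1[k]] <- s[b$a1[k]] + b$order[k]
    s[b$a2[k]] <- s[b$a2[k]] + b$order[k]
  }
  s
}

#' Complete implicit hydrogen counts from valence
#'
#' Fills `hcount` for atoms where it is `NA`, as effective valence minus the
#' sum of incident bond orders. Atoms whose bond-order sum exceeds their
#' plausible valence (or whose element is unknown) get `hcount = 0` and the
#' record is flagged `"valence"`.
#'
#' @param rec a [mol_record()]
#' @return the record with `hcount` filled
#' @export
complete_hydrogens <- function(rec) {
  if (n_atoms(rec) == 0L) return(rec)
  bos <- bond_order_sums(rec)
  a <- rec$atoms
  bad <- FALSE
  for (i in seq_len(nrow(a))) {
    v <- effective_valence(a$elem[i], a$charge[i])
    if (is.na(v)) { bad <- TRUE; if (is.na(a$hcount[i])) a$hcount[i] <- 0L; next }
    free <- v - bos[i]
    if (is.na(a$hcount[i])) {
      if (free < 0L) { bad <- TRUE; a$hcount[i] <- 0L } else a$hcount[i] <- free
    } else if (bos[i] + a$hcount[i] > v + 1L) {
      # one unit of slack tolerates hypervalent drawings fixed downstream
      bad <- TRUE
    }
  }
  rec$atoms <- a
  if (bad) rec <- add_flag(rec, "valence")
  rec
}

#' Random atom-order permutation of a record (test/generator utility)
#'
#' Relabels atoms by a random permutation, preserving graph, attributes and
#' wedge direction semantics. Identity keys must be invariant under this.
#'
#' @param rec a [mol_record()]
#' @param perm optional explicit permutation (new index of each old atom)
#' @return a relabelled `mol_record`
#' @export
permute_atoms <- function(rec, perm = sample(n_atoms(rec))) {
  n <- n_atoms(rec)
  stopifnot(length(perm) == n)
  inv <- integer(n); inv[perm] <- seq_len(n)
  atoms <- rec$atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- rec$bonds
  if (nrow(b)) { b$a1 <- perm[b$a1]; b$a2 <- perm[b$a2] }
  mol_record(rec$source_id, atoms, b, rec$flags)
}
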