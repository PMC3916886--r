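
# Stereochemistry-quality statistics for a record collection: how many
# structures have no tetrahedral (atom) stereocenters, how many specify all
# of them, and how many leave at least one unspecified — and the same triple
# for stereogenic double bonds. Substituent distinctness is judged by graph
# symmetry classes (no CIP), and ring double bonds are never counted as bond
# stereocenters.

#' Find potential tetrahedral stereocenters of a record
#'
#' A potential center is an atom with four graph-distinct substituents
#' (distinctness by canonical symmetry classes; an implicit hydrogen counts
#' as one substituent). A center is *specified* when a wedge with its narrow
#' end at the atom is drawn and yields a derivable parity.
#'
#' @param rec a parsed [mol_record()]
#' @return data.frame with columns `atom` (index) and `specified` (logical)
#' @export
find_atom_stereocenters <- function(rec) {
  cls <- symmetry_classes(rec)
  idx <- atom_stereocenters_idx(rec, cls)
  spec <- vapply(idx, function(i)
    atom_parity(rec, i, seq_len(n_atoms(rec))) != 0L, logical(1))
  data.frame(atom = idx, specified = spec)
}

#' Find stereogenic double bonds of a record
#'
#' A stereogenic double bond is a non-ring double bond whose two ends each
#' bear two graph-distinct substituents. It is *specified* when its cis/trans
#' geometry is derivable from the 2D coordinates and the bond is not marked
#' "either"; records without coordinates count all their stereogenic double
#' bonds as unspecified.
#'
#' @param rec a parsed [mol_record()]
#' @return data.frame with columns `bond` (row index in `rec$bonds`) and
#'   `specified` (logical)
#' @export
find_bond_stereocenters <- function(rec) {
  cls <- symmetry_classes(rec)
  idx <- bond_stereocenters_idx(rec, cls)
  spec <- vapply(idx, function(k)
    nzchar(bond_geometry(rec, k, seq_len(n_atoms(rec)))), logical(1))
  data.frame(bond = idx, specified = spec)
}

classify_stereo <- function(found) {
  if (nrow(found) == 0L) "none" else if (all(found$specified)) "full" else "unspec"
}

#' Stereochemistry summary of a record collection
#'
#' Classifies every record into exactly one atom-stereo class (no centers /
#' all specified / at least one unspecified) and one bond-stereo class, with
#' percentages relative to a caller-supplied original record count (so parse
#' failures and rejections show up in the denominators, matching how
#' databases report their raw record counts).
#'
#' @param records list of [mol_record()]
#' @param original_count the collection's original record count
#'   (>= `length(records)`)
#' @return a list of class `stereo_summary`: `n_records`, six counts and six
#'   percentages (one decimal)
#' @export
summarize_stereo <- function(records, original_count = length(records)) {
  if (original_count == 0L) stop("original_count must be positive")
  stopifnot(original_count >= length(records))
  ac <- vapply(records, function(r) classify_stereo(find_atom_stereocenters(r)),
               character(1))
  bc <- vapply(records, function(r) classify_stereo(find_bond_stereocenters(r)),
               character(1))
  cnt <- function(x, lvl) sum(x == lvl)
  counts <- c(no_atom_stereo = cnt(ac, "none"), full_atom_spec = cnt(ac, "full"),
              unspec_atom = cnt(ac, "unspec"),
              no_bond_stereo = cnt(bc, "none"), full_bond_spec = cnt(bc, "full"),
              unspec_bond = cnt(bc, "unspec"))
  structure(list(n_records = length(records), original_count = original_count,
                 counts = counts,
                 percentages = round(100 * counts / original_count, 1)),
            class = "stereo_summary")
}

#' @export
print.stereo_summary <- function(x, ...) {
  cat(sprintf("Stereo summary over %d records (of %d original):\n",
              x$n_records, x$original_count))
  for (nm in names(x$counts))
    cat(sprintf("  %-16s %8d (%.1f%%)\n", nm, x$counts[nm], x$percentages[nm]))
  invisible(x)
}

#' Export stereo summaries as a six-column TSV
#' @param summaries named list of `stereo_summary` objects (names = rows)
#' @param path output path
#' @export
write_stereo_table <- function(summaries, path) {
  df <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    cbind(data.frame(collection = nm),
          as.data.frame(as.list(s$counts)))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
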