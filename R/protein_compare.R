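
# UniProt accession-set comparison: de-duplicated ID loading, species splits
# with Swiss-Prot/TrEMBL ratios, n-way consensus sets, and GO top-level
# molecular-function distributions. Annotations are always an input table —
# never fetched live — so every analysis is reproducible at desk scale.

# UniProt accession grammar (6- and 10-character forms)
.uniprot_regex <- paste0(
  "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$")

is_uniprot_accession <- function(x) grepl(.uniprot_regex, x)

#' Load a UniProt accession list
#'
#' Reads one accession per line, validates against the UniProt accession
#' grammar, de-duplicates, and logs malformed lines.
#'
#' @param path path to a plain-text ID list
#' @return list with `accessions` (character, unique, input order),
#'   `n_lines`, `n_duplicates`, and `malformed` (character vector of
#'   rejected lines)
#' @export
load_ids <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  ok <- is_uniprot_accession(lines)
  acc <- unique(lines[ok])
  list(accessions = acc,
       n_lines = length(lines),
       n_duplicates = sum(ok) - length(acc),
       malformed = lines[!ok])
}

#' Join accessions with an annotation table
#'
#' @param accessions character vector of accessions
#' @param annotations data.frame with columns `accession`, `species`,
#'   `reviewed` (`"SP"`/`"TR"`), `go` (semicolon-joined top-level GO
#'   molecular-function labels; may be empty), e.g. from
#'   [read_annotation_table()]
#' @return data.frame of protein entries: `accession`, `species`, `reviewed`,
#'   `go_categories` (list column). Missing annotations yield species
#'   `"unknown"` and reviewed `"TR"` (an unknown review status is counted as
#'   unreviewed), with a warning.
#' @export
protein_entries <- function(accessions, annotations) {
  idx <- match(accessions, annotations$accession)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " accession(s) missing from annotation table",
            call. = FALSE)
  species <- ifelse(is.na(idx), "unknown", annotations$species[idx])
  reviewed <- ifelse(is.na(idx), "TR", annotations$reviewed[idx])
  go_raw <- ifelse(is.na(idx), "", annotations$go[idx])
  go <- lapply(strsplit(go_raw, ";", fixed = TRUE),
               function(g) unique(g[nzchar(trimws(g))]))
  data.frame(accession = accessions, species = species, reviewed = reviewed,
             go_categories = I(go), stringsAsFactors = FALSE)
}

#' Read a protein annotation TSV
#' @param path TSV with columns accession, species, reviewed, go
#' @return data.frame
#' @export
read_annotation_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
}

#' Species split and Swiss-Prot/TrEMBL ratio of a protein set
#'
#' The row structure mirrors how database protein content is usually
#' tabulated: total, target-species count, number of species, largest
#' non-target species, the SP:TR ratio, and the target-species TrEMBL-only
#' count — the curation-error signal, since expert review of the human
#' proteome is essentially complete and human mappings should carry a
#' Swiss-Prot ID.
#'
#' @param entries data.frame from [protein_entries()]
#' @param target_species species label of interest (default `"human"`)
#' @return list of class `species_split`
#' @export
species_split <- function(entries, target_species = "human") {
  per <- table(entries$species)
  non_target <- per[setdiff(names(per), target_species)]
  largest <- if (length(non_target)) {
    nm <- names(non_target)[which.max(non_target)]
    list(species = nm, count = as.integer(non_target[nm]))
  } else list(species = NA_character_, count = 0L)
  sp <- sum(entries$reviewed == "SP")
  tr <- sum(entries$reviewed == "TR")
  target_tr <- sum(entries$species == target_species & entries$reviewed == "TR")
  structure(list(total = nrow(entries),
                 target_species = target_species,
                 target_count = as.integer(sum(entries$species == target_species)),
                 n_species = length(per),
                 per_species = as.list(per),
                 largest_non_target = largest,
                 sp_count = sp, tr_count = tr,
                 target_tr_only = target_tr),
            class = "species_split")
}

#' @export
print.species_split <- function(x, ...) {
  cat(sprintf("All %d | %s %d | species %d | largest non-%s: %s (%d) | SP:TR %d:%d | %s TR-only %d\n",
              x$total, x$target_species, x$target_count, x$n_species,
              x$target_species, x$largest_non_target$species,
              x$largest_non_target$count, x$sp_count, x$tr_count,
              x$target_species, x$target_tr_only))
  invisible(x)
}

#' Consensus (n-way Venn) of accession sets
#'
#' Accession sets are ordinary keyed sets; this reuses the exact Venn
#' partition machinery so all its conservation laws carry over.
#'
#' @param sets named list (label -> character vector of accessions), 2-4 sets
#' @return a `venn_partition` (see [venn()])
#' @export
consensus <- function(sets) {
  ks <- lapply(names(sets), function(nm)
    keyed_set(nm, sets[[nm]], level = "accession"))
  venn(ks)
}

#' GO top-level molecular-function distribution
#'
#' Each protein contributes once per assigned category (GO terms fork, so a
#' protein may appear under several); fractions are over total assignments,
#' not proteins. Unannotated proteins are reported separately, never mixed
#' into the distribution.
#'
#' @param entries data.frame from [protein_entries()]
#' @return list with `distribution` (data.frame: category, count, fraction),
#'   `n_assignments`, `n_unannotated`
#' @export
go_distribution <- function(entries) {
  cats <- unlist(entries$go_categories)
  n_unann <- sum(vapply(entries$go_categories, length, integer(1)) == 0L)
  if (!length(cats)) {
    warning("no GO annotations present", call. = FALSE)
    return(list(distribution = data.frame(category = character(),
                                          count = integer(),
                                          fraction = numeric()),
                n_assignments = 0L, n_unannotated = n_unann))
  }
  tab <- sort(table(cats), decreasing = TRUE)
  list(distribution = data.frame(category = names(tab),
                                 count = as.integer(tab),
                                 fraction = as.numeric(tab) / sum(tab),
                                 stringsAsFactors = FALSE),
       n_assignments = sum(tab),
       n_unannotated = n_unann)
}

#' Export species splits as a compact comparison TSV
#' @param splits named list of `species_split` (names = sources)
#' @param path output path
#' @export
write_species_table <- function(splits, path) {
  df <- do.call(rbind, lapply(names(splits), function(nm) {
    s <- splits[[nm]]
    data.frame(source = nm, all = s$total, target = s$target_count,
               species_total = s$n_species,
               largest_non_target = sprintf("%s (%d)",
                                            s$largest_non_target$species,
                                            s$largest_non_target$count),
               sp_tr = sprintf("%d:%d", s$sp_count, s$tr_count),
               target_tr_only = s$target_tr_only)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
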