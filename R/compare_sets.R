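
# Keyed-set statistics: unique counts, pairwise overlap matrices, n-way Venn
# partitions, release diffs with skeleton-level linking, and category
# profiles. The unit of set algebra is the identity key, not the record:
# two records with one key are one element, exactly how "unique structures"
# are counted when comparing compound collections.

#' Construct a keyed set
#'
#' @param label source name
#' @param keys character vector of identity keys (de-duplicated)
#' @param level sensitivity level or external provider tag the keys were
#'   computed at
#' @param original_count the source's original record count (defaults to the
#'   number of keys supplied before de-duplication)
#' @return object of class `keyed_set`
#' @export
keyed_set <- function(label, keys, level, original_count = length(keys)) {
  keys <- unique(as.character(keys[!is.na(keys)]))
  if (length(keys) > original_count)
    stop("original_count smaller than the number of distinct keys")
  structure(list(label = label, level = level, keys = keys,
                 original_count = as.integer(original_count)),
            class = "keyed_set")
}

#' Keyed set from a key table at a given level
#' @param kt result of [key_table()]
#' @param level column name in `kt$keys` (e.g. `"ficts"`)
#' @param label source name
#' @param original_count original record count; defaults to rows + rejects
#' @export
keyed_set_from_table <- function(kt, level, label,
                                 original_count = nrow(kt$keys) +
                                   nrow(kt$rejected)) {
  if (!level %in% names(kt$keys)) stop("level absent from key table: ", level)
  keyed_set(label, kt$keys[[level]], level, original_count)
}

#' @export
print.keyed_set <- function(x, ...) {
  cat(sprintf("<keyed_set %s [%s]: %d unique keys of %d records>\n",
              x$label, x$level, length(x$keys), x$original_count))
  invisible(x)
}

#' Unique-structure count and percentage at one level
#'
#' @param bundles a list of key bundles (from [compute_keys()]) or a
#'   `key_table()` result
#' @param level sensitivity level name
#' @param original_count original record count (>= 1)
#' @return list with `unique_count` and `percentage` (one decimal, of the
#'   original count)
#' @export
unique_stats <- function(bundles, level, original_count) {
  stopifnot(original_count >= 1)
  keys <- extract_level_keys(bundles, level)
  u <- length(unique(keys))
  list(unique_count = u, percentage = round(100 * u / original_count, 1))
}

extract_level_keys <- function(bundles, level) {
  if (is.list(bundles) && !is.null(bundles$keys) && is.data.frame(bundles$keys)) {
    if (!level %in% names(bundles$keys)) stop("level absent: ", level)
    return(bundles$keys[[level]])
  }
  ks <- vapply(bundles, function(b) {
    if (!level %in% names(b$keys)) stop("level absent: ", level)
    b$keys[[level]]
  }, character(1))
  ks
}

#' Pairwise overlap matrix of keyed sets
#'
#' Symmetric matrix of pairwise intersection counts with the per-set unique
#' counts on the diagonal. All sets must be keyed at the same level.
#'
#' @param sets list of [keyed_set()]
#' @return integer matrix with set labels as dimnames
#' @export
overlap_matrix <- function(sets) {
  check_same_level(sets)
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(vapply(sets, `[[`, "", "label"),
                                        vapply(sets, `[[`, "", "label")))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- if (i == j) length(sets[[i]]$keys)
               else length(intersect(sets[[i]]$keys, sets[[j]]$keys))
  }
  m
}

check_same_level <- function(sets) {
  lv <- unique(vapply(sets, `[[`, "", "level"))
  if (length(lv) != 1L)
    stop("sets are keyed at different levels: ", paste(lv, collapse = ", "))
  invisible(lv)
}

#' Coverage of one source by another
#'
#' `100 * |A n B| / |B|`: how much of set `of` is covered by set `by`.
#'
#' @param by,of [keyed_set()] objects at the same level
#' @param digits rounding (0 = nearest integer, the prose convention)
#' @return percentage
#' @export
coverage <- function(by, of, digits = 0) {
  check_same_level(list(by, of))
  round(100 * length(intersect(by$keys, of$keys)) / length(of$keys), digits)
}

#' Exact n-way Venn partition of 2-4 keyed sets
#'
#' Partitions the union into the `2^n - 1` exclusive cells by membership
#' mask. Cell masks are recorded as label subsets, not bit positions.
#'
#' @param sets list of 2-4 [keyed_set()] at the same level
#' @return object of class `venn_partition`: `labels`, and `cells`, a named
#'   list (mask string of `1`/`0` per source) of `list(count, keys, labels)`
#' @export
venn <- function(sets) {
  if (length(sets) < 2L || length(sets) > 4L)
    stop("venn requires between 2 and 4 sets")
  check_same_level(sets)
  labels <- vapply(sets, `[[`, "", "label")
  all_keys <- unique(unlist(lapply(sets, `[[`, "keys")))
  member <- vapply(sets, function(s) all_keys %in% s$keys,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L)
  mask <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  cells <- list()
  for (m in sort(unique(mask))) {
    ks <- all_keys[mask == m]
    cells[[m]] <- list(count = length(ks), keys = ks,
                       labels = labels[strsplit(m, "")[[1]] == "1"])
  }
  structure(list(labels = labels, cells = cells,
                 union_size = length(all_keys)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition of %s: union %d>\n",
              paste(x$labels, collapse = ", "), x$union_size))
  for (m in names(x$cells))
    cat(sprintf("  [%s] %s: %d\n", m,
                paste(x$cells[[m]]$labels, collapse = "&"), x$cells[[m]]$count))
  invisible(x)
}

#' Cell count of a Venn partition by label subset
#' @param vp a `venn_partition`
#' @param labels character vector: exactly the sources the cell belongs to
#' @return integer count (0 when the cell is empty)
#' @export
venn_cell <- function(vp, labels) {
  mask <- paste(as.integer(vp$labels %in% labels), collapse = "")
  if (is.null(vp$cells[[mask]])) 0L else vp$cells[[mask]]$count
}

#' Release diff between two keyed versions of one source
#'
#' Per level: keys maintained (present in both releases), removed (old only)
#' and added (new only). `skeleton_links` counts old/new key pairs that join
#' only at the skeleton level — records whose basic connectivity persisted
#' while a more sensitive feature (stereo, tautomer drawing, salt form ...)
#' was curated; linking those requires disregarding the improvement.
#'
#' @param old,new `key_table()` results (or lists of key bundles) for the two
#'   releases
#' @param sensitive_level level used for the sensitive comparison
#' @return object of class `release_diff`: per-level `maintained`, `removed`,
#'   `added`, plus `skeleton_links`
#' @export
release_diff <- function(old, new, sensitive_level = "ficts") {
  levels <- c(sensitive_level, "uuuuu")
  per <- lapply(levels, function(lv) {
    ok <- unique(extract_level_keys(old, lv))
    nk <- unique(extract_level_keys(new, lv))
    list(maintained = length(intersect(ok, nk)),
         removed = length(setdiff(ok, nk)),
         added = length(setdiff(nk, ok)))
  })
  names(per) <- levels
  # skeleton links: skeleton keys shared by both releases whose sensitive
  # keys do not overlap across releases
  os <- extract_level_keys(old, sensitive_level)
  ns <- extract_level_keys(new, sensitive_level)
  ou <- extract_level_keys(old, "uuuuu")
  nu <- extract_level_keys(new, "uuuuu")
  shared_skel <- intersect(unique(ou), unique(nu))
  links <- 0L
  for (sk in shared_skel) {
    s_old <- unique(os[ou == sk]); s_new <- unique(ns[nu == sk])
    if (!length(intersect(s_old, s_new))) links <- links + 1L
  }
  structure(list(levels = per, skeleton_links = links,
                 sensitive_level = sensitive_level),
            class = "release_diff")
}

#' @export
print.release_diff <- function(x, ...) {
  for (lv in names(x$levels)) {
    p <- x$levels[[lv]]
    cat(sprintf("  %-6s maintained %d, removed %d, added %d\n",
                lv, p$maintained, p$removed, p$added))
  }
  cat(sprintf("  skeleton-only links: %d\n", x$skeleton_links))
  invisible(x)
}

#' Category profile of a keyed set
#'
#' Percentage of the set's keys falling in each category. The category map
#' may be partial: unmapped keys belong to no category.
#'
#' @param set a [keyed_set()]
#' @param categories named list: key -> character vector of category labels
#' @return named numeric vector of percentages (over `|set|`)
#' @export
category_profile <- function(set, categories) {
  if (!length(set$keys)) stop("empty set")
  cats <- sort(unique(unlist(categories)))
  out <- stats::setNames(numeric(length(cats)), cats)
  have <- intersect(set$keys, names(categories))
  for (k in have) for (cc in categories[[k]]) out[cc] <- out[cc] + 1
  100 * out / length(set$keys)
}

#' Export a Venn partition as JSON or TSV
#' @param vp a `venn_partition`
#' @param path output path; format chosen by extension (.json else TSV)
#' @param keys include member keys (JSON only)
#' @export
write_venn <- function(vp, path, keys = FALSE) {
  if (grepl("\\.json$", path)) {
    obj <- lapply(vp$cells, function(cl) {
      if (keys) list(labels = cl$labels, count = cl$count, keys = cl$keys)
      else list(labels = cl$labels, count = cl$count)
    })
    jsonlite::write_json(obj, path, auto_unbox = TRUE)
  } else {
    df <- do.call(rbind, lapply(names(vp$cells), function(m)
      data.frame(members = paste(vp$cells[[m]]$labels, collapse = "&"),
                 count = vp$cells[[m]]$count)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Export an overlap matrix as TSV
#' @param m matrix from [overlap_matrix()]
#' @param path output path
#' @export
write_overlap_matrix <- function(m, path) {
  utils::write.table(cbind(data.frame(source = rownames(m)), as.data.frame(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
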