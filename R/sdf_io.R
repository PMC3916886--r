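
# MDL V2000 SD file reading/writing.
#
# The reader is deliberately strict about per-record accounting: every
# "$$$$"-terminated block either yields a mol_record or a ParseReport row
# with its ordinal and a reason; nothing is silently dropped. V3000 blocks
# are counted as failures ("unsupported version"). Aromatic (order-4) bonds
# are kekulized on read; blocks that cannot be kekulized fail.

.wedge_codes <- c("0" = "none", "1" = "up", "6" = "down", "4" = "either")
.wedge_nums <- c(none = 0L, up = 1L, down = 6L, either = 4L)

# legacy atom-block charge column: 0 none, 1 +3, 2 +2, 3 +1, 5 -1, 6 -2, 7 -3
.legacy_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                    `5` = -1L, `6` = -2L, `7` = -3L)

parse_molfile_block <- function(lines, id_field) {
  if (length(lines) < 4L) stop("truncated molfile header")
  title <- trimws(lines[1])
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE)) stop("unsupported version")
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 0L || nb < 0L)
    stop("malformed counts line")
  if (length(lines) < 4L + na + nb) stop("truncated atom/bond block")
  atom_lines <- lines[seq_len(na) + 4L]
  bond_lines <- if (nb > 0L) lines[seq_len(nb) + 4L + na] else character()

  x <- suppressWarnings(as.numeric(substr(atom_lines, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 11, 20)))
  elem <- trimws(substr(atom_lines, 32, 34))
  ccode <- trimws(substr(atom_lines, 37, 39))
  if (any(is.na(x)) || any(is.na(y)) || any(elem == ""))
    stop("malformed atom block")
  charge <- .legacy_charge[ccode]
  charge[is.na(charge)] <- 0L
  atoms <- data.frame(elem = elem, charge = as.integer(charge),
                      isotope = NA_integer_, hcount = NA_integer_,
                      x = x, y = y, stringsAsFactors = FALSE)

  a1 <- suppressWarnings(as.integer(substr(bond_lines, 1, 3)))
  a2 <- suppressWarnings(as.integer(substr(bond_lines, 4, 6)))
  ord <- suppressWarnings(as.integer(substr(bond_lines, 7, 9)))
  stv <- trimws(substr(bond_lines, 10, 12))
  stv[stv == ""] <- "0"
  if (nb > 0L && (any(is.na(a1)) || any(is.na(a2)) || any(is.na(ord))))
    stop("malformed bond block")
  if (nb > 0L && (any(a1 < 1L | a1 > na) || any(a2 < 1L | a2 > na)))
    stop("bond references nonexistent atom")
  wedge <- unname(.wedge_codes[stv])
  wedge[is.na(wedge)] <- "none"
  bonds <- data.frame(a1 = a1, a2 = a2, order = ord, wedge = wedge,
                      stringsAsFactors = FALSE)

  # properties block: M CHG / M ISO override, first "M  CHG" resets charges
  rest <- lines[-seq_len(4L + na + nb)]
  chg_seen <- FALSE
  for (ln in rest) {
    if (startsWith(ln, "M  END")) break
    if (startsWith(ln, "M  CHG") || startsWith(ln, "M  ISO")) {
      kind <- substr(ln, 4, 6)
      nn <- suppressWarnings(as.integer(substr(ln, 7, 9)))
      if (is.na(nn)) stop("malformed properties line")
      if (kind == "CHG" && !chg_seen) { atoms$charge[] <- 0L; chg_seen <- TRUE }
      for (k in seq_len(nn)) {
        off <- 10L + (k - 1L) * 8L          # pairs of 4-char fields
        ai <- suppressWarnings(as.integer(trimws(substr(ln, off, off + 3L))))
        vv <- suppressWarnings(as.integer(trimws(substr(ln, off + 4L, off + 7L))))
        if (is.na(ai) || ai < 1L || ai > na) stop("malformed properties line")
        if (kind == "CHG") atoms$charge[ai] <- vv else atoms$isotope[ai] <- vv
      }
    }
  }

  # data fields
  fields <- list()
  i <- which(startsWith(rest, "> "))
  for (j in i) {
    tag <- sub("^.*<([^>]+)>.*$", "\\1", rest[j])
    val <- character()
    k <- j + 1L
    while (k <= length(rest) && nzchar(trimws(rest[k])) &&
           !startsWith(rest[k], "> ")) {
      val <- c(val, rest[k]); k <- k + 1L
    }
    fields[[tag]] <- paste(val, collapse = "\n")
  }

  sid <- if (identical(id_field, "title")) title else fields[[id_field]]
  if (is.null(sid) || !nzchar(sid)) sid <- title
  if (!nzchar(sid)) sid <- NA_character_

  rec <- mol_record(sid, atoms, bonds)
  if (any(rec$bonds$order == 4L)) rec <- kekulize(rec)
  if (any(!rec$bonds$order %in% 1:3)) stop("unsupported bond order")
  complete_hydrogens(rec)
}

#' Kekulize aromatic (order-4) bonds
#'
#' Assigns alternating single/double orders to molfile aromatic bonds by
#' backtracking: every carbon in the aromatic system must receive exactly one
#' double bond (among aromatic or pre-existing double bonds); N, O and S may
#' contribute a lone pair instead (pyrrole/furan-type atoms). Throws if no
#' assignment exists.
#'
#' @param rec a record possibly containing order-4 bonds
#' @return the record with all bonds in {1,2,3}
#' @keywords internal
kekulize <- function(rec) {
  b <- rec$bonds
  arom <- which(b$order == 4L)
  if (!length(arom)) return(rec)
  n <- n_atoms(rec)
  # atoms already engaged in an explicit double/triple bond can't take another
  pre_double <- logical(n)
  for (k in which(b$order >= 2L & b$order != 4L)) {
    pre_double[b$a1[k]] <- TRUE; pre_double[b$a2[k]] <- TRUE
  }
  optional <- rec$atoms$elem %in% c("N", "O", "S")
  arom_atoms <- unique(c(b$a1[arom], b$a2[arom]))
  matched <- pre_double  # TRUE = cannot accept (or already has) a double
  assign <- integer(length(arom))  # 1 or 2

  bt <- function(i) {
    if (i > length(arom)) {
      need <- setdiff(arom_atoms[!optional[arom_atoms]], which(matched))
      return(length(need) == 0L)
    }
    k <- arom[i]
    u <- b$a1[k]; v <- b$a2[k]
    # try double first (favors full matchings)
    if (!matched[u] && !matched[v]) {
      matched[u] <<- TRUE; matched[v] <<- TRUE; assign[i] <<- 2L
      if (bt(i + 1L)) return(TRUE)
      matched[u] <<- FALSE; matched[v] <<- FALSE
    }
    assign[i] <<- 1L
    bt(i + 1L)
  }
  if (!bt(1L)) stop("kekulization failed")
  rec$bonds$order[arom] <- assign
  rec
}

#' Read an SD file
#'
#' Parses an MDL V2000 SD file into molecule records. Each record block gets
#' its `source_id` from the named SD data field, falling back to the molfile
#' title line. Blocks that fail to parse are skipped, counted and reported —
#' never silently dropped.
#'
#' @param path path to the SD file
#' @param id_field SD data-field tag carrying the record id, or `"title"` to
#'   use the molfile title line
#' @return a list with `records` (list of [mol_record()]) and `report`, a
#'   ParseReport list with `records_read`, `records_failed` and a `failures`
#'   data.frame (`ordinal`, `reason`)
#' @export
read_sdf <- function(path, id_field = "title") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  term <- which(trimws(lines) == "$$$$")
  starts <- c(1L, head(term, -1L) + 1L)
  records <- list()
  fails <- data.frame(ordinal = integer(), reason = character(),
                      stringsAsFactors = FALSE)
  seen_ids <- character()
  for (bi in seq_along(term)) {
    block <- lines[starts[bi]:(term[bi] - 1L)]
    res <- tryCatch(parse_molfile_block(block, id_field),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fails <- rbind(fails, data.frame(ordinal = bi, reason = res,
                                       stringsAsFactors = FALSE))
    } else {
      if (!is.na(res$source_id) && res$source_id %in% seen_ids)
        warning("duplicate source_id: ", res$source_id, call. = FALSE)
      seen_ids <- c(seen_ids, res$source_id)
      records[[length(records) + 1L]] <- res
    }
  }
  list(records = records,
       report = list(records_read = length(records),
                     records_failed = nrow(fails),
                     failures = fails))
}

#' Write records to an SD file
#'
#' Emits MDL V2000 blocks (charges as `M  CHG`, isotopes as `M  ISO`, wedges
#' in the bond-block stereo column) with the `source_id` both on the title
#' line and in a `<ID>` data field. `read_sdf(write_sdf(x))` reproduces
#' graphs and ids exactly, up to atom order.
#'
#' @param records list of [mol_record()]
#' @param path output path
#' @return `invisible(path)`
#' @export
write_sdf <- function(records, path) {
  out <- character()
  for (rec in records) {
    a <- rec$atoms; b <- rec$bonds
    out <- c(out, rec$source_id, "  chemcollate", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nrow(b)))
    out <- c(out, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      a$x, a$y, 0, a$elem))
    if (nrow(b))
      out <- c(out, sprintf("%3d%3d%3d%3d  0  0  0", b$a1, b$a2, b$order,
                            unname(.wedge_nums[b$wedge])))
    chg <- which(a$charge != 0L)
    for (grp in split(chg, ceiling(seq_along(chg) / 8)))
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp, a$charge[grp]),
                                  collapse = "")))
    iso <- which(!is.na(a$isotope))
    for (grp in split(iso, ceiling(seq_along(iso) / 8)))
      out <- c(out, paste0("M  ISO", sprintf("%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp, a$isotope[grp]),
                                  collapse = "")))
    out <- c(out, "M  END", "> <ID>", rec$source_id, "", "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Serialize a ParseReport to TSV
#' @param report the `report` element returned by [read_sdf()]
#' @param path output path
#' @export
write_parse_report <- function(report, path) {
  utils::write.table(report$failures, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
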