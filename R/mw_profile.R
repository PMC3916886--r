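
# Molecular weight and distribution statistics for compound collections.

#' Molecular weight of a record
#'
#' Sum of standard (abundance-averaged) atomic weights over all atoms,
#' including implicit hydrogens; isotope-labelled atoms contribute their
#' nuclide mass. Strictly additive over fragments, so
#' `MW(salt) = MW(parent) + MW(counterion)`.
#'
#' @param rec a [mol_record()] with completed hydrogen counts
#' @return molecular weight in Da
#' @export
molecular_weight <- function(rec) {
  a <- rec$atoms
  if (nrow(a) == 0L) return(0)
  w <- vapply(seq_len(nrow(a)), function(i)
    atomic_weight_of(a$elem[i], a$isotope[i]), numeric(1))
  sum(w) + sum(a$hcount) * .atomic_weight[["H"]]
}

#' Distribution statistics of molecular weights
#'
#' Mean, population standard deviation, and quartiles by inclusive linear
#' interpolation (`stats::quantile` type 7).
#'
#' @param x either a numeric vector of weights or a list of records (then
#'   weights are computed with [molecular_weight()] on the parent fragment of
#'   the base-normalized record, or on the whole record when
#'   `parent_only = FALSE`)
#' @param parent_only drop counterions before weighing (salt-free profile)
#' @return list of class `mw_stats`: `n`, `mean`, `std_dev`, `q1`, `median`,
#'   `q3`, all in Da
#' @export
mw_stats <- function(x, parent_only = TRUE) {
  mw <- collection_mw(x, parent_only)
  if (!length(mw)) stop("no records to profile")
  q <- unname(stats::quantile(mw, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n = length(mw), mean = mean(mw),
                 std_dev = sqrt(mean((mw - mean(mw))^2)),
                 q1 = q[1], median = q[2], q3 = q[3]),
            class = "mw_stats")
}

collection_mw <- function(x, parent_only = TRUE) {
  if (is.numeric(x)) return(as.numeric(x))
  vapply(x, function(rec) {
    r <- normalize_base(rec)
    if (parent_only && fragment_count(r) > 1L) r <- select_parent(r)
    molecular_weight(r)
  }, numeric(1))
}

#' @export
print.mw_stats <- function(x, ...) {
  cat(sprintf(
    "MW stats (n=%d): mean %.1f, sd %.1f, Q1 %.1f, median %.1f, Q3 %.1f Da\n",
    x$n, x$mean, x$std_dev, x$q1, x$median, x$q3))
  invisible(x)
}

#' Histogram of molecular weights
#'
#' Fixed-width binning from 0 upward. An optional key subset (paired with the
#' records' identity keys) restricts the histogram to "exclusive content",
#' the overlay used when profiling what one release holds that another does
#' not.
#'
#' @param x numeric weights or list of records (see [mw_stats()])
#' @param bin_width bin width in Da
#' @param keys optional character vector of per-record keys, parallel to `x`
#' @param subset optional set of keys to keep (requires `keys`)
#' @param parent_only see [mw_stats()]
#' @return data.frame with `bin_start`, `bin_end`, `count`
#' @export
mw_histogram <- function(x, bin_width = 50, keys = NULL, subset = NULL,
                         parent_only = TRUE) {
  mw <- collection_mw(x, parent_only)
  if (!is.null(subset)) {
    if (is.null(keys) || length(keys) != length(mw))
      stop("subset selection requires one key per record")
    mw <- mw[keys %in% subset]
  }
  if (!length(mw)) stop("no records to profile")
  bin <- floor(mw / bin_width)
  tab <- table(bin)
  data.frame(bin_start = as.integer(names(tab)) * bin_width,
             bin_end = (as.integer(names(tab)) + 1L) * bin_width,
             count = as.integer(tab))
}

#' Local modes of a molecular-weight histogram
#'
#' A bin is a mode when its count exceeds both neighbors (absent neighbors
#' count zero) and reaches `min_frac` of the total. Used to detect planted
#' bi-/tri-modality in synthetic mixtures.
#'
#' @param hist data.frame from [mw_histogram()]
#' @param min_frac minimum fraction of total count a mode must hold
#' @return numeric vector of mode bin centers (Da)
#' @export
histogram_modes <- function(hist, min_frac = 0.02) {
  w <- hist$bin_end[1] - hist$bin_start[1]
  grid <- seq(min(hist$bin_start), max(hist$bin_start), by = w)
  cnt <- hist$count[match(grid, hist$bin_start)]
  cnt[is.na(cnt)] <- 0L
  n <- length(cnt)
  lo <- c(0L, cnt[-n]); hi <- c(cnt[-1], 0L)
  is_mode <- cnt > lo & cnt >= hi & cnt >= min_frac * sum(cnt)
  grid[is_mode] + w / 2
}

#' Export MW statistics as a TSV shaped like a per-collection summary table
#' @param stats named list of `mw_stats` (names = collection labels)
#' @param path output path
#' @export
write_mw_table <- function(stats, path) {
  df <- do.call(rbind, lapply(names(stats), function(nm) {
    s <- stats[[nm]]
    data.frame(collection = nm, n = s$n, mean = round(s$mean, 1),
               std_dev = round(s$std_dev, 1), q1 = round(s$q1, 1),
               median = round(s$median, 1), q3 = round(s$q3, 1))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
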