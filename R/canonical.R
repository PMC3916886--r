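
# Canonical graph serialization by iterative neighborhood refinement
# (Weisfeiler-Lehman colors) with deterministic branch-and-compare
# tie-breaking, plus coordinate-derived stereo descriptors. Identity keys
# are hashes of these serializations, so everything here must be invariant
# under atom-order permutation.

# --- symmetry classes ------------------------------------------------------

#' Graph symmetry classes of the atoms of a record
#'
#' Iterative neighborhood refinement over (element, charge, isotope, H count,
#' degree) seeds; two atoms share a class when refinement cannot distinguish
#' their environments. Stereo marks never enter the classes.
#'
#' @param rec a [mol_record()]
#' @param use_charge,use_isotope include charge / isotope in the seed
#' @return integer vector of dense class ids (1 = "smallest" class label)
#' @export
symmetry_classes <- function(rec, use_charge = TRUE, use_isotope = TRUE) {
  n <- n_atoms(rec)
  if (n == 0L) return(integer())
  a <- rec$atoms
  seed <- paste(a$elem,
                if (use_charge) a$charge else 0L,
                if (use_isotope) ifelse(is.na(a$isotope), 0L, a$isotope) else 0L,
                a$hcount, sep = "/")
  col <- match(seed, sort(unique(seed)))
  refine_colors(rec, col)
}

# refine an initial coloring to a stable partition
refine_colors <- function(rec, col) {
  b <- rec$bonds
  n <- length(col)
  repeat {
    sig <- character(n)
    nbr <- vector("list", n)
    for (k in seq_len(nrow(b))) {
      u <- b$a1[k]; v <- b$a2[k]; o <- b$order[k]
      nbr[[u]] <- c(nbr[[u]], sprintf("%d:%06d", o, col[v]))
      nbr[[v]] <- c(nbr[[v]], sprintf("%d:%06d", o, col[u]))
    }
    for (i in seq_len(n))
      sig[i] <- paste0(sprintf("%06d", col[i]), "|",
                       paste(sort(nbr[[i]]), collapse = ","))
    newcol <- match(sig, sort(unique(sig)))
    if (identical(newcol, col) || length(unique(newcol)) == length(unique(col)))
      { col <- newcol; break }
    col <- newcol
  }
  col
}

# --- canonical order of one connected fragment -----------------------------

# Returns the canonical position of each atom (1..n). Ties in the refined
# partition are broken by individualizing each member of the first
# non-singleton class in turn and keeping the branch whose serialization is
# lexicographically smallest.
canonical_order_fragment <- function(rec) {
  n <- n_atoms(rec)
  col <- symmetry_classes(rec)
  best <- NULL
  search <- function(col) {
    tab <- table(col)
    multi <- as.integer(names(tab)[tab > 1L])
    if (!length(multi)) {
      ord <- order(col)
      pos <- integer(n); pos[ord] <- seq_len(n)
      ser <- serialize_plain(rec, pos)
      if (is.null(best) || ser < best$ser) best <<- list(pos = pos, ser = ser)
      return(invisible())
    }
    cls <- min(multi)
    for (i in which(col == cls)) {
      c2 <- col * 2L
      c2[i] <- c2[i] - 1L
      c2 <- match(c2, sort(unique(c2)))
      search(refine_colors(rec, c2))
    }
  }
  search(col)
  best$pos
}

# structural serialization of a fragment given canonical positions
serialize_plain <- function(rec, pos) {
  a <- rec$atoms
  ord <- order(pos)
  atom_s <- paste0(a$elem[ord], ",", a$charge[ord], ",",
                   ifelse(is.na(a$isotope[ord]), "", a$isotope[ord]), ",",
                   a$hcount[ord])
  b <- rec$bonds
  if (nrow(b)) {
    i <- pmin(pos[b$a1], pos[b$a2]); j <- pmax(pos[b$a1], pos[b$a2])
    bs <- sprintf("%d-%d:%d", i, j, b$order)
    bond_s <- paste(bs[order(i, j)], collapse = ";")
  } else bond_s <- ""
  paste0(paste(atom_s, collapse = ";"), "!", bond_s)
}

# --- stereo perception and descriptors -------------------------------------

# potential tetrahedral centers: indices of atoms with four graph-distinct
# substituents (implicit H counts as one substituent, at most one H)
atom_stereocenters_idx <- function(rec, classes = symmetry_classes(rec)) {
  a <- rec$atoms
  deg <- integer(n_atoms(rec))
  adj <- adjacency(rec)
  out <- integer()
  for (i in seq_len(n_atoms(rec))) {
    nb <- adj[[i]]
    nsub <- length(nb) + a$hcount[i]
    if (nsub != 4L || a$hcount[i] > 1L) next
    if (any(rec$bonds$order[rec$bonds$a1 == i | rec$bonds$a2 == i] > 1L)) next
    if (anyDuplicated(classes[nb])) next
    out <- c(out, i)
  }
  out
}

# bonds (row indices) that are stereogenic double bonds: non-ring double
# bond, each end bearing exactly two graph-distinct substituents
bond_stereocenters_idx <- function(rec, classes = symmetry_classes(rec)) {
  b <- rec$bonds
  if (!nrow(b)) return(integer())
  ring <- ring_bonds(rec)
  adj <- adjacency(rec)
  a <- rec$atoms
  end_ok <- function(atom, partner) {
    nb <- setdiff(adj[[atom]], partner)
    nsub <- length(nb) + a$hcount[atom]
    if (nsub != 2L) return(FALSE)
    if (length(nb) == 2L && classes[nb[1]] == classes[nb[2]]) return(FALSE)
    if (length(nb) == 0L) return(FALSE)  # =CH2 / =O ends
    TRUE
  }
  out <- integer()
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 2L || ring[k]) next
    if (end_ok(b$a1[k], b$a2[k]) && end_ok(b$a2[k], b$a1[k]))
      out <- c(out, k)
  }
  out
}

# logical vector: is each bond part of a cycle (i.e. not a bridge)?
ring_bonds <- function(rec) {
  n <- n_atoms(rec)
  b <- rec$bonds
  m <- nrow(b)
  if (!m) return(logical())
  # iterative DFS bridge-finding (Tarjan low-link)
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], list(c(b$a2[k], k)))
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], list(c(b$a1[k], k)))
  }
  disc <- rep(NA_integer_, n); low <- integer(n)
  is_bridge <- logical(m)
  timer <- 0L
  for (root in seq_len(n)) {
    if (!is.na(disc[root])) next
    stack <- list(list(v = root, pe = 0L, i = 1L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$i == 1L) { timer <- timer + 1L; disc[v] <- timer; low[v] <- timer }
      if (fr$i <= length(adj[[v]])) {
        stack[[length(stack)]]$i <- fr$i + 1L
        e <- adj[[v]][[fr$i]]
        w <- e[1]; ek <- e[2]
        if (ek == fr$pe) next
        if (!is.na(disc[w])) {
          low[v] <- min(low[v], disc[w])
        } else {
          stack[[length(stack) + 1L]] <- list(v = w, pe = ek, i = 1L)
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack)) {
          pf <- stack[[length(stack)]]
          low[pf$v] <- min(low[pf$v], low[v])
          if (low[v] > disc[pf$v]) is_bridge[fr$pe] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

# is a given atom's stereo specified (a wedge with its narrow end here)?
# pos (canonical positions) makes the choice among several wedges canonical.
atom_wedge_info <- function(rec, i, pos = seq_len(n_atoms(rec))) {
  b <- rec$bonds
  k <- which(b$a1 == i & b$wedge %in% c("up", "down"))
  if (!length(k)) return(NULL)
  k <- k[order(pos[b$a2[k]])][1]
  list(nbr = b$a2[k], dir = if (b$wedge[k] == "up") 1 else -1)
}

has_coords <- function(rec) {
  a <- rec$atoms
  nrow(a) > 0L && any(abs(a$x) > 1e-9 | abs(a$y) > 1e-9)
}

# tetrahedral parity of center i given canonical positions pos: sign of the
# signed volume of the substituents ordered by canonical position (implicit H
# last). Wedge neighbor lifted to z = dir; implicit H placed opposite.
atom_parity <- function(rec, i, pos) {
  w <- atom_wedge_info(rec, i, pos)
  if (is.null(w) || !has_coords(rec)) return(0L)
  adj <- adjacency(rec)
  nb <- adj[[i]]
  a <- rec$atoms
  pts <- lapply(nb, function(j) {
    z <- if (j == w$nbr) w$dir else 0
    c(a$x[j], a$y[j], z)
  })
  ranks <- pos[nb]
  if (a$hcount[i] == 1L) {
    # implicit H: generic position opposite the mean of the neighbors,
    # lifted to the opposite side of the wedge
    mx <- mean(a$x[nb]); my <- mean(a$y[nb])
    hp <- c(2 * a$x[i] - mx, 2 * a$y[i] - my, -w$dir)
    pts <- c(pts, list(hp))
    ranks <- c(ranks, Inf)
  }
  o <- order(ranks)
  p <- pts[o]
  v1 <- p[[2]] - p[[1]]; v2 <- p[[3]] - p[[1]]; v3 <- p[[4]] - p[[1]]
  det3 <- v1[1] * (v2[2] * v3[3] - v2[3] * v3[2]) -
          v1[2] * (v2[1] * v3[3] - v2[3] * v3[1]) +
          v1[3] * (v2[1] * v3[2] - v2[2] * v3[1])
  if (abs(det3) < 1e-9) 0L else if (det3 > 0) 1L else 2L
}

# cis/trans descriptor of a stereogenic double bond (bond row k) from 2D
# coordinates: reference substituent at each end = lowest canonical position.
# Returns "Z" (same side), "E" (opposite), or "" when underivable.
bond_geometry <- function(rec, k, pos) {
  b <- rec$bonds
  if (b$wedge[k] == "either" || !has_coords(rec)) return("")
  adj <- adjacency(rec)
  a <- rec$atoms
  u <- b$a1[k]; v <- b$a2[k]
  ru_c <- setdiff(adj[[u]], v); rv_c <- setdiff(adj[[v]], u)
  if (!length(ru_c) || !length(rv_c)) return("")
  ru <- ru_c[which.min(pos[ru_c])]
  rv <- rv_c[which.min(pos[rv_c])]
  dx <- a$x[v] - a$x[u]; dy <- a$y[v] - a$y[u]
  s1 <- dx * (a$y[ru] - a$y[u]) - dy * (a$x[ru] - a$x[u])
  s2 <- dx * (a$y[rv] - a$y[v]) - dy * (a$x[rv] - a$x[v])
  if (abs(s1) < 1e-9 || abs(s2) < 1e-9) return("")
  if (sign(s1) == sign(s2)) "Z" else "E"
}

# --- full serialization ----------------------------------------------------

#' Canonical serialization of a record
#'
#' Fragments are canonicalized independently and their serial strings sorted,
#' so the result is invariant under both atom and fragment permutation. With
#' `with_stereo = TRUE`, parity descriptors for specified tetrahedral centers
#' and E/Z descriptors for specified double bonds (both defined relative to
#' canonical atom positions) are appended.
#'
#' @param rec a [mol_record()]
#' @param with_stereo include stereo descriptors
#' @return a single string
#' @export
canonical_serialization <- function(rec, with_stereo = TRUE) {
  if (n_atoms(rec) == 0L) return("")
  comp <- components_of(rec)
  serials <- vapply(seq_len(max(comp)), function(ci) {
    f <- extract_fragment(rec, ci, comp)
    pos <- canonical_order_fragment(f)
    s <- serialize_plain(f, pos)
    if (with_stereo) {
      cls <- symmetry_classes(f)
      ac <- atom_stereocenters_idx(f, cls)
      ap <- character()
      for (i in ac) {
        p <- atom_parity(f, i, pos)
        if (p != 0L) ap <- c(ap, sprintf("@%d:%d", pos[i], p))
      }
      bc <- bond_stereocenters_idx(f, cls)
      bp <- character()
      for (k in bc) {
        g <- bond_geometry(f, k, pos)
        if (nzchar(g))
          bp <- c(bp, sprintf("=%d-%d:%s",
                              min(pos[f$bonds$a1[k]], pos[f$bonds$a2[k]]),
                              max(pos[f$bonds$a1[k]], pos[f$bonds$a2[k]]), g))
      }
      s <- paste0(s, "!", paste(sort(ap), collapse = ","),
                  "!", paste(sort(bp), collapse = ","))
    }
    s
  }, character(1))
  paste(sort(serials), collapse = "|")
}

# --- hashing ---------------------------------------------------------------

.b32_alphabet <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ234567", "")[[1]]

#' Hash a canonical serialization into a fixed-length key
#'
#' 128-bit digest rendered as 27 base-32 characters (26 data characters plus
#' a terminal version character), echoing the shape of hashed structure keys
#' like InChIKey. Collisions are vanishingly unlikely at library scale.
#'
#' @param serial string from [canonical_serialization()]
#' @return a 27-character key
#' @export
hash_key <- function(serial) {
  hx <- rlang::hash(serial)                      # 32 hex chars = 128 bits
  bits <- unlist(lapply(strtoi(strsplit(hx, "")[[1]], 16L), function(v)
    as.integer(intToBits(v))[4:1]))
  bits <- c(bits, 0L, 0L)                        # pad to 130 = 26 * 5
  idx <- vapply(seq_len(26), function(i) {
    sum(bits[(i - 1L) * 5L + 1:5] * c(16L, 8L, 4L, 2L, 1L))
  }, integer(1))
  paste0(paste(.b32_alphabet[idx + 1L], collapse = ""), "A")
}
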