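
# Small hand-built molecules used in documentation, tests and as
# counterions. Coordinates are plain 2D depictions (molfile units); implicit
# hydrogen counts are completed from valence at construction.

#' Build a named example molecule
#'
#' A small library of hand-drawn structures covering the phenomena the
#' normalization cascade addresses: tautomer pairs (acetone/propen-2-ol,
#' 2-hydroxypyridine/2-pyridone), alternate nitro drawings, charge states
#' (acetic acid/acetate), a quaternary ammonium, wedge and flat drawings of
#' alanine, and cis/trans/either drawings of 2-butene.
#'
#' @param name one of `"water"`, `"ethanol"`, `"benzene"`, `"acetone"`,
#'   `"propen2ol"`, `"acetic_acid"`, `"acetate"`, `"acetate_na"`,
#'   `"tma"`, `"nitrobenzene_neutral"`, `"nitrobenzene_charged"`,
#'   `"hydroxypyridine"`, `"pyridone"`, `"alanine_wedge"`, `"alanine_flat"`,
#'   `"alanine_down"`, `"trans2butene"`, `"cis2butene"`, `"either2butene"`,
#'   `"glucose"`
#' @param source_id id to stamp on the record (defaults to `name`)
#' @return a [mol_record()]
#' @export
example_mol <- function(name, source_id = name) {
  A <- function(elem, x = 0, y = 0, charge = 0L, isotope = NA_integer_)
    data.frame(elem = elem, charge = charge, isotope = isotope,
               hcount = NA_integer_, x = x, y = y, stringsAsFactors = FALSE)
  B <- function(a1, a2, order = 1L, wedge = "none")
    data.frame(a1 = a1, a2 = a2, order = order, wedge = wedge,
               stringsAsFactors = FALSE)
  hexagon <- function(cx = 0, cy = 0, r = 1)
    list(x = cx + r * cos(seq(0, by = pi / 3, length.out = 6)),
         y = cy + r * sin(seq(0, by = pi / 3, length.out = 6)))
  rec <- switch(
    name,
    water = mol_record(source_id, A("O")),
    ethanol = mol_record(source_id,
      A(c("C", "C", "O"), x = 0:2, y = c(0, 0.5, 0)),
      rbind(B(1, 2), B(2, 3))),
    benzene = {
      h <- hexagon()
      mol_record(source_id, A(rep("C", 6), h$x, h$y),
                 rbind(B(1, 2, 2L), B(2, 3, 1L), B(3, 4, 2L),
                       B(4, 5, 1L), B(5, 6, 2L), B(6, 1, 1L)))
    },
    acetone = mol_record(source_id,
      A(c("C", "C", "O", "C"), x = c(0, 0.87, 0.87, 1.73), y = c(0, 0.5, 1.5, 0)),
      rbind(B(1, 2), B(2, 3, 2L), B(2, 4))),
    propen2ol = mol_record(source_id,
      A(c("C", "C", "O", "C"), x = c(0, 0.87, 0.87, 1.73), y = c(0, 0.5, 1.5, 0)),
      rbind(B(1, 2, 2L), B(2, 3, 1L), B(2, 4))),
    acetic_acid = mol_record(source_id,
      A(c("C", "C", "O", "O"), x = c(0, 0.87, 0.87, 1.73), y = c(0, 0.5, 1.5, 0)),
      rbind(B(1, 2), B(2, 3, 2L), B(2, 4))),
    acetate = mol_record(source_id,
      A(c("C", "C", "O", "O"), x = c(0, 0.87, 0.87, 1.73), y = c(0, 0.5, 1.5, 0),
        charge = c(0L, 0L, 0L, -1L)),
      rbind(B(1, 2), B(2, 3, 2L), B(2, 4))),
    acetate_na = mol_record(source_id,
      A(c("C", "C", "O", "O", "Na"), x = c(0, 0.87, 0.87, 1.73, 4),
        y = c(0, 0.5, 1.5, 0, 0), charge = c(0L, 0L, 0L, -1L, 1L)),
      rbind(B(1, 2), B(2, 3, 2L), B(2, 4))),
    tma = mol_record(source_id,
      A(c("N", "C", "C", "C", "C"), x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1),
        charge = c(1L, 0L, 0L, 0L, 0L)),
      rbind(B(1, 2), B(1, 3), B(1, 4), B(1, 5))),
    nitrobenzene_neutral = {
      h <- hexagon()
      mol_record(source_id,
        A(c(rep("C", 6), "N", "O", "O"), c(h$x, 2, 3, 2), c(h$y, 0, 0.5, -1)),
        rbind(B(1, 2, 2L), B(2, 3, 1L), B(3, 4, 2L), B(4, 5, 1L),
              B(5, 6, 2L), B(6, 1, 1L), B(1, 7, 1L), B(7, 8, 2L), B(7, 9, 2L)))
    },
    nitrobenzene_charged = {
      h <- hexagon()
      mol_record(source_id,
        A(c(rep("C", 6), "N", "O", "O"), c(h$x, 2, 3, 2), c(h$y, 0, 0.5, -1),
          charge = c(rep(0L, 6), 1L, 0L, -1L)),
        rbind(B(1, 2, 2L), B(2, 3, 1L), B(3, 4, 2L), B(4, 5, 1L),
              B(5, 6, 2L), B(6, 1, 1L), B(1, 7, 1L), B(7, 8, 2L), B(7, 9, 1L)))
    },
    hydroxypyridine = {
      h <- hexagon()
      mol_record(source_id,
        A(c("N", rep("C", 5), "O"), c(h$x, 2), c(h$y, 0.5)),
        rbind(B(1, 2, 2L), B(2, 3, 1L), B(3, 4, 2L), B(4, 5, 1L),
              B(5, 6, 2L), B(6, 1, 1L), B(2, 7, 1L)))
    },
    pyridone = {
      h <- hexagon()
      mol_record(source_id,
        A(c("N", rep("C", 5), "O"), c(h$x, 2), c(h$y, 0.5)),
        rbind(B(1, 2, 1L), B(2, 3, 1L), B(3, 4, 2L), B(4, 5, 1L),
              B(5, 6, 2L), B(6, 1, 1L), B(2, 7, 2L)))
    },
    alanine_wedge = mol_record(source_id,
      A(c("N", "C", "C", "O", "O", "C"), x = c(0, 0.87, 1.73, 1.73, 2.60, 0.87),
        y = c(1, 0.5, 1, 2, 0.5, -0.5)),
      rbind(B(1, 2), B(2, 3), B(3, 4, 2L), B(3, 5), B(2, 6, 1L, "up"))),
    alanine_down = mol_record(source_id,
      A(c("N", "C", "C", "O", "O", "C"), x = c(0, 0.87, 1.73, 1.73, 2.60, 0.87),
        y = c(1, 0.5, 1, 2, 0.5, -0.5)),
      rbind(B(1, 2), B(2, 3), B(3, 4, 2L), B(3, 5), B(2, 6, 1L, "down"))),
    alanine_flat = mol_record(source_id,
      A(c("N", "C", "C", "O", "O", "C"), x = c(0, 0.87, 1.73, 1.73, 2.60, 0.87),
        y = c(1, 0.5, 1, 2, 0.5, -0.5)),
      rbind(B(1, 2), B(2, 3), B(3, 4, 2L), B(3, 5), B(2, 6))),
    trans2butene = mol_record(source_id,
      A(rep("C", 4), x = c(0, 1, 2, 3), y = c(0, 0.5, 0, 0.5)),
      rbind(B(1, 2), B(2, 3, 2L), B(3, 4))),
    cis2butene = mol_record(source_id,
      A(rep("C", 4), x = c(0, 1, 2, 2.5), y = c(0, 0.5, 0, -0.8)),
      rbind(B(1, 2), B(2, 3, 2L), B(3, 4))),
    either2butene = mol_record(source_id,
      A(rep("C", 4), x = c(0, 1, 2, 3), y = c(0, 0.5, 0, 0.5)),
      rbind(B(1, 2), B(2, 3, 2L, "either"), B(3, 4))),
    glucose = mol_record(source_id,
      A(c("C", "C", "C", "C", "C", "O", "O", "O", "O", "O", "C", "O"),
        x = c(0, 1, 2, 2, 1, 0, 0, 1, 3, 3, 1, 2), y = c(0, 0, 0, 1, 1, 1, -1, -1, -1, 1, 2, 3)),
      rbind(B(1, 2), B(2, 3), B(3, 4), B(4, 5), B(5, 6), B(6, 1),
            B(1, 7), B(2, 8), B(3, 9), B(4, 10), B(5, 11), B(11, 12))),
    stop("unknown example molecule: ", name)
  )
  complete_hydrogens(rec)
}
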