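
# Element data used for implicit-H completion, neutralization and MW.
# Default valences follow the MDL/SMILES convention for organic subset
# elements; metals default to 0 bonds (they occur here as counterions).

.default_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
  Si = 4, P = 3, S = 2, Cl = 1, Br = 1, I = 1,
  Li = 1, Na = 1, K = 1, Mg = 2, Ca = 2, Zn = 2, Fe = 2
)

# Standard (abundance-averaged) atomic weights, Da.
.atomic_weight <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
  Li = 6.94, Na = 22.990, K = 39.098, Mg = 24.305, Ca = 40.078,
  Zn = 65.38, Fe = 55.845
)

# Nuclide masses for common isotope labels; key "<elem>:<massnumber>".
# Labels outside this table fall back to the mass number itself.
.nuclide_mass <- c(
  "H:1" = 1.00783, "H:2" = 2.01410, "H:3" = 3.01605,
  "C:12" = 12.0, "C:13" = 13.00335, "C:14" = 14.00324,
  "N:14" = 14.00307, "N:15" = 15.00011,
  "O:16" = 15.99491, "O:17" = 16.99913, "O:18" = 17.99916,
  "S:32" = 31.97207, "S:34" = 33.96787,
  "Cl:35" = 34.96885, "Cl:37" = 36.96590,
  "P:31" = 30.97376, "F:19" = 18.99840, "Br:79" = 78.91834,
  "Br:81" = 80.91629, "I:127" = 126.90447
)

#' Effective valence of an element at a given formal charge
#'
#' The number of bonds (including implicit hydrogens) expected for a
#' chemically plausible atom. Charge shifts valence in the usual way:
#' `N+` takes 4 bonds, `O-` takes 1, `C-` takes 3, halide anions 0.
#'
#' @param elem element symbol
#' @param charge integer formal charge
#' @return integer valence, or `NA` for unknown elements
#' @keywords internal
effective_valence <- function(elem, charge = 0L) {
  v <- .default_valence[elem]
  if (is.na(v)) return(NA_integer_)
  out <- if (elem %in% c("N", "P", "B")) {
    v + charge
  } else if (elem %in% c("O", "S")) {
    v + charge
  } else if (elem %in% c("F", "Cl", "Br", "I")) {
    v + charge
  } else if (elem %in% c("H", "Li", "Na", "K")) {
    v - charge
  } else if (elem == "C") {
    v - abs(charge)
  } else {
    # divalent metals: as cations they carry no H
    max(0, v - abs(charge) * 2)
  }
  as.integer(max(0, out))
}

#' @keywords internal
atomic_weight_of <- function(elem, isotope = NA_integer_) {
  if (!is.na(isotope)) {
    key <- paste0(elem, ":", isotope)
    m <- .nuclide_mass[key]
    return(if (is.na(m)) as.numeric(isotope) else unname(m))
  }
  w <- .atomic_weight[elem]
  if (is.na(w)) stop("unknown element: ", elem, call. = FALSE)
  unname(w)
}
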