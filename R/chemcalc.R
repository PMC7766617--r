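# Molecular-formula arithmetic and the adduct/isotope/neutral-loss m/z
# calculus that all annotation rests on.

# IUPAC monoisotopic atomic masses (Da), >= 6 decimal places.
ATOMIC_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  S  = 31.97207117,
  P  = 30.97376200,
  Na = 22.98976928,
  K  = 38.96370649,
  Cl = 34.96885268
)

PROTON_MASS <- 1.00727646   # H minus one electron
ELECTRON_MASS <- 0.00054858
C13_MASS_SHIFT <- 1.003355  # 13C minus 12C

#' Parse a molecular-formula string
#'
#' Accepts element-count strings such as `"C25H32O13"` in Hill or arbitrary
#' order. Supported elements are C, H, N, O, S, P, Na, K and Cl. Repeated
#' element symbols are summed.
#'
#' @param text A single formula string. The empty string yields the empty
#'   formula (zero atoms, mass 0).
#' @return An object of class `molecular_formula`: a named integer vector of
#'   element counts in Hill order (C first, then H, then the rest
#'   alphabetically).
#' @examples
#' parse_formula("C8H10O3")   # hydroxytyrosol
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (text == "") {
    counts <- integer(0)
    class(counts) <- "molecular_formula"
    return(counts)
  }
  pattern <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (paste(tokens, collapse = "") != text) {
    stop("malformed formula string: '", text, "'", call. = FALSE)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(ATOMIC_MASSES)) {
      stop("unknown element symbol: '", sym, "'", call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts <- counts[counts > 0L]
  counts <- counts[hill_order(names(counts))]
  class(counts) <- "molecular_formula"
  counts
}

hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    c("C", intersect("H", symbols), rest)
  } else {
    sort(symbols)
  }
}

#' @export
format.molecular_formula <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", format(round(monoisotopic_mass(x), 5),
      nsmall = 5), " Da)\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a molecular formula
#'
#' @param f A `molecular_formula` (see [parse_formula()]) or a formula string.
#' @return Monoisotopic mass in Da; the empty formula has mass 0.
#' @examples
#' monoisotopic_mass("C8H10O3")  # 154.0630
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) return(0)
  sum(ATOMIC_MASSES[names(f)] * unclass(f))
}

as_formula <- function(f) {
  if (inherits(f, "molecular_formula")) f else parse_formula(f)
}

# ---- Adduct registry -------------------------------------------------------

delta_mass <- function(add = "", remove = "", electrons = 0L) {
  monoisotopic_mass(add) - monoisotopic_mass(remove) - electrons * ELECTRON_MASS
}

build_adduct_registry <- function() {
  base <- list(
    # name, multimer, charge, mass_delta (electron mass included)
    list("[M-H]-",          1L, -1L, -PROTON_MASS),
    list("[2M-H]-",         2L, -1L, -PROTON_MASS),
    list("[4M-H]-",         4L, -1L, -PROTON_MASS),
    list("[M+Cl]-",         1L, -1L, delta_mass("Cl", electrons = -1L)),
    list("[M-H+HCOOH]-",    1L, -1L, delta_mass("CH2O2", "H", electrons = -1L)),
    list("[M+H]+",          1L,  1L, PROTON_MASS),
    list("[2M+H]+",         2L,  1L, PROTON_MASS),
    list("[M+NH4]+",        1L,  1L, delta_mass("NH4", electrons = 1L)),
    list("[2M+NH4]+",       2L,  1L, delta_mass("NH4", electrons = 1L)),
    list("[M+Na]+",         1L,  1L, delta_mass("Na", electrons = 1L)),
    list("[2M+Na]+",        2L,  1L, delta_mass("Na", electrons = 1L)),
    list("[M+K]+",          1L,  1L, delta_mass("K", electrons = 1L)),
    list("[M+C2H8N]+",      1L,  1L, delta_mass("C2H8N", electrons = 1L)),
    list("[M+H+CH3COOK]+",  1L,  1L, delta_mass("C2H3O2K", electrons = 0L) +
                                     PROTON_MASS),
    list("[4M+3H]3+",       4L,  3L, 3 * PROTON_MASS),
    list("[4M+H+K]2+",      4L,  2L, PROTON_MASS +
                                     delta_mass("K", electrons = 1L))
  )
  rows <- lapply(base, function(b) {
    data.frame(name = c(b[[1]], paste0("13C", b[[1]]),
                        paste0("(2)13C", b[[1]])),
               multimer = b[[2]], charge = b[[3]], mass_delta = b[[4]],
               isotope_shift = 0:2, stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, rows)
  reg$polarity <- ifelse(reg$charge > 0, "+", "-")
  reg
}

.olivemet_env <- new.env(parent = emptyenv())

#' The registered adduct species
#'
#' Every bracketed ion species appearing in the packaged annotation table,
#' including formate and chloride adducts, ammonium and alkali cations,
#' multimers up to 4M, charges up to 3, and first/second 13C isotopologues
#' (prefixed `13C`/`(2)13C`). Species outside this registry are rejected by
#' [mz_for_adduct()], not guessed.
#'
#' @return A data frame with columns `name`, `multimer`, `charge`,
#'   `mass_delta` (Da, electron mass included), `isotope_shift` and
#'   `polarity`.
#' @export
adduct_registry <- function() {
  if (is.null(.olivemet_env$adducts)) {
    .olivemet_env$adducts <- build_adduct_registry()
  }
  .olivemet_env$adducts
}

get_adduct <- function(name) {
  reg <- adduct_registry()
  i <- match(name, reg$name)
  if (is.na(i)) stop("unregistered adduct species: '", name, "'",
                     call. = FALSE)
  reg[i, ]
}

#' Theoretical m/z of an adduct species
#'
#' Computes `(multimer * M + isotope_shift * 1.003355 + mass_delta) /
#' |charge|` where `M` is the monoisotopic mass of the neutral formula and
#' `mass_delta` carries the electron-mass correction for the charge state.
#'
#' @param f Molecular formula (object or string) of the neutral molecule M.
#' @param adduct Registered adduct name, e.g. `"[M-H]-"`, `"[M+NH4]+"`,
#'   `"13C[M-H]-"`, `"[2M-H]-"`.
#' @return Theoretical m/z in Da.
#' @examples
#' mz_for_adduct("C25H32O13", "[M-H]-")    # oleuropein, 539.1770
#' mz_for_adduct("C25H32O13", "[M+NH4]+")  # 558.2181
#' @export
mz_for_adduct <- function(f, adduct) {
  a <- get_adduct(adduct)
  if (a$charge == 0L) stop("adduct charge must be nonzero", call. = FALSE)
  M <- monoisotopic_mass(f)
  (a$multimer * M + a$isotope_shift * C13_MASS_SHIFT + a$mass_delta) /
    abs(a$charge)
}

# m/z for an arbitrary neutral mass under a registered adduct row; used by
# the role-inference machinery where no formula is known yet.
mz_for_neutral_mass <- function(M, adduct_row) {
  (adduct_row$multimer * M + adduct_row$isotope_shift * C13_MASS_SHIFT +
     adduct_row$mass_delta) / abs(adduct_row$charge)
}

# Invert: candidate neutral mass from an observed m/z under an adduct row.
neutral_mass_for_mz <- function(mz, adduct_row) {
  (mz * abs(adduct_row$charge) - adduct_row$isotope_shift * C13_MASS_SHIFT -
     adduct_row$mass_delta) / adduct_row$multimer
}

#' Parts-per-million mass error
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z; must be positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  1e6 * (observed - theoretical) / theoretical
}

# ---- Neutral losses --------------------------------------------------------

#' Registered neutral losses
#'
#' The closed table of neutral losses used for in-source-fragment matching
#' and for the diagnostic class rules: sugar residues (hexose, rhamnose),
#' small molecules (H2O, CO2, CH2O, CH3OH, CO, C2H4O2), the dehydrated
#' hydroxytyrosol moiety (136.0524 Da) and the caffeoyl group. Open-ended
#' loss search is deliberately not supported, to avoid inventing structure.
#'
#' @return A data frame with columns `name`, `formula` and `mass` (Da); the
#'   mass of each row equals the monoisotopic mass of its formula.
#' @export
neutral_losses <- function() {
  if (is.null(.olivemet_env$losses)) {
    losses <- data.frame(
      name = c("hexose", "rhamnose", "H2O", "CO2", "CH2O", "CH3OH", "CO",
               "C2H4O2", "hydroxytyrosol", "caffeoyl"),
      formula = c("C6H10O5", "C6H10O4", "H2O", "CO2", "CH2O", "CH4O", "CO",
                  "C2H4O2", "C8H8O2", "C9H6O3"),
      stringsAsFactors = FALSE
    )
    losses$mass <- vapply(losses$formula, monoisotopic_mass, numeric(1))
    .olivemet_env$losses <- losses
  }
  .olivemet_env$losses
}
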