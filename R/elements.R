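#' @importFrom utils read.csv write.csv head
#' @importFrom stats aggregate approx coef cor dist lm mad median optim
#'   predict quantile rnorm runif sd setNames var
NULL

.spectroml_env <- new.env(parent = emptyenv())

#' Element and isotope reference table
#'
#' Returns the vendored periodic-table data used throughout the package:
#' symbol, atomic number Z, IUPAC group (1-18; lanthanides and actinides are
#' assigned group 3), period (1-7), atomic mass (u), empirical atomic radius
#' (Angstrom, Slater), first ionization potential IP (eV), electron affinity
#' EA (eV, 0 where the anion is unbound), Pauling electronegativity chi
#' (NA for the lighter noble gases), and mass_number (set only for the
#' hydrogen isotopes D and T).
#'
#' @return A data.frame with one row per element/isotope symbol.
#' @export
element_table <- function() {
  if (is.null(.spectroml_env$elements)) {
    path <- system.file("extdata", "element_table.csv", package = "spectroml")
    if (path == "") {  # allow use from a source checkout (e.g. pkgload)
      path <- file.path("inst", "extdata", "element_table.csv")
    }
    tab <- read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(tab$group >= 1 & tab$group <= 18),
              all(tab$period >= 1 & tab$period <= 7),
              all(tab$mass > 0), all(tab$radius > 0))
    rownames(tab) <- tab$symbol
    .spectroml_env$elements <- tab
  }
  .spectroml_env$elements
}

#' Look up one element or isotope
#'
#' @param symbol Element symbol, case sensitive ("Na", "D", ...).
#' @return A one-row data.frame (an `ElementRecord`).
#' @export
element_record <- function(symbol) {
  tab <- element_table()
  if (!symbol %in% tab$symbol) {
    stop("unknown element symbol: '", symbol, "'", call. = FALSE)
  }
  tab[symbol, , drop = FALSE]
}

#' Number of valence electrons of an element
#'
#' Block-wise convention: s-block elements count their group number (He: 2),
#' p-block elements group - 10, d-block elements their group number, and
#' f-block elements (Z 58-71 and 90-103) count 3.  The convention is a
#' documented choice; empirical rules that use the valence-electron count
#' never defined it for the full table.
#'
#' @param element One-row element record (or several rows).
#' @return Integer vector of valence-electron counts.
#' @export
valence_electrons <- function(element) {
  z <- element$Z; g <- element$group
  n <- ifelse((z >= 58 & z <= 71) | (z >= 90 & z <= 103), 3L,
       ifelse(z == 2, 2L,
       ifelse(g >= 13, g - 10L, g)))
  as.integer(n)
}

#' Parse a diatomic formula into its two atoms
#'
#' Splits a concatenated two-symbol formula ("NaK", "DF", "HgH") into its
#' constituent element records.  Matching is case sensitive over the full
#' symbol table including the hydrogen isotopes D and T.  When more than one
#' split is valid, the split whose first token has two letters wins (greedy
#' longest match).  Homonuclear formulas are rejected; isotopes count as
#' distinct atoms (so "HD" is fine).
#'
#' @param formula Character scalar.
#' @return List with elements `atom1` and `atom2` (one-row element records),
#'   in written order.
#' @export
parse_diatomic_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  tab <- element_table()
  n <- nchar(formula)
  if (n < 2L) stop("cannot parse diatomic formula: '", formula, "'",
                   call. = FALSE)
  splits <- list()
  for (cut in seq_len(n - 1L)) {
    tok1 <- substr(formula, 1L, cut)
    tok2 <- substr(formula, cut + 1L, n)
    if (tok1 %in% tab$symbol && tok2 %in% tab$symbol) {
      splits[[length(splits) + 1L]] <- c(tok1, tok2)
    }
  }
  if (length(splits) == 0L) {
    # diagnose the offending token for the message
    first1 <- substr(formula, 1L, 1L)
    first2 <- substr(formula, 1L, 2L)
    bad <- if (first1 %in% tab$symbol || first2 %in% tab$symbol) {
      if (first2 %in% tab$symbol) substr(formula, 3L, n) else
        substr(formula, 2L, n)
    } else first1
    stop("cannot parse diatomic formula '", formula,
         "': unknown symbol '", bad, "'", call. = FALSE)
  }
  # prefer the split with the longer (two-letter) first token
  pick <- splits[[which.max(vapply(splits, function(s) nchar(s[1]), 0))]]
  if (pick[1] == pick[2]) {
    stop("homonuclear formula '", formula, "' is not supported", call. = FALSE)
  }
  list(atom1 = tab[pick[1], , drop = FALSE],
       atom2 = tab[pick[2], , drop = FALSE])
}

#' Reduced mass of a two-body system
#'
#' @param mass1,mass2 Masses in u (both > 0).
#' @return m1 * m2 / (m1 + m2), in u.
#' @export
reduced_mass <- function(mass1, mass2) {
  if (any(mass1 <= 0) || any(mass2 <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  mass1 * mass2 / (mass1 + mass2)
}

#' Dissociation energy from the potential minimum
#'
#' Converts the binding energy D_0 (measured from the vibrational ground
#' level) to the well depth D_e measured from the potential minimum:
#' D_e = D_0 + omega_e / 2 - omega_e x_e / 4, with the vibrational constants
#' converted from cm^-1 to eV internally.
#'
#' @param D0 Binding energy (eV), >= 0.
#' @param we Harmonic frequency (cm^-1), > 0 (0 allowed as a limit).
#' @param wexe First anharmonic correction (cm^-1); may be NA.
#' @param missing_wexe Either "error" (default) or "zero": how to treat a
#'   missing anharmonic correction.
#' @return D_e in eV.
#' @export
dissociation_energy <- function(D0, we, wexe = NA,
                                missing_wexe = c("error", "zero")) {
  missing_wexe <- match.arg(missing_wexe)
  if (any(D0 < 0, na.rm = TRUE)) stop("D0 must be >= 0", call. = FALSE)
  if (any(we < 0, na.rm = TRUE)) stop("we must be >= 0", call. = FALSE)
  if (anyNA(wexe)) {
    if (missing_wexe == "error") {
      stop("missing wexe; pass missing_wexe = \"zero\" to treat it as 0",
           call. = FALSE)
    }
    warning("missing wexe treated as 0")
    wexe[is.na(wexe)] <- 0
  }
  k <- spectro_constants$cm1_to_eV
  D0 + we * k / 2 - wexe * k / 4
}

#' Ratio of bond length to the sum of atomic radii
#'
#' Re / (R1 + R2) is a rough bond-type indicator: close to 1 for covalent
#' bonds, below for ionic-leaning, above for van der Waals pairs.
#'
#' @param Re Equilibrium distance (Angstrom).
#' @param radius1,radius2 Empirical atomic radii (Angstrom).
#' @return Dimensionless ratio.
#' @export
radius_ratio <- function(Re, radius1, radius2) {
  if (anyNA(radius1) || anyNA(radius2)) {
    stop("missing atomic radius", call. = FALSE)
  }
  Re / (radius1 + radius2)
}
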