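#' Build a spectroscopic constants dataset from a data.frame
#'
#' Parses the diatomic formulas, attaches per-atom periodic-table fields and
#' the reduced mass, and validates invariants (heteronuclear pairs, positive
#' Re and we, unique formulas).  The result is a data.frame of class
#' `"spectro_dataset"` with one row per molecule; ground-state constants live
#' in columns `Re`, `we`, `wexe`, `D0`, and the optional A-state constants in
#' `Re_A`, `we_A`.
#'
#' @param df A data.frame with columns `formula`, `Re`, `we`, and optionally
#'   `wexe`, `D0`, `Re_A`, `we_A`.
#' @param strict If TRUE a bad row is an error; otherwise bad rows are
#'   dropped and reported via a warning.
#' @return A `spectro_dataset`.
#' @export
spectro_dataset <- function(df, strict = FALSE) {
  required <- c("formula", "Re", "we")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("wexe", "D0", "Re_A", "we_A")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  n <- nrow(df)
  keep <- rep(TRUE, n)
  problems <- character(0)
  parsed <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch(parse_diatomic_formula(df$formula[i]),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      keep[i] <- FALSE
      problems <- c(problems, sprintf("row %d: %s", i, res))
    } else {
      parsed[[i]] <- res
    }
    if (keep[i] && (!is.finite(df$Re[i]) || df$Re[i] <= 0)) {
      keep[i] <- FALSE
      problems <- c(problems, sprintf("row %d: nonpositive or missing Re", i))
    }
    if (keep[i] && (!is.finite(df$we[i]) || df$we[i] <= 0)) {
      keep[i] <- FALSE
      problems <- c(problems, sprintf("row %d: nonpositive or missing we", i))
    }
  }
  if (length(problems)) {
    if (strict) stop(paste(problems, collapse = "\n"), call. = FALSE)
    warning(length(problems), " row(s) dropped:\n",
            paste(problems, collapse = "\n"))
  }
  df <- df[keep, , drop = FALSE]
  parsed <- parsed[keep]
  if (anyDuplicated(df$formula)) {
    stop("duplicate formulas in dataset: ",
         paste(unique(df$formula[duplicated(df$formula)]), collapse = ", "),
         call. = FALSE)
  }
  a1 <- do.call(rbind, lapply(parsed, `[[`, "atom1"))
  a2 <- do.call(rbind, lapply(parsed, `[[`, "atom2"))
  out <- data.frame(
    formula = df$formula,
    atom1 = a1$symbol, atom2 = a2$symbol,
    Z1 = a1$Z, Z2 = a2$Z,
    g1 = a1$group, g2 = a2$group,
    p1 = a1$period, p2 = a2$period,
    mass1 = a1$mass, mass2 = a2$mass,
    mn1 = ifelse(is.na(a1$mass_number), 1L, a1$mass_number),
    mn2 = ifelse(is.na(a2$mass_number), 1L, a2$mass_number),
    radius1 = a1$radius, radius2 = a2$radius,
    IP1 = a1$IP, IP2 = a2$IP,
    EA1 = a1$EA, EA2 = a2$EA,
    chi1 = a1$chi, chi2 = a2$chi,
    Re = df$Re, we = df$we, wexe = df$wexe, D0 = df$D0,
    Re_A = df$Re_A, we_A = df$we_A,
    stringsAsFactors = FALSE
  )
  out$m <- reduced_mass(out$mass1, out$mass2)
  rownames(out) <- out$formula
  class(out) <- c("spectro_dataset", "data.frame")
  out
}

#' Load a constants table from CSV
#'
#' Reads a CSV with header and columns `formula`, `Re`, `we` and optionally
#' `wexe`, `D0`, `Re_A`, `we_A` (rename foreign headers with `column_map`).
#' If a `state` column is present, rows are pivoted so that state-A constants
#' become the `Re_A`/`we_A` columns of the matching ground-state molecule.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping file columns to
#'   canonical names, e.g. `c(Re = "r_equil")`.
#' @param strict Passed to [spectro_dataset()].
#' @param D0_units Either "eV" (default) or "cm-1"; binding energies in
#'   cm^-1 are converted on load.
#' @return A `spectro_dataset`.
#' @export
load_dataset <- function(path, column_map = NULL, strict = FALSE,
                         D0_units = c("eV", "cm-1")) {
  D0_units <- match.arg(D0_units)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      from <- column_map[[canon]]
      if (!from %in% names(df)) {
        stop("column-map source '", from, "' not in file", call. = FALSE)
      }
      names(df)[names(df) == from] <- canon
    }
  }
  if ("state" %in% names(df)) {
    x_rows <- df[df$state %in% c("X", ""), , drop = FALSE]
    a_rows <- df[df$state == "A", , drop = FALSE]
    df <- x_rows[, setdiff(names(x_rows), "state"), drop = FALSE]
    if (nrow(a_rows)) {
      idx <- match(df$formula, a_rows$formula)
      df$Re_A <- a_rows$Re[idx]
      df$we_A <- a_rows$we[idx]
    }
  }
  if ("D0" %in% names(df) && D0_units == "cm-1") {
    df$D0 <- df$D0 * spectro_constants$cm1_to_eV
  }
  ds <- spectro_dataset(df, strict = strict)
  message(sprintf(
    "loaded %d molecules (%d with D0, %d with A-state constants)",
    nrow(ds), sum(!is.na(ds$D0)), sum(!is.na(ds$Re_A) & !is.na(ds$we_A))))
  ds
}

#' Echo a dataset with derived audit columns
#'
#' Writes the canonical CSV form of a dataset plus the derived quantities
#' (reduced mass, D_e where computable, and the bond-type radius ratio).
#'
#' @param ds A `spectro_dataset`.
#' @param path Output CSV path.
#' @return The augmented data.frame, invisibly.
#' @export
write_dataset <- function(ds, path) {
  out <- as.data.frame(ds)
  out$radius_ratio <- radius_ratio(out$Re, out$radius1, out$radius2)
  out$De <- ifelse(!is.na(out$D0) & !is.na(out$wexe),
                   dissociation_energy(ifelse(is.na(out$D0), 0, out$D0),
                                       out$we,
                                       ifelse(is.na(out$wexe), 0, out$wexe),
                                       missing_wexe = "zero"),
                   NA_real_)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Rows usable for a given learning target
#'
#' Returns the subset of the dataset whose rows carry every quantity the
#' target needs, together with the label vector:
#' \describe{
#'   \item{Re}{equilibrium distance of the ground state (Angstrom).}
#'   \item{we}{ground-state harmonic frequency (cm^-1); also needs Re.}
#'   \item{Dlabel}{binding-energy regression label (see
#'     [binding_label()]); needs D0, we, wexe, Re.}
#'   \item{Re_A}{A-state equilibrium distance; needs Re.}
#'   \item{we_A}{A-state harmonic frequency; needs we, Re, Re_A.}
#' }
#'
#' @param ds A `spectro_dataset`.
#' @param target One of "Re", "we", "Dlabel", "Re_A", "we_A".
#' @param binding_transform Transform name for the Dlabel target, passed to
#'   [binding_label()].
#' @return List with `data` (subset of ds) and `y` (numeric labels).
#' @export
dataset_view <- function(ds, target = c("Re", "we", "Dlabel", "Re_A", "we_A"),
                         binding_transform = "ln_ZZ_over_De") {
  target <- match.arg(target)
  ok <- switch(target,
    Re     = rep(TRUE, nrow(ds)),
    we     = !is.na(ds$we) & !is.na(ds$Re),
    Dlabel = !is.na(ds$D0) & !is.na(ds$we),
    Re_A   = !is.na(ds$Re_A),
    we_A   = !is.na(ds$we_A) & !is.na(ds$Re_A) & !is.na(ds$we)
  )
  sub <- ds[ok, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows usable for target ", target,
                            call. = FALSE)
  y <- switch(target,
    Re     = sub$Re,
    we     = sub$we,
    Dlabel = binding_label(sub, transform = binding_transform),
    Re_A   = sub$Re_A,
    we_A   = sub$we_A
  )
  list(data = sub, y = y, target = target)
}

#' @export
print.spectro_dataset <- function(x, ...) {
  cat(sprintf(
    "spectro_dataset: %d heteronuclear molecules (%d with D0, %d with A state)\n",
    nrow(x), sum(!is.na(x$D0)), sum(!is.na(x$Re_A))))
  print(utils::head(as.data.frame(x)[, c("formula", "Re", "we", "wexe",
                                         "D0", "Re_A", "we_A")]), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
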