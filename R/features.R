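FEATURE_TOKENS <- c("g1", "g2", "p1", "p2", "g1_iso", "g2_iso",
                    "g_bar", "p_bar", "inv_Re_X", "inv_Re_A", "we_X",
                    "Re_X", "Re", "D_ip_ea", "inv_Re_pred", "Re_pred",
                    "log_ZZ", "inv_Re2", "parr_freq")

# swap images of atom-indexed tokens; symmetric tokens map to themselves
.SWAP_MAP <- c(g1 = "g2", g2 = "g1", p1 = "p2", p2 = "p1",
               g1_iso = "g2_iso", g2_iso = "g1_iso")

#' Define a feature recipe
#'
#' A feature spec names the ordered list of descriptor tokens that map a
#' molecule to a numeric vector.  Atom-indexed tokens (`g1`, `p2`,
#' `g1_iso`, ...) follow the written atom order; symmetric tokens (`g_bar`,
#' `p_bar`, `inv_Re_X`, `D_ip_ea`, ...) are invariant under atom exchange.
#' `inv_Re_pred` is the inverse of a GP-predicted equilibrium distance and is
#' filled in per training split by the evaluation machinery.
#'
#' @param components Character vector of tokens, a subset of
#'   `spectroml:::FEATURE_TOKENS`.
#' @param target Label the recipe is meant for ("Re", "we", "Dlabel",
#'   "Re_A", "we_A").
#' @param name Recipe name used in reports.
#' @param augment If TRUE the training matrix is permutation-augmented
#'   (atom-swap images appended) before fitting.
#' @param delta_iso Offset added to the group per extra neutron for hydrogen
#'   isotopes (H -> 1.0, D -> 1.1, T -> 1.2 at the default 0.1).
#' @param gbar_from_iso If TRUE, `g_bar` averages the isotope-encoded groups
#'   instead of the plain groups.
#' @param d_ip_ea_form Variant of the electron-transfer descriptor, see
#'   [d_ip_ea()].
#' @return An object of class `"feature_spec"`.
#' @export
feature_spec <- function(components, target, name = NULL, augment = TRUE,
                         delta_iso = 0.1, gbar_from_iso = FALSE,
                         d_ip_ea_form = c("ip_minus_ea", "chi_weighted")) {
  d_ip_ea_form <- match.arg(d_ip_ea_form)
  bad <- setdiff(components, FEATURE_TOKENS)
  if (length(bad)) stop("unknown feature token(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(name)) name <- paste(components, collapse = "+")
  structure(list(name = name, components = components, target = target,
                 augment = augment, delta_iso = delta_iso,
                 gbar_from_iso = gbar_from_iso,
                 d_ip_ea_form = d_ip_ea_form),
            class = "feature_spec")
}

#' Isotope-aware group number
#'
#' Returns the IUPAC group for every element except the hydrogen isotopes,
#' which are offset by `delta` per extra neutron so that H, D and T are
#' distinguishable while staying adjacent in feature space.
#'
#' @param Z Atomic number vector.
#' @param group Group vector.
#' @param mass_number Mass-number vector (1 for elements without an explicit
#'   isotope label).
#' @param delta Offset per extra neutron (default 0.1).
#' @return Numeric vector.
#' @export
g_iso <- function(Z, group, mass_number, delta = 0.1) {
  ifelse(Z == 1, group + delta * (mass_number - 1), group)
}

#' Electron-transfer descriptor D(IP, EA)
#'
#' Qualitatively measures the cost of transferring an electron toward the
#' more electronegative atom of the pair.  The default form is
#' IP(donor) - EA(acceptor), with the acceptor chosen as the atom of higher
#' Pauling electronegativity; when the electronegativities tie, the two
#' directions are averaged so the descriptor stays symmetric under atom
#' exchange.  The `chi_weighted` variant is
#' |chi1 - chi2| * (mean IP - mean EA).
#'
#' @param IP1,EA1,chi1 Donor/acceptor candidate 1 properties (eV, eV,
#'   Pauling).
#' @param IP2,EA2,chi2 Properties of atom 2.
#' @param form "ip_minus_ea" (default) or "chi_weighted".
#' @return Numeric vector (eV).
#' @export
d_ip_ea <- function(IP1, EA1, chi1, IP2, EA2, chi2,
                    form = c("ip_minus_ea", "chi_weighted")) {
  form <- match.arg(form)
  if (anyNA(c(IP1, EA1, chi1, IP2, EA2, chi2))) {
    stop("missing IP, EA or electronegativity for d_ip_ea", call. = FALSE)
  }
  switch(form,
    ip_minus_ea = ifelse(chi2 > chi1, IP1 - EA2,
                  ifelse(chi1 > chi2, IP2 - EA1,
                         ((IP1 - EA2) + (IP2 - EA1)) / 2)),
    chi_weighted = abs(chi1 - chi2) * ((IP1 + IP2) / 2 - (EA1 + EA2) / 2)
  )
}

# exchange all atom-indexed columns of a dataset (atom1 <-> atom2)
swap_atoms <- function(data) {
  pairs <- list(c("atom1", "atom2"), c("Z1", "Z2"), c("g1", "g2"),
                c("p1", "p2"), c("mass1", "mass2"), c("mn1", "mn2"),
                c("radius1", "radius2"), c("IP1", "IP2"), c("EA1", "EA2"),
                c("chi1", "chi2"))
  out <- data
  for (pr in pairs) {
    out[[pr[1]]] <- data[[pr[2]]]
    out[[pr[2]]] <- data[[pr[1]]]
  }
  out
}

# one feature column for a token; re_pred holds predicted Re where needed
token_column <- function(data, token, spec, re_pred = NULL) {
  giso1 <- g_iso(data$Z1, data$g1, data$mn1, spec$delta_iso)
  giso2 <- g_iso(data$Z2, data$g2, data$mn2, spec$delta_iso)
  G1 <- if (spec$gbar_from_iso) giso1 else data$g1
  G2 <- if (spec$gbar_from_iso) giso2 else data$g2
  switch(token,
    g1 = data$g1, g2 = data$g2, p1 = data$p1, p2 = data$p2,
    g1_iso = giso1, g2_iso = giso2,
    g_bar = (G1 + G2) / 2,
    p_bar = (data$p1 + data$p2) / 2,
    inv_Re_X = 1 / data$Re,
    inv_Re_A = 1 / data$Re_A,
    we_X = data$we,
    Re_X = data$Re,
    Re = data$Re,
    D_ip_ea = d_ip_ea(data$IP1, data$EA1, data$chi1,
                      data$IP2, data$EA2, data$chi2,
                      form = spec$d_ip_ea_form),
    inv_Re_pred = {
      if (is.null(re_pred)) stop("feature token inv_Re_pred needs a fitted ",
                                 "Re model (re_pred)", call. = FALSE)
      1 / pmax(re_pred, 0.5)
    },
    Re_pred = {
      if (is.null(re_pred)) stop("feature token Re_pred needs a fitted ",
                                 "Re model (re_pred)", call. = FALSE)
      pmax(re_pred, 0.5)
    },
    log_ZZ = log(data$Z1 * data$Z2),
    inv_Re2 = data$Re^-2,
    parr_freq = sqrt(data$Z1 * data$Z2 * exp(-2 * 0.97 * data$Re) / data$m),
    stop("unknown token ", token, call. = FALSE)
  )
}

#' Assemble a feature matrix
#'
#' Maps every row of a dataset through a feature spec, column per token.
#' Rows producing any non-finite feature are an error (the dataset views are
#' expected to have filtered unusable rows already).
#'
#' @param data A `spectro_dataset` (or a view's `data` component).
#' @param spec A [feature_spec()].
#' @param y Optional label vector aligned with `data` (stored alongside X).
#' @param re_pred Optional vector of predicted equilibrium distances for the
#'   `inv_Re_pred` token (clipped below at 0.5 Angstrom).
#' @return A list of class `"feature_matrix"` with `X` (numeric matrix),
#'   `y`, and `row_ids` (formulas; duplicated ids mark augmented rows).
#' @export
build_features <- function(data, spec, y = NULL, re_pred = NULL) {
  if (nrow(data) == 0L) stop("empty dataset for featurization", call. = FALSE)
  cols <- lapply(spec$components, function(tok)
    token_column(data, tok, spec, re_pred))
  X <- do.call(cbind, cols)
  colnames(X) <- spec$components
  rownames(X) <- data$formula
  if (!all(is.finite(X))) {
    bad <- which(!apply(is.finite(X), 1, all))
    stop("non-finite features for: ",
         paste(data$formula[utils::head(bad, 5)], collapse = ", "),
         call. = FALSE)
  }
  structure(list(X = X, y = y, row_ids = data$formula, spec = spec),
            class = "feature_matrix")
}

#' Append atom-swap images to a feature matrix
#'
#' Doubles the matrix: the new rows are the features of the same molecules
#' with the two atoms exchanged.  Because every token has a well-defined
#' swap image (atom-indexed tokens exchange with their partner, symmetric
#' tokens map to themselves), the swap rows are an exact column permutation
#' of the originals; labels and row ids are copied.  Used on training data
#' so the fitted model respects the permutational invariance of the
#' molecule's properties.
#'
#' @param fm A `feature_matrix` from [build_features()].
#' @return A `feature_matrix` with twice the rows; `row_ids` duplicated.
#' @export
permutation_augment <- function(fm) {
  comp <- fm$spec$components
  partner <- ifelse(comp %in% names(.SWAP_MAP), .SWAP_MAP[comp], comp)
  missing_p <- setdiff(partner, comp)
  if (length(missing_p)) {
    stop("swap image undefined: spec lacks partner token(s) ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  Xsw <- fm$X[, match(partner, comp), drop = FALSE]
  colnames(Xsw) <- comp
  structure(list(X = rbind(fm$X, Xsw),
                 y = c(fm$y, fm$y),
                 row_ids = c(fm$row_ids, fm$row_ids),
                 spec = fm$spec),
            class = "feature_matrix")
}

#' Predicted equilibrium distances as a feature input
#'
#' Fits a GP for the ground-state equilibrium distance on the training rows
#' using the plain group/period features (g1, g2, p1, p2) and returns its
#' prediction for an arbitrary set of rows.  Predictions are clipped below
#' at 0.5 Angstrom so the downstream inverse-distance feature stays finite
#' and positive.
#'
#' @param train_data Training rows (a `spectro_dataset` subset) with `Re`.
#' @param newdata Rows to predict for.
#' @param model_spec GP model settings, see [gp_model_spec()]; defaults to
#'   the exponential kernel with a linear basis.
#' @param seed Seed for the hyperparameter restarts.
#' @return Numeric vector of predicted Re (Angstrom), >= 0.5.
#' @export
predicted_Re_feature <- function(train_data, newdata,
                                 model_spec = gp_model_spec(
                                   kernel = "exponential", basis = "linear"),
                                 seed = 1L) {
  spec <- feature_spec(c("g1", "g2", "p1", "p2"), target = "Re",
                       name = "re_aux", augment = TRUE)
  fm <- build_features(train_data, spec, y = train_data$Re)
  fm_aug <- permutation_augment(fm)
  fit <- fit_gp(fm_aug$X, fm_aug$y, kernel = model_spec$kernel,
                basis = model_spec$basis,
                n_restarts = model_spec$n_restarts, seed = seed)
  pred <- predict(fit, build_features(newdata, spec)$X)
  pmax(pred$mean, 0.5)
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("feature_spec '%s' -> %s: (%s)%s\n", x$name, x$target,
              paste(x$components, collapse = ", "),
              if (x$augment) " [augmented]" else ""))
  invisible(x)
}
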