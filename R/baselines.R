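#' Define an empirical bond-length/frequency rule
#'
#' The historical rules assert that some power combination
#' v = Re^a * we^b * m^(use_mass) * n^(n_power) is constant across
#' molecules, with m the reduced mass and n the valence-electron count of
#' the pair (product of the two atoms' counts).
#'
#' @param a Exponent of Re.
#' @param b Exponent of we.
#' @param use_mass Multiply by the reduced mass m (TRUE/FALSE).
#' @param n_power Exponent on the valence-electron count (0 to omit).
#' @param name Rule name for reports.
#' @return A list of class `"rule_spec"`.
#' @export
rule_spec <- function(a, b, use_mass = FALSE, n_power = 0, name = NULL) {
  if (a == 0 && b == 0) stop("degenerate rule: a = b = 0", call. = FALSE)
  if (is.null(name)) {
    name <- sprintf("Re^%g we^%g%s%s", a, b,
                    if (use_mass) " m" else "",
                    if (n_power != 0) sprintf(" n^%g", n_power) else "")
  }
  structure(list(a = a, b = b, use_mass = use_mass, n_power = n_power,
                 name = name), class = "rule_spec")
}

#' Shipped rule presets
#'
#' The historical constancy rules: `kratzer` (Re^2 we^2 m, the hydrogen
#' halide relation), `mecke` (Re^2 we), `morse` (Re^3 we), `badger3`
#' (Re^3 we^2 m, the Badger-precursor form with i = 3), and `valence`
#' (m Re^6 we^2 n, with the rational exponent on n defaulting to 1).
#'
#' @return Named list of [rule_spec()] objects.
#' @export
rule_presets <- function() {
  list(
    kratzer = rule_spec(2, 2, use_mass = TRUE, name = "kratzer"),
    mecke   = rule_spec(2, 1, name = "mecke"),
    morse   = rule_spec(3, 1, name = "morse"),
    badger3 = rule_spec(3, 2, use_mass = TRUE, name = "badger3"),
    valence = rule_spec(6, 2, use_mass = TRUE, n_power = 1, name = "valence")
  )
}

#' Evaluate a constancy rule over a dataset
#'
#' Computes v_i = Re^a we^b m^(use_mass) n^(n_power) per molecule,
#' normalizes by the dataset median, and summarizes the spread.  A rule
#' that truly holds gives a coefficient of variation near zero.
#'
#' @param ds A `spectro_dataset`.
#' @param rule A [rule_spec()] or a preset name from [rule_presets()].
#' @return List with `values` (median-normalized, named by formula) and
#'   `summary` (median, quartiles, min, max, cv).
#' @export
rule_statistic <- function(ds, rule) {
  if (is.character(rule)) rule <- rule_presets()[[rule]]
  stopifnot(inherits(rule, "rule_spec"))
  tab <- element_table()
  n1 <- valence_electrons(tab[ds$atom1, ])
  n2 <- valence_electrons(tab[ds$atom2, ])
  v <- ds$Re^rule$a * ds$we^rule$b
  if (rule$use_mass) v <- v * ds$m
  if (rule$n_power != 0) {
    nn <- as.numeric(n1 * n2)
    if (any(nn <= 0) && rule$n_power != round(rule$n_power)) {
      stop("nonpositive valence count with fractional exponent",
           call. = FALSE)
    }
    v <- v * nn^rule$n_power
  }
  med <- median(v)
  vals <- v / med
  names(vals) <- ds$formula
  qs <- quantile(vals, c(0.25, 0.5, 0.75))
  list(values = vals,
       summary = c(median = unname(qs[2]), q1 = unname(qs[1]),
                   q3 = unname(qs[3]), min = min(vals), max = max(vals),
                   cv = sd(vals) / mean(vals)),
       rule = rule$name)
}

#' Binding-energy regression label
#'
#' Builds the label used when regressing the binding energy.  All variants
#' start from D_e = D_0 + we/2 - wexe/4 (a missing wexe is treated as 0):
#' \describe{
#'   \item{ln_ZZ_over_De}{log(Z1 Z2 / D_e) (default; linear in Re under the
#'     electron-density model).}
#'   \item{identity_De}{D_e itself (eV).}
#'   \item{sqrt_De}{sqrt(D_e).}
#' }
#'
#' @param ds A `spectro_dataset` (rows must have D0 and we).
#' @param transform Variant name.
#' @return Numeric label vector.
#' @export
binding_label <- function(ds, transform = c("ln_ZZ_over_De", "identity_De",
                                            "sqrt_De")) {
  transform <- match.arg(transform)
  wexe <- ifelse(is.na(ds$wexe), 0, ds$wexe)
  De <- dissociation_energy(ds$D0, ds$we, wexe, missing_wexe = "zero")
  if (any(De <= 0)) {
    stop("nonpositive D_e for: ",
         paste(ds$formula[De <= 0], collapse = ", "), call. = FALSE)
  }
  switch(transform,
    ln_ZZ_over_De = log(ds$Z1 * ds$Z2 / De),
    identity_De = De,
    sqrt_De = sqrt(De))
}

#' Harmonic frequency from the electron-density model
#'
#' The density-overlap model gives m we^2 = 4 pi C Z1 Z2 exp(-2 xi Re); the
#' right-hand side is treated as a force constant in eV/Angstrom^2 and
#' converted to a wavenumber via the fixed factor in [spectro_constants]
#' (inputs: Re in Angstrom, m in u; output cm^-1).
#'
#' @param Z1Z2 Product of atomic numbers.
#' @param Re Equilibrium distance (Angstrom).
#' @param m Reduced mass (u).
#' @param C Density prefactor (> 0, eV/Angstrom^2 scale).
#' @param xi Density decay constant (> 0, 1/Angstrom).
#' @return we in cm^-1.
#' @export
parr_frequency <- function(Z1Z2, Re, m, C, xi) {
  if (any(c(Z1Z2, Re, m, C, xi) <= 0)) {
    stop("parr_frequency needs positive arguments", call. = FALSE)
  }
  k_eff <- 4 * pi * C * Z1Z2 * exp(-2 * xi * Re)   # eV / A^2
  spectro_constants$wavenumber_factor * sqrt(k_eff / m)
}

#' Linear-baseline recipes
#'
#' Predictor/target pairs for the physics-based linear models:
#' \describe{
#'   \item{logZZ}{Re ~ log(Z1 Z2); the slope and intercept invert to the
#'     electron-density parameters xi = 1/slope and
#'     A = exp(-intercept * xi).}
#'   \item{parr_freq}{we ~ sqrt(Z1 Z2 exp(-2*0.97*Re) / m), the transformed
#'     frequency form of the density model.}
#'   \item{inv_Re2}{we ~ Re^-2.}
#'   \item{re_to_binding}{binding label ~ Re.}
#' }
#' @return Named list of recipes (feature spec + target).
#' @export
baseline_recipes <- function() {
  list(
    logZZ = list(feature = feature_spec("log_ZZ", target = "Re",
                                        name = "LR log(Z1Z2)",
                                        augment = FALSE)),
    parr_freq = list(feature = feature_spec("parr_freq", target = "we",
                                            name = "LR parr-freq",
                                            augment = FALSE)),
    inv_Re2 = list(feature = feature_spec("inv_Re2", target = "we",
                                          name = "LR Re^-2",
                                          augment = FALSE)),
    re_to_binding = list(feature = feature_spec("Re", target = "Dlabel",
                                                name = "LR Re",
                                                augment = FALSE))
  )
}

#' Fit and evaluate a physics-based linear baseline
#'
#' Ordinary least squares on the recipe's predictor, evaluated under the
#' same stratified Monte-Carlo protocol as the GP models (identical plan and
#' seed give identical splits, enabling paired comparison).  For the
#' `logZZ` recipe the full-data fit is also inverted to the
#' electron-density parameters xi-hat and A-hat.
#'
#' @param ds A `spectro_dataset`.
#' @param recipe Recipe name from [baseline_recipes()] or such a list.
#' @param plan A [split_plan()].
#' @param binding_transform Transform for the `Dlabel` target.
#' @return List with `report` (an `eval_report`), `fit` (full-data lm) and,
#'   for logZZ, `xi_hat` and `A_hat`.
#' @export
fit_linear_baseline <- function(ds, recipe = "logZZ", plan = split_plan(),
                                binding_transform = "ln_ZZ_over_De") {
  if (is.character(recipe)) recipe <- baseline_recipes()[[recipe]]
  feature <- recipe$feature
  report <- mc_evaluate(ds, feature, lr_model_spec(), plan,
                        binding_transform = binding_transform)
  view <- dataset_view(ds, feature$target,
                       binding_transform = binding_transform)
  X <- build_features(view$data, feature)$X
  fit <- lm(view$y ~ X)
  out <- list(report = report, fit = fit,
              coef = setNames(coef(fit), c("intercept", feature$components)))
  if (identical(feature$components, "log_ZZ")) {
    slope <- coef(fit)[2]; intercept <- coef(fit)[1]
    out$xi_hat <- unname(1 / slope)
    out$A_hat <- unname(exp(-intercept * out$xi_hat))
  }
  out
}
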