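.default_pool <- c(
  "H", "D", "Li", "Be", "B", "C", "N", "O", "F", "Na", "Mg", "Al", "Si",
  "P", "S", "Cl", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co",
  "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Ag", "Cd", "In", "Sn", "Sb", "Te", "I", "Cs", "Ba", "La",
  "Hf", "W", "Pt", "Au", "Hg", "Tl", "Pb", "Bi")

#' Synthetic-dataset configuration
#'
#' Study conditions for the pseudo-molecule generator.  Truth models:
#' \describe{
#'   \item{smooth_gp_surface}{Re drawn from a GP over (g-bar, p-bar) with
#'     sigma_f = 0.4 Angstrom, l = 3.0 and mean 0.55 p-bar + 0.9, clipped to
#'     [0.8, 4.5]; we follows the Badger-form link modulated by a mild
#'     smooth factor so no power rule is exactly constant.}
#'   \item{parr_exact}{Re solves Z1 Z2 = A exp(xi Re) exactly
#'     (defaults xi = 2.0, A = 10); we from the density model
#'     [parr_frequency()].}
#'   \item{badger_exact}{Re as in smooth_gp_surface, we = c / (Re^1.5
#'     sqrt(m)) exactly, so Re^3 we^2 m is constant.}
#' }
#' The binding truth is D_e = A_D m we^2 Re^3 in all models, inverted to
#' D_0 through D_e = D_0 + we/2 - wexe/4 with wexe = 0.01 we.
#'
#' @param n_molecules Number of unique heteronuclear pairs (>= 30).
#' @param noise_Re Additive Gaussian noise sd on Re (Angstrom).
#' @param noise_we Relative Gaussian noise sd on we (and on D_0).
#' @param seed Integer seed; generation is fully deterministic.
#' @param truth Truth model name.
#' @param pool Character vector of element symbols to draw pairs from.
#' @param a_state Fraction of molecules that also receive A-state labels
#'   (0 disables).
#' @param d0_frac Fraction of molecules that keep their D_0 value.
#' @param xi,A Parameters of the parr_exact truth model.
#' @param C Density prefactor for parr_exact frequencies.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_molecules = 250L, noise_Re = 0.05,
                         noise_we = 0.02, seed = 1L,
                         truth = c("smooth_gp_surface", "parr_exact",
                                   "badger_exact"),
                         pool = .default_pool, a_state = 0,
                         d0_frac = 1, xi = 2.0, A = 10, C = 120) {
  truth <- match.arg(truth)
  stopifnot(n_molecules >= 30L, noise_Re >= 0, noise_we >= 0,
            a_state >= 0, a_state <= 1, d0_frac >= 0, d0_frac <= 1)
  tab <- element_table()
  pool <- intersect(pool, tab$symbol)
  if (length(pool) < 10L || length(unique(tab[pool, "period"])) < 3L) {
    stop("element pool must have >= 10 elements spanning >= 3 periods",
         call. = FALSE)
  }
  structure(list(n_molecules = as.integer(n_molecules), noise_Re = noise_Re,
                 noise_we = noise_we, seed = as.integer(seed), truth = truth,
                 pool = pool, a_state = a_state, d0_frac = d0_frac,
                 xi = xi, A = A, C = C),
            class = "synth_config")
}

# draw a GP surface value per unique (gb, pb) cell
.gp_surface <- function(gb, pb, sigma_f = 0.4, l = 3.0) {
  pts <- unique(cbind(gb, pb))
  D <- as.matrix(dist(pts))
  K <- kernel_eval(D, "matern52", sigma_f, l)
  diag(K) <- sigma_f^2 + 1e-10
  L <- t(chol(K))
  z <- drop(L %*% rnorm(nrow(pts)))
  z[match(paste(gb, pb), paste(pts[, 1], pts[, 2]))]
}

#' Generate a synthetic spectroscopic dataset
#'
#' Samples unique heteronuclear element pairs, builds noiseless constants
#' from the configured truth model, adds independent Gaussian noise, and
#' returns a `spectro_dataset` carrying the noiseless truth as the
#' `"truth"` attribute (a sidecar data.frame) and the generator settings as
#' `"config"`.
#'
#' @param config A [synth_config()].
#' @param out_dir Optional directory: writes `data.csv`, `truth.csv` and
#'   `generator.json` there.
#' @return A `spectro_dataset`.
#' @export
generate_dataset <- function(config = synth_config(), out_dir = NULL) {
  tab <- element_table()
  pool <- tab[config$pool, ]
  np <- nrow(pool)
  n_pairs <- np * (np - 1) / 2
  if (n_pairs < config$n_molecules) {
    stop("pool of ", np, " elements yields only ", n_pairs,
         " unique pairs; need ", config$n_molecules, call. = FALSE)
  }
  dat <- with_seed(config$seed, {
    combos <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
    if (config$truth == "parr_exact") {
      # keep only pairs whose exact log-linear solution gives a physical
      # bond length (>= 0.4 Angstrom), so the generating relation holds
      # without clipping
      zz <- pool$Z[combos[, 1]] * pool$Z[combos[, 2]]
      ok <- (log(zz) - log(config$A)) / config$xi >= 0.4
      combos <- combos[ok, , drop = FALSE]
      if (nrow(combos) < config$n_molecules) {
        stop("pool yields only ", nrow(combos),
             " pairs compatible with the parr_exact truth; need ",
             config$n_molecules, call. = FALSE)
      }
    }
    pick <- combos[sample.int(nrow(combos), config$n_molecules), ,
                   drop = FALSE]
    flip <- runif(config$n_molecules) < 0.5      # written atom order
    i1 <- ifelse(flip, pick[, 2], pick[, 1])
    i2 <- ifelse(flip, pick[, 1], pick[, 2])
    a1 <- pool[i1, ]; a2 <- pool[i2, ]
    m <- reduced_mass(a1$mass, a2$mass)
    gb <- (a1$group + a2$group) / 2
    pb <- (a1$period + a2$period) / 2
    ZZ <- a1$Z * a2$Z

    Re_t <- switch(config$truth,
      parr_exact = (log(ZZ) - log(config$A)) / config$xi,
      {   # smooth_gp_surface and badger_exact share the Re surface
        mu <- 0.55 * pb + 0.9
        pmin(pmax(mu + .gp_surface(gb, pb), 0.8), 4.5)
      })

    cw <- 6000   # Angstrom^1.5 sqrt(u) cm^-1: sets the frequency scale
    we_t <- switch(config$truth,
      parr_exact = parr_frequency(ZZ, Re_t, m, config$C, config$xi),
      badger_exact = cw / (Re_t^1.5 * sqrt(m)),
      smooth_gp_surface = cw / (Re_t^1.5 * sqrt(m)) *
        (1 + 0.1 * sin(gb / 3) * cos(pb / 2)))

    wexe_t <- 0.01 * we_t
    A_D <- 1.5e-7     # eV / (u cm^-2 Angstrom^3): binding-energy scale
    De_t <- A_D * m * we_t^2 * Re_t^3
    k <- spectro_constants$cm1_to_eV
    D0_t <- pmax(De_t - we_t * k / 2 + wexe_t * k / 4, 0.05)

    Re <- Re_t + rnorm(config$n_molecules, 0, config$noise_Re)
    Re <- pmax(Re, 0.3)
    we <- we_t * (1 + rnorm(config$n_molecules, 0, config$noise_we))
    we <- pmax(we, 10)
    D0 <- D0_t * (1 + rnorm(config$n_molecules, 0, config$noise_we))
    D0 <- pmax(D0, 0.01)
    keep_d0 <- runif(config$n_molecules) <= config$d0_frac
    D0[!keep_d0] <- NA_real_

    Re_A_t <- we_A_t <- Re_A <- we_A <- rep(NA_real_, config$n_molecules)
    if (config$a_state > 0) {
      has_a <- runif(config$n_molecules) <= config$a_state
      # excited state: longer bond, softer curvature, smooth in (gb, pb)
      Re_A_t[has_a] <- Re_t[has_a] + 0.15 + 0.03 * (pb[has_a] - 3)
      we_A_t[has_a] <- 0.85 * we_t[has_a] *
        (Re_t[has_a] / Re_A_t[has_a])^1.5
      Re_A[has_a] <- pmax(Re_A_t[has_a] +
                            rnorm(sum(has_a), 0, config$noise_Re), 0.3)
      we_A[has_a] <- pmax(we_A_t[has_a] *
                            (1 + rnorm(sum(has_a), 0, config$noise_we)), 10)
    }
    data.frame(formula = paste0(a1$symbol, a2$symbol),
               Re = Re, we = we, wexe = wexe_t, D0 = D0,
               Re_A = Re_A, we_A = we_A,
               Re_true = Re_t, we_true = we_t, D0_true = D0_t,
               De_true = De_t, Re_A_true = Re_A_t, we_A_true = we_A_t,
               stringsAsFactors = FALSE)
  })
  ds <- spectro_dataset(dat[, c("formula", "Re", "we", "wexe", "D0",
                                "Re_A", "we_A")])
  truth <- dat[, c("formula", "Re_true", "we_true", "D0_true", "De_true",
                   "Re_A_true", "we_A_true")]
  attr(ds, "truth") <- truth
  attr(ds, "config") <- config
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(dat[, c("formula", "Re", "we", "wexe", "D0", "Re_A", "we_A")],
              file.path(out_dir, "data.csv"), row.names = FALSE)
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                digits = NA),
               file.path(out_dir, "generator.json"))
  }
  ds
}

#' Write a ready-made synthetic fixture
#'
#' `tiny` is a 40-molecule set with full D_0 and A-state coverage for fast
#' unit tests; `standard` is a 250-molecule set with 75% D_0 and 50%
#' A-state coverage, mirroring the coverage proportions of experimental
#' constants tables.
#'
#' @param kind "tiny" or "standard".
#' @param seed Generator seed.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written file paths, invisibly; the
#'   dataset itself as the return value's `"dataset"` attribute.
#' @export
make_fixture <- function(kind = c("tiny", "standard"), seed = 11L,
                         dir = tempfile("fixture")) {
  kind <- match.arg(kind)
  config <- switch(kind,
    tiny = synth_config(n_molecules = 40L, seed = seed, a_state = 1,
                        d0_frac = 1),
    standard = synth_config(n_molecules = 250L, seed = seed, a_state = 0.5,
                            d0_frac = 0.75))
  ds <- generate_dataset(config, out_dir = dir)
  paths <- file.path(dir, c("data.csv", "truth.csv", "generator.json"))
  attr(paths, "dataset") <- ds
  invisible(paths)
}
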