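#' Named feature/model presets for the experiment grids
#'
#' Every row of the ground-state grid (`table1`) and the A-state grid
#' (`table2`): target, regression model (GPR or LR) and feature recipe.
#' GPR rows use the exponential kernel with a linear basis for equilibrium
#' distances and the Matern-5/2 kernel with a constant basis for
#' frequencies and the binding label.
#'
#' @param name "table1" or "table2".
#' @return Named list of grid rows, each `list(name, feature, model)`.
#' @export
experiment_grid <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  gp_re <- gp_model_spec("exponential", "linear")
  gp_cn <- gp_model_spec("matern52", "constant")
  lr <- lr_model_spec()
  fs <- function(comp, target, aug = TRUE, iso = FALSE)
    feature_spec(comp, target = target, augment = aug, gbar_from_iso = FALSE)
  if (name == "table1") {
    rows <- list(
      Re_gp_gp12     = list(feature = fs(c("g1", "g2", "p1", "p2"), "Re"),
                            model = gp_re),
      Re_lr_logZZ    = list(feature = fs("log_ZZ", "Re", aug = FALSE),
                            model = lr),
      we_gp_true     = list(feature = fs(c("inv_Re_X", "g1", "g2", "p1",
                                           "p2"), "we"), model = gp_cn),
      we_gp_pred     = list(feature = fs(c("inv_Re_pred", "g1", "g2", "p1",
                                           "p2"), "we"), model = gp_cn),
      we_gp_iso_true = list(feature = fs(c("inv_Re_X", "g1_iso", "g2_iso",
                                           "p1", "p2"), "we"), model = gp_cn),
      we_gp_iso_pred = list(feature = fs(c("inv_Re_pred", "g1_iso", "g2_iso",
                                           "p1", "p2"), "we"), model = gp_cn),
      we_gp_pbar_true = list(feature = fs(c("inv_Re_X", "g1_iso", "g2_iso",
                                            "p1", "p2", "p_bar"), "we"),
                             model = gp_cn),
      we_gp_pbar_pred = list(feature = fs(c("inv_Re_pred", "g1_iso",
                                            "g2_iso", "p1", "p2", "p_bar"),
                                          "we"), model = gp_cn),
      we_gp_gbar_true = list(feature = fs(c("inv_Re_X", "g1_iso", "g2_iso",
                                            "p1", "p2", "g_bar"), "we"),
                             model = gp_cn),
      we_gp_gbar_pred = list(feature = fs(c("inv_Re_pred", "g1_iso",
                                            "g2_iso", "p1", "p2", "g_bar"),
                                          "we"), model = gp_cn),
      we_lr_parr     = list(feature = fs("parr_freq", "we", aug = FALSE),
                            model = lr),
      we_lr_invRe2   = list(feature = fs("inv_Re2", "we", aug = FALSE),
                            model = lr),
      D_gp_true      = list(feature = fs(c("Re", "g_bar", "p_bar"),
                                         "Dlabel"), model = gp_cn),
      D_gp_pred      = list(feature = fs(c("Re_pred", "g_bar", "p_bar"),
                                         "Dlabel"), model = gp_cn),
      D_lr_Re        = list(feature = fs("Re", "Dlabel", aug = FALSE),
                            model = lr)
    )
  } else {
    rows <- list(
      ReA_gp         = list(feature = fs(c("Re_X", "g1", "g2", "p1", "p2"),
                                         "Re_A"), model = gp_re),
      ReA_gp_dipea   = list(feature = fs(c("Re_X", "g1", "g2", "p1", "p2",
                                           "D_ip_ea"), "Re_A"),
                            model = gp_re),
      weA_gp_gbar    = list(feature = fs(c("we_X", "inv_Re_X", "inv_Re_A",
                                           "g1_iso", "g2_iso", "p1", "p2",
                                           "g_bar"), "we_A"), model = gp_cn),
      weA_gp_iso     = list(feature = fs(c("we_X", "inv_Re_X", "inv_Re_A",
                                           "g1_iso", "g2_iso", "p1", "p2"),
                                         "we_A"), model = gp_cn),
      weA_gp_plain   = list(feature = fs(c("we_X", "inv_Re_X", "inv_Re_A",
                                           "g1", "g2", "p1", "p2"), "we_A"),
                            model = gp_cn)
    )
  }
  for (nm in names(rows)) rows[[nm]]$name <- nm
  rows
}

# tiny polynomial rolling hash for provenance stamps (no external digest
# dependency; collision resistance is irrelevant here)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "|"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run an experiment grid end to end
#'
#' Evaluates every grid row with [mc_evaluate()] under one shared plan, so
#' GPR and LR rows for the same target consume identical split sequences
#' (paired comparison).  A failed row is marked and the grid continues.
#'
#' @param ds A `spectro_dataset`.
#' @param grid "table1", "table2", or a list from [experiment_grid()].
#' @param plan A [split_plan()].
#' @param out_dir Optional directory for `comparison.csv`,
#'   `comparison.json` and per-row outlier listings.
#' @param n_outliers Outliers listed per row (default 5).
#' @return List of class `"grid_result"`: `comparison` (data.frame),
#'   `reports` (per-row eval reports or NULL), `outliers`, `provenance`.
#' @export
run_grid <- function(ds, grid = "table1", plan = split_plan(),
                     out_dir = NULL, n_outliers = 5L) {
  if (is.character(grid)) grid <- experiment_grid(grid)
  if (length(grid) == 0L) stop("empty experiment grid", call. = FALSE)
  reports <- vector("list", length(grid))
  names(reports) <- vapply(grid, `[[`, "", "name")
  rows <- list()
  outliers <- list()
  for (i in seq_along(grid)) {
    g <- grid[[i]]
    rep_i <- tryCatch(mc_evaluate(ds, g$feature, g$model, plan),
                      error = function(e) conditionMessage(e))
    if (is.character(rep_i)) {
      rows[[i]] <- data.frame(
        row = g$name, target = g$feature$target,
        model = if (inherits(g$model, "gp_model_spec")) "GPR" else "LR",
        feature = g$feature$name, status = paste("failed:", rep_i),
        MAE = NA_real_, MAE_sd = NA_real_, RMSE = NA_real_,
        RMSE_sd = NA_real_, r_E = NA_real_, r_E_sd = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    reports[[i]] <- rep_i
    s <- rep_i$test_summary
    rows[[i]] <- data.frame(
      row = g$name, target = g$feature$target,
      model = if (inherits(g$model, "gp_model_spec")) "GPR" else "LR",
      feature = g$feature$name, status = "ok",
      MAE = s["MAE", "mean"], MAE_sd = s["MAE", "sd"],
      RMSE = s["RMSE", "mean"], RMSE_sd = s["RMSE", "sd"],
      r_E = s["r_E", "mean"], r_E_sd = s["r_E", "sd"],
      stringsAsFactors = FALSE)
    outliers[[g$name]] <- report_outliers(rep_i, n_outliers, ds = ds)
  }
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  provenance <- list(
    seed = plan$seed, n_mc = plan$n_mc, n_strata = plan$n_strata,
    n_test = plan$n_test, n_molecules = nrow(ds),
    package_version = as.character(utils::packageVersion("spectroml")),
    config_hash = fnv1a(c(plan$seed, plan$n_mc, plan$n_strata, plan$n_test,
                          names(reports), nrow(ds))))
  out <- structure(list(comparison = comparison, reports = reports,
                        outliers = outliers, provenance = provenance),
                   class = "grid_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(comparison, file.path(out_dir, "comparison.csv"),
              row.names = FALSE)
    writeLines(jsonlite::toJSON(
      list(comparison = comparison, provenance = provenance,
           outliers = outliers),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(out_dir, "comparison.json"))
  }
  out
}

#' Rank the worst-predicted molecules of a report
#'
#' Top-k molecules by absolute error of the mean as-test prediction, tagged
#' by bond type from the radius ratio Re / (R1 + R2) (below `bands[1]`
#' ionic-leaning, between the bands covalent, above `bands[2]`
#' van-der-Waals-leaning).
#'
#' @param report An `eval_report`.
#' @param k Number of molecules to list (truncated to the available count).
#' @param ds Optional `spectro_dataset` for the bond-type tag.
#' @param bands Radius-ratio band edges (default c(0.8, 1.2)).
#' @return data.frame ranked by decreasing absolute test error.
#' @export
report_outliers <- function(report, k = 5L, ds = NULL,
                            bands = c(0.8, 1.2)) {
  pm <- report$per_molecule
  pm <- pm[!is.na(pm$test_mean), , drop = FALSE]
  err <- abs(pm$test_mean - pm$y_true)
  ord <- order(err, decreasing = TRUE)
  k <- min(k, length(ord))
  if (k == 0L) {
    return(data.frame(formula = character(0), y_true = numeric(0),
                      test_mean = numeric(0), abs_error = numeric(0),
                      bond_type = character(0)))
  }
  top <- pm[ord[seq_len(k)], , drop = FALSE]
  bond <- rep(NA_character_, k)
  if (!is.null(ds)) {
    idx <- match(top$formula, ds$formula)
    rr <- radius_ratio(ds$Re[idx], ds$radius1[idx], ds$radius2[idx])
    bond <- ifelse(rr < bands[1], "ionic-leaning",
            ifelse(rr > bands[2], "vdW-leaning", "covalent"))
  }
  data.frame(formula = top$formula, y_true = top$y_true,
             test_mean = top$test_mean,
             abs_error = abs(top$test_mean - top$y_true),
             bond_type = bond, stringsAsFactors = FALSE)
}

#' @export
print.grid_result <- function(x, ...) {
  cat("grid_result (config", x$provenance$config_hash, ")\n")
  print(x$comparison, digits = 4)
  invisible(x)
}
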