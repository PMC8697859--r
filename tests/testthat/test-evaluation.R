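test_that("stratification cuts labels into equal-count quantile blocks", {
  s <- stratify(1:50, 25)
  expect_equal(as.integer(table(s)), rep(2L, 25))
  expect_equal(s[1:4], c(1L, 1L, 2L, 2L))      # contiguous in label order
  # degenerate ties still give balanced strata
  s2 <- stratify(rep(1, 50), 25)
  expect_true(max(table(s2)) - min(table(s2)) <= 1)
  # singleton strata at n == n_strata
  s3 <- stratify(rnorm(25), 25)
  expect_equal(sort(as.integer(table(s3))), rep(1L, 25))
  expect_error(stratify(1:10, 25), "at least")
})

test_that("Monte-Carlo splits are exact, disjoint and deterministic", {
  y <- rnorm(200)
  strata <- stratify(y, 25)
  plan <- split_plan(n_strata = 25, n_test = 25, n_mc = 10, seed = 42)
  for (r in 1:10) {
    sp <- mc_split(strata, plan, r)
    expect_length(sp$test, 25)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), 1:200)
    # one test molecule per stratum when n_test == n_strata
    expect_equal(as.integer(table(strata[sp$test])), rep(1L, 25))
  }
  expect_identical(mc_split(strata, plan, 3), mc_split(strata, plan, 3))
  expect_false(identical(mc_split(strata, plan, 3)$test,
                         mc_split(strata, plan, 4)$test))
})

test_that("test frequencies follow the within-stratum sampling rate", {
  # 50 labels, 25 strata of size 2: every molecule is a test case with
  # probability 1/2 per repetition
  y <- seq_len(50)
  strata <- stratify(y, 25)
  plan <- split_plan(n_mc = 400, seed = 9)
  cnt <- numeric(50)
  for (r in seq_len(plan$n_mc)) {
    cnt[mc_split(strata, plan, r)$test] <- cnt[mc_split(strata, plan, r)$test] + 1
  }
  p <- cnt / plan$n_mc
  bound <- 4 * sqrt(0.5 * 0.5 / plan$n_mc)
  expect_true(all(abs(p - 0.5) < bound))
})

test_that("metrics match hand computations and identities", {
  expect_equal(unname(metrics(c(1, 2, 3), c(1, 2, 3))), c(0, 0, 0))
  m <- metrics(c(0, 2), c(1, 1))
  expect_equal(unname(m), c(1, 1, 50))
  # constant error: MAE == RMSE (equality case of Jensen)
  m2 <- metrics(c(1, 2, 4), c(1.5, 2.5, 4.5))
  expect_equal(unname(m2["MAE"]), unname(m2["RMSE"]))
  # fixed external range
  m3 <- metrics(c(0, 1), c(0.5, 0.5), range_y = 10)
  expect_equal(unname(m3["r_E"]), 100 * unname(m3["RMSE"]) / 10)
  expect_error(metrics(c(1, 1), c(1, 2)), "zero label range")
})

test_that("nested CV picks the well-specified candidate", {
  ds <- medium_ds()
  view <- dataset_view(ds, "Re")
  good <- list(feature = feature_spec(c("g_bar", "p_bar"), "Re",
                                      augment = FALSE),
               model = gp_model_spec("matern52", "constant",
                                     n_restarts = 2))
  # mis-specified: a single uninformative predictor
  bad <- list(feature = feature_spec("we_X", "Re", augment = FALSE),
              model = lr_model_spec())
  wins <- 0
  for (s in 1:10) {
    sel <- nested_cv_select(view$data, view$y, list(bad, good), seed = s)
    wins <- wins + (sel$choice == 2)
  }
  expect_gte(wins, 9)
  # single candidate comes back unchanged, with its CV score logged
  sel1 <- nested_cv_select(view$data, view$y, list(good), seed = 1)
  expect_equal(sel1$choice, 1)
  expect_true(is.finite(sel1$cv_rmse[1]))
  # fold assignment is deterministic given the seed
  expect_identical(spectroml:::stratified_folds(view$y, 5, seed = 4),
                   spectroml:::stratified_folds(view$y, 5, seed = 4))
})

test_that("evaluation reports conserve counts and are reproducible", {
  ds <- medium_ds()
  plan <- split_plan(n_mc = 4, seed = 13)
  feature <- feature_spec(c("g_bar", "p_bar"), "Re", augment = FALSE)
  model <- gp_model_spec("matern52", "constant", n_restarts = 2)
  rep1 <- mc_evaluate(ds, feature, model, plan)
  pm <- rep1$per_molecule
  expect_true(all(pm$n_train + pm$n_test == plan$n_mc))
  expect_true(all(pm$train_sd >= 0, na.rm = TRUE))
  expect_gt(sd(rep1$metrics_test["RMSE", ]), 0)   # splits differ
  rep2 <- mc_evaluate(ds, feature, model, plan)
  expect_identical(rep1$metrics_test, rep2$metrics_test)
  expect_identical(rep1$per_molecule, rep2$per_molecule)
})

test_that("stored per-repetition predictions reproduce the pooled metrics", {
  ds <- medium_ds()
  plan <- split_plan(n_mc = 6, seed = 23)
  feature <- feature_spec(c("g_bar", "p_bar"), "Re", augment = FALSE)
  rep1 <- mc_evaluate(ds, feature,
                      gp_model_spec("matern52", "constant", n_restarts = 2),
                      plan)
  y <- rep1$per_molecule$y_true
  errs <- abs(rep1$pred_test - y)          # n x n_mc, NA where training
  pooled_mae <- mean(errs, na.rm = TRUE)
  expect_equal(pooled_mae, mean(rep1$metrics_test["MAE", ]),
               tolerance = 1e-12)
  # per-molecule means weighted by appearance counts give the same pool
  pm <- rep1$per_molecule
  mean_abs <- rowMeans(errs, na.rm = TRUE)
  expect_equal(sum(mean_abs * pm$n_test, na.rm = TRUE) / sum(pm$n_test),
               pooled_mae, tolerance = 1e-12)
})

test_that("learning curves are consistent with full-size evaluation", {
  ds <- medium_ds()
  feature <- feature_spec(c("g_bar", "p_bar"), "Re", augment = FALSE)
  model <- gp_model_spec("matern52", "constant", n_restarts = 2)
  plan <- split_plan(n_mc = 6, seed = 3)
  lc <- learning_curve(ds, feature, model, sizes = c(30, 75), plan = plan)
  expect_s3_class(lc, "data.frame")
  expect_setequal(unique(lc$N), c(30, 75))
  # N = full training size reproduces mc_evaluate within MC error
  full <- mc_evaluate(ds, feature, model, plan)
  lc_full <- learning_curve(ds, feature, model, sizes = nrow(ds) - 25,
                            plan = plan)
  got <- lc_full[lc_full$role == "test" & lc_full$metric == "RMSE", ]
  want <- full$test_summary["RMSE", ]
  expect_equal(got$mean, unname(want["mean"]), tolerance = 1e-10)
})
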