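#' Monte-Carlo split plan
#'
#' Settings of the stratified train/test protocol: the label view is cut
#' into `n_strata` equal-count strata, and in each of `n_mc` repetitions
#' `n_test` molecules are drawn across strata (one per stratum when
#' `n_test == n_strata`) to form the test set; the rest train.
#'
#' @param n_strata Number of label strata (default 25).
#' @param n_test Test-set size per repetition (default 25).
#' @param n_mc Number of Monte-Carlo repetitions (default 1000).
#' @param seed Integer seed; every repetition derives its own stream.
#' @return A list of class `"split_plan"`.
#' @export
split_plan <- function(n_strata = 25L, n_test = 25L, n_mc = 1000L, seed = 1L) {
  structure(list(n_strata = as.integer(n_strata), n_test = as.integer(n_test),
                 n_mc = as.integer(n_mc), seed = as.integer(seed)),
            class = "split_plan")
}

# deterministic per-repetition seed below 2^31
rep_seed <- function(seed, rep_index, offset = 0L) {
  as.integer((as.numeric(seed) * 1000003 + rep_index * 7919 +
                offset * 104729) %% 2147483629)
}

#' Assign labels to equal-count strata
#'
#' Sorts the labels (stably, so ties keep input order) and cuts them into
#' `n_strata` contiguous quantile blocks whose sizes differ by at most one.
#'
#' @param labels Numeric vector.
#' @param n_strata Number of strata (<= length(labels)).
#' @return Integer stratum index per input position (1 = lowest labels).
#' @export
stratify <- function(labels, n_strata = 25L) {
  n <- length(labels)
  if (n < n_strata) stop("need at least n_strata = ", n_strata,
                         " labels, got ", n, call. = FALSE)
  ord <- order(labels)                      # stable for ties
  base <- n %/% n_strata
  extra <- n %% n_strata
  sizes <- rep(base, n_strata) + c(rep(1L, extra), rep(0L, n_strata - extra))
  out <- integer(n)
  out[ord] <- rep(seq_len(n_strata), times = sizes)
  out
}

#' One Monte-Carlo train/test split
#'
#' Draws the test set for repetition `rep_index`: test slots are distributed
#' round-robin over the strata (exactly one per stratum when
#' `n_test == n_strata`) and filled by uniform sampling without replacement
#' within each stratum.  Deterministic given `(plan$seed, rep_index)`.
#'
#' @param strata Stratum assignment from [stratify()].
#' @param plan A [split_plan()].
#' @param rep_index Repetition number (1-based).
#' @return List with integer index vectors `train` and `test`.
#' @export
mc_split <- function(strata, plan, rep_index) {
  k <- max(strata)
  n <- length(strata)
  quota <- rep(plan$n_test %/% k, k)
  rem <- plan$n_test %% k
  if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
  sizes <- tabulate(strata, k)
  # re-balance quotas that exceed a stratum's population
  over <- pmax(quota - sizes, 0L)
  if (any(over > 0)) {
    quota <- pmin(quota, sizes)
    surplus <- sum(over)
    room <- sizes - quota
    i <- 1L
    while (surplus > 0L && any(room > 0L)) {
      if (room[i] > 0L) {
        quota[i] <- quota[i] + 1L; room[i] <- room[i] - 1L
        surplus <- surplus - 1L
      }
      i <- if (i == k) 1L else i + 1L
    }
    message("mc_split: quotas re-balanced over strata (rep ", rep_index, ")")
  }
  test <- with_seed(rep_seed(plan$seed, rep_index), {
    unlist(lapply(seq_len(k), function(s) {
      idx <- which(strata == s)
      if (quota[s] == 0L) return(integer(0))
      idx[sample.int(length(idx), quota[s])]
    }))
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Regression error metrics
#'
#' MAE = mean |y - yhat|, RMSE = sqrt(mean (y - yhat)^2), and the normalized
#' error r_E = RMSE / range(y) in percent.  The range defaults to that of
#' `y_true` but is normally fixed to the full label-set range so r_E is
#' comparable across Monte-Carlo repetitions.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @param range_y Denominator of r_E; defaults to `diff(range(y_true))`.
#' @return Named numeric vector `c(MAE, RMSE, r_E)` (r_E in percent).
#' @export
metrics <- function(y_true, y_pred, range_y = NULL) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1L)
  if (is.null(range_y)) range_y <- diff(range(y_true))
  if (range_y <= 0) stop("r_E undefined: zero label range", call. = FALSE)
  err <- y_pred - y_true
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  c(MAE = mae, RMSE = rmse, r_E = 100 * rmse / range_y)
}

# stratified k-fold assignment, deterministic given seed
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  ord <- order(labels)
  fold <- integer(n)
  with_seed(seed, {
    i <- 1L
    while (i <= n) {
      block <- ord[i:min(i + k - 1L, n)]
      fold[block] <- sample(seq_len(k))[seq_along(block)]
      i <- i + k
    }
  })
  fold
}

# fit one candidate (feature + model) on train rows, predict train and test
fit_and_predict <- function(train_data, y_train, test_data, feature, model,
                            seed = 1L) {
  re_tr <- re_te <- NULL
  if (any(c("inv_Re_pred", "Re_pred") %in% feature$components)) {
    aux_spec <- feature_spec(c("g1", "g2", "p1", "p2"), target = "Re",
                             name = "re_aux", augment = TRUE)
    fm_aux <- build_features(train_data, aux_spec, y = train_data$Re)
    fm_aux <- permutation_augment(fm_aux)
    aux <- fit_gp(fm_aux$X, fm_aux$y, kernel = "exponential",
                  basis = "linear", n_restarts = 3L, seed = seed)
    re_tr <- pmax(predict(aux, build_features(train_data, aux_spec)$X)$mean,
                  0.5)
    re_te <- pmax(predict(aux, build_features(test_data, aux_spec)$X)$mean,
                  0.5)
  }
  fm <- build_features(train_data, feature, y = y_train, re_pred = re_tr)
  if (feature$augment) fm <- permutation_augment(fm)
  Xte <- build_features(test_data, feature, re_pred = re_te)$X
  Xtr0 <- build_features(train_data, feature, re_pred = re_tr)$X
  if (inherits(model, "gp_model_spec") ||
      (is.list(model) && identical(model$type, "gpr"))) {
    fit <- fit_gp(fm$X, fm$y, kernel = model$kernel, basis = model$basis,
                  n_restarts = model$n_restarts, seed = seed)
    list(fit = fit,
         pred_train = predict(fit, Xtr0)$mean,
         pred_test = predict(fit, Xte)$mean)
  } else {
    Hf <- cbind(1, fm$X)
    qrH <- qr(Hf)
    if (qrH$rank < ncol(Hf)) stop("rank-deficient linear design",
                                  call. = FALSE)
    cf <- qr.coef(qrH, fm$y)
    list(fit = list(type = "lr", coef = cf),
         pred_train = drop(cbind(1, Xtr0) %*% cf),
         pred_test = drop(cbind(1, Xte) %*% cf))
  }
}

#' Select a model/feature candidate by stratified 5-fold cross-validation
#'
#' Folds are stratified on the training labels; each candidate is fitted on
#' the fold-train portion (with augmentation applied inside the fold only)
#' and scored by RMSE on the held-out fold.  The candidate with the lowest
#' mean fold RMSE wins; ties go to the first in candidate order.
#'
#' @param train_data Training rows (a `spectro_dataset` subset).
#' @param y_train Their labels.
#' @param candidates List of candidates, each a list with elements `feature`
#'   (a [feature_spec()]) and `model` (a [gp_model_spec()] or
#'   [lr_model_spec()]).
#' @param k Number of folds (default 5).
#' @param seed Seed controlling fold assignment and fits.
#' @return List with `choice` (winning candidate index), `candidate` and
#'   `cv_rmse` (mean fold RMSE per candidate).
#' @export
nested_cv_select <- function(train_data, y_train, candidates, k = 5L,
                             seed = 1L) {
  fold <- stratified_folds(y_train, k = k, seed = seed)
  scores <- rep(NA_real_, length(candidates))
  diag_msgs <- character(length(candidates))
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    rmse <- numeric(0)
    ok <- TRUE
    for (f in seq_len(k)) {
      tr <- which(fold != f); te <- which(fold == f)
      res <- tryCatch(
        fit_and_predict(train_data[tr, , drop = FALSE], y_train[tr],
                        train_data[te, , drop = FALSE], cand$feature,
                        cand$model, seed = rep_seed(seed, ci, f)),
        error = function(e) conditionMessage(e))
      if (is.character(res)) { ok <- FALSE; diag_msgs[ci] <- res; break }
      rmse <- c(rmse, sqrt(mean((res$pred_test - y_train[te])^2)))
    }
    if (ok) scores[ci] <- mean(rmse)
  }
  if (all(is.na(scores))) {
    stop("all candidates failed in cross-validation:\n",
         paste(sprintf("  [%d] %s", seq_along(candidates), diag_msgs),
               collapse = "\n"), call. = FALSE)
  }
  choice <- which.min(scores)        # ties: first index wins
  list(choice = choice, candidate = candidates[[choice]], cv_rmse = scores)
}

#' Monte-Carlo evaluation of a model under the stratified split protocol
#'
#' For each repetition: draw the stratified split, optionally pick a
#' candidate by nested cross-validation on the training rows only, fit on
#' the (augmented) training rows, and predict every molecule.  Reports the
#' per-repetition test and train metrics (mean and sd over repetitions) and
#' per-molecule prediction summaries in both roles.  Fully reproducible
#' from `(plan$seed, plan)`.
#'
#' @param ds A `spectro_dataset`.
#' @param feature A [feature_spec()] (its `target` selects the label view).
#' @param model A [gp_model_spec()] or [lr_model_spec()].
#' @param plan A [split_plan()].
#' @param candidates Optional candidate list for per-repetition nested CV
#'   (see [nested_cv_select()]); overrides `feature`/`model` per repetition.
#' @param binding_transform Transform for the `Dlabel` target.
#' @param keep_reps Keep the full per-repetition test-prediction matrix
#'   (needed to re-derive pooled metrics; default TRUE).
#' @return An object of class `"eval_report"`.
#' @export
mc_evaluate <- function(ds, feature, model, plan = split_plan(),
                        candidates = NULL,
                        binding_transform = "ln_ZZ_over_De",
                        keep_reps = TRUE) {
  view <- dataset_view(ds, feature$target,
                       binding_transform = binding_transform)
  data <- view$data; y <- view$y
  n <- nrow(data)
  range_y <- diff(range(y))
  strata <- stratify(y, plan$n_strata)

  m_test <- matrix(NA_real_, 3, plan$n_mc,
                   dimnames = list(c("MAE", "RMSE", "r_E"), NULL))
  m_train <- m_test
  sum_tr <- sum2_tr <- cnt_tr <- numeric(n)
  sum_te <- sum2_te <- cnt_te <- numeric(n)
  pred_te <- if (keep_reps) matrix(NA_real_, n, plan$n_mc) else NULL
  failures <- integer(0)

  for (r in seq_len(plan$n_mc)) {
    res <- tryCatch({
      sp <- mc_split(strata, plan, r)
      feat <- feature; mod <- model
      if (!is.null(candidates)) {
        sel <- nested_cv_select(data[sp$train, , drop = FALSE], y[sp$train],
                                candidates, seed = rep_seed(plan$seed, r, 1L))
        feat <- sel$candidate$feature; mod <- sel$candidate$model
      }
      fp <- fit_and_predict(data[sp$train, , drop = FALSE], y[sp$train],
                            data[sp$test, , drop = FALSE], feat, mod,
                            seed = rep_seed(plan$seed, r, 2L))
      list(sp = sp, fp = fp)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, r)
      if (length(failures) > 0.05 * plan$n_mc) {
        stop("more than 5% of repetitions failed (last: ", res, ")",
             call. = FALSE)
      }
      next
    }
    sp <- res$sp; fp <- res$fp
    m_test[, r] <- metrics(y[sp$test], fp$pred_test, range_y)
    m_train[, r] <- metrics(y[sp$train], fp$pred_train, range_y)
    sum_tr[sp$train] <- sum_tr[sp$train] + fp$pred_train
    sum2_tr[sp$train] <- sum2_tr[sp$train] + fp$pred_train^2
    cnt_tr[sp$train] <- cnt_tr[sp$train] + 1
    sum_te[sp$test] <- sum_te[sp$test] + fp$pred_test
    sum2_te[sp$test] <- sum2_te[sp$test] + fp$pred_test^2
    cnt_te[sp$test] <- cnt_te[sp$test] + 1
    if (keep_reps) pred_te[sp$test, r] <- fp$pred_test
  }

  msd <- function(s, s2, k) {
    mean_ <- ifelse(k > 0, s / k, NA_real_)
    var_ <- ifelse(k > 1, pmax(0, (s2 - s^2 / k) / (k - 1)), 0)
    list(mean = mean_, sd = ifelse(k > 0, sqrt(var_), NA_real_))
  }
  tr <- msd(sum_tr, sum2_tr, cnt_tr)
  te <- msd(sum_te, sum2_te, cnt_te)
  done <- setdiff(seq_len(plan$n_mc), failures)
  agg <- function(M) {
    t(apply(M[, done, drop = FALSE], 1,
            function(v) c(mean = mean(v), sd = sd(v))))
  }
  structure(list(
    target = feature$target,
    feature = feature$name,
    model = if (inherits(model, "gp_model_spec"))
      paste0("GPR(", model$kernel, ",", model$basis, ")") else "LR",
    plan = plan, n = n, range_y = range_y,
    per_molecule = data.frame(
      formula = data$formula, y_true = y,
      n_train = cnt_tr, train_mean = tr$mean, train_sd = tr$sd,
      n_test = cnt_te, test_mean = te$mean, test_sd = te$sd,
      stringsAsFactors = FALSE),
    metrics_test = m_test, metrics_train = m_train,
    test_summary = agg(m_test), train_summary = agg(m_train),
    pred_test = pred_te, failures = failures),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: target %s, %s, features %s\n",
              x$target, x$model, x$feature))
  cat(sprintf("  %d molecules, %d MC reps (%d failed)\n",
              x$n, x$plan$n_mc, length(x$failures)))
  s <- x$test_summary
  cat(sprintf("  test  MAE %.4g +/- %.2g | RMSE %.4g +/- %.2g | r_E %.3g%% +/- %.2g\n",
              s["MAE", "mean"], s["MAE", "sd"], s["RMSE", "mean"],
              s["RMSE", "sd"], s["r_E", "mean"], s["r_E", "sd"]))
  s <- x$train_summary
  cat(sprintf("  train MAE %.4g +/- %.2g | RMSE %.4g +/- %.2g | r_E %.3g%% +/- %.2g\n",
              s["MAE", "mean"], s["MAE", "sd"], s["RMSE", "mean"],
              s["RMSE", "sd"], s["r_E", "mean"], s["r_E", "sd"]))
  invisible(x)
}

#' Learning curve under the Monte-Carlo protocol
#'
#' For each training-set size N, repeats the stratified split, subsamples
#' the training rows to N (stratified, proportional over strata), fits, and
#' records train/test error.  Sizes below the minimum feasible fit size are
#' skipped with a message.
#'
#' @param ds A `spectro_dataset`.
#' @param feature,model As in [mc_evaluate()].
#' @param sizes Integer vector of training-set sizes N.
#' @param plan A [split_plan()]; its `n_mc` (default here 500) sets the
#'   repetitions per curve point.
#' @param binding_transform Transform for the `Dlabel` target.
#' @return A data.frame with columns N, role (train/test), metric, mean, sd,
#'   var, n_mc.
#' @export
learning_curve <- function(ds, feature, model, sizes,
                           plan = split_plan(n_mc = 500L),
                           binding_transform = "ln_ZZ_over_De") {
  view <- dataset_view(ds, feature$target,
                       binding_transform = binding_transform)
  data <- view$data; y <- view$y
  range_y <- diff(range(y))
  strata <- stratify(y, plan$n_strata)
  out <- list()
  for (N in sizes) {
    min_fit <- 6L
    if (N < min_fit) { message("skipping N = ", N, ": below minimum fit size")
      next }
    rm_test <- matrix(NA_real_, 3, plan$n_mc)
    rm_train <- rm_test
    for (r in seq_len(plan$n_mc)) {
      sp <- mc_split(strata, plan, r)
      tr_idx <- sp$train
      if (N < length(tr_idx)) {
        # proportional stratified subsample of the training rows
        tr_strata <- strata[tr_idx]
        tab <- tabulate(tr_strata, max(strata))
        want <- floor(N * tab / sum(tab))
        rem <- N - sum(want)
        frac <- N * tab / sum(tab) - want
        if (rem > 0) {
          add <- order(frac, decreasing = TRUE)[seq_len(rem)]
          want[add] <- want[add] + 1L
        }
        want <- pmin(want, tab)
        short <- N - sum(want)
        keep <- with_seed(rep_seed(plan$seed, r, 3L), {
          picked <- unlist(lapply(which(want > 0), function(s) {
            idx <- tr_idx[tr_strata == s]
            idx[sample.int(length(idx), want[s])]
          }))
          if (short > 0) {
            pool <- setdiff(tr_idx, picked)
            picked <- c(picked, pool[sample.int(length(pool), short)])
          }
          picked
        })
        tr_idx <- sort(keep)
      }
      res <- tryCatch(
        fit_and_predict(data[tr_idx, , drop = FALSE], y[tr_idx],
                        data[sp$test, , drop = FALSE], feature, model,
                        seed = rep_seed(plan$seed, r, 2L)),
        error = function(e) NULL)
      if (is.null(res)) next
      rm_test[, r] <- metrics(y[sp$test], res$pred_test, range_y)
      rm_train[, r] <- metrics(y[tr_idx], res$pred_train, range_y)
    }
    for (role in c("train", "test")) {
      M <- if (role == "train") rm_train else rm_test
      for (met in c("MAE", "RMSE", "r_E")) {
        v <- M[match(met, c("MAE", "RMSE", "r_E")), ]
        v <- v[is.finite(v)]
        out[[length(out) + 1L]] <- data.frame(
          N = N, role = role, metric = met, mean = mean(v), sd = sd(v),
          var = var(v), n_mc = length(v))
      }
    }
  }
  do.call(rbind, out)
}
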