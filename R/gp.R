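# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Evaluate a covariance kernel at a distance
#'
#' Isotropic kernels on the Euclidean distance r between (standardized)
#' feature vectors:
#' exponential, sigma_f^2 exp(-r / l), and Matern-5/2,
#' sigma_f^2 (1 + sqrt(5) r / l + 5 r^2 / (3 l^2)) exp(-sqrt(5) r / l).
#'
#' @param r Distance(s), >= 0.
#' @param kind "exponential" or "matern52".
#' @param sigma_f Signal standard deviation (> 0).
#' @param length_scale Characteristic length scale l (> 0).
#' @return Covariance value(s).
#' @export
kernel_eval <- function(r, kind = c("exponential", "matern52"),
                        sigma_f = 1, length_scale = 1) {
  kind <- match.arg(kind)
  if (any(r < 0)) stop("distances must be nonnegative", call. = FALSE)
  stopifnot(sigma_f > 0, length_scale > 0)
  s <- r / length_scale
  switch(kind,
    exponential = sigma_f^2 * exp(-s),
    matern52 = {
      q <- sqrt(5) * s
      sigma_f^2 * (1 + q + q^2 / 3) * exp(-q)
    })
}

# design matrix of the explicit basis
basis_matrix <- function(X, basis) {
  switch(basis,
    constant = matrix(1, nrow(X), 1L),
    linear   = cbind(1, X),
    stop("unknown basis kind ", basis, call. = FALSE))
}

#' GP model settings
#'
#' @param kernel "exponential" or "matern52".
#' @param basis "constant" or "linear".
#' @param n_restarts Number of seeded restarts for the marginal-likelihood
#'   maximization (default 5).
#' @return A list of class `"gp_model_spec"`.
#' @export
gp_model_spec <- function(kernel = c("exponential", "matern52"),
                          basis = c("constant", "linear"), n_restarts = 5L) {
  structure(list(type = "gpr", kernel = match.arg(kernel),
                 basis = match.arg(basis), n_restarts = as.integer(n_restarts)),
            class = "gp_model_spec")
}

#' Linear-regression model settings (ordinary least squares on the features)
#' @return A list of class `"lr_model_spec"`.
#' @export
lr_model_spec <- function() {
  structure(list(type = "lr"), class = "lr_model_spec")
}

# Cholesky with jitter escalation; returns list(L, jitter)
chol_jittered <- function(K) {
  scale <- mean(diag(K))
  for (j in c(0, 1e-10, 1e-8, 1e-6)) {
    L <- tryCatch(t(chol(K + diag(j * scale, nrow(K)))),
                  error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
  }
  stop("covariance matrix singular even after jitter escalation",
       call. = FALSE)
}

# profiled log marginal likelihood with analytic gradient in
# (log sigma_f, log l, log sigma_y); beta is profiled out by GLS, so its
# dependence on the hyperparameters drops from the gradient (envelope
# theorem: dL/dbeta = H' K^-1 r = 0 at the GLS solution)
gp_nll_grad <- function(D, H, y, kernel, lt) {
  sigma_f <- exp(lt[1]); length_scale <- exp(lt[2]); sigma_y <- exp(lt[3])
  n <- length(y)
  Kf <- kernel_eval(D, kernel, sigma_f, length_scale)
  K <- Kf
  diag(K) <- sigma_f^2 + sigma_y^2
  cj <- tryCatch(chol_jittered(K), error = function(e) NULL)
  if (is.null(cj)) return(list(value = 1e10, grad = c(0, 0, 0)))
  L <- cj$L
  A <- forwardsolve(L, H)
  b <- forwardsolve(L, y)
  AtA <- crossprod(A)
  beta <- tryCatch(solve(AtA, crossprod(A, b)), error = function(e) NULL)
  if (is.null(beta)) return(list(value = 1e10, grad = c(0, 0, 0)))
  r <- y - H %*% beta
  br <- forwardsolve(L, r)
  lml <- -0.5 * sum(br^2) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  if (!is.finite(lml)) return(list(value = 1e10, grad = c(0, 0, 0)))
  alpha_r <- backsolve(t(L), br)
  Kinv <- chol2inv(t(L))
  # dK/dlog sigma_f = 2 Kf ; dK/dlog sigma_y = 2 sigma_y^2 I
  s <- D / length_scale
  dK_dlogl <- switch(kernel,
    exponential = Kf * s,
    matern52 = {
      q <- sqrt(5) * s
      sigma_f^2 * exp(-q) * q^2 * (1 + q) / 3
    })
  quad <- function(M) 0.5 * (drop(crossprod(alpha_r, M %*% alpha_r)) -
                               sum(Kinv * M))
  g_sf <- quad(Kf) * 2
  g_l <- quad(dK_dlogl)
  g_sy <- sigma_y^2 * (sum(alpha_r^2) - sum(diag(Kinv)))
  list(value = -lml, grad = -c(g_sf, g_l, g_sy))
}

# profiled log marginal likelihood and the GLS pieces at fixed hyperparameters
gp_solve <- function(D, H, y, kernel, sigma_f, length_scale, sigma_y) {
  n <- length(y)
  K <- kernel_eval(D, kernel, sigma_f, length_scale)
  diag(K) <- sigma_f^2 + sigma_y^2
  cj <- chol_jittered(K)
  L <- cj$L
  A <- forwardsolve(L, H)              # n x q
  b <- forwardsolve(L, y)
  AtA <- crossprod(A)
  beta <- tryCatch(solve(AtA, crossprod(A, b)), error = function(e) {
    # ridge fallback for a rank-deficient basis on the training set
    solve(AtA + diag(1e-8 * mean(diag(AtA)), ncol(AtA)), crossprod(A, b))
  })
  r <- y - H %*% beta
  br <- forwardsolve(L, r)
  lml <- -0.5 * sum(br^2) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  alpha <- backsolve(t(L), br)
  list(lml = as.numeric(lml), beta = beta, alpha = alpha, L = L, A = A,
       AtA = AtA, jitter = cj$jitter)
}

#' Fit a Gaussian process with explicit basis functions
#'
#' The model is y = h(x)' beta + f(x) + eps, with f a zero-mean GP under the
#' chosen kernel and eps ~ N(0, sigma_y^2).  Basis coefficients beta are
#' estimated by generalized least squares; the kernel hyperparameters
#' (sigma_f, l, sigma_y), unless supplied, are set by maximizing the
#' profiled log marginal likelihood with seeded multi-start L-BFGS-B on the
#' log scale, with bounds l in [1e-2, 1e3] (standardized feature units) and
#' sigma_y in [1e-6, range(y)].
#'
#' @param X Numeric feature matrix (n x d).
#' @param y Numeric labels (length n).
#' @param kernel,basis Kernel and basis kind, see [gp_model_spec()].
#' @param sigma_f,length_scale,sigma_y Optional fixed hyperparameters; all
#'   three must be given to skip estimation.
#' @param n_restarts Multi-start count for the optimizer.
#' @param seed Seed for the restart draws (the caller's RNG stream is left
#'   untouched).
#' @param standardize Z-score the feature columns with training statistics
#'   (stored in the model and applied at prediction time).  Default TRUE.
#' @return An object of class `"gp_model"`.
#' @export
fit_gp <- function(X, y, kernel = c("exponential", "matern52"),
                   basis = c("constant", "linear"),
                   sigma_f = NULL, length_scale = NULL, sigma_y = NULL,
                   n_restarts = 5L, seed = 1L, standardize = TRUE) {
  kernel <- match.arg(kernel); basis <- match.arg(basis)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  q <- if (basis == "constant") 1L else ncol(X) + 1L
  if (n < q + 1L) stop("need at least ", q + 1L, " observations", call. = FALSE)

  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    center <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  D <- as.matrix(dist(Xs))
  H <- basis_matrix(Xs, basis)

  sdy <- sd(y)
  fixed <- !is.null(sigma_f) && !is.null(length_scale) && !is.null(sigma_y)
  if (!fixed && (is.na(sdy) || sdy == 0)) {
    # constant labels: the basis absorbs everything
    sigma_f <- max(abs(y[1]), 1) * 1e-6; length_scale <- 1; sigma_y <- 1e-6
    fixed <- TRUE
  }
  if (fixed) {
    sol <- gp_solve(D, H, y, kernel, sigma_f, length_scale, sigma_y)
    theta <- c(sigma_f, length_scale, sigma_y)
  } else {
    ry <- diff(range(y))
    lower <- log(c(1e-3 * sdy, 1e-2, 1e-6))
    upper <- log(c(10 * sdy, 1e3, ry))
    cache_par <- NULL; cache_res <- NULL
    eval_pt <- function(lt) {
      if (!identical(lt, cache_par)) {
        cache_res <<- gp_nll_grad(D, H, y, kernel, lt)
        cache_par <<- lt
      }
      cache_res
    }
    obj <- function(lt) eval_pt(lt)$value
    obj_gr <- function(lt) eval_pt(lt)$grad
    med_d <- median(D[upper.tri(D)])
    if (!is.finite(med_d) || med_d <= 0) med_d <- 1
    starts <- with_seed(seed, {
      s0 <- log(c(sdy, med_d, 0.1 * sdy))
      extra <- replicate(max(0L, n_restarts - 1L),
                         runif(3, lower, upper), simplify = FALSE)
      c(list(pmin(pmax(s0, lower), upper)), extra)
    })
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        optim(st, obj, obj_gr, method = "L-BFGS-B", lower = lower,
              upper = upper, control = list(maxit = 60, factr = 1e9)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
    if (is.null(best) || best$value >= 1e10) {
      stop("marginal likelihood non-finite at every restart ",
           "(n = ", n, ", kernel = ", kernel, ")", call. = FALSE)
    }
    theta <- exp(best$par)
    sol <- gp_solve(D, H, y, kernel, theta[1], theta[2], theta[3])
  }

  structure(list(kernel = kernel, basis = basis,
                 sigma_f = theta[1], length_scale = theta[2],
                 sigma_y = theta[3],
                 beta = drop(sol$beta), alpha = drop(sol$alpha),
                 L = sol$L, A = sol$A, AtA = sol$AtA,
                 X_train = Xs, center = center, scale = scl,
                 lml = sol$lml, jitter = sol$jitter, n = n),
            class = "gp_model")
}

#' Posterior mean and standard deviation at query points
#'
#' Returns the latent-function posterior: the predictive standard deviation
#' excludes the observation noise, so at a training point with sigma_y near
#' zero it collapses to (numerical) zero.  The basis-coefficient uncertainty
#' is propagated, so far from the data the prediction reverts to the basis
#' fit h(x)' beta with inflated uncertainty.
#'
#' @param object A fitted `gp_model`.
#' @param newdata Raw feature matrix (same columns as at fit time).
#' @param ... Unused.
#' @return List with numeric vectors `mean` and `sd`.
#' @export
predict.gp_model <- function(object, newdata, ...) {
  Xq <- as.matrix(newdata)
  if (ncol(Xq) != ncol(object$X_train)) {
    stop("query has ", ncol(Xq), " columns, model expects ",
         ncol(object$X_train), call. = FALSE)
  }
  Xqs <- sweep(sweep(Xq, 2, object$center), 2, object$scale, "/")
  # cross-distances query x train, accumulated per feature: avoids the
  # cancellation of the x^2 + y^2 - 2xy form, which the exponential
  # kernel's kink at r = 0 would amplify
  Dq2 <- matrix(0, nrow(Xqs), nrow(object$X_train))
  for (k in seq_len(ncol(Xqs))) {
    Dq2 <- Dq2 + outer(Xqs[, k], object$X_train[, k], "-")^2
  }
  Dq <- sqrt(Dq2)
  Kq <- kernel_eval(Dq, object$kernel, object$sigma_f, object$length_scale)
  Hq <- basis_matrix(Xqs, object$basis)
  mu <- drop(Hq %*% object$beta + Kq %*% object$alpha)
  V <- forwardsolve(object$L, t(Kq))              # n x m
  var_f <- object$sigma_f^2 - colSums(V^2)
  Rm <- t(Hq) - crossprod(object$A, V)            # q x m
  corr <- colSums(Rm * solve(object$AtA, Rm))
  list(mean = mu, sd = sqrt(pmax(var_f + corr, 0)))
}

#' Profiled log marginal likelihood of a fitted or hypothetical model
#'
#' Exact Gaussian log evidence of the data under the model's kernel
#' hyperparameters, with the basis coefficients replaced by their GLS
#' estimate.  With no data arguments, returns the value cached at fit time.
#'
#' @param model A `gp_model`.
#' @param X,y Optional data to evaluate on (raw features; the model's
#'   standardization is applied).
#' @return Scalar log likelihood.
#' @export
log_marginal_likelihood <- function(model, X = NULL, y = NULL) {
  if (is.null(X)) return(model$lml)
  Xs <- sweep(sweep(as.matrix(X), 2, model$center), 2, model$scale, "/")
  D <- as.matrix(dist(Xs))
  H <- basis_matrix(Xs, model$basis)
  gp_solve(D, H, y, model$kernel, model$sigma_f, model$length_scale,
           model$sigma_y)$lml
}

#' Serialize a GP model to JSON
#'
#' Writes hyperparameters, basis coefficients, standardization statistics
#' and a digest of the training inputs, enough to audit a fit and re-predict
#' exactly after [gp_from_json()].
#'
#' @param model A `gp_model`.
#' @param path Output file; if NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
gp_to_json <- function(model, path = NULL) {
  y <- drop(basis_matrix(model$X_train, model$basis) %*% model$beta) +
    drop((kernel_eval(as.matrix(dist(model$X_train)), model$kernel,
                      model$sigma_f, model$length_scale) +
            diag(model$sigma_y^2, model$n)) %*% model$alpha)
  doc <- list(kernel = model$kernel, basis = model$basis,
              sigma_f = model$sigma_f, length_scale = model$length_scale,
              sigma_y = model$sigma_y, beta = model$beta,
              center = model$center, scale = model$scale,
              X_train = model$X_train, y_train = y,
              lml = model$lml, n = model$n)
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Rebuild a GP model from its JSON serialization
#' @param path File path or JSON string from [gp_to_json()].
#' @return A `gp_model` usable with [predict.gp_model()].
#' @export
gp_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  Xs <- as.matrix(doc$X_train)
  D <- as.matrix(dist(Xs))
  H <- basis_matrix(Xs, doc$basis)
  sol <- gp_solve(D, H, doc$y_train, doc$kernel, doc$sigma_f,
                  doc$length_scale, doc$sigma_y)
  structure(list(kernel = doc$kernel, basis = doc$basis,
                 sigma_f = doc$sigma_f, length_scale = doc$length_scale,
                 sigma_y = doc$sigma_y, beta = drop(sol$beta),
                 alpha = drop(sol$alpha),
                 L = sol$L, A = sol$A, AtA = sol$AtA,
                 X_train = Xs, center = doc$center, scale = doc$scale,
                 lml = doc$lml, jitter = sol$jitter, n = doc$n),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf(
    "gp_model: %s kernel, %s basis, n = %d\n  sigma_f = %.4g, l = %.4g, sigma_y = %.4g, lml = %.4g\n",
    x$kernel, x$basis, x$n, x$sigma_f, x$length_scale, x$sigma_y, x$lml))
  invisible(x)
}
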