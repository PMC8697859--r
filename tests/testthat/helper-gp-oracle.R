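# Brute-force dense-solve GP oracle: explicit kernel formulas, solve() and
# plain matrix algebra throughout -- independent of the package's
# Cholesky-based implementation path.
oracle_kernel <- function(r, kind, sf, l) {
  if (kind == "exponential") {
    sf^2 * exp(-r / l)
  } else {
    q <- sqrt(5) * r / l
    sf^2 * (1 + q + q^2 / 3) * exp(-q)
  }
}

oracle_gp <- function(X, y, Xq, kind, basis, sf, l, sy) {
  n <- nrow(X)
  K <- oracle_kernel(as.matrix(dist(X)), kind, sf, l)
  Ky <- K + diag(sy^2, n)
  H <- if (basis == "constant") matrix(1, n, 1) else cbind(1, X)
  Hq <- if (basis == "constant") matrix(1, nrow(Xq), 1) else cbind(1, Xq)
  Kinv <- solve(Ky)
  B <- solve(t(H) %*% Kinv %*% H)
  beta <- B %*% t(H) %*% Kinv %*% y
  resid <- y - H %*% beta
  Dq <- matrix(0, nrow(Xq), n)
  for (i in seq_len(nrow(Xq)))
    for (j in seq_len(n))
      Dq[i, j] <- sqrt(sum((Xq[i, ] - X[j, ])^2))
  Kq <- oracle_kernel(Dq, kind, sf, l)
  mu <- Hq %*% beta + Kq %*% Kinv %*% resid
  Rm <- t(Hq) - t(H) %*% Kinv %*% t(Kq)
  v <- sf^2 - diag(Kq %*% Kinv %*% t(Kq)) + diag(t(Rm) %*% B %*% Rm)
  list(mean = drop(mu), var = v)
}

# dense-determinant profiled log marginal likelihood oracle
oracle_lml <- function(X, y, kind, basis, sf, l, sy) {
  n <- nrow(X)
  K <- oracle_kernel(as.matrix(dist(X)), kind, sf, l)
  Ky <- K + diag(sy^2, n)
  H <- if (basis == "constant") matrix(1, n, 1) else cbind(1, X)
  Kinv <- solve(Ky)
  beta <- solve(t(H) %*% Kinv %*% H) %*% t(H) %*% Kinv %*% y
  r <- y - H %*% beta
  drop(-0.5 * t(r) %*% Kinv %*% r - 0.5 * log(det(Ky)) - n / 2 * log(2 * pi))
}
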