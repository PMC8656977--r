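# Independent oracles and small builders shared across the suite.
# Nothing here calls the package's simplex: the LP oracle enumerates basic
# solutions directly, so agreement is a genuine cross-check.

# Exact LP oracle by basic-solution enumeration.
# min c'x s.t. A x (<=|==) b, x >= 0, for tiny problems only.
enum_lp <- function(objective, A, b, dir, tol = 1e-8) {
  m <- nrow(A)
  n_slack <- sum(dir == "<=")
  S <- matrix(0, m, n_slack)
  S[cbind(which(dir == "<="), seq_len(n_slack))] <- 1
  M <- cbind(A, S)
  nn <- ncol(M)
  best <- Inf
  best_x <- NULL
  for (cols in utils::combn(nn, m, simplify = FALSE)) {
    B <- M[, cols, drop = FALSE]
    if (abs(det(B)) < 1e-12) next
    xb <- solve(B, b)
    if (any(xb < -tol)) next
    x <- numeric(nn)
    x[cols] <- xb
    if (any(abs(M %*% x - b) > 1e-7)) next
    obj <- sum(objective * x[seq_len(ncol(A))])
    if (obj < best - 1e-12) { best <- obj; best_x <- x[seq_len(ncol(A))] }
  }
  list(objval = best, x = best_x)
}

# DEA score by basic-solution enumeration (independent of the package LP).
enum_dea <- function(X, Y, x0, y0, vrs = FALSE) {
  n <- nrow(X)
  objective <- c(1, rep(0, n))
  A <- rbind(cbind(-x0, t(X)), cbind(rep(0, ncol(Y)), -t(Y)))
  b <- c(rep(0, ncol(X)), -y0)
  dir <- rep("<=", nrow(A))
  if (vrs) {
    A <- rbind(A, c(0, rep(1, n)))
    b <- c(b, 1)
    dir <- c(dir, "==")
  }
  enum_lp(objective, A, b, dir)$objval
}

# single-ratio CRS oracle for 1-input/1-output technologies
ratio_oracle <- function(x, y) (y / x) / max(y / x)

# quick panel from explicit input/output matrices (one year)
toy_panel <- function(X, Y, year = 2019, dmu = sprintf("T%02d", seq_len(nrow(X)))) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d <- data.frame(dmu = dmu, year = year)
  ins <- paste0("x", seq_len(ncol(X)))
  outs <- paste0("y", seq_len(ncol(Y)))
  for (j in seq_len(ncol(X))) d[[ins[j]]] <- X[, j]
  for (j in seq_len(ncol(Y))) d[[outs[j]]] <- Y[, j]
  dmu_panel(d, inputs = ins, outputs = outs)
}

# stack one-year toy slices into a multi-year panel
toy_multi_panel <- function(slices) {
  df <- do.call(rbind, lapply(slices, as.data.frame))
  dmu_panel(df, inputs = attr(slices[[1]], "inputs"),
            outputs = attr(slices[[1]], "outputs"))
}

# censored-normal log-likelihood evaluated directly (for grid oracles)
tobit_ll_direct <- function(mu, sigma, y) {
  sum(ifelse(y > 0, dnorm(y, mu, sigma, log = TRUE),
             pnorm(-mu / sigma, log.p = TRUE)))
}
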