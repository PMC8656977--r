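#' Solve a small dense linear program
#'
#' Two-phase primal simplex with Bland's anti-cycling rule, for problems of
#' the size DEA envelopment models produce (a handful of rows, tens of
#' columns). Minimizes `c'x` subject to `A x (<=|==|>=) b` and `x >= 0`.
#'
#' Bland's rule (always entering the lowest-index improving column, breaking
#' leaving ties by lowest basis index) guarantees termination on the highly
#' degenerate bases that envelopment LPs routinely generate, at a speed cost
#' that is irrelevant at this scale. Phase 1 minimizes the sum of artificial
#' variables; any artificial left in the basis at zero level marks a
#' redundant row and is pivoted out when possible.
#'
#' @param objective numeric cost vector (length = number of columns of `A`).
#' @param A constraint matrix.
#' @param b right-hand side.
#' @param dir character vector of constraint directions, each one of
#'   `"<="`, `"=="`, `">="`.
#' @param tol numerical tolerance for pivoting and optimality tests.
#' @param maxit iteration cap across both phases.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxit"`), and for optimal solves `x` (primal solution on the original
#'   columns) and `objval`.
#' @examples
#' # min -x1 - x2 s.t. x1 + x2 <= 1
#' simplex_lp(c(-1, -1), matrix(c(1, 1), 1), 1, "<=")$objval
#' @export
simplex_lp <- function(objective, A, b, dir, tol = 1e-9, maxit = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(objective) == n, length(b) == m, length(dir) == m,
            all(dir %in% c("<=", "==", ">=")))
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]
  }

  # columns: original (n) | slack/surplus | artificial
  n_slack <- sum(dir != "==")
  Sl <- matrix(0, m, n_slack)
  k <- 0L
  slack_col <- integer(m)
  for (i in seq_len(m)) {
    if (dir[i] != "==") {
      k <- k + 1L
      Sl[i, k] <- if (dir[i] == "<=") 1 else -1
      slack_col[i] <- n + k
    }
  }
  need_art <- dir != "<="
  n_art <- sum(need_art)
  Ar <- matrix(0, m, n_art)
  art_rows <- which(need_art)
  for (j in seq_along(art_rows)) Ar[art_rows[j], j] <- 1

  Tb <- cbind(A, Sl, Ar)
  rhs <- b
  basis <- integer(m)
  ak <- 0L
  for (i in seq_len(m)) {
    if (dir[i] == "<=") basis[i] <- slack_col[i]
    else { ak <- ak + 1L; basis[i] <- n + n_slack + ak }
  }

  pivot <- function(r, cin) {
    piv <- Tb[r, cin]
    Tb[r, ] <<- Tb[r, ] / piv
    rhs[r] <<- rhs[r] / piv
    other <- which(abs(Tb[, cin]) > 0 & seq_len(m) != r)
    for (i in other) {
      f <- Tb[i, cin]
      Tb[i, ] <<- Tb[i, ] - f * Tb[r, ]
      rhs[i] <<- rhs[i] - f * rhs[r]
    }
    basis[r] <<- cin
  }

  iters <- 0L
  run_phase <- function(cost, allowed) {
    repeat {
      iters <<- iters + 1L
      if (iters > maxit) return("maxit")
      red <- cost - as.vector(cost[basis] %*% Tb)
      red[!allowed] <- Inf
      improving <- which(red < -tol)
      if (!length(improving)) return("optimal")
      cin <- improving[1L]                     # Bland: lowest index enters
      col <- Tb[, cin]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratio <- rhs[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      pivot(cand[which.min(basis[cand])], cin)  # Bland: lowest basis leaves
    }
  }

  if (n_art > 0L) {
    st <- run_phase(c(rep(0, n + n_slack), rep(1, n_art)), rep(TRUE, ncol(Tb)))
    if (st != "optimal") return(list(status = st))
    if (sum(rhs[basis > n + n_slack]) > 1e-7) return(list(status = "infeasible"))
    for (i in seq_len(m)) {
      if (basis[i] > n + n_slack) {
        real <- which(abs(Tb[i, seq_len(n + n_slack)]) > tol)
        if (length(real)) pivot(i, real[1L])   # else: redundant row, harmless
      }
    }
  }

  st <- run_phase(c(objective, rep(0, n_slack + n_art)),
                  c(rep(TRUE, n + n_slack), rep(FALSE, n_art)))
  if (st != "optimal") return(list(status = st))
  x <- numeric(ncol(Tb)); x[basis] <- rhs
  x <- x[seq_len(n)]
  list(status = "optimal", x = x, objval = sum(objective * x))
}
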