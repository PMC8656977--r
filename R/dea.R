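# Envelopment-form DEA. Decision variables are (theta, lambda_1..lambda_n);
# the LP minimizes theta subject to
#   sum_i lambda_i x_si <= theta * x_s0   for every input s
#   sum_i lambda_i y_ri >= y_r0           for every output r
#   lambda >= 0                           (plus sum lambda = 1 under VRS)
# The same kernel scores cross-period targets, where theta may exceed 1.
dea_lp <- function(X, Y, x0, y0, vrs = FALSE, slack_max = FALSE, tol = 1e-9) {
  n <- nrow(X); ns <- ncol(X); nr <- ncol(Y)
  objective <- c(1, rep(0, n))
  A <- rbind(cbind(-x0, t(X)), cbind(rep(0, nr), -t(Y)))
  b <- c(rep(0, ns), -y0)
  dir <- rep("<=", ns + nr)
  if (vrs) {
    A <- rbind(A, c(0, rep(1, n)))
    b <- c(b, 1)
    dir <- c(dir, "==")
  }
  res <- simplex_lp(objective, A, b, dir, tol = tol)
  if (res$status != "optimal") {
    stop("DEA envelopment LP failed with solver status '", res$status, "'",
         call. = FALSE)
  }
  theta <- res$x[1]
  lambda <- res$x[-1]
  if (slack_max) {
    # second phase: at fixed theta*, maximize total slack to pin a canonical
    # vertex among alternate optima (standard two-phase DEA practice).
    # vars: (lambda, s_x, s_y); X'lam + s_x = theta* x0; Y'lam - s_y = y0
    nv <- n + ns + nr
    obj2 <- c(rep(0, n), rep(-1, ns + nr))      # maximize => minimize negative
    A2 <- rbind(cbind(t(X), diag(ns), matrix(0, ns, nr)),
                cbind(t(Y), matrix(0, nr, ns), -diag(nr)))
    b2 <- c(theta * x0, y0)
    dir2 <- rep("==", ns + nr)
    if (vrs) {
      A2 <- rbind(A2, c(rep(1, n), rep(0, ns + nr)))
      b2 <- c(b2, 1)
      dir2 <- c(dir2, "==")
    }
    res2 <- simplex_lp(obj2, A2, b2, dir2, tol = tol)
    if (res2$status == "optimal") lambda <- res2$x[seq_len(n)]
  }
  list(theta = theta, lambda = lambda)
}

#' Input-oriented CRS (CCR) efficiency of one DMU
#'
#' Solves the constant-returns-to-scale envelopment linear program for a
#' single target against a one-year reference slice: the largest
#' proportional input contraction keeping the target's outputs attainable
#' as a non-negative combination of the slice's DMUs.
#'
#' @param panel a [dmu_panel()].
#' @param target DMU label (or row index within the year slice).
#' @param year year defining the reference slice; optional for single-year
#'   panels.
#' @param slack_max if `TRUE`, run a second LP phase maximizing total slack
#'   at the optimal score, which selects a canonical intensity vector when
#'   the optimum is degenerate.
#' @return list with `dmu`, `year`, `theta` (Farrell score in (0, 1]),
#'   `lambda` (named intensity weights over the slice), `lambda_sum`,
#'   `rts` label, and `peers`.
#' @examples
#' p <- generate_panel(synthetic_config(n_dmus = 8, n_years = 1, seed = 1))$panel
#' solve_crs_input(p, target = "H01")$theta
#' @export
solve_crs_input <- function(panel, target, year = NULL, slack_max = FALSE) {
  dea_solve_one(panel, target, year, vrs = FALSE, slack_max = slack_max)
}

#' Input-oriented VRS (BCC) efficiency of one DMU
#'
#' As [solve_crs_input()] with the convexity constraint (intensity weights
#' summing to one), yielding pure technical efficiency.
#'
#' @inheritParams solve_crs_input
#' @return as [solve_crs_input()]; `theta` under VRS is never below the CRS
#'   score of the same target.
#' @export
solve_vrs_input <- function(panel, target, year = NULL, slack_max = FALSE) {
  dea_solve_one(panel, target, year, vrs = TRUE, slack_max = slack_max)
}

dea_solve_one <- function(panel, target, year, vrs, slack_max = FALSE) {
  slice <- panel_slice(panel, year)
  pm <- panel_matrices(slice)
  if (is.character(target)) {
    j <- match(target, pm$dmu)
    if (is.na(j)) stop("target DMU '", target, "' not in slice", call. = FALSE)
  } else {
    j <- as.integer(target)
    stopifnot(j >= 1L, j <= nrow(pm$X))
  }
  sol <- dea_lp(pm$X, pm$Y, pm$X[j, ], pm$Y[j, ], vrs = vrs, slack_max = slack_max)
  lambda <- stats::setNames(sol$lambda, pm$dmu)
  theta <- min(sol$theta, 1)   # clip numerical noise above 1 (self in slice)
  list(dmu = pm$dmu[j], year = slice$year[1], theta = theta,
       lambda = lambda, lambda_sum = sum(lambda),
       rts = classify_rts(sum(lambda)),
       peers = reference_set(lambda))
}

#' Scale efficiency from CRS and VRS scores
#'
#' Technical efficiency decomposes multiplicatively: the CRS score equals
#' the VRS (pure technical) score times scale efficiency, so scale
#' efficiency is their ratio, clipped at one.
#'
#' @param theta_crs CRS score(s) in (0, 1].
#' @param theta_vrs VRS score(s) in (0, 1]; must weakly dominate `theta_crs`.
#' @param tol tolerance on the nesting check.
#' @return scale efficiency value(s) in (0, 1].
#' @examples
#' scale_efficiency(0.5032, 0.6916)   # 0.7276 at 4 decimals
#' @export
scale_efficiency <- function(theta_crs, theta_vrs, tol = 1e-6) {
  if (any(theta_vrs <= 0)) stop("VRS score must be positive", call. = FALSE)
  if (any(theta_crs <= 0) || any(theta_crs > 1 + tol) || any(theta_vrs > 1 + tol))
    stop("scores must lie in (0, 1]", call. = FALSE)
  if (any(theta_crs > theta_vrs + tol))
    stop("CRS score exceeds VRS score beyond tolerance", call. = FALSE)
  pmin(theta_crs / theta_vrs, 1)
}

#' Classify returns to scale from the CRS intensity-weight sum
#'
#' Under the CRS envelopment model the sum of optimal intensity weights
#' locates the target relative to the most productive scale size: a sum
#' above one means decreasing returns to scale, below one increasing, and
#' one (the self-enveloping efficient case) constant.
#'
#' @param lambda_sum sum of the optimal CRS intensity weights.
#' @param tol classification tolerance on `|lambda_sum - 1|`.
#' @return `"constant"`, `"increasing"` or `"decreasing"` (vectorized).
#' @examples
#' classify_rts(c(1.066, 0.757, 1.000))
#' @export
classify_rts <- function(lambda_sum, tol = 1e-6) {
  stopifnot(all(lambda_sum >= 0))
  out <- rep("constant", length(lambda_sum))
  out[lambda_sum > 1 + tol] <- "decreasing"
  out[lambda_sum < 1 - tol] <- "increasing"
  out
}

#' Peer (reference) set from intensity weights
#'
#' DMUs whose intensity weight exceeds a threshold, ordered by decreasing
#' weight: the benchmarks whose practices envelope the evaluated unit.
#'
#' @param lambda named intensity-weight vector from an optimal solution.
#' @param threshold minimum weight for membership.
#' @return character vector of peer labels.
#' @export
reference_set <- function(lambda, threshold = 1e-6) {
  keep <- lambda > threshold
  names(sort(lambda[keep], decreasing = TRUE))
}

#' Score every DMU of a year slice
#'
#' Runs the CRS and VRS envelopment programs for each DMU in one year,
#' decomposes scale efficiency, classifies returns to scale, extracts
#' peers, and summarizes the unrounded score columns. When a factor table
#' with size dummies `D1`-`D3` is supplied, per-size-group score means are
#' added (rows with all dummies zero form the `small` group).
#'
#' @param panel a [dmu_panel()].
#' @param year year to evaluate (optional for single-year panels).
#' @param factors optional data.frame with `dmu` and dummy columns
#'   `D1`, `D2`, `D3` for group means.
#' @param slack_max passed to the per-DMU solvers.
#' @return object of class `dea_evaluation`: list with `results` (one row
#'   per DMU: `dmu`, `year`, `crs`, `vrs`, `se`, `lambda_sum`, `rts`,
#'   `peers`), `lambda` (full CRS intensity matrix), `summary` (mean,
#'   median, max, min, sd per score column), `rts_counts`, and optionally
#'   `group_means`.
#' @examples
#' p <- generate_panel(synthetic_config(n_dmus = 10, n_years = 1, seed = 1))$panel
#' ev <- dea_evaluate(p)
#' ev$summary
#' @export
dea_evaluate <- function(panel, year = NULL, factors = NULL, slack_max = FALSE) {
  slice <- panel_slice(panel, year)
  pm <- panel_matrices(slice)
  n <- nrow(pm$X)
  crs <- lapply(seq_len(n), function(j)
    dea_solve_one(slice, j, NULL, vrs = FALSE, slack_max = slack_max))
  vrs <- lapply(seq_len(n), function(j)
    dea_solve_one(slice, j, NULL, vrs = TRUE, slack_max = slack_max))
  theta_c <- vapply(crs, `[[`, numeric(1), "theta")
  theta_v <- vapply(vrs, `[[`, numeric(1), "theta")
  lam_sum <- vapply(crs, `[[`, numeric(1), "lambda_sum")
  results <- data.frame(
    dmu = pm$dmu, year = slice$year[1],
    crs = theta_c, vrs = theta_v,
    se = scale_efficiency(theta_c, pmax(theta_v, theta_c)),
    lambda_sum = lam_sum,
    rts = classify_rts(lam_sum),
    peers = vapply(crs, function(s) paste(s$peers, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  lambda <- do.call(rbind, lapply(crs, `[[`, "lambda"))
  rownames(lambda) <- pm$dmu

  out <- list(results = results,
              lambda = lambda,
              summary = score_summary(results),
              rts_counts = table(factor(results$rts,
                levels = c("constant", "increasing", "decreasing"))))
  if (!is.null(factors)) out$group_means <- size_group_means(results, factors)
  class(out) <- "dea_evaluation"
  out
}

# mean/median/max/min/sd for the three score columns
score_summary <- function(results, cols = c("crs", "vrs", "se")) {
  out <- lapply(cols, function(v) {
    x <- results[[v]]
    data.frame(score = v, mean = mean(x), median = stats::median(x),
               maximum = max(x), minimum = min(x), sd = stats::sd(x))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Score means by hospital size group
#'
#' Joins a score table to size dummies and averages the requested score
#' columns per group. Groups follow the bed-capacity convention: `D1` very
#' large (>= 600 beds), `D2` large (400-599), `D3` medium (200-399), and
#' all-dummies-zero `small` (< 200).
#'
#' @param results data.frame with a `dmu` column and score columns.
#' @param factors data.frame with `dmu`, `D1`, `D2`, `D3`.
#' @param cols score columns to average.
#' @return data.frame of group sizes and per-group score means.
#' @examples
#' size_group_means(load_fixture("scores_2019"), load_fixture("factors_2019"))
#' @export
size_group_means <- function(results, factors, cols = c("crs", "vrs", "se")) {
  cols <- intersect(cols, names(results))
  stopifnot(all(c("dmu", "D1", "D2", "D3") %in% names(factors)),
            "dmu" %in% names(results), length(cols) > 0)
  if (any(factors$D1 + factors$D2 + factors$D3 > 1))
    stop("size dummies are not mutually exclusive", call. = FALSE)
  m <- merge(results, factors[, c("dmu", "D1", "D2", "D3")], by = "dmu")
  grp <- with(m, ifelse(D1 == 1, "very_large",
                 ifelse(D2 == 1, "large",
                 ifelse(D3 == 1, "medium", "small"))))
  grp <- factor(grp, levels = c("very_large", "large", "medium", "small"))
  out <- data.frame(group = levels(grp),
                    n = as.vector(table(grp)))
  for (v in cols) out[[paste0("mean_", v)]] <-
    as.vector(tapply(m[[v]], grp, mean))
  out
}

#' @export
print.dea_evaluation <- function(x, digits = 4, ...) {
  r <- x$results
  cat(sprintf("<dea_evaluation> %d DMUs, year %s\n", nrow(r), r$year[1]))
  s <- x$summary
  cat(sprintf("  mean CRS %.*f | mean VRS %.*f | mean SE %.*f\n",
              digits, s$mean[s$score == "crs"], digits, s$mean[s$score == "vrs"],
              digits, s$mean[s$score == "se"]))
  cat("  returns to scale: ",
      paste(sprintf("%s %d", names(x$rts_counts), x$rts_counts), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
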