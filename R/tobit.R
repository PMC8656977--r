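#' Transform efficiency scores into left-censored inefficiency scores
#'
#' Efficiency scores live in (0, 1] and pile up at 1, so the second-stage
#' regression works on the reciprocal transformation `1/score - 1`: zero
#' for efficient units (the left-censoring mass) and increasing with
#' inefficiency.
#'
#' @param scores numeric vector of Farrell efficiency scores in (0, 1].
#' @param tol tolerance above 1 treated as numerical noise.
#' @return inefficiency scores, `>= 0`, exactly 0 for scores at 1.
#' @examples
#' transform_scores(c(1, 0.5, 0.7252))
#' @export
transform_scores <- function(scores, tol = 1e-8) {
  if (any(scores <= 0) || any(scores > 1 + tol))
    stop("scores must lie in (0, 1]", call. = FALSE)
  pmax(1 / pmin(scores, 1) - 1, 0)
}

# ---- censored-normal likelihood machinery ---------------------------------

# stable inverse Mills ratio phi(z)/Phi(z)
mills <- function(z) exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))

# negative log-likelihood of the left-censored-at-zero normal model,
# par = (beta, log sigma)
tobit_nll <- function(par, X, y, cens) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  sigma <- exp(par[k + 1L])
  mu <- drop(X %*% beta)
  ll <- numeric(length(y))
  ll[!cens] <- stats::dnorm(y[!cens], mu[!cens], sigma, log = TRUE)
  ll[cens] <- stats::pnorm(-mu[cens] / sigma, log.p = TRUE)
  -sum(ll)
}

tobit_nll_grad <- function(par, X, y, cens) {
  k <- ncol(X)
  beta <- par[seq_len(k)]
  sigma <- exp(par[k + 1L])
  mu <- drop(X %*% beta)
  gb <- numeric(k); gs <- 0
  if (any(!cens)) {
    r <- (y[!cens] - mu[!cens]) / sigma
    gb <- gb + drop(crossprod(X[!cens, , drop = FALSE], r / sigma))
    gs <- gs + sum(r^2 - 1)
  }
  if (any(cens)) {
    z <- -mu[cens] / sigma
    lam <- mills(z)
    gb <- gb - drop(crossprod(X[cens, , drop = FALSE], lam / sigma))
    gs <- gs - sum(lam * z)
  }
  -c(gb, gs)
}

# design matrix with leading constant; errors on rank deficiency
tobit_design <- function(data, covariates) {
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("covariate(s) not in data: ", paste(miss, collapse = ", "), call. = FALSE)
  X <- cbind(constant = 1, as.matrix(data[, covariates, drop = FALSE]))
  if (!is.numeric(X)) stop("covariates must be numeric", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

tobit_response <- function(data, response) {
  y <- data[[response]]
  if (is.null(y)) stop("response column '", response, "' not found", call. = FALSE)
  if (any(y < 0)) stop("inefficiency scores must be >= 0", call. = FALSE)
  y
}

#' Pooled Tobit (left-censored at zero) regression
#'
#' Maximum-likelihood fit of the censored normal model: the latent
#' inefficiency is `x'beta + e`, `e ~ N(0, sigma_e^2)`, observed as 0
#' whenever the latent value is non-positive. Optimization runs on
#' `(beta, log sigma)` from a least-squares start plus deterministic
#' perturbations, keeping the best likelihood; standard errors come from
#' the observed information at the optimum.
#'
#' @param data data.frame of observations.
#' @param covariates character vector of covariate column names (the
#'   constant is added automatically and represents the reference group).
#' @param response name of the non-negative inefficiency column
#'   (default `"ineff"`); zeros are the censored observations.
#' @param group optional grouping column name recorded for reporting.
#' @return object of class `tobit_fit`: coefficients, standard errors,
#'   covariance of the coefficients, `sigma_e` (`sigma_u` fixed at 0),
#'   log-likelihood, Wald chi-squared over the non-constant coefficients
#'   with its degrees of freedom, and bookkeeping (`n_obs`, `n_censored`,
#'   `n_groups`, `obs_per_group`).
#' @examples
#' d <- generate_tobit_panel(synthetic_config(n_dmus = 30, n_years = 3,
#'                                            seed = 2, sigma_u = 0))$data
#' fit <- fit_tobit_pooled(d, covariates = c("Z1", "Z3", "Z5"))
#' coef(fit)
#' @export
fit_tobit_pooled <- function(data, covariates, response = "ineff", group = NULL) {
  X <- tobit_design(data, covariates)
  y <- tobit_response(data, response)
  cens <- y <= 0
  if (all(cens)) stop("all observations are censored; model degenerate", call. = FALSE)

  ls <- stats::lm.fit(X, y)
  sigma0 <- max(stats::sd(ls$residuals), 1e-3)
  start0 <- c(ls$coefficients, log(sigma0))
  starts <- list(start0,
                 start0 + c(rep(0, ncol(X)), log(1.5)),
                 c(start0[seq_len(ncol(X))] * 1.2, log(sigma0 * 0.7)))
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, tobit_nll, gr = tobit_nll_grad, X = X, y = y,
                        cens = cens, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$convergence != 0)
    warning("Tobit optimizer did not report convergence (code ",
            best$convergence, ")")
  H <- stats::optimHess(best$par, tobit_nll, gr = tobit_nll_grad,
                        X = X, y = y, cens = cens)
  finish_tobit_fit(best, H, X, y, cens, data, group,
                   method = "pooled", sigma_u = 0, covariates = covariates)
}

# shared assembly of a tobit_fit object; `extra_par` = number of trailing
# log-scale parameters beyond (beta, log sigma_e)
finish_tobit_fit <- function(opt, H, X, y, cens, data, group, method,
                             sigma_u, covariates, nodes = NULL) {
  k <- ncol(X)
  vcov_all <- tryCatch(solve(H), error = function(e) {
    warning("observed information is singular; standard errors unavailable")
    matrix(NA_real_, nrow(H), ncol(H))
  })
  beta <- opt$par[seq_len(k)]
  names(beta) <- colnames(X)
  vc_beta <- vcov_all[seq_len(k), seq_len(k), drop = FALSE]
  dimnames(vc_beta) <- list(names(beta), names(beta))
  se <- sqrt(diag(vc_beta))
  sigma_e <- unname(exp(opt$par[k + 1L]))
  groups <- if (!is.null(group)) data[[group]] else NULL
  fit <- list(coefficients = beta, se = se, vcov = vc_beta,
              sigma_e = sigma_e, sigma_u = sigma_u,
              loglik = -opt$value,
              n_obs = length(y), n_censored = sum(cens),
              n_groups = if (is.null(groups)) NA_integer_ else length(unique(groups)),
              obs_per_group = if (is.null(groups)) NA_real_ else
                mean(table(groups)),
              method = method, covariates = covariates, nodes = nodes,
              convergence = opt$convergence)
  class(fit) <- "tobit_fit"
  w <- wald_test(fit)
  fit$wald_stat <- w$statistic
  fit$wald_df <- w$df
  fit
}

#' @export
coef.tobit_fit <- function(object, ...) object$coefficients

#' @export
logLik.tobit_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) +
              1L + (object$method == "re"), class = "logLik")
}

#' @export
vcov.tobit_fit <- function(object, ...) object$vcov

#' @export
print.tobit_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<tobit_fit> %s, %d obs (%d censored)", x$method, x$n_obs,
              x$n_censored))
  if (!is.na(x$n_groups)) cat(sprintf(", %d groups", x$n_groups))
  cat("\n")
  tab <- data.frame(estimate = round(x$coefficients, digits),
                    se = round(x$se, digits),
                    z = round(x$coefficients / x$se, 2))
  print(tab)
  cat(sprintf("sigma_e %.4f", x$sigma_e))
  if (x$method == "re") cat(sprintf("  sigma_u %.4f", x$sigma_u))
  cat(sprintf("  logLik %.4f  Wald chi2(%d) %.2f\n", x$loglik, x$wald_df,
              x$wald_stat))
  invisible(x)
}

# negative marginal log-likelihood of the random-intercept model,
# par = (beta, log sigma_e, log sigma_u); the group effect is integrated
# out by adaptive Gauss-Hermite quadrature: nodes are recentred at each
# group's posterior mode and rescaled by its curvature (found by a short
# vectorized Newton iteration), which keeps even modest node counts
# accurate when the group posterior is shifted against the prior.
tobit_re_nll <- function(par, X, y, cens, gid, gh) {
  if (any(!is.finite(par))) return(1e10)
  k <- ncol(X)
  beta <- par[seq_len(k)]
  sigma_e <- min(max(exp(par[k + 1L]), 1e-8), 1e8)
  sigma_u <- min(max(exp(par[k + 2L]), 1e-10), 1e8)
  mu <- drop(X %*% beta)
  G <- max(gid)

  # per-observation contributions to the gradient/curvature of
  # h(u) = sum_i log f(y_i | mu_i + u) + log phi(u; sigma_u) at u = uhat
  uhat <- numeric(G)
  for (it in 1:25) {
    m <- mu + uhat[gid]
    g1 <- numeric(length(y)); g2 <- numeric(length(y))
    r <- (y[!cens] - m[!cens]) / sigma_e
    g1[!cens] <- r / sigma_e
    g2[!cens] <- -1 / sigma_e^2
    z <- -m[cens] / sigma_e
    lam <- mills(z)
    g1[cens] <- -lam / sigma_e
    g2[cens] <- -lam * (z + lam) / sigma_e^2
    h1 <- drop(rowsum(g1, gid)) - uhat / sigma_u^2
    h2 <- pmin(drop(rowsum(g2, gid)) - 1 / sigma_u^2, -1e-12)
    step <- h1 / h2
    step[!is.finite(step)] <- 0
    step <- sign(step) * pmin(abs(step), 5 * sigma_u + sigma_e)
    uhat <- uhat - step
    if (max(abs(step)) < 1e-10) break
  }
  tau <- sqrt(-1 / h2)

  # log integrand (including the prior) at the recentred nodes
  lse <- matrix(NA_real_, G, length(gh$nodes))
  for (q in seq_along(gh$nodes)) {
    u_q <- uhat + sqrt(2) * tau * gh$nodes[q]
    m <- mu + u_q[gid]
    l <- numeric(length(y))
    l[!cens] <- stats::dnorm(y[!cens], m[!cens], sigma_e, log = TRUE)
    l[cens] <- stats::pnorm(-m[cens] / sigma_e, log.p = TRUE)
    lse[, q] <- drop(rowsum(l, gid)) +
      stats::dnorm(u_q, 0, sigma_u, log = TRUE) +
      log(gh$weights[q]) + gh$nodes[q]^2
  }
  mx <- apply(lse, 1, max)
  ll <- sum(log(sqrt(2) * tau) + mx + log(rowSums(exp(lse - mx))))
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Random-intercept (panel) Tobit regression
#'
#' Adds a normal group-level intercept `u_g ~ N(0, sigma_u^2)` to the
#' pooled censored model and integrates it out with Gauss-Hermite
#' quadrature, giving the random-effects panel Tobit appropriate for
#' repeated observations per DMU. Starting points include the pooled
#' solution with a near-zero group scale, so the fitted marginal likelihood
#' never falls below the pooled one (up to quadrature error).
#'
#' @inheritParams fit_tobit_pooled
#' @param group grouping column (default `"dmu"`).
#' @param nodes number of Gauss-Hermite quadrature nodes (>= 3, default 12).
#' @param sigma_u `NULL` (default) estimates the group scale; `0` fixes it
#'   at zero, under which the marginal likelihood factorizes and the fit
#'   coincides with the pooled estimator.
#' @return a `tobit_fit` with `method = "re"` and a `sigma_u` estimate.
#' @examples
#' d <- generate_tobit_panel(synthetic_config(n_dmus = 25, n_years = 4,
#'                                            seed = 3))$data
#' fit <- fit_tobit_re(d, covariates = c("Z1", "Z3", "Z5"), nodes = 8)
#' fit$sigma_u
#' @export
fit_tobit_re <- function(data, covariates, response = "ineff", group = "dmu",
                         nodes = 12L, sigma_u = NULL) {
  if (nodes < 3L) stop("quadrature needs at least 3 nodes", call. = FALSE)
  if (!group %in% names(data)) stop("group column '", group, "' not found",
                                    call. = FALSE)
  if (length(unique(data[[group]])) < 2L)
    stop("random-effects fit needs at least 2 groups", call. = FALSE)
  if (!is.null(sigma_u)) {
    if (sigma_u != 0) stop("only sigma_u = 0 can be fixed", call. = FALSE)
    fit <- fit_tobit_pooled(data, covariates, response = response, group = group)
    fit$method <- "re"
    fit$sigma_u <- 0
    fit$nodes <- nodes
    return(fit)
  }
  X <- tobit_design(data, covariates)
  y <- tobit_response(data, response)
  cens <- y <= 0
  if (all(cens)) stop("all observations are censored; model degenerate", call. = FALSE)
  gid <- match(data[[group]], unique(data[[group]]))
  gh <- statmod::gauss.quad(nodes, kind = "hermite")

  pooled <- fit_tobit_pooled(data, covariates, response = response,
                             group = group)
  bp <- pooled$coefficients; sp <- pooled$sigma_e
  starts <- list(c(bp, log(sp), log(sp * 1e-3)),   # pooled limit
                 c(bp, log(sp * 0.9), log(sp * 0.5)),
                 c(bp, log(sp * 0.8), log(sp)))
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, tobit_re_nll, X = X, y = y, cens = cens,
                        gid = gid, gh = gh, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  H <- stats::optimHess(best$par, tobit_re_nll, X = X, y = y, cens = cens,
                        gid = gid, gh = gh)
  finish_tobit_fit(best, H, X, y, cens, data, group, method = "re",
                   sigma_u = unname(exp(best$par[ncol(X) + 2L])),
                   covariates = covariates, nodes = nodes)
}

#' Wald test on a set of coefficients
#'
#' Quadratic form `b' V^-1 b` over the selected coefficients, the usual
#' joint test that they all vanish. By default every non-constant
#' coefficient enters, reproducing the "Wald chi2" a censored-regression
#' routine prints for the whole covariate set.
#'
#' @param fit a `tobit_fit`.
#' @param terms coefficient names (or indices) to test; default all but the
#'   constant. An empty set gives statistic 0 on 0 degrees of freedom.
#' @return list with `statistic`, `df`, and `p_value`.
#' @export
wald_test <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "tobit_fit"))
  cn <- names(fit$coefficients)
  if (is.null(terms)) terms <- setdiff(cn, "constant")
  if (is.numeric(terms)) terms <- cn[terms]
  if (!length(terms)) return(list(statistic = 0, df = 0L, p_value = NA_real_))
  bad <- setdiff(terms, cn)
  if (length(bad)) stop("unknown coefficient(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  b <- fit$coefficients[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  list(statistic = stat, df = length(terms),
       p_value = stats::pchisq(stat, length(terms), lower.tail = FALSE))
}

#' The six packaged candidate covariate sets
#'
#' The default model grid for [compare_models()]: combinations of the
#' activity ratio `Z1`, sole-hospital flag `Z2`, catchment-age structure
#' `Z3`/`Z4`, utilization rates `Z5`-`Z7` and the size dummies `D1`-`D3`.
#'
#' @return named list of character vectors.
#' @export
default_tobit_models <- function() {
  list(m1 = c("Z1", "Z2", "Z3", "Z4", "Z5", "Z6"),
       m2 = c("Z1", "Z2", "Z3", "Z5", "Z6"),
       m3 = c("Z1", "Z3", "D1", "D2", "D3", "Z5", "Z7"),
       m4 = c("Z1", "Z2", "Z3", "D1", "D2", "D3", "Z5", "Z7"),
       m5 = c("Z1", "Z2", "Z3", "Z4", "D1", "D2", "D3", "Z5", "Z7"),
       m6 = c("Z1", "Z2", "Z3", "Z4", "D1", "D2", "D3", "Z5", "Z6"))
}

#' Fit and rank candidate Tobit models
#'
#' Fits every candidate covariate set and ranks the successful fits by
#' their Wald chi-squared statistic (log-likelihood reported alongside).
#' A candidate that fails (for instance through collinear covariates) is
#' kept in the table with its error message; the others are unaffected.
#'
#' @inheritParams fit_tobit_pooled
#' @param models named list of covariate sets; default
#'   [default_tobit_models()].
#' @param method `"pooled"` or `"re"`; `"auto"` (default) picks the
#'   random-intercept fit when any group has repeated observations.
#' @param group grouping column for the random-intercept fit.
#' @param nodes quadrature nodes for the random-intercept fit.
#' @return object of class `tobit_comparison`: `table` (one row per
#'   candidate, ranked, with `wald`, `df`, `loglik`, `error`) and `fits`
#'   (list of `tobit_fit` or `NULL`).
#' @export
compare_models <- function(data, models = default_tobit_models(),
                           response = "ineff", method = c("auto", "pooled", "re"),
                           group = "dmu", nodes = 12L) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (group %in% names(data) &&
                  any(table(data[[group]]) > 1L)) "re" else "pooled"
  }
  if (is.null(names(models)))
    names(models) <- paste0("m", seq_along(models))
  fits <- vector("list", length(models))
  names(fits) <- names(models)
  rows <- lapply(names(models), function(nm) {
    fit <- tryCatch(
      if (method == "re")
        fit_tobit_re(data, models[[nm]], response = response, group = group,
                     nodes = nodes)
      else fit_tobit_pooled(data, models[[nm]], response = response),
      error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(model = nm, k = length(models[[nm]]), wald = NA_real_,
                 df = NA_integer_, loglik = NA_real_,
                 error = conditionMessage(fit), stringsAsFactors = FALSE)
    } else {
      fits[[nm]] <<- fit
      data.frame(model = nm, k = length(models[[nm]]), wald = fit$wald_stat,
                 df = fit$wald_df, loglik = fit$loglik, error = "",
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  if (length(models) > 1L) tab <- tab[order(-tab$wald, na.last = TRUE), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, method = method),
            class = "tobit_comparison")
}

#' @export
print.tobit_comparison <- function(x, ...) {
  cat(sprintf("<tobit_comparison> %d candidate model(s), %s estimator\n",
              nrow(x$table), x$method))
  print(x$table)
  invisible(x)
}

#' Variance inflation factors
#'
#' Multicollinearity screen: each covariate is regressed on the remaining
#' ones (with intercept) and its VIF is `1 / (1 - R^2)`.
#'
#' @param data data.frame holding the covariates.
#' @param covariates character vector of column names to screen.
#' @return data.frame with `covariate` and `vif` (each `>= 1`).
#' @examples
#' vif_report(load_fixture("factors_2019"),
#'            c("Z1", "Z3", "Z5", "Z6"))
#' @export
vif_report <- function(data, covariates) {
  stopifnot(length(covariates) >= 2L)
  X <- as.matrix(data[, covariates, drop = FALSE])
  const <- covariates[apply(X, 2, function(v) stats::var(v) == 0)]
  if (length(const))
    stop("VIF undefined for constant covariate(s): ",
         paste(const, collapse = ", "), call. = FALSE)
  vifs <- vapply(seq_along(covariates), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / (1 - r2)
  }, numeric(1))
  data.frame(covariate = covariates, vif = vifs, stringsAsFactors = FALSE)
}
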