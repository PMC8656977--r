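#' Configuration for the synthetic hospital-panel generator
#'
#' Bundles and validates every knob of the data-generating process. The
#' defaults emulate the shape of the national study panel the packaged
#' fixtures come from: 39 DMUs over 5 years, three inputs and two outputs
#' on hospital scales, roughly 13% of units on the frontier, and an annual
#' frontier improvement of 7%.
#'
#' @param n_dmus number of DMUs (>= 2).
#' @param n_years number of panel years.
#' @param start_year first calendar year.
#' @param seed integer seed; every generator call is fully reproducible.
#' @param input_meanlog,input_sdlog log-normal parameters of the three
#'   frontier input scales (beds, other health workers, physicians).
#' @param frac_efficient fraction of DMUs placed exactly on the frontier.
#' @param eff_shape1,eff_shape2 Beta parameters of the true Farrell scores
#'   of inefficient DMUs (defaults give mean ~0.69, sd ~0.13, matching the
#'   dispersion of the packaged score table).
#' @param drift multiplicative technology improvement per year (> 0);
#'   outputs attainable from given inputs scale by this factor annually.
#' @param rts `"crs"` (linear frontier technology; true scores are exact
#'   DEA scores by construction) or `"vrs"` (concave technology with
#'   scale-dependent productivity).
#' @param theta_time `"constant"` keeps each DMU's true efficiency fixed
#'   across years; `"redraw"` draws it anew each year.
#' @param tech positive 2 x 3 matrix mapping inputs to frontier outputs.
#' @param beta_true named coefficient vector of the censored-regression
#'   DGP (must include `constant`); defaults mirror the packaged
#'   second-stage estimates, which imply ~13% censoring under the
#'   covariate distributions used.
#' @param sigma_e residual scale of the latent inefficiency (> 0).
#' @param sigma_u group (DMU-level) random-intercept scale (>= 0).
#' @param z_time `"vary"` gives covariates mild year-to-year variation;
#'   `"fixed"` holds them at their DMU-level draw.
#' @return a validated list of class `synthetic_config`.
#' @examples
#' synthetic_config(n_dmus = 10, n_years = 2, seed = 42)
#' @export
synthetic_config <- function(n_dmus = 39L, n_years = 5L, start_year = 2015L,
                             seed = 1L,
                             input_meanlog = log(c(290, 300, 90)),
                             input_sdlog = c(0.5, 0.5, 0.5),
                             frac_efficient = 5 / 39,
                             eff_shape1 = 8, eff_shape2 = 3.7,
                             drift = 1.07,
                             rts = c("crs", "vrs"),
                             theta_time = c("constant", "redraw"),
                             tech = rbind(c(12, 10, 40), c(150, 120, 500)),
                             beta_true = c(constant = 0.5857, Z1 = -0.0185,
                                           Z2 = 0.0346, Z3 = 2.4384,
                                           Z4 = -4.1911, D1 = -0.0298,
                                           D2 = -0.1141, D3 = -0.0596,
                                           Z5 = -0.0135, Z6 = -0.0025),
                             sigma_e = 0.15, sigma_u = 0.10,
                             z_time = c("vary", "fixed")) {
  rts <- match.arg(rts)
  theta_time <- match.arg(theta_time)
  z_time <- match.arg(z_time)
  stopifnot(n_dmus >= 2, n_years >= 1, drift > 0,
            frac_efficient >= 0, frac_efficient <= 1,
            sigma_e > 0, sigma_u >= 0,
            length(input_meanlog) == 3, length(input_sdlog) == 3,
            is.matrix(tech), nrow(tech) == 2, ncol(tech) == 3, all(tech > 0),
            "constant" %in% names(beta_true))
  structure(list(n_dmus = as.integer(n_dmus), n_years = as.integer(n_years),
                 start_year = as.integer(start_year), seed = as.integer(seed),
                 input_meanlog = input_meanlog, input_sdlog = input_sdlog,
                 frac_efficient = frac_efficient,
                 eff_shape1 = eff_shape1, eff_shape2 = eff_shape2,
                 drift = drift, rts = rts, theta_time = theta_time,
                 tech = tech, beta_true = beta_true,
                 sigma_e = sigma_e, sigma_u = sigma_u, z_time = z_time),
            class = "synthetic_config")
}

#' Generate a synthetic DMU panel with exact ground truth
#'
#' Builds a hospital panel on a known frontier technology. Efficient DMUs
#' sit exactly on the frontier; each inefficient DMU is the radial input
#' inflation (by `1/theta_true`) of a frontier point constructed inside
#' the cone (CRS) or convex hull (VRS) of the efficient DMUs' input
#' bundles. Under CRS this makes the true Farrell score of every DMU
#' *exactly* its DEA score against the generated sample, which is what
#' turns the generator into an oracle for the LP stage. The frontier
#' technology improves by the configured drift factor each year.
#'
#' @param config a [synthetic_config()].
#' @return list with `panel` (a [dmu_panel()]) and `truth` (data.frame
#'   `dmu`, `year`, `theta_true`, `efficient`).
#' @examples
#' g <- generate_panel(synthetic_config(n_dmus = 6, n_years = 1, seed = 9))
#' g$truth
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_dmus
  n_eff <- max(2L, round(config$frac_efficient * n))
  dmu <- sprintf("H%02d", seq_len(n))
  eff <- c(rep(TRUE, n_eff), rep(FALSE, n - n_eff))
  years <- config$start_year + seq_len(config$n_years) - 1L
  B <- config$tech

  # frontier input bundles of the efficient DMUs
  Xe <- sapply(1:3, function(s)
    rlnorm(n_eff, config$input_meanlog[s], config$input_sdlog[s]))
  Xe <- matrix(Xe, n_eff, 3)

  draw_theta <- function() {
    th <- rep(1, n)
    if (n > n_eff)
      th[!eff] <- pmin(pmax(rbeta(n - n_eff, config$eff_shape1,
                                  config$eff_shape2), 0.05), 0.995)
    th
  }
  theta0 <- draw_theta()

  # frontier point of every DMU: efficient DMUs are their own bundle;
  # inefficient ones combine efficient bundles (plus a free CRS scaling)
  Xf <- matrix(0, n, 3)
  Xf[eff, ] <- Xe
  if (n > n_eff) {
    for (i in which(!eff)) {
      w <- rgamma(n_eff, 1); w <- w / sum(w)
      s <- if (config$rts == "crs") rlnorm(1, 0, 0.35) else 1
      Xf[i, ] <- s * drop(w %*% Xe)
    }
  }
  frontier_outputs <- function(Xf) {
    Y <- t(B %*% t(Xf))
    if (config$rts == "vrs") {
      # concave technology: productivity falls with operating scale
      size <- rowSums(Xf) / mean(rowSums(Xf))
      Y <- Y * size^(-0.2)
    }
    Y
  }

  rows <- NULL; truth <- NULL
  for (k in seq_along(years)) {
    th <- if (config$theta_time == "redraw" && k > 1L) draw_theta() else theta0
    Yf <- frontier_outputs(Xf) * config$drift^(k - 1L)
    X <- Xf / th
    rows <- rbind(rows, data.frame(
      dmu = dmu, year = years[k],
      beds = X[, 1], workers = X[, 2], physicians = X[, 3],
      inpatients = Yf[, 1], outpatients = Yf[, 2],
      stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(dmu = dmu, year = years[k],
                                     theta_true = th, efficient = eff,
                                     stringsAsFactors = FALSE))
  }
  panel <- dmu_panel(rows)
  attr(panel, "seed") <- config$seed
  list(panel = panel, truth = truth)
}

#' Generate censored-regression panel data with known parameters
#'
#' Draws environmental covariates on realistic hospital ranges (activity
#' ratio, sole-hospital flag, catchment age structure, bed utilization
#' rates, mutually exclusive size dummies), builds the latent inefficiency
#' `x'beta + u_group + e`, and censors it from below at zero. The default
#' coefficients reproduce a censoring share near 13% (about 5 efficient
#' DMUs out of 39).
#'
#' @param config a [synthetic_config()]; uses `beta_true`, `sigma_e`,
#'   `sigma_u`, `n_dmus`, `n_years`, `z_time` and `seed`.
#' @return list with `data` (data.frame `dmu`, `year`, covariates,
#'   censored `ineff`) and `truth` (list `beta`, `sigma_e`, `sigma_u`,
#'   `latent`, `censoring_rate`).
#' @examples
#' g <- generate_tobit_panel(synthetic_config(n_dmus = 20, n_years = 5, seed = 4))
#' g$truth$censoring_rate
#' @export
generate_tobit_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)   # independent stream from generate_panel
  n <- config$n_dmus
  years <- config$start_year + seq_len(config$n_years) - 1L
  dmu <- sprintf("H%02d", seq_len(n))

  # DMU-level covariate draws
  base <- data.frame(
    dmu = dmu,
    Z1 = rlnorm(n, log(2.1), 0.35),
    Z2 = rbinom(n, 1, 8 / 39),
    Z3 = rbeta(n, 40, 138),
    Z4 = rbeta(n, 4, 496),
    Z5 = pmax(rnorm(n, 42, 14), 2),
    Z6 = pmax(rnorm(n, 62, 17), 5),
    Z7 = pmax(rnorm(n, 5.7, 1.9), 0.5),
    stringsAsFactors = FALSE)
  size <- sample(c("D1", "D2", "D3", "small"), n, replace = TRUE,
                 prob = c(8, 10, 12, 9) / 39)
  base$D1 <- as.integer(size == "D1")
  base$D2 <- as.integer(size == "D2")
  base$D3 <- as.integer(size == "D3")

  u <- rnorm(n, 0, config$sigma_u)
  beta <- config$beta_true
  covs <- setdiff(names(beta), "constant")

  rows <- NULL
  for (k in seq_along(years)) {
    d <- base
    if (config$z_time == "vary" && k > 1L) {
      for (v in c("Z1", "Z3", "Z4", "Z5", "Z6", "Z7"))
        d[[v]] <- d[[v]] * exp(rnorm(n, 0, 0.05))
    }
    d$year <- years[k]
    rows <- rbind(rows, d)
  }
  miss <- setdiff(covs, names(rows))
  if (length(miss))
    stop("beta_true names covariates the generator does not draw: ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- cbind(constant = 1, as.matrix(rows[, covs, drop = FALSE]))
  latent <- drop(X %*% beta[c("constant", covs)]) +
    u[match(rows$dmu, dmu)] + rnorm(nrow(rows), 0, config$sigma_e)
  rows$ineff <- pmax(latent, 0)
  rows <- rows[, c("dmu", "year", covs, setdiff(names(base)[-1], covs), "ineff")]
  rownames(rows) <- NULL
  list(data = rows,
       truth = list(beta = beta, sigma_e = config$sigma_e,
                    sigma_u = config$sigma_u, latent = latent,
                    censoring_rate = mean(latent <= 0)))
}
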