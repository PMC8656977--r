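#' Cross-period Farrell input distance
#'
#' Efficiency of one DMU's data from period `data_year` measured against
#' the frontier built from all DMUs of `frontier_year`. Within-period calls
#' (`data_year == frontier_year`) reproduce the ordinary score; genuine
#' cross-period values may exceed one when the evaluated bundle lies
#' outside the reference technology.
#'
#' @param panel a [dmu_panel()].
#' @param dmu DMU label.
#' @param data_year year the evaluated input/output bundle is taken from.
#' @param frontier_year year whose DMUs form the reference technology.
#' @param rts `"crs"` (the Malmquist convention) or `"vrs"`.
#' @return the distance value (unclipped Farrell efficiency).
#' @examples
#' p <- generate_panel(synthetic_config(n_dmus = 8, n_years = 2, seed = 1))$panel
#' cross_period_distance(p, "H03", data_year = 2016, frontier_year = 2015)
#' @export
cross_period_distance <- function(panel, dmu, data_year, frontier_year,
                                  rts = c("crs", "vrs")) {
  rts <- match.arg(rts)
  ref <- panel_slice(panel, frontier_year)
  dat <- panel_slice(panel, data_year)
  j <- match(dmu, dat$dmu)
  if (is.na(j)) stop("DMU '", dmu, "' absent from year ", data_year, call. = FALSE)
  pm <- panel_matrices(ref)
  tgt <- panel_matrices(dat)
  sol <- tryCatch(
    dea_lp(pm$X, pm$Y, tgt$X[j, ], tgt$Y[j, ], vrs = (rts == "vrs")),
    error = function(e) stop("cross-period LP failed for DMU ", dmu,
                             " (data ", data_year, ", frontier ", frontier_year,
                             "): ", conditionMessage(e), call. = FALSE))
  sol$theta
}

#' Malmquist productivity index from four distances
#'
#' Geometric mean of the productivity ratios measured against the two
#' adjacent frontiers. Arguments follow the `d_<frontier>_<data>` naming:
#' `d_t_t1` is period-(t+1) data against the period-t frontier.
#'
#' @param d_t_t,d_t_t1,d_t1_t,d_t1_t1 Farrell distances (all positive).
#' @return the index; values above one mean productivity growth.
#' @examples
#' malmquist_index(0.8, 0.9, 0.7, 0.85)
#' @export
malmquist_index <- function(d_t_t, d_t_t1, d_t1_t, d_t1_t1) {
  check_positive_distances(d_t_t, d_t_t1, d_t1_t, d_t1_t1)
  sqrt((d_t_t1 / d_t_t) * (d_t1_t1 / d_t1_t))
}

#' Efficiency change (catch-up) component
#'
#' Ratio of the own-period scores in the two periods.
#'
#' @param d_t_t,d_t1_t1 own-period Farrell scores.
#' @return efficiency-change factor.
#' @export
efficiency_change <- function(d_t_t, d_t1_t1) {
  check_positive_distances(d_t_t, d_t1_t1)
  d_t1_t1 / d_t_t
}

#' Technological change (frontier shift) component
#'
#' Geometric mean of the shifts of the frontier measured at the two data
#' points.
#'
#' @inheritParams malmquist_index
#' @return frontier-shift factor; the index equals efficiency change times
#'   this factor.
#' @export
technological_change <- function(d_t_t, d_t_t1, d_t1_t, d_t1_t1) {
  check_positive_distances(d_t_t, d_t_t1, d_t1_t, d_t1_t1)
  sqrt((d_t_t1 / d_t1_t1) * (d_t_t / d_t1_t))
}

#' Scale-efficiency change component
#'
#' Efficiency change splits into a pure (VRS-based) component and a scale
#' component; the scale component is their ratio.
#'
#' @param ech CRS efficiency change.
#' @param pech pure (VRS) efficiency change.
#' @return scale-efficiency change, `ech / pech`.
#' @export
scale_efficiency_change <- function(ech, pech) {
  check_positive_distances(ech, pech)
  ech / pech
}

check_positive_distances <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("distance values must be positive and finite", call. = FALSE)
  invisible(TRUE)
}

#' Adjacent-period Malmquist analysis of a balanced panel
#'
#' For every adjacent year pair, computes the four CRS cross-period
#' distances per DMU, the productivity index and its decomposition into
#' efficiency change (further split into pure and scale components via
#' within-period VRS scores) and technological change. Whole-period per-DMU
#' values and per-pair cross-DMU averages are geometric means, consistent
#' with a multiplicative index (arithmetic averaging is available for
#' comparison).
#'
#' @param panel a [dmu_panel()]; must be balanced over `years`.
#' @param years ordered years to chain; default all years present.
#' @param average `"geometric"` (default) or `"arithmetic"` for the summary
#'   rows.
#' @return object of class `malmquist_result`: list with `records` (one row
#'   per DMU and adjacent pair: distances and `tfpch`, `ech`, `tech`,
#'   `pech`, `sech`), `dmu_summary` (whole-period per DMU), `pair_summary`
#'   (per pair across DMUs) and `overall` (one row).
#' @examples
#' p <- generate_panel(synthetic_config(n_dmus = 8, n_years = 3, seed = 1))$panel
#' m <- run_malmquist(p)
#' head(m$records)
#' @export
run_malmquist <- function(panel, years = NULL,
                          average = c("geometric", "arithmetic")) {
  average <- match.arg(average)
  stopifnot(inherits(panel, "dmu_panel"))
  if (is.null(years)) years <- sort(unique(panel$year))
  years <- as.integer(years)
  if (length(years) < 2L) stop("need at least two years", call. = FALSE)
  dmus <- sort(unique(panel$dmu[panel$year %in% years]))
  missing <- unlist(lapply(dmus, function(d) {
    miss <- setdiff(years, panel$year[panel$dmu == d])
    if (length(miss)) sprintf("(%s, %d)", d, miss) else character(0)
  }))
  if (length(missing))
    stop("unbalanced panel; missing ", paste(missing, collapse = ", "),
         call. = FALSE)

  # within-period CRS and VRS scores for every year (unclipped not needed:
  # own-period targets are in their own reference set)
  within <- lapply(years, function(y) {
    slice <- panel_slice(panel, y)
    pm <- panel_matrices(slice)
    idx <- match(dmus, pm$dmu)
    crs <- vapply(idx, function(j) dea_lp(pm$X, pm$Y, pm$X[j, ], pm$Y[j, ])$theta,
                  numeric(1))
    vrs <- vapply(idx, function(j) dea_lp(pm$X, pm$Y, pm$X[j, ], pm$Y[j, ],
                                          vrs = TRUE)$theta, numeric(1))
    list(crs = pmin(crs, 1), vrs = pmin(vrs, 1))
  })
  names(within) <- as.character(years)

  records <- NULL
  for (k in seq_len(length(years) - 1L)) {
    t0 <- years[k]; t1 <- years[k + 1L]
    d_t_t   <- within[[as.character(t0)]]$crs
    d_t1_t1 <- within[[as.character(t1)]]$crs
    d_t_t1 <- vapply(dmus, function(d)
      cross_period_distance(panel, d, data_year = t1, frontier_year = t0),
      numeric(1))
    d_t1_t <- vapply(dmus, function(d)
      cross_period_distance(panel, d, data_year = t0, frontier_year = t1),
      numeric(1))
    ech <- efficiency_change(d_t_t, d_t1_t1)
    tech <- technological_change(d_t_t, d_t_t1, d_t1_t, d_t1_t1)
    pech <- within[[as.character(t1)]]$vrs / within[[as.character(t0)]]$vrs
    records <- rbind(records, data.frame(
      dmu = dmus, from = t0, to = t1,
      d_t_t = d_t_t, d_t_t1 = d_t_t1, d_t1_t = d_t1_t, d_t1_t1 = d_t1_t1,
      tfpch = malmquist_index(d_t_t, d_t_t1, d_t1_t, d_t1_t1),
      ech = ech, tech = tech, pech = pech,
      sech = scale_efficiency_change(ech, pech),
      stringsAsFactors = FALSE))
  }
  rownames(records) <- NULL

  avg <- if (average == "geometric") function(x) exp(mean(log(x))) else mean
  idx_cols <- c("tfpch", "ech", "tech", "pech", "sech")
  dmu_summary <- do.call(rbind, lapply(split(records, records$dmu), function(d)
    data.frame(dmu = d$dmu[1],
               as.list(vapply(idx_cols, function(v) avg(d[[v]]), numeric(1))))))
  rownames(dmu_summary) <- NULL
  pair_summary <- do.call(rbind, lapply(
    split(records, paste(records$from, records$to, sep = "-")), function(d)
      data.frame(pair = paste(d$from[1], d$to[1], sep = "-"),
                 as.list(vapply(idx_cols, function(v) avg(d[[v]]), numeric(1))))))
  rownames(pair_summary) <- NULL
  overall <- data.frame(as.list(vapply(idx_cols, function(v) avg(records[[v]]),
                                       numeric(1))))
  out <- list(records = records, dmu_summary = dmu_summary,
              pair_summary = pair_summary, overall = overall,
              years = years, average = average)
  class(out) <- "malmquist_result"
  out
}

#' @export
print.malmquist_result <- function(x, digits = 3, ...) {
  cat(sprintf("<malmquist_result> %d DMUs, years %d-%d (%s averages)\n",
              length(unique(x$records$dmu)), min(x$years), max(x$years),
              x$average))
  ov <- round(x$overall, digits)
  cat(sprintf("  overall: tfpch %.3f = ech %.3f x tech %.3f (pech %.3f, sech %.3f)\n",
              ov$tfpch, ov$ech, ov$tech, ov$pech, ov$sech))
  invisible(x)
}
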