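#' Format an evaluation as a publication-style score table
#'
#' Rounds a [dea_evaluate()] result to the conventional print precision
#' (4 decimals for scores, 3 for the intensity-weight sum) and appends the
#' summary rows. Computation everywhere else keeps full precision; this is
#' purely a formatting layer.
#'
#' @param evaluation a `dea_evaluation`.
#' @param digits decimals for the score columns.
#' @return data.frame ready for `write.csv`.
#' @export
format_score_table <- function(evaluation, digits = 4) {
  stopifnot(inherits(evaluation, "dea_evaluation"))
  r <- evaluation$results
  body <- data.frame(dmu = r$dmu,
                     crs = round(r$crs, digits),
                     vrs = round(r$vrs, digits),
                     se = round(r$se, digits),
                     lambda_sum = round(r$lambda_sum, 3),
                     rts = r$rts, peers = r$peers,
                     stringsAsFactors = FALSE)
  s <- evaluation$summary
  stat_rows <- data.frame(
    dmu = c("Mean", "Median", "Maximum", "Minimum", "Standard Deviation"),
    crs = round(c(s$mean[1], s$median[1], s$maximum[1], s$minimum[1], s$sd[1]), digits),
    vrs = round(c(s$mean[2], s$median[2], s$maximum[2], s$minimum[2], s$sd[2]), digits),
    se = round(c(s$mean[3], s$median[3], s$maximum[3], s$minimum[3], s$sd[3]), digits),
    lambda_sum = NA, rts = "", peers = "", stringsAsFactors = FALSE)
  rbind(body, stat_rows)
}

#' Format a Malmquist analysis as a publication-style table
#'
#' Per-DMU whole-period decomposition rows (3 decimals) followed by the
#' adjacent-pair and overall average rows.
#'
#' @param malmquist a `malmquist_result` from [run_malmquist()].
#' @param digits decimals for the index columns.
#' @return data.frame keyed by `unit`.
#' @export
format_malmquist_table <- function(malmquist, digits = 3) {
  stopifnot(inherits(malmquist, "malmquist_result"))
  cols <- c("tfpch", "tech", "ech", "pech", "sech")
  d <- malmquist$dmu_summary
  p <- malmquist$pair_summary
  o <- malmquist$overall
  out <- rbind(
    data.frame(unit = d$dmu, round(d[, cols], digits)),
    data.frame(unit = p$pair, round(p[, cols], digits)),
    data.frame(unit = sprintf("%d-%d", min(malmquist$years), max(malmquist$years)),
               round(o[, cols], digits)))
  rownames(out) <- NULL
  out
}
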