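#' Construct a DMU panel
#'
#' Builds and validates the long-format hospital-year table every other
#' stage consumes: one row per decision-making unit (DMU) and year, with
#' strictly positive inputs and non-negative outputs (at least one output
#' per row must be positive).
#'
#' @param data data.frame with one row per DMU-year.
#' @param id name of the DMU label column (default `"dmu"`).
#' @param year name of the integer year column (default `"year"`).
#' @param inputs character vector naming the input columns, in a fixed
#'   order (conventionally beds, health workers without physicians,
#'   physicians).
#' @param outputs character vector naming the output columns (conventionally
#'   case-mix-weighted inpatient episodes, outpatient episodes).
#'
#' @return A `dmu_panel`: a data.frame with standardized `dmu` and `year`
#'   columns followed by the input and output columns, carrying `inputs` and
#'   `outputs` attributes.
#' @examples
#' d <- data.frame(dmu = c("H01", "H02"), year = 2019,
#'                 beds = c(300, 500), staff = c(400, 700), phys = c(90, 150),
#'                 inpatient = c(9000, 14000), outpatient = c(1.4e5, 2.1e5))
#' p <- dmu_panel(d, inputs = c("beds", "staff", "phys"),
#'                outputs = c("inpatient", "outpatient"))
#' @export
dmu_panel <- function(data, id = "dmu", year = "year",
                      inputs = c("beds", "workers", "physicians"),
                      outputs = c("inpatients", "outpatients")) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(id, year, inputs, outputs), names(data))
  if (length(missing_cols)) {
    stop("panel configuration error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(dmu = as.character(data[[id]]),
                    year = as.integer(data[[year]]),
                    data[, c(inputs, outputs), drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL

  for (v in c(inputs, outputs)) {
    if (!is.numeric(out[[v]])) stop("column '", v, "' is not numeric", call. = FALSE)
    if (anyNA(out[[v]])) stop("column '", v, "' contains missing values", call. = FALSE)
  }
  bad <- which(sapply(seq_len(nrow(out)), function(i)
    any(unlist(out[i, inputs]) <= 0)))
  if (length(bad)) {
    msg <- vapply(bad, function(i) {
      cols <- inputs[unlist(out[i, inputs]) <= 0]
      sprintf("(%s, %d, %s)", out$dmu[i], out$year[i], paste(cols, collapse = "/"))
    }, character(1))
    stop("non-positive input value(s) at ", paste(msg, collapse = "; "), call. = FALSE)
  }
  bad_y <- which(sapply(seq_len(nrow(out)), function(i)
    all(unlist(out[i, outputs]) <= 0) || any(unlist(out[i, outputs]) < 0)))
  if (length(bad_y)) {
    stop("invalid outputs (negative, or all zero) for ",
         paste(sprintf("(%s, %d)", out$dmu[bad_y], out$year[bad_y]), collapse = "; "),
         call. = FALSE)
  }
  if (anyDuplicated(out[, c("dmu", "year")])) {
    dup <- out[duplicated(out[, c("dmu", "year")]), c("dmu", "year")]
    stop("duplicate (dmu, year) pair(s): ",
         paste(sprintf("(%s, %d)", dup$dmu, dup$year), collapse = "; "), call. = FALSE)
  }

  attr(out, "inputs") <- inputs
  attr(out, "outputs") <- outputs
  class(out) <- c("dmu_panel", "data.frame")
  out
}

#' @export
print.dmu_panel <- function(x, ...) {
  cat(sprintf("<dmu_panel> %d DMUs x %d year(s); %d input(s), %d output(s)\n",
              length(unique(x$dmu)), length(unique(x$year)),
              length(attr(x, "inputs")), length(attr(x, "outputs"))))
  print(as.data.frame(utils::head(x, 10)))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

panel_inputs <- function(panel) attr(panel, "inputs")
panel_outputs <- function(panel) attr(panel, "outputs")

#' Extract one year of a panel
#'
#' @param panel a [dmu_panel()].
#' @param year calendar year to keep; `NULL` keeps everything (valid only if
#'   the panel holds a single year).
#' @return a `dmu_panel` restricted to the requested year.
#' @export
panel_slice <- function(panel, year = NULL) {
  stopifnot(inherits(panel, "dmu_panel"))
  if (is.null(year)) {
    if (length(unique(panel$year)) > 1L)
      stop("panel spans several years; pass `year`", call. = FALSE)
    return(panel)
  }
  if (!year %in% panel$year) stop("year ", year, " not present in panel", call. = FALSE)
  out <- panel[panel$year == year, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "inputs") <- panel_inputs(panel)
  attr(out, "outputs") <- panel_outputs(panel)
  class(out) <- class(panel)
  out
}

# input/output matrices of a single-year slice, DMUs in row order
panel_matrices <- function(slice) {
  list(X = as.matrix(slice[, panel_inputs(slice), drop = FALSE]),
       Y = as.matrix(slice[, panel_outputs(slice), drop = FALSE]),
       dmu = slice$dmu)
}

#' Read a DMU panel from CSV
#'
#' Thin wrapper around [utils::read.csv()] plus [dmu_panel()] validation, so
#' arbitrary column headers can be mapped onto the panel schema.
#'
#' @inheritParams dmu_panel
#' @param path CSV file with a header row.
#' @return a validated [dmu_panel()].
#' @export
read_dmu_panel <- function(path, id = "dmu", year = "year",
                           inputs = c("beds", "workers", "physicians"),
                           outputs = c("inpatients", "outpatients")) {
  dmu_panel(utils::read.csv(path, check.names = FALSE),
            id = id, year = year, inputs = inputs, outputs = outputs)
}

#' Write a DMU panel to CSV
#'
#' @param panel a [dmu_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dmu_panel <- function(panel, path) {
  stopifnot(inherits(panel, "dmu_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Descriptive statistics of panel variables
#'
#' Mean, median, maximum, minimum and standard deviation of every input and
#' output column for one year of the panel.
#'
#' @param panel a [dmu_panel()].
#' @param year year to summarize; may be `NULL` for single-year panels.
#' @param sd_method `"sample"` (n-1 denominator, the default) or
#'   `"population"` (n denominator).
#' @return data.frame with one row per variable.
#' @examples
#' p <- generate_panel(synthetic_config(n_dmus = 10, n_years = 1, seed = 1))$panel
#' summarize_panel(p)
#' @export
summarize_panel <- function(panel, year = NULL, sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  slice <- panel_slice(panel, year)
  if (nrow(slice) == 0L) stop("empty panel slice", call. = FALSE)
  vars <- c(panel_inputs(slice), panel_outputs(slice))
  res <- lapply(vars, function(v) {
    x <- slice[[v]]
    s <- if (length(x) < 2L) {
      if (sd_method == "population") 0 else NA_real_
    } else if (sd_method == "sample") stats::sd(x) else {
      sqrt(mean((x - mean(x))^2))
    }
    data.frame(variable = v, mean = mean(x), median = stats::median(x),
               maximum = max(x), minimum = min(x), sd = s)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
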