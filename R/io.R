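#' Read a delimited age-rate table
#'
#' Accepts comma-delimited files (or tab-delimited, auto-detected from a
#' `.tsv` extension), UTF-8, `.` decimal, with a header row and optional
#' `#`-prefixed comment lines. Comments of the form `# key: value` are
#' collected as metadata (a `label` key becomes the series label). Columns:
#' either `age` or the pair `age_low`,`age_high`, plus `rate` and an
#' optional `population`. Malformed rows raise errors naming the offending
#' file line.
#'
#' @param path file path.
#' @return an [age_rate_series()]; metadata is attached as the
#'   `"metadata"` attribute.
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  meta_raw <- sub("^\\s*#\\s*", "", lines[is_comment])
  kv <- regmatches(meta_raw, regexec("^([^:]+):\\s*(.*)$", meta_raw))
  meta <- list()
  for (m in kv) if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  data_lines <- which(!is_comment & !is_blank)
  if (length(data_lines) < 2) stop("no data rows in ", path)
  tab <- utils::read.table(text = lines[data_lines], sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  line_of <- data_lines[-1]  # file line numbers of the data rows
  has_interval <- all(c("age_low", "age_high") %in% names(tab))
  if (!has_interval && !"age" %in% names(tab))
    stop("missing column: need 'age' or 'age_low'+'age_high' in ", path)
  if (!"rate" %in% names(tab)) stop("missing column 'rate' in ", path)
  check_num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric '", col, "' at line ", line_of[bad[1]], " of ", path)
    v
  }
  rate <- check_num("rate")
  bad <- which(rate < 0)
  if (length(bad))
    stop("negative rate at line ", line_of[bad[1]], " of ", path)
  ages <- if (has_interval) (check_num("age_low") + check_num("age_high")) / 2
          else check_num("age")
  bad <- which(diff(ages) <= 0)
  if (length(bad))
    stop("ages not strictly increasing at line ", line_of[bad[1] + 1],
         " of ", path)
  pop <- if ("population" %in% names(tab)) check_num("population") else NULL
  s <- if (has_interval)
    age_rate_series(age_low = check_num("age_low"),
                    age_high = check_num("age_high"), rates = rate,
                    population = pop, label = meta$label %||% "")
  else
    age_rate_series(ages = ages, rates = rate, population = pop,
                    label = meta$label %||% "")
  attr(s, "metadata") <- meta
  s
}

#' Write an age-rate series as a delimited table
#'
#' Inverse of [read_rate_table()]: `#` metadata header (label, units) then
#' the data columns. Tab-delimited when the path ends in `.tsv`.
#'
#' @param series an [age_rate_series()].
#' @param path output path.
#' @param units unit note recorded in the metadata header.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(series, path,
                             units = "deaths per 100,000 per year") {
  if (!is_age_rate_series(series)) stop("series must be an age_rate_series")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nzchar(series_label(series)))
    writeLines(paste("# label:", series_label(series)), con)
  writeLines(paste("# units:", units), con)
  interval <- !all(is.na(series$age_low))
  cols <- if (interval) c("age_low", "age_high", "rate") else c("age", "rate")
  if (!is.null(series$population)) cols <- c(cols, "population")
  utils::write.table(as.data.frame(series)[cols], con, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit result (or forecast) as a JSON report
#'
#' Versioned schema `tbm-report/1`. Numeric fields are serialized at full
#' precision so that a write/read round trip reproduces them bit-exactly.
#'
#' @param result a `"tbm_fit"`, `"tbm_forecast"` or `"tbm_prediction_report"`.
#' @param path output path.
#' @param year optional calendar year tag (stored for [parameter_trajectory()]
#'   use; a forecast's own year wins).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(result, path, year = NULL) {
  kind <- if (inherits(result, "tbm_fit")) "fit"
          else if (inherits(result, "tbm_forecast")) "forecast"
          else if (inherits(result, "tbm_prediction_report")) "prediction"
          else stop("unsupported result type")
  nm <- c("K", "theta", "a", "t_m", "d0")
  doc <- list(
    schema = "tbm-report/1",
    kind = kind,
    year = if (kind == "forecast") result$year else year,
    label = result$label %||% NULL,
    parameters = as.list(unlist(result$params[nm])),
    exponent = result$params$n,
    std_errors = as.list(result$std_errors %||%
                           stats::setNames(rep(NA_real_, 5), nm)),
    fixed = as.list(result$fixed %||% character()),
    critical_age = result$critical_age %||% NA_real_,
    critical_age_se = result$critical_age_se %||% NA_real_,
    free_critical_age = result$free_critical_age %||% FALSE,
    covariance = if (!is.null(result$covariance))
      list(names = rownames(result$covariance),
           matrix = unclass(result$covariance)) else NULL,
    gof = list(chi2_origin = result$chi2_origin %||% NA_real_,
               chi2_conventional =
                 as.numeric(result$chi2_conventional %||% NA_real_),
               n_excluded = attr(result$chi2_conventional, "n_excluded") %||%
                 result$n_excluded %||% NA_integer_,
               dof = result$dof %||% NA_integer_,
               p_value = result$p_value %||% NA_real_),
    n_points = result$n_points %||% NA_integer_,
    iterations = result$iterations %||% NA_integer_,
    converged = result$converged %||% NA)
  # I(17) significant digits keeps doubles bit-exact across a round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON fit report
#'
#' @param path a file written by [write_fit_report()].
#' @return a list of class `"tbm_report"` mirroring the report schema, with
#'   `params` reassembled as a [tbm_params()] object.
#' @export
read_fit_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$schema, "tbm-report/1"))
    stop("not a tbm-report/1 document: ", path)
  pr <- doc$parameters
  doc$params <- tbm_params(pr$K, pr$theta, pr$a, pr$t_m, pr$d0, doc$exponent)
  se <- doc$std_errors
  se[vapply(se, is.null, logical(1))] <- NA_real_
  doc$std_errors <- unlist(se)
  doc$fixed <- unlist(doc$fixed) %||% character()
  doc$year <- if (is.null(doc$year)) NULL else as.numeric(doc$year)
  if (!is.null(doc$covariance$matrix)) {
    cn <- unlist(doc$covariance$names)
    doc$covariance <- matrix(unlist(doc$covariance$matrix), nrow = length(cn),
                             byrow = TRUE, dimnames = list(cn, cn))
  } else {
    doc$covariance <- NULL
  }
  doc$critical_age <- as.numeric(doc$critical_age %||% NA_real_)
  doc$critical_age_se <- as.numeric(doc$critical_age_se %||% NA_real_)
  doc$gof <- lapply(doc$gof, function(v) as.numeric(v %||% NA_real_))
  doc$gof$dof <- as.integer(doc$gof$dof)
  structure(doc, class = "tbm_report")
}

#' Export a banded curve as CSV
#'
#' Columns `age`, `central`, `lower`, `upper` and, when an observed series
#' is supplied, `observed`.
#'
#' @param band a [predict_curve()] result.
#' @param path output path.
#' @param observed optional [age_rate_series()] on the same grid.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(band, path, observed = NULL) {
  if (!inherits(band, "tbm_band")) stop("band must be a tbm_band")
  out <- as.data.frame(band)
  if (!is.null(observed)) {
    if (!isTRUE(all.equal(observed$age, band$age)))
      stop("observed series grid does not match the band grid")
    out$observed <- observed$rate
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
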