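#' One subject's longitudinal biomarker series
#'
#' A `patient_series` holds a subject identifier, strictly increasing visit
#' times (days) and the biomarker values measured at those visits. At least
#' two visits are required: with fewer, mono- and bi-phasic trajectories are
#' indistinguishable and no change point is admissible.
#'
#' @param patient_id identifier (coerced to character).
#' @param times numeric vector of visit days, strictly increasing, finite.
#' @param values numeric vector of biomarker measurements, same length.
#' @return An object of class `patient_series`.
#' @examples
#' patient_series("p1", c(0, 21, 42), c(90, 85, 81))
#' @export
patient_series <- function(patient_id, times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (length(times) < 2L)
    stop("invalid series for patient ", patient_id,
         ": at least 2 observations are required")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("invalid series for patient ", patient_id,
         ": times and values must be finite")
  if (any(diff(times) <= 0))
    stop("invalid series for patient ", patient_id,
         ": times must be strictly increasing")
  structure(list(patient_id = as.character(patient_id),
                 times = times, values = values),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient_series> %s: %d visits, t in [%g, %g]\n",
              x$patient_id, length(x$times), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' A cohort of patient series
#'
#' @param patients list of [patient_series] objects.
#' @return An object of class `cohort` (a list of series with a `t_max`
#'   attribute holding the maximum follow-up time over all patients).
#' @examples
#' cohort(list(patient_series("a", c(0, 21), c(90, 85))))
#' @export
cohort <- function(patients) {
  if (length(patients) < 1L) stop("a cohort needs at least one patient")
  ok <- vapply(patients, inherits, logical(1), "patient_series")
  if (!all(ok)) stop("all elements must be patient_series objects")
  tmax <- max(vapply(patients, function(p) p$times[length(p$times)],
                     numeric(1)))
  structure(patients, t_max = tmax, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  m <- vapply(x, function(p) length(p$times), integer(1))
  cat(sprintf("<cohort> %d patients, %d-%d visits each, T_max = %g days\n",
              length(x), min(m), max(m), t_max(x)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param x a [cohort].
#' @return Integer count.
#' @export
n_patients <- function(x) length(x)

#' Maximum follow-up time of a cohort
#' @param x a [cohort].
#' @return The latest visit time (days) over all patients.
#' @export
t_max <- function(x) attr(x, "t_max")

#' Read a long-format longitudinal table into a cohort
#'
#' Expects delimited text (comma or tab, sniffed from the header line) with a
#' header and one row per observation. Rows are grouped by patient and sorted
#' by time; patients with fewer than two usable visits are dropped with a
#' warning.
#'
#' @param path file path.
#' @param column_map named character vector remapping the expected column
#'   names; defaults to `c(patient_id = "patient_id", time = "time",
#'   value = "value")`.
#' @return A [cohort].
#' @export
read_long_table <- function(path,
                            column_map = c(patient_id = "patient_id",
                                           time = "time", value = "value")) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- column_map[c("patient_id", "time", "value")]
  missing_cols <- setdiff(unname(need), names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  id <- as.character(df[[need[["patient_id"]]]])
  tm <- df[[need[["time"]]]]
  vl <- df[[need[["value"]]]]
  if (!is.numeric(tm) || !is.numeric(vl)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tm))) |
                   !is.finite(suppressWarnings(as.numeric(vl))))
    stop("non-numeric time/value entries at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  dup <- duplicated(paste(id, tm))
  if (any(dup))
    stop("duplicate (patient, time) rows at row(s): ",
         paste(which(dup), collapse = ", "))
  series <- list()
  for (pid in unique(id)) {
    sel <- id == pid
    o <- order(tm[sel])
    if (sum(sel) < 2L) {
      warning("dropping patient ", pid, ": fewer than 2 observations")
      next
    }
    series[[length(series) + 1L]] <-
      patient_series(pid, tm[sel][o], vl[sel][o])
  }
  if (length(series) == 0L) stop("no usable patients in ", path)
  cohort(series)
}

#' Write a cohort as a long-format delimited table
#'
#' @param x a [cohort].
#' @param path output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  # 17 significant digits so a write/read round trip is bitwise exact
  df <- do.call(rbind, lapply(x, function(p)
    data.frame(patient_id = p$patient_id,
               time = sprintf("%.17g", p$times),
               value = sprintf("%.17g", p$values),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
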