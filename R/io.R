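# Plain-text readers/writers for the pipeline's stage artifacts: cohort and
# risk tables as CSV, critical-velocity curves as CSV with the +Inf sentinel
# serialized as the literal "inf", simulation traces as JSONL.

#' Write / read a cohort table as CSV
#'
#' One row per subject with the fixed header `subject_id, sex, ethnicity, age,
#' weight, height, bmi, tstt, t_score, abmd, frax_hfp`.
#'
#' @param cohort Cohort data.frame from [generate_cohort()].
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("subject_id", "sex", "ethnicity", "age", "weight", "height",
            "bmi", "tstt", "t_score", "abmd", "frax_hfp")
  stopifnot(all(cols %in% names(cohort)))
  utils::write.csv(cohort[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a critical-velocity curve as CSV
#'
#' Columns `fall_angle, v_crit, protector`; the `+Inf` no-fracture sentinel is
#' written as the literal string `inf`.
#'
#' @param curve A `cv_curve`.
#' @param path File path.
#' @return `write_curve_csv` returns `path` invisibly; `read_curve_csv` the
#'   `cv_curve`.
#' @export
write_curve_csv <- function(curve, path) {
  out <- data.frame(
    fall_angle = curve$fall_angle,
    v_crit = ifelse(is.infinite(curve$v_crit), "inf",
                    format(curve$v_crit, digits = 10)),
    protector = isTRUE(attr(curve, "protector"))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  v <- ifelse(trimws(raw$v_crit) == "inf", Inf, suppressWarnings(as.numeric(raw$v_crit)))
  structure(
    data.frame(fall_angle = raw$fall_angle, v_crit = v),
    protector = isTRUE(raw$protector[1]),
    class = c("cv_curve", "data.frame")
  )
}

#' Write / read per-subject risk estimates as CSV
#'
#' Columns `subject_id, p_fx, p_fx_hp, rr`; an undefined RR (zero baseline) is
#' written as an empty field.
#'
#' @param risks Data.frame with those columns.
#' @param path File path.
#' @return `write_risk_csv` returns `path` invisibly; `read_risk_csv` the
#'   data.frame with `NA` for undefined RRs.
#' @export
write_risk_csv <- function(risks, path) {
  out <- risks[, c("subject_id", "p_fx", "p_fx_hp", "rr")]
  out$rr <- ifelse(is.na(out$rr), "", format(out$rr, digits = 10))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_risk_csv
#' @export
read_risk_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$rr <- suppressWarnings(as.numeric(raw$rr))
  raw
}

#' Write / read fall-simulation records as JSON lines
#'
#' One JSON object per line with the record fields (`fall_angle`,
#' `impact_velocity`, `fracture_length`, `protector`, `fractured`, plus any
#' extra columns such as `iteration`).
#'
#' @param records Data.frame of fall-simulation records.
#' @param path File path.
#' @return `write_records_jsonl` returns `path` invisibly;
#'   `read_records_jsonl` the data.frame.
#' @export
write_records_jsonl <- function(records, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(jsonlite::toJSON(as.list(records[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_records_jsonl
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
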