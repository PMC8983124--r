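#' Read a typed measurement table from CSV
#'
#' Dispatches on the header to one of the pipeline's table schemas
#' (UTF-8, '.' decimal, header required):
#'
#' * flow/volume trace: `time_s, flow_ml_s, volume_ml[, pressure_cmh2o]`
#' * PV loop: `pressure_cmh2o, volume_ml[, limb]`
#' * cohort: `animal, genotype, sex, age_days, body_length_cm, <response>`
#' * inhibition curve: `volume_ul, activity`
#'
#' Extra columns are preserved. Missing required columns are reported by
#' name; a trace with non-increasing or repeated timestamps is rejected.
#'
#' @param path CSV path.
#' @param type force a schema instead of auto-detection.
#' @return A data frame classed as `flow_volume_trace`, `pv_loop`,
#'   `cohort_table` or `inhibition_curve`. Traces carry an inferred `dt`
#'   attribute.
#' @export
read_trace_table <- function(path, type = c("auto", "trace", "pv_loop",
                                            "cohort", "inhibition")) {
  type <- match.arg(type)
  if (!file.exists(path)) fl_input_error("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  have <- names(df)
  schemas <- list(
    trace = c("time_s", "flow_ml_s", "volume_ml"),
    pv_loop = c("pressure_cmh2o", "volume_ml"),
    cohort = c("animal", "genotype", "sex", "age_days", "body_length_cm"),
    inhibition = c("volume_ul", "activity"))
  if (type == "auto") {
    type <- if (all(schemas$trace %in% have)) "trace"
      else if (all(schemas$cohort %in% have)) "cohort"
      else if (all(schemas$inhibition %in% have)) "inhibition"
      else if (all(schemas$pv_loop %in% have)) "pv_loop"
      else fl_input_error("cannot identify the schema of %s from header: %s",
                          path, paste(have, collapse = ", "))
  }
  miss <- setdiff(schemas[[type]], have)
  if (length(miss))
    fl_input_error("%s is missing required column(s): %s", path,
                   paste(miss, collapse = ", "))
  switch(type,
    trace = {
      dtv <- diff(df$time_s)
      if (any(dtv == 0))
        fl_input_error("%s has repeated timestamps", path)
      if (any(dtv < 0))
        fl_input_error("%s has non-increasing time", path)
      structure(df, class = c("flow_volume_trace", "data.frame"),
                dt = median(dtv))
    },
    pv_loop = structure(df, class = c("pv_loop", "data.frame")),
    cohort = structure(df, class = c("cohort_table", "data.frame")),
    inhibition = structure(df, class = c("inhibition_curve", "data.frame")))
}

#' Write a measurement table as CSV
#'
#' @param x data frame (any of the pipeline's table classes).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
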