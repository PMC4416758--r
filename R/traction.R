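#' Population-average traction trace with event markers
#'
#' Builds the time series of the population mean net traction magnitude
#' from per-step records, marks differentiation/proliferation/apoptosis
#' instants, and flags discontinuities: a step-to-step change whose
#' magnitude exceeds \code{k_mad} times the median absolute step-to-step
#' change of the trace.
#'
#' @param records per-step records from a replicate (or several bound
#'   together, sharing one time axis).
#' @param events event log of the same run (optional).
#' @param k_mad discontinuity multiplier (default 3).
#' @return list with \code{trace} (data.frame time_days, mean_F_trac,
#'   n_cells, jump, delta), and \code{markers} (events joined with the
#'   trace delta at the event step and its sign).
#' @export
summarize_traction <- function(records, events = NULL, k_mad = 3) {
  if (is.null(records) || !nrow(records)) {
    stop("empty input: no records to summarize", call. = FALSE)
  }
  agg <- stats::aggregate(records$F_trac, by = list(time_days = records$time_days),
                          FUN = mean)
  names(agg)[2] <- "mean_F_trac"
  cnt <- stats::aggregate(records$F_trac, by = list(time_days = records$time_days),
                          FUN = length)
  agg$n_cells <- cnt$x
  agg <- agg[order(agg$time_days), ]
  d <- c(NA, diff(agg$mean_F_trac))
  med <- stats::median(abs(d), na.rm = TRUE)
  agg$delta <- d
  agg$jump <- !is.na(d) & abs(d) > k_mad * max(med, .Machine$double.eps)
  markers <- NULL
  if (!is.null(events) && nrow(events)) {
    idx <- match(round(events$time_days, 9), round(agg$time_days, 9))
    # records hold the forces computed before the step's events fired, so
    # an event's effect on the trace shows between its step and the next
    idx1 <- ifelse(is.na(idx) | idx >= nrow(agg), NA, idx + 1L)
    d_after <- agg$delta[idx1]
    markers <- cbind(events,
                     delta = agg$delta[idx],
                     delta_after = d_after,
                     jump = agg$jump[idx],
                     jump_after = agg$jump[idx1],
                     direction = ifelse(is.na(d_after), NA,
                                        ifelse(d_after > 0,
                                               "increase", "decrease")))
  }
  list(trace = agg, markers = markers)
}
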