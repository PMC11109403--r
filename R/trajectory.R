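# TumorTrajectory: the time-stamped size series all modules exchange.

#' Tumor size trajectory
#'
#' A time-stamped series of tumor sizes for one subject, with an opaque
#' size unit. Times are real-valued days from an arbitrary per-study
#' origin; sizes are positive reals.
#'
#' @param times Strictly increasing observation times, days.
#' @param sizes Positive sizes, same length as `times`.
#' @param subject_id,arm Identification labels.
#' @param unit Free-text size unit label.
#' @return An object of class `tumor_trajectory`.
#' @export
tumor_trajectory <- function(times, sizes, subject_id = "s1", arm = "",
                             unit = "mm^3") {
  stopifnot(is.numeric(times), is.numeric(sizes))
  if (length(times) != length(sizes))
    stop("times and sizes must have equal length")
  if (length(times) && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("sizes must be positive and finite")
  structure(list(subject_id = as.character(subject_id),
                 arm = as.character(arm),
                 times = as.numeric(times), sizes = as.numeric(sizes),
                 unit = as.character(unit)),
            class = "tumor_trajectory")
}

#' @export
print.tumor_trajectory <- function(x, ...) {
  cat(sprintf("Tumor trajectory '%s'%s: %d points, days %g-%g, sizes %g-%g %s\n",
              x$subject_id,
              if (nzchar(x$arm)) paste0(" (arm ", x$arm, ")") else "",
              length(x$times), min(x$times), max(x$times),
              min(x$sizes), max(x$sizes), x$unit))
  invisible(x)
}

#' @export
as.data.frame.tumor_trajectory <- function(x, ...) {
  data.frame(subject_id = x$subject_id, arm = x$arm,
             time_days = x$times, size = x$sizes, unit = x$unit,
             stringsAsFactors = FALSE)
}

#' @export
length.tumor_trajectory <- function(x) length(x$times)

#' @export
plot.tumor_trajectory <- function(x, log = "y", ...) {
  plot(x$times, x$sizes, log = log, xlab = "time (days)",
       ylab = paste0("size (", x$unit, ")"),
       main = x$subject_id, type = "b", ...)
  invisible(x)
}
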