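#' Stimulus protocol
#'
#' Describes one sensory stimulation epoch within a sweep and the three
#' analysis windows derived from it: `stim_pre` (the 6 s immediately
#' preceding stimulus onset by default), `stim_on` (the stimulus train
#' itself) and `stim_post` (a window of the same duration as `stim_pre`
#' beginning after a configurable exclusion gap that drops the first
#' post-stimulus pyloric cycle or two).
#'
#' Conditions follow the crab stomatogastric naming: `"IV"` is the
#' chemosensory inferior ventricular pathway (40 Hz high-frequency trains),
#' `"VCN"` the mechanosensory ventral cardiac pathway (15 Hz trains),
#' `"bimodal"` simultaneous activation of both, and `"none"` an unstimulated
#' control sweep. All windows are half-open `[start, end)`.
#'
#' @param condition One of `"IV"`, `"VCN"`, `"bimodal"`, `"none"`.
#' @param pulse_rate Stimulus pulse rate in Hz (e.g. 40 for high-frequency
#'   IV trains, 1 for low-frequency latency protocols).
#' @param onset,offset Stimulus train start and end in seconds within the
#'   sweep. Default 6-s train.
#' @param pre_duration Duration of `stim_pre` and `stim_post`, seconds.
#' @param post_gap Exclusion gap between `offset` and the start of
#'   `stim_post`, seconds.
#' @return An object of class `stim_protocol`: a list with the condition,
#'   pulse rate, onset/offset and the three windows.
#' @examples
#' p <- stim_protocol("IV", pulse_rate = 40, onset = 7)
#' p$stim_on
#' @export
stim_protocol <- function(condition = c("IV", "VCN", "bimodal", "none"),
                          pulse_rate = 40, onset = 7, offset = onset + 6,
                          pre_duration = 6, post_gap = 1.5) {
  condition <- match.arg(condition)
  check_number(pulse_rate, "pulse_rate", lower = 0)
  check_number(onset, "onset", lower = 0)
  check_number(offset, "offset")
  if (offset <= onset) abort_bad_arg("offset", "must exceed onset")
  check_number(pre_duration, "pre_duration", lower = 1e-9)
  check_number(post_gap, "post_gap", lower = 0)
  if (onset - pre_duration < 0)
    abort_bad_arg("onset", "stim_pre window would start before the sweep")
  structure(list(
    condition  = condition,
    pulse_rate = pulse_rate,
    onset      = onset,
    offset     = offset,
    post_gap   = post_gap,
    stim_pre   = c(onset - pre_duration, onset),
    stim_on    = c(onset, offset),
    stim_post  = c(offset + post_gap, offset + post_gap + pre_duration)
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %s @ %g Hz, train [%g, %g) s, pre [%g, %g), post [%g, %g)\n",
    x$condition, x$pulse_rate, x$onset, x$offset,
    x$stim_pre[1], x$stim_pre[2], x$stim_post[1], x$stim_post[2]))
  invisible(x)
}

is_stim_protocol <- function(x) inherits(x, "stim_protocol")

check_protocol <- function(x, arg = "protocol") {
  if (!is_stim_protocol(x)) abort_bad_arg(arg, "must be a stim_protocol")
  invisible(x)
}
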