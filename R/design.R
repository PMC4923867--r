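#' Define a reproduction session
#'
#' A session is an ordered set of stimulus durations, each presented a fixed
#' number of times. The session mean stimulus `t_bar` is derived from the
#' durations and is the quantity the prior is centred on (and the default
#' normaliser for the error partition).
#'
#' @param label Session label: `"short"`, `"long"`, or any custom string.
#' @param durations_ms Strictly increasing vector of positive durations, ms.
#' @param trials_per_duration Number of presentations of each duration.
#' @return An object of class `session_design`.
#' @examples
#' session_design("short", seq(1006, 1536, length.out = 11), 7)
#' @export
session_design <- function(label, durations_ms, trials_per_duration = 7) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop_timeprior("DOMAIN", "`label` must be a non-empty string.")
  }
  if (!is.numeric(durations_ms) || length(durations_ms) < 1L ||
      any(!is.finite(durations_ms)) || any(durations_ms <= 0)) {
    stop_timeprior("DOMAIN", "`durations_ms` must be positive finite durations.")
  }
  if (is.unsorted(durations_ms, strictly = TRUE)) {
    stop_timeprior("DOMAIN", "`durations_ms` must be strictly increasing.")
  }
  trials_per_duration <- assert_count(trials_per_duration, "trials_per_duration")
  structure(
    list(label = label, durations_ms = as.numeric(durations_ms),
         trials_per_duration = trials_per_duration,
         mean_stimulus_ms = mean(durations_ms)),
    class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design '%s'> %d durations in [%g, %g] ms, %d trials each (%d total), t_bar = %g ms\n",
              x$label, length(x$durations_ms), min(x$durations_ms),
              max(x$durations_ms), x$trials_per_duration,
              length(x$durations_ms) * x$trials_per_duration,
              x$mean_stimulus_ms))
  invisible(x)
}

#' Build the two-session reproduction paradigm
#'
#' The default paradigm of the reproduction task: a "short" session of 11
#' linearly spaced durations from 1006 to 1536 ms and a "long" session of 11
#' durations from 1270 to 1800 ms (both with 53 ms spacing), each duration
#' presented 7 times for 77 trials per session.
#'
#' @param trials_per_duration Presentations of each duration (default 7).
#' @return An object of class `paradigm_design` with elements `short` and
#'   `long`, each a [session_design()].
#' @examples
#' build_paradigm()
#' @export
build_paradigm <- function(trials_per_duration = 7) {
  trials_per_duration <- assert_count(trials_per_duration, "trials_per_duration")
  structure(
    list(short = session_design("short", seq(1006, 1536, length.out = 11),
                                trials_per_duration),
         long = session_design("long", seq(1270, 1800, length.out = 11),
                               trials_per_duration),
         trials_per_duration = trials_per_duration),
    class = "paradigm_design")
}

#' @export
print.paradigm_design <- function(x, ...) {
  cat("<paradigm_design>\n")
  print(x$short)
  print(x$long)
  invisible(x)
}

#' Mean stimulus averaged over the sessions of a paradigm
#'
#' Used when a single `t_bar` is needed for a cross-session quantity, such as
#' inverting a session-averaged regression index to a prior width.
#'
#' @param design A [paradigm_design][build_paradigm()] or a single
#'   [session_design()].
#' @return Mean stimulus duration in ms.
#' @examples
#' paradigm_mean_stimulus(build_paradigm()) # 1403
#' @export
paradigm_mean_stimulus <- function(design) {
  if (inherits(design, "session_design")) return(design$mean_stimulus_ms)
  if (!inherits(design, "paradigm_design")) {
    stop_timeprior("DOMAIN", "`design` must be a paradigm_design or session_design.")
  }
  mean(c(design$short$mean_stimulus_ms, design$long$mean_stimulus_ms))
}

# internal: coerce either design flavour to a list of session_designs
as_session_list <- function(design) {
  if (inherits(design, "session_design")) return(list(design))
  if (inherits(design, "paradigm_design")) return(list(design$short, design$long))
  stop_timeprior("DOMAIN", "`design` must be a paradigm_design or session_design.")
}
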