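#' Protocol timing and saturation-power parameters
#'
#' Deterministic arithmetic for a segmented zero-echo-time (RUFIS) acquisition
#' with an interleaved MT preparation train. Defaults describe the silent
#' ihMT protocol: TR 1.764 ms, 32 spokes per segment, a train of 10 Fermi
#' pulses of 500 us width with 500 us gaps at 8.75 uT root-mean-square B1,
#' 48 dummy segments, 65 s scan time per volume and five ihMT volumes.
#' Segment and preparation overheads (gradient ramps and switching) are
#' explicit parameters, back-computed so the stated totals of 68.6 ms per
#' segment and 10.8 ms per preparation hold exactly.
#'
#' @param tr repetition time per spoke, ms.
#' @param spokes_per_segment spokes acquired per RUFIS segment.
#' @param segment_overhead ramps and switching per segment, ms.
#' @param n_sat_pulses saturation pulses per preparation train.
#' @param pulse_width saturation pulse width, ms.
#' @param pulse_gap gap between saturation pulses, ms.
#' @param prep_overhead extra preparation time (ramps, switching), ms.
#' @param n_dummy_segments dummy segments played before data acquisition.
#' @param pulse_b1rms root-mean-square B1 of one saturation pulse, uT.
#' @param per_volume_scan_time acquisition time per volume, s (excluding the
#'   dummy preamble).
#' @param n_volumes number of volumes in the protocol.
#' @return An object of class \code{protocol_timing}.
#' @export
protocol_timing <- function(tr = 1.764,
                            spokes_per_segment = 32,
                            segment_overhead = 68.6 - 32 * 1.764,
                            n_sat_pulses = 10,
                            pulse_width = 0.5,
                            pulse_gap = 0.5,
                            prep_overhead = 0.8,
                            n_dummy_segments = 48,
                            pulse_b1rms = 8.75,
                            per_volume_scan_time = 65,
                            n_volumes = 5) {
  p <- list(tr = tr, spokes_per_segment = spokes_per_segment,
            segment_overhead = segment_overhead, n_sat_pulses = n_sat_pulses,
            pulse_width = pulse_width, pulse_gap = pulse_gap,
            prep_overhead = prep_overhead, n_dummy_segments = n_dummy_segments,
            pulse_b1rms = pulse_b1rms,
            per_volume_scan_time = per_volume_scan_time, n_volumes = n_volumes)
  pos <- c("tr", "spokes_per_segment", "n_sat_pulses", "pulse_width",
           "pulse_b1rms", "per_volume_scan_time", "n_volumes")
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]))
      stop(nm, " must be a single number")
    if (nm %in% pos && p[[nm]] <= 0) stop(nm, " must be > 0")
    if (!(nm %in% pos) && p[[nm]] < 0) stop(nm, " must be >= 0")
  }
  structure(p, class = "protocol_timing")
}

#' @export
print.protocol_timing <- function(x, ...) {
  cat(sprintf("protocol_timing: segment %.1f ms | prep %.1f ms | dummies %.1f s | total %s | module B1rms %.1f uT\n",
              segment_time(x), prep_time(x), dummy_duration(x),
              attr(protocol_duration(x), "formatted"), module_b1rms(x)))
  invisible(x)
}

#' RUFIS segment time
#'
#' Time of one acquisition segment, including ramps and switching:
#' \code{spokes_per_segment * tr + segment_overhead}, in ms.
#'
#' @param p a \code{\link{protocol_timing}}.
#' @return segment time in ms.
#' @export
segment_time <- function(p) {
  stopifnot(inherits(p, "protocol_timing"))
  p$spokes_per_segment * p$tr + p$segment_overhead
}

#' MT preparation train time
#'
#' \code{n_sat_pulses * (pulse_width + pulse_gap) + prep_overhead}, in ms.
#'
#' @inheritParams segment_time
#' @return preparation time in ms.
#' @export
prep_time <- function(p) {
  stopifnot(inherits(p, "protocol_timing"))
  p$n_sat_pulses * (p$pulse_width + p$pulse_gap) + p$prep_overhead
}

#' Duration of the dummy-segment preamble
#'
#' Dummy segments are acquisition segments played without recording data,
#' until longitudinal magnetization reaches steady state. They are costed at
#' the segment time only (no preparation between dummies). Reported in
#' seconds to one decimal.
#'
#' @inheritParams segment_time
#' @return dummy preamble duration in s, rounded to 0.1 s.
#' @export
dummy_duration <- function(p) {
  stopifnot(inherits(p, "protocol_timing"))
  round(p$n_dummy_segments * segment_time(p) / 1000, 1)
}

#' Total protocol duration
#'
#' \code{n_volumes * (per_volume_scan_time + dummy_duration)}, rounded to the
#' nearest whole second. The per-volume scan time is taken to exclude the
#' dummy preamble, whose cost is added per volume.
#'
#' @inheritParams segment_time
#' @return total duration in s (integer), with attribute \code{formatted}
#'   giving "M minutes S seconds".
#' @export
protocol_duration <- function(p) {
  stopifnot(inherits(p, "protocol_timing"))
  total <- round(p$n_volumes * (p$per_volume_scan_time +
                                  p$n_dummy_segments * segment_time(p) / 1000))
  structure(total, formatted = sprintf("%d minutes %d seconds",
                                       total %/% 60, total %% 60))
}

#' Root-mean-square B1 over the preparation module
#'
#' The pulse B1rms scaled by the square root of the train duty cycle
#' (pulse-on time over the pulse+gap window; the preparation overhead is
#' excluded from the window). Returned exact; displayed to 0.1 uT.
#'
#' @inheritParams segment_time
#' @return module B1rms in uT.
#' @export
module_b1rms <- function(p) {
  stopifnot(inherits(p, "protocol_timing"))
  duty <- p$pulse_width / (p$pulse_width + p$pulse_gap)
  p$pulse_b1rms * sqrt(duty)
}
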