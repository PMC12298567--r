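# Stabilogram reconstruction: triaxial acceleration -> antero-posterior and
# medio-lateral displacement traces, plus sliding-window segmentation.

#' Sensor-node geometry
#'
#' @param H1 metres; node-to-floor distance (AP lever arm).
#' @param H2 metres; node-to-belt-joint distance (ML lever arm).
#' @return Object of class `node_geometry`.
#' @export
node_geometry <- function(H1, H2) {
  stop_if_not(is.numeric(H1) && H1 > 0 && is.numeric(H2) && H2 > 0,
              "H1 and H2 must be positive")
  structure(list(H1 = H1, H2 = H2), class = "node_geometry")
}

#' Reconstruct the stabilogram from a triaxial acceleration record
#'
#' Projects the measured gravity direction back to horizontal displacements of
#' the node using the lever-arm geometry:
#' \deqn{D_{AP} = H_1 \, A_z / \sqrt{A_y^2 + A_x^2}, \qquad
#'       D_{ML} = H_2 \, A_x / \sqrt{A_y^2 + A_z^2}.}
#' Both are ratios of accelerations, so the result does not depend on whether
#' the record is expressed in g or in m/s^2. Valid under the quasi-static
#' assumption (slow tilts, negligible inertial terms).
#'
#' Samples whose denominator falls below `eps` (in the record's acceleration
#' units) indicate a free-fall-like regime where the projection is undefined;
#' the whole record is rejected rather than clamped, since clamping would
#' fabricate displacements.
#'
#' @param record an `accel_record` (or any data.frame with columns `t`,
#'   `ax_g`, `ay_g`, `az_g`).
#' @param geom a [node_geometry()]; defaults to the geometry stored on the
#'   record by the simulator, if any.
#' @param eps denominator floor (default `1e-6`).
#' @return A `data.frame` of class `stabilogram_trace` with columns `t`,
#'   `dap_m`, `dml_m`; carries the record's `label`, `case_id`, `fs` and
#'   `record_id` attributes.
#' @export
compute_displacements <- function(record, geom = NULL, eps = 1e-6) {
  stop_if_not(nrow(record) > 0, "record must be non-empty")
  if (is.null(geom)) {
    h1 <- attr(record, "H1"); h2 <- attr(record, "H2")
    stop_if_not(!is.null(h1) && !is.null(h2),
                "no geometry on record; supply geom = node_geometry(H1, H2)")
    geom <- node_geometry(h1, h2)
  }
  ax <- record$ax_g; ay <- record$ay_g; az <- record$az_g
  den_ap <- sqrt(ay^2 + ax^2)
  den_ml <- sqrt(ay^2 + az^2)
  if (any(den_ap < eps) || any(den_ml < eps)) {
    stop("record rejected: acceleration denominator below ", eps,
         " (free-fall-like sample, outside model validity)", call. = FALSE)
  }
  out <- data.frame(t = record$t,
                    dap_m = geom$H1 * az / den_ap,
                    dml_m = geom$H2 * ax / den_ml)
  structure(out,
            label = attr(record, "label"), case_id = attr(record, "case_id"),
            fs = attr(record, "fs") %||% (1 / stats::median(diff(record$t))),
            record_id = attr(record, "record_id"),
            class = c("stabilogram_trace", "data.frame"))
}

#' Sliding-window specification
#'
#' Defaults follow the acquisition protocol: 10 s analysis windows with a new
#' pattern emitted every 1 s (i.e. consecutive windows share 9 s of data).
#' Setting `shift = 9` instead gives the alternative reading in which windows
#' share only 1 s.
#'
#' @param window_length seconds (default 10).
#' @param shift seconds between successive window starts (default 1);
#'   must satisfy `0 < shift <= window_length`.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(window_length = 10, shift = 1) {
  stop_if_not(shift > 0 && shift <= window_length,
              "must have 0 < shift <= window_length")
  structure(list(window_length = window_length, shift = shift),
            class = "window_spec")
}

#' Number of full windows in a trace of given duration
#'
#' `floor((T - W) / S) + 1` for duration `T`, window `W`, shift `S`;
#' 0 if `T < W`.
#'
#' @param duration trace duration in seconds.
#' @param spec a [window_spec()].
#' @return Integer window count.
#' @export
count_windows <- function(duration, spec = window_spec()) {
  if (duration < spec$window_length) return(0L)
  as.integer(floor((duration - spec$window_length) / spec$shift + 1e-9)) + 1L
}

#' Segment a stabilogram trace into overlapping windows
#'
#' Windows start at multiples of the shift; the incomplete tail is discarded.
#' Each window inherits the parent trace's label and provenance and records
#' its start time in the `window_start` attribute.
#'
#' @param trace a `stabilogram_trace`.
#' @param spec a [window_spec()].
#' @return List of `stabilogram_trace` windows (empty, with a warning, if the
#'   trace is shorter than one window).
#' @export
segment_windows <- function(trace, spec = window_spec()) {
  n <- nrow(trace)
  fs <- attr(trace, "fs")
  stop_if_not(!is.null(fs) && fs > 0, "trace must carry a sampling rate fs")
  duration <- n / fs
  k <- count_windows(duration, spec)
  if (k == 0L) {
    warning("trace shorter than one window (", duration, " s < ",
            spec$window_length, " s); no windows produced", call. = FALSE)
    return(list())
  }
  wlen <- round(spec$window_length * fs)
  lapply(seq_len(k) - 1L, function(j) {
    start <- round(j * spec$shift * fs)
    w <- trace[(start + 1L):(start + wlen), , drop = FALSE]
    rownames(w) <- NULL
    structure(w,
              label = attr(trace, "label"), case_id = attr(trace, "case_id"),
              fs = fs, record_id = attr(trace, "record_id"),
              window_start = start / fs,
              class = c("stabilogram_trace", "data.frame"))
  })
}
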