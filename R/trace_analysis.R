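#' Estimate the minimum-amplitude noise floor from control traces
#'
#' Non-beating control wells record only instrument noise; the minimum
#' amplitude required to call a contraction is taken as a multiple of the
#' pooled standard deviation of those traces after removing any linear
#' drift.  The default multiplier 3 applies the three-sigma rule.
#'
#' @param traces A list of `calcium_trace` objects from non-beating control
#'   wells (at least one).
#' @param multiplier Number of pooled SDs defining the floor (default 3).
#' @return The noise floor in fluorescence units (strictly positive for any
#'   non-constant input; 0 for constant traces).
#' @export
estimate_noise_floor <- function(traces, multiplier = 3) {
  if (inherits(traces, "calcium_trace")) traces <- list(traces)
  if (length(traces) == 0) stopf("at least one control trace is required")
  assert_scalar_number(multiplier, "multiplier", min = 0)
  ss <- 0
  df <- 0
  for (tr in traces) {
    x <- tr$samples
    t <- seq_along(x)
    res <- stats::lm.fit(cbind(1, t), x)$residuals
    ss <- ss + sum(res^2)
    df <- df + length(x) - 2L
  }
  if (df <= 0) stopf("control traces are too short to estimate a floor")
  multiplier * sqrt(ss / df)
}

# Indices of local maxima; on plateaus the first sample of the plateau wins.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 2L) return(integer(0))
  left <- c(TRUE, x[-1] > x[-n])          # rises into i
  right <- c(x[-n] >= x[-1], TRUE)        # does not rise out of i
  idx <- which(left & right)
  idx[x[idx] > min(x)]
}

# Centered moving average with shrinking windows at the edges, so the output
# has the input's length and a noiseless trace keeps its peak positions.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect calcium-transient peaks
#'
#' Identifies contraction peaks in a calcium-flux trace as local maxima whose
#' height above the preceding inter-peak valley reaches the noise floor.
#' Candidate maxima separated by a valley that does not drop at least
#' `noise_floor` below both are treated as one peak (the higher survives).
#' Each accepted peak's magnitude is its maximum minus its own baseline, the
#' trace minimum in the valley preceding that peak; the per-trace summary is
#' the mean of those magnitudes plus the count of peaks in the recording
#' window.  Peaks at the window edges count whenever their maximum lies
#' inside the window.
#'
#' Candidate summits are found on a lightly smoothed copy of the trace
#' (centred moving average over `smooth_window` samples) so that measurement
#' noise does not spawn spurious contractions; each accepted summit is then
#' refined to the raw-trace maximum in its neighbourhood, and all magnitudes
#' are measured on the raw trace, so noiseless traces are recovered exactly.
#'
#' @param trace A `calcium_trace`.
#' @param noise_floor Minimum peak magnitude in fluorescence units, e.g. from
#'   [estimate_noise_floor()].
#' @param smooth_window Samples in the detection-stage moving average
#'   (default 5, i.e. 0.5 s at the standard 0.1 s sampling); 1 disables
#'   smoothing.
#' @return A list of class `peak_features`: `well_id`, `peak_count`,
#'   `mean_peak_magnitude` (NA when no peaks), `peak_times` (s),
#'   `peak_magnitudes` and `noise_floor_used`.
#' @export
detect_peaks <- function(trace, noise_floor, smooth_window = 5L) {
  stopifnot(inherits(trace, "calcium_trace"))
  assert_scalar_number(noise_floor, "noise_floor", min = 0)
  x <- trace$samples
  xs <- moving_average(x, smooth_window)
  cand <- local_maxima(xs)

  peaks <- integer(0)      # accepted summit indices (on the smoothed trace)
  bounds <- integer(0)     # left search boundary of each accepted peak
  for (c_i in cand) {
    if (length(peaks) == 0L) {
      valley <- min(xs[seq_len(c_i)])
      if (xs[c_i] - valley >= noise_floor && xs[c_i] > valley) {
        peaks <- c_i
        bounds <- 1L
      }
    } else {
      last <- peaks[length(peaks)]
      sep <- min(xs[last:c_i])
      if (xs[c_i] - sep >= noise_floor && xs[last] - sep >= noise_floor) {
        peaks <- c(peaks, c_i)
        bounds <- c(bounds, last)
      } else if (xs[c_i] > xs[last]) {
        peaks[length(peaks)] <- c_i   # same peak, keep the higher summit
      }
    }
  }

  # refine each summit to the raw maximum nearby; magnitude = raw maximum
  # minus the raw minimum of the valley preceding the peak
  h <- max(1L, (smooth_window - 1L) %/% 2L)
  n <- length(x)
  peaks <- vapply(peaks, function(p) {
    win <- max(1L, p - h):min(n, p + h)
    win[which.max(x[win])]
  }, integer(1))
  mags <- vapply(seq_along(peaks), function(j) {
    x[peaks[j]] - min(x[bounds[j]:peaks[j]])
  }, numeric(1))
  keep <- mags >= noise_floor & mags > 0
  peaks <- peaks[keep]
  mags <- mags[keep]

  structure(
    list(well_id = trace$well_id,
         peak_count = length(peaks),
         mean_peak_magnitude = if (length(mags)) mean(mags) else NA_real_,
         peak_times = (peaks - 1L) * trace$dt,
         peak_magnitudes = mags,
         noise_floor_used = noise_floor),
    class = "peak_features"
  )
}

#' Extract peak features for every trace in a screen
#'
#' Estimates the noise floor from the screen's non-beating lethal-control
#' wells, then runs [detect_peaks()] over every well.
#'
#' @param screen A `synthetic_screen`, or a list with `plate_map` and
#'   `traces` in the same layout.
#' @param floor_multiplier Passed to [estimate_noise_floor()].
#' @param noise_floor Optional explicit floor overriding the estimate.
#' @return A tibble with one row per well: `plate_id`, `well_id`,
#'   `peak_count`, `mean_peak_magnitude`, `noise_floor`.
#' @export
analyze_screen_traces <- function(screen, floor_multiplier = 3,
                                  noise_floor = NULL) {
  pm <- screen$plate_map
  if (is.null(noise_floor)) {
    flat_keys <- paste(pm$plate_id[pm$role == "lethal_control"],
                       pm$well_id[pm$role == "lethal_control"], sep = ":")
    if (length(flat_keys) == 0) {
      stopf("no lethal-control wells to estimate the noise floor from; ",
            "supply `noise_floor`")
    }
    noise_floor <- estimate_noise_floor(screen$traces[flat_keys],
                                        multiplier = floor_multiplier)
  }
  keys <- paste(pm$plate_id, pm$well_id, sep = ":")
  feats <- lapply(screen$traces[keys], detect_peaks, noise_floor = noise_floor)
  tibble::tibble(
    plate_id = pm$plate_id,
    well_id = pm$well_id,
    peak_count = vapply(feats, `[[`, integer(1), "peak_count",
                        USE.NAMES = FALSE),
    mean_peak_magnitude = vapply(feats, `[[`, numeric(1),
                                 "mean_peak_magnitude", USE.NAMES = FALSE),
    noise_floor = noise_floor
  )
}

#' Contractility metrics from an engineered-tissue force trace
#'
#' Segments a paced force trace into beats by pacing period and measures,
#' per beat: active tension (beat maximum minus beat baseline), beat
#' duration (time spent above baseline plus `duration_frac` of the active
#' tension, with linearly interpolated crossings), and the contraction and
#' relaxation slopes.  Slopes default to the maximum instantaneous
#' central-difference derivative on the rise and fall; `method = "secant"`
#' instead uses the secant from the duration-threshold crossing to the beat
#' maximum.  Metrics are averaged over all detected beats.
#'
#' @param trace A `force_trace`.
#' @param duration_frac Fraction of active tension above baseline defining
#'   beat onset/offset (default 0.1).
#' @param method `"derivative"` (default) or `"secant"`.
#' @param min_amplitude Smallest beat-window excursion treated as a beat;
#'   defaults to one quarter of the largest window excursion.
#' @return A list of class `contraction_metrics` with `tissue_id`,
#'   `active_tension`, `beat_duration`, `contraction_slope`,
#'   `relaxation_slope` and `n_beats`.
#' @export
contraction_metrics <- function(trace, duration_frac = 0.1,
                                method = c("derivative", "secant"),
                                min_amplitude = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  method <- match.arg(method)
  x <- trace$samples
  dt <- trace$dt
  t <- (seq_along(x) - 1L) * dt
  period <- 1 / trace$pacing_hz
  n_windows <- floor((t[length(t)] + dt / 2) / period)
  if (n_windows < 1) stopf("trace shorter than one pacing period")

  window_stats <- lapply(seq_len(n_windows), function(k) {
    idx <- which(t >= (k - 1) * period & t < k * period)
    if (k == n_windows) idx <- which(t >= (k - 1) * period)
    list(idx = idx, amp = max(x[idx]) - min(x[idx]))
  })
  amps <- vapply(window_stats, `[[`, numeric(1), "amp")
  if (is.null(min_amplitude)) min_amplitude <- max(amps) / 4
  beats <- which(amps > min_amplitude & amps > .Machine$double.eps^0.5)
  if (length(beats) == 0) stopf("no beats detected in force trace")

  one_beat <- function(idx) {
    seg <- x[idx]
    ts <- t[idx]
    base <- min(seg)
    peak_i <- which.max(seg)
    tension <- seg[peak_i] - base
    th <- base + duration_frac * tension
    above <- seg >= th
    first <- which(above)[1]
    last <- which(above)[sum(above)]
    # interpolate the threshold crossings
    t_on <- if (first > 1) {
      ts[first - 1] + dt * (th - seg[first - 1]) / (seg[first] - seg[first - 1])
    } else ts[first]
    t_off <- if (last < length(seg)) {
      ts[last] + dt * (seg[last] - th) / (seg[last] - seg[last + 1])
    } else ts[last]
    if (method == "derivative") {
      d <- (seg[-(1:2)] - seg[1:(length(seg) - 2)]) / (2 * dt)
      up <- max(d)
      down <- abs(min(d))
    } else {
      up <- (seg[peak_i] - th) / max(ts[peak_i] - t_on, dt)
      down <- (seg[peak_i] - th) / max(t_off - ts[peak_i], dt)
    }
    c(tension = tension, duration = t_off - t_on, up = up, down = down)
  }

  m <- vapply(beats, function(k) one_beat(window_stats[[k]]$idx), numeric(4))
  structure(
    list(tissue_id = trace$tissue_id,
         active_tension = mean(m["tension", ]),
         beat_duration = mean(m["duration", ]),
         contraction_slope = mean(m["up", ]),
         relaxation_slope = mean(m["down", ]),
         n_beats = length(beats)),
    class = "contraction_metrics"
  )
}
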