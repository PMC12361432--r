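#' Trailing rolling average of a kinetic trace
#'
#' Causal (trailing) mean over `window` acquisition points, matching online
#' plate-reader processing; the window shrinks at the left edge so the
#' series length is preserved. With the default 0.5 s spacing, 10 points
#' span 5 s.
#'
#' @param trace a [kinetic_trace].
#' @param window integer number of points (default 10).
#' @return A [kinetic_trace] with every channel smoothed.
#' @export
rolling_average <- function(trace, window = 10L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  window <- as.integer(window)
  n <- length(trace$times)
  if (window < 1L) stop("window must be >= 1")
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  smooth1 <- function(v) {
    cs <- cumsum(v)
    i <- seq_len(n)
    lo <- pmax(i - window, 0L)
    (cs - c(0, cs)[lo + 1L]) / (i - lo)
  }
  trace$channels <- lapply(trace$channels, smooth1)
  trace
}

# mean of the baseline_points samples immediately preceding an injection
.baseline_value <- function(times, values, injection, baseline_points) {
  pre <- which(times < injection)
  if (length(pre) < baseline_points)
    stop("fewer than ", baseline_points, " samples precede injection at ",
         injection, " s")
  idx <- utils::tail(pre, baseline_points)
  mean(values[idx])
}

#' Baseline-normalize a trace to its own pre-injection signal
#'
#' Divides every channel by the mean of the `baseline_points` samples
#' immediately preceding the injection. With two injections (antagonist
#' mode) each segment is normalized to its own pre-injection window: the
#' first segment (up to the second injection) by the window before the
#' first injection, the remainder by the window before the second.
#'
#' @param trace a [kinetic_trace].
#' @param injection injection time(s); default `trace$injections`.
#' @param baseline_points window width in samples (default 10).
#' @return A [kinetic_trace]; per-channel baselines stored in attribute
#'   `"baselines"`.
#' @export
baseline_normalize <- function(trace, injection = NULL,
                               baseline_points = 10L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (is.null(injection)) injection <- trace$injections
  injection <- sort(injection)
  baselines <- list()
  seg_start <- c(-Inf, injection[-1])
  seg_end <- c(injection[-1], Inf)
  for (ch in names(trace$channels)) {
    v <- trace$channels[[ch]]
    out <- v
    b <- numeric(length(injection))
    for (s in seq_along(injection)) {
      b[s] <- .baseline_value(trace$times, v, injection[s], baseline_points)
      if (b[s] <= 0)
        stop("nonpositive baseline for channel '", ch, "' before injection ",
             s, " (ratio undefined)")
      idx <- trace$times >= seg_start[s] & trace$times < seg_end[s]
      out[idx] <- v[idx] / b[s]
    }
    trace$channels[[ch]] <- out
    baselines[[ch]] <- b
  }
  attr(trace, "baselines") <- baselines
  trace
}

#' Pointwise ratio of a trace to its vehicle (buffer) trace
#'
#' @param norm_trace,norm_buffer_trace [kinetic_trace]s on the same time
#'   grid, typically already baseline-normalized.
#' @return A [kinetic_trace] with each channel divided pointwise.
#' @export
vehicle_ratio <- function(norm_trace, norm_buffer_trace) {
  stopifnot(inherits(norm_trace, "kinetic_trace"),
            inherits(norm_buffer_trace, "kinetic_trace"))
  if (!isTRUE(all.equal(norm_trace$times, norm_buffer_trace$times)))
    stop("time grids of trace and buffer trace differ")
  for (ch in names(norm_trace$channels)) {
    if (is.null(norm_buffer_trace$channels[[ch]]))
      stop("buffer trace lacks channel '", ch, "'")
    b <- norm_buffer_trace$channels[[ch]]
    if (any(b <= 0)) stop("buffer trace channel '", ch,
                          "' has nonpositive values")
    norm_trace$channels[[ch]] <- norm_trace$channels[[ch]] / b
  }
  norm_trace
}

.response_value <- function(well_id, assay, value, window_params) {
  structure(list(well_id = well_id, assay = assay, value = value,
                 window_params = window_params), class = "response_value")
}

#' @export
print.response_value <- function(x, ...) {
  cat(sprintf("<response_value> %s [%s] = %.6g\n", x$well_id, x$assay,
              x$value))
  invisible(x)
}

#' Peak calcium response of an agonist well
#'
#' Smooth (rolling window), normalize each well to its own pre-injection
#' baseline, divide by the vehicle well, and report the post-injection
#' maximum of the resulting ratio. Buffer-vs-buffer wells score 1.
#'
#' @param agonist_trace,buffer_trace raw [kinetic_trace]s (channel
#'   `"fluo"`) on the same grid.
#' @param injection injection time; default from the agonist trace.
#' @param window,baseline_points smoothing and baseline settings.
#' @return A `response_value` with assay `"ca_peak"`.
#' @export
ca_peak_response <- function(agonist_trace, buffer_trace, injection = NULL,
                             window = 10L, baseline_points = 10L) {
  if (is.null(injection)) injection <- agonist_trace$injections[1]
  a <- baseline_normalize(rolling_average(agonist_trace, window),
                          injection, baseline_points)
  b <- baseline_normalize(rolling_average(buffer_trace, window),
                          injection, baseline_points)
  r <- vehicle_ratio(a, b)
  post <- r$times >= injection
  v <- r$channels[["fluo"]][post]
  .response_value(agonist_trace$well_id, "ca_peak", max(v),
                  list(window = window, baseline_points = baseline_points))
}

#' BRET ratio trace (acceptor/donor)
#'
#' Forms the pointwise 540/470 emission ratio as a single-channel trace.
#'
#' @param trace a [kinetic_trace] with channels `"em540"` and `"em470"`.
#' @return A [kinetic_trace] with single channel `"bret"`.
#' @export
bret_ratio <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  for (ch in c("em540", "em470"))
    if (is.null(trace$channels[[ch]]))
      stop("trace ", trace$well_id, " lacks channel '", ch, "'")
  if (any(trace$channels[["em470"]] <= 0))
    stop("nonpositive donor (em470) signal in ", trace$well_id)
  kinetic_trace(trace$well_id, trace$times,
                list(bret = trace$channels[["em540"]] /
                       trace$channels[["em470"]]),
                trace$injections)
}

# shared normalization for the BRET area responses: smoothed ratio,
# injection-normalized, divided by the buffer well
.bret_norm_ratio <- function(agonist_trace, buffer_trace, injection,
                             window, baseline_points) {
  a <- baseline_normalize(rolling_average(bret_ratio(agonist_trace), window),
                          injection, baseline_points)
  b <- baseline_normalize(rolling_average(bret_ratio(buffer_trace), window),
                          injection, baseline_points)
  vehicle_ratio(a, b)
}

.trapz_window <- function(trace, channel, injection, horizon) {
  t_end <- injection + horizon
  tmax <- max(trace$times)
  if (t_end > tmax + 1e-9) {
    warning("horizon extends past the trace end (", tmax,
            " s); truncating")
    t_end <- tmax
  }
  idx <- trace$times >= injection & trace$times <= t_end
  pracma::trapz(trace$times[idx], trace$channels[[channel]][idx])
}

#' Arrestin-recruitment BRET response (area under the curve)
#'
#' The smoothed BRET ratio is normalized to its pre-injection value and to
#' the buffer well, and the area of (normalized ratio - 1) is integrated by
#' trapezoids over `[injection, injection + horizon]`. Buffer wells score 0.
#' Set `subtract_baseline = FALSE` to integrate the unsubtracted ratio.
#'
#' @param agonist_trace,buffer_trace raw dual-channel [kinetic_trace]s.
#' @param injection injection time; default from the agonist trace.
#' @param horizon integration horizon, seconds (default 600, i.e. 10 min).
#' @param window,baseline_points smoothing and baseline settings.
#' @param subtract_baseline integrate (ratio - 1) rather than the ratio.
#' @return A `response_value` with assay `"arr_bret_auc"` (ratio-seconds).
#' @export
bret_auc_response <- function(agonist_trace, buffer_trace, injection = NULL,
                              horizon = 600, window = 10L,
                              baseline_points = 10L,
                              subtract_baseline = TRUE) {
  if (is.null(injection)) injection <- agonist_trace$injections[1]
  r <- .bret_norm_ratio(agonist_trace, buffer_trace, injection, window,
                        baseline_points)
  if (subtract_baseline)
    r$channels[["bret"]] <- r$channels[["bret"]] - 1
  auc <- .trapz_window(r, "bret", injection, horizon)
  .response_value(agonist_trace$well_id, "arr_bret_auc", auc,
                  list(window = window, baseline_points = baseline_points,
                       horizon = horizon,
                       subtract_baseline = subtract_baseline))
}

#' G-protein dissociation BRET response (area over the curve)
#'
#' Dissociation of the donor-tagged G-alpha from the acceptor-tagged
#' G-beta-gamma lowers the BRET ratio; the response is the trapezoidal area
#' of (1 - normalized ratio) over the horizon, positive for dissociation.
#'
#' @inheritParams bret_auc_response
#' @return A `response_value` with assay `"g_dissoc_aoc"`.
#' @export
g_dissoc_aoc <- function(agonist_trace, buffer_trace, injection = NULL,
                         horizon = 600, window = 10L, baseline_points = 10L) {
  if (is.null(injection)) injection <- agonist_trace$injections[1]
  r <- .bret_norm_ratio(agonist_trace, buffer_trace, injection, window,
                        baseline_points)
  r$channels[["bret"]] <- 1 - r$channels[["bret"]]
  aoc <- .trapz_window(r, "bret", injection, horizon)
  .response_value(agonist_trace$well_id, "g_dissoc_aoc", aoc,
                  list(window = window, baseline_points = baseline_points,
                       horizon = horizon))
}

#' Antagonist-mode peak response after the second injection
#'
#' For dual-injection wells (test article first, agonist probe second), the
#' peak response is computed on the post-second-injection segment with each
#' segment baseline- and vehicle-normalized to its own pre-injection window.
#' With a vehicle pretreatment this reduces to the plain agonist-mode peak
#' of the probe.
#'
#' @param trace raw [kinetic_trace] with two injections (channel `"fluo"`).
#' @param buffer_trace matching vehicle-only dual-injection trace.
#' @param window,baseline_points smoothing and baseline settings.
#' @return A `response_value` with assay `"antagonist_peak"`.
#' @export
antagonist_response <- function(trace, buffer_trace, window = 10L,
                                baseline_points = 10L) {
  if (length(trace$injections) < 2L)
    stop("antagonist mode requires two recorded injections")
  a <- baseline_normalize(rolling_average(trace, window),
                          trace$injections, baseline_points)
  b <- baseline_normalize(rolling_average(buffer_trace, window),
                          trace$injections, baseline_points)
  r <- vehicle_ratio(a, b)
  post <- r$times >= trace$injections[2]
  .response_value(trace$well_id, "antagonist_peak",
                  max(r$channels[["fluo"]][post]),
                  list(window = window, baseline_points = baseline_points))
}
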