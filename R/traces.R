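# Per-ROI time-series analysis: delta-F/F, stimulus-evoked transient metrics,
# exclusion rules, Peredox/RCaMP response ratios, cohort averaging on a
# binned common time axis, and normality-gated group comparisons.

#' Per-ROI sensor time series
#'
#' @param roi_id ROI label.
#' @param sensor Sensor label: `"Peredox"`, `"RCaMP"`, `"SBFI"` or
#'   `"mito-RCaMP"`.
#' @param times Sample times (s), strictly increasing; typically 10-60 s
#'   spacing outside stimulation and ~0.25 s during it.
#' @param values Sensor readout per sample: lifetime (ns) for lifetime
#'   sensors, photon counts for intensity sensors.  Must be finite; lifetimes
#'   must be positive.
#' @param stim_time Optional stimulus onset (s).
#' @param units Value units (`"ns"` or `"counts"`, or `"dff"` after
#'   normalisation).
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(roi_id, sensor = c("Peredox", "RCaMP", "SBFI", "mito-RCaMP"),
                      times, values, stim_time = NULL, units = NULL) {
  sensor <- match.arg(sensor)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values) || length(times) < 1L)
    stop_invalid("`times` and `values` must be equal-length, non-empty")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop_invalid("`times` must be finite and strictly increasing")
  if (any(!is.finite(values))) stop_invalid("`values` must be finite")
  if (is.null(units))
    units <- if (sensor %in% c("Peredox", "RCaMP", "mito-RCaMP")) "ns" else "counts"
  if (units == "ns" && any(values <= 0))
    stop_invalid("lifetime values must be > 0 ns")
  out <- list(roi_id = as.character(roi_id), sensor = sensor, times = times,
              values = values, stim_time = stim_time, units = units)
  class(out) <- "roi_trace"
  out
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("ROI trace %s (%s, %s): %d samples, t = %.1f..%.1f s%s\n",
              x$roi_id, x$sensor, x$units, length(x$times),
              min(x$times), max(x$times),
              if (is.null(x$stim_time)) "" else
                sprintf(", stim at %.1f s", x$stim_time)))
  invisible(x)
}

#' Analysis thresholds for transient inclusion
#'
#' Quality rules applied before computing response ratios: recordings with a
#' Ca2+ transient (delta RCaMP lifetime) below `min_delta_rcamp` or with an
#' RCaMP half-decay of `max_half_decay` or longer are excluded.
#'
#' @param min_delta_rcamp Minimum RCaMP lifetime change (ns, default 0.2).
#' @param max_half_decay Maximum RCaMP half-decay time (s, default 35).
#' @param baseline_window Pre-stimulus window used for baselines (s,
#'   default 60).
#' @return An object of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(min_delta_rcamp = 0.2, max_half_decay = 35,
                                baseline_window = 60) {
  out <- list(
    min_delta_rcamp = check_scalar(min_delta_rcamp, "min_delta_rcamp",
                                   lower = 0, strict_lower = TRUE),
    max_half_decay = check_scalar(max_half_decay, "max_half_decay",
                                  lower = 0, strict_lower = TRUE),
    baseline_window = check_scalar(baseline_window, "baseline_window",
                                   lower = 0, strict_lower = TRUE)
  )
  class(out) <- "analysis_thresholds"
  out
}

#' Baseline-normalise an intensity trace to delta-F/F
#'
#' `value(t) = (F(t) - F0) / F0` with `F0` the mean over the pre-stimulus
#' baseline window.
#'
#' @param trace An intensity [roi_trace()] (units `"counts"`).
#' @param baseline_window Length of the pre-stimulus window (s) whose mean
#'   defines `F0`; requires at least 3 samples there.
#' @param stim_time Stimulus time (s); defaults to the trace's own.
#' @return A new `roi_trace` in `"dff"` units.
#' @export
delta_f_over_f <- function(trace, baseline_window = 60, stim_time = NULL) {
  stopifnot(inherits(trace, "roi_trace"))
  stim_time <- stim_time %||% trace$stim_time
  if (is.null(stim_time)) stop_invalid("no stimulus time available")
  in_base <- trace$times < stim_time & trace$times >= stim_time - baseline_window
  if (sum(in_base) < 3L)
    stop_invalid("baseline window holds %d sample(s); at least 3 required",
                 sum(in_base))
  f0 <- mean(trace$values[in_base])
  if (f0 <= 0) stop_invalid("baseline mean must be > 0 (got %g)", f0)
  out <- trace
  out$values <- (trace$values - f0) / f0
  out$units <- "dff"
  out$stim_time <- stim_time
  attr(out, "baseline_f0") <- f0
  out
}

#' Quantify a stimulus-evoked transient
#'
#' Computes the pre-stimulus baseline, the signed peak change after the
#' stimulus (minimum for downward transients such as SBFI quench, maximum for
#' upward ones), the time to peak, and the half-decay time: the time from the
#' peak until the signal first returns halfway to baseline, linearly
#' interpolated between samples and flagged `NA` if no crossing occurs within
#' the trace.
#'
#' @param trace An [roi_trace()].
#' @param stim_time Stimulus time (s); defaults to the trace's own.
#' @param polarity `"up"` or `"down"`: direction of the expected transient.
#' @param thresholds An [analysis_thresholds()] (supplies the baseline
#'   window).
#' @param peak_window Optional `c(start, end)` in seconds after the stimulus
#'   restricting the peak search (default: stimulus to end of trace).
#' @return An object of class `transient_metrics` with fields `baseline`,
#'   `delta_peak`, `dff_peak` (for `"dff"` traces), `time_to_peak`,
#'   `half_decay_time` (NA if undefined), `half_decay_defined`, `polarity`.
#' @export
transient_metrics <- function(trace, stim_time = NULL,
                              polarity = c("up", "down"),
                              thresholds = analysis_thresholds(),
                              peak_window = NULL) {
  stopifnot(inherits(trace, "roi_trace"))
  polarity <- match.arg(polarity)
  stim_time <- stim_time %||% trace$stim_time
  if (is.null(stim_time)) stop_invalid("no stimulus time available")
  if (stim_time < min(trace$times) || stim_time > max(trace$times))
    stop_invalid("stim_time %g outside the trace span", stim_time)
  t <- trace$times; v <- trace$values
  in_base <- t < stim_time & t >= stim_time - thresholds$baseline_window
  baseline <- if (any(in_base)) mean(v[in_base]) else v[1L]
  post <- which(t >= stim_time)
  if (length(post) < 3L) stop_invalid("fewer than 3 post-stimulus samples")
  if (is.null(peak_window)) peak_window <- c(0, max(t) - stim_time)
  search <- post[t[post] <= stim_time + peak_window[2] &
                   t[post] >= stim_time + peak_window[1]]
  if (!length(search)) stop_invalid("empty peak-search window")
  dv <- v[search] - baseline
  pk <- if (polarity == "down") which.min(dv) else which.max(dv)
  delta_peak <- dv[pk]
  peak_idx <- search[pk]
  time_to_peak <- t[peak_idx] - stim_time

  # first return halfway to baseline after the peak, linear interpolation
  half_level <- baseline + delta_peak / 2
  half_decay <- NA_real_
  after <- seq.int(peak_idx, length(t))
  if (length(after) >= 2L && abs(delta_peak) > 0) {
    crossed <- if (polarity == "down") v[after] >= half_level else v[after] <= half_level
    hit <- which(crossed)[1L]
    if (!is.na(hit) && hit > 1L) {
      i1 <- after[hit - 1L]; i2 <- after[hit]
      frac <- (half_level - v[i1]) / (v[i2] - v[i1])
      half_decay <- t[i1] + frac * (t[i2] - t[i1]) - t[peak_idx]
    } else if (!is.na(hit) && hit == 1L) half_decay <- 0
  }
  out <- list(baseline = baseline, delta_peak = delta_peak,
              dff_peak = if (identical(trace$units, "dff")) baseline + delta_peak else NA_real_,
              time_to_peak = time_to_peak,
              half_decay_time = half_decay,
              half_decay_defined = is.finite(half_decay),
              polarity = polarity, roi_id = trace$roi_id, sensor = trace$sensor)
  class(out) <- "transient_metrics"
  out
}

#' @export
print.transient_metrics <- function(x, ...) {
  cat(sprintf(
    "Transient (%s, %s, %s): baseline %.4g, delta peak %+.4g, t_peak %.2f s, t1/2 %s\n",
    x$roi_id, x$sensor, x$polarity, x$baseline, x$delta_peak, x$time_to_peak,
    if (x$half_decay_defined) sprintf("%.2f s", x$half_decay_time) else "undefined"))
  invisible(x)
}

#' Ratio of Peredox to RCaMP lifetime responses, with exclusion rules
#'
#' Computes `delta_peredox / delta_rcamp` for one recording, unless the
#' recording fails an inclusion rule: the RCaMP lifetime change must be at
#' least `thresholds$min_delta_rcamp` (small Ca2+ transients make the ratio
#' noisy) and the RCaMP half-decay must be defined and shorter than
#' `thresholds$max_half_decay`.
#'
#' @param peredox,rcamp [transient_metrics()] for the Peredox and RCaMP
#'   transients of the same ROI and stimulus.
#' @param thresholds An [analysis_thresholds()].
#' @return An object of class `ratio_result`: either
#'   `list(included = TRUE, ratio = ...)` or
#'   `list(included = FALSE, excluded_by = <rule>, ...)`.
#' @export
peredox_rcamp_ratio <- function(peredox, rcamp,
                                thresholds = analysis_thresholds()) {
  stopifnot(inherits(peredox, "transient_metrics"),
            inherits(rcamp, "transient_metrics"))
  base <- list(roi_id = peredox$roi_id,
               delta_peredox = peredox$delta_peak,
               delta_rcamp = rcamp$delta_peak)
  if (rcamp$delta_peak < thresholds$min_delta_rcamp) {
    out <- c(base, list(included = FALSE,
                        excluded_by = sprintf("delta_rcamp < %g ns",
                                              thresholds$min_delta_rcamp)))
  } else if (!rcamp$half_decay_defined ||
             rcamp$half_decay_time >= thresholds$max_half_decay) {
    out <- c(base, list(included = FALSE,
                        excluded_by = sprintf("rcamp half-decay >= %g s",
                                              thresholds$max_half_decay)))
  } else {
    out <- c(base, list(included = TRUE,
                        ratio = peredox$delta_peak / rcamp$delta_peak))
  }
  class(out) <- "ratio_result"
  out
}

#' @export
print.ratio_result <- function(x, ...) {
  if (isTRUE(x$included))
    cat(sprintf("ROI %s: dPeredox/dRCaMP = %.4f\n", x$roi_id, x$ratio))
  else
    cat(sprintf("ROI %s: excluded (%s)\n", x$roi_id, x$excluded_by))
  invisible(x)
}

# Bin sample times of one stimulus-aligned trace: to the nearest `coarse`
# seconds outside the stimulation window, nearest `fine` seconds inside it;
# samples falling in one bin are averaged.
bin_trace_times <- function(times, values, stim_window, coarse, fine) {
  in_fine <- times >= stim_window[1] & times <= stim_window[2]
  bt <- ifelse(in_fine, round(times / fine) * fine, round(times / coarse) * coarse)
  agg <- tapply(values, bt, mean)
  list(times = as.numeric(names(agg)), values = as.numeric(agg))
}

#' Average stimulus-aligned traces on a common binned time axis
#'
#' Each trace is shifted so its stimulus is at t = 0, its sample times are
#' binned (to the nearest `coarse_bin` outside `stim_window`, the nearest
#' `fine_bin` inside it), and it is linearly interpolated onto the union of
#' all binned time points — without extrapolation, so each grid point only
#' averages the traces that span it.
#'
#' @param traces List of [roi_trace()] objects, each with a `stim_time`.
#' @param coarse_bin Bin width outside the stimulation window (s, default 1).
#' @param fine_bin Bin width inside it (s, default 0.01).
#' @param stim_window `c(start, end)` of the finely sampled window, seconds
#'   relative to the stimulus (default `c(-2, 5)`).
#' @return An object of class `averaged_trace`: a data frame with columns
#'   `time`, `mean`, `sd`, `sem`, `n`.
#' @export
bin_and_average <- function(traces, coarse_bin = 1, fine_bin = 0.01,
                            stim_window = c(-2, 5)) {
  if (length(traces) < 2L) stop_invalid("at least 2 traces are required")
  binned <- lapply(traces, function(tr) {
    stopifnot(inherits(tr, "roi_trace"))
    if (is.null(tr$stim_time))
      stop_invalid("trace %s has no stim_time", tr$roi_id)
    bin_trace_times(tr$times - tr$stim_time, tr$values,
                    stim_window, coarse_bin, fine_bin)
  })
  grid <- sort(unique(unlist(lapply(binned, `[[`, "times"))))
  vals <- vapply(binned, function(b) {
    if (length(b$times) == 1L)
      return(ifelse(abs(grid - b$times) < 1e-9, b$values, NA_real_))
    approx(b$times, b$values, xout = grid, method = "linear", rule = 1)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- rowSums(!is.na(vals))
  mn <- rowMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 1L, sd, na.rm = TRUE)
  sdv[n < 2L] <- ifelse(n[n < 2L] == 1L, 0, NA_real_)
  keep <- n >= 1L
  out <- data.frame(time = grid[keep], mean = mn[keep], sd = sdv[keep],
                    sem = sdv[keep] / sqrt(n[keep]), n = n[keep])
  class(out) <- c("averaged_trace", "data.frame")
  out
}

#' Plot an averaged trace
#'
#' Mean with a +/- SEM band, base graphics.
#'
#' @param x An `averaged_trace`.
#' @param ... Passed to [plot()].
#' @export
plot.averaged_trace <- function(x, ...) {
  graphics::plot(x$time, x$mean, type = "l", xlab = "time from stimulus (s)",
                 ylab = "mean signal", ...)
  graphics::polygon(c(x$time, rev(x$time)),
                    c(x$mean + x$sem, rev(x$mean - x$sem)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$time, x$mean)
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk tests each group at `alpha_normality`; if both pass, a
#' (paired) t-test is used, otherwise a paired Wilcoxon or Mann-Whitney test.
#' Constant groups are treated as non-normal (the Shapiro-Wilk statistic is
#' undefined there); identical paired samples report the null result
#' (statistic 0, p = 1).
#'
#' @param a,b Numeric vectors (each n >= 3; equal length if `paired`).
#' @param paired Paired design flag.
#' @param alpha_normality Significance level of the normality gate
#'   (default 0.05).
#' @return A list with `test` (name), `statistic`, `p_value`, `normal_a`,
#'   `normal_b`, `paired`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha_normality = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop_invalid("each group needs at least 3 values")
  if (paired && length(a) != length(b))
    stop_invalid("paired groups must have equal length")
  normal_p <- function(x) {
    if (length(unique(x)) < 3L) return(0)  # constant/degenerate: not normal
    tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  }
  pa <- normal_p(a); pb <- normal_p(b)
  normal <- pa > alpha_normality && pb > alpha_normality
  if (paired && all(a == b)) {
    test <- if (normal) "paired t-test" else "paired Wilcoxon"
    res <- list(test = test, statistic = 0, p_value = 1)
  } else if (normal) {
    ht <- t.test(a, b, paired = paired)
    res <- list(test = if (paired) "paired t-test" else "two-sample t-test",
                statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE))
    res <- list(test = if (paired) "paired Wilcoxon" else "Mann-Whitney",
                statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  c(res, list(normal_a = pa > alpha_normality, normal_b = pb > alpha_normality,
              shapiro_p_a = pa, shapiro_p_b = pb,
              paired = paired, n_a = length(a), n_b = length(b)))
}

#' Box-plot summary statistics
#'
#' Mean, median and the 5-95% range (linear-interpolation percentiles,
#' [stats::quantile()] type 7).
#'
#' @param values Numeric vector (n >= 1).
#' @return A list with `mean`, `median`, `p5`, `p95`, `n`.
#' @export
summarize_box <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop_invalid("`values` is empty")
  if (any(!is.finite(values))) stop_invalid("`values` must be finite")
  q <- unname(quantile(values, c(0.05, 0.95), type = 7))
  list(mean = mean(values), median = median(values), p5 = q[1], p95 = q[2],
       n = length(values))
}
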