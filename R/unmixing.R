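# Red/green spectral bleed-through estimation and correction.
#
# A green-emitting fluorophore (Peredox or SBFI) leaks a small fraction of
# its photons into the red detection channel.  The correction subtracts
# `ratio * green` from the red signal, per TCSPC bin or per frame intensity.
# The ratio is estimated from control ROIs expressing only the green
# fluorophore as the mean of per-ROI red/green count ratios.

#' Estimate the red/green bleed-through ratio from control ROIs
#'
#' @param control_pairs A two-column matrix or data frame (columns red, green
#'   counts), or a list of `c(red, green)` pairs, one per control ROI not
#'   expressing the red fluorophore.
#' @return An object of class `unmixing_ratio` with fields `ratio` (mean of
#'   per-ROI red/green ratios), `sd` (sample SD of those ratios, 0 for a
#'   single pair) and `n_control_rois`.
#' @export
#' @examples
#' estimate_bleedthrough(rbind(c(53, 1000), c(53, 1000)))  # ratio 0.053
estimate_bleedthrough <- function(control_pairs) {
  if (is.list(control_pairs) && !is.data.frame(control_pairs))
    control_pairs <- do.call(rbind, control_pairs)
  control_pairs <- as.matrix(control_pairs)
  if (ncol(control_pairs) != 2L || nrow(control_pairs) < 1L)
    stop_invalid("`control_pairs` must be (red, green) count pairs")
  red <- as.numeric(control_pairs[, 1])
  green <- as.numeric(control_pairs[, 2])
  bad <- which(green <= 0)
  if (length(bad))
    stop_invalid("green counts must be > 0; offending pair(s): %s",
                 paste(bad, collapse = ", "))
  if (any(red < 0)) stop_invalid("red counts must be >= 0")
  r <- red / green
  out <- list(ratio = mean(r),
              sd = if (length(r) > 1L) sd(r) else 0,
              n_control_rois = length(r))
  class(out) <- "unmixing_ratio"
  out
}

#' @export
print.unmixing_ratio <- function(x, ...) {
  cat(sprintf("Bleed-through ratio: %.4f +/- %.4f (n = %d control ROIs)\n",
              x$ratio, x$sd, x$n_control_rois))
  invisible(x)
}

#' Construct an unmixing ratio directly
#'
#' @param ratio Red counts per green count for the contaminating fluorophore
#'   (in `[0, 1)`); 0.053 is a typical SBFI-into-red value.
#' @param sd Optional spread of the estimate.
#' @param n_control_rois Optional number of control ROIs behind the estimate.
#' @return An object of class `unmixing_ratio`.
#' @export
unmixing_ratio <- function(ratio, sd = 0, n_control_rois = 0L) {
  out <- list(ratio = check_scalar(ratio, "ratio", lower = 0, upper = 1,
                                   strict_upper = TRUE),
              sd = check_scalar(sd, "sd", lower = 0),
              n_control_rois = as.integer(n_control_rois))
  class(out) <- "unmixing_ratio"
  out
}

#' Subtract green bleed-through from a red signal
#'
#' `corrected = red - ratio * green`, per TCSPC bin (histogram inputs) or per
#' element (numeric intensity inputs).  Negative corrected values are clamped
#' to zero; the number of clamped entries is attached as attribute
#' `"n_clamped"` (and reported via a message when any occur).
#'
#' @param red A [tcspc_histogram()] (red channel) or numeric vector of
#'   intensities.
#' @param green The matching green signal (same type and shape).
#' @param ratio An [unmixing_ratio()] or a bare number.
#' @return Corrected red signal of the same type as `red`.
#' @export
unmix_red <- function(red, green, ratio) {
  if (inherits(ratio, "unmixing_ratio")) ratio <- ratio$ratio
  ratio <- check_scalar(ratio, "ratio", lower = 0, upper = 1, strict_upper = TRUE)
  if (inherits(red, "tcspc_histogram")) {
    if (!inherits(green, "tcspc_histogram"))
      stop_invalid("`green` must be a tcspc_histogram when `red` is one")
    if (length(red$counts) != length(green$counts) ||
        max(abs(red$bin_edges - green$bin_edges)) > 1e-9)
      stop_invalid("red and green histograms are not aligned on the same bins")
    corrected <- red$counts - ratio * green$counts
    n_clamped <- sum(corrected < 0)
    corrected <- round(pmax(corrected, 0))
    out <- tcspc_histogram(red$bin_edges, corrected, channel = red$channel)
  } else {
    red <- as.numeric(red); green <- as.numeric(green)
    if (length(red) != length(green))
      stop_invalid("red and green signals differ in length (%d vs %d)",
                   length(red), length(green))
    corrected <- red - ratio * green
    n_clamped <- sum(corrected < 0)
    out <- pmax(corrected, 0)
  }
  if (n_clamped > 0)
    message(sprintf("unmix_red: clamped %d negative value(s) to 0", n_clamped))
  attr(out, "n_clamped") <- n_clamped
  out
}
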