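# SBFI dye calibration, Hill-model Na+/K+-pump activation and transport
# stoichiometry bookkeeping.
#
# SBFI fluorescence excited at 790 nm is quenched as Na+ binds; with a
# single-site binding isotherm f(x) = x / (kd + x) the fluorescence is
#   F([Na+]) = F_free * (1 - a * f([Na+]))
# and dF/F referenced to the resting level na_rest is
#   dF/F = -a * (f(na) - f(na_rest)) / (1 - a * f(na_rest)),
# which is zero at rest and strictly decreasing in [Na+].  The quench
# amplitude `a` is a package constant (0.74) fixed once against the paired
# conversions -25.6% <-> +25 mM and -11.5% <-> +8 mM used throughout the
# package's worked examples.

#' SBFI calibration parameters
#'
#' Parameters of the single-site quench model used to convert SBFI
#' fluorescence changes (\eqn{\Delta F/F}, excitation 790 nm) into changes of
#' intracellular \eqn{[Na^+]}.
#'
#' @param kd Apparent Na+ dissociation constant of the dye in situ (mM).
#' @param na_rest Baseline intracellular \eqn{[Na^+]} (mM) to which
#'   \eqn{\Delta F/F} is referenced.
#' @param quench_amplitude_a Fraction of fluorescence lost at Na+ saturation
#'   relative to the Na+-free fluorescence (dimensionless, in (0, 1]).
#'
#' @return An object of class `sbfi_calibration`.
#' @seealso [dff_from_na()], [na_from_dff()]
#' @export
#' @examples
#' calib <- sbfi_calibration()
#' dff_from_na(38, calib)   # about -0.256
#' na_from_dff(-0.256, calib)  # about +25 mM above baseline
sbfi_calibration <- function(kd = 26, na_rest = 13, quench_amplitude_a = 0.74) {
  out <- list(
    kd = check_scalar(kd, "kd", lower = 0, strict_lower = TRUE),
    na_rest = check_scalar(na_rest, "na_rest", lower = 0),
    quench_amplitude_a = check_scalar(quench_amplitude_a, "quench_amplitude_a",
                                      lower = 0, upper = 1,
                                      strict_lower = TRUE)
  )
  class(out) <- "sbfi_calibration"
  out
}

#' @export
print.sbfi_calibration <- function(x, ...) {
  cat(sprintf("SBFI calibration: Kd = %g mM, na_rest = %g mM, quench a = %g\n",
              x$kd, x$na_rest, x$quench_amplitude_a))
  invisible(x)
}

sbfi_occupancy <- function(na, calib) na / (calib$kd + na)

#' SBFI dF/F expected at a given intracellular sodium concentration
#'
#' Evaluates the single-site quench calibration: the fractional fluorescence
#' change relative to the fluorescence at `calib$na_rest`.
#'
#' @param na Intracellular \eqn{[Na^+]} in mM (vectorised, each >= 0).
#' @param calib An [sbfi_calibration()] object.
#' @return \eqn{\Delta F/F} (dimensionless, <= 0 for `na >= na_rest`).
#' @export
dff_from_na <- function(na, calib = sbfi_calibration()) {
  stopifnot(inherits(calib, "sbfi_calibration"))
  if (!is.numeric(na) || any(!is.finite(na)) || any(na < 0))
    stop_invalid("`na` must be finite and >= 0 (mM)")
  a <- calib$quench_amplitude_a
  f0 <- sbfi_occupancy(calib$na_rest, calib)
  -a * (sbfi_occupancy(na, calib) - f0) / (1 - a * f0)
}

#' Maximal SBFI quench reachable under a calibration
#'
#' The \eqn{\Delta F/F} limit as \eqn{[Na^+] \to \infty}; inversion is only
#' defined for `dff` above this bound.
#'
#' @inheritParams dff_from_na
#' @return A negative scalar.
#' @export
max_quench <- function(calib = sbfi_calibration()) {
  a <- calib$quench_amplitude_a
  f0 <- sbfi_occupancy(calib$na_rest, calib)
  -a * (1 - f0) / (1 - a * f0)
}

#' Invert the SBFI calibration: dF/F to sodium increase above baseline
#'
#' Exact algebraic inversion of [dff_from_na()].  Returns the *increase* of
#' intracellular \eqn{[Na^+]} above `calib$na_rest`, in mM.
#'
#' @param dff Observed \eqn{\Delta F/F} (dimensionless, vectorised).  Must lie
#'   in the achievable range `(max_quench(calib), 0]` for increases; values
#'   above 0 (fluorescence rise) correspond to a sodium decrease and are also
#'   inverted provided the implied concentration is non-negative.
#' @param calib An [sbfi_calibration()] object.
#' @return Sodium change above baseline, mM (positive for quench).
#' @export
na_from_dff <- function(dff, calib = sbfi_calibration()) {
  stopifnot(inherits(calib, "sbfi_calibration"))
  if (!is.numeric(dff) || any(!is.finite(dff)))
    stop_invalid("`dff` must be finite")
  a <- calib$quench_amplitude_a
  f0 <- sbfi_occupancy(calib$na_rest, calib)
  mq <- max_quench(calib)
  if (any(dff <= mq))
    stop_invalid("dff = %g is at or below the maximal quench %.4f: out of range",
                 min(dff), mq)
  f <- f0 - dff * (1 - a * f0) / a
  if (any(f < 0))
    stop_invalid("dff = %g implies negative dye occupancy: out of range", max(dff))
  if (any(f >= 1))
    stop_invalid("dff implies occupancy >= 1: out of range")
  na <- calib$kd * f / (1 - f)
  na - calib$na_rest
}

#' Hill model of Na+/K+-pump activation by intracellular sodium
#'
#' @param isozyme Pump isozyme label, `"alpha1beta1"` or `"alpha3"`.
#' @param k_half Half-activation \eqn{[Na^+]} (mM).  Defaults to 13 mM for
#'   alpha1beta1; no default exists for alpha3 and `k_half` must be supplied.
#' @param hill_n Hill coefficient (dimensionless, ~3: three transported Na+).
#' @return An object of class `hill_pump`.
#' @export
#' @examples
#' pump <- hill_pump()
#' hill_fraction(38, pump)        # ~0.96 of maximal activity
#' fold_activation(13, 38, pump)  # ~1.9-fold
hill_pump <- function(isozyme = c("alpha1beta1", "alpha3"), k_half = NULL,
                      hill_n = 3) {
  isozyme <- match.arg(isozyme)
  if (is.null(k_half)) {
    if (isozyme == "alpha1beta1") k_half <- 13
    else stop_invalid("no default k_half exists for the alpha3 isozyme; supply one")
  }
  out <- list(
    isozyme = isozyme,
    k_half = check_scalar(k_half, "k_half", lower = 0, strict_lower = TRUE),
    hill_n = check_scalar(hill_n, "hill_n", lower = 0, strict_lower = TRUE)
  )
  class(out) <- "hill_pump"
  out
}

#' @export
print.hill_pump <- function(x, ...) {
  cat(sprintf("Na+/K+ pump (%s): K0.5 = %g mM, Hill n = %g\n",
              x$isozyme, x$k_half, x$hill_n))
  invisible(x)
}

#' Fractional pump activity at a given intracellular sodium
#'
#' \eqn{na^n / (na^n + K_{0.5}^n)}: monotone increasing from 0 to 1, equal to
#' 0.5 at `k_half`.
#'
#' @param na Intracellular \eqn{[Na^+]} in mM (vectorised, >= 0).
#' @param pump A [hill_pump()] object.
#' @return Fraction of maximal activity in `[0, 1)`.
#' @export
hill_fraction <- function(na, pump = hill_pump()) {
  stopifnot(inherits(pump, "hill_pump"))
  if (!is.numeric(na) || any(!is.finite(na)) || any(na < 0))
    stop_invalid("`na` must be finite and >= 0 (mM)")
  x <- (na / pump$k_half)^pump$hill_n
  x / (1 + x)
}

#' Fold-change of pump activity between two sodium levels
#'
#' @param na_base Baseline \eqn{[Na^+]} (mM, > 0).
#' @param na_peak Peak \eqn{[Na^+]} (mM, >= 0).
#' @param pump A [hill_pump()] object.
#' @return `hill_fraction(na_peak) / hill_fraction(na_base)`.
#' @export
fold_activation <- function(na_base, na_peak, pump = hill_pump()) {
  base <- hill_fraction(na_base, pump)
  if (any(base == 0))
    stop_invalid("baseline activity is zero (na_base = %g); fold undefined", na_base)
  hill_fraction(na_peak, pump) / base
}

#' Ion-transport stoichiometries
#'
#' Fixed molar stoichiometries of the transporters handling neuronal Na+ and
#' Ca2+: the Na+/K+ pump (3 Na+ out, 2 K+ in per ATP), forward-mode NCX
#' (3 Na+ in per Ca2+ out), PMCA (1 Ca2+ per ATP), SERCA (2 Ca2+ per ATP).
#'
#' @return An object of class `transport_stoichiometry`.
#' @export
transport_stoichiometry <- function() {
  out <- list(na_per_ca_ncx = 3L, na_per_atp_nka = 3L, k_per_atp_nka = 2L,
              ca_per_atp_pmca = 1L, ca_per_atp_serca = 2L)
  class(out) <- "transport_stoichiometry"
  out
}

#' Sodium load imported by forward NCX transport
#'
#' Forward-mode Na+/Ca2+ exchange imports 3 Na+ for every Ca2+ extruded.
#'
#' @param ca_extruded Amount or flux of Ca2+ extruded (>= 0, any units).
#' @param stoich A [transport_stoichiometry()] object.
#' @return Na+ imported, same units as the input.
#' @export
ncx_na_load <- function(ca_extruded, stoich = transport_stoichiometry()) {
  stopifnot(inherits(stoich, "transport_stoichiometry"))
  if (!is.numeric(ca_extruded) || any(!is.finite(ca_extruded)) || any(ca_extruded < 0))
    stop_invalid("`ca_extruded` must be finite and >= 0")
  stoich$na_per_ca_ncx * ca_extruded
}

#' ATP consumed by the Na+/K+ pump to extrude a sodium load
#'
#' @param na_extruded Amount of Na+ extruded (>= 0, any units).
#' @param stoich A [transport_stoichiometry()] object.
#' @return ATP consumed (`na_extruded / 3`).
#' @export
atp_cost <- function(na_extruded, stoich = transport_stoichiometry()) {
  stopifnot(inherits(stoich, "transport_stoichiometry"))
  if (!is.numeric(na_extruded) || any(!is.finite(na_extruded)) || any(na_extruded < 0))
    stop_invalid("`na_extruded` must be finite and >= 0")
  na_extruded / stoich$na_per_atp_nka
}

# --- reporting helpers --------------------------------------------------------
# Rounding conventions used when quoting estimates at the precision the
# biology supports: mM to the nearest integer, percent of maximal activity to
# the nearest 5 points, fold changes to the nearest 0.5.  Raw values are
# always retained alongside.

#' Round an estimate to its reporting precision
#'
#' `round_mm()` rounds a concentration to the nearest mM, `round_percent5()`
#' a percentage to the nearest 5 points, and `round_fold_half()` a fold
#' change to the nearest 0.5.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @export
round_mm <- function(x) round(x)

#' @rdname round_mm
#' @export
round_percent5 <- function(x) 5 * round(x / 5)

#' @rdname round_mm
#' @export
round_fold_half <- function(x) 0.5 * round(x / 0.5)

#' Summarise pump activation between two sodium levels
#'
#' Convenience wrapper reporting raw and reporting-precision values for the
#' activity at baseline and peak and the fold change.
#'
#' @inheritParams fold_activation
#' @return A list with `percent_base`, `percent_peak`, `fold` and their
#'   rounded counterparts.
#' @export
pump_activation_report <- function(na_base, na_peak, pump = hill_pump()) {
  pb <- 100 * hill_fraction(na_base, pump)
  pp <- 100 * hill_fraction(na_peak, pump)
  fd <- fold_activation(na_base, na_peak, pump)
  list(percent_base = pb, percent_peak = pp, fold = fd,
       percent_base_rounded = round_percent5(pb),
       percent_peak_rounded = round_percent5(pp),
       fold_rounded = round_fold_half(fd))
}
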