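#' Kinetic parameters of the heat shock response network
#'
#' Constructs the full parameter set of the HSF1/HSP70 titration model:
#' rate constants, regulation thresholds, lifetimes and the reference HSF1
#' concentration. Defaults are the published calibration of the network and
#' are used unchanged throughout the package; per-cell variability enters
#' only through the initial chaperone concentration and the cell's total
#' HSF1 level, never through these rates.
#'
#' @param k_d denaturation rate at the reference temperature scale (uM).
#' @param k_r renaturation rate (dimensionless).
#' @param mu basal HSP transcription rate (uM).
#' @param lam active (HSF1-driven) HSP transcription rate (uM).
#' @param S0 HSP transcription regulation threshold on the free-HSF1
#'   fraction (dimensionless).
#' @param beta HSP translation rate (dimensionless).
#' @param H0 translation regulation threshold on the free-HSP fraction
#'   (dimensionless).
#' @param hsf1_tot_ref reference total HSF1 concentration (uM), used to
#'   renormalize fluorescence into concentration units.
#' @param tau_temp incubator temperature rise time (h).
#' @param tau_mfp misfolded-protein lifetime (h).
#' @param tau_mhsp HSP mRNA lifetime (h).
#' @param tau_hsp HSP protein lifetime (h).
#' @return An object of class `hsr_params` (named list of the twelve
#'   positive scalars).
#' @examples
#' p <- hsr_params()
#' p$k_d
#' @export
hsr_params <- function(k_d = 1.76, k_r = 17.7, mu = 1.47e-3, lam = 0.78,
                       S0 = 0.18, beta = 10, H0 = 0.32,
                       hsf1_tot_ref = 4.0e-2, tau_temp = 1 / 15,
                       tau_mfp = 0.5, tau_mhsp = 1, tau_hsp = 10) {
  p <- list(k_d = k_d, k_r = k_r, mu = mu, lam = lam, S0 = S0, beta = beta,
            H0 = H0, hsf1_tot_ref = hsf1_tot_ref, tau_temp = tau_temp,
            tau_mfp = tau_mfp, tau_mhsp = tau_mhsp, tau_hsp = tau_hsp)
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) {
    stop("all model parameters must be finite, strictly positive scalars; ",
         "offending: ", paste(names(p)[bad], collapse = ", "))
  }
  structure(p, class = "hsr_params")
}

#' Per-cell parameters
#'
#' The two quantities that vary from cell to cell: the total HSF1
#' concentration and the initial chaperone (HSP) concentration.
#'
#' @param hsf1_tot total HSF1 concentration of the cell (uM).
#' @param hsp0 initial HSP concentration of the cell (uM).
#' @return An object of class `hsr_cell`.
#' @export
hsr_cell <- function(hsf1_tot, hsp0) {
  stopifnot(is.numeric(hsf1_tot), length(hsf1_tot) == 1L,
            is.finite(hsf1_tot), hsf1_tot > 0,
            is.numeric(hsp0), length(hsp0) == 1L, is.finite(hsp0), hsp0 > 0)
  structure(list(hsf1_tot = hsf1_tot, hsp0 = hsp0), class = "hsr_cell")
}

#' Piecewise-constant temperature protocol
#'
#' A hyperthermia protocol is a schedule of incubator setpoints: contiguous,
#' non-overlapping time segments each held at a constant temperature. The
#' cell-environment temperature relaxes towards the current setpoint with
#' the incubator rise time `tau_temp`.
#'
#' @param segments a data.frame with columns `start`, `end` (hours) and
#'   `setpoint` (degC); segments must be contiguous and ordered.
#' @param theta0 initial cell-environment temperature (degC); defaults to
#'   the first segment's setpoint.
#' @return An object of class `hsr_protocol`.
#' @seealso [stress_protocol()] for the standard
#'   normothermia/hyperthermia/normothermia design.
#' @export
hsr_protocol <- function(segments, theta0 = segments$setpoint[1]) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "setpoint") %in% names(segments)),
            nrow(segments) >= 1L)
  segments <- segments[order(segments$start), , drop = FALSE]
  if (any(segments$end <= segments$start)) {
    stop("protocol segments must have end > start")
  }
  if (nrow(segments) > 1L) {
    gaps <- abs(segments$start[-1L] - segments$end[-nrow(segments)])
    if (any(gaps > 1e-9)) stop("protocol segments must be contiguous")
    segments$start[-1L] <- segments$end[-nrow(segments)]
  }
  if (any(segments$setpoint < 30 | segments$setpoint > 50)) {
    stop("setpoints outside the physiological sanity range [30, 50] degC")
  }
  structure(list(segments = segments, theta0 = theta0),
            class = "hsr_protocol")
}

#' Standard transient-hyperthermia protocol
#'
#' Normothermia at 37 degC, a stress window at `stress_temperature`
#' starting at time 0, then return to 37 degC. Time is measured in hours
#' relative to stress onset.
#'
#' @param stress_temperature hyperthermia setpoint (degC), typically 41-44.
#' @param stress_duration length of the hyperthermia window (h).
#' @param pre_h observation time before stress onset (h).
#' @param post_h observation time after the stress window (h).
#' @return An `hsr_protocol`.
#' @export
stress_protocol <- function(stress_temperature, stress_duration = 3,
                            pre_h = 1 / 6, post_h = 1) {
  segs <- data.frame(
    start = c(-pre_h, 0, stress_duration),
    end = c(0, stress_duration, stress_duration + post_h),
    setpoint = c(37, stress_temperature, 37)
  )
  segs <- segs[segs$end > segs$start, , drop = FALSE]
  hsr_protocol(segs, theta0 = 37)
}

#' Setpoint of a protocol at given times
#'
#' @param protocol an `hsr_protocol`.
#' @param times times (h); each must fall inside the protocol window.
#' @return Numeric vector of setpoints (degC). Times on a segment boundary
#'   take the later segment's setpoint.
#' @export
protocol_setpoint <- function(protocol, times) {
  segs <- protocol$segments
  idx <- findInterval(times, segs$start)
  if (any(idx < 1L) || any(times > segs$end[nrow(segs)] + 1e-9)) {
    stop("times outside the protocol window")
  }
  segs$setpoint[idx]
}
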