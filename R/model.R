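#' @useDynLib hsrdyn
NULL

#' Dynamical state of one cell
#'
#' @param theta cell-environment temperature (degC).
#' @param mfp misfolded protein concentration (uM).
#' @param hsp heat shock protein concentration (uM).
#' @param mhsp HSP mRNA concentration (uM).
#' @return Named numeric vector `c(theta, mfp, hsp, mhsp)`.
#' @export
hsr_state <- function(theta, mfp, hsp, mhsp) {
  s <- c(theta = theta, mfp = mfp, hsp = hsp, mhsp = mhsp)
  if (any(!is.finite(s))) stop("non-finite state")
  if (any(s[c("mfp", "hsp", "mhsp")] < 0)) {
    stop("concentrations must be non-negative")
  }
  s
}

as_state <- function(state) {
  s <- unlist(state[c("theta", "mfp", "hsp", "mhsp")])
  if (length(s) != 4L || any(is.na(names(s)))) {
    stop("state must carry theta, mfp, hsp and mhsp")
  }
  s
}

#' Temperature-dependent denaturation rate
#'
#' The only temperature input of the network: the rate at which proteins
#' misfold, which grows steeply with temperature above 37 degC. Below about
#' 34.7 degC the raw expression turns negative and is clamped at zero
#' (denaturation cannot run backwards).
#'
#' @param theta temperature (degC).
#' @param params an [hsr_params()] object.
#' @return Denaturation rate (uM), vectorized over `theta`.
#' @export
denaturation_rate <- function(theta, params = hsr_params()) {
  if (any(!is.finite(theta))) stop("theta must be finite")
  pmax(0, params$k_d * (1 - 0.4 * exp(37 - theta)) * 1.4^(theta - 37))
}

#' Free-chaperone fraction
#'
#' Fraction of the HSP pool not engaged by misfolded protein,
#' `hsp / (hsp + mfp)`; the empty pool (both zero) is taken as 0 by
#' continuous extension along hsp -> 0.
#'
#' @param state state vector or list with `hsp` and `mfp`.
#' @return Fraction in [0, 1].
#' @export
hsp_free_fraction <- function(state) {
  hsp <- state[["hsp"]]
  mfp <- state[["mfp"]]
  if (hsp < 0 || mfp < 0) stop("concentrations must be non-negative")
  pool <- hsp + mfp
  if (pool == 0) 0 else hsp / pool
}

#' Free-HSF1 fraction
#'
#' Fraction of total HSF1 not sequestered by free chaperone:
#' `hsf1_tot / (hsf1_tot + hsp * hsp_free_fraction)`. Strictly in (0, 1].
#'
#' @param state state vector or list with `hsp` and `mfp`.
#' @param cell an [hsr_cell()] (only `hsf1_tot` is used).
#' @return Fraction in (0, 1].
#' @export
hsf1_free_fraction <- function(state, cell) {
  if (cell$hsf1_tot <= 0) stop("hsf1_tot must be strictly positive")
  cell$hsf1_tot / (cell$hsf1_tot + state[["hsp"]] * hsp_free_fraction(state))
}

#' Foci fraction readout
#'
#' The model's activation readout: the fraction F of a cell's HSF1
#' fluorescence localized in nuclear stress bodies, modeled as the cube of
#' the free-HSF1 fraction. The cubic nonlinearity makes F hypersensitive:
#' negligible (below the 1 % detection limit) in unstressed cells and
#' rising steeply once misfolded protein titrates the chaperone pool away
#' from HSF1.
#'
#' @inheritParams hsf1_free_fraction
#' @return F in [0, 1].
#' @export
foci_fraction <- function(state, cell) {
  hsf1_free_fraction(state, cell)^3
}

#' Time derivatives of the network state
#'
#' Reference (R-level) implementation of the network equations; the
#' integrator uses an identical compiled version. Titration ratios with an
#' empty pool evaluate to 0.
#'
#' @param state state vector (`theta`, `mfp`, `hsp`, `mhsp`).
#' @param cell an [hsr_cell()].
#' @param setpoint incubator setpoint (degC).
#' @param params an [hsr_params()].
#' @return Named numeric vector of time derivatives (per hour).
#' @export
hsr_derivatives <- function(state, cell, setpoint, params = hsr_params()) {
  s <- as_state(state)
  if (any(!is.finite(s))) stop("non-finite state")
  theta <- s[["theta"]]
  mfp <- max(0, s[["mfp"]])
  hsp <- max(0, s[["hsp"]])
  mhsp <- max(0, s[["mhsp"]])

  pool <- hsp + mfp
  hsp_free <- if (pool > 0) hsp / pool else 0
  mfp_ratio <- if (pool > 0) mfp / pool else 0
  hsf1_free <- cell$hsf1_tot / (cell$hsf1_tot + hsp * hsp_free)
  f3 <- hsf1_free^3

  c(theta = (setpoint - theta) / params$tau_temp,
    mfp = (denaturation_rate(theta, params) - mfp * mfp_ratio -
             params$k_r * mfp * hsp_free) / params$tau_mfp,
    hsp = (params$beta * hsp_free / (params$H0 + hsp_free) * mhsp - hsp) /
      params$tau_hsp,
    mhsp = (params$mu + params$lam * f3 / (params$S0^3 + f3) - mhsp) /
      params$tau_mhsp)
}

# parameter vector handed to the compiled right-hand side; order must match
# src/hsr_model.c
.model_parms <- function(params, hsf1_tot, setpoint) {
  c(params$k_d, params$k_r, params$mu, params$lam, params$S0, params$beta,
    params$H0, params$tau_temp, params$tau_mfp, params$tau_mhsp,
    params$tau_hsp, hsf1_tot, setpoint)
}

# integrate one constant-setpoint span, returning the deSolve output matrix
.integrate_span <- function(y0, times, setpoint, hsf1_tot, params,
                            rtol = 1e-8, atol = 1e-10) {
  out <- deSolve::ode(
    y = y0, times = times, func = "hsr_derivs", parms =
      .model_parms(params, hsf1_tot, setpoint),
    dllname = "hsrdyn", initfunc = "hsr_initmod",
    method = "lsoda", rtol = rtol, atol = atol
  )
  if (attr(out, "istate")[1L] < 0) {
    stop(sprintf("ODE integration failed near t = %.3f h",
                 out[nrow(out), 1L]))
  }
  out
}

#' Quasi-steady initial state for a given chaperone level
#'
#' The stress window is short compared with the HSP lifetime, so the slow
#' variable is the chaperone concentration itself; the fast variables (MFP
#' and the mRNA) are slaved to it. Given `hsp0`, MFP is set on its
#' nullcline at 37 degC (positive root of the titration balance) and the
#' mRNA on its own nullcline.
#'
#' @param cell an [hsr_cell()]; `hsp0` fixes the chaperone level.
#' @param params an [hsr_params()].
#' @param theta ambient temperature (degC), normally 37.
#' @return State vector with `hsp = hsp0` and slaved `mfp`, `mhsp`.
#' @export
initial_state <- function(cell, params = hsr_params(), theta = 37) {
  kap <- denaturation_rate(theta, params)
  hsp <- cell$hsp0
  # kappa*(hsp+mfp) = mfp^2 + k_r*mfp*hsp  =>  positive root
  b <- params$k_r * hsp - kap
  mfp <- (-b + sqrt(b^2 + 4 * kap * hsp)) / 2
  st <- c(theta = theta, mfp = mfp, hsp = hsp, mhsp = 0)
  f3 <- hsf1_free_fraction(st, cell)^3
  st[["mhsp"]] <- params$mu + params$lam * f3 / (params$S0^3 + f3)
  st
}

#' Normothermic steady state
#'
#' Relaxes the network to its fixed point at a constant temperature by
#' long-horizon integration (at least 20 HSP lifetimes), with a convergence
#' check on the derivative residual. The resulting `hsp` component defines
#' the population-typical initial chaperone concentration; the `hsp0` of
#' `cell` is used only as the integration start.
#'
#' @param cell an [hsr_cell()].
#' @param params an [hsr_params()].
#' @param theta culture temperature (degC).
#' @param tol residual tolerance on the largest absolute derivative.
#' @return Converged state vector.
#' @export
steady_state <- function(cell, params = hsr_params(), theta = 37,
                         tol = 1e-8) {
  y0 <- initial_state(cell, params, theta)
  horizon <- 20 * params$tau_hsp
  for (i in 1:4) {
    out <- .integrate_span(y0, c(0, horizon), theta, cell$hsf1_tot, params,
                           rtol = 1e-10, atol = 1e-12)
    y0 <- as_state(out[nrow(out), -1L])
    res <- max(abs(hsr_derivatives(y0, cell, theta, params)))
    if (res < tol) return(y0)
    horizon <- horizon * 2
  }
  stop(sprintf("steady state not reached: residual %.3e > %.1e", res, tol))
}

#' Simulate a single-cell trajectory
#'
#' Integrates the network over a temperature protocol (stiff-capable
#' adaptive integration, segment by segment across setpoint switches) and
#' samples the foci-fraction readout on the requested grid. The initial
#' state is the quasi-steady state conditional on the cell's `hsp0` at the
#' protocol's starting temperature.
#'
#' @param cell an [hsr_cell()].
#' @param protocol an [hsr_protocol()].
#' @param params an [hsr_params()].
#' @param times sampling grid (h), strictly increasing, within the protocol
#'   window; defaults to 10-minute sampling over the whole window.
#' @param cell_id identifier carried into the result.
#' @param condition optional named list of condition labels (e.g.
#'   temperature, coating).
#' @param rtol,atol integrator tolerances.
#' @return An object of class `hsr_trajectory`: list with `cell_id`,
#'   `times`, `f_values`, `total_fluorescence` (NA here; filled by the
#'   population generator), `condition`, and a `states` matrix of the
#'   sampled state variables.
#' @export
simulate_trajectory <- function(cell, protocol, params = hsr_params(),
                                times = NULL, cell_id = "cell",
                                condition = list(), rtol = 1e-8,
                                atol = 1e-10) {
  segs <- protocol$segments
  window <- c(segs$start[1L], segs$end[nrow(segs)])
  if (is.null(times)) {
    times <- seq(window[1L], window[2L], by = 1 / 6)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1L] < window[1L] - 1e-9 ||
      times[length(times)] > window[2L] + 1e-9) {
    stop("times must lie within the protocol window")
  }

  y <- initial_state(cell, params, protocol$theta0)
  states <- matrix(NA_real_, nrow = length(times), ncol = 4L,
                   dimnames = list(NULL, c("theta", "mfp", "hsp", "mhsp")))
  t_cur <- times[1L]
  if (abs(t_cur - segs$start[1L]) < 1e-12 || t_cur > segs$start[1L]) {
    # state at the first sample time equals the initial state only when the
    # first sample is the window start; otherwise integrate up to it
    if (t_cur > window[1L] + 1e-12) {
      for (k in seq_len(nrow(segs))) {
        a <- max(segs$start[k], window[1L]); b <- min(segs$end[k], t_cur)
        if (b <= a + 1e-12) next
        out <- .integrate_span(y, c(a, b), segs$setpoint[k], cell$hsf1_tot,
                               params, rtol, atol)
        y <- as_state(out[nrow(out), -1L])
        if (b >= t_cur - 1e-12) break
      }
    }
  }
  states[1L, ] <- y

  for (k in seq_len(nrow(segs))) {
    a <- max(segs$start[k], t_cur); b <- segs$end[k]
    if (b <= a + 1e-12) next
    inside <- which(times > a + 1e-12 & times <= b + 1e-12)
    grid <- sort(unique(c(a, times[inside], b)))
    out <- .integrate_span(y, grid, segs$setpoint[k], cell$hsf1_tot,
                           params, rtol, atol)
    if (length(inside)) {
      idx <- vapply(times[inside],
                    function(tt) which.min(abs(out[, 1L] - tt)), integer(1))
      states[inside, ] <- out[idx, -1L, drop = FALSE]
    }
    y <- as_state(out[nrow(out), -1L])
  }

  conc <- states[, c("mfp", "hsp", "mhsp")]
  if (min(conc) < -1e-9) {
    stop("integration produced substantially negative concentrations")
  }
  states[, c("mfp", "hsp", "mhsp")] <- pmax(conc, 0)

  f <- vapply(seq_len(nrow(states)),
              function(i) foci_fraction(states[i, ], cell), numeric(1))
  structure(list(cell_id = cell_id, times = times,
                 f_values = pmin(pmax(f, 0), 1),
                 total_fluorescence = rep(NA_real_, length(times)),
                 condition = condition, states = states),
            class = "hsr_trajectory")
}

#' @export
print.hsr_trajectory <- function(x, ...) {
  cat(sprintf("<hsr_trajectory> %s: %d samples over [%.2f, %.2f] h, max F = %.3g\n",
              x$cell_id, length(x$times), min(x$times), max(x$times),
              max(x$f_values)))
  invisible(x)
}
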