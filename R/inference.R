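#' Renormalize total fluorescence into HSF1 concentration
#'
#' HSF1:eGFP fluorescence is assumed proportional to HSF1 concentration in
#' each cell; the conversion factor is fixed by making the population mean
#' fluorescence correspond to the reference HSF1 concentration of the
#' model. The mean of the returned concentrations therefore equals the
#' reference exactly.
#'
#' @param total_fluorescence per-cell total HSF1:eGFP signal (arbitrary
#'   units, > 0; non-positive cells are excluded with a message and return
#'   NA).
#' @param reference_hsf1 reference concentration (uM); default the model's
#'   reference total HSF1.
#' @return Per-cell `hsf1_tot` (uM), NA where excluded.
#' @export
fluorescence_to_hsf1 <- function(total_fluorescence,
                                 reference_hsf1 = hsr_params()$hsf1_tot_ref) {
  ok <- is.finite(total_fluorescence) & total_fluorescence > 0
  if (!any(ok)) stop("no cells with positive fluorescence")
  if (any(!ok)) {
    message(sum(!ok), " cell(s) with non-positive fluorescence excluded")
  }
  out <- rep(NA_real_, length(total_fluorescence))
  out[ok] <- total_fluorescence[ok] *
    (reference_hsf1 / mean(total_fluorescence[ok]))
  out
}

#' Average fitting error between observed and modeled foci fractions
#'
#' @param observed_f,model_f equal-length F series on the same grid.
#' @param metric `"mad"` (mean absolute deviation, the default) or
#'   `"rmse"`.
#' @return Scalar error in absolute F units (so the 2 % satisfactory-fit
#'   gate corresponds to 0.02).
#' @export
fit_error <- function(observed_f, model_f, metric = c("mad", "rmse")) {
  metric <- match.arg(metric)
  if (length(observed_f) != length(model_f)) {
    stop("observed and model series must have the same length")
  }
  d <- observed_f - model_f
  switch(metric, mad = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Candidate grid of initial chaperone concentrations
#'
#' Log-spaced candidates spanning three decades around the normothermic
#' steady-state HSP level (0.1x to 100x), wide enough to express the
#' non-responder degeneracy at high chaperone levels.
#'
#' @param params an [hsr_params()].
#' @param n number of grid points.
#' @param lower_factor,upper_factor grid span as multiples of the
#'   steady-state HSP concentration.
#' @return Numeric vector of candidate `hsp0` values (uM), increasing.
#' @export
default_hsp0_grid <- function(params = hsr_params(), n = 60,
                              lower_factor = 0.1, upper_factor = 100) {
  ref <- steady_state(hsr_cell(params$hsf1_tot_ref, 0.1), params)[["hsp"]]
  exp(seq(log(lower_factor * ref), log(upper_factor * ref),
          length.out = n))
}

#' Fit a cell's initial chaperone concentration by grid search
#'
#' The single free parameter of the per-cell fit: with all network rates
#' fixed and the cell's total HSF1 set from its fluorescence, each
#' candidate initial HSP concentration is simulated through the protocol
#' and scored by the average F error against the observed trace. The full
#' error profile is retained (the likelihood step needs it), so the search
#' is exhaustive over the grid rather than a local optimization.
#'
#' @param trajectory an `hsr_trajectory` or per-cell record with `times`
#'   and observed `f_values`.
#' @param hsf1_tot the cell's total HSF1 concentration (uM).
#' @param protocol the [hsr_protocol()] the cell experienced.
#' @param params an [hsr_params()].
#' @param hsp0_grid candidate initial HSP concentrations (uM); default
#'   [default_hsp0_grid()].
#' @param error_gate satisfactory-fit threshold on the average error;
#'   default 0.02, the measurement error of F.
#' @param sigma measurement error used for the likelihood weights.
#' @param metric error metric, see [fit_error()].
#' @return An object of class `hsr_fit`: `cell_id`, `hsp0_grid`,
#'   `error_profile`, `best_hsp0`, `best_error`, `satisfactory`,
#'   `likelihood` (normalized weights over the grid), `n_time_points`.
#' @export
fit_cell <- function(trajectory, hsf1_tot, protocol,
                     params = hsr_params(), hsp0_grid = NULL,
                     error_gate = 0.02, sigma = 0.02,
                     metric = c("mad", "rmse")) {
  metric <- match.arg(metric)
  tr <- .as_one_cell(trajectory)
  if (is.null(hsp0_grid)) hsp0_grid <- default_hsp0_grid(params)
  errs <- vapply(hsp0_grid, function(h0) {
    sim <- tryCatch(
      simulate_trajectory(hsr_cell(hsf1_tot, h0), protocol, params,
                          times = tr$times, cell_id = tr$cell_id),
      error = function(e) NULL)
    if (is.null(sim)) return(Inf)
    fit_error(tr$f_values, sim$f_values, metric)
  }, numeric(1))
  if (all(!is.finite(errs))) {
    stop("all candidate simulations failed for cell ", tr$cell_id)
  }
  best <- which.min(errs)
  fit <- structure(
    list(cell_id = tr$cell_id, hsp0_grid = hsp0_grid,
         error_profile = errs, best_hsp0 = hsp0_grid[best],
         best_error = errs[best],
         satisfactory = errs[best] < error_gate,
         likelihood = NULL, n_time_points = length(tr$times)),
    class = "hsr_fit")
  fit$likelihood <- cell_likelihood(fit, sigma = sigma)
  fit
}

#' Likelihood weights over the candidate grid
#'
#' Converts a fit's error profile into a normalized likelihood under a
#' Gaussian measurement model on F with standard deviation `sigma` and
#' independent time points:
#' `w_j proportional to exp(-error_j^2 * n_t / (2 sigma^2))`.
#' Non-responders, whose error profile is flat at high chaperone levels,
#' get a likelihood plateau there instead of a spurious point estimate.
#'
#' @param fit an `hsr_fit`.
#' @param sigma measurement error on F; default 0.02.
#' @return Normalized weights (non-negative, sum 1) over `fit$hsp0_grid`.
#' @export
cell_likelihood <- function(fit, sigma = 0.02) {
  errs <- fit$error_profile
  if (all(!is.finite(errs))) stop("error profile has no finite entries")
  n_t <- fit$n_time_points
  ll <- -errs^2 * n_t / (2 * sigma^2)
  ll[!is.finite(errs)] <- -Inf
  w <- exp(ll - max(ll[is.finite(ll)]))
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Population-level chaperone expression distribution
#'
#' Sums the per-cell likelihood weights over a shared candidate grid and
#' renormalizes: each cell contributes a unit of probability mass, spread
#' over the chaperone levels compatible with its response.
#'
#' @param fits list of `hsr_fit` objects sharing one `hsp0_grid`.
#' @return List of class `hsr_expression_distribution`: `grid` (uM),
#'   `density` (sums to 1), `n_cells`.
#' @export
population_distribution <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  grid <- fits[[1L]]$hsp0_grid
  for (f in fits) {
    if (length(f$hsp0_grid) != length(grid) ||
        any(abs(log(f$hsp0_grid) - log(grid)) > 1e-9)) {
      stop("all fits must share one hsp0 grid")
    }
  }
  total <- Reduce(`+`, lapply(fits, function(f) f$likelihood))
  structure(list(grid = grid, density = total / sum(total),
                 n_cells = length(fits)),
            class = "hsr_expression_distribution")
}

#' Median of a gridded expression distribution
#'
#' The grid point at which the cumulative mass first reaches one half.
#'
#' @param dist an `hsr_expression_distribution`.
#' @return Concentration (uM).
#' @export
distribution_median <- function(dist) {
  dist$grid[which(cumsum(dist$density) >= 0.5)[1L]]
}

#' Fit-success comparison: HSF1 heterogeneity alone vs. adding chaperone
#'
#' Fits every cell twice: a control arm where the initial chaperone level
#' is pinned at the population steady-state value (only HSF1 heterogeneity
#' enters), and a free arm where it is fitted on the grid. Reports the
#' percentage of cells whose average error passes the satisfactory-fit
#' gate in each arm. The control value is inserted into the grid, so the
#' free arm can never do worse.
#'
#' @param trajectories list of per-cell trajectories (or long table).
#' @param hsf1_tots per-cell total HSF1 (uM), aligned with the cells.
#' @param protocol the shared [hsr_protocol()].
#' @param params an [hsr_params()].
#' @param hsp0_grid candidate grid; default [default_hsp0_grid()].
#' @param control_hsp0 chaperone level of the control arm; default the
#'   normothermic steady-state HSP concentration.
#' @param error_gate satisfactory-fit threshold; default 0.02.
#' @return List with `percent_free`, `percent_control`, and `fits` (the
#'   free-arm `hsr_fit` objects, whose error profiles also carry the
#'   control candidate).
#' @export
fit_success_comparison <- function(trajectories, hsf1_tots, protocol,
                                   params = hsr_params(),
                                   hsp0_grid = NULL, control_hsp0 = NULL,
                                   error_gate = 0.02) {
  cells <- .as_cell_list(trajectories)
  if (length(cells) != length(hsf1_tots)) {
    stop("need one hsf1_tot per trajectory")
  }
  if (is.null(control_hsp0)) {
    control_hsp0 <- steady_state(hsr_cell(params$hsf1_tot_ref, 0.1),
                                 params)[["hsp"]]
  }
  if (is.null(hsp0_grid)) hsp0_grid <- default_hsp0_grid(params)
  grid <- sort(unique(c(hsp0_grid, control_hsp0)))
  ctrl_idx <- which(abs(grid - control_hsp0) < 1e-12)[1L]

  fits <- vector("list", length(cells))
  ctrl_err <- numeric(length(cells))
  for (i in seq_along(cells)) {
    fits[[i]] <- fit_cell(cells[[i]], hsf1_tots[i], protocol, params,
                          hsp0_grid = grid, error_gate = error_gate)
    ctrl_err[i] <- fits[[i]]$error_profile[ctrl_idx]
  }
  free_ok <- vapply(fits, function(f) f$satisfactory, logical(1))
  list(percent_free = 100 * mean(free_ok),
       percent_control = 100 * mean(ctrl_err < error_gate),
       fits = fits)
}
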