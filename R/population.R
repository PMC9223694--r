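#' @importFrom stats rnorm
NULL

#' Log-normal draws parameterized by median and coefficient of variation
#'
#' Protein expression across cells is log-normal; the natural summary pair
#' is the median (the log-scale location) and the coefficient of variation.
#' Draws are `median * exp(sigma * Z)` with
#' `sigma = sqrt(log(1 + cv^2))`, so the distribution median equals
#' `median` and the CV equals `cv` exactly.
#'
#' @param n number of draws.
#' @param median distribution median (> 0).
#' @param cv coefficient of variation (>= 0); 0 returns `median` exactly.
#' @param seed optional integer; when given, draws are made under a local
#'   RNG state (the caller's RNG is untouched).
#' @return `n` positive values.
#' @export
sample_lognormal <- function(n, median, cv, seed = NULL) {
  if (!is.finite(median) || median <= 0) stop("median must be positive")
  if (!is.finite(cv) || cv < 0) stop("cv must be non-negative")
  if (cv == 0) return(rep(median, n))
  sdlog <- sqrt(log(1 + cv^2))
  z <- if (is.null(seed)) rnorm(n) else .with_seed(seed, rnorm(n))
  median * exp(sdlog * z)
}

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic single-cell experiment
#'
#' Encodes the study design the generator emulates: a population of cells
#' with log-normal chaperone and HSF1 expression, exposed to a transient
#' hyperthermia and imaged every ten minutes, with measurement noise on the
#' foci fraction.
#'
#' @param n_cells number of cells; default 500, a typical imaging run.
#' @param hsp0_median median initial chaperone concentration (uM); default
#'   the normothermic steady-state HSP level of the reference cell.
#' @param hsp0_cv chaperone expression CV; default 0.4.
#' @param hsf1_median median total HSF1 (uM); default the model reference.
#' @param hsf1_cv HSF1 expression CV; default 0.4.
#' @param stress_temperature hyperthermia setpoint (degC).
#' @param stress_duration stress window length (h); default 3.
#' @param pre_h pre-stress observation (h); default one sample at -10 min.
#' @param post_h post-stress observation (h); default 1.
#' @param sampling_interval imaging period (h); default 1/6 (10 minutes).
#' @param noise_sigma additive Gaussian measurement noise on F; default
#'   0.02.
#' @param detection_limit foci detection limit of the imaging pipeline;
#'   time points whose true F is below it are recorded as 0 (the blob
#'   detector does not fire), and measurement noise applies only to
#'   detected foci. Default 0.01; set to 0 to disable censoring.
#' @param fluorescence_scale arbitrary-unit scale converting hsf1_tot to
#'   total fluorescence.
#' @param fluorescence_cv multiplicative log-normal noise on the
#'   fluorescence readout; default 0 (fluorescence exactly proportional to
#'   HSF1).
#' @param expression_correlation log-scale correlation between hsp0 and
#'   hsf1_tot across cells; default 0.
#' @param coating condition label, `"col-"` or `"col+"`.
#' @param seed integer seed making the whole dataset reproducible.
#' @return List of class `hsr_population_spec`.
#' @export
population_spec <- function(n_cells = 500, hsp0_median = NULL,
                            hsp0_cv = 0.4, hsf1_median = NULL,
                            hsf1_cv = 0.4, stress_temperature = 43,
                            stress_duration = 3, pre_h = 1 / 6, post_h = 1,
                            sampling_interval = 1 / 6, noise_sigma = 0.02,
                            detection_limit = 0.01,
                            fluorescence_scale = 1000,
                            fluorescence_cv = 0,
                            expression_correlation = 0, coating = "col-",
                            seed = 1L) {
  stopifnot(n_cells >= 1, hsp0_cv >= 0, hsf1_cv >= 0,
            sampling_interval > 0, noise_sigma >= 0, detection_limit >= 0,
            abs(expression_correlation) <= 1)
  structure(list(n_cells = as.integer(n_cells), hsp0_median = hsp0_median,
                 hsp0_cv = hsp0_cv, hsf1_median = hsf1_median,
                 hsf1_cv = hsf1_cv,
                 stress_temperature = stress_temperature,
                 stress_duration = stress_duration, pre_h = pre_h,
                 post_h = post_h, sampling_interval = sampling_interval,
                 noise_sigma = noise_sigma,
                 detection_limit = detection_limit,
                 fluorescence_scale = fluorescence_scale,
                 fluorescence_cv = fluorescence_cv,
                 expression_correlation = expression_correlation,
                 coating = coating, seed = as.integer(seed)),
            class = "hsr_population_spec")
}

#' Shift a population spec to a chaperone-overexpressing condition
#'
#' Models a culture-condition effect (e.g. collagen coating) as a
#' multiplicative shift of the median chaperone expression, all else
#' unchanged.
#'
#' @param spec an [population_spec()].
#' @param chaperone_median_factor multiplier on `hsp0_median` (> 0).
#' @param coating new condition label; default `"col+"`.
#' @return A modified copy of the spec.
#' @export
condition_shift <- function(spec, chaperone_median_factor,
                            coating = "col+") {
  stopifnot(chaperone_median_factor > 0)
  out <- spec
  if (is.null(out$hsp0_median)) {
    out$hsp0_median <- steady_state(hsr_cell(hsr_params()$hsf1_tot_ref, 0.1),
                                    hsr_params())[["hsp"]]
  }
  out$hsp0_median <- out$hsp0_median * chaperone_median_factor
  out$coating <- coating
  out
}

#' Generate a synthetic single-cell dataset
#'
#' Draws per-cell expression levels, simulates every cell through the
#' stress protocol, and emits a long trajectory table with measurement
#' noise plus a ground-truth sidecar. Identical `(spec, seed)` give
#' byte-identical output.
#'
#' @param spec an [population_spec()].
#' @param params an [hsr_params()].
#' @return List with `trajectories` (data.frame: `cell_id`, `time_h`, `F`,
#'   `total_fluorescence`, `temperature_C`, `coating`), `ground_truth`
#'   (data.frame: `cell_id`, `true_hsp0_uM`, `true_hsf1_uM`), `protocol`,
#'   and `spec` (with defaults resolved).
#' @export
generate_population <- function(spec, params = hsr_params()) {
  if (is.null(spec$hsp0_median) || is.null(spec$hsf1_median)) {
    ss <- steady_state(hsr_cell(params$hsf1_tot_ref, 0.1), params)
    if (is.null(spec$hsp0_median)) spec$hsp0_median <- ss[["hsp"]]
    if (is.null(spec$hsf1_median)) spec$hsf1_median <- params$hsf1_tot_ref
  }
  protocol <- stress_protocol(spec$stress_temperature,
                              spec$stress_duration, spec$pre_h,
                              spec$post_h)
  times <- seq(-spec$pre_h,
               spec$stress_duration + spec$post_h + 1e-9,
               by = spec$sampling_interval)

  draws <- .with_seed(spec$seed, {
    z1 <- rnorm(spec$n_cells)
    z2 <- rnorm(spec$n_cells)
    rho <- spec$expression_correlation
    zh <- rho * z1 + sqrt(1 - rho^2) * z2
    list(
      hsf1 = spec$hsf1_median * exp(sqrt(log(1 + spec$hsf1_cv^2)) * z1),
      hsp0 = spec$hsp0_median * exp(sqrt(log(1 + spec$hsp0_cv^2)) * zh),
      f_noise = matrix(rnorm(spec$n_cells * length(times),
                             sd = spec$noise_sigma),
                       nrow = spec$n_cells),
      fl_noise = if (spec$fluorescence_cv > 0)
        exp(sqrt(log(1 + spec$fluorescence_cv^2)) * rnorm(spec$n_cells))
      else rep(1, spec$n_cells)
    )
  })

  ids <- sprintf("cell_%04d", seq_len(spec$n_cells))
  tabs <- vector("list", spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    tr <- tryCatch(
      simulate_trajectory(hsr_cell(draws$hsf1[i], draws$hsp0[i]), protocol,
                          params, times = times, cell_id = ids[i]),
      error = function(e) stop("cell ", ids[i], ": ", conditionMessage(e)))
    f <- tr$f_values
    detected <- f >= spec$detection_limit
    if (spec$noise_sigma > 0) {
      f <- pmin(pmax(f + draws$f_noise[i, ], 0), 1)
    }
    f[!detected] <- 0
    tabs[[i]] <- data.frame(
      cell_id = ids[i], time_h = times, F = f,
      total_fluorescence = draws$hsf1[i] * spec$fluorescence_scale *
        draws$fl_noise[i],
      temperature_C = spec$stress_temperature, coating = spec$coating)
  }
  trajectories <- do.call(rbind, tabs)
  rownames(trajectories) <- NULL
  ground_truth <- data.frame(cell_id = ids, true_hsp0_uM = draws$hsp0,
                             true_hsf1_uM = draws$hsf1)
  list(trajectories = trajectories, ground_truth = ground_truth,
       protocol = protocol, spec = spec)
}

#' Write / read trajectory tables
#'
#' The on-disk dialect is a plain CSV with header
#' `cell_id,time_h,F,total_fluorescence,temperature_C,coating`, times in
#' hours relative to stress onset and F as a fraction in [0, 1].
#'
#' @param trajectories trajectory data.frame.
#' @param path file path.
#' @return `read_trajectories` returns the data.frame.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
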