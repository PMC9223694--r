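#' @importFrom stats quantile median coef nls resid setNames
NULL

# trajectories may arrive as a list of hsr_trajectory objects or as a long
# table (cell_id, time_h, F, ...); normalize to a list of per-cell records
.as_cell_list <- function(trajectories) {
  if (is.data.frame(trajectories)) {
    need <- c("cell_id", "time_h", "F")
    if (!all(need %in% names(trajectories))) {
      stop("trajectory table must have columns cell_id, time_h, F")
    }
    split_rows <- split(trajectories, trajectories$cell_id)
    lapply(split_rows, function(d) {
      d <- d[order(d$time_h), , drop = FALSE]
      list(cell_id = as.character(d$cell_id[1L]), times = d$time_h,
           f_values = d$F,
           total_fluorescence = if ("total_fluorescence" %in% names(d))
             d$total_fluorescence else rep(NA_real_, nrow(d)))
    })
  } else if (inherits(trajectories, "hsr_trajectory")) {
    setNames(list(unclass(trajectories)), trajectories$cell_id)
  } else if (is.list(trajectories) && !is.null(trajectories$times)) {
    setNames(list(trajectories), as.character(trajectories$cell_id))
  } else {
    # a list of per-cell records, in any of the accepted forms
    cells <- lapply(trajectories, function(x) .as_cell_list(x)[[1L]])
    setNames(cells, vapply(cells, function(x) as.character(x$cell_id),
                           character(1)))
  }
}

# a single cell's record, whatever form it arrives in
.as_one_cell <- function(trajectory) {
  cells <- .as_cell_list(trajectory)
  if (length(cells) != 1L) stop("expected exactly one cell, got ",
                                length(cells))
  cells[[1L]]
}

# nearest sample to a requested time point, within a matching tolerance
.match_time <- function(times, t, tol = 1 / 12) {
  i <- which.min(abs(times - t))
  if (abs(times[i] - t) > tol + 1e-12) {
    stop(sprintf("no sample within %.3f h of t = %.3f h", tol, t))
  }
  i
}

#' Call responder status per cell
#'
#' A cell is a responder ("positive") when its foci fraction strictly
#' exceeds the detection threshold at some time during the observation
#' window. The call is made once per cell from the maximum of F over the
#' window; it is not a per-time-point gate.
#'
#' @param trajectories list of `hsr_trajectory` objects or a long table
#'   with columns `cell_id`, `time_h`, `F`.
#' @param threshold detection threshold on F; default 0.01 (the 1 %
#'   microscopy detection limit for foci).
#' @param window two-element numeric, observation window (h); default the
#'   3-hour hyperthermia phase `c(0, 3)`.
#' @return data.frame with `cell_id`, `max_f`, `is_positive`.
#' @export
call_responders <- function(trajectories, threshold = 0.01,
                            window = c(0, 3)) {
  cells <- .as_cell_list(trajectories)
  if (!length(cells)) stop("no trajectories supplied")
  rows <- lapply(cells, function(tr) {
    sel <- tr$times >= window[1L] - 1e-9 & tr$times <= window[2L] + 1e-9
    if (!any(sel)) stop("trajectory ", tr$cell_id,
                        " has no samples in the window")
    mx <- max(tr$f_values[sel])
    data.frame(cell_id = tr$cell_id, max_f = mx,
               is_positive = mx > threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of responding cells
#'
#' @param calls data.frame from [call_responders()].
#' @return Proportion of positive cells in [0, 1].
#' @export
responder_fraction <- function(calls) {
  if (nrow(calls) < 1L) stop("need at least one responder call")
  mean(calls$is_positive)
}

#' Hill summary curve of responder fraction vs. temperature
#'
#' Least-squares fit of
#' `fraction(T) = plateau * (T - 37)^h / ((T50 - 37)^h + (T - 37)^h)`
#' to responder fractions measured at several stress temperatures. As in
#' dose-response practice this is an eye-guide summary, not a mechanistic
#' fit.
#'
#' @param temperatures stress temperatures (degC), all > 37.
#' @param fractions responder fractions in [0, 1], same length.
#' @return List with `t50`, `hill`, `plateau`, `residual` (sum of squared
#'   residuals) and `degenerate` (TRUE when the data carry no response to
#'   fit, in which case parameters are NA).
#' @export
fit_hill_curve <- function(temperatures, fractions) {
  stopifnot(length(temperatures) == length(fractions),
            length(temperatures) >= 3L, all(temperatures > 37))
  if (all(fractions <= 0)) {
    return(list(t50 = NA_real_, hill = NA_real_, plateau = NA_real_,
                residual = 0, degenerate = TRUE))
  }
  d <- data.frame(x = temperatures - 37, y = fractions)
  half <- max(fractions) / 2
  t50_guess <- d$x[which.min(abs(fractions - half))]
  fit <- minpack.lm::nlsLM(
    y ~ plateau * x^h / (t50^h + x^h), data = d,
    start = list(plateau = max(fractions), h = 8,
                 t50 = max(t50_guess, 0.5)),
    lower = c(plateau = 0, h = 0.1, t50 = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- coef(fit)
  list(t50 = unname(cf["t50"]) + 37, hill = unname(cf["h"]),
       plateau = unname(cf["plateau"]),
       residual = sum(resid(fit)^2), degenerate = FALSE)
}

#' Mean foci dynamics over responding cells
#'
#' Pointwise arithmetic mean of F restricted to cells called positive.
#' Conditioning is on cell identity (the responder call), so low-F time
#' points of responding cells are retained and do not bias the average.
#'
#' @inheritParams call_responders
#' @param calls data.frame from [call_responders()].
#' @return data.frame with `time_h`, `mean_f`, `n_cells`; zero rows (with a
#'   warning) when no cell is positive.
#' @export
mean_foci_dynamics <- function(trajectories, calls) {
  cells <- .as_cell_list(trajectories)
  pos <- calls$cell_id[calls$is_positive]
  if (!length(pos)) {
    warning("no positive cells; returning empty result")
    return(data.frame(time_h = numeric(0), mean_f = numeric(0),
                      n_cells = integer(0)))
  }
  kept <- cells[as.character(pos)]
  times <- kept[[1L]]$times
  fmat <- vapply(kept, function(tr) {
    if (length(tr$times) != length(times) ||
        any(abs(tr$times - times) > 1e-9)) {
      stop("positive cells must share one sampling grid")
    }
    tr$f_values
  }, numeric(length(times)))
  data.frame(time_h = times, mean_f = rowMeans(as.matrix(fmat)),
             n_cells = length(kept))
}

#' Amplitude distribution of the response at chosen time points
#'
#' Box-and-whisker style percentile summaries (9/25/50/75/91) of F over
#' responding cells, at the samples nearest the requested time points.
#'
#' @inheritParams mean_foci_dynamics
#' @param time_points times (h) at which to summarize; default 1 h and 3 h
#'   after stress onset.
#' @return data.frame with one row per time point: `time_h`, `p09`, `p25`,
#'   `p50`, `p75`, `p91`, `n_cells`.
#' @export
amplitude_distribution <- function(trajectories, calls,
                                   time_points = c(1, 3)) {
  cells <- .as_cell_list(trajectories)
  pos <- as.character(calls$cell_id[calls$is_positive])
  if (length(pos) < 2L) stop("need at least two positive cells")
  kept <- cells[pos]
  rows <- lapply(time_points, function(tp) {
    f <- vapply(kept, function(tr) {
      tr$f_values[.match_time(tr$times, tp)]
    }, numeric(1))
    q <- quantile(f, c(0.09, 0.25, 0.50, 0.75, 0.91), names = FALSE,
                  type = 7)
    data.frame(time_h = tp, p09 = q[1], p25 = q[2], p50 = q[3],
               p75 = q[4], p91 = q[5], n_cells = length(f))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relaxation index of a single trajectory
#'
#' The ratio of the foci fraction three hours after stress onset to its
#' value one hour after onset. 0 means perfect adaptation (the response
#' rose and fully relaxed), 1 a plateau, values above 1 a continuing
#' increase.
#'
#' @param trajectory an `hsr_trajectory` or per-cell record.
#' @param t_early,t_late the two sampling times (h).
#' @return The index (dimensionless), or NA (with a message) when F at the
#'   early time point is 0, where the ratio is undefined.
#' @export
relaxation_index <- function(trajectory, t_early = 1, t_late = 3) {
  tr <- .as_one_cell(trajectory)
  f1 <- tr$f_values[.match_time(tr$times, t_early)]
  f3 <- tr$f_values[.match_time(tr$times, t_late)]
  if (f1 <= 0) {
    message("cell ", tr$cell_id, ": F(", t_early,
            " h) = 0, relaxation index undefined; excluded")
    return(NA_real_)
  }
  f3 / f1
}

#' Histogram of relaxation indices
#'
#' Counts over four contiguous half-open bins capturing the qualitative
#' response shapes: adaptation (eta < 0.25), imperfect adaptation
#' (0.25 <= eta < 0.75), plateau (0.75 <= eta < 1.25) and continuing
#' increase (eta >= 1.25).
#'
#' @param etas relaxation indices (NAs dropped).
#' @return List of class `hsr_relaxation_histogram`: `breaks`, `counts`,
#'   `n_cells`.
#' @export
relaxation_histogram <- function(etas) {
  etas <- etas[!is.na(etas)]
  if (any(etas < 0)) stop("negative relaxation index")
  breaks <- c(0, 0.25, 0.75, 1.25, Inf)
  counts <- as.integer(table(cut(etas, breaks, right = FALSE,
                                 include.lowest = FALSE)))
  structure(list(breaks = breaks, counts = counts, n_cells = length(etas)),
            class = "hsr_relaxation_histogram")
}

#' Activation function binned by expression ratio
#'
#' The empirical dependence of the foci fraction on the
#' chaperone-to-HSF1 expression ratio: cells are segmented into
#' logarithmically spaced ratio classes and the F distribution in each
#' class summarized by its quartiles. Sparse classes are suppressed.
#'
#' @param f_values one F snapshot per cell.
#' @param chaperone_level per-cell chaperone expression (arbitrary units,
#'   > 0; non-positive cells are excluded with a message).
#' @param hsf1_level per-cell HSF1 expression (same convention).
#' @param min_class_size classes with at most this many cells are dropped;
#'   default 30 (strictly more than 30 cells are required to display a
#'   class).
#' @param classes_per_decade number of log-spaced classes per decade of
#'   ratio.
#' @return data.frame with `ratio_lo`, `ratio_hi`, `ratio_mid` (geometric
#'   midpoint), `p25`, `p50`, `p75`, `n_cells`.
#' @export
activation_function_by_ratio <- function(f_values, chaperone_level,
                                         hsf1_level, min_class_size = 30,
                                         classes_per_decade = 8) {
  stopifnot(length(f_values) == length(chaperone_level),
            length(f_values) == length(hsf1_level))
  ok <- chaperone_level > 0 & hsf1_level > 0 &
    is.finite(chaperone_level) & is.finite(hsf1_level)
  if (any(!ok)) {
    message(sum(!ok), " cell(s) with non-positive expression excluded")
  }
  ratio <- chaperone_level[ok] / hsf1_level[ok]
  f <- f_values[ok]
  if (!length(ratio)) stop("no cells with valid expression levels")

  lr <- log10(ratio)
  step <- 1 / classes_per_decade
  lo <- floor(min(lr) / step) * step
  edges <- seq(lo, max(lr) + step, by = step)
  cls <- findInterval(lr, edges, rightmost.closed = FALSE)

  rows <- lapply(sort(unique(cls)), function(k) {
    fk <- f[cls == k]
    if (length(fk) <= min_class_size) return(NULL)
    q <- quantile(fk, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(ratio_lo = 10^edges[k], ratio_hi = 10^edges[k + 1L],
               ratio_mid = 10^((edges[k] + edges[k + 1L]) / 2),
               p25 = q[1], p50 = q[2], p75 = q[3], n_cells = length(fk))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ratio_lo = numeric(0), ratio_hi = numeric(0),
                      ratio_mid = numeric(0), p25 = numeric(0),
                      p50 = numeric(0), p75 = numeric(0),
                      n_cells = integer(0))
  }
  rownames(out) <- NULL
  out
}
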