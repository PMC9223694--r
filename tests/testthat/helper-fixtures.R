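# shared fixtures, computed once per test run
ref_params <- hsr_params()
ref_cell <- hsr_cell(ref_params$hsf1_tot_ref, 0.1)
ref_steady <- steady_state(ref_cell, ref_params)
ref_protocol_43 <- stress_protocol(43)

# sort-based percentile oracle: linear interpolation between order
# statistics (h = (n-1)p + 1), independent of stats::quantile
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(x[n])
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }, numeric(1))
}

# hand-built trajectory record on a 10-minute grid
make_trace <- function(times, f, cell_id = "c1") {
  list(cell_id = cell_id, times = times, f_values = f,
       total_fluorescence = rep(NA_real_, length(times)))
}

# small synthetic population, memoized across tests within a run
pop_cache <- new.env(parent = emptyenv())
cached_population <- function(key, spec) {
  if (is.null(pop_cache[[key]])) {
    pop_cache[[key]] <- generate_population(spec)
  }
  pop_cache[[key]]
}
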