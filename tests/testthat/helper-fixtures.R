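# Shared small-scale fixtures built in code.

small_geom <- function(L0 = 200, width = 60) {
  domain_geometry(L0 = L0, ymin = 0, ymax = width)
}

# a non-overlapping population with clocks attached, deterministic given seed
small_population <- function(n_throw = 60, geom = small_geom(), R = 7,
                             params = cycle_params(), seed = 42) {
  set.seed(seed)
  cells <- initialize_cells(geom, n_throw, R)
  n <- nrow(cells)
  cells$T_len <- sample_cycle_length(n, "slow", params)
  cells$C <- sample_initial_age(cells$T_len)
  cells$program <- rep("slow", n)
  cells$recruited <- rep(FALSE, n)
  cells$lineage <- cells$cell_id
  cells
}

# brute-force front-cell oracle: double loop over all pairs
front_oracle <- function(cells, geom, R) {
  n <- nrow(cells)
  W <- geom$width
  vapply(seq_len(n), function(i) {
    dy <- cells$y - cells$y[i]
    dy <- abs(dy - W * round(dy / W))
    !any(cells$x > cells$x[i] & dy < R)
  }, logical(1))
}

# small deterministic observation curve
curve_of <- function(t, value) tibble::tibble(t = t, value = value)
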