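# Shared fixtures, built in code.

# Regular grid of rectangular patches; ids row-major p01, p02, ...
grid_patches <- function(nx = 2, ny = 1, cell = 1000,
                         landuse = rep("field", nx * ny), origin = c(0, 0)) {
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  rings <- lapply(seq_len(nrow(grid)), function(k) {
    x0 <- origin[1] + (grid$ix[k] - 1) * cell
    y0 <- origin[2] + (grid$iy[k] - 1) * cell
    cbind(c(x0, x0 + cell, x0 + cell, x0), c(y0, y0, y0 + cell, y0 + cell))
  })
  make_patches(sprintf("p%02d", seq_len(nrow(grid))), landuse, rings)
}

# Hourly track through the supplied coordinates.
hourly_track <- function(xy, id = "h1",
                         t0 = as.POSIXct("2020-06-01", tz = "UTC")) {
  xy <- matrix(xy, ncol = 2)
  tibble::tibble(individual_id = id,
                 timestamp = t0 + 3600 * (seq_len(nrow(xy)) - 1),
                 x = xy[, 1], y = xy[, 2])
}

# Brute-force moving-window oracle: for every start fix, loop over all
# fixes and collect those inside [t0, t0+T] reachable without a gap.
brute_force_windows <- function(fixes, T_hours, interval_hours = 1) {
  tt <- as.numeric(fixes$timestamp)
  n <- length(tt)
  lapply(seq_len(n), function(i) {
    rows <- i
    for (j in seq(i + 1, length.out = max(0, n - i))) {
      if (tt[j] - tt[j - 1] > interval_hours * 3600 + 1) break
      if (tt[j] > tt[i] + T_hours * 3600) break
      rows <- c(rows, j)
    }
    rows
  })
}
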