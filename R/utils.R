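# Internal helpers shared across modules.

# Validation error with a consistent class so callers can catch them.
stop_invalid <- function(msg, class = "endolink_invalid") {
  abort(msg, class = c(class, "endolink_error"))
}

check_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    stop_invalid(sprintf("`%s` must be positive and finite.", name),
                 class = "endolink_invalid_dimension")
  }
  invisible(x)
}

# Species name normalization used when matching trait tables to tree tips:
# case-insensitive, spaces and underscores unified. Documented, never fuzzy.
normalize_species <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ _]+", "_", x)
}

#' Highest posterior density interval
#'
#' Narrowest interval containing a given probability mass of a sample,
#' computed by scanning all windows of the sorted draws.
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Probability mass the interval must contain (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n == 0) stop_invalid("No finite draws supplied.")
  k <- max(1L, ceiling(prob * n))
  if (k >= n) {
    return(c(lower = draws[1], upper = draws[n]))
  }
  starts <- seq_len(n - k)
  widths <- draws[starts + k] - draws[starts]
  i <- which.min(widths)
  c(lower = draws[i], upper = draws[i + k])
}

# Effective sample size via the initial positive sequence estimator on
# sample autocorrelations (Geyer). Conservative for short chains.
ess <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(n)
  acf_vals <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[, 1, 1]
  # sum consecutive pairs while positive
  s <- 0
  m <- floor((length(acf_vals) - 1) / 2)
  for (j in seq_len(m)) {
    pair <- acf_vals[2 * j] + acf_vals[2 * j + 1]
    if (pair < 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

# Split-R-hat across chains (each column one chain), plain Gelman-Rubin on
# split halves.
split_rhat <- function(draws_matrix) {
  halves <- do.call(cbind, lapply(seq_len(ncol(draws_matrix)), function(j) {
    x <- draws_matrix[, j]
    h <- floor(length(x) / 2)
    cbind(x[seq_len(h)], x[h + seq_len(h)])
  }))
  m <- ncol(halves)
  n <- nrow(halves)
  mu <- colMeans(halves)
  w <- mean(apply(halves, 2, var))
  b <- n * var(mu)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}
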