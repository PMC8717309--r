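#' @export
print.pmm_fit <- function(x, ...) {
  cat("Bayesian phylogenetic mixed model (Gibbs)\n")
  cat(sprintf("  n = %d, %s phylogenetic term, %d chains x %d retained draws\n",
              x$n, if (x$has_phylo) "with" else "without",
              x$settings$chains,
              (x$settings$iterations - x$settings$burnin) %/% x$settings$thin))
  cat(sprintf("  DIC = %.2f (pD = %.2f)\n", x$dic, x$pd))
  print(tidy(x))
  invisible(x)
}

#' Tidy posterior summaries of a phylogenetic mixed model
#'
#' One row per parameter (fixed effects, variance components, and the
#' phylogenetic heritability) with posterior mean, SD, and 95% HPD bounds.
#'
#' @param x A [pmm_fit()] object.
#' @param prob HPD mass (default 0.95).
#' @param ... Unused.
#' @export
tidy.pmm_fit <- function(x, prob = 0.95, ...) {
  pars <- setdiff(names(x$draws), c(".chain", ".iteration"))
  if (!x$has_phylo) pars <- setdiff(pars, c("h2", "sigma2_phylo"))
  purrr::map_dfr(pars, function(pn) {
    v <- x$draws[[pn]]
    hpd <- hpd_interval(v, prob)
    tibble(term = pn, estimate = mean(v), std.error = sd(v),
           conf.low = hpd[["lower"]], conf.high = hpd[["upper"]])
  })
}

#' One-row model summary
#'
#' @param x A [pmm_fit()] object.
#' @param ... Unused.
#' @return Tibble with sample size, DIC, pD, heritability posterior mean
#'   and HPD, worst split-R-hat and smallest effective sample size.
#' @export
glance.pmm_fit <- function(x, ...) {
  h2 <- pmm_heritability(x)
  tibble(n = x$n, dic = x$dic, pd = x$pd,
         h2_mean = h2$mean, h2_hpd_lower = h2$hpd_lower,
         h2_hpd_upper = h2$hpd_upper,
         max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
         min_ess = min(x$diagnostics$ess))
}

#' Posterior density panels for a fitted mixed model
#'
#' @param object A [pmm_fit()] object.
#' @param ... Unused.
#' @return A ggplot: per-parameter posterior densities, colored by chain.
#' @export
autoplot.pmm_fit <- function(object, ...) {
  pars <- setdiff(names(object$draws), c(".chain", ".iteration"))
  if (!object$has_phylo) pars <- setdiff(pars, c("h2", "sigma2_phylo"))
  long <- object$draws %>%
    select(all_of(c(".chain", pars))) %>%
    tidyr::pivot_longer(all_of(pars), names_to = "parameter") %>%
    mutate(.chain = factor(.data$.chain))
  ggplot(long, aes(x = .data$value, color = .data$.chain)) +
    geom_density() +
    facet_wrap(~parameter, scales = "free") +
    labs(x = NULL, y = "posterior density", color = "chain") +
    theme_minimal()
}

#' @export
print.pmm_ranking <- function(x, ...) {
  cat("DIC model ranking (", sum(!x$failed), " fitted, ",
      sum(x$competing, na.rm = TRUE), " competing)\n", sep = "")
  NextMethod()
  invisible(x)
}

#' DIC ranking plot
#'
#' @param object A [pmm_dredge()] ranking.
#' @param ... Unused.
#' @export
autoplot.pmm_ranking <- function(object, ...) {
  d <- as_tibble(object) %>%
    filter(!.data$failed) %>%
    mutate(model = factor(.data$model, levels = rev(.data$model)))
  ggplot(d, aes(x = .data$delta_dic, y = .data$model,
                fill = .data$competing)) +
    geom_col() +
    labs(x = expression(Delta * "DIC"), y = NULL, fill = "competing") +
    theme_minimal()
}
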