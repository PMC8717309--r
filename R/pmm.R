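#' Build the response and design matrix for the germination model
#'
#' The response is log(SGS + 1) (zeros are informative and kept); the
#' predictors are log-transformed to reduce heteroscedasticity, with an
#' intercept column first. Species excluded from modelling (zero control
#' capacity) must be removed before calling.
#'
#' @param table Derived trait table.
#' @param predictors Character vector of predictor columns (may be empty
#'   for an intercept-only design).
#' @param response Response column, default `"sgs"`.
#' @return List with `y` (numeric), `X` (matrix, columns
#'   `(Intercept)`, `log(<predictor>)` in the given order), and
#'   `species` (the `species_name` column if present).
#' @export
pmm_design <- function(table, predictors = character(), response = "sgs") {
  d <- as.data.frame(table)
  if (!response %in% names(d)) {
    stop_invalid(sprintf("Response column `%s` not found.", response))
  }
  y_raw <- d[[response]]
  if (anyNA(y_raw)) {
    stop_invalid(sprintf("Missing values in `%s` (rows %s); exclude those species first.",
                         response,
                         paste(head(which(is.na(y_raw)), 5), collapse = ", ")))
  }
  if (any(y_raw < 0)) stop_invalid("Response must be non-negative.")
  y <- log(y_raw + 1)
  X <- matrix(1, nrow = nrow(d), ncol = 1,
              dimnames = list(NULL, "(Intercept)"))
  for (p in predictors) {
    if (!p %in% names(d)) stop_invalid(sprintf("Predictor `%s` not found.", p))
    v <- d[[p]]
    bad <- which(is.na(v) | v <= 0)
    if (length(bad)) {
      stop_invalid(sprintf("Predictor `%s` must be positive for the log transform (rows %s).",
                           p, paste(head(bad, 5), collapse = ", ")))
    }
    X <- cbind(X, log(v))
    colnames(X)[ncol(X)] <- paste0("log(", p, ")")
  }
  list(y = y, X = X,
       species = if ("species_name" %in% names(d)) d$species_name else NULL)
}

#' Fit the Bayesian phylogenetic mixed model by Gibbs sampling
#'
#' Samples from the posterior of
#' \deqn{y = X\beta + a + e,\quad a \sim N(0, \sigma^2_p R),\quad
#'       e \sim N(0, \sigma^2_e I)}
#' with a flat prior on the fixed effects and inverse-gamma(`prior_shape`,
#' `prior_rate`) priors on both variances. `R` is the phylogenetic
#' correlation (or covariance) matrix across rows; with `R = NULL` the
#' phylogenetic term is dropped and the phylogenetic heritability is 0 by
#' construction.
#'
#' The sampler works in the eigenbasis of `R`, where both covariance
#' structures are diagonal: the fixed effects are drawn with the random
#' effects integrated out (blocked update), then the random effects, then
#' the two variances from their conjugate inverse-gamma conditionals. This
#' makes each sweep O(n) after one eigendecomposition and mixes well even
#' when the phylogenetic variance is small.
#'
#' The deviance information criterion uses the marginal Gaussian deviance
#' \eqn{y \sim N(X\beta, \sigma^2_p R + \sigma^2_e I)}, i.e. the random
#' effects integrated out analytically, which keeps the effective number of
#' parameters pD stable.
#'
#' @param y Numeric response (from [pmm_design()]).
#' @param X Design matrix with intercept.
#' @param R Phylogenetic correlation/covariance matrix, or `NULL`.
#' @param iterations,burnin,thin MCMC settings per chain; retained draws per
#'   chain are `(iterations - burnin) / thin`.
#' @param chains Number of independent chains (default 2, for split-R-hat).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param prior_shape,prior_rate Inverse-gamma hyperparameters for both
#'   variance priors (default 0.001, 0.001).
#' @return Object of class `pmm_fit` with elements `draws` (tibble:
#'   `.chain`, `.iteration`, one column per parameter, `h2`), `dic`, `pd`,
#'   `diagnostics`, and the model inputs.
#' @export
pmm_fit <- function(y, X, R = NULL, iterations = 50000, burnin = 5000,
                    thin = 10, chains = 2, seed = 1,
                    prior_shape = 0.001, prior_rate = 0.001) {
  if (is.list(y) && all(c("y", "X") %in% names(y))) {
    X <- y$X; y <- y$y
  }
  n <- length(y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop_invalid("`y` and `X` have inconsistent sizes.")
  if (iterations <= burnin) stop_invalid("`iterations` must exceed `burnin`.")
  if (thin < 1) stop_invalid("`thin` must be >= 1.")
  p <- ncol(X)
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(max(p - 1, 0))))[seq_len(p)]
  }
  has_phylo <- !is.null(R)

  if (has_phylo) {
    R <- as.matrix(R)
    if (!isTRUE(all.equal(dim(R), c(n, n)))) {
      stop_invalid("`R` must be n x n.")
    }
    eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
    if (min(eg$values) <= 1e-10 * max(eg$values)) {
      stop_invalid("`R` is not positive definite.",
                   class = "endolink_not_pd")
    }
    U <- eg$vectors; dvals <- eg$values
    ys <- drop(crossprod(U, y))
    Xs <- crossprod(U, X)
  } else {
    U <- NULL; dvals <- rep(1, n)
    ys <- y; Xs <- X
  }

  n_keep <- (iterations - burnin) %/% thin
  if (n_keep < 100) {
    warn(sprintf("Only %d retained draws per chain; summaries will be noisy.",
                 n_keep))
  }

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    # init at OLS / method-of-moments
    XtX <- crossprod(Xs)
    beta <- drop(solve(XtX, crossprod(Xs, ys)))
    r0 <- ys - drop(Xs %*% beta)
    s2e <- max(var(r0), 1e-6)
    s2p <- if (has_phylo) s2e / 2 else 0
    astar <- rep(0, n)
    out <- matrix(NA_real_, n_keep, p + 2)
    kept <- 0L
    ap <- prior_shape; bp <- prior_rate
    for (it in seq_len(iterations)) {
      if (has_phylo) {
        # beta | variances (a integrated out): GLS under diagonal Sigma
        w <- 1 / (s2p * dvals + s2e)
        XtWX <- crossprod(Xs, Xs * w)
        XtWy <- crossprod(Xs, ys * w)
        ch <- chol(XtWX)
        mu <- backsolve(ch, forwardsolve(t(ch), XtWy))
        beta <- drop(mu + backsolve(ch, rnorm(p)))
        # a | beta, variances: independent normals in the eigenbasis
        resid <- ys - drop(Xs %*% beta)
        prec <- 1 / (s2p * dvals) + 1 / s2e
        astar <- rnorm(n, (resid / s2e) / prec, sqrt(1 / prec))
        # variances | rest
        s2p <- 1 / rgamma(1, ap + n / 2, bp + sum(astar^2 / dvals) / 2)
        s2e <- 1 / rgamma(1, ap + n / 2, bp + sum((resid - astar)^2) / 2)
      } else {
        ch <- chol(XtX)
        mu <- backsolve(ch, forwardsolve(t(ch), crossprod(Xs, ys)))
        beta <- drop(mu + sqrt(s2e) * backsolve(ch, rnorm(p)))
        resid <- ys - drop(Xs %*% beta)
        s2e <- 1 / rgamma(1, ap + n / 2, bp + sum(resid^2) / 2)
      }
      if (!is.finite(s2e) || (has_phylo && !is.finite(s2p))) {
        abort(sprintf("Variance update diverged at iteration %d.", it),
              class = "endolink_divergence")
      }
      if (it > burnin && (it - burnin) %% thin == 0) {
        kept <- kept + 1L
        out[kept, ] <- c(beta, s2p, s2e)
      }
    }
    out
  }

  chain_draws <- lapply(seq_len(chains), function(cc) run_chain(seed + cc - 1))
  par_names <- c(colnames(X), "sigma2_phylo", "sigma2_resid")
  all_draws <- do.call(rbind, chain_draws)
  colnames(all_draws) <- par_names
  h2 <- if (has_phylo) {
    all_draws[, "sigma2_phylo"] / (all_draws[, "sigma2_phylo"] +
                                     all_draws[, "sigma2_resid"])
  } else rep(0, nrow(all_draws))

  draws <- as_tibble(all_draws) %>%
    mutate(.chain = rep(seq_len(chains), each = n_keep),
           .iteration = rep(seq_len(n_keep), chains),
           h2 = h2, .before = 1)

  # marginal deviance for DIC
  dev <- function(beta, s2p, s2e) {
    sig <- if (has_phylo) s2p * dvals + s2e else rep(s2e, n)
    r <- ys - drop(Xs %*% beta)
    sum(log(2 * pi * sig) + r^2 / sig)
  }
  devs <- vapply(seq_len(nrow(all_draws)), function(i) {
    dev(all_draws[i, seq_len(p)], all_draws[i, "sigma2_phylo"],
        all_draws[i, "sigma2_resid"])
  }, numeric(1))
  ok <- is.finite(devs)
  if (!all(ok)) {
    warn(sprintf("%d draws with singular marginal covariance skipped in DIC.",
                 sum(!ok)))
  }
  dbar <- mean(devs[ok])
  theta_bar <- colMeans(all_draws)
  dhat <- dev(theta_bar[seq_len(p)], theta_bar["sigma2_phylo"],
              theta_bar["sigma2_resid"])
  pd <- dbar - dhat
  dic <- dbar + pd

  diag_pars <- c(par_names[seq_len(p)], "sigma2_resid",
                 if (has_phylo) "sigma2_phylo")
  diagnostics <- purrr::map_dfr(diag_pars, function(pn) {
    mat <- sapply(seq_len(chains),
                  function(cc) chain_draws[[cc]][, match(pn, par_names)])
    mat <- matrix(mat, ncol = chains)
    tibble(parameter = pn,
           ess = sum(apply(mat, 2, ess)),
           rhat = if (chains > 1 || nrow(mat) > 3) split_rhat(mat) else NA_real_)
  })

  structure(list(draws = draws, dic = dic, pd = pd, deviance_mean = dbar,
                 diagnostics = diagnostics, y = y, X = X, R = R,
                 has_phylo = has_phylo, n = n,
                 settings = list(iterations = iterations, burnin = burnin,
                                 thin = thin, chains = chains, seed = seed,
                                 prior_shape = prior_shape,
                                 prior_rate = prior_rate)),
            class = "pmm_fit")
}

#' Lynch's phylogenetic heritability
#'
#' Posterior mean and highest-posterior-density interval of
#' \eqn{h^2 = \sigma^2_p / (\sigma^2_p + \sigma^2_e)}, computed draw-wise.
#' For a fit without a phylogenetic term the heritability is 0 by
#' construction.
#'
#' @param fit A [pmm_fit()] object.
#' @param prob HPD mass (default 0.95).
#' @return Tibble with `mean`, `hpd_lower`, `hpd_upper`, `prob`.
#' @export
pmm_heritability <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "pmm_fit"))
  h2 <- fit$draws$h2
  if (length(h2) < 100) warn("Fewer than 100 retained draws; HPD is unstable.")
  hpd <- hpd_interval(h2, prob)
  tibble(mean = mean(h2), hpd_lower = hpd[["lower"]],
         hpd_upper = hpd[["upper"]], prob = prob)
}

#' Deviance information criterion of a fitted model
#'
#' @param fit A [pmm_fit()] object.
#' @return Tibble with `dic`, `pd` (effective parameters) and `deviance_mean`.
#' @export
pmm_dic <- function(fit) {
  stopifnot(inherits(fit, "pmm_fit"))
  tibble(dic = fit$dic, pd = fit$pd, deviance_mean = fit$deviance_mean)
}

#' All-subsets model selection by DIC
#'
#' Fits every subset of the candidate predictors (including the
#' intercept-only model), ranks by DIC ascending, and flags models within
#' `competing_window` DIC units of the best as competing. Ties are broken
#' by parameter count, then by predictor names alphabetically. Subsets that
#' fail to sample are kept in the table with `failed = TRUE` rather than
#' dropped.
#'
#' @param table Derived trait table (rows already restricted to modelled
#'   species and ordered to match `R`).
#' @param predictors Candidate predictor columns (at most 12).
#' @param R Phylogenetic correlation matrix or `NULL`.
#' @param competing_window DIC window for competing models (default 2).
#' @param keep_fits Keep the fitted objects in a list column (default FALSE).
#' @param ... Passed to [pmm_fit()] (chain settings, seed, priors). Each
#'   subset m uses `seed + m - 1` so the ranking is reproducible.
#' @return Object of class `pmm_ranking`: tibble with `model`, `k`
#'   (number of fixed effects), `dic`, `pd`, `delta_dic`, `competing`,
#'   `failed`, ordered best first.
#' @export
pmm_dredge <- function(table, predictors, R = NULL, competing_window = 2,
                       keep_fits = FALSE, response = "sgs", seed = 1, ...) {
  if (length(predictors) > 12) {
    stop_invalid("At most 12 predictors (2^k subsets are enumerated).")
  }
  k <- length(predictors)
  subsets <- purrr::map(0:(2^k - 1), function(m) {
    predictors[bitwAnd(m, bitwShiftL(1, seq_len(k) - 1)) > 0]
  })
  rows <- purrr::imap(subsets, function(ps, m) {
    des <- pmm_design(table, ps, response = response)
    fit <- tryCatch(
      pmm_fit(des$y, des$X, R = R, seed = seed + m - 1, ...),
      error = function(e) e)
    if (inherits(fit, "error")) {
      tibble(model = if (length(ps)) paste(sort(ps), collapse = "+") else "1",
             k = length(ps) + 1L, dic = NA_real_, pd = NA_real_,
             failed = TRUE, fit = list(NULL))
    } else {
      tibble(model = if (length(ps)) paste(sort(ps), collapse = "+") else "1",
             k = length(ps) + 1L, dic = fit$dic, pd = fit$pd,
             failed = FALSE, fit = list(fit))
    }
  })
  res <- bind_rows(rows) %>%
    arrange(is.na(.data$dic), .data$dic, .data$k, .data$model) %>%
    mutate(delta_dic = .data$dic - .data$dic[1],
           competing = !is.na(.data$delta_dic) &
             .data$delta_dic <= competing_window)
  if (!keep_fits) res$fit <- NULL
  class(res) <- c("pmm_ranking", class(res))
  res
}
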