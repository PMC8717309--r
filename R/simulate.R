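#' Simulate a pure-birth (Yule) phylogeny
#'
#' Forward simulation: starting from a single lineage, each of the k
#' current lineages splits after an exponential waiting time with total
#' rate k * `birth_rate`, the splitting lineage chosen uniformly, until
#' `n_tips` lineages exist. The resulting tree is ultrametric with expected
#' depth \eqn{\sum_{k=1}^{n-1} 1/(\lambda k)}.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate lambda (> 0).
#' @param seed Integer seed (optional; the generator also respects the
#'   ambient RNG state when `seed` is `NULL`).
#' @return An ultrametric [ape::phylo] tree with tips `t1..tn`.
#' @export
sim_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2) stop_invalid("`n_tips` must be >= 2.")
  check_positive(birth_rate, "birth_rate")
  if (!is.null(seed)) set.seed(seed)
  # event times: k lineages wait Exp(k * lambda)
  waits <- rexp(n_tips - 1, rate = seq_len(n_tips - 1) * birth_rate)
  split_times <- cumsum(waits)        # time of the k-th split
  depth <- split_times[n_tips - 1] +
    rexp(1, rate = n_tips * birth_rate)  # extend past the last split
  # build edge list: node k-th split creates a new lineage
  # lineages tracked as (current tip-or-node id, birth time)
  n_nodes <- n_tips - 1
  edge <- matrix(0L, 2 * n_tips - 2, 2)
  edge_len <- numeric(2 * n_tips - 2)
  next_tip <- 1L
  next_node <- n_tips + 1L
  # active lineages: parent node id and time that lineage started
  act_parent <- c(0L); act_start <- c(0)
  e <- 0L
  for (k in seq_len(n_nodes)) {
    i <- sample.int(length(act_parent), 1)
    node <- next_node; next_node <- next_node + 1L
    if (act_parent[i] != 0L) {
      e <- e + 1L
      edge[e, ] <- c(act_parent[i], node)
      edge_len[e] <- split_times[k] - act_start[i]
    }
    # replace lineage i by two children of `node`
    act_parent <- c(act_parent[-i], node, node)
    act_start <- c(act_start[-i], split_times[k], split_times[k])
  }
  for (i in seq_along(act_parent)) {
    e <- e + 1L
    edge[e, ] <- c(act_parent[i], next_tip)
    edge_len[e] <- depth - act_start[i]
    next_tip <- next_tip + 1L
  }
  tr <- structure(list(edge = edge[seq_len(e), , drop = FALSE],
                       edge.length = edge_len[seq_len(e)],
                       tip.label = paste0("t", seq_len(n_tips)),
                       Nnode = n_nodes),
                  class = "phylo", order = "cladewise")
  ape::reorder.phylo(tr)
}

#' Simulate Brownian-motion trait values at the tips
#'
#' Draws tip values exactly from the Brownian model implied by the tree:
#' multivariate normal with mean `root` and covariance
#' `rate * phylo_vcv(tree)` (via Cholesky).
#'
#' @param tree An [ape::phylo] tree.
#' @param root Root (ancestral) value.
#' @param rate Brownian rate sigma^2 per unit branch length (>= 0; a zero
#'   rate returns the root value at every tip).
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
sim_bm_traits <- function(tree, root = 0, rate = 1, seed = NULL) {
  if (rate < 0) stop_invalid("`rate` must be non-negative.")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  if (rate == 0) return(setNames(rep(root, n), tree$tip.label))
  C <- phylo_vcv(tree)
  L <- chol(rate * C)
  setNames(root + drop(crossprod(L, rnorm(n))), rownames(C))
}

#' Simulate a feeding-trial trait and germination table
#'
#' Generates a species table with the statistical structure the germination
#' model assumes: log-scale traits evolve by Brownian motion on the tree,
#' the linear predictor is
#' \eqn{\eta = X\beta + a + e} with a phylogenetic random effect
#' \eqn{a \sim N(0, \sigma^2_p R)} (R the phylogenetic correlation) and
#' residual \eqn{e \sim N(0, \sigma^2_e I)}, and the standardized
#' germination success is \eqn{\max(e^\eta - 1, 0)}. Feces seedling counts
#' are the nearest integer consistent with that SGS given `seeds_fed` and
#' `capacity` (or a binomial draw with `counts = "binomial"`, a
#' misspecification stress test).
#'
#' @param tree Phylogeny whose tips name the species.
#' @param beta Named vector of effects on the log(SGS + 1) scale:
#'   intercept first, then one per trait column in `trait_means`.
#' @param sigma2_phylo,sigma2_resid Phylogenetic and residual variances.
#' @param trait_means Named numeric vector of log-scale trait means
#'   (default `c(density = -7, ei = 0.6, area = 2)`, the scale of the
#'   feeding-trial table).
#' @param trait_rate Brownian rate for the log-scale traits.
#' @param seeds_fed Seeds fed per species (scalar or per-tip vector, > 0).
#' @param capacity Control germination capacity in percent (scalar or
#'   per-tip).
#' @param counts `"deterministic"` (inverse-formula rounding) or
#'   `"binomial"`.
#' @param seed Optional integer seed.
#' @return Tibble ingestible by [derive_seed_traits()] / [pmm_design()]:
#'   `species_name`, trait columns, `seeds_fed`, `control_germ_pct`,
#'   `feces_germ`, `sgs` (recomputed from the integer counts), and the
#'   latent `sgs_true`.
#' @export
sim_germination <- function(tree, beta = c(intercept = 2.5, density = 0.1,
                                           ei = 0.2, area = -0.1),
                            sigma2_phylo = 0.2, sigma2_resid = 0.3,
                            trait_means = c(density = -7, ei = 0.6, area = 2),
                            trait_rate = 0.1, seeds_fed = 800, capacity = 70,
                            counts = c("deterministic", "binomial"),
                            seed = NULL) {
  counts <- match.arg(counts)
  if (!is.null(seed)) set.seed(seed)
  if (any(seeds_fed <= 0)) stop_invalid("`seeds_fed` must be positive.")
  if (any(capacity <= 0 | capacity > 100)) {
    stop_invalid("`capacity` must lie in (0, 100].")
  }
  n <- length(tree$tip.label)
  traits <- sapply(names(trait_means), function(tn) {
    sim_bm_traits(tree, root = trait_means[[tn]], rate = trait_rate)
  })
  X <- cbind(1, traits)
  if (length(beta) != ncol(X)) {
    stop_invalid("`beta` must have one entry per trait plus the intercept.")
  }
  R <- vcv_to_correlation(phylo_vcv(tree))
  a <- if (sigma2_phylo > 0) {
    drop(crossprod(chol(sigma2_phylo * R), rnorm(n)))
  } else rep(0, n)
  e <- rnorm(n, 0, sqrt(sigma2_resid))
  eta <- drop(X %*% beta) + a + e
  sgs_true <- pmax(exp(eta) - 1, 0)
  fed <- rep_len(seeds_fed, n)
  cap <- rep_len(capacity, n)
  p_germ <- pmin(sgs_true / 100 * cap / 100, 1)
  feces <- switch(counts,
    deterministic = as.integer(round(p_germ * fed)),
    binomial = rbinom(n, fed, p_germ))
  trait_cols <- setNames(lapply(colnames(traits), function(cn) exp(traits[, cn])),
                         colnames(traits))
  tibble(species_name = tree$tip.label,
         !!!trait_cols,
         seeds_fed = fed, control_germ_pct = cap, feces_germ = feces,
         sgs = standardized_germination(feces, cap, fed),
         sgs_true = sgs_true)
}

#' Simulate a mosaic land-use landscape
#'
#' Jittered rectangular-grid mosaic: the extent is divided into
#' `round(side / sqrt(mean_patch_ha * 1e4))` columns and rows whose break
#' positions are jittered and rescaled to tile the extent exactly; each
#' cell becomes one patch with a land-use type drawn from
#' `type_proportions`. Mean patch area therefore equals the extent area
#' divided by the number of cells, i.e. the requested size up to grid
#' rounding.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in meters.
#' @param mean_patch_ha Target mean patch area in hectares (27.5 for the
#'   simple, 2.9 for the complex landscape of the study regions).
#' @param type_proportions Named vector of land-use proportions (summing to
#'   1) over grassland, forest, field, wetland, quarry, urban.
#' @param jitter Relative break jitter in (0, 0.5); default 0.3.
#' @param seed Optional integer seed.
#' @return Patch tibble as from [make_patches()].
#' @export
sim_landscape <- function(extent = c(0, 3000, 0, 3000), mean_patch_ha = 27.5,
                          type_proportions = c(field = 0.6, grassland = 0.2,
                                               forest = 0.15, wetland = 0.05),
                          jitter = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(type_proportions) - 1) > 1e-8) {
    stop_invalid("`type_proportions` must sum to 1.")
  }
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  side <- sqrt(mean_patch_ha * 1e4)
  nx <- max(1L, round(w / side)); ny <- max(1L, round(h / side))
  if (nx * ny < 2) stop_invalid("Extent too small for the requested patch size.")
  jb <- function(k, lo, len) {
    b <- seq(0, 1, length.out = k + 1)
    if (k > 1) {
      b[2:k] <- b[2:k] + runif(k - 1, -jitter / k, jitter / k)
      b <- sort(b)
    }
    lo + b * len
  }
  xb <- jb(nx, extent[1], w); yb <- jb(ny, extent[3], h)
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  rings <- purrr::map2(grid$ix, grid$iy, function(i, j) {
    cbind(c(xb[i], xb[i + 1], xb[i + 1], xb[i]),
          c(yb[j], yb[j], yb[j + 1], yb[j + 1]))
  })
  ids <- sprintf("p%03d", seq_len(nrow(grid)))
  landuse <- sample(names(type_proportions), nrow(grid), replace = TRUE,
                    prob = type_proportions)
  make_patches(ids, landuse, rings)
}

# wrapped-Cauchy deviates by inverse transform
rwrappedcauchy <- function(n, mu = 0, rho = 0.7) {
  if (rho <= 0) return(runif(n, -pi, pi))
  u <- runif(n)
  theta <- mu + 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5)))
  ((theta + pi) %% (2 * pi)) - pi
}

#' Simulate an hourly correlated-random-walk track
#'
#' Gamma-distributed step lengths and wrapped-Cauchy turning angles,
#' reflected at the extent borders, with an optional bias toward grassland:
#' at each step, `n_candidates` candidate headings are drawn and a
#' candidate landing in grassland is chosen with weight `1 + habitat_bias`
#' relative to the others.
#'
#' @param patches Patch tibble (defines the extent; used for habitat bias).
#' @param n_steps Number of hourly steps.
#' @param start `c(x, y)` start position (default: extent center).
#' @param step_shape,step_scale Gamma parameters of hourly step length in
#'   meters (defaults 2 and 90: mean 180 m/h, matching free-ranging hare
#'   travel of roughly 1.3 km per 7 h).
#' @param turn_rho Wrapped-Cauchy concentration of turning angles in
#'   [0, 1) (default 0.6).
#' @param habitat_bias Non-negative grassland preference weight (default 0,
#'   no bias).
#' @param n_candidates Candidate headings per step when biased (default 5).
#' @param individual_id Id for the output track.
#' @param t0 Start time (POSIXct, default 2020-01-01 00:00 UTC).
#' @param seed Optional integer seed.
#' @return Fix tibble (`individual_id`, `timestamp`, `x`, `y`), hourly.
#' @export
sim_track <- function(patches, n_steps = 240, start = NULL,
                      step_shape = 2, step_scale = 90, turn_rho = 0.6,
                      habitat_bias = 0, n_candidates = 5,
                      individual_id = "sim1",
                      t0 = as.POSIXct("2020-01-01", tz = "UTC"),
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  allx <- unlist(purrr::map(patches$ring, ~ .x[, 1]))
  ally <- unlist(purrr::map(patches$ring, ~ .x[, 2]))
  ext <- c(min(allx), max(allx), min(ally), max(ally))
  if (is.null(start)) start <- c(mean(ext[1:2]), mean(ext[3:4]))
  if (start[1] < ext[1] || start[1] > ext[2] ||
        start[2] < ext[3] || start[2] > ext[4]) {
    stop_invalid("`start` must lie inside the landscape extent.")
  }
  reflect <- function(v, lo, hi) {
    # reflect into [lo, hi]
    rng <- hi - lo
    v <- (v - lo) %% (2 * rng)
    lo + ifelse(v > rng, 2 * rng - v, v)
  }
  grass <- patches %>% filter(.data$landuse == "grassland")
  x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
  x[1] <- start[1]; y[1] <- start[2]
  heading <- runif(1, -pi, pi)
  for (s in seq_len(n_steps)) {
    len <- rgamma(1, shape = step_shape, scale = step_scale)
    if (habitat_bias > 0 && nrow(grass)) {
      turns <- rwrappedcauchy(n_candidates, 0, turn_rho)
      cx <- reflect(x[s] + len * cos(heading + turns), ext[1], ext[2])
      cy <- reflect(y[s] + len * sin(heading + turns), ext[3], ext[4])
      ing <- rowSums(vapply(grass$ring,
                            function(r) mgcv::in.out(r, cbind(cx, cy)),
                            logical(n_candidates))) > 0
      wgt <- ifelse(ing, 1 + habitat_bias, 1)
      pick <- sample.int(n_candidates, 1, prob = wgt)
      heading <- heading + turns[pick]
      x[s + 1] <- cx[pick]; y[s + 1] <- cy[pick]
    } else {
      heading <- heading + rwrappedcauchy(1, 0, turn_rho)
      x[s + 1] <- reflect(x[s] + len * cos(heading), ext[1], ext[2])
      y[s + 1] <- reflect(y[s] + len * sin(heading), ext[3], ext[4])
    }
  }
  tibble(individual_id = individual_id,
         timestamp = t0 + 3600 * (0:n_steps),
         x = x, y = y)
}
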