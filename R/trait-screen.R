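#' Greedy collinearity filter for candidate predictors
#'
#' Pairwise Pearson screening: while any pair of retained predictors has
#' |r| above `threshold`, the offending pair encountered first in matrix
#' order (upper triangle, row-major) loses its lower-priority member. The
#' priority ordering is the `priority` vector followed by the remaining
#' predictors in column order, so named traits survive their correlated
#' partners deterministically and the result does not depend on row order.
#'
#' @param table Data frame of species records.
#' @param predictors Character vector of numeric predictor columns.
#' @param threshold Absolute Pearson correlation above which a pair is
#'   collinear (default 0.7).
#' @param priority Character vector; predictors listed here (in order) are
#'   preferred for retention.
#' @param log Log-transform the predictors before correlating
#'   (default TRUE; predictors must then be positive).
#' @return An object of class `trait_screen`: list with `retained`,
#'   `dropped` (tibble of predictor, dropped_for), and `correlations`
#'   (full Pearson matrix on the screening scale).
#' @export
screen_collinearity <- function(table, predictors, threshold = 0.7,
                                priority = character(), log = TRUE) {
  if (length(predictors) < 2) {
    stop_invalid("Need at least two predictors to screen.")
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop_invalid("`threshold` must lie in (0, 1).")
  }
  missing_cols <- setdiff(predictors, names(table))
  if (length(missing_cols)) {
    stop_invalid(paste0("Predictors not in table: ",
                        paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(as.data.frame(table)[, predictors, drop = FALSE])
  if (anyNA(x)) stop_invalid("Predictors contain missing values.")
  if (log) {
    if (any(x <= 0)) stop_invalid("Log screening requires positive predictors.")
    x <- base::log(x)
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop_invalid(paste0("Constant column(s): ",
                        paste(predictors[sds == 0], collapse = ", "),
                        "; correlation undefined."),
                 class = "endolink_undefined_correlation")
  }
  cm <- cor(x)
  rank_order <- c(intersect(priority, predictors),
                  setdiff(predictors, priority))
  prio <- match(predictors, rank_order)

  retained <- predictors
  dropped <- tibble(predictor = character(), dropped_for = character())
  repeat {
    sub <- cm[retained, retained, drop = FALSE]
    off <- which(upper.tri(sub) & abs(sub) > threshold, arr.ind = TRUE)
    if (nrow(off) == 0) break
    off <- off[order(off[, "row"], off[, "col"]), , drop = FALSE]
    a <- retained[off[1, "row"]]; b <- retained[off[1, "col"]]
    loser <- if (prio[match(a, predictors)] <= prio[match(b, predictors)]) b else a
    winner <- setdiff(c(a, b), loser)
    dropped <- bind_rows(dropped,
                         tibble(predictor = loser, dropped_for = winner))
    retained <- setdiff(retained, loser)
  }
  structure(list(retained = retained, dropped = dropped,
                 correlations = cm, threshold = threshold, log = log),
            class = "trait_screen")
}

#' @export
print.trait_screen <- function(x, ...) {
  cat("Collinearity screen (|r| > ", x$threshold,
      if (x$log) ", log scale" else "", ")\n", sep = "")
  cat("Retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("Dropped: ",
        paste(sprintf("%s (vs %s)", x$dropped$predictor, x$dropped$dropped_for),
              collapse = ", "), "\n", sep = "")
  } else cat("Dropped: none\n")
  invisible(x)
}

#' Exploratory PCA of standardized seed-trait predictors
#'
#' Principal components of the centered, unit-variance predictor matrix,
#' used (like the source analysis) only to inspect how candidate traits
#' load before model selection — not as a modelling step.
#'
#' @inheritParams screen_collinearity
#' @return Object of class `trait_pca`: list with `loadings` (orthonormal
#'   rotation matrix), `variance` (tibble: component, eigenvalue,
#'   proportion, cumulative), and `scores`.
#' @export
trait_pca <- function(table, predictors, log = TRUE) {
  if (length(predictors) < 2) stop_invalid("Need at least two predictors.")
  x <- as.matrix(as.data.frame(table)[, predictors, drop = FALSE])
  if (anyNA(x)) stop_invalid("Predictors contain missing values.")
  if (log) {
    if (any(x <= 0)) stop_invalid("Log PCA requires positive predictors.")
    x <- base::log(x)
  }
  if (nrow(x) < length(predictors)) {
    warn("Fewer rows than predictors; trailing components are rank-deficient.")
  }
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  eig <- p$sdev^2
  structure(list(
    loadings = p$rotation,
    variance = tibble(component = paste0("PC", seq_along(eig)),
                      eigenvalue = eig,
                      proportion = eig / sum(eig),
                      cumulative = cumsum(eig) / sum(eig)),
    scores = p$x
  ), class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("PCA of", nrow(x$loadings), "standardized predictors\n")
  print(x$variance, n = nrow(x$variance))
  invisible(x)
}
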