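#' Seed shape and dispersal-syndrome indices
#'
#' Morphological indices commonly used to characterize the endozoochorous
#' seed dispersal syndrome. All functions are vectorized over their
#' arguments and validate that dimensions are positive.
#'
#' * `seed_eccentricity()` — elongation, length / width.
#' * `seed_flatness()` — (length + width) / (2 * height).
#' * `seed_density()` — mass per volume.
#' * `seed_shape_variance()` — variance of the three length-scaled
#'   dimensions (1, width/length, height/length); 0 for a perfect sphere,
#'   bounded by 2/9 when length is the longest dimension.
#'
#' @param length,width,height Seed dimensions in mm.
#' @param mass Seed mass (units as supplied; never converted).
#' @param volume Seed volume in mm^3.
#' @return Numeric vector of index values.
#' @examples
#' seed_eccentricity(2, 1)      # 2
#' seed_flatness(3, 1, 0.5)     # 4
#' seed_shape_variance(1, 1, 1) # 0
#' @name seed-indices
NULL

#' @rdname seed-indices
#' @export
seed_eccentricity <- function(length, width) {
  check_positive(length, "length")
  check_positive(width, "width")
  length / width
}

#' @rdname seed-indices
#' @export
seed_flatness <- function(length, width, height) {
  if (any(is.na(height))) {
    stop_invalid("`height` is missing; flatness is undefined without it.",
                 class = "endolink_missing_trait")
  }
  check_positive(length, "length")
  check_positive(width, "width")
  check_positive(height, "height")
  (length + width) / (2 * height)
}

#' @rdname seed-indices
#' @export
seed_density <- function(mass, volume) {
  check_positive(mass, "mass")
  check_positive(volume, "volume")
  mass / volume
}

#' @rdname seed-indices
#' @export
seed_shape_variance <- function(length, width, height) {
  if (any(is.na(height))) {
    stop_invalid("`height` is missing; shape variance is undefined without it.",
                 class = "endolink_missing_trait")
  }
  check_positive(length, "length")
  check_positive(width, "width")
  check_positive(height, "height")
  x1 <- rep_len(1, base::length(length))
  x2 <- width / length
  x3 <- height / length
  xbar <- (x1 + x2 + x3) / 3
  ((x1 - xbar)^2 + (x2 - xbar)^2 + (x3 - xbar)^2) / 3
}

# Thomsen approximation to the ellipsoid surface area, exact for spheres,
# error < 1.1% for any axis ratio.
ellipsoid_area_thomsen <- function(a, b, c, p = 1.6075) {
  4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

# Exact ellipsoid surface area by 2-d quadrature of the surface integral.
ellipsoid_area_quadrature <- function(a, b, c) {
  f <- function(phi, theta) {
    sp <- sin(phi)
    sp * sqrt((b * c * sp * cos(theta))^2 +
                (a * c * sp * sin(theta))^2 +
                (a * b * cos(phi))^2)
  }
  inner <- function(theta) {
    vapply(theta, function(th) {
      stats::integrate(function(phi) f(phi, th), 0, pi,
                       rel.tol = 1e-9)$value
    }, numeric(1))
  }
  stats::integrate(inner, 0, 2 * pi, rel.tol = 1e-8)$value
}

#' Seed surface area with shape-dependent formula choice
#'
#' Approximates seed surface area from the three linear dimensions. Seeds
#' with dimensional shape variance below `vs_threshold` are treated as
#' ellipsoids with semi-axes (length/2, width/2, height/2); more elongated
#' seeds are treated as cylinders of length `length` and radius
#' `(width + height) / 4` (or `width / 2` with `radius = "width"`), with
#' area 2*pi*r^2 + 2*pi*r*L.
#'
#' With the default threshold of 1 the cylinder branch can never fire: when
#' length is the longest dimension the shape variance is bounded by 2/9, and
#' a warning (class `endolink_dead_branch`) reports the dead branch once per
#' call. Pass e.g. `vs_threshold = 0.1` to make the branch reachable.
#'
#' @inheritParams seed-indices
#' @param vs_threshold Shape-variance cutoff between the ellipsoid and
#'   cylinder formulas (default 1).
#' @param method Ellipsoid approximation: `"thomsen"` (closed form,
#'   p = 1.6075) or `"quadrature"` (numerical integration of the exact
#'   surface integral).
#' @param radius Cylinder radius rule: `"mean"` for (width + height)/4,
#'   `"width"` for width/2.
#' @return Numeric vector of areas in mm^2, with attributes `branch`
#'   (character, `"ellipsoid"` or `"cylinder"` per element) and `method`.
#' @examples
#' seed_surface_area(2, 2, 2)  # sphere: 4*pi
#' @export
seed_surface_area <- function(length, width, height, vs_threshold = 1,
                              method = c("thomsen", "quadrature"),
                              radius = c("mean", "width")) {
  method <- match.arg(method)
  radius <- match.arg(radius)
  if (!is.numeric(vs_threshold) || length(vs_threshold) != 1 || vs_threshold <= 0) {
    stop_invalid("`vs_threshold` must be a single positive number.")
  }
  vs <- seed_shape_variance(length, width, height)
  use_cyl <- vs >= vs_threshold
  if (vs_threshold >= 2 / 9 && all(length >= pmax(width, height))) {
    warn(paste0(
      "With length the longest dimension, shape variance is bounded by ",
      "2/9; vs_threshold = ", format(vs_threshold),
      " makes the cylinder branch unreachable."),
      class = "endolink_dead_branch")
  }
  a <- length / 2; b <- width / 2; c <- height / 2
  ell <- switch(method,
    thomsen = ellipsoid_area_thomsen(a, b, c),
    quadrature = mapply(ellipsoid_area_quadrature, a, b, c)
  )
  r <- if (radius == "mean") (width + height) / 4 else width / 2
  cyl <- 2 * pi * r^2 + 2 * pi * r * length
  out <- ifelse(use_cyl, cyl, ell)
  attr(out, "branch") <- ifelse(use_cyl, "cylinder", "ellipsoid")
  attr(out, "method") <- method
  out
}

#' Seed surface-area-to-mass ratio
#'
#' @param area Seed surface area in mm^2.
#' @param mass Seed mass (units as supplied).
#' @return area / mass.
#' @export
area_mass_ratio <- function(area, mass) {
  check_positive(area, "area")
  check_positive(mass, "mass")
  area / mass
}

#' Standardized germination success after gut passage
#'
#' Expresses the number of seedlings germinating from feces relative to the
#' number of fed seeds expected to be germinable given the species' control
#' germination capacity:
#' \deqn{SGS = 100 \cdot \frac{n_{feces}}{(capacity/100) \cdot n_{fed}}}
#' Values can exceed 100 when gut passage stimulates germination beyond the
#' control rate.
#'
#' @param feces_germ Count of seedlings emerging from feces.
#' @param control_germ_pct Control germination capacity in percent (0-100].
#'   Species with zero capacity are not standardizable and raise an error of
#'   class `endolink_excluded_species`.
#' @param seeds_fed Number of seeds fed (> 0).
#' @return Standardized germination success in percent.
#' @examples
#' standardized_germination(15, 1, 685)  # 218.98
#' @export
standardized_germination <- function(feces_germ, control_germ_pct, seeds_fed) {
  if (any(!is.finite(seeds_fed) | seeds_fed <= 0)) {
    stop_invalid("`seeds_fed` must be positive.")
  }
  if (any(!is.finite(control_germ_pct) | control_germ_pct < 0 |
            control_germ_pct > 100)) {
    stop_invalid("`control_germ_pct` must lie in [0, 100].")
  }
  if (any(control_germ_pct == 0)) {
    stop_invalid(
      "Species with zero control germination capacity cannot be standardized; exclude them upstream.",
      class = "endolink_excluded_species")
  }
  if (any(feces_germ < 0) || any(feces_germ > seeds_fed)) {
    stop_invalid("`feces_germ` must lie in [0, seeds_fed].")
  }
  100 * feces_germ / ((control_germ_pct / 100) * seeds_fed)
}
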