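#' Construct a land-use patch table
#'
#' Builds the patch representation used by the movement analysis: one row
#' per patch with its id, land-use type, polygon ring (closed is optional;
#' the first vertex is reused as the last), polygon area, and centroid.
#'
#' @param patch_id Character vector of unique ids.
#' @param landuse Character vector of land-use types (one of grassland,
#'   forest, field, wetland, quarry, urban).
#' @param rings List of two-column numeric matrices (x, y in meters).
#' @return Tibble with `patch_id`, `landuse`, `ring` (list), `area_m2`,
#'   `centroid_x`, `centroid_y`.
#' @export
make_patches <- function(patch_id, landuse, rings) {
  types <- c("grassland", "forest", "field", "wetland", "quarry", "urban")
  if (anyDuplicated(patch_id)) stop_invalid("`patch_id` must be unique.")
  if (!all(landuse %in% types)) {
    stop_invalid(paste0("Unknown landuse; expected one of: ",
                        paste(types, collapse = ", ")))
  }
  geom <- purrr::map_dfr(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || nrow(r) < 3 || anyNA(r)) {
      stop_invalid("Each ring needs >= 3 finite (x, y) vertices.")
    }
    # drop an explicit closing vertex
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    xs <- r[, 1]; ys <- r[, 2]
    xn <- c(xs[-1], xs[1]); yn <- c(ys[-1], ys[1])
    cross <- xs * yn - xn * ys
    a2 <- sum(cross)            # twice the signed area
    if (abs(a2) < 1e-12) stop_invalid("Degenerate polygon (zero area).")
    tibble(area_m2 = abs(a2) / 2,
           centroid_x = sum((xs + xn) * cross) / (3 * a2),
           centroid_y = sum((ys + yn) * cross) / (3 * a2))
  })
  tibble(patch_id = as.character(patch_id), landuse = landuse,
         ring = purrr::map(rings, ~ {
           r <- as.matrix(.x)
           if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
           r
         })) %>%
    bind_cols(geom)
}

#' Resample a GPS track to hourly fixes
#'
#' For each whole hour keeps the fix closest to the hour mark within
#' `tolerance_min` minutes; other fixes are discarded and gaps are left as
#' gaps (no interpolation).
#'
#' @param fixes Tibble with `individual_id`, `timestamp` (POSIXct), `x`, `y`.
#' @param tolerance_min Maximal distance to the hour mark in minutes
#'   (default 10).
#' @return The retained fixes, sorted per individual.
#' @export
track_resample_hourly <- function(fixes, tolerance_min = 10) {
  validate_fixes(fixes)
  fixes %>%
    mutate(.hour = as.POSIXct(round(as.numeric(.data$timestamp) / 3600) * 3600,
                              origin = "1970-01-01", tz = "UTC"),
           .off = abs(as.numeric(.data$timestamp) - as.numeric(.data$.hour))) %>%
    filter(.data$.off <= tolerance_min * 60) %>%
    group_by(.data$individual_id, .data$.hour) %>%
    filter(row_number(.data$.off) == 1) %>%
    ungroup() %>%
    arrange(.data$individual_id, .data$timestamp) %>%
    select(-".hour", -".off")
}

validate_fixes <- function(fixes) {
  need <- c("individual_id", "timestamp", "x", "y")
  missing_cols <- setdiff(need, names(fixes))
  if (length(missing_cols)) {
    stop_invalid(paste0("Fix table lacks columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!all(is.finite(fixes$x)) || !all(is.finite(fixes$y))) {
    stop_invalid("Coordinates must be finite.")
  }
  unsorted <- fixes %>%
    group_by(.data$individual_id) %>%
    summarise(bad = any(diff(as.numeric(.data$timestamp)) <= 0),
              .groups = "drop")
  if (any(unsorted$bad)) {
    stop_invalid(paste0("Timestamps not strictly increasing for: ",
                        paste(unsorted$individual_id[unsorted$bad],
                              collapse = ", ")))
  }
  invisible(fixes)
}

# TRUE where point (px, py) lies on the boundary of ring r (within eps).
on_ring_boundary <- function(px, py, r, eps = 1e-9) {
  n <- nrow(r)
  scale <- max(abs(r)) + 1
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- r[i, 1]; ay <- r[i, 2]; bx <- r[j, 1]; by <- r[j, 2]
    vx <- bx - ax; vy <- by - ay
    wx <- px - ax; wy <- py - ay
    cross <- vx * wy - vy * wx
    if (abs(cross) > eps * scale * scale) next
    dot <- wx * vx + wy * vy
    len2 <- vx * vx + vy * vy
    if (dot >= -eps && dot <= len2 + eps) return(TRUE)
  }
  FALSE
}

#' Assign GPS fixes to land-use patches
#'
#' Point-in-polygon assignment of every fix to at most one patch. Fixes
#' outside all patches are labelled `"matrix"` (and carry `patch_id = NA`);
#' fixes on a shared patch boundary go to the lexicographically smallest
#' `patch_id` among the touching patches (inclusive-edge rule). A fix
#' strictly inside more than one polygon means the patch layer overlaps,
#' which is an error naming the offending patches.
#'
#' @param fixes Fix tibble (`individual_id`, `timestamp`, `x`, `y`).
#' @param patches Patch tibble from [make_patches()] /
#'   [read_landscape_geojson()].
#' @return `fixes` with `patch_id` and `landuse` columns appended.
#' @export
assign_patches <- function(fixes, patches) {
  validate_fixes(fixes)
  pts <- cbind(fixes$x, fixes$y)
  inside <- vapply(patches$ring,
                   function(r) mgcv::in.out(r, pts),
                   logical(nrow(fixes)))
  inside <- matrix(inside, nrow = nrow(fixes))
  hits <- rowSums(inside)

  pid <- rep(NA_character_, nrow(fixes))
  use <- rep("matrix", nrow(fixes))
  one <- hits == 1
  if (any(one)) {
    j <- apply(inside[one, , drop = FALSE], 1, which.max)
    pid[one] <- patches$patch_id[j]
    use[one] <- patches$landuse[j]
  }
  for (i in which(hits != 1)) {
    onb <- which(vapply(patches$ring,
                        function(r) on_ring_boundary(pts[i, 1], pts[i, 2], r),
                        logical(1)))
    if (length(onb)) {
      j <- onb[order(patches$patch_id[onb])][1]
      pid[i] <- patches$patch_id[j]
      use[i] <- patches$landuse[j]
    } else if (hits[i] > 1) {
      off <- patches$patch_id[inside[i, ]]
      stop_invalid(paste0("Overlapping patches at fix ", i, ": ",
                          paste(off, collapse = ", ")))
    } # else: matrix
  }
  fixes %>% mutate(patch_id = pid, landuse = use)
}

#' Centroid distance matrix of visited patches
#'
#' Euclidean distances between patch centroids, with summary means and SDs
#' per habitat-pair class: pairs of differing land-use types, and the
#' same-type pairs field-field, grassland-grassland, forest-forest.
#'
#' @param patches Patch tibble (usually filtered to visited patches).
#' @return List with `distances` (symmetric matrix, meters, patch ids as
#'   dimnames) and `classes` (tibble: class, n_pairs, mean_m, sd_m; empty
#'   classes appear with `n_pairs = 0`).
#' @export
patch_distance_matrix <- function(patches) {
  if (nrow(patches) < 2) {
    warn("Fewer than two patches; distance matrix is empty.")
    return(list(distances = matrix(numeric(0), 0, 0),
                classes = tibble(class = character(), n_pairs = integer(),
                                 mean_m = numeric(), sd_m = numeric())))
  }
  D <- as.matrix(dist(cbind(patches$centroid_x, patches$centroid_y)))
  dimnames(D) <- list(patches$patch_id, patches$patch_id)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  pair_class <- ifelse(
    patches$landuse[idx[, 1]] != patches$landuse[idx[, 2]], "differing",
    paste(patches$landuse[idx[, 1]], patches$landuse[idx[, 2]], sep = "-"))
  vals <- D[upper.tri(D)]
  wanted <- c("differing", "field-field", "grassland-grassland",
              "forest-forest")
  classes <- purrr::map_dfr(wanted, function(cl) {
    v <- vals[pair_class == cl]
    tibble(class = cl, n_pairs = length(v),
           mean_m = if (length(v)) mean(v) else NA_real_,
           sd_m = if (length(v) > 1) sd(v) else NA_real_)
  })
  list(distances = D, classes = classes)
}

#' Retention-time moving windows over a track
#'
#' For every fix of a single individual's (resampled) track, the maximal
#' run of consecutive fixes whose timestamps fall in the closed interval
#' [t0, t0 + T]. Runs are truncated where consecutive fixes are further
#' apart than `fix_interval_hours` (gaps are never bridged). With hourly
#' fixes a fractional T such as 5.6 h therefore admits floor(T) + 1 fixes.
#'
#' @param fixes Fix tibble for one individual.
#' @param retention_hours Window duration T in hours (> 0).
#' @param fix_interval_hours Nominal fix spacing (default 1 h); consecutive
#'   gaps beyond this (plus 1 s slack) truncate the window.
#' @return Tibble: `window_id`, `start`, `n_fixes`, `rows` (list of row
#'   indices into `fixes`), `truncated` (TRUE when the track ended or a gap
#'   cut the window before T was spanned).
#' @export
sliding_windows <- function(fixes, retention_hours, fix_interval_hours = 1) {
  if (retention_hours <= 0) stop_invalid("`retention_hours` must be > 0.")
  validate_fixes(fixes)
  if (length(unique(fixes$individual_id)) > 1) {
    stop_invalid("`sliding_windows()` expects a single individual.")
  }
  tt <- as.numeric(fixes$timestamp)
  n <- length(tt)
  gap_ok <- c(TRUE, diff(tt) <= fix_interval_hours * 3600 + 1)
  purrr::map_dfr(seq_len(n), function(i) {
    j <- i
    while (j < n && gap_ok[j + 1] && tt[j + 1] <= tt[i] + retention_hours * 3600) {
      j <- j + 1
    }
    full_span <- tt[j] - tt[i] >=
      (floor(retention_hours / fix_interval_hours) * fix_interval_hours) * 3600 - 1
    tibble(window_id = i, start = fixes$timestamp[i], n_fixes = j - i + 1L,
           rows = list(i:j), truncated = !full_span)
  })
}

#' Connectivity counts within one window
#'
#' @param window_rows Integer row indices of the window's fixes.
#' @param assigned Fix tibble with `patch_id` and `landuse` (from
#'   [assign_patches()]).
#' @return List with `n_types` (distinct non-matrix land-use types),
#'   `patches_per_type` (tibble landuse, n_patches), and `all_matrix`.
#' @export
window_connectivity <- function(window_rows, assigned) {
  d <- assigned[window_rows, , drop = FALSE] %>%
    filter(.data$landuse != "matrix")
  if (nrow(d) == 0) {
    return(list(n_types = 0L,
                patches_per_type = tibble(landuse = character(),
                                          n_patches = integer()),
                all_matrix = TRUE))
  }
  per_type <- d %>%
    group_by(.data$landuse) %>%
    summarise(n_patches = n_distinct(.data$patch_id), .groups = "drop")
  list(n_types = nrow(per_type), patches_per_type = per_type,
       all_matrix = FALSE)
}

#' Distance traveled within one window
#'
#' Cumulative Euclidean path length over consecutive fixes (default), or
#' net displacement from first to last fix.
#'
#' @param window_rows Integer row indices of the window's fixes.
#' @param fixes Fix tibble.
#' @param mode `"path"` (cumulative, default) or `"net"`.
#' @return Distance in km (0 for a single-fix window).
#' @export
window_travel_distance <- function(window_rows, fixes, mode = c("path", "net")) {
  mode <- match.arg(mode)
  d <- fixes[window_rows, , drop = FALSE]
  if (nrow(d) < 2) return(0)
  if (mode == "path") {
    sum(sqrt(diff(d$x)^2 + diff(d$y)^2)) / 1000
  } else {
    sqrt((d$x[nrow(d)] - d$x[1])^2 + (d$y[nrow(d)] - d$y[1])^2) / 1000
  }
}

#' Moving-window habitat connectivity summary
#'
#' The full mobile-link analysis for a set of tracked individuals: fixes
#' are assigned to patches, windows of each retention time are slid along
#' every track, and per-window land-use type counts, unique-patch counts
#' per type, and travel distances are averaged per individual, then
#' aggregated across individuals (mean +/- SD). Patch-to-patch connections
#' are operationalized as consecutive-fix transitions between different
#' patches (matrix fixes and self-transitions excluded) and summarized as
#' the percentage composition of unordered land-use type pairs.
#'
#' @param fixes Fix tibble for one or more individuals (hourly resolution;
#'   use [track_resample_hourly()] first if needed).
#' @param patches Patch tibble.
#' @param retention_hours Numeric vector of window durations (default
#'   `c(5.6, 7, 8.4)`, the gut retention mean and its confidence bounds).
#' @param min_days Minimum tracking span per individual (default 10 days);
#'   shorter individuals are excluded with a message.
#' @param travel_mode Passed to [window_travel_distance()].
#' @return Object of class `connectivity_summary`: list with
#'   `per_individual` (individual x retention: mean types, mean travel km,
#'   n windows), `per_type` (mean unique patches per land-use type),
#'   `aggregate` (across-individual mean/sd), `composition` (unordered
#'   type-pair percentages, summing to 100), and `excluded` (ids below
#'   `min_days`).
#' @export
connectivity_summary <- function(fixes, patches,
                                 retention_hours = c(5.6, 7, 8.4),
                                 min_days = 10, travel_mode = "path") {
  validate_fixes(fixes)
  span <- fixes %>%
    group_by(.data$individual_id) %>%
    summarise(days = diff(range(as.numeric(.data$timestamp))) / 86400,
              .groups = "drop")
  excluded <- span$individual_id[span$days < min_days]
  if (length(excluded)) {
    message("Excluded (tracked < ", min_days, " days): ",
            paste(excluded, collapse = ", "))
  }
  fixes <- fixes %>% filter(!.data$individual_id %in% excluded)
  if (nrow(fixes) == 0) stop_invalid("No individual meets the minimum tracking duration.")
  assigned <- assign_patches(fixes, patches)

  ids <- unique(assigned$individual_id)
  per_individual <- list(); per_type <- list()
  transitions <- list()
  for (id in ids) {
    trk <- assigned %>% filter(.data$individual_id == id)
    # transitions: consecutive non-matrix fixes in different patches
    np <- trk %>% filter(.data$landuse != "matrix")
    if (nrow(np) >= 2) {
      keep <- np$patch_id[-1] != np$patch_id[-nrow(np)]
      if (any(keep)) {
        a <- np$landuse[-nrow(np)][keep]; b <- np$landuse[-1][keep]
        pair <- purrr::map2_chr(a, b, ~ paste(sort(c(.x, .y)), collapse = "-"))
        transitions[[id]] <- tibble(individual_id = id, pair = pair)
      }
    }
    for (Th in retention_hours) {
      w <- sliding_windows(trk, Th)
      # average over full-span windows; tail- or gap-truncated windows hold
      # fewer fixes and would bias counts downward. Fall back to all windows
      # only when the track never spans T.
      if (any(!w$truncated)) w <- w[!w$truncated, ]
      conn <- purrr::map(w$rows, window_connectivity, assigned = trk)
      travel <- purrr::map_dbl(w$rows, window_travel_distance, fixes = trk,
                               mode = travel_mode)
      per_individual[[length(per_individual) + 1]] <- tibble(
        individual_id = id, retention_h = Th,
        mean_types = mean(purrr::map_int(conn, "n_types")),
        mean_travel_km = mean(travel),
        n_windows = nrow(w))
      ppt <- purrr::map_dfr(seq_along(conn), function(k) {
        conn[[k]]$patches_per_type %>% mutate(window_id = k)
      })
      if (nrow(ppt)) {
        # windows not visiting a type count as 0 patches of that type
        per_type[[length(per_type) + 1]] <- ppt %>%
          tidyr::complete(window_id = seq_along(conn),
                          landuse = unique(ppt$landuse),
                          fill = list(n_patches = 0L)) %>%
          group_by(.data$landuse) %>%
          summarise(mean_unique_patches = mean(.data$n_patches),
                    .groups = "drop") %>%
          mutate(individual_id = id, retention_h = Th)
      }
    }
  }
  per_individual <- bind_rows(per_individual)
  per_type <- bind_rows(per_type)
  aggregate <- per_individual %>%
    group_by(.data$retention_h) %>%
    summarise(n_individuals = n(),
              mean_types = mean(.data$mean_types),
              sd_types = sd(.data$mean_types),
              mean_travel_km = mean(.data$mean_travel_km),
              sd_travel_km = sd(.data$mean_travel_km), .groups = "drop")
  trans <- bind_rows(transitions)
  composition <- if (nrow(trans)) {
    trans %>%
      group_by(.data$pair) %>%
      summarise(n = n(), .groups = "drop") %>%
      mutate(pct = 100 * .data$n / sum(.data$n)) %>%
      arrange(dplyr::desc(.data$pct))
  } else {
    tibble(pair = character(), n = integer(), pct = numeric())
  }
  structure(list(per_individual = per_individual, per_type = per_type,
                 aggregate = aggregate, composition = composition,
                 excluded = excluded, retention_hours = retention_hours),
            class = "connectivity_summary")
}

#' @export
print.connectivity_summary <- function(x, ...) {
  cat("Moving-window connectivity,", length(unique(x$per_individual$individual_id)),
      "individuals, T =", paste(x$retention_hours, collapse = "/"), "h\n")
  print(x$aggregate)
  if (nrow(x$composition)) {
    cat("Connection composition (%):\n")
    print(x$composition)
  }
  invisible(x)
}

#' Connectivity summary panels
#'
#' @param object A [connectivity_summary()] object.
#' @param ... Unused.
#' @return A ggplot of per-individual mean connected land-use types by
#'   retention time.
#' @export
autoplot.connectivity_summary <- function(object, ...) {
  ggplot(object$per_individual,
         aes(x = factor(.data$retention_h), y = .data$mean_types)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.1, alpha = 0.5) +
    labs(x = "retention time [h]", y = "mean connected land-use types") +
    theme_minimal()
}
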