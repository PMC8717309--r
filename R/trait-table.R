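#' Derive the full seed-trait table
#'
#' Takes a per-species record table and adds every derived dispersal-syndrome
#' quantity that its columns allow: eccentricity (`ei`), flatness (`fi`),
#' shape variance (`vs`), density, surface area (`area`, with the branch
#' taken in `area_branch`), `area_mass`, and standardized germination
#' success (`sgs`).
#'
#' Raw dimensions (`length`, `width`, `height`) take precedence: when they
#' are present the indices are (re)computed from them; otherwise an already
#' present index column is kept as supplied (trait compilations often print
#' the indices without the underlying dimensions). Rows with missing height
#' keep `fi`, `vs` and `area` as `NA` and are flagged in `height_missing`
#' rather than imputed. Species with zero control germination capacity get
#' `sgs = NA` and `sgs_excluded = TRUE`.
#'
#' @param records Data frame with one row per species. Must contain
#'   `species_name` (unique). Recognized columns: `length`, `width`,
#'   `height`, `mass`, `volume`, `seeds_fed`, `control_germ_pct`,
#'   `feces_germ`, plus any pre-computed index columns.
#' @param vs_threshold,method,radius Passed to [seed_surface_area()].
#' @return A tibble with the input columns plus the derived ones.
#' @export
derive_seed_traits <- function(records, vs_threshold = 1,
                               method = c("thomsen", "quadrature"),
                               radius = c("mean", "width")) {
  method <- match.arg(method)
  radius <- match.arg(radius)
  records <- as_tibble(records)
  if (nrow(records) == 0) return(records)
  if (!"species_name" %in% names(records)) {
    stop_invalid("`records` must have a `species_name` column.")
  }
  if (anyDuplicated(records$species_name)) {
    dups <- unique(records$species_name[duplicated(records$species_name)])
    stop_invalid(paste0("Duplicate species: ", paste(dups, collapse = ", ")))
  }
  validate_trait_records(records)

  has <- function(nm) nm %in% names(records)
  col_or_na <- function(nm) if (has(nm)) records[[nm]] else rep(NA_real_, nrow(records))
  out <- records

  dims_present <- has("length") && has("width")
  if (dims_present) {
    l <- records$length; w <- records$width
    h <- if (has("height")) records$height else rep(NA_real_, nrow(records))
    out$height_missing <- is.na(h)
    out$ei <- seed_eccentricity(l, w)
    out$fi <- out$vs <- out$area <- rep(NA_real_, nrow(records))
    out$area_branch <- rep(NA_character_, nrow(records))
    ok <- !is.na(h)
    if (any(ok)) {
      out$fi[ok] <- seed_flatness(l[ok], w[ok], h[ok])
      out$vs[ok] <- seed_shape_variance(l[ok], w[ok], h[ok])
      ar <- seed_surface_area(l[ok], w[ok], h[ok], vs_threshold = vs_threshold,
                              method = method, radius = radius)
      out$area[ok] <- as.numeric(ar)
      out$area_branch[ok] <- attr(ar, "branch")
    }
  } else {
    out$height_missing <- if (has("height")) is.na(records$height) else NA
  }

  if (has("mass") && has("volume")) {
    out$density <- seed_density(records$mass, records$volume)
  }
  if (has("mass") && !is.null(out[["area"]])) {
    ok <- !is.na(out$area)
    out$area_mass <- rep(NA_real_, nrow(out))
    out$area_mass[ok] <- area_mass_ratio(out$area[ok], records$mass[ok])
  }

  if (has("feces_germ") && has("control_germ_pct") && has("seeds_fed")) {
    cap <- records$control_germ_pct
    out$sgs_excluded <- cap == 0
    out$sgs <- rep(NA_real_, nrow(out))
    ok <- cap > 0
    out$sgs[ok] <- standardized_germination(records$feces_germ[ok], cap[ok],
                                            records$seeds_fed[ok])
  } else if (has("sgs")) {
    out$sgs_excluded <- is.na(records$sgs)
  }
  out
}

# Invariant checks shared by derive_seed_traits() and read_trait_csv().
validate_trait_records <- function(records) {
  chk <- function(nm, cond, msg) {
    if (nm %in% names(records)) {
      bad <- which(!is.na(records[[nm]]) & !cond(records[[nm]]))
      if (length(bad)) {
        stop_invalid(sprintf("Column `%s` %s (rows %s).", nm, msg,
                             paste(head(bad, 5), collapse = ", ")))
      }
    }
  }
  pos <- function(x) x > 0
  chk("length", pos, "must be positive")
  chk("width", pos, "must be positive")
  chk("height", pos, "must be positive")
  chk("mass", pos, "must be positive")
  chk("volume", pos, "must be positive")
  chk("seeds_fed", pos, "must be positive")
  chk("control_germ_pct", function(x) x >= 0 & x <= 100, "must lie in [0, 100]")
  if (all(c("feces_germ", "seeds_fed") %in% names(records))) {
    bad <- which(!is.na(records$feces_germ) &
                   records$feces_germ > records$seeds_fed)
    if (length(bad)) {
      stop_invalid(sprintf("`feces_germ` exceeds `seeds_fed` (rows %s).",
                           paste(head(bad, 5), collapse = ", ")))
    }
  }
  invisible(records)
}

#' Packaged feeding-trial seed trait table
#'
#' The 44-species seed trait and germination table from the hare feeding
#' experiment, as printed: seeds fed, germination temperature regime,
#' control germination capacity, standardized germination success (`sgs`),
#' flatness and eccentricity indices, mass, volume, density, surface area,
#' area/mass ratio, seed origin, neophyte status, and red-list status.
#'
#' Feces seedling counts are not printed in the source table; `feces_germ`
#' is recovered by inverting the standardized-germination formula and
#' rounding to the nearest integer (all inversions land within 0.05 of an
#' integer; the counts total 177). Raw seed dimensions are not part of the
#' printed table, so `ei`/`fi`/`area` are carried as printed rather than
#' recomputed. Mass is carried in the units printed, never converted.
#'
#' @return A tibble with 44 rows, one per species, including a normalized
#'   `species_name` key (genus_species, lower case).
#' @export
hare_seed_traits <- function() {
  path <- system.file("extdata", "hare_feeding_seed_traits.csv",
                      package = "endolink", mustWork = TRUE)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  d <- d %>%
    mutate(
      species_name = normalize_species(paste(.data$genus, .data$species)),
      neophyte = .data$neophyte == "yes",
      feces_germ = ifelse(
        is.na(.data$sgs), 0L,
        as.integer(round(.data$sgs / 100 * .data$control_germ_pct / 100 *
                           .data$seeds_fed)))
    )
  validate_trait_records(d)
  d
}

#' Mean standardized germination success by species group
#'
#' Arithmetic mean of `sgs` per level of a grouping flag (e.g. neophyte or
#' red-list status), after removing named species. The `zero_capacity`
#' policy controls species whose control capacity was zero (standardization
#' undefined): `"zero"` counts them as 0% success, `"drop"` removes them.
#'
#' @param table Derived trait table with `species_name`, `sgs` and the
#'   grouping column.
#' @param group Name of the grouping column.
#' @param exclude Character vector of `species_name`s to drop first.
#' @param zero_capacity `"zero"` or `"drop"`.
#' @return Tibble with one row per group level: `group`, level, `n`,
#'   `mean_sgs`. Empty groups appear with `n = 0` and `mean_sgs = NA`.
#' @export
germination_by_group <- function(table, group, exclude = character(),
                                 zero_capacity = c("zero", "drop")) {
  zero_capacity <- match.arg(zero_capacity)
  if (!group %in% names(table)) {
    stop_invalid(sprintf("Grouping column `%s` not found.", group))
  }
  if (!"sgs" %in% names(table)) stop_invalid("`sgs` column required.")
  missing_sp <- setdiff(exclude, table$species_name)
  if (length(missing_sp)) {
    stop_invalid(paste0("Excluded species not in table: ",
                        paste(missing_sp, collapse = ", ")))
  }
  d <- table %>% filter(!.data$species_name %in% exclude)
  if (zero_capacity == "zero") {
    d <- d %>% mutate(sgs = ifelse(is.na(.data$sgs), 0, .data$sgs))
  } else {
    d <- d %>% filter(!is.na(.data$sgs))
  }
  d %>%
    group_by(level = .data[[group]]) %>%
    summarise(n = n(), mean_sgs = mean(.data$sgs), .groups = "drop") %>%
    mutate(group = group, .before = 1)
}
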