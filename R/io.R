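# Readers and writers for the pipeline's exchange formats: trait CSV,
# GPS CSV (ISO 8601 UTC, projected meters), land-use GeoJSON, and the
# run-output directory. All numeric I/O is point-decimal, locale-fixed.

trait_numeric_cols <- c("length", "width", "height", "mass", "volume",
                        "seeds_fed", "control_germ_pct", "feces_germ",
                        "sgs", "fi", "ei", "density", "area", "area_mass")

#' Read a per-species seed trait CSV
#'
#' Expects one row per species with a `species_name` column (or `genus` +
#' `species`, which are combined and normalized). Numeric columns are
#' validated cell by cell; unparseable cells (including comma decimals) are
#' reported with row and column.
#'
#' @param path CSV path (UTF-8, point decimal).
#' @return Validated tibble; rows with missing `height` are flagged via
#'   `height_missing` once derived.
#' @export
read_trait_csv <- function(path) {
  # grouping mark set to "'" so comma-decimal cells fail loudly instead of
  # being read as grouped integers
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       locale = readr::locale(decimal_mark = ".",
                                              grouping_mark = "'"))
  if (nrow(d) == 0 || ncol(d) == 0) {
    stop_invalid("Empty trait file or missing header.")
  }
  if (!"species_name" %in% names(d)) {
    if (all(c("genus", "species") %in% names(d))) {
      d$species_name <- normalize_species(paste(d$genus, d$species))
    } else {
      stop_invalid("Need `species_name` or `genus` + `species` columns.")
    }
  }
  for (cn in intersect(trait_numeric_cols, names(d))) {
    if (!is.numeric(d[[cn]])) {
      parsed <- suppressWarnings(as.numeric(d[[cn]]))
      bad <- which(!is.na(d[[cn]]) & is.na(parsed) &
                     !d[[cn]] %in% c("NA", ""))
      if (length(bad)) {
        stop_invalid(sprintf(
          "Unparseable numeric cell(s) in `%s`: row %s value '%s' (point decimal required).",
          cn, bad[1], d[[cn]][bad[1]]))
      }
      d[[cn]] <- parsed
    }
  }
  validate_trait_records(d)
  as_tibble(d)
}

#' Write a derived trait table to CSV
#'
#' @param table Trait tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Read a Movebank-style GPS fix CSV
#'
#' Columns: `individual_id`, `timestamp` (ISO 8601, read as UTC), `x`, `y`
#' (projected meters). Coordinates that all fit in degree ranges are
#' rejected — the analysis requires a projected planar frame and never
#' reprojects silently. Out-of-order rows are sorted with a warning;
#' duplicate timestamps within an individual are an error.
#'
#' @param path CSV path.
#' @return Fix tibble sorted by individual and time.
#' @export
read_gps_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("individual_id", "timestamp", "x", "y")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop_invalid(paste0("GPS file lacks columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!inherits(d$timestamp, "POSIXct")) {
    d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                             "%Y-%m-%d %H:%M:%S"))
  }
  attr(d$timestamp, "tzone") <- "UTC"
  if (anyNA(d$timestamp)) stop_invalid("Unparseable timestamps (ISO 8601 UTC required).")
  if (all(abs(d$x) <= 180) && all(abs(d$y) <= 90)) {
    stop_invalid(paste0(
      "Coordinates look geographic (degrees); supply projected x/y in ",
      "meters — no silent reprojection."))
  }
  dup <- d %>%
    group_by(.data$individual_id) %>%
    summarise(bad = anyDuplicated(.data$timestamp) > 0, .groups = "drop")
  if (any(dup$bad)) {
    stop_invalid(paste0("Duplicate timestamps for: ",
                        paste(dup$individual_id[dup$bad], collapse = ", ")))
  }
  sorted <- d %>% arrange(.data$individual_id, .data$timestamp)
  if (!identical(sorted$timestamp, d$timestamp) ||
        !identical(sorted$individual_id, d$individual_id)) {
    warn("GPS fixes were out of order; sorted by individual and time.")
  }
  validate_fixes(sorted)
  sorted
}

#' Write GPS fixes to CSV (ISO 8601 UTC)
#'
#' @param fixes Fix tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gps_csv <- function(fixes, path) {
  out <- fixes %>%
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a land-use landscape from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with properties
#' `patch_id` and `landuse`; only the outer ring of each polygon is used.
#'
#' @param path GeoJSON path.
#' @return Patch tibble as from [make_patches()].
#' @export
read_landscape_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$type) || g$type != "FeatureCollection") {
    stop_invalid("Expected a GeoJSON FeatureCollection.")
  }
  feats <- g$features
  rows <- purrr::imap(feats, function(f, i) {
    props <- f$properties
    if (is.null(props$patch_id) || is.null(props$landuse)) {
      stop_invalid(sprintf("Feature %d lacks patch_id or landuse property.", i))
    }
    if (is.null(f$geometry) || f$geometry$type != "Polygon") {
      stop_invalid(sprintf("Feature %d is not a Polygon.", i))
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    list(patch_id = as.character(props$patch_id),
         landuse = as.character(props$landuse), ring = m)
  })
  make_patches(purrr::map_chr(rows, "patch_id"),
               purrr::map_chr(rows, "landuse"),
               purrr::map(rows, "ring"))
}

#' Write a patch table as GeoJSON
#'
#' @param patches Patch tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape_geojson <- function(patches, path) {
  feats <- purrr::pmap(patches[, c("patch_id", "landuse", "ring")],
                       function(patch_id, landuse, ring) {
    closed <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(patch_id = patch_id, landuse = landuse),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(closed)),
                                                   function(i) as.list(unname(closed[i, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a stage's outputs with run metadata
#'
#' Data frames become CSV, everything else JSON, plus a
#' `run_metadata.json` recording package version, seed, and a hash of the
#' configuration — so identical inputs and seed give byte-identical output
#' directories. Nothing is written if any element fails to serialize.
#'
#' @param results Named list of data frames / lists.
#' @param dir Output directory (created if needed).
#' @param seed The seed the run used.
#' @param config Optional list of settings; hashed into the metadata.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(results, dir, seed = NA_integer_, config = list()) {
  if (is.null(names(results)) || any(names(results) == "")) {
    stop_invalid("`results` must be a fully named list.")
  }
  cfg_file <- tempfile()
  jsonlite::write_json(config[order(names(config))] , cfg_file,
                       auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile("endolink_out_")
  dir.create(tmp)
  paths <- purrr::imap_chr(results, function(obj, nm) {
    if (is.data.frame(obj)) {
      p <- file.path(tmp, paste0(nm, ".csv"))
      readr::write_csv(obj, p, progress = FALSE)
    } else {
      p <- file.path(tmp, paste0(nm, ".json"))
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
    }
    p
  })
  meta <- list(package = "endolink",
               version = as.character(utils::packageVersion("endolink")),
               seed = seed, config_hash = cfg_hash)
  mp <- file.path(tmp, "run_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  final <- file.path(dir, basename(c(paths, mp)))
  ok <- file.copy(c(paths, mp), final, overwrite = TRUE)
  unlink(tmp, recursive = TRUE)
  if (!all(ok)) stop_invalid("Failed to write outputs.", class = "endolink_io")
  invisible(final)
}
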