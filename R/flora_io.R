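#' Required columns of a long-format occurrence table
#'
#' One row per (reserve, species) record. `areal_type` is the phytogeographic
#' distribution-type code of the record's genus (Wu's classification in the
#' real data; a closed synthetic vocabulary in simulations). `endemic` flags
#' species confined to China; `cultivated` flags introduced cultivated species,
#' which are excluded from all analyses by [filter_cultivated()].
#' @keywords internal
occurrence_columns <- c(
  "reserve_id", "species", "genus", "family",
  "areal_type", "endemic", "cultivated"
)

norm_ws <- function(x) {
  gsub("\\s+", " ", trimws(as.character(x)))
}

#' Validate a long-format occurrence table
#'
#' Checks the schema (seven required columns), normalizes whitespace in name
#' columns, coerces the flag columns to logical, collapses duplicate
#' (reserve, species) records, and enforces taxonomic consistency: a species
#' must map to exactly one genus and a genus to exactly one family.
#'
#' @param x A data frame with the columns listed in `occurrence_columns`.
#' @return A tibble of class `flora_occurrences` with a `report` attribute
#'   (counts of reserves, species, genera, families, and duplicates removed).
#' @export
validate_occurrences <- function(x) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(occurrence_columns, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "occurrence table is missing required column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "qdmflora_schema_error"
    )
  }
  x <- dplyr::mutate(
    x,
    dplyr::across(c("reserve_id", "species", "genus", "family", "areal_type"), norm_ws),
    dplyr::across(c("endemic", "cultivated"), as.logical)
  )
  if (anyNA(x$endemic) || anyNA(x$cultivated)) {
    abort("endemic/cultivated flags must be interpretable as logical",
      class = "qdmflora_schema_error"
    )
  }
  if (nrow(x) == 0) {
    abort("occurrence table has no records", class = "qdmflora_empty_error")
  }

  # species -> genus and genus -> family must be functions
  sp_gen <- dplyr::distinct(x, .data$species, .data$genus)
  bad_sp <- sp_gen$species[duplicated(sp_gen$species)]
  if (length(bad_sp) > 0) {
    abort(
      paste0(
        "species mapped to more than one genus: ",
        paste(unique(bad_sp), collapse = ", ")
      ),
      class = "qdmflora_consistency_error"
    )
  }
  gen_fam <- dplyr::distinct(x, .data$genus, .data$family)
  bad_gen <- gen_fam$genus[duplicated(gen_fam$genus)]
  if (length(bad_gen) > 0) {
    abort(
      paste0(
        "genus mapped to more than one family: ",
        paste(unique(bad_gen), collapse = ", ")
      ),
      class = "qdmflora_consistency_error"
    )
  }

  n_before <- nrow(x)
  x <- dplyr::distinct(x, .data$reserve_id, .data$species, .keep_all = TRUE)

  report <- list(
    n_records = nrow(x),
    n_duplicates_removed = n_before - nrow(x),
    n_reserves = dplyr::n_distinct(x$reserve_id),
    n_species = dplyr::n_distinct(x$species),
    n_genera = dplyr::n_distinct(x$genus),
    n_families = dplyr::n_distinct(x$family)
  )
  structure(x, class = c("flora_occurrences", class(tibble::tibble())), report = report)
}

#' Read a long-format occurrence CSV
#'
#' @param path Path to a UTF-8 comma-separated file whose header contains the
#'   seven required columns (`reserve_id, species, genus, family, areal_type,
#'   endemic, cultivated`). Extra columns are carried along untouched.
#' @return A validated `flora_occurrences` tibble; see [validate_occurrences()].
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "qdmflora_io_error")
  }
  validate_occurrences(readr::read_csv(path, show_col_types = FALSE))
}

#' Write an occurrence table to CSV
#' @param x An occurrence table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

#' Retrieve the validation report attached to an occurrence table
#' @param x A `flora_occurrences` tibble.
#' @return A named list of record/taxon counts.
#' @export
occurrence_report <- function(x) attr(x, "report")

#' Drop introduced cultivated species
#'
#' Removes every record of any species flagged cultivated in at least one
#' record; the number of distinct species removed is attached as the
#' `removed_species` attribute (and reported via `message()`).
#'
#' @param x A validated occurrence table.
#' @param quiet Suppress the message.
#' @return The filtered `flora_occurrences` tibble.
#' @export
filter_cultivated <- function(x, quiet = FALSE) {
  x <- validate_occurrences(x)
  cult_species <- unique(x$species[x$cultivated])
  out <- dplyr::filter(x, !(.data$species %in% cult_species))
  if (nrow(out) == 0) {
    abort("all records are cultivated; nothing left to analyse",
      class = "qdmflora_empty_error"
    )
  }
  out <- validate_occurrences(out)
  attr(out, "removed_species") <- length(cult_species)
  if (!quiet) {
    message("filter_cultivated: removed ", length(cult_species), " cultivated species")
  }
  out
}

#' Build a reserve-by-taxon presence matrix
#'
#' Cell (r, t) is `TRUE` iff reserve r holds at least one record of taxon t at
#' the requested level. The genus level collapses congeneric species; the
#' areal-type level collapses genera to their distribution-type code. Rows and
#' columns are ordered lexicographically, so the matrix is a pure function of
#' the record set.
#'
#' @param x A validated occurrence table.
#' @param level One of `"species"`, `"genus"`, `"areal_type"`.
#' @param reserves Optional character vector of reserve ids that must all be
#'   represented; a listed reserve with zero records is a construction error.
#' @return A logical matrix of class `flora_presence` with attribute `level`.
#' @export
to_presence <- function(x, level = c("species", "genus", "areal_type"),
                        reserves = NULL) {
  level <- match.arg(level)
  x <- validate_occurrences(x)
  taxon <- x[[level]]
  rid <- x$reserve_id
  if (!is.null(reserves)) {
    empty <- setdiff(reserves, unique(rid))
    if (length(empty) > 0) {
      abort(
        paste0(
          "reserve(s) with no records cannot enter a presence matrix: ",
          paste(empty, collapse = ", ")
        ),
        class = "qdmflora_empty_error"
      )
    }
    x <- x[rid %in% reserves, , drop = FALSE]
    taxon <- x[[level]]
    rid <- x$reserve_id
  }
  rows <- sort(unique(rid))
  cols <- sort(unique(taxon))
  m <- matrix(FALSE, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(match(rid, rows), match(taxon, cols))] <- TRUE
  structure(m, class = c("flora_presence", "matrix", "array"), level = level)
}

#' @export
tidy.flora_presence <- function(x, ...) {
  tibble::tibble(
    reserve_id = rep(rownames(x), ncol(x)),
    taxon = rep(colnames(x), each = nrow(x)),
    present = as.vector(x)
  )
}

#' Write a presence (or any square reserve) matrix as CSV with ids
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(m)), rownames = "reserve_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' Richness summary per reserve or for the whole table
#'
#' Counts families, genera, species, endemic species and endemic genera. A
#' genus is counted endemic iff every one of its recorded species is flagged
#' endemic — a proxy for literature-attributed endemic-genus status, which the
#' occurrence schema does not carry directly.
#'
#' @param x A validated occurrence table.
#' @param by_reserve If `TRUE`, one row per reserve; otherwise a single global row.
#' @return A tibble with columns `n_families, n_genera, n_species,
#'   n_endemic_species, n_endemic_genera` (plus `reserve_id` when per-reserve).
#' @export
richness_summary <- function(x, by_reserve = FALSE) {
  x <- validate_occurrences(x)
  endemic_genera <- x |>
    dplyr::distinct(.data$genus, .data$species, .data$endemic) |>
    dplyr::summarise(all_end = all(.data$endemic), .by = "genus") |>
    dplyr::filter(.data$all_end) |>
    dplyr::pull("genus")
  count_one <- function(d) {
    tibble::tibble(
      n_families = dplyr::n_distinct(d$family),
      n_genera = dplyr::n_distinct(d$genus),
      n_species = dplyr::n_distinct(d$species),
      n_endemic_species = dplyr::n_distinct(d$species[d$endemic]),
      n_endemic_genera = dplyr::n_distinct(d$genus[d$genus %in% endemic_genera])
    )
  }
  if (!by_reserve) {
    return(count_one(x))
  }
  x |>
    dplyr::group_by(.data$reserve_id) |>
    dplyr::group_modify(~ count_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$reserve_id)
}

#' Read reserve metadata (coordinates, elevations, climate variables)
#'
#' @param path CSV with columns `reserve_id, lon, lat, elev_base, elev_mean,
#'   elev_peak` plus any number of numeric environment columns (annual
#'   precipitation, annual/coldest-quarter/warmest-quarter mean temperature,
#'   each current and LGM, in the study data).
#' @param occurrences Optional occurrence table; reserves present in metadata
#'   but absent from the occurrences are dropped with a warning.
#' @return A validated tibble.
#' @export
read_reserves <- function(path, occurrences = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "qdmflora_io_error")
  }
  validate_reserves(readr::read_csv(path, show_col_types = FALSE), occurrences)
}

#' Validate a reserve metadata table
#' @inheritParams read_reserves
#' @param x Data frame of reserve metadata.
#' @return A tibble; errors on missing columns or elevation-order violations.
#' @export
validate_reserves <- function(x, occurrences = NULL) {
  x <- tibble::as_tibble(x)
  need <- c("reserve_id", "lon", "lat", "elev_base", "elev_mean", "elev_peak")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("reserve metadata missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "qdmflora_schema_error"
    )
  }
  x$reserve_id <- norm_ws(x$reserve_id)
  if (anyDuplicated(x$reserve_id)) {
    abort("duplicate reserve_id in metadata", class = "qdmflora_consistency_error")
  }
  bad <- x$reserve_id[!(x$elev_base <= x$elev_mean & x$elev_mean <= x$elev_peak)]
  if (length(bad) > 0) {
    abort(
      paste0(
        "elevation order base <= mean <= peak violated for: ",
        paste(bad, collapse = ", ")
      ),
      class = "qdmflora_consistency_error"
    )
  }
  if (!is.null(occurrences)) {
    occurrences <- validate_occurrences(occurrences)
    extra <- setdiff(x$reserve_id, unique(occurrences$reserve_id))
    if (length(extra) > 0) {
      warn(paste0(
        "dropping ", length(extra),
        " reserve(s) present in metadata but absent from occurrences: ",
        paste(extra, collapse = ", ")
      ))
      x <- dplyr::filter(x, !(.data$reserve_id %in% extra))
    }
  }
  x
}

#' Read a genus-to-geographic-component table
#'
#' Genus-level rows give the component and origin center of a Chinese endemic
#' genus; optional species-level rows (non-missing `species`) override the
#' genus assignment for that species, as needed when congeners have distinct
#' origins.
#'
#' @param path CSV with columns `genus, component, origin_lon, origin_lat` and
#'   optionally `species`.
#' @return A validated tibble.
#' @export
read_components <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "qdmflora_io_error")
  }
  validate_components(readr::read_csv(path, show_col_types = FALSE))
}

#' Validate a component table
#' @param x Data frame with `genus, component, origin_lon, origin_lat` and
#'   optional `species` override column.
#' @return A tibble with a `species` column (NA for genus-level rows).
#' @export
validate_components <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("genus", "component", "origin_lon", "origin_lat")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("component table missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "qdmflora_schema_error"
    )
  }
  if (!"species" %in% names(x)) x$species <- NA_character_
  x$genus <- norm_ws(x$genus)
  x$component <- norm_ws(x$component)
  genus_rows <- dplyr::filter(x, is.na(.data$species))
  if (anyDuplicated(genus_rows$genus)) {
    abort("a genus may carry at most one genus-level component row",
      class = "qdmflora_consistency_error"
    )
  }
  x
}
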