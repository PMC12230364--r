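#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius); coordinates are WGS84 decimal degrees.
#'
#' @param lon1,lat1,lon2,lat2 Coordinate vectors, recycled as usual.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371008.8) / 1000
}

#' Annotate endemic occurrence records with their geographic component
#'
#' Joins the genus-level component assignments onto every endemic record, then
#' applies species-level overrides (rows of the component table carrying a
#' species name), which take precedence — congeners can have distinct origins,
#' so species of the same genus are considered separately. Endemic genera
#' absent from the component table are labelled `"Uncertain"`; non-endemic
#' records keep `NA`.
#'
#' @param x A validated occurrence table.
#' @param components A component table (see [read_components()]).
#' @return The occurrence tibble with added columns `component`, `origin_lon`,
#'   `origin_lat`.
#' @export
assign_components <- function(x, components) {
  x <- validate_occurrences(x)
  components <- validate_components(components)

  genus_rows <- components |>
    dplyr::filter(is.na(.data$species)) |>
    dplyr::select("genus", "component", "origin_lon", "origin_lat")
  species_rows <- components |>
    dplyr::filter(!is.na(.data$species)) |>
    dplyr::select("genus", "species",
      component_sp = "component",
      origin_lon_sp = "origin_lon", origin_lat_sp = "origin_lat"
    )

  endemic_genera <- unique(x$genus[x$endemic])
  listed <- unique(c(genus_rows$genus, species_rows$genus))
  # genera absent from the data are silently ignored; only genera that are
  # present yet carry no endemic records indicate a labelling conflict
  not_endemic <- setdiff(intersect(listed, unique(x$genus)), endemic_genera)
  if (length(not_endemic) > 0) {
    warn(paste0(
      "component table lists genera with no endemic records: ",
      paste(not_endemic, collapse = ", ")
    ))
  }

  out <- x |>
    dplyr::left_join(genus_rows, by = "genus") |>
    dplyr::left_join(species_rows, by = c("genus", "species")) |>
    dplyr::mutate(
      component = dplyr::coalesce(.data$component_sp, .data$component),
      origin_lon = dplyr::coalesce(.data$origin_lon_sp, .data$origin_lon),
      origin_lat = dplyr::coalesce(.data$origin_lat_sp, .data$origin_lat),
      component = dplyr::if_else(.data$endemic & is.na(.data$component),
        "Uncertain", .data$component
      )
    ) |>
    dplyr::select(-dplyr::ends_with("_sp"))
  out <- tibble::as_tibble(out)
  attr(out, "report") <- NULL
  attr(out, "removed_species") <- NULL
  out
}

#' Dataset-wide component composition of endemic genera
#'
#' Counts distinct endemic genera per geographic component (a genus split by
#' species-level overrides contributes once to each component it appears
#' under) and reports each count as a percentage of the total, rounded to two
#' decimals.
#'
#' @param annotated Output of [assign_components()].
#' @return A tibble `component, n_genera, proportion` sorted by decreasing
#'   count; proportions are percentages.
#' @export
component_summary <- function(annotated) {
  ann <- dplyr::filter(annotated, .data$endemic, !is.na(.data$component))
  if (nrow(ann) == 0) {
    abort("no endemic genera with component assignments",
      class = "qdmflora_empty_error"
    )
  }
  counts <- ann |>
    dplyr::distinct(.data$component, .data$genus) |>
    dplyr::count(.data$component, name = "n_genera")
  total <- sum(counts$n_genera)
  counts |>
    dplyr::mutate(proportion = round(100 * .data$n_genera / total, 2)) |>
    dplyr::arrange(dplyr::desc(.data$n_genera), .data$component)
}

#' Per-reserve counts of endemic genera by geographic component
#'
#' @param annotated Output of [assign_components()].
#' @param drop_uncertain Exclude genera of uncertain origin (default keeps them).
#' @return A long tibble `reserve_id, component, n_genera, proportion` of class
#'   `flora_component_counts`; proportions are within-reserve fractions of the
#'   reserve's distinct endemic genera, summing to 1 for reserves with at
#'   least one endemic genus.
#' @export
component_counts <- function(annotated, drop_uncertain = FALSE) {
  ann <- dplyr::filter(annotated, .data$endemic, !is.na(.data$component))
  if (drop_uncertain) ann <- dplyr::filter(ann, .data$component != "Uncertain")
  counts <- ann |>
    dplyr::distinct(.data$reserve_id, .data$component, .data$genus) |>
    dplyr::count(.data$reserve_id, .data$component, name = "n_genera") |>
    dplyr::mutate(
      proportion = .data$n_genera / sum(.data$n_genera),
      .by = "reserve_id"
    ) |>
    dplyr::arrange(.data$reserve_id, .data$component)
  counts <- tibble::as_tibble(counts)
  attr(counts, "report") <- NULL
  class(counts) <- c("flora_component_counts", class(counts))
  counts
}

#' Widen component counts to a reserve-by-component matrix
#' @param counts Output of [component_counts()].
#' @return Integer matrix, reserves in rows, zero-filled.
#' @export
component_count_matrix <- function(counts) {
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(counts), "reserve_id", "component", "n_genera"),
    names_from = "component", values_from = "n_genera", values_fill = 0
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$reserve_id
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Distance-decay gradient test for one geographic component
#'
#' Operationalizes the "spreads with decreasing proportion" reading of a
#' component's dispersal: Spearman correlation between each reserve's
#' great-circle distance from the component origin and its genus count, with
#' a two-sided permutation p-value from seeded shuffles of the counts.
#'
#' @param counts A `flora_component_counts` tibble (zero counts are filled in
#'   for reserves listed in `meta` but absent for this component).
#' @param meta Reserve metadata with `reserve_id, lon, lat`.
#' @param component Component name to test.
#' @param origin Length-2 numeric `c(lon, lat)` of the origin center; defaults
#'   to the origin recorded for the component in `counts`' source table when
#'   given via `origin`.
#' @param n_perm Number of permutations (>= 199).
#' @param seed Integer seed for the permutation stream.
#' @return A one-row tibble of class `flora_gradient`: `component, rho, p_perm,
#'   n_reserves, direction` with `direction` in `decay | increase | flat`
#'   (flat unless p < 0.05).
#' @export
gradient_test <- function(counts, meta, component, origin, n_perm = 999, seed = 1) {
  if (n_perm < 199) {
    abort("n_perm must be at least 199", class = "qdmflora_domain_error")
  }
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) < 5) {
    abort("gradient test needs at least five reserves with coordinates",
      class = "qdmflora_domain_error"
    )
  }
  cc <- dplyr::filter(tibble::as_tibble(counts), .data$component == .env$component)
  df <- meta |>
    dplyr::select("reserve_id", "lon", "lat") |>
    dplyr::left_join(dplyr::select(cc, "reserve_id", "n_genera"), by = "reserve_id") |>
    dplyr::mutate(
      n_genera = dplyr::coalesce(.data$n_genera, 0L),
      dist_km = haversine_km(.data$lon, .data$lat, origin[1], origin[2])
    )

  res <- if (length(unique(df$n_genera)) < 2 || length(unique(df$dist_km)) < 2) {
    tibble::tibble(
      component = component, rho = NA_real_, p_perm = 1,
      n_reserves = nrow(df), direction = "flat"
    )
  } else {
    rho_obs <- cor(df$dist_km, df$n_genera, method = "spearman")
    perm_rhos <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        cor(df$dist_km, sample(df$n_genera), method = "spearman")
      }, numeric(1))
    })
    p <- (1 + sum(abs(perm_rhos) >= abs(rho_obs) - 1e-12)) / (n_perm + 1)
    direction <- if (p < 0.05 && rho_obs < 0) {
      "decay"
    } else if (p < 0.05 && rho_obs > 0) {
      "increase"
    } else {
      "flat"
    }
    tibble::tibble(
      component = component, rho = rho_obs, p_perm = p,
      n_reserves = nrow(df), direction = direction
    )
  }
  class(res) <- c("flora_gradient", class(res))
  res
}

#' Gradient tests for every component in a count table
#'
#' @param counts A `flora_component_counts` tibble.
#' @param meta Reserve metadata.
#' @param origins Tibble `component, origin_lon, origin_lat` (e.g. distinct
#'   rows of the component table).
#' @inheritParams gradient_test
#' @return A `flora_gradient` tibble, one row per component.
#' @export
gradient_tests <- function(counts, meta, origins, n_perm = 999, seed = 1) {
  origins <- dplyr::distinct(
    tibble::as_tibble(origins), .data$component, .data$origin_lon, .data$origin_lat
  )
  origins <- dplyr::filter(origins, !is.na(.data$origin_lon))
  res <- purrr::pmap(origins, function(component, origin_lon, origin_lat) {
    gradient_test(counts, meta, component, c(origin_lon, origin_lat),
      n_perm = n_perm, seed = seed
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("flora_gradient", class(tibble::tibble()))
  out
}

#' Export per-reserve component counts as a GeoJSON FeatureCollection
#'
#' One Point feature per reserve-component cell with positive count (the
#' count drives point size on a map) plus one feature per origin center.
#' Reserves without coordinates are skipped with a warning.
#'
#' @param counts A `flora_component_counts` tibble.
#' @param meta Reserve metadata with coordinates.
#' @param origins Tibble `component, origin_lon, origin_lat`.
#' @param path Optional output path; when given, pretty-printed GeoJSON is
#'   written there.
#' @return The FeatureCollection as a list (invisibly when written to file).
#' @export
export_component_map <- function(counts, meta, origins = NULL, path = NULL) {
  meta <- tibble::as_tibble(meta)
  df <- dplyr::inner_join(
    dplyr::filter(tibble::as_tibble(counts), .data$n_genera > 0),
    dplyr::select(meta, "reserve_id", "lon", "lat"),
    by = "reserve_id"
  )
  skipped <- setdiff(unique(counts$reserve_id), meta$reserve_id)
  miss <- df$reserve_id[is.na(df$lon) | is.na(df$lat)]
  skipped <- unique(c(skipped, miss))
  if (length(skipped) > 0) {
    warn(paste0(
      "skipping reserve(s) without coordinates: ",
      paste(skipped, collapse = ", ")
    ))
    df <- dplyr::filter(df, !(.data$reserve_id %in% skipped))
  }
  features <- purrr::pmap(df, function(reserve_id, component, n_genera, proportion, lon, lat) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(lon, lat)),
      properties = list(
        kind = "reserve", reserve_id = reserve_id, component = component,
        n_genera = n_genera, proportion = proportion
      )
    )
  })
  if (!is.null(origins)) {
    origins <- dplyr::distinct(
      tibble::as_tibble(origins), .data$component, .data$origin_lon, .data$origin_lat
    )
    origins <- dplyr::filter(origins, !is.na(.data$origin_lon))
    features <- c(features, purrr::pmap(origins, function(component, origin_lon, origin_lat) {
      list(
        type = "Feature",
        geometry = list(type = "Point", coordinates = c(origin_lon, origin_lat)),
        properties = list(kind = "origin", component = component)
      )
    }))
  }
  fc <- list(type = "FeatureCollection", features = features)
  if (is.null(path)) {
    return(fc)
  }
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fc)
}
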