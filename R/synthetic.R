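default_components <- function() {
  tibble::tibble(
    component = c(
      "Central-East China", "Southwest China", "North China",
      "Northwest China", "Qinling", "South China"
    ),
    # compass corners/midpoints of the 102-116 E x 29-37 N study frame
    origin_lon = c(116, 102, 113, 102, 108, 112),
    origin_lat = c(32, 29, 37, 37, 34, 29),
    weight = c(41, 24, 8, 6, 3, 1)
  )
}

#' Configuration of the synthetic flora generator
#'
#' Defaults mirror the structure of the Qinling-Daba reserve flora the
#' pipeline was designed around: five latent regions of eight reserves each
#' spanning a 102–116°E band, a 2000-species background pool with strong
#' within-region (0.7) and weak between-region (0.2) species overlap, nested
#' species/genus/family taxonomy, 15 areal-type codes, 89 Chinese endemic
#' genera spread over six geographic components (plus uncertain), exponential
#' distance decay of endemic-genus presence from the component origin centers
#' (length scale 500 km), region-structured climate variables (current + LGM),
#' elevations with 600 m within-region spread and 1500 m between-region
#' offsets, and 372 introduced cultivated species.
#'
#' @param n_regions,reserves_per_region Latent region structure.
#' @param species_pool_size Background (non-endemic) species pool size.
#' @param within_region_overlap,between_region_overlap Target Sørensen
#'   similarity of reserves within/between regions; must satisfy
#'   `within > between`.
#' @param species_per_genus,genera_per_family Taxonomy nesting.
#' @param n_areal_types Size of the areal-type vocabulary.
#' @param n_endemic_genera Endemic genera shared across the frame (decay-thinned).
#' @param endemic_species_per_genus Species per endemic genus.
#' @param prop_uncertain Fraction of endemic genera left out of the component
#'   table (labelled Uncertain downstream).
#' @param components Tibble `component, origin_lon, origin_lat, weight`.
#' @param decay_length_km Exponential length scale of endemic-genus presence.
#' @param env_effect_size Multiplier on the region effects of all climate
#'   variables (0 gives a null environment).
#' @param elevation_within_spread,elevation_between_offset Metres.
#' @param n_cultivated Introduced cultivated species planted in the table.
#' @param seed Integer; all randomness flows from it through fixed per-stage
#'   substreams.
#' @return A validated config list of class `flora_generator_config`.
#' @export
generator_config <- function(n_regions = 5, reserves_per_region = 8,
                             species_pool_size = 2000,
                             within_region_overlap = 0.7,
                             between_region_overlap = 0.2,
                             species_per_genus = 5, genera_per_family = 4,
                             n_areal_types = 15,
                             n_endemic_genera = 89,
                             endemic_species_per_genus = 2,
                             prop_uncertain = 6 / 89,
                             components = default_components(),
                             decay_length_km = 500,
                             env_effect_size = 1,
                             elevation_within_spread = 600,
                             elevation_between_offset = 1500,
                             n_cultivated = 372,
                             seed = 1) {
  cfg <- as.list(environment())
  if (!(within_region_overlap > between_region_overlap)) {
    abort("within_region_overlap must exceed between_region_overlap",
      class = "qdmflora_config_error"
    )
  }
  sizes <- c(
    n_regions, reserves_per_region, species_pool_size, species_per_genus,
    genera_per_family, n_areal_types, n_endemic_genera, endemic_species_per_genus
  )
  if (any(sizes <= 0)) {
    abort("all size parameters must be positive", class = "qdmflora_config_error")
  }
  structure(cfg, class = "flora_generator_config")
}

# fixed per-stage substreams: adding a stage never perturbs earlier draws
stage_seed <- function(seed, stage) {
  offsets <- c(
    geography = 1, taxonomy = 2, sampling = 3, components = 4,
    thinning = 5, env = 6, elevation = 7, cultivated = 8
  )
  (as.integer(seed) %% 1000003L) * 2011L + offsets[[stage]] * 7919L
}

make_taxonomy <- function(n_species, species_per_genus, genera_per_family, prefix) {
  genus_idx <- ceiling(seq_len(n_species) / species_per_genus)
  family_idx <- ceiling(genus_idx / genera_per_family)
  sp_in_genus <- seq_len(n_species) - (genus_idx - 1) * species_per_genus
  tibble::tibble(
    species = sprintf("%s%04d sp%02d", prefix, genus_idx, sp_in_genus),
    genus = sprintf("%s%04d", prefix, genus_idx),
    family = sprintf("%sFam%03d", prefix, family_idx)
  )
}

#' Generate a full synthetic reserve-flora dataset
#'
#' Produces the three input tables the pipeline consumes plus the ground
#' truth. Background species live in disjoint region core pools and a shared
#' pool sized so that expected between-region Sørensen similarity matches
#' `between_region_overlap` while the reserve occupancy probability equals
#' `within_region_overlap`; endemic genera are available frame-wide but
#' thinned per reserve with probability `exp(-d_origin / decay_length_km)`;
#' climate variables are region means plus Gaussian noise; elevations are
#' region base levels plus uniform within-region spread.
#'
#' @param cfg A [generator_config()].
#' @return A list with elements `occurrences` (validated occurrence tibble),
#'   `components` (genus-to-component table with origins), `meta` (reserve
#'   metadata), and `truth` (list: `region` named vector, `decay_length_km`,
#'   `env_effect_size`).
#' @export
generate_flora <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "flora_generator_config"))
  n_res <- cfg$n_regions * cfg$reserves_per_region
  region_of <- rep(seq_len(cfg$n_regions), each = cfg$reserves_per_region)
  reserve_id <- sprintf("R%d.%02d", region_of, sequence(rep(cfg$reserves_per_region, cfg$n_regions)))

  # -- geography: regions strung west-to-east across the study frame
  geo <- withr::with_seed(stage_seed(cfg$seed, "geography"), {
    center_lon <- seq(103, 115, length.out = cfg$n_regions)
    center_lat <- seq(33.5, 32.5, length.out = cfg$n_regions)
    tibble::tibble(
      reserve_id = reserve_id,
      region = region_of,
      lon = center_lon[region_of] + runif(n_res, -0.8, 0.8),
      lat = center_lat[region_of] + runif(n_res, -1.2, 1.2)
    )
  })

  # -- background pool: disjoint cores + shared pool sized by the overlap targets
  ratio <- cfg$between_region_overlap / cfg$within_region_overlap
  m <- cfg$species_pool_size / (cfg$n_regions - (cfg$n_regions - 1) * ratio)
  shared_n <- round(ratio * m)
  core_n <- max(1, round(m) - shared_n)
  n_bg <- cfg$n_regions * core_n + shared_n
  bg_tax <- make_taxonomy(n_bg, cfg$species_per_genus, cfg$genera_per_family, "Genus")
  pool_region <- c(rep(seq_len(cfg$n_regions), each = core_n), rep(0L, shared_n))

  # areal types: each region's genera draw from a sliding window of the
  # vocabulary (regional floristic spectra), shared-pool genera from the
  # central window, the last code being reserved for endemic-China genera;
  # without this turnover every rich reserve would hold every type and the
  # areal-type level would be uninformative
  bg_areal <- withr::with_seed(stage_seed(cfg$seed, "taxonomy"), {
    genera <- unique(bg_tax$genus)
    genus_region <- pool_region[match(genera, bg_tax$genus)]
    n_types <- max(2, cfg$n_areal_types - 1)
    w <- max(2, ceiling(n_types / 2))
    win_start <- function(r) {
      pos <- if (r == 0) (cfg$n_regions + 1) / 2 else r
      1 + round((pos - 1) / max(1, cfg$n_regions - 1) * (n_types - w))
    }
    type_idx <- vapply(genus_region, function(r) {
      s <- win_start(r)
      sample(seq(s, min(s + w - 1, n_types)), 1)
    }, numeric(1))
    setNames(sprintf("AT%02d", type_idx), genera)
  })

  occ_bg <- withr::with_seed(stage_seed(cfg$seed, "sampling"), {
    rows <- purrr::map(seq_len(n_res), function(i) {
      r <- region_of[i]
      avail <- pool_region == r | pool_region == 0L
      keep <- avail & (runif(n_bg) < cfg$within_region_overlap)
      if (!any(keep)) keep[which(avail)[1]] <- TRUE
      dplyr::mutate(bg_tax[keep, ], reserve_id = reserve_id[i])
    })
    dplyr::bind_rows(rows)
  })
  occ_bg$areal_type <- bg_areal[occ_bg$genus]
  occ_bg$endemic <- FALSE
  occ_bg$cultivated <- FALSE

  # -- endemic genera: frame-wide availability, distance-decay thinning
  end_tax <- make_taxonomy(
    cfg$n_endemic_genera * cfg$endemic_species_per_genus,
    cfg$endemic_species_per_genus, cfg$genera_per_family, "Endemogenus"
  )
  end_genera <- unique(end_tax$genus)
  comp_assign <- withr::with_seed(stage_seed(cfg$seed, "components"), {
    n_unc <- round(cfg$prop_uncertain * cfg$n_endemic_genera)
    listed <- head(end_genera, cfg$n_endemic_genera - n_unc)
    comp <- sample(cfg$components$component, length(listed),
      replace = TRUE, prob = cfg$components$weight
    )
    tibble::tibble(genus = listed, component = comp)
  })
  component_table <- comp_assign |>
    dplyr::left_join(
      dplyr::select(cfg$components, "component", "origin_lon", "origin_lat"),
      by = "component"
    ) |>
    dplyr::mutate(species = NA_character_, .after = "genus")

  origin_of <- component_table |>
    dplyr::select("genus", "origin_lon", "origin_lat")
  occ_end <- withr::with_seed(stage_seed(cfg$seed, "thinning"), {
    rows <- purrr::map(seq_len(n_res), function(i) {
      d <- rep(0, length(end_genera))
      names(d) <- end_genera
      d[origin_of$genus] <- haversine_km(
        geo$lon[i], geo$lat[i], origin_of$origin_lon, origin_of$origin_lat
      )
      p_keep <- cfg$within_region_overlap * exp(-d / cfg$decay_length_km)
      keep_genus <- end_genera[runif(length(end_genera)) < p_keep]
      dplyr::mutate(
        dplyr::filter(end_tax, .data$genus %in% keep_genus),
        reserve_id = reserve_id[i]
      )
    })
    dplyr::bind_rows(rows)
  })
  if (nrow(occ_end) > 0) {
    occ_end$areal_type <- sprintf("AT%02d", cfg$n_areal_types) # endemic-China code
    occ_end$endemic <- TRUE
    occ_end$cultivated <- FALSE
  }

  # -- cultivated species: planted so that exactly n_cultivated appear
  occ_cult <- withr::with_seed(stage_seed(cfg$seed, "cultivated"), {
    if (cfg$n_cultivated == 0) {
      NULL
    } else {
      cult_tax <- make_taxonomy(
        cfg$n_cultivated, cfg$species_per_genus, cfg$genera_per_family, "Cultigenus"
      )
      host <- sample.int(n_res, cfg$n_cultivated, replace = TRUE)
      dplyr::mutate(cult_tax,
        reserve_id = reserve_id[host],
        areal_type = "AT01", endemic = FALSE, cultivated = TRUE
      )
    }
  })

  occurrences <- dplyr::bind_rows(occ_bg, occ_end, occ_cult) |>
    dplyr::select(
      "reserve_id", "species", "genus", "family",
      "areal_type", "endemic", "cultivated"
    )

  # -- environment: region means + noise, current and LGM
  env <- withr::with_seed(stage_seed(cfg$seed, "env"), {
    r <- region_of
    e <- cfg$env_effect_size
    tibble::tibble(
      precip_annual_cur = 700 + e * 120 * r + rnorm(n_res, 0, 60),
      temp_annual_cur = 14 - e * 0.8 * r + rnorm(n_res, 0, 0.7),
      temp_coldest_q_cur = 2 - e * 0.9 * r + rnorm(n_res, 0, 0.8),
      temp_warmest_q_cur = 24 - e * 0.6 * r + rnorm(n_res, 0, 0.7),
      precip_annual_lgm = 500 + e * 90 * r + rnorm(n_res, 0, 60),
      temp_annual_lgm = 8 - e * 0.8 * r + rnorm(n_res, 0, 0.8),
      temp_coldest_q_lgm = -6 - e * 0.9 * r + rnorm(n_res, 0, 0.9),
      temp_warmest_q_lgm = 19 - e * 0.6 * r + rnorm(n_res, 0, 0.8)
    )
  })

  elev <- withr::with_seed(stage_seed(cfg$seed, "elevation"), {
    base_level <- 400 + (region_of - 1) * cfg$elevation_between_offset
    elev_base <- base_level + runif(n_res, 0, cfg$elevation_within_spread)
    elev_mean <- elev_base + 350 + runif(n_res, 0, 150)
    elev_peak <- elev_mean + 250 + runif(n_res, 0, 150)
    tibble::tibble(elev_base = elev_base, elev_mean = elev_mean, elev_peak = elev_peak)
  })

  meta <- dplyr::bind_cols(
    dplyr::select(geo, "reserve_id", "lon", "lat"), elev, env
  )

  list(
    occurrences = validate_occurrences(occurrences),
    components = validate_components(component_table),
    meta = validate_reserves(meta),
    truth = list(
      region = setNames(region_of, reserve_id),
      decay_length_km = cfg$decay_length_km,
      env_effect_size = cfg$env_effect_size
    )
  )
}

#' Write a generated dataset to the CSV schemas the readers consume
#' @param dataset Output of [generate_flora()] or [make_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    occurrences = file.path(dir, "occurrences.csv"),
    components = file.path(dir, "components.csv"),
    reserves = file.path(dir, "reserves.csv")
  )
  readr::write_csv(tibble::as_tibble(dataset$occurrences), paths[["occurrences"]])
  readr::write_csv(tibble::as_tibble(dataset$components), paths[["components"]])
  readr::write_csv(tibble::as_tibble(dataset$meta), paths[["reserves"]])
  invisible(paths)
}

#' Canned deterministic micro-datasets for tests and examples
#'
#' * `tiny`: 3 reserves, 10 species, 5 genera, 3 families, one cultivated and
#'   two endemic genera — hand-built, no randomness.
#' * `table1_like`: one reserve holding 89 endemic genera whose component
#'   counts are 41/24/8/6/3/1 plus 6 unlisted (uncertain-origin) genera.
#' * `decay_demo`: ten reserves strung eastward from a western origin with
#'   perfectly nested endemic-genus sets, so counts fall monotonically with
#'   distance.
#' * `null_env`: a [generate_flora()] run with `env_effect_size = 0` (climate
#'   unrelated to region membership), seed 404.
#'
#' @param name One of `"tiny"`, `"table1_like"`, `"decay_demo"`, `"null_env"`.
#' @return A list with `occurrences`, `components`, `meta` (and `truth` where
#'   meaningful).
#' @export
make_fixture <- function(name = c("tiny", "table1_like", "decay_demo", "null_env")) {
  name <- match.arg(name)
  switch(name,
    tiny = fixture_tiny(),
    table1_like = fixture_table1(),
    decay_demo = fixture_decay(),
    null_env = generate_flora(generator_config(env_effect_size = 0, seed = 404))
  )
}

fixture_tiny <- function() {
  occ <- tibble::tribble(
    ~reserve_id, ~species, ~genus, ~family, ~areal_type, ~endemic, ~cultivated,
    "A", "Acer truncatum", "Acer", "Sapindaceae", "AT08", FALSE, FALSE,
    "A", "Acer davidii", "Acer", "Sapindaceae", "AT08", FALSE, FALSE,
    "A", "Metasequoia glyptostroboides", "Metasequoia", "Cupressaceae", "AT15", TRUE, FALSE,
    "A", "Pinus armandii", "Pinus", "Pinaceae", "AT08", FALSE, FALSE,
    "A", "Quercus aliena", "Quercus", "Fagaceae", "AT08", FALSE, FALSE,
    "B", "Acer truncatum", "Acer", "Sapindaceae", "AT08", FALSE, FALSE,
    "B", "Metasequoia glyptostroboides", "Metasequoia", "Cupressaceae", "AT15", TRUE, FALSE,
    "B", "Dipteronia sinensis", "Dipteronia", "Sapindaceae", "AT15", TRUE, FALSE,
    "B", "Ginkgo biloba", "Ginkgo", "Ginkgoaceae", "AT15", FALSE, TRUE,
    "C", "Pinus armandii", "Pinus", "Pinaceae", "AT08", FALSE, FALSE,
    "C", "Pinus tabuliformis", "Pinus", "Pinaceae", "AT08", FALSE, FALSE,
    "C", "Quercus variabilis", "Quercus", "Fagaceae", "AT08", FALSE, FALSE,
    "C", "Betula albosinensis", "Betula", "Betulaceae", "AT08", FALSE, FALSE
  )
  comp <- tibble::tibble(
    genus = c("Metasequoia", "Dipteronia"),
    species = NA_character_,
    component = c("Central-East China", "Central-East China"),
    origin_lon = 116, origin_lat = 32
  )
  meta <- tibble::tibble(
    reserve_id = c("A", "B", "C"),
    lon = c(110.2, 111.5, 106.3), lat = c(33.5, 31.8, 33.0),
    elev_base = c(600, 750, 2100), elev_mean = c(1200, 1300, 2800),
    elev_peak = c(2200, 2300, 3900),
    precip_annual_cur = c(850, 960, 720),
    temp_annual_cur = c(13.2, 14.8, 9.1)
  )
  list(
    occurrences = validate_occurrences(occ),
    components = validate_components(comp),
    meta = validate_reserves(meta)
  )
}

fixture_table1 <- function() {
  counts <- c(
    "Central-East China" = 41, "Southwest China" = 24, "North China" = 8,
    "Northwest China" = 6, "Qinling" = 3, "South China" = 1
  )
  comps <- default_components()
  genera <- sprintf("Endemogenus%04d", seq_len(sum(counts) + 6))
  listed <- genera[seq_len(sum(counts))]
  comp_tab <- tibble::tibble(
    genus = listed,
    species = NA_character_,
    component = rep(names(counts), counts)
  ) |>
    dplyr::left_join(
      dplyr::select(comps, "component", "origin_lon", "origin_lat"),
      by = "component"
    )
  occ <- tibble::tibble(
    reserve_id = "R01",
    species = paste(genera, "sp01"),
    genus = genera,
    family = sprintf("Fam%03d", ceiling(seq_along(genera) / 4)),
    areal_type = "AT15",
    endemic = TRUE,
    cultivated = FALSE
  )
  meta <- tibble::tibble(
    reserve_id = "R01", lon = 110, lat = 32,
    elev_base = 500, elev_mean = 1000, elev_peak = 1500
  )
  list(
    occurrences = validate_occurrences(occ),
    components = validate_components(comp_tab),
    meta = validate_reserves(meta)
  )
}

fixture_decay <- function() {
  n_res <- 10
  genera <- sprintf("Endemogenus%04d", seq_len(n_res))
  # reserve j holds the first n_res - j + 1 genera: nested, monotone decay
  occ <- purrr::map(seq_len(n_res), function(j) {
    g <- genera[seq_len(n_res - j + 1)]
    tibble::tibble(
      reserve_id = sprintf("D%02d", j),
      species = paste(g, "sp01"),
      genus = g,
      family = "Fam001",
      areal_type = "AT15",
      endemic = TRUE,
      cultivated = FALSE
    )
  }) |> dplyr::bind_rows()
  comp_tab <- tibble::tibble(
    genus = genera, species = NA_character_,
    component = "West", origin_lon = 102, origin_lat = 33
  )
  meta <- tibble::tibble(
    reserve_id = sprintf("D%02d", seq_len(n_res)),
    lon = 102 + seq_len(n_res), lat = 33,
    elev_base = 500, elev_mean = 1000, elev_peak = 1500
  )
  list(
    occurrences = validate_occurrences(occ),
    components = validate_components(comp_tab),
    meta = validate_reserves(meta)
  )
}
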