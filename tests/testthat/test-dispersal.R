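test_that("component assignment applies genus rows, overrides, and defaults", {
  occ <- tibble::tibble(
    reserve_id = "A",
    species = c("Biondia chinensis", "Biondia henryi", "Kingdonia uniflora", "Mystus novus"),
    genus = c("Biondia", "Biondia", "Kingdonia", "Mystus"),
    family = c("Apocynaceae", "Apocynaceae", "Circaeasteraceae", "Mysteriaceae"),
    areal_type = "AT15", endemic = TRUE, cultivated = FALSE
  )
  comp <- tibble::tibble(
    genus = c("Biondia", "Biondia", "Kingdonia"),
    species = c(NA, "Biondia chinensis", NA),
    component = c("Southwest China", "Qinling", "Central-East China"),
    origin_lon = c(102, 108, 116), origin_lat = c(29, 34, 32)
  )
  ann <- assign_components(occ, comp)
  # species-level override beats the genus-level row; congeners keep theirs
  expect_equal(ann$component[ann$species == "Biondia chinensis"], "Qinling")
  expect_equal(ann$component[ann$species == "Biondia henryi"], "Southwest China")
  expect_equal(ann$component[ann$genus == "Kingdonia"], "Central-East China")
  expect_equal(ann$component[ann$genus == "Mystus"], "Uncertain")
})

test_that("component table rows for non-endemic genera raise a warning", {
  occ <- toy_occurrences()
  comp <- tibble::tibble(
    genus = c("Davidia", "Abies"), species = NA_character_,
    component = "Central-East China", origin_lon = 116, origin_lat = 32
  )
  expect_warning(assign_components(occ, comp), regexp = "Abies")
})

test_that("component summary reproduces worked proportions", {
  fx <- make_fixture("table1_like")
  ann <- assign_components(fx$occurrences, fx$components)
  s <- component_summary(ann)
  expect_equal(sum(s$n_genera), 89)
  expect_equal(
    s$proportion[match(
      c(
        "Central-East China", "Southwest China", "North China",
        "Northwest China", "Qinling", "South China", "Uncertain"
      ),
      s$component
    )],
    c(46.07, 26.97, 8.99, 6.74, 3.37, 1.12, 6.74)
  )
  expect_lt(abs(sum(s$proportion) - 100), 0.05)

  solo <- component_summary(dplyr::filter(ann, component == "Qinling"))
  expect_equal(solo$proportion, 100)

  expect_error(
    component_summary(dplyr::filter(ann, !endemic)),
    class = "qdmflora_empty_error"
  )
})

test_that("per-reserve component counts match hand enumeration", {
  occ <- tibble::tibble(
    reserve_id = c("A", "A", "A", "B", "B"),
    species = c("g1 sp1", "g2 sp1", "g3 sp1", "g1 sp1", "g3 sp1"),
    genus = c("g1", "g2", "g3", "g1", "g3"),
    family = "f", areal_type = "AT15", endemic = TRUE, cultivated = FALSE
  )
  comp <- tibble::tibble(
    genus = c("g1", "g2", "g3"), species = NA_character_,
    component = c("East", "East", "West"),
    origin_lon = c(116, 116, 102), origin_lat = 32
  )
  counts <- component_counts(assign_components(occ, comp))
  m <- component_count_matrix(counts)
  expect_equal(m, matrix(c(2L, 1L, 1L, 1L), 2,
    dimnames = list(c("A", "B"), c("East", "West"))
  ))
  # genus present in both reserves counts once per reserve; row sums conserve
  sums <- rowSums(m)
  expect_equal(unname(sums), c(3, 2))
  props <- dplyr::summarise(tibble::as_tibble(counts),
    total = sum(proportion), .by = reserve_id
  )
  expect_true(all(abs(props$total - 1) < 1e-12))
})

test_that("haversine agrees with the law-of-cosines oracle within 1 m", {
  withr::with_seed(7, {
    lon1 <- runif(200, 102, 116)
    lat1 <- runif(200, 29, 37)
    lon2 <- lon1 + runif(200, -5, 5)
    lat2 <- lat1 + runif(200, -4, 4)
    hk <- haversine_km(lon1, lat1, lon2, lat2)
    sk <- oracle_slc_km(lon1, lat1, lon2, lat2)
    keep <- hk <= 1000
    expect_true(any(keep))
    expect_lt(max(abs(hk[keep] - sk[keep])), 1e-3)
  })
})

test_that("a perfectly nested decay fixture gives rho -1 and direction decay", {
  fx <- make_fixture("decay_demo")
  counts <- component_counts(assign_components(fx$occurrences, fx$components))
  g <- gradient_test(counts, fx$meta, "West", c(102, 33), n_perm = 499, seed = 1)
  expect_equal(g$rho, -1)
  expect_equal(g$direction, "decay")
  expect_lt(g$p_perm, 0.05)
  expect_equal(g$n_reserves, 10)
})

test_that("gradient test handles constant counts and validates inputs", {
  fx <- make_fixture("decay_demo")
  counts <- component_counts(assign_components(fx$occurrences, fx$components))
  const <- dplyr::mutate(counts, n_genera = 3L)
  class(const) <- class(counts)
  g <- gradient_test(const, fx$meta, "West", c(102, 33), n_perm = 199, seed = 1)
  expect_equal(g$direction, "flat")
  expect_equal(g$p_perm, 1)
  expect_true(is.na(g$rho))

  expect_error(
    gradient_test(counts, fx$meta, "West", c(102, 33), n_perm = 99),
    class = "qdmflora_domain_error"
  )
  expect_error(
    gradient_test(counts, fx$meta[1:3, ], "West", c(102, 33)),
    class = "qdmflora_domain_error"
  )
})

test_that("gradient permutation p-values are well calibrated under the null", {
  # counts shuffled independently of distance: p should be (super-)uniform
  fx <- make_fixture("decay_demo")
  counts <- component_counts(assign_components(fx$occurrences, fx$components))
  ps <- withr::with_seed(99, {
    purrr::map_dbl(1:200, function(i) {
      shuffled <- dplyr::mutate(counts, n_genera = sample(n_genera))
      class(shuffled) <- class(counts)
      gradient_test(shuffled, fx$meta, "West", c(102, 33),
        n_perm = 199, seed = i
      )$p_perm
    })
  })
  # permutation p-values live on a discrete grid; ties are expected
  expect_gte(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.09)
})

test_that("GeoJSON export round-trips counts and skips missing coordinates", {
  fx <- make_fixture("tiny")
  ann <- assign_components(fx$occurrences, fx$components)
  counts <- component_counts(ann)
  f <- withr::local_tempfile(fileext = ".geojson")
  export_component_map(counts, fx$meta, fx$components, path = f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  pts <- purrr::keep(gj$features, ~ .x$properties$kind == "reserve")
  expect_equal(length(pts), nrow(dplyr::filter(counts, n_genera > 0)))
  got <- purrr::map_dfr(pts, ~ tibble::tibble(
    reserve_id = .x$properties$reserve_id,
    component = .x$properties$component,
    n_genera = .x$properties$n_genera
  ))
  expect_equal(
    dplyr::arrange(got, reserve_id, component),
    dplyr::arrange(
      dplyr::select(tibble::as_tibble(counts), reserve_id, component, n_genera),
      reserve_id, component
    )
  )
  origins <- purrr::keep(gj$features, ~ .x$properties$kind == "origin")
  expect_equal(length(origins), 1) # one distinct component origin in tiny

  expect_warning(
    export_component_map(counts, fx$meta[-1, ], fx$components),
    regexp = "A"
  )
})
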