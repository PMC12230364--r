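#' Run configuration for the end-to-end pipeline
#'
#' The level-to-coefficient pairing defaults to the classification design the
#' package implements: species incidence compared by Sørensen, genus incidence
#' by Szymkiewicz–Simpson overlap, areal-type incidence by Jaccard.
#'
#' @param occurrences,components,reserves Input CSV paths (ignored when
#'   `simulate = TRUE`).
#' @param simulate Generate the inputs with [generate_flora()] instead of
#'   reading files.
#' @param generator Optional [generator_config()] overriding the default when
#'   simulating (its seed is replaced by `seed`).
#' @param coefficients Named map level -> coefficient.
#' @param k_range,linkage Clustering controls (see [regionalize()]).
#' @param n_perm Permutations for gradient tests.
#' @param n_trees,n_repeats Random-forest importance controls.
#' @param seed Master seed for all stochastic stages.
#' @param out_dir Output directory.
#' @return A list of class `flora_run_config`.
#' @export
run_config <- function(occurrences = NULL, components = NULL, reserves = NULL,
                       simulate = is.null(occurrences),
                       generator = NULL,
                       coefficients = c(
                         species = "sorensen",
                         genus = "szymkiewicz",
                         areal_type = "jaccard"
                       ),
                       k_range = 2:10, linkage = "average",
                       n_perm = 999, n_trees = 500, n_repeats = 100,
                       seed = 1, out_dir = tempfile("qdmflora_run_")) {
  cfg <- as.list(environment())
  stopifnot(all(c("species", "genus", "areal_type") %in% names(coefficients)))
  structure(cfg, class = "flora_run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path Config file; keys as in [run_config()].
#' @return A `flora_run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$coefficients)) raw$coefficients <- unlist(raw$coefficients)
  if (!is.null(raw$k_range) && length(raw$k_range) == 2) {
    raw$k_range <- seq(raw$k_range[1], raw$k_range[2])
  }
  do.call(run_config, raw)
}

load_inputs <- function(cfg) {
  if (isTRUE(cfg$simulate)) {
    gen <- cfg$generator %||% generator_config()
    gen$seed <- cfg$seed
    generate_flora(gen)
  } else {
    occ <- read_occurrences(cfg$occurrences)
    list(
      occurrences = occ,
      components = read_components(cfg$components),
      meta = read_reserves(cfg$reserves, occ),
      truth = NULL
    )
  }
}

#' Execute the full regionalization and corridor analysis
#'
#' Stages: (1) read/validate (or simulate) and drop cultivated species;
#' (2) presence matrices and the three level similarities; (3) consensus
#' regionalization; (4) endemic-component counts, Table-1-style summary,
#' distance-decay gradient tests, GeoJSON map export; (5) driver importance,
#' gated region tests, elevation report. All artifacts are written under
#' `cfg$out_dir` together with a JSON manifest recording the seed, config
#' hash, package version and per-stage record counts.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return An object of class `flora_run` (list of all stage results plus
#'   `manifest` and `out_dir`), invisibly.
#' @export
run_all <- function(cfg = run_config(), quiet = FALSE) {
  t0 <- Sys.time()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[qdmflora] ", ...)
  stage_counts <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
        class = "qdmflora_stage_error", parent = e
      )
    })
  }

  # 1 -- io
  inputs <- run_stage("flora_io", {
    inp <- load_inputs(cfg)
    inp$occurrences <- filter_cultivated(inp$occurrences, quiet = TRUE)
    inp
  })
  occ <- inputs$occurrences
  rep1 <- occurrence_report(occ)
  stage_counts$flora_io <- rep1
  say(
    "flora_io: ", rep1$n_reserves, " reserves, ", rep1$n_species, " species (",
    attr(occ, "removed_species"), " cultivated removed)"
  )
  write_occurrences(occ, file.path(cfg$out_dir, "occurrences_clean.csv"))
  jsonlite::write_json(rep1, file.path(cfg$out_dir, "validation_report.json"),
    auto_unbox = TRUE
  )

  # 2 -- similarity
  sims <- run_stage("similarity", {
    purrr::imap(cfg$coefficients, function(coef, level) {
      m <- to_presence(occ, level)
      s <- similarity_matrix(m, coef)
      write_similarity(s, file.path(cfg$out_dir, paste0("similarity_", level, ".csv")))
      s
    })
  })
  stage_counts$similarity <- list(levels = names(sims))
  say("similarity: ", paste(names(sims), unname(cfg$coefficients), sep = "/", collapse = ", "))

  # 3 -- regionalize
  regions <- run_stage("regionalize", {
    dists <- purrr::map(sims, to_distance)
    regionalize(dists, k_range = cfg$k_range, linkage = cfg$linkage, meta = inputs$meta)
  })
  stage_counts$regionalize <- list(k = regions$k)
  say("regionalize: k = ", regions$k)
  readr::write_csv(tidy(regions), file.path(cfg$out_dir, "region_assignment.csv"))
  readr::write_csv(regions$k_diagnostics, file.path(cfg$out_dir, "k_diagnostics.csv"))
  write_matrix_csv(regions$consensus, file.path(cfg$out_dir, "consensus_matrix.csv"))
  region_tree_newick(regions, file.path(cfg$out_dir, "region_tree.nwk"))

  # 4 -- endemic dispersal
  dispersal <- run_stage("endemic_dispersal", {
    ann <- assign_components(occ, inputs$components)
    counts <- component_counts(ann)
    summary <- component_summary(ann)
    gradients <- gradient_tests(counts, inputs$meta, inputs$components,
      n_perm = cfg$n_perm, seed = cfg$seed
    )
    export_component_map(counts, inputs$meta, inputs$components,
      path = file.path(cfg$out_dir, "component_map.geojson")
    )
    readr::write_csv(summary, file.path(cfg$out_dir, "component_summary.csv"))
    readr::write_csv(
      tibble::as_tibble(counts),
      file.path(cfg$out_dir, "component_counts.csv")
    )
    readr::write_csv(gradients, file.path(cfg$out_dir, "gradient_tests.csv"))
    list(annotated = ann, counts = counts, summary = summary, gradients = gradients)
  })
  stage_counts$endemic_dispersal <- list(
    n_components = nrow(dispersal$summary),
    n_endemic_genera = sum(dispersal$summary$n_genera)
  )
  say("endemic_dispersal: ", sum(dispersal$summary$n_genera), " endemic genera in ",
    nrow(dispersal$summary), " components")

  # 5 -- env drivers
  drivers <- run_stage("env_drivers", {
    env_vars <- setdiff(
      names(inputs$meta)[vapply(inputs$meta, is.numeric, logical(1))],
      c("lon", "lat")
    )
    features <- as.data.frame(inputs$meta[, env_vars])
    rownames(features) <- inputs$meta$reserve_id
    imp <- importance(features, regions$labels[inputs$meta$reserve_id],
      n_trees = cfg$n_trees, n_repeats = cfg$n_repeats, seed = cfg$seed
    )
    tests <- region_tests(inputs$meta, regions, variables = env_vars)
    elev <- elevation_report(inputs$meta, regions)
    readr::write_csv(tibble::as_tibble(imp), file.path(cfg$out_dir, "importance.csv"))
    readr::write_csv(
      dplyr::select(tests, -"group_stats"),
      file.path(cfg$out_dir, "region_tests.csv")
    )
    readr::write_csv(elev$pairs, file.path(cfg$out_dir, "elevation_pairs.csv"))
    readr::write_csv(elev$within_maxima, file.path(cfg$out_dir, "elevation_within_maxima.csv"))
    jsonlite::write_json(glance(elev), file.path(cfg$out_dir, "elevation_flags.json"),
      auto_unbox = TRUE
    )
    list(importance = imp, tests = tests, elevation = elev)
  })
  stage_counts$env_drivers <- list(
    top_driver = drivers$importance$variable[1],
    corridor_effect = drivers$elevation$corridor_effect
  )
  say(
    "env_drivers: top driver = ", drivers$importance$variable[1],
    ", corridor effect = ", drivers$elevation$corridor_effect
  )

  cfg_for_hash <- cfg
  cfg_for_hash$out_dir <- NULL
  manifest <- list(
    package = "qdmflora",
    version = as.character(utils::packageVersion("qdmflora")),
    seed = cfg$seed,
    config_hash = digest::digest(cfg_for_hash),
    stages = stage_counts,
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  )
  manifest_for_hash <- manifest[c("package", "version", "seed", "config_hash", "stages")]
  manifest$manifest_hash <- digest::digest(manifest_for_hash)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  say("done: 5 stages complete -> ", cfg$out_dir)

  invisible(structure(
    list(
      inputs = inputs, similarities = sims, regions = regions,
      dispersal = dispersal, drivers = drivers,
      manifest = manifest, out_dir = cfg$out_dir
    ),
    class = "flora_run"
  ))
}

#' @export
print.flora_run <- function(x, ...) {
  cat("qdmflora pipeline run\n")
  cat("  output:", x$out_dir, "\n")
  cat("  regions:", x$regions$k, " reserves:", length(x$regions$labels), "\n")
  cat("  top driver:", x$drivers$importance$variable[1], "\n")
  invisible(x)
}

# ---- thin stage wrappers used by the command-line script -------------------

#' Single-stage entry points
#'
#' Thin wrappers over the module functions, sharing the [run_config()]
#' surface, used by the `flora_pipeline.R` command-line script and handy for
#' running one stage interactively.
#'
#' @param cfg A [run_config()].
#' @name stages
NULL

#' @rdname stages
#' @export
stage_validate <- function(cfg) {
  inputs <- load_inputs(cfg)
  occurrence_report(inputs$occurrences)
}

#' @rdname stages
#' @param level,coefficient Level and coefficient for a single similarity matrix.
#' @export
stage_similarity <- function(cfg, level = "species",
                             coefficient = cfg$coefficients[[level]]) {
  inputs <- load_inputs(cfg)
  occ <- filter_cultivated(inputs$occurrences, quiet = TRUE)
  similarity_matrix(to_presence(occ, level), coefficient)
}

#' @rdname stages
#' @export
stage_regionalize <- function(cfg) {
  inputs <- load_inputs(cfg)
  occ <- filter_cultivated(inputs$occurrences, quiet = TRUE)
  dists <- purrr::imap(cfg$coefficients, function(coef, level) {
    to_distance(similarity_matrix(to_presence(occ, level), coef))
  })
  regionalize(dists, k_range = cfg$k_range, linkage = cfg$linkage, meta = inputs$meta)
}

#' @rdname stages
#' @export
stage_components <- function(cfg) {
  inputs <- load_inputs(cfg)
  occ <- filter_cultivated(inputs$occurrences, quiet = TRUE)
  ann <- assign_components(occ, inputs$components)
  counts <- component_counts(ann)
  list(
    summary = component_summary(ann),
    counts = counts,
    gradients = gradient_tests(counts, inputs$meta, inputs$components,
      n_perm = cfg$n_perm, seed = cfg$seed
    )
  )
}

#' @rdname stages
#' @export
stage_drivers <- function(cfg) {
  inputs <- load_inputs(cfg)
  occ <- filter_cultivated(inputs$occurrences, quiet = TRUE)
  regions <- stage_regionalize(cfg)
  env_vars <- setdiff(
    names(inputs$meta)[vapply(inputs$meta, is.numeric, logical(1))],
    c("lon", "lat")
  )
  features <- as.data.frame(inputs$meta[, env_vars])
  list(
    importance = importance(features, regions$labels[inputs$meta$reserve_id],
      n_trees = cfg$n_trees, n_repeats = cfg$n_repeats, seed = cfg$seed
    ),
    tests = region_tests(inputs$meta, regions, variables = env_vars),
    elevation = elevation_report(inputs$meta, regions)
  )
}

#' @rdname stages
#' @param dir Directory to write the simulated CSVs into.
#' @export
stage_simulate <- function(cfg, dir = cfg$out_dir) {
  gen <- cfg$generator %||% generator_config()
  gen$seed <- cfg$seed
  ds <- generate_flora(gen)
  write_dataset(ds, dir)
}
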