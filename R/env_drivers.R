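stack_groups <- function(groups) {
  if (length(groups) < 2) {
    abort("need at least two groups", class = "qdmflora_domain_error")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  list(values = as.numeric(values), g = g)
}

#' Brown–Forsythe test for homogeneity of variance
#'
#' Levene's test with median centering: a one-way F test on the absolute
#' deviations of each observation from its group median. Used as the gate
#' that decides between ANOVA and Kruskal–Wallis in [region_tests()].
#'
#' @param groups A list of numeric vectors, each of length >= 2.
#' @return A one-row tibble: `statistic, df1, df2, p_value, method`.
#' @export
levene <- function(groups) {
  if (any(lengths(groups) < 2)) {
    abort("every group needs at least two observations",
      class = "qdmflora_domain_error"
    )
  }
  s <- stack_groups(groups)
  z <- abs(s$values - ave(s$values, s$g, FUN = median))
  if (all(z < 1e-12)) {
    # all deviations zero: perfectly homogeneous
    return(tibble::tibble(
      statistic = 0, df1 = nlevels(s$g) - 1,
      df2 = length(z) - nlevels(s$g), p_value = 1,
      method = "brown-forsythe"
    ))
  }
  ht <- oneway.test(z ~ s$g, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
    p_value = unname(ht$p.value), method = "brown-forsythe"
  )
}

#' Classical one-way analysis of variance
#'
#' `F = (SSB/dfB) / (SSW/dfW)` with the p-value from the F(dfB, dfW)
#' distribution.
#'
#' @inheritParams levene
#' @return A one-row tibble: `statistic, df1, df2, p_value, method`.
#' @export
oneway_anova <- function(groups) {
  if (any(lengths(groups) < 2)) {
    abort("every group needs at least two observations",
      class = "qdmflora_domain_error"
    )
  }
  s <- stack_groups(groups)
  group_var <- tapply(s$values, s$g, function(v) sum((v - mean(v))^2))
  if (sum(group_var) < 1e-24 && var(s$values) < 1e-24) {
    warn("all values identical; F undefined")
    return(tibble::tibble(
      statistic = NA_real_, df1 = nlevels(s$g) - 1,
      df2 = length(s$values) - nlevels(s$g), p_value = NA_real_,
      method = "anova"
    ))
  }
  ht <- oneway.test(s$values ~ s$g, var.equal = TRUE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
    p_value = unname(ht$p.value), method = "anova"
  )
}

#' Kruskal–Wallis rank-sum test
#'
#' Tie-corrected `H` statistic with a chi-square reference on g - 1 degrees
#' of freedom.
#'
#' @param groups A list of numeric vectors (each n >= 1, total N >= 3).
#' @return A one-row tibble: `statistic, df1, p_value, method`.
#' @export
kruskal_wallis <- function(groups) {
  s <- stack_groups(groups)
  if (length(s$values) < 3) {
    abort("need at least three observations in total", class = "qdmflora_domain_error")
  }
  if (length(unique(s$values)) == 1) {
    return(tibble::tibble(
      statistic = 0, df1 = nlevels(s$g) - 1, p_value = 1,
      method = "kruskal-wallis"
    ))
  }
  ht <- kruskal.test(s$values, s$g)
  tibble::tibble(
    statistic = unname(ht$statistic), df1 = unname(ht$parameter),
    p_value = unname(ht$p.value), method = "kruskal-wallis"
  )
}

oob_votes_accuracy <- function(pred_individual, inbag, y) {
  lev <- levels(y)
  n <- length(y)
  votes <- matrix(0L, n, length(lev), dimnames = list(NULL, lev))
  oob <- inbag == 0
  for (l in lev) {
    votes[, l] <- rowSums((pred_individual == l) & oob)
  }
  has_oob <- rowSums(oob) > 0
  vote <- lev[max.col(votes, ties.method = "first")]
  mean(vote[has_oob] == as.character(y)[has_oob])
}

#' Permutation importance of environmental variables (mean decrease in accuracy)
#'
#' Fits a random forest classifying region membership from the environmental
#' features, then scores each variable by the mean, over `n_repeats` seeded
#' permutations of its column, of the drop in out-of-bag accuracy relative to
#' the unpermuted baseline. Raw importances are clipped at zero and
#' normalized to percentages summing to 100.
#'
#' @param features A data frame of numeric variables, one row per reserve.
#' @param labels Region labels (factor or coercible), one per row; at least
#'   two distinct regions are required.
#' @param n_trees Trees in the forest.
#' @param n_repeats Permutation repeats per variable.
#' @param seed Integer seed governing the forest and the permutation stream.
#' @return A tibble of class `flora_importance` with columns `variable,
#'   raw_importance, relative_importance`, and attributes `n_trees`,
#'   `n_repeats`, `seed`, `baseline_accuracy`.
#' @export
importance <- function(features, labels, n_trees = 500, n_repeats = 100, seed = 1) {
  features <- as.data.frame(features)
  if (!all(vapply(features, is.numeric, logical(1)))) {
    abort("all features must be numeric", class = "qdmflora_domain_error")
  }
  if (anyNA(features)) {
    abort("missing feature values are not allowed", class = "qdmflora_domain_error")
  }
  y <- factor(labels)
  if (nlevels(y) < 2) {
    abort("need at least two regions to rank drivers", class = "qdmflora_domain_error")
  }
  constant <- vapply(features, function(v) length(unique(v)) == 1, logical(1))
  if (any(constant)) {
    warn(paste0(
      "constant feature(s) carry no information: ",
      paste(names(features)[constant], collapse = ", ")
    ))
  }

  withr::with_seed(seed, {
    rf <- randomForest::randomForest(
      x = features, y = y, ntree = n_trees,
      keep.forest = TRUE, keep.inbag = TRUE
    )
    inbag <- rf$inbag
    base_pred <- predict(rf, features, predict.all = TRUE)$individual
    baseline <- oob_votes_accuracy(base_pred, inbag, y)
    raw <- vapply(names(features), function(v) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        perm <- features
        perm[[v]] <- sample(perm[[v]])
        pred <- predict(rf, perm, predict.all = TRUE)$individual
        baseline - oob_votes_accuracy(pred, inbag, y)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })

  clipped <- pmax(raw, 0)
  if (sum(clipped) <= 0) {
    warn("no variable shows positive importance; relative importances set to 0")
    rel <- rep(0, length(raw))
  } else {
    rel <- 100 * clipped / sum(clipped)
  }
  out <- tibble::tibble(
    variable = names(features),
    raw_importance = unname(raw),
    relative_importance = unname(rel)
  ) |>
    dplyr::arrange(dplyr::desc(.data$relative_importance))
  structure(out,
    class = c("flora_importance", class(tibble::tibble())),
    n_trees = n_trees, n_repeats = n_repeats, seed = seed,
    baseline_accuracy = baseline
  )
}

#' @export
glance.flora_importance <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x),
    n_trees = attr(x, "n_trees"),
    n_repeats = attr(x, "n_repeats"),
    seed = attr(x, "seed"),
    baseline_accuracy = attr(x, "baseline_accuracy")
  )
}

#' Bar chart of relative variable importance
#' @param object A `flora_importance` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flora_importance <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    variable = stats::reorder(.data$variable, .data$relative_importance)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$relative_importance, .data$variable)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "relative importance (%)", y = NULL,
      title = "Environmental drivers of the regionalization"
    ) +
    ggplot2::theme_minimal()
}

region_labels_of <- function(regions) {
  if (inherits(regions, "flora_regions")) regions$labels else regions
}

#' Homogeneity-gated comparison of environmental variables across regions
#'
#' For each variable: a Brown–Forsythe test decides the comparison — one-way
#' ANOVA when variances are homogeneous (p >= alpha), Kruskal–Wallis
#' otherwise. Raw p-values are Benjamini–Hochberg adjusted across the tested
#' variables; constant variables are flagged and excluded from adjustment.
#' Regions with fewer than two reserves cannot enter the variance gate and
#' are dropped from that variable's comparison.
#'
#' @param meta Reserve metadata containing the variables.
#' @param regions A `flora_regions` object or named label vector.
#' @param variables Character vector of column names to test; defaults to all
#'   numeric columns except coordinates.
#' @param alpha Gate level for the homogeneity test.
#' @return A tibble of class `flora_region_tests`: one row per variable with
#'   `levene_p, test_used, statistic, p_value, p_adj, note` and a
#'   `group_stats` list-column of per-region means/medians.
#' @export
region_tests <- function(meta, regions, variables = NULL, alpha = 0.05) {
  meta <- tibble::as_tibble(meta)
  labels <- region_labels_of(regions)
  if (!all(meta$reserve_id %in% names(labels))) {
    abort("every reserve in meta must carry a region label",
      class = "qdmflora_alignment_error"
    )
  }
  meta$region <- labels[meta$reserve_id]
  if (is.null(variables)) {
    variables <- setdiff(
      names(meta)[vapply(meta, is.numeric, logical(1))],
      c("lon", "lat", "region")
    )
  }
  rows <- purrr::map(variables, function(v) {
    vals <- meta[[v]]
    groups <- split(vals, meta$region)
    group_stats <- tibble::tibble(
      region = names(groups),
      n = lengths(groups),
      mean = vapply(groups, mean, numeric(1)),
      median = vapply(groups, median, numeric(1))
    )
    groups <- groups[lengths(groups) >= 2]
    if (length(unique(vals)) == 1) {
      return(tibble::tibble(
        variable = v, levene_p = NA_real_, test_used = NA_character_,
        statistic = NA_real_, p_value = NA_real_,
        note = "constant variable; excluded",
        group_stats = list(group_stats)
      ))
    }
    if (length(groups) < 2) {
      return(tibble::tibble(
        variable = v, levene_p = NA_real_, test_used = NA_character_,
        statistic = NA_real_, p_value = NA_real_,
        note = "fewer than two regions with >= 2 reserves",
        group_stats = list(group_stats)
      ))
    }
    lev <- levene(groups)
    if (lev$p_value >= alpha) {
      ht <- oneway_anova(groups)
      used <- "anova"
    } else {
      ht <- kruskal_wallis(groups)
      used <- "kruskal_wallis"
    }
    tibble::tibble(
      variable = v, levene_p = lev$p_value, test_used = used,
      statistic = ht$statistic, p_value = ht$p_value, note = NA_character_,
      group_stats = list(group_stats)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_adj[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out <- dplyr::relocate(out, "p_adj", .after = "p_value")
  class(out) <- c("flora_region_tests", class(tibble::tibble()))
  out
}

#' Within- and between-region elevation differences
#'
#' Computes all pairwise absolute differences in base, mean and peak elevation,
#' split into within-region and between-region pairs, together with per-region
#' maxima and the corridor threshold flags: within-region base differences
#' below 900 m, mean below 800 m (regions exceeding it are listed as
#' exceptions rather than failures), peak below 1000 m. The corridor-effect
#' statement is emitted when every within-region maximum is below 1000 m and
#' every between-region pair reaches at least 1000 m in each elevation
#' variable. Single-reserve regions contribute no within-region pairs.
#'
#' @param meta Reserve metadata with `elev_base, elev_mean, elev_peak`.
#' @param regions A `flora_regions` object or named label vector.
#' @return An object of class `flora_elevation`: list with `pairs` (long
#'   tibble of pairwise differences), `within_maxima`, `between_maxima`,
#'   `flags`, `exceptions`, and `corridor_effect`.
#' @export
elevation_report <- function(meta, regions) {
  meta <- tibble::as_tibble(meta)
  labels <- region_labels_of(regions)
  if (!all(meta$reserve_id %in% names(labels))) {
    abort("every reserve in meta must carry a region label",
      class = "qdmflora_alignment_error"
    )
  }
  meta$region <- labels[meta$reserve_id]
  vars <- c("elev_base", "elev_mean", "elev_peak")
  idx <- which(upper.tri(diag(nrow(meta))), arr.ind = TRUE)
  pairs <- purrr::map(vars, function(v) {
    tibble::tibble(
      reserve_a = meta$reserve_id[idx[, 1]],
      reserve_b = meta$reserve_id[idx[, 2]],
      region_a = meta$region[idx[, 1]],
      region_b = meta$region[idx[, 2]],
      variable = v,
      diff = abs(meta[[v]][idx[, 1]] - meta[[v]][idx[, 2]]),
      within = meta$region[idx[, 1]] == meta$region[idx[, 2]]
    )
  }) |> dplyr::bind_rows()

  within_maxima <- pairs |>
    dplyr::filter(.data$within) |>
    dplyr::summarise(
      max_diff = max(.data$diff),
      .by = c("region_a", "variable")
    ) |>
    dplyr::rename(region = "region_a") |>
    dplyr::arrange(.data$region, .data$variable)

  between_maxima <- pairs |>
    dplyr::filter(!.data$within) |>
    dplyr::mutate(
      pair = paste(pmin(.data$region_a, .data$region_b),
        pmax(.data$region_a, .data$region_b),
        sep = "-"
      )
    ) |>
    dplyr::summarise(max_diff = max(.data$diff), .by = c("pair", "variable")) |>
    dplyr::arrange(.data$pair, .data$variable)

  thresholds <- c(elev_base = 900, elev_mean = 800, elev_peak = 1000)
  exceptions <- within_maxima |>
    dplyr::filter(.data$max_diff >= thresholds[.data$variable])
  flag_of <- function(v) {
    wm <- within_maxima$max_diff[within_maxima$variable == v]
    length(wm) == 0 || all(wm < thresholds[v])
  }
  flags <- list(
    within_base_lt_900 = flag_of("elev_base"),
    within_mean_lt_800 = flag_of("elev_mean"),
    within_peak_lt_1000 = flag_of("elev_peak")
  )
  corridor <- (nrow(within_maxima) == 0 || all(within_maxima$max_diff < 1000)) &&
    nrow(between_maxima) > 0 && all(between_maxima$max_diff >= 1000)

  structure(
    list(
      pairs = pairs,
      within_maxima = within_maxima,
      between_maxima = between_maxima,
      flags = flags,
      exceptions = exceptions,
      corridor_effect = corridor
    ),
    class = "flora_elevation"
  )
}

#' @export
print.flora_elevation <- function(x, ...) {
  cat("Elevation-difference report\n")
  cat(
    "  within-region maxima < 900/800/1000 m (base/mean/peak):",
    paste(unlist(x$flags), collapse = " / "), "\n"
  )
  if (nrow(x$exceptions) > 0) {
    cat("  exceptions:\n")
    print(x$exceptions)
  }
  cat(
    "  corridor effect (within < 1000 m, between >= 1000 m):",
    x$corridor_effect, "\n"
  )
  invisible(x)
}

#' @export
tidy.flora_elevation <- function(x, ...) x$pairs

#' @export
glance.flora_elevation <- function(x, ...) {
  tibble::tibble(
    within_base_lt_900 = x$flags$within_base_lt_900,
    within_mean_lt_800 = x$flags$within_mean_lt_800,
    within_peak_lt_1000 = x$flags$within_peak_lt_1000,
    n_exceptions = nrow(x$exceptions),
    corridor_effect = x$corridor_effect
  )
}

#' Boxplots of within- vs between-region elevation differences
#' @param object A `flora_elevation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flora_elevation <- function(object, ...) {
  df <- dplyr::mutate(object$pairs,
    scope = dplyr::if_else(.data$within, "within region", "between regions")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$scope, .data$diff)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 1000, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~variable) +
    ggplot2::labs(
      x = NULL, y = "pairwise elevation difference (m)",
      title = "Elevation differences and the 1000 m corridor threshold"
    ) +
    ggplot2::theme_minimal()
}
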