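test_that("one-way ANOVA matches hand computation and the projection oracle", {
  res <- oneway_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$statistic, 1.5) # SSB = 1.5, SSW = 4, df = (1, 4)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  expect_equal(res$p_value, stats::pf(1.5, 1, 4, lower.tail = FALSE))

  same <- oneway_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)

  withr::with_seed(31, {
    for (i in 1:20) {
      groups <- purrr::map(1:sample(2:5, 1), ~ rnorm(sample(3:9, 1)))
      expect_equal(oneway_anova(groups)$statistic, oracle_anova_F(groups),
        tolerance = 1e-10
      )
    }
  })

  expect_error(oneway_anova(list(1, c(1, 2))), class = "qdmflora_domain_error")
  expect_warning(oneway_anova(list(c(2, 2), c(2, 2))), regexp = "identical")
})

test_that("Kruskal-Wallis matches the rank-sum hand value and midrank oracle", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 3.857, tolerance = 5e-4) # R = (6, 15), no ties
  expect_equal(res$df1, 1)

  same <- kruskal_wallis(list(c(5, 5, 5), c(5, 5)))
  expect_equal(same$statistic, 0)

  withr::with_seed(32, {
    for (i in 1:20) {
      groups <- purrr::map(1:sample(2:4, 1), ~ sample(1:6, sample(3:8, 1), replace = TRUE))
      expect_equal(kruskal_wallis(groups)$statistic, oracle_kw_H(groups),
        tolerance = 1e-10
      )
    }
  })
})

test_that("Brown-Forsythe gate detects heteroscedasticity and matches car", {
  expect_equal(levene(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)

  het <- levene(list(c(0, 0, 0, 0), c(-5, 5, -5, 5)))
  expect_gt(het$statistic, 10)
  expect_lt(het$p_value, 0.05)

  withr::with_seed(33, {
    for (i in 1:10) {
      groups <- purrr::map(1:3, ~ rnorm(sample(4:9, 1), sd = runif(1, 0.5, 3)))
      mine <- levene(groups)
      df <- data.frame(
        y = unlist(groups),
        g = factor(rep(seq_along(groups), lengths(groups)))
      )
      ref <- car::leveneTest(y ~ g, data = df, center = median)
      expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-10)
      expect_equal(mine$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
    }
  })

  expect_error(levene(list(1, c(1, 2))), class = "qdmflora_domain_error")
})

test_that("Brown-Forsythe type-I error is near nominal under equal variances", {
  rej <- withr::with_seed(34, {
    mean(purrr::map_lgl(1:400, function(i) {
      levene(list(rnorm(8), rnorm(8), rnorm(8)))$p_value < 0.05
    }))
  })
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("importance ranks the label-determining variable first", {
  firsts <- purrr::map_lgl(1:5, function(s) {
    withr::with_seed(s, {
      n <- 40
      feats <- data.frame(
        x_signal = runif(n),
        x_noise1 = rnorm(n), x_noise2 = rnorm(n), x_noise3 = rnorm(n)
      )
      labels <- ifelse(feats$x_signal > median(feats$x_signal), "hi", "lo")
      imp <- importance(feats, labels, n_trees = 200, n_repeats = 10, seed = s)
      imp$variable[1] == "x_signal"
    })
  })
  expect_true(all(firsts))
})

test_that("pure-noise features get near-zero raw importance summing to 100", {
  withr::with_seed(55, {
    n <- 40
    feats <- data.frame(x = runif(n), junk = rnorm(n))
    labels <- ifelse(feats$x > median(feats$x), "a", "b")
    imp <- importance(feats, labels, n_trees = 300, n_repeats = 20, seed = 5)
    expect_lt(abs(imp$raw_importance[imp$variable == "junk"]), 0.06)
    expect_equal(sum(imp$relative_importance), 100, tolerance = 0.01)
    expect_true(all(imp$relative_importance >= 0))
  })
})

test_that("duplicated informative features split their importance share", {
  withr::with_seed(56, {
    n <- 60
    x <- runif(n)
    labels <- ifelse(x > median(x), "a", "b")
    noise <- rnorm(n)
    solo <- importance(data.frame(x = x, noise = noise), labels,
      n_trees = 300, n_repeats = 15, seed = 2
    )
    dup <- importance(data.frame(x1 = x, x2 = x, noise = noise), labels,
      n_trees = 300, n_repeats = 15, seed = 2
    )
    solo_raw <- solo$raw_importance[solo$variable == "x"]
    dup_raw <- dup$raw_importance[dup$variable %in% c("x1", "x2")]
    expect_true(all(dup_raw < solo_raw))
    expect_gt(min(dup_raw), solo$raw_importance[solo$variable == "noise"])
  })
})

test_that("importance validates inputs and flags constant features", {
  feats <- data.frame(a = 1:10, b = rep(2, 10))
  expect_error(importance(feats, rep("one", 10), n_trees = 50, n_repeats = 2),
    class = "qdmflora_domain_error"
  )
  labels <- rep(c("x", "y"), each = 5)
  expect_warning(
    imp <- importance(feats, labels, n_trees = 50, n_repeats = 2, seed = 1),
    regexp = "constant"
  )
  expect_lt(abs(imp$raw_importance[imp$variable == "b"]), 1e-9)
})

test_that("region tests gate on homogeneity and adjust across variables", {
  ds <- generate_flora(generator_config(seed = 12))
  rt <- region_tests(ds$meta, ds$truth$region)
  expect_s3_class(rt, "flora_region_tests")
  tested <- dplyr::filter(rt, !is.na(p_value))
  expect_true(all(tested$test_used[tested$levene_p >= 0.05] == "anova"))
  expect_true(all(tested$test_used[tested$levene_p < 0.05] == "kruskal_wallis"))
  # strong planted region effects: precipitation should come out significant
  expect_lt(rt$p_adj[rt$variable == "precip_annual_cur"], 0.01)
  expect_equal(
    dplyr::arrange(tested, p_value)$p_adj,
    p.adjust(dplyr::arrange(tested, p_value)$p_value, "BH")
  )
})

test_that("constant variables are flagged and excluded from adjustment", {
  ds <- generate_flora(generator_config(
    n_regions = 2, reserves_per_region = 4,
    species_pool_size = 100, n_endemic_genera = 4, n_cultivated = 0, seed = 13
  ))
  meta <- dplyr::mutate(ds$meta, flatvar = 7)
  rt <- region_tests(meta, ds$truth$region, variables = c("precip_annual_cur", "flatvar"))
  expect_true(is.na(rt$p_value[rt$variable == "flatvar"]))
  expect_match(rt$note[rt$variable == "flatvar"], "constant")
  expect_false(is.na(rt$p_adj[rt$variable == "precip_annual_cur"]))
})

test_that("null environments give roughly uniform raw p-values", {
  ds <- make_fixture("null_env")
  ps <- withr::with_seed(77, {
    purrr::map_dbl(1:60, function(i) {
      labels <- setNames(sample(ds$truth$region), names(ds$truth$region))
      rt <- region_tests(ds$meta, labels, variables = "precip_annual_cur")
      rt$p_value
    })
  })
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("elevation report computes pairwise differences and corridor flags", {
  meta <- tibble::tibble(
    reserve_id = c("a", "b", "c", "d", "e"),
    lon = 1:5, lat = 1,
    elev_base = c(100, 300, 800, 1900, 2100),
    elev_mean = c(600, 800, 1300, 2400, 2600),
    elev_peak = c(1100, 1300, 1800, 2900, 3100)
  )
  labels <- setNames(c(1, 1, 1, 2, 2), meta$reserve_id)
  er <- elevation_report(meta, labels)
  # toy hand check: region 1 base {100, 300, 800} -> max within diff 700
  expect_equal(
    er$within_maxima$max_diff[er$within_maxima$region == 1 &
      er$within_maxima$variable == "elev_base"],
    700
  )
  expect_true(er$flags$within_base_lt_900)
  expect_true(er$flags$within_mean_lt_800)
  expect_true(er$flags$within_peak_lt_1000)
  expect_true(er$corridor_effect)
  # within + between pair counts = n(n-1)/2 per variable
  per_var <- dplyr::count(er$pairs, variable)
  expect_true(all(per_var$n == 10))
  expect_true(all(er$pairs$diff >= 0))

  # an 800 m-exceeding mean spread is listed as an exception, not a failure
  meta2 <- dplyr::mutate(meta, elev_mean = ifelse(reserve_id == "c", 1900, elev_mean),
    elev_peak = ifelse(reserve_id == "c", 2400, elev_peak))
  er2 <- elevation_report(meta2, labels)
  expect_false(er2$flags$within_mean_lt_800)
  expect_true(nrow(er2$exceptions) >= 1)
})

test_that("generator elevations satisfy every corridor flag by construction", {
  ds <- generate_flora(generator_config(seed = 21))
  er <- elevation_report(ds$meta, ds$truth$region)
  expect_true(er$flags$within_base_lt_900)
  expect_true(er$flags$within_mean_lt_800)
  expect_true(er$flags$within_peak_lt_1000)
  expect_true(er$corridor_effect)
  g <- glance(er)
  expect_true(g$corridor_effect)
})

test_that("single-reserve regions contribute no within pairs and do not crash", {
  meta <- tibble::tibble(
    reserve_id = c("a", "b", "c"), lon = 1:3, lat = 1,
    elev_base = c(100, 200, 5000), elev_mean = c(600, 700, 5500),
    elev_peak = c(1100, 1200, 6000)
  )
  labels <- setNames(c(1, 1, 2), meta$reserve_id)
  er <- elevation_report(meta, labels)
  expect_false(2 %in% er$within_maxima$region)
  expect_equal(nrow(dplyr::filter(er$pairs, within)), 3)
})
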