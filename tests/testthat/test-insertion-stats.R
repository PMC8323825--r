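test_that("buckling rates reproduce the published per-condition table", {
  tab <- buckling_rate_table(penetration_counts())
  cond <- dplyr::filter(tab, scope == "condition")
  expect_equal(round(cond$buckling_rate_pct[cond$membrane == "pia_only"], 1),
               c(9.1, 0, 0, 11.1, 0, 0, 0, 9.1, 0, 0, 0))
  expect_equal(round(cond$buckling_rate_pct[cond$membrane == "dura_pia"], 1),
               c(28.6, 0, 0, 42.9, 7.1, 0, 57.1, 7.1, 0))
  pooled <- dplyr::filter(tab, scope == "pooled")
  expect_equal(pooled$penetrated, c(103, 112))
  expect_equal(pooled$total, c(123, 115))
  expect_equal(round(pooled$buckling_rate_pct, 1), c(16.3, 2.6))
  # degenerate rows
  expect_equal(buckling_rate_table(
    tibble::tibble(penetrated = 10, total = 10))$buckling_rate_pct, c(0, 0))
  expect_error(buckling_rate_table(tibble::tibble(penetrated = 1, total = 0)),
               "undefined")
  expect_error(buckling_rate_table(tibble::tibble(penetrated = 3, total = 2)),
               "total")
})

test_that("diameter fit on means equals raw fit for balanced noiseless data", {
  des <- study_design(animals = 3,
                      animal_sd_mn = c(pia_only = 0, dura_pia = 0),
                      residual_sd_mn = c(pia_only = 0, dura_pia = 0),
                      dimpling_sd_mm = c(pia_only = 0, dura_pia = 0))
  tab <- simulate_study(des, seed = 3)
  fm <- diameter_linearity_fit(tab, "rupture_force_mn", "pia_only", tip = "blunt")
  fr <- diameter_linearity_fit(tab, "rupture_force_mn", "pia_only", tip = "blunt",
                               use_means = FALSE)
  expect_equal(fm$slope, fr$slope, tolerance = 1e-10)
  expect_equal(fm$intercept, fr$intercept, tolerance = 1e-10)
  expect_equal(fm$r_squared, 1)
  expect_error(
    diameter_linearity_fit(dplyr::filter(tab, diameter_um == 25),
                           "rupture_force_mn", "pia_only"),
    "two diameter")
})

test_that("linear diameter model outranks the cross-sectional-area model", {
  wins <- vapply(1:40, function(s) {
    tab <- simulate_study(small_design(), seed = 100 + s)
    g <- glance(diameter_linearity_fit(tab, "rupture_force_mn", "pia_only",
                                       tip = "blunt"))
    g$preferred == "linear"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("ANOVA has the expected invariances and degenerate behaviour", {
  tab <- simulate_study(study_design(animals = 3), seed = 7)
  base <- tidy(three_factor_anova(tab, "rupture_force_mn", "pia_only"))
  expect_equal(base$term, c("material", "tip", "diameter_um"))
  expect_true(all(base$statistic >= 0))
  expect_true(all(base$p.value >= 0 & base$p.value <= 1))
  # relabeling factor levels leaves p-values unchanged
  relab <- dplyr::mutate(tab,
    material = c(tungsten = "W", stainless_steel = "SS")[material],
    tip = toupper(tip))
  expect_equal(tidy(three_factor_anova(relab, "rupture_force_mn", "pia_only"))$p.value,
               base$p.value)
  # affine transform of the response leaves F unchanged
  shifted <- dplyr::mutate(tab, rupture_force_mn = 5 + 2 * rupture_force_mn)
  expect_equal(tidy(three_factor_anova(shifted, "rupture_force_mn", "pia_only"))$statistic,
               base$statistic)
  # identical observations in every group: F = 0
  flat <- dplyr::mutate(tab, rupture_force_mn =
                          ifelse(outcome == "penetrated", 1, NA_real_))
  f0 <- tidy(suppressWarnings(three_factor_anova(flat, "rupture_force_mn", "pia_only")))
  expect_true(all(abs(f0$statistic) < 1e-10 | is.nan(f0$statistic)))
  # inestimable factor named in the error
  expect_error(
    three_factor_anova(dplyr::filter(tab, material == "tungsten"),
                       "rupture_force_mn", "pia_only"),
    "material")
})

test_that("correlation strata, bands and degenerate cases behave", {
  # exact linear relation: r = 1, strong
  tab <- tibble::tibble(
    membrane = "pia_only", outcome = "penetrated",
    material = "tungsten", tip = rep(c("sharp", "blunt"), each = 10),
    diameter_um = rep(c(25, 50), 10),
    rupture_force_mn = seq(0.5, 3, length.out = 20))
  tab$dimpling_mm <- tab$rupture_force_mn / 3
  res <- rupture_dimpling_correlation(tab, "pia_only")
  expect_equal(res$r[res$stratum == "all"], 1)
  expect_equal(res$strength[res$stratum == "all"], "strong")
  # constant vector: undefined r
  const <- dplyr::mutate(tab, dimpling_mm = 0.5)
  resc <- rupture_dimpling_correlation(const, "pia_only")
  expect_true(is.na(resc$r[resc$stratum == "all"]))
  # small stratum: r reported, p undefined
  tiny <- tab[1:2, ]
  rest <- rupture_dimpling_correlation(tiny, "pia_only")
  expect_true(all(is.na(rest$p.value)))
  # estimator is unbiased on bivariate normal draws across rho
  for (rho in c(0, 0.7)) {
    rs <- vapply(1:300, function(s) {
      set.seed(4000 + s)
      x <- stats::rnorm(30)
      y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(30)
      stats::cor(x, y)
    }, numeric(1))
    # small negative bias of order rho(1-rho^2)/(2n) is expected
    expect_lt(abs(mean(rs) - rho), 0.05)
  }
})

test_that("dimpling-to-force ratio is homogeneous and matches the simulator", {
  tab <- tibble::tibble(membrane = "pia_only", material = "tungsten",
                        tip = "blunt", diameter_um = 25,
                        outcome = "penetrated",
                        rupture_force_mn = 2, dimpling_mm = 0.5)
  expect_equal(dimpling_force_ratio(tab)$ratio_mm_per_mn, 0.25)
  # joint rescaling leaves the ratio unchanged
  scaled <- dplyr::mutate(tab, rupture_force_mn = 7 * rupture_force_mn,
                          dimpling_mm = 7 * dimpling_mm)
  expect_equal(dimpling_force_ratio(scaled)$ratio_mm_per_mn, 0.25)
  # noiseless synthetic study: ratio = 1/k_m everywhere
  des <- study_design(animals = 2,
                      animal_sd_mn = c(pia_only = 0, dura_pia = 0),
                      residual_sd_mn = c(pia_only = 0, dura_pia = 0),
                      dimpling_sd_mm = c(pia_only = 0, dura_pia = 0))
  sim <- dimpling_force_ratio(simulate_study(des, seed = 5))
  pia <- dplyr::filter(sim, membrane == "pia_only")
  expect_equal(pia$ratio_mm_per_mn, rep(1 / 3, nrow(pia)), tolerance = 1e-10)
  # non-positive force excluded with a warning
  bad <- dplyr::mutate(tab, rupture_force_mn = 0)
  expect_warning(out <- dimpling_force_ratio(bad), "non-positive")
  expect_true(is.na(out$ratio_mm_per_mn))
})

test_that("study report bookkeeping matches its inputs", {
  tab <- simulate_study(small_design(), seed = 9)
  rep <- study_report(tab)
  expect_equal(sum(rep$counts$total), nrow(tab))
  expect_equal(nrow(rep$counts), nrow(dplyr::distinct(
    tab, membrane, material, tip, diameter_um)))
  expect_equal(sort(names(rep$correlations)), c("dura_pia", "pia_only"))
  expect_length(rep$anovas, 6)
  expect_s3_class(rep$fits[["pia_only.rupture_force_mn"]], "diameter_fit")
  # printed pooled rates agree with direct computation
  pooled <- dplyr::filter(rep$buckling_rates, scope == "pooled")
  direct <- tab |>
    dplyr::group_by(membrane) |>
    dplyr::summarise(r = mean(outcome != "penetrated") * 100)
  expect_equal(sort(pooled$buckling_rate_pct), sort(direct$r))
  # empty study: valid, empty report
  empty <- study_report(tab[0, ])
  expect_s3_class(empty, "study_report")
  expect_equal(empty$n_trials, 0)
  expect_length(empty$fits, 0)
  expect_no_error(utils::capture.output(print(rep)))
})
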