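#' Buckling-rate table from penetration counts
#'
#' The buckling rate of a condition is the number of buckled (failed)
#' trials as a percentage of all trials: `(total - penetrated)/total * 100`.
#' Pooled rows sum counts within each membrane condition and overall.
#'
#' @param counts A tibble with columns `penetrated` and `total` plus any
#'   condition columns (see [penetration_counts()]); `membrane` is used for
#'   pooling when present.
#' @return The per-row table with `buckling_rate_pct` appended, followed by
#'   pooled rows (condition columns `NA`, `scope` `"pooled"` /
#'   `"pooled_all"`).
#' @examples
#' buckling_rate_table(penetration_counts())
#' @export
buckling_rate_table <- function(counts) {
  if (!all(c("penetrated", "total") %in% names(counts))) {
    abort("`counts` needs columns `penetrated` and `total`.")
  }
  if (any(counts$total <= 0)) abort("Rows with `total` = 0 have an undefined rate.")
  if (any(counts$penetrated > counts$total) || any(counts$penetrated < 0)) {
    abort("`penetrated` must lie in [0, total].")
  }
  rate <- function(p, t) (t - p) / t * 100
  rows <- mutate(counts, scope = "condition",
                 buckling_rate_pct = rate(.data$penetrated, .data$total))
  pooled <- if ("membrane" %in% names(counts)) {
    counts |>
      group_by(.data$membrane) |>
      summarise(penetrated = sum(.data$penetrated), total = sum(.data$total),
                .groups = "drop") |>
      mutate(scope = "pooled",
             buckling_rate_pct = rate(.data$penetrated, .data$total))
  }
  overall <- summarise(counts, penetrated = sum(.data$penetrated),
                       total = sum(.data$total)) |>
    mutate(scope = "pooled_all",
           buckling_rate_pct = rate(.data$penetrated, .data$total))
  bind_rows(rows, pooled, overall)
}

#' Count outcomes of a simulated or recovered study table
#'
#' Collapses a trial table to per-condition penetrated/total counts in the
#' shape [buckling_rate_table()] consumes.
#'
#' @param table A study table (see [simulate_study()]).
#' @return A tibble of counts by membrane, material, tip and diameter.
#' @export
outcome_counts <- function(table) {
  table |>
    group_by(.data$membrane, .data$material, .data$tip, .data$diameter_um) |>
    summarise(penetrated = sum(.data$outcome == "penetrated"),
              total = n(), .groups = "drop")
}

#' Linear fit of a response against microwire diameter
#'
#' The study's headline trend: mean rupture force (and dimpling depth) rise
#' linearly with microwire *diameter*, not cross-sectional area. Following
#' the study's procedure the fit is ordinary least squares of per-condition
#' mean response (condition = material x tip x diameter) on diameter; a
#' raw-trial fit is available with `use_means = FALSE`. A competing fit on
#' diameter squared (the cross-sectional-area model) is returned for model
#' comparison.
#'
#' @param table A study table; only `penetrated` trials are used.
#' @param response `"rupture_force_mn"` or `"dimpling_mm"`.
#' @param membrane Membrane condition to analyse.
#' @param tip Optional tip filter (`"sharp"`/`"blunt"`).
#' @param use_means Fit on condition means (default, the study's choice) or
#'   on raw trials.
#' @return A `diameter_fit` object; see [tidy.diameter_fit()],
#'   [glance.diameter_fit()] and [autoplot.diameter_fit()].
#' @examples
#' tab <- simulate_study(study_design(animals = 4), seed = 1)
#' fit <- diameter_linearity_fit(tab, "rupture_force_mn", "pia_only")
#' glance(fit)
#' @export
diameter_linearity_fit <- function(table,
                                   response = c("rupture_force_mn", "dimpling_mm"),
                                   membrane = c("pia_only", "dura_pia"),
                                   tip = NULL,
                                   use_means = TRUE) {
  response <- match.arg(response)
  membrane <- match.arg(membrane)
  dat <- filter(table, .data$membrane == !!membrane, .data$outcome == "penetrated")
  if (!is.null(tip)) dat <- filter(dat, .data$tip == !!tip)
  if (length(unique(dat$diameter_um)) < 2) {
    abort("Need at least two diameter levels with penetrated trials.")
  }
  means <- dat |>
    group_by(.data$material, .data$tip, .data$diameter_um) |>
    summarise(mean_response = mean(.data[[response]]),
              se_response = stats::sd(.data[[response]]) / sqrt(n()),
              n = n(), .groups = "drop")
  fit_dat <- if (use_means) {
    tibble(y = means$mean_response, diameter_um = means$diameter_um)
  } else {
    tibble(y = dat[[response]], diameter_um = dat$diameter_um)
  }
  fit_lin <- stats::lm(y ~ diameter_um, data = fit_dat)
  fit_quad <- stats::lm(y ~ I(diameter_um^2), data = fit_dat)
  # direct R^2 (summary.lm warns on numerically perfect fits)
  r2 <- function(fit) {
    tss <- sum((fit_dat$y - mean(fit_dat$y))^2)
    if (tss == 0) return(NaN)
    1 - sum(stats::resid(fit)^2) / tss
  }
  structure(
    list(response = response, membrane = membrane, tip = tip,
         use_means = use_means, means = means,
         fit_linear = fit_lin, fit_quadratic = fit_quad,
         slope = unname(stats::coef(fit_lin)[2]),
         intercept = unname(stats::coef(fit_lin)[1]),
         r_squared = r2(fit_lin),
         r_squared_quadratic = r2(fit_quad)),
    class = "diameter_fit"
  )
}

#' @export
print.diameter_fit <- function(x, ...) {
  cat(sprintf(
    "Diameter-linearity fit (%s, %s%s, %s)\n  slope %.4g per um, intercept %.4g, R^2 %.3f (diameter^2 model R^2 %.3f)\n",
    x$response, x$membrane, if (is.null(x$tip)) "" else paste0(", ", x$tip),
    if (x$use_means) "condition means" else "raw trials",
    x$slope, x$intercept, x$r_squared, x$r_squared_quadratic))
  invisible(x)
}

#' Main-effects ANOVA on insertion responses
#'
#' Analysis of variance of a response (rupture force, dimpling depth, or
#' the dimpling-to-rupture-force ratio) on the three microwire factors --
#' material, tip geometry and diameter -- for one membrane condition, on
#' penetrated trials only. Main effects only; diameter enters as a factor.
#' Unbalanced cells are handled with partial (type II) sums of squares.
#'
#' @param table A study table.
#' @param response `"rupture_force_mn"`, `"dimpling_mm"` or
#'   `"ratio_mm_per_mn"` (computed on the fly via
#'   [dimpling_force_ratio()]).
#' @param membrane Membrane condition to analyse.
#' @param factors Factor columns to include.
#' @return An `insertion_anova` object wrapping the type II ANOVA table;
#'   `tidy()` gives one row per factor (`term`, `df`, `statistic`,
#'   `p.value`), `glance()` the residual summary.
#' @examples
#' tab <- simulate_study(study_design(animals = 4), seed = 1)
#' tidy(three_factor_anova(tab, "rupture_force_mn", "pia_only"))
#' @export
three_factor_anova <- function(table,
                               response = c("rupture_force_mn", "dimpling_mm",
                                            "ratio_mm_per_mn"),
                               membrane = c("pia_only", "dura_pia"),
                               factors = c("material", "tip", "diameter_um")) {
  response <- match.arg(response)
  membrane <- match.arg(membrane)
  if (response == "ratio_mm_per_mn" && !"ratio_mm_per_mn" %in% names(table)) {
    table <- dimpling_force_ratio(table)
  }
  dat <- table |>
    filter(.data$membrane == !!membrane, .data$outcome == "penetrated") |>
    tidyr::drop_na(dplyr::all_of(response)) |>
    mutate(across(dplyr::all_of(factors), as.factor))
  for (f in factors) {
    if (length(unique(dat[[f]])) < 2) {
      abort(sprintf("Factor `%s` has fewer than two observed levels; not estimable.", f))
    }
  }
  fml <- stats::reformulate(factors, response = response)
  fit <- stats::lm(fml, data = dat)
  aov_tab <- if (stats::sd(dat[[response]]) < .Machine$double.eps^0.5) {
    # degenerate: constant response carries no variance to partition
    df <- vapply(factors, function(f) nlevels(dat[[f]]) - 1L, integer(1))
    structure(
      data.frame(`Sum Sq` = c(rep(0, length(factors)), 0),
                 Df = c(df, nrow(dat) - sum(df) - 1L),
                 `F value` = c(rep(0, length(factors)), NA),
                 `Pr(>F)` = c(rep(1, length(factors)), NA),
                 row.names = c(factors, "Residuals"), check.names = FALSE),
      class = c("anova", "data.frame"))
  } else {
    car::Anova(fit, type = 2)
  }
  structure(
    list(response = response, membrane = membrane, factors = factors,
         fit = fit, anova = aov_tab, n = nrow(dat)),
    class = "insertion_anova"
  )
}

#' @export
print.insertion_anova <- function(x, ...) {
  cat(sprintf("Type II main-effects ANOVA: %s ~ %s (%s, n = %d)\n",
              x$response, paste(x$factors, collapse = " + "), x$membrane, x$n))
  print(tidy(x))
  invisible(x)
}

#' Pearson correlation between rupture force and dimpling depth
#'
#' Correlates rupture force with dimpling depth at rupture within the
#' strata used by the study: all penetrated insertions, each tip geometry,
#' and each diameter level. Strata with fewer than `min_n` trials (or with
#' a constant variable) report an undefined correlation. Strengths follow
#' the study's bands: strong when `|r| > 0.7` with `p < 0.05`, moderate
#' when `0.3 < |r| <= 0.7`, weak otherwise.
#'
#' @param table A study table.
#' @param membrane Membrane condition.
#' @param min_n Minimum stratum size for a defined test (default 3).
#' @return A tibble: `stratum`, `n`, `r`, `p.value`, `strength`.
#' @examples
#' tab <- simulate_study(study_design(animals = 4), seed = 1)
#' rupture_dimpling_correlation(tab, "pia_only")
#' @export
rupture_dimpling_correlation <- function(table,
                                         membrane = c("pia_only", "dura_pia"),
                                         min_n = 3) {
  membrane <- match.arg(membrane)
  dat <- filter(table, .data$membrane == !!membrane,
                .data$outcome == "penetrated") |>
    tidyr::drop_na("rupture_force_mn", "dimpling_mm")
  strata <- c(
    list(all = dat),
    split(dat, paste0("tip_", dat$tip)),
    split(dat, paste0("diameter_", dat$diameter_um))
  )
  purrr::imap_dfr(strata, function(d, nm) {
    n <- nrow(d)
    defined <- n >= min_n &&
      stats::sd(d$rupture_force_mn) > 0 && stats::sd(d$dimpling_mm) > 0
    if (!defined) {
      r <- if (n >= 2 && stats::sd(d$rupture_force_mn) > 0 &&
               stats::sd(d$dimpling_mm) > 0) {
        stats::cor(d$rupture_force_mn, d$dimpling_mm)
      } else NA_real_
      return(tibble(stratum = nm, n = n, r = r, p.value = NA_real_,
                    strength = NA_character_))
    }
    ct <- stats::cor.test(d$rupture_force_mn, d$dimpling_mm,
                          method = "pearson", alternative = "two.sided")
    r <- unname(ct$estimate)
    strength <- if (abs(r) > 0.7 && ct$p.value < 0.05) "strong"
      else if (abs(r) > 0.3 && abs(r) <= 0.7) "moderate" else "weak"
    tibble(stratum = nm, n = n, r = r, p.value = ct$p.value, strength = strength)
  })
}

#' Dimpling-to-rupture-force ratio
#'
#' Appends the per-trial ratio of dimpling depth (mm) to rupture force
#' (mN) -- the quantity that makes dimpling a poor universal proxy for
#' force, as it depends on tip and diameter. Buckled trials and trials
#' with non-positive force get `NA`.
#'
#' @param table A study table.
#' @return `table` with `ratio_mm_per_mn` appended.
#' @seealso [ratio_summary()] for per-condition summaries.
#' @export
dimpling_force_ratio <- function(table) {
  bad <- !is.na(table$rupture_force_mn) & table$rupture_force_mn <= 0
  if (any(bad)) {
    warn(sprintf("%d trial(s) with non-positive rupture force excluded from the ratio.",
                 sum(bad)))
  }
  mutate(table, ratio_mm_per_mn = ifelse(
    .data$outcome == "penetrated" & .data$rupture_force_mn > 0,
    .data$dimpling_mm / .data$rupture_force_mn, NA_real_))
}

#' @rdname dimpling_force_ratio
#' @export
ratio_summary <- function(table) {
  if (!"ratio_mm_per_mn" %in% names(table)) table <- dimpling_force_ratio(table)
  table |>
    filter(!is.na(.data$ratio_mm_per_mn)) |>
    group_by(.data$membrane, .data$material, .data$tip, .data$diameter_um) |>
    summarise(mean_ratio = mean(.data$ratio_mm_per_mn),
              se_ratio = stats::sd(.data$ratio_mm_per_mn) / sqrt(n()),
              n = n(), .groups = "drop")
}

#' Full study report
#'
#' Runs the complete statistical battery over a study table: outcome
#' counts and buckling rates, diameter-linearity fits of rupture force and
#' dimpling for each membrane, the six main-effects ANOVAs (three responses
#' x two membranes), the correlation strata, and per-condition ratio and
#' response summaries.
#'
#' @param table A study table.
#' @return A `study_report` list with elements `counts`, `buckling_rates`,
#'   `fits`, `anovas`, `correlations`, `ratio_summary`,
#'   `condition_summary`; all tabular elements are tibbles.
#' @examples
#' rep <- study_report(simulate_study(study_design(animals = 4), seed = 1))
#' rep$buckling_rates
#' @export
study_report <- function(table) {
  membranes <- intersect(c("pia_only", "dura_pia"), unique(table$membrane))
  empty <- nrow(filter(table, .data$outcome == "penetrated")) == 0

  counts <- if (nrow(table) > 0) outcome_counts(table) else
    tibble(membrane = character(), material = character(), tip = character(),
           diameter_um = double(), penetrated = integer(), total = integer())
  rates <- if (nrow(counts) > 0) buckling_rate_table(counts) else counts

  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  fits <- anovas <- cors <- list()
  if (!empty) {
    for (mb in membranes) {
      for (resp in c("rupture_force_mn", "dimpling_mm")) {
        fits[[paste(mb, resp, sep = ".")]] <-
          safe(diameter_linearity_fit(table, resp, mb))
      }
      for (resp in c("rupture_force_mn", "dimpling_mm", "ratio_mm_per_mn")) {
        anovas[[paste(mb, resp, sep = ".")]] <-
          safe(three_factor_anova(table, resp, mb))
      }
      cors[[mb]] <- safe(rupture_dimpling_correlation(table, mb))
    }
  }
  cond <- if (!empty) {
    table |>
      filter(.data$outcome == "penetrated") |>
      group_by(.data$membrane, .data$material, .data$tip, .data$diameter_um) |>
      summarise(
        mean_force_mn = mean(.data$rupture_force_mn),
        se_force_mn = stats::sd(.data$rupture_force_mn) / sqrt(n()),
        mean_dimpling_mm = mean(.data$dimpling_mm),
        se_dimpling_mm = stats::sd(.data$dimpling_mm) / sqrt(n()),
        n = n(), .groups = "drop")
  } else tibble()

  structure(
    list(counts = counts, buckling_rates = rates,
         fits = purrr::compact(fits),
         anovas = purrr::map(purrr::compact(anovas), tidy),
         correlations = purrr::compact(cors),
         ratio_summary = if (!empty) ratio_summary(table) else tibble(),
         condition_summary = cond, n_trials = nrow(table)),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Insertion study report (%d trials)\n\n", x$n_trials))
  cat("Buckling rates (% of trials):\n")
  print(x$buckling_rates, n = Inf)
  if (length(x$fits) > 0) {
    cat("\nDiameter-linearity fits (condition means):\n")
    for (nm in names(x$fits)) {
      f <- x$fits[[nm]]
      cat(sprintf("  %-28s slope %8.4g /um  R^2 %.3f\n", nm, f$slope, f$r_squared))
    }
  }
  if (length(x$anovas) > 0) {
    cat("\nType II main-effects ANOVA (F, p):\n")
    for (nm in names(x$anovas)) {
      a <- x$anovas[[nm]]
      cat(sprintf("  %s\n", nm))
      for (i in seq_len(nrow(a))) {
        cat(sprintf("    %-12s F = %8.3f  p = %.4g\n",
                    a$term[i], a$statistic[i], a$p.value[i]))
      }
    }
  }
  if (length(x$correlations) > 0) {
    cat("\nRupture force vs dimpling depth (Pearson):\n")
    for (nm in names(x$correlations)) {
      cat(sprintf("  %s:\n", nm))
      print(x$correlations[[nm]], n = Inf)
    }
  }
  invisible(x)
}
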