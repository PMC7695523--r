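#' Raw daily values of the stable phase
#'
#' Convenience extractor: the daily values falling in the baseline window,
#' shaped for [phase_summaries()].
#'
#' @param daily output of [build_daily_series()].
#' @param window tibble (`patient_id`, `date`), e.g. from
#'   [select_stable_window()].
#' @return tibble with `patient_id`, `variable`, `value`.
#' @export
stable_phase_values <- function(daily, window) {
  daily |>
    inner_join(window, by = c("patient_id", "date")) |>
    select("patient_id", "variable", "value")
}

#' Compare a variable across the stable, pre- and post-exacerbation phases
#'
#' Pools patient-days and compares the three periods — stable state (the
#' baseline window), pre-exacerbation (days -14..-1) and post-exacerbation
#' recovery (days +1..+13) — in the variable's raw units. The treatment day
#' itself (day 0) is reported separately and belongs to neither phase by
#' default, following the convention that recovery runs from day 1.
#'
#' The omnibus test is one-way ANOVA, switching to Kruskal-Wallis when a
#' Shapiro-Wilk check on the residuals rejects normality (or when forced
#' via `test`); pairwise post-hoc comparisons use the matching t or
#' rank-sum tests without multiplicity adjustment. Day-to-day variability
#' is compared between the stable and pre-exacerbation phases with a
#' variance-ratio (F) test. With identical values everywhere the omnibus
#' statistic is 0 with p = 1 (no evidence of any difference).
#'
#' @param aligned output of [align_to_event()].
#' @param stable_values output of [stable_phase_values()].
#' @param variable one of `"HR"`, `"SpO2"`, `"CAT"`, `"PEF"`.
#' @param test `"auto"` (default), `"anova"` or `"kruskal"`.
#' @param include_day0_in_post count day 0 into the post phase
#'   (default `FALSE`).
#' @return object of class `copd_phases`: a list with `variable`,
#'   `summary` (per-phase n/mean/sd), `day0` (mean across patients),
#'   `omnibus` (method, statistic, p_value), `pairwise` (per-pair p
#'   values), `variance_test` (stable vs pre SD ratio and p).
#' @export
phase_summaries <- function(aligned, stable_values, variable,
                            test = c("auto", "anova", "kruskal"),
                            include_day0_in_post = FALSE) {
  test <- match.arg(test)
  variable <- match.arg(variable, VARIABLES)
  pre <- aligned |>
    filter(.data$variable == !!variable, .data$day_index >= -14,
           .data$day_index <= -1)
  post_lo <- if (include_day0_in_post) 0L else 1L
  post <- aligned |>
    filter(.data$variable == !!variable, .data$day_index >= post_lo,
           .data$day_index <= 13)
  day0 <- aligned |>
    filter(.data$variable == !!variable, .data$day_index == 0)
  stable <- filter(stable_values, .data$variable == !!variable)

  df <- bind_rows(
    tibble(phase = "stable", value = stable$value),
    tibble(phase = "pre", value = pre$value),
    tibble(phase = "post", value = post$value)
  ) |>
    filter(is.finite(.data$value)) |>
    mutate(phase = factor(.data$phase, levels = c("stable", "pre", "post")))

  summary <- df |>
    summarise(n = dplyr::n(), mean = mean(.data$value),
              sd = sd(.data$value), .by = "phase") |>
    arrange(.data$phase)

  populated <- summary$n >= 2
  if (sum(populated) < 2) {
    omnibus <- list(method = "none", statistic = NA_real_,
                    p_value = NA_real_)
    pairwise <- tibble(comparison = character(), p_value = numeric())
  } else if (sd(df$value) == 0) {
    omnibus <- list(method = "degenerate", statistic = 0, p_value = 1)
    pairwise <- tibble(comparison = character(), p_value = numeric())
  } else {
    use_kruskal <- test == "kruskal" ||
      (test == "auto" && !residuals_look_normal(df))
    if (use_kruskal) {
      kt <- kruskal.test(value ~ phase, data = df)
      omnibus <- list(method = "kruskal-wallis",
                      statistic = unname(kt$statistic),
                      p_value = kt$p.value)
      pw <- suppressWarnings(
        pairwise.wilcox.test(df$value, df$phase, p.adjust.method = "none",
                             exact = FALSE))
    } else {
      fit <- aov(value ~ phase, data = df)
      an <- summary(fit)[[1]]
      omnibus <- list(method = "anova", statistic = an$`F value`[1],
                      p_value = an$`Pr(>F)`[1])
      pw <- pairwise.t.test(df$value, df$phase, p.adjust.method = "none")
    }
    pairwise <- as.data.frame(as.table(pw$p.value)) |>
      filter(!is.na(.data$Freq)) |>
      transmute(comparison = paste(.data$Var2, "vs", .data$Var1),
                p_value = .data$Freq) |>
      as_tibble()
  }

  variance_test <- local({
    s <- df$value[df$phase == "stable"]
    p <- df$value[df$phase == "pre"]
    if (length(s) >= 2 && length(p) >= 2 && sd(s) > 0 && sd(p) > 0) {
      vt <- var.test(p, s)
      list(sd_stable = sd(s), sd_pre = sd(p),
           f_ratio = unname(vt$statistic), p_value = vt$p.value)
    } else {
      list(sd_stable = if (length(s) >= 2) sd(s) else NA_real_,
           sd_pre = if (length(p) >= 2) sd(p) else NA_real_,
           f_ratio = NA_real_, p_value = NA_real_)
    }
  })

  structure(list(
    variable = variable,
    summary = summary,
    day0 = list(n = nrow(day0),
                mean = if (nrow(day0)) mean(day0$value) else NA_real_),
    omnibus = omnibus,
    pairwise = pairwise,
    variance_test = variance_test
  ), class = "copd_phases")
}

# Shapiro-Wilk on centred residuals; capped at its n = 5000 limit
residuals_look_normal <- function(df, alpha = 0.05) {
  res <- df$value - ave(df$value, df$phase)
  if (length(res) < 3 || sd(res) == 0) return(TRUE)
  if (length(res) > 5000) res <- res[seq(1, length(res), length.out = 5000)]
  shapiro.test(res)$p.value >= alpha
}

#' @export
print.copd_phases <- function(x, ...) {
  cat(sprintf("<copd_phases> %s\n", x$variable))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-7s n=%4d  mean %8.2f  sd %6.3f\n",
                as.character(s$phase[i]), s$n[i], s$mean[i], s$sd[i]))
  }
  cat(sprintf("  day 0: mean %s (n=%d)\n",
              format(x$day0$mean, digits = 4), x$day0$n))
  cat(sprintf("  omnibus %s: statistic %.3f, p = %.3g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p_value))
  cat(sprintf("  variability stable vs pre: SD %.3f vs %.3f, F p = %.3g\n",
              x$variance_test$sd_stable, x$variance_test$sd_pre,
              x$variance_test$p_value))
  invisible(x)
}

#' @export
tidy.copd_phases <- function(x, ...) {
  mutate(x$summary, variable = x$variable, .before = 1)
}

#' @export
glance.copd_phases <- function(x, ...) {
  tibble(variable = x$variable, method = x$omnibus$method,
         statistic = x$omnibus$statistic, p_value = x$omnibus$p_value,
         sd_stable = x$variance_test$sd_stable,
         sd_pre = x$variance_test$sd_pre,
         var_p_value = x$variance_test$p_value,
         day0_mean = x$day0$mean)
}
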