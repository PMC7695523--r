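#' Group mean Z-score trajectory, event-aligned
#'
#' Arithmetic mean of the available per-patient Z scores for each day index
#' (-15..+13), the figure-style summary of exacerbation trajectories: day
#' -15 carries the stable-period mean (Z = 0), days -14..-1 the
#' pre-exacerbation drift, day 0 the treatment start, days +1..+13 the
#' recovery. When a manifest is supplied, trajectories are computed per
#' monitoring arm.
#'
#' @param z output of [zseries()].
#' @param manifest optional tibble with `patient_id`, `arm` to split
#'   trajectories by arm.
#' @return tibble of class `copd_trajectory` with `variable`, (`arm`,)
#'   `day_index`, `mean_z`, `n_patients`; days with no data are omitted.
#' @export
group_z_trajectory <- function(z, manifest = NULL) {
  if (!is.null(manifest)) {
    z <- inner_join(z, select(manifest, "patient_id", "arm"),
                    by = "patient_id")
    groups <- c("variable", "arm", "day_index")
  } else {
    groups <- c("variable", "day_index")
  }
  out <- z |>
    filter(!is.na(.data$z)) |>
    summarise(mean_z = mean(.data$z), n_patients = dplyr::n(),
              .by = dplyr::all_of(groups)) |>
    arrange(factor(.data$variable, levels = VARIABLES_Z), .data$day_index)
  structure(out, class = c("copd_trajectory", class(tibble())))
}

#' Plot event-aligned mean Z trajectories
#'
#' One panel per variable: x is the day index (-15..+13, day -15 the
#' stable mean, day 0 treatment start), y the group mean Z score, with
#' horizontal reference lines at the +-`threshold` significance band.
#'
#' @param trajectory output of [group_z_trajectory()].
#' @param threshold reference band in SD units (default 1.96).
#' @return a ggplot object.
#' @export
plot_z_trajectory <- function(trajectory, threshold = 1.96) {
  has_arm <- "arm" %in% names(trajectory)
  p <- ggplot(trajectory,
              aes(x = .data$day_index, y = .data$mean_z,
                  colour = if (has_arm) .data$arm else NULL)) +
    geom_hline(yintercept = c(-threshold, threshold),
               colour = "red", linetype = "dashed", linewidth = 0.3) +
    geom_hline(yintercept = 0, colour = "grey60", linewidth = 0.2) +
    geom_vline(xintercept = 0, colour = "grey60", linetype = "dotted") +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~ factor(variable, levels = VARIABLES_Z), scales = "free_y") +
    labs(x = "day relative to treatment start",
         y = "mean Z score (baseline SD units)",
         colour = if (has_arm) "arm" else NULL) +
    theme_minimal(base_size = 10)
  p
}

#' @export
autoplot.copd_trajectory <- function(object, threshold = 1.96, ...) {
  plot_z_trajectory(object, threshold = threshold)
}
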