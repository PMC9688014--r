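#' Plot helpers
#'
#' Minimal ggplot2 summaries of the main result types: Kaplan-Meier step
#' curves, WE pathway score bars, and alteration-frequency densities
#' (ridgeline-style, one panel per alteration class).
#'
#' @param object,x Result object.
#' @param ... Ignored.
#' @name rin_plots
NULL

#' @rdname rin_plots
#' @exportS3Method ggplot2::autoplot
autoplot.rin_km <- function(object, ...) {
  d <- tidy(object)
  d0 <- bind_rows(tibble(time = 0, survival = 1),
                  select(d, "time", "survival"))
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' @rdname rin_plots
#' @param km_list Named list of `rin_km` fits (e.g. High/Low arms).
#' @export
plot_survival <- function(km_list, ...) {
  d <- purrr::imap_dfr(km_list, function(fit, nm) {
    mutate(bind_rows(tibble(time = 0, survival = 1), select(tidy(fit), "time", "survival")),
           arm = nm)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  color = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days", y = "Survival probability", color = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname rin_plots
#' @param we WE score table from [we_scores()].
#' @export
plot_we_scores <- function(we, ...) {
  ggplot2::ggplot(we, ggplot2::aes(x = stats::reorder(.data$pathway, .data$we),
                                   y = .data$we)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "WE score (High vs Low)") +
    ggplot2::theme_minimal()
}

#' @rdname rin_plots
#' @param freqs Alteration-frequency table from [alteration_frequencies()].
#' @export
plot_alteration_frequencies <- function(freqs, ...) {
  ggplot2::ggplot(freqs, ggplot2::aes(x = .data$frequency, color = .data$cohort)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~alteration, scales = "free_y") +
    ggplot2::labs(x = "Per-gene alteration frequency", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
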