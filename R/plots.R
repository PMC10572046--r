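# ggplot2 views of the main result types.

#' Phase-plane portrait
#'
#' Nullclines, steady states and (when bistable) the separatrix of the
#' dimensionless model on the unit square.
#'
#' @param clusters A [ric_clusters] object.
#' @param states Optional precomputed [find_steady_states()] result.
#' @param separatrix Optional precomputed [compute_separatrix()] result.
#' @return A ggplot object.
#' @export
plot_phase_plane <- function(clusters, states = NULL, separatrix = NULL) {
  if (is.null(states)) states <- find_steady_states(clusters)
  if (is.null(separatrix)) {
    separatrix <- compute_separatrix(clusters, states = states)
  }
  nc <- nullclines(clusters)
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = nc,
                       ggplot2::aes(.data$X, .data$Y, colour = .data$curve),
                       linetype = "dashed") +
    ggplot2::geom_point(
      data = states,
      ggplot2::aes(.data$X, .data$Y, shape = .data$stability),
      size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "relative cancer burden X",
                  y = "relative infection burden Y",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(separatrix)) {
    p <- p + ggplot2::geom_path(data = separatrix$points,
                                ggplot2::aes(.data$X, .data$Y),
                                colour = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname scan_alpha
#' @param object A `ric_bifurcation` object.
#' @param ... Unused.
#' @method autoplot ric_bifurcation
#' @export
autoplot.ric_bifurcation <- function(object, ...) {
  br <- tidyr::pivot_longer(object$branches, c("X", "Y"),
                            names_to = "axis", values_to = "burden")
  ggplot2::ggplot(br, ggplot2::aes(.data$alpha, .data$burden,
                                   colour = .data$role,
                                   linetype = .data$stability)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::geom_vline(xintercept = object$sn_points$alpha,
                        colour = "grey40", linetype = "dotted") +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(x = "naive T-cell production rate alpha",
                  y = "equilibrium burden") +
    ggplot2::theme_minimal()
}

#' @rdname escape_curve
#' @param object A `ric_escape` object.
#' @param ... Unused.
#' @method autoplot ric_escape
#' @export
autoplot.ric_escape <- function(object, ...) {
  cv <- dplyr::filter(object$curve, is.finite(.data$probability))
  ggplot2::ggplot(cv, ggplot2::aes(.data$age, .data$probability)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "cyan3") +
    ggplot2::labs(x = "age (years)",
                  y = if (object$calibrated) "escape probability (%/year)"
                      else "escape probability (a.u.)") +
    ggplot2::theme_minimal()
}

#' @rdname simulate_treated
#' @param object A `ric_treatment` object.
#' @param ... Unused.
#' @method autoplot ric_treatment
#' @export
autoplot.ric_treatment <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("X", "Y", "alpha"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "dimensionless time T") +
    ggplot2::theme_minimal()
}

#' @rdname fit_prevalence_slope
#' @param object A `ric_prevalence_fit` object.
#' @method autoplot ric_prevalence_fit
#' @export
autoplot.ric_prevalence_fit <- function(object, ...) {
  tb <- object$table
  ggplot2::ggplot(tb, ggplot2::aes(.data$age_mid, .data$prevalence)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$prevalence - .data$se,
                                        ymax = .data$prevalence + .data$se),
                           width = 1, colour = "red") +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$used), colour = "blue") +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope_per_year, colour = "cyan3") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "age (years)", y = "prevalence (%)") +
    ggplot2::theme_minimal()
}

#' Baseline versus follow-up allele burden
#'
#' Scatter of follow-up against baseline VAF for re-invited subjects, with
#' the diagonal of no change; undiagnosed subjects below the diagonal are
#' the non-progressing group.
#'
#' @param cohort A cohort tibble (see [generate_screening_cohort()]).
#' @return A ggplot object.
#' @export
plot_cohort_vaf <- function(cohort) {
  cc <- dplyr::filter(tibble::as_tibble(cohort), .data$survived,
                      is.finite(.data$vaf_followup))
  cc$status <- ifelse(cc$diagnosed_interim | cc$diagnosed_at_followup,
                      "diagnosed", "undiagnosed")
  ggplot2::ggplot(cc, ggplot2::aes(.data$vaf_baseline, .data$vaf_followup,
                                   colour = .data$status,
                                   shape = .data$status)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "baseline VAF (%)", y = "follow-up VAF (%)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
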