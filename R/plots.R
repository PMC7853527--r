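#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   labs facet_wrap theme_minimal geom_hline
#' @export
ggplot2::autoplot

#' @export
autoplot.pe_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble(E = seq(0, max(object$data$E) * 1.05, length.out = n_grid))
  grid$P <- predict(object, grid$E)
  ggplot(object$data, aes(x = .data$E, y = .data$P)) +
    geom_point() +
    geom_line(data = grid, colour = "steelblue") +
    labs(x = expression(paste("E (", mu, "mol photons ", m^-2, " ", s^-1, ")")),
         y = "response",
         title = sprintf("P-E fit (%s)", object$model_form)) +
    theme_minimal()
}

#' @export
autoplot.kd_fit <- function(object, ...) {
  zmax <- max(object$layer_breaks) * 2 + 5
  z <- seq(0, zmax, length.out = 100)
  d <- tibble(depth = z, E = par_at_depth(object, z))
  ggplot(d, aes(x = .data$E, y = .data$depth)) +
    geom_line() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_x_log10() +
    labs(x = "PAR", y = "depth (m)", title = "Fitted light attenuation") +
    theme_minimal()
}

#' @export
autoplot.phi_glm <- function(object, ...) {
  d <- object$terms %>% filter(.data$term != "(Intercept)")
  ggplot(d, aes(x = stats::reorder(.data$term, .data$estimate),
                y = .data$estimate)) +
    geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(aes(ymin = .data$estimate - .data$std_error,
                               ymax = .data$estimate + .data$std_error),
                           width = 0.2) +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "coefficient (log-link, standardised covariates)") +
    theme_minimal()
}

#' Diagnostic plots for a pipeline run
#'
#' `plot_phi_by_date()` shows the distribution of the electron requirement
#' per date and basin; `plot_gpp_comparison()` shows FRRf-derived against
#' 13C-derived daily productivity with the 1:1 line.
#'
#' @param run a `phiec_run` from [run_pipeline()].
#' @return a ggplot object.
#' @export
plot_phi_by_date <- function(run) {
  ggplot(run$phi_records,
         aes(x = .data$date, y = .data$phi_e_c)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    geom_hline(yintercept = 4, linetype = "dashed", colour = "grey40") +
    facet_wrap(~basin, scales = "free_x") +
    ggplot2::scale_y_log10() +
    labs(x = NULL, y = expression(Phi["e,C"]~"(mol e"^-{}~"mol C"^-1*")")) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_phi_by_date
#' @param model which fitted requirement model's GPP to plot.
#' @export
plot_gpp_comparison <- function(run, model = "best") {
  col <- paste0("gpp_f_", model)
  d <- run$gpp
  ggplot(d, aes(x = .data$gpp_13c, y = .data[[col]], colour = .data$basin)) +
    geom_point(size = 2) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = expression(GPP["13C"]~"(mg C"~m^-2~d^-1*")"),
         y = expression(GPP[f]~"(mg C"~m^-2~d^-1*")")) +
    theme_minimal()
}
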