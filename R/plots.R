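#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot simulation observables
#'
#' Time courses of outgrowth, recruitment limit and cell counts from a
#' simulation.
#'
#' @param object A `regen_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regen_sim <- function(object, ...) {
  ob <- object$observables |>
    dplyr::select("t_days", "outgrowth", "xi", "n_cells", "n_recruited") |>
    tidyr::pivot_longer(-"t_days", names_to = "observable")
  ggplot2::ggplot(ob, ggplot2::aes(.data$t_days, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time post-amputation (days)", y = NULL)
}

#' Plot a cell snapshot
#'
#' Discs at the cell positions in amputation-plane coordinates, coloured
#' by recruitment status; the amputation plane is the dashed line at
#' `z = 0`.
#'
#' @param cells A snapshot tibble (e.g. an element of `sim$snapshots` or
#'   `sim$cells`) with columns `z`, `y`, `recruited`.
#' @param R Cell radius (um), used for the point size scale only.
#' @return A ggplot.
#' @export
plot_cells <- function(cells, R = 7) {
  ggplot2::ggplot(cells, ggplot2::aes(.data$z, .data$y,
                                      colour = .data$recruited)) +
    ggplot2::geom_point(size = R / 4) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::coord_fixed() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "AP position z (um)", y = "circumference (um)")
}

#' Plot a spatial phase profile
#'
#' Fractions of cells in the pooled G0/G1 and S/G2 channels along the AP
#' axis, as produced by [phase_profile()].
#'
#' @param profile A tibble from [phase_profile()].
#' @return A ggplot.
#' @export
plot_phase_profile <- function(profile) {
  pr <- profile |>
    tidyr::pivot_longer(c("frac_g0g1", "frac_sg2"), names_to = "channel") |>
    dplyr::mutate(channel = dplyr::recode(.data$channel,
                                          frac_g0g1 = "G0/G1",
                                          frac_sg2 = "S/G2"))
  ggplot2::ggplot(pr, ggplot2::aes(.data$z_mid, .data$value,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`G0/G1` = "forestgreen",
                                            `S/G2` = "magenta3")) +
    ggplot2::labs(x = "AP position z (um)", y = "fraction of cells",
                  colour = NULL) +
    ggplot2::ylim(0, 1)
}

#' Plot a fit sweep
#'
#' Error landscape over the `(D, k)` grid with the accepted set
#' highlighted and iso-characteristic-length annotated by point size.
#'
#' @param object A `regen_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regen_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$D, .data$k, fill = log10(.data$error))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(tidy(object), .data$accepted),
                        shape = 21, colour = "white", size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "D (um^2/s)", y = "k (1/day)",
                  fill = "log10 error")
}
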