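#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an H-bond frequency-over-distance profile
#'
#' Frequency per donor-acceptor distance bin; empty bins (no frames) are
#' omitted rather than drawn at zero.
#'
#' @param object An [hbond_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hbond_profile
#' @export
autoplot.hbond_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$n_frames > 0, ]
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$frequency)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_frames), alpha = 0.6) +
    ggplot2::scale_size_continuous(name = "frames") +
    ggplot2::labs(x = "donor-acceptor distance (Å)",
                  y = "H-bond frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a face series as a per-frame label strip plus counts
#'
#' @param object A [face_series()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot face_series
#' @export
autoplot.face_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = 1, fill = .data$face)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(re = "#D55E00", si = "#0072B2",
                                          indeterminate = "grey70"),
                               drop = FALSE) +
    ggplot2::labs(x = "frame", y = NULL,
                  title = "Prochiral face toward the nearest hydride") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot mean contact frequencies per residue and system
#'
#' @param object A [contact_report()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot contact_report
#' @export
autoplot.contact_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$residue <- factor(df$residue)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$mean_frequency,
                                   fill = .data$system)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "residue", y = "mean contact frequency (< cutoff)",
                  fill = "system") +
    ggplot2::theme_minimal()
}
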