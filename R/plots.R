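# Plot methods. Convenience visualisations; not part of the numerical
# contract of the package.

#' Plot a cleavage-aligned frequency matrix
#'
#' Stacked per-position residue frequencies around the cleavage site (the
#' data behind a frequency-style sequence logo).
#'
#' @param object An [frequency_matrix()] result.
#' @param min_freq Residues below this frequency at a position are pooled
#'   into "other" to keep the legend readable. Default 0.05.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sp_freq_matrix
#' @export
autoplot.sp_freq_matrix <- function(object, min_freq = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$freq) & df$freq > 0, ]
  df$residue <- ifelse(df$freq < min_freq, "other", df$residue)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$position, levels = sort(unique(.data$position))),
    y = .data$freq, fill = .data$residue
  )) +
    ggplot2::geom_col(position = "stack", colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = sum(unique(df$position) < 0) + 0.5,
                        linetype = 2) +
    ggplot2::labs(x = "position relative to cleavage site",
                  y = "residue frequency", fill = "residue") +
    ggplot2::theme_minimal()
}

#' Plot an emPAI abundance ranking
#'
#' @param object A `protein_quant` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot protein_quant
#' @export
autoplot.protein_quant <- function(object, ...) {
  df <- tibble::as_tibble(tidy(object))
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$empai)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "abundance rank", y = "emPAI") +
    ggplot2::theme_minimal()
}

#' Plot the N-terminal hydropathy profile of a sequence
#'
#' Windowed Kyte-Doolittle profile with the hydrophobicity threshold used
#' for h-region detection.
#'
#' @param seq Amino-acid string.
#' @param params A [sp_classifier_params()] object.
#' @param n_terminal Number of N-terminal residues to show (default 40).
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(seq, params = sp_classifier_params(),
                            n_terminal = 40) {
  prefix <- substr(seq, 1, min(nchar(seq), n_terminal))
  df <- tibble::tibble(
    position = seq_len(nchar(prefix)),
    score = hydropathy_profile(prefix, params$hydropathy_window)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = params$hydropathy_threshold,
                        linetype = 2) +
    ggplot2::labs(x = "residue position", y = "windowed hydropathy") +
    ggplot2::theme_minimal()
}
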