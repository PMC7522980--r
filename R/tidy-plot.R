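#' Tidy a diffusion result
#'
#' @param x A `diffusion_result`.
#' @param ... Unused.
#' @return Long tibble with genome_id, variable (integer index), entry.
#' @method tidy diffusion_result
#' @export
tidy.diffusion_result <- function(x, ...) {
  tibble::as_tibble(x$variables, rownames = "genome_id") |>
    tidyr::pivot_longer(-"genome_id", names_to = "variable", values_to = "entry") |>
    dplyr::mutate(variable = as.integer(sub("^v", "", .data$variable)))
}

#' One-row summaries per diffusion variable
#'
#' @param x A `diffusion_result`.
#' @param ... Unused.
#' @return Tibble with variable, eigenvalue, localization (IPR).
#' @method glance diffusion_result
#' @export
glance.diffusion_result <- function(x, ...) {
  tibble::tibble(variable = seq_len(ncol(x$variables)),
                 eigenvalue = x$eigenvalues[-1L],
                 localization = unname(x$localization))
}

#' Scatter two diffusion variables
#'
#' @param object A `diffusion_result`.
#' @param vars Length-2 integer vector of variable indices (default 1:2).
#' @param labels Optional per-genome grouping vector for color.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diffusion_result
#' @export
autoplot.diffusion_result <- function(object, vars = c(1L, 2L), labels = NULL, ...) {
  df <- tibble::tibble(genome_id = object$genome_ids,
                       x = object$variables[, vars[1L]],
                       y = object$variables[, vars[2L]])
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  } else {
    df$group <- labels
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("diffusion variable %d", vars[1L]),
                  y = sprintf("diffusion variable %d", vars[2L]))
}

#' Eigenvalue scree plot
#'
#' @param R A `diffusion_result`.
#' @return A ggplot of ascending non-trivial eigenvalues (variable importance).
#' @export
plot_eigenvalues <- function(R) {
  ggplot2::ggplot(glance(R), ggplot2::aes(x = .data$variable, y = .data$eigenvalue)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "diffusion variable", y = "Laplacian eigenvalue")
}

#' Heatmap of an ecosystem fingerprint
#'
#' @param object A `fingerprint`.
#' @param ... Unused.
#' @return A ggplot tile map, ecosystems x niches.
#' @method autoplot fingerprint
#' @export
autoplot.fingerprint <- function(object, ...) {
  ggplot2::ggplot(tidy.fingerprint(object),
                  ggplot2::aes(x = .data$niche_id, y = .data$ecosystem_label,
                               fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue", limits = c(0, 1)) +
    ggplot2::labs(x = "niche (variable extremum)", y = "ecosystem",
                  fill = "proportion\nof samples") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Volcano-style view of an enrichment table
#'
#' @param object An `enrichment_table`.
#' @param ... Unused.
#' @return A ggplot of ES vs -log10 adjusted p.
#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$es, y = -log10(.data$p_adj),
                                       colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "enrichment score", y = expression(-log[10]~p[adj]))
}
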