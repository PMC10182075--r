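#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of pairwise genetic correlations
#'
#' @param object A `genetic_covariance` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot genetic_covariance
#' @export
autoplot.genetic_covariance <- function(object, ...) {
  R <- rg_matrix(object)
  df <- tidyr::expand_grid(trait_a = rownames(R), trait_b = colnames(R)) |>
    dplyr::mutate(rg = as.vector(t(R)))
  ggplot2::ggplot(df, ggplot2::aes(.data$trait_a, .data$trait_b, fill = .data$rg)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rg)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  high = "firebrick", mid = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "rg",
                  title = "Pairwise genetic correlations") +
    ggplot2::theme_minimal()
}

#' Bar chart of standardized factor loadings
#'
#' @param object A `factor_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot factor_fit
#' @export
autoplot.factor_fit <- function(object, ...) {
  td <- tidy(object) |> dplyr::filter(.data$type == "loading")
  parts <- strsplit(td$term, " =~ ")
  td$factor <- vapply(parts, `[`, "", 1)
  td$trait <- vapply(parts, `[`, "", 2)
  ggplot2::ggplot(td, ggplot2::aes(.data$trait, .data$std_estimate,
                                   fill = .data$factor)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ factor, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "standardized loading",
                  title = sprintf("%s model (CFI %.3f, SRMR %.3f)",
                                  object$spec$name, object$cfi, object$srmr)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Manhattan-style plot of a factor GWAS
#'
#' @param gwas A factor GWAS tibble (columns CHR, BP, P).
#' @param p_sig Genome-wide line (default 5e-8).
#' @param p_seed Region-seed line (default 1e-6).
#' @return A ggplot.
#' @export
plot_manhattan <- function(gwas, p_sig = 5e-8, p_seed = 1e-6) {
  ggplot2::ggplot(gwas, ggplot2::aes(.data$BP / 1e6, -log10(.data$P))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(p_sig), colour = "firebrick",
                        linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(p_seed), colour = "steelblue",
                        linetype = 3) +
    ggplot2::facet_grid(. ~ CHR, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Posterior-probability bars for colocalization results
#'
#' @param object A `coloc_result` (one row) or a tibble of results with
#'   pp0..pp4 columns.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coloc_result
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("pp0", "pp1", "pp2", "pp3", "pp4")],
    dplyr::everything(), names_to = "hypothesis", values_to = "pp"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$hypothesis, .data$pp)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = 0.9, linetype = 2, colour = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal()
}
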