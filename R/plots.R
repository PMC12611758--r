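# ggplot2 figures.

#' Plot a mutational catalogue or corrected spectrum
#'
#' @param catalogue a `mut_catalogue` or a tibble with `channel` and `count`
#'   or `prob`.
#' @return a ggplot.
#' @export
plot_spectrum <- function(catalogue) {
  df <- as_tibble(catalogue)
  ycol <- if ("count" %in% names(df)) "count" else "prob"
  df$channel <- factor(df$channel, levels = df$channel)
  sys <- attr(catalogue, "system") %||% ""
  if (sys %in% c("SBS96", "")) {
    df$group <- stringr::str_extract(as.character(df$channel), "[ACGT]>[ACGT]")
  } else {
    df$group <- sub(":.*$", "", as.character(df$channel))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data[[ycol]],
                                   fill = .data$group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(~group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = if (ycol == "count") "mutations" else
      "probability", title = sys) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 4))
}

#' Plot burdens against age with the fitted regression
#'
#' @param burdens tibble with `age`, `burden` and optionally `lower`,
#'   `upper`.
#' @param fit optional [regress_burden_on_age()] result to overlay.
#' @return a ggplot.
#' @export
plot_burden_age <- function(burdens, fit = NULL) {
  df <- as_tibble(burdens)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$burden)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "age (years)", y = "mutation burden") +
    ggplot2::theme_minimal()
  if (all(c("lower", "upper") %in% names(df))) {
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                                 ymax = .data$upper),
                                    width = 0, alpha = 0.4)
  }
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(intercept = fit$intercept,
                                  slope = fit$slope, colour = "firebrick")
  }
  p
}

#' Plot per-gene dN/dS ratios with CIs
#'
#' @param selection a [gene_dnds()] result.
#' @param impact impact class to show.
#' @param q_threshold label genes below this two-sided q-value.
#' @return a ggplot.
#' @export
plot_gene_selection <- function(selection, impact = "all_nonsynonymous",
                                q_threshold = 0.05) {
  df <- as_tibble(selection)
  df <- df[df$impact == impact, ]
  df <- arrange(df, .data$omega)
  df$gene_id <- factor(df$gene_id, levels = df$gene_id)
  df$significant <- df$q_two_sided < q_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$omega,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "dN/dS (omega)", colour = "significant",
                  title = impact) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a gene's site-level mutation map
#'
#' Mutation recurrence along the coding sequence, coloured by consequence,
#' with duplex coverage shading.
#'
#' @param site_results `sites` element of a [site_dnds()] result for one
#'   gene.
#' @param coverage optional coverage profile to shade.
#' @return a ggplot.
#' @export
plot_site_map <- function(site_results, coverage = NULL) {
  df <- as_tibble(site_results)
  df <- df[df$k > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$k,
                                        fill = .data$impact))
  if (!is.null(coverage)) {
    cov <- as_tibble(coverage)
    cov <- cov[cov$contig %in% unique(site_results$contig), ]
    sc <- max(df$k, 1) / max(cov$depth, 1)
    p <- p + ggplot2::geom_area(data = cov,
                                ggplot2::aes(x = .data$pos,
                                             y = .data$depth * sc),
                                inherit.aes = FALSE, fill = "grey85")
  }
  p + ggplot2::geom_col() +
    ggplot2::labs(x = "position", y = "mutant molecules") +
    ggplot2::theme_minimal()
}
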