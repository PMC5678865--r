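#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_tile
#'   geom_point labs scale_fill_gradient2 facet_wrap
#' @export
ggplot2::autoplot

#' Tidy experiment results
#'
#' `tidy()` returns the per-timepoint (or per-composition) observations as
#' one tibble; `glance()` returns a one-row run summary.
#'
#' @param x a `setup1_result`, `setup2_result` or `sweep_result`.
#' @param ... unused.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.setup1_result <- function(x, ...) {
  dplyr::mutate(x$gradient, metric = "cell_derived",
                isoform = x$isoform, .before = 1)
}

#' @rdname tidiers
#' @export
glance.setup1_result <- function(x, ...) {
  tibble(isoform = x$isoform,
         final_gradient_nM_per_um = x$final_gradient,
         time_to_steady_h = x$time_to_steady_h,
         converged = x$converged,
         total_cxcl12_nM_voxels = x$total$total_nM_voxels[nrow(x$total)],
         n_secreting = x$config$clusters$n_secreting,
         n_scavenging = x$config$clusters$n_scavenging)
}

#' @rdname tidiers
#' @export
tidy.setup2_result <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$gradients, "time_h", "metric", "value_nM_per_um", "sign"),
    isoform = x$isoform, .before = 1)
}

#' @rdname tidiers
#' @export
glance.setup2_result <- function(x, ...) {
  g <- x$gradients
  peak <- function(m) {
    v <- g$value_nM_per_um[g$metric == m]
    v[which.max(abs(v))]
  }
  tibble(isoform = x$isoform,
         max_blood_tissue = peak("blood_tissue"),
         max_endothelial_tissue = peak("endothelial_tissue"),
         sign_constant = all(c(
           length(unique(sign(g$value_nM_per_um[g$metric == "blood_tissue"]))) == 1,
           length(unique(sign(g$value_nM_per_um[g$metric == "endothelial_tissue"]))) == 1)),
         stage1_hours = x$stage1_hours,
         stage1_converged = x$stage1_converged)
}

#' @rdname tidiers
#' @export
tidy.sweep_result <- function(x, ...) {
  dplyr::mutate(x$summary, isoform = x$isoform, .before = 1)
}

#' @rdname tidiers
#' @export
glance.sweep_result <- function(x, ...) {
  s <- x$summary
  tibble(isoform = x$isoform,
         n_compositions = nrow(s),
         strongest_into_tissue = max(c(s$value, 0)),
         strongest_into_blood = min(c(s$value, 0)),
         frac_into_blood = mean(s$value < 0))
}

#' Plot experiment results
#'
#' Time-course of the inter-cluster gradient (`setup1_result`), the
#' circadian-stage gradient traces with the 0.002 nM/um chemotactic
#' threshold (`setup2_result`), or the signed max-gradient heatmap over the
#' composition sweep (`sweep_result`).
#'
#' @param object a result object.
#' @param ... unused.
#' @return a ggplot.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.setup1_result <- function(object, ...) {
  ggplot(object$gradient, aes(x = .data$time_h, y = .data$value)) +
    geom_line() +
    labs(x = "time (h)", y = "cell-derived gradient (nM/µm)",
         title = sprintf("CXCL12-%s inter-cluster gradient", object$isoform))
}

#' @rdname plots
#' @export
autoplot.setup2_result <- function(object, ...) {
  ggplot(object$gradients,
         aes(x = .data$time_h, y = .data$value_nM_per_um,
             colour = .data$metric)) +
    geom_hline(yintercept = c(-0.002, 0, 0.002),
               linetype = c("dotted", "solid", "dotted"),
               colour = "grey40") +
    geom_line() +
    labs(x = "clock time (h)", y = "gradient (nM/µm)",
         title = sprintf("CXCL12-%s gradients over the circadian stage",
                         object$isoform))
}

#' @rdname plots
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot(object$summary,
         aes(x = factor(.data$n_secreting), y = factor(.data$n_scavenging),
             fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         midpoint = 0) +
    labs(x = "CXCL12-secreting cells", y = "CXCR7+ cells",
         fill = "max gradient\n(nM/µm)",
         title = sprintf("CXCL12-%s signed max blood-tissue gradient",
                         object$isoform))
}

#' @export
print.setup1_result <- function(x, ...) {
  cat(sprintf(
    "<setup1_result> CXCL12-%s: final gradient %.4g nM/um, %s (t_ss = %s h)\n",
    x$isoform, x$final_gradient,
    if (x$converged) "steady" else "not converged",
    format(x$time_to_steady_h, digits = 3)))
  invisible(x)
}

#' @export
print.setup2_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<setup2_result> CXCL12-%s: max blood-tissue %.4g, max endothelial-tissue %.4g nM/um, sign %s\n",
    x$isoform, g$max_blood_tissue, g$max_endothelial_tissue,
    if (g$sign_constant) "constant" else "changes"))
  invisible(x)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> CXCL12-%s, %d compositions\n",
              x$isoform, nrow(x$summary)))
  print(x$summary, n = 10)
  invisible(x)
}
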