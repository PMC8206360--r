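#' Tidy a BIC cluster scan
#'
#' @param x A `bic_scan`.
#' @param ... Unused.
#' @return Tibble `k`, `wss`, `bic`, `delta_bic` (improvement to the
#'   next K; `NA` at `k_max`).
#' @export
tidy.bic_scan <- function(x, ...) x$scan

#' @rdname tidy.bic_scan
#' @export
glance.bic_scan <- function(x, ...) {
  tibble::tibble(k_best = x$k_best, bic_min = min(x$scan$bic), n = x$n)
}

#' Tidy a PCA basis
#'
#' @param x A `pca_basis`.
#' @param ... Unused.
#' @return Tibble `component`, `eigenvalue`, `variance_fraction`,
#'   `cumulative_fraction` (fractions of the total variance of the
#'   input matrix).
#' @export
tidy.pca_basis <- function(x, ...) {
  vf <- x$eigenvalues / x$total_variance
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = vf,
    cumulative_fraction = cumsum(vf)
  )
}

#' Tidy a fitted DAPC
#'
#' @param x A `dapc`.
#' @param ... Unused.
#' @return Long tibble of training-sample discriminant coordinates:
#'   `sample`, `group`, `axis`, `coordinate`.
#' @export
tidy.dapc <- function(x, ...) {
  da <- x$scores_da
  out <- tibble::tibble(
    sample = rep(seq_len(nrow(da)), times = ncol(da)),
    group = rep(as.character(x$labels), times = ncol(da)),
    axis = rep(seq_len(ncol(da)), each = nrow(da)),
    coordinate = as.vector(da)
  )
  out
}

#' @rdname tidy.dapc
#' @export
glance.dapc <- function(x, ...) {
  acc <- reassignment_accuracy(dapc_predict(x, x$scores_pc), x$labels)
  tibble::tibble(
    n_groups = length(x$group_labels), n_pcs = x$n_pcs, n_da = x$n_da,
    reassignment_accuracy = acc$overall
  )
}

#' Tidy a DAPC assignment
#'
#' @param x A `dapc_assignment`.
#' @param ... Unused.
#' @return Long tibble `sample`, `group`, `posterior`, `assigned`.
#' @export
tidy.dapc_assignment <- function(x, ...) {
  post <- x$posterior
  tibble::tibble(
    sample = rep(seq_len(nrow(post)), times = ncol(post)),
    group = rep(colnames(post), each = nrow(post)),
    posterior = as.vector(post),
    assigned = rep(as.character(x$assigned), times = ncol(post))
  )
}

#' Tidy a PC-retention cross-validation
#'
#' @param x A `dapc_xval`.
#' @param ... Unused.
#' @return Tibble `n_pcs`, `rmse`.
#' @export
tidy.dapc_xval <- function(x, ...) x$rmse

#' @rdname tidy.dapc_xval
#' @export
glance.dapc_xval <- function(x, ...) {
  tibble::tibble(chosen_npcs = x$chosen_npcs,
                 rmse_min = min(x$rmse$rmse),
                 reps = max(x$results$rep))
}

#' Tidy a pairwise external validation
#'
#' @param x A `pairwise_validation`.
#' @param ... Unused.
#' @return Tibble `rep`, `accuracy`.
#' @export
tidy.pairwise_validation <- function(x, ...) {
  tibble::tibble(rep = seq_along(x$per_rep_accuracy),
                 accuracy = x$per_rep_accuracy)
}

#' @rdname tidy.pairwise_validation
#' @export
glance.pairwise_validation <- function(x, ...) {
  tibble::tibble(pair = paste(x$pair, collapse = "-"),
                 mean = x$mean, sd = x$sd,
                 reps = length(x$per_rep_accuracy))
}

#' BIC curve plot
#'
#' @param object A `bic_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bic_scan <- function(object, ...) {
  d <- object$scan
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_best, linetype = 2) +
    ggplot2::labs(x = "Number of clusters (K)", y = "BIC") +
    ggplot2::theme_minimal()
}

#' Discriminant-space plot of a fitted DAPC
#'
#' Scatter of the first two discriminant axes, or a density over the
#' single axis for two-group fits.
#'
#' @param object A `dapc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dapc <- function(object, ...) {
  d <- tidy(object)
  if (object$n_da >= 2) {
    w <- tidyr::pivot_wider(d, names_from = "axis", names_prefix = "da",
                            values_from = "coordinate")
    ggplot2::ggplot(w, ggplot2::aes(x = .data$da1, y = .data$da2,
                                    colour = .data$group)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "Discriminant axis 1",
                    y = "Discriminant axis 2") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d[d$axis == 1, ],
                    ggplot2::aes(x = .data$coordinate,
                                 fill = .data$group)) +
      ggplot2::geom_density(alpha = 0.5) +
      ggplot2::labs(x = "Discriminant axis 1", y = "Density") +
      ggplot2::theme_minimal()
  }
}

#' Per-subgroup F_ROH distribution plot
#'
#' @param froh_table Tibble with `froh` and `subgroup` columns (e.g.
#'   [froh()] joined to sample metadata).
#' @return A ggplot.
#' @export
plot_froh <- function(froh_table) {
  ggplot2::ggplot(froh_table,
                  ggplot2::aes(x = .data$subgroup, y = .data$froh,
                               fill = .data$subgroup)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = expression(F[ROH])) +
    ggplot2::theme_minimal()
}

#' ROH length-class summary plot
#'
#' @param summary_table Tibble from [roh_summary()].
#' @return A ggplot.
#' @export
plot_roh_classes <- function(summary_table) {
  d <- summary_table[summary_table$length_class != "all", ]
  d$length_class <- factor(d$length_class,
                           levels = c("1-2", "2-4", "4-8", "8-16", ">16"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length_class,
                                  y = .data$mean_per_individual,
                                  fill = .data$subgroup)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "ROH length class (Mb)",
                  y = "Mean ROH per individual") +
    ggplot2::theme_minimal()
}
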