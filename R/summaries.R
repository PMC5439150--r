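#' Heritability trajectory of a fitted model
#'
#' In the no-residual model the phenotypic variance at a trait-time cell is
#' the genetic plus the pseudo-permanent variance (the latter absorbs
#' residual variation), plus the group-intercept variance when fitted:
#' `h2 = var_g / (var_g + var_p [+ var_group])`.
#'
#' @param fit A `sad_fit`.
#' @param include_group Include the group-intercept variance in the
#'   phenotypic denominator (default `TRUE`; switchable since conventions
#'   differ).
#' @return A tibble of class `sad_herit` with columns `trait`, `time`,
#'   `var_g`, `var_p`, `var_group`, `h2`.
#' @export
heritability <- function(fit, include_group = TRUE) {
  stopifnot(inherits(fit, "sad_fit"))
  cells <- trait_time_cells(fit$am$times, fit$am$traits)
  vg <- unname(diag(fit$U)[cells$cell])
  vp <- unname(diag(fit$P)[cells$cell])
  vgrp <- if (!is.null(fit$group_var) && include_group) {
    unname(fit$group_var[cells$trait])
  } else {
    rep(0, nrow(cells))
  }
  denom <- vg + vp + vgrp
  if (any(denom <= 0)) abort("Zero phenotypic variance at some cell.")
  out <- tibble::tibble(
    trait = cells$trait, time = cells$time,
    var_g = vg, var_p = vp, var_group = vgrp,
    h2 = vg / denom
  )
  class(out) <- c("sad_herit", class(out))
  out
}

#' Genetic and permanent correlation matrices
#'
#' Correlations across trait-time cells implied by the fitted genetic
#' covariance `U` (resp. pseudo-permanent `P`).
#'
#' @param fit A `sad_fit`.
#' @return A labelled correlation matrix of class `sad_corr`.
#' @export
genetic_correlations <- function(fit) {
  stopifnot(inherits(fit, "sad_fit"))
  out <- correlation_from_covariance(fit$U)
  structure(out, effect = "genetic", class = c("sad_corr", class(out)))
}

#' @rdname genetic_correlations
#' @export
permanent_correlations <- function(fit) {
  stopifnot(inherits(fit, "sad_fit"))
  out <- correlation_from_covariance(fit$P)
  structure(out, effect = "permanent", class = c("sad_corr", class(out)))
}

#' Eigen decomposition of a genetic covariance matrix
#'
#' Spectral summary over trait-time cells: which linear combinations of the
#' per-parity breeding values carry the genetic variance, useful for
#' building selection indices on a few leading combinations.
#'
#' @param U Symmetric PD matrix (or a `sad_fit`, whose `U` is used).
#' @return List with `values` (descending), `vectors` (columns matching
#'   `values`) and `proportion` (share of total variance).
#' @export
eigen_summary <- function(U) {
  if (inherits(U, "sad_fit")) U <- U$U
  if (!isTRUE(all.equal(U, t(U), tolerance = 1e-8))) {
    abort("`U` must be symmetric.")
  }
  e <- eigen((U + t(U)) / 2, symmetric = TRUE)
  rownames(e$vectors) <- rownames(U)
  list(values = e$values, vectors = e$vectors,
       proportion = e$values / sum(e$values))
}

#' @method autoplot sad_herit
#' @export
autoplot.sad_herit <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$h2,
                                       colour = .data$trait)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, NA)) +
    ggplot2::labs(x = "time (parity)", y = expression(h^2),
                  colour = "trait",
                  title = "Heritability trajectory") +
    ggplot2::theme_minimal()
}

#' @method autoplot sad_corr
#' @export
autoplot.sad_corr <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object), rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "correlation")
  lv <- rownames(object)
  df$row <- factor(df$row, levels = rev(lv))
  df$col <- factor(df$col, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#b2182b",
                                  mid = "white", high = "#2166ac") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste(attr(object, "effect"), "correlations")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot heritability trajectories of one or more fits
#'
#' Convenience wrapper around [heritability()] + [autoplot()].
#'
#' @param ... Named `sad_fit` objects.
#' @param include_group Passed to [heritability()].
#' @return A ggplot object.
#' @export
plot_heritability <- function(..., include_group = TRUE) {
  fits <- list(...)
  nms <- names(fits) %||% paste0("fit", seq_along(fits))
  df <- purrr::map2_dfr(fits, nms, function(f, nm) {
    dplyr::mutate(heritability(f, include_group), model = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$h2,
                                   colour = .data$trait,
                                   linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, NA)) +
    ggplot2::labs(x = "time (parity)", y = expression(h^2)) +
    ggplot2::theme_minimal()
}
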