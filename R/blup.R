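#' Predicted breeding values (BLUP)
#'
#' Best linear unbiased predictions of the additive genetic effect at the
#' estimated variance parameters, one value per animal, trait and time point
#' (so `T x n_traits` values per animal).  Animals without records receive
#' predictions through the relationship matrix.  Computed as
#' `u_hat = (A[, rec] (x) U) Z' V^-1 (y - X beta_hat)`.
#'
#' @param fit A [sad_fit()] result.
#' @param animals Optional subset of animal ids (default: whole pedigree).
#' @return A tibble with columns `animal`, `trait`, `time`, `ebv`.
#' @export
predict_breeding_values <- function(fit, animals = NULL) {
  stopifnot(inherits(fit, "sad_fit"))
  am <- fit$am
  comp <- list(U = fit$U, P = fit$P, group_var = fit$group_var)
  resid <- am$y - as.vector(am$X %*% fit$beta)
  Py <- solve_V(comp, am, resid)[, 1]
  d <- nrow(am$cells)
  # scatter Z'Py onto (recorded animal) x cell
  Wmat <- matrix(0, length(am$rec_ids), d)
  Wmat[cbind(am$records$.an, am$records$.cell)] <-
    Wmat[cbind(am$records$.an, am$records$.cell)] + Py
  A <- relationship_matrix(fit$ped)
  animals <- animals %||% fit$ped$animal
  bad <- setdiff(animals, fit$ped$animal)
  if (length(bad)) abort(sprintf("Animal(s) not in pedigree: %s",
                                 paste(head(bad, 5), collapse = ", ")))
  Ebv <- A[animals, am$rec_ids, drop = FALSE] %*% Wmat %*% fit$U
  tidyr::expand_grid(animal = animals, cell = seq_len(d)) |>
    dplyr::mutate(
      trait = am$cells$trait[.data$cell],
      time = am$cells$time[.data$cell],
      ebv = as.vector(t(Ebv))
    ) |>
    dplyr::select("animal", "trait", "time", "ebv")
}
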