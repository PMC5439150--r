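#' Describe a synthetic longitudinal breeding design
#'
#' Bundles everything needed to generate a pedigree and phenotypes whose
#' statistical structure matches the SAD analysis assumptions: a nested
#' mating design (sires, dams per sire, recorded female offspring per dam),
#' the true model specification and parameter values, fixed-effect
#' generators, monotone attrition across parities and per-trait missingness.
#'
#' @param spec True [sad_model()] specification (its `times`/`traits` define
#'   the grid).
#' @param params True parameter vector in [param_layout()] order
#'   (unconstrained scale, as used throughout).
#' @param n_sires,dams_per_sire,offspring_per_dam Nested pedigree design;
#'   `offspring_per_dam` is the mean of a (truncated-at-zero optional)
#'   Poisson when `poisson_offspring` is `TRUE`, otherwise a fixed count.
#' @param n_generations Number of generations below the founders (1 =
#'   founders plus one recorded generation).
#' @param poisson_offspring Draw litter sizes from a Poisson distribution.
#' @param mu Named list per trait of length-T vectors of parity means.
#' @param covariate_effect Named vector per trait: coefficient on a shared
#'   standard-normal record-level covariate `x` (0 drops it).
#' @param n_groups Number of contemporary-group levels (0 = none; requires
#'   `spec$group`).
#' @param attrition Length `T-1` vector: probability that a female recorded
#'   at parity `j` continues to parity `j+1` (attrition is monotone: once
#'   missing, an animal has no later records).
#' @param missingness Named list per trait of length-T observation
#'   probabilities (applied after attrition).
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(spec, params,
                       n_sires = 50, dams_per_sire = 5, offspring_per_dam = 4,
                       n_generations = 1, poisson_offspring = FALSE,
                       mu = NULL, covariate_effect = NULL,
                       n_groups = 0,
                       attrition = NULL, missingness = NULL) {
  assert_valid_spec(spec)
  k <- length(param_layout(spec))
  if (length(params) != k) {
    abort(sprintf("`params` must have length %d for this spec.", k))
  }
  T_ <- length(spec$times)
  mu <- mu %||% setNames(lapply(spec$traits, function(tr) rep(0, T_)), spec$traits)
  covariate_effect <- covariate_effect %||% setNames(rep(0, length(spec$traits)), spec$traits)
  attrition <- attrition %||% rep(1, max(T_ - 1, 0))
  missingness <- missingness %||% setNames(lapply(spec$traits, function(tr) rep(1, T_)), spec$traits)
  stopifnot(length(attrition) == max(T_ - 1, 0),
            all(attrition >= 0 & attrition <= 1),
            all(vapply(missingness, length, integer(1)) == T_))
  if (n_groups > 0 && is.null(spec$group)) {
    abort("`n_groups > 0` requires a spec with a group random intercept.")
  }
  if (n_sires < 1 || dams_per_sire < 1) abort("Design needs at least one mating.")
  structure(list(
    spec = spec, params = params,
    n_sires = n_sires, dams_per_sire = dams_per_sire,
    offspring_per_dam = offspring_per_dam, n_generations = n_generations,
    poisson_offspring = poisson_offspring,
    mu = mu, covariate_effect = covariate_effect, n_groups = n_groups,
    attrition = attrition, missingness = missingness
  ), class = "sim_design")
}

#' Simulate a pedigree from a design
#'
#' Discrete generations with nested random mating (each dam mated to a
#' single sire, no selfing); females of the final generation are flagged as
#' the recorded animals.  Deterministic given `seed`.
#'
#' @param design A [sim_design()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A [pedigree()] with attribute `recorded` (character ids).
#' @export
simulate_pedigree <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(seed)
  sires <- sprintf("S%04d", seq_len(design$n_sires))
  dams <- sprintf("D%04d", seq_len(design$n_sires * design$dams_per_sire))
  ped <- tibble::tibble(
    animal = c(sires, dams),
    sire = NA_character_, dam = NA_character_
  )
  if (design$n_generations == 0L) {
    # founders only: the founder females are the recorded animals
    out <- pedigree(ped$animal, ped$sire, ped$dam)
    attr(out, "recorded") <- dams
    return(out)
  }
  males <- sires; females <- dams
  counter <- 0L
  for (g in seq_len(design$n_generations)) {
    n_mat <- length(females)
    sire_of <- rep(males, length.out = n_mat)
    offs <- list()
    for (i in seq_len(n_mat)) {
      n_off <- if (design$poisson_offspring) rpois(1, design$offspring_per_dam)
               else design$offspring_per_dam
      if (n_off == 0) next
      ids <- sprintf("G%d_%05d", g, counter + seq_len(n_off))
      counter <- counter + n_off
      offs[[length(offs) + 1]] <- tibble::tibble(
        animal = ids, sire = sire_of[i], dam = females[i]
      )
    }
    offs <- dplyr::bind_rows(offs)
    if (nrow(offs) == 0) abort("Design produced no offspring.")
    ped <- dplyr::bind_rows(ped, offs)
    if (g < design$n_generations) {
      sex <- runif(nrow(offs)) < 0.5
      males <- offs$animal[sex]
      females <- offs$animal[!sex]
      if (!length(males) || !length(females)) abort("A generation ran out of one sex.")
    } else {
      recorded <- offs$animal
    }
  }
  out <- pedigree(ped$animal, ped$sire, ped$dam)
  attr(out, "recorded") <- recorded
  out
}

#' Simulate phenotypes under the SAD model
#'
#' Genetic values for the whole pedigree are drawn with covariance
#' `A (x) U` using the Kronecker Cholesky identity
#' `chol(A (x) U) = chol(A) (x) chol(U)` (dense; the reference method at the
#' package's target scale of a few thousand animals); permanent effects are
#' drawn per recorded animal from `P`.  The phenotype is the fixed part plus
#' the two random effects (plus a group intercept when designed) with no
#' residual.  Attrition and per-trait missingness are then applied.
#' Deterministic given `seed`.
#'
#' @param design A [sim_design()].
#' @param ped Pedigree from [simulate_pedigree()] (with `recorded`
#'   attribute); regenerated from `design` if omitted.
#' @param seed Integer seed.
#' @return A long-format phenotype tibble (animal, time, trait, value, `x`
#'   covariate, group column if designed) with attribute `truth` holding the
#'   true `U`, `P`, parameter vector and group variances.
#' @export
simulate_phenotypes <- function(design, ped = NULL, seed) {
  stopifnot(inherits(design, "sim_design"))
  if (is.null(ped)) ped <- simulate_pedigree(design, seed)
  recorded <- attr(ped, "recorded") %||% ped$animal
  spec <- design$spec
  set.seed(seed + 1L)

  sl <- split_params(spec, design$params)
  U <- sad_covariance(spec$genetic, sl$genetic, spec$times, spec$traits)
  P <- sad_covariance(spec$permanent, sl$permanent, spec$times, spec$traits)
  d <- nrow(U)
  n_all <- nrow(ped)
  if (all(is.na(ped$sire) & is.na(ped$dam))) {
    # founders only: A is the identity, skip the dense Cholesky
    u_all <- matrix(rnorm(n_all * d), n_all, d) %*% chol(U)
  } else {
    A <- relationship_matrix(ped)
    u_all <- t(chol(A)) %*% matrix(rnorm(n_all * d), n_all, d) %*% chol(U)
  }
  rownames(u_all) <- ped$animal
  n_rec <- length(recorded)
  p_rec <- matrix(rnorm(n_rec * d), n_rec, d) %*% chol(P)
  rownames(p_rec) <- recorded

  group_var <- NULL
  g_eff <- NULL
  g_of <- NULL
  if (design$n_groups > 0) {
    group_var <- setNames(exp(sl$group_logvar), spec$traits)
    g_eff <- vapply(spec$traits, function(tr)
      rnorm(design$n_groups, sd = sqrt(group_var[[tr]])), numeric(design$n_groups))
    g_of <- sample.int(design$n_groups, n_rec, replace = TRUE)
  }

  cells <- trait_time_cells(spec$times, spec$traits)
  T_ <- length(spec$times)
  # monotone attrition: last recorded parity per animal
  last <- rep(T_, n_rec)
  if (T_ > 1) {
    cont <- matrix(runif(n_rec * (T_ - 1)) <
                     rep(design$attrition, each = n_rec), n_rec, T_ - 1)
    last <- apply(cont, 1, function(z) {
      stop_at <- which(!z)
      if (length(stop_at)) stop_at[1] else T_
    })
  }

  recs <- tidyr::expand_grid(animal = recorded, j = seq_len(T_)) |>
    dplyr::mutate(time = spec$times[.data$j]) |>
    dplyr::filter(.data$j <= last[match(.data$animal, recorded)])
  recs$x <- rnorm(nrow(recs))
  out <- tidyr::expand_grid(recs, trait = spec$traits) |>
    dplyr::mutate(
      cell = cells$cell[match(paste0(.data$trait, "@", .data$time), cells$label)]
    )
  ai <- match(out$animal, recorded)
  out$value <- design_mu(design, out$trait, out$j) +
    unname(design$covariate_effect[out$trait]) * out$x +
    u_all[cbind(match(out$animal, ped$animal), out$cell)] +
    p_rec[cbind(ai, out$cell)]
  if (design$n_groups > 0) {
    out$value <- out$value + g_eff[cbind(g_of[ai], match(out$trait, spec$traits))]
    out[[spec$group]] <- sprintf("g%03d", g_of[ai])
  }
  # per-trait, per-parity missingness
  keep_prob <- mapply(function(tr, j) design$missingness[[tr]][j], out$trait, out$j)
  out <- out[runif(nrow(out)) < keep_prob, ]
  out <- dplyr::select(out, -"j", -"cell")
  attr(out, "truth") <- list(U = U, P = P, params = design$params,
                             group_var = group_var)
  out
}

design_mu <- function(design, trait, j) {
  vapply(seq_along(trait), function(i) design$mu[[trait[i]]][j[i]], numeric(1))
}
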