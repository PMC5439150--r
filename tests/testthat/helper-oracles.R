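# Independent oracles and random-case generators shared across tests.

# Dense REML log-likelihood from first principles: build V entry by entry
# from the relationship matrix and the trait-time covariances, project y
# onto an orthonormal basis of error contrasts, and evaluate the Gaussian
# density directly.  Shares no code with the package's block evaluator.
dense_reml_oracle <- function(par, dat, spec, ped) {
  A <- relationship_matrix(ped)
  sl <- sadmix:::split_params(spec, par)
  U <- sad_covariance(spec$genetic, sl$genetic, spec$times, spec$traits)
  P <- sad_covariance(spec$permanent, sl$permanent, spec$times, spec$traits)
  am <- assemble_model(dat, spec, ped)
  rec <- am$records
  n <- nrow(rec)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      V[i, j] <- A[rec$animal[i], rec$animal[j]] * U[rec$.cell[i], rec$.cell[j]] +
        (rec$animal[i] == rec$animal[j]) * P[rec$.cell[i], rec$.cell[j]]
    }
  }
  if (!is.null(spec$group)) {
    gv <- exp(sl$group_logvar)
    names(gv) <- spec$traits
    g <- as.character(rec[[spec$group]])
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (g[i] == g[j] && rec$trait[i] == rec$trait[j]) {
          V[i, j] <- V[i, j] + gv[[rec$trait[i]]]
        }
      }
    }
  }
  X <- am$X
  y <- am$y
  p <- ncol(X)
  K <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  Vk <- t(K) %*% V %*% K
  yk <- drop(t(K) %*% y)
  -0.5 * ((n - p) * log(2 * pi) + determinant(Vk, logarithm = TRUE)$modulus[1] +
            sum(yk * solve(Vk, yk)))
}

# Monte-Carlo covariance oracle: simulate the antedependence recursion of
# the model equations literally, cell by cell in dependence order, and
# return the empirical covariance of the stacked trait-time vector.
mc_recursion_cov <- function(effect, params, times, traits, n_rep = 2e5) {
  ord_traits <- sadmix:::slice_trait_order(effect, traits)
  pv <- sadmix:::unpack_effect_params(effect, params, traits)
  T_ <- length(times)
  ntr <- length(ord_traits)
  d <- T_ * ntr
  vals <- matrix(0, n_rep, d)
  cell_of <- function(j, k) (j - 1L) * ntr + k
  e1 <- NULL
  for (j in seq_len(T_)) {
    for (k in seq_len(ntr)) {
      tr <- ord_traits[k]
      w <- effect$within[[tr]]
      sd_e <- sqrt(innovation_variance(pv$within[[tr]]$b, times[j]))
      e <- rnorm(n_rep, sd = sd_e)
      x <- e
      if (j == 1 && k == 1) e1 <- e
      if (j == 1 && k == 2 && !is.null(pv$rho)) {
        x <- x + pv$rho * vals[, cell_of(1, 1)]
      }
      for (s in seq_len(w$order)) {
        if (j - s >= 1) {
          x <- x + eval_poly(pv$within[[tr]]$a[[s]], times[j]) * vals[, cell_of(j - s, k)]
        }
      }
      for (ci in seq_along(effect$crosses)) {
        cr <- effect$crosses[[ci]]
        if (cr$to != tr) next
        lags <- cr$start_lag:cr$end_lag
        for (li in seq_along(lags)) {
          if (j - lags[li] >= 1) {
            x <- x + eval_poly(pv$crosses[[ci]]$coef[[li]], times[j]) *
              vals[, cell_of(j - lags[li], match(cr$from, ord_traits))]
          }
        }
      }
      vals[, cell_of(j, k)] <- x
    }
  }
  cells <- trait_time_cells(times, ord_traits)
  want <- trait_time_cells(times, traits)$label
  colnames(vals) <- cells$label
  stats::cov(vals[, want, drop = FALSE])
}

# Random small two-trait effect specification (T <= 4).
random_small_effect <- function(with_cross = NA, with_rho = NA) {
  traits <- c("y1", "y2")
  w <- lapply(traits, function(tr) {
    ord <- sample(0:2, 1)
    sad_within(ord, sample(0:1, ord, replace = TRUE), sample(0:1, 1))
  })
  names(w) <- traits
  crosses <- list()
  use_cross <- if (is.na(with_cross)) runif(1) < 0.6 else with_cross
  if (use_cross) {
    lag0 <- sample(0:1, 1)
    crosses <- list(sad_cross("y1", "y2", lag0, lag0, degrees = sample(0:1, 1)))
  }
  use_rho <- if (is.na(with_rho)) runif(1) < 0.3 else with_rho
  if (use_rho && (length(crosses) == 0 || crosses[[1]]$start_lag > 0)) {
    rho <- TRUE
  } else {
    rho <- FALSE
  }
  sad_effect(within = w, crosses = crosses, initial_correlation = rho)
}

random_effect_params <- function(effect, sd = 0.3) {
  rnorm(count_parameters(effect), sd = sd)
}

# Random multi-generation pedigree for pedigree-module property tests.
random_pedigree <- function(n_founders = 20, n_extra = 80) {
  ids <- sprintf("F%03d", seq_len(n_founders))
  sire <- rep(NA_character_, n_founders)
  dam <- rep(NA_character_, n_founders)
  for (i in seq_len(n_extra)) {
    pool <- c(ids)
    par_ids <- sample(pool, 2)
    ids <- c(ids, sprintf("X%03d", i))
    sire <- c(sire, par_ids[1])
    dam <- c(dam, par_ids[2])
  }
  pedigree(ids, sire, dam)
}

# Small single-trait SAD 100/100 design used by several tests.
sad100_single_design <- function(theta_g = 0.5, theta_p = 0.1,
                                 log_vg = 0, log_vp = log(2),
                                 n_sires = 30, dams_per_sire = 2,
                                 offspring_per_dam = 4, times = 1:5) {
  spec <- sad_model(
    traits = "y", times = times,
    genetic = sad_effect(within = list(y = "100")),
    permanent = sad_effect(within = list(y = "100"))
  )
  truth <- c(theta_g, log_vg, theta_p, log_vp)
  names(truth) <- param_layout(spec)
  sim_design(spec, truth, n_sires = n_sires, dams_per_sire = dams_per_sire,
             offspring_per_dam = offspring_per_dam)
}

fast_control <- function(n_starts = 1, maxit = 400) {
  fit_control(n_starts = n_starts, maxit = maxit)
}
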