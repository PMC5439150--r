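#' Optimizer settings for REML fitting
#'
#' @param n_starts Number of optimizer starts; the first uses the supplied
#'   (or default) initialization, later ones are jittered copies.
#' @param jitter_sd Standard deviation of the Gaussian jitter applied to
#'   extra starts.
#' @param seed Seed controlling the jitters (fixed for reproducibility).
#' @param maxit Iteration cap passed to [stats::optim()].
#' @param factr L-BFGS-B convergence tolerance (multiple of machine
#'   precision).
#' @param method Primary optimizer; on failure a Nelder-Mead pass is run.
#' @param verbose Print per-start progress.
#' @return A list of class `sad_fit_control`.
#' @export
fit_control <- function(n_starts = 3, jitter_sd = 0.1, seed = 1,
                        maxit = 400, factr = 1e8, method = "L-BFGS-B",
                        verbose = FALSE) {
  structure(list(n_starts = n_starts, jitter_sd = jitter_sd, seed = seed,
                 maxit = maxit, factr = factr, method = method,
                 verbose = verbose),
            class = "sad_fit_control")
}

# Default initialization: all (cross-)antedependence coefficients at 0 and
# per-trait log innovation variances set from the sample variances, split
# evenly between the genetic and permanent (and group) parts.
default_init_sad <- function(spec, am) {
  nm <- param_layout(spec)
  par <- setNames(numeric(length(nm)), nm)
  n_parts <- 2 + !is.null(spec$group)
  vars <- am$records |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(v = stats::var(.data$value), .groups = "drop")
  v <- setNames(pmax(vars$v, 1e-6), vars$trait)
  for (tr in spec$traits) {
    vtr <- if (tr %in% names(v)) v[[tr]] else 1
    single <- length(spec$traits) == 1L
    b0 <- if (single) "b_0" else paste0(tr, ".b_0")
    for (eff in c("genetic", "permanent")) {
      key <- paste0(eff, ".", b0)
      if (key %in% nm) par[key] <- log(vtr / n_parts)
    }
    gkey <- paste0("group.", tr, ".logvar")
    if (gkey %in% nm) par[gkey] <- log(vtr / n_parts)
  }
  par
}

# Typical scale per parameter for optimizer preconditioning: a coefficient
# multiplying t^q moves the objective ~ mean(t^q) times as fast as a
# constant, so it is scaled down accordingly (read off the ",q" suffix of
# the layout names).
layout_parscale <- function(layout, times) {
  ts <- mean(abs(times))
  q <- suppressWarnings(as.integer(sub("^.*[,_](\\d+)$", "\\1", layout)))
  q[is.na(q)] <- 0L
  q[!grepl("(a|b|d)_[0-9]", sub("^.*\\.", "", layout))] <- 0L
  ts^(-q)
}

# Shared optimizer over a covariance builder.  `build(par)` must return
# list(U, P, group_var).  Returns the best start.
fit_engine <- function(am, build, init, control, parscale = NULL) {
  negll <- function(par) {
    val <- tryCatch(reml_core(build(par), am)$loglik, error = function(e) -Inf)
    if (!is.finite(val)) 1e10 else -val
  }
  parscale <- parscale %||% rep(1, length(init))
  # forward-difference gradient (k+1 evaluations instead of optim's 2k
  # central differences); step scaled per parameter
  fd_grad <- function(par) {
    f0 <- negll(par)
    vapply(seq_along(par), function(i) {
      h <- 1e-6 * max(abs(par[i]), parscale[i])
      par2 <- par
      par2[i] <- par2[i] + h
      (negll(par2) - f0) / h
    }, numeric(1))
  }
  # analytic gradient through cell-aggregated score kernels (the data-side
  # derivative is exact; the small d x d covariance derivatives are taken
  # by forward differences on the builder).  Only valid without a shared
  # group random effect, which couples the blocks.
  grad <- if (is.null(am$Zg)) {
    function(par) {
      g <- tryCatch({
        comp <- build(par)
        core <- reml_core(comp, am)
        if (!is.finite(core$loglik)) return(fd_grad(par))
        sc <- reml_block_scores(am$Tm, am$offsets, am$an, am$cell0, am$Amats,
                                comp$U, comp$P, core$beta, core$Cinv)
        if (!isTRUE(sc$ok)) return(fd_grad(par))
        vapply(seq_along(par), function(i) {
          h <- 1e-6 * max(abs(par[i]), parscale[i])
          par2 <- par
          par2[i] <- par2[i] + h
          comp2 <- build(par2)
          0.5 * (sum(sc$SU * (comp2$U - comp$U)) +
                   sum(sc$SP * (comp2$P - comp$P))) / h
        }, numeric(1))
      }, error = function(e) NULL)
      g %||% fd_grad(par)
    }
  } else {
    fd_grad
  }
  starts <- list(init)
  if (control$n_starts > 1) {
    withr_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(control$seed)
    for (s in seq_len(control$n_starts - 1)) {
      starts[[s + 1]] <- init + rnorm(length(init), sd = control$jitter_sd)
    }
    if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, envir = globalenv())
  }
  runs <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    fit <- tryCatch(
      optim(starts[[s]], negll, gr = grad, method = control$method,
            control = list(maxit = control$maxit, factr = control$factr,
                           parscale = parscale)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) {
      fit <- tryCatch(
        optim(starts[[s]], negll, method = "Nelder-Mead",
              control = list(maxit = 5 * control$maxit, parscale = parscale)),
        error = function(e) NULL
      )
    }
    if (control$verbose && !is.null(fit)) {
      message(sprintf("start %d: logL = %.4f (convergence %d)",
                      s, -fit$value, fit$convergence))
    }
    runs[[s]] <- fit
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) abort("All optimizer starts failed.")
  values <- vapply(runs, function(r) if (is.null(r)) Inf else r$value, numeric(1))
  best <- which.min(values)
  trace <- tibble::tibble(
    start = seq_along(runs),
    logLik = -values,
    convergence = vapply(runs, function(r) if (is.null(r)) NA_integer_ else r$convergence,
                         integer(1))
  )
  if (all(trace$convergence != 0L, na.rm = TRUE)) {
    warn("Optimizer did not report convergence at any start; returning best point found.")
  }
  list(par = runs[[best]]$par, trace = trace)
}

#' Fit a multiple-trait SAD mixed model by REML
#'
#' Maximizes the restricted likelihood over the unconstrained parameter
#' vector (polynomial coefficients are unbounded; the initial correlation is
#' optimized on the `atanh` scale; group variances on the log scale) using
#' L-BFGS-B with a Nelder-Mead fallback and a small number of jittered
#' multi-starts.
#'
#' @param data Long-format phenotype tibble (see [assemble_model()]).
#' @param ped A [pedigree()].
#' @param spec A [sad_model()] specification.
#' @param init Optional numeric start in [param_layout()] order; defaults to
#'   zero coefficients with innovation variances from the per-trait sample
#'   variances split evenly across random parts.
#' @param control A [fit_control()].
#' @return An object of class `sad_fit` with the estimated parameters,
#'   implied `U` and `P` matrices, fixed-effect estimates, the REML
#'   log-likelihood and AIC, and a convergence trace.
#' @export
sad_fit <- function(data, ped, spec, init = NULL, control = fit_control()) {
  assert_valid_spec(spec)
  am <- assemble_model(data, spec, ped)
  build <- sad_param_builder(spec)
  init <- init %||% default_init_sad(spec, am)
  k <- length(param_layout(spec))
  if (length(init) != k) abort(sprintf("`init` must have length %d.", k))
  run <- fit_engine(am, build, init, control,
                    parscale = layout_parscale(param_layout(spec), spec$times))
  finish_fit(run, am, build, spec, ped, family = "SAD",
             n_params = count_parameters(spec),
             layout = param_layout(spec))
}

finish_fit <- function(run, am, build, spec, ped, family, n_params, layout) {
  comp <- build(run$par)
  core <- reml_core(comp, am)
  structure(list(
    family = family,
    spec = spec,
    par = setNames(run$par, layout),
    logLik = core$loglik,
    n_params = n_params,
    aic = -2 * core$loglik + 2 * n_params,
    U = core$U, P = core$P, group_var = core$group_var,
    beta = core$beta,
    convergence = run$trace,
    am = am, ped = ped,
    fingerprint = am$fingerprint
  ), class = "sad_fit")
}

#' @export
print.sad_fit <- function(x, ...) {
  cat(sprintf("%s mixed-model REML fit: %d records, %d covariance parameters\n",
              x$family, x$am$n, x$n_params))
  cat(sprintf("  logLik (REML) = %.4f   AIC = %.4f\n", x$logLik, x$aic))
  cat("  traits:", paste(x$am$traits, collapse = ", "),
      " times:", paste(x$am$times, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.sad_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_params, class = "logLik")
}

#' Akaike information criterion of a fit
#'
#' `AIC = -2 logL + 2 k` with `k` the number of covariance parameters only;
#' fixed effects are identical across the model comparisons this package
#' performs, as is standard for REML-based AIC.
#'
#' @param fit A `sad_fit`.
#' @return Numeric scalar.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "sad_fit"))
  -2 * fit$logLik + 2 * fit$n_params
}

#' @method tidy sad_fit
#' @export
tidy.sad_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$par),
    estimate = unname(x$par)
  ) |>
    dplyr::mutate(
      estimate = ifelse(grepl("\\.rho$|^rho$", .data$term),
                        tanh(.data$estimate), .data$estimate),
      scale = dplyr::case_when(
        grepl("\\.rho$|^rho$", .data$term) ~ "correlation",
        grepl("logvar$", .data$term) ~ "log-variance",
        TRUE ~ "coefficient"
      )
    )
}

#' @method glance sad_fit
#' @export
glance.sad_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    logLik = x$logLik,
    AIC = x$aic,
    n_params = x$n_params,
    n_records = x$am$n,
    n_animals = length(x$am$rec_ids),
    converged = any(x$convergence$convergence == 0L, na.rm = TRUE)
  )
}
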