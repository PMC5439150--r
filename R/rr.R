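#' Normalized Legendre polynomial basis
#'
#' Evaluates the orthonormal Legendre basis at a time point after mapping
#' the time range onto `[-1, 1]` via `s = -1 + 2 (t - t_min)/(t_max - t_min)`.
#' Basis functions are normalized so that the squared function integrates
#' to one over `[-1, 1]`: the constant is `sqrt(1/2)`, the linear term
#' `sqrt(3/2) s`, and so on.
#'
#' @param t Time value(s).
#' @param degree Maximum polynomial degree (>= 0).
#' @param t_min,t_max Standardization range (must satisfy `t_min < t_max`
#'   unless `degree` is 0).
#' @return A matrix with `length(t)` rows and `degree + 1` columns.
#' @export
legendre_basis <- function(t, degree, t_min, t_max) {
  degree <- as.integer(degree)
  if (degree < 0) abort("`degree` must be >= 0.")
  if (degree > 0 && t_min >= t_max) abort("Need t_min < t_max.")
  s <- if (t_min < t_max) -1 + 2 * (t - t_min) / (t_max - t_min) else rep(0, length(t))
  P <- matrix(0, length(t), degree + 1L)
  P[, 1] <- 1
  if (degree >= 1) P[, 2] <- s
  if (degree >= 2) {
    for (j in 2:degree) {
      # (j) P_j = (2j - 1) s P_{j-1} - (j - 1) P_{j-2}
      P[, j + 1] <- ((2 * j - 1) * s * P[, j] - (j - 1) * P[, j - 1]) / j
    }
  }
  norm <- sqrt((2 * seq(0, degree) + 1) / 2)
  sweep(P, 2, norm, "*")
}

#' Random-regression model specification
#'
#' The comparison baseline: random coefficients on a normalized Legendre
#' basis of time for the genetic and permanent effects (coefficients
#' correlated across traits through full covariance matrices `K`), plus an
#' explicit residual which is independent across parities but may be
#' correlated across traits within a parity.  The Legendre argument is
#' standardized over `[first time, last time]`.
#'
#' @param traits Trait labels.
#' @param times Time grid.
#' @param genetic_degree,permanent_degree Polynomial degree per trait
#'   (recycled if scalar).
#' @param residual_cor Estimate a within-parity residual correlation between
#'   the two traits (requires exactly 2 traits).
#' @param fixed,group As in [sad_model()].
#' @return An object of class `rr_model_spec`.
#' @export
rr_model <- function(traits, times, genetic_degree = 1, permanent_degree = 0,
                     residual_cor = TRUE, fixed = NULL, group = NULL) {
  traits <- as.character(traits)
  times <- as.numeric(times)
  genetic_degree <- setNames(as.integer(rep_len(genetic_degree, length(traits))), traits)
  permanent_degree <- setNames(as.integer(rep_len(permanent_degree, length(traits))), traits)
  if (any(c(genetic_degree, permanent_degree) < 0)) abort("Degrees must be >= 0.")
  if (any(c(genetic_degree, permanent_degree) > length(times) - 1L)) {
    abort("A degree above T - 1 is not identifiable from T time points.")
  }
  if (residual_cor && length(traits) != 2L) {
    abort("`residual_cor` requires exactly two traits.")
  }
  if (is.null(fixed)) fixed <- setNames(replicate(length(traits), ~1), traits)
  structure(list(
    traits = traits, times = times,
    genetic_degree = genetic_degree, permanent_degree = permanent_degree,
    residual_cor = residual_cor, fixed = fixed, group = group
  ), class = "rr_model_spec")
}

#' @export
count_parameters.rr_model_spec <- function(x) {
  dg <- sum(x$genetic_degree + 1L)
  dp <- sum(x$permanent_degree + 1L)
  k <- dg * (dg + 1L) / 2L + dp * (dp + 1L) / 2L +
    length(x$traits) + as.integer(x$residual_cor)
  as.integer(k + if (is.null(x$group)) 0L else length(x$traits))
}

#' @export
print.rr_model_spec <- function(x, ...) {
  cat("Multiple-trait random-regression model specification\n")
  cat("  genetic degrees:", paste(x$genetic_degree, collapse = ","),
      "  permanent degrees:", paste(x$permanent_degree, collapse = ","), "\n")
  cat("  free covariance parameters:", count_parameters(x), "\n")
  invisible(x)
}

# Block basis matrix over trait-time cells: row (t, trait) holds that
# trait's Legendre basis, zeros elsewhere.
rr_basis_matrix <- function(degrees, times, traits) {
  cells <- trait_time_cells(times, traits)
  t_min <- min(times); t_max <- max(times)
  cols <- sum(degrees[traits] + 1L)
  Phi <- matrix(0, nrow(cells), cols)
  off <- 0L
  for (tr in traits) {
    B <- legendre_basis(times, degrees[[tr]], t_min, t_max)
    rows <- which(cells$trait == tr)
    Phi[rows, off + seq_len(ncol(B))] <- B[match(cells$time[rows], times), , drop = FALSE]
    off <- off + ncol(B)
  }
  rownames(Phi) <- cells$label
  Phi
}

#' Random-regression covariance over the trait-time grid
#'
#' Computes `Phi K Phi' (+ residual)`, where `Phi` is the block Legendre
#' basis matrix over trait-by-time cells and `K` the random-coefficient
#' covariance matrix (traits stacked in order, each contributing
#' `degree + 1` coefficients).
#'
#' @param K Symmetric PSD coefficient covariance matrix.
#' @param degrees Named per-trait polynomial degrees.
#' @param times,traits Grid definition.
#' @param residual Optional per-parity residual covariance: a
#'   `n_traits x n_traits` matrix placed on same-time cells (independent
#'   across parities).
#' @return A `d x d` labelled covariance matrix.
#' @export
rr_covariance <- function(K, degrees, times, traits, residual = NULL) {
  Phi <- rr_basis_matrix(degrees, times, traits)
  if (nrow(K) != ncol(Phi)) {
    abort(sprintf("K must be %d x %d for these degrees.", ncol(Phi), ncol(Phi)))
  }
  G <- Phi %*% K %*% t(Phi)
  if (!is.null(residual)) {
    cells <- trait_time_cells(times, traits)
    for (tm in times) {
      rows <- which(cells$time == tm)
      G[rows, rows] <- G[rows, rows] + residual
    }
  }
  dimnames(G) <- list(rownames(Phi), rownames(Phi))
  (G + t(G)) / 2
}

# Parameter layout for the RR family: log-Cholesky of Kg and Kp
# (column-major lower triangle, log on the diagonal), residual log-sds,
# optional atanh residual correlation, group log-variances.
rr_param_layout <- function(rr) {
  chol_names <- function(tag, dim) {
    unlist(lapply(seq_len(dim), function(j)
      sprintf("%s.L_%d,%d", tag, j:dim, j)))
  }
  dg <- sum(rr$genetic_degree + 1L)
  dp <- sum(rr$permanent_degree + 1L)
  c(chol_names("Kg", dg), chol_names("Kp", dp),
    sprintf("resid.%s.logsd", rr$traits),
    if (rr$residual_cor) "resid.atanh_cor",
    if (!is.null(rr$group)) paste0("group.", rr$traits, ".logvar"))
}

chol_from_logchol <- function(theta, dim) {
  L <- matrix(0, dim, dim)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(pmin(diag(L), 25))
  L
}

rr_param_builder <- function(rr) {
  force(rr)
  dg <- sum(rr$genetic_degree + 1L)
  dp <- sum(rr$permanent_degree + 1L)
  ng <- dg * (dg + 1L) / 2L
  np <- dp * (dp + 1L) / 2L
  ntr <- length(rr$traits)
  # precompute the basis matrices and the residual placement pattern
  Phi_g <- rr_basis_matrix(rr$genetic_degree, rr$times, rr$traits)
  Phi_p <- rr_basis_matrix(rr$permanent_degree, rr$times, rr$traits)
  cells <- trait_time_cells(rr$times, rr$traits)
  time_rows <- lapply(rr$times, function(tm) which(cells$time == tm))
  labs <- cells$label
  function(par) {
    i <- 0L
    take <- function(n) { out <- par[i + seq_len(n)]; i <<- i + n; out }
    Lg <- chol_from_logchol(take(ng), dg)
    Lp <- chol_from_logchol(take(np), dp)
    sd_r <- exp(pmin(take(ntr), 25))
    cor_r <- if (rr$residual_cor) tanh(take(1L)) else 0
    R0 <- diag(sd_r^2, ntr)
    if (ntr == 2) {
      R0[1, 2] <- R0[2, 1] <- cor_r * prod(sd_r)
    }
    gv <- if (!is.null(rr$group)) exp(pmin(take(ntr), 50)) else NULL
    U <- tcrossprod(Phi_g %*% Lg)
    P <- tcrossprod(Phi_p %*% Lp)
    for (rows in time_rows) P[rows, rows] <- P[rows, rows] + R0
    dimnames(U) <- dimnames(P) <- list(labs, labs)
    list(
      U = U, P = (P + t(P)) / 2,
      group_var = if (!is.null(gv)) setNames(gv, rr$traits) else NULL
    )
  }
}

default_init_rr <- function(rr, am) {
  nm <- rr_param_layout(rr)
  par <- setNames(numeric(length(nm)), nm)
  vars <- am$records |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(v = stats::var(.data$value), .groups = "drop")
  v <- setNames(pmax(vars$v, 1e-6), vars$trait)
  n_parts <- 3 + !is.null(rr$group)
  # diagonal log-chol entries: leading (constant) coefficient variance
  # 2*v/n_parts (phi_0^2 = 1/2), higher-order coefficients started small
  for (tag in c("Kg", "Kp")) {
    degs <- if (tag == "Kg") rr$genetic_degree else rr$permanent_degree
    off <- 0L
    for (tr in rr$traits) {
      dtr <- degs[[tr]] + 1L
      lead <- sprintf("%s.L_%d,%d", tag, off + 1L, off + 1L)
      par[lead] <- 0.5 * log(2 * v[[tr]] / n_parts)
      if (dtr > 1) {
        for (j in 2:dtr) {
          par[sprintf("%s.L_%d,%d", tag, off + j, off + j)] <-
            0.5 * log(2 * v[[tr]] / n_parts) - 2
        }
      }
      off <- off + dtr
    }
  }
  for (tr in rr$traits) {
    par[sprintf("resid.%s.logsd", tr)] <- 0.5 * log(v[[tr]] / n_parts)
    gkey <- paste0("group.", tr, ".logvar")
    if (gkey %in% nm) par[gkey] <- log(v[[tr]] / n_parts)
  }
  par
}

#' Fit a multiple-trait random-regression model by REML
#'
#' Same estimation machinery as [sad_fit()] with the random-regression
#' covariance construction: coefficient covariance matrices are optimized
#' through their log-Cholesky factors, residual variances on the log scale.
#'
#' @param data Long-format phenotype tibble.
#' @param ped A [pedigree()].
#' @param rr An [rr_model()] specification.
#' @param init Optional start in `rr` parameter layout order.
#' @param control A [fit_control()].
#' @return A `sad_fit` object with `family = "RR"`.
#' @export
rr_fit <- function(data, ped, rr, init = NULL, control = fit_control()) {
  stopifnot(inherits(rr, "rr_model_spec"))
  am <- assemble_model(data, rr, ped)
  build <- rr_param_builder(rr)
  init <- init %||% default_init_rr(rr, am)
  layout <- rr_param_layout(rr)
  if (length(init) != length(layout)) {
    abort(sprintf("`init` must have length %d.", length(layout)))
  }
  run <- fit_engine(am, build, init, control)
  finish_fit(run, am, build, rr, ped, family = "RR",
             n_params = count_parameters(rr), layout = layout)
}
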