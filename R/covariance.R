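#' Evaluate a polynomial in time
#'
#' Antedependence coefficients and log innovation variances are polynomials
#' in the raw time value: `sum_q coeffs[q+1] * t^q`.
#'
#' @param coeffs Numeric coefficient vector, constant term first.
#' @param t Time value(s).
#' @return Numeric of the same length as `t`.
#' @export
eval_poly <- function(coeffs, t) {
  if (length(coeffs) == 0) abort("`coeffs` must be non-empty.")
  out <- rep(0, length(t))
  for (q in seq_along(coeffs)) out <- out + coeffs[q] * t^(q - 1)
  out
}

#' Innovation variance at a time point
#'
#' The innovation variance is modelled on the log scale as a polynomial in
#' time, `exp(sum_q b_q t^q)`, guaranteeing positivity.  The exponent is
#' capped at +/- 50 to guard against overflow during optimization.
#'
#' @param coeffs Coefficients of the log-variance polynomial.
#' @param t Time value(s).
#' @return Positive numeric.
#' @export
innovation_variance <- function(coeffs, t) {
  expo <- eval_poly(coeffs, t)
  exp(pmin(pmax(expo, -50), 50))
}

#' Trait-by-time cell index
#'
#' Cells are ordered time-major (all traits at the first time, then all
#' traits at the second, ...), with traits within a time slice following the
#' topological order imposed by lag-0 cross-dependences so that the
#' antedependence factor stays lower triangular.
#'
#' @param times Numeric time grid.
#' @param traits Trait labels in within-slice order.
#' @return A tibble with columns `cell`, `time`, `trait`, `label`.
#' @export
trait_time_cells <- function(times, traits) {
  times <- as.numeric(times)
  time <- rep(times, each = length(traits))
  trait <- rep(traits, times = length(times))
  tibble::tibble(
    cell = seq_along(time),
    time = time,
    trait = trait,
    label = paste0(trait, "@", time)
  )
}

#' Antedependence Cholesky factor of a random effect
#'
#' Builds the unit lower-triangular matrix `L` and the diagonal of innovation
#' variances `D` for which the inverse covariance is `L' D^-1 L`.  Row `j` of
#' `L` carries 1 on the diagonal, the negated within-trait antedependence
#' coefficients at the own-trait lagged cells, the negated cross-dependence
#' coefficients at the other trait's lagged cells, and the negated initial
#' correlation in the second trait's first-time row.  Lags reaching before
#' the first time point are truncated.
#'
#' @param effect A [sad_effect()].
#' @param params Numeric parameter slice matching `param_layout(effect)`.
#' @param times Numeric time grid.
#' @param traits Trait labels (defaults to the effect's traits).
#' @return List with `L`, `D` (vector of innovation variances) and `cells`
#'   (the [trait_time_cells()] index used).
#' @export
build_LD <- function(effect, params, times, traits = NULL, check = TRUE) {
  traits <- traits %||% names(effect$within)
  if (check) assert_valid_spec(effect, traits)
  ord_traits <- slice_trait_order(effect, traits)
  pv <- unpack_effect_params(effect, params, traits)
  times <- as.numeric(times)
  T_ <- length(times)
  ntr <- length(ord_traits)
  d <- T_ * ntr
  # cell index of (time j, trait position k) in time-major order
  cell_of <- function(j, k) (j - 1L) * ntr + k
  L <- diag(d)
  D <- numeric(d)
  for (k in seq_len(ntr)) {
    tr <- ord_traits[k]
    w <- effect$within[[tr]]
    theta <- lapply(seq_len(w$order), function(s) eval_poly(pv$within[[tr]]$a[[s]], times))
    for (j in seq_len(T_)) {
      r <- cell_of(j, k)
      for (s in seq_len(w$order)) {
        if (j - s >= 1) L[r, cell_of(j - s, k)] <- -theta[[s]][j]
      }
    }
    D[cell_of(seq_len(T_), k)] <- innovation_variance(pv$within[[tr]]$b, times)
  }
  for (ci in seq_along(effect$crosses)) {
    cr <- effect$crosses[[ci]]
    k_to <- match(cr$to, ord_traits)
    k_from <- match(cr$from, ord_traits)
    lags <- cr$start_lag:cr$end_lag
    for (li in seq_along(lags)) {
      s <- lags[li]
      delta <- eval_poly(pv$crosses[[ci]]$coef[[li]], times)
      for (j in seq_len(T_)) {
        if (j - s >= 1) L[cell_of(j, k_to), cell_of(j - s, k_from)] <- -delta[j]
      }
    }
  }
  if (!is.null(pv$rho)) {
    # second trait's first-time innovation regressed on the first trait's
    L[2, 1] <- -pv$rho
  }
  cells <- trait_time_cells(times, ord_traits)
  dimnames(L) <- list(cells$label, cells$label)
  names(D) <- cells$label
  list(L = L, D = D, cells = cells)
}

#' SAD covariance matrix of a random effect
#'
#' Returns the covariance matrix over the trait-by-time grid implied by the
#' antedependence factorization: the inverse covariance is `L' D^-1 L`, so
#' the covariance itself is computed as `L^-1 D L^-T` by triangular solves.
#' The result is always symmetric positive definite for finite parameters.
#'
#' @inheritParams build_LD
#' @param declared_order Logical: return rows/columns in the declared
#'   trait order within each time slice (default) rather than the
#'   topological order used internally.
#' @return A symmetric positive-definite matrix with trait-time labels.
#' @export
sad_covariance <- function(effect, params, times, traits = NULL,
                           declared_order = TRUE, check = TRUE) {
  traits <- traits %||% names(effect$within)
  ld <- build_LD(effect, params, times, traits, check = check)
  if (any(ld$D <= 0)) abort("Non-positive innovation variance.")
  Linv <- forwardsolve(ld$L, diag(nrow(ld$L)))
  P <- Linv %*% (ld$D * t(Linv))
  P <- (P + t(P)) / 2
  dimnames(P) <- dimnames(ld$L)
  if (declared_order && !identical(ld$cells$trait[seq_along(traits)], traits)) {
    want <- trait_time_cells(times, traits)$label
    P <- P[want, want, drop = FALSE]
  }
  P
}

# Precompiled evaluator for one effect's covariance: enumerates the L/D
# entry pattern once so that repeated evaluation (optimizer inner loop)
# is a few small matrix products.  Produces the same matrix as
# sad_covariance() in declared trait order.
effect_cov_plan <- function(effect, times, traits) {
  assert_valid_spec(effect, traits)
  ord_traits <- slice_trait_order(effect, traits)
  times <- as.numeric(times)
  T_ <- length(times)
  ntr <- length(ord_traits)
  d <- T_ * ntr
  cell_of <- function(j, k) (j - 1L) * ntr + k

  # parameter offsets in the effect slice (mirrors unpack_effect_params)
  i <- 0L
  a_idx <- list(); cross_idx <- list(); b_idx <- list()
  for (tr in traits) {
    w <- effect$within[[tr]]
    a_idx[[tr]] <- lapply(seq_len(w$order), function(s) {
      out <- i + seq_len(w$ante_degrees[s] + 1L)
      i <<- i + w$ante_degrees[s] + 1L
      out
    })
  }
  for (ci in seq_along(effect$crosses)) {
    cr <- effect$crosses[[ci]]
    cross_idx[[ci]] <- lapply(seq_along(cr$degrees), function(li) {
      out <- i + seq_len(cr$degrees[li] + 1L)
      i <<- i + cr$degrees[li] + 1L
      out
    })
  }
  for (tr in traits) {
    w <- effect$within[[tr]]
    b_idx[[tr]] <- i + seq_len(w$innov_degree + 1L)
    i <- i + w$innov_degree + 1L
  }
  rho_idx <- if (effect$initial_correlation) i + 1L else NULL
  k_eff <- i + as.integer(effect$initial_correlation)

  rows <- integer(0); cols <- integer(0)
  EL <- matrix(0, 0, k_eff)
  add_entry <- function(r, c, pidx, tj) {
    rows <<- c(rows, r); cols <<- c(cols, c)
    e <- numeric(k_eff)
    e[pidx] <- tj^(seq_along(pidx) - 1L)
    EL <<- rbind(EL, e)
  }
  for (k in seq_len(ntr)) {
    tr <- ord_traits[k]
    w <- effect$within[[tr]]
    for (j in seq_len(T_)) {
      for (s in seq_len(w$order)) {
        if (j - s >= 1) add_entry(cell_of(j, k), cell_of(j - s, k),
                                  a_idx[[tr]][[s]], times[j])
      }
    }
  }
  for (ci in seq_along(effect$crosses)) {
    cr <- effect$crosses[[ci]]
    k_to <- match(cr$to, ord_traits); k_from <- match(cr$from, ord_traits)
    lags <- cr$start_lag:cr$end_lag
    for (li in seq_along(lags)) {
      for (j in seq_len(T_)) {
        if (j - lags[li] >= 1) {
          add_entry(cell_of(j, k_to), cell_of(j - lags[li], k_from),
                    cross_idx[[ci]][[li]], times[j])
        }
      }
    }
  }
  ED <- matrix(0, d, k_eff)
  for (k in seq_len(ntr)) {
    tr <- ord_traits[k]
    for (j in seq_len(T_)) {
      ED[cell_of(j, k), b_idx[[tr]]] <- times[j]^(seq_along(b_idx[[tr]]) - 1L)
    }
  }
  lab_ord <- trait_time_cells(times, ord_traits)$label
  lab_dec <- trait_time_cells(times, traits)$label
  perm <- match(lab_dec, lab_ord)
  ij <- cbind(rows, cols)
  Id <- diag(d)
  function(par) {
    L <- Id
    if (nrow(ij)) L[ij] <- -as.vector(EL %*% par)
    if (!is.null(rho_idx)) L[2, 1] <- -tanh(par[rho_idx])
    D <- exp(pmin(pmax(as.vector(ED %*% par), -50), 50))
    Linv <- forwardsolve(L, Id)
    U <- Linv %*% (D * t(Linv))
    U <- (U + t(U)) / 2
    U <- U[perm, perm, drop = FALSE]
    dimnames(U) <- list(lab_dec, lab_dec)
    U
  }
}

#' Correlation matrix from a covariance matrix
#'
#' @param cov Symmetric covariance matrix with positive diagonal.
#' @return Correlation matrix with unit diagonal, preserving labels.
#' @export
correlation_from_covariance <- function(cov) {
  if (any(diag(cov) <= 0)) abort("Covariance diagonal must be positive.")
  stats::cov2cor(cov)
}

#' Export a labelled matrix to delimited text
#'
#' @param m Matrix with row/column labels (e.g. from [sad_covariance()]).
#' @param path Output file.
#' @param delim Field delimiter.
#' @return Invisibly `path`.
#' @export
write_matrix <- function(m, path, delim = ",") {
  df <- tibble::as_tibble(m, rownames = "cell")
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Read a labelled matrix written by [write_matrix()]
#' @param path Input file.
#' @param delim Field delimiter.
#' @return A labelled matrix.
#' @export
read_matrix <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
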