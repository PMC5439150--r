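#' REML log-likelihood of a multiple-trait SAD mixed model
#'
#' Evaluates the restricted log-likelihood of the no-residual model
#' `y = X beta + u + p (+ group)`, where the genetic effect has covariance
#' `A (x) U`, the permanent effect `I (x) P`, and `U`, `P` are the SAD
#' covariance matrices implied by `params`.  The criterion is the density of
#' an orthonormal basis of error contrasts,
#' `-0.5 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| - log|X'X| + y'Py ]`,
#' which is invariant to nonsingular reparameterizations of the fixed
#' design.  Evaluation is block-wise over independent animal families, with
#' a Woodbury correction for the group random intercept.
#'
#' @param params Numeric parameter vector in [param_layout()] order
#'   (unconstrained scale; the initial correlation is `atanh`-transformed).
#' @param am An [assemble_model()] object.
#' @param spec The [sad_model()] specification used in assembly.
#' @return The REML log-likelihood (scalar).
#' @export
reml_loglik <- function(params, am, spec) {
  build <- sad_param_builder(spec)
  reml_core(build(params), am)$loglik
}

# Turn a spec into a builder: params -> list(U, P, group_var)
sad_param_builder <- function(spec) {
  force(spec)
  assert_valid_spec(spec)
  plan_g <- effect_cov_plan(spec$genetic, spec$times, spec$traits)
  plan_p <- effect_cov_plan(spec$permanent, spec$times, spec$traits)
  kg <- count_parameters(spec$genetic)
  kp <- count_parameters(spec$permanent)
  ng <- if (is.null(spec$group)) 0L else length(spec$traits)
  function(par) {
    if (length(par) != kg + kp + ng) {
      abort(sprintf("Parameter vector has length %d; spec requires %d.",
                    length(par), kg + kp + ng))
    }
    list(
      U = plan_g(par[seq_len(kg)]),
      P = plan_p(par[kg + seq_len(kp)]),
      group_var = if (ng > 0)
        setNames(exp(pmin(par[kg + kp + seq_len(ng)], 50)), spec$traits)
      else NULL
    )
  }
}

# Core REML evaluation given covariance components.
# Returns loglik plus the pieces needed for GLS estimates and BLUP.
reml_core <- function(comp, am) {
  U <- comp$U; P <- comp$P
  q <- if (is.null(am$Zg)) 0L else ncol(am$Zg)
  if (q > 0 && is.null(comp$group_var)) {
    abort("Assembled model includes a group effect but no group variances supplied.")
  }
  pr <- reml_block_products(am$Tm, am$offsets, am$an, am$cell0, am$Amats, U, P)
  if (!isTRUE(pr$ok)) {
    return(list(loglik = -Inf))
  }
  p <- am$p
  ix <- seq_len(p); iy <- p + 1L; ig <- if (q > 0) p + 1L + seq_len(q) else integer(0)
  M <- pr$M
  logdetV <- pr$logdet
  if (q > 0) {
    svec <- comp$group_var[am$group_cols$trait]
    Wmat <- diag(1 / svec, q) + M[ig, ig]
    cw <- tryCatch(chol(Wmat), error = function(e) NULL)
    if (is.null(cw)) return(list(loglik = -Inf))
    logdetV <- logdetV + sum(log(svec)) + 2 * sum(log(diag(cw)))
    # a'V^-1 b = a'Vb^-1 b - (Zg'Vb^-1 a)' W^-1 (Zg'Vb^-1 b)
    Mg <- M[ig, c(ix, iy), drop = FALSE]
    corr <- crossprod(Mg, chol2inv(cw) %*% Mg)
    Mxy <- M[c(ix, iy), c(ix, iy)] - corr
  } else {
    Mxy <- M[c(ix, iy), c(ix, iy)]
  }
  XtViX <- Mxy[seq_len(p), seq_len(p), drop = FALSE]
  XtViy <- Mxy[seq_len(p), p + 1L]
  ytViy <- Mxy[p + 1L, p + 1L]
  cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cx)) return(list(loglik = -Inf))
  beta <- backsolve(cx, forwardsolve(t(cx), XtViy))
  yPy <- ytViy - sum(XtViy * beta)
  ll <- -0.5 * (logdetV + 2 * sum(log(diag(cx))) - am$logdetXtX +
                  yPy + (am$n - p) * log(2 * pi))
  list(loglik = ll, beta = setNames(beta, colnames(am$X)),
       Cinv = chol2inv(cx),
       U = U, P = P, group_var = comp$group_var)
}

# Solve V x = rhs for the full phenotype covariance (blocks + group part).
solve_V <- function(comp, am, rhs) {
  rhs <- as.matrix(rhs)
  q <- if (is.null(am$Zg)) 0L else ncol(am$Zg)
  if (q == 0) {
    return(reml_block_solve(rhs, am$offsets, am$an, am$cell0, am$Amats,
                            comp$U, comp$P))
  }
  S1 <- reml_block_solve(cbind(rhs, am$Zg), am$offsets, am$an, am$cell0,
                         am$Amats, comp$U, comp$P)
  k <- ncol(rhs)
  Vbr <- S1[, seq_len(k), drop = FALSE]
  VbZ <- S1[, k + seq_len(q), drop = FALSE]
  svec <- comp$group_var[am$group_cols$trait]
  Wmat <- diag(1 / svec, q) + crossprod(am$Zg, VbZ)
  Vbr - VbZ %*% solve(Wmat, crossprod(am$Zg, Vbr))
}
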