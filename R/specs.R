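#' Within-trait structured antedependence specification
#'
#' A single-trait SAD structure is described by the antedependence order
#' `order` (number of own-trait lags entering the recursion), one polynomial
#' degree per antedependence coefficient, and the polynomial degree of the log
#' innovation variance.  The compact field code `SAD a b1...ba g` (e.g.
#' `"111"`, `"2201"`) concatenates these digits: order first, then one degree
#' per antedependence coefficient, then the innovation-variance degree.
#'
#' @param order Antedependence order (non-negative integer), or a compact
#'   character code such as `"111"` from which all fields are parsed.
#' @param ante_degrees Integer vector of polynomial degrees, one per
#'   antedependence coefficient (length `order`).
#' @param innov_degree Polynomial degree of the log innovation variance.
#' @return An object of class `sad_within`.
#' @examples
#' sad_within("111")
#' sad_within(2, c(2, 0), 1)   # the SAD 2201 structure
#' @export
sad_within <- function(order, ante_degrees = integer(), innov_degree = 0) {
  if (is.character(order)) {
    return(parse_sad_code(order))
  }
  order <- as.integer(order)
  ante_degrees <- as.integer(ante_degrees)
  innov_degree <- as.integer(innov_degree)
  if (length(order) != 1L || is.na(order) || order < 0L) {
    abort("`order` must be a single non-negative integer.")
  }
  if (length(ante_degrees) != order || anyNA(ante_degrees) || any(ante_degrees < 0L)) {
    abort("`ante_degrees` must hold one non-negative degree per antedependence coefficient.")
  }
  if (length(innov_degree) != 1L || is.na(innov_degree) || innov_degree < 0L) {
    abort("`innov_degree` must be a single non-negative integer.")
  }
  structure(
    list(order = order, ante_degrees = ante_degrees, innov_degree = innov_degree),
    class = "sad_within"
  )
}

#' Parse a compact SAD code
#'
#' @param code Character scalar like `"100"`, `"111"` or `"2201"`: first digit
#'   is the antedependence order `a`, the next `a` digits are the degrees of
#'   the antedependence coefficient polynomials, and the final digit is the
#'   degree of the log innovation variance polynomial.
#' @return A [sad_within()] object.
#' @export
parse_sad_code <- function(code) {
  code <- gsub("^\\s*SAD\\s*", "", as.character(code)[1])
  digits <- suppressWarnings(as.integer(strsplit(code, "")[[1]]))
  if (anyNA(digits) || length(digits) < 2L) {
    abort(sprintf("Cannot parse SAD code '%s'.", code))
  }
  order <- digits[1]
  if (length(digits) != order + 2L) {
    abort(sprintf(
      "SAD code '%s' has %d digits; order %d requires %d.",
      code, length(digits), order, order + 2L
    ))
  }
  sad_within(order,
             ante_degrees = if (order > 0) digits[2:(order + 1L)] else integer(),
             innov_degree = digits[length(digits)])
}

#' Label of a within-trait SAD structure
#' @param x A `sad_within` object.
#' @return Character scalar such as `"SAD 111"`.
#' @export
sad_label <- function(x) {
  stopifnot(inherits(x, "sad_within"))
  paste0("SAD ", paste0(c(x$order, x$ante_degrees, x$innov_degree), collapse = ""))
}

#' @export
print.sad_within <- function(x, ...) {
  cat(sad_label(x), "\n")
  invisible(x)
}

#' Cross-antedependence between two traits
#'
#' Regresses the `to` trait's random effect at time `t_j` on the `from`
#' trait's effect at times `t_{j-start_lag}, ..., t_{j-end_lag}`.  A starting
#' lag of 0 encodes a recursive same-time dependence (no simultaneous
#' feedback is permitted: the lag-0 dependence graph must be acyclic).
#' Omitting a cross in one direction encodes the purely recursive case.
#'
#' @param from,to Trait labels (must differ).
#' @param start_lag,end_lag Lag window, `0 <= start_lag <= end_lag`.
#' @param degrees Polynomial degrees, one per lag (recycled if scalar).
#' @return An object of class `sad_cross`.
#' @export
sad_cross <- function(from, to, start_lag = 0, end_lag = start_lag, degrees = 0) {
  start_lag <- as.integer(start_lag); end_lag <- as.integer(end_lag)
  if (identical(from, to)) abort("`from` and `to` traits must differ.")
  if (start_lag < 0L || end_lag < start_lag) {
    abort("Require 0 <= start_lag <= end_lag.")
  }
  n_lag <- end_lag - start_lag + 1L
  degrees <- as.integer(rep_len(degrees, n_lag))
  if (anyNA(degrees) || any(degrees < 0L)) abort("`degrees` must be non-negative.")
  structure(
    list(from = as.character(from), to = as.character(to),
         start_lag = start_lag, end_lag = end_lag, degrees = degrees),
    class = "sad_cross"
  )
}

#' Antedependence structure of one random effect
#'
#' Bundles the within-trait SAD structures of all traits, any
#' cross-antedependences, and an optional initial correlation between the two
#' traits' innovations at the first time point.  The initial correlation is
#' only identifiable when neither direction carries a lag-0 (same-time)
#' cross-dependence.
#'
#' @param within Named list of [sad_within()] structures, one per trait
#'   (compact character codes accepted).
#' @param crosses List of [sad_cross()] objects.
#' @param initial_correlation Logical: allow a correlation between the two
#'   traits' innovations at the first time point.
#' @param name Optional label (e.g. `"genetic"`).
#' @return An object of class `sad_effect`.
#' @examples
#' sad_effect(within = list(LS = "111", ABW = "111"),
#'            crosses = list(sad_cross("LS", "ABW", 0, 0, degrees = 2)))
#' @export
sad_effect <- function(within, crosses = list(), initial_correlation = FALSE,
                       name = NULL) {
  if (is.null(names(within)) || any(!nzchar(names(within)))) {
    abort("`within` must be a named list (names are trait labels).")
  }
  within <- lapply(within, function(w) if (is.character(w)) parse_sad_code(w) else w)
  ok <- vapply(within, inherits, logical(1), what = "sad_within")
  if (!all(ok)) abort("Every `within` entry must be a `sad_within`.")
  if (inherits(crosses, "sad_cross")) crosses <- list(crosses)
  ok <- vapply(crosses, inherits, logical(1), what = "sad_cross")
  if (length(crosses) && !all(ok)) abort("Every `crosses` entry must be a `sad_cross`.")
  structure(
    list(name = name, within = within, crosses = crosses,
         initial_correlation = isTRUE(initial_correlation)),
    class = "sad_effect"
  )
}

#' Full model specification for a multiple-trait SAD mixed model
#'
#' The phenotype decomposes as fixed effects + additive genetic effect +
#' pseudo-permanent animal effect, with no separate residual: the permanent
#' covariance absorbs residual variation.  Both random animal effects carry
#' SAD covariance structures over the trait-by-time grid; an optional shared
#' random intercept (e.g. contemporary group) with independent per-trait
#' variances can be added.
#'
#' @param traits Character vector of trait labels (order is the display
#'   order; lag-0 crosses may impose a topological order internally).
#' @param times Strictly increasing numeric time points (e.g. parities 1:5).
#' @param genetic,permanent [sad_effect()] structures.
#' @param fixed Named list mapping each trait to a one-sided formula of fixed
#'   effects evaluated on the phenotype table (default intercept only).
#' @param group Optional name of a grouping column in the data to be fitted
#'   as a random intercept, constant over times, with independent per-trait
#'   variances.
#' @return An object of class `sad_model_spec`.
#' @export
sad_model <- function(traits, times, genetic, permanent, fixed = NULL,
                      group = NULL) {
  traits <- as.character(traits)
  times <- as.numeric(times)
  if (length(traits) < 1L) abort("At least one trait is required.")
  if (length(times) < 1L || anyNA(times) || any(!is.finite(times)) ||
      is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing and finite.")
  }
  stopifnot(inherits(genetic, "sad_effect"), inherits(permanent, "sad_effect"))
  genetic$name <- "genetic"; permanent$name <- "permanent"
  if (is.null(fixed)) {
    fixed <- setNames(replicate(length(traits), ~1), traits)
  }
  structure(
    list(traits = traits, times = times, genetic = genetic,
         permanent = permanent, fixed = fixed, group = group),
    class = "sad_model_spec"
  )
}

#' @export
print.sad_model_spec <- function(x, ...) {
  cat("Multiple-trait SAD model specification\n")
  cat("  traits:", paste(x$traits, collapse = ", "),
      " times:", paste(x$times, collapse = ", "), "\n")
  for (eff in list(x$genetic, x$permanent)) {
    cat("  ", eff$name, ": ",
        paste(sprintf("%s %s", names(eff$within),
                      vapply(eff$within, sad_label, character(1))),
              collapse = "; "), "\n", sep = "")
    for (cr in eff$crosses) {
      cat("     cross ", cr$from, " -> ", cr$to, " lags ", cr$start_lag, "..",
          cr$end_lag, " degrees ", paste(cr$degrees, collapse = ","), "\n",
          sep = "")
    }
    if (eff$initial_correlation) cat("     initial correlation at t1\n")
  }
  if (!is.null(x$group)) cat("  random group intercept:", x$group, "\n")
  cat("  free covariance parameters:", count_parameters(x), "\n")
  invisible(x)
}

# ---- parameter counting -----------------------------------------------------

#' Count free covariance parameters
#'
#' Each polynomial of degree `d` contributes `d + 1` coefficients: within-trait
#' antedependence coefficients and the log innovation variance per trait,
#' cross-antedependence coefficients per lag, plus one parameter for an
#' initial correlation and one variance per trait for a random group
#' intercept.
#'
#' @param x A `sad_within`, `sad_cross`, `sad_effect` or `sad_model_spec`.
#' @return Non-negative integer.
#' @examples
#' count_parameters(sad_within("111"))  # 4
#' @export
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.sad_within <- function(x) {
  as.integer(sum(x$ante_degrees + 1L) + x$innov_degree + 1L)
}

#' @export
count_parameters.sad_cross <- function(x) as.integer(sum(x$degrees + 1L))

#' @export
count_parameters.sad_effect <- function(x) {
  as.integer(sum(vapply(x$within, count_parameters, integer(1))) +
    sum(vapply(x$crosses, count_parameters, integer(1))) +
    as.integer(x$initial_correlation))
}

#' @export
count_parameters.sad_model_spec <- function(x) {
  assert_valid_spec(x)
  n_group <- if (is.null(x$group)) 0L else length(x$traits)
  count_parameters(x$genetic) + count_parameters(x$permanent) + n_group
}

#' Parameter count of an unstructured alternative
#'
#' Number of free parameters if each random effect instead carried a full
#' symmetric covariance matrix over the trait-by-time grid.
#'
#' @param n_traits,n_times Grid dimensions.
#' @param n_effects Number of unstructured random effects (default 2:
#'   genetic and permanent).
#' @return Integer, `n_effects * d(d+1)/2` with `d = n_traits * n_times`.
#' @export
unstructured_parameter_count <- function(n_traits, n_times, n_effects = 2) {
  d <- as.integer(n_traits) * as.integer(n_times)
  as.integer(n_effects * d * (d + 1L) / 2L)
}

# ---- validation -------------------------------------------------------------

#' Validate a model specification
#'
#' Checks structural and identifiability rules and returns a report rather
#' than erroring.  Rules include: every trait has a within-trait structure;
#' cross-dependences reference declared traits; the lag-0 cross-dependence
#' graph is acyclic (no simultaneous feedback); an initial correlation
#' requires both directions to be free of lag-0 crosses and exactly two
#' traits.
#'
#' @param x A `sad_effect` or `sad_model_spec`.
#' @param traits Trait labels (required when validating a bare effect).
#' @return A tibble with columns `rule` and `message`; zero rows mean the
#'   specification is valid.
#' @export
validate_spec <- function(x, traits = NULL) UseMethod("validate_spec")

violation <- function(rule, message) tibble::tibble(rule = rule, message = message)

no_violations <- function() tibble::tibble(rule = character(), message = character())

#' @export
validate_spec.sad_effect <- function(x, traits = NULL) {
  out <- list()
  traits <- traits %||% names(x$within)
  if (!setequal(names(x$within), traits)) {
    out <- c(out, list(violation(
      "within_per_trait",
      "every declared trait needs exactly one within-trait SAD structure"
    )))
  }
  for (cr in x$crosses) {
    if (!all(c(cr$from, cr$to) %in% traits)) {
      out <- c(out, list(violation(
        "cross_traits_declared",
        sprintf("cross %s->%s references undeclared traits", cr$from, cr$to)
      )))
    }
  }
  # duplicate cross directions
  dirs <- vapply(x$crosses, function(cr) paste(cr$from, cr$to, sep = "->"), character(1))
  if (anyDuplicated(dirs)) {
    out <- c(out, list(violation("cross_unique",
      "at most one cross-dependence per ordered trait pair")))
  }
  # lag-0 graph acyclic
  lag0 <- Filter(function(cr) cr$start_lag == 0L, x$crosses)
  if (length(lag0)) {
    edges <- vapply(lag0, function(cr) c(cr$from, cr$to), character(2))
    if (is.null(topological_order(traits, t(edges)))) {
      out <- c(out, list(violation("simultaneous_feedback",
        "lag-0 cross-dependences form a cycle (simultaneous feedback)")))
    }
  }
  if (x$initial_correlation) {
    if (length(traits) != 2L) {
      out <- c(out, list(violation("initial_correlation_two_traits",
        "an initial correlation is only supported for two traits")))
    }
    if (length(lag0)) {
      out <- c(out, list(violation("initial_correlation_requires_positive_lags",
        "initial correlation requires c>0 and c'>0 (no lag-0 cross in either direction)")))
    }
  }
  dplyr::bind_rows(c(list(no_violations()), out))
}

#' @export
validate_spec.sad_model_spec <- function(x, traits = NULL) {
  vg <- validate_spec(x$genetic, x$traits)
  vg$rule <- paste0("genetic:", vg$rule)
  vp <- validate_spec(x$permanent, x$traits)
  vp$rule <- paste0("permanent:", vp$rule)
  out <- dplyr::bind_rows(vg, vp)
  if (!setequal(names(x$fixed), x$traits)) {
    out <- dplyr::bind_rows(out, violation("fixed_per_trait",
      "`fixed` must name exactly the declared traits"))
  }
  out
}

#' Stop unless a specification is valid
#' @param x Specification object.
#' @param traits Trait labels for bare effects.
#' @return Invisibly `x`.
#' @export
assert_valid_spec <- function(x, traits = NULL) {
  rep <- validate_spec(x, traits)
  if (nrow(rep) > 0) {
    abort(paste0("Invalid specification:\n",
                 paste0("- [", rep$rule, "] ", rep$message, collapse = "\n")))
  }
  invisible(x)
}

# Kahn topological sort; returns NULL on a cycle.  `edges` is a 2-column
# matrix (from, to); stable with respect to the input order of `nodes`.
topological_order <- function(nodes, edges) {
  if (is.null(edges) || nrow(edges) == 0) return(nodes)
  indeg <- setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) indeg[edges[i, 2]] <- indeg[edges[i, 2]] + 1L
  out <- character(0)
  avail <- nodes[indeg[nodes] == 0L]
  indeg_w <- indeg
  while (length(avail)) {
    n <- avail[1]; avail <- avail[-1]
    out <- c(out, n)
    for (i in seq_len(nrow(edges))) {
      if (edges[i, 1] == n) {
        m <- edges[i, 2]
        indeg_w[m] <- indeg_w[m] - 1L
        if (indeg_w[m] == 0L) avail <- c(avail, m)
      }
    }
    avail <- nodes[nodes %in% avail]  # keep declared order among available
  }
  if (length(out) != length(nodes)) NULL else out
}

# Within-slice trait ordering: topological order of the lag-0 cross graph,
# stable w.r.t. declared order.  Needed so the L factor stays lower triangular.
slice_trait_order <- function(effect, traits) {
  lag0 <- Filter(function(cr) cr$start_lag == 0L, effect$crosses)
  if (!length(lag0)) return(traits)
  edges <- do.call(rbind, lapply(lag0, function(cr) c(cr$from, cr$to)))
  ord <- topological_order(traits, edges)
  if (is.null(ord)) abort("lag-0 cross-dependences form a cycle.")
  ord
}

# ---- parameter layout -------------------------------------------------------

#' Deterministic layout of the free-parameter vector
#'
#' The order is, per random effect: antedependence coefficients trait by
#' trait (coefficient `s`, then power `q`), then cross-antedependence
#' coefficients in declared order (lag, then power), then log innovation
#' variance coefficients trait by trait, then the initial correlation; group
#' intercept log-variances come last.  Trait prefixes are dropped for
#' single-trait structures, effect prefixes for bare effects.
#'
#' @param x A `sad_within`, `sad_effect` or `sad_model_spec`.
#' @param traits Optional trait labels for a bare effect.
#' @return Character vector of parameter names, with length equal to
#'   [count_parameters()].
#' @export
param_layout <- function(x, traits = NULL) UseMethod("param_layout")

#' @export
param_layout.sad_within <- function(x, traits = NULL) {
  a <- unlist(lapply(seq_len(x$order), function(s) {
    sprintf("a_%d,%d", s, 0:x$ante_degrees[s])
  }))
  c(a, sprintf("b_%d", 0:x$innov_degree))
}

#' @export
param_layout.sad_effect <- function(x, traits = NULL) {
  trs <- traits %||% names(x$within)
  single <- length(trs) == 1L
  pre <- function(tr, nm) if (single) nm else paste0(tr, ".", nm)
  a <- unlist(lapply(trs, function(tr) {
    w <- x$within[[tr]]
    if (w$order == 0L) return(character(0))
    pre(tr, unlist(lapply(seq_len(w$order), function(s)
      sprintf("a_%d,%d", s, 0:w$ante_degrees[s]))))
  }))
  d <- unlist(lapply(x$crosses, function(cr) {
    lags <- cr$start_lag:cr$end_lag
    unlist(lapply(seq_along(lags), function(i)
      sprintf("%s<-%s.d_%d,%d", cr$to, cr$from, lags[i], 0:cr$degrees[i])))
  }))
  b <- unlist(lapply(trs, function(tr)
    pre(tr, sprintf("b_%d", 0:x$within[[tr]]$innov_degree))))
  out <- c(a, d, b, if (x$initial_correlation) "rho")
  as.character(out)
}

#' @export
param_layout.sad_model_spec <- function(x, traits = NULL) {
  assert_valid_spec(x)
  out <- c(
    paste0("genetic.", param_layout(x$genetic, x$traits)),
    paste0("permanent.", param_layout(x$permanent, x$traits))
  )
  if (!is.null(x$group)) {
    out <- c(out, paste0("group.", x$traits, ".logvar"))
  }
  out
}

# Split a model-level parameter vector into per-effect slices (plus group
# log-variances).  Layout must match param_layout().
split_params <- function(spec, par) {
  kg <- count_parameters(spec$genetic)
  kp <- count_parameters(spec$permanent)
  ng <- if (is.null(spec$group)) 0L else length(spec$traits)
  if (length(par) != kg + kp + ng) {
    abort(sprintf("Parameter vector has length %d; spec requires %d.",
                  length(par), kg + kp + ng))
  }
  list(
    genetic = par[seq_len(kg)],
    permanent = par[kg + seq_len(kp)],
    group_logvar = if (ng > 0) par[kg + kp + seq_len(ng)] else numeric(0)
  )
}

# Unpack one effect's parameter slice into evaluable pieces:
# $within[[trait]]$a (list of coefficient vectors per lag s), $b;
# $crosses[[i]]$coef (list per lag); $rho (numeric, on (-1,1)).
unpack_effect_params <- function(effect, par, traits = NULL) {
  trs <- traits %||% names(effect$within)
  i <- 0L
  take <- function(n) {
    out <- par[i + seq_len(n)]
    i <<- i + n
    out
  }
  within <- list()
  for (tr in trs) {
    w <- effect$within[[tr]]
    within[[tr]] <- list(
      a = lapply(seq_len(w$order), function(s) take(w$ante_degrees[s] + 1L)),
      b = NULL
    )
  }
  crosses <- lapply(effect$crosses, function(cr) {
    list(from = cr$from, to = cr$to, lags = cr$start_lag:cr$end_lag,
         coef = lapply(seq_along(cr$degrees), function(j) take(cr$degrees[j] + 1L)))
  })
  for (tr in trs) {
    within[[tr]]$b <- take(effect$within[[tr]]$innov_degree + 1L)
  }
  rho <- if (effect$initial_correlation) tanh(take(1L)) else NULL
  if (i != length(par)) abort("Parameter slice length mismatch.")
  list(within = within, crosses = crosses, rho = rho)
}

#' Preset model specifications at the scale of the motivating datasets
#'
#' `rabbit_spec()` returns the two-trait specification selected for the
#' rabbit-style design (genetic: SAD 111 on both traits plus a recursive
#' lag-0 cross of degree 2 from litter size to birth weight; permanent:
#' SAD 100 for litter size, SAD 111 for birth weight plus the same form of
#' cross), totalling 20 covariance parameters.  `pig_spec()` returns the
#' pig-style selection (genetic: SAD 101 / SAD 111 with a degree-0 lag-0
#' cross; permanent: SAD 101 on both traits with a degree-1 lag-0 cross,
#' plus a contemporary-group random intercept), 16 covariance parameters
#' for the genetic and permanent structures.
#'
#' @param times Time grid (default parities 1 to 5).
#' @param group Group column name for `pig_spec` (default `"cg"`; `NULL`
#'   drops the random group intercept).
#' @return A [sad_model()] specification.
#' @export
rabbit_spec <- function(times = 1:5) {
  sad_model(
    traits = c("LS", "ABW"), times = times,
    genetic = sad_effect(
      within = list(LS = "111", ABW = "111"),
      crosses = list(sad_cross("LS", "ABW", 0, 0, degrees = 2))
    ),
    permanent = sad_effect(
      within = list(LS = "100", ABW = "111"),
      crosses = list(sad_cross("LS", "ABW", 0, 0, degrees = 2))
    )
  )
}

#' @rdname rabbit_spec
#' @export
pig_spec <- function(times = 1:5, group = "cg") {
  sad_model(
    traits = c("LS", "ABW"), times = times,
    genetic = sad_effect(
      within = list(LS = "101", ABW = "111"),
      crosses = list(sad_cross("LS", "ABW", 0, 0, degrees = 0))
    ),
    permanent = sad_effect(
      within = list(LS = "101", ABW = "101"),
      crosses = list(sad_cross("LS", "ABW", 0, 0, degrees = 1))
    ),
    group = group
  )
}
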