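#' Likelihood-ratio test between nested fits
#'
#' `statistic = 2 (logL_full - logL_nested)` (clipped at zero), with degrees
#' of freedom equal to the difference in covariance-parameter counts and a
#' chi-square reference.  Both fits must be on the same data (checked by a
#' fingerprint) with the same fixed effects.  Note that when the extra
#' parameter sits on a boundary of its space the chi-square reference is
#' conservative; all degree/order extensions tested by the stepwise
#' procedure are interior parameters.
#'
#' @param nested,full `sad_fit` objects, `nested` a restriction of `full`.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(nested, full) {
  stopifnot(inherits(nested, "sad_fit"), inherits(full, "sad_fit"))
  if (!isTRUE(all.equal(nested$fingerprint, full$fingerprint))) {
    abort("Fits are not on the same data (fingerprint mismatch).")
  }
  if (!identical(nested$family, full$family)) {
    abort("Fits are from different model families; compare with AIC instead.")
  }
  if (!spec_is_nested(nested$spec, full$spec)) {
    abort("`nested` is not a restriction of `full`.")
  }
  df <- full$n_params - nested$n_params
  if (df < 0) abort("`full` must have more covariance parameters than `nested`.")
  statistic <- max(0, 2 * (full$logLik - nested$logLik))
  # df = 0 covers the degenerate comparison of a model with itself
  p <- if (df == 0) as.numeric(statistic <= 1e-8) else {
    pchisq(statistic, df = df, lower.tail = FALSE)
  }
  tibble::tibble(statistic = statistic, df = df, p_value = p)
}

# Structural nesting check.
spec_is_nested <- function(n, f) {
  if (inherits(n, "rr_model_spec") && inherits(f, "rr_model_spec")) {
    return(identical(n$traits, f$traits) && identical(n$times, f$times) &&
             identical(n$group, f$group) &&
             all(n$genetic_degree <= f$genetic_degree) &&
             all(n$permanent_degree <= f$permanent_degree) &&
             (!n$residual_cor || f$residual_cor))
  }
  if (!inherits(n, "sad_model_spec") || !inherits(f, "sad_model_spec")) return(FALSE)
  if (!identical(n$traits, f$traits) || !identical(n$times, f$times) ||
      !identical(n$group, f$group)) {
    return(FALSE)
  }
  for (eff in c("genetic", "permanent")) {
    en <- n[[eff]]; ef <- f[[eff]]
    for (tr in n$traits) {
      wn <- en$within[[tr]]; wf <- ef$within[[tr]]
      if (wn$order > wf$order) return(FALSE)
      if (wn$order > 0 &&
          any(wn$ante_degrees > wf$ante_degrees[seq_len(wn$order)])) return(FALSE)
      if (wn$innov_degree > wf$innov_degree) return(FALSE)
    }
    for (cn in en$crosses) {
      match_f <- Filter(function(cf) cf$from == cn$from && cf$to == cn$to, ef$crosses)
      if (!length(match_f)) return(FALSE)
      cf <- match_f[[1]]
      if (cf$start_lag != cn$start_lag || cf$end_lag < cn$end_lag) return(FALSE)
      shared <- seq_len(cn$end_lag - cn$start_lag + 1L)
      if (any(cn$degrees > cf$degrees[shared])) return(FALSE)
    }
    if (en$initial_correlation && !ef$initial_correlation) return(FALSE)
  }
  TRUE
}

#' Candidate ladder of the stepwise single-trait search
#'
#' Generates and tests candidates in the published order: starting from a
#' base structure, first an increase of the innovation-variance degree
#' (`gamma`), then of each antedependence-coefficient degree (`beta_s`),
#' repeating that cycle while any increase is accepted; once a full cycle
#' brings no improvement, an increase of the antedependence order is tested
#' with a constant (degree 0) new coefficient, after which degree cycles
#' resume.  For example, if the accepted order-1 model is SAD 121, the next
#' candidate is SAD 2201.
#'
#' @param start A [sad_within()] (or code) to start from (typically
#'   `"100"`).
#' @param decide Function taking (candidate `sad_within`, current
#'   `sad_within`) and returning `TRUE` to accept the candidate.
#' @param max_order,max_degree Search caps ensuring termination.
#' @return List with `state` (the selected structure) and `candidates`
#'   (tibble of labels and decisions in test order).
#' @export
ladder_sequence <- function(start, decide, max_order = 2, max_degree = 2) {
  state <- if (is.character(start)) parse_sad_code(start) else start
  cand_log <- list()
  note <- function(cand, accepted) {
    cand_log[[length(cand_log) + 1]] <<- tibble::tibble(
      label = sad_label(cand), accepted = accepted)
  }
  try_candidate <- function(cand) {
    acc <- isTRUE(decide(cand, state))
    note(cand, acc)
    if (acc) state <<- cand
    acc
  }
  repeat {
    # degree cycles
    repeat {
      pass_improved <- FALSE
      if (state$innov_degree < max_degree) {
        cand <- sad_within(state$order, state$ante_degrees, state$innov_degree + 1L)
        if (try_candidate(cand)) pass_improved <- TRUE
      }
      for (s in seq_len(state$order)) {
        if (state$ante_degrees[s] < max_degree) {
          deg <- state$ante_degrees
          deg[s] <- deg[s] + 1L
          cand <- sad_within(state$order, deg, state$innov_degree)
          if (try_candidate(cand)) pass_improved <- TRUE
        }
      }
      if (!pass_improved) break
    }
    # order increase with a constant new antedependence coefficient
    if (state$order >= max_order) break
    cand <- sad_within(state$order + 1L, c(state$ante_degrees, 0L), state$innov_degree)
    if (!try_candidate(cand)) break
  }
  list(state = state, candidates = dplyr::bind_rows(cand_log))
}

#' Stepwise selection of within-trait SAD structures
#'
#' Applies the single-trait stepwise ladder (see [ladder_sequence()]) to the
#' genetic and then the pseudo-permanent effect of one trait, holding the
#' other effect's structure fixed at its current selection.  Each candidate
#' is accepted when the likelihood-ratio test against the current model is
#' significant at `alpha`.
#'
#' @param data Long-format phenotype table (filtered to `trait` if it
#'   contains several traits).
#' @param ped A [pedigree()].
#' @param trait Trait to analyze (defaults to the single trait present).
#' @param effects Which random effects to search, in order.
#' @param start Starting structure (default SAD 100).
#' @param alpha LRT significance level for accepting a candidate.
#' @param max_order,max_degree Search caps.
#' @param times Time grid (default: sorted unique times in the data).
#' @param fixed Optional one-sided fixed-effect formula for the trait.
#' @param control A [fit_control()]; selection defaults to single-start
#'   fits for speed.
#' @return List with the selected `genetic` and `permanent` structures, the
#'   selection `trace` (every candidate, with test results), and the final
#'   `fit`.
#' @export
stepwise_sad <- function(data, ped, trait = NULL,
                         effects = c("genetic", "permanent"),
                         start = "100", alpha = 0.05,
                         max_order = 2, max_degree = 2,
                         times = NULL, fixed = NULL,
                         control = fit_control(n_starts = 1)) {
  data <- tibble::as_tibble(data)
  trait <- trait %||% unique(data$trait)
  if (length(trait) != 1L) abort("Specify a single `trait` to search.")
  data <- dplyr::filter(data, .data$trait == !!trait)
  times <- times %||% sort(unique(data$time))
  fixed_list <- if (is.null(fixed)) NULL else setNames(list(fixed), trait)

  state <- list(
    genetic = if (is.character(start)) parse_sad_code(start) else start,
    permanent = if (is.character(start)) parse_sad_code(start) else start
  )
  make_spec <- function(st) {
    sad_model(traits = trait, times = times,
              genetic = sad_effect(within = setNames(list(st$genetic), trait)),
              permanent = sad_effect(within = setNames(list(st$permanent), trait)),
              fixed = fixed_list)
  }
  current_fit <- sad_fit(data, ped, make_spec(state), control = control)
  trace <- list()
  for (eff in effects) {
    decide <- function(cand, cur) {
      st2 <- state
      st2[[eff]] <- cand
      cand_fit <- tryCatch(
        sad_fit(data, ped, make_spec(st2), control = control),
        error = function(e) NULL
      )
      if (is.null(cand_fit)) {
        warn(sprintf("Candidate %s (%s) failed to fit; step skipped.",
                     sad_label(cand), eff))
        trace[[length(trace) + 1]] <<- tibble::tibble(
          effect = eff, label = sad_label(cand), logLik = NA_real_,
          n_params = NA_integer_, statistic = NA_real_, df = NA_integer_,
          p_value = NA_real_, accepted = FALSE)
        return(FALSE)
      }
      test <- lrt(current_fit, cand_fit)
      acc <- test$p_value < alpha
      trace[[length(trace) + 1]] <<- tibble::tibble(
        effect = eff, label = sad_label(cand), logLik = cand_fit$logLik,
        n_params = cand_fit$n_params, statistic = test$statistic,
        df = test$df, p_value = test$p_value, accepted = acc)
      if (acc) {
        state[[eff]] <<- cand
        current_fit <<- cand_fit
      }
      acc
    }
    res <- ladder_sequence(state[[eff]], decide,
                           max_order = max_order, max_degree = max_degree)
    state[[eff]] <- res$state
  }
  list(genetic = state$genetic, permanent = state$permanent,
       trace = dplyr::bind_rows(trace), fit = current_fit)
}

#' Select the cross-antedependence structure of a multiple-trait SAD model
#'
#' With the within-trait structures fixed from the single-trait step, starts
#' from a recursive lag-0 cross of degree 0 in the given direction (for the
#' genetic, then the permanent effect), accepting it and successive degree
#' increases by likelihood-ratio test.  A candidate combining an initial
#' correlation with a lag-0 cross is rejected up front as unidentifiable.
#'
#' @param data Two-trait long-format phenotype table.
#' @param ped A [pedigree()].
#' @param within Named list per effect (`genetic`, `permanent`) of named
#'   lists trait -> [sad_within()] structure.
#' @param direction Length-2 character vector `c(from, to)`: the biological
#'   direction of the recursive cross (a modelling input, not selected).
#' @param alpha LRT level.
#' @param max_degree Cap on the cross polynomial degree.
#' @param times Time grid (default from data).
#' @param fixed Optional named list of per-trait fixed-effect formulas.
#' @param test_initial_correlation Also test adding an initial correlation
#'   at the first time point; candidates that would combine it with a
#'   selected lag-0 cross are rejected before fitting (unidentifiable).
#' @param control A [fit_control()].
#' @return List with the selected `spec`, selection `trace` and final `fit`.
#' @export
select_cross <- function(data, ped, within, direction, alpha = 0.05,
                         max_degree = 2, times = NULL, fixed = NULL,
                         test_initial_correlation = FALSE,
                         control = fit_control(n_starts = 1)) {
  data <- tibble::as_tibble(data)
  traits <- unique(data$trait)
  if (length(traits) != 2L) abort("`select_cross` expects exactly two traits.")
  if (!all(direction %in% traits)) abort("`direction` must name the two traits.")
  traits <- c(direction[1], setdiff(traits, direction[1]))  # from-trait first
  times <- times %||% sort(unique(data$time))

  cross_state <- list(genetic = NULL, permanent = NULL)  # NULL = no cross
  ic_state <- list(genetic = FALSE, permanent = FALSE)
  make_spec <- function(cs, ic = ic_state) {
    sad_model(
      traits = traits, times = times,
      genetic = sad_effect(within = within$genetic,
                           crosses = if (is.null(cs$genetic)) list() else list(cs$genetic),
                           initial_correlation = ic$genetic),
      permanent = sad_effect(within = within$permanent,
                             crosses = if (is.null(cs$permanent)) list() else list(cs$permanent),
                             initial_correlation = ic$permanent),
      fixed = fixed
    )
  }
  current_fit <- sad_fit(data, ped, make_spec(cross_state), control = control)
  trace <- list()
  try_cross <- function(eff, cand) {
    cs2 <- cross_state
    cs2[[eff]] <- cand
    spec2 <- make_spec(cs2)
    rep <- validate_spec(spec2)
    label <- sprintf("%s cross %s->%s deg %d", eff, cand$from, cand$to,
                     max(cand$degrees))
    if (nrow(rep) > 0) {
      trace[[length(trace) + 1]] <<- tibble::tibble(
        effect = eff, label = paste0(label, " [rejected: ", rep$rule[1], "]"),
        logLik = NA_real_, n_params = NA_integer_, statistic = NA_real_,
        df = NA_integer_, p_value = NA_real_, accepted = FALSE)
      return(FALSE)
    }
    cand_fit <- sad_fit(data, ped, spec2, control = control)
    test <- lrt(current_fit, cand_fit)
    acc <- test$p_value < alpha
    trace[[length(trace) + 1]] <<- tibble::tibble(
      effect = eff, label = label, logLik = cand_fit$logLik,
      n_params = cand_fit$n_params, statistic = test$statistic, df = test$df,
      p_value = test$p_value, accepted = acc)
    if (acc) {
      cross_state[[eff]] <<- cand
      current_fit <<- cand_fit
    }
    acc
  }
  for (eff in c("genetic", "permanent")) {
    if (!try_cross(eff, sad_cross(direction[1], direction[2], 0, 0, degrees = 0))) next
    deg <- 0L
    while (deg < max_degree) {
      deg <- deg + 1L
      if (!try_cross(eff, sad_cross(direction[1], direction[2], 0, 0, degrees = deg))) {
        break
      }
    }
  }
  if (test_initial_correlation) {
    for (eff in c("genetic", "permanent")) {
      ic2 <- ic_state
      ic2[[eff]] <- TRUE
      spec2 <- make_spec(cross_state, ic2)
      rep <- validate_spec(spec2)
      label <- sprintf("%s initial correlation", eff)
      if (nrow(rep) > 0) {
        # unidentifiable together with a lag-0 cross: rejected before fitting
        trace[[length(trace) + 1]] <- tibble::tibble(
          effect = eff, label = paste0(label, " [rejected: ", rep$rule[1], "]"),
          logLik = NA_real_, n_params = NA_integer_, statistic = NA_real_,
          df = NA_integer_, p_value = NA_real_, accepted = FALSE)
        next
      }
      cand_fit <- sad_fit(data, ped, spec2, control = control)
      test <- lrt(current_fit, cand_fit)
      acc <- test$p_value < alpha
      trace[[length(trace) + 1]] <- tibble::tibble(
        effect = eff, label = label, logLik = cand_fit$logLik,
        n_params = cand_fit$n_params, statistic = test$statistic,
        df = test$df, p_value = test$p_value, accepted = acc)
      if (acc) {
        ic_state[[eff]] <- TRUE
        current_fit <- cand_fit
      }
    }
  }
  list(spec = make_spec(cross_state), trace = dplyr::bind_rows(trace),
       fit = current_fit)
}
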