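#' Synthetic designs at the scale of the motivating pig and rabbit datasets
#'
#' Ready-made [sim_design()]s emulating the two reproduction datasets that
#' motivate the package.  No real pig or rabbit records ship with the
#' package; these presets are synthetic stand-ins that reproduce the
#' *design* of those datasets — about 2300 recorded does (or 1800 sows),
#' five parities, declining litter counts across parities, and (for the
#' rabbit design) birth weight observed for only a minority of first-parity
#' litters — together with true parameters chosen so that the implied
#' heritability trajectories and correlation patterns fall in the
#' qualitative ranges typical of litter size (LS, low-to-moderate
#' heritability) and average birth weight (ABW, moderate heritability, a
#' strong negative same-parity permanent correlation with LS).
#'
#' `rabbit_like_design()` uses the rabbit-selected structure
#' ([rabbit_spec()]); `pig_like_design()` the pig-selected structure
#' ([pig_spec()]) including a contemporary-group random intercept.
#'
#' @param n_does,n_sows Number of recorded females (final-generation
#'   animals with phenotypes).
#' @param attrition,missingness Override the preset Table-1-style retention
#'   and trait-observation probabilities.
#' @return A [sim_design()].
#' @export
rabbit_like_design <- function(n_does = 2300, attrition = NULL,
                               missingness = NULL) {
  spec <- rabbit_spec()
  spec$fixed <- list(LS = ~ factor(time) + x, ABW = ~ factor(time) + x)
  params <- c(
    # genetic: LS SAD 111, ABW SAD 111, recursive lag-0 cross LS->ABW (deg 2)
    1.09, 0, 0.75, 0, -0.28, -0.22, -0.012, 0, -0.35, 3.75, -0.08,
    # permanent: LS SAD 100, ABW SAD 111, recursive lag-0 cross (deg 2)
    0.05, 0.05, 0, -2.35, -0.085, 0, 2.1, 4.56, 0
  )
  # nested families: 4 dams per sire, 5 recorded does per dam
  n_sires <- max(1L, round(n_does / 20))
  sim_design(
    spec, params,
    n_sires = n_sires, dams_per_sire = 4, offspring_per_dam = 5,
    mu = list(LS = c(8.1, 9.5, 10.0, 10.3, 10.0),
              ABW = c(84, 85, 83, 82, 82)),
    covariate_effect = c(LS = 0.3, ABW = 2),
    attrition = attrition %||% c(0.93, 0.97, 0.90, 0.84),
    missingness = missingness %||% list(
      LS = rep(1, 5),
      ABW = c(0.057, 0.51, 0.65, 0.55, 0.25)
    )
  )
}

#' @rdname rabbit_like_design
#' @export
pig_like_design <- function(n_sows = 1800, attrition = NULL,
                            missingness = NULL) {
  spec <- pig_spec()
  spec$fixed <- list(LS = ~ factor(time) + x, ABW = ~ factor(time) + x)
  params <- c(
    # genetic: LS SAD 101, ABW SAD 111, recursive lag-0 cross (deg 0)
    0.958, 0.995, 0, -0.9, 2.3, -1.2, 9.1, -3.5,
    # permanent: LS SAD 101, ABW SAD 101, recursive lag-0 cross (deg 1)
    0.05, 0.05, -4.4, -0.1, 2.25, 0, 5.9, 0,
    # contemporary-group variances (log scale)
    log(0.65), log(45)
  )
  n_sires <- max(1L, round(n_sows / 20))
  sim_design(
    spec, params,
    n_sires = n_sires, dams_per_sire = 4, offspring_per_dam = 5,
    mu = list(LS = c(11.7, 12.0, 12.6, 12.5, 12.4),
              ABW = c(1419, 1565, 1564, 1566, 1566)),
    covariate_effect = c(LS = 0.4, ABW = 5),
    n_groups = 60,
    attrition = attrition %||% c(0.75, 0.76, 0.60, 0.64),
    missingness = missingness
  )
}
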