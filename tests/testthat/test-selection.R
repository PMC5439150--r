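test_that("likelihood-ratio test bookkeeping", {
  set.seed(21)
  des <- sad100_single_design(n_sires = 15, dams_per_sire = 2, offspring_per_dam = 3)
  ped <- simulate_pedigree(des, 61)
  dat <- simulate_phenotypes(des, ped, 61)
  fit100 <- sad_fit(dat, ped, des$spec, control = fast_control())
  spec101 <- sad_model("y", 1:5,
                       sad_effect(within = list(y = "101")),
                       sad_effect(within = list(y = "100")))
  fit101 <- sad_fit(dat, ped, spec101, control = fast_control())

  # identical fits: statistic 0, p = 1
  same <- lrt(fit100, fit101)
  expect_identical(same$df, 1L)
  self <- lrt(fit100, sad_fit(dat, ped, des$spec, control = fast_control()))
  expect_equal(self$statistic, 0, tolerance = 1e-6)
  expect_equal(self$p_value, 1, tolerance = 1e-4)

  # df equals the parameter-count difference
  expect_identical(same$df, fit101$n_params - fit100$n_params)

  # order matters: the nested model must come first
  expect_error(lrt(fit101, fit100), "restriction")
  # different data are rejected by fingerprint
  dat2 <- dat; dat2$value <- dat2$value * 2
  fit_other <- sad_fit(dat2, ped, spec101, control = fast_control())
  expect_error(lrt(fit100, fit_other), "fingerprint")
})

test_that("structural nesting is checked", {
  s100 <- sad_model("y", 1:5, sad_effect(within = list(y = "100")),
                    sad_effect(within = list(y = "100")))
  s101 <- sad_model("y", 1:5, sad_effect(within = list(y = "101")),
                    sad_effect(within = list(y = "100")))
  s110 <- sad_model("y", 1:5, sad_effect(within = list(y = "110")),
                    sad_effect(within = list(y = "100")))
  expect_true(sadmix:::spec_is_nested(s100, s101))
  expect_true(sadmix:::spec_is_nested(s100, s110))
  expect_false(sadmix:::spec_is_nested(s101, s110))
  expect_false(sadmix:::spec_is_nested(s101, s100))
})

test_that("AIC counts covariance parameters only and is consistent", {
  fake <- structure(list(logLik = -100, n_params = 4L), class = "sad_fit")
  expect_equal(aic(fake), 208)
  # an unused extra parameter leaves logL unchanged and adds 2
  fake5 <- structure(list(logLik = -100, n_params = 5L), class = "sad_fit")
  expect_equal(aic(fake5) - aic(fake), 2)
})

test_that("the stepwise candidate ladder follows the published order", {
  # all degree improvements accepted twice, then nothing: the candidates
  # start SAD 101, SAD 111 and continue with the degree cycle before the
  # constant order-2 extension of the accepted model
  script <- c("SAD 101" = TRUE, "SAD 111" = TRUE, "SAD 112" = FALSE,
              "SAD 121" = FALSE, "SAD 2101" = FALSE)
  seen <- character(0)
  decide <- function(cand, cur) {
    seen <<- c(seen, sad_label(cand))
    isTRUE(script[[sad_label(cand)]])
  }
  res <- ladder_sequence("100", decide, max_order = 2, max_degree = 2)
  expect_identical(seen[1:2], c("SAD 101", "SAD 111"))
  expect_identical(sad_label(res$state), "SAD 111")
  # the order-2 candidate extends the accepted order-1 model with a
  # constant (degree 0) coefficient
  expect_identical(seen[length(seen)], "SAD 2101")

  # from an accepted SAD 121 the next order-2 candidate is SAD 2201
  seen <- character(0)
  res2 <- ladder_sequence("121", function(cand, cur) {
    seen <<- c(seen, sad_label(cand)); FALSE
  }, max_order = 2, max_degree = 2)
  expect_identical(seen, c("SAD 122", "SAD 2201"))
  expect_identical(sad_label(res2$state), "SAD 121")

  # nothing significant: selection stays at the starting structure
  res0 <- ladder_sequence("100", function(cand, cur) FALSE)
  expect_identical(sad_label(res0$state), "SAD 100")
})

test_that("null LRT rejection rate at df = 1 is near nominal", {
  # data simulated under SAD 100; test SAD 100 vs SAD 101 (an interior
  # parameter, so the chi-square reference applies without boundary issues)
  des <- sad100_single_design(theta_g = 0.4, theta_p = 0.1,
                              n_sires = 18, dams_per_sire = 2,
                              offspring_per_dam = 4, times = 1:3)
  spec101 <- sad_model("y", 1:3, sad_effect(within = list(y = "101")),
                       sad_effect(within = list(y = "100")))
  n_rep <- 200
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    ped <- simulate_pedigree(des, 3000 + r)
    dat <- simulate_phenotypes(des, ped, 3000 + r)
    f0 <- sad_fit(dat, ped, des$spec, control = fast_control(maxit = 200))
    f1 <- sad_fit(dat, ped, spec101, init = unname(c(f0$par[1:2], 0, f0$par[3:4])),
                  control = fast_control(maxit = 200))
    rej[r] <- lrt(f0, f1)$p_value < 0.05
  }
  # binomial 95% band around the nominal 5% level
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_gte(mean(rej), band[1] - 1e-9)
  expect_lte(mean(rej), band[2] + 1e-9)
})

test_that("stepwise selection finds strong time trends", {
  # SAD 111 truth with pronounced trends in both the antedependence
  # coefficient and the innovation variance
  spec111 <- sad_model("y", 1:5, sad_effect(within = list(y = "111")),
                       sad_effect(within = list(y = "100")))
  truth <- c(1.4, -0.3, -1, 0.4, 0.1, log(1.5))
  names(truth) <- param_layout(spec111)
  des <- sim_design(spec111, truth, n_sires = 60, dams_per_sire = 2,
                    offspring_per_dam = 4)
  hits <- 0L
  for (r in 1:5) {
    ped <- simulate_pedigree(des, 4000 + r)
    dat <- simulate_phenotypes(des, ped, 4000 + r)
    sel <- stepwise_sad(dat, ped, trait = "y", control = fast_control(maxit = 200))
    if (sad_label(sel$genetic) == "SAD 111") hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("cross-dependence selection keeps true crosses and drops absent ones", {
  within <- list(genetic = list(y1 = sad_within("100"), y2 = sad_within("100")),
                 permanent = list(y1 = sad_within("100"), y2 = sad_within("100")))
  # truth without any cross-dependence
  spec0 <- sad_model(c("y1", "y2"), 1:4,
                     sad_effect(within = within$genetic),
                     sad_effect(within = within$permanent))
  truth0 <- c(0.5, 0.5, 0, 0, 0.1, 0.1, log(2), log(2))
  names(truth0) <- param_layout(spec0)
  des0 <- sim_design(spec0, truth0, n_sires = 40, dams_per_sire = 2,
                     offspring_per_dam = 4)
  ped <- simulate_pedigree(des0, 71)
  dat <- simulate_phenotypes(des0, ped, 71)
  sel0 <- select_cross(dat, ped, within, direction = c("y1", "y2"),
                       control = fast_control(maxit = 200))
  # the trace records one degree-0 candidate per effect (plus any degree
  # escalations after an acceptance), and the selected spec mirrors it
  expect_identical(sum(grepl("deg 0", sel0$trace$label)), 2L)
  expect_identical(length(sel0$spec$genetic$crosses) > 0,
                   any(sel0$trace$accepted[sel0$trace$effect == "genetic"]))

  # truth with a strong permanent lag-0 cross
  specx <- sad_model(c("y1", "y2"), 1:4,
                     sad_effect(within = within$genetic),
                     sad_effect(within = within$permanent,
                                crosses = list(sad_cross("y1", "y2", 0, 0, 0))))
  truthx <- c(0.5, 0.5, 0, 0, 0.1, 0.1, -0.8, log(2), log(2))
  names(truthx) <- param_layout(specx)
  desx <- sim_design(specx, truthx, n_sires = 40, dams_per_sire = 2,
                     offspring_per_dam = 4)
  pedx <- simulate_pedigree(desx, 72)
  datx <- simulate_phenotypes(desx, pedx, 72)
  selx <- select_cross(datx, pedx, within, direction = c("y1", "y2"),
                       control = fast_control(maxit = 200))
  expect_identical(length(selx$spec$permanent$crosses), 1L)
})

test_that("an initial-correlation candidate alongside a lag-0 cross is rejected before fitting", {
  within <- list(genetic = list(y1 = sad_within("100"), y2 = sad_within("100")),
                 permanent = list(y1 = sad_within("100"), y2 = sad_within("100")))
  specx <- sad_model(c("y1", "y2"), 1:3,
                     sad_effect(within = within$genetic,
                                crosses = list(sad_cross("y1", "y2", 0, 0, 0))),
                     sad_effect(within = within$permanent,
                                crosses = list(sad_cross("y1", "y2", 0, 0, 0))))
  truth <- c(0.5, 0.5, -0.9, 0, 0, 0.1, 0.1, -0.9, log(2), log(2))
  names(truth) <- param_layout(specx)
  des <- sim_design(specx, truth, n_sires = 30, dams_per_sire = 2,
                    offspring_per_dam = 4)
  ped <- simulate_pedigree(des, 73)
  dat <- simulate_phenotypes(des, ped, 73)
  sel <- select_cross(dat, ped, within, direction = c("y1", "y2"),
                      test_initial_correlation = TRUE,
                      control = fast_control(maxit = 150))
  ic_rows <- grepl("initial correlation", sel$trace$label)
  expect_true(any(ic_rows))
  # wherever the lag-0 cross was kept, the candidate is vetoed without a fit
  kept_cross <- grepl("rejected: ", sel$trace$label[ic_rows])
  if (length(sel$spec$genetic$crosses) || length(sel$spec$permanent$crosses)) {
    expect_true(any(kept_cross))
    expect_true(all(is.na(sel$trace$logLik[ic_rows][kept_cross])))
  }
})
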