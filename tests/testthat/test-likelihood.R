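make_tiny_instance <- function(group = FALSE) {
  ped <- pedigree(
    c("s1", "d1", "d2", "a", "b", "c"),
    c(NA, NA, NA, "s1", "s1", NA),
    c(NA, NA, NA, "d1", "d2", NA)
  )
  spec <- sad_model(
    traits = c("y1", "y2"), times = 1:2,
    genetic = random_small_effect(with_rho = FALSE),
    permanent = random_small_effect(with_rho = FALSE),
    fixed = list(y1 = ~x, y2 = ~1),
    group = if (group) "g" else NULL
  )
  dat <- tidyr::expand_grid(animal = c("a", "b", "c"), time = 1:2,
                            trait = c("y1", "y2"))
  dat$x <- rnorm(nrow(dat))
  dat$value <- rnorm(nrow(dat), sd = 2)
  if (group) dat$g <- sample(c("g1", "g2"), nrow(dat), replace = TRUE)
  dat <- dat[-sample(nrow(dat), 3), ]  # unbalanced missing cells
  list(ped = ped, spec = spec, dat = dat)
}

test_that("block REML equals the dense first-principles oracle on tiny instances", {
  set.seed(901)
  for (r in 1:25) {
    inst <- make_tiny_instance()
    par <- rnorm(length(param_layout(inst$spec)), sd = 0.3)
    am <- assemble_model(inst$dat, inst$spec, inst$ped)
    expect_equal(reml_loglik(par, am, inst$spec),
                 dense_reml_oracle(par, inst$dat, inst$spec, inst$ped),
                 tolerance = 1e-8)
  }
})

test_that("REML with a group random intercept equals the dense oracle", {
  set.seed(902)
  for (r in 1:5) {
    inst <- make_tiny_instance(group = TRUE)
    par <- rnorm(length(param_layout(inst$spec)), sd = 0.3)
    am <- assemble_model(inst$dat, inst$spec, inst$ped)
    expect_equal(reml_loglik(par, am, inst$spec),
                 dense_reml_oracle(par, inst$dat, inst$spec, inst$ped),
                 tolerance = 1e-8)
  }
})

test_that("REML is invariant to translation, record order and X reparameterization", {
  set.seed(903)
  inst <- make_tiny_instance()
  par <- rnorm(length(param_layout(inst$spec)), sd = 0.3)
  base <- reml_loglik(par, assemble_model(inst$dat, inst$spec, inst$ped), inst$spec)

  shifted <- inst$dat
  shifted$value <- shifted$value + 7
  expect_equal(reml_loglik(par, assemble_model(shifted, inst$spec, inst$ped), inst$spec),
               base, tolerance = 1e-10)

  perm <- inst$dat[sample(nrow(inst$dat)), ]
  expect_equal(reml_loglik(par, assemble_model(perm, inst$spec, inst$ped), inst$spec),
               base, tolerance = 1e-10)

  # nonsingular reparameterization of the fixed design: x -> 3x - 1
  repar <- inst$dat
  repar$x <- 3 * repar$x - 1
  expect_equal(reml_loglik(par, assemble_model(repar, inst$spec, inst$ped), inst$spec),
               base, tolerance = 1e-10)
})

test_that("assembly validates inputs and builds the documented design", {
  ped <- pedigree(c("a"), NA, NA)
  spec <- sad_model("y", 1:2,
                    sad_effect(within = list(y = "100")),
                    sad_effect(within = list(y = "100")))
  dat <- tibble::tibble(animal = "a", time = c(1, 2), trait = "y", value = c(1, 2))
  am <- assemble_model(dat, spec, ped)
  expect_equal(unname(am$X), cbind(c(1, 1)), ignore_attr = TRUE)

  expect_error(
    assemble_model(dplyr::mutate(dat, time = c(1, 9)), spec, ped),
    "outside the model grid"
  )
  expect_error(
    assemble_model(dplyr::bind_rows(dat, dat[1, ]), spec, ped),
    "Duplicate"
  )
  expect_error(
    assemble_model(dplyr::mutate(dat, trait = c("y", "z")), spec, ped),
    "Undeclared"
  )

  # two traits with trait-specific intercepts: block-diagonal X
  spec2 <- sad_model(c("y1", "y2"), 1:2,
                     sad_effect(within = list(y1 = "100", y2 = "100")),
                     sad_effect(within = list(y1 = "100", y2 = "100")))
  dat2 <- tidyr::expand_grid(animal = "a", time = 1:2, trait = c("y1", "y2"))
  dat2$value <- rnorm(4)
  am2 <- assemble_model(dat2, spec2, ped)
  X <- am2$X
  r1 <- am2$records$trait == "y1"
  expect_true(all(X[r1, grepl("^y2", colnames(X))] == 0))
  expect_true(all(X[!r1, grepl("^y1", colnames(X))] == 0))
})

test_that("fitting data simulated without antedependence recovers theta near zero", {
  des <- sad100_single_design(theta_g = 0, theta_p = 0, log_vg = 0, log_vp = log(2),
                              n_sires = 25, dams_per_sire = 2, offspring_per_dam = 4)
  est <- vapply(1:6, function(r) {
    ped <- simulate_pedigree(des, 500 + r)
    dat <- simulate_phenotypes(des, ped, 500 + r)
    fit <- sad_fit(dat, ped, des$spec, control = fast_control())
    fit$par[["genetic.a_1,0"]]
  }, numeric(1))
  # mean of the replicate estimates should sit within 3 MC standard errors of 0
  expect_lt(abs(mean(est)), 3 * stats::sd(est) / sqrt(length(est)) + 1e-8)
})

test_that("refitting from the solution reproduces the log-likelihood", {
  set.seed(905)
  des <- sad100_single_design()
  ped <- simulate_pedigree(des, 31)
  dat <- simulate_phenotypes(des, ped, 31)
  fit <- sad_fit(dat, ped, des$spec, control = fast_control())
  refit <- sad_fit(dat, ped, des$spec, init = unname(fit$par),
                   control = fast_control())
  expect_equal(refit$logLik, fit$logLik, tolerance = 1e-6)
})

test_that("a nested fit never beats the full model started from its solution", {
  set.seed(906)
  des <- sad100_single_design()
  ped <- simulate_pedigree(des, 33)
  dat <- simulate_phenotypes(des, ped, 33)
  nested <- sad_fit(dat, ped, des$spec, control = fast_control())
  spec_full <- sad_model(
    traits = "y", times = des$spec$times,
    genetic = sad_effect(within = list(y = "101")),
    permanent = sad_effect(within = list(y = "100"))
  )
  # pad the nested solution with a zero for the new parameter
  init <- c(nested$par[1:2], 0, nested$par[3:4])
  full <- sad_fit(dat, ped, spec_full, init = unname(init),
                  control = fast_control())
  expect_gte(full$logLik, nested$logLik - 1e-6)
})

test_that("breeding-value prediction has the documented shape and symmetries", {
  set.seed(907)
  des <- sad100_single_design(n_sires = 10, dams_per_sire = 2, offspring_per_dam = 3)
  ped <- simulate_pedigree(des, 35)
  dat <- simulate_phenotypes(des, ped, 35)
  fit <- sad_fit(dat, ped, des$spec, control = fast_control())
  ebv <- predict_breeding_values(fit)
  # one prediction per animal x trait x time, including unrecorded ancestors
  expect_identical(nrow(ebv), nrow(fit$ped) * length(des$spec$times))
  expect_identical(
    nrow(dplyr::distinct(ebv, trait, time)),
    length(des$spec$times)
  )

  # zero genetic variance limit: all EBVs vanish
  fit0 <- fit
  fit0$U[] <- 0
  expect_equal(max(abs(predict_breeding_values(fit0)$ebv)), 0)

  # full sibs with identical records receive identical EBVs
  ped2 <- pedigree(c("s", "d", "t1", "t2"), c(NA, NA, "s", "s"), c(NA, NA, "d", "d"))
  dat2 <- tidyr::expand_grid(animal = c("t1", "t2"), time = 1:5, trait = "y")
  dat2$value <- rep(rnorm(5), 2)  # identical record sequences for the two sibs
  fit2 <- sad_fit(dat2, ped2, des$spec, control = fast_control(maxit = 100))
  ebv2 <- predict_breeding_values(fit2)
  e1 <- ebv2$ebv[ebv2$animal == "t1"]
  e2 <- ebv2$ebv[ebv2$animal == "t2"]
  expect_equal(e1, e2, tolerance = 1e-8)
})
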