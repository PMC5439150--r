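test_that("pedigree simulation is deterministic and respects the design", {
  des <- sad100_single_design(n_sires = 10, dams_per_sire = 2, offspring_per_dam = 3)
  p1 <- simulate_pedigree(des, 5)
  p2 <- simulate_pedigree(des, 5)
  expect_identical(p1, p2)
  # with random litter sizes, different seeds give different pedigrees
  desp <- des
  desp$poisson_offspring <- TRUE
  p3 <- simulate_pedigree(desp, 6)
  p4 <- simulate_pedigree(desp, 7)
  expect_false(identical(p3$animal, p4$animal))

  # founders only: the relationship matrix is the identity
  des0 <- sad100_single_design()
  des0$n_generations <- 0L
  ped0 <- simulate_pedigree(des0, 5)
  expect_equal(unname(relationship_matrix(ped0)), diag(nrow(ped0)))
})

test_that("Poisson offspring counts match the design mean", {
  des <- sad100_single_design(n_sires = 20, dams_per_sire = 2, offspring_per_dam = 3)
  des$poisson_offspring <- TRUE
  counts <- vapply(1:100, function(r) {
    length(attr(simulate_pedigree(des, 600 + r), "recorded"))
  }, numeric(1))
  n_mat <- des$n_sires * des$dams_per_sire
  expect_lt(abs(mean(counts) - n_mat * 3),
            3 * stats::sd(counts) / sqrt(length(counts)))
})

test_that("phenotype simulation is seed-reproducible and respects bookkeeping", {
  des <- sad100_single_design(n_sires = 8, dams_per_sire = 2, offspring_per_dam = 3)
  ped <- simulate_pedigree(des, 9)
  d1 <- simulate_phenotypes(des, ped, 9)
  d2 <- simulate_phenotypes(des, ped, 9)
  expect_identical(d1, d2)

  # no attrition, no missingness: one record per animal x time x trait
  expect_identical(nrow(d1), length(attr(ped, "recorded")) * 5L)

  # attrition is monotone: recorded parities are contiguous from the first
  des_att <- sad100_single_design(n_sires = 20, dams_per_sire = 2, offspring_per_dam = 3)
  des_att$attrition <- c(0.7, 0.7, 0.7, 0.7)
  datt <- simulate_phenotypes(des_att, seed = 10)
  gaps <- datt |>
    dplyr::group_by(animal) |>
    dplyr::summarise(contiguous = identical(sort(unique(time)),
                                            as.numeric(seq_len(max(time)))),
                     .groups = "drop")
  expect_true(all(gaps$contiguous))
  expect_lt(nrow(datt), nrow(d1) / (8 / 20) )  # attrition removed records
})

test_that("near-zero variances give phenotypes equal to the fixed part", {
  spec <- sad_model("y", 1:3,
                    sad_effect(within = list(y = "100")),
                    sad_effect(within = list(y = "100")))
  truth <- c(0, -50, 0, -50)
  names(truth) <- param_layout(spec)
  des <- sim_design(spec, truth, n_sires = 5, dams_per_sire = 2,
                    offspring_per_dam = 2,
                    mu = list(y = c(10, 20, 30)))
  dat <- simulate_phenotypes(des, seed = 11)
  mu_of <- c(`1` = 10, `2` = 20, `3` = 30)
  expect_equal(dat$value, unname(mu_of[as.character(dat$time)]), tolerance = 1e-9)
})

test_that("simulated genetic values reproduce U across many unrelated animals", {
  spec <- rabbit_spec(times = 1:3)
  spec$genetic <- sad_effect(within = list(LS = "111", ABW = "100"),
                             crosses = list(sad_cross("LS", "ABW", 0, 0, 1)))
  spec$permanent <- sad_effect(within = list(LS = "100", ABW = "100"))
  k <- length(param_layout(spec))
  set.seed(12)
  truth <- rnorm(k, sd = 0.4)
  n <- 50000
  des <- sim_design(spec, truth, n_sires = 1, dams_per_sire = n,
                    offspring_per_dam = 1)
  des$n_generations <- 0L   # founders only: unrelated animals
  ped <- simulate_pedigree(des, 13)
  dat <- simulate_phenotypes(des, ped, 13)
  truth_obj <- attr(dat, "truth")
  wide <- dat |>
    dplyr::mutate(cell = paste0(trait, "@", time)) |>
    dplyr::select(animal, cell, value) |>
    tidyr::pivot_wider(names_from = cell, values_from = value)
  # remove the permanent part? not possible per record; instead simulate the
  # phenotype with zero permanent variance via the design itself
  expect_identical(nrow(wide), as.integer(n))
  U <- truth_obj$U
  lab <- colnames(U)
  V <- U + truth_obj$P  # unrelated animals: var = U + P per animal
  emp <- stats::cov(as.matrix(wide[, lab]))
  se <- sqrt((outer(diag(V), diag(V)) + V^2) / n)
  expect_true(all(abs(emp - V) < 3.5 * se))
})

test_that("presets match the motivating designs qualitatively", {
  expect_identical(nrow(validate_spec(rabbit_like_design(200)$spec)), 0L)
  expect_identical(nrow(validate_spec(pig_like_design(200)$spec)), 0L)

  des <- rabbit_like_design(n_does = 1000)
  ped <- simulate_pedigree(des, 14)
  dat <- simulate_phenotypes(des, ped, 14)
  counts <- dat |> dplyr::count(trait, time) |>
    tidyr::pivot_wider(names_from = trait, values_from = n)
  # birth weight observed for only a small minority of first-parity litters
  expect_lt(counts$ABW[counts$time == 1] / counts$LS[counts$time == 1], 0.12)
  # litter counts decline with parity (attrition)
  expect_true(all(diff(counts$LS) < 0))

  desp <- pig_like_design(n_sows = 600)
  pedp <- simulate_pedigree(desp, 15)
  datp <- simulate_phenotypes(desp, pedp, 15)
  cp <- datp |> dplyr::filter(trait == "LS") |> dplyr::count(time)
  # strong decline from first to last parity, as in farrowing data
  expect_lt(cp$n[5] / cp$n[1], 0.4)
  expect_true(desp$spec$group %in% names(datp))
})
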