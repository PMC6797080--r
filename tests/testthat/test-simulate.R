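test_that("draws are deterministic in the seed and have the right shape", {
  d1 <- draw_population(cbt, population_config(seed = 42))
  d2 <- draw_population(cbt, population_config(seed = 42))
  d3 <- draw_population(cbt, population_config(seed = 43))
  expect_identical(d1, d2)
  expect_false(identical(d1$patients, d3$patients))

  expect_equal(nrow(d1$patients), 6000L)
  expect_equal(nrow(d1$practitioners), 200L)
  expect_equal(nrow(d1$organizations), 40L)
  expect_setequal(d1$gated, c("D2", "X4", "X5", "T1", "Y2"))
})

test_that("selection masks exactly the non-implementing organizations", {
  d <- draw_population(cbt, population_config(seed = 7))
  org <- d$organizations
  expect_equal(sum(org$D1 == 1) + sum(org$D1 == 0), 40L)
  impl <- org$org[org$D1 == 1]
  # downstream variables exist iff the organization implements
  expect_true(all(is.na(org$D2[!org$org %in% impl])))
  expect_true(all(!is.na(org$D2[org$org %in% impl])))
  pt <- d$patients
  expect_true(all(is.na(pt$T1[!pt$org %in% impl])))
  expect_true(all(is.na(pt$Y2[!pt$org %in% impl])))
  expect_true(all(!is.na(pt$T1[pt$org %in% impl])))
  # pre-selection variables are never masked
  expect_true(all(!is.na(pt$Y1)))

  # variables respect their kinds
  expect_true(all(pt$T1 %in% c(0, 1, NA)))
  expect_true(all(pt$V2 %in% c(0, 1)))
  expect_true(all(is.finite(pt$Y1)))
  expect_true(all(is.finite(d$practitioners$X2)))
  # the aggregate cost is the exact sum of its parts
  expect_equal(org$W, org$W1 + org$W2)
})

test_that("zero-coefficient decisions are fair coin flips", {
  m0 <- cbt_all_zero()
  d <- draw_population(m0, population_config(seed = 19))
  n_org <- nrow(d$organizations)
  expect_lt(abs(mean(d$organizations$D1) - 0.5), 3 * sqrt(0.25 / n_org))
  t1 <- d$patients$T1[!is.na(d$patients$T1)]
  expect_lt(abs(mean(t1) - 0.5), 3 * sqrt(0.25 / length(t1)))
  # and every true effect vanishes
  expect_equal(unname(true_sample_effects(m0, d)), rep(0, 5))
})

test_that("the management-style/leadership error correlation is honoured", {
  rho <- numeric(10)
  for (i in 1:10) {
    d <- draw_population(cbt, population_config(seed = 100 + i))
    z2 <- d$organizations$Z2[d$practitioners$org]
    rho[i] <- stats::cor(z2, d$practitioners$X2)
  }
  expect_lt(abs(mean(rho) - 0.5), 0.05)
})

test_that("true linear effects equal the structural coefficients exactly", {
  for (seed in c(3, 14, 15)) {
    d <- draw_population(cbt, population_config(seed = seed))
    te <- true_sample_effects(cbt, d)
    expect_equal(unname(te["ate_D2_X4"]), 0.5, tolerance = 1e-12)
    expect_equal(unname(te["ate_D2_X5"]), 0.5, tolerance = 1e-12)
    expect_equal(unname(te["ate_T1_Y2"]), 1.0, tolerance = 1e-12)
  }
})

test_that("the marginal-effect truth matches a finite-difference oracle", {
  d <- draw_population(cbt, population_config(seed = 8))
  te <- true_sample_effects(cbt, d)
  # rebuild the treatment-assignment index by hand from the tables and
  # difference the threshold-crossing probability directly
  af <- merged_patient_frame(d)
  af <- af[af$D1 == 1, ]
  cf <- cbt$equations$T1$coefficients
  idx <- with(af, cf[["X4"]] * X4 + cf[["X5"]] * X5 + cf[["Z1"]] * Z1 +
                cf[["X2"]] * X2 + cf[["X3"]] * X3 + cf[["V1"]] * V1 +
                cf[["V2"]] * V2 + cf[["Y1"]] * Y1)
  delta <- 1e-6
  fd_x4 <- mean(stats::pnorm(idx + cf[["X4"]] * delta) - stats::pnorm(idx)) / delta
  fd_x5 <- mean(stats::pnorm(idx + cf[["X5"]] * delta) - stats::pnorm(idx)) / delta
  expect_lt(abs(fd_x4 - te[["ame_X4_T1"]]), 1e-6)
  expect_lt(abs(fd_x5 - te[["ame_X5_T1"]]), 1e-6)
})

test_that("raising the strategy intercept raises enhanced-strategy uptake", {
  frac <- vapply(c(-1, 0, 1), function(a) {
    m <- canonical_cbt_model(overrides = list(
      equations = list(D2 = list(intercept = a))))
    d <- draw_population(m, population_config(seed = 77))
    mean(d$organizations$D2, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("without case-mix confounding the naive contrast recovers the truth", {
  m <- canonical_cbt_model(overrides = list(equations = list(
    T1 = list(coefficients = c(V1 = 0, V2 = 0, Y1 = 0)))))
  diffs <- numeric(50)
  for (i in 1:50) {
    d <- draw_population(m, population_config(seed = 500 + i))
    pt <- d$patients[!is.na(d$patients$T1), ]
    diffs[i] <- mean(pt$Y2[pt$T1 == 1]) - mean(pt$Y2[pt$T1 == 0])
  }
  expect_lt(abs(mean(diffs) - 1.0), 3 * stats::sd(diffs) / sqrt(50))
})

test_that("dataset bundles round-trip losslessly", {
  d <- draw_population(cbt, population_config(seed = 31))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  d2 <- read_dataset(dir)
  expect_equal(d2$organizations, d$organizations, tolerance = 1e-12)
  expect_equal(d2$practitioners, d$practitioners, tolerance = 1e-12)
  expect_equal(d2$patients, d$patients, tolerance = 1e-12)
  expect_equal(d2$errors, d$errors, tolerance = 1e-12)
  expect_equal(d2$hierarchy, d$hierarchy)
  # replay still works after the round trip
  expect_equal(true_sample_effects(cbt, d2), true_sample_effects(cbt, d),
               tolerance = 1e-10)
})

test_that("corrupt bundles are rejected", {
  d <- draw_population(cbt, population_config(seed = 32))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  pt <- utils::read.csv(file.path(dir, "patients.csv"), na.strings = "")
  pt$pract[1] <- 99999L
  utils::write.csv(pt, file.path(dir, "patients.csv"), row.names = FALSE, na = "")
  expect_error(read_dataset(dir), "unknown practitioner",
               class = "junctures_input_error")

  write_dataset(d, dir)
  pt <- utils::read.csv(file.path(dir, "patients.csv"), na.strings = "")
  utils::write.csv(pt[-1, ], file.path(dir, "patients.csv"),
                   row.names = FALSE, na = "")
  expect_error(read_dataset(dir), "manifest", class = "junctures_input_error")
})

test_that("a draw with no implementing organization is still writable", {
  m <- canonical_cbt_model(overrides = list(
    equations = list(D1 = list(intercept = -50))))
  d <- draw_population(m, population_config(seed = 2))
  expect_equal(sum(d$organizations$D1), 0)
  expect_true(all(is.na(d$patients$T1)))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  d2 <- read_dataset(dir)
  expect_equal(d2$patients, d$patients, tolerance = 1e-12)
})

test_that("replay requires retained errors", {
  d <- draw_population(cbt, population_config(seed = 4))
  d$errors <- NULL
  expect_error(true_sample_effects(cbt, d), class = "junctures_contract_error")
})
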