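make_eif3_experiment <- function(E_grid, constants, R_total = 30, T_total = 2,
                                 K3_assumed = constants$K3) {
  lanes <- do.call(rbind, lapply(E_grid, function(E) {
    fr <- band_fractions(solve_equilibrium(
      mixture_totals(R_total, T_total, E), constants))
    data.frame(titrant_total_nM = E, frac_free = fr[1], frac_43S = fr[2],
               frac_43S_eIF3 = fr[3])
  }))
  titration_experiment(lanes, titrant = "eIF3",
                       fixed_totals = list(R_total = R_total, T_total = T_total),
                       K3_assumed = K3_assumed)
}

test_that("lane validation enforces fraction and ordering invariants", {
  lanes <- data.frame(titrant_total_nM = c(30, 100), frac_free = c(0.6, 0.4),
                      frac_43S = c(0.2, 0.2), frac_43S_eIF3 = c(0.2, 0.4))
  expect_s3_class(
    titration_experiment(lanes, "eIF3", list(R_total = 30, T_total = 2), 15),
    "titration_experiment")

  bad <- lanes; bad$frac_free[1] <- 1.2
  expect_error(titration_experiment(bad, "eIF3", list(), 15), "\\[0, 1\\]")
  bad <- lanes; bad$frac_free[1] <- 0.2 # sum 0.6
  expect_error(titration_experiment(bad, "eIF3", list(), 15), "sum")
  bad <- lanes; bad$titrant_total_nM <- c(100, 30)
  expect_error(titration_experiment(bad, "eIF3", list(), 15), "increasing")
})

test_that("free eIF3 in a lane inverts the equilibrium model exactly", {
  k <- equilibrium_constants(104, 38, 15)
  for (E_total in c(30, 75, 150, 300, 500)) {
    st <- solve_equilibrium(mixture_totals(30, 2, E_total), k)
    fr <- band_fractions(st)
    cor <- free_eif3_in_lane(fr["frac_free"], fr["frac_43S_eIF3"],
                             T_total = 2, E_total = E_total, K3 = k$K3)
    expect_equal(cor$E_free, st$E_free, tolerance = 1e-8)
    expect_equal(cor$RE, st$RE, tolerance = 1e-8)
    expect_equal(cor$RTE, st$RTE, tolerance = 1e-8)
    expect_false(cor$floored)
  }
})

test_that("free-eIF3 limiting cases behave as the algebra dictates", {
  # no supershift: every eIF3 molecule is free
  cor <- free_eif3_in_lane(0.6, 0, T_total = 2, E_total = 120, K3 = 15)
  expect_equal(cor$RE, 0)
  expect_equal(cor$E_free, 120)

  # K3 -> 0: the 40S-eIF3 pool vanishes from the correction
  cor <- free_eif3_in_lane(0.5, 0.3, T_total = 2, E_total = 120, K3 = 1e-12)
  expect_equal(cor$RE, 0, tolerance = 1e-10)
  expect_equal(cor$E_free, 120 - 0.6, tolerance = 1e-9)

  # a lane with no free-tracer band cannot be corrected
  expect_error(free_eif3_in_lane(0, 0.3, 2, 120, 15), "frac_free")
  expect_error(free_eif3_in_lane(0.5, 0.3, 2, 120, 0), "K3")

  # noisy fractions can push free eIF3 negative: floored and flagged
  expect_warning(
    cor <- free_eif3_in_lane(0.05, 0.9, T_total = 30, E_total = 20, K3 = 15),
    "floored")
  expect_true(cor$floored)
  expect_equal(cor$E_free, 0)
})

test_that("a corrected titration reproduces the generator's true free eIF3", {
  k <- equilibrium_constants(104, 38, 15)
  E_grid <- c(30, 60, 120, 250, 500)
  exp <- make_eif3_experiment(E_grid, k)
  curve <- correct_titration(exp)
  expect_s3_class(curve, "corrected_curve")
  expect_equal(nrow(curve), length(E_grid))
  true_free <- sapply(E_grid, function(E) {
    solve_equilibrium(mixture_totals(30, 2, E), k)$E_free
  })
  expect_equal(curve$free_ligand, true_free, tolerance = 1e-8)
  expect_true(all(curve$free_ligand >= 0))
  expect_false(any(curve$flagged))
  expect_identical(attr(curve, "response_def"), "frac_43S_eIF3")
})

test_that("the correction becomes negligible at excess eIF3", {
  k <- equilibrium_constants(104, 38, 15)
  exp <- make_eif3_experiment(c(5000, 10000, 20000), k)
  curve <- correct_titration(exp)
  expect_true(all(abs(curve$free_ligand - exp$lanes$titrant_total_nM) /
                    exp$lanes$titrant_total_nM < 0.01))
})

test_that("a wrong K3 biases the correction most at low eIF3", {
  k <- equilibrium_constants(104, 38, 15)
  E_grid <- c(30, 60, 120, 250, 500, 1000, 4000)
  exp <- make_eif3_experiment(E_grid, k, K3_assumed = 2 * k$K3)
  curve <- correct_titration(exp)
  true_free <- sapply(E_grid, function(E) {
    solve_equilibrium(mixture_totals(30, 2, E), k)$E_free
  })
  rel_dev <- abs(curve$free_ligand - true_free) / true_free
  # deviation decays monotonically along the titration and vanishes in excess
  expect_true(all(diff(rel_dev) < 1e-12))
  expect_lt(rel_dev[length(rel_dev)], 0.01)
  expect_gt(rel_dev[1], rel_dev[length(rel_dev)] * 10)
})

test_that("single-lane experiments correct to single-point curves", {
  k <- equilibrium_constants(104, 38, 15)
  exp <- make_eif3_experiment(100, k)
  curve <- correct_titration(exp)
  expect_equal(nrow(curve), 1)
})

test_that("correct_titration demands the right titrant and K3", {
  lanes <- data.frame(titrant_total_nM = c(10, 40), frac_free = c(0.8, 0.5),
                      frac_43S = c(0.15, 0.3), frac_43S_eIF3 = c(0.05, 0.2))
  exp40 <- titration_experiment(lanes, "40S", list(T_total = 1))
  expect_error(correct_titration(exp40), "40S titrations")
  exp_no_k3 <- titration_experiment(lanes, "eIF3",
                                    list(R_total = 30, T_total = 2))
  expect_error(correct_titration(exp_no_k3), "K3_assumed")
})

test_that("TC binding curves sum the two PIC bands in total-40S coordinates", {
  lanes <- data.frame(titrant_total_nM = c(10, 100), frac_free = c(0.8, 0.4),
                      frac_43S = c(0.15, 0.3), frac_43S_eIF3 = c(0.05, 0.3))
  exp <- titration_experiment(lanes, "40S", list(T_total = 1))
  curve <- tc_binding_curve(exp)
  expect_equal(curve$free_ligand, c(10, 100))
  expect_equal(curve$response, c(0.2, 0.6))
  expect_identical(attr(curve, "response_def"), "frac_TC_bound")

  # all-free lanes give a flat zero curve
  flat <- data.frame(titrant_total_nM = c(10, 100), frac_free = c(1, 1),
                     frac_43S = 0, frac_43S_eIF3 = 0)
  expect_equal(tc_binding_curve(
    titration_experiment(flat, "40S", list(T_total = 1)))$response, c(0, 0))
})

test_that("TC binding from the full equilibrium half-saturates near K3 when eIF3 saturates", {
  # with eIF3 well above K2 and K4, TC effectively titrates the 40S-eIF3 pool
  k <- equilibrium_constants(104, 5, 15)
  grid <- c(2, 5, 10, 20, 40, 80, 160, 320)
  lanes <- do.call(rbind, lapply(grid, function(R) {
    fr <- band_fractions(solve_equilibrium(mixture_totals(R, 1, 2000), k))
    data.frame(titrant_total_nM = R, frac_free = fr[1], frac_43S = fr[2],
               frac_43S_eIF3 = fr[3])
  }))
  exp <- titration_experiment(lanes, "40S", list(T_total = 1, E_total = 2000))
  fit <- fit_langmuir(tc_binding_curve(exp))
  expect_false(fit$failed)
  expect_equal(fit$K_app, 15, tolerance = 0.1)
})

test_that("titration tables round-trip through the delimited-text interface", {
  k <- equilibrium_constants(104, 38, 15)
  des <- titration_design("eIF3", constants = k, n_replicates = 2)
  tab <- simulate_titration(des, noise_model(0.02, 5))
  for (sep in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_titration_table(tab, path, sep = sep)
    back <- read_titration_table(path)
    expect_equal(back$frac_free, tab$frac_free, tolerance = 1e-12)
    expect_equal(back$titrant_total_nM, tab$titrant_total_nM)
    expect_equal(back$replicate_id, tab$replicate_id)
  }
  expect_error(read_titration_table("no/such/file.csv"), "not found")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", path)
  expect_error(read_titration_table(path), "missing column")
})

test_that("split_titrations rebuilds per-replicate experiments", {
  k <- equilibrium_constants(104, 38, 15)
  tab <- simulate_titration(titration_design("eIF3", constants = k,
                                             n_replicates = 3),
                            noise_model(0.01, 9))
  exps <- split_titrations(tab, list(R_total = 30, T_total = 2),
                           K3_assumed = 15)
  expect_length(exps, 3)
  expect_setequal(names(exps), c("rep1", "rep2", "rep3"))
  expect_true(all(vapply(exps, inherits, TRUE, "titration_experiment")))
})
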