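test_that("the fourth constant closes the thermodynamic cycle", {
  expect_equal(derive_fourth_constant(100, 50, 50), 100)
  expect_equal(derive_fourth_constant(104, 38, 15), 104 * 38 / 15,
               tolerance = 1e-12)
  # K1 = K3 forces K4 = K2
  expect_equal(derive_fourth_constant(77, 3.2, 77), 3.2)

  k <- equilibrium_constants(104, 38, 15)
  expect_equal(k$K1 * k$K2, k$K3 * k$K4, tolerance = 1e-9)

  expect_error(derive_fourth_constant(-1, 2, 3), "positive")
  expect_error(derive_fourth_constant(0, 2, 3), "positive")
  expect_error(equilibrium_constants(1, 2, Inf), "positive")
  # a supplied K4 violating closure is rejected
  expect_error(equilibrium_constants(104, 38, 15, K4 = 100), "closure")
  expect_silent(equilibrium_constants(104, 38, 15, K4 = 104 * 38 / 15))
})

test_that("cycle closure holds for every constructed constant set", {
  set.seed(11)
  for (i in 1:200) {
    ks <- 10^stats::runif(3, -2, 4)
    k <- equilibrium_constants(ks[1], ks[2], ks[3])
    expect_lt(abs(k$K1 * k$K2 - k$K3 * k$K4) / (k$K1 * k$K2), 1e-9)
  }
})

test_that("degenerate mixtures collapse to the analytic two-species solutions", {
  k <- equilibrium_constants(104, 38, 15)

  # no eIF3: single T + R reaction with K1
  st <- solve_equilibrium(mixture_totals(30, 2, 0), k)
  RT_expected <- oracle_two_species(30, 2, 104)
  expect_equal(st$RT, RT_expected, tolerance = 1e-10)
  expect_equal(st$RE, 0)
  expect_equal(st$RTE, 0)
  # RT is the admissible root of the quadratic
  expect_equal(st$RT^2 - (30 + 2 + 104) * st$RT + 30 * 2, 0, tolerance = 1e-8)
  expect_true(st$RT >= 0 && st$RT <= 2)

  # no tracer: single E + R reaction with K4
  st <- solve_equilibrium(mixture_totals(30, 0, 100), k)
  expect_equal(st$RE, oracle_two_species(30, 100, k$K4), tolerance = 1e-10)
  expect_equal(st$RT + st$RTE, 0)

  # no 40S: everything free
  st <- solve_equilibrium(mixture_totals(0, 2, 100), k)
  expect_equal(st$T_free, 2)
  expect_equal(st$E_free, 100)
  expect_equal(st$RT + st$RE + st$RTE + st$R_free, 0)
})

test_that("no-binding limit leaves all species free", {
  k <- equilibrium_constants(1e14, 1e14, 1e14)
  st <- solve_equilibrium(mixture_totals(30, 2, 100), k)
  expect_lt(st$RT + st$RE + st$RTE, 1e-9)
  expect_equal(st$R_free, 30, tolerance = 1e-9)
  expect_equal(st$T_free, 2, tolerance = 1e-9)
  expect_equal(st$E_free, 100, tolerance = 1e-9)
})

test_that("solver matches the nested-bisection oracle on the reference mixture", {
  k <- equilibrium_constants(104, 38, 15)
  st <- solve_equilibrium(mixture_totals(30, 2, 100), k)
  or <- oracle_equilibrium(30, 2, 100, k$K1, k$K2, k$K3, k$K4)
  expect_state_close(st, or, tol = 1e-8)

  fr <- band_fractions(st)
  expect_equal(unname(fr["frac_free"]), or$T_free / 2, tolerance = 1e-8)
  expect_equal(unname(fr["frac_43S"]), or$RT / 2, tolerance = 1e-8)
  expect_equal(unname(fr["frac_43S_eIF3"]), or$RTE / 2, tolerance = 1e-8)
})

test_that("solver matches the oracle on random instances", {
  set.seed(42)
  for (i in 1:100) {
    totals <- 10^stats::runif(3, -1, 3)
    ks <- 10^stats::runif(3, 0, 3)
    k <- equilibrium_constants(ks[1], ks[2], ks[3])
    st <- solve_equilibrium(mixture_totals(totals[1], totals[2], totals[3]), k)
    or <- oracle_equilibrium(totals[1], totals[2], totals[3],
                             k$K1, k$K2, k$K3, k$K4)
    expect_state_close(st, or, tol = 1e-8)
  }
})

test_that("conservation and nonnegativity hold over randomized mixtures", {
  set.seed(7)
  for (i in 1:2000) {
    totals <- 10^stats::runif(3, -2, 3.5)
    ks <- 10^stats::runif(3, -1, 4)
    k <- equilibrium_constants(ks[1], ks[2], ks[3])
    st <- solve_equilibrium(mixture_totals(totals[1], totals[2], totals[3]), k)
    sp <- unlist(unclass(st))
    expect_true(all(sp >= 0))
    expect_lt(abs(st$R_free + st$RT + st$RE + st$RTE - totals[1]) / totals[1], 1e-9)
    expect_lt(abs(st$T_free + st$RT + st$RTE - totals[2]) / totals[2], 1e-9)
    expect_lt(abs(st$E_free + st$RE + st$RTE - totals[3]) / totals[3], 1e-9)
    # all four mass-action relations, on the scale of the species involved
    sc <- max(sp, 1)
    expect_lt(abs(st$R_free * st$T_free - k$K1 * st$RT) / (sc * sc), 1e-7)
    expect_lt(abs(st$E_free * st$RT - k$K2 * st$RTE) / (sc * sc), 1e-7)
    expect_lt(abs(st$T_free * st$RE - k$K3 * st$RTE) / (sc * sc), 1e-7)
    expect_lt(abs(st$E_free * st$R_free - k$K4 * st$RE) / (sc * sc), 1e-7)
  }
})

test_that("bound species respond monotonically to added totals", {
  k <- equilibrium_constants(104, 38, 15)
  # RTE non-decreasing in total eIF3 at fixed R, T
  rte <- sapply(seq(0, 500, by = 25), function(E) {
    solve_equilibrium(mixture_totals(30, 2, E), k)$RTE
  })
  expect_true(all(diff(rte) >= -1e-10))
  # total TC-bound fraction non-decreasing in total 40S at fixed T, E.
  # (The supershifted fraction alone is NOT monotone in 40S: past ~150 nM,
  # excess free subunits sequester eIF3 as 40S-eIF3 and the 43S-eIF3 band
  # recedes -- the competition that motivates the free-eIF3 correction.)
  f_bound <- sapply(seq(5, 320, by = 15), function(R) {
    sum(band_fractions(solve_equilibrium(mixture_totals(R, 2, 100), k))[2:3])
  })
  expect_true(all(diff(f_bound) >= -1e-10))
  f_super <- sapply(c(150, 235, 320), function(R) {
    band_fractions(solve_equilibrium(mixture_totals(R, 2, 100), k))["frac_43S_eIF3"]
  })
  expect_lt(f_super[3], f_super[1])
})

test_that("relabelling T and E maps solutions onto each other", {
  set.seed(99)
  for (i in 1:25) {
    totals <- 10^stats::runif(3, -1, 3)
    ks <- 10^stats::runif(3, 0, 3)
    k <- equilibrium_constants(ks[1], ks[2], ks[3])
    st <- solve_equilibrium(mixture_totals(totals[1], totals[2], totals[3]), k)
    # swapped system: T <-> E, K1 <-> K4, K2 <-> K3
    k_swap <- equilibrium_constants(k$K4, k$K3, k$K2)
    expect_equal(k_swap$K4, k$K1, tolerance = 1e-9)
    st_swap <- solve_equilibrium(
      mixture_totals(totals[1], totals[3], totals[2]), k_swap)
    expect_equal(st_swap$T_free, st$E_free, tolerance = 1e-7)
    expect_equal(st_swap$E_free, st$T_free, tolerance = 1e-7)
    expect_equal(st_swap$RT, st$RE, tolerance = 1e-6)
    expect_equal(st_swap$RE, st$RT, tolerance = 1e-6)
    expect_equal(st_swap$RTE, st$RTE, tolerance = 1e-6)
  }
})

test_that("band fractions are tracer fractions and sum to one", {
  k <- equilibrium_constants(104, 38, 15)
  st <- solve_equilibrium(mixture_totals(30, 2, 100), k)
  fr <- band_fractions(st)
  expect_equal(sum(fr), 1, tolerance = 1e-9)

  # direct arithmetic case: T_free = 1, RT = 0.6, RTE = 0.4 of T_total = 2
  st2 <- picbind:::new_species_state(10, 1, 50, 0.6, 3, 0.4,
                                     mixture_totals(14, 2, 53.4), k)
  expect_equal(unname(band_fractions(st2)), c(0.5, 0.3, 0.2))

  # without eIF3 there is no supershifted band
  st3 <- solve_equilibrium(mixture_totals(30, 2, 0), k)
  expect_equal(unname(band_fractions(st3)["frac_43S_eIF3"]), 0)

  st4 <- solve_equilibrium(mixture_totals(30, 0, 100), k)
  expect_error(band_fractions(st4), "T_total")
})
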