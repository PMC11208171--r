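test_that("growth simulation is deterministic per seed and leaves RNG alone", {
  set.seed(123)
  before <- .Random.seed
  a <- simulate_growth(seed = 42)
  expect_identical(.Random.seed, before)  # no global RNG pollution
  b <- simulate_growth(seed = 42)
  expect_identical(a$values, b$values)
  c <- simulate_growth(seed = 43)
  expect_false(identical(a$values, c$values))
})

test_that("noiseless growth curves reach the carrying capacity", {
  od <- simulate_growth(mu = 0.05, lag = 0, od0 = 0.05, od_max = 1.0,
                        noise_cv = 0, seed = 1, times = seq(0, 300, 10))
  expect_equal(utils::tail(od$values, 1), 1.0, tolerance = 1e-9)
  expect_true(all(diff(od$values) >= 0))
  expect_equal(od$values[1], 0.05)
  # lag holds the inoculum OD
  od2 <- simulate_growth(mu = 0.05, lag = 20, od0 = 0.05, noise_cv = 0,
                         seed = 1, times = seq(0, 60, 5))
  expect_true(all(od2$values[od2$times <= 20] == 0.05))
})

test_that("simulated noise has roughly the configured CV", {
  od <- simulate_growth(mu = 0, lag = 0, od0 = 1, od_max = 1,
                        noise_cv = 0.05, seed = 7,
                        times = seq(0, 999, length.out = 1000))
  expect_equal(stats::sd(od$values) / mean(od$values), 0.05,
               tolerance = 0.15)
  expect_equal(mean(od$values), 1, tolerance = 0.01)
})

test_that("growth_rate recovers mu within 10% across seeds at 5% noise", {
  for (mu in c(0.02, 0.05)) {
    times <- if (mu == 0.02) seq(0, 250, by = 5) else seq(0, 120, by = 3)
    for (seed in 1:20) {
      od <- simulate_growth(mu = mu, lag = 10, od0 = 0.05, od_max = 1.0,
                            noise_cv = 0.05, seed = seed, times = times)
      fit <- growth_rate(od)
      expect_lt(abs(fit$mu - mu) / mu, 0.10,
                label = sprintf("mu=%g seed=%d", mu, seed))
    }
  }
})

mut_formate_solution <- function() {
  solve_steady_state(
    build_model(oracle_genotype_mut(), condition_spec("formate")), "acetate")
}

test_that("noiseless conversion endpoints equal the model ratios exactly", {
  sim <- simulate_conversion(mut_formate_solution(), substrate0 = 100,
                             rate = 200, noise_cv = 0, seed = 1)
  expect_setequal(names(sim), c("formate", "acetate"))
  expect_equal(utils::tail(sim$formate$values, 1), 0)
  expect_equal(utils::tail(sim$acetate$values, 1), 25)  # 4:1 ledger ratio
  # stoichiometric consistency along the whole noiseless trajectory
  consumed <- 100 - sim$formate$values
  expect_equal(sim$acetate$values, consumed / 4, tolerance = 1e-12)
})

test_that("the sodium-depleted CO solution converts CO 1:1 to formate", {
  sol <- solve_steady_state(
    build_model(oracle_genotype_mut(),
                condition_spec("CO", na_available = FALSE)), "formate")
  sim <- simulate_conversion(sol, substrate0 = 30, rate = 100,
                             noise_cv = 0, seed = 1)
  expect_setequal(names(sim), c("CO", "formate"))
  expect_equal(utils::tail(sim$formate$values, 1), 30)
  expect_false("acetate" %in% names(sim))
  # carbon conserved at every sampled time
  expect_equal(sim$CO$values + sim$formate$values, rep(30, 25),
               tolerance = 1e-12)
})

test_that("conversion handles zero rate, noise determinism and errors", {
  sol <- mut_formate_solution()
  flat <- simulate_conversion(sol, substrate0 = 50, rate = 0,
                              noise_cv = 0, seed = 1)
  expect_true(all(flat$formate$values == 50))
  expect_true(all(flat$acetate$values == 0))

  a <- simulate_conversion(sol, seed = 5)
  b <- simulate_conversion(sol, seed = 5)
  expect_identical(lapply(a, `[[`, "values"), lapply(b, `[[`, "values"))

  infeas <- solve_steady_state(
    build_model(oracle_genotype_mut(), condition_spec(c("H2", "CO2"))),
    "acetate")
  expect_error(simulate_conversion(infeas), "infeasible")
  expect_error(simulate_conversion(sol, substrate0 = -5), "substrate0")
})

test_that("recovered specific rate matches the configured one", {
  sol <- mut_formate_solution()
  sim <- simulate_conversion(sol, substrate0 = 250, rate = 800,
                             protein_conc = 1, noise_cv = 0, seed = 1)
  est <- specific_rate(sim$formate, window = c(0, 2))
  expect_equal(est$rate, 800, tolerance = 1e-9)
  # and within noise tolerance when noise is on
  sim2 <- simulate_conversion(sol, substrate0 = 250, rate = 800,
                              protein_conc = 1, noise_cv = 0.05, seed = 3)
  est2 <- specific_rate(sim2$formate, window = c(0, 2))
  expect_lt(abs(est2$rate - 800) / 800, 0.25)
})

test_that("simulated SNP tables sweep exactly one locus to fixation", {
  tab <- simulate_snp_table(8, sweep_locus = 3, seed = 11)
  expect_equal(nrow(tab), 8)
  freq <- snp_frequencies(tab)
  expect_equal(unname(freq[3, "10th transfer"]), 100)
  expect_true(all(freq[-3, ] < 90))
  expect_true(all(diff(freq[3, ]) >= 0))     # monotone sweep
  rep <- snp_report(tab, "10th transfer", min_frequency = 100)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$position, tab$position[3])

  expect_identical(simulate_snp_table(8, 3, seed = 11),
                   simulate_snp_table(8, 3, seed = 11))
  one <- simulate_snp_table(1, 1, seed = 2)
  expect_equal(unname(snp_frequencies(one)[1, "10th transfer"]), 100)
  expect_error(simulate_snp_table(3, 9), "out of range")
})

test_that("simulated SNP tables round-trip through the TSV dialect", {
  tab <- simulate_snp_table(5, 2, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_snp_table(tab, f)
  tab2 <- read_snp_table(f)
  expect_equal(tab2$position, tab$position)
  expect_equal(unname(snp_frequencies(tab2)), unname(snp_frequencies(tab)),
               tolerance = 1e-6)
  expect_equal(colnames(snp_frequencies(tab2)),
               colnames(snp_frequencies(tab)))
  unlink(f)
})
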