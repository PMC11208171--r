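test_that("solver reproduces every hand-written canonical ledger exactly", {
  for (name in names(canonical_oracles())) {
    o <- canonical_oracles()[[name]]
    sol <- solve_steady_state(oracle_model(o), o$product)
    expect_s3_class(sol, "flux_solution")
    for (rid in names(o$fluxes)) {
      actual <- sol$fluxes[[rid]]
      if (is.null(actual)) {
        # reaction absent from the assembled network: ledger must say zero
        expect_equal(unname(o$fluxes[rid]), "0",
                     label = paste(name, rid, "absent"))
      } else {
        expect_rational_equal(actual, unname(o$fluxes[rid]))
      }
    }
    expect_rational_equal(sol$na_pumped, o$na_pumped)
    expect_rational_equal(sol$slp_net, o$slp)
    expect_rational_equal(atp_yield(sol), o$atp)
    expect_equal(atp_yield(sol, exact = FALSE), o$atp_reported)
  }
})

test_that("all internal balances are identically zero, never merely small", {
  for (name in names(canonical_oracles())) {
    o <- canonical_oracles()[[name]]
    sol <- solve_steady_state(oracle_model(o), o$product)
    for (s in names(sol$balances)) {
      expect_true(sol$balances[[s]] == 0, label = paste(name, s))
    }
  }
})

test_that("carbon in equals carbon out for every feasible solution", {
  carbon <- c(CO = 1, CO2 = 1, formate = 1, fructose = 6, acetate = 2,
              H2 = 0)
  for (name in names(canonical_oracles())) {
    o <- canonical_oracles()[[name]]
    sol <- solve_steady_state(oracle_model(o), o$product)
    c_in <- rational(0); c_out <- rational(0)
    for (s in names(sol$substrate_consumed)) {
      c_in <- c_in + sol$substrate_consumed[[s]] * rational(carbon[[s]])
    }
    for (p in names(sol$products_formed)) {
      c_out <- c_out + sol$products_formed[[p]] * rational(carbon[[p]])
    }
    expect_true(c_in == c_out, label = name)
  }
})

test_that("formate and H2+CO2 give the wild type the same ATP yield", {
  y1 <- atp_yield(solve_steady_state(
    build_model(oracle_genotype_wt(), condition_spec("formate")), "acetate"))
  y2 <- atp_yield(solve_steady_state(
    build_model(oracle_genotype_wt(), condition_spec(c("H2", "CO2"))),
    "acetate"))
  expect_true(y1 == y2)
  expect_rational_equal(y1, "10/33")
})

test_that("the hydrogenase-free mutant cannot balance H2 + CO2", {
  sol <- solve_steady_state(
    build_model(oracle_genotype_mut(), condition_spec(c("H2", "CO2"))),
    "acetate")
  expect_s3_class(sol, "infeasibility_report")
  expect_gt(length(sol$unbalanceable_species), 0)
  expect_true(any(c("Fd2-", "NADH") %in% sol$unbalanceable_species))
  expect_error(atp_yield(sol), "infeasible")
})

test_that("removing Rnf makes every acetate-producing scenario infeasible", {
  no_rnf_wt <- genotype_spec(rnf_present = FALSE)
  no_rnf_mut <- genotype_spec(hydABC_present = FALSE,
                              hdcr_hydrogenase_module_present = FALSE,
                              fd_hdcr_enabled = TRUE, rnf_present = FALSE)
  cases <- list(list(no_rnf_wt, condition_spec(c("H2", "CO2"))),
                list(no_rnf_wt, condition_spec("CO")),
                list(no_rnf_wt, condition_spec("formate")),
                list(no_rnf_mut, condition_spec("CO")),
                list(no_rnf_mut, condition_spec("formate")))
  for (case in cases) {
    sol <- solve_steady_state(build_model(case[[1]], case[[2]]), "acetate")
    expect_s3_class(sol, "infeasibility_report")
  }
})

test_that("solutions are homogeneous of degree 1 in the target flux", {
  m <- build_model(oracle_genotype_mut(), condition_spec("formate"))
  s1 <- solve_steady_state(m, "acetate", flux = rational(1))
  s7 <- solve_steady_state(m, "acetate", flux = rational(7, 3))
  for (rid in names(s1$fluxes)) {
    expect_true(s7$fluxes[[rid]] == s1$fluxes[[rid]] * rational(7, 3),
                label = rid)
  }
  expect_true(atp_yield(s7) == atp_yield(s1) * rational(7, 3))
})

test_that("mixed-product solutions interpolate linearly in phi", {
  m <- build_model(oracle_genotype_mut(), condition_spec("CO"))
  s_ac <- solve_steady_state(m, "acetate")               # phi = 0 limit
  s_half <- solve_steady_state(m, "acetate", phi = rational(1, 2))
  s_q <- solve_steady_state(m, "acetate", phi = rational(1, 4))
  # the pure-formate route ledger (phi = 1 limit)
  formate_route <- c(cooS = "1", hdcr_fd = "1", ex_CO = "1",
                     ex_formate = "1")
  for (rid in names(s_ac$fluxes)) {
    f0 <- s_ac$fluxes[[rid]]
    f1 <- parse_rational(
      if (rid %in% names(formate_route)) formate_route[[rid]] else "0")
    expect_true(s_half$fluxes[[rid]] ==
                  f0 * rational(1, 2) + f1 * rational(1, 2), label = rid)
    expect_true(s_q$fluxes[[rid]] ==
                  f0 * rational(3, 4) + f1 * rational(1, 4), label = rid)
  }
  # at phi = 1/2 the CO : acetate : formate ratio is 5 : 1 : 1
  r <- substrate_product_ratios(s_half)
  expect_rational_equal(r$exact[["CO:acetate"]], "5")
  expect_rational_equal(r$exact[["formate:acetate"]], "1")
})

test_that("under-determined and inconsistent systems are told apart", {
  A <- list(rational(c(1, 1, 0)), rational(c(2, 2, 0)))
  res <- acetoflux:::.rat_solve(A, rational(c(1, 2)))
  expect_equal(res$status, "underdetermined")
  res2 <- acetoflux:::.rat_solve(A, rational(c(1, 3)))
  expect_equal(res2$status, "inconsistent")
  res3 <- acetoflux:::.rat_solve(
    list(rational(c(1, 1)), rational(c(1, -1))), rational(c(1, 0)))
  expect_equal(res3$status, "unique")
  expect_equal(as.character(res3$x), c("1/2", "1/2"))
})

test_that("phi outside [0,1] and on single-export models is rejected", {
  m <- build_model(oracle_genotype_mut(), condition_spec("CO"))
  expect_error(solve_steady_state(m, "acetate", phi = rational(3, 2)),
               "phi")
  m_formate <- build_model(oracle_genotype_mut(), condition_spec("formate"))
  # formate is the substrate here; a product split makes no sense
  expect_error(solve_steady_state(m_formate, "acetate", phi = rational(1, 2)),
               "substrate")
})

test_that("carrier ledger renders the scheme arithmetic", {
  wt_f <- solve_steady_state(
    build_model(oracle_genotype_wt(), condition_spec("formate")), "acetate")
  led <- carrier_ledger(wt_f)
  fd <- led[["Fd2-"]]
  expect_setequal(fd$reactions,
                  c("hydABC", "codh_acs_carbonyl_from_co2", "rnf"))
  expect_rational_equal(fd$values[match("hydABC", fd$reactions)], "3/2")
  expect_rational_equal(
    fd$values[match("codh_acs_carbonyl_from_co2", fd$reactions)], "-1")
  expect_rational_equal(fd$values[match("rnf", fd$reactions)], "-1/2")

  mut_f <- solve_steady_state(
    build_model(oracle_genotype_mut(), condition_spec("formate")), "acetate")
  fd2 <- carrier_ledger(mut_f)[["Fd2-"]]
  vals <- as.character(fd2$values)
  expect_setequal(vals, c("3", "-1", "-2"))
})
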