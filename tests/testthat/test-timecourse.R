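test_that("endpoint ratios reproduce the printed conversion figures", {
  expect_equal(endpoint_ratio(22.9, 58.6)$reported, 2.6)
  expect_equal(endpoint_ratio(35.3, 31.9,
                              orientation = "consumed_per_produced")$reported,
               1.1)
  expect_equal(endpoint_ratio(28.9, 25.6,
                              orientation = "consumed_per_produced")$reported,
               1.1)
  # formate consumed : acetate formed on 100 mM formate cultures
  expect_equal(endpoint_ratio(100, 26.3,
                              orientation = "consumed_per_produced",
                              decimals = 1)$reported, 3.8)
  expect_equal(endpoint_ratio(5, 5)$reported, 1.0)
  expect_error(endpoint_ratio(0, 10), "positive")
  expect_error(endpoint_ratio(10, -1), "positive")
})

test_that("fold changes reproduce the printed activity comparisons", {
  expect_equal(fold_change(27.3, 4.1)$reported, 6.7)
  expect_equal(fold_change(55.3, 2.2)$reported, 25)   # integer above 10x
  expect_equal(fold_change(3.3, 3.3)$reported, 1.0)
  expect_error(fold_change(1, 0), "> 0")
})

test_that("ratio and fold-change operations are scale invariant", {
  set.seed(4)
  for (k in c(0.01, 0.5, 3, 250)) {
    a <- runif(1, 1, 50); b <- runif(1, 1, 50)
    expect_equal(endpoint_ratio(k * a, k * b)$raw,
                 endpoint_ratio(a, b)$raw, tolerance = 1e-12)
    expect_equal(fold_change(k * a, k * b)$raw, fold_change(a, b)$raw,
                 tolerance = 1e-12)
  }
})

test_that("growth rate is recovered exactly from a noiseless exponential", {
  od <- simulate_growth(mu = 0.05, lag = 0, od0 = 0.02, od_max = Inf,
                        noise_cv = 0, seed = 1, times = 0:40)
  fit <- growth_rate(od)
  expect_lt(abs(fit$mu - 0.05), 1e-9)
  expect_equal(fit$r_squared, 1)
  # with lag and stationary phase the fit window excludes both
  od2 <- simulate_growth(mu = 0.02, lag = 12, od0 = 0.05, od_max = 1,
                         noise_cv = 0, seed = 1, times = seq(0, 250, 3))
  expect_lt(abs(growth_rate(od2)$mu - 0.02), 1e-9)
})

test_that("growth rate is invariant to rescaling the OD series", {
  od <- simulate_growth(mu = 0.05, seed = 3)
  f1 <- growth_rate(od)
  od_scaled <- timecourse(od$times, 7.3 * od$values, unit = "OD600")
  f2 <- growth_rate(od_scaled)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-12)
  expect_equal(f1$window, f2$window)
})

test_that("degenerate and malformed OD series are handled", {
  fit <- growth_rate(timecourse(0:5, rep(0.3, 6), unit = "OD600"))
  expect_true(fit$degenerate)
  expect_equal(fit$mu, 0)
  expect_true(is.na(fit$r_squared))
  expect_error(growth_rate(timecourse(0:3, c(0, 0, 0, 0), unit = "OD600")),
               "positive OD")
  expect_error(growth_rate(timecourse(0:2, c(1, 2, 4), unit = "OD600"),
                           window_min_points = 4), "positive OD")
})

test_that("specific rates convert mM/h to nmol min^-1 mg^-1", {
  tc <- timecourse(c(0, 1), c(60, 0), protein_conc = 1)
  expect_equal(specific_rate(tc)$rate, 1000)
  tc2 <- timecourse(c(0, 2, 4), c(10, 10, 10), protein_conc = 0.5)
  expect_equal(specific_rate(tc2)$rate, 0)
  # doubling protein halves the specific rate
  tc3 <- timecourse(c(0, 1), c(60, 0), protein_conc = 2)
  expect_equal(specific_rate(tc3)$rate, 500)
  expect_error(specific_rate(timecourse(c(0, 1), c(1, 2))), "protein_conc")
  expect_error(specific_rate(tc, window = c(5, 6)), "fewer than 2")
})

test_that("timecourse CSV dialect round-trips with metadata", {
  tc <- timecourse(c(0, 0.5, 1), c(250, 130, 10), series = "formate",
                   unit = "mM", protein_conc = 1)
  f <- tempfile(fileext = ".csv")
  write_timecourse(tc, f)
  tc2 <- read_timecourse(f)
  expect_equal(tc2$times, tc$times)
  expect_equal(tc2$values, tc$values)
  expect_equal(tc2$series, "formate")
  expect_equal(tc2$protein_conc, 1)
  unlink(f)
})

test_that("timecourse invariants are enforced", {
  expect_error(timecourse(1, 1), "at least 2")
  expect_error(timecourse(c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(timecourse(c(0, 1), c(-1, 2)), "non-negative")
  expect_error(timecourse(c(0, Inf), c(1, 2)), "finite")
})

snp_fixture <- function() {
  read_snp_table(system.file("extdata", "snp_table1.tsv",
                             package = "acetoflux"))
}

test_that("the hycB2 variant is the unique fixed mutation after adaptation", {
  tab <- snp_fixture()
  expect_equal(nrow(tab), 15)
  fixed <- snp_report(tab, "10th transfer", min_frequency = 100)
  expect_equal(nrow(fixed), 1)
  expect_equal(fixed$gene, "hycB2")
  expect_equal(fixed$position, 950586)
  expect_equal(fixed$frequency, 100)
  # also fixed at the first adaptation timepoint
  fixed6 <- snp_report(tab, "after adaptation", min_frequency = 100)
  expect_equal(fixed6$gene, "hycB2")
})

test_that("the 75% screen finds hycB2, modC2 and fdhC in rank order", {
  rep <- snp_report(snp_fixture(), "10th transfer", min_frequency = 75)
  expect_equal(rep$gene, c("hycB2", "modC2", "fdhC"))
  expect_equal(rep$frequency, c(100, 81.2, 78.9))
})

test_that("snp_report(min = 0) returns everything in a total order", {
  tab <- snp_fixture()
  rep <- snp_report(tab, "10th transfer", min_frequency = 0)
  expect_equal(nrow(rep), nrow(tab))
  expect_true(all(diff(rep$frequency) <= 0))
  ties <- split(rep$position, rep$frequency)
  expect_true(all(vapply(ties, function(p) !is.unsorted(p), logical(1))))
  # undetected variants count as 0% with provenance retained
  det <- attr(tab, "detected")
  expect_false(det[tab$gene == "fdhC", "before adaptation"])
  expect_equal(snp_frequencies(tab)[tab$gene == "fdhC",
                                    "before adaptation"][[1]], 0)
})

test_that("SNP TSV dialect round-trips and flags malformed frequencies", {
  tab <- snp_fixture()
  f <- tempfile(fileext = ".tsv")
  write_snp_table(tab, f)
  tab2 <- read_snp_table(f)
  expect_equal(tab2$position, tab$position)
  expect_equal(snp_frequencies(tab2), snp_frequencies(tab))
  expect_equal(attr(tab2, "detected"), attr(tab, "detected"))
  unlink(f)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("position\tmutation\tfreq_10th\tgene",
               "100\tA->T\t55\tx", "200\tG->C\t140\ty"), bad)
  expect_error(read_snp_table(bad), "row 2")
  unlink(bad)

  empty <- snp_report(tab, "10th transfer", min_frequency = 101)
  expect_equal(nrow(empty), 0)
})
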