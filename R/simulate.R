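#' @title Seeded synthetic data generators
#' @description Batch growth curves (lag -> exponential -> stationary with
#'   multiplicative noise), resting-cell metabolite conversion timecourses
#'   whose endpoint stoichiometry matches a flux solution, and SNP frequency
#'   tables with one sweeping locus. All generators are deterministic per
#'   seed and leave the caller's global RNG state untouched.
#' @name synthetic_data
NULL

# Run code under a fixed seed without disturbing global RNG state.
.with_seed <- function(seed, fn) {
  if (!is.numeric(seed) || !is.finite(seed)) stop("seed must be an integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

# multiplicative lognormal noise with unit mean and the given CV
.mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Simulate a batch growth curve
#'
#' Three-phase batch curve: OD is held at `od0` through the lag, grows
#' exponentially at rate `mu` (so the exponential phase is exactly
#' log-linear, making `mu` the quantity [growth_rate()] estimates), and
#' saturates at the carrying capacity `od_max`:
#' `OD(t) = min(od0 * exp(mu * max(t - lag, 0)), od_max)`. With
#' `od_max = Inf` the curve is purely exponential. Noise is multiplicative
#' lognormal with unit mean and coefficient of variation `noise_cv`
#' (OD readings are positive, so noise must be). Bit-for-bit reproducible
#' per seed.
#'
#' Defaults emulate the CO-adapted cultures: mu = 0.05 1/h from an
#' inoculation OD600 of 0.05 to a final OD600 of 1.0, sampled every 3 h
#' over 120 h, 5% noise.
#'
#' @param mu specific growth rate (1/h), >= 0.
#' @param lag lag phase (h).
#' @param od0 inoculation OD600, > 0.
#' @param od_max carrying capacity (OD600), >= od0; `Inf` for unbounded
#'   exponential growth.
#' @param noise_cv fractional multiplicative noise (0.05 = 5%).
#' @param seed integer seed.
#' @param times sampling times (h).
#' @return a `timecourse` (unit OD600).
#' @examples
#' od <- simulate_growth(seed = 42)
#' growth_rate(od)
#' @export
simulate_growth <- function(mu = 0.05, lag = 0, od0 = 0.05, od_max = 1.0,
                            noise_cv = 0.05, seed = 1,
                            times = seq(0, 120, by = 3)) {
  if (mu < 0) stop("mu must be >= 0")
  if (od0 <= 0) stop("od0 must be > 0")
  if (od_max < od0) stop("od_max must be >= od0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  tt <- pmax(times - lag, 0)
  od <- pmin(od0 * exp(mu * tt), od_max)
  noisy <- .with_seed(seed, function() od * .mult_noise(length(od), noise_cv))
  timecourse(times, noisy, series = "OD600", unit = "OD600")
}

#' Simulate a resting-cell conversion timecourse
#'
#' The substrate declines linearly at the configured specific rate until
#' exhaustion; each product rises with a slope scaled by its stoichiometric
#' ratio to the substrate taken from the flux solution, so noiseless
#' endpoint ratios equal the model's ratios exactly. Gaseous CO2 is not
#' included among the reported series (the experiments it emulates measure
#' dissolved metabolites).
#'
#' @param solution a feasible `flux_solution` fixing the
#'   product:substrate stoichiometry.
#' @param substrate0 initial substrate concentration (mM), > 0.
#' @param rate specific substrate consumption rate
#'   (nmol min^-1 mg^-1), >= 0.
#' @param protein_conc suspension protein concentration (mg/mL).
#' @param noise_cv fractional multiplicative noise per point.
#' @param seed integer seed.
#' @param times sampling times (h); by default 25 points spanning 120% of
#'   the exhaustion time (24 h when `rate = 0`).
#' @return named list of `timecourse` objects: the substrate and every
#'   dissolved product with non-zero stoichiometry.
#' @examples
#' mut <- genotype_spec(hydABC_present = FALSE,
#'                      hdcr_hydrogenase_module_present = FALSE,
#'                      fd_hdcr_enabled = TRUE)
#' sol <- solve_steady_state(build_model(mut, condition_spec("formate")),
#'                           "acetate")
#' sim <- simulate_conversion(sol, substrate0 = 100, rate = 200,
#'                            noise_cv = 0, seed = 1)
#' vapply(sim, function(tc) tail(tc$values, 1), numeric(1))
#' @export
simulate_conversion <- function(solution, substrate0 = 250, rate = 800,
                                protein_conc = 1, noise_cv = 0.05, seed = 1,
                                times = NULL) {
  if (inherits(solution, "infeasibility_report")) {
    stop("cannot simulate an infeasible scenario: ",
         solution$missing_capability)
  }
  stopifnot(inherits(solution, "flux_solution"))
  if (substrate0 <= 0) stop("substrate0 must be > 0")
  if (rate < 0) stop("rate must be >= 0")
  subs <- solution$substrate_consumed
  if (!length(subs)) stop("solution consumes no substrate")
  substrate <- names(subs)[1]
  sub_flux <- as.numeric(subs[[substrate]])

  slope <- rate * 60 * protein_conc / 1000  # nmol/min/mg -> mM/h
  if (is.null(times)) {
    t_end <- if (slope > 0) 1.2 * substrate0 / slope else 24
    times <- seq(0, t_end, length.out = 25)
  }
  consumed <- pmin(slope * times, substrate0)

  prods <- solution$products_formed
  prods <- prods[names(prods) %in% c("acetate", "formate")]
  ratios <- vapply(prods, function(v) as.numeric(v) / sub_flux, numeric(1))

  n <- length(times)
  k <- 1 + length(ratios)
  noise <- .with_seed(seed, function()
    matrix(.mult_noise(n * k, noise_cv), n, k))

  out <- list()
  out[[substrate]] <- timecourse(times,
                                 (substrate0 - consumed) * noise[, 1],
                                 series = substrate, unit = "mM",
                                 protein_conc = protein_conc)
  for (m in seq_along(ratios)) {
    p <- names(ratios)[m]
    out[[p]] <- timecourse(times, ratios[m] * consumed * noise[, m + 1],
                           series = p, unit = "mM",
                           protein_conc = protein_conc)
  }
  out
}

#' Simulate a SNP frequency table
#'
#' Emulates the structure of an adaptive-laboratory-evolution variant
#' table: one locus sweeps to fixation (100%) by the final timepoint while
#' the remaining loci fluctuate below fixation (frequencies drawn in
#' \[0, 90)).
#'
#' @param loci number of variant loci, >= 1.
#' @param sweep_locus index of the sweeping locus.
#' @param timepoints character timepoint labels.
#' @param seed integer seed.
#' @return a `snp_table`.
#' @examples
#' tab <- simulate_snp_table(5, sweep_locus = 2, seed = 7)
#' snp_report(tab, "10th transfer", min_frequency = 100)
#' @export
simulate_snp_table <- function(loci, sweep_locus = 1,
                               timepoints = c("before adaptation",
                                              "after adaptation",
                                              "10th transfer"),
                               seed = 1) {
  if (loci < 1) stop("loci must be >= 1")
  if (sweep_locus < 1 || sweep_locus > loci) {
    stop("sweep_locus out of range 1..", loci)
  }
  k <- length(timepoints)
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, function() {
    positions <- sort(sample.int(4e6, loci))
    ref <- sample(bases, loci, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    freq <- matrix(stats::runif(loci * k, 0, 90), loci, k,
                   dimnames = list(NULL, timepoints))
    sweep <- c(sort(stats::runif(k - 1, 0, 90)), 100)
    freq[sweep_locus, ] <- sweep
    det <- freq > 0
    df <- data.frame(position = positions,
                     mutation = paste0(ref, "->", alt),
                     aa_change = "",
                     gene = sprintf("locus_%03d", seq_len(loci)),
                     annotation = ifelse(seq_len(loci) == sweep_locus,
                                         "sweeping variant",
                                         "segregating variant"),
                     stringsAsFactors = FALSE)
    .snp_table(df, freq, det)
  })
}
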