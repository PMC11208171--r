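#' @title Named scenario registry
#' @description Config-driven reproductions of the bioenergetic schemes
#'   (wild type and hydrogenase-free mutant on CO, formate, H2 + CO2 and
#'   fructose) and the resting-cell conditions (Na+ depletion, bicarbonate
#'   uncoupling, mixed acetate/formate production), each solved end-to-end
#'   from a YAML preset.
#' @name scenarios
NULL

#' Load the scenario registry
#'
#' @param path YAML registry file; defaults to the registry shipped with the
#'   package.
#' @return A list with `genotypes`, `conditions` and `scenarios`.
#' @export
scenario_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scenarios.yaml", package = "acetoflux")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("scenario registry not found: ", path)
  }
  reg <- yaml::read_yaml(path)
  for (need in c("genotypes", "conditions", "scenarios")) {
    if (is.null(reg[[need]])) stop("registry lacks a '", need, "' section")
  }
  reg
}

#' Names of the registered scenarios
#' @param registry parsed registry (defaults to the shipped one).
#' @return character vector of scenario names.
#' @export
list_scenarios <- function(registry = scenario_registry()) {
  names(registry$scenarios)
}

.genotype_from_preset <- function(p) {
  genotype_spec(hydABC_present = isTRUE(p$hydABC_present),
                hdcr_hydrogenase_module_present =
                  isTRUE(p$hdcr_hydrogenase_module_present),
                hdcr_fdh_module_present = isTRUE(p$hdcr_fdh_module_present),
                fd_hdcr_enabled = isTRUE(p$fd_hdcr_enabled),
                cooS_present = isTRUE(p$cooS_present),
                rnf_present = isTRUE(p$rnf_present),
                label = if (is.null(p$label)) "" else p$label)
}

.condition_from_preset <- function(p) {
  condition_spec(substrates_available = unlist(p$substrates_available),
                 na_available = !isFALSE(p$na_available),
                 atp_coupling_available = !isFALSE(p$atp_coupling_available),
                 co2_available_as_acceptor =
                   !isFALSE(p$co2_available_as_acceptor),
                 label = if (is.null(p$label)) "" else p$label)
}

#' Build the model behind a named scenario
#'
#' @param name scenario name (see [list_scenarios()]).
#' @param registry parsed registry.
#' @param parameters chemiosmotic parameters.
#' @return a `stoich_model`.
#' @export
scenario_model <- function(name, registry = scenario_registry(),
                           parameters = model_parameters()) {
  sc <- registry$scenarios[[name]]
  if (is.null(sc)) {
    stop("unknown scenario '", name, "'; registry has: ",
         paste(names(registry$scenarios), collapse = ", "))
  }
  gt <- registry$genotypes[[sc$genotype]]
  if (is.null(gt)) stop("scenario '", name, "': unknown genotype preset '",
                        sc$genotype, "'")
  cn <- registry$conditions[[sc$condition]]
  if (is.null(cn)) stop("scenario '", name, "': unknown condition preset '",
                        sc$condition, "'")
  build_model(.genotype_from_preset(gt), .condition_from_preset(cn),
              parameters)
}

#' Run a named scenario
#'
#' Assembles the scenario's model, solves its steady state per unit product
#' and summarises the energetics. Infeasible scenarios (e.g. the
#' hydrogenase-free mutant on H2 + CO2) carry the infeasibility report
#' verbatim instead of yields.
#'
#' @param name scenario name.
#' @param phi optional formate branch fraction, overriding the registry
#'   default for scenarios that expose it.
#' @param flux product flux normalisation (default 1).
#' @param registry parsed registry.
#' @param parameters chemiosmotic parameters.
#' @return An object of class `scenario_report`.
#' @examples
#' run_scenario("wt_formate")
#' run_scenario("mut_formate")
#' @export
run_scenario <- function(name, phi = NULL, flux = rational(1),
                         registry = scenario_registry(),
                         parameters = model_parameters()) {
  sc <- registry$scenarios[[name]]
  if (is.null(sc)) {
    stop("unknown scenario '", name, "'; registry has: ",
         paste(names(registry$scenarios), collapse = ", "))
  }
  model <- scenario_model(name, registry, parameters)
  if (is.null(phi) && !is.null(sc$phi)) phi <- parse_rational(sc$phi)
  sol <- solve_steady_state(model, product = sc$product, flux = flux,
                            phi = phi)
  if (inherits(sol, "infeasibility_report")) {
    return(structure(list(name = name, feasible = FALSE,
                          infeasibility = sol,
                          notes = sc$notes),
                     class = "scenario_report"))
  }
  structure(list(name = name, feasible = TRUE, solution = sol,
                 atp_yield_exact = atp_yield(sol),
                 atp_yield_reported = atp_yield(sol, exact = FALSE),
                 na_pumped = sol$na_pumped,
                 ratios = substrate_product_ratios(sol),
                 ledger = carrier_ledger(sol),
                 notes = sc$notes),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  if (!x$feasible) {
    print(x$infeasibility)
    return(invisible(x))
  }
  cat("  ATP yield per product: ", as.character(x$atp_yield_exact),
      " (reported ", format(x$atp_yield_reported, nsmall = 1), ")\n",
      sep = "")
  cat("  Na+ pumped per product:", as.character(x$na_pumped), "\n")
  if (length(x$ratios$reported)) {
    cat("  ratios:", paste(names(x$ratios$reported),
                           format(x$ratios$reported),
                           sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare the ATP yields of two scenarios
#'
#' @param a,b scenario names (both must be feasible).
#' @param ... passed to [run_scenario()].
#' @return list with exact rational yields, the exact yield delta, and the
#'   percent change `(yield_a - yield_b) / yield_b * 100` rounded half-up to
#'   the nearest integer.
#' @examples
#' compare_scenarios("mut_formate", "wt_formate")$percent_change  # 300
#' @export
compare_scenarios <- function(a, b, ...) {
  ra <- run_scenario(a, ...)
  rb <- run_scenario(b, ...)
  if (!ra$feasible) stop("scenario '", a, "' is infeasible")
  if (!rb$feasible) stop("scenario '", b, "' is infeasible")
  ya <- ra$atp_yield_exact
  yb <- rb$atp_yield_exact
  if (yb == 0) stop("reference scenario '", b, "' has zero ATP yield")
  pct <- (ya - yb) / yb * rational(100)
  list(yield_a = ya, yield_b = yb, delta = ya - yb,
       percent_change = round_half_up(pct, 0))
}
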