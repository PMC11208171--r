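#' @title Exact steady-state flux solver
#' @description Solves the assembled network for the unique flux
#'   distribution per unit product by exact rational Gaussian elimination
#'   over the species balance matrix, checks uniqueness via the null space,
#'   verifies irreversibility post hoc, and accounts the Na+ and ATP ledgers.
#' @name flux_solver
NULL

# --- rational linear algebra ------------------------------------------------
# A rational matrix is a list of rational row vectors; tiny systems only.

.rref <- function(rows) {
  nr <- length(rows)
  nc <- if (nr) length(rows[[1]]) else 0
  pivots <- integer(0)
  lead <- 1L
  for (col in seq_len(nc)) {
    if (lead > nr) break
    piv <- NA_integer_
    for (i in lead:nr) {
      if (!(rows[[i]][col] == 0)) { piv <- i; break }
    }
    if (is.na(piv)) next
    tmp <- rows[[lead]]; rows[[lead]] <- rows[[piv]]; rows[[piv]] <- tmp
    rows[[lead]] <- rows[[lead]] / rows[[lead]][col]
    for (i in seq_len(nr)) {
      if (i != lead && !(rows[[i]][col] == 0)) {
        rows[[i]] <- rows[[i]] - rows[[i]][col] * rows[[lead]]
      }
    }
    pivots <- c(pivots, col)
    lead <- lead + 1L
  }
  list(rows = rows, pivots = pivots, rank = length(pivots))
}

# Solve A x = b exactly.  Returns one of:
#   list(status="unique", x=rational)
#   list(status="underdetermined", free=<column indices of null directions>)
#   list(status="inconsistent", rows=<indices of original rows implicated>)
.rat_solve <- function(A, b) {
  nr <- length(A)
  nc <- if (nr) length(A[[1]]) else 0
  aug <- lapply(seq_len(nr), function(i) c(A[[i]], b[i]))
  red <- .rref(aug)
  # inconsistency: pivot in the augmented column
  if ((nc + 1L) %in% red$pivots) {
    bad <- which(vapply(red$rows, function(r) {
      all(as.numeric(r[seq_len(nc)]) == 0) && !(r[nc + 1L] == 0)
    }, logical(1)))
    return(list(status = "inconsistent", red = red, rows = bad))
  }
  pivots <- red$pivots
  if (length(pivots) < nc) {
    return(list(status = "underdetermined",
                free = setdiff(seq_len(nc), pivots), red = red))
  }
  x <- rational(rep(0, nc))
  for (k in seq_along(pivots)) x[pivots[k]] <- red$rows[[k]][nc + 1L]
  list(status = "unique", x = x)
}

# --- solver -----------------------------------------------------------------

.balance_system <- function(model) {
  # rows: every species except the ATP energy ledger (ATP is reported net,
  # not balanced; Na+ *is* balanced, which realises Na_pumped/na_per_atp as
  # synthase flux).  columns: reactions in model order.
  sp_ids <- names(model$species)
  balanced <- sp_ids[vapply(sp_ids, function(s)
    model$species[[s]]$role != "energy_ledger", logical(1))]
  rids <- reaction_ids(model)
  rows <- lapply(balanced, function(s) {
    r <- rational(rep(0, length(rids)))
    for (j in seq_along(model$reactions)) {
      co <- model$reactions[[j]]$stoich[[s]]
      if (!is.null(co)) r[j] <- co
    }
    r
  })
  list(rows = rows, species = balanced, reactions = rids)
}

.unit_row <- function(n, j, scale = rational(1)) {
  r <- rational(rep(0, n))
  r[j] <- scale
  r
}

#' Solve the steady state of an acetogenesis model per unit product
#'
#' Computes the flux through every reaction such that the net production of
#' every balanced species is exactly zero and the targeted product export
#' equals `flux`. The linear system is solved by exact rational Gaussian
#' elimination; the solution is accepted only if it is unique (null space of
#' dimension zero after the normalisation rows) and respects every
#' irreversible reaction's direction. Sodium is balanced through the ATP
#' synthase, so the chemiosmotic ATP appears as synthase flux; ATP itself is
#' a reported net, giving `atp_yield = slp_net + na_pumped / na_per_atp`.
#'
#' When both acetate and formate can be formed, the product split is not
#' determined by stoichiometry alone; supply `phi`, the formate branch
#' fraction, to fix acetate export at `(1 - phi) * flux` and formate export
#' at `phi * flux`. Without `phi` the non-target product's export is closed.
#'
#' @param model a validated [build_model()] result.
#' @param product `"acetate"` or `"formate"`.
#' @param flux the product flux used for normalisation (rational or integer;
#'   default 1). Solutions are homogeneous of degree 1 in `flux`.
#' @param phi optional formate branch fraction in \[0, 1\].
#' @return An object of class `flux_solution` (feasible) or
#'   `infeasibility_report` (no exact balance exists); an error is raised if
#'   the constrained system retains a free flux direction.
#' @examples
#' wt <- build_model(genotype_spec(label = "wild type"),
#'                   condition_spec(c("H2", "CO2")))
#' sol <- solve_steady_state(wt, "acetate")
#' sol
#' atp_yield(sol)
#' @export
solve_steady_state <- function(model, product = "acetate",
                               flux = rational(1), phi = NULL) {
  stopifnot(inherits(model, "stoich_model"))
  product <- match.arg(product, c("acetate", "formate"))
  flux <- .as_rat(flux)
  if (!(flux > 0)) stop("target flux must be > 0")
  diags <- validate_model(model)
  if (length(diags)) {
    stop("model failed validation:\n  ", paste(diags, collapse = "\n  "))
  }

  sys <- .balance_system(model)
  rids <- sys$reactions
  n <- length(rids)
  ex_ac <- match("ex_acetate", rids)
  ex_fo <- match("ex_formate", rids)

  A <- sys$rows
  b <- rational(rep(0, length(A)))
  labels <- sys$species

  add_row <- function(j, value, what) {
    if (is.na(j)) {
      stop("product exchange '", what, "' is not part of this model")
    }
    A[[length(A) + 1L]] <<- .unit_row(n, j)
    b <<- c(b, value)
    labels <<- c(labels, what)
  }

  if (!is.null(phi)) {
    phi <- .as_rat(phi)
    if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
    if (is.na(ex_ac) || is.na(ex_fo)) {
      stop("phi requires both the acetate and formate exchanges to be open")
    }
    if ("formate" %in% model$condition$substrates_available) {
      stop("phi splits the product exports; it is not meaningful when ",
           "formate is a substrate")
    }
    # exports carry coefficient -1 on the species, so export flux is the
    # reaction flux itself
    add_row(ex_ac, (rational(1) - phi) * flux, "acetate export")
    add_row(ex_fo, phi * flux, "formate export")
  } else {
    tgt <- if (product == "acetate") ex_ac else ex_fo
    oth_sp <- setdiff(c("acetate", "formate"), product)
    oth <- if (product == "acetate") ex_fo else ex_ac
    add_row(tgt, flux, paste(product, "export"))
    # close the non-target product's export -- unless that species is a
    # substrate, in which case its exchange is the (free) uptake
    if (!is.na(oth) &&
        !(oth_sp %in% model$condition$substrates_available)) {
      add_row(oth, rational(0), paste(oth_sp, "export"))
    }
  }

  res <- .rat_solve(A, b)

  if (res$status == "underdetermined") {
    free_rxns <- rids[res$free]
    stop("steady state is under-determined: free flux direction through ",
         paste(free_rxns, collapse = ", "),
         "; fix it (e.g. via phi) or close an exchange")
  }
  if (res$status == "inconsistent") {
    return(.infeasibility_report(model, A, b, labels, length(sys$rows)))
  }

  x <- res$x
  # Irreversibility is imposed post hoc on the unique solution.
  for (j in seq_len(n)) {
    r <- model$reactions[[j]]
    if (!r$reversible && x[j] < 0) {
      return(.infeasibility_report_direction(model, rids[j], x[j]))
    }
  }
  .flux_solution(model, x, product, flux, phi)
}

# Name a minimal set of species whose balances cannot close: each balance
# row whose removal (alone) restores consistency of the linear system is
# part of an irreducible conflict.  A static producer/consumer scan over the
# active reactions supplies the mechanistic reading (e.g. "no route to
# regenerate NADH").
.infeasibility_report <- function(model, A, b, labels, n_balance) {
  bad_species <- character(0)
  for (i in seq_len(n_balance)) {
    sub <- .rat_solve(A[-i], b[-i])
    if (sub$status != "inconsistent") bad_species <- c(bad_species, labels[i])
  }
  scan <- .capability_scan(model)
  if (length(scan$species)) {
    bad_species <- unique(c(bad_species, scan$species))
  }
  if (!length(bad_species)) bad_species <- labels[seq_len(n_balance)]
  structure(list(unbalanceable_species = bad_species,
                 missing_capability = scan$text,
                 model_label = model$genotype$label),
            class = "infeasibility_report")
}

.capability_scan <- function(model) {
  sp <- model$species
  msgs <- character(0); bad <- character(0)
  for (s in names(sp)) {
    if (!(sp[[s]]$role %in% c("internal_carrier", "thf_intermediate"))) next
    prod <- FALSE; cons <- FALSE
    for (r in model$reactions) {
      co <- r$stoich[[s]]
      if (is.null(co)) next
      if (co > 0 || (r$reversible && co < 0)) prod <- TRUE
      if (co < 0 || (r$reversible && co > 0)) cons <- TRUE
    }
    if (!prod) {
      bad <- c(bad, s)
      msgs <- c(msgs, sprintf("no route to regenerate %s", s))
    } else if (!cons) {
      bad <- c(bad, s)
      msgs <- c(msgs, sprintf("no route to re-oxidise/consume %s", s))
    }
  }
  if (!length(msgs)) {
    msgs <- "balances over the active reactions are mutually inconsistent"
    if (!("rnf" %in% reaction_ids(model))) {
      msgs <- c(msgs, paste0("without the Rnf complex there is no ",
                             "chemiosmotic route between the ferredoxin ",
                             "and NAD(H) pools"))
    }
  }
  list(species = bad, text = paste(msgs, collapse = "; "))
}

.infeasibility_report_direction <- function(model, rid, value) {
  structure(list(unbalanceable_species = character(0),
                 missing_capability = sprintf(
                   paste0("the unique balanced solution drives irreversible ",
                          "reaction '%s' backwards (flux %s)"),
                   rid, as.character(value)),
                 signed_flux = stats::setNames(as.numeric(value), rid),
                 model_label = model$genotype$label),
            class = "infeasibility_report")
}

#' @export
is_feasible <- function(x) inherits(x, "flux_solution")

#' @export
print.infeasibility_report <- function(x, ...) {
  cat("Infeasible scenario")
  if (nzchar(x$model_label)) cat(" [", x$model_label, "]", sep = "")
  cat("\n  ", x$missing_capability, "\n", sep = "")
  if (length(x$unbalanceable_species)) {
    cat("  unbalanceable species:",
        paste(x$unbalanceable_species, collapse = ", "), "\n")
  }
  invisible(x)
}

# --- flux solution object ---------------------------------------------------

.flux_solution <- function(model, x, product, flux, phi) {
  rids <- reaction_ids(model)
  fluxes <- stats::setNames(lapply(seq_along(rids), function(j) x[j]), rids)

  # residuals (all exactly zero by construction; recomputed as a guarantee)
  sys <- .balance_system(model)
  residuals <- stats::setNames(lapply(seq_along(sys$rows), function(i) {
    acc <- rational(0)
    row <- sys$rows[[i]]
    for (j in seq_along(rids)) acc <- acc + row[j] * x[j]
    acc
  }), sys$species)

  na_pumped <- rational(0)
  slp <- rational(0)
  for (j in seq_along(rids)) {
    r <- model$reactions[[j]]
    if (r$enzyme_tag == "rnf") na_pumped <- na_pumped + r$na_translocated * x[j]
    atp <- r$stoich[["ATP"]]
    if (!is.null(atp) && r$enzyme_tag != "atp_synthase") {
      slp <- slp + atp * x[j]
    }
  }
  atp <- slp + na_pumped / model$parameters$na_per_atp

  substrate_consumed <- list()
  for (s in model$condition$substrates_available) {
    j <- match(paste0("ex_", s), rids)
    if (!is.na(j) && x[j] > 0) substrate_consumed[[s]] <- x[j]
  }
  products_formed <- list()
  for (p in c("acetate", "formate", "CO2", "H2")) {
    j <- match(paste0("ex_", p), rids)
    if (is.na(j)) next
    r <- model$reactions[[j]]
    v <- if (r$stoich[[p]] < 0) x[j] else -x[j]  # export flux, positive out
    if (v > 0) products_formed[[p]] <- v
  }

  structure(list(model = model, fluxes = fluxes, balances = residuals,
                 na_pumped = na_pumped, slp_net = slp, atp_yield = atp,
                 substrate_consumed = substrate_consumed,
                 products_formed = products_formed,
                 target = list(product = product, flux = flux, phi = phi)),
            class = "flux_solution")
}

#' Net ATP yield of a steady-state solution
#'
#' Substrate-level net (acetate kinase minus formyl-THF synthetase, plus any
#' lumped catabolic ATP) plus the chemiosmotic share, Na+ pumped by Rnf
#' divided by the Na+/ATP stoichiometry of the synthase.
#'
#' @param solution a `flux_solution`.
#' @param exact return the exact rational (default) or the 1-decimal
#'   reported value.
#' @return rational (exact) or numeric (reported).
#' @export
atp_yield <- function(solution, exact = TRUE) {
  if (inherits(solution, "infeasibility_report")) {
    stop("atp_yield() is undefined for an infeasible scenario: ",
         solution$missing_capability)
  }
  stopifnot(inherits(solution, "flux_solution"))
  if (exact) solution$atp_yield else round_half_up(solution$atp_yield, 1)
}

#' Substrate : product ratios of a solution
#'
#' Consumption of every substrate and formation of every secondary product,
#' normalised to the first (targeted) product. Returned exactly, with a
#' 1-decimal rendering per the reporting convention.
#'
#' @param solution a `flux_solution`.
#' @return a list with components `exact` (named list of rationals) and
#'   `reported` (named numeric, round-half-up to 1 decimal), both keyed
#'   `"<species>:<product>"`.
#' @export
substrate_product_ratios <- function(solution) {
  if (inherits(solution, "infeasibility_report")) {
    stop("no ratios for an infeasible scenario")
  }
  stopifnot(inherits(solution, "flux_solution"))
  prods <- solution$products_formed
  prods <- prods[names(prods) != "CO2"]
  if (!length(prods)) stop("solution forms no product; ratios undefined")
  first <- names(prods)[1]
  ref <- prods[[first]]
  if (!(ref > 0)) stop("zero product flux; ratios undefined")
  out <- list()
  for (s in names(solution$substrate_consumed)) {
    out[[paste0(s, ":", first)]] <- solution$substrate_consumed[[s]] / ref
  }
  for (p in setdiff(names(prods), first)) {
    out[[paste0(p, ":", first)]] <- prods[[p]] / ref
  }
  list(exact = out,
       reported = vapply(out, round_half_up, numeric(1), digits = 1))
}

#' Per-carrier production/consumption ledger
#'
#' Renders the arithmetic of the bioenergetic scheme: for each electron
#' carrier (and the Na+/ATP ledgers), the signed contribution of every
#' reaction with non-zero flux, exactly as the scheme diagrams tally them.
#'
#' @param solution a `flux_solution`.
#' @param carriers species to tabulate; defaults to the electron carriers
#'   and ledgers present.
#' @return An object of class `carrier_ledger`: a named list mapping species
#'   to a named `rational` vector of per-reaction contributions.
#' @export
carrier_ledger <- function(solution,
                           carriers = c("Fd2-", "NADH", "H2", "Na+", "ATP")) {
  stopifnot(inherits(solution, "flux_solution"))
  model <- solution$model
  rids <- reaction_ids(model)
  out <- list()
  for (s in intersect(carriers, names(model$species))) {
    entries <- rational(numeric(0)); who <- character(0)
    for (j in seq_along(rids)) {
      co <- model$reactions[[j]]$stoich[[s]]
      if (is.null(co)) next
      v <- co * solution$fluxes[[rids[j]]]
      if (!(v == 0)) { entries <- c(entries, v); who <- c(who, rids[j]) }
    }
    if (length(who)) out[[s]] <- list(reactions = who, values = entries)
  }
  structure(out, class = "carrier_ledger")
}

#' @export
print.carrier_ledger <- function(x, ...) {
  if (!length(x)) { cat("(empty ledger)\n"); return(invisible(x)) }
  for (s in names(x)) {
    cat(s, ":\n", sep = "")
    v <- x[[s]]
    for (i in seq_along(v$reactions)) {
      cat(sprintf("  %+8.4g  %-28s (%s)\n", as.numeric(v$values[i]),
                  v$reactions[i], as.character(v$values[i])))
    }
  }
  invisible(x)
}

#' @export
print.flux_solution <- function(x, ...) {
  tg <- x$target
  cat("Steady-state flux solution per ", as.character(tg$flux), " ",
      tg$product, if (!is.null(tg$phi))
        paste0(" (phi = ", as.character(tg$phi), ")"), "\n", sep = "")
  nz <- Filter(function(v) !(v == 0), x$fluxes)
  for (id in names(nz)) {
    cat(sprintf("  %-28s %10s\n", id, as.character(nz[[id]])))
  }
  cat("  Na+ pumped: ", as.character(x$na_pumped),
      "   SLP net: ", as.character(x$slp_net),
      "   ATP yield: ", as.character(x$atp_yield),
      " (", round_half_up(x$atp_yield, 1), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.flux_solution <- function(object, ...) {
  print(object)
  cat("\nCarrier ledger:\n")
  print(carrier_ledger(object))
  r <- substrate_product_ratios(object)
  cat("Ratios:", paste(names(r$reported), format(r$reported), sep = " = ",
                       collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.flux_solution <- function(object, ...) {
  vapply(object$fluxes, as.numeric, numeric(1))
}

#' Exact flux through one reaction
#' @param solution a `flux_solution`.
#' @param id reaction id.
#' @return a length-1 `rational`.
#' @export
flux_of <- function(solution, id) {
  stopifnot(inherits(solution, "flux_solution"))
  v <- solution$fluxes[[id]]
  if (is.null(v)) stop("no reaction '", id, "' in this model")
  v
}
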