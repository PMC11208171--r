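#' @title Species, reactions and model assembly for the acetogenesis network
#' @description Internal constructors for the electron-flow network of
#'   *Acetobacterium woodii*: the Wood-Ljungdahl pathway (methyl and carbonyl
#'   branches), the electron-bifurcating hydrogenase HydABC, the
#'   hydrogen-dependent CO2 reductase (HDCR) in its H2 and ferredoxin modes,
#'   the monofunctional CO dehydrogenase CooS, the Na+-translocating Rnf
#'   complex and the Na+ F1F0 ATP synthase.
#' @name network_core
NULL

# ---------------------------------------------------------------------------
# Species table.  Degree of reduction is counted in electrons relative to the
# fully oxidised reference (CO2, NAD+, oxidised Fd, unloaded THF = 0); every
# two-electron reduction step adds 2.  Carbon counts only the mobile C1/C2
# unit for THF-bound and CoA-bound intermediates.
# ---------------------------------------------------------------------------

.species_table <- function() {
  sp <- list(
    list(id = "CO2",           role = "external_product",  carbon = 1, dor = 0),
    list(id = "CO",            role = "external_substrate", carbon = 1, dor = 2),
    list(id = "formate",       role = "external_product",  carbon = 1, dor = 2),
    list(id = "H2",            role = "external_substrate", carbon = 0, dor = 2),
    list(id = "fructose",      role = "external_substrate", carbon = 6, dor = 24),
    list(id = "acetate",       role = "external_product",  carbon = 2, dor = 8),
    list(id = "Fd2-",          role = "internal_carrier",  carbon = 0, dor = 2),
    list(id = "NADH",          role = "internal_carrier",  carbon = 0, dor = 2),
    list(id = "THF",           role = "thf_intermediate",  carbon = 0, dor = 0),
    list(id = "formyl-THF",    role = "thf_intermediate",  carbon = 1, dor = 2),
    list(id = "methylene-THF", role = "thf_intermediate",  carbon = 1, dor = 4),
    list(id = "methyl-THF",    role = "thf_intermediate",  carbon = 1, dor = 6),
    list(id = "[CO]",          role = "internal_carrier",  carbon = 1, dor = 2),
    list(id = "acetyl-CoA",    role = "internal_carrier",  carbon = 2, dor = 8),
    list(id = "Na+",           role = "ion_ledger",        carbon = 0, dor = 0),
    list(id = "ATP",           role = "energy_ledger",     carbon = 0, dor = 0)
  )
  ids <- vapply(sp, `[[`, character(1), "id")
  stats::setNames(sp, ids)
}

#' Model parameters of the chemiosmotic ledger
#'
#' @param na_per_atp Na+ ions consumed by the ATP synthase per ATP, as an
#'   exact rational. Default 33/10, the c-ring stoichiometry of the
#'   *A. woodii* Na+ F1F0 ATP synthase.
#' @param na_per_fd2_rnf Na+ ions pumped by the Rnf complex per reduced
#'   ferredoxin oxidised (i.e. per 2 electrons). Default 2.
#' @param h2_escape_fraction fraction of pathway hydrogen lost to the
#'   headspace rather than recaptured; the default 0 is the closed-ledger
#'   idealisation of the wild-type schemes. A value > 0 opens an H2 export.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(na_per_atp = rational(33, 10),
                             na_per_fd2_rnf = rational(2),
                             h2_escape_fraction = rational(0)) {
  na_per_atp <- .as_rat(na_per_atp)
  na_per_fd2_rnf <- .as_rat(na_per_fd2_rnf)
  h2_escape_fraction <- .as_rat(h2_escape_fraction)
  if (!(na_per_atp > 0)) stop("na_per_atp must be > 0")
  if (na_per_fd2_rnf < 0) stop("na_per_fd2_rnf must be >= 0")
  if (h2_escape_fraction < 0 || h2_escape_fraction > 1) {
    stop("h2_escape_fraction must lie in [0, 1]")
  }
  structure(list(na_per_atp = na_per_atp,
                 na_per_fd2_rnf = na_per_fd2_rnf,
                 h2_escape_fraction = h2_escape_fraction),
            class = "model_parameters")
}

#' Genotype specification
#'
#' Which enzyme modules the strain carries. The wild type has both
#' hydrogenases; the hydrogenase-free double mutant lacks HydABC and the
#' HydA2 hydrogenase module of the HDCR, and (after adaptation on CO) runs
#' the HDCR on reduced ferredoxin instead.
#'
#' @param hydABC_present electron-bifurcating hydrogenase HydABC present.
#' @param hdcr_hydrogenase_module_present HydA2 module of the HDCR present.
#' @param hdcr_fdh_module_present formate-dehydrogenase module of the HDCR
#'   present.
#' @param fd_hdcr_enabled ferredoxin-mode HDCR active (the CO-adapted
#'   mutant's capability; requires the FDH module).
#' @param cooS_present monofunctional CO dehydrogenase CooS present.
#' @param rnf_present Rnf complex present.
#' @param label free-text strain label.
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(hydABC_present = TRUE,
                          hdcr_hydrogenase_module_present = TRUE,
                          hdcr_fdh_module_present = TRUE,
                          fd_hdcr_enabled = FALSE,
                          cooS_present = TRUE,
                          rnf_present = TRUE,
                          label = "") {
  if (fd_hdcr_enabled && !hdcr_fdh_module_present) {
    stop("inconsistent genotype: fd_hdcr_enabled = TRUE requires ",
         "hdcr_fdh_module_present = TRUE")
  }
  structure(list(hydABC_present = isTRUE(hydABC_present),
                 hdcr_hydrogenase_module_present =
                   isTRUE(hdcr_hydrogenase_module_present),
                 hdcr_fdh_module_present = isTRUE(hdcr_fdh_module_present),
                 fd_hdcr_enabled = isTRUE(fd_hdcr_enabled),
                 cooS_present = isTRUE(cooS_present),
                 rnf_present = isTRUE(rnf_present),
                 label = as.character(label)),
            class = "genotype_spec")
}

#' Cultivation / assay condition specification
#'
#' @param substrates_available character subset of
#'   `c("CO", "H2", "CO2", "formate", "fructose")`; must be non-empty.
#' @param na_available FALSE models Na+ depletion: the Rnf complex and the
#'   Na+ ATP synthase are removed from the network (not merely bounded), so
#'   infeasibility diagnostics name the carrier that can no longer be
#'   regenerated.
#' @param atp_coupling_available FALSE models bicarbonate uncoupling, which
#'   depletes cellular ATP so the ATP-dependent formyl-THF synthetase cannot
#'   run.
#' @param co2_available_as_acceptor whether CO2/bicarbonate is available as
#'   terminal electron acceptor for the carbonyl branch.
#' @param label free-text condition label.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(substrates_available,
                           na_available = TRUE,
                           atp_coupling_available = TRUE,
                           co2_available_as_acceptor = TRUE,
                           label = "") {
  known <- c("CO", "H2", "CO2", "formate", "fructose")
  substrates_available <- as.character(substrates_available)
  if (length(substrates_available) == 0) {
    stop("substrates_available must be non-empty")
  }
  bad <- setdiff(substrates_available, known)
  if (length(bad)) stop("unknown substrate(s): ", paste(bad, collapse = ", "))
  structure(list(substrates_available = substrates_available,
                 na_available = isTRUE(na_available),
                 atp_coupling_available = isTRUE(atp_coupling_available),
                 co2_available_as_acceptor = isTRUE(co2_available_as_acceptor),
                 label = as.character(label)),
            class = "condition_spec")
}

# One reaction: stoichiometry as a named list of rationals (negative =
# consumed), Na+ translocation per unit flux (positive = pumped out of the
# cell), reversibility.
.reaction <- function(id, enzyme_tag, stoich, na_translocated = rational(0),
                      reversible = FALSE) {
  stoich <- lapply(stoich, .as_rat)
  structure(list(id = id, enzyme_tag = enzyme_tag, stoich = stoich,
                 na_translocated = .as_rat(na_translocated),
                 reversible = isTRUE(reversible)),
            class = "reaction")
}

# The full catalogue of non-exchange reactions.  One flux unit of HydABC is
# the bifurcation event: 2 H2 oxidised to reduce one Fd and one NAD+.  The
# methyl branch is lumped into two NADH-consuming steps (formyl->methylene
# including the cyclohydrolase, and methylene->methyl), matching the
# resolution of the carrier ledgers.
.reaction_catalogue <- function(params) {
  list(
    .reaction("cooS", "cooS",
              list("CO" = rational(-1), "CO2" = rational(1),
                   "Fd2-" = rational(1))),
    .reaction("codh_acs_carbonyl_from_co2", "codh_acs_carbonyl_from_co2",
              list("CO2" = rational(-1), "Fd2-" = rational(-1),
                   "[CO]" = rational(1))),
    .reaction("acs_carbonyl_direct_co", "acs_carbonyl_direct_co",
              list("CO" = rational(-1), "[CO]" = rational(1))),
    .reaction("hydABC", "hydABC",
              list("H2" = rational(-2), "Fd2-" = rational(1),
                   "NADH" = rational(1)),
              reversible = TRUE),
    .reaction("hdcr_h2", "hdcr_h2",
              list("H2" = rational(-1), "CO2" = rational(-1),
                   "formate" = rational(1)),
              reversible = TRUE),
    .reaction("hdcr_fd", "hdcr_fd",
              list("Fd2-" = rational(-1), "CO2" = rational(-1),
                   "formate" = rational(1)),
              reversible = TRUE),
    .reaction("fhs", "fhs",
              list("formate" = rational(-1), "THF" = rational(-1),
                   "ATP" = rational(-1), "formyl-THF" = rational(1))),
    .reaction("mtd_lumped", "mtd_lumped",
              list("formyl-THF" = rational(-1), "NADH" = rational(-1),
                   "methylene-THF" = rational(1))),
    .reaction("mtr", "mtr",
              list("methylene-THF" = rational(-1), "NADH" = rational(-1),
                   "methyl-THF" = rational(1))),
    .reaction("acs_condensation", "acs_condensation",
              list("methyl-THF" = rational(-1), "[CO]" = rational(-1),
                   "acetyl-CoA" = rational(1), "THF" = rational(1))),
    .reaction("pta_ack", "pta_ack",
              list("acetyl-CoA" = rational(-1), "acetate" = rational(1),
                   "ATP" = rational(1))),
    .reaction("rnf", "rnf",
              list("Fd2-" = rational(-1), "NADH" = rational(1),
                   "Na+" = params$na_per_fd2_rnf),
              na_translocated = params$na_per_fd2_rnf),
    .reaction("atp_synthase", "atp_synthase",
              list("Na+" = -params$na_per_atp, "ATP" = rational(1)),
              na_translocated = -params$na_per_atp),
    .reaction("fructose_catabolism_lumped", "fructose_catabolism_lumped",
              list("fructose" = rational(-1), "acetate" = rational(2),
                   "CO2" = rational(2), "NADH" = rational(2),
                   "Fd2-" = rational(2), "ATP" = rational(4)))
  )
}

.exchange <- function(species, direction) {
  # uptake: {} -> species (flux >= 0); export: species -> {} (flux >= 0);
  # free: reversible (substrate that may also be released, e.g. CO2).
  coef <- if (direction == "export") rational(-1) else rational(1)
  .reaction(paste0("ex_", species), "exchange",
            stats::setNames(list(coef), species),
            reversible = identical(direction, "free"))
}

#' Assemble the active stoichiometric model for a scenario
#'
#' Builds the reaction network containing exactly the reactions permitted by
#' the genotype and the condition. Disabled reactions are absent from the
#' model, not zero-bounded, so infeasibility diagnostics can name the carrier
#' whose balance cannot close.
#'
#' Gating rules: HydABC only if present in the genotype; H2-mode HDCR only if
#' both HDCR modules are present; ferredoxin-mode HDCR only if enabled; CooS
#' only if present *and* CO is available; the carbonyl branch enters directly
#' from CO when CO is available, and from CO2 (CODH/ACS, ferredoxin-driven)
#' otherwise; formyl-THF synthetase only under ATP coupling; Rnf and the ATP
#' synthase only when Na+ is available. Exchange reactions are opened for the
#' available substrates and for the products acetate, formate and CO2 (plus
#' H2 if `h2_escape_fraction > 0`).
#'
#' @param genotype a [genotype_spec()].
#' @param condition a [condition_spec()].
#' @param parameters a [model_parameters()].
#' @return An object of class `stoich_model`.
#' @examples
#' m <- build_model(genotype_spec(label = "wild type"),
#'                  condition_spec(c("H2", "CO2")))
#' m
#' @export
build_model <- function(genotype = genotype_spec(),
                        condition,
                        parameters = model_parameters()) {
  stopifnot(inherits(genotype, "genotype_spec"),
            inherits(condition, "condition_spec"),
            inherits(parameters, "model_parameters"))
  subs <- condition$substrates_available
  co_here <- "CO" %in% subs

  keep <- function(tag) {
    switch(tag,
      cooS = genotype$cooS_present && co_here,
      codh_acs_carbonyl_from_co2 = !co_here &&
        condition$co2_available_as_acceptor,
      acs_carbonyl_direct_co = co_here,
      hydABC = genotype$hydABC_present,
      hdcr_h2 = genotype$hdcr_hydrogenase_module_present &&
        genotype$hdcr_fdh_module_present,
      hdcr_fd = genotype$fd_hdcr_enabled,
      fhs = condition$atp_coupling_available,
      mtd_lumped = TRUE,
      mtr = TRUE,
      acs_condensation = TRUE,
      pta_ack = TRUE,
      rnf = genotype$rnf_present && condition$na_available,
      atp_synthase = condition$na_available,
      fructose_catabolism_lumped = "fructose" %in% subs,
      FALSE)
  }

  reactions <- Filter(function(r) keep(r$enzyme_tag),
                      .reaction_catalogue(parameters))

  # Exchanges: one reaction per external species.  CO2 is reversible when it
  # is both a substrate and a potential product; other substrates are
  # uptake-only, products export-only.
  products <- c("acetate", "formate", "CO2")
  if (parameters$h2_escape_fraction > 0) products <- c(products, "H2")
  for (s in subs) {
    if (s %in% products) {
      reactions <- c(reactions, list(.exchange(s, "free")))
    } else {
      reactions <- c(reactions, list(.exchange(s, "uptake")))
    }
  }
  for (p in setdiff(products, subs)) {
    reactions <- c(reactions, list(.exchange(p, "export")))
  }

  reactions <- .prune_dead_branches(reactions)

  all_sp <- .species_table()
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  species <- all_sp[intersect(names(all_sp), used)]

  model <- structure(list(species = species,
                          reactions = reactions,
                          parameters = parameters,
                          genotype = genotype,
                          condition = condition),
                     class = "stoich_model")
  diags <- validate_model(model)
  if (length(diags)) {
    stop("assembled model failed validation:\n  ",
         paste(diags, collapse = "\n  "))
  }
  model
}

# Dead-branch pruning: a balanced species with no producer (or no consumer)
# among the assembled reactions forces every reaction touching it to zero
# flux, so those reactions are removed outright (to a fixed point).  This is
# the "absent, not zero-bounded" semantics: e.g. without the formyl-THF
# synthetase (bicarbonate uncoupling) the whole methyl branch downstream is
# dead and the assembled network reduces to CooS + Fd-HDCR + exchanges.
# Reversible reactions count as both producer and consumer; uptake exchanges
# count as producers, exports as consumers.  Removing only flux-zero
# reactions never changes the solution set.
.prune_dead_branches <- function(reactions) {
  repeat {
    species <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
    species <- setdiff(species, "ATP")  # reported net, never balanced
    dead <- character(0)
    for (s in species) {
      prod <- FALSE; cons <- FALSE
      for (r in reactions) {
        co <- r$stoich[[s]]
        if (is.null(co)) next
        if (co > 0 || (r$reversible && co < 0)) prod <- TRUE
        if (co < 0 || (r$reversible && co > 0)) cons <- TRUE
      }
      if (!prod || !cons) dead <- c(dead, s)
    }
    # a balanced species touched by exactly one (non-exchange) reaction also
    # forces that reaction to zero, even if the reaction is reversible
    counts <- table(unlist(lapply(reactions, function(r)
      intersect(names(r$stoich), species))))
    lonely <- names(counts)[counts == 1]
    keep <- vapply(reactions, function(r) {
      if (r$enzyme_tag == "exchange") return(TRUE)
      !any(dead %in% names(r$stoich)) && !any(lonely %in% names(r$stoich))
    }, logical(1))
    if (all(keep)) return(reactions)
    reactions <- reactions[keep]
  }
}

#' Reaction ids of a model
#' @param model a `stoich_model`.
#' @return character vector of reaction ids, in stable assembly order.
#' @export
reaction_ids <- function(model) {
  vapply(model$reactions, `[[`, character(1), "id")
}

#' Validate carbon balance, electron balance and the Na+ ledger conventions
#'
#' Returns an empty character vector when every non-exchange reaction is
#' carbon- and electron-balanced (in exact rational arithmetic), the Na+
#' translocation conventions hold (Rnf pumps `na_per_fd2_rnf` per Fd2-
#' oxidised, the ATP synthase consumes `na_per_atp` per ATP, all other
#' reactions translocate nothing), and every internal carrier / THF
#' intermediate present in the network takes part in at least two reactions.
#' Violations are reported as diagnostics, one per offence, never as errors.
#'
#' @param model a `stoich_model`.
#' @return character vector of diagnostics (empty when the model is sound).
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  diags <- character(0)
  sp <- model$species
  for (r in model$reactions) {
    if (r$enzyme_tag == "exchange") next
    cbal <- rational(0); ebal <- rational(0)
    for (s in names(r$stoich)) {
      info <- sp[[s]]
      if (is.null(info)) {
        diags <- c(diags, sprintf("reaction '%s': unknown species '%s'",
                                  r$id, s))
        next
      }
      cbal <- cbal + r$stoich[[s]] * rational(info$carbon)
      ebal <- ebal + r$stoich[[s]] * rational(info$dor)
    }
    if (!(cbal == 0)) {
      diags <- c(diags, sprintf(
        "reaction '%s': carbon imbalance of %+g atoms per unit flux",
        r$id, as.numeric(cbal)))
    }
    if (!(ebal == 0)) {
      diags <- c(diags, sprintf(
        "reaction '%s': electron imbalance of %+g electrons per unit flux",
        r$id, as.numeric(ebal)))
    }
    expected_na <- switch(r$enzyme_tag,
                          rnf = model$parameters$na_per_fd2_rnf,
                          atp_synthase = -model$parameters$na_per_atp,
                          rational(0))
    if (!(r$na_translocated == expected_na)) {
      diags <- c(diags, sprintf(
        paste0("reaction '%s': na_translocated is %s but the ledger ",
               "convention (%s Na+ per Fd2- through Rnf, %s Na+ per ATP ",
               "through the synthase, 0 elsewhere) requires %s"),
        r$id, as.character(r$na_translocated),
        as.character(model$parameters$na_per_fd2_rnf),
        as.character(model$parameters$na_per_atp),
        as.character(expected_na)))
    }
  }
  # Carriers and THF intermediates must be producible *and* consumable.
  counts <- table(unlist(lapply(model$reactions,
                                function(r) names(r$stoich))))
  for (s in names(sp)) {
    if (sp[[s]]$role %in% c("internal_carrier", "thf_intermediate") &&
        s %in% names(counts) && counts[[s]] < 2) {
      diags <- c(diags, sprintf(
        "species '%s' (%s) appears in only one reaction and cannot balance",
        s, sp[[s]]$role))
    }
  }
  diags
}

#' @export
print.stoich_model <- function(x, ...) {
  g <- x$genotype; cn <- x$condition
  cat("Stoichiometric acetogenesis model\n")
  if (nzchar(g$label)) cat("  genotype:  ", g$label, "\n", sep = "")
  cat("  substrates:", paste(cn$substrates_available, collapse = ", "), "\n")
  cat("  Na+ available:", cn$na_available,
      " ATP coupling:", cn$atp_coupling_available, "\n")
  cat("  reactions (", length(x$reactions), "): ",
      paste(reaction_ids(x), collapse = ", "), "\n", sep = "")
  cat("  Na+/ATP = ", as.character(x$parameters$na_per_atp),
      ", Na+/Fd2- (Rnf) = ", as.character(x$parameters$na_per_fd2_rnf),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.stoich_model <- function(object, ...) {
  cat("Reactions:\n")
  for (r in object$reactions) {
    lhs <- character(0); rhs <- character(0)
    for (s in names(r$stoich)) {
      co <- r$stoich[[s]]
      tag <- if (abs(co) == 1) s else paste(as.character(abs(co)), s)
      if (co < 0) lhs <- c(lhs, tag) else rhs <- c(rhs, tag)
    }
    cat(sprintf("  %-28s %s %s %s\n", r$id,
                paste(lhs, collapse = " + "),
                if (r$reversible) "<->" else "->",
                paste(rhs, collapse = " + ")))
  }
  invisible(object)
}
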