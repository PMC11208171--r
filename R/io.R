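#' @title Model serialisation
#' @description Export/import of an assembled model as a structured,
#'   versioned JSON document. Exact rational coefficients travel as
#'   `"p/q"` strings so a round trip is lossless.
#' @name model_io
NULL

.MODEL_SCHEMA_VERSION <- 1L

#' Serialise a model to JSON
#'
#' @param model a `stoich_model`.
#' @param path optional file; when `NULL` the JSON text is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "stoich_model"))
  doc <- list(
    schema_version = .MODEL_SCHEMA_VERSION,
    parameters = list(
      na_per_atp = as.character(model$parameters$na_per_atp),
      na_per_fd2_rnf = as.character(model$parameters$na_per_fd2_rnf),
      h2_escape_fraction = as.character(model$parameters$h2_escape_fraction)),
    genotype = unclass(model$genotype),
    condition = unclass(model$condition),
    species = lapply(unname(model$species), function(s)
      list(id = s$id, role = s$role, carbon_atoms = s$carbon,
           degree_of_reduction = s$dor)),
    reactions = lapply(model$reactions, function(r)
      list(id = r$id, enzyme_tag = r$enzyme_tag,
           stoichiometry = lapply(r$stoich, as.character),
           na_translocated_per_unit_flux = as.character(r$na_translocated),
           reversible = r$reversible))
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Deserialise a model from JSON
#'
#' @param input a file path or a JSON string produced by [model_to_json()].
#' @return a `stoich_model` (validated on load).
#' @export
model_from_json <- function(input) {
  doc <- if (file.exists(input)) {
    jsonlite::fromJSON(input, simplifyVector = FALSE)
  } else {
    jsonlite::fromJSON(input, simplifyVector = FALSE)
  }
  if (is.null(doc$schema_version) ||
      doc$schema_version != .MODEL_SCHEMA_VERSION) {
    stop("unsupported model schema version: ",
         if (is.null(doc$schema_version)) "(none)" else doc$schema_version)
  }
  params <- model_parameters(
    na_per_atp = parse_rational(doc$parameters$na_per_atp),
    na_per_fd2_rnf = parse_rational(doc$parameters$na_per_fd2_rnf),
    h2_escape_fraction = parse_rational(doc$parameters$h2_escape_fraction))
  g <- doc$genotype
  genotype <- genotype_spec(g$hydABC_present,
                            g$hdcr_hydrogenase_module_present,
                            g$hdcr_fdh_module_present,
                            g$fd_hdcr_enabled, g$cooS_present,
                            g$rnf_present, label = g$label)
  cn <- doc$condition
  condition <- condition_spec(unlist(cn$substrates_available),
                              cn$na_available, cn$atp_coupling_available,
                              cn$co2_available_as_acceptor,
                              label = cn$label)
  species <- stats::setNames(
    lapply(doc$species, function(s)
      list(id = s$id, role = s$role, carbon = s$carbon_atoms,
           dor = s$degree_of_reduction)),
    vapply(doc$species, `[[`, character(1), "id"))
  reactions <- lapply(doc$reactions, function(r) {
    .reaction(r$id, r$enzyme_tag,
              lapply(r$stoichiometry, function(v) parse_rational(v)),
              na_translocated =
                parse_rational(r$na_translocated_per_unit_flux),
              reversible = isTRUE(r$reversible))
  })
  model <- structure(list(species = species, reactions = reactions,
                          parameters = params, genotype = genotype,
                          condition = condition),
                     class = "stoich_model")
  diags <- validate_model(model)
  if (length(diags)) {
    stop("imported model failed validation:\n  ",
         paste(diags, collapse = "\n  "))
  }
  model
}
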