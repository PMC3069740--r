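# The standard protocol library shipped with every installation: 26
# protocols across five groups covering the protein-production pipeline from
# PCR to diffraction. Input/output sample types and multiplicities are fixed;
# each protocol's parameter set here is a deliberately minimal starter that
# laboratories customize by copying.

default_protocol_table <- function() {
  row <- function(name, group, inputs, outputs)
    list(name = name, group = group, inputs = inputs, outputs = outputs)
  s <- function(type, mult = 1L) list(type = type, mult = as.integer(mult))
  list(
    row("PCR", "Processing DNA",
        list(s("Primers"), s("Template")), list(s("PCR product"))),
    row("PCR cleanup", "Processing DNA",
        list(s("PCR product")), list(s("PCR product"))),
    row("PCR product digest", "Processing DNA",
        list(s("PCR product")), list(s("PCR product"))),
    row("Ligation", "Processing DNA",
        list(s("PCR product"), s("Linearized vector")), list(s("Ligated plasmid"))),
    row("Bicistronic cloning", "Processing DNA",
        list(s("PCR product", 2L), s("Vector")), list(s("Recombinant plasmid"))),
    row("Bicistronic InFusion", "Processing DNA",
        list(s("PCR product", 2L), s("Vector")), list(s("Recombinant plasmid"))),
    row("Vector digest", "Processing DNA",
        list(s("Vector")), list(s("Linearized vector"))),
    row("Clone verification", "Processing DNA",
        list(s("Template")), list(s("PCR product"))),
    row("Transformation", "Cell growth and protein expression",
        list(s("Plasmid"), s("Competent cells")), list(s("Transformed cells"))),
    row("Culture", "Cell growth and protein expression",
        list(s("Transformed cells"), s("Culture medium")), list(s("Transformed cells"))),
    row("Miniprep", "Cell growth and protein expression",
        list(s("Transformed cells")), list(s("Purified plasmid"))),
    row("Trial expression", "Cell growth and protein expression",
        list(s("Plasmid")), list(s("Protein"))),
    row("Large-scale expression", "Cell growth and protein expression",
        list(s("Plasmid")), list(s("Pellet"), s("Supernatant"))),
    row("Solubilization", "Cell growth and protein expression",
        list(s("Pellet")), list(s("Soluble protein"))),
    row("Tag cleavage", "Processing protein samples",
        list(s("Soluble protein"), s("Enzyme")), list(s("Soluble protein"))),
    row("Chromatography", "Processing protein samples",
        list(s("Soluble protein")), list(s("Soluble protein"))),
    row("Size-exclusion chromatography", "Processing protein samples",
        list(s("Soluble protein")), list(s("Soluble protein"))),
    row("Complexation", "Processing protein samples",
        list(s("Soluble protein", 2L)), list(s("Soluble protein"))),
    row("Concentration", "Processing protein samples",
        list(s("Soluble protein")), list(s("Soluble protein"))),
    row("Dynamic light scattering (DLS)", "Protein characterization",
        list(s("Soluble protein")), list()),
    row("Mass spectrometry", "Protein characterization",
        list(s("Soluble protein")), list()),
    row("Crystal screen", "Crystallography",
        list(s("Soluble protein")), list(s("Crystal"))),
    row("Crystal optimization", "Crystallography",
        list(s("Soluble protein")), list(s("Crystal"))),
    row("Crystal harvest", "Crystallography",
        list(s("Crystal")), list(s("Mounted crystal"))),
    row("Test diffraction", "Crystallography",
        list(s("Mounted crystal")), list()),
    row("Diffraction", "Crystallography",
        list(s("Mounted crystal")), list())
  )
}

default_parameter_sets <- function() {
  list(
    "PCR" = list(
      lims_parameter("annealing temperature", "setup", "number", default = 55, units = "C"),
      lims_parameter("cycles", "setup", "number", default = 30),
      lims_parameter("product size", "result", "number", units = "bp")),
    "Culture" = list(
      lims_parameter("medium volume", "setup", "number", default = 500, units = "mL"),
      lims_parameter("temperature", "setup", "number", default = 37, units = "C"),
      lims_parameter("final OD600", "result", "number")),
    "Trial expression" = list(
      lims_parameter("induction", "setup", "text", default = "IPTG 1 mM"),
      lims_parameter("expressed", "result", "boolean")),
    "Large-scale expression" = list(
      lims_parameter("culture volume", "setup", "number", default = 2, units = "L"),
      lims_parameter("yield", "result", "number", units = "mg"))
  )
}

#' Seed the default protocol library
#'
#' Creates the standard set of 26 protocols (five groups: Processing DNA;
#' Cell growth and protein expression; Processing protein samples; Protein
#' characterization; Crystallography) in the PUBLIC notebook, where every
#' user can read them. Input/output slot types and multiplicities follow the
#' standard library; slot roles are the lower-cased type names (output roles
#' gain an "(out)" suffix when a protocol reads and writes the same type).
#'
#' @inheritParams lims_get
#' @return list of the 26 protocol records.
#' @export
lims_seed_default_protocols <- function(store) {
  if (isTRUE(store$seeded))
    lims_abort("lims_already_seeded_error", "default protocols are already seeded")
  params <- default_parameter_sets()
  out <- lapply(default_protocol_table(), function(rw) {
    roles <- character()
    mk <- function(sl, dir) {
      role <- tolower(sl$type)
      if (role %in% roles) role <- paste(role, "(out)")
      roles <<- c(roles, role)
      lims_slot(role, dir, sl$type, sl$mult)
    }
    ins <- lapply(rw$inputs, mk, dir = "input")
    outs <- lapply(rw$outputs, mk, dir = "output")
    lims_create_protocol(store, rw$name, protocol_type = rw$group,
                         input_slots = ins, output_slots = outs,
                         parameters = params[[rw$name]] %||% list(),
                         methods = sprintf("Standard %s protocol.", rw$name),
                         notebook_id = store$public_notebook_id)
  })
  store$seeded <- TRUE
  out
}
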