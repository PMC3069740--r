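# Deterministic synthetic data: random open reading frames and multi-stage
# protein-production workflows built through the public API, so every module
# can be exercised (and property-tested) without any external data. All
# randomness comes from one PRNG stream seeded from the spec; draws happen
# in a fixed documented order (per target: sequence; per construct: tag
# coin; per stage: dropout coin), so identical specs give byte-identical
# bulk exports.

# Run code under its own seeded RNG stream, restoring the caller's stream
# afterwards. seed = NULL means "draw from the ambient stream" (leave state
# alone), which is how nested fixture calls share one documented stream.
with_fixture_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Generate a synthetic target with a random open reading frame
#'
#' The DNA is a complete ORF — ATG, random synonymous codons, one stop
#' codon — whose translation has exactly \code{protein_len} residues
#' (starting with M). Deterministic for a given seed.
#'
#' @inheritParams lims_get
#' @param notebook_id notebook to file the target in.
#' @param protein_len protein length in residues, >= 10.
#' @param seed optional integer; NULL draws from the current RNG stream.
#' @param name target name.
#' @return the target record.
#' @export
lims_generate_target <- function(store, notebook_id, protein_len = 150L,
                                 seed = NULL, name = NULL) {
  protein_len <- as.integer(protein_len)
  if (is.na(protein_len) || protein_len < 10L)
    abort_validation("protein_len must be >= 10")
  with_fixture_seed(seed, {
    tab <- codons_by_aa()
    aas <- setdiff(names(tab), "*")
    protein <- paste0("M", paste(sample(aas, protein_len - 1L, replace = TRUE),
                                 collapse = ""))
    residues <- strsplit(protein, "")[[1]]
    codons <- vapply(residues, function(a) {
      opts <- tab[[a]]
      opts[sample.int(length(opts), 1L)]
    }, character(1))
    dna <- paste0(paste(codons, collapse = ""),
                  sample(tab[["*"]], 1L))
    lims_create_target(store, name %||% sprintf("synthetic-target-%d", store$counter + 1L),
                       notebook_id,
                       protein_sequence = protein, dna_sequence = dna,
                       description = "synthetic fixture ORF")
  })
}

#' Fixture workflow specification
#'
#' @param seed integer PRNG seed.
#' @param n_targets number of synthetic targets.
#' @param n_constructs_per_target constructs designed per target.
#' @param workflow_depth number of chain stages to run, 0..7 (PCR, Ligation,
#'   Transformation, Culture, Miniprep, Large-scale expression,
#'   Solubilization).
#' @param failure_rate per-stage Bernoulli dropout probability: scalar or
#'   vector of length \code{workflow_depth}; a failed stage ends that
#'   construct's chain.
#' @param protein_len residue length of the synthetic targets.
#' @return a \code{lims_fixture_spec} list.
#' @export
lims_fixture_spec <- function(seed = 1L, n_targets = 4L,
                              n_constructs_per_target = 1L,
                              workflow_depth = 7L, failure_rate = 0,
                              protein_len = 120L) {
  workflow_depth <- as.integer(workflow_depth)
  if (workflow_depth < 0L || workflow_depth > 7L)
    abort_validation("workflow_depth must be between 0 and 7")
  if (length(failure_rate) == 1L)
    failure_rate <- rep(failure_rate, workflow_depth)
  if (length(failure_rate) != workflow_depth)
    abort_validation("failure_rate must be scalar or one value per stage")
  if (any(failure_rate < 0 | failure_rate > 1))
    abort_validation("failure rates must lie in [0, 1]")
  if (n_targets < 0L || n_constructs_per_target < 0L)
    abort_validation("counts must be >= 0")
  structure(list(seed = as.integer(seed), n_targets = as.integer(n_targets),
                 n_constructs_per_target = as.integer(n_constructs_per_target),
                 workflow_depth = workflow_depth, failure_rate = failure_rate,
                 protein_len = as.integer(protein_len)),
            class = "lims_fixture_spec")
}

# The seven chain stages. Two are lab copies of default protocols with one
# input type changed, created on demand via the regular copy-then-edit
# route, mirroring how laboratories adapt the standard library.
FIXTURE_STAGES <- c("PCR", "Ligation", "Transformation (ligated plasmid)",
                    "Culture", "Miniprep",
                    "Large-scale expression (purified plasmid)",
                    "Solubilization")

protocol_by_name <- function(store, name) {
  for (id in lims_ls(store, "protocol"))
    if (identical(store$objects[[id]]$name, name)) return(store$objects[[id]])
  NULL
}

ensure_fixture_protocols <- function(store) {
  if (is.null(protocol_by_name(store, "Transformation (ligated plasmid)"))) {
    src <- protocol_by_name(store, "Transformation")
    cp <- lims_copy_protocol(store, src$id, "Transformation (ligated plasmid)")
    slots <- cp$input_slots
    slots[[1]]$sample_type <- "Ligated plasmid"
    lims_modify_protocol(store, cp$id, list(input_slots = slots))
  }
  if (is.null(protocol_by_name(store, "Large-scale expression (purified plasmid)"))) {
    src <- protocol_by_name(store, "Large-scale expression")
    cp <- lims_copy_protocol(store, src$id, "Large-scale expression (purified plasmid)")
    slots <- cp$input_slots
    slots[[1]]$sample_type <- "Purified plasmid"
    lims_modify_protocol(store, cp$id, list(input_slots = slots))
  }
}

#' Generate a synthetic multi-stage workflow
#'
#' For each construct, runs the chain PCR -> Ligation -> Transformation ->
#' Culture -> Miniprep -> Large-scale expression -> Solubilization (to
#' \code{workflow_depth}), with an independent Bernoulli dropout at each
#' stage; a dropped chain records no further experiments. Ancillary inputs
#' (linearized vector, competent cells, culture medium) are created fresh
#' per use. The populated store always passes [lims_audit()].
#'
#' @inheritParams lims_get
#' @param spec a [lims_fixture_spec()].
#' @param notebook_id notebook for all fixture records; created if NULL.
#' @return list: notebook_id, target_ids, construct_ids, founder_ids (the
#'   template samples, one per construct), stage_names, and reached — an
#'   integer per construct giving the number of completed stages.
#' @export
lims_generate_workflow <- function(store, spec, notebook_id = NULL) {
  if (!inherits(spec, "lims_fixture_spec"))
    abort_validation("spec must come from lims_fixture_spec()")
  if (!isTRUE(store$seeded))
    abort_validation("seed the default protocol library first")
  with_fixture_seed(spec$seed, {
    nb <- notebook_id %||% lims_create_notebook(store, "Fixtures",
                                                "synthetic workflow data")$id
    ensure_fixture_protocols(store)
    stage_names <- FIXTURE_STAGES[seq_len(spec$workflow_depth)]
    stage_ids <- vapply(stage_names, function(nm) protocol_by_name(store, nm)$id,
                        character(1))
    targets <- character(); constructs <- character(); founders <- character()
    reached <- integer()
    for (ti in seq_len(spec$n_targets)) {
      tgt <- lims_generate_target(store, nb, protein_len = spec$protein_len)
      targets <- c(targets, tgt$id)
      for (ci in seq_len(spec$n_constructs_per_target)) {
        tags <- if (stats::runif(1) < 0.5) list(tag_his6("N", cleavable = TRUE))
                else list()
        des <- lims_design_construct(store, tgt$id, 1L, spec$protein_len,
                                     tags = tags, notebook_id = nb)
        constructs <- c(constructs, des$construct$id)
        template <- des$samples[[1]]$id
        fwd <- des$samples[[2]]$id
        founders <- c(founders, template)
        current <- NULL  # sample carried between stages
        done <- 0L
        for (k in seq_len(spec$workflow_depth)) {
          if (stats::runif(1) < spec$failure_rate[k]) break
          prot_id <- stage_ids[[k]]
          exp <- switch(stage_names[k],
            "PCR" = lims_instantiate_experiment(store, prot_id,
              list(primers = fwd, template = template), notebook_id = nb),
            "Ligation" = lims_instantiate_experiment(store, prot_id,
              list("pcr product" = current,
                   "linearized vector" = lims_create_sample(
                     store, "Linearized vector", nb)$id), notebook_id = nb),
            "Transformation (ligated plasmid)" = lims_instantiate_experiment(store, prot_id,
              list(plasmid = current,
                   "competent cells" = lims_create_sample(
                     store, "Competent cells", nb)$id), notebook_id = nb),
            "Culture" = lims_instantiate_experiment(store, prot_id,
              list("transformed cells" = current,
                   "culture medium" = lims_create_sample(
                     store, "Culture medium", nb)$id), notebook_id = nb),
            "Miniprep" = lims_instantiate_experiment(store, prot_id,
              list("transformed cells" = current), notebook_id = nb),
            "Large-scale expression (purified plasmid)" = lims_instantiate_experiment(
              store, prot_id, list(plasmid = current), notebook_id = nb),
            "Solubilization" = lims_instantiate_experiment(store, prot_id,
              list(pellet = current), notebook_id = nb))
          # carry the pellet (not the supernatant) out of expression
          current <- exp$output_sample_ids[[1]]
          done <- k
        }
        reached <- c(reached, done)
      }
    }
    list(notebook_id = nb, target_ids = targets, construct_ids = constructs,
         founder_ids = founders, stage_names = stage_names, reached = reached)
  })
}
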