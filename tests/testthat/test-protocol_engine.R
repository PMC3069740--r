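test_that("the default library seeds 26 protocols across five groups with the right slots", {
  s <- lims_store()
  ps <- lims_seed_default_protocols(s)
  expect_length(ps, 26)
  groups <- unique(vapply(ps, `[[`, "", "protocol_type"))
  expect_setequal(groups, c("Processing DNA", "Cell growth and protein expression",
                            "Processing protein samples", "Protein characterization",
                            "Crystallography"))
  byname <- setNames(ps, vapply(ps, `[[`, "", "name"))
  pcr <- byname[["PCR"]]
  expect_setequal(vapply(pcr$input_slots, `[[`, "", "sample_type"),
                  c("Primers", "Template"))
  expect_equal(vapply(pcr$output_slots, `[[`, "", "sample_type"), "PCR product")
  dls <- byname[["Dynamic light scattering (DLS)"]]
  expect_length(dls$output_slots, 0)
  expect_equal(vapply(dls$input_slots, `[[`, "", "sample_type"), "Soluble protein")
  bic <- byname[["Bicistronic cloning"]]
  mult <- vapply(bic$input_slots, `[[`, 1L, "multiplicity")
  expect_setequal(mult, c(2L, 1L))
  cpx <- byname[["Complexation"]]
  expect_equal(cpx$input_slots[[1]]$multiplicity, 2L)
  expect_lims_error(lims_seed_default_protocols(s), "lims_already_seeded_error")
})

test_that("used protocols are immutable and undeletable; copies stay editable", {
  w <- store_with_notebook(seeded = TRUE)
  s <- w$store
  pcr <- lims_search_protocols_by_type(s, "Processing DNA")
  pcr <- Filter(function(p) p$name == "PCR", pcr)[[1]]
  # unused: modifiable
  p <- lims_create_protocol(s, "scratch", input_slots = list(lims_slot("a", "input", "DNA")),
                            notebook_id = w$nb)
  lims_modify_protocol(s, p$id, list(methods_description = "v2"))
  expect_equal(lims_get(s, p$id)$methods_description, "v2")
  lims_delete_protocol(s, p$id)
  expect_lims_error(lims_get(s, p$id), "lims_not_found_error")
  # use PCR, then try to modify it
  primers <- lims_create_sample(s, "Primers", w$nb)
  template <- lims_create_sample(s, "Template", w$nb)
  lims_instantiate_experiment(s, pcr$id, list(primers = primers$id, template = template$id))
  expect_true(lims_protocol_used(s, pcr$id))
  err <- tryCatch(lims_modify_protocol(s, pcr$id, list(methods_description = "no")),
                  lims_immutable_error = function(e) e)
  expect_match(conditionMessage(err), "1 experiment")
  expect_lims_error(lims_delete_protocol(s, pcr$id), "lims_immutable_error")
  cp <- lims_copy_protocol(s, pcr$id, "PCR (touchdown)")
  expect_identical(cp$copied_from, pcr$id)
  lims_modify_protocol(s, cp$id, list(methods_description = "touchdown cycling"))
  expect_equal(lims_get(s, pcr$id)$methods_description, "Standard PCR protocol.")
  expect_lims_error(lims_copy_protocol(s, pcr$id, "PCR"), "lims_validation_error")
  expect_lims_error(lims_create_protocol(s, "PCR"), "lims_validation_error")
})

test_that("protocol suggestion filters by input sample type over the default library", {
  w <- store_with_notebook(seeded = TRUE)
  sol <- lims_create_sample(w$store, "Soluble protein", w$nb)
  sug <- lims_suggest_protocols(w$store, sol$id)
  expect_setequal(vapply(sug, `[[`, "", "name"),
                  c("Tag cleavage", "Chromatography", "Size-exclusion chromatography",
                    "Complexation", "Concentration", "Dynamic light scattering (DLS)",
                    "Mass spectrometry", "Crystal screen", "Crystal optimization"))
  expect_false("PCR" %in% vapply(sug, `[[`, "", "name"))
  mc <- lims_create_sample(w$store, "Mounted crystal", w$nb)
  expect_setequal(vapply(lims_suggest_protocols(w$store, mc$id), `[[`, "", "name"),
                  c("Test diffraction", "Diffraction"))
})

test_that("recently used protocols float to the top of suggestions", {
  w <- store_with_notebook(seeded = TRUE)
  u <- lims_create_user(w$store, "ada")
  g <- lims_create_group(w$store, "lab", "ada")
  lims_grant(w$store, g$id, w$nb, "write")
  sol <- lims_create_sample(w$store, "Soluble protein", w$nb)
  sug0 <- lims_suggest_protocols(w$store, sol$id, user = "ada")
  # alphabetical baseline, then access one late-alphabet protocol
  ms <- Filter(function(p) p$name == "Mass spectrometry", sug0)[[1]]
  lims_record_access(w$store, "ada", ms$id)
  sug1 <- lims_suggest_protocols(w$store, sol$id, user = "ada")
  expect_equal(sug1[[1]]$name, "Mass spectrometry")
  expect_setequal(vapply(sug1, `[[`, "", "name"), vapply(sug0, `[[`, "", "name"))
})

test_that("compatible_samples returns exactly the type-matched shortlist", {
  w <- store_with_notebook(seeded = TRUE)
  s <- w$store
  for (i in 1:2) lims_create_sample(s, "Template", w$nb, label = paste("t", i))
  for (i in 1:3) lims_create_sample(s, "Soluble protein", w$nb, label = paste("sp", i))
  plasmid <- lims_create_sample(s, "Plasmid", w$nb)
  pcr <- Filter(function(p) p$name == "PCR",
                lims_search_protocols_by_type(s, "Processing DNA"))[[1]]
  hits <- lims_compatible_samples(s, pcr$id, "template")
  expect_length(hits, 2)
  expect_true(all(vapply(hits, `[[`, "", "sample_type") == "Template"))
  # a purification protocol never lists plasmids
  chrom <- Filter(function(p) p$name == "Chromatography",
                  lims_search_protocols_by_type(s, "Processing protein samples"))[[1]]
  ids <- vapply(lims_compatible_samples(s, chrom$id, "soluble protein"), `[[`, "", "id")
  expect_false(plasmid$id %in% ids)
  expect_lims_error(lims_compatible_samples(s, pcr$id, "no such role"),
                    "lims_not_found_error")
  empty <- store_with_notebook(seeded = TRUE)
  expect_length(lims_compatible_samples(empty$store, pcr$id, "template"), 0)
})

test_that("experiment instantiation enforces types and multiplicity atomically", {
  w <- store_with_notebook(seeded = TRUE)
  s <- w$store
  primers <- lims_create_sample(s, "Primers", w$nb)
  template <- lims_create_sample(s, "Template", w$nb)
  sol <- lims_create_sample(s, "Soluble protein", w$nb)
  byname <- function(nm) Filter(function(p) p$name == nm,
    lapply(lims_ls(s, "protocol"), function(i) lims_get(s, i)))[[1]]
  pcr <- byname("PCR")
  exp <- lims_instantiate_experiment(s, pcr$id,
                                     list(primers = primers$id, template = template$id))
  expect_length(exp$output_sample_ids, 1)
  prod <- lims_get(s, exp$output_sample_ids[1])
  expect_equal(prod$sample_type, "PCR product")
  expect_identical(prod$produced_by, exp$id)
  # type mismatch names the slot and types, and persists nothing
  lig <- byname("Ligation")
  before <- length(lims_ls(s))
  err <- tryCatch(lims_instantiate_experiment(s, lig$id,
                    list("pcr product" = sol$id,
                         "linearized vector" = lims_create_sample(s, "Linearized vector", w$nb)$id)),
                  lims_type_error = function(e) e)
  expect_s3_class(err, "lims_type_error")
  expect_match(conditionMessage(err), "pcr product")
  expect_match(conditionMessage(err), "Soluble protein")
  expect_equal(length(lims_ls(s)), before + 1)  # only the vector sample we made
  # multiplicity-2 slot rejects a single binding and duplicate ids
  bic <- byname("Bicistronic cloning")
  pp <- lims_create_sample(s, "PCR product", w$nb)
  vec <- lims_create_sample(s, "Vector", w$nb)
  expect_lims_error(
    lims_instantiate_experiment(s, bic$id,
                                list("pcr product" = pp$id, vector = vec$id)),
    "lims_validation_error")
  expect_lims_error(
    lims_instantiate_experiment(s, bic$id,
                                list("pcr product" = c(pp$id, pp$id), vector = vec$id)),
    "lims_validation_error")
  pp2 <- lims_create_sample(s, "PCR product", w$nb)
  ok <- lims_instantiate_experiment(s, bic$id,
                                    list("pcr product" = c(pp$id, pp2$id), vector = vec$id))
  expect_equal(lims_get(s, ok$output_sample_ids[1])$sample_type, "Recombinant plasmid")
})

test_that("required setup parameters resolve from values or defaults", {
  w <- store_with_notebook()
  p <- lims_create_protocol(
    w$store, "growth", input_slots = list(lims_slot("cells", "input", "Cells")),
    parameters = list(
      lims_parameter("temperature", "setup", "number", required = TRUE, default = 37),
      lims_parameter("volume", "setup", "number", required = TRUE),
      lims_parameter("od600", "result", "number")),
    notebook_id = w$nb)
  cells <- lims_create_sample(w$store, "Cells", w$nb)
  expect_lims_error(
    lims_instantiate_experiment(w$store, p$id, list(cells = cells$id)),
    "lims_validation_error")
  exp <- lims_instantiate_experiment(w$store, p$id, list(cells = cells$id),
                                     setup_values = list(volume = 50))
  expect_equal(exp$setup_values$temperature, 37)
  expect_equal(exp$setup_values$volume, 50)
})

test_that("result recording validates phase and audits overwrites", {
  w <- store_with_notebook(seeded = TRUE)
  s <- w$store
  plasmid <- lims_create_sample(s, "Plasmid", w$nb)
  lse <- Filter(function(p) p$name == "Large-scale expression",
                lims_search_protocols_by_type(s, "Cell growth and protein expression"))[[1]]
  exp <- lims_instantiate_experiment(s, lse$id, list(plasmid = plasmid$id))
  lims_record_results(s, exp$id, list(yield = 1.2))
  expect_equal(lims_get(s, exp$id)$result_values$yield, 1.2)
  expect_lims_error(lims_record_results(s, exp$id, list("culture volume" = 4)),
                    "lims_validation_error")
  expect_lims_error(lims_record_results(s, exp$id, list(nonesuch = 1)),
                    "lims_validation_error")
  n_notes <- length(lims_get(s, exp$id)$notes)
  lims_record_results(s, exp$id, list(yield = 2.5))
  after <- lims_get(s, exp$id)
  expect_equal(after$result_values$yield, 2.5)
  expect_length(after$notes, n_notes + 1)
})

test_that("search by protocol group returns whole sections", {
  s <- seeded_store()
  cryst <- lims_search_protocols_by_type(s, "Crystallography")
  expect_length(cryst, 5)
  dna <- vapply(lims_search_protocols_by_type(s, "Processing DNA"), `[[`, "", "name")
  expect_true(all(c("PCR", "Vector digest") %in% dna))
  expect_length(lims_search_protocols_by_type(s, "Astrology"), 0)
})
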