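make_target <- function(store, nb, len = 80, seed = 21)
  lims_generate_target(store, nb, protein_len = len, seed = seed)

test_that("expressed and final sequences assemble from Met, tags and the residue window", {
  w <- store_with_notebook()
  tgt <- make_target(w$store, w$nb, len = 100)
  prot <- tgt$protein_sequence
  # full-length window, region already starts with M
  d1 <- lims_design_construct(w$store, tgt$id, 1, 100, add_n_met = TRUE)
  expect_identical(d1$construct$expressed_protein, prot)
  expect_identical(d1$construct$final_protein, prot)
  # window from residue 2 with an added Met
  d2 <- lims_design_construct(w$store, tgt$id, 2, 60, add_n_met = TRUE)
  expect_identical(d2$construct$expressed_protein, paste0("M", substr(prot, 2, 60)))
  # cleavable N-terminal His6: expressed keeps it, final drops it
  d3 <- lims_design_construct(w$store, tgt$id, 5, 80,
                              tags = list(tag_his6("N", cleavable = TRUE)))
  expect_identical(d3$construct$expressed_protein, paste0("HHHHHH", substr(prot, 5, 80)))
  expect_identical(d3$construct$final_protein, substr(prot, 5, 80))
  # non-cleavable C tag survives into the final protein
  d4 <- lims_design_construct(w$store, tgt$id, 5, 80,
                              tags = list(lims_tag("StrepII", "WSHPQFEK", "C", cleavable = FALSE)))
  expect_identical(d4$construct$final_protein, d4$construct$expressed_protein)
  expect_lims_error(lims_design_construct(w$store, tgt$id, 1, 101), "lims_range_error")
  expect_lims_error(lims_design_construct(w$store, tgt$id, 0, 10), "lims_range_error")
})

test_that("construct design is a no-input experiment producing template plus two primers", {
  w <- store_with_notebook()
  tgt <- make_target(w$store, w$nb)
  d <- lims_design_construct(w$store, tgt$id, 1, 80)
  expect_length(d$experiment$input_bindings, 0)
  types <- vapply(d$samples, `[[`, "", "sample_type")
  expect_identical(types, c("Template", "Primers", "Primers"))
  for (smp in d$samples) {
    expect_identical(smp$construct_id, d$construct$id)
    expect_identical(smp$produced_by, d$experiment$id)
  }
  expect_identical(lims_audit(w$store), character(0))
})

test_that("primer annealing regions are target substrings at the declared Tm", {
  set.seed(31)
  for (i in 1:6) {
    w <- store_with_notebook()
    tgt <- make_target(w$store, w$nb, len = sample(40:150, 1), seed = 100 + i)
    start <- sample(1:5, 1)
    stop <- nchar(tgt$protein_sequence) - sample(0:4, 1)
    d <- lims_design_construct(w$store, tgt$id, start, stop, target_tm = 58)
    fwd <- d$construct$forward_primer
    rev <- d$construct$reverse_primer
    fa <- substr(fwd$sequence, nchar(fwd$sequence) - fwd$anneal_len + 1, nchar(fwd$sequence))
    ra <- substr(rev$sequence, nchar(rev$sequence) - rev$anneal_len + 1, nchar(rev$sequence))
    expect_true(grepl(fa, tgt$dna_sequence, fixed = TRUE))
    expect_true(grepl(reverse_complement(ra), tgt$dna_sequence, fixed = TRUE))
    # reported Tm is exactly the Tm of the annealing region, no drift
    expect_equal(fwd$tm_c, melting_temperature(fa), tolerance = 1e-9)
    expect_equal(rev$tm_c, melting_temperature(ra), tolerance = 1e-9)
    # forward anneal starts at the first codon of start_aa
    cds0 <- 3 * (start - 1)
    expect_identical(substr(tgt$dna_sequence, cds0 + 1, cds0 + fwd$anneal_len), fa)
  }
})

test_that("annealing length is 18 at easy targets and monotone in target Tm", {
  w <- store_with_notebook()
  tgt <- make_target(w$store, w$nb, len = 90, seed = 77)
  d <- lims_design_construct(w$store, tgt$id, 1, 90, target_tm = 0)
  expect_equal(d$construct$forward_primer$anneal_len, 18L)
  expect_equal(d$construct$reverse_primer$anneal_len, 18L)
  lens <- vapply(seq(40, 80, by = 5), function(tm) {
    lims_design_primers(w$store, d$construct$id, target_tm = tm)$forward$anneal_len
  }, integer(1))
  expect_true(all(diff(lens) >= 0))
  # unreachable target flagged, capped at 35
  p <- lims_design_primers(w$store, d$construct$id, target_tm = 95)
  expect_false(p$forward$tm_reached)
  expect_equal(p$forward$anneal_len, 35L)
})

# independent one-codon-per-residue oracle for the add-on check below
backtranslate_oracle <- function(aa) {
  map <- c(H = "CAT")
  paste(map[strsplit(aa, "")[[1]]], collapse = "")
}

test_that("primer 5' add-ons carry Met/tag/stop codons outside the annealing region", {
  w <- store_with_notebook()
  tgt <- make_target(w$store, w$nb, len = 60, seed = 55)
  # force a region that does not start with M
  d <- lims_design_construct(w$store, tgt$id, 2, 55, add_n_met = TRUE,
                             tags = list(tag_his6("N", cleavable = TRUE)))
  fwd <- d$construct$forward_primer
  addon <- substr(fwd$sequence, 1, nchar(fwd$sequence) - fwd$anneal_len)
  expect_identical(translate_dna(addon, to_stop = FALSE), "MHHHHHH")
  # no C tag: reverse primer starts with the reverse complement of TAA
  rev <- d$construct$reverse_primer
  tail_ <- substr(rev$sequence, 1, nchar(rev$sequence) - rev$anneal_len)
  expect_identical(tail_, "TTA")
  # with a C tag, no stop is added; the tag codons ride along instead
  d2 <- lims_design_construct(w$store, tgt$id, 2, 55,
                              tags = list(tag_his6("C", cleavable = FALSE)))
  rev2 <- d2$construct$reverse_primer
  tail2 <- substr(rev2$sequence, 1, nchar(rev2$sequence) - rev2$anneal_len)
  expect_identical(reverse_complement(tail2), backtranslate_oracle("HHHHHH"))
})

test_that("a target without DNA cannot have primers designed", {
  w <- store_with_notebook()
  tgt <- lims_create_target(w$store, "prot only", w$nb,
                            protein_sequence = paste(rep("MKTAYIAKQR", 5), collapse = ""))
  expect_lims_error(lims_design_construct(w$store, tgt$id, 1, 50),
                    "lims_missing_sequence_error")
})

test_that("plates fill row-major and derived plates preserve well labels", {
  w <- store_with_notebook()
  tgt <- make_target(w$store, w$nb, len = 60, seed = 9)
  cons <- lapply(1:3, function(i)
    lims_design_construct(w$store, tgt$id, i, 55 + i)$construct$id)
  plate <- lims_layout_constructs(w$store, unlist(cons))
  expect_identical(names(plate$wells), c("A1", "A2", "A3"))
  derived <- lims_derive_plates(w$store, plate$id)
  for (well in names(plate$wells)) {
    cid <- plate$wells[[well]]
    tpl <- lims_get(w$store, derived$template$wells[[well]])
    expect_identical(tpl$construct_id, cid)
    expect_equal(tpl$sample_type, "Template")
    fp <- lims_get(w$store, derived$forward_primers$wells[[well]])
    expect_identical(fp$construct_id, cid)
    expect_equal(fp$sample_type, "Primers")
  }
  orders <- lims_primer_orders(w$store, plate$id)
  expect_equal(nrow(orders), 6)
  expect_setequal(unique(orders$primer), c("forward", "reverse"))
  # capacity: 97 constructs cannot fit a 96-well plate
  many <- rep(cons[[1]], 97)
  expect_lims_error(lims_layout_constructs(w$store, many), "lims_capacity_error")
})
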