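test_that("an isolated sample yields a one-node graph with no truncation", {
  w <- store_with_notebook()
  smp <- lims_create_sample(w$store, "DNA", w$nb)
  g <- lims_build_graph(w$store, smp$id, depth = 2)
  expect_equal(nrow(g$nodes), 1)
  expect_length(g$truncated, 0)
  expect_identical(g$center, smp$id)
})

test_that("depth-1 neighborhoods truncate correctly and re-centring reveals more", {
  fx <- chain_fixture()
  g <- lims_build_graph(fx$store, fx$s1, depth = 1)
  expect_setequal(g$nodes$id, c(fx$e1, fx$s1, fx$e2))
  expect_setequal(g$truncated, c(fx$e1, fx$e2))
  # re-centre on a truncated node: previously hidden S0 appears
  g2 <- lims_build_graph(fx$store, fx$e1, depth = 1)
  expect_true(fx$s0 %in% g2$nodes$id)
  # at depth >= diameter the whole component is present, untruncated
  gfull <- lims_build_graph(fx$store, fx$s1, depth = 10)
  expect_setequal(gfull$nodes$id, c(fx$s0, fx$e1, fx$s1, fx$e2, fx$s2))
  expect_length(gfull$truncated, 0)
})

test_that("DOT output draws experiments as ellipses, samples as diamonds, with the colour legend", {
  fx <- chain_fixture()
  g <- lims_build_graph(fx$store, fx$s1, depth = 1)
  dot <- lims_export_dot(g)
  expect_match(dot, "^digraph workflow \\{")
  expect_equal(sum(gregexpr("\\{", dot)[[1]] > 0), sum(gregexpr("\\}", dot)[[1]] > 0))
  expect_equal(length(gregexpr("shape=", dot)[[1]]), nrow(g$nodes))
  expect_equal(length(gregexpr(" -> ", dot)[[1]]), nrow(g$edges))
  expect_match(dot, sprintf("\"%s\" \\[[^]]*shape=diamond[^]]*fillcolor=\"#FFFFFF\"[^]]*color=\"#FF0000\"", fx$s1))
  for (tid in g$truncated)
    expect_match(dot, sprintf("\"%s\" \\[[^]]*fillcolor=\"#90EE90\"", tid))
  expect_match(dot, "shape=ellipse")
})

test_that("sample history lists every ancestor stage once, ancestors first", {
  fx <- chain_fixture()
  h0 <- lims_sample_history(fx$store, fx$s0)
  expect_length(h0$stages, 0)
  h2 <- lims_sample_history(fx$store, fx$s2)
  expect_equal(vapply(h2$stages, `[[`, "", "protocol_name"), c("step1", "step2"))
  expect_equal(sort(vapply(h2$stages, `[[`, "", "experiment_id")),
               oracle_ancestor_experiments(fx$store, fx$s2))
})

test_that("diamond provenance keeps each ancestor experiment exactly once", {
  s <- lims_store()
  nb <- lims_create_notebook(s, "diamond")$id
  split_p <- lims_create_protocol(s, "splitter",
    input_slots = list(lims_slot("in", "input", "A")),
    output_slots = list(lims_slot("out", "output", "B")), notebook_id = nb)
  merge_p <- lims_create_protocol(s, "merger",
    input_slots = list(lims_slot("x", "input", "B"), lims_slot("y", "input", "B")),
    output_slots = list(lims_slot("out", "output", "C")), notebook_id = nb)
  root <- lims_create_sample(s, "A", nb)
  e1 <- lims_instantiate_experiment(s, split_p$id, list("in" = root$id))
  e2 <- lims_instantiate_experiment(s, split_p$id, list("in" = root$id))
  em <- lims_instantiate_experiment(s, merge_p$id,
          list(x = e1$output_sample_ids[1], y = e2$output_sample_ids[1]))
  h <- lims_sample_history(s, em$output_sample_ids[1])
  ids <- vapply(h$stages, `[[`, "", "experiment_id")
  expect_length(ids, 3)
  expect_false(anyDuplicated(ids) > 0)
  expect_equal(ids[3], em$id)  # merger last
})

test_that("history export renders text and round-trips through XML", {
  fx <- chain_fixture()
  h <- lims_sample_history(fx$store, fx$s2)
  txt <- lims_export_history(h, "text")
  expect_match(txt, "Stages: 2")
  expect_match(txt, "digraph workflow", fixed = TRUE)
  xml <- lims_export_history(h, "xml")
  doc <- xml2::read_xml(xml)
  expect_equal(xml2::xml_attr(doc, "stages"), "2")
  expect_length(xml2::xml_find_all(doc, "./stage"), 2)
  expect_length(xml2::xml_find_all(doc, "./workflow[@format='dot']"), 1)
  # empty history still renders a subject header
  h0 <- lims_sample_history(fx$store, fx$s0)
  expect_match(lims_export_history(h0, "text"), "Sample history:")
  expect_equal(xml2::xml_attr(xml2::read_xml(lims_export_history(h0, "xml")), "stages"), "0")
})

test_that("cohort tracking reports per-stage survival and is monotone", {
  w <- store_with_notebook(seeded = TRUE)
  spec <- lims_fixture_spec(seed = 17, n_targets = 6, workflow_depth = 4,
                            failure_rate = c(0, 0.5, 0.5, 0.5))
  res <- lims_generate_workflow(w$store, spec, notebook_id = w$nb)
  co <- lims_cohort_report(w$store, res$founder_ids, res$stage_names)
  expect_equal(dim(co), c(6, 4))
  expect_equal(unname(colSums(co)[1]), 6)  # no stage-1 dropout
  # column sums match the chain lengths the generator reports
  for (j in seq_along(res$stage_names))
    expect_equal(unname(colSums(co)[j]), sum(res$reached >= j))
  # survival can only shrink along the chain
  expect_true(all(diff(colSums(co)) <= 0))
  # empty stage list
  co0 <- lims_cohort_report(w$store, res$founder_ids, character())
  expect_equal(dim(co0), c(6, 0))
  # a founder with no experiments is all-false
  lone <- lims_create_sample(w$store, "Template", w$nb)
  co1 <- lims_cohort_report(w$store, lone$id, res$stage_names)
  expect_false(any(co1))
  # monotone: running one more experiment never clears a cell
  before <- lims_cohort_report(w$store, res$founder_ids, res$stage_names)
  dead <- res$founder_ids[res$reached == 0]
  if (length(dead)) {
    fwd <- Filter(function(i) {
      smp <- lims_get(w$store, i)
      identical(smp$construct_id, lims_get(w$store, dead[1])$construct_id) &&
        smp$sample_type == "Primers"
    }, lims_ls(w$store, "sample"))[[1]]
    pcr <- Filter(function(p) p$name == "PCR",
                  lims_search_protocols_by_type(w$store, "Processing DNA"))[[1]]
    lims_instantiate_experiment(w$store, pcr$id,
                                list(primers = fwd, template = dead[1]))
  }
  after <- lims_cohort_report(w$store, res$founder_ids, res$stage_names)
  expect_true(all(after[before]))
})
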