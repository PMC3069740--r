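test_that("single-file stores initialise once, reopen intact, and check versions", {
  path <- tempfile(fileext = ".json")
  s <- lims_init_store(path)
  expect_lims_error(lims_init_store(path), "lims_already_exists_error")
  lims_seed_default_protocols(s)
  nb <- lims_create_notebook(s, "bench")$id
  lims_create_sample(s, "DNA", nb, label = "x1")
  lims_save_store(s)
  s2 <- lims_open_store(path)
  expect_equal(length(lims_ids(s2)), length(lims_ids(s)))
  expect_true(s2$seeded)
  expect_identical(lims_audit(s2), character(0))
  # new records in the reopened store do not collide with old ids
  fresh <- lims_create_sample(s2, "DNA", nb)
  expect_false(fresh$id %in% lims_ids(s))
  expect_lims_error(lims_open_store(tempfile()), "lims_not_found_error")
  # version check
  bad <- tempfile(fileext = ".json")
  writeLines('{"format":"lims-store","schema_version":99,"meta":{},"entities":[],"permissions":[]}', bad)
  expect_lims_error(lims_open_store(bad), "lims_version_error")
})

populated_store <- function(seed = 23) {
  w <- store_with_notebook(seeded = TRUE)
  spec <- lims_fixture_spec(seed = seed, n_targets = 3, workflow_depth = 5,
                            failure_rate = 0.2)
  res <- lims_generate_workflow(w$store, spec, notebook_id = w$nb)
  g <- lims_create_group(w$store, "team", c("ada"))
  lims_grant(w$store, g$id, w$nb, "write")
  list(store = w$store, nb = w$nb, res = res)
}

test_that("two exports of an unchanged store are byte-identical in both formats", {
  fx <- populated_store()
  expect_identical(lims_export_bulk(fx$store, format = "xml"),
                   lims_export_bulk(fx$store, format = "xml"))
  expect_identical(lims_export_bulk(fx$store, format = "json"),
                   lims_export_bulk(fx$store, format = "json"))
})

test_that("export -> import into a fresh store is content-isomorphic", {
  fx <- populated_store()
  for (fmt in c("xml", "json")) {
    doc <- lims_export_bulk(fx$store, format = fmt)
    dst <- lims_store()
    summary <- lims_import_bulk(dst, doc)
    expect_equal(summary$created + summary$skipped, length(lims_ids(fx$store)))
    expect_equal(length(lims_ids(dst)), length(lims_ids(fx$store)))
    expect_identical(lims_audit(dst), character(0))
    # per-kind counts match
    kind_counts <- function(s) table(vapply(lims_ids(s), function(i)
      lims_get(s, i)$kind, character(1)))
    expect_equal(kind_counts(dst), kind_counts(fx$store))
    # histories are isomorphic: same protocol-name stage sequences
    for (f in fx$res$founder_ids) {
      sol <- lims_sample_history(fx$store, f)
      dup <- lims_sample_history(dst, f)
      expect_identical(vapply(dup$stages, `[[`, "", "protocol_name"),
                       vapply(sol$stages, `[[`, "", "protocol_name"))
    }
    # second import: everything skipped
    again <- lims_import_bulk(dst, doc)
    expect_equal(again$created, 0)
  }
})

test_that("attachments survive the round trip byte-identically", {
  w <- store_with_notebook()
  smp <- lims_create_sample(w$store, "DNA", w$nb)
  payload <- as.raw(c(137, 80, 78, 71, sample(0:255, 200, replace = TRUE)))
  r <- lims_attach_file(w$store, smp$id, "gel.png", "image/png", payload)
  aid <- attr(r, "attachment_id")
  for (fmt in c("xml", "json")) {
    dst <- lims_store()
    lims_import_bulk(dst, lims_export_bulk(w$store, format = fmt))
    expect_identical(lims_get_attachment(dst, aid)$payload, payload)
  }
})

test_that("notebook-scoped export keeps other notebooks out but public protocols in", {
  fx <- populated_store()
  other <- lims_create_notebook(fx$store, "other lab")$id
  secret <- lims_create_sample(fx$store, "DNA", other, label = "secret")
  doc <- lims_export_bulk(fx$store, scope = fx$nb, format = "json")
  parsed <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  ids <- vapply(parsed$entities, `[[`, "", "id")
  expect_false(secret$id %in% ids)
  kinds <- vapply(parsed$entities, `[[`, "", "kind")
  # referenced public protocols (e.g. PCR) travel along
  nms <- vapply(parsed$entities[kinds == "protocol"], function(e) e$name, "")
  expect_true("PCR" %in% nms)
  # and the scoped document imports cleanly
  dst <- lims_store()
  expect_silent(lims_import_bulk(dst, doc))
  expect_identical(lims_audit(dst), character(0))
})

test_that("a truncated document is rejected atomically", {
  fx <- populated_store()
  doc <- lims_export_bulk(fx$store, format = "xml")
  dst <- lims_store()
  n0 <- length(lims_ids(dst))
  expect_lims_error(lims_import_bulk(dst, substr(doc, 1, nchar(doc) %/% 2)),
                    "lims_format_error")
  expect_equal(length(lims_ids(dst)), n0)
  expect_lims_error(lims_import_bulk(dst, "not a document at all"),
                    "lims_format_error")
})

test_that("text search matches substrings case-insensitively within one kind", {
  w <- store_with_notebook()
  lims_create_sample(w$store, "Soluble protein", w$nb, label = "Lysozyme batch 1")
  s2 <- lims_create_sample(w$store, "Soluble protein", w$nb, label = "b2",
                           description = "hen LYSOZYME, second prep")
  lims_create_sample(w$store, "Soluble protein", w$nb, label = "unrelated")
  lims_create_target(w$store, "lysozyme gene", w$nb, protein_sequence = "MKALIV")
  hits <- lims_search(w$store, "sample", "lysozyme")
  expect_length(hits, 2)
  # notes are searched too
  lims_annotate(w$store, s2$id, "crystallized readily")
  expect_length(lims_search(w$store, "sample", "crystallized"), 1)
  expect_lims_error(lims_search(w$store, "sample", "  "), "lims_validation_error")
  expect_lims_error(lims_search(w$store, "gizmo", "x"), "lims_validation_error")
})

test_that("recent lists deduplicate, order newest-first and cap at n", {
  w <- store_with_notebook()
  lims_create_user(w$store, "ada")
  g <- lims_create_group(w$store, "team", "ada")
  lims_grant(w$store, g$id, w$nb, "read")
  a <- lims_create_sample(w$store, "DNA", w$nb, label = "A")
  b <- lims_create_sample(w$store, "DNA", w$nb, label = "B")
  lims_record_access(w$store, "ada", a$id)
  lims_record_access(w$store, "ada", b$id)
  lims_record_access(w$store, "ada", a$id)
  got <- vapply(lims_recent(w$store, "ada", "sample", 10), `[[`, "", "id")
  expect_identical(got, c(a$id, b$id))
  expect_identical(vapply(lims_recent(w$store, "ada", "sample", 1), `[[`, "", "id"),
                   a$id)
  expect_length(lims_recent(w$store, "bob", "sample", 10), 0)
})
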