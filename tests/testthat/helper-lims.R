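# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (brute-force filters, literal codon map, transitive closures) and
# never call the code paths they check.

new_store <- function() lims_store()

seeded_store <- function() {
  s <- lims_store()
  lims_seed_default_protocols(s)
  s
}

# store + one notebook, returned together
store_with_notebook <- function(seeded = FALSE) {
  s <- if (seeded) seeded_store() else lims_store()
  nb <- lims_create_notebook(s, "bench")
  list(store = s, nb = nb$id)
}

# Literal standard genetic code, written out independently of any library.
ORACLE_CODON_MAP <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(dna, frame = 0, to_stop = TRUE) {
  body <- substr(dna, frame + 1, nchar(dna))
  n <- nchar(body) %/% 3
  aa <- character(n)
  for (i in seq_len(n))
    aa[i] <- ORACLE_CODON_MAP[[substr(body, 3 * i - 2, 3 * i)]]
  aa <- paste(aa, collapse = "")
  if (to_stop) sub("\\*.*$", "", aa) else aa
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Brute-force protocol suggestion: scan every protocol record directly.
oracle_suggest <- function(store, sample_id, user = NULL) {
  smp <- lims_get(store, sample_id)
  key <- tolower(trimws(smp$sample_type))
  hits <- character()
  for (id in lims_ls(store, "protocol")) {
    if (!is.null(user) && !lims_can_read(store, user, id)) next
    p <- lims_get(store, id)
    types <- vapply(p$input_slots, function(sl) tolower(trimws(sl$sample_type)),
                    character(1))
    if (key %in% types) hits <- c(hits, id)
  }
  sort(hits)
}

# Brute-force slot compatibility filter.
oracle_compatible <- function(store, protocol_id, slot_role, user = NULL) {
  p <- lims_get(store, protocol_id)
  slot <- NULL
  for (sl in c(p$input_slots, p$output_slots))
    if (sl$role == slot_role) slot <- sl
  key <- tolower(trimws(slot$sample_type))
  hits <- character()
  for (id in lims_ls(store, "sample")) {
    if (!is.null(user) && !lims_can_read(store, user, id)) next
    if (tolower(trimws(lims_get(store, id)$sample_type)) == key)
      hits <- c(hits, id)
  }
  sort(hits)
}

# Transitive closure of "produced by" over input bindings, by fixpoint
# iteration on the raw records.
oracle_ancestor_experiments <- function(store, sample_id) {
  exps <- character()
  samples <- sample_id
  repeat {
    new_exps <- character()
    for (sid in samples) {
      p <- lims_get(store, sid)$produced_by
      if (!is.null(p)) new_exps <- c(new_exps, p)
    }
    new_exps <- setdiff(unique(new_exps), exps)
    if (!length(new_exps)) break
    exps <- c(exps, new_exps)
    for (e in new_exps)
      samples <- unique(c(samples, unlist(lims_get(store, e)$input_bindings)))
  }
  sort(exps)
}

# A small typed chain for provenance tests: S0 -[E1]-> S1 -[E2]-> S2.
chain_fixture <- function() {
  s <- lims_store()
  nb <- lims_create_notebook(s, "chain")$id
  p1 <- lims_create_protocol(s, "step1",
                             input_slots = list(lims_slot("in", "input", "T0")),
                             output_slots = list(lims_slot("out", "output", "T1")),
                             notebook_id = nb)
  p2 <- lims_create_protocol(s, "step2",
                             input_slots = list(lims_slot("in", "input", "T1")),
                             output_slots = list(lims_slot("out", "output", "T2")),
                             notebook_id = nb)
  s0 <- lims_create_sample(s, "T0", nb, label = "S0")
  e1 <- lims_instantiate_experiment(s, p1$id, list("in" = s0$id))
  s1 <- e1$output_sample_ids[1]
  e2 <- lims_instantiate_experiment(s, p2$id, list("in" = s1))
  s2 <- e2$output_sample_ids[1]
  list(store = s, nb = nb, s0 = s0$id, e1 = e1$id, s1 = s1, e2 = e2$id, s2 = s2,
       p1 = p1$id, p2 = p2$id)
}

# A random library of protocols over a closed pool of sample types, plus
# random samples — the arena for the type-safety equivalence checks.
random_arena <- function(store, nb, n_protocols, n_samples, n_types = 8) {
  types <- paste("type", seq_len(n_types))
  for (i in seq_len(n_protocols)) {
    n_in <- sample(1:3, 1)
    ins <- lapply(seq_len(n_in), function(k)
      lims_slot(paste("in", k), "input", sample(types, 1),
                multiplicity = sample(1:2, 1, prob = c(0.8, 0.2))))
    outs <- if (stats::runif(1) < 0.8)
      list(lims_slot("out", "output", sample(types, 1))) else list()
    lims_create_protocol(store, paste("rand protocol", i),
                         input_slots = ins, output_slots = outs,
                         notebook_id = nb)
  }
  for (i in seq_len(n_samples))
    lims_create_sample(store, sample(types, 1), nb, label = paste("rs", i))
  types
}

expect_lims_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}

# Random provenance DAG grown through the API: a pool of samples, each new
# experiment consuming one or two of them and contributing its output.
random_dag_store <- function(seed, n_roots = 8, n_experiments = 60) {
  set.seed(seed)
  s <- lims_store()
  nb <- lims_create_notebook(s, "dag")$id
  p1 <- lims_create_protocol(s, "unary step",
          input_slots = list(lims_slot("a", "input", "stuff")),
          output_slots = list(lims_slot("out", "output", "stuff")), notebook_id = nb)
  p2 <- lims_create_protocol(s, "binary step",
          input_slots = list(lims_slot("a", "input", "stuff"),
                             lims_slot("b", "input", "stuff")),
          output_slots = list(lims_slot("out", "output", "stuff")), notebook_id = nb)
  pool <- vapply(seq_len(n_roots), function(i)
    lims_create_sample(s, "stuff", nb, label = paste("root", i))$id, character(1))
  for (i in seq_len(n_experiments)) {
    if (stats::runif(1) < 0.5 || length(pool) < 2) {
      e <- lims_instantiate_experiment(s, p1$id, list(a = sample(pool, 1)))
    } else {
      ab <- sample(pool, 2)
      e <- lims_instantiate_experiment(s, p2$id, list(a = ab[1], b = ab[2]))
    }
    pool <- c(pool, e$output_sample_ids)
  }
  list(store = s, samples = pool)
}
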