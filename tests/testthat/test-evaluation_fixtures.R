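# These tests exercise the RDKit-backed descriptor bridge; the Python
# helper ships with the package and RDKit is part of the supported stack.

test_that("mol_properties flags invalid SMILES and returns sane descriptors", {
  df <- mol_properties(c("CCO", "C((", "CCO", "c1ccccc1O"))
  expect_equal(df$valid, c(TRUE, FALSE, TRUE, TRUE))
  expect_true(all(is.na(df[2, c("qed", "sa", "logp", "tpsa", "mw")])))
  expect_true(all(df$qed[df$valid] >= 0 & df$qed[df$valid] <= 1))
  # determinism: same SMILES twice gives identical values
  expect_identical(unname(unlist(df[1, -1])), unname(unlist(df[3, -1])))
  expect_equal(df$mw[1], 46.07, tolerance = 1e-2)
  fps <- attr(df, "fingerprints")
  expect_null(fps[[2]])
  expect_identical(fps[[1]], fps[[3]])
})

test_that("diversity follows the ordered-pair Tanimoto formula", {
  # N identical molecules -> 0
  expect_equal(diversity(rep("CCO", 4)), 0)

  # two molecules with zero fingerprint overlap -> 1 - (1+0+0+1)/4 = 0.5
  df <- mol_properties(c("C", "O"))
  fps <- attr(df, "fingerprints")
  expect_equal(pocketmolgen:::tanimoto(fps[[1]], fps[[2]]), 0)
  expect_equal(diversity(c("C", "O")), 0.5)

  # random 10-molecule set matches the double-loop oracle exactly
  corpus <- tiny_corpus()
  smi <- unique(corpus$smiles)[1:10]
  df10 <- mol_properties(smi)
  f10 <- attr(df10, "fingerprints")
  oracle <- 0
  for (a in 1:10) for (b in 1:10)
    oracle <- oracle + pocketmolgen:::tanimoto(f10[[a]], f10[[b]])
  oracle <- 1 - oracle / 100
  expect_equal(diversity(smi), oracle, tolerance = 1e-9)
  # permutation invariance
  expect_equal(diversity(rev(smi)), oracle, tolerance = 1e-9)
})

test_that("high_affinity_ratio counts better-or-equal scores", {
  expect_equal(high_affinity_ratio(c(-7.5, -7.5), -7.5), 100)
  expect_equal(high_affinity_ratio(c(-6, -5), -7.5), 0)
  expect_equal(high_affinity_ratio(c(-8, -7, -7.5), -7.5), 200 / 3,
               tolerance = 1e-9)
  expect_true(is.na(high_affinity_ratio(numeric(0), -7.5)))
  # flipped convention
  expect_equal(high_affinity_ratio(c(8, 7, 7.5), 7.5, better = "ge"),
               200 / 3, tolerance = 1e-9)
})

test_that("compliance computes inclusive threshold fractions", {
  props <- data.frame(qed = c(0.7, 0.7, 0.7), sa = c(3.5, 4.0, 4.3))
  expect_equal(compliance(props, list(qed = hard_property("QED", 0.6, "ge"))),
               c(qed = 1.0))
  expect_equal(compliance(props, list(sa = hard_property("SA", 4.0, "le"))),
               c(sa = 2 / 3))
  expect_length(compliance(props, list()), 0L)
})

test_that("pocket fixtures are reproducible and well-formed", {
  p1 <- make_pocket_fixture(31, n_residues = 10L)
  p2 <- make_pocket_fixture(31, n_residues = 10L)
  expect_identical(p1, p2)
  expect_length(p1$residues, 10L)
  natoms <- vapply(p1$residues, function(r) nrow(r$atoms), integer(1))
  expect_true(all(natoms >= 4L & natoms <= 8L))
  # different seed differs
  expect_false(identical(make_pocket_fixture(32, n_residues = 10L), p1))
})

test_that("conditioned corpus encodes the learnable nitrogen rule", {
  corpus <- suppressWarnings(make_conditioned_corpus(55, n_records = 200L,
                                                     n_pockets = 4L))
  # every emitted SMILES parses
  df <- mol_properties(corpus$smiles)
  expect_true(all(df$valid))

  # records with affinity bit 1 all contain nitrogen
  bits <- vapply(corpus$records, function(r) r$y[1], numeric(1))
  hasN <- grepl("N", corpus$smiles, fixed = TRUE)
  expect_true(all(hasN[bits == 1]))

  # binarizing the pseudo docking scores recovers the nitrogen flag >= 95%
  scores <- vapply(corpus$records, `[[`, numeric(1), "docking_score")
  rule <- hard_property("affinity", -7.5, "le")
  rec_bit <- vapply(scores, binarize_property, numeric(1), rule = rule)
  expect_gte(mean(rec_bit == as.numeric(hasN)), 0.95)

  # reproducibility
  corpus2 <- suppressWarnings(make_conditioned_corpus(55, n_records = 200L,
                                                      n_pockets = 4L))
  expect_identical(corpus$smiles, corpus2$smiles)
  expect_identical(corpus$vocab$tokens, corpus2$vocab$tokens)
})

test_that("evaluate assembles the metrics report", {
  # all-invalid input: validity 0, everything else missing
  rep0 <- evaluate(c("C((", ")("))
  expect_equal(rep0$validity_rate, 0)
  expect_true(is.na(rep0$diversity))

  # single valid molecule: diversity 0 (self-pair only)
  rep1 <- evaluate("CCO")
  expect_equal(rep1$diversity, 0)

  # toy set with hand-computed metrics and the mock scorer
  smi <- c("CCN", "CCO", "C((")
  sc <- mock_scorer()
  s <- sc$score(NULL, c("CCN", "CCO"))
  # mock model: -3 - 1.5 nN - 0.5 nO - 0.25 heavy
  expect_equal(s, c(-3 - 1.5 - 0.75, -3 - 0.5 - 0.75))
  rep2 <- evaluate(smi, reference = -5.0, scorer = sc,
                   conditions = list(sa = hard_property("SA", 4.0, "le")))
  expect_equal(rep2$validity_rate, 2 / 3)
  expect_equal(rep2$har, high_affinity_ratio(s, -5.0))
  props <- mol_properties(c("CCN", "CCO"))
  expect_equal(rep2$property_summary$mean[rep2$property_summary$property == "qed"],
               mean(props$qed))
  expect_equal(unname(rep2$compliance["sa"]),
               mean(props$sa <= 4.0))

  # report writer emits both TSVs
  m <- tempfile(fileext = ".tsv")
  pm <- tempfile(fileext = ".tsv")
  write_metrics_report(rep2, m, pm)
  got <- read.delim(m)
  expect_equal(got$validity_rate, 2 / 3, tolerance = 1e-9)
  expect_equal(nrow(read.delim(pm)), 3L)

  # unavailable scorer: HAR omitted with a notice
  bad <- list(name = "missing", available = FALSE)
  expect_message(rep3 <- evaluate("CCO", reference = -5, scorer = bad),
                 "unavailable")
  expect_true(is.na(rep3$har))
})

test_that("a corpus read back from files matches the in-memory one", {
  dir <- file.path(tempdir(), "pmg-roundtrip")
  dir.create(dir, showWarnings = FALSE)
  corpus <- suppressWarnings(make_conditioned_corpus(88, n_records = 30L,
                                                     n_pockets = 2L))
  smi <- file.path(dir, "c.smi")
  tsv <- file.path(dir, "c.tsv")
  write_smiles(corpus$smiles, smi)
  write_property_sidecar(corpus, tsv)
  pdbs <- vapply(seq_along(corpus$pockets), function(i) {
    p <- file.path(dir, sprintf("p%d.pdb", i))
    writeLines(write_pocket_pdb(corpus$pockets[[i]]), p)
    p
  }, character(1))
  back <- suppressWarnings(
    read_conditioned_corpus(smi, tsv, pdbs, corpus$schema,
                            vocab = corpus$vocab))
  expect_identical(back$smiles, corpus$smiles)
  for (i in c(1L, 15L, 30L)) {
    expect_identical(back$records[[i]]$token_ids,
                     corpus$records[[i]]$token_ids)
    expect_equal(back$records[[i]]$y, corpus$records[[i]]$y)
  }
  expect_length(back$pockets, 2L)

  # soft-property standardization is applied only when requested
  sch <- property_schema(hard_property("affinity", -7.5, "le"),
                         soft_property("heavy_atoms", standardize = TRUE,
                                       mean = 7, sd = 2))
  y <- pocketmolgen:::schema_vector(list(affinity = -8, heavy_atoms = 11),
                                    sch)
  expect_equal(y, c(1, 2))
})

test_that("the CLI drives fixtures and evaluation end to end", {
  dir <- file.path(tempdir(), "pmg-cli")
  unlink(dir, recursive = TRUE)
  suppressWarnings(suppressMessages(
    cli_main(c("make-fixtures", "--seed", "3", "--n-records", "40",
               "--out-dir", dir))))
  expect_true(file.exists(file.path(dir, "corpus.smi")))
  expect_true(file.exists(file.path(dir, "corpus.tsv")))
  expect_true(file.exists(file.path(dir, "vocab.txt")))
  expect_gt(length(Sys.glob(file.path(dir, "pocket_*.pdb"))), 0L)
  # pockets re-parse
  pdb <- Sys.glob(file.path(dir, "pocket_*.pdb"))[1]
  expect_s3_class(parse_pocket(readLines(pdb)), "PocketStructure")
  sidecar <- read.delim(file.path(dir, "corpus.tsv"))
  expect_true(all(c("smiles", "affinity", "heavy_atoms", "docking_score")
                  %in% names(sidecar)))

  out <- file.path(dir, "metrics.tsv")
  pmol <- file.path(dir, "per_mol.tsv")
  suppressMessages(
    cli_main(c("evaluate", "--generated", file.path(dir, "corpus.smi"),
               "--scorer", "mock", "--out", out, "--per-molecule", pmol)))
  expect_true(file.exists(out))
  expect_equal(read.delim(out)$validity_rate, 1)
})
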