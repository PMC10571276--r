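# Reader, normalization and cross-set deduplication.

test_that("well-formed tables read one record per row, in file order", {
  path <- write_fixture_table(simple_compounds())
  tbl <- read_compound_table(path, source = "hmdb_gut")
  expect_equal(nrow(tbl), 3L)
  expect_equal(tbl$id, c("a1", "a2", "a3"))
  expect_equal(nrow(attr(tbl, "skipped")), 0L)
  expect_true(all(tbl$in_gut) && !any(tbl$in_serum))
})

test_that("unparseable SMILES rows are skipped and counted", {
  df <- simple_compounds()
  df$smiles[2] <- "not_a_smiles"
  path <- write_fixture_table(df)
  expect_warning(tbl <- read_compound_table(path, source = "hmdb_gut"),
                 "unparseable")
  expect_equal(nrow(tbl), 2L)
  sk <- attr(tbl, "skipped")
  expect_equal(sk$id, "a2")
  expect_equal(sk$reason, "unparseable_smiles")
})

test_that("quantification-status filter drops disallowed rows", {
  df <- simple_compounds()
  df$quant_status[1] <- "expected"
  path <- write_fixture_table(df)
  tbl <- read_compound_table(path, source = "hmdb_gut")
  expect_equal(tbl$id, c("a2", "a3"))
  expect_true("quant_status_filtered" %in% attr(tbl, "skipped")$reason)
})

test_that("duplicate ids are kept at read time and flagged", {
  df <- simple_compounds()[c(1, 1), ]
  path <- write_fixture_table(df)
  tbl <- read_compound_table(path, source = "hmdb_gut")
  expect_equal(nrow(tbl), 2L)
  expect_equal(attr(tbl, "dup_ids"), "a1")
})

test_that("column mapping and missing SMILES column behave per contract", {
  df <- simple_compounds()
  names(df)[names(df) == "smiles"] <- "SMILES_STR"
  path <- write_fixture_table(df)
  expect_error(read_compound_table(path, source = "hmdb_gut"), "missing")
  cfg <- compound_read_config(columns = list(smiles = "SMILES_STR"))
  tbl <- read_compound_table(path, source = "hmdb_gut", config = cfg)
  expect_equal(nrow(tbl), 3L)
  expect_error(read_compound_table(tempfile(), source = "hmdb_gut"),
               "not found")
})

test_that("normalization strips salts, neutralizes and is idempotent", {
  # sodium acetate -> neutral acetic acid parent (backend oracle, frozen)
  expect_equal(normalize_structure("CC(=O)[O-].[Na+]"), "CC(=O)O")
  expect_equal(normalize_structure("c1ccccc1"), "c1ccccc1")
  expect_error(normalize_structure("not_a_smiles"), "invalid")
  probes <- c("CC(=O)[O-].[Na+]", "C(CS([O-])(=O)=O)O", "OC(=O)c1ccccc1",
              "CCN", "CC(N)C(=O)O", "c1ccc2[nH]ccc2c1")
  once <- normalize_structures(probes)
  expect_identical(normalize_structures(once), once)
})

test_that("stereo stripping is available and canonical", {
  chiral <- "C[C@@H](N)C(=O)O"
  flat <- normalize_structure(chiral, keep_stereo = FALSE)
  expect_false(grepl("@", flat))
  expect_identical(normalize_structure(flat), flat)
})

test_that("deduplication keeps DrugBank over metabolites and unions flags", {
  rec <- data.frame(
    id = c("g1", "d1", "g2", "s2", "u1"),
    smiles = c("CCO", "CCO", "CC(=O)O", "CC(=O)O", "CCN"),
    source = c("hmdb_gut", "drugbank", "hmdb_gut", "hmdb_serum", "hmdb_gut"),
    in_gut = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    in_serum = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    pka_strongest_acidic = c(NA, NA, 4.76, NA, NA),
    pka_strongest_basic = NA_real_,
    chem_class = c(NA, "Other", NA, "Organic acids and derivatives", NA),
    quant_status = "quantified",
    stringsAsFactors = FALSE
  )
  out <- deduplicate_across_sets(rec)
  expect_equal(nrow(out), 3L)
  expect_false(any(duplicated(out$smiles)))
  # drugbank wins the shared structure
  eth <- out[out$smiles == "CCO", ]
  expect_equal(eth$source, "drugbank")
  # within-metabolite duplicate unions the biospecimen flags and merges fields
  ace <- out[out$smiles == "CC(=O)O", ]
  expect_true(ace$in_gut && ace$in_serum)
  expect_equal(ace$pka_strongest_acidic, 4.76)
  expect_equal(ace$chem_class, "Organic acids and derivatives")
  # all-unique input is untouched
  uniq <- rec[c(1, 3, 5), ]
  expect_equal(deduplicate_across_sets(uniq)$id, uniq$id,
               ignore_attr = TRUE)
})

test_that("writer round-trips every field of valid rows", {
  path <- write_fixture_table(simple_compounds())
  tbl <- read_compound_table(path, source = "hmdb_serum")
  out <- tempfile(fileext = ".csv")
  write_compound_table(tbl, out)
  back <- read_compound_table(out, source = "hmdb_serum")
  expect_equal(back[COMPOUND_COLUMNS], tbl[COMPOUND_COLUMNS],
               ignore_attr = TRUE)
})

test_that("SDF reader recovers structures and data fields", {
  smi <- c(m1 = "CCO", m2 = "c1ccccc1")
  sdfstr <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0(paste(smi, names(smi)), collapse = "\n"))
  path <- tempfile(fileext = ".sdf")
  writeLines(sdfstr, path)
  tbl <- read_compound_sdf(path, source = "drugbank")
  expect_equal(nrow(tbl), 2L)
  expect_false(any(tbl$in_gut))
  expect_identical(normalize_structures(tbl$smiles),
                   normalize_structures(unname(smi)))
})
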