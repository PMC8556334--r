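test_that("independent re-parsing flags exactly the corrupt structures", {
  good <- c("CCO", "c1ccccc1", "C[C@H](N)C(=O)O")
  v <- validate_parse(good, parser = "rdkit")
  expect_equal(v$parse_valid_fraction, 1)
  expect_equal(nrow(v$failures), 0)

  mixed <- c(good, "C1CC")
  v2 <- validate_parse(mixed, parser = "rdkit")
  expect_equal(v2$parse_valid_fraction, 3 / 4)
  expect_equal(v2$failures$row, 4L)

  v3 <- validate_parse(mixed, parser = "openbabel")
  expect_equal(v3$parse_valid_fraction, 3 / 4)

  empty <- validate_parse(character(0))
  expect_true(is.na(empty$parse_valid_fraction))
})

test_that("multiplicity tables cross-tabulate group by measurement count", {
  num <- tibble::tibble(group = c("A", "B"), n_values = c(1L, 3L),
                        n_unique = c(1L, 2L))
  cat_ <- tibble::tibble(group = c("A", "C"), n_labels = c(1L, 2L),
                         n_unique_labels = c(1L, 1L))
  tabs <- multiplicity_tables(num, cat_)
  cell <- function(t, g, m) t$n[t$group == g & t$multiplicity == m]
  expect_equal(cell(tabs$numeric_source, "A", 1), 1L)
  expect_equal(cell(tabs$numeric_source, "B", 3), 1L)
  expect_equal(cell(tabs$numeric_unique, "B", 2), 1L)
  expect_equal(cell(tabs$categorical_source, "C", 2), 1L)
  for (t in tabs[1:2]) expect_equal(sum(t$n), nrow(num))
  for (t in tabs[3:4]) expect_equal(sum(t$n), nrow(cat_))
})

test_that("stream-aggregated multiplicities equal a brute-force recount", {
  run <- run_synthetic_pipeline(synthetic_config(n_molecules = 60, seed = 5))
  res <- run$res
  tabs <- multiplicity_tables(res$numeric, res$categorical)
  # brute-force: recount surviving source values per molecule from the
  # generator's own record log
  rt <- run$gen$records_truth
  truth <- run$gen$truth
  truth$inchi <- smiles_to_inchi(truth$smiles)
  per_mol <- vapply(truth$mol_id, function(id) {
    sum(!is.na(rt$logBB[rt$mol_id == id]) & rt$logBB[rt$mol_id == id] > -9)
  }, integer(1))
  names(per_mol) <- truth$inchi
  for (i in seq_len(nrow(res$numeric))) {
    k <- res$numeric$inchi[i]
    expect_equal(res$numeric$n_values[i], unname(per_mol[[k]]))
  }
  expect_equal(sum(tabs$numeric_source$n), nrow(res$numeric))
  expect_equal(sum(tabs$categorical_unique$n), nrow(res$categorical))
})

test_that("distribution summaries bin and summarize correctly", {
  rec <- tibble::tibble(logbb = c(-0.1, 0.1, 0.3, 1.9))
  s <- summarize_distributions(rec)
  expect_equal(s$fraction_in_minus2_2, 1)
  expect_equal(sum(s$histogram$n), 4)
  expect_equal(s$median_logbb, 0.2)
  # values beyond the range land in the edge bins, none are lost
  s2 <- summarize_distributions(tibble::tibble(logbb = c(-5, 3)))
  expect_equal(sum(s2$histogram$n), 2)
  expect_equal(s2$fraction_in_minus2_2, 0)

  prof <- ro5_profile(c("CCO", "CCN"))
  s3 <- summarize_distributions(rec, prof, labels = c("BBB+", "BBB+"))
  expect_equal(nrow(s3$class_summaries), 1)
  expect_equal(s3$class_summaries$label, "BBB+")
})

test_that("recounting a written curated file reproduces the in-memory counts", {
  run <- run_synthetic_pipeline(synthetic_config(n_molecules = 40, seed = 3))
  res <- run$res
  rc <- recount_curated(res$paths$categorical, with_mw = TRUE)
  expect_equal(rc$n_rows, nrow(res$categorical))
  expect_equal(unname(rc$label_counts[["BBB+"]]),
               sum(res$categorical$label == "BBB+"))
  for (g in c("A", "B", "C", "D")) {
    expect_equal(unname(rc$group_counts[[g]]),
                 sum(res$categorical$group == g))
  }
  expect_true(rc$bbb_plus_mw_lt_500 >= 0 && rc$bbb_plus_mw_lt_500 <= 1)
  rn <- recount_curated(res$paths$numeric)
  expect_equal(rn$n_rows, nrow(res$numeric))
})

test_that("the serialized QC report is valid JSON with the expected blocks", {
  run <- run_synthetic_pipeline(synthetic_config(n_molecules = 30, seed = 9),
                                descriptor_provider = "openbabel")
  qc <- run$res$qc
  expect_s3_class(qc, "qc_report")
  expect_equal(qc$parse_valid$parse_valid_fraction, 1)
  j <- jsonlite::read_json(run$res$paths$qc)
  expect_true(all(c("parse_valid", "multiplicity", "distributions",
                    "ro5_fractions") %in% names(j)))
})
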