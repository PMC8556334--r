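test_that("a plain table maps directly onto source records", {
  f <- write_csv_fixture(c(
    "name,smiles,logBB",
    "ethanol,CCO,-0.20",
    "benzene,c1ccccc1,0.37",
    "glycine,NCC(=O)O,-1.1"
  ))
  out <- read_source_table(f, c(compound_name = "name", smiles_raw = "smiles",
                                logbb = "logBB"), "R1")
  expect_equal(nrow(out$records), 3)
  expect_equal(nrow(out$rejects), 0)
  expect_true(all(is.na(out$records$label)))
  expect_equal(out$records$logbb, c(-0.20, 0.37, -1.1))
  expect_equal(out$records$source_id, rep("R1", 3))
})

test_that("invariant-violating rows are rejected with reasons, never dropped", {
  f <- write_csv_fixture(c(
    "name,smiles,logBB,ref",
    "ethanol,CCO,n/a,r1",       # unparsable numeric, no label -> reject
    ",,0.2,r2",                 # no identity
    "benzene,c1ccccc1,0.37,r3"  # fine
  ))
  out <- read_source_table(f, c(compound_name = "name", smiles_raw = "smiles",
                                logbb = "logBB", reference = "ref"), "R2")
  expect_equal(nrow(out$records) + nrow(out$rejects), 3)
  expect_equal(nrow(out$records), 1)
  expect_match(out$rejects$reason[out$rejects$row == 1], "unparsable numeric")
  expect_match(out$rejects$reason[out$rejects$row == 2], "no identity")
})

test_that("labels are normalized, including the typeset Unicode minus", {
  f <- write_csv_fixture(c(
    "name,smiles,label",
    "a,CCO,BBB+",
    "b,CCN,BBB−",   # Unicode minus
    "c,CCC,maybe"        # outside the alphabet
  ))
  out <- read_source_table(f, c(compound_name = "name", smiles_raw = "smiles",
                                label = "label"), "R3")
  expect_equal(out$records$label, c("BBB+", "BBB-"))
  expect_match(out$rejects$reason, "invalid label")
})

test_that("missing and unmappable inputs are fatal before any work", {
  expect_error(read_source_table(tempfile(), c(logbb = "x"), "R4"), "not found")
  f <- write_csv_fixture(c("a,b", "1,2"))
  expect_error(read_source_table(f, c(logbb = "nonexistent"), "R4"),
               "not present")
  expect_error(read_source_table(f, c(bogus_field = "a"), "R4"), "record fields")
})

test_that("consistency checks count but do not modify", {
  rec <- tibble::tibble(
    source_id = "R1", row = 1:4,
    compound_name = c("a", "a", "b", "c"),
    smiles_raw = c("CCO", "CCO", "CCN", "CCC"),
    cid = NA_integer_,
    logbb = c(0.1, 0.1, Inf, 0.2),
    label = c(NA, NA, NA, "bogus"),
    threshold = NA_real_, reference = NA_character_
  )
  # duplicate check ignores the row counter
  rec2 <- rec; rec2$row <- 1L
  chk <- consistency_check(rec2)
  expect_equal(chk$n_records, 4)
  expect_equal(chk$duplicate_rows, 1)
  expect_equal(chk$non_finite_logbb, 1)
  expect_equal(chk$invalid_label, 1)

  clean <- consistency_check(rec[3:4, ][0, ])
  expect_equal(clean$duplicate_rows, 0)
  expect_equal(clean$non_finite_logbb, 0)
})

test_that("curated CSVs follow the two-track column layout", {
  num_row <- tibble::tibble(
    compound_name = "ethanol", iupac_name = "ethanol", smiles = "CCO",
    cid = "702", logbb = -0.203456, inchi = "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3",
    reference = "R1; R2", group = "B", comment = NA_character_
  )
  f <- tempfile(fileext = ".csv")
  write_curated(num_row, f, "numeric")
  hdr <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_false("BBB+/BBB-" %in% hdr)
  expect_false("threshold" %in% hdr)
  expect_equal(hdr[1:3], c("compound name", "IUPAC name", "SMILES"))

  cat_row <- dplyr::mutate(num_row, label = "BBB+", threshold = -1,
                           logbb = NA_real_)
  g <- tempfile(fileext = ".csv")
  write_curated(cat_row, g, "categorical")
  hdr2 <- strsplit(readLines(g, n = 1), ",")[[1]]
  expect_true(all(c("BBB+/BBB-", "threshold") %in% hdr2))

  # empty input still yields a header-only file
  h <- tempfile(fileext = ".csv")
  write_curated(num_row[0, ], h, "numeric")
  expect_equal(length(readLines(h)), 1L)
})

test_that("write and read of curated rows round-trips field-for-field", {
  rows <- tibble::tibble(
    compound_name = c("a", "b"), iupac_name = c(NA, "iupac-b"),
    smiles = c("CCO", "CCN"), cid = c("1", NA),
    logbb = c(-0.203456, 1.25), inchi = c("InChI=1S/x", "InChI=1S/y"),
    reference = c("R1", "R1; R2"), group = c("A", "B"),
    comment = c(NA, "note")
  )
  f <- tempfile(fileext = ".csv")
  write_curated(rows, f, "numeric")
  back <- read_curated(f)
  for (col in names(rows)) expect_equal(back[[col]], rows[[col]], label = col)
})

test_that("mixed tracks are fatal on write", {
  rows <- tibble::tibble(
    compound_name = "x", iupac_name = NA, smiles = "CCO", cid = NA,
    logbb = 0.1, label = "BBB+", inchi = "InChI=1S/x", threshold = -1,
    reference = "R1", group = "A", comment = NA
  )
  expect_error(write_curated(rows, tempfile(), "numeric"), "mixed tracks")
  rows$label <- NA_character_
  expect_error(write_curated(rows, tempfile(), "categorical"), "mixed tracks")
})
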