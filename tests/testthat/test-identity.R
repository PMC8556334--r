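stub_table <- function() {
  tibble::tibble(
    query_type = c("name", "name", "name", "cid", "smiles", "smiles"),
    query = c("ethanol", "ambiguol", "ambiguol", "702", "CCO", "CC(=O)O"),
    cid = c(702L, 11L, 12L, 702L, 702L, 176L),
    smiles = c("CCO", "CC(C)O", "CCC", "CCO", "CCO", "CC(=O)O"),
    name = c("ethanol", "ambiguol", "ambiguol-iso", "ethanol", "ethanol",
             "acetic acid"),
    iupac_name = c("ethanol", "propan-2-ol", "propane", "ethanol", "ethanol",
                   "acetic acid")
  )
}

test_that("missing fields are filled from the first registry match", {
  res <- resolver_offline(stub_table())
  rec <- tibble::tibble(
    source_id = "R1", row = 1:3,
    compound_name = c("ethanol", "ambiguol", "unknownol"),
    smiles_raw = NA_character_, cid = NA_integer_,
    logbb = 0.1, label = NA_character_, threshold = NA_real_,
    reference = NA_character_
  )
  out <- resolve_missing(rec, res)
  expect_equal(out$smiles_raw[1], "CCO")
  expect_equal(out$cid[1], 702L)
  expect_true(is.na(out$resolver_note[1]))
  # two matches: first instance used and ambiguity flagged
  expect_equal(out$smiles_raw[2], "CC(C)O")
  expect_equal(out$cid[2], 11L)
  expect_match(out$resolver_note[2], "ambiguous")
  # unresolved stays unresolved, with a note
  expect_true(is.na(out$smiles_raw[3]))
  expect_equal(out$resolver_note[3], "unresolved")
})

test_that("fully-populated records pass through unchanged", {
  res <- resolver_offline(stub_table())
  rec <- tibble::tibble(
    source_id = "R1", row = 1L, compound_name = "ethanol",
    smiles_raw = "OCC", cid = 9999L, logbb = 0.1,
    label = NA_character_, threshold = NA_real_, reference = NA_character_
  )
  out <- resolve_missing(rec, res)
  expect_equal(out$compound_name, "ethanol")
  expect_equal(out$smiles_raw, "OCC")
  expect_equal(out$cid, 9999L)
})

test_that("the cache answers repeat queries without touching the inner resolver", {
  cache_file <- tempfile(fileext = ".tsv")
  warm <- resolver_cached(cache_file, inner = resolver_offline(stub_table()))
  first <- resolver_query(warm, "name", "ethanol")
  expect_equal(first$cid, 702L)
  miss <- resolver_query(warm, "name", "unknownol")
  expect_equal(nrow(miss), 0)

  # same cache, no inner resolver at all: identical answers, zero lookups
  cold <- resolver_cached(cache_file, inner = NULL)
  expect_equal(resolver_query(cold, "name", "ethanol"), first)
  expect_equal(nrow(resolver_query(cold, "name", "unknownol")), 0)
})

test_that("the merge key unifies resonance forms and separates enantiomers", {
  std <- standardize_molecules(c("CCO", "OCC", "C1=CC=CC=C1", "c1ccccc1",
                                 "C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O"))
  key <- make_key(std)
  expect_equal(key[1], key[2])
  expect_equal(key[3], key[4])   # kekule vs aromatic form
  expect_false(key[5] == key[6]) # enantiomers stay distinct
})

test_that("CIDs are refreshed from the standardized structure", {
  res <- resolver_offline(stub_table())
  mols <- tibble::tibble(smiles = c("CC(=O)O", "CCCCCCCCN"),
                         cid = c(999L, 5L))  # 999: the salt's CID
  out <- update_cid(mols, res)
  expect_equal(out$cid[1], 176L)
  expect_true(is.na(out$cid[2]))
  expect_match(out$cid_note[2], "not found")
  # consistent resolver makes the update idempotent
  again <- update_cid(out[, c("smiles", "cid")], res)
  expect_equal(again$cid, out$cid)
})

test_that("identity merging is invariant under record order", {
  rec <- tibble::tibble(
    source_id = sprintf("R%d", 1:6), row = 1:6,
    compound_name = NA_character_,
    smiles_raw = c("CCO", "OCC", "c1ccccc1", "C1=CC=CC=C1", "CCO", "CCN"),
    cid = NA_integer_,
    logbb = c(0.1, 0.2, 0.3, 0.4, 0.15, 0.5),
    label = NA_character_, threshold = NA_real_, reference = NA_character_
  )
  std <- standardize_molecules(rec$smiles_raw)
  sets1 <- build_measurement_sets(rec, std$inchi)
  perm <- c(4, 2, 6, 1, 5, 3)
  sets2 <- build_measurement_sets(rec[perm, ], std$inchi[perm])
  expect_setequal(sets1$inchi, sets2$inchi)
  for (k in sets1$inchi) {
    v1 <- sort(sets1$logbb_values[[which(sets1$inchi == k)]])
    v2 <- sort(sets2$logbb_values[[which(sets2$inchi == k)]])
    expect_equal(v1, v2)
  }
})
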