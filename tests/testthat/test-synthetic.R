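test_that("configuration validates its rates", {
  expect_error(synthetic_config(conflict_rate = 1.2), "rate out of")
  expect_error(synthetic_config(n_molecules = 0), "n_molecules")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_molecules = 30, seed = 123)
  g1 <- generate_synthetic(cfg)
  g2 <- generate_synthetic(cfg)
  expect_identical(g1$tables, g2$tables)
  expect_identical(g1$truth, g2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic(g1, d1); write_synthetic(g2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and the generator does not disturb the global RNG stream
  set.seed(5); before <- stats::runif(1)
  set.seed(5); invisible(generate_synthetic(cfg)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("a clean channel recovers the truth exactly", {
  run <- run_synthetic_pipeline(synthetic_config(
    n_molecules = 40, noise_sd = 0, outlier_rate = 0, conflict_rate = 0,
    whitespace_rate = 0, salt_rate = 0, charge_rate = 0,
    name_only_rate = 0, cid_only_rate = 0, seed = 2
  ))
  sc <- score_recovery(run$res$numeric, run$res$categorical, run$gen$truth)
  expect_equal(sc$identity_merge, 1)
  expect_equal(sc$numeric_group_recovery, 1)
  expect_equal(sc$value_agreement, 1)
  expect_equal(sc$categorical_group_recovery, 1)
  expect_equal(sc$label_recovery, 1)
  # with zero noise every numeric molecule has one unique value: group A
  expect_true(all(run$res$numeric$group == "A"))
})

test_that("forced outlier injection marks every numeric value implausible", {
  gen <- generate_synthetic(synthetic_config(
    n_molecules = 20, outlier_rate = 1, p_numeric = 1, seed = 4
  ))
  vals <- gen$records_truth$logBB
  expect_true(all(vals[!is.na(vals)] <= -9))
  expect_true(all(gen$records_truth$outlier[!is.na(vals)]))
  # the expected outcome is an all-outliers discard for every molecule
  expect_true(all(gen$truth$expected_discard == "all values outliers"))
})

test_that("label conflicts produce ties at the binomial rate", {
  gen <- generate_synthetic(synthetic_config(
    n_molecules = 300, conflict_rate = 0.5, p_numeric = 0,
    noise_sd = 0, whitespace_rate = 0, salt_rate = 0, charge_rate = 0,
    name_only_rate = 0, cid_only_rate = 0, threshold_report_rate = 1,
    seed = 8
  ))
  rt <- gen$records_truth
  two_rec <- gen$truth$mol_id[gen$truth$n_records == 2]
  tied <- vapply(two_rec, function(id) {
    labs <- rt$label[rt$mol_id == id]
    length(unique(labs)) == 2
  }, logical(1))
  # two sources, each flipped independently with p = 0.5:
  # P(exactly one flip) = 0.5
  expect_gt(length(tied), 50)
  expect_equal(mean(tied), 0.5, tolerance = 0.15)
  # and those molecules are recorded as expected label-tie discards
  exp_disc <- gen$truth$expected_discard[match(two_rec[tied], gen$truth$mol_id)]
  expect_true(all(grepl("label_tie", exp_disc)))
})

test_that("the literal grouping oracle reproduces its worked examples", {
  expect_equal(oracle_group(0.42), list(group = "A", value = 0.42))
  expect_true(is.na(oracle_group(c(0.1, 0.1, 0.3, 0.3, 0.5))$group))
  expect_equal(oracle_group(c(0.1, 0.1, 0.3))$value, (2 * 0.1 + 0.3) / 3,
               tolerance = 1e-12)
  expect_true(is.na(oracle_group(numeric(0))$group))
})

test_that("noisy-channel value recovery stays near the truth", {
  # noise sd 0.02 per record, reported at 2 decimals; for single-record
  # molecules about 1.3% land further than 0.05 log units from the truth,
  # so recovery sits just below 0.99 for this pinned seed (182/184).
  run <- run_synthetic_pipeline(synthetic_config(
    n_molecules = 200, noise_sd = 0.02, outlier_rate = 0, conflict_rate = 0,
    p_numeric = 1, whitespace_rate = 0, salt_rate = 0, charge_rate = 0,
    name_only_rate = 0, cid_only_rate = 0, seed = 1
  ))
  sc <- score_recovery(run$res$numeric, run$res$categorical, run$gen$truth)
  expect_equal(sc$value_agreement, 1)
  expect_equal(sc$value_recovery, 182 / 184, tolerance = 1e-9)
  expect_gt(sc$value_recovery, 0.97)
})

test_that("recovery degrades as the conflict rate grows", {
  frac_tied <- function(conflict) {
    gen <- generate_synthetic(synthetic_config(
      n_molecules = 150, conflict_rate = conflict, p_numeric = 0,
      whitespace_rate = 0, salt_rate = 0, charge_rate = 0,
      name_only_rate = 0, cid_only_rate = 0, seed = 31
    ))
    mean(!is.na(gen$truth$expected_discard))
  }
  rates <- vapply(c(0, 0.25, 0.5), frac_tied, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[1], 0)
})
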