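# Shared fixture builders. Everything is generated in code at test time;
# no binary or static fixture files.

write_csv_fixture <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

default_schema_map <- c(compound_name = "name", smiles_raw = "smiles",
                        cid = "cid", logbb = "logBB", label = "label",
                        threshold = "threshold", reference = "reference")

# Generate fixtures, run the full offline pipeline on them, return both.
run_synthetic_pipeline <- function(config, descriptor_provider = NULL,
                                   out_dir = tempfile("out"), verbose = FALSE) {
  gen <- generate_synthetic(config)
  dir <- tempfile("synth")
  write_synthetic(gen, dir)
  sources <- lapply(names(gen$tables), function(s) {
    list(path = file.path(dir, paste0(s, ".csv")), source_id = s,
         schema_map = gen$schema_map)
  })
  cfg <- run_config(sources, out_dir = out_dir,
                    resolver = resolver_offline(gen$resolver_table),
                    descriptor_provider = descriptor_provider,
                    verbose = verbose)
  res <- suppressMessages(run_pipeline(cfg))
  list(gen = gen, res = res, fixture_dir = dir, config = cfg)
}

# A small value alphabet (two-decimal grid) for curation property tests.
sample_value_list <- function(max_len = 6) {
  alphabet <- seq(-0.2, 0.2, by = 0.05)
  sample(alphabet, sample.int(max_len, 1), replace = TRUE)
}
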