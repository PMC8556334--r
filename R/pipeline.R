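# End-to-end workflow: ingest -> resolve -> standardize -> merge -> curate
# -> extend -> validate, driven by a single configuration object, with
# stage-count accounting (input = output + rejected at every stage).

#' Build a validated pipeline configuration
#'
#' @param sources List of source descriptions, each a list with `path`,
#'   `source_id`, and `schema_map` (named character vector, see
#'   [read_source_table()]).
#' @param out_dir Output directory for all artifacts.
#' @param resolver Resolver object (e.g. [resolver_offline()]), or `NULL`
#'   to skip registry lookups.
#' @param element_opts,curation_opts Named lists overriding the
#'   standardization and curation defaults (`max_z`, `exclude_metals`,
#'   `max_boron`; `outlier_cutoff`, `max_spread`, `tol`, `digits`,
#'   `threshold`).
#' @param descriptor_provider `"openbabel"` (default), `"mordred"`, or
#'   `NULL` to skip descriptor extension.
#' @param qc_parser Parser for the independent re-parse (`"rdkit"` default).
#' @param verbose Emit per-stage count messages (default `TRUE`).
#' @return A `run_config` list.
#' @export
run_config <- function(sources, out_dir, resolver = NULL,
                       element_opts = list(), curation_opts = list(),
                       descriptor_provider = "openbabel",
                       qc_parser = "rdkit", verbose = TRUE) {
  for (s in sources) {
    if (is.null(s$path) || is.null(s$source_id) || is.null(s$schema_map)) {
      stop("each source needs path, source_id and schema_map", call. = FALSE)
    }
    if (!file.exists(s$path)) {
      stop("configured source table does not exist: ", s$path, call. = FALSE)
    }
  }
  curation_defaults <- list(outlier_cutoff = -9, max_spread = 1, tol = 0.05,
                            digits = 2, threshold = -1)
  structure(list(
    sources = sources, out_dir = out_dir, resolver = resolver,
    element_opts = element_opts,
    curation_opts = utils::modifyList(curation_defaults, curation_opts),
    descriptor_provider = descriptor_provider,
    qc_parser = qc_parser, verbose = verbose
  ), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors [run_config()]: a `sources` list (each with `path`,
#' `source_id`, `schema_map`), `out_dir`, optional `element_opts` /
#' `curation_opts`, `descriptor_provider`, `qc_parser`, and a `resolver`
#' block (`mode`: `offline` with `table` TSV/CSV path, `cache` with `path`,
#' `live`, or `none`). Relative paths resolve against the YAML's directory.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  sources <- lapply(cfg$sources, function(s) {
    list(path = rel(s$path), source_id = s$source_id,
         schema_map = unlist(s$schema_map))
  })
  resolver <- NULL
  if (!is.null(cfg$resolver)) {
    mode <- cfg$resolver$mode %||% "none"
    resolver <- switch(mode,
      none = NULL,
      offline = {
        tab <- readr::read_tsv(rel(cfg$resolver$table),
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE, show_col_types = FALSE)
        resolver_offline(tab)
      },
      cache = resolver_cached(rel(cfg$resolver$path),
                              if (isTRUE(cfg$resolver$live)) resolver_pubchem()),
      live = resolver_pubchem(),
      stop("unknown resolver mode: ", mode, call. = FALSE)
    )
  }
  run_config(
    sources = sources,
    out_dir = rel(cfg$out_dir %||% "curated"),
    resolver = resolver,
    element_opts = cfg$element_opts %||% list(),
    curation_opts = cfg$curation_opts %||% list(),
    descriptor_provider = if (isFALSE(cfg$descriptor_provider)) NULL else
      cfg$descriptor_provider %||% "openbabel",
    qc_parser = cfg$qc_parser %||% "rdkit",
    verbose = cfg$verbose %||% TRUE
  )
}

#' Run the full curation workflow
#'
#' @param config A [run_config()].
#' @return List with `counts` (per-stage accounting), `numeric`,
#'   `categorical` (curated tibbles), `discards`, `rejects`, `qc`
#'   (the [qc_report()]), and `paths` (written artifacts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  copts <- config$curation_opts

  # -- ingest ---------------------------------------------------------------
  reads <- lapply(config$sources, function(s) {
    read_source_table(s$path, s$schema_map, s$source_id)
  })
  records <- dplyr::bind_rows(lapply(reads, `[[`, "records"))
  rejects <- dplyr::bind_rows(lapply(reads, `[[`, "rejects"))
  n_rows_in <- nrow(records) + nrow(rejects)
  stopifnot(n_rows_in == sum(vapply(reads, function(r) {
    nrow(r$records) + nrow(r$rejects)
  }, integer(1))))
  say("collected %d rows from %d sources (%d accepted, %d rejected)",
      n_rows_in, length(config$sources), nrow(records), nrow(rejects))
  consistency <- consistency_check(records)

  # -- resolve --------------------------------------------------------------
  if (!is.null(config$resolver)) {
    records <- resolve_missing(records, config$resolver)
  } else {
    records$iupac_name <- NA_character_
    records$resolver_note <- NA_character_
  }
  n_no_structure <- sum(is.na(records$smiles_raw))
  say("resolved identities: %d records still lack a structure", n_no_structure)

  # -- standardize ----------------------------------------------------------
  std <- standardize_molecules(
    ifelse(is.na(records$smiles_raw), "", records$smiles_raw),
    element_opts = config$element_opts
  )
  std$rejected_reason[is.na(records$smiles_raw)] <- "unresolvable"
  n_std_ok <- sum(is.na(std$rejected_reason))
  stopifnot(n_std_ok + sum(!is.na(std$rejected_reason)) == nrow(records))
  say("standardized structures: %d accepted, %d rejected",
      n_std_ok, nrow(records) - n_std_ok)
  std_rejects <- tibble::tibble(
    source_id = records$source_id[!is.na(std$rejected_reason)],
    row = records$row[!is.na(std$rejected_reason)],
    reason = std$rejected_reason[!is.na(std$rejected_reason)]
  )

  # -- merge ----------------------------------------------------------------
  sets <- build_measurement_sets(records, std$inchi)
  say("merged into %d unique molecular identities", nrow(sets))

  # -- curate ---------------------------------------------------------------
  num <- curate_numeric(sets, outlier_cutoff = copts$outlier_cutoff,
                        max_spread = copts$max_spread, tol = copts$tol,
                        digits = copts$digits)
  cat_ <- curate_categorical(sets, num$records, threshold = copts$threshold)
  discards <- dplyr::bind_rows(
    dplyr::mutate(num$discards, track = "numeric"),
    dplyr::mutate(cat_$discards, track = "categorical")
  )
  say("curated: %d numeric records, %d categorical records, %d discards",
      nrow(num$records), nrow(cat_$records), nrow(discards))

  # -- assemble output rows -------------------------------------------------
  ident <- molecule_identity_table(records, std, config$resolver)
  numeric_rows <- assemble_curated_rows(num$records, ident, track = "numeric",
                                        threshold = copts$threshold)
  categorical_rows <- assemble_curated_rows(cat_$records, ident,
                                            track = "categorical",
                                            threshold = copts$threshold)

  paths <- list(
    numeric = file.path(config$out_dir, "curated_numeric.csv"),
    categorical = file.path(config$out_dir, "curated_categorical.csv"),
    rejects = file.path(config$out_dir, "rejects.csv"),
    discards = file.path(config$out_dir, "discards.csv"),
    consistency = file.path(config$out_dir, "consistency_report.json"),
    qc = file.path(config$out_dir, "qc_report.json")
  )
  write_curated(numeric_rows, paths$numeric, "numeric")
  write_curated(categorical_rows, paths$categorical, "categorical")
  write_rejects(dplyr::bind_rows(rejects, std_rejects), paths$rejects)
  readr::write_csv(discards, paths$discards, na = "", progress = FALSE)
  cons_ser <- consistency
  cons_ser$duplicates <- as.data.frame(cons_ser$duplicates)
  jsonlite::write_json(cons_ser, paths$consistency, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")

  # -- extend ---------------------------------------------------------------
  profiles <- NULL
  if (!is.null(config$descriptor_provider)) {
    uniq <- categorical_rows[!duplicated(categorical_rows$inchi), ]
    block <- compute_descriptors(uniq, provider = config$descriptor_provider)
    ext_num <- extend_with_descriptors(numeric_rows, block)
    ext_cat <- extend_with_descriptors(categorical_rows, block)
    paths$numeric_extended <- file.path(config$out_dir, "curated_numeric_extended.csv")
    paths$categorical_extended <- file.path(config$out_dir, "curated_categorical_extended.csv")
    readr::write_csv(ext_num, paths$numeric_extended, na = "", progress = FALSE)
    readr::write_csv(ext_cat, paths$categorical_extended, na = "", progress = FALSE)
    say("extended with %d descriptors (provider %s)", length(block$names),
        block$provider)
    profiles <- ro5_profile(categorical_rows$smiles)
  }

  # -- validate -------------------------------------------------------------
  qc <- qc_report(numeric_rows, categorical_rows, profiles = profiles,
                  labels = if (!is.null(profiles)) categorical_rows$label,
                  parser = config$qc_parser, json_path = paths$qc)
  say("parse validity (%s): %.4f over %d structures", qc$parse_valid$parser,
      qc$parse_valid$parse_valid_fraction, qc$parse_valid$n)

  list(
    counts = list(
      rows_in = n_rows_in, records = nrow(records),
      ingest_rejects = nrow(rejects),
      standardized = n_std_ok,
      standardization_rejects = nrow(std_rejects),
      identities = nrow(sets),
      numeric = nrow(num$records), categorical = nrow(cat_$records),
      discards = nrow(discards)
    ),
    consistency = consistency,
    numeric = numeric_rows, categorical = categorical_rows,
    discards = discards,
    rejects = dplyr::bind_rows(rejects, std_rejects),
    qc = qc, paths = paths
  )
}

# Representative identity fields (name, IUPAC name, CID, canonical SMILES)
# for each InChI, taken from the first record carrying each; CIDs are
# refreshed from the standardized SMILES when a resolver is available.
molecule_identity_table <- function(records, std, resolver) {
  keep <- !is.na(std$inchi)
  df <- tibble::tibble(
    inchi = std$inchi[keep],
    smiles = std$smiles[keep],
    compound_name = records$compound_name[keep],
    iupac_name = records$iupac_name[keep],
    cid = records$cid[keep],
    std_comment = std$comment[keep],
    resolver_note = records$resolver_note[keep]
  )
  first_non_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[1] else NA
  }
  ident <- df |>
    dplyr::group_by(.data$inchi) |>
    dplyr::summarise(
      smiles = first_non_na(.data$smiles),
      compound_name = first_non_na(.data$compound_name),
      iupac_name = first_non_na(.data$iupac_name),
      cid = first_non_na(.data$cid),
      std_comment = first_non_na(.data$std_comment),
      resolver_note = first_non_na(.data$resolver_note),
      .groups = "drop"
    )
  if (!is.null(resolver)) ident <- update_cid(ident, resolver)
  ident
}

assemble_curated_rows <- function(curated, ident, track, threshold = -1) {
  idx <- match(curated$inchi, ident$inchi)
  comment <- curated$comment
  extra <- function(cur, add) ifelse(
    is.na(add), cur, ifelse(is.na(cur), add, paste(cur, add, sep = "; "))
  )
  comment <- extra(comment, ident$std_comment[idx])
  note <- ident$resolver_note[idx]
  note[!is.na(note) & note == "unresolved"] <- NA
  comment <- extra(comment, note)
  out <- tibble::tibble(
    compound_name = ident$compound_name[idx],
    iupac_name = ident$iupac_name[idx],
    smiles = ident$smiles[idx],
    cid = as.character(ident$cid[idx]),
    inchi = curated$inchi,
    reference = curated$sources,
    group = curated$group,
    comment = comment
  )
  if (track == "numeric") {
    out$logbb <- curated$logbb
    out$n_values <- curated$n_values
    out$n_unique <- curated$n_unique
  } else {
    out$logbb <- NA_real_
    out$label <- curated$label
    out$threshold <- curated$threshold_used
    out$n_labels <- curated$n_labels
    out$n_unique_labels <- curated$n_unique_labels
  }
  out
}
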