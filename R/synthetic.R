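# Synthetic fixture generation with known ground truth.
#
# The generator emulates the heterogeneity of multi-source permeability
# tables: per-molecule record multiplicity, measurement noise on log BB,
# injected outliers, label conflicts, salt/charge/whitespace corruption of
# SMILES, missing-field patterns (name-only / CID-only rows), and
# present-or-absent threshold metadata. Every corruption is logged in the
# truth table, and the expected curation outcome is recomputed from the
# generated records with oracle_group() -- a literal, independent
# restatement of the grouping rules -- so end-to-end recovery is scorable.

#' Built-in library of simple valid structures
#'
#' Fifty hand-listed organics (alkanes, alcohols, acids, aromatics,
#' heterocycles, amino acids including one enantiomer pair), each with an
#' optional salt form and charged form used by the corruption machinery.
#' All identifiers (CIDs, names) are synthetic.
#'
#' @return Tibble: `name`, `smiles` (clean), `salt_form`, `charged_form`,
#'   `cid` (synthetic), `iupac_name` (synthetic).
#' @export
molecule_library <- function() {
  lib <- tibble::tribble(
    ~name,                 ~smiles,                          ~salt_form,                  ~charged_form,
    "ethanol",             "CCO",                            NA,                          NA,
    "propan-1-ol",         "CCCO",                           NA,                          NA,
    "propan-2-ol",         "CC(C)O",                         NA,                          NA,
    "acetone",             "CC(C)=O",                        NA,                          NA,
    "acetic acid",         "CC(=O)O",                        "CC(=O)[O-].[Na+]",          "CC(=O)[O-]",
    "propanoic acid",      "CCC(=O)O",                       "CCC(=O)[O-].[Na+]",         "CCC(=O)[O-]",
    "butanoic acid",       "CCCC(=O)O",                      NA,                          "CCCC(=O)[O-]",
    "benzene",             "c1ccccc1",                       NA,                          NA,
    "toluene",             "Cc1ccccc1",                      NA,                          NA,
    "phenol",              "Oc1ccccc1",                      NA,                          NA,
    "aniline",             "Nc1ccccc1",                      "Cl.Nc1ccccc1",              "[NH3+]c1ccccc1",
    "pyridine",            "c1ccncc1",                       "Cl.c1ccncc1",               NA,
    "benzoic acid",        "OC(=O)c1ccccc1",                 "[O-]C(=O)c1ccccc1.[Na+]",   "[O-]C(=O)c1ccccc1",
    "naphthalene",         "c1ccc2ccccc2c1",                 NA,                          NA,
    "furan",               "c1ccoc1",                        NA,                          NA,
    "thiophene",           "c1ccsc1",                        NA,                          NA,
    "pyrrole",             "c1cc[nH]c1",                     NA,                          NA,
    "imidazole",           "c1c[nH]cn1",                     NA,                          NA,
    "pyrimidine",          "c1cncnc1",                       NA,                          NA,
    "quinoline",           "c1ccc2ncccc2c1",                 NA,                          NA,
    "indole",              "c1ccc2[nH]ccc2c1",               NA,                          NA,
    "glycine",             "NCC(=O)O",                       NA,                          "[NH3+]CC(=O)[O-]",
    "L-alanine",           "C[C@H](N)C(=O)O",                NA,                          "C[C@H]([NH3+])C(=O)[O-]",
    "D-alanine",           "C[C@@H](N)C(=O)O",               NA,                          "C[C@@H]([NH3+])C(=O)[O-]",
    "L-serine",            "OC[C@H](N)C(=O)O",               NA,                          NA,
    "cyclohexane",         "C1CCCCC1",                       NA,                          NA,
    "cyclohexanol",        "OC1CCCCC1",                      NA,                          NA,
    "anisole",             "COc1ccccc1",                     NA,                          NA,
    "benzaldehyde",        "O=Cc1ccccc1",                    NA,                          NA,
    "acetophenone",        "CC(=O)c1ccccc1",                 NA,                          NA,
    "ethylamine",          "CCN",                            "Cl.CCN",                    "CC[NH3+]",
    "dimethylamine",       "CNC",                            "Cl.CNC",                    "C[NH2+]C",
    "trimethylamine",      "CN(C)C",                         NA,                          "C[NH+](C)C",
    "diethyl ether",       "CCOCC",                          NA,                          NA,
    "tetrahydrofuran",     "C1CCOC1",                        NA,                          NA,
    "1,4-dioxane",         "C1COCCO1",                       NA,                          NA,
    "morpholine",          "C1COCCN1",                       "Cl.C1COCCN1",               NA,
    "piperidine",          "C1CCNCC1",                       "Cl.C1CCNCC1",               NA,
    "piperazine",          "C1CNCCN1",                       NA,                          NA,
    "urea",                "NC(N)=O",                        NA,                          NA,
    "acetamide",           "CC(N)=O",                        NA,                          NA,
    "paracetamol",         "CC(=O)Nc1ccc(O)cc1",             NA,                          NA,
    "benzamide",           "NC(=O)c1ccccc1",                 NA,                          NA,
    "catechol",            "Oc1ccccc1O",                     NA,                          NA,
    "resorcinol",          "Oc1cccc(O)c1",                   NA,                          NA,
    "chlorobenzene",       "Clc1ccccc1",                     NA,                          NA,
    "fluorobenzene",       "Fc1ccccc1",                      NA,                          NA,
    "acetonitrile",        "CC#N",                           NA,                          NA,
    "ethylene glycol",     "OCCO",                           NA,                          NA,
    "lactic acid",         "CC(O)C(=O)O",                    NA,                          NA
  )
  lib$cid <- 100000L + seq_len(nrow(lib))
  lib$iupac_name <- paste0("synthetic-iupac-", gsub("[^a-z0-9]+", "-", tolower(lib$name)))
  lib
}

# Homolog series used when more distinct structures are requested than the
# hand list holds. Chains start at length 5 so no homolog collides with a
# library molecule's identity.
homolog_structures <- function(n_extra) {
  series <- c(alcohol = "O", acid = "C(=O)O", amine = "N",
              nitrile = "C#N", thiol = "S", `methyl ether` = "OC")
  out <- vector("list", n_extra)
  k <- 5L
  i <- 0L
  while (i < n_extra) {
    for (s in seq_along(series)) {
      if (i >= n_extra) break
      i <- i + 1L
      out[[i]] <- tibble::tibble(
        name = sprintf("%s homolog C%d", names(series)[s], k),
        smiles = paste0(strrep("C", k), series[[s]]),
        salt_form = NA_character_, charged_form = NA_character_
      )
    }
    k <- k + 1L
  }
  res <- dplyr::bind_rows(out)
  res$cid <- 200000L + seq_len(nrow(res))
  res$iupac_name <- paste0("synthetic-iupac-", gsub("[^a-z0-9]+", "-", tolower(res$name)))
  res
}

#' Configuration for the synthetic fixture generator
#'
#' Defaults model the study conditions the curation rules were designed
#' for: a truncated-Poisson record multiplicity (mean 2, max 23), log BB
#' noise of 0.02 log units, a true log BB distribution concentrated on
#' \[-2, 2\] (normal mixture at 0.0 and -1.2, sd 0.5), and the -1 label
#' threshold.
#'
#' @param n_molecules Number of distinct molecules (>= 1).
#' @param record_count_mean,record_count_max Truncated-Poisson parameters
#'   for per-molecule record counts (defaults 2 and 23; minimum 1).
#' @param noise_sd Gaussian noise on reported log BB, in log units.
#' @param outlier_rate Probability a numeric record is replaced by an
#'   implausible value <= -9.
#' @param conflict_rate Probability a categorical source flips the true
#'   label.
#' @param p_numeric Probability a record is numeric rather than
#'   categorical.
#' @param whitespace_rate,salt_rate,charge_rate Probabilities of SMILES
#'   corruption per record (whitespace insertion; salt form; charged form;
#'   the latter two apply only to molecules with such variants).
#' @param name_only_rate,cid_only_rate Probabilities a record omits all
#'   structure fields but its name / its CID.
#' @param threshold_report_rate Probability a categorical source reports
#'   its threshold.
#' @param n_sources Number of synthetic sources records are spread over.
#' @param logbb_mix_means,logbb_mix_sd True log BB mixture parameters.
#' @param threshold Label threshold (default -1).
#' @param report_digits Decimal places at which sources report log BB
#'   (default 2, the typical literature precision; aligned with the
#'   distinctness rounding used in curation).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_molecules = 100,
                             record_count_mean = 2, record_count_max = 23,
                             noise_sd = 0.02, outlier_rate = 0.02,
                             conflict_rate = 0.05, p_numeric = 0.3,
                             whitespace_rate = 0.05, salt_rate = 0.05,
                             charge_rate = 0.05, name_only_rate = 0.05,
                             cid_only_rate = 0.05,
                             threshold_report_rate = 0.6, n_sources = 12,
                             logbb_mix_means = c(0, -1.2), logbb_mix_sd = 0.5,
                             threshold = -1, report_digits = 2, seed = 1L) {
  cfg <- as.list(environment())
  rates <- c("noise_sd", "outlier_rate", "conflict_rate", "p_numeric",
             "whitespace_rate", "salt_rate", "charge_rate", "name_only_rate",
             "cid_only_rate", "threshold_report_rate")
  for (r in setdiff(rates, "noise_sd")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop("rate out of [0,1]: ", r, call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$n_molecules < 1) stop("n_molecules must be >= 1", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

insert_whitespace <- function(s) {
  if (nchar(s) < 2L) return(paste0(s, " "))
  pos <- sample(nchar(s) - 1L, 1L)
  paste0(substr(s, 1, pos), " ", substring(s, pos + 1L))
}

#' Generate messy multi-source fixtures with known ground truth
#'
#' @param config A [synthetic_config()].
#' @return List:
#'   * `tables`: named list of per-source tibbles in the ingest schema
#'     (`name`, `smiles`, `cid`, `logBB`, `label`, `threshold`,
#'     `reference`);
#'   * `schema_map`: the schema map that reads those tables;
#'   * `truth`: per-molecule tibble with the clean structure, true and
#'     expected values/labels/groups, and corruption bookkeeping;
#'   * `records_truth`: per-record tibble logging every applied corruption;
#'   * `resolver_table`: offline registry table covering all molecules.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_synthetic_impl(config))
}

generate_synthetic_impl <- function(cfg) {
  lib <- molecule_library()
  if (cfg$n_molecules > nrow(lib)) {
    lib <- dplyr::bind_rows(lib, homolog_structures(cfg$n_molecules - nrow(lib)))
  }
  mols <- lib[sample(nrow(lib), cfg$n_molecules), , drop = FALSE]
  mols$mol_id <- seq_len(nrow(mols))

  comp <- sample(length(cfg$logbb_mix_means), cfg$n_molecules, replace = TRUE)
  mols$true_logbb <- stats::rnorm(cfg$n_molecules,
                                  mean = cfg$logbb_mix_means[comp],
                                  sd = cfg$logbb_mix_sd)
  mols$true_label <- label_from_logbb(mols$true_logbb, cfg$threshold)
  mols$n_records <- pmin(pmax(stats::rpois(cfg$n_molecules,
                                           cfg$record_count_mean), 1L),
                         cfg$record_count_max)

  recs <- vector("list", cfg$n_molecules)
  for (i in seq_len(cfg$n_molecules)) {
    m <- mols$n_records[i]
    numeric_rec <- stats::runif(m) < cfg$p_numeric
    value <- rep(NA_real_, m)
    label <- rep(NA_character_, m)
    thr <- rep(NA_real_, m)
    outlier <- logical(m)
    flipped <- logical(m)
    for (j in seq_len(m)) {
      if (numeric_rec[j]) {
        if (stats::runif(1) < cfg$outlier_rate) {
          value[j] <- round(stats::runif(1, -15, -9.01), cfg$report_digits)
          outlier[j] <- TRUE
        } else {
          v <- mols$true_logbb[i] +
            if (cfg$noise_sd > 0) stats::rnorm(1, 0, cfg$noise_sd) else 0
          # sources report log BB at finite precision; quantize accordingly
          value[j] <- round(v, cfg$report_digits)
        }
      } else {
        flipped[j] <- stats::runif(1) < cfg$conflict_rate
        lab <- mols$true_label[i]
        if (flipped[j]) lab <- if (lab == "BBB+") "BBB-" else "BBB+"
        label[j] <- lab
        if (stats::runif(1) < cfg$threshold_report_rate) thr[j] <- cfg$threshold
      }
    }
    smiles <- rep(mols$smiles[i], m)
    corruption <- rep("none", m)
    for (j in seq_len(m)) {
      if (stats::runif(1) < cfg$salt_rate && !is.na(mols$salt_form[i])) {
        smiles[j] <- mols$salt_form[i]
        corruption[j] <- "salt"
      } else if (stats::runif(1) < cfg$charge_rate && !is.na(mols$charged_form[i])) {
        smiles[j] <- mols$charged_form[i]
        corruption[j] <- "charge"
      }
      if (stats::runif(1) < cfg$whitespace_rate) {
        smiles[j] <- insert_whitespace(smiles[j])
        corruption[j] <- paste0(corruption[j], "+whitespace")
      }
    }
    name <- rep(mols$name[i], m)
    cid <- rep(mols$cid[i], m)
    omission <- rep("none", m)
    for (j in seq_len(m)) {
      u <- stats::runif(1)
      if (u < cfg$name_only_rate) {
        smiles[j] <- NA_character_
        cid[j] <- NA_integer_
        omission[j] <- "name_only"
      } else if (u < cfg$name_only_rate + cfg$cid_only_rate) {
        smiles[j] <- NA_character_
        name[j] <- NA_character_
        omission[j] <- "cid_only"
      }
    }
    recs[[i]] <- tibble::tibble(
      mol_id = mols$mol_id[i], name = name, smiles = smiles, cid = cid,
      logBB = value, label = label, threshold = thr,
      corruption = corruption, omission = omission,
      outlier = outlier, flipped = flipped,
      source = sample(sprintf("S%02d", seq_len(cfg$n_sources)), m, replace = TRUE)
    )
  }
  records <- dplyr::bind_rows(recs)
  records$reference <- paste0("synthetic source ", records$source)

  # Expected curation outcome, from the literal rule definitions.
  mols$expected_numeric_group <- NA_character_
  mols$expected_logbb <- NA_real_
  mols$expected_cat_group <- NA_character_
  mols$expected_label <- NA_character_
  mols$expected_discard <- NA_character_
  for (i in seq_len(nrow(mols))) {
    mr <- records[records$mol_id == mols$mol_id[i], , drop = FALSE]
    vals <- mr$logBB[!is.na(mr$logBB)]
    surviving <- vals[vals > -9]
    if (length(vals)) {
      if (!length(surviving)) {
        mols$expected_discard[i] <- "all values outliers"
      } else if (max(surviving) - min(surviving) > 1) {
        mols$expected_discard[i] <- "value spread > 1"
      } else {
        g <- oracle_group(surviving)
        if (is.na(g$group)) {
          mols$expected_discard[i] <- "numeric modal_tie"
        } else {
          mols$expected_numeric_group[i] <- g$group
          mols$expected_logbb[i] <- g$value
        }
      }
    }
    if (!is.na(mols$expected_numeric_group[i])) {
      mols$expected_cat_group[i] <- "A"
      mols$expected_label[i] <- label_from_logbb(mols$expected_logbb[i], cfg$threshold)
    } else {
      labs <- mr$label[!is.na(mr$label)]
      thrs <- mr$threshold[!is.na(mr$label)]
      if (length(labs)) {
        g <- assign_categorical_group(labs, thrs, NA_real_, cfg$threshold)
        if (is.na(g$group)) {
          mols$expected_discard[i] <- paste(
            stats::na.omit(c(mols$expected_discard[i], "categorical label_tie")),
            collapse = "; ")
        } else {
          mols$expected_cat_group[i] <- g$group
          mols$expected_label[i] <- g$label
        }
      }
    }
  }

  tables <- lapply(split(records, records$source), function(df) {
    df[, c("name", "smiles", "cid", "logBB", "label", "threshold", "reference")]
  })

  resolver_table <- dplyr::bind_rows(
    tibble::tibble(query_type = "name", query = lib$name, cid = lib$cid,
                   smiles = lib$smiles, name = lib$name,
                   iupac_name = lib$iupac_name),
    tibble::tibble(query_type = "cid", query = as.character(lib$cid),
                   cid = lib$cid, smiles = lib$smiles, name = lib$name,
                   iupac_name = lib$iupac_name),
    tibble::tibble(query_type = "smiles", query = lib$smiles, cid = lib$cid,
                   smiles = lib$smiles, name = lib$name,
                   iupac_name = lib$iupac_name)
  )

  list(
    tables = tables,
    schema_map = c(compound_name = "name", smiles_raw = "smiles", cid = "cid",
                   logbb = "logBB", label = "label", threshold = "threshold",
                   reference = "reference"),
    truth = tibble::as_tibble(mols),
    records_truth = records,
    resolver_table = resolver_table,
    config = cfg
  )
}

#' Write generated fixtures to disk
#'
#' Emits one CSV per synthetic source (ingest schema), the resolver table
#' (TSV) and the truth table (JSON).
#'
#' @param gen Output of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_synthetic <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (src in names(gen$tables)) {
    p <- file.path(dir, paste0(src, ".csv"))
    readr::write_csv(gen$tables[[src]], p, na = "", progress = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "resolver.tsv")
  readr::write_tsv(gen$resolver_table, p, progress = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "truth.json")
  jsonlite::write_json(gen$truth, p, auto_unbox = FALSE, digits = NA, na = "null")
  paths <- c(paths, p)
  invisible(paths)
}

#' Literal restatement of the numeric grouping rules (test oracle)
#'
#' An independent brute-force application of the A/B/C/D definitions, coded
#' separately from [assign_numeric_group()] so the two can be compared on
#' random inputs. Intended for value lists drawn from a small,
#' two-decimal alphabet.
#'
#' @param values Numeric vector (post-filter).
#' @param tol Group-B relative tolerance (default 0.05).
#' @param digits Rounding used to judge distinctness (default 2).
#' @return List with `group` (`NA` on discard) and `value`.
#' @export
oracle_group <- function(values, tol = 0.05, digits = 2) {
  if (length(values) == 0L) return(list(group = NA_character_, value = NA_real_))
  rounded <- round(values, digits)
  distinct <- sort(unique(rounded))
  # A: only one unique value
  if (length(distinct) == 1L) {
    return(list(group = "A", value = sum(values) / length(values)))
  }
  # B: every reported value differs from the mean by at most tol * |mean|
  mean_value <- sum(values) / length(values)
  if (abs(mean_value) >= 1e-8 &&
      max(abs(values - mean_value)) / abs(mean_value) <= tol) {
    return(list(group = "B", value = mean_value))
  }
  # C: exactly two distinct values -> mean weighted by multiplicity
  if (length(distinct) == 2L) {
    w <- vapply(distinct, function(d) sum(rounded == d), numeric(1))
    return(list(group = "C", value = sum(w * distinct) / sum(w)))
  }
  # D: mode of the distinct values; a tie for the mode discards
  freq <- vapply(distinct, function(d) sum(rounded == d), numeric(1))
  winners <- distinct[freq == max(freq)]
  if (length(winners) > 1L) return(list(group = NA_character_, value = NA_real_))
  list(group = "D", value = winners)
}

#' Score end-to-end recovery of the generator's ground truth
#'
#' @param numeric_records,categorical_records Curated outputs produced from
#'   the generated tables.
#' @param truth The generator's `truth` tibble.
#' @param tol Log-unit tolerance for value recovery against the true log BB
#'   (default 0.05).
#' @return List of fractions: `identity_merge` (expected molecules that
#'   appear exactly once), `numeric_group_recovery`, `value_agreement`
#'   (exact agreement with the expected consensus), `value_recovery`
#'   (within `tol` of the *true* log BB), `categorical_group_recovery`,
#'   `label_recovery`, plus `mismatches` (tibble) and counts.
#' @export
score_recovery <- function(numeric_records, categorical_records, truth,
                           tol = 0.05) {
  truth$inchi <- smiles_to_inchi(truth$smiles)
  mism <- list()

  exp_num <- truth[!is.na(truth$expected_numeric_group), , drop = FALSE]
  ni <- match(exp_num$inchi, numeric_records$inchi)
  merged_once_num <- !is.na(ni) &
    vapply(exp_num$inchi, function(k) sum(numeric_records$inchi == k) == 1L,
           logical(1))
  group_ok <- !is.na(ni) & numeric_records$group[ni] == exp_num$expected_numeric_group
  value_ok <- !is.na(ni) &
    abs(numeric_records$logbb[ni] - exp_num$expected_logbb) < 1e-9
  value_near_truth <- !is.na(ni) &
    abs(numeric_records$logbb[ni] - exp_num$true_logbb) <= tol
  if (any(!group_ok | !value_ok, na.rm = TRUE)) {
    bad <- which(!group_ok | !value_ok)
    mism[[length(mism) + 1L]] <- tibble::tibble(
      track = "numeric", name = exp_num$name[bad], inchi = exp_num$inchi[bad])
  }

  exp_cat <- truth[!is.na(truth$expected_cat_group), , drop = FALSE]
  ci <- match(exp_cat$inchi, categorical_records$inchi)
  merged_once_cat <- !is.na(ci) &
    vapply(exp_cat$inchi, function(k) sum(categorical_records$inchi == k) == 1L,
           logical(1))
  cgroup_ok <- !is.na(ci) &
    categorical_records$group[ci] == exp_cat$expected_cat_group
  label_ok <- !is.na(ci) &
    categorical_records$label[ci] == exp_cat$expected_label
  if (any(!cgroup_ok | !label_ok, na.rm = TRUE)) {
    bad <- which(!cgroup_ok | !label_ok)
    mism[[length(mism) + 1L]] <- tibble::tibble(
      track = "categorical", name = exp_cat$name[bad], inchi = exp_cat$inchi[bad])
  }

  frac <- function(x) if (length(x)) mean(x) else NA_real_
  list(
    n_expected_numeric = nrow(exp_num),
    n_expected_categorical = nrow(exp_cat),
    identity_merge = frac(c(merged_once_num, merged_once_cat)),
    numeric_group_recovery = frac(group_ok),
    value_agreement = frac(value_ok),
    value_recovery = frac(value_near_truth),
    categorical_group_recovery = frac(cgroup_ok),
    label_recovery = frac(label_ok),
    mismatches = dplyr::bind_rows(mism)
  )
}
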