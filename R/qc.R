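# Technical-validation analytics: cross-toolkit parse validity,
# redundancy/multiplicity cross-tabulations, distribution summaries, and
# recounts over curated CSVs.

#' Re-validate curated SMILES with an independent parser
#'
#' Every curated structure is re-parsed with a second, independent parser
#' backend -- by default RDKit through a python subprocess, which shares no
#' code with the OpenBabel backend used for cleaning. This catches dialect
#' assumptions a single-toolkit pipeline cannot see.
#'
#' @param rows Curated tibble with a `smiles` column, or a character vector
#'   of SMILES.
#' @param parser `"rdkit"` (default) or `"openbabel"`.
#' @return List: `parse_valid_fraction` (NA for empty input), `n`,
#'   `failures` (tibble of offending SMILES with their row index), and
#'   `parser`.
#' @export
validate_parse <- function(rows, parser = c("rdkit", "openbabel")) {
  parser <- match.arg(parser)
  smiles <- if (is.character(rows)) rows else rows$smiles
  n <- length(smiles)
  if (n == 0L) {
    return(list(parse_valid_fraction = NA_real_, n = 0L,
                failures = tibble::tibble(row = integer(0), smiles = character(0)),
                parser = parser))
  }
  ok <- switch(parser,
    openbabel = smiles_is_valid(smiles),
    rdkit = rdkit_parse_ok(smiles)
  )
  ok[is.na(smiles)] <- FALSE
  list(
    parse_valid_fraction = mean(ok),
    n = n,
    failures = tibble::tibble(row = which(!ok), smiles = smiles[!ok]),
    parser = parser
  )
}

rdkit_parse_ok <- function(smiles) {
  py <- python_binary()
  if (!nzchar(py)) {
    stop("validate_parse(parser = 'rdkit') needs a python interpreter with ",
         "rdkit on PATH", call. = FALSE)
  }
  script <- '
import sys
from rdkit import Chem
from rdkit import RDLogger
RDLogger.DisableLog("rdApp.*")
for line in open(sys.argv[1]):
    s = line.rstrip("\\n")
    print(1 if (s and Chem.MolFromSmiles(s) is not None) else 0)
'
  infile <- tempfile(fileext = ".smi")
  scriptfile <- tempfile(fileext = ".py")
  on.exit(unlink(c(infile, scriptfile)), add = TRUE)
  writeLines(ifelse(is.na(smiles), "", smiles), infile)
  writeLines(script, scriptfile)
  out <- system2(py, c(scriptfile, infile), stdout = TRUE, stderr = FALSE)
  if (length(out) != length(smiles)) {
    stop("rdkit parse validation returned ", length(out), " results for ",
         length(smiles), " inputs", call. = FALSE)
  }
  out == "1"
}

#' Multiplicity cross-tabulations of the curated datasets
#'
#' Reproduces the redundancy analysis: how many source measurements (and how
#' many unique measurements) back each curated molecule, broken out by
#' reliability group.
#'
#' @param numeric_records Curated numeric tibble (`group`, `n_values`,
#'   `n_unique` columns).
#' @param categorical_records Curated categorical tibble (`group`,
#'   `n_labels`, `n_unique_labels`).
#' @return List of four tibbles (`group`, `multiplicity`, `n`):
#'   `numeric_source`, `numeric_unique`, `categorical_source`,
#'   `categorical_unique`. Counts in each table sum to the corresponding
#'   dataset size.
#' @export
multiplicity_tables <- function(numeric_records, categorical_records) {
  xtab <- function(df, group_col, mult_col) {
    if (!nrow(df)) {
      return(tibble::tibble(group = character(0), multiplicity = integer(0),
                            n = integer(0)))
    }
    out <- dplyr::count(df, group = .data[[group_col]],
                        multiplicity = .data[[mult_col]], name = "n")
    dplyr::arrange(out, .data$multiplicity, .data$group)
  }
  list(
    numeric_source = xtab(numeric_records, "group", "n_values"),
    numeric_unique = xtab(numeric_records, "group", "n_unique"),
    categorical_source = xtab(categorical_records, "group", "n_labels"),
    categorical_unique = xtab(categorical_records, "group", "n_unique_labels")
  )
}

#' Distribution summaries of the curated data
#'
#' @param numeric_records Curated numeric tibble with a `logbb` column.
#' @param profiles Optional [ro5_profile()] tibble for per-class summaries.
#' @param labels Optional class labels aligned with `profiles`.
#' @param binwidth,range Histogram bin width and range for log BB
#'   (defaults 0.25 over \[-3, 2\]; values outside the range land in the
#'   open edge bins).
#' @return List: `histogram` (tibble `bin_lo`, `bin_hi`, `n`),
#'   `fraction_in_minus2_2`, `median_logbb`, and `class_summaries` (per
#'   class: median/mean of MW, HBD, HBA, logP) when profiles are given.
#' @export
summarize_distributions <- function(numeric_records, profiles = NULL,
                                    labels = NULL, binwidth = 0.25,
                                    range = c(-3, 2)) {
  v <- numeric_records$logbb
  v <- v[!is.na(v)]
  breaks <- seq(range[1], range[2], by = binwidth)
  clamped <- pmin(pmax(v, range[1]), range[2] - binwidth / 2)
  bin <- findInterval(clamped, breaks, rightmost.closed = TRUE)
  hist <- tibble::tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    n = vapply(seq_len(length(breaks) - 1L),
               function(b) sum(bin == b), integer(1))
  )
  out <- list(
    histogram = hist,
    fraction_in_minus2_2 = if (length(v)) mean(v >= -2 & v <= 2) else NA_real_,
    median_logbb = if (length(v)) stats::median(v) else NA_real_,
    binwidth = binwidth,
    range = range
  )
  if (!is.null(profiles) && !is.null(labels)) {
    cls <- list()
    for (lab in sort(unique(stats::na.omit(labels)))) {
      in_class <- !is.na(labels) & labels == lab
      if (!any(in_class)) next
      cls[[length(cls) + 1L]] <- tibble::tibble(
        label = lab, n = sum(in_class),
        mw_median = stats::median(profiles$mw[in_class], na.rm = TRUE),
        hbd_median = stats::median(profiles$hbd[in_class], na.rm = TRUE),
        hba_median = stats::median(profiles$hba[in_class], na.rm = TRUE),
        logp_median = stats::median(profiles$logp[in_class], na.rm = TRUE)
      )
    }
    out$class_summaries <- dplyr::bind_rows(cls)
  }
  out
}

#' Assemble and optionally serialize the full QC report
#'
#' @param numeric_records,categorical_records Curated tibbles.
#' @param profiles,labels Optional Rule-of-5 profiles and class labels.
#' @param parser Parser backend for the independent re-parse.
#' @param json_path Optional path; when given the report is written as JSON.
#' @return A `qc_report` list: `parse_valid` (both tracks),
#'   `multiplicity`, `distributions`, `ro5_fractions`.
#' @export
qc_report <- function(numeric_records, categorical_records, profiles = NULL,
                      labels = NULL, parser = "rdkit", json_path = NULL) {
  all_smiles <- unique(c(numeric_records$smiles, categorical_records$smiles))
  all_smiles <- all_smiles[!is.na(all_smiles)]
  report <- list(
    parse_valid = validate_parse(all_smiles, parser = parser),
    multiplicity = multiplicity_tables(numeric_records, categorical_records),
    distributions = summarize_distributions(numeric_records, profiles, labels),
    ro5_fractions = if (!is.null(profiles) && !is.null(labels)) {
      class_fractions(profiles, labels)
    }
  )
  class(report) <- "qc_report"
  if (!is.null(json_path)) {
    ser <- report
    ser$parse_valid$failures <- as.data.frame(ser$parse_valid$failures)
    jsonlite::write_json(unclass(ser), json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", null = "null")
  }
  report
}

#' Recount a curated dataset CSV
#'
#' Filter-and-count summaries over a curated file in the published layout:
#' total rows, class counts, per-group counts, and the fraction of BBB+
#' molecules lighter than 500 Dalton (when profiles can be computed).
#'
#' @param path Curated CSV/TSV path.
#' @param with_mw Also compute the BBB+ molecular-weight fraction
#'   (requires the structure backend; default `FALSE`).
#' @return List: `n_rows`, `group_counts` (named), `label_counts` (named,
#'   categorical track only), `bbb_plus_mw_lt_500` (when requested).
#' @export
recount_curated <- function(path, with_mw = FALSE) {
  rows <- read_curated(path)
  out <- list(
    n_rows = nrow(rows),
    group_counts = table(factor(rows$group, levels = c("A", "B", "C", "D")))
  )
  if ("label" %in% names(rows)) {
    out$label_counts <- table(factor(rows$label, levels = c("BBB+", "BBB-")))
    if (with_mw) {
      prof <- ro5_profile(rows$smiles)
      plus <- !is.na(rows$label) & rows$label == "BBB+"
      out$bbb_plus_mw_lt_500 <- mean(prof$mw[plus] < 500, na.rm = TRUE)
    }
  }
  out
}

#' Plot the log BB distribution
#'
#' @param numeric_records Curated numeric tibble.
#' @param binwidth Histogram bin width (default 0.25).
#' @return A ggplot object.
#' @export
plot_logbb_distribution <- function(numeric_records, binwidth = 0.25) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_logbb_distribution() needs ggplot2", call. = FALSE)
  }
  ggplot2::ggplot(numeric_records, ggplot2::aes(x = .data$logbb)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "log BB", y = "molecules") +
    ggplot2::theme_minimal()
}
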