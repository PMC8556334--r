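# Reading heterogeneous source tables into a unified record schema, and
# writing curated datasets in the published column layout.

SOURCE_FIELDS <- c("compound_name", "smiles_raw", "cid", "logbb", "label",
                   "threshold", "reference")

# Published column layout of the curated CSVs. The numeric track omits the
# label and threshold columns.
CURATED_COLUMNS <- c("compound name", "IUPAC name", "SMILES", "CID", "logBB",
                     "BBB+/BBB-", "InChI", "threshold", "reference", "group",
                     "comment")

normalize_label <- function(x) {
  # Accept the Unicode minus variants that appear in typeset tables.
  x <- gsub("[‐‑‒–—−]", "-", trimws(as.character(x)))
  x[x == ""] <- NA_character_
  x
}

parse_numeric_cell <- function(x) {
  x <- trimws(as.character(x))
  x <- gsub("[‐‑‒–—−]", "-", x)
  out <- suppressWarnings(as.numeric(x))
  out[!nzchar(x) | is.na(x)] <- NA_real_
  list(value = out, bad = nzchar(x) & !is.na(x) & is.na(out) &
         !(toupper(x) %in% c("NA", "NAN")))
}

read_table_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    tibble::as_tibble(readxl::read_excel(path, col_types = "text"))
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
  }
}

#' Read one source table into unified measurement records
#'
#' Source tables from different publications have incompatible layouts, so
#' the mapping from file columns to record fields is explicit configuration:
#' no header auto-detection is attempted. Rows that violate the record
#' invariants (no identity field, no measurement, unparsable numeric cell)
#' are returned in a rejects table with reasons, never silently dropped.
#'
#' @param path CSV or XLSX file.
#' @param schema_map Named character vector mapping record fields
#'   (`compound_name`, `smiles_raw`, `cid`, `logbb`, `label`, `threshold`,
#'   `reference`) to column names in the file. Fields absent from the file
#'   are simply omitted from the map.
#' @param source_id Short provenance tag for this source (e.g. `"R27"`).
#' @return A list with `records` (tibble of accepted rows: `source_id`,
#'   `row`, the seven record fields) and `rejects` (tibble: `source_id`,
#'   `row`, `reason`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("name,smiles,logBB", "ethanol,CCO,-0.2"), f)
#' read_source_table(f, c(compound_name = "name", smiles_raw = "smiles",
#'                        logbb = "logBB"), "R1")
#' @export
read_source_table <- function(path, schema_map, source_id) {
  if (!file.exists(path)) {
    stop("source table not found: ", path, call. = FALSE)
  }
  if (is.null(names(schema_map)) || !all(names(schema_map) %in% SOURCE_FIELDS)) {
    stop("schema_map names must be record fields (",
         paste(SOURCE_FIELDS, collapse = ", "), ")", call. = FALSE)
  }
  raw <- read_table_any(path)
  missing_cols <- setdiff(unname(schema_map), names(raw))
  if (length(missing_cols)) {
    stop("columns named in schema_map not present in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  n <- nrow(raw)
  rec <- tibble::tibble(
    source_id = rep(source_id, n),
    row = seq_len(n),
    compound_name = NA_character_,
    smiles_raw = NA_character_,
    cid = NA_integer_,
    logbb = NA_real_,
    label = NA_character_,
    threshold = NA_real_,
    reference = NA_character_
  )
  reasons <- vector("list", n)
  add_reason <- function(i, why) reasons[[i]] <<- c(reasons[[i]], why)

  get_col <- function(field) {
    if (field %in% names(schema_map)) raw[[schema_map[[field]]]] else NULL
  }

  for (field in c("compound_name", "smiles_raw", "reference")) {
    col <- get_col(field)
    if (!is.null(col)) {
      col <- trimws(as.character(col))
      col[!nzchar(col)] <- NA_character_
      rec[[field]] <- col
    }
  }
  col <- get_col("cid")
  if (!is.null(col)) {
    p <- parse_numeric_cell(col)
    for (i in which(p$bad)) add_reason(i, "unparsable numeric (cid)")
    cid <- p$value
    cid[!is.na(cid) & (cid <= 0 | cid != floor(cid))] <- NA_real_
    rec$cid <- as.integer(cid)
  }
  for (field in c("logbb", "threshold")) {
    col <- get_col(field)
    if (!is.null(col)) {
      p <- parse_numeric_cell(col)
      for (i in which(p$bad)) add_reason(i, paste0("unparsable numeric (", field, ")"))
      rec[[field]] <- p$value
    }
  }
  col <- get_col("label")
  if (!is.null(col)) {
    lab <- normalize_label(col)
    bad_lab <- !is.na(lab) & !(lab %in% c("BBB+", "BBB-"))
    for (i in which(bad_lab)) add_reason(i, "invalid label")
    lab[bad_lab] <- NA_character_
    rec$label <- lab
  }

  no_identity <- is.na(rec$compound_name) & is.na(rec$smiles_raw) & is.na(rec$cid)
  for (i in which(no_identity)) add_reason(i, "no identity")
  no_measurement <- is.na(rec$logbb) & is.na(rec$label)
  for (i in which(no_measurement)) add_reason(i, "no measurement")
  nonfinite_thr <- !is.na(rec$threshold) & !is.finite(rec$threshold)
  for (i in which(nonfinite_thr)) add_reason(i, "non-finite threshold")

  rejected <- !vapply(reasons, is.null, logical(1))
  rejects <- tibble::tibble(
    source_id = source_id,
    row = which(rejected),
    reason = vapply(reasons[rejected], paste, character(1), collapse = "; ")
  )
  list(records = rec[!rejected, , drop = FALSE], rejects = rejects)
}

#' Automated consistency checks over source records
#'
#' Reporting only -- nothing is modified or dropped. Checks: non-finite
#' log BB values, labels outside the BBB+/BBB- alphabet, and byte-identical
#' duplicate rows within a single source.
#'
#' @param records Tibble of source records as returned by
#'   [read_source_table()] (possibly concatenated over sources).
#' @return A list of counts: `n_records`, `non_finite_logbb`,
#'   `invalid_label`, `duplicate_rows`, plus `duplicates`, a tibble locating
#'   the duplicated rows.
#' @export
consistency_check <- function(records) {
  stopifnot(is.data.frame(records))
  non_finite <- sum(!is.na(records$logbb) & !is.finite(records$logbb))
  invalid_label <- sum(!is.na(records$label) &
                         !(records$label %in% c("BBB+", "BBB-")))
  fields <- intersect(c("source_id", SOURCE_FIELDS), names(records))
  key <- do.call(paste, c(records[fields], sep = "\r"))
  dup <- duplicated(key)
  dup_tbl <- records[dup, intersect(c("source_id", "row"), names(records)), drop = FALSE]
  list(
    n_records = nrow(records),
    non_finite_logbb = non_finite,
    invalid_label = invalid_label,
    duplicate_rows = sum(dup),
    duplicates = tibble::as_tibble(dup_tbl)
  )
}

# Internal <-> published column name mapping for curated rows.
curated_internal_fields <- function(track) {
  fields <- c(compound_name = "compound name", iupac_name = "IUPAC name",
              smiles = "SMILES", cid = "CID", logbb = "logBB",
              label = "BBB+/BBB-", inchi = "InChI", threshold = "threshold",
              reference = "reference", group = "group", comment = "comment")
  if (track == "numeric") fields <- fields[!names(fields) %in% c("label", "threshold")]
  fields
}

#' Write a curated dataset as CSV in the published column layout
#'
#' The numeric track omits the `BBB+/BBB-` and `threshold` columns, which
#' belong to the categorical dataset only. Missing values are serialized as
#' empty strings; numeric values keep full precision so a read-back
#' round-trips field-for-field.
#'
#' @param rows Tibble of curated rows with internal field names
#'   (`compound_name`, `iupac_name`, `smiles`, `cid`, `logbb`, `label`,
#'   `inchi`, `threshold`, `reference`, `group`, `comment`).
#' @param path Output CSV path.
#' @param track `"numeric"` or `"categorical"`. Rows must be homogeneous in
#'   track: numeric rows carry `logbb` and no `label`; categorical rows the
#'   reverse.
#' @return Invisibly, `path`.
#' @export
write_curated <- function(rows, path, track = c("numeric", "categorical")) {
  track <- match.arg(track)
  fields <- curated_internal_fields(track)
  rows <- tibble::as_tibble(rows)
  for (f in names(fields)) if (!f %in% names(rows)) rows[[f]] <- NA
  if (nrow(rows)) {
    if (track == "numeric" && ("label" %in% names(rows)) &&
        any(!is.na(rows$label))) {
      stop("numeric track rows must not carry labels (mixed tracks)", call. = FALSE)
    }
    if (track == "categorical" && any(is.na(rows$label))) {
      stop("categorical track rows must all carry labels (mixed tracks)", call. = FALSE)
    }
  }
  out <- rows[names(fields)]
  names(out) <- unname(fields)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a curated dataset CSV back into internal representation
#'
#' Accepts both the ASCII hyphen-minus and the Unicode minus in the
#' `BBB+/BBB-` column, as typeset versions of the layout use the latter.
#'
#' @param path CSV written by [write_curated()] (or the published curated
#'   datasets in the same layout; tab-separated files are detected by the
#'   `.tsv` extension).
#' @return Tibble with internal field names; the track is inferred from the
#'   header (presence of the label column).
#' @export
read_curated <- function(path) {
  ext <- tolower(tools::file_ext(path))
  reader <- if (ext == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE, show_col_types = FALSE)
  hdr <- names(raw)
  # tolerate the Unicode minus in the header itself
  hdr_ascii <- gsub("[‐‑‒–—−]", "-", hdr)
  track <- if ("BBB+/BBB-" %in% hdr_ascii) "categorical" else "numeric"
  fields <- curated_internal_fields(track)
  out <- tibble::tibble(.rows = nrow(raw))
  for (f in names(fields)) {
    col <- raw[[match(fields[[f]], hdr_ascii)]]
    if (is.null(col)) col <- rep(NA_character_, nrow(raw))
    out[[f]] <- col
  }
  out$logbb <- if ("logbb" %in% names(out)) suppressWarnings(as.numeric(out$logbb)) else NULL
  if ("threshold" %in% names(out)) {
    out$threshold <- suppressWarnings(as.numeric(out$threshold))
  }
  if ("label" %in% names(out)) out$label <- normalize_label(out$label)
  for (f in intersect(c("compound_name", "iupac_name", "smiles", "cid",
                        "inchi", "reference", "group", "comment"), names(out))) {
    v <- out[[f]]
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    out[[f]] <- v
  }
  out
}

#' Write row-level rejects with reasons
#'
#' @param rejects Tibble with at least `source_id`, `row`, `reason`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_rejects <- function(rejects, path) {
  readr::write_csv(tibble::as_tibble(rejects), path, na = "", progress = FALSE)
  invisible(path)
}
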