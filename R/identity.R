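# Identity resolution: fill missing name/SMILES/CID fields through a
# compound-registry resolver, and assign the InChI merge key.
#
# The resolver is an interface with three implementations:
#   * resolver_offline(): table-backed stub, used by all tests;
#   * resolver_cached(): flat-file TSV cache wrapped around another
#     resolver, giving reproducible, rate-limit-friendly runs;
#   * resolver_pubchem(): live PUG-REST client (name->CID, CID->properties,
#     SMILES->CID). Never exercised in tests; requires network.

#' Offline table-backed resolver
#'
#' @param table Tibble with columns `query_type` (`"name"`, `"cid"`, or
#'   `"smiles"`), `query`, `cid`, `smiles`, `name`, `iupac_name`. Multiple
#'   rows for one query model registry ambiguity.
#' @return A resolver object.
#' @export
resolver_offline <- function(table) {
  table <- tibble::as_tibble(table)
  needed <- c("query_type", "query", "cid", "smiles", "name", "iupac_name")
  for (f in setdiff(needed, names(table))) table[[f]] <- NA
  structure(list(table = table), class = c("bbb_resolver_offline", "bbb_resolver"))
}

#' Caching resolver
#'
#' Wraps another resolver with a persistent tab-separated cache keyed by
#' (query type, query string). With a populated cache, a repeat run performs
#' zero lookups against the inner resolver and produces identical output.
#'
#' @param path Cache file path (created on first write).
#' @param inner Resolver consulted on cache misses; `NULL` makes misses
#'   resolve to no matches.
#' @return A resolver object.
#' @export
resolver_cached <- function(path, inner = NULL) {
  structure(list(path = path, inner = inner),
            class = c("bbb_resolver_cached", "bbb_resolver"))
}

#' Live PubChem PUG-REST resolver
#'
#' Queries the PubChem registry over HTTPS with simple retry. Intended for
#' interactive use only; wrap it in [resolver_cached()] for reproducible
#' runs, and prefer the offline resolver in tests.
#'
#' @param retries Number of attempts per query (default 3).
#' @param delay Seconds between attempts (default 1).
#' @return A resolver object.
#' @export
resolver_pubchem <- function(retries = 3, delay = 1) {
  structure(list(retries = retries, delay = delay),
            class = c("bbb_resolver_pubchem", "bbb_resolver"))
}

#' Query a resolver
#'
#' @param resolver A resolver object.
#' @param type `"name"`, `"cid"`, or `"smiles"`.
#' @param query Query string.
#' @return Tibble of matches (`cid`, `smiles`, `name`, `iupac_name`), in
#'   registry order; zero rows when unresolved. `NULL` signals a transport
#'   failure (distinct from a confirmed miss).
#' @export
resolver_query <- function(resolver, type, query) {
  UseMethod("resolver_query")
}

empty_matches <- function() {
  tibble::tibble(cid = integer(0), smiles = character(0),
                 name = character(0), iupac_name = character(0))
}

#' @export
resolver_query.bbb_resolver_offline <- function(resolver, type, query) {
  hits <- resolver$table[
    resolver$table$query_type == type &
      !is.na(resolver$table$query) & resolver$table$query == query, ,
    drop = FALSE
  ]
  tibble::tibble(
    cid = suppressWarnings(as.integer(hits$cid)),
    smiles = as.character(hits$smiles),
    name = as.character(hits$name),
    iupac_name = as.character(hits$iupac_name)
  )
}

cache_read <- function(path) {
  if (!file.exists(path)) {
    return(tibble::tibble(query_type = character(0), query = character(0),
                          match_index = character(0), cid = character(0),
                          smiles = character(0), name = character(0),
                          iupac_name = character(0)))
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, show_col_types = FALSE)
}

#' @export
resolver_query.bbb_resolver_cached <- function(resolver, type, query) {
  cache <- cache_read(resolver$path)
  hits <- cache[cache$query_type == type & cache$query == query, , drop = FALSE]
  if (nrow(hits)) {
    hits <- hits[order(as.integer(hits$match_index)), , drop = FALSE]
    real <- hits[!is.na(hits$cid) | !is.na(hits$smiles) | !is.na(hits$name), , drop = FALSE]
    return(tibble::tibble(
      cid = suppressWarnings(as.integer(real$cid)),
      smiles = as.character(real$smiles),
      name = as.character(real$name),
      iupac_name = as.character(real$iupac_name)
    ))
  }
  if (is.null(resolver$inner)) return(empty_matches())
  res <- resolver_query(resolver$inner, type, query)
  if (is.null(res)) return(NULL)  # transport failure: do not cache
  entry <- if (nrow(res)) {
    tibble::tibble(query_type = type, query = query,
                   match_index = as.character(seq_len(nrow(res))),
                   cid = as.character(res$cid), smiles = res$smiles,
                   name = res$name, iupac_name = res$iupac_name)
  } else {
    # a confirmed miss is cached too (all-NA payload)
    tibble::tibble(query_type = type, query = query, match_index = "1",
                   cid = NA_character_, smiles = NA_character_,
                   name = NA_character_, iupac_name = NA_character_)
  }
  readr::write_tsv(dplyr::bind_rows(cache, entry), resolver$path, progress = FALSE)
  res
}

pubchem_fetch <- function(url, retries, delay) {
  for (k in seq_len(retries)) {
    res <- tryCatch(jsonlite::fromJSON(url), error = function(e) NULL)
    if (!is.null(res)) return(res)
    Sys.sleep(delay)
  }
  NULL
}

#' @export
resolver_query.bbb_resolver_pubchem <- function(resolver, type, query) {
  base <- "https://pubchem.ncbi.nlm.nih.gov/rest/pug/compound"
  url <- switch(type,
    name = sprintf("%s/name/%s/property/CanonicalSMILES,IsomericSMILES,IUPACName,Title/JSON",
                   base, utils::URLencode(query, reserved = TRUE)),
    cid = sprintf("%s/cid/%s/property/CanonicalSMILES,IsomericSMILES,IUPACName,Title/JSON",
                  base, query),
    smiles = sprintf("%s/smiles/%s/property/CanonicalSMILES,IsomericSMILES,IUPACName,Title/JSON",
                     base, utils::URLencode(query, reserved = TRUE)),
    stop("unknown query type: ", type)
  )
  res <- pubchem_fetch(url, resolver$retries, resolver$delay)
  if (is.null(res)) return(NULL)
  props <- res$PropertyTable$Properties
  if (is.null(props) || !nrow(props)) return(empty_matches())
  smi <- if (!is.null(props$IsomericSMILES)) props$IsomericSMILES else props$CanonicalSMILES
  tibble::tibble(
    cid = as.integer(props$CID),
    smiles = as.character(smi),
    name = as.character(if (!is.null(props$Title)) props$Title else NA),
    iupac_name = as.character(if (!is.null(props$IUPACName)) props$IUPACName else NA)
  )
}

#' Fill missing identity fields of source records from a registry
#'
#' For every record lacking one of name / SMILES / CID, the registry is
#' queried (by name, else CID, else SMILES); absent fields are filled from
#' the first match, and multi-match ambiguity is flagged in the notes
#' rather than resolved silently. Resolver failures leave the record
#' unchanged with an `"unresolved"` note -- never fatal mid-pipeline.
#'
#' @param records Tibble of source records.
#' @param resolver A resolver object.
#' @return The records tibble with absent fields filled where possible and
#'   two added columns: `iupac_name` and `resolver_note` (`NA`,
#'   `"ambiguous: first registry instance used"`, or `"unresolved"`).
#' @export
resolve_missing <- function(records, resolver) {
  records <- tibble::as_tibble(records)
  if (!"iupac_name" %in% names(records)) records$iupac_name <- NA_character_
  records$resolver_note <- NA_character_
  needs <- is.na(records$compound_name) | is.na(records$smiles_raw) |
    is.na(records$cid) | is.na(records$iupac_name)
  for (i in which(needs)) {
    qt <- if (!is.na(records$compound_name[i])) c("name", records$compound_name[i])
      else if (!is.na(records$cid[i])) c("cid", as.character(records$cid[i]))
      else if (!is.na(records$smiles_raw[i])) c("smiles", records$smiles_raw[i])
      else next
    matches <- resolver_query(resolver, qt[1], qt[2])
    if (is.null(matches)) {
      records$resolver_note[i] <- "unresolved"
      next
    }
    if (!nrow(matches)) {
      if (is.na(records$smiles_raw[i])) records$resolver_note[i] <- "unresolved"
      next
    }
    first <- matches[1, ]
    if (is.na(records$compound_name[i]) && !is.na(first$name)) {
      records$compound_name[i] <- first$name
    }
    if (is.na(records$smiles_raw[i]) && !is.na(first$smiles)) {
      records$smiles_raw[i] <- first$smiles
    }
    if (is.na(records$cid[i]) && !is.na(first$cid)) records$cid[i] <- first$cid
    if (is.na(records$iupac_name[i]) && !is.na(first$iupac_name)) {
      records$iupac_name[i] <- first$iupac_name
    }
    if (nrow(matches) > 1L) {
      records$resolver_note[i] <- "ambiguous: first registry instance used"
    }
  }
  records
}

#' Merge key of a standardized molecule
#'
#' Identity is the byte-identical standard InChI: resonance-variant SMILES
#' of one molecule collapse to one key, while enantiomers with explicit
#' stereo keep distinct keys (stereochemistry matters for carrier-mediated
#' barrier transport).
#'
#' @param mol Tibble of standardized molecules (from
#'   [standardize_molecules()]) or a character vector of InChI strings.
#' @return Character vector of merge keys.
#' @export
make_key <- function(mol) {
  if (is.character(mol)) return(mol)
  stopifnot(is.data.frame(mol), "inchi" %in% names(mol))
  mol$inchi
}

#' Refresh registry identifiers after standardization
#'
#' Standardization (salt stripping, neutralization) changes the structure,
#' so any CID inherited from the raw record may identify the salt rather
#' than the parent. Look the standardized SMILES up in the registry and
#' replace the CID with the parent's; absent if not found.
#'
#' @param mols Tibble of standardized molecules with a `smiles` column and
#'   optionally `cid`.
#' @param resolver A resolver object.
#' @return `mols` with `cid` updated and a `cid_note` column (`NA` or
#'   `"cid not found for standardized structure"`).
#' @export
update_cid <- function(mols, resolver) {
  mols <- tibble::as_tibble(mols)
  if (!"cid" %in% names(mols)) mols$cid <- NA_integer_
  mols$cid_note <- NA_character_
  for (i in seq_len(nrow(mols))) {
    if (is.na(mols$smiles[i])) next
    matches <- resolver_query(resolver, "smiles", mols$smiles[i])
    if (is.null(matches)) {
      mols$cid_note[i] <- "unresolved"
      next
    }
    if (nrow(matches) && !is.na(matches$cid[1])) {
      mols$cid[i] <- matches$cid[1]
    } else {
      mols$cid[i] <- NA_integer_
      mols$cid_note[i] <- "cid not found for standardized structure"
    }
  }
  mols
}
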