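# Structure standardization: text repair -> parse -> desalt/neutralize ->
# element filter -> canonicalize (+ InChI).
#
# The stage order matters chemically: salts are stripped before the element
# filter so that a sodium or calcium counterion does not doom an otherwise
# acceptable organic parent, and before neutralization so that the
# neutralizer does not re-protonate an anion while an intact counterion
# still holds the opposite charge.

#' Repair the textual form of a SMILES string
#'
#' Removes all whitespace and line breaks (transcription artefacts of
#' copy-pasted tables) and normalizes typographic dash variants (en/em dash,
#' Unicode minus) to the ASCII minus used in SMILES charge annotations.
#'
#' @param raw Character vector of raw SMILES strings. Must be non-empty
#'   after cleaning.
#' @return Character vector of repaired SMILES strings.
#' @examples
#' fix_smiles_text("C C O\n")   # "CCO"
#' fix_smiles_text("[O–]") # "[O-]"
#' @export
fix_smiles_text <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (any(is.na(raw) | !nzchar(trimws(raw)))) {
    stop("fix_smiles_text(): empty SMILES input", call. = FALSE)
  }
  out <- gsub("[[:space:]]+", "", raw)
  # en dash, em dash, minus sign, hyphen, figure dash -> ASCII hyphen-minus
  out <- gsub("[‐‑‒–—−]", "-", out)
  if (any(!nzchar(out))) {
    stop("fix_smiles_text(): empty SMILES input", call. = FALSE)
  }
  out
}

# Split a (possibly multi-fragment) SMILES on the dot bond and keep the
# largest organic covalent fragment. Organic = contains carbon. Returns
# list(smiles=, stripped=logical, reason=NA or "unresolvable").
largest_organic_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 1L) {
    counts <- smiles_element_counts(frags)
    if (!("C" %in% names(counts))) {
      return(list(smiles = NA_character_, stripped = FALSE, reason = "unresolvable"))
    }
    return(list(smiles = frags, stripped = FALSE, reason = NA_character_))
  }
  info <- lapply(frags, smiles_element_counts)
  organic <- vapply(info, function(x) "C" %in% names(x), logical(1))
  if (!any(organic)) {
    return(list(smiles = NA_character_, stripped = FALSE, reason = "unresolvable"))
  }
  heavy <- vapply(info, function(x) {
    if (!length(x)) return(0L)
    sum(x[setdiff(names(x), "H")])
  }, integer(1))
  heavy[!organic] <- -1L
  pick <- which.max(heavy)
  list(smiles = frags[pick], stripped = TRUE, reason = NA_character_)
}

#' Strip salts and neutralize charges
#'
#' Retains the largest organic covalent fragment of a multi-fragment record,
#' then adjusts protonation so the net formal charge is zero where this is
#' chemically possible. Fixed charges (e.g. quaternary ammonium) are kept
#' and reported in the comment rather than rejected: such drugs legitimately
#' occur in permeability datasets.
#'
#' @param smiles A single valid SMILES string.
#' @return A list with elements `smiles` (standardized fragment or `NA`),
#'   `flags` (character vector drawn from `salt_stripped`,
#'   `charge_neutralized`), `comment` (`NA` or a note), and
#'   `rejected_reason` (`NA` or `"unresolvable"`).
#' @examples
#' \dontrun{
#' desalt_neutralize("CC(=O)[O-].[Na+]")  # acetic acid, salt_stripped + charge_neutralized
#' }
#' @export
desalt_neutralize <- function(smiles) {
  stopifnot(length(smiles) == 1L, !is.na(smiles))
  frag <- largest_organic_fragment(smiles)
  if (!is.na(frag$reason)) {
    return(list(smiles = NA_character_, flags = character(0),
                comment = NA_character_, rejected_reason = frag$reason))
  }
  flags <- character(0)
  if (frag$stripped) flags <- c(flags, "salt_stripped")
  # charged centres include zwitterions, whose *net* charge is already 0
  had_charges <- grepl("\\[[^]]*[+-][^]]*\\]", frag$smiles)
  neutral <- ob_neutralize(frag$smiles)
  if (is.na(neutral)) neutral <- frag$smiles
  q1 <- smiles_net_charge(neutral)
  comment <- NA_character_
  if (had_charges) {
    if (!is.na(q1) && q1 != 0L) {
      comment <- sprintf("net formal charge %+d could not be neutralized", q1)
    } else if (!identical(smiles_to_canonical(frag$smiles), neutral)) {
      flags <- c(flags, "charge_neutralized")
    }
  }
  list(smiles = neutral, flags = flags, comment = comment,
       rejected_reason = NA_character_)
}

#' Element-based structure filter
#'
#' Rejects molecules containing atoms heavier than a cutoff atomic number,
#' metal atoms (of any atomic number, by default), or an excessive number of
#' boron atoms. The defaults follow the curation convention of excluding
#' any atom with Z > 20 and more than 7 borons; the predicate is
#' configurable because the literal Z > 20 rule also excludes Br/I-bearing
#' drugs, which some users may wish to keep.
#'
#' @param smiles A single valid (desalted) SMILES string.
#' @param max_z Maximum allowed atomic number (default 20).
#' @param exclude_metals Reject metals regardless of atomic number
#'   (Li, Be, Na, Mg, Al, K, Ca are the metals not already caught by
#'   `max_z = 20`). Default `TRUE`.
#' @param max_boron Maximum allowed boron count (default 7; the boundary is
#'   strict: 7 borons pass, 8 are rejected).
#' @return `NA_character_` if the molecule passes, otherwise the rejection
#'   reason (`"metal_or_heavy_atom"` or `"boron_excess"`).
#' @examples
#' \dontrun{
#' element_filter("c1ccccc1")        # NA: keep
#' element_filter("Clc1ccccc1")      # NA: chlorine is Z = 17
#' element_filter("Ic1ccccc1")       # "metal_or_heavy_atom" (Z = 53)
#' }
#' @export
element_filter <- function(smiles, max_z = 20, exclude_metals = TRUE,
                           max_boron = 7) {
  counts <- smiles_element_counts(smiles)
  if (!length(counts)) return("metal_or_heavy_atom")
  syms <- names(counts)
  z <- ELEMENT_Z[syms]
  if (any(is.na(z)) || any(z > max_z)) return("metal_or_heavy_atom")
  if (exclude_metals && any(syms %in% LIGHT_METALS)) return("metal_or_heavy_atom")
  b <- if ("B" %in% syms) counts[["B"]] else 0L
  if (b > max_boron) return("boron_excess")
  NA_character_
}

#' Canonicalize a SMILES string and derive its InChI
#'
#' @param smiles A single valid SMILES string.
#' @param prefer_isomeric Keep stereo descriptors when the input carries them
#'   (default). `FALSE` strips stereo, yielding the plain canonical form.
#' @return A list with `smiles` (canonical) and `inchi` (standard InChI), or
#'   `rejected_reason = "unresolvable"` if InChI generation fails.
#' @export
canonicalize_smiles <- function(smiles, prefer_isomeric = TRUE) {
  stopifnot(length(smiles) == 1L)
  can <- smiles_to_canonical(smiles)
  if (!is.na(can) && !prefer_isomeric) {
    props <- ob_properties(can)
    if (!is.null(props) && "cansmiNS" %in% names(props)) {
      can <- gsub("[[:space:]]", "", props$cansmiNS[1])
    }
  }
  if (is.na(can)) {
    return(list(smiles = NA_character_, inchi = NA_character_,
                rejected_reason = "invalid_smiles"))
  }
  inchi <- smiles_to_inchi(can)
  if (is.na(inchi)) {
    return(list(smiles = can, inchi = NA_character_,
                rejected_reason = "unresolvable"))
  }
  list(smiles = can, inchi = inchi, rejected_reason = NA_character_)
}

#' Standardize a vector of raw SMILES strings
#'
#' Runs the full structure-standardization pipeline: textual repair, parse
#' validation, salt stripping, charge neutralization, element filtering, and
#' canonicalization with InChI generation. Rejections are values, never
#' errors: each input row comes back with either a standardized structure or
#' a `rejected_reason`.
#'
#' @param smiles_raw Character vector of raw SMILES strings (may contain
#'   whitespace, salts, charged species, or garbage).
#' @param prefer_isomeric Keep stereo descriptors when present (default
#'   `TRUE`).
#' @param element_opts List of options for [element_filter()]:
#'   `max_z`, `exclude_metals`, `max_boron`.
#' @return A tibble with one row per input: `smiles_raw`, `smiles`
#'   (canonical, `NA` if rejected), `inchi`, `flags` (semicolon-joined subset
#'   of `whitespace_fixed`, `salt_stripped`, `charge_neutralized`),
#'   `rejected_reason` (`NA`, `invalid_smiles`, `metal_or_heavy_atom`,
#'   `boron_excess`, or `unresolvable`) and `comment`.
#' @examples
#' \dontrun{
#' standardize_molecules(c("C C O", "CC(=O)[O-].[Na+]", "C1CC"))
#' }
#' @export
standardize_molecules <- function(smiles_raw, prefer_isomeric = TRUE,
                                  element_opts = list()) {
  eopts <- utils::modifyList(
    list(max_z = 20, exclude_metals = TRUE, max_boron = 7), element_opts
  )
  n <- length(smiles_raw)
  res <- tibble::tibble(
    smiles_raw = as.character(smiles_raw),
    smiles = NA_character_,
    inchi = NA_character_,
    flags = "",
    rejected_reason = NA_character_,
    comment = NA_character_
  )
  if (n == 0L) return(res)

  fixed <- rep(NA_character_, n)
  ok_in <- !is.na(smiles_raw) & nzchar(trimws(smiles_raw))
  fixed[ok_in] <- fix_smiles_text(smiles_raw[ok_in])
  ws_fixed <- ok_in & fixed != smiles_raw
  res$rejected_reason[!ok_in] <- "invalid_smiles"

  # parse check (batched)
  can0 <- rep(NA_character_, n)
  can0[ok_in] <- smiles_to_canonical(fixed[ok_in])
  bad <- ok_in & is.na(can0)
  res$rejected_reason[bad] <- "invalid_smiles"

  live <- which(ok_in & !bad)
  frag_smiles <- rep(NA_character_, n)
  flags <- vector("list", n)
  for (i in live) {
    ds <- desalt_neutralize(can0[i])
    if (!is.na(ds$rejected_reason)) {
      res$rejected_reason[i] <- ds$rejected_reason
      next
    }
    frag_smiles[i] <- ds$smiles
    flags[[i]] <- ds$flags
    if (!is.na(ds$comment)) res$comment[i] <- ds$comment
  }

  live <- which(!is.na(frag_smiles))
  for (i in live) {
    reason <- element_filter(frag_smiles[i], max_z = eopts$max_z,
                             exclude_metals = eopts$exclude_metals,
                             max_boron = eopts$max_boron)
    if (!is.na(reason)) {
      res$rejected_reason[i] <- reason
      frag_smiles[i] <- NA_character_
    }
  }

  live <- which(!is.na(frag_smiles))
  if (length(live)) {
    if (!prefer_isomeric) {
      frag_smiles[live] <- vapply(frag_smiles[live], function(s) {
        canonicalize_smiles(s, prefer_isomeric = FALSE)$smiles %||% NA_character_
      }, character(1), USE.NAMES = FALSE)
    }
    can <- smiles_to_canonical(frag_smiles[live])
    inchi <- smiles_to_inchi(ifelse(is.na(can), frag_smiles[live], can))
    for (k in seq_along(live)) {
      i <- live[k]
      if (is.na(can[k]) || is.na(inchi[k])) {
        res$rejected_reason[i] <- "unresolvable"
        next
      }
      res$smiles[i] <- can[k]
      res$inchi[i] <- inchi[k]
      f <- flags[[i]]
      if (ws_fixed[i]) f <- c("whitespace_fixed", f)
      res$flags[i] <- paste(f, collapse = ";")
    }
  }
  res
}
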