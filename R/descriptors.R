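# Descriptor extension and Rule-of-5 physicochemical profiling.
#
# The descriptor provider is pluggable. The default ("openbabel") computes
# a compact physicochemical block in-process. The "mordred" provider drives
# the full 2D set (1613 descriptors at version 1.1.1) through a python
# subprocess and fails with an installation instruction when that module is
# not importable. Per-molecule failures become NA rows, never a batch abort.

DESCRIPTOR_PROVIDERS <- c("openbabel", "mordred")

OB_DESCRIPTOR_NAMES <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")

python_binary <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  p
}

compute_descriptors_openbabel <- function(smiles) {
  vals <- matrix(NA_real_, nrow = length(smiles), ncol = length(OB_DESCRIPTOR_NAMES),
                 dimnames = list(NULL, OB_DESCRIPTOR_NAMES))
  failed <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    props <- if (!is.na(smiles[i])) ob_properties(smiles[i]) else NULL
    if (is.null(props)) {
      failed[i] <- TRUE
      next
    }
    for (d in OB_DESCRIPTOR_NAMES) {
      v <- suppressWarnings(as.numeric(props[[d]][1]))
      vals[i, d] <- if (length(v)) v else NA_real_
    }
    if (all(is.na(vals[i, ]))) failed[i] <- TRUE
  }
  list(names = OB_DESCRIPTOR_NAMES, values = vals, failed = failed)
}

compute_descriptors_mordred <- function(smiles) {
  py <- python_binary()
  probe <- if (nzchar(py)) {
    suppressWarnings(system2(py, c("-c", shQuote("import mordred")),
                             stdout = FALSE, stderr = FALSE))
  } else 1L
  if (!identical(probe, 0L)) {
    stop("descriptor provider 'mordred' is unavailable: the python module ",
         "'mordred' is not importable. Install it with `pip install mordred` ",
         "to compute the full 2D descriptor set.", call. = FALSE)
  }
  script <- '
import sys, csv, json
from rdkit import Chem
from mordred import Calculator, descriptors
calc = Calculator(descriptors, ignore_3D=True)
smiles = [l.rstrip("\\n") for l in open(sys.argv[1])]
mols = [Chem.MolFromSmiles(s) if s else None for s in smiles]
names = [str(d) for d in calc.descriptors]
w = csv.writer(sys.stdout)
w.writerow(names)
for m in mols:
    if m is None:
        w.writerow([""] * len(names))
        continue
    row = calc(m)
    w.writerow(["" if r is None or isinstance(r, Exception) else r for r in row])
'
  infile <- tempfile(fileext = ".smi")
  scriptfile <- tempfile(fileext = ".py")
  on.exit(unlink(c(infile, scriptfile)), add = TRUE)
  writeLines(ifelse(is.na(smiles), "", smiles), infile)
  writeLines(script, scriptfile)
  out <- system2(py, c(scriptfile, infile), stdout = TRUE, stderr = FALSE)
  tab <- utils::read.csv(text = paste(out, collapse = "\n"), check.names = FALSE)
  vals <- suppressWarnings(as.matrix(as.data.frame(lapply(tab, as.numeric))))
  colnames(vals) <- names(tab)
  list(names = names(tab), values = vals,
       failed = apply(vals, 1, function(r) all(is.na(r))))
}

#' Compute a molecular-descriptor block
#'
#' @param mols Tibble of standardized molecules (with `smiles` and `inchi`
#'   columns) or a character vector of SMILES strings.
#' @param provider `"openbabel"` (default; compact physicochemical set,
#'   in-process) or `"mordred"` (full 2D set, via python; errors with an
#'   installation instruction when the module is absent).
#' @return A `descriptor_block`: list with `keys` (InChI, or the SMILES
#'   when no InChI is supplied), `names` (descriptor names, deterministic
#'   order), `values` (numeric matrix, `|keys|` rows; per-molecule failures
#'   are NA rows), `failed` (logical), and `provider`.
#' @export
compute_descriptors <- function(mols, provider = "openbabel") {
  provider <- match.arg(provider, DESCRIPTOR_PROVIDERS)
  if (is.character(mols)) {
    smiles <- mols
    keys <- smiles_to_inchi(smiles)
    keys[is.na(keys)] <- smiles[is.na(keys)]
  } else {
    stopifnot(is.data.frame(mols), "smiles" %in% names(mols))
    smiles <- mols$smiles
    keys <- if ("inchi" %in% names(mols)) mols$inchi else smiles_to_inchi(smiles)
  }
  res <- switch(provider,
    openbabel = compute_descriptors_openbabel(smiles),
    mordred = compute_descriptors_mordred(smiles)
  )
  structure(
    list(keys = keys, names = res$names, values = res$values,
         failed = res$failed, provider = provider),
    class = "descriptor_block"
  )
}

#' @export
print.descriptor_block <- function(x, ...) {
  cat(sprintf("<descriptor_block> %d molecules x %d descriptors (provider: %s; %d failed)\n",
              length(x$keys), length(x$names), x$provider, sum(x$failed)))
  invisible(x)
}

#' Append a descriptor block to a curated table
#'
#' @param rows Curated tibble with an `inchi` column.
#' @param block A `descriptor_block` whose keys cover the rows' InChIs.
#' @return `rows` with the descriptor columns appended (NA where the block
#'   has no entry for a row).
#' @export
extend_with_descriptors <- function(rows, block) {
  stopifnot(inherits(block, "descriptor_block"))
  idx <- match(rows$inchi, block$keys)
  desc <- block$values[idx, , drop = FALSE]
  dplyr::bind_cols(rows, tibble::as_tibble(as.data.frame(desc)))
}

#' Lipinski Rule-of-5 profile
#'
#' Uses Lipinski's original counting convention: hydrogen-bond donors are
#' the hydrogens on nitrogen or oxygen (an NH2 contributes two), acceptors
#' are the nitrogen and oxygen atoms. log P comes from the backend's
#' atom-contribution estimator; the estimator name is recorded so profiles
#' computed with different estimators are not silently mixed.
#'
#' @param smiles Character vector of standardized SMILES.
#' @param hbd_smarts,hba_smarts Override the counting patterns for stricter
#'   pharmacophore definitions (`hbd_smarts` entries are weighted by their
#'   hydrogen count: pattern n counts atoms bearing exactly n hydrogens).
#' @return Tibble: `smiles`, `mw` (Dalton), `hbd`, `hba`, `logp`,
#'   `passes_mw` (< 500), `passes_hbd` (< 5), `passes_hba` (< 10),
#'   `passes_logp` (< 5), with attribute `logp_estimator`.
#' @examples
#' \dontrun{
#' ro5_profile("CCO")  # mw 46.07, hbd 1, hba 1, all passes TRUE
#' }
#' @export
ro5_profile <- function(smiles,
                        hbd_smarts = paste0("[#7,#8;H", 1:4, "]"),
                        hba_smarts = "[#7,#8]") {
  n <- length(smiles)
  out <- tibble::tibble(
    smiles = smiles, mw = NA_real_, hbd = NA_integer_, hba = NA_integer_,
    logp = NA_real_
  )
  for (i in seq_len(n)) {
    if (is.na(smiles[i])) next
    props <- ob_properties(smiles[i])
    if (is.null(props)) next
    out$mw[i] <- suppressWarnings(as.numeric(props$MW[1]))
    out$logp[i] <- suppressWarnings(as.numeric(props$logP[1]))
    hbd <- 0L
    for (k in seq_along(hbd_smarts)) {
      cnt <- ob_smarts_count(smiles[i], hbd_smarts[k])
      if (!is.na(cnt)) hbd <- hbd + k * cnt
    }
    out$hbd[i] <- hbd
    hba <- ob_smarts_count(smiles[i], hba_smarts)
    out$hba[i] <- if (is.na(hba)) NA_integer_ else hba
  }
  out$passes_mw <- out$mw < 500
  out$passes_hbd <- out$hbd < 5
  out$passes_hba <- out$hba < 10
  out$passes_logp <- out$logp < 5
  attr(out, "logp_estimator") <- "openbabel atom-contribution logP"
  out
}

#' Per-class Rule-of-5 pass fractions
#'
#' @param profiles Tibble from [ro5_profile()].
#' @param labels Character vector of class labels (`"BBB+"` / `"BBB-"`)
#'   aligned with `profiles` rows.
#' @return Tibble: `label`, `rule` (`mw`, `hbd`, `hba`, `logp`), `fraction`
#'   (of class members satisfying the rule; NA for an empty class), `n`.
#' @export
class_fractions <- function(profiles, labels) {
  stopifnot(nrow(profiles) == length(labels))
  rules <- c("mw", "hbd", "hba", "logp")
  out <- list()
  for (lab in sort(unique(stats::na.omit(labels)))) {
    in_class <- !is.na(labels) & labels == lab
    for (r in rules) {
      ok <- profiles[[paste0("passes_", r)]][in_class]
      out[[length(out) + 1L]] <- tibble::tibble(
        label = lab, rule = r,
        fraction = if (any(!is.na(ok))) mean(ok, na.rm = TRUE) else NA_real_,
        n = sum(in_class)
      )
    }
  }
  dplyr::bind_rows(out)
}
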