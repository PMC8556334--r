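# OpenBabel-backed cheminformatics primitives.
#
# Two access paths are used deliberately:
#   * the `obabel` CLI, batched, for canonical SMILES and InChI -- the CLI
#     preserves tetrahedral stereo in InChI output, which the in-process
#     conversion route does not;
#   * ChemmineOB in-process calls for per-molecule properties and SMARTS
#     counts, where no stereo is involved.
# All conversions are memoised in a session cache keyed by (operation, input)
# so that pipelines over redundant multi-source records pay for each unique
# structure once.

.ob_cache <- new.env(parent = emptyenv())

#' Clear the cached structure conversions
#'
#' Conversion results (canonical SMILES, InChI, properties) are memoised for
#' the session. Call this to force recomputation, e.g. after upgrading the
#' OpenBabel installation.
#'
#' @return Invisibly, the number of entries dropped.
#' @export
clear_structure_cache <- function() {
  n <- length(ls(.ob_cache))
  rm(list = ls(.ob_cache), envir = .ob_cache)
  invisible(n)
}

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("The 'obabel' executable was not found on PATH; ",
         "install OpenBabel 3.x to use the structure backend.", call. = FALSE)
  }
  p
}

# Batched conversion through the obabel CLI. Returns a character vector
# aligned with `smiles`; entries obabel cannot parse are NA. Titles m<i> map
# outputs back to inputs because obabel silently drops failed records.
ob_cli_convert <- function(smiles, to = c("can", "inchi")) {
  to <- match.arg(to)
  out <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0L) return(out)

  todo <- !is.na(smiles) & nzchar(smiles)
  keys <- paste0(to, "\r", smiles)
  cached <- vapply(keys, function(k) {
    if (!todo[match(k, keys)]) return(NA_character_)
    get0(k, envir = .ob_cache, ifnotfound = NA_character_)
  }, character(1), USE.NAMES = FALSE)
  out[!is.na(cached)] <- cached[!is.na(cached)]
  run <- todo & is.na(cached)
  if (!any(run)) return(out)

  idx <- which(run)
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  # SMILES must not contain whitespace here; fix_smiles_text() guarantees it
  # upstream, but guard anyway so titles stay aligned.
  smi_in <- gsub("[[:space:]]", "", smiles[idx])
  writeLines(paste(smi_in, paste0("m", seq_along(idx))), infile)

  args <- c(infile, if (to == "can") "-ocan" else c("-oinchi", "-xt"), "-e")
  res <- suppressWarnings(
    system2(obabel_path(), args, stdout = TRUE, stderr = FALSE)
  )
  if (length(res)) {
    if (to == "can") {
      parts <- strsplit(res, "\t", fixed = TRUE)
      vals <- vapply(parts, `[`, character(1), 1L)
      tags <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, character(1)))
    } else {
      res <- res[startsWith(res, "InChI=")]
      sp <- regexpr(" ", res, fixed = TRUE)
      vals <- ifelse(sp > 0, substr(res, 1L, sp - 1L), res)
      tags <- ifelse(sp > 0, substring(res, sp + 1L), NA_character_)
    }
    pos <- match(tags, paste0("m", seq_along(idx)))
    ok <- !is.na(pos) & nzchar(vals)
    out[idx[pos[ok]]] <- vals[ok]
    for (j in which(ok)) {
      assign(paste0(to, "\r", smiles[idx[pos[j]]]), vals[j], envir = .ob_cache)
    }
  }
  # Cache failures too: reparsing a known-bad SMILES is wasted work.
  failed <- idx[is.na(out[idx])]
  for (j in failed) assign(paste0(to, "\r", smiles[j]), NA_character_, envir = .ob_cache)
  out[failed] <- NA_character_
  out
}

#' Canonical SMILES via the structure backend
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical (isomeric where input carries
#'   stereo) SMILES; `NA` where the input does not parse.
#' @export
smiles_to_canonical <- function(smiles) ob_cli_convert(smiles, "can")

#' Standard InChI via the structure backend
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of standard InChI strings; `NA` where the input
#'   does not parse or InChI generation fails.
#' @export
smiles_to_inchi <- function(smiles) ob_cli_convert(smiles, "inchi")

#' Does a SMILES string parse to a valid molecular graph?
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector.
#' @export
smiles_is_valid <- function(smiles) !is.na(smiles_to_canonical(smiles))

# Neutralize +1/-1 centres where chemically possible (obabel --neutralize).
# Quaternary ammonium and similar fixed charges pass through unchanged.
ob_neutralize <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0L) return(out)
  todo <- which(!is.na(smiles) & nzchar(smiles))
  if (!length(todo)) return(out)
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(gsub("[[:space:]]", "", smiles[todo]),
                   paste0("m", seq_along(todo))), infile)
  res <- suppressWarnings(
    system2(obabel_path(), c(infile, "-ocan", "--neutralize", "-e"),
            stdout = TRUE, stderr = FALSE)
  )
  if (length(res)) {
    parts <- strsplit(res, "\t", fixed = TRUE)
    vals <- vapply(parts, `[`, character(1), 1L)
    tags <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, character(1)))
    pos <- match(tags, paste0("m", seq_along(todo)))
    ok <- !is.na(pos) & nzchar(vals)
    out[todo[pos[ok]]] <- vals[ok]
  }
  out
}

# Per-molecule OpenBabel property block (MW, logP, TPSA, HB counts, formula,
# ...). Returns a one-row data.frame or NULL if the molecule fails.
ob_properties <- function(smiles) {
  key <- paste0("prop\r", smiles)
  hit <- get0(key, envir = .ob_cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  props <- tryCatch(
    suppressWarnings(
      ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles, identity))
    ),
    error = function(e) NULL
  )
  assign(key, props, envir = .ob_cache)
  props
}

# Count SMARTS matches (unique atom sets) in one molecule.
ob_smarts_count <- function(smiles, smarts) {
  key <- paste0("sm\r", smarts, "\r", smiles)
  hit <- get0(key, envir = .ob_cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  n <- tryCatch(
    suppressWarnings(
      ChemmineOB::smartsSearch_OB(
        ChemmineOB::forEachMol("SMILES", smiles, identity), smarts
      )
    ),
    error = function(e) NA_integer_
  )
  n <- as.integer(n)
  assign(key, n, envir = .ob_cache)
  n
}

# Standard atomic numbers, H through Og.
ELEMENT_Z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26,
  Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34,
  Br = 35, Kr = 36, Rb = 37, Sr = 38, Y = 39, Zr = 40, Nb = 41, Mo = 42,
  Tc = 43, Ru = 44, Rh = 45, Pd = 46, Ag = 47, Cd = 48, In = 49, Sn = 50,
  Sb = 51, Te = 52, I = 53, Xe = 54, Cs = 55, Ba = 56, La = 57, Ce = 58,
  Pr = 59, Nd = 60, Pm = 61, Sm = 62, Eu = 63, Gd = 64, Tb = 65, Dy = 66,
  Ho = 67, Er = 68, Tm = 69, Yb = 70, Lu = 71, Hf = 72, Ta = 73, W = 74,
  Re = 75, Os = 76, Ir = 77, Pt = 78, Au = 79, Hg = 80, Tl = 81, Pb = 82,
  Bi = 83, Po = 84, At = 85, Rn = 86, Fr = 87, Ra = 88, Ac = 89, Th = 90,
  Pa = 91, U = 92, Np = 93, Pu = 94, Am = 95, Cm = 96, Bk = 97, Cf = 98,
  Es = 99, Fm = 100, Md = 101, No = 102, Lr = 103, Rf = 104, Db = 105,
  Sg = 106, Bh = 107, Hs = 108, Mt = 109, Ds = 110, Rg = 111, Cn = 112,
  Nh = 113, Fl = 114, Mc = 115, Lv = 116, Ts = 117, Og = 118
)

# Metals with Z <= 20: named by the element-filter default, which excludes
# metals of any atomic number (heavier metals are already caught by Z > 20).
LIGHT_METALS <- c("Li", "Be", "Na", "Mg", "Al", "K", "Ca")

# Parse a Hill-style molecular formula ("C6H5ClO", "C2H4O2.Na") into a named
# integer vector of element counts. Charges and separator dots are ignored.
formula_element_counts <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(integer(0))
  pieces <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  counts <- integer(0)
  for (p in pieces) {
    sym <- sub("[0-9]+$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}

# Element counts of a molecule from its backend-computed formula.
smiles_element_counts <- function(smiles) {
  props <- ob_properties(smiles)
  if (is.null(props)) return(integer(0))
  formula_element_counts(props$formula[1])
}

# Net formal charge from the bracket-atom annotations of a SMILES string.
# In SMILES grammar formal charge appears only inside [...], so a textual
# scan over canonical output is exact.
smiles_net_charge <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_integer_)
    brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    if (!length(brackets)) return(0L)
    total <- 0L
    for (b in brackets) {
      m <- regmatches(b, regexpr("(\\+[0-9]*|\\++|-[0-9]*|-+)\\]$", b))
      if (!length(m)) next
      sign_chr <- substr(m, 1L, 1L)
      body <- sub("\\]$", "", m)
      digits <- sub("^[+-]+", "", body)
      mag <- if (nzchar(digits)) as.integer(digits) else nchar(body)
      total <- total + if (sign_chr == "+") mag else -mag
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}

# Heavy (non-hydrogen) atom count from the backend formula.
smiles_heavy_atoms <- function(smiles) {
  counts <- smiles_element_counts(smiles)
  if (!length(counts)) return(NA_integer_)
  sum(counts[setdiff(names(counts), "H")])
}
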