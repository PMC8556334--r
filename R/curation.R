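# Consensus curation: collapse per-identity measurement sets into one
# numeric value and/or one categorical label, graded A-D by reliability.
#
# Numeric track (applied to the post-filter value list of one molecule):
#   A: a single unique value            -> that value
#   B: several values, all within 5% of their mean -> the mean
#   C: exactly two distinct values (failing B)     -> multiplicity-weighted mean
#   D: more than two distinct values (failing B)   -> modal value; modal tie
#      discards the molecule
# Categorical track:
#   A: molecule has curated numeric data -> label derived from log BB at
#      threshold -1
#   B: all labels agree, every source reports threshold -1
#   C: all labels agree, threshold metadata incomplete
#   D: conflicting labels -> majority label; exact tie discards
#
# "Distinct" is judged after rounding to `digits` decimal places (log BB is
# typically reported to 2), configurable throughout.

#' Move outlying log BB values aside
#'
#' Values at or below the cutoff are regarded as physically implausible
#' reporting artefacts and removed per instance (the molecule keeps its
#' other values).
#'
#' @param values Numeric vector of log BB values.
#' @param cutoff Outlier cutoff; values `<= cutoff` are dropped
#'   (default -9, inclusive).
#' @return List with `kept` and `dropped` numeric vectors.
#' @examples
#' filter_outliers(c(-9.5, 0.2))  # kept 0.2, dropped -9.5
#' filter_outliers(c(-9))         # boundary value is dropped
#' @export
filter_outliers <- function(values, cutoff = -9) {
  values <- as.numeric(values)
  drop <- !is.na(values) & values <= cutoff
  list(kept = values[!drop & !is.na(values)], dropped = values[drop])
}

#' Should a molecule's value list be kept, given its spread?
#'
#' Molecules whose reported values disagree by more than `max_spread` log
#' units are judged irreconcilable and discarded whole.
#'
#' @param values Non-empty numeric vector (post-outlier).
#' @param max_spread Maximum allowed `max - min` (default 1; the boundary is
#'   strict, a spread of exactly 1 is kept).
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
spread_filter <- function(values, max_spread = 1) {
  stopifnot(length(values) > 0)
  (max(values) - min(values)) <= max_spread
}

#' Assign the numeric reliability group and consensus value
#'
#' @param values Numeric vector that already survived [filter_outliers()]
#'   and [spread_filter()].
#' @param tol Relative tolerance for group B: every value must satisfy
#'   `|v - mean| <= tol * |mean|` (default 0.05). When the mean is within
#'   `1e-8` of zero the relative tolerance is undefined and group B demands
#'   all values identical after rounding.
#' @param digits Decimal places used to decide whether two values are
#'   distinct (default 2).
#' @return A list with `group` (`"A"`, `"B"`, `"C"`, `"D"`, or `NA` for a
#'   discard), `logbb` (consensus value or `NA`), `n_values`, `n_unique`,
#'   and `reason` (`NA` or `"modal_tie"` / `"empty"`).
#' @examples
#' assign_numeric_group(c(0.42))              # A
#' assign_numeric_group(c(-0.50, -0.51, -0.50))  # B, mean
#' assign_numeric_group(c(0.10, 0.10, 0.30))  # C, weighted mean 0.1667
#' assign_numeric_group(c(0.1, 0.1, 0.3, 0.3, 0.5))  # modal tie: discard
#' @export
assign_numeric_group <- function(values, tol = 0.05, digits = 2) {
  values <- as.numeric(values)
  n <- length(values)
  out <- list(group = NA_character_, logbb = NA_real_, n_values = n,
              n_unique = 0L, reason = NA_character_)
  if (n == 0L) {
    out$reason <- "empty"
    return(out)
  }
  rounded <- round(values, digits)
  uniq <- unique(rounded)
  out$n_unique <- length(uniq)

  if (length(uniq) == 1L) {
    out$group <- "A"
    out$logbb <- mean(values)
    return(out)
  }
  m <- mean(values)
  within_tol <- if (abs(m) < 1e-8) FALSE else all(abs(values - m) <= tol * abs(m))
  if (within_tol) {
    out$group <- "B"
    out$logbb <- m
    return(out)
  }
  if (length(uniq) == 2L) {
    # weighted mean, weights = multiplicity of each distinct value; equal to
    # the plain mean of the raw list
    out$group <- "C"
    out$logbb <- m
    return(out)
  }
  counts <- table(rounded)
  top <- max(counts)
  modes <- as.numeric(names(counts)[counts == top])
  if (length(modes) > 1L) {
    out$reason <- "modal_tie"
    return(out)
  }
  out$group <- "D"
  out$logbb <- mean(values[rounded == modes])
  out
}

#' Derive a permeability label from a log BB value
#'
#' @param logbb Finite numeric log BB value(s).
#' @param threshold Classification threshold (default -1, the most widely
#'   used convention). The boundary is classified BBB+ (`>=`).
#' @return `"BBB+"` or `"BBB-"`, vectorized over `logbb`.
#' @examples
#' label_from_logbb(-0.5)  # "BBB+"
#' label_from_logbb(-1.5)  # "BBB-"
#' label_from_logbb(-1)    # boundary: "BBB+"
#' @export
label_from_logbb <- function(logbb, threshold = -1) {
  if (any(!is.finite(logbb)) || !is.finite(threshold)) {
    stop("label_from_logbb(): non-finite input", call. = FALSE)
  }
  ifelse(logbb >= threshold, "BBB+", "BBB-")
}

#' Assign the categorical reliability group and consensus label
#'
#' @param labels Character vector of source labels (`"BBB+"` / `"BBB-"`);
#'   may be empty when numeric data is present.
#' @param thresholds Numeric vector aligned with `labels`; `NA` where the
#'   source did not report its threshold.
#' @param numeric_logbb Curated numeric log BB for this molecule, or `NA`
#'   if the molecule has no numeric record.
#' @param threshold Classification threshold for group A (default -1).
#' @return List with `group` (`"A"`..`"D"` or `NA` for discard), `label`,
#'   `threshold_used` (-1 for group A, the common threshold for B, `NA`
#'   otherwise), and `reason` (`NA` or `"label_tie"` / `"empty"`).
#' @export
assign_categorical_group <- function(labels, thresholds = rep(NA_real_, length(labels)),
                                     numeric_logbb = NA_real_, threshold = -1) {
  out <- list(group = NA_character_, label = NA_character_,
              threshold_used = NA_real_, reason = NA_character_)
  if (!is.na(numeric_logbb)) {
    out$group <- "A"
    out$label <- label_from_logbb(numeric_logbb, threshold)
    out$threshold_used <- threshold
    return(out)
  }
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) {
    out$reason <- "empty"
    return(out)
  }
  uniq <- unique(labels)
  if (length(uniq) == 1L) {
    thr_known <- length(thresholds) == length(labels) &&
      all(!is.na(thresholds)) && all(thresholds == threshold)
    out$group <- if (thr_known) "B" else "C"
    out$label <- uniq
    if (thr_known) out$threshold_used <- threshold
    return(out)
  }
  counts <- table(labels)
  top <- max(counts)
  modes <- names(counts)[counts == top]
  if (length(modes) > 1L) {
    out$reason <- "label_tie"
    return(out)
  }
  out$group <- "D"
  out$label <- modes
  out
}

#' Build per-identity measurement sets from standardized source records
#'
#' @param records Tibble of source records (with `logbb`, `label`,
#'   `threshold`, `source_id` columns).
#' @param inchi Character vector aligned with `records` rows: the merge key
#'   of each record's standardized structure (`NA` for rejected records,
#'   which are excluded).
#' @return Tibble with one row per unique InChI: list-columns
#'   `logbb_values`, `logbb_sources`, `labels`, `label_thresholds`,
#'   `label_sources`, plus `inchi` and `n_records`.
#' @export
build_measurement_sets <- function(records, inchi) {
  stopifnot(nrow(records) == length(inchi))
  keep <- !is.na(inchi)
  records <- records[keep, , drop = FALSE]
  inchi <- inchi[keep]
  if (!nrow(records)) {
    return(tibble::tibble(inchi = character(0), n_records = integer(0),
                          logbb_values = list(), logbb_sources = list(),
                          labels = list(), label_thresholds = list(),
                          label_sources = list()))
  }
  split_idx <- split(seq_len(nrow(records)), inchi)
  tibble::tibble(
    inchi = names(split_idx),
    n_records = lengths(split_idx),
    logbb_values = lapply(split_idx, function(i) {
      v <- records$logbb[i]; v[!is.na(v)]
    }),
    logbb_sources = lapply(split_idx, function(i) {
      records$source_id[i][!is.na(records$logbb[i])]
    }),
    labels = lapply(split_idx, function(i) {
      l <- records$label[i]; l[!is.na(l)]
    }),
    label_thresholds = lapply(split_idx, function(i) {
      records$threshold[i][!is.na(records$label[i])]
    }),
    label_sources = lapply(split_idx, function(i) {
      records$source_id[i][!is.na(records$label[i])]
    })
  )
}

#' Curate the numeric track
#'
#' Applies, per molecule: instance-level outlier removal, molecule-level
#' spread filtering, then reliability grouping.
#'
#' @param sets Measurement sets from [build_measurement_sets()].
#' @param outlier_cutoff,max_spread,tol,digits Rule parameters; see
#'   [filter_outliers()], [spread_filter()], [assign_numeric_group()].
#' @return List with `records` (tibble: `inchi`, `logbb`, `group`,
#'   `n_values`, `n_unique`, `sources`, `comment`) and `discards` (tibble:
#'   `inchi`, `reason`).
#' @export
curate_numeric <- function(sets, outlier_cutoff = -9, max_spread = 1,
                           tol = 0.05, digits = 2) {
  has_num <- lengths(sets$logbb_values) > 0
  sets <- sets[has_num, , drop = FALSE]
  rows <- vector("list", nrow(sets))
  discards <- vector("list", nrow(sets))
  for (i in seq_len(nrow(sets))) {
    vals <- sets$logbb_values[[i]]
    srcs <- sets$logbb_sources[[i]]
    fo <- filter_outliers(vals, cutoff = outlier_cutoff)
    srcs <- srcs[!(vals <= outlier_cutoff)]
    comment <- NA_character_
    if (length(fo$dropped)) {
      comment <- sprintf("%d outlier value(s) <= %g removed",
                         length(fo$dropped), outlier_cutoff)
    }
    if (!length(fo$kept)) {
      discards[[i]] <- tibble::tibble(inchi = sets$inchi[i], reason = "all values outliers")
      next
    }
    if (!spread_filter(fo$kept, max_spread = max_spread)) {
      discards[[i]] <- tibble::tibble(inchi = sets$inchi[i],
                                      reason = sprintf("value spread > %g", max_spread))
      next
    }
    g <- assign_numeric_group(fo$kept, tol = tol, digits = digits)
    if (is.na(g$group)) {
      discards[[i]] <- tibble::tibble(inchi = sets$inchi[i],
                                      reason = paste0("numeric ", g$reason))
      next
    }
    rows[[i]] <- tibble::tibble(
      inchi = sets$inchi[i], logbb = g$logbb, group = g$group,
      n_values = g$n_values, n_unique = g$n_unique,
      sources = paste(unique(srcs), collapse = "; "),
      comment = comment
    )
  }
  list(records = dplyr::bind_rows(rows), discards = dplyr::bind_rows(discards))
}

#' Curate the categorical track
#'
#' Molecules with curated numeric data form group A (label derived from the
#' consensus log BB at the classification threshold); remaining molecules
#' are graded by label concordance and threshold metadata. Conflicting
#' source labels for a numeric (group A) molecule are noted in the comment,
#' not used.
#'
#' @param sets Measurement sets from [build_measurement_sets()].
#' @param numeric_records Curated numeric records
#'   (`curate_numeric()$records`).
#' @param threshold Classification threshold (default -1).
#' @return List with `records` (tibble: `inchi`, `label`, `group`,
#'   `threshold_used`, `n_labels`, `n_unique_labels`, `sources`, `comment`)
#'   and `discards`.
#' @export
curate_categorical <- function(sets, numeric_records, threshold = -1) {
  num_idx <- match(sets$inchi, numeric_records$inchi)
  rows <- vector("list", nrow(sets))
  discards <- vector("list", nrow(sets))
  for (i in seq_len(nrow(sets))) {
    labels <- sets$labels[[i]]
    thrs <- sets$label_thresholds[[i]]
    srcs <- sets$label_sources[[i]]
    num_logbb <- if (!is.na(num_idx[i])) numeric_records$logbb[num_idx[i]] else NA_real_
    g <- assign_categorical_group(labels, thrs, numeric_logbb = num_logbb,
                                  threshold = threshold)
    if (is.na(g$group)) {
      if (identical(g$reason, "empty")) next  # numeric-only molecule that failed numeric curation
      discards[[i]] <- tibble::tibble(inchi = sets$inchi[i],
                                      reason = paste0("categorical ", g$reason))
      next
    }
    comment <- NA_character_
    if (g$group == "A" && length(unique(labels)) > 1L) {
      comment <- "conflicting source labels superseded by numeric data"
    } else if (g$group == "A" && length(labels) &&
               !all(labels == g$label)) {
      comment <- "source label disagrees with numeric-derived label"
    }
    n_labels <- length(labels)
    rows[[i]] <- tibble::tibble(
      inchi = sets$inchi[i], label = g$label, group = g$group,
      threshold_used = g$threshold_used,
      # group A labels are derived from the single curated value
      n_labels = if (g$group == "A") 1L else n_labels,
      n_unique_labels = if (g$group == "A") 1L else length(unique(labels)),
      sources = if (g$group == "A") {
        paste(unique(c(sets$logbb_sources[[i]], srcs)), collapse = "; ")
      } else {
        paste(unique(srcs), collapse = "; ")
      },
      comment = comment
    )
  }
  list(records = dplyr::bind_rows(rows), discards = dplyr::bind_rows(discards))
}
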