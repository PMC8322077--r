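# TMT / LFQ PSM filters, redundancy collapse, match-between-runs, and
# Tukey median polish summarization.

reporter_columns <- function(psms) {
  cols <- grep("^reporter_", names(psms), value = TRUE)
  if (!length(cols)) stop("missing field: reporter_* intensity columns")
  cols
}

#' TMT PSM filters
#'
#' Removes, in order, PSMs that are (1) from decoy proteins; (2) from
#' peptides shorter than 7 residues; (3) with isolation specificity below
#' 0.5; (4) whose minimum reporter-ion intensity across channels is below
#' 256; or (5) whose summed reporter-ion intensity across all channels is
#' below 30,000. All inequalities are strict, so a PSM exactly at a
#' threshold is retained. Rule 4's "reporter ion intensity less than 256" is
#' interpreted against the per-channel minimum (configurable via
#' `min_reporter_rule`).
#'
#' @param psms PSM table with `decoy`, `peptide_sequence`,
#'   `isolation_specificity` and `reporter_*` columns.
#' @param min_length,min_specificity,min_reporter,min_summed thresholds.
#' @param min_reporter_rule "min" (default) tests the per-channel minimum;
#'   "any" is equivalent; "all" removes only if every channel is below.
#' @return list: `retained` (filtered table) and `removed` (named counts per
#'   rule, applied sequentially).
#' @export
filter_tmt_psms <- function(psms, min_length = 7L, min_specificity = 0.5,
                            min_reporter = 256, min_summed = 30000,
                            min_reporter_rule = c("min", "all")) {
  min_reporter_rule <- match.arg(min_reporter_rule)
  for (f in c("decoy", "peptide_sequence", "isolation_specificity")) {
    if (!f %in% names(psms)) stop("missing field: ", f)
  }
  rep_cols <- reporter_columns(psms)
  removed <- c(decoy = 0L, short_peptide = 0L, low_specificity = 0L,
               low_reporter = 0L, low_summed = 0L)
  keep <- !psms$decoy
  removed["decoy"] <- sum(!keep)
  psms <- psms[keep, , drop = FALSE]

  keep <- nchar(psms$peptide_sequence) >= min_length
  removed["short_peptide"] <- sum(!keep)
  psms <- psms[keep, , drop = FALSE]

  keep <- psms$isolation_specificity >= min_specificity
  removed["low_specificity"] <- sum(!keep)
  psms <- psms[keep, , drop = FALSE]

  rep_mat <- as.matrix(psms[rep_cols])
  stat <- if (min_reporter_rule == "min") {
    apply(rep_mat, 1, min)
  } else {
    apply(rep_mat, 1, max)
  }
  keep <- stat >= min_reporter
  removed["low_reporter"] <- sum(!keep)
  psms <- psms[keep, , drop = FALSE]

  keep <- rowSums(as.matrix(psms[rep_cols])) >= min_summed
  removed["low_summed"] <- sum(!keep)
  psms <- psms[keep, , drop = FALSE]

  list(retained = psms, removed = removed)
}

#' Label-free PSM filters
#'
#' Removes, in order, PSMs that are (1) from decoy proteins; (2) from
#' peptides shorter than 7 residues; (3) with quantification confidence
#' scores below 71; or (4) with peak area below 256. Strict inequalities: a
#' PSM exactly at a threshold is retained.
#'
#' @param psms PSM table with `decoy`, `peptide_sequence`,
#'   `quant_confidence`, `peak_area`.
#' @param min_length,min_confidence,min_area thresholds.
#' @return list: `retained` and per-rule `removed` counts.
#' @export
filter_lfq_features <- function(psms, min_length = 7L, min_confidence = 71,
                                min_area = 256) {
  for (f in c("decoy", "peptide_sequence", "quant_confidence", "peak_area")) {
    if (!f %in% names(psms)) stop("missing field: ", f)
  }
  removed <- c(decoy = 0L, short_peptide = 0L, low_confidence = 0L,
               low_area = 0L)
  keep <- !psms$decoy
  removed["decoy"] <- sum(!keep)
  psms <- psms[keep, , drop = FALSE]

  keep <- nchar(psms$peptide_sequence) >= min_length
  removed["short_peptide"] <- sum(!keep)
  psms <- psms[keep, , drop = FALSE]

  keep <- psms$quant_confidence >= min_confidence
  removed["low_confidence"] <- sum(!keep)
  psms <- psms[keep, , drop = FALSE]

  keep <- psms$peak_area >= min_area
  removed["low_area"] <- sum(!keep)
  psms <- psms[keep, , drop = FALSE]

  list(retained = psms, removed = removed)
}

#' Collapse redundant PSMs
#'
#' TMT mode: per peptide and fraction, take the channel-wise maximum
#' reporter intensity across PSMs, then keep the fraction whose summed
#' reporter intensity is maximal. LFQ mode: per peptide and run, take the
#' maximum peak area.
#'
#' @param psms filtered PSM table; peptides are keyed by sequence +
#'   modification multiset.
#' @param mode "tmt" or "lfq".
#' @return one row per peptide (TMT) or per peptide x run (LFQ).
#' @export
collapse_redundant <- function(psms, mode = c("tmt", "lfq")) {
  mode <- match.arg(mode)
  key <- peptide_key(psms$peptide_sequence, psms$mods)
  if (mode == "tmt") {
    rep_cols <- reporter_columns(psms)
    frac <- if ("fraction_id" %in% names(psms)) psms$fraction_id else 1L
    groups <- split(seq_len(nrow(psms)), paste(key, frac, sep = "\r"))
    per_frac <- lapply(groups, function(idx) {
      row <- psms[idx[1], , drop = FALSE]
      row[rep_cols] <- as.list(apply(psms[idx, rep_cols, drop = FALSE], 2, max))
      row
    })
    tab <- do.call(rbind, per_frac)
    tab_key <- peptide_key(tab$peptide_sequence, tab$mods)
    sums <- rowSums(as.matrix(tab[rep_cols]))
    ord <- order(-sums)
    tab <- tab[ord, , drop = FALSE]
    tab <- tab[!duplicated(tab_key[ord]), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  } else {
    groups <- split(seq_len(nrow(psms)), paste(key, psms$run_id, sep = "\r"))
    rows <- lapply(groups, function(idx) {
      psms[idx[which.max(psms$peak_area[idx])], , drop = FALSE]
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab
  }
}

#' Cross-run quantification completion (match between runs)
#'
#' For every identified peptide (anchor) and every run lacking a direct
#' identification, searches that run's MS1 feature table for a feature
#' within `ppm_tol` of the peptide's theoretical precursor m/z and within
#' `rt_tol` minutes of the expected retention time. The expected RT is the
#' median anchor RT across runs plus a per-run median shift estimated from
#' the run's own identified anchors. The maximum-area match is transferred;
#' no match leaves the cell missing.
#'
#' @param quant long table of identified quantities: columns `feature_id`,
#'   `run_id`, `log2_area`, `mz`, `rt`.
#' @param run_features per-run MS1 features: columns `run_id`, `mz`, `rt`,
#'   `area`.
#' @param ppm_tol m/z tolerance in ppm (default 10, the usual XIC window).
#' @param rt_tol retention-time tolerance in minutes (default 2).
#' @return `quant` completed with transferred rows (flagged
#'   `matched = TRUE`).
#' @export
match_between_runs <- function(quant, run_features, ppm_tol = 10,
                               rt_tol = 2) {
  runs <- unique(c(quant$run_id, run_features$run_id))
  quant$matched <- FALSE
  ref_rt <- tapply(quant$rt, quant$feature_id, stats::median)
  shift <- vapply(runs, function(r) {
    q <- quant[quant$run_id == r, , drop = FALSE]
    if (!nrow(q)) return(0)
    stats::median(q$rt - ref_rt[q$feature_id])
  }, 1)
  names(shift) <- runs
  feats <- unique(quant$feature_id)
  add <- list()
  for (f in feats) {
    qf <- quant[quant$feature_id == f, , drop = FALSE]
    mz_f <- qf$mz[1]
    missing_runs <- setdiff(runs, qf$run_id)
    for (r in missing_runs) {
      rf <- run_features[run_features$run_id == r, , drop = FALSE]
      if (!nrow(rf)) next
      exp_rt <- ref_rt[[f]] + shift[[r]]
      ok <- abs(ppm_error(rf$mz, mz_f)) <= ppm_tol &
        abs(rf$rt - exp_rt) <= rt_tol
      if (!any(ok)) next
      hit <- rf[ok, , drop = FALSE]
      hit <- hit[which.max(hit$area), , drop = FALSE]
      add[[length(add) + 1]] <- data.frame(
        feature_id = f, run_id = r, log2_area = log2(hit$area),
        mz = hit$mz, rt = hit$rt, matched = TRUE,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(add)) {
    quant <- rbind(quant[names(add[[1]])], do.call(rbind, add))
  }
  rownames(quant) <- NULL
  quant
}

#' Tukey median polish summarization of one feature
#'
#' Decomposes a peptides x samples log2 matrix into overall + row + column
#' effects + residuals by alternating row/column median sweeps
#' (`stats::medpolish`, 10 iterations max, convergence tolerance 0.01,
#' missing values ignored). The per-sample abundance is overall + column
#' effect; an all-missing column yields a missing abundance.
#'
#' @param x numeric matrix (rows = peptide forms, columns = samples), log2
#'   scale, NAs allowed.
#' @return list: `abundance` (named per-sample vector), `overall`, `row`,
#'   `col`, `residuals`.
#' @export
tukey_median_polish <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1 || ncol(x) < 1) stop("need at least one row and column")
  keep <- colSums(!is.na(x)) > 0
  ab <- rep(NA_real_, ncol(x))
  names(ab) <- colnames(x)
  res <- matrix(NA_real_, nrow(x), ncol(x),
                dimnames = dimnames(x))
  roweff <- rep(NA_real_, nrow(x))
  coleff <- rep(NA_real_, ncol(x))
  if (!any(keep)) {
    return(list(abundance = ab, overall = NA_real_, row = roweff,
                col = coleff, residuals = res))
  }
  xs <- x[, keep, drop = FALSE]
  keep_r <- rowSums(!is.na(xs)) > 0
  xs <- xs[keep_r, , drop = FALSE]
  if (nrow(xs) == 1) {
    ab[keep] <- xs[1, ]
    res[keep_r, keep] <- 0 * xs
    ov <- stats::median(xs, na.rm = TRUE)
    coleff[keep] <- ab[keep] - ov
    roweff[keep_r] <- 0
    return(list(abundance = ab, overall = ov, row = roweff, col = coleff,
                residuals = res))
  }
  mp <- suppressWarnings(
    stats::medpolish(xs, eps = 0.01, maxiter = 10L, trace.iter = FALSE,
                     na.rm = TRUE)
  )
  ab[keep] <- mp$overall + mp$col
  roweff[keep_r] <- mp$row
  coleff[keep] <- mp$col
  res[keep_r, keep] <- mp$residuals
  list(abundance = ab, overall = mp$overall, row = roweff, col = coleff,
       residuals = res)
}

#' Summarize peptides to protein-site abundances
#'
#' Builds the feature x sample log2 abundance matrix by applying Tukey
#' median polish per feature over its peptide forms.
#'
#' @param long long table: `feature_id`, `peptide_key`, `sample_id`,
#'   `log2_intensity`.
#' @param samples optional character vector fixing the column order.
#' @return numeric matrix, features x samples.
#' @export
summarize_features <- function(long, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(long$sample_id))
  feats <- unique(long$feature_id)
  out <- matrix(NA_real_, length(feats), length(samples),
                dimnames = list(feats, samples))
  for (f in feats) {
    sub <- long[long$feature_id == f, , drop = FALSE]
    peps <- unique(sub$peptide_key)
    m <- matrix(NA_real_, length(peps), length(samples),
                dimnames = list(peps, samples))
    m[cbind(match(sub$peptide_key, peps), match(sub$sample_id, samples))] <-
      sub$log2_intensity
    out[f, ] <- tukey_median_polish(m)$abundance
  }
  out
}
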