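# Target-decoy discriminant rescoring and FDR filtering.

#' Peptide key used when collapsing PSMs
#'
#' Sequence plus the (order-normalised) modification multiset; charge is
#' ignored.
#' @keywords internal
peptide_key <- function(sequence, mods) {
  norm <- vapply(mods, function(m) {
    p <- parse_mods(m)
    if (nrow(p) == 0) return("")
    p <- p[order(p$position, p$name), , drop = FALSE]
    paste(p$name, p$position, sep = "@", collapse = ";")
  }, "", USE.NAMES = FALSE)
  paste(sequence, norm, sep = "/")
}

#' Fit a target-decoy linear discriminant scorer
#'
#' Two-class linear discriminant (pooled within-class covariance) separating
#' target from decoy PSMs. Default features: search score, absolute
#' precursor ppm error, peptide length, missed cleavages. The returned
#' scoring function projects a PSM table onto the discriminant axis,
#' oriented so that higher scores are more target-like. If the pooled
#' covariance is degenerate (constant or collinear features) the scorer
#' falls back to the raw search score with a warning.
#'
#' @param psms PSM table with a logical `decoy` column.
#' @param features named list mapping feature names to numeric vectors
#'   aligned with `psms` rows; if NULL, the default four features are pulled
#'   from columns `search_score`, `ppm`, `peptide_sequence`,
#'   `missed_cleavages` (absent columns are skipped).
#' @return object of class `gg_discriminant`: a list with `score(psms or
#'   feature data.frame)` plus the fitted `lda` object (or NULL on fallback).
#' @export
fit_discriminant <- function(psms, features = NULL) {
  if (sum(!psms$decoy) < 20 || sum(psms$decoy) < 20) {
    stop("need at least 20 target and 20 decoy PSMs to fit a discriminant; ",
         "use the raw search score instead")
  }
  extract <- function(tab) {
    if (!is.null(features)) return(as.data.frame(features))
    f <- list(search_score = tab$search_score)
    if ("ppm" %in% names(tab)) f$abs_ppm <- abs(tab$ppm)
    f$length <- nchar(tab$peptide_sequence)
    if ("missed_cleavages" %in% names(tab)) {
      f$missed_cleavages <- tab$missed_cleavages
    }
    as.data.frame(f)
  }
  x <- extract(psms)
  grp <- factor(ifelse(psms$decoy, "decoy", "target"))
  fit <- tryCatch(MASS::lda(x, grouping = grp),
                  error = function(e) NULL,
                  warning = function(w) {
                    # collinear / constant-within-group features
                    tryCatch(suppressWarnings(MASS::lda(x, grouping = grp)),
                             error = function(e) NULL)
                  })
  if (is.null(fit)) {
    warning("degenerate covariance; falling back to raw search score")
    scorer <- function(tab) tab$search_score
    return(structure(list(score = scorer, lda = NULL,
                          features = names(x)),
                     class = "gg_discriminant"))
  }
  w <- fit$scaling[, 1]
  mu <- colMeans(fit$means)
  # orient: targets score higher
  sgn <- sign(sum((fit$means["target", ] - fit$means["decoy", ]) * w))
  if (sgn == 0) sgn <- 1
  scorer <- function(tab) {
    xt <- if (all(names(x) %in% names(tab))) {
      tab[names(x)]
    } else {
      extract(tab)
    }
    sgn * as.numeric(as.matrix(xt) %*% w - sum(mu * w))
  }
  structure(list(score = scorer, lda = fit, features = names(x),
                 direction = sgn * w),
            class = "gg_discriminant")
}

#' @export
print.gg_discriminant <- function(x, ...) {
  cat("Target-decoy linear discriminant\n")
  if (is.null(x$lda)) {
    cat("  degenerate covariance: raw search-score fallback\n")
  } else {
    cat("  features:", paste(x$features, collapse = ", "), "\n")
    cat("  direction:", paste(signif(x$direction, 4), collapse = " "), "\n")
  }
  invisible(x)
}

#' Score/threshold selection at a target FDR
#'
#' Estimated FDR at threshold t is `#(decoys >= t) / #(targets >= t)`; the
#' smallest t whose estimate is at or below `target_fdr` is chosen, so the
#' retained set is maximal. Ties at the threshold are retained (inclusive).
#' At the peptide level, PSMs are first collapsed to the best-scoring PSM
#' per peptide (sequence + modification multiset).
#'
#' @param scored data.frame with columns `score`, `decoy`, and (for peptide
#'   level) `peptide_sequence`, `mods`.
#' @param level "psm" or "peptide".
#' @param target_fdr fraction in (0, 1).
#' @return list: `threshold`, `retained` (target rows of the collapsed
#'   table), `fdr_estimate`, `level`.
#' @export
compute_fdr_threshold <- function(scored, level = c("psm", "peptide"),
                                  target_fdr = 0.05) {
  level <- match.arg(level)
  stopifnot(target_fdr > 0, target_fdr < 1)
  tab <- scored
  if (level == "peptide") {
    key <- peptide_key(tab$peptide_sequence, tab$mods)
    ord <- order(-tab$score)
    tab <- tab[ord, , drop = FALSE]
    tab <- tab[!duplicated(key[ord]), , drop = FALSE]
  }
  # the retained target set only changes at target scores, so those are the
  # candidate thresholds
  cand <- sort(unique(tab$score[!tab$decoy]))
  est <- vapply(cand, function(t) {
    nt <- sum(tab$score >= t & !tab$decoy)
    nd <- sum(tab$score >= t & tab$decoy)
    if (nt == 0) Inf else nd / nt
  }, 1)
  ok <- which(est <= target_fdr)
  if (!length(ok)) {
    warning("no threshold achieves the target FDR; returning empty set")
    return(list(threshold = Inf,
                retained = tab[0, , drop = FALSE],
                fdr_estimate = NA_real_, level = level))
  }
  t0 <- cand[min(ok)]
  list(threshold = t0,
       retained = tab[tab$score >= t0 & !tab$decoy, , drop = FALSE],
       fdr_estimate = est[min(ok)],
       level = level)
}

#' Protein-level decoy FDR of a retained peptide set
#'
#' Collapses to the best-scoring peptide per protein accession and reports
#' the decoy/target protein ratio.
#'
#' @param peptides data.frame with columns `accession`, `decoy`, `score`.
#' @return fraction: decoy proteins / target proteins.
#' @export
protein_fdr <- function(peptides) {
  if (nrow(peptides) == 0) stop("empty peptide set")
  ord <- order(-peptides$score)
  best <- peptides[ord, , drop = FALSE]
  best <- best[!duplicated(best$accession), , drop = FALSE]
  n_decoy <- sum(best$decoy)
  n_target <- sum(!best$decoy)
  if (n_target == 0) stop("no target proteins retained")
  n_decoy / n_target
}

#' Precursor ppm mass-window filter
#'
#' Retains PSMs whose signed precursor ppm error lies inside the closed
#' window, default -5 to +4 ppm — deliberately asymmetric to follow the
#' typical slight positive calibration bias of Orbitrap precursor masses.
#'
#' @param psms PSM table with columns `observed_mz`, `charge`,
#'   `peptide_sequence`, `mods` (or a precomputed `ppm` column).
#' @param low_ppm,high_ppm inclusive window bounds.
#' @return the retained subset, with a `ppm` column attached.
#' @export
mass_tolerance_filter <- function(psms, low_ppm = -5, high_ppm = 4) {
  if (!"ppm" %in% names(psms)) {
    theo <- vapply(seq_len(nrow(psms)), function(i) {
      precursor_mz(peptide_mass(psms$peptide_sequence[i], psms$mods[i]),
                   psms$charge[i])
    }, 1)
    psms$ppm <- ppm_error(psms$observed_mz, theo)
  }
  psms[psms$ppm >= low_ppm & psms$ppm <= high_ppm, , drop = FALSE]
}
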