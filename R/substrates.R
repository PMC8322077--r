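# Substrate calling, experiment intersection, and sequence-preference
# profiling of N-terminal GGX peptides.

#' Call substrates from contrast results
#'
#' A feature passes a contrast when `log2FC > lfc_min` and `p < p_max`, both
#' strict, so a feature sitting exactly on a cutoff is not called. A feature
#' is `high_confidence` when it passes every required contrast. Features
#' missing an estimate for a required contrast are flagged and never called.
#' By default the unadjusted model p-value gates the call (the BH-adjusted
#' value is carried alongside in the contrast table); set `use_adjusted_p`
#' to gate on `p_adj` instead.
#'
#' @param results `gg_contrasts` table from [fit_contrasts()].
#' @param required_contrasts character vector of contrast names the call
#'   must satisfy (default: all contrasts present).
#' @param lfc_min log2 fold-change cutoff (default 1.0).
#' @param p_max p-value cutoff (default 0.05).
#' @param use_adjusted_p gate on BH-adjusted p instead of raw p.
#' @return data.frame, one row per feature: `feature_id`, per-contrast
#'   `log2FC_*`, `p_*` and `pass_*` columns, `n_pass`, `high_confidence`,
#'   `flag` ("" or "missing_contrast").
#' @export
call_substrates <- function(results, required_contrasts = NULL,
                            lfc_min = 1.0, p_max = 0.05,
                            use_adjusted_p = FALSE) {
  if (is.null(required_contrasts)) {
    required_contrasts <- unique(results$contrast)
  }
  missing_c <- setdiff(required_contrasts, unique(results$contrast))
  if (length(missing_c)) {
    stop("results lack required contrast(s): ",
         paste(missing_c, collapse = ", "))
  }
  feats <- unique(results$feature_id)
  out <- data.frame(feature_id = feats, stringsAsFactors = FALSE)
  pass_mat <- matrix(NA, length(feats), length(required_contrasts),
                     dimnames = list(feats, required_contrasts))
  for (cn in required_contrasts) {
    d <- results[results$contrast == cn, , drop = FALSE]
    i <- match(feats, d$feature_id)
    lfc <- d$log2FC[i]
    p <- if (use_adjusted_p) d$p_adj[i] else d$p[i]
    pass <- !is.na(lfc) & !is.na(p) & lfc > lfc_min & p < p_max
    pass[is.na(lfc) | is.na(p)] <- NA
    pass_mat[, cn] <- pass
    out[[paste0("log2FC_", cn)]] <- lfc
    out[[paste0("p_", cn)]] <- p
    out[[paste0("pass_", cn)]] <- pass
  }
  incomplete <- apply(pass_mat, 1, anyNA)
  out$n_pass <- rowSums(pass_mat, na.rm = TRUE)
  out$high_confidence <- !incomplete & rowSums(pass_mat) == length(required_contrasts)
  out$flag <- ifelse(incomplete, "missing_contrast", "")
  rownames(out) <- NULL
  out
}

#' Intersection (Venn region) counts across experiments
#'
#' @param call_sets named list (>= 2 elements) of identifier vectors, one per
#'   experiment.
#' @return data.frame with one row per non-empty membership region:
#'   `region` ("A", "A&B", ...), `count`; attribute `union_size` carries the
#'   union total.
#' @export
intersect_experiments <- function(call_sets) {
  if (length(call_sets) < 2) stop("need at least two call sets")
  if (is.null(names(call_sets)) || any(!nzchar(names(call_sets)))) {
    stop("call sets must be named")
  }
  all_ids <- unique(unlist(call_sets))
  member <- vapply(call_sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, names(call_sets)))
  region <- apply(member, 1, function(m) {
    paste(names(call_sets)[m], collapse = "&")
  })
  counts <- table(region)
  out <- data.frame(region = names(counts),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "union_size") <- length(all_ids)
  out
}

#' Residue frequency at the X position of N-terminal GG peptides
#'
#' @param peptides character vector of matched peptide sequences, each
#'   carrying an N-terminal GG remnant (the X position is the peptide's
#'   first residue, i.e. position 3 counting the two remnant glycines).
#' @param position residue position within the peptide to profile
#'   (default 1 = the X position).
#' @return data.frame `residue`, `count`, `fraction` sorted by decreasing
#'   count.
#' @export
residue_frequency_profile <- function(peptides, position = 1L) {
  if (length(peptides) == 0) stop("empty peptide set")
  res <- substr(peptides, position, position)
  if (any(!nzchar(res))) stop("peptide(s) shorter than the requested position")
  counts <- table(res)
  out <- data.frame(residue = names(counts),
                    count = as.integer(counts),
                    fraction = as.integer(counts) / length(peptides),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$residue), ]
}

#' Position probability matrix and information content for sequence logos
#'
#' Aligns peptides with the two remnant glycines at positions 1-2 and the
#' matched sequence from position 3 on, pads/truncates to `length`, and
#' computes pseudocount-smoothed per-position probabilities over the 20
#' standard residues. Information content per position is
#' `log2(20) - H` with `H` the Shannon entropy in bits (uniform background).
#'
#' @param peptides N-terminal GG peptide sequences (without the GG letters).
#' @param length total logo length including the GG prefix (default 6).
#' @param pseudocount added to every residue count per position
#'   (default 0.5).
#' @return object of class `gg_logo`: list with `prob` (20 x length matrix),
#'   `ic` (bits per position), `n` (peptides used).
#' @export
sequence_logo_matrix <- function(peptides, length = 6L, pseudocount = 0.5) {
  if (base::length(peptides) == 0) stop("empty peptide set")
  aa <- sort(names(AA_MONO_MASS))
  aa <- aa[!duplicated(aa)]
  padded <- paste0("GG", peptides)
  prob <- matrix(NA_real_, base::length(aa), length,
                 dimnames = list(aa, seq_len(length)))
  ic <- numeric(length)
  for (p in seq_len(length)) {
    res <- substr(padded, p, p)
    res <- res[nzchar(res) & res %in% aa]
    counts <- stats::setNames(rep(pseudocount, base::length(aa)), aa)
    if (base::length(res)) {
      tb <- table(res)
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
    }
    pr <- counts / sum(counts)
    prob[, p] <- pr
    nz <- pr > 0
    h <- -sum(pr[nz] * log2(pr[nz]))
    ic[p] <- log2(base::length(aa)) - h
  }
  structure(list(prob = prob, ic = ic, n = base::length(peptides),
                 pseudocount = pseudocount),
            class = "gg_logo")
}

#' @export
print.gg_logo <- function(x, ...) {
  cat("Sequence logo matrix over", x$n, "peptides\n")
  cat("  information content (bits):",
      paste(signif(x$ic, 3), collapse = " "), "\n")
  top <- apply(x$prob, 2, function(p) rownames(x$prob)[which.max(p)])
  cat("  consensus:", paste(top, collapse = ""), "\n")
  invisible(x)
}

#' @export
plot.gg_logo <- function(x, ...) {
  graphics::barplot(x$ic, names.arg = seq_along(x$ic),
                    xlab = "position", ylab = "information content (bits)",
                    ...)
  invisible(x)
}

#' Write a logo matrix as TSV
#' @param logo `gg_logo` object.
#' @param path output path.
#' @export
write_logo_matrix <- function(logo, path) {
  tab <- as.data.frame(t(logo$prob))
  tab <- cbind(position = seq_len(nrow(tab)), ic = logo$ic, tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' MetAP compatibility annotation of substrate calls
#'
#' For each called substrate, reports the protein's second residue, whether
#' it belongs to the Met-aminopeptidase-susceptible set (A, C, G, P, S, T,
#' V), the observed site kind, and a `surprising` flag for initiator-Met
#' sites whose second residue is susceptible — proteins one would have
#' expected to be Met-clipped before ubiquitination.
#'
#' @param calls data.frame with columns `accession` and `site_kind`
#'   ("initiator_met" / "met_clipped" or the classifier verdict names).
#' @param proteome protein table.
#' @return annotation data.frame; unresolvable accessions are flagged.
#' @export
metap_compatibility <- function(calls, proteome) {
  i <- match(calls$accession, proteome$accession)
  second <- ifelse(is.na(i), NA, substr(proteome$sequence[i], 2, 2))
  susceptible <- !is.na(second) & second %in% METAP_SUSCEPTIBLE
  initiator <- calls$site_kind %in% c("initiator_met",
                                      "NTERM_UB_INITIATOR_MET")
  data.frame(
    accession = calls$accession,
    site_kind = calls$site_kind,
    second_residue = second,
    metap_susceptible = susceptible,
    surprising = initiator & susceptible,
    flag = ifelse(is.na(i), "unresolved_accession", ""),
    stringsAsFactors = FALSE
  )
}
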