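# End-to-end orchestration: classification -> FDR -> quantitative filters ->
# summarization -> contrasts -> substrate calls -> profiles.

#' Pipeline parameter set
#'
#' Bundles every tunable threshold with its default. The defaults reproduce
#' the production settings of the analysis: peptide FDR 3% (the pilot
#' screen used 5%), precursor ppm window -5 to +4, substrate gates
#' log2FC > 1 and p < 0.05 on both informative contrasts, TMT filters
#' (length >= 7, isolation specificity >= 50%, min reporter >= 256, summed
#' reporters >= 30,000), LFQ filters (length >= 7, confidence >= 71, peak
#' area >= 256), match-between-runs tolerances 10 ppm / 2 min, semi-tryptic
#' digestion with up to 2 missed cleavages.
#'
#' @param peptide_fdr target peptide-level FDR.
#' @param ppm_window length-2 numeric, inclusive precursor window.
#' @param lfc_min,p_max substrate-call gates.
#' @param required_contrasts contrast names a high-confidence call must pass.
#' @param mbr_ppm_tol,mbr_rt_tol match-between-runs tolerances.
#' @param max_missed,specificity digestion settings.
#' @param seed RNG seed for any stochastic step.
#' @param ... overrides for the TMT/LFQ filter thresholds
#'   (`tmt_min_length`, `tmt_min_specificity`, `tmt_min_reporter`,
#'   `tmt_min_summed`, `lfq_min_length`, `lfq_min_confidence`,
#'   `lfq_min_area`).
#' @return list of class `gg_params`.
#' @export
pipeline_params <- function(peptide_fdr = 0.03, ppm_window = c(-5, 4),
                            lfc_min = 1.0, p_max = 0.05,
                            required_contrasts = c("UBE2W-Control",
                                                   "Combo-RNF4"),
                            mbr_ppm_tol = 10, mbr_rt_tol = 2,
                            max_missed = 2L, specificity = "semi",
                            seed = 1L, ...) {
  extra <- list(...)
  defaults <- list(tmt_min_length = 7L, tmt_min_specificity = 0.5,
                   tmt_min_reporter = 256, tmt_min_summed = 30000,
                   lfq_min_length = 7L, lfq_min_confidence = 71,
                   lfq_min_area = 256)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  defaults[names(extra)] <- extra
  stopifnot(peptide_fdr > 0, peptide_fdr < 1,
            length(ppm_window) == 2, ppm_window[1] < ppm_window[2],
            p_max > 0, p_max <= 1, lfc_min >= 0)
  structure(c(list(peptide_fdr = peptide_fdr, ppm_window = ppm_window,
                   lfc_min = lfc_min, p_max = p_max,
                   required_contrasts = required_contrasts,
                   mbr_ppm_tol = mbr_ppm_tol, mbr_rt_tol = mbr_rt_tol,
                   max_missed = max_missed, specificity = specificity,
                   metap_set = METAP_SUSCEPTIBLE, seed = seed),
              defaults),
            class = "gg_params")
}

#' @export
print.gg_params <- function(x, ...) {
  cat("ggscan pipeline parameters\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper chaining [generate_proteome()] and
#' [generate_experiment()] under one seed.
#'
#' @param seed RNG seed.
#' @param mode "tmt" or "lfq".
#' @param n_proteins proteome size.
#' @param ... forwarded to [generate_experiment()].
#' @return list as from [generate_experiment()].
#' @export
simulate_experiment <- function(seed = 1L, mode = "tmt", n_proteins = 500,
                                ...) {
  prot <- generate_proteome(n_proteins = n_proteins, seed = seed)
  generate_experiment(prot, mode = mode, seed = seed, ...)
}

#' Run the full GG-remnant pipeline
#'
#' Stages, in order: GG-PSM classification against the proteome; precursor
#' ppm-window filter; target-decoy discriminant scoring and peptide-level
#' FDR filtering; TMT/LFQ quantitative filters; redundancy collapse;
#' (LFQ) match-between-runs completion; Tukey median polish summarization to
#' protein N-terminal sites; per-feature condition contrasts with BH
#' adjustment; substrate calling; X-position and logo profiling. Every stage
#' logs input/output counts.
#'
#' @param psms PSM table (see [generate_experiment()] for the schema).
#' @param proteome protein table including decoys.
#' @param design sample -> condition table.
#' @param params `gg_params` object.
#' @param contrasts contrast definition table (default
#'   [default_contrasts()]).
#' @param mode "tmt" or "lfq".
#' @param run_features LFQ MS1 feature table for match-between-runs
#'   (optional).
#' @param truth optional generator truth; adds recovery metrics.
#' @param output_dir optional directory; writes the standard TSV/JSON
#'   outputs and a plain-text log.
#' @return list: `classifications`, `scored`, `fdr`, `filter_report`,
#'   `matrix`, `contrasts`, `calls`, `x_profile`, `logo`, `metap`, `log`,
#'   and `recovery` when truth is supplied.
#' @export
run_pipeline <- function(psms, proteome, design, params = pipeline_params(),
                         contrasts = default_contrasts(),
                         mode = c("tmt", "lfq"), run_features = NULL,
                         truth = NULL, output_dir = NULL) {
  mode <- match.arg(mode)
  log <- character()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  note("input: %d PSMs, %d proteins (%d decoys)", nrow(psms),
       nrow(proteome), sum(proteome$is_decoy))

  # 1. precursor mass window -------------------------------------------
  psms <- mass_tolerance_filter(psms, params$ppm_window[1],
                                params$ppm_window[2])
  note("ppm window [%g, %g]: %d PSMs retained", params$ppm_window[1],
       params$ppm_window[2], nrow(psms))

  # 2. discriminant + peptide FDR ---------------------------------------
  scorer <- tryCatch(fit_discriminant(psms), error = function(e) NULL)
  psms$score <- if (is.null(scorer)) psms$search_score else scorer$score(psms)
  fdr_res <- compute_fdr_threshold(psms, level = "peptide",
                                   target_fdr = params$peptide_fdr)
  retained_keys <- peptide_key(fdr_res$retained$peptide_sequence,
                               fdr_res$retained$mods)
  keep <- peptide_key(psms$peptide_sequence, psms$mods) %in% retained_keys &
    !psms$decoy
  psms <- psms[keep, , drop = FALSE]
  note("peptide FDR <= %g (achieved %.3g, threshold %.3g): %d PSMs retained",
       params$peptide_fdr, fdr_res$fdr_estimate, fdr_res$threshold,
       nrow(psms))

  # 3. classification ----------------------------------------------------
  cls <- classify_gg_psms(psms, proteome, on_unmapped = "error")
  note("classification: %s",
       paste(names(table(cls$verdict)), table(cls$verdict),
             sep = "=", collapse = ", "))
  nterm_ids <- cls$psm_id[cls$verdict %in% c("NTERM_UB_INITIATOR_MET",
                                             "NTERM_UB_NEO_NTERM")]
  gg_nterm <- cls[cls$verdict %in% c("NTERM_UB_INITIATOR_MET",
                                     "NTERM_UB_NEO_NTERM",
                                     "INTERNAL_ENCODED_GGX"), , drop = FALSE]

  # profiles use every enriched GGX peptide (internal + N-terminal)
  x_profile <- residue_frequency_profile(gg_nterm$peptide_sequence)
  logo <- sequence_logo_matrix(gg_nterm$peptide_sequence)

  quant_in <- psms[psms$psm_id %in% nterm_ids, , drop = FALSE]
  site_kind <- ifelse(cls$verdict == "NTERM_UB_INITIATOR_MET",
                      "initiator_met", "met_clipped")
  quant_in$feature_id <- paste(cls$accession[match(quant_in$psm_id,
                                                   cls$psm_id)],
                               site_kind[match(quant_in$psm_id, cls$psm_id)],
                               sep = "|")
  note("N-terminal ubiquitination PSMs entering quantification: %d",
       nrow(quant_in))

  # 4. quantitative filters + collapse ----------------------------------
  if (mode == "tmt") {
    flt <- filter_tmt_psms(quant_in, min_length = params$tmt_min_length,
                           min_specificity = params$tmt_min_specificity,
                           min_reporter = params$tmt_min_reporter,
                           min_summed = params$tmt_min_summed)
  } else {
    flt <- filter_lfq_features(quant_in,
                               min_length = params$lfq_min_length,
                               min_confidence = params$lfq_min_confidence,
                               min_area = params$lfq_min_area)
  }
  filter_report <- data.frame(rule = names(flt$removed),
                              removed = as.integer(flt$removed))
  note("quant filters: removed %s; %d PSMs retained",
       paste(names(flt$removed), flt$removed, sep = "=", collapse = ", "),
       nrow(flt$retained))
  collapsed <- collapse_redundant(flt$retained, mode = mode)
  note("redundancy collapse: %d records", nrow(collapsed))

  # 5. long-format quant + optional MBR + TMP ---------------------------
  if (mode == "tmt") {
    rep_cols <- grep("^reporter_", names(collapsed), value = TRUE)
    samples <- sub("^reporter_", "", rep_cols)
    long <- do.call(rbind, lapply(seq_along(rep_cols), function(k) {
      data.frame(feature_id = collapsed$feature_id,
                 peptide_key = peptide_key(collapsed$peptide_sequence,
                                           collapsed$mods),
                 sample_id = samples[k],
                 log2_intensity = log2(collapsed[[rep_cols[k]]]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    long <- data.frame(feature_id = collapsed$feature_id,
                       peptide_key = peptide_key(collapsed$peptide_sequence,
                                                 collapsed$mods),
                       sample_id = collapsed$sample_id,
                       log2_intensity = log2(collapsed$peak_area),
                       stringsAsFactors = FALSE)
    if (!is.null(run_features)) {
      # complete missing run-level quantities per peptide form
      key_map <- unique(data.frame(
        fkey = paste(collapsed$feature_id,
                     peptide_key(collapsed$peptide_sequence, collapsed$mods),
                     sep = "\r"),
        mz = vapply(seq_len(nrow(collapsed)), function(i) {
          precursor_mz(peptide_mass(collapsed$peptide_sequence[i],
                                    collapsed$mods[i]),
                       collapsed$charge[i])
        }, 1)))
      quant <- data.frame(
        feature_id = paste(collapsed$feature_id,
                           peptide_key(collapsed$peptide_sequence,
                                       collapsed$mods), sep = "\r"),
        run_id = collapsed$sample_id,
        log2_area = log2(collapsed$peak_area),
        mz = key_map$mz[match(paste(collapsed$feature_id,
                                    peptide_key(collapsed$peptide_sequence,
                                                collapsed$mods),
                                    sep = "\r"), key_map$fkey)],
        rt = collapsed$rt, stringsAsFactors = FALSE)
      completed <- match_between_runs(quant, run_features,
                                      ppm_tol = params$mbr_ppm_tol,
                                      rt_tol = params$mbr_rt_tol)
      added <- completed[completed$matched, , drop = FALSE]
      note("match between runs: %d values transferred", nrow(added))
      if (nrow(added)) {
        parts <- strsplit(added$feature_id, "\r", fixed = TRUE)
        long <- rbind(long, data.frame(
          feature_id = vapply(parts, `[[`, "", 1L),
          peptide_key = vapply(parts, `[[`, "", 2L),
          sample_id = added$run_id,
          log2_intensity = added$log2_area,
          stringsAsFactors = FALSE))
      }
    }
  }
  mat <- summarize_features(long, samples = design$sample_id)
  note("median-polish summarization: %d features x %d samples",
       nrow(mat), ncol(mat))

  # 6. contrasts + calls -------------------------------------------------
  res <- fit_contrasts(mat, design, contrasts)
  calls <- call_substrates(res, required_contrasts =
                             intersect(params$required_contrasts,
                                       contrasts$name),
                           lfc_min = params$lfc_min, p_max = params$p_max)
  note("substrate calls: %d high-confidence of %d features",
       sum(calls$high_confidence), nrow(calls))

  site_tab <- do.call(rbind, strsplit(calls$feature_id, "|", fixed = TRUE))
  calls$accession <- site_tab[, 1]
  calls$site_kind <- site_tab[, 2]
  metap <- metap_compatibility(calls, proteome)

  out <- list(classifications = cls, fdr = fdr_res,
              filter_report = filter_report, matrix = mat,
              contrasts = res, calls = calls, x_profile = x_profile,
              logo = logo, metap = metap, log = log)
  if (!is.null(truth)) {
    out$recovery <- evaluate_recovery(calls, truth)
    note("recovery: sensitivity %.3f, false-call %.3f, RMSE %.3f",
         out$recovery$sensitivity, out$recovery$false_call_fraction,
         out$recovery$rmse)
    out$log <- log
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(output_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(cls, "classifications.tsv")
    wt(filter_report, "filter_report.tsv")
    wt(as.data.frame(res), "contrasts.tsv")
    wt(calls, "substrate_calls.tsv")
    wt(x_profile, "x_position_profile.tsv")
    write_logo_matrix(logo, file.path(output_dir, "logo_matrix.tsv"))
    wt(metap, "metap_compatibility.tsv")
    writeLines(out$log, file.path(output_dir, "log.txt"))
    if (!is.null(truth)) {
      jsonlite::write_json(out$recovery,
                           file.path(output_dir, "recovery.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out
}
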