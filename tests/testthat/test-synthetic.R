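test_that("proteome generation is deterministic and honours fractions", {
  g1 <- generate_proteome(n_proteins = 60, seed = 7)
  g2 <- generate_proteome(n_proteins = 60, seed = 7)
  expect_identical(g1, g2)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(g1$proteins, f1)
  write_proteome_fasta(g2$proteins, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed differs
  g3 <- generate_proteome(n_proteins = 60, seed = 8)
  expect_false(identical(g1$proteins$sequence, g3$proteins$sequence))
  # fractions realised
  expect_equal(sum(g1$proteins$starts_with_X), 3)   # 5% of 60
  expect_equal(nrow(g1$truth$internal_motifs), 6)   # 10% of 60
  expect_true(all(substr(g1$proteins$sequence[!g1$proteins$starts_with_X],
                         1, 1) == "M"))
})

test_that("planted internal motifs are the complete motif truth", {
  g <- generate_proteome(n_proteins = 80, seed = 9)
  found <- lapply(g$proteins$sequence, find_internal_ggx_motifs)
  names(found) <- g$proteins$accession
  n_found <- sum(lengths(found))
  expect_equal(n_found, nrow(g$truth$internal_motifs))
  for (r in seq_len(nrow(g$truth$internal_motifs))) {
    acc <- g$truth$internal_motifs$accession[r]
    expect_true(g$truth$internal_motifs$position[r] %in% found[[acc]])
  }
  # zero motif fraction: no protein carries any motif
  g0 <- generate_proteome(n_proteins = 50, frac_internal_motif = 0, seed = 10)
  expect_true(all(lengths(lapply(g0$proteins$sequence,
                                 find_internal_ggx_motifs)) == 0))
})

test_that("an all-X-start proteome leads to wholesale rejection", {
  g <- generate_proteome(n_proteins = 30, frac_x_start = 1,
                         frac_internal_motif = 0, seed = 11)
  expect_true(all(g$proteins$starts_with_X))
  # every N-terminal GG PSM classifies as REJECT_X_START
  pep <- vapply(g$proteins$sequence, function(s) {
    ggscan:::nterm_peptide(s, 2L)
  }, "", USE.NAMES = FALSE)
  ok <- !is.na(pep) & nchar(pep) >= 6
  verdicts <- vapply(which(ok), function(i) {
    classify_gg_psm(pep[i], "gg@0", g$proteins)$verdict
  }, "")
  expect_true(all(verdicts == "REJECT_X_START"))
})

test_that("experiment generation is deterministic and schema-complete", {
  prot <- generate_proteome(n_proteins = 150, seed = 12)
  e1 <- generate_experiment(prot, n_substrates = 10, n_null_nterm = 30,
                            n_keps = 8, n_decoy_psms = 30, seed = 12)
  e2 <- generate_experiment(prot, n_substrates = 10, n_null_nterm = 30,
                            n_keps = 8, n_decoy_psms = 30, seed = 12)
  expect_identical(e1$psms, e2$psms)
  expect_s3_class(e1$psms, "data.frame")
  needed <- c("psm_id", "peptide_sequence", "mods", "charge", "observed_mz",
              "search_score", "decoy", "isolation_specificity",
              "fraction_id")
  expect_true(all(needed %in% names(e1$psms)))
  expect_equal(sum(grepl("^reporter_", names(e1$psms))), 11)
  expect_equal(nrow(e1$truth$substrates), 10)
  expect_equal(nrow(e1$truth$null_features), 30)
  # every planted N-terminal feature maps back to its protein
  for (r in seq_len(nrow(e1$truth$substrates))) {
    s <- e1$truth$substrates[r, ]
    seq_ <- prot$proteins$sequence[prot$proteins$accession == s$accession]
    expect_equal(substr(seq_, s$start, s$start + nchar(s$peptide) - 1),
                 s$peptide)
  }
  expect_error(generate_experiment(prot, sigma = 0, seed = 1), "sigma")
})

test_that("the noiseless limit returns the planted effects exactly", {
  prot <- generate_proteome(n_proteins = 150, seed = 13)
  e <- generate_experiment(prot, n_substrates = 8, n_null_nterm = 20,
                           n_keps = 5, n_decoy_psms = 10, sigma = 1e-9,
                           seed = 13)
  res <- run_pipeline(e$psms, e$proteome, e$design, mode = "tmt",
                      truth = e$truth)
  # abundance noise is off; search-score noise still governs FDR retention,
  # so compare planted effects on the quantified substrates
  subs <- e$truth$substrates
  subs <- subs[subs$feature_id %in% rownames(res$matrix), ]
  expect_gt(nrow(subs), 0)
  est <- res$calls[match(subs$feature_id, res$calls$feature_id), ]
  for (cn in c("log2FC_UBE2W-Control", "log2FC_Combo-RNF4")) {
    expect_equal(est[[cn]], subs$effect, tolerance = 1e-6)
  }
  # planted effect 2 clears the strict log2FC > 1 gate; planted effect 1
  # sits exactly on the boundary, so only the former can be asserted
  expect_true(all(est$high_confidence[subs$effect == 2]))
  expect_equal(res$recovery$false_call_fraction, 0)
})

test_that("LFQ mode emits run-level payloads and a feature table", {
  prot <- generate_proteome(n_proteins = 150, seed = 14)
  e <- generate_experiment(prot, n_substrates = 8, n_null_nterm = 20,
                           n_keps = 5, n_decoy_psms = 20, mode = "lfq",
                           seed = 14)
  expect_true(all(c("peak_area", "quant_confidence", "rt", "sample_id")
                  %in% names(e$psms)))
  expect_false(is.null(e$run_features))
  expect_true(all(c("run_id", "mz", "rt", "area") %in%
                    names(e$run_features)))
  # dropout leaves some identifications missing but recoverable
  nterm <- e$psms[!e$psms$decoy &
                    e$psms$feature_id %in% e$truth$substrates$feature_id, ]
  expect_lt(nrow(nterm), nrow(e$truth$substrates) * 11 * 1.5)
})

test_that("scored PSM generator matches its two-Gaussian model", {
  s1 <- generate_scored_psms(n = 2000, separation = 2.5, seed = 15)
  s2 <- generate_scored_psms(n = 2000, separation = 2.5, seed = 15)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2000)
  expect_equal(sum(s1$is_true), 1000)
  expect_equal(sum(s1$decoy), 500)
  expect_false(any(s1$is_true & s1$decoy))
  expect_equal(mean(s1$score[s1$is_true]) - mean(s1$score[s1$decoy]), 2.5,
               tolerance = 0.15)
  # zero separation: the filter retains essentially nothing at 1%
  s0 <- generate_scored_psms(n = 2000, separation = 0, seed = 16)
  res <- suppressWarnings(compute_fdr_threshold(s0, "psm", 0.01))
  expect_lt(nrow(res$retained), 0.02 * sum(!s0$decoy))
})

test_that("recovery metrics match hand-computed values on a toy truth", {
  truth <- list(
    substrates = data.frame(feature_id = paste0("s", 1:4),
                            effect = c(1, 2, 2, 1)),
    null_features = data.frame(feature_id = paste0("n", 1:6))
  )
  calls <- data.frame(
    feature_id = c(paste0("s", 1:4), paste0("n", 1:6)),
    high_confidence = c(TRUE, TRUE, FALSE, FALSE,
                        TRUE, rep(FALSE, 5)),
    "log2FC_UBE2W-Control" = c(1.1, 2.2, 0.4, 0.2, 1.4, rep(0, 5)),
    "log2FC_Combo-RNF4" = c(0.9, 1.8, 0.5, 0.1, 1.2, rep(0, 5)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  m <- evaluate_recovery(calls, truth)
  expect_equal(m$sensitivity, 0.5)            # s1, s2 of 4
  expect_equal(m$false_call_fraction, 1 / 6)  # n1 of 6
  # RMSE over called substrates: mean-estimate vs planted effect
  want <- sqrt(mean(c((1.0 - 1)^2, (2.0 - 2)^2)))
  expect_equal(m$rmse, want, tolerance = 1e-12)
  expect_equal(m$n_called, 3)
  # disjoint namespaces error; empty calls give zero sensitivity
  expect_error(evaluate_recovery(
    data.frame(feature_id = "zz", high_confidence = TRUE,
               "log2FC_UBE2W-Control" = 1, check.names = FALSE), truth),
    "share no feature ids")
  none <- calls
  none$high_confidence <- FALSE
  expect_equal(evaluate_recovery(none, truth)$sensitivity, 0)
})
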