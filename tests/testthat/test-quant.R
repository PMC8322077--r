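tmt_psm <- function(n = 1, peptide = "MLTNARWW", decoy = FALSE,
                    spec = 0.9, reporters = rep(10000, 4), fraction = 1L) {
  row <- data.frame(peptide_sequence = peptide, mods = "gg@0",
                    decoy = decoy, isolation_specificity = spec,
                    fraction_id = fraction, stringsAsFactors = FALSE)
  for (k in seq_along(reporters)) row[[paste0("reporter_", k)]] <- reporters[k]
  row[rep(1, n), , drop = FALSE]
}

test_that("TMT filters apply the printed thresholds strictly, in order", {
  psms <- rbind(
    tmt_psm(decoy = TRUE),                       # rule 1
    tmt_psm(peptide = "MLTNAR"),                 # rule 2 (length 6)
    tmt_psm(spec = 0.49),                        # rule 3
    tmt_psm(spec = 0.50),                        # retained: strict <
    tmt_psm(reporters = c(255, 9e4, 9e4, 9e4)),  # rule 4 (min channel)
    tmt_psm(reporters = c(256, 9e4, 9e4, 9e4)),  # retained
    tmt_psm(reporters = rep(29999 / 4, 4)),      # rule 5
    tmt_psm(reporters = rep(7500, 4)),           # retained (sum 30000)
    tmt_psm()                                    # retained
  )
  res <- filter_tmt_psms(psms)
  expect_equal(unname(res$removed),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(nrow(res$retained), 4)
  expect_error(filter_tmt_psms(psms[, setdiff(names(psms),
                                              "isolation_specificity")]),
               "isolation_specificity")
})

test_that("LFQ filters apply the printed thresholds strictly", {
  lfq <- function(peptide = "MLTNARWW", decoy = FALSE, conf = 90,
                  area = 1e5) {
    data.frame(peptide_sequence = peptide, mods = "gg@0", decoy = decoy,
               quant_confidence = conf, peak_area = area,
               stringsAsFactors = FALSE)
  }
  psms <- rbind(lfq(decoy = TRUE), lfq(peptide = "MLTNAR"),
                lfq(conf = 70), lfq(conf = 71),
                lfq(area = 255), lfq(area = 256), lfq())
  res <- filter_lfq_features(psms)
  expect_equal(unname(res$removed), c(1L, 1L, 1L, 1L))
  expect_equal(nrow(res$retained), 3)
})

test_that("TMT collapse takes channel maxima then the best fraction", {
  psms <- rbind(
    tmt_psm(reporters = c(100, 200, 300, 400), fraction = 1L),
    tmt_psm(reporters = c(150, 150, 350, 350), fraction = 1L),
    tmt_psm(reporters = c(1e6, 1, 1, 1), fraction = 2L)
  )
  out <- collapse_redundant(psms, mode = "tmt")
  expect_equal(nrow(out), 1)
  # fraction 2 (summed 1e6 + 3) beats fraction 1 (channel maxima 150..400)
  expect_equal(unlist(out[paste0("reporter_", 1:4)], use.names = FALSE),
               c(1e6, 1, 1, 1))
  # single PSM per peptide: identity
  single <- tmt_psm()
  expect_equal(collapse_redundant(single, "tmt")[names(single)], single)
})

test_that("collapse equals a group-by-max oracle on random tables", {
  set.seed(31)
  peps <- sprintf("PEPTIDE%dK", 1:6)
  psms <- data.frame(
    peptide_sequence = sample(peps, 40, replace = TRUE),
    mods = "gg@0", run_id = sample(c("r1", "r2", "r3"), 40, replace = TRUE),
    peak_area = runif(40, 1e3, 1e6), stringsAsFactors = FALSE
  )
  out <- collapse_redundant(psms, mode = "lfq")
  want <- aggregate(peak_area ~ peptide_sequence + run_id, psms, max)
  got <- out[order(out$peptide_sequence, out$run_id),
             c("peptide_sequence", "run_id", "peak_area")]
  want <- want[order(want$peptide_sequence, want$run_id),
               c("peptide_sequence", "run_id", "peak_area")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("median polish recovers additive structure exactly", {
  row_eff <- c(0, 1, -2)
  col_eff <- c(0.5, -0.5, 1, 2)
  x <- outer(row_eff, col_eff, "+") + 10
  colnames(x) <- paste0("s", 1:4)
  mp <- tukey_median_polish(x)
  expect_equal(max(abs(mp$residuals)), 0)
  expect_equal(unname(mp$abundance), 10 + col_eff + median(row_eff),
               tolerance = 1e-12)
  # constant matrix
  mpc <- tukey_median_polish(matrix(3, 2, 3))
  expect_equal(mpc$overall, 3)
  expect_true(all(mpc$residuals == 0))
  expect_equal(unname(mpc$abundance), rep(3, 3))
})

test_that("median polish matches an independent oracle and reconstructs", {
  set.seed(33)
  for (rep in 1:20) {
    nr <- sample(3:10, 1)
    nc <- sample(3:8, 1)
    x <- matrix(rnorm(nr * nc, 12, 2), nr, nc)
    if (rep %% 2 == 0) x[sample(length(x), ceiling(length(x) / 6))] <- NA
    keep_r <- rowSums(!is.na(x)) > 0
    keep_c <- colSums(!is.na(x)) > 0
    x <- x[keep_r, keep_c, drop = FALSE]
    if (nrow(x) < 2 || ncol(x) < 2) next
    colnames(x) <- paste0("s", seq_len(ncol(x)))
    mp <- tukey_median_polish(x)
    oracle <- median_polish_oracle(x)
    expect_equal(mp$overall, oracle$overall, tolerance = 1e-9)
    expect_equal(unname(mp$col), unname(oracle$col), tolerance = 1e-9)
    expect_equal(unname(mp$abundance), oracle$overall + oracle$col,
                 tolerance = 1e-9)
    # reconstruction identity at observed cells
    recon <- mp$overall + outer(mp$row, mp$col, "+") + mp$residuals
    obs <- !is.na(x)
    expect_equal(recon[obs], x[obs], tolerance = 1e-9)
  }
})

test_that("per-sample abundance is invariant to row permutation", {
  set.seed(34)
  x <- matrix(rnorm(24, 10), 6, 4, dimnames = list(NULL, paste0("s", 1:4)))
  mp1 <- tukey_median_polish(x)
  mp2 <- tukey_median_polish(x[sample(6), ])
  expect_equal(mp1$abundance, mp2$abundance, tolerance = 1e-12)
})

test_that("all-missing columns yield missing abundances", {
  x <- matrix(c(1, 2, NA, NA, 3, 4), 2, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  mp <- tukey_median_polish(x)
  expect_true(is.na(mp$abundance["b"]))
  expect_false(anyNA(mp$abundance[c("a", "c")]))
})

test_that("match between runs transfers within tolerances only", {
  theo <- 650.0
  quant <- data.frame(
    feature_id = "f1", run_id = c("r1", "r2"),
    log2_area = c(20, 20.1), mz = theo, rt = c(30, 30.2)
  )
  feats <- data.frame(
    run_id = c("r3", "r3", "r4"),
    mz = c(theo * (1 + 5e-6), theo * (1 + 12e-6), theo),
    rt = c(30.5, 30.1, 45),      # r4 feature is 15 min off
    area = c(2^19, 2^21, 2^22)
  )
  out <- match_between_runs(quant, feats, ppm_tol = 10, rt_tol = 2)
  got <- out[out$matched, ]
  # only the +5 ppm feature in r3 qualifies; +12 ppm and wrong-RT do not
  expect_equal(got$run_id, "r3")
  expect_equal(got$log2_area, 19)
  # identical runs: nothing to transfer
  out2 <- match_between_runs(quant, feats[0, ], 10, 2)
  expect_false(any(out2$matched))
})

test_that("a constant RT shift between runs is recovered", {
  set.seed(36)
  rts <- runif(8, 10, 90)
  quant <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(feature_id = paste0("f", i), run_id = c("r1", "r2"),
               log2_area = 20, mz = 500 + i, rt = c(rts[i], rts[i] + 3))
  }))
  # r2 runs 3 minutes late; drop f1's identification in r2
  quant <- quant[!(quant$feature_id == "f1" & quant$run_id == "r2"), ]
  feats <- data.frame(run_id = "r2", mz = 501, rt = rts[1] + 3, area = 2^18)
  out <- match_between_runs(quant, feats, ppm_tol = 10, rt_tol = 2)
  got <- out[out$matched, ]
  expect_equal(got$feature_id, "f1")
  expect_equal(got$log2_area, 18)
})

test_that("summarize_features builds the feature x sample matrix", {
  long <- data.frame(
    feature_id = rep(c("A", "B"), each = 4),
    peptide_key = rep(c("p1", "p2"), 4),
    sample_id = rep(c("s1", "s2"), 4),
    log2_intensity = c(10, 11, 10.5, 11.5, 20, 21, NA, 21.5)
  )
  m <- summarize_features(long, samples = c("s1", "s2"))
  expect_equal(dim(m), c(2, 2))
  expect_equal(rownames(m), c("A", "B"))
  expect_false(anyNA(m["A", ]))
})
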