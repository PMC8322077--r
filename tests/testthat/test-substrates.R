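mk_results <- function(tab) {
  # tab: feature_id, contrast, log2FC, p
  tab$SE <- 0.1
  tab$df <- 7
  tab$t <- tab$log2FC / tab$SE
  tab$p_adj <- ave(tab$p, tab$contrast,
                   FUN = function(p) p.adjust(p, "BH"))
  class(tab) <- c("gg_contrasts", "data.frame")
  tab
}

test_that("substrate gates are strict at both boundaries", {
  tab <- mk_results(data.frame(
    feature_id = rep(c("hit", "at_lfc", "at_p", "weak"), each = 2),
    contrast = rep(c("UBE2W-Control", "Combo-RNF4"), 4),
    log2FC = c(1.2, 1.4, 1.0, 1.0, 2, 2, 0.2, 0.1),
    p = c(0.01, 0.02, 0.001, 0.001, 0.05, 0.05, 0.6, 0.7),
    stringsAsFactors = FALSE
  ))
  calls <- call_substrates(tab)
  hc <- calls$high_confidence
  names(hc) <- calls$feature_id
  expect_true(hc[["hit"]])
  expect_false(hc[["at_lfc"]])   # log2FC == 1 exactly fails the strict >
  expect_false(hc[["at_p"]])     # p == 0.05 exactly fails the strict <
  expect_false(hc[["weak"]])
  expect_equal(calls$n_pass[calls$feature_id == "hit"], 2)
})

test_that("high confidence requires every required contrast", {
  tab <- mk_results(data.frame(
    feature_id = rep(c("both", "one"), each = 2),
    contrast = rep(c("UBE2W-Control", "Combo-RNF4"), 2),
    log2FC = c(2, 2, 2, 0.1),
    p = c(0.001, 0.001, 0.001, 0.9),
    stringsAsFactors = FALSE
  ))
  calls <- call_substrates(tab)
  expect_equal(calls$high_confidence[calls$feature_id == "both"], TRUE)
  expect_equal(calls$high_confidence[calls$feature_id == "one"], FALSE)
  # single required contrast: "one" passes it
  calls1 <- call_substrates(tab, required_contrasts = "UBE2W-Control")
  expect_true(all(calls1$high_confidence))
})

test_that("missing required contrasts flag the feature and never call it", {
  tab <- mk_results(data.frame(
    feature_id = c("full", "full", "partial"),
    contrast = c("UBE2W-Control", "Combo-RNF4", "UBE2W-Control"),
    log2FC = c(2, 2, 3), p = c(0.001, 0.001, 0.001),
    stringsAsFactors = FALSE
  ))
  # 'partial' has no Combo-RNF4 row at all
  calls <- call_substrates(tab)
  expect_equal(calls$flag[calls$feature_id == "partial"], "missing_contrast")
  expect_false(calls$high_confidence[calls$feature_id == "partial"])
  expect_error(call_substrates(tab, required_contrasts = "no-such"),
               "lack required")
})

test_that("degenerate thresholds disable the gate", {
  tab <- mk_results(data.frame(
    feature_id = rep(c("a", "b"), each = 2),
    contrast = rep(c("UBE2W-Control", "Combo-RNF4"), 2),
    log2FC = c(0.01, 0.02, -1, -2), p = c(0.99, 0.98, 0.5, 0.6),
    stringsAsFactors = FALSE
  ))
  calls <- call_substrates(tab, lfc_min = -Inf, p_max = 1.0)
  expect_true(all(calls$high_confidence))
})

test_that("experiment intersection counts conserve the union", {
  out <- intersect_experiments(list(E1 = c("a", "b", "c"),
                                    E2 = c("b", "c", "d")))
  counts <- setNames(out$count, out$region)
  expect_equal(unname(counts[c("E1", "E1&E2", "E2")]), c(1L, 2L, 1L))
  expect_equal(attr(out, "union_size"), 4)
  # identical sets: one shared region
  out2 <- intersect_experiments(list(A = letters[1:5], B = letters[1:5]))
  expect_equal(out2$region, "A&B")
  expect_equal(out2$count, 5L)
  # union conservation on random sets
  set.seed(51)
  for (i in 1:10) {
    sets <- lapply(1:3, function(k) sample(letters, sample(3:15, 1)))
    names(sets) <- c("X", "Y", "Z")
    out3 <- intersect_experiments(sets)
    expect_equal(sum(out3$count), length(unique(unlist(sets))))
  }
  expect_error(intersect_experiments(list(A = "a")), "at least two")
  expect_error(intersect_experiments(list(c("a"), c("b"))), "named")
})

test_that("X-position frequency profile counts exactly", {
  prof <- residue_frequency_profile(c("MLTNAR", "MAVLK", "MQWER", "LIFAGK"))
  expect_equal(prof$residue[1], "M")
  expect_equal(prof$count[prof$residue == "M"], 3L)
  expect_equal(prof$fraction[prof$residue == "M"], 0.75)
  expect_equal(prof$fraction[prof$residue == "L"], 0.25)
  expect_equal(sum(prof$fraction), 1)
  one <- residue_frequency_profile("MAVLK")
  expect_equal(one$fraction, 1)
  expect_error(residue_frequency_profile(character()), "empty")
  # profile of a synthetic set reproduces the generator composition
  set.seed(52)
  xs <- sample(c("M", "L", "S"), 200, replace = TRUE,
               prob = c(0.5, 0.3, 0.2))
  peps <- paste0(xs, vapply(1:200, function(i) random_peptide(6), ""))
  prof2 <- residue_frequency_profile(peps)
  expect_equal(setNames(prof2$count, prof2$residue)[c("M", "L", "S")],
               table(xs)[c("M", "L", "S")], ignore_attr = TRUE)
})

test_that("logo matrix probabilities normalise and IC spans its range", {
  # identical peptides, no pseudocount: IC = log2(20) at every position
  logo0 <- sequence_logo_matrix(rep("MLTN", 20), length = 6, pseudocount = 0)
  expect_equal(logo0$ic, rep(log2(20), 6), tolerance = 1e-9)
  expect_equal(colSums(logo0$prob), rep(1, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  # uniform composition at position 3: IC near 0 there
  peps <- paste0(rep(sort(names(ggscan:::AA_MONO_MASS)), 10), "AAAA")
  logo_u <- sequence_logo_matrix(peps, length = 3, pseudocount = 0)
  expect_lt(logo_u$ic[3], 1e-9)
  expect_error(sequence_logo_matrix(character()), "empty")
})

test_that("logo information content matches an entropy oracle", {
  set.seed(53)
  peps <- vapply(1:60, function(i) random_peptide(sample(4:8, 1)), "")
  logo <- sequence_logo_matrix(peps, length = 6, pseudocount = 0.5)
  for (p in 1:6) {
    expect_equal(logo$ic[p], ic_oracle(logo$prob[, p]), tolerance = 1e-9)
    expect_equal(sum(logo$prob[, p]), 1, tolerance = 1e-9)
    expect_gte(logo$ic[p], 0)
    expect_lte(logo$ic[p], log2(20))
  }
  # GG prefix dominates positions 1-2
  expect_equal(logo$prob["G", 1], max(logo$prob[, 1]))
  expect_gt(logo$ic[1], 3)
})

test_that("MetAP compatibility annotates second residues", {
  prot <- make_protein_table(c("SUSC", "NOT"), c("MAVLK", "MQVLK"))
  calls <- data.frame(accession = c("SUSC", "NOT", "GONE"),
                      site_kind = "initiator_met",
                      stringsAsFactors = FALSE)
  ann <- metap_compatibility(calls, prot)
  expect_equal(ann$second_residue[1:2], c("A", "Q"))
  expect_equal(ann$metap_susceptible[1:2], c(TRUE, FALSE))
  # initiator-Met site with susceptible second residue is the surprising case
  expect_true(ann$surprising[1])
  expect_false(ann$surprising[2])
  expect_equal(ann$flag[3], "unresolved_accession")
})
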