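# Synthetic study-shaped data with known ground truth: toy proteome with
# planted internal [K/R]GG motifs and 'X'-start fragments, GG-remnant PSM
# tables with TMT or label-free payloads, and recovery metrics.

# Run code under a fixed, documented RNG state (Mersenne-Twister /
# inversion / rejection sampling), restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

random_sequence <- function(n, alphabet = names(AA_MONO_MASS)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' The study's default experimental design
#'
#' Four conditions — Control, UBE2W, RNF4, Combo (RNF4 + UBE2W) — with 3, 3,
#' 2 and 3 replicates respectively (11 samples, matching an 11-channel TMT
#' layout).
#'
#' @return data.frame `sample_id`, `condition`.
#' @export
default_design <- function() {
  cond <- c(rep("Control", 3), rep("UBE2W", 3), rep("RNF4", 2),
            rep("Combo", 3))
  data.frame(
    sample_id = paste(cond, stats::ave(seq_along(cond), cond,
                                       FUN = seq_along), sep = "_"),
    condition = cond,
    stringsAsFactors = FALSE
  )
}

#' Default condition contrasts
#'
#' UBE2W substrates show increased N-terminal GG abundance in the two
#' UBE2W-expressing conditions, so the two informative contrasts are
#' UBE2W-Control and Combo-RNF4.
#'
#' @return data.frame `name`, `plus`, `minus`.
#' @export
default_contrasts <- function() {
  data.frame(
    name = c("UBE2W-Control", "Combo-RNF4"),
    plus = c("UBE2W", "Combo"),
    minus = c("Control", "RNF4"),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic proteome with planted features
#'
#' Random protein sequences (uniform residue background). A stated fraction
#' receive an internal genome-encoded R/K-GG-X motif at a recorded
#' position; a stated fraction are emitted as unreviewed 'X'-start fragments
#' (TrEMBL-style); all remaining proteins start with Met. Deterministic
#' given the seed.
#'
#' @param n_proteins number of target proteins.
#' @param length_range integer range of sequence lengths.
#' @param frac_internal_motif fraction of proteins carrying a planted
#'   internal motif.
#' @param frac_x_start fraction emitted as 'X'-start unreviewed entries.
#' @param seed RNG seed.
#' @return list: `proteins` (protein table) and `truth` (list with
#'   `internal_motifs` data.frame, `x_start_accessions`, `params`).
#' @export
generate_proteome <- function(n_proteins = 500, length_range = c(80, 240),
                              frac_internal_motif = 0.10,
                              frac_x_start = 0.05, seed = 1L) {
  stopifnot(frac_internal_motif >= 0, frac_internal_motif <= 1,
            frac_x_start >= 0, frac_x_start <= 1,
            frac_internal_motif + frac_x_start <= 1,
            length_range[1] >= 30)
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n_proteins,
                   replace = TRUE)
    seqs <- vapply(lens, function(n) {
      paste0("M", random_sequence(n - 1L))
    }, "")
    acc <- sprintf("SYN%04d", seq_len(n_proteins))
    n_x <- round(frac_x_start * n_proteins)
    n_motif <- round(frac_internal_motif * n_proteins)
    roles <- sample(n_proteins)
    x_idx <- roles[seq_len(n_x)]
    motif_idx <- roles[n_x + seq_len(n_motif)]
    # 'X'-start fragments: prepend the variable residue
    seqs[x_idx] <- paste0("X", seqs[x_idx])
    motif_pos <- integer(0)
    for (i in motif_idx) {
      n <- nchar(seqs[i])
      p <- sample(6:(n - 10), 1)
      pre <- sample(c("K", "R"), 1)
      substr(seqs[i], p - 1, p + 1) <- paste0(pre, "GG")
      motif_pos <- c(motif_pos, p)
    }
    # scrub chance [K/R]GG motifs so the planted set is the complete truth
    planted <- stats::setNames(rep(NA_integer_, n_proteins), acc)
    planted[motif_idx] <- motif_pos
    for (i in seq_len(n_proteins)) {
      repeat {
        found <- find_internal_ggx_motifs(seqs[i])
        stray <- setdiff(found, planted[i])
        if (!length(stray)) break
        substr(seqs[i], stray[1], stray[1]) <- "L"
      }
    }
    proteins <- new_protein_records(
      accession = acc,
      source_db = ifelse(seq_len(n_proteins) %in% x_idx,
                         "unreviewed", "reviewed"),
      sequence = seqs, is_decoy = FALSE
    )
    truth <- list(
      internal_motifs = data.frame(accession = acc[motif_idx],
                                   position = motif_pos,
                                   stringsAsFactors = FALSE),
      x_start_accessions = acc[x_idx],
      params = list(n_proteins = n_proteins, length_range = length_range,
                    frac_internal_motif = frac_internal_motif,
                    frac_x_start = frac_x_start, seed = seed)
    )
    list(proteins = proteins, truth = truth)
  })
}

# Countable internal cleavage sites of a peptide (K/R not before P).
count_missed <- function(peptide) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2) return(0L)
  sum(res[1:(n - 1)] %in% c("K", "R") & res[2:n] != "P")
}

# N-terminal fully tryptic peptide (0 missed cleavages) from a given start.
nterm_peptide <- function(sequence, start) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts < n & res[pmin(cuts + 1, n)] != "P"]
  cuts <- cuts[cuts >= start]
  end <- if (length(cuts)) cuts[1] else n
  substr(sequence, start, end)
}

mz_with_jitter <- function(sequence, mods, charge, ppm_sd = 1) {
  theo <- precursor_mz(peptide_mass(sequence, mods), charge)
  theo * (1 + stats::rnorm(1, 0, ppm_sd) * 1e-6)
}

#' Generate a synthetic GG-remnant experiment
#'
#' Emits study-shaped PSM tables with known truth: (i) N-terminal GG PSMs
#' for planted substrates, whose log2 abundance gains the planted effect in
#' the UBE2W-expressing conditions (UBE2W, Combo); (ii) null N-terminal GG
#' features with no condition effect; (iii) abundant, condition-invariant
#' internal encoded-GGX PSMs; (iv) K-epsilon-GG PSMs; (v) decoy PSMs with a
#' lower search-score distribution (two-Gaussian score model). Noise is
#' Normal on the log2 scale. TMT mode carries per-channel reporter
#' intensities, isolation specificity and fraction ids; LFQ mode carries
#' per-run peak areas, confidence scores and retention times with a per-run
#' RT shift (plus a per-run MS1 feature table) so match-between-runs is
#' exercised. Deterministic given the seed.
#'
#' The PSM score model is the standard two-Gaussian target-decoy picture:
#' correct identifications score `Normal(mu_t, 1)` while noise matches —
#' decoy hits and an equal number of incorrect target hits (unmodified
#' internal peptides) — score `Normal(mu_t - score_separation, 1)`. Pairing
#' decoys with incorrect targets keeps the decoy-based FDR estimate
#' consistent with the realized false-discovery proportion.
#'
#' @param proteome_truth output of [generate_proteome()].
#' @param design design table (default [default_design()]).
#' @param n_substrates,n_null_nterm,n_keps,n_decoy_psms feature counts;
#'   `n_decoy_psms` also sets the number of incorrect-target PSMs.
#' @param effect_levels planted log2 fold-changes, sampled uniformly per
#'   substrate (default c(1, 2)).
#' @param sigma log2-scale noise standard deviation (default 0.25).
#' @param mode "tmt" or "lfq".
#' @param score_separation mean search-score gap between target and decoy
#'   PSMs (default 2.5; both classes have unit SD).
#' @param dropout_rate LFQ only: probability a feature's identification is
#'   missing in a given run (recoverable through the feature table).
#' @param seed RNG seed.
#' @return list: `psms` (PSM table), `design`, `truth` (completed
#'   SyntheticTruth), `run_features` (LFQ only), `proteome` (targets +
#'   decoys).
#' @export
generate_experiment <- function(proteome_truth, design = default_design(),
                                n_substrates = 40L, n_null_nterm = 160L,
                                n_keps = 30L, n_decoy_psms = 60L,
                                effect_levels = c(1, 2), sigma = 0.25,
                                mode = c("tmt", "lfq"),
                                score_separation = 2.5,
                                dropout_rate = 0.15, seed = 1L) {
  mode <- match.arg(mode)
  if (sigma <= 0) stop("sigma must be positive")
  if (length(unique(design$condition)) < 2) stop("need >= 2 conditions")
  proteins <- proteome_truth$proteins
  truth0 <- proteome_truth$truth
  full_db <- build_decoy_db(proteins)
  with_seed(seed + 1L, {
    is_x <- proteins$accession %in% truth0$x_start_accessions
    has_motif <- proteins$accession %in% truth0$internal_motifs$accession
    # eligible N-terminal feature hosts: Met-start, motif-free targets whose
    # fully tryptic N-terminal peptide survives the length-7 quant filter
    elig <- which(!is_x & !has_motif)
    pep1 <- vapply(elig, function(i) nterm_peptide(proteins$sequence[i], 1L),
                   "")
    ok <- nchar(pep1) >= 7 & nchar(pep1) <= 35
    elig <- elig[ok]
    pep1 <- pep1[ok]
    need <- n_substrates + n_null_nterm
    if (length(elig) < need) {
      stop("proteome too small: ", length(elig),
           " eligible N-terminal hosts for ", need, " features")
    }
    pick <- sample(seq_along(elig), need)
    sub_i <- pick[seq_len(n_substrates)]
    null_i <- pick[n_substrates + seq_len(n_null_nterm)]

    site_for <- function(i) {
      seq_ <- proteins$sequence[elig[i]]
      r2 <- substr(seq_, 2, 2)
      if (r2 %in% METAP_SUSCEPTIBLE && stats::runif(1) < 0.3) {
        list(kind = "met_clipped", start = 2L,
             peptide = nterm_peptide(seq_, 2L))
      } else {
        list(kind = "initiator_met", start = 1L, peptide = pep1[i])
      }
    }
    mk_features <- function(idx, effects) {
      out <- vector("list", length(idx))
      for (k in seq_along(idx)) {
        s <- site_for(idx[k])
        if (nchar(s$peptide) < 7) {     # met-clipped form too short
          s <- list(kind = "initiator_met", start = 1L,
                    peptide = pep1[idx[k]])
        }
        out[[k]] <- data.frame(
          accession = proteins$accession[elig[idx[k]]],
          site_kind = s$kind, start = s$start, peptide = s$peptide,
          effect = effects[k], stringsAsFactors = FALSE
        )
      }
      do.call(rbind, out)
    }
    effects <- if (length(effect_levels) == 1L) {
      rep(effect_levels, n_substrates)
    } else {
      sample(effect_levels, n_substrates, replace = TRUE)
    }
    substrates <- mk_features(sub_i, effects)
    nulls <- mk_features(null_i, rep(0, n_null_nterm))
    substrates$feature_id <- paste(substrates$accession,
                                   substrates$site_kind, sep = "|")
    nulls$feature_id <- paste(nulls$accession, nulls$site_kind, sep = "|")

    # internal encoded-GGX features: the modified-interpretation PSM whose
    # peptide starts right after the encoded GG
    internal <- NULL
    if (nrow(truth0$internal_motifs) > 0) {
      im <- truth0$internal_motifs
      pepi <- vapply(seq_len(nrow(im)), function(r) {
        seq_ <- proteins$sequence[proteins$accession == im$accession[r]]
        nterm_peptide(seq_, im$position[r] + 2L)
      }, "")
      keep <- nchar(pepi) >= 7 & nchar(pepi) <= 35
      internal <- data.frame(accession = im$accession[keep],
                             position = im$position[keep],
                             peptide = pepi[keep],
                             stringsAsFactors = FALSE)
      internal$feature_id <- paste(internal$accession,
                                   paste0("internal_", internal$position),
                                   sep = "|")
    }

    # K-epsilon-GG features: missed-cleavage peptides with an internal K
    keps <- NULL
    host <- sample(which(!is_x), min(n_keps * 3L, sum(!is_x)))
    krows <- list()
    for (i in host) {
      if (length(krows) >= n_keps) break
      dg <- digest(proteins$sequence[i], max_missed = 1, specificity = "full",
                   min_length = 7, max_length = 35,
                   accession = proteins$accession[i])
      dg <- dg[dg$missed_cleavages == 1, , drop = FALSE]
      if (!nrow(dg)) next
      p <- dg[sample(nrow(dg), 1), , drop = FALSE]
      kpos <- which(strsplit(p$sequence, "")[[1]] == "K")
      kpos <- kpos[kpos < nchar(p$sequence)]
      if (!length(kpos)) next
      krows[[length(krows) + 1]] <- data.frame(
        accession = p$accession, peptide = p$sequence,
        gg_position = kpos[1], stringsAsFactors = FALSE
      )
    }
    if (length(krows)) {
      keps <- do.call(rbind, krows)
      keps$feature_id <- paste(keps$accession, paste0("K", keps$gg_position),
                               sep = "|")
    }

    # 'X'-start fragment PSMs: peptide = the Met-start substring at pos 2
    xstart <- NULL
    if (length(truth0$x_start_accessions)) {
      xp <- vapply(truth0$x_start_accessions, function(a) {
        nterm_peptide(proteins$sequence[proteins$accession == a], 2L)
      }, "", USE.NAMES = FALSE)
      keep <- nchar(xp) >= 7 & nchar(xp) <= 35
      xstart <- data.frame(accession = truth0$x_start_accessions[keep],
                           peptide = xp[keep], stringsAsFactors = FALSE)
    }

    # assemble PSM rows --------------------------------------------------
    samples <- design$sample_id
    conds <- design$condition
    up <- conds %in% c("UBE2W", "Combo")
    target_mu <- 8
    psm_rows <- list()
    feature_rows <- list()
    add_psm <- function(peptide, mods, accession, feature_id, base,
                        effect, decoy = FALSE, noise = decoy, fraction = 1L,
                        run = NA_character_, rt = NA_real_,
                        observed = TRUE) {
      charge <- sample(2:3, 1)
      score <- stats::rnorm(1, if (noise) target_mu - score_separation
                               else target_mu, 1)
      mz <- mz_with_jitter(peptide, mods, charge)
      if (mode == "tmt") {
        vals <- 2^(base + effect * up + stats::rnorm(length(samples), 0, sigma))
        row <- data.frame(
          psm_id = NA_character_, peptide_sequence = peptide, mods = mods,
          charge = charge, observed_mz = mz, search_score = score,
          run_id = "tmt_run1", decoy = decoy,
          accession = accession, feature_id = feature_id,
          isolation_specificity = stats::runif(1, 0.6, 1),
          fraction_id = fraction, missed_cleavages = count_missed(peptide),
          stringsAsFactors = FALSE
        )
        for (k in seq_along(samples)) {
          row[[paste0("reporter_", samples[k])]] <- vals[k]
        }
        psm_rows[[length(psm_rows) + 1]] <<- row
      } else {
        # one PSM per run (sample); dropout leaves recoverable features
        for (k in seq_along(samples)) {
          area <- 2^(base + effect * up[k] + stats::rnorm(1, 0, sigma))
          rt_k <- rt + run_shift[k] + stats::rnorm(1, 0, 0.05)
          feature_rows[[length(feature_rows) + 1]] <<- data.frame(
            run_id = samples[k], mz = mz, rt = rt_k, area = area,
            stringsAsFactors = FALSE
          )
          if (stats::runif(1) < dropout_rate && !decoy) next
          psm_rows[[length(psm_rows) + 1]] <<- data.frame(
            psm_id = NA_character_, peptide_sequence = peptide, mods = mods,
            charge = charge, observed_mz = mz,
            search_score = stats::rnorm(1, if (noise)
              target_mu - score_separation else target_mu, 1),
            run_id = samples[k], sample_id = samples[k], decoy = decoy,
            accession = accession, feature_id = feature_id,
            peak_area = area, quant_confidence = stats::runif(1, 80, 100),
            rt = rt_k, missed_cleavages = count_missed(peptide), stringsAsFactors = FALSE
          )
        }
      }
      invisible(NULL)
    }
    run_shift <- stats::setNames(
      seq(-0.8, 0.8, length.out = length(samples)), samples)

    nterm_all <- rbind(substrates, nulls)
    for (r in seq_len(nrow(nterm_all))) {
      base <- stats::runif(1, 14, 17)
      rt <- stats::runif(1, 10, 90)
      add_psm(nterm_all$peptide[r], "gg@0", nterm_all$accession[r],
              nterm_all$feature_id[r], base, nterm_all$effect[r], rt = rt)
      # a second, semi-tryptic peptide form of the same site for a subset,
      # exercising multi-row median polish
      if (r %% 3 == 0 && nchar(nterm_all$peptide[r]) >= 9) {
        semi <- substr(nterm_all$peptide[r], 1,
                       nchar(nterm_all$peptide[r]) - 2)
        add_psm(semi, "gg@0", nterm_all$accession[r],
                nterm_all$feature_id[r], base - 0.5, nterm_all$effect[r],
                rt = rt + 0.5)
      }
    }
    if (!is.null(internal) && nrow(internal)) {
      for (r in seq_len(nrow(internal))) {
        add_psm(internal$peptide[r], "gg@0", internal$accession[r],
                internal$feature_id[r], stats::runif(1, 17, 19), 0,
                rt = stats::runif(1, 10, 90))
      }
    }
    if (!is.null(keps) && nrow(keps)) {
      for (r in seq_len(nrow(keps))) {
        add_psm(keps$peptide[r], paste0("gg@", keps$gg_position[r]),
                keps$accession[r], keps$feature_id[r],
                stats::runif(1, 15, 18), 0, rt = stats::runif(1, 10, 90))
      }
    }
    if (!is.null(xstart) && nrow(xstart)) {
      for (r in seq_len(nrow(xstart))) {
        add_psm(xstart$peptide[r], "gg@0", xstart$accession[r],
                paste(xstart$accession[r], "x_start", sep = "|"),
                stats::runif(1, 14, 17), 0, rt = stats::runif(1, 10, 90))
      }
    }
    # noise matches: decoy PSMs plus an equal number of incorrect-target
    # PSMs (unmodified internal peptides), both scoring on the lower
    # Gaussian — the decoy-based FDR estimate then tracks the realized
    # false-discovery proportion
    noise_psm <- function(ptab, is_decoy) {
      i <- sample(nrow(ptab), 1)
      dg <- digest(ptab$sequence[i], max_missed = 0, specificity = "full",
                   min_length = 7, max_length = 35,
                   accession = ptab$accession[i])
      dg <- dg[!grepl("X", dg$sequence, fixed = TRUE), , drop = FALSE]
      if (!nrow(dg)) return(invisible(NULL))
      p <- dg[sample(nrow(dg), 1), , drop = FALSE]
      if (mode == "tmt") {
        add_psm(p$sequence, "", p$accession, NA_character_,
                stats::runif(1, 9, 12), 0, decoy = is_decoy, noise = TRUE)
      } else {
        # noise matches get a single-run PSM
        k <- sample(length(samples), 1)
        charge <- sample(2:3, 1)
        psm_rows[[length(psm_rows) + 1]] <<- data.frame(
          psm_id = NA_character_, peptide_sequence = p$sequence, mods = "",
          charge = charge,
          observed_mz = mz_with_jitter(p$sequence, "", charge),
          search_score = stats::rnorm(1, target_mu - score_separation, 1),
          run_id = samples[k], sample_id = samples[k], decoy = is_decoy,
          accession = p$accession, feature_id = NA_character_,
          peak_area = 2^stats::runif(1, 9, 12),
          quant_confidence = stats::runif(1, 60, 95),
          rt = stats::runif(1, 10, 90),
          missed_cleavages = count_missed(p$sequence),
          stringsAsFactors = FALSE
        )
      }
      invisible(NULL)
    }
    decoys <- full_db[full_db$is_decoy, , drop = FALSE]
    for (r in seq_len(n_decoy_psms)) noise_psm(decoys, TRUE)
    for (r in seq_len(n_decoy_psms)) noise_psm(proteins, FALSE)
    psms <- do.call(rbind, psm_rows)
    psms$psm_id <- sprintf("psm%05d", seq_len(nrow(psms)))
    rownames(psms) <- NULL
    run_features <- if (mode == "lfq" && length(feature_rows)) {
      do.call(rbind, feature_rows)
    } else {
      NULL
    }
    truth <- c(truth0, list(
      substrates = substrates, null_features = nulls,
      internal_features = internal, keps_features = keps,
      xstart_features = xstart,
      params = c(truth0$params,
                 list(effect_levels = effect_levels, sigma = sigma,
                      mode = mode, score_separation = score_separation,
                      seed = seed, design = design))
    ))
    list(psms = psms, design = design, truth = truth,
         run_features = run_features, proteome = full_db)
  })
}

#' Generate scored target/decoy PSMs with known truth labels
#'
#' Two-Gaussian score model for FDR calibration studies: correct target
#' PSMs score `Normal(separation, 1)`, incorrect targets and decoys score
#' `Normal(0, 1)`, with equal numbers of incorrect targets and decoys (the
#' target-decoy estimator's core assumption).
#'
#' @param n total number of PSMs.
#' @param separation mean score gap (default 2.5).
#' @param frac_true fraction of PSMs that are correct targets (default 0.5);
#'   the remainder splits evenly into incorrect targets and decoys.
#' @param seed RNG seed.
#' @return data.frame `score`, `decoy`, `is_true`, plus `peptide_sequence` /
#'   `mods` stubs so peptide-level collapse is exercised trivially.
#' @export
generate_scored_psms <- function(n = 5000L, separation = 2.5,
                                 frac_true = 0.5, seed = 1L) {
  with_seed(seed, {
    n_true <- round(n * frac_true)
    n_false <- floor((n - n_true) / 2)
    n_decoy <- n - n_true - n_false
    score <- c(stats::rnorm(n_true, separation, 1),
               stats::rnorm(n_false, 0, 1),
               stats::rnorm(n_decoy, 0, 1))
    data.frame(
      score = score,
      decoy = rep(c(FALSE, FALSE, TRUE), c(n_true, n_false, n_decoy)),
      is_true = rep(c(TRUE, FALSE, FALSE), c(n_true, n_false, n_decoy)),
      peptide_sequence = sprintf("PEPTIDEK%05d", seq_len(n)),
      mods = "",
      stringsAsFactors = FALSE
    )
  })
}

#' Recovery metrics of substrate calls against generator truth
#'
#' @param calls output of [call_substrates()] (feature ids =
#'   `accession|site_kind`).
#' @param truth truth list from [generate_experiment()].
#' @param call_col logical column of `calls` defining a positive call
#'   (default "high_confidence").
#' @return list: `sensitivity`, `false_call_fraction`, `rmse` (over called
#'   substrates, planted vs mean estimated log2FC), `n_substrates`,
#'   `n_nulls`, `n_called`.
#' @export
evaluate_recovery <- function(calls, truth, call_col = "high_confidence") {
  subs <- truth$substrates
  nulls <- truth$null_features
  if (!any(c(subs$feature_id, nulls$feature_id) %in% calls$feature_id)) {
    stop("calls and truth share no feature ids")
  }
  called <- calls$feature_id[calls[[call_col]] %in% TRUE]
  tp <- sum(subs$feature_id %in% called)
  fp <- sum(nulls$feature_id %in% called)
  lfc_cols <- grep("^log2FC_", names(calls), value = TRUE)
  est <- rowMeans(calls[lfc_cols], na.rm = TRUE)
  i <- match(subs$feature_id, calls$feature_id)
  ok <- !is.na(i) & subs$feature_id %in% called
  rmse <- if (any(ok)) {
    sqrt(mean((est[i[ok]] - subs$effect[ok])^2))
  } else {
    NA_real_
  }
  list(sensitivity = tp / nrow(subs),
       false_call_fraction = if (nrow(nulls)) fp / nrow(nulls) else 0,
       rmse = rmse,
       n_substrates = nrow(subs), n_nulls = nrow(nulls),
       n_called = length(called))
}
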