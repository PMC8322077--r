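# Proteome-aware classification of diglycine-remnant PSMs.
#
# A tryptic peptide beginning Gly-Gly-X can arise three ways: a genome-encoded
# internal GGX motif exposed by trypsin (preceded by K/R), the canonical
# K-epsilon-GG remnant on a lysine side chain, or true N-terminal
# ubiquitination (diglycine on the alpha-amine of the initiator Met or of a
# Met-clipped neo-N-terminus). Telling these apart against the proteome is
# the core of the analysis.

GG_VERDICTS <- c("NTERM_UB_INITIATOR_MET", "NTERM_UB_NEO_NTERM",
                 "INTERNAL_ENCODED_GGX", "K_EPS_GG", "REJECT_X_START",
                 "AMBIGUOUS", "NO_GG")

# Positions of the GG modification within a PSM's mods string:
# 0 = peptide N-terminus, k >= 1 = lysine side chain at residue k.
gg_position <- function(sequence, mods) {
  m <- parse_mods(mods)
  m <- m[m$name == "gg", , drop = FALSE]
  if (nrow(m) == 0) return(NA_integer_)
  if (nrow(m) > 1) stop("multiple GG remnants on one peptide are not supported")
  pos <- m$position
  if (pos > 0 && substr(sequence, pos, pos) != "K") {
    stop("internal GG remnant must sit on a lysine (position ", pos, ")")
  }
  pos
}

# All occurrences (1-based starts) of peptide in a protein sequence.
find_occurrences <- function(peptide, protein_seq) {
  hits <- gregexpr(peptide, protein_seq, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer() else as.integer(hits)
}

#' Scan a protein for genome-encoded internal GGX motifs
#'
#' Returns the 1-based positions p at which residues (p, p+1) read "GG" with
#' residue (p-1) being K or R — i.e. tryptic cleavage would expose a
#' genome-encoded GGX peptide indistinguishable in sequence from an
#' N-terminally ubiquitinated one.
#'
#' @param sequence protein sequence.
#' @return integer vector of motif positions (position of the first G).
#' @examples
#' find_internal_ggx_motifs("AKGGMLTNAR")  # 3
#' @export
find_internal_ggx_motifs <- function(sequence) {
  hits <- gregexpr("(?<=[KR])GG", sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) integer() else as.integer(hits)
}

#' Classify one GG-bearing PSM against the proteome
#'
#' Decision procedure, in order:
#' 1. no GG modification -> `NO_GG`;
#' 2. GG on a lysine side chain -> `K_EPS_GG`;
#' 3. GG on the peptide N-terminus: if any matching target protein encodes
#'    "GG" immediately before the peptide start with K/R before that GG (or
#'    the encoded GG sits at protein positions 1-2), the diglycine is
#'    genome-encoded -> `INTERNAL_ENCODED_GGX`;
#' 4. else if every matching protein starts with the variable residue 'X'
#'    (unreviewed TrEMBL fragments) -> `REJECT_X_START`;
#' 5. else if the peptide begins at a valid N-terminal form ->
#'    `NTERM_UB_INITIATOR_MET` (start 1) or `NTERM_UB_NEO_NTERM` (Met-clipped
#'    start 2);
#' 6. else -> `AMBIGUOUS`.
#'
#' Across multiple matching proteins any internal-encoded explanation
#' dominates; otherwise a valid N-terminal match (initiator Met preferred
#' over neo-N-terminus) wins over `AMBIGUOUS`. Decoy records are never used
#' for classification.
#'
#' @param peptide_sequence matched peptide (GG is a modification, not
#'   sequence letters).
#' @param mods modification string, e.g. `"gg@0"` or `"gg@6"`.
#' @param proteome protein table ([read_proteome_fasta()]).
#' @param permissive_nterm if TRUE, any peptide start is accepted as a
#'   neo-N-terminus (signal-peptide / internal-proteolysis exploration);
#'   default FALSE restricts neo-N-termini to Met-clipped position 2.
#' @return list with `verdict`, `accession`, `start`, `encoded_gg`
#'   (whether a genome-encoded GG explains the remnant).
#' @export
classify_gg_psm <- function(peptide_sequence, mods, proteome,
                            permissive_nterm = FALSE) {
  ggpos <- gg_position(peptide_sequence, mods)
  if (is.na(ggpos)) {
    return(list(verdict = "NO_GG", accession = NA_character_,
                start = NA_integer_, encoded_gg = FALSE))
  }
  if (ggpos > 0) {
    return(list(verdict = "K_EPS_GG", accession = NA_character_,
                start = NA_integer_, encoded_gg = FALSE))
  }
  targets <- proteome[!proteome$is_decoy, , drop = FALSE]
  best <- NULL  # running best under dominance order
  rank <- c(INTERNAL_ENCODED_GGX = 1, NTERM_UB_INITIATOR_MET = 2,
            NTERM_UB_NEO_NTERM = 3, AMBIGUOUS = 4, REJECT_X_START = 5)
  n_match <- 0L
  all_x_start <- TRUE
  for (i in seq_len(nrow(targets))) {
    seqi <- targets$sequence[i]
    occ <- find_occurrences(peptide_sequence, seqi)
    if (!length(occ)) next
    n_match <- n_match + length(occ)
    xi <- targets$starts_with_X[i]
    if (!xi) all_x_start <- FALSE
    for (s in occ) {
      verdict <- NULL
      encoded <- s >= 3 &&
        substr(seqi, s - 2, s - 1) == "GG" &&
        (s == 3 || substr(seqi, s - 3, s - 3) %in% c("K", "R"))
      if (encoded) {
        verdict <- "INTERNAL_ENCODED_GGX"
      } else if (xi) {
        verdict <- "REJECT_X_START"
      } else if (s == 1L) {
        verdict <- "NTERM_UB_INITIATOR_MET"
      } else if (s == 2L && substr(seqi, 1, 1) == "M" &&
                 (permissive_nterm ||
                  substr(seqi, 2, 2) %in% METAP_SUSCEPTIBLE)) {
        verdict <- "NTERM_UB_NEO_NTERM"
      } else if (permissive_nterm && s >= 2L) {
        verdict <- "NTERM_UB_NEO_NTERM"
      } else {
        verdict <- "AMBIGUOUS"
      }
      cand <- list(verdict = verdict, accession = targets$accession[i],
                   start = s, encoded_gg = encoded)
      if (is.null(best) || rank[[verdict]] < rank[[best$verdict]]) best <- cand
    }
  }
  if (n_match == 0L) {
    stop("peptide '", peptide_sequence,
         "' not found in any target protein")
  }
  if (best$verdict != "INTERNAL_ENCODED_GGX" && all_x_start) {
    # every matching protein is an 'X'-start fragment
    best$verdict <- "REJECT_X_START"
    best$encoded_gg <- FALSE
  }
  best
}

#' Classify a table of PSMs
#'
#' Vectorised driver over [classify_gg_psm()].
#'
#' @param psms PSM table with columns `peptide_sequence` and `mods` (and
#'   optionally `psm_id`).
#' @param proteome protein table.
#' @param on_unmapped "error" (default) or "drop" rows whose peptide maps to
#'   no target protein.
#' @inheritParams classify_gg_psm
#' @return data.frame: `psm_id`, `peptide_sequence`, `verdict`, `accession`,
#'   `start`, `encoded_gg`.
#' @export
classify_gg_psms <- function(psms, proteome, permissive_nterm = FALSE,
                             on_unmapped = c("error", "drop")) {
  on_unmapped <- match.arg(on_unmapped)
  ids <- if ("psm_id" %in% names(psms)) psms$psm_id else seq_len(nrow(psms))
  out <- vector("list", nrow(psms))
  for (i in seq_len(nrow(psms))) {
    cl <- tryCatch(
      classify_gg_psm(psms$peptide_sequence[i], psms$mods[i], proteome,
                      permissive_nterm = permissive_nterm),
      error = function(e) {
        if (on_unmapped == "drop" && grepl("not found", conditionMessage(e))) {
          NULL
        } else {
          stop(e)
        }
      }
    )
    if (is.null(cl)) next
    out[[i]] <- data.frame(
      psm_id = ids[i], peptide_sequence = psms$peptide_sequence[i],
      verdict = cl$verdict, accession = cl$accession, start = cl$start,
      encoded_gg = cl$encoded_gg, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The X-position residue of an N-terminal GG peptide
#'
#' For a peptide carrying the diglycine remnant on its N-terminus, returns
#' the first residue of the matched sequence — the "X" of GGX, i.e. position
#' 3 counting the two remnant glycines.
#'
#' @inheritParams classify_gg_psm
#' @return single amino-acid letter.
#' @export
x_position_residue <- function(peptide_sequence, mods) {
  ggpos <- gg_position(peptide_sequence, mods)
  if (is.na(ggpos) || ggpos != 0) {
    stop("peptide does not carry an N-terminal GG remnant")
  }
  substr(peptide_sequence, 1, 1)
}
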