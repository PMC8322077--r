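# Proteome parsing, in-silico digestion, N-terminal forms, decoy databases.

VALID_RESIDUES <- c(names(AA_MONO_MASS), "X")

# Residues after which Met aminopeptidase typically clips the initiator Met.
METAP_SUSCEPTIBLE <- c("A", "C", "G", "P", "S", "T", "V")

DECOY_PREFIX <- "REV_"

new_protein_records <- function(accession, source_db, sequence, is_decoy) {
  out <- data.frame(
    accession = unname(accession),
    source_db = unname(source_db),
    sequence = unname(sequence),
    is_decoy = is_decoy,
    starts_with_X = unname(substr(sequence, 1, 1) == "X"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a proteome FASTA into a protein table
#'
#' Headers in the UniProt dialect `sp|ACC|NAME` are flagged reviewed
#' (SwissProt) and `tr|ACC|NAME` unreviewed (TrEMBL); any other header is
#' treated as unreviewed and its first whitespace-delimited word used as the
#' accession. Accessions carrying the decoy prefix `REV_` are flagged decoys.
#' Unreviewed TrEMBL fragments may begin with a variable residue 'X'; these
#' are parsed (and flagged via `starts_with_X`) so downstream classification
#' can exclude them.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession`, `source_db`
#'   ("reviewed"/"unreviewed"), `sequence`, `is_decoy`, `starts_with_X`.
#' @export
read_proteome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # read as raw strings first so residue validation produces a named error
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0) {
    return(new_protein_records(character(), character(), character(),
                               logical()))
  }
  headers <- names(aas)
  seqs <- toupper(as.character(aas))
  bad <- grepl(paste0("[^", paste(VALID_RESIDUES, collapse = ""), "]"), seqs)
  if (any(bad)) {
    stop("illegal residue character(s) in record(s): ",
         paste(headers[bad], collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence in record(s): ",
         paste(headers[!nzchar(seqs)], collapse = ", "))
  }
  first <- sub("\\s.*$", "", headers)
  fields <- strsplit(first, "|", fixed = TRUE)
  parse_one <- function(f, hdr) {
    if (length(f) >= 2 && f[[1]] %in% c("sp", "tr")) {
      if (!nzchar(f[[2]])) stop("malformed header: ", hdr)
      c(f[[2]], if (f[[1]] == "sp") "reviewed" else "unreviewed")
    } else {
      c(f[[1]], "unreviewed")
    }
  }
  parsed <- mapply(parse_one, fields, headers)
  acc <- parsed[1, ]
  src <- parsed[2, ]
  new_protein_records(acc, src, seqs, startsWith(acc, DECOY_PREFIX))
}

#' Write a protein table as FASTA
#'
#' Emits UniProt-style headers (`sp|ACC|ACC` for reviewed, `tr|ACC|ACC`
#' otherwise); decoy records keep their `REV_`-prefixed accession.
#'
#' @param proteins protein table as from [read_proteome_fasta()].
#' @param path output path.
#' @export
write_proteome_fasta <- function(proteins, path) {
  aas <- Biostrings::AAStringSet(proteins$sequence)
  tag <- ifelse(proteins$source_db == "reviewed", "sp", "tr")
  names(aas) <- paste0(tag, "|", proteins$accession, "|", proteins$accession)
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' In-silico tryptic / semi-tryptic digestion
#'
#' Cleaves after K or R; cleavage before proline is suppressed by default
#' (the classical trypsin rule). The protein N-terminus, a valid Met-clipped
#' start at residue 2 (initiator Met followed by a MetAP-susceptible
#' residue), and the protein C-terminus all count as tryptic termini. `specificity = "full"` returns peptides with both termini
#' tryptic; `"semi"` additionally returns peptides with exactly one tryptic
#' terminus. Peptides containing more than `max_missed` internal cleavage
#' sites are excluded; a K/R followed by P is not a countable site when
#' proline suppression is on.
#'
#' @param sequence protein sequence (single string).
#' @param max_missed maximum missed cleavages (default 2).
#' @param specificity "full" or "semi".
#' @param min_length,max_length peptide length bounds.
#' @param cleave_before_proline if FALSE (default), K/R followed by P is not
#'   a cleavage site.
#' @param accession optional parent accession carried into the output.
#' @return data.frame with columns `accession`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, `nterm_tryptic`, `cterm_tryptic` (1-based inclusive
#'   coordinates).
#' @examples
#' digest("MQLKPMEINPEMLNKK", max_missed = 1)
#' @export
digest <- function(sequence, max_missed = 2L,
                   specificity = c("full", "semi"),
                   min_length = 1L, max_length = Inf,
                   cleave_before_proline = FALSE,
                   accession = NA_character_) {
  specificity <- match.arg(specificity)
  stopifnot(max_missed >= 0)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  # permissible cleavage sites: cut after residue i
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts < n]
  if (!cleave_before_proline) cuts <- cuts[res[cuts + 1] != "P"]
  # prefix count of cut sites at or before position i
  iscut <- integer(n)
  iscut[cuts] <- 1L
  cumcut <- cumsum(iscut)
  # permissible sites strictly internal to the peptide: i in [a, b-1]
  n_missed <- function(a, b) {
    ifelse(b > a, cumcut[pmax(b - 1L, 1L)] - c(0L, cumcut)[a], 0L)
  }
  tryptic_starts <- sort(unique(c(
    1L,
    if (res[1] == "M" && n >= 2 && res[2] %in% METAP_SUSCEPTIBLE) 2L,
    cuts + 1L
  )))
  tryptic_ends <- sort(unique(c(cuts, n)))
  # furthest end from start a with at most max_missed internal sites
  end_window <- function(a) {
    ahead <- cuts[cuts >= a]
    if (length(ahead) > max_missed) ahead[max_missed + 1L] else n
  }
  start_window <- function(b) {
    behind <- cuts[cuts <= b - 1L]
    if (length(behind) > max_missed) behind[length(behind) - max_missed] + 1L else 1L
  }
  rows <- vector("list", 3L)
  # fully tryptic
  full <- do.call(rbind, lapply(tryptic_starts, function(a) {
    e <- tryptic_ends[tryptic_ends >= a & tryptic_ends <= end_window(a)]
    if (!length(e)) return(NULL)
    cbind(a, e)
  }))
  rows[[1]] <- full
  if (specificity == "semi") {
    # tryptic N-terminus, ragged C-terminus
    rows[[2]] <- do.call(rbind, lapply(tryptic_starts, function(a) {
      e <- setdiff(a:end_window(a), tryptic_ends)
      if (!length(e)) return(NULL)
      cbind(a, e)
    }))
    # ragged N-terminus, tryptic C-terminus
    rows[[3]] <- do.call(rbind, lapply(tryptic_ends, function(b) {
      a <- setdiff(start_window(b):b, tryptic_starts)
      if (!length(a)) return(NULL)
      cbind(a, b)
    }))
  }
  m <- do.call(rbind, rows)
  pep <- data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  pep <- pep[!duplicated(pep), , drop = FALSE]
  len <- pep$end - pep$start + 1L
  pep <- pep[len >= min_length & len <= max_length, , drop = FALSE]
  pep$missed_cleavages <- n_missed(pep$start, pep$end)
  pep$nterm_tryptic <- pep$start %in% tryptic_starts
  pep$cterm_tryptic <- pep$end %in% tryptic_ends
  pep$sequence <- substr(rep(sequence, nrow(pep)), pep$start, pep$end)
  pep$accession <- accession
  pep <- pep[order(pep$start, pep$end), ]
  rownames(pep) <- NULL
  pep[, c("accession", "start", "end", "sequence", "missed_cleavages",
          "nterm_tryptic", "cterm_tryptic")]
}

#' Enumerate valid N-terminal forms of a protein
#'
#' Every protein has an initiator form starting at residue 1. If the protein
#' begins with methionine and its second residue belongs to the
#' Met-aminopeptidase-susceptible set (Ala, Cys, Gly, Pro, Ser, Thr, Val), a
#' Met-clipped neo-N-terminal form starting at residue 2 is added. Note that
#' Pro is included per the aminopeptidase specificity rule even though
#' Met-Pro N-termini resist N-terminal acetylation; forms arising from a
#' clipped Met-Pro are flagged in the `note` column.
#'
#' @param sequence protein sequence.
#' @param accession optional accession carried into the output.
#' @return data.frame with columns `accession`, `start` (1 or 2), `kind`
#'   ("initiator_met" or "met_clipped"), `note`.
#' @export
enumerate_nterm_forms <- function(sequence, accession = NA_character_) {
  if (substr(sequence, 1, 1) == "X") {
    stop("protein starts with 'X'; exclude such entries from N-terminal analysis")
  }
  out <- data.frame(accession = accession, start = 1L,
                    kind = "initiator_met", note = "",
                    stringsAsFactors = FALSE)
  r1 <- substr(sequence, 1, 1)
  r2 <- substr(sequence, 2, 2)
  if (r1 == "M" && r2 %in% METAP_SUSCEPTIBLE) {
    out <- rbind(out, data.frame(
      accession = accession, start = 2L, kind = "met_clipped",
      note = if (r2 == "P") "met-pro_clip_uncertain" else "",
      stringsAsFactors = FALSE
    ))
  }
  out
}

#' Append reversed-sequence decoys to a protein table
#'
#' One decoy per target: the full sequence reversed, the accession prefixed
#' with `REV_`. Targets are returned unchanged alongside their decoys.
#'
#' @param proteins target protein table (no decoys).
#' @return protein table of targets followed by decoys.
#' @export
build_decoy_db <- function(proteins) {
  if (any(proteins$is_decoy)) {
    stop("input already contains decoy records; decoys of decoys are not allowed")
  }
  if (anyDuplicated(proteins$accession)) {
    stop("duplicate accessions in input")
  }
  revseq <- vapply(strsplit(proteins$sequence, "", fixed = TRUE),
                   function(x) paste(rev(x), collapse = ""), "")
  decoys <- new_protein_records(
    paste0(DECOY_PREFIX, proteins$accession),
    proteins$source_db, revseq, is_decoy = TRUE
  )
  rbind(proteins, decoys)
}
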