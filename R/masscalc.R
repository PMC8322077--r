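# Monoisotopic mass arithmetic for peptides, modifications and fragment ions.

#' Physical constants (monoisotopic, Da)
#' @keywords internal
#' @name mass-constants
NULL

PROTON_MASS <- 1.0072765
WATER_MASS <- 18.0105646

# Standard 20-residue monoisotopic masses, 5 decimals.
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Built-in modification registry
#'
#' Returns the registry of post-translational and labelling modifications the
#' pipeline understands. Deltas are monoisotopic and stored to six decimals;
#' the commonly quoted four-decimal values (e.g. the +114.0429 Da diglycine
#' remnant left on a ubiquitinated residue after tryptic cleavage of
#' ubiquitin) are the reporting precision of these constants.
#'
#' @return A data.frame with columns `name`, `target` (residue or terminus the
#'   modification attaches to) and `delta` (mass shift in Da).
#' @examples
#' modification_registry()
#' @export
modification_registry <- function() {
  data.frame(
    name = c("gg", "carbamidomethyl", "oxidation", "tmt", "tmt_k"),
    target = c("nterm_or_lysine", "cysteine", "methionine",
               "peptide_nterm", "lysine"),
    delta = c(114.042927, 57.021464, 15.994915, 229.162932, 229.162932),
    stringsAsFactors = FALSE
  )
}

#' Write / read the modification registry as TSV
#'
#' @param registry data.frame as returned by [modification_registry()].
#' @param path file path.
#' @return `read_modification_registry` returns the registry data.frame.
#' @export
write_modification_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_modification_registry
#' @export
read_modification_registry <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# Parse a modification string like "gg@0;carbamidomethyl@9" into a
# data.frame(name, position). Position 0 denotes the peptide N-terminus.
parse_mods <- function(mods) {
  if (is.null(mods) || length(mods) == 0 ||
      (length(mods) == 1 && (is.na(mods) || !nzchar(mods)))) {
    return(data.frame(name = character(), position = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- unlist(strsplit(mods, ";", fixed = TRUE))
  parts <- parts[nzchar(parts)]
  at <- strsplit(parts, "@", fixed = TRUE)
  bad <- vapply(at, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed modification token(s): ",
         paste(parts[bad], collapse = ", "))
  }
  out <- data.frame(
    name = vapply(at, `[[`, "", 1L),
    position = as.integer(vapply(at, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$position)) {
    stop("at most one modification per position; duplicated position in '",
         paste(mods, collapse = ";"), "'")
  }
  out
}

# Resolve parsed modifications to deltas, validating names and positions.
resolve_mods <- function(sequence, mods, registry = modification_registry()) {
  m <- parse_mods(mods)
  if (nrow(m) == 0) {
    m$delta <- numeric()
    return(m)
  }
  idx <- match(m$name, registry$name)
  if (anyNA(idx)) {
    stop("unknown modification(s): ",
         paste(unique(m$name[is.na(idx)]), collapse = ", "))
  }
  n <- nchar(sequence)
  if (any(m$position < 0 | m$position > n)) {
    stop("modification position outside peptide (length ", n, ")")
  }
  m$delta <- registry$delta[idx]
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water plus all modification
#' deltas. Modifications are given as `"name@position"` tokens joined by
#' `";"`, with position 0 denoting the peptide N-terminus (e.g. the diglycine
#' remnant of an N-terminally ubiquitinated peptide is `"gg@0"`; the same
#' remnant on lysine 6 is `"gg@6"`).
#'
#' @param sequence peptide sequence (standard 20 amino-acid letters).
#' @param mods character vector of modification tokens, or a single
#'   `";"`-joined string; empty for an unmodified peptide.
#' @param registry modification registry, see [modification_registry()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")                      # 75.03203
#' peptide_mass("MFGSAPQRPVAMTTAQR", "gg@0")
#' @export
peptide_mass <- function(sequence, mods = character(),
                         registry = modification_registry()) {
  stopifnot(length(sequence) == 1, is.character(sequence), nzchar(sequence))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(res, names(AA_MONO_MASS))
  if (length(unknown) > 0) {
    stop("residue(s) with undefined mass: ", paste(unknown, collapse = ", "))
  }
  m <- resolve_mods(sequence, mods, registry)
  sum(AA_MONO_MASS[res]) + WATER_MASS + sum(m$delta)
}

#' Precursor m/z at a given charge
#'
#' @param neutral_mass neutral monoisotopic mass in Da.
#' @param charge positive integer charge state.
#' @return m/z in Thomson: `(neutral_mass + charge * proton) / charge`.
#' @examples
#' precursor_mz(peptide_mass("MFGSAPQRPVAMTTAQR", "gg@0"), 3)
#' @export
precursor_mz <- function(neutral_mass, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer")
  }
  (neutral_mass + charge * PROTON_MASS) / charge
}

#' Signed parts-per-million mass error
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z (> 0).
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Theoretical b- and y-series fragment ions
#'
#' Enumerates singly to `max_charge`-charged b and y ions. N-terminal
#' modifications (diglycine remnant, TMT label) ride the b-series from b1
#' onward; a modification on residue k contributes to b_i for i >= k and to
#' y_j for j >= n - k + 1.
#'
#' @inheritParams peptide_mass
#' @param max_charge highest fragment charge to emit.
#' @return data.frame with columns `series` ("b"/"y"), `index`, `charge`, `mz`.
#' @examples
#' head(fragment_ions("GGMLTNAR"))
#' @export
fragment_ions <- function(sequence, mods = character(), max_charge = 1L,
                          registry = modification_registry()) {
  stopifnot(max_charge >= 1)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2) stop("fragment ions require a peptide of length >= 2")
  unknown <- setdiff(res, names(AA_MONO_MASS))
  if (length(unknown) > 0) {
    stop("residue(s) with undefined mass: ", paste(unknown, collapse = ", "))
  }
  m <- resolve_mods(sequence, mods, registry)
  # per-position added mass; N-terminal mods (position 0) count as position 1
  # for prefix sums so they appear from b1 onward
  posmass <- AA_MONO_MASS[res]
  if (nrow(m) > 0) {
    eff <- pmax(m$position, 1L)
    for (i in seq_len(nrow(m))) posmass[eff[i]] <- posmass[eff[i]] + m$delta[i]
  }
  prefix <- cumsum(posmass)              # b_i neutral residue sums
  suffix <- rev(cumsum(rev(posmass)))    # y_j sums via suffix[n - j + 1]
  idx <- seq_len(n - 1)
  out <- vector("list", 2 * max_charge)
  k <- 0
  for (z in seq_len(max_charge)) {
    b_mz <- (prefix[idx] + z * PROTON_MASS) / z
    y_mz <- (suffix[n - idx + 1] + WATER_MASS + z * PROTON_MASS) / z
    k <- k + 1
    out[[k]] <- data.frame(series = "b", index = idx, charge = z, mz = b_mz)
    k <- k + 1
    out[[k]] <- data.frame(series = "y", index = idx, charge = z, mz = y_mz)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export a theoretical spectrum as TSV
#'
#' @param ions data.frame from [fragment_ions()].
#' @param path output file path.
#' @export
write_theoretical_spectrum <- function(ions, path) {
  utils::write.table(ions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
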