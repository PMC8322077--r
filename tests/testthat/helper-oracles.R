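# Independent oracles used to validate the implementation.

random_peptide <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                           "I", "K", "L", "M", "N", "P", "Q",
                                           "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force digestion: enumerate every substring and test the terminus /
# missed-cleavage predicates directly.
brute_force_digest <- function(sequence, max_missed, specificity,
                               cleave_before_proline = FALSE) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  is_cut <- function(i) {
    i >= 1 && i < n && res[i] %in% c("K", "R") &&
      (cleave_before_proline || res[i + 1] != "P")
  }
  nterm_ok <- function(a) {
    a == 1 ||
      (a == 2 && res[1] == "M" &&
         res[2] %in% c("A", "C", "G", "P", "S", "T", "V")) ||
      is_cut(a - 1)
  }
  cterm_ok <- function(b) b == n || is_cut(b)
  rows <- list()
  for (a in seq_len(n)) {
    for (b in a:n) {
      internal <- if (b > a) sum(vapply(a:(b - 1), is_cut, TRUE)) else 0L
      if (internal > max_missed) next
      nt <- nterm_ok(a)
      ct <- cterm_ok(b)
      keep <- if (specificity == "full") nt && ct else (nt + ct) >= 1
      if (!keep) next
      rows[[length(rows) + 1]] <- data.frame(
        start = a, end = b, sequence = substr(sequence, a, b),
        missed_cleavages = internal, nterm_tryptic = nt, cterm_tryptic = ct
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), ]
}

# Independent median polish: plain alternating sweeps.
median_polish_oracle <- function(x, eps = 0.01, maxiter = 10) {
  overall <- 0
  row_eff <- rep(0, nrow(x))
  col_eff <- rep(0, ncol(x))
  z <- x
  old_sum <- 0
  for (it in seq_len(maxiter)) {
    rmed <- apply(z, 1, median, na.rm = TRUE)
    z <- sweep(z, 1, rmed)
    row_eff <- row_eff + rmed
    cmed_r <- median(col_eff, na.rm = TRUE)
    col_eff <- col_eff - cmed_r
    overall <- overall + cmed_r
    cmed <- apply(z, 2, median, na.rm = TRUE)
    z <- sweep(z, 2, cmed)
    col_eff <- col_eff + cmed
    rmed_c <- median(row_eff, na.rm = TRUE)
    row_eff <- row_eff - rmed_c
    overall <- overall + rmed_c
    new_sum <- sum(abs(z), na.rm = TRUE)
    converged <- new_sum == 0 ||
      abs(new_sum - old_sum) < eps * new_sum
    if (converged) break
    old_sum <- new_sum
  }
  list(overall = unname(overall), row = unname(row_eff),
       col = unname(col_eff), residuals = z)
}

# Benjamini-Hochberg step-up, from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Closed-form two-class LDA direction: Sw^{-1} (mu_target - mu_decoy),
# returned as a unit vector oriented so targets project higher.
lda_direction_oracle <- function(x, is_target) {
  x <- as.matrix(x)
  mu1 <- colMeans(x[is_target, , drop = FALSE])
  mu0 <- colMeans(x[!is_target, , drop = FALSE])
  s1 <- crossprod(scale(x[is_target, , drop = FALSE], center = mu1,
                        scale = FALSE))
  s0 <- crossprod(scale(x[!is_target, , drop = FALSE], center = mu0,
                        scale = FALSE))
  sw <- (s1 + s0) / (nrow(x) - 2)
  w <- solve(sw, mu1 - mu0)
  w / sqrt(sum(w^2))
}

# Shannon-entropy information content, independently of the package.
ic_oracle <- function(prob_col) {
  nz <- prob_col[prob_col > 0]
  log2(length(prob_col)) + sum(nz * log2(nz))
}

make_protein_table <- function(accession, sequence,
                               source_db = "reviewed", is_decoy = FALSE) {
  data.frame(
    accession = accession, source_db = source_db, sequence = sequence,
    is_decoy = is_decoy, starts_with_X = substr(sequence, 1, 1) == "X",
    stringsAsFactors = FALSE
  )
}
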