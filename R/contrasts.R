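# Per-feature differential abundance: one-way fixed-effects linear model on
# log2 abundances, condition contrasts, Benjamini-Hochberg adjustment.

#' Fit condition contrasts per feature
#'
#' For each feature (row of the log2 abundance matrix) fits the one-way
#' fixed-effects layout `abundance ~ condition` across all samples with
#' observed values, then estimates each requested contrast as a difference
#' of condition means. The standard error uses the residual variance pooled
#' across all conditions observed for that feature, and the two-sided
#' p-value comes from the t distribution with the feature's residual degrees
#' of freedom — so in a balanced two-condition design the result is exactly
#' the classical pooled two-sample t-test. P-values are BH-adjusted per
#' contrast across features.
#'
#' A contrast is estimable for a feature only if both of its conditions have
#' at least `min_obs` observed samples; otherwise the feature is flagged
#' missing for that contrast and excluded from the BH adjustment. Missing
#' values are never imputed.
#'
#' @param mat numeric matrix, features x samples, log2 scale (NAs allowed).
#' @param design data.frame with columns `sample_id`, `condition` (and
#'   optionally `batch`; a declared batch with >1 level adds an additive
#'   batch term via `stats::lm`).
#' @param contrasts data.frame with columns `name`, `plus`, `minus` naming
#'   the conditions compared (estimate = plus - minus).
#' @param min_obs minimum observed samples per compared condition (default 2).
#' @param moderate if TRUE, residual variances are shrunk toward the
#'   cross-feature mean with a method-of-moments inverse-chi-square prior
#'   (off by default).
#' @return data.frame of class `gg_contrasts`: `feature_id`, `contrast`,
#'   `log2FC`, `SE`, `df`, `t`, `p`, `p_adj` (NA rows mark inestimable
#'   contrasts).
#' @export
fit_contrasts <- function(mat, design, contrasts, min_obs = 2L,
                          moderate = FALSE) {
  stopifnot(all(c("sample_id", "condition") %in% names(design)))
  if (is.null(colnames(mat))) stop("matrix must carry sample ids as colnames")
  idx <- match(colnames(mat), design$sample_id)
  if (anyNA(idx)) stop("sample(s) without a condition label: ",
                       paste(colnames(mat)[is.na(idx)], collapse = ", "))
  cond <- design$condition[idx]
  has_batch <- "batch" %in% names(design) &&
    length(unique(design$batch[idx])) > 1
  conds <- unique(cond)
  for (cn in c(contrasts$plus, contrasts$minus)) {
    if (!cn %in% conds) stop("contrast condition not in design: ", cn)
  }
  obs <- !is.na(mat)
  # per-condition means, counts, and within-condition sums of squares
  nfeat <- nrow(mat)
  means <- counts <- matrix(NA_real_, nfeat, length(conds),
                            dimnames = list(rownames(mat), conds))
  ss <- 0
  npooled <- 0
  ncond_present <- 0
  ssvec <- rep(0, nfeat)
  for (cn in conds) {
    cols <- which(cond == cn)
    sub <- mat[, cols, drop = FALSE]
    k <- rowSums(!is.na(sub))
    mu <- rowSums(sub, na.rm = TRUE) / ifelse(k > 0, k, NA)
    means[, cn] <- mu
    counts[, cn] <- k
    dev <- sweep(sub, 1, mu, "-")
    ssvec <- ssvec + rowSums(dev^2, na.rm = TRUE)
  }
  present <- counts > 0
  df <- rowSums(counts) - rowSums(present)
  s2 <- ifelse(df > 0, ssvec / df, NA_real_)
  d0 <- 0
  if (moderate) {
    ok <- !is.na(s2) & df > 0
    s0 <- mean(s2[ok])
    # method of moments on the scaled chi-square model: between-feature
    # variance in s2 beyond sampling noise sets the prior df
    samp <- mean(2 * s0^2 / df[ok])
    tau2 <- max(stats::var(s2[ok]) - samp, 1e-12)
    d0 <- min(2 * s0^2 / tau2, 1e6)
    s2 <- ifelse(ok, (d0 * s0 + df * s2) / (d0 + df), s2)
  }
  batch_fits <- NULL
  if (has_batch) {
    # additive batch term: refit per feature with stats::lm and take
    # contrasts on the condition coefficients
    batch <- factor(design$batch[idx])
    condf <- factor(cond, levels = conds)
    batch_fits <- lapply(seq_len(nfeat), function(i) {
      y <- mat[i, ]
      ok <- !is.na(y)
      if (sum(ok) < 3) return(NULL)
      fit <- tryCatch(stats::lm(y[ok] ~ 0 + condf[ok] + batch[ok]),
                      error = function(e) NULL)
      if (is.null(fit) || fit$df.residual < 1) return(NULL)
      list(coef = stats::coef(fit), vcov = stats::vcov(fit),
           df = fit$df.residual,
           names = paste0("condf[ok]", levels(condf)))
    })
  }
  out <- vector("list", nrow(contrasts))
  for (j in seq_len(nrow(contrasts))) {
    cp <- contrasts$plus[j]
    cm <- contrasts$minus[j]
    estimable <- counts[, cp] >= min_obs & counts[, cm] >= min_obs & df > 0
    lfc <- means[, cp] - means[, cm]
    se <- sqrt(s2 * (1 / counts[, cp] + 1 / counts[, cm]))
    tt <- lfc / se
    p <- 2 * stats::pt(-abs(tt), df + d0)
    # zero residual variance (e.g. noiseless synthetic data)
    zero <- !is.na(se) & se == 0
    tt[zero] <- ifelse(lfc[zero] == 0, 0, sign(lfc[zero]) * Inf)
    p[zero] <- ifelse(lfc[zero] == 0, 1, 0)
    if (has_batch) {
      for (i in seq_len(nfeat)) {
        bf <- batch_fits[[i]]
        ok_ij <- !is.null(bf) &&
          all(paste0("condf[ok]", c(cp, cm)) %in% names(bf$coef)) &&
          !anyNA(bf$coef[paste0("condf[ok]", c(cp, cm))])
        if (!ok_ij) {
          estimable[i] <- FALSE
          next
        }
        kp <- paste0("condf[ok]", cp)
        km <- paste0("condf[ok]", cm)
        lfc[i] <- bf$coef[[kp]] - bf$coef[[km]]
        se[i] <- sqrt(bf$vcov[kp, kp] + bf$vcov[km, km] - 2 * bf$vcov[kp, km])
        tt[i] <- lfc[i] / se[i]
        p[i] <- 2 * stats::pt(-abs(tt[i]), bf$df)
        df[i] <- bf$df
      }
    }
    lfc[!estimable] <- NA
    se[!estimable] <- NA
    tt[!estimable] <- NA
    p[!estimable] <- NA
    p_adj <- rep(NA_real_, nfeat)
    p_adj[estimable] <- stats::p.adjust(p[estimable], method = "BH")
    out[[j]] <- data.frame(
      feature_id = rownames(mat), contrast = contrasts$name[j],
      log2FC = unname(lfc), SE = unname(se),
      df = unname(df + d0), t = unname(tt), p = unname(p),
      p_adj = p_adj, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gg_contrasts", "data.frame")
  res
}

#' @export
print.gg_contrasts <- function(x, ...) {
  cat("Per-feature condition contrasts (", length(unique(x$contrast)),
      " contrast(s), ", length(unique(x$feature_id)), " features)\n",
      sep = "")
  NextMethod()
}

#' Summary of fitted contrasts
#'
#' @param object `gg_contrasts` result.
#' @param lfc_min,p_max thresholds used to count candidate features.
#' @param ... unused.
#' @export
summary.gg_contrasts <- function(object, lfc_min = 1, p_max = 0.05, ...) {
  by_contrast <- split(object, object$contrast)
  tab <- do.call(rbind, lapply(by_contrast, function(d) {
    data.frame(
      contrast = d$contrast[1],
      n_features = nrow(d),
      n_estimable = sum(!is.na(d$p)),
      n_pass = sum(d$log2FC > lfc_min & d$p < p_max, na.rm = TRUE)
    )
  }))
  rownames(tab) <- NULL
  tab
}
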