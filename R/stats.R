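#' Per-subject Spearman monotonicity of a feature over conditions
#'
#' For each subject, computes Spearman's rho between the condition grid
#' (delta SNR) and the feature values, with midrank tie handling, and
#' averages over subjects.  A subject whose feature vector is constant
#' contributes rho = 0 by convention (flagged with a warning; no subject
#' is excluded from the mean).
#'
#' @param values Matrix with subjects in rows and conditions in columns
#'   (columns ordered by ascending delta SNR), or a numeric vector for one
#'   subject.
#' @param delta_snr_db Condition values; defaults to the column index.
#' @return List with `rho_by_subject`, `mean_rho` and `n_constant`.
#' @export
#' @examples
#' spearman_monotonicity(matrix(1:6, nrow = 1))$mean_rho  # 1
spearman_monotonicity <- function(values, delta_snr_db = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (ncol(values) < 3)
    stop_data("need at least 3 conditions for a monotonicity estimate")
  if (is.null(delta_snr_db)) delta_snr_db <- seq_len(ncol(values))
  if (length(delta_snr_db) != ncol(values))
    stop_config("delta_snr_db length does not match the condition count")
  rho <- apply(values, 1, function(v) {
    if (sd(v) == 0) NA_real_ else cor(delta_snr_db, v, method = "spearman")
  })
  n_const <- sum(is.na(rho))
  if (n_const > 0) {
    warning(n_const, " subject(s) with a constant feature; rho set to 0",
            call. = FALSE)
    rho[is.na(rho)] <- 0
  }
  list(rho_by_subject = rho, mean_rho = mean(rho), n_constant = n_const)
}

#' Kruskal-Wallis test across conditions
#'
#' Rank-based one-way test of the hypothesis that all condition groups
#' share the same distribution, with midrank tie correction (delegates to
#' [stats::kruskal.test()]).
#'
#' @param values Numeric observations.
#' @param groups Group (condition) labels, same length as `values`.
#' @return List with `chi2` (the H statistic), `p` and `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_data("need at least 2 groups")
  if (any(table(groups) == 0)) stop_data("every group must be nonempty")
  if (length(unique(values)) == 1L)    # fully tied sample: H = 0 by definition
    return(list(chi2 = 0, p = 1, df = nlevels(groups) - 1))
  kt <- kruskal.test(values, groups)
  list(chi2 = unname(kt$statistic), p = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise Dunn z statistics on the midranks of the pooled sample, with
#' tie correction, two-sided p-values, and Bonferroni multiplication by
#' the number of pairs (clipped at 1).  Intended as the follow-up to a
#' rejected Kruskal-Wallis test; the function itself runs unconditionally.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @return List with symmetric matrices `p_adj` (unit diagonal), `p_raw`
#'   and `z`, plus `n_pairs`.
#' @export
dunn_bonferroni_posthoc <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop_data("need at least 2 groups")
  if (any(table(groups) == 0)) stop_data("every group must be nonempty")
  N <- length(values)
  rk <- rank(values)                       # midranks
  mean_rank <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  lv <- levels(groups)
  z <- p_raw <- matrix(0, k, k, dimnames = list(lv, lv))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(v0 * (1 / n_g[i] + 1 / n_g[j]))
    zij <- if (se == 0) 0 else (mean_rank[i] - mean_rank[j]) / se
    z[i, j] <- zij; z[j, i] <- -zij
    p_raw[i, j] <- p_raw[j, i] <- 2 * pnorm(-abs(zij))
  }
  diag(p_raw) <- 1
  n_pairs <- k * (k - 1) / 2
  p_adj <- pmin(p_raw * n_pairs, 1)
  diag(p_adj) <- 1
  list(p_adj = p_adj, p_raw = p_raw, z = z, n_pairs = n_pairs)
}

#' Electrode-wise statistics for one TRF feature
#'
#' For every electrode, computes the mean over subjects of the per-subject
#' Spearman rho between delta SNR and the feature, a Kruskal-Wallis test
#' across conditions (observations pooled over subjects), and the
#' Dunn-Bonferroni pairwise condition comparisons.
#'
#' @param features Feature table from [extract_feature_table()].
#' @param feature Column to analyze (e.g. `"rms"`, `"n1_amp"`,
#'   `"n1_lat_ms"`).
#' @return Data frame per electrode: `electrode`, `mean_rho`, `kw_chi2`,
#'   `kw_p`, `kw_df`; the pairwise adjusted p matrices are attached as
#'   attribute `posthoc` (a named list).
#' @export
electrode_stat_map <- function(features, feature = "rms") {
  if (!feature %in% names(features))
    stop_config("feature column ", feature, " not found")
  electrodes <- unique(features$electrode)
  conds <- sort(unique(features$condition))
  posthoc <- list()
  rows <- lapply(electrodes, function(el) {
    sub <- features[features$electrode == el, ]
    m <- matrix(NA_real_, length(unique(sub$subject)), length(conds))
    subj <- sort(unique(sub$subject))
    for (i in seq_along(subj)) {
      si <- sub[sub$subject == subj[i], ]
      m[i, ] <- si[[feature]][match(conds, si$condition)]
    }
    mono <- suppressWarnings(spearman_monotonicity(m, conds))
    kw <- kruskal_wallis(sub[[feature]], sub$condition)
    posthoc[[el]] <<- dunn_bonferroni_posthoc(sub[[feature]], sub$condition)$p_adj
    data.frame(electrode = el, mean_rho = mono$mean_rho,
               kw_chi2 = kw$chi2, kw_p = kw$p, kw_df = kw$df)
  })
  out <- do.call(rbind, rows)
  attr(out, "posthoc") <- posthoc
  out
}
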