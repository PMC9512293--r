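# Differential protein screening: fold change of group means, significance
# test on log2 relative values, and the up/down/ns call.

#' Screening configuration
#'
#' @param fc_threshold fold-change threshold for up-regulation (strict,
#'   `fc > fc_threshold`); down-regulation uses the reciprocal
#'   `fc < 1/fc_threshold`. Default 1.3.
#' @param alpha significance level, inclusive (`p <= alpha`). Default 0.05.
#' @param test `"t_log2"` (two-sided pooled-variance Student t on log2
#'   relative values, default), `"welch_t_log2"` (Welch t; note it is
#'   noticeably conservative at 3 samples per group) or `"wilcoxon"`
#'   (exact rank-sum).
#' @param adjust p-value adjustment method passed to [stats::p.adjust()];
#'   `"none"` (default, matching a raw-p screen) or e.g. `"BH"`. When not
#'   `"none"`, the call uses the adjusted p.
#' @return A validated list of class `screen_config`.
#' @export
screen_config <- function(fc_threshold = 1.3, alpha = 0.05,
                          test = c("t_log2", "welch_t_log2", "wilcoxon"),
                          adjust = "none") {
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1L || fc_threshold <= 1)
    stop_config("fc_threshold", "must be a single number > 1")
  alpha <- check_fraction(alpha, "alpha", lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  structure(list(fc_threshold = as.numeric(fc_threshold), alpha = alpha,
                 test = match.arg(test), adjust = adjust),
            class = "screen_config")
}

protein_matrix <- function(proteins, groups, numerator, denominator) {
  key_cols <- intersect(c("protein_id", "n_peptides"), names(proteins))
  if (!"protein_id" %in% key_cols)
    stop_input("protein table needs a protein_id column")
  samples <- setdiff(names(proteins), key_cols)
  groups <- check_groups(groups, sample_ids = samples)
  for (g in c(numerator, denominator))
    if (!g %in% groups$group)
      stop_input(sprintf("group '%s' not present in groups table", g))
  list(mat = as.matrix(proteins[samples]),
       ids = proteins$protein_id,
       num = samples[groups$group == numerator],
       den = samples[groups$group == denominator])
}

#' Per-protein fold change between two groups
#'
#' Fold change is the ratio of group means of the protein relative values,
#' \deqn{FC_k = \mathrm{mean}_i(R_{ik}, i \in A) / \mathrm{mean}_i(R_{ik}, i \in B),}
#' with means over observed values. For the NET-stimulation contrast the
#' numerator group A is the treatment and the denominator B the control.
#' Proteins with no observed value in either group get `NA` with a warning.
#'
#' @param proteins protein table from [rollup_proteins()].
#' @param groups data.frame `sample_id`, `group`.
#' @param numerator,denominator group labels forming the contrast.
#' @return Named numeric vector of fold changes (names = protein ids).
#' @export
compute_fold_change <- function(proteins, groups,
                                numerator = "treatment", denominator = "control") {
  pm <- protein_matrix(proteins, groups, numerator, denominator)
  m_num <- rowMeans(pm$mat[, pm$num, drop = FALSE], na.rm = TRUE)
  m_den <- rowMeans(pm$mat[, pm$den, drop = FALSE], na.rm = TRUE)
  fc <- m_num / m_den
  fc[is.nan(m_num) | is.nan(m_den)] <- NA_real_
  if (anyNA(fc))
    warning(sprintf("%d protein(s) incalculable (no observed value in a group)",
                    sum(is.na(fc))))
  names(fc) <- pm$ids
  fc
}

# Vectorized two-sided t on log2 values, pooled (Student) or Welch; handles
# the degenerate zero-variance conventions (equal means -> p = 1,
# unequal -> p = 0).
row_t_log2 <- function(mat_num, mat_den, pooled = TRUE) {
  l1 <- log2(mat_num); l2 <- log2(mat_den)
  n1 <- rowSums(!is.na(l1)); n2 <- rowSums(!is.na(l2))
  m1 <- rowMeans(l1, na.rm = TRUE); m2 <- rowMeans(l2, na.rm = TRUE)
  v1 <- apply(l1, 1L, var, na.rm = TRUE); v2 <- apply(l2, 1L, var, na.rm = TRUE)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * pt(-abs((m1 - m2) / sqrt(se2)), df)
  degen <- !is.na(se2) & se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    if (any(p[degen] == 0))
      warning("zero-variance protein(s) with unequal means: p set to 0")
  }
  p[n1 < 2L | n2 < 2L] <- NA_real_
  p
}

#' Per-protein significance test
#'
#' Default is a two-sided pooled-variance Student t-test on
#' log2-transformed protein relative values, which is exactly calibrated at
#' the 3-vs-3 design scale; `"welch_t_log2"` and `"wilcoxon"` (exact
#' rank-sum) are available alternatives. Proteins with
#' fewer than 2 observed values in either group get `NA` with a warning.
#' Degenerate zero-variance cases follow the convention: equal constant
#' groups give p = 1, unequal constant groups give p = 0 (with a warning).
#'
#' @inheritParams compute_fold_change
#' @param config a [screen_config()].
#' @return Named numeric vector of p-values in \[0, 1\].
#' @export
test_significance <- function(proteins, groups, config = screen_config(),
                              numerator = "treatment", denominator = "control") {
  stopifnot(inherits(config, "screen_config"))
  pm <- protein_matrix(proteins, groups, numerator, denominator)
  mn <- pm$mat[, pm$num, drop = FALSE]
  md <- pm$mat[, pm$den, drop = FALSE]
  if (config$test %in% c("t_log2", "welch_t_log2")) {
    p <- row_t_log2(mn, md, pooled = config$test == "t_log2")
  } else {
    p <- vapply(seq_len(nrow(mn)), function(r) {
      x <- mn[r, ][!is.na(mn[r, ])]; y <- md[r, ][!is.na(md[r, ])]
      if (length(x) < 2L || length(y) < 2L) return(NA_real_)
      suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
    }, numeric(1))
  }
  if (anyNA(p))
    warning(sprintf("%d protein(s) with < 2 observations in a group: p undefined",
                    sum(is.na(p))))
  names(p) <- pm$ids
  p
}

#' Classify proteins as up, down or not significant
#'
#' A protein is `up` when `fc > fc_threshold` and `p <= alpha`; `down` when
#' `fc < 1/fc_threshold` and `p <= alpha`; otherwise `ns`. Thresholds are
#' strict on fold change and inclusive on p. `NA` in either input yields
#' `NA` (incalculable).
#'
#' @param fc fold changes (named as returned by [compute_fold_change()]).
#' @param p p-values aligned with `fc`.
#' @param config a [screen_config()]; when `config$adjust != "none"` the
#'   adjusted p-values are used for the call and returned as `p_adjusted`.
#' @return data.frame `protein_id`, `fc`, `log2fc`, `p_value`
#'   (plus `p_adjusted` when adjusting), `neg_log10_p`, `call`, with a
#'   `summary` attribute `c(n_up, n_down, n_ns)`.
#' @export
classify_proteins <- function(fc, p, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"), length(fc) == length(p))
  p_used <- if (config$adjust != "none") p.adjust(p, method = config$adjust) else p
  call <- rep("ns", length(fc))
  call[fc > config$fc_threshold & p_used <= config$alpha] <- "up"
  call[fc < 1 / config$fc_threshold & p_used <= config$alpha] <- "down"
  call[is.na(fc) | is.na(p_used)] <- NA_character_
  out <- data.frame(
    protein_id = if (!is.null(names(fc))) names(fc) else as.character(seq_along(fc)),
    fc = as.numeric(fc),
    log2fc = log2(as.numeric(fc)),
    p_value = as.numeric(p),
    stringsAsFactors = FALSE
  )
  if (config$adjust != "none") out$p_adjusted <- as.numeric(p_used)
  out$neg_log10_p <- -log10(as.numeric(p_used))
  out$call <- call
  attr(out, "summary") <- c(n_up = sum(call == "up", na.rm = TRUE),
                            n_down = sum(call == "down", na.rm = TRUE),
                            n_ns = sum(call == "ns", na.rm = TRUE))
  out
}

#' Run the full differential screen on a protein table
#'
#' Convenience wrapper chaining [compute_fold_change()],
#' [test_significance()] and [classify_proteins()].
#'
#' @inheritParams test_significance
#' @return The classified data.frame from [classify_proteins()].
#' @examples
#' sim <- simulate_tmt_experiment(tmt_sim_config(n_proteins = 100, seed = 3))
#' prot <- rollup_proteins(center_peptides(sim$peptides))
#' res <- screen_proteins(prot, sim$groups)
#' attr(res, "summary")
#' @export
screen_proteins <- function(proteins, groups, config = screen_config(),
                            numerator = "treatment", denominator = "control") {
  fc <- compute_fold_change(proteins, groups, numerator, denominator)
  p <- test_significance(proteins, groups, config, numerator, denominator)
  classify_proteins(fc, p, config)
}
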