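# Independent brute-force recomputations of the three quantification
# formulas and the log-rank statistic. Deliberately written as plain loops
# with no shared code with the package internals.

oracle_center <- function(mat) {
  out <- mat
  for (r in seq_len(nrow(mat))) {
    obs <- !is.na(mat[r, ])
    m <- sum(mat[r, obs]) / sum(obs)
    for (c in seq_len(ncol(mat)))
      out[r, c] <- if (obs[c]) mat[r, c] / m else NA_real_
  }
  out
}

oracle_rollup <- function(rel_mat, protein_of) {
  prots <- unique(protein_of)
  out <- matrix(NA_real_, length(prots), ncol(rel_mat),
                dimnames = list(prots, colnames(rel_mat)))
  for (k in prots) {
    rows <- which(protein_of == k)
    for (c in seq_len(ncol(rel_mat))) {
      vals <- rel_mat[rows, c]
      vals <- vals[!is.na(vals)]
      if (length(vals)) out[k, c] <- median(vals)
    }
  }
  out
}

oracle_fc <- function(prot_mat, idx_num, idx_den) {
  fc <- numeric(nrow(prot_mat))
  for (r in seq_len(nrow(prot_mat))) {
    a <- prot_mat[r, idx_num]; a <- a[!is.na(a)]
    b <- prot_mat[r, idx_den]; b <- b[!is.na(b)]
    fc[r] <- mean(a) / mean(b)
  }
  fc
}

# Literal observed-minus-expected log-rank with hypergeometric variance,
# looping over distinct event times.
oracle_logrank <- function(time, event, g1) {
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(0)
  (O - E)^2 / V
}

# Small random peptide table (<= 10 peptides x <= 6 samples) with optional
# missing cells, for property suites.
random_peptide_table <- function(seed, n_pep = NULL, n_samp = NULL,
                                 missing_rate = 0.1) {
  set.seed(seed)
  if (is.null(n_pep)) n_pep <- sample(2:10, 1)
  if (is.null(n_samp)) n_samp <- sample(4:6, 1)
  mat <- matrix(rlnorm(n_pep * n_samp, 5, 1), n_pep, n_samp)
  if (missing_rate > 0) {
    mat[runif(length(mat)) < missing_rate] <- NA_real_
    for (r in seq_len(n_pep))  # keep every peptide observable
      if (all(is.na(mat[r, ]))) mat[r, 1] <- rlnorm(1, 5, 1)
  }
  colnames(mat) <- paste0("s", seq_len(n_samp))
  prot <- sort(sample(sprintf("P%02d", 1:4), n_pep, replace = TRUE))
  tab <- data.frame(protein_id = prot,
                    peptide_id = paste0("pep", seq_len(n_pep)),
                    stringsAsFactors = FALSE)
  cbind(tab, as.data.frame(mat))
}

random_cohort <- function(seed, n = 8, censor = TRUE, tie_prob = 0.3) {
  set.seed(seed)
  time <- round(rexp(n, 0.2), ifelse(runif(n) < tie_prob, 0, 2))
  time[time == 0] <- 0.5
  data.frame(
    patient_id = sprintf("p%02d", seq_len(n)),
    time = time,
    event = if (censor) rbinom(n, 1, 0.7) else rep(1L, n),
    marker = rnorm(n),
    stringsAsFactors = FALSE
  )
}
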