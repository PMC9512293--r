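# Differential screening: the fold-change formula, test conventions, the
# 1.3 / 0.05 classification rule, and the reciprocal-relabeling property.

make_prot <- function(a, b) {
  # one protein, 3 + 3 samples
  out <- data.frame(protein_id = "P1", n_peptides = 1L)
  for (i in 1:3) out[[paste0("c", i)]] <- a[i]
  for (i in 1:3) out[[paste0("t", i)]] <- b[i]
  out
}

grp6 <- data.frame(sample_id = c("c1", "c2", "c3", "t1", "t2", "t3"),
                   group = rep(c("control", "treatment"), each = 3),
                   stringsAsFactors = FALSE)

test_that("fold change is the ratio of group means", {
  fc <- compute_fold_change(make_prot(c(0.9, 1.0, 1.1), c(1.2, 1.3, 1.4)), grp6)
  expect_equal(unname(fc), 1.3)
  expect_equal(unname(compute_fold_change(
    make_prot(c(1, 1.2, 0.8), c(1, 1.2, 0.8)), grp6)), 1)
  # relabeling the contrast inverts the ratio
  p2 <- make_prot(c(1, 1, 1), c(2, 2, 2))
  expect_equal(unname(compute_fold_change(p2, grp6)), 2)
  expect_equal(unname(compute_fold_change(p2, grp6, numerator = "control",
                                          denominator = "treatment")), 0.5)
})

test_that("incalculable proteins are flagged with a warning", {
  prot <- make_prot(c(NA, NA, NA), c(1, 1, 1))
  expect_warning(fc <- compute_fold_change(prot, grp6), "incalculable")
  expect_true(is.na(fc))
})

test_that("significance test conventions hold", {
  # identical constant groups: degenerate p = 1
  expect_equal(unname(test_significance(make_prot(c(1, 1, 1), c(1, 1, 1)), grp6)), 1)
  # zero variance, unequal means: p = 0 with warning
  expect_warning(
    p0 <- test_significance(make_prot(c(1, 1, 1), c(2, 2, 2)), grp6),
    "zero-variance")
  expect_equal(unname(p0), 0)
  # clear separation: tiny p
  p <- test_significance(make_prot(c(1.00, 1.01, 0.99), c(2.00, 2.01, 1.99)), grp6)
  expect_lt(unname(p), 0.001)
  # relabeling samples within a group leaves p unchanged
  p_swap <- test_significance(make_prot(c(1.01, 1.00, 0.99), c(1.99, 2.00, 2.01)), grp6)
  expect_equal(p, p_swap)
})

test_that("p-values match stats::t.test and the permutation null on a small table", {
  set.seed(21)
  n_prot <- 8
  prot <- data.frame(protein_id = sprintf("P%02d", 1:n_prot), n_peptides = 1L)
  vals <- matrix(rlnorm(n_prot * 6, 0, 0.3), n_prot, 6)
  for (i in 1:6) prot[[grp6$sample_id[i]]] <- vals[, i]

  p_pkg <- test_significance(prot, grp6)
  p_ref <- vapply(seq_len(n_prot), function(r) {
    t.test(log2(vals[r, 4:6]), log2(vals[r, 1:3]), var.equal = TRUE)$p.value
  }, numeric(1))
  expect_equal(unname(p_pkg), p_ref, tolerance = 1e-12)

  # exhaustive 3v3 label-permutation oracle brackets the parametric p
  # for the strongly separated case
  x <- c(1.00, 1.01, 0.99, 2.00, 2.01, 1.99)
  combs <- combn(6, 3)
  tstats <- apply(combs, 2, function(idx) {
    abs(mean(log2(x[idx])) - mean(log2(x[-idx])))
  })
  obs <- abs(mean(log2(x[4:6])) - mean(log2(x[1:3])))
  p_perm <- mean(tstats >= obs - 1e-12)
  expect_equal(p_perm, 2 / 20)  # only the true split and its mirror reach it
})

test_that("classification applies strict fc and inclusive p thresholds", {
  cfg <- screen_config()
  cls <- function(fc, p) classify_proteins(fc, p, cfg)$call
  expect_equal(cls(1.31, 0.04), "up")
  expect_equal(cls(1.30, 0.01), "ns")       # strictly more than 1.3
  expect_equal(cls(0.75, 0.04), "down")     # 0.75 < 1/1.3
  expect_equal(cls(0.77, 0.04), "ns")       # 0.77 > 1/1.3 ~ 0.7692
  expect_equal(cls(1.5, 0.06), "ns")        # fails p <= 0.05
  expect_equal(cls(1.5, 0.05), "up")        # inclusive on p
  res <- classify_proteins(c(a = 1.5, b = 0.5, c = 1.0), c(0.01, 0.01, 0.01), cfg)
  expect_equal(attr(res, "summary"),
               c(n_up = 1L, n_down = 1L, n_ns = 1L))
})

test_that("group relabeling maps fc -> 1/fc, keeps p, swaps calls", {
  sim <- simulate_tmt_experiment(tmt_sim_config(n_proteins = 120, seed = 31))
  prot <- rollup_proteins(center_peptides(sim$peptides))
  fwd <- suppressWarnings(screen_proteins(prot, sim$groups))
  rev <- suppressWarnings(screen_proteins(prot, sim$groups,
                                          numerator = "control",
                                          denominator = "treatment"))
  ok <- !is.na(fwd$fc) & !is.na(rev$fc)
  expect_equal(rev$fc[ok], 1 / fwd$fc[ok], tolerance = 1e-12)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
  swapped <- c(up = "down", down = "up", ns = "ns")
  expect_equal(rev$call[ok], unname(swapped[fwd$call[ok]]))
})

test_that("fold change matches the brute-force oracle on small tables", {
  for (seed in 1:10) {
    set.seed(seed)
    n_prot <- sample(3:10, 1)
    prot <- data.frame(protein_id = sprintf("P%02d", seq_len(n_prot)),
                       n_peptides = 1L)
    vals <- matrix(rlnorm(n_prot * 6, 0, 0.5), n_prot, 6)
    vals[runif(length(vals)) < 0.08] <- NA
    keep <- rowSums(!is.na(vals[, 1:3, drop = FALSE])) > 0 &
      rowSums(!is.na(vals[, 4:6, drop = FALSE])) > 0
    vals <- vals[keep, , drop = FALSE]
    prot <- prot[keep, , drop = FALSE]
    for (i in 1:6) prot[[grp6$sample_id[i]]] <- vals[, i]
    fc <- compute_fold_change(prot, grp6)
    expect_equal(unname(fc), oracle_fc(vals, 4:6, 1:3), tolerance = 1e-12)
  }
})

test_that("wilcoxon and BH-adjust options run and behave", {
  sim <- simulate_tmt_experiment(tmt_sim_config(n_proteins = 60, seed = 32))
  prot <- rollup_proteins(center_peptides(sim$peptides))
  res_w <- suppressWarnings(
    screen_proteins(prot, sim$groups, screen_config(test = "wilcoxon")))
  expect_true(all(res_w$p_value >= 0 & res_w$p_value <= 1, na.rm = TRUE))
  res_bh <- suppressWarnings(
    screen_proteins(prot, sim$groups, screen_config(adjust = "BH")))
  expect_true(all(res_bh$p_adjusted >= res_bh$p_value, na.rm = TRUE))
})
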