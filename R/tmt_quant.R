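# Relative quantification: peptide centering and median rollup to proteins.
# Tables are plain data.frames: key columns first, then one numeric column
# per sample; missing cells are NA (never 0).

peptide_key_cols <- c("protein_id", "peptide_id")

sample_cols <- function(table, key_cols) setdiff(names(table), key_cols)

check_peptide_table <- function(peptides) {
  if (!is.data.frame(peptides) || !all(peptide_key_cols %in% names(peptides)))
    stop_input("peptide table needs columns protein_id and peptide_id")
  samples <- sample_cols(peptides, peptide_key_cols)
  if (length(samples) < 1L)
    stop_input("peptide table needs at least one sample column")
  if (anyDuplicated(peptides[peptide_key_cols]))
    stop_input("duplicate (protein_id, peptide_id) keys in peptide table")
  mat <- as.matrix(peptides[samples])
  if (!is.numeric(mat))
    stop_input("sample columns must be numeric")
  if (any(mat < 0, na.rm = TRUE))
    stop_input("negative intensities are not allowed")
  samples
}

#' Center peptide intensities to relative values
#'
#' Converts each observed reporter intensity to a relative value by dividing
#' by the peptide's mean over its observed samples:
#' \deqn{R_{ij} = I_{ij} / \mathrm{mean}_i(I_{ij}),}
#' so every peptide's observed relative values average exactly 1. Missing
#' cells stay missing; zero intensities are coerced to missing with a
#' warning (a zero would make downstream ratios undefined); peptides with no
#' observed value at all are dropped with a warning.
#'
#' @param peptides data.frame with columns `protein_id`, `peptide_id`, then
#'   one non-negative intensity column per sample (`NA` = missing).
#' @return A data.frame of the same shape holding relative values `R_ij`.
#' @examples
#' tab <- data.frame(protein_id = "P1", peptide_id = "p1",
#'                   s1 = 2, s2 = 4, s3 = 6, s4 = 4)
#' center_peptides(tab)
#' @export
center_peptides <- function(peptides) {
  samples <- check_peptide_table(peptides)
  mat <- as.matrix(peptides[samples])

  n_zero <- sum(mat == 0, na.rm = TRUE)
  if (n_zero > 0) {
    warning(sprintf("%d zero intensities treated as missing", n_zero))
    mat[mat == 0] <- NA_real_
  }
  n_obs <- rowSums(!is.na(mat))
  if (any(n_obs == 0L)) {
    dropped <- peptides$peptide_id[n_obs == 0L]
    warning(sprintf("dropped %d peptide(s) with no observed intensity: %s",
                    length(dropped), paste(head(dropped, 5L), collapse = ", ")))
    keep <- n_obs > 0L
    peptides <- peptides[keep, , drop = FALSE]
    mat <- mat[keep, , drop = FALSE]
  }
  rel <- mat / rowMeans(mat, na.rm = TRUE)
  out <- peptides[peptide_key_cols]
  out[samples] <- as.data.frame(rel)
  rownames(out) <- NULL
  out
}

#' Roll peptide relative values up to protein relative values
#'
#' A protein's relative value in a sample is the median over its peptides'
#' relative values observed in that sample:
#' \deqn{R_{ik} = \mathrm{median}_{j \in k}(R_{ij}).}
#' Even peptide counts use the conventional midpoint (mean of the two
#' central order statistics). Proteins represented by fewer than
#' `min_peptides` peptides are excluded with a warning.
#'
#' @param rel centered peptide table from [center_peptides()].
#' @param min_peptides minimum peptides per protein (default 1, no filter).
#' @return data.frame with `protein_id`, `n_peptides`, then one relative
#'   value column per sample (`NA` where no peptide of the protein was
#'   observed in that sample).
#' @export
rollup_proteins <- function(rel, min_peptides = 1L) {
  samples <- check_peptide_table(rel)
  min_peptides <- check_count(min_peptides, "min_peptides")
  mat <- as.matrix(rel[samples])
  f <- factor(rel$protein_id, levels = unique(rel$protein_id))

  n_pep <- as.integer(table(f))
  med <- vapply(samples, function(s) {
    tapply(mat[, s], f, median, na.rm = TRUE)
  }, numeric(nlevels(f)))
  med <- matrix(med, nrow = nlevels(f), dimnames = list(NULL, samples))
  med[is.nan(med)] <- NA_real_

  out <- data.frame(protein_id = levels(f), n_peptides = n_pep,
                    stringsAsFactors = FALSE)
  out[samples] <- as.data.frame(med)

  if (any(n_pep < min_peptides)) {
    excluded <- out$protein_id[n_pep < min_peptides]
    warning(sprintf("excluded %d protein(s) with < %d peptides",
                    length(excluded), min_peptides))
    out <- out[n_pep >= min_peptides, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' MS2 spectra utilization rate
#'
#' Percentage of collected MS2 spectra that were effective (identified),
#' reported to one decimal place.
#'
#' @param effective number of effective (identified) spectra.
#' @param total number of spectra collected (> 0).
#' @return `round(100 * effective / total, 1)`.
#' @examples
#' spectra_utilization(83412, 363519)  # 22.9
#' @export
spectra_utilization <- function(effective, total) {
  total <- check_count(total, "total", min = 1L)
  effective <- check_count(effective, "effective", min = 0L)
  if (effective > total)
    stop_input("'effective' spectra cannot exceed 'total'")
  round(100 * effective / total, 1)
}
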