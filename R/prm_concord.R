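# Concordance of discovery fold changes with targeted-validation fold
# changes over a protein panel.

#' Discovery vs targeted-validation concordance over a protein panel
#'
#' Compares per-protein fold changes from the discovery screen with those
#' from a targeted (PRM-style) validation run. Direction agreement means
#' both fold changes lie strictly on the same side of 1; a fold change of
#' exactly 1 on either side counts as non-agreeing (conservative). Rank
#' agreement is the Spearman correlation of log2 fold changes over the
#' panel. Validation fold changes are expected to come from the same
#' quantification and screening chain applied to the panel table.
#'
#' @param discovery,validation classified data.frames from
#'   [screen_proteins()] (need columns `protein_id`, `fc`; `call` used for
#'   the validated-significant count when present).
#' @param panel character vector of protein ids to compare.
#' @return list of class `concordance_report`: `table` (per-protein rows in
#'   panel order: `protein_id`, `discovery_fc`, `validation_fc`,
#'   `direction_agrees`), `sign_agreement_rate`, `rank_correlation`
#'   (Spearman, `NA` for panels < 2), `n_validated_significant` (panel
#'   proteins called up or down in validation), `missing` (panel ids absent
#'   from either input, excluded from all rates).
#' @export
concordance <- function(discovery, validation, panel) {
  for (nm in c("discovery", "validation")) {
    d <- get(nm)
    if (!is.data.frame(d) || !all(c("protein_id", "fc") %in% names(d)))
      stop_input(sprintf("'%s' must be a data.frame with protein_id and fc", nm))
  }
  panel <- unique(as.character(panel))
  if (!length(panel)) stop_input("empty panel")
  missing <- panel[!(panel %in% discovery$protein_id) |
                     !(panel %in% validation$protein_id)]
  if (length(missing))
    warning(sprintf("%d panel protein(s) missing from an input, excluded: %s",
                    length(missing), paste(head(missing, 5L), collapse = ", ")))
  used <- setdiff(panel, missing)
  if (!length(used)) stop_input("no panel protein present in both inputs")

  d_fc <- discovery$fc[match(used, discovery$protein_id)]
  v_fc <- validation$fc[match(used, validation$protein_id)]
  agrees <- (d_fc > 1 & v_fc > 1) | (d_fc < 1 & v_fc < 1)
  tab <- data.frame(protein_id = used, discovery_fc = d_fc,
                    validation_fc = v_fc, direction_agrees = agrees,
                    stringsAsFactors = FALSE)
  rho <- if (length(used) >= 2L)
    suppressWarnings(cor(log2(d_fc), log2(v_fc), method = "spearman",
                         use = "complete.obs"))
  else NA_real_
  n_sig <- if ("call" %in% names(validation))
    sum(validation$call[match(used, validation$protein_id)] %in% c("up", "down"))
  else NA_integer_
  structure(list(table = tab,
                 panel_size = length(used),
                 sign_agreement_rate = mean(agrees, na.rm = TRUE),
                 rank_correlation = rho,
                 n_validated_significant = n_sig,
                 missing = missing),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance over %d panel protein(s)\n", x$panel_size))
  cat(sprintf("  direction agreement: %.3f\n", x$sign_agreement_rate))
  cat(sprintf("  Spearman rank correlation (log2 fc): %s\n",
              formatC(x$rank_correlation, digits = 3, format = "f")))
  if (!is.na(x$n_validated_significant))
    cat(sprintf("  validated significant: %d\n", x$n_validated_significant))
  if (length(x$missing))
    cat(sprintf("  missing from an input: %s\n", paste(x$missing, collapse = ", ")))
  invisible(x)
}
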