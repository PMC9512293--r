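# TSV readers/writers for every table the pipeline exchanges. All files are
# plain tab-separated text with a header row; missing cells are empty
# fields, never zeros or sentinels.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "", check.names = FALSE)
}

#' Read a peptide intensity table (TSV)
#'
#' Expected schema: header `protein_id`, `peptide_id`, then one numeric
#' intensity column per sample; empty fields encode missing cells.
#' Validation failures report the offending line number (counting the
#' header as line 1).
#'
#' @param path TSV file path.
#' @return data.frame in the [center_peptides()] input schema.
#' @export
read_peptide_table <- function(path) {
  df <- read_tsv(path)
  if (!all(peptide_key_cols %in% names(df)))
    stop_input(sprintf("%s: missing required column(s) %s", path,
                       paste(setdiff(peptide_key_cols, names(df)), collapse = ", ")))
  dup <- which(duplicated(df[peptide_key_cols]))
  if (length(dup))
    stop_input(sprintf("%s: duplicate key (%s, %s) at line %d", path,
                       df$protein_id[dup[1]], df$peptide_id[dup[1]], dup[1] + 1L))
  samples <- setdiff(names(df), peptide_key_cols)
  for (s in samples) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(!is.na(df[[s]]) & is.na(v))
    if (length(bad))
      stop_input(sprintf("%s: non-numeric intensity in column %s at line %d",
                         path, s, bad[1] + 1L))
    neg <- which(v < 0)
    if (length(neg))
      stop_input(sprintf("%s: negative intensity in column %s at line %d",
                         path, s, neg[1] + 1L))
    df[[s]] <- v
  }
  df
}

#' Write a peptide intensity table (TSV)
#' @param table peptide table data.frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_peptide_table <- function(table, path) {
  check_peptide_table(table)
  write_tsv(table, path)
}

#' Read/write the sample-to-group mapping (TSV: sample_id, group)
#' @param path TSV file path.
#' @return data.frame `sample_id`, `group`.
#' @export
read_groups_table <- function(path) {
  df <- read_tsv(path)
  check_groups(df)
}

#' @rdname read_groups_table
#' @param groups groups data.frame.
#' @export
write_groups_table <- function(groups, path) {
  check_groups(groups)
  write_tsv(groups, path)
}

#' Read a survival cohort table (TSV: patient_id, time, event, marker)
#' @param path TSV file path.
#' @return `survival_cohort` data.frame.
#' @export
read_cohort_table <- function(path) {
  df <- read_tsv(path)
  need <- c("time", "event", "marker")
  if (!all(need %in% names(df)))
    stop_input(sprintf("%s: missing required column(s) %s", path,
                       paste(setdiff(need, names(df)), collapse = ", ")))
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  df$marker <- as.numeric(df$marker)
  check_cohort(df)
  class(df) <- c("survival_cohort", "data.frame")
  df
}
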