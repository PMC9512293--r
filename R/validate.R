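# Internal argument checks. All raise classed errors so callers/tests can
# distinguish configuration problems from data problems.

stop_config <- function(field, msg) {
  stop(structure(
    class = c("tmtscreen_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field '%s': %s", field, msg),
         call = sys.call(-1))
  ))
}

stop_input <- function(msg) {
  stop(structure(
    class = c("tmtscreen_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok)
    stop_config(field, sprintf("must be in %s%g, %g%s",
                               if (lo_open) "(" else "[", lo, hi,
                               if (hi_open) ")" else "]"))
  as.numeric(x)
}

check_positive <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (if (strict) x <= 0 else x < 0))
    stop_config(field, sprintf("must be a single %s number", if (strict) "positive" else "non-negative"))
  as.numeric(x)
}

# Sample group mapping used across modules: data.frame(sample_id, group).
check_groups <- function(groups, sample_ids = NULL, min_per_group = 1L) {
  if (!is.data.frame(groups) || !all(c("sample_id", "group") %in% names(groups)))
    stop_input("'groups' must be a data.frame with columns sample_id and group")
  if (anyDuplicated(groups$sample_id))
    stop_input("duplicate sample_id in groups table")
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, groups$sample_id)
    if (length(missing))
      stop_input(paste0("samples absent from groups table: ",
                        paste(missing, collapse = ", ")))
    groups <- groups[match(sample_ids, groups$sample_id), , drop = FALSE]
  }
  tab <- table(groups$group)
  if (length(tab) < 2L)
    stop_input("need at least two groups")
  if (any(tab < min_per_group))
    stop_input(sprintf("every group needs >= %d samples", min_per_group))
  groups
}
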