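# One-command pipeline: simulate -> quantify -> screen -> select -> validate,
# emitting every intermediate TSV plus a JSON run manifest.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    sim = list(n_proteins = 1000L, frac_up = 0.1, frac_down = 0.05,
               effect_fc = 2, peptides_per_protein_mean = 3, n_per_group = 3L,
               baseline_log_mean = 14, baseline_log_sd = 1.5,
               peptide_cv = 0.1, missing_rate = 0.05,
               total_spectra = 363519L, effective_rate = 0.229),
    quant = list(min_peptides = 1L),
    screen = list(fc_threshold = 1.3, alpha = 0.05, test = "t_log2",
                  adjust = "none"),
    select = list(target_size = 29L, step = 1L, mode = "intersection",
                  n_trees = 500L),
    schema_version = "1"
  )
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults and overrides them with the supplied
#' values; every seed and parameter is materialized after this call, and
#' unknown keys are rejected so typos cannot silently fall back to
#' defaults. Sections: `sim` (see [tmt_sim_config()]), `quant`
#' (`min_peptides`), `screen` (see [screen_config()]), `select`
#' (`target_size`, `step`, `mode`, `n_trees`), plus top-level `seed` and
#' `out_dir`.
#'
#' @param ... named overrides, either top-level (`seed = 7`) or nested
#'   lists (`screen = list(alpha = 0.01)`).
#' @param config_file optional path to a JSON config file applied before
#'   `...`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., config_file = NULL) {
  cfg <- default_pipeline_config()
  apply_over <- function(base, over, prefix = "") {
    unknown <- setdiff(names(over), names(base))
    if (length(unknown))
      stop_config(paste0(prefix, unknown[1]), "unknown configuration key")
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- apply_over(base[[nm]], over[[nm]], paste0(prefix, nm, "."))
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  if (!is.null(config_file))
    cfg <- apply_over(cfg, jsonlite::read_json(config_file, simplifyVector = TRUE))
  cfg <- apply_over(cfg, list(...))
  cfg$seed <- check_count(cfg$seed, "seed", min = -.Machine$integer.max)
  # validate sections eagerly so errors name the field before any work runs
  do.call(tmt_sim_config, c(cfg$sim, list(seed = cfg$seed)))
  do.call(screen_config, cfg$screen)
  check_count(cfg$quant$min_peptides, "quant.min_peptides")
  check_count(cfg$select$target_size, "select.target_size")
  structure(cfg, class = c("pipeline_config", "list"))
}

run_stage <- function(manifest, name, expr) {
  warns <- character(0)
  res <- withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop_input(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    }),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  list(result = res, warnings = warns)
}

#' Run the full synthetic discovery pipeline
#'
#' Executes simulate -> quantify -> screen -> select -> validate
#' (concordance) under one configuration, writing every intermediate table
#' as TSV into `config$out_dir` together with a JSON run manifest that
#' echoes parameters, row counts and stage warnings. Identical
#' configuration and seed give byte-identical outputs. Any stage failure
#' aborts with the stage name; tables already written are preserved.
#'
#' The validation panel is the consensus shortlist; when the consensus is
#' empty the union of the two method shortlists is used instead (recorded
#' in the manifest).
#'
#' @param config a [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(schema_version = config$schema_version,
                   config = unclass(config), stages = list())
  note <- function(name, files, rows, warns) {
    manifest$stages[[name]] <<- list(outputs = files, rows = rows,
                                     warnings = warns)
  }

  st <- run_stage(manifest, "simulate", {
    sim_cfg <- do.call(tmt_sim_config, c(config$sim, list(seed = config$seed)))
    simulate_tmt_experiment(sim_cfg)
  })
  sim <- st$result
  write_peptide_table(sim$peptides, out("peptides.tsv"))
  write_groups_table(sim$groups, out("groups.tsv"))
  write_tsv(sim$truth, out("ground_truth.tsv"))
  jsonlite::write_json(unclass(sim$config), out("sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  note("simulate", c("peptides.tsv", "groups.tsv", "ground_truth.tsv"),
       nrow(sim$peptides), st$warnings)

  st <- run_stage(manifest, "quant", {
    rollup_proteins(center_peptides(sim$peptides),
                    min_peptides = config$quant$min_peptides)
  })
  proteins <- st$result
  write_tsv(proteins, out("proteins.tsv"))
  note("quant", "proteins.tsv", nrow(proteins), st$warnings)

  st <- run_stage(manifest, "screen", {
    screen_proteins(proteins, sim$groups, do.call(screen_config, config$screen))
  })
  diff <- st$result
  write_tsv(diff, out("diff.tsv"))
  note("screen", "diff.tsv", nrow(diff), st$warnings)
  manifest$stages$screen$summary <- as.list(attr(diff, "summary"))

  st <- run_stage(manifest, "select", {
    up <- diff$protein_id[!is.na(diff$call) & diff$call == "up"]
    if (length(up) < config$select$target_size)
      stop(sprintf("target_size %d exceeds the %d up-regulated protein(s)",
                   config$select$target_size, length(up)))
    fm <- build_feature_matrix(proteins, sim$groups, features = up)
    select_features(fm$x, fm$y, target_size = config$select$target_size,
                    step = config$select$step, mode = config$select$mode,
                    seed = config$seed, n_trees = config$select$n_trees)
  })
  sel <- st$result
  sel_tab <- data.frame(feature = names(sel$margin$ranking),
                        rank_margin = unname(sel$margin$ranking),
                        rank_forest = unname(sel$forest$ranking[names(sel$margin$ranking)]),
                        consensus = names(sel$margin$ranking) %in% sel$consensus,
                        stringsAsFactors = FALSE)
  write_tsv(sel_tab, out("selection.tsv"))
  note("select", "selection.tsv", nrow(sel_tab), st$warnings)

  st <- run_stage(manifest, "concord", {
    panel <- sel$consensus
    if (!length(panel)) {
      warning("empty consensus: validating the union of both shortlists")
      panel <- union(sel$margin$selected, sel$forest$selected)
    }
    sim_cfg <- do.call(tmt_sim_config, c(config$sim, list(seed = config$seed)))
    prm <- simulate_prm_panel(sim$truth, panel, sim_cfg)
    prm_prot <- rollup_proteins(center_peptides(prm$peptides),
                                min_peptides = config$quant$min_peptides)
    val <- screen_proteins(prm_prot, prm$groups,
                           do.call(screen_config, config$screen))
    list(panel = panel, report = concordance(diff, val, panel), validation = val)
  })
  rep <- st$result$report
  write_tsv(rep$table, out("concordance.tsv"))
  write_tsv(st$result$validation, out("diff_prm.tsv"))
  note("concord", c("concordance.tsv", "diff_prm.tsv"), nrow(rep$table),
       st$warnings)
  manifest$stages$concord$sign_agreement_rate <- rep$sign_agreement_rate
  manifest$stages$concord$rank_correlation <- rep$rank_correlation

  # atomic manifest write: the file appears only after the run completed
  tmp <- out(".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  file.rename(tmp, out("manifest.json"))
  invisible(manifest)
}
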