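#' Configuration for the synthetic TMT discovery experiment
#'
#' Bundles and validates every knob of the two-group (control vs
#' NET-stimulated) peptide-level reporter-intensity simulator. Defaults
#' describe a 3-vs-3 design at discovery scale: log-normal protein
#' abundances, a fixed log-normal per-peptide ionization efficiency,
#' multiplicative log-normal measurement noise with a given coefficient of
#' variation, and completely-at-random missing cells.
#'
#' @param n_proteins number of simulated proteins.
#' @param frac_up,frac_down fractions of proteins spiked up/down;
#'   `frac_up + frac_down` must be <= 1. Spiked counts are rounded half-up.
#' @param effect_fc true fold change (> 1) applied to spiked proteins:
#'   treatment-group expected intensities are multiplied by `effect_fc`
#'   (up) or divided by it (down).
#' @param peptides_per_protein_mean mean peptides per protein; the count is
#'   `1 + Poisson(mean - 1)`, so every protein has at least one peptide.
#' @param n_per_group samples per group (>= 2; the study design is 3).
#' @param baseline_log_mean,baseline_log_sd natural-log location/spread of
#'   the protein abundance distribution.
#' @param peptide_cv coefficient of variation of the multiplicative
#'   measurement noise (0 = noise-free).
#' @param missing_rate probability that any intensity cell is missing (NA).
#' @param total_spectra,effective_rate total MS2 spectra collected and the
#'   fraction that are identified ("effective"); only used to report the
#'   spectra-utilization summary alongside the table.
#' @param seed integer seed; identical configs give bit-identical output.
#'
#' @return A validated list of class `tmt_sim_config`.
#' @seealso [simulate_tmt_experiment()]
#' @export
tmt_sim_config <- function(n_proteins = 1000L,
                           frac_up = 0.1,
                           frac_down = 0.05,
                           effect_fc = 2,
                           peptides_per_protein_mean = 3,
                           n_per_group = 3L,
                           baseline_log_mean = 14,
                           baseline_log_sd = 1.5,
                           peptide_cv = 0.1,
                           missing_rate = 0.05,
                           total_spectra = 363519L,
                           effective_rate = 0.229,
                           seed = 1L) {
  cfg <- list(
    n_proteins = check_count(n_proteins, "n_proteins"),
    frac_up = check_fraction(frac_up, "frac_up"),
    frac_down = check_fraction(frac_down, "frac_down"),
    effect_fc = check_positive(effect_fc, "effect_fc"),
    peptides_per_protein_mean = check_positive(peptides_per_protein_mean, "peptides_per_protein_mean"),
    n_per_group = check_count(n_per_group, "n_per_group", min = 2L),
    baseline_log_mean = check_positive(baseline_log_mean, "baseline_log_mean", strict = FALSE),
    baseline_log_sd = check_positive(baseline_log_sd, "baseline_log_sd", strict = FALSE),
    peptide_cv = check_positive(peptide_cv, "peptide_cv", strict = FALSE),
    missing_rate = check_fraction(missing_rate, "missing_rate", hi = 1, hi_open = TRUE),
    total_spectra = check_count(total_spectra, "total_spectra"),
    effective_rate = check_fraction(effective_rate, "effective_rate", lo = 0, lo_open = TRUE),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (cfg$frac_up + cfg$frac_down > 1)
    stop_config("frac_up", "frac_up + frac_down must be <= 1")
  if (cfg$effect_fc <= 1)
    stop_config("effect_fc", "must be > 1")
  if (cfg$peptides_per_protein_mean < 1)
    stop_config("peptides_per_protein_mean", "must be >= 1")
  structure(cfg, class = "tmt_sim_config")
}

# Half-up rounding; base round() is banker's rounding.
round_half_up <- function(x) floor(x + 0.5)

# Log-normal multiplier with unit mean and given CV, so expected intensities
# (and therefore true fold changes) are preserved under noise.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Core generator shared by discovery and PRM simulation. `truth` rows carry
# protein_id and true_fc (treatment/control ratio of expected intensities).
simulate_peptide_table <- function(truth, cfg, sample_prefixes = c("ctrl", "net")) {
  n_prot <- nrow(truth)
  n_pep <- 1L + rpois(n_prot, cfg$peptides_per_protein_mean - 1)
  protein <- rep(truth$protein_id, n_pep)
  peptide <- paste0(protein, "_pep", unlist(lapply(n_pep, seq_len), use.names = FALSE))
  n_rows <- length(peptide)

  baseline <- rlnorm(n_prot, cfg$baseline_log_mean, cfg$baseline_log_sd)
  ion_eff <- rlnorm(n_rows, 0, 0.5)           # fixed per-peptide ionization multiplier
  expected_ctrl <- rep(baseline, n_pep) * ion_eff
  fc_row <- rep(truth$true_fc, n_pep)

  n_samp <- 2L * cfg$n_per_group
  sample_ids <- c(paste0(sample_prefixes[1], "_", seq_len(cfg$n_per_group)),
                  paste0(sample_prefixes[2], "_", seq_len(cfg$n_per_group)))
  is_trt <- rep(c(FALSE, TRUE), each = cfg$n_per_group)

  mat <- matrix(NA_real_, n_rows, n_samp, dimnames = list(NULL, sample_ids))
  for (i in seq_len(n_samp)) {
    mu <- expected_ctrl * (if (is_trt[i]) fc_row else 1)
    mat[, i] <- mu * rlnorm_cv(n_rows, cfg$peptide_cv)
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(n_rows * n_samp) < cfg$missing_rate, n_rows, n_samp)
    mat[miss] <- NA_real_
  }

  peptides <- data.frame(protein_id = protein, peptide_id = peptide,
                         stringsAsFactors = FALSE)
  peptides <- cbind(peptides, as.data.frame(mat))
  groups <- data.frame(
    sample_id = sample_ids,
    group = rep(c("control", "treatment"), each = cfg$n_per_group),
    stringsAsFactors = FALSE
  )
  list(peptides = peptides, groups = groups)
}

#' Simulate a TMT discovery experiment with known ground truth
#'
#' Generates a peptide-level reporter-intensity table for a two-group
#' design with a protein-to-peptide hierarchy, plus a ground-truth ledger
#' stating each protein's true direction and fold change. The intensity
#' model is: protein baseline ~ log-normal; a fixed log-normal per-peptide
#' ionization multiplier; treatment samples of spiked proteins scaled by
#' `effect_fc` (up) or `1/effect_fc` (down); unit-mean multiplicative
#' log-normal noise with CV `peptide_cv`; cells knocked out completely at
#' random at `missing_rate` (encoded `NA`, never zero).
#'
#' @param config a [tmt_sim_config()].
#' @return A list of class `tmt_sim` with elements
#'   `peptides` (data.frame: `protein_id`, `peptide_id`, one intensity column
#'   per sample), `groups` (data.frame: `sample_id`, `group` with levels
#'   `control`/`treatment`), `truth` (data.frame: `protein_id`,
#'   `true_direction` in up/down/null, `true_fc`), `spectra`
#'   (`total`, `effective` counts), and the echoed `config`.
#' @examples
#' sim <- simulate_tmt_experiment(tmt_sim_config(n_proteins = 50, seed = 7))
#' table(sim$truth$true_direction)
#' @export
simulate_tmt_experiment <- function(config = tmt_sim_config()) {
  stopifnot(inherits(config, "tmt_sim_config"))
  set.seed(config$seed)

  n_up <- as.integer(round_half_up(config$frac_up * config$n_proteins))
  n_down <- as.integer(round_half_up(config$frac_down * config$n_proteins))
  if (n_up + n_down > config$n_proteins) # can occur from rounding both halves up
    n_down <- config$n_proteins - n_up
  protein_id <- sprintf("P%04d", seq_len(config$n_proteins))
  direction <- rep("null", config$n_proteins)
  spiked <- sample.int(config$n_proteins, n_up + n_down)
  direction[spiked[seq_len(n_up)]] <- "up"
  if (n_down > 0) direction[spiked[n_up + seq_len(n_down)]] <- "down"
  true_fc <- ifelse(direction == "up", config$effect_fc,
                    ifelse(direction == "down", 1 / config$effect_fc, 1))
  truth <- data.frame(protein_id = protein_id, true_direction = direction,
                      true_fc = true_fc, stringsAsFactors = FALSE)

  tab <- simulate_peptide_table(truth, config)
  structure(
    list(peptides = tab$peptides, groups = tab$groups, truth = truth,
         spectra = list(total = config$total_spectra,
                        effective = as.integer(round_half_up(
                          config$effective_rate * config$total_spectra))),
         config = config),
    class = "tmt_sim")
}

#' Simulate a targeted (PRM-style) validation table for a protein panel
#'
#' Re-measures a chosen panel of proteins with an independent noise draw but
#' the same true effects as the discovery ledger, emulating targeted
#' validation of a discovery shortlist. The RNG stream is derived from
#' `config$seed + 1` so the draw is independent of the discovery table for
#' the same configuration.
#'
#' @param ledger ground-truth data.frame from [simulate_tmt_experiment()]
#'   (`truth` element): columns `protein_id`, `true_direction`, `true_fc`.
#' @param panel character vector of protein ids to re-measure (non-empty,
#'   all present in the ledger).
#' @param config the [tmt_sim_config()] governing design and noise.
#' @return A list with `peptides` and `groups` as in
#'   [simulate_tmt_experiment()], restricted to the panel.
#' @export
simulate_prm_panel <- function(ledger, panel, config = tmt_sim_config()) {
  stopifnot(inherits(config, "tmt_sim_config"))
  if (!is.data.frame(ledger) || !all(c("protein_id", "true_fc") %in% names(ledger)))
    stop_input("'ledger' must have columns protein_id and true_fc")
  panel <- unique(as.character(panel))
  if (length(panel) == 0L)
    stop_input("empty panel: at least one protein id required")
  unknown <- setdiff(panel, ledger$protein_id)
  if (length(unknown))
    stop_input(paste0("panel proteins absent from ledger: ",
                      paste(unknown, collapse = ", ")))
  set.seed(config$seed + 1L)
  truth <- ledger[match(panel, ledger$protein_id), , drop = FALSE]
  simulate_peptide_table(truth, config)
}

#' Configuration for the synthetic survival cohort
#'
#' @param n_patients cohort size.
#' @param true_cutoff marker threshold at which the hazard changes.
#' @param hazard_low,hazard_high exponential event rates below/above the
#'   cutoff (must differ for a detectable cutpoint signal; equal rates give
#'   a null cohort and are allowed).
#' @param censor_rate per-patient probability of being censored before the
#'   event; implemented as an independent exponential censoring time whose
#'   rate is tied to the patient's own hazard, so the probability is exact.
#' @param marker_mean,marker_sd normal distribution of the continuous marker.
#' @param seed integer seed.
#' @return A validated list of class `surv_sim_config`.
#' @export
surv_sim_config <- function(n_patients = 400L,
                            true_cutoff = 1.0,
                            hazard_low = 0.05,
                            hazard_high = 0.20,
                            censor_rate = 0.2,
                            marker_mean = 1.0,
                            marker_sd = 0.5,
                            seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients", min = 2L),
    true_cutoff = check_positive(true_cutoff, "true_cutoff", strict = FALSE),
    hazard_low = check_positive(hazard_low, "hazard_low"),
    hazard_high = check_positive(hazard_high, "hazard_high"),
    censor_rate = check_fraction(censor_rate, "censor_rate", hi = 1, hi_open = TRUE),
    marker_mean = as.numeric(marker_mean),
    marker_sd = check_positive(marker_sd, "marker_sd"),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  structure(cfg, class = "surv_sim_config")
}

#' Simulate a right-censored survival cohort with a threshold marker effect
#'
#' Event times are exponential with rate `hazard_low` for patients whose
#' marker is below `true_cutoff` and `hazard_high` otherwise. Censoring is
#' independent exponential with a per-patient rate of
#' `hazard * censor_rate / (1 - censor_rate)`, which makes each patient's
#' probability of censoring exactly `censor_rate`.
#'
#' @param config a [surv_sim_config()].
#' @return A data.frame of class `survival_cohort` with columns
#'   `patient_id`, `time`, `event` (1 = death observed, 0 = censored) and
#'   `marker`.
#' @export
simulate_survival_cohort <- function(config = surv_sim_config()) {
  stopifnot(inherits(config, "surv_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  marker <- rnorm(n, config$marker_mean, config$marker_sd)
  hazard <- ifelse(marker < config$true_cutoff, config$hazard_low, config$hazard_high)
  t_event <- rexp(n, hazard)
  if (config$censor_rate > 0) {
    c_rate <- hazard * config$censor_rate / (1 - config$censor_rate)
    t_cens <- rexp(n, c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  out <- data.frame(
    patient_id = sprintf("PT%04d", seq_len(n)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    marker = marker,
    stringsAsFactors = FALSE
  )
  class(out) <- c("survival_cohort", "data.frame")
  out
}
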