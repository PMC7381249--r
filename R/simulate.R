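#' Microarray simulation configuration
#'
#' Defaults restate the structure of the motivating cohort: 2,656 probed
#' miRs of which 125 are expressed above the 80-AU filter, 7 smoker vs 6
#' non-smoker arrays (the 13 analyzed after QC), and 8 planted smoker
#' effects — six up-regulated miRs at log2 fold changes +0.6..+1.0
#' (miR-181a-5p, let-7c-5p, miR-92a-3p, let-7d-5p, let-7e-5p, miR-150-5p)
#' and two down-regulated (miR-3196, miR-4723-5p) at -0.6 and -1.0.
#' Background intensities are lognormal around each sample's noise mean;
#' expressed signals are lognormal with per-feature baselines and normal
#' log2 residuals (SD 0.3).
#'
#' @param n_features total probed features.
#' @param n_expressed features with true signal (baselines drawn above the
#'   expression filter).
#' @param n_smokers,n_nonsmokers group sizes (>= 2).
#' @param planted_effects named log2-fold-change vector (smoker - non-smoker);
#'   names become expressed feature ids.
#' @param noise_mean_range,noise_sd_range per-sample background noise ranges
#'   (AU), drawn uniformly.
#' @param expressed_mean_range baseline intensity range (AU) for unplanted
#'   expressed features; minimum must exceed 80.
#' @param planted_mean_range baseline range for planted features (kept well
#'   above the filter so a negative effect cannot push them out).
#' @param residual_sd_log2 residual SD on the log2 scale.
#' @param n_bad_samples extra low-quality arrays (signal collapsed into
#'   tight background, so they fail detection QC), appended after the good
#'   arrays.
#' @param bg_sdlog,bad_sdlog lognormal sdlog of background spots on good and
#'   bad arrays.
#' @return list of class `microarray_sim_config`.
#' @export
microarray_sim_config <- function(
    n_features = 2656, n_expressed = 125, n_smokers = 7, n_nonsmokers = 6,
    planted_effects = c(
      "miR-181a-5p" = 0.60, "let-7c-5p" = 0.68, "miR-92a-3p" = 0.76,
      "let-7d-5p" = 0.84, "let-7e-5p" = 0.92, "miR-150-5p" = 1.00,
      "miR-3196" = -0.60, "miR-4723-5p" = -1.00),
    noise_mean_range = c(8, 12), noise_sd_range = c(1, 2),
    expressed_mean_range = c(120, 4000), planted_mean_range = c(400, 2000),
    residual_sd_log2 = 0.3, n_bad_samples = 0,
    bg_sdlog = 0.35, bad_sdlog = 0.05) {
  if (n_smokers < 2 || n_nonsmokers < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (length(planted_effects) > n_expressed)
    stop("planted features must fit inside the expressed set", call. = FALSE)
  if (is.null(names(planted_effects)) || anyDuplicated(names(planted_effects)))
    stop("planted_effects must have unique names", call. = FALSE)
  if (n_expressed > n_features) stop("n_expressed > n_features", call. = FALSE)
  if (expressed_mean_range[1] <= 80)
    stop("expressed_mean_range minimum must exceed 80 AU", call. = FALSE)
  structure(as.list(environment()), class = "microarray_sim_config")
}

#' Simulate a smoker/non-smoker miRNA microarray cohort
#'
#' A pure function of (config, seed): identical inputs give byte-identical
#' outputs. Bad arrays (if any) have their entire signal collapsed into a
#' tight lognormal at the background level, so almost nothing exceeds the
#' noise mean + 2 SD detection threshold and they fall out at QC, emulating
#' the two arrays the original cohort lost.
#'
#' @param cfg a [microarray_sim_config()].
#' @param seed integer seed.
#' @return list: `raw` (`expr_matrix`, kind `raw_intensity`), `noise`
#'   ([noise_stats()]), `meta` ([sample_table()]), `truth` (list:
#'   `planted_effects`, `expressed`, `bad_samples`, `smokers`).
#' @export
simulate_microarray <- function(cfg = microarray_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "microarray_sim_config"))
  set.seed(as.integer(seed))
  n_good <- cfg$n_smokers + cfg$n_nonsmokers
  n_samp <- n_good + cfg$n_bad_samples
  ids <- c(sprintf("SM%02d", seq_len(cfg$n_smokers)),
           sprintf("NS%02d", seq_len(cfg$n_nonsmokers)),
           if (cfg$n_bad_samples) sprintf("BAD%02d", seq_len(cfg$n_bad_samples)))
  smoker <- c(rep(TRUE, cfg$n_smokers), rep(FALSE, cfg$n_nonsmokers),
              rep(c(TRUE, FALSE), length.out = cfg$n_bad_samples))
  planted <- names(cfg$planted_effects)
  n_other <- cfg$n_expressed - length(planted)
  expressed <- c(planted, sprintf("miR-sim-%04d", seq_len(n_other)))
  background <- sprintf("miR-bg-%04d", seq_len(cfg$n_features - cfg$n_expressed))
  features <- c(expressed, background)

  noise_mean <- stats::runif(n_samp, cfg$noise_mean_range[1], cfg$noise_mean_range[2])
  noise_sd <- stats::runif(n_samp, cfg$noise_sd_range[1], cfg$noise_sd_range[2])

  baseline <- c(
    2^stats::runif(length(planted), log2(cfg$planted_mean_range[1]),
                   log2(cfg$planted_mean_range[2])),
    2^stats::runif(n_other, log2(cfg$expressed_mean_range[1]),
                   log2(cfg$expressed_mean_range[2])))
  effect <- c(cfg$planted_effects, stats::setNames(rep(0, n_other), NULL))

  x <- matrix(NA_real_, cfg$n_features, n_samp, dimnames = list(features, ids))
  is_bad <- seq_len(n_samp) > n_good
  for (s in seq_len(n_samp)) {
    if (is_bad[s]) {
      # whole array collapsed to tight background: fails detection
      x[, s] <- stats::rlnorm(cfg$n_features, log(noise_mean[s]), cfg$bad_sdlog)
    } else {
      mu <- log2(baseline) + effect * smoker[s]
      signal <- 2^(mu + stats::rnorm(cfg$n_expressed, 0, cfg$residual_sd_log2))
      x[seq_len(cfg$n_expressed), s] <- noise_mean[s] + signal
      x[-seq_len(cfg$n_expressed), s] <-
        stats::rlnorm(cfg$n_features - cfg$n_expressed, log(noise_mean[s]), cfg$bg_sdlog)
    }
  }
  meta <- sample_table(data.frame(
    sample_id = ids,
    diagnosis = rep(c("RA", "HC"), length.out = n_samp),
    smoker = smoker,
    condition = "control",
    pooled_n = rep(c(1L, 2L, 3L), length.out = n_samp),
    stringsAsFactors = FALSE))
  list(raw = expr_matrix(x, "raw_intensity"),
       noise = noise_stats(data.frame(sample_id = ids, noise_mean = noise_mean,
                                      noise_sd = noise_sd, stringsAsFactors = FALSE)),
       meta = meta,
       truth = list(planted_effects = cfg$planted_effects,
                    expressed = expressed,
                    bad_samples = ids[is_bad],
                    smokers = ids[smoker & !is_bad]))
}

#' qPCR cohort simulation configuration
#'
#' Defaults restate the nicotine-stimulation experiment: 25 paired
#' control/nicotine CD8+ cultures planted as 8 high-, 11 intermediate- and
#' 6 low-ratio samples around the 1.5 / (1/1.5) cutoffs, on the default
#' FOXO-pathway [analyte_panel()]. `group_effect` is the multiplicative RQ
#' shift applied to the mRNA side (high group) or miR side (low group) —
#' with the default twofold shift a high sample's expected ratio is 4.
#' Under nicotine, high-ratio samples shift toward miR dominance and
#' low-ratio samples the opposite way; `nicotine_inversion_strength` in
#' (0, 1] scales that planted inversion (1 = full sign flip of the planted
#' log-ratio). CT noise reflects technical-replicate-averaged CT values
#' (about 0.15 CT per well over triplicates).
#'
#' @param panel an [analyte_panel()].
#' @param n_per_group named integer vector (high/intermediate/low), each >= 1.
#' @param group_effect multiplicative planted shift (> 1).
#' @param nicotine_inversion_strength in (0, 1].
#' @param ct_noise_sd SD (CT units) added independently to every measured CT.
#' @param reference_ct_mean mean CT of the reference targets.
#' @param base_dct_range uniform range of each analyte's baseline dCT
#'   (target minus reference).
#' @param smoker_prob_extreme,smoker_prob_intermediate smoker probability in
#'   the high/low vs intermediate groups.
#' @return list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(
    panel = analyte_panel(),
    n_per_group = c(high = 8, intermediate = 11, low = 6),
    group_effect = 2, nicotine_inversion_strength = 1,
    ct_noise_sd = 0.09, reference_ct_mean = 20,
    base_dct_range = c(2, 7),
    smoker_prob_extreme = 0.75, smoker_prob_intermediate = 0.2) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (!all(c("high", "intermediate", "low") %in% names(n_per_group)))
    stop("n_per_group needs named high/intermediate/low entries", call. = FALSE)
  if (any(n_per_group < 1)) stop("group sizes must be >= 1", call. = FALSE)
  if (nicotine_inversion_strength <= 0 || nicotine_inversion_strength > 1)
    stop("nicotine_inversion_strength must lie in (0, 1]", call. = FALSE)
  if (group_effect <= 1) stop("group_effect must be > 1", call. = FALSE)
  structure(as.list(environment()), class = "qpcr_sim_config")
}

#' Simulate paired control/nicotine qPCR CT tables
#'
#' The generator inverts the quantification model so that the dCT/RQ stage
#' is genuinely exercised: each measured CT is
#' `reference_ct_mean + base_dct(analyte) - planted_log2_quantity + noise`,
#' and reference CTs carry their own noise. Planted log2 quantities are
#' `+/- log2(group_effect)` on the side each group overexpresses, 0 for the
#' intermediate group; nicotine subtracts `2 * strength * log2(group_effect)`
#' from the dominant side and adds it to the other, flipping the planted
#' log-ratio at full strength.
#'
#' @param cfg a [qpcr_sim_config()].
#' @param seed integer seed.
#' @return list: `ct_control`, `ct_nicotine` (`expr_matrix`, kind `ct`,
#'   analytes + both references in rows), `meta` ([sample_table()], 2 rows
#'   per donor with `pair_id`), `truth` (list: `groups` named by control
#'   sample id, `log2_quantity_control`/`_nicotine`, `smokers`).
#' @export
simulate_qpcr_cohort <- function(cfg = qpcr_sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "qpcr_sim_config"))
  set.seed(as.integer(seed))
  groups <- rep(c("high", "intermediate", "low"),
                cfg$n_per_group[c("high", "intermediate", "low")])
  n <- length(groups)
  donors <- sprintf("P%02d", seq_len(n))
  panel <- cfg$panel
  analytes <- c(panel$mrna_ids, panel$mir_ids)
  is_mrna <- analytes %in% panel$mrna_ids
  ge <- log2(cfg$group_effect)

  # planted log2 quantities, analyte x donor
  lq_ctrl <- matrix(0, length(analytes), n, dimnames = list(analytes, donors))
  lq_ctrl[is_mrna, groups == "high"] <- ge
  lq_ctrl[!is_mrna, groups == "high"] <- -ge
  lq_ctrl[is_mrna, groups == "low"] <- -ge
  lq_ctrl[!is_mrna, groups == "low"] <- ge
  shift <- 2 * cfg$nicotine_inversion_strength * ge
  lq_nic <- lq_ctrl
  lq_nic[is_mrna, groups == "high"] <- lq_ctrl[is_mrna, groups == "high"] - shift
  lq_nic[!is_mrna, groups == "high"] <- lq_ctrl[!is_mrna, groups == "high"] + shift
  lq_nic[is_mrna, groups == "low"] <- lq_ctrl[is_mrna, groups == "low"] + shift
  lq_nic[!is_mrna, groups == "low"] <- lq_ctrl[!is_mrna, groups == "low"] - shift

  base_dct <- stats::runif(length(analytes), cfg$base_dct_range[1], cfg$base_dct_range[2])
  make_ct <- function(lq, suffix) {
    ct <- matrix(NA_real_, length(analytes) + 2, n,
                 dimnames = list(c(analytes, panel$mrna_reference, panel$mir_reference),
                                 paste0(donors, suffix)))
    ct[seq_along(analytes), ] <- cfg$reference_ct_mean + base_dct - lq +
      stats::rnorm(length(analytes) * n, 0, cfg$ct_noise_sd)
    ct[length(analytes) + 1, ] <- cfg$reference_ct_mean +
      stats::rnorm(n, 0, cfg$ct_noise_sd)
    ct[length(analytes) + 2, ] <- cfg$reference_ct_mean +
      stats::rnorm(n, 0, cfg$ct_noise_sd)
    expr_matrix(ct, "ct")
  }
  ct_control <- make_ct(lq_ctrl, "_ctrl")
  ct_nicotine <- make_ct(lq_nic, "_nic")

  p_smoke <- ifelse(groups == "intermediate", cfg$smoker_prob_intermediate,
                    cfg$smoker_prob_extreme)
  smoker <- stats::rbinom(n, 1, p_smoke) == 1
  meta <- sample_table(data.frame(
    sample_id = c(paste0(donors, "_ctrl"), paste0(donors, "_nic")),
    diagnosis = "RA",
    smoker = rep(smoker, 2),
    condition = rep(c("control", "nicotine"), each = n),
    pair_id = rep(donors, 2),
    stringsAsFactors = FALSE))
  list(ct_control = ct_control, ct_nicotine = ct_nicotine, meta = meta,
       truth = list(groups = stats::setNames(groups, paste0(donors, "_ctrl")),
                    log2_quantity_control = lq_ctrl,
                    log2_quantity_nicotine = lq_nic,
                    smokers = donors[smoker]))
}

#' Simulate phenotype-marker tables
#'
#' Generates one row per score marker with planted naive-memory samples drawn
#' `separation` log-units above the effector samples (residual SD
#' `marker_sd`), so planted samples clear the cohort median on at least
#' `min_points` markers with high probability. Smoker labels are drawn with
#' an enrichment in the naive-memory group whose defaults match the
#' published 2x2 (expected 9/13 vs 5/16); `smoker_mode = "expected"` forces
#' the counts to their rounded expectations deterministically.
#'
#' @param n_samples cohort size.
#' @param n_naive_memory planted naive-memory samples (< `n_samples`).
#' @param variant a [score_config()].
#' @param seed integer seed.
#' @param separation planted group separation (arbitrary log units).
#' @param marker_sd residual SD.
#' @param p_smoker_naive,p_smoker_effector smoker probability by planted
#'   class.
#' @param smoker_mode `"random"` draws, `"expected"` forces rounded counts.
#' @return list: `markers` (`expr_matrix`, kind `log2`), `meta`
#'   ([sample_table()]), `truth` (list `labels`, `smokers`).
#' @export
simulate_phenotype_markers <- function(n_samples = 29, n_naive_memory = 13,
                                       variant = score_config("A"), seed = 1,
                                       separation = 1.5, marker_sd = 0.5,
                                       p_smoker_naive = 9 / 13,
                                       p_smoker_effector = 5 / 16,
                                       smoker_mode = c("random", "expected")) {
  stopifnot(inherits(variant, "score_config"))
  smoker_mode <- match.arg(smoker_mode)
  if (n_naive_memory > n_samples)
    stop("n_naive_memory must be <= n_samples", call. = FALSE)
  if (n_naive_memory == n_samples)
    stop("planting every sample naive_memory leaves no effector cohort",
         call. = FALSE)
  set.seed(as.integer(seed))
  ids <- sprintf("D%02d", seq_len(n_samples))
  is_nm <- seq_len(n_samples) <= n_naive_memory
  mu <- ifelse(is_nm, separation / 2, -separation / 2)
  m <- length(variant$markers)
  vals <- matrix(stats::rnorm(m * n_samples, rep(mu, each = m), marker_sd),
                 m, n_samples, dimnames = list(variant$markers, ids))
  n_eff <- n_samples - n_naive_memory
  smoker <- if (smoker_mode == "expected") {
    c(seq_len(n_naive_memory) <= round(p_smoker_naive * n_naive_memory),
      seq_len(n_eff) <= round(p_smoker_effector * n_eff))
  } else {
    stats::rbinom(n_samples, 1, ifelse(is_nm, p_smoker_naive, p_smoker_effector)) == 1
  }
  meta <- sample_table(data.frame(
    sample_id = ids, diagnosis = "RA", smoker = smoker, condition = "control",
    stringsAsFactors = FALSE))
  list(markers = expr_matrix(vals, "log2"), meta = meta,
       truth = list(labels = stats::setNames(
         ifelse(is_nm, "naive_memory", "effector"), ids),
         smokers = ids[smoker]))
}
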