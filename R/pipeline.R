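#' Run the full analysis pipeline from one configuration
#'
#' Executes the stage sequence simulate/ingest -> normalize -> differential
#' expression -> cluster -> qPCR quantification -> phenotype score -> ratio
#' classification + paired shift, writing every intermediate as a plain-text
#' file under `out_dir` (stages communicate only via files, so any stage can
#' be rerun in isolation) and a JSON run manifest tying outputs to inputs,
#' parameters and the seed.
#'
#' The configuration is a YAML or JSON file (or an R list) with optional
#' blocks `microarray` (either `simulate: true` with generator overrides, or
#' `files:` with `intensities` and `noise` paths plus a `metadata` path),
#' `normalize`, `de`, `cluster`, `qpcr` (simulate or `files:` with
#' `ct_control`, `ct_nicotine`, `metadata`), `score`, `ratio`. A missing
#' `qpcr` block skips the qPCR branch (score/ratio included) and the
#' manifest marks it skipped; likewise for a missing `microarray` block.
#'
#' @param config list, or path to a YAML/JSON config file.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for all randomness in the run.
#' @return the run manifest (list of class `run_manifest`), invisibly
#'   written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = list(microarray = list(simulate = TRUE),
                                       qpcr = list(simulate = TRUE)),
                         out_dir = tempfile("foxomir_run_"), seed = 1) {
  config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "foxomir",
                   version = as.character(utils::packageVersion("foxomir")),
                   seed = as.integer(seed), config = config,
                   started = format(Sys.time(), tz = "UTC"), stages = list())
  outfile <- function(name) file.path(out_dir, name)
  record <- function(stage, status, files = character()) {
    manifest$stages[[stage]] <<- list(
      status = status,
      files = if (length(files))
        lapply(stats::setNames(files, basename(files)),
               function(f) unname(tools::md5sum(f))) else list())
  }

  on_fail <- function(stage, err) {
    record(stage, paste("failed:", conditionMessage(err)))
    manifest$finished <- format(Sys.time(), tz = "UTC")
    write_manifest(manifest, outfile("manifest.json"))
    stop("stage '", stage, "' failed: ", conditionMessage(err), call. = FALSE)
  }

  # ---- microarray branch -------------------------------------------------
  if (!is.null(config$microarray)) {
    ma <- config$microarray
    tryCatch({
      if (isTRUE(ma$simulate) || is.list(ma$simulate)) {
        ov <- if (is.list(ma$simulate)) ma$simulate else list()
        cfg <- do.call(microarray_sim_config, ov)
        sim <- simulate_microarray(cfg, seed = seed)
        raw <- sim$raw; noise <- sim$noise; meta <- sim$meta
        write_expression_table(raw, outfile("raw_intensities.tsv"))
        utils::write.table(noise, outfile("noise_stats.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(as.data.frame(meta), outfile("array_metadata.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(sim$truth, outfile("array_truth.json"),
                             auto_unbox = TRUE, digits = NA)
        record("simulate_microarray", "complete",
               outfile(c("raw_intensities.tsv", "noise_stats.tsv",
                         "array_metadata.tsv", "array_truth.json")))
      } else {
        raw <- read_expression_table(ma$files$intensities, "raw_intensity")
        noise <- read_noise_stats(ma$files$noise)
        meta <- read_sample_metadata(ma$files$metadata)
        record("simulate_microarray", "skipped (files supplied)")
      }
    }, error = function(e) on_fail("simulate_microarray", e))

    tryCatch({
      np <- config$normalize %||% list()
      norm <- normalize_microarray(
        raw, noise,
        k_sd = np$k_sd %||% 2, min_detected = np$min_detected,
        mean_threshold = np$mean_threshold %||% 80, top_n = np$top_n,
        offset = np$offset %||% 1, span = np$span %||% 0.7,
        iterations = np$iterations %||% 3)
      write_expression_table(norm$normalized, outfile("normalized.tsv"))
      jsonlite::write_json(list(
        detected_count_per_sample = as.list(norm$detection$detected_count_per_sample),
        excluded = norm$qc$excluded, min_detected = norm$qc$min_detected,
        kept_feature_count = length(norm$kept_features)),
        outfile("qc_report.json"), auto_unbox = TRUE, digits = NA)
      record("normalize", "complete", outfile(c("normalized.tsv", "qc_report.json")))
    }, error = function(e) on_fail("normalize", e))

    tryCatch({
      dep <- config$de %||% list()
      design <- design_from_metadata(meta, contrast = dep$contrast %||% "smoker",
                                     samples = colnames(norm$normalized))
      fits <- fit_feature_models(norm$normalized, design)
      mod <- ebayes_moderate(fits)
      sel <- select_differential(mod, lfc_cut = dep$lfc %||% 0.5,
                                 p_cut = dep$p %||% 0.05,
                                 use_adjusted = isTRUE(dep$use_adjusted))
      utils::write.table(sel$results, outfile("de_results.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      record("de", "complete", outfile("de_results.tsv"))
    }, error = function(e) on_fail("de", e))

    tryCatch({
      clp <- config$cluster %||% list()
      de_ids <- c(sel$up$feature_id, sel$down$feature_id)
      use_feats <- if (isTRUE(clp$all_features) || length(de_ids) < 2)
        rownames(norm$normalized) else de_ids
      sub <- norm$normalized[use_feats, , drop = FALSE]
      dmat <- spearman_distance_matrix(sub, axis = "samples",
                                       center_features =
                                         !isFALSE(clp$center_features))
      dend <- ward_cluster(dmat, k = clp$k %||% 2)
      sep <- cluster_separation_check(dend, meta, attribute = clp$attribute %||% "smoker")
      dendrogram_newick(dend, outfile("dendrogram.nwk"))
      utils::write.table(data.frame(sample_id = names(dend$clusters),
                                    cluster = dend$clusters),
                         outfile("cluster_assignments.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(purity = sep$purity, pure = sep$pure,
                                features_used = use_feats),
                           outfile("cluster_report.json"),
                           auto_unbox = TRUE, digits = NA)
      record("cluster", "complete",
             outfile(c("dendrogram.nwk", "cluster_assignments.tsv",
                       "cluster_report.json")))
    }, error = function(e) on_fail("cluster", e))
  } else {
    record("simulate_microarray", "skipped")
    record("normalize", "skipped")
    record("de", "skipped")
    record("cluster", "skipped")
  }

  # ---- qPCR branch -------------------------------------------------------
  if (!is.null(config$qpcr)) {
    qp <- config$qpcr
    panel <- do.call(analyte_panel, qp$panel %||% list())
    tryCatch({
      if (isTRUE(qp$simulate) || is.list(qp$simulate)) {
        ov <- if (is.list(qp$simulate)) qp$simulate else list()
        ov$panel <- panel
        qcfg <- do.call(qpcr_sim_config, ov)
        qsim <- simulate_qpcr_cohort(qcfg, seed = seed)
        ctc <- qsim$ct_control; ctn <- qsim$ct_nicotine; qmeta <- qsim$meta
        write_expression_table(ctc, outfile("ct_control.tsv"))
        write_expression_table(ctn, outfile("ct_nicotine.tsv"))
        utils::write.table(as.data.frame(qmeta), outfile("qpcr_metadata.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(groups = as.list(qsim$truth$groups),
                                  smokers = qsim$truth$smokers),
                             outfile("qpcr_truth.json"), auto_unbox = TRUE,
                             digits = NA)
        record("simulate_qpcr", "complete",
               outfile(c("ct_control.tsv", "ct_nicotine.tsv",
                         "qpcr_metadata.tsv", "qpcr_truth.json")))
      } else {
        ctc <- read_expression_table(qp$files$ct_control, "ct")
        ctn <- read_expression_table(qp$files$ct_nicotine, "ct")
        qmeta <- read_sample_metadata(qp$files$metadata)
        record("simulate_qpcr", "skipped (files supplied)")
      }
    }, error = function(e) on_fail("simulate_qpcr", e))

    tryCatch({
      ctrl_ids <- colnames(ctc)
      q_ctrl <- panel_dct_quantities(ctc, panel)
      q_nic <- panel_dct_quantities(ctn, panel)
      rq_ctrl <- relative_quantity_to_median(q_ctrl, sample_scope = ctrl_ids)
      # nicotine RQ on the control-culture medians, so conditions share a scale
      med <- attr(rq_ctrl, "scope_medians")
      rq_nic <- expr_matrix(unclass(q_nic)[names(med), , drop = FALSE] / med, "rq")
      attr(rq_nic, "normalization_scope") <- "vs_cohort_median"
      write_expression_table(rq_ctrl, outfile("rq_control.tsv"), id_column = "analyte")
      write_expression_table(rq_nic, outfile("rq_nicotine.tsv"), id_column = "analyte")
      record("qpcr", "complete", outfile(c("rq_control.tsv", "rq_nicotine.tsv")))
    }, error = function(e) on_fail("qpcr", e))

    tryCatch({
      scp <- config$score %||% list()
      sc <- score_config(scp$variant %||% "B",
                         markers = scp$markers, min_points = scp$min_points)
      calls <- score_naive_memory(rq_ctrl[sc$markers, , drop = FALSE], sc)
      assoc <- phenotype_smoking_association(calls, qmeta)
      utils::write.table(calls, outfile("phenotype_calls.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(table = unclass(assoc$table),
                                odds_ratio = assoc$odds_ratio,
                                fisher_p = assoc$test$p_two_sided),
                           outfile("phenotype_association.json"),
                           auto_unbox = TRUE, digits = NA)
      record("score", "complete",
             outfile(c("phenotype_calls.tsv", "phenotype_association.json")))
    }, error = function(e) on_fail("score", e))

    tryCatch({
      rp <- config$ratio %||% list()
      ctrl <- classify_ratio(mrna_mir_ratio(rq_ctrl, panel),
                             hi_cut = rp$hi %||% 1.5, lo_cut = rp$lo %||% (2 / 3))
      nic <- classify_ratio(mrna_mir_ratio(rq_nic, panel),
                            hi_cut = rp$hi %||% 1.5, lo_cut = rp$lo %||% (2 / 3))
      shift <- nicotine_response_shift(ctrl, nic, qmeta)
      utils::write.table(ctrl, outfile("ratio_control.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(group_sizes = as.list(attr(ctrl, "group_sizes")),
                                shift = shift),
                           outfile("ratio_report.json"), auto_unbox = TRUE,
                           digits = NA)
      record("ratio", "complete",
             outfile(c("ratio_control.tsv", "ratio_report.json")))
    }, error = function(e) on_fail("ratio", e))
  } else {
    record("simulate_qpcr", "skipped")
    record("qpcr", "skipped")
    record("score", "skipped")
    record("ratio", "skipped")
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  write_manifest(manifest, outfile("manifest.json"))
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path", call. = FALSE)
  known <- c("microarray", "normalize", "de", "cluster", "qpcr", "score", "ratio")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  config
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}
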