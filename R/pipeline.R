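#' Map promoter-scan offsets back to genomic coordinates
#'
#' [scan_pwm()] reports matches in promoter-local coordinates. Given the
#' gene model the promoter was extracted from, this returns the genomic
#' 0-based half-open interval of each match. For a `-` strand gene the
#' promoter reads on the reverse strand, so offsets are mirrored.
#'
#' @param matches output of [scan_pwm()] on one promoter.
#' @param model one-row slice of a [gene_models()] data.frame.
#' @param width motif width.
#' @param upstream_len promoter length used at extraction.
#' @param anchor `"tls"` or `"tss"` as used at extraction.
#' @return data.frame `chrom`, `start`, `end`, `strand` (genomic strand of
#'   the match), one row per match.
#' @export
promoter_match_coords <- function(matches, model, width,
                                  upstream_len = 700L, anchor = "tls") {
  a <- model[[anchor]]
  L <- as.integer(upstream_len)
  if (model$strand == "+") {
    start <- a - L + matches$offset
    strand <- matches$strand
  } else {
    start <- a + L - matches$offset - width
    strand <- ifelse(matches$strand == "+", "-", "+")
  }
  data.frame(chrom = model$chrom, start = start, end = start + width,
             strand = strand, gene_id = model$gene_id,
             stringsAsFactors = FALSE)
}

#' Predict X-box intervals and genes by scanning battery promoters
#'
#' Extracts the battery genes' promoters, scans them with the PWM and
#' returns both the genomic motif intervals and the set of genes with at
#' least one match.
#'
#' @param world output of [synth_genome_and_genes()] or a list with
#'   `genome`, `models`, `battery`.
#' @param pwm a [build_pwm()] object.
#' @param frac_of_max score threshold as fraction of the PWM maximum.
#' @param upstream_len,anchor promoter definition.
#' @return list `intervals` (data.frame chrom/start/end/strand/gene_id),
#'   `genes` (character vector).
#' @export
predict_xboxes <- function(world, pwm, frac_of_max = 0.8,
                           upstream_len = 700L, anchor = "tls") {
  models <- world$models
  bm <- models[models$gene_id %in% world$battery$gene_id, , drop = FALSE]
  proms <- extract_promoters(world$genome, bm, upstream_len, anchor)
  rows <- list()
  for (i in seq_len(nrow(bm))) {
    hits <- scan_pwm(pwm, as.character(proms[[i]]),
                     frac_of_max = frac_of_max)
    if (!nrow(hits)) next
    rows[[length(rows) + 1L]] <-
      promoter_match_coords(hits, bm[i, ], pwm$width, upstream_len, anchor)
  }
  intervals <- if (length(rows)) do.call(rbind, rows)
               else data.frame(chrom = character(0), start = integer(0),
                               end = integer(0), strand = character(0),
                               gene_id = character(0))
  list(intervals = intervals, genes = unique(intervals$gene_id))
}

PIPELINE_STAGES <- c("simulate", "motifs", "peaks", "positional",
                     "sc", "synergy")

validate_run_config <- function(config) {
  allowed <- c("seed", "out_dir", "stages", "synth", "scan", "screen",
               "synergy")
  bad <- setdiff(names(config), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config$stages <- stages
  config$seed <- as.integer(config$seed %||% 1L)
  config$scan <- utils::modifyList(list(frac_of_max = 0.8), config$scan %||%
                                     list())
  config$screen <- utils::modifyList(list(min_fold = 5, fdr = 0.001),
                                     config$screen %||% list())
  config$synergy <- utils::modifyList(list(alpha = 0.05),
                                      config$synergy %||% list())
  config
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Executes, in dependency order: synthetic-data generation; promoter
#' motif prediction (X-box scan plus k-mer over-representation); peak
#' annotation, battery binding and TF prioritization; central enrichment,
#' X-box-to-peak distances and dual-signature classification; the
#' single-cell enrichment screen and correlation profile; and the
#' multiplicative synergy test. Inputs and a versioned JSON report (tool
#' version, seed, input checksums, per-stage results) are written under
#' `out_dir`.
#'
#' @param config a YAML file path or a named list; recognized keys: `seed`,
#'   `stages`, `synth` (overrides for [synth_config()]), `scan`, `screen`,
#'   `synergy`. Unknown keys are rejected.
#' @param out_dir output directory (created if needed).
#' @return the report, invisibly (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("ciliareg_")) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(synth_config, c(list(seed = config$seed),
                                 config$synth %||% list()))
  report <- list(
    tool = "ciliareg",
    version = as.character(utils::packageVersion("ciliareg")),
    seed = config$seed,
    stages = config$stages,
    config = config[setdiff(names(config), "stages")])
  files <- character(0)

  needs_world <- any(c("simulate", "motifs", "peaks", "positional") %in%
                       config$stages)
  world <- if (needs_world) synth_genome_and_genes(cfg)
  if ("simulate" %in% config$stages) {
    write_fasta(world$genome, file.path(out_dir, "genome.fa"))
    utils::write.table(as.data.frame(world$models),
                       file.path(out_dir, "gene_models.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_battery(world$battery, file.path(out_dir, "battery.tsv"))
    jsonlite::write_json(world$truth,
                         file.path(out_dir, "motif_truth.json"))
    files <- c(files, "genome.fa", "gene_models.tsv", "battery.tsv",
               "motif_truth.json")
    report$simulate <- list(n_genes = nrow(world$models),
                            battery = as.list(category_counts(world$battery)),
                            n_planted = nrow(world$truth))
  }

  pwm <- cfg$motifs$pwm
  xb <- if (any(c("motifs", "positional") %in% config$stages))
    predict_xboxes(world, pwm, config$scan$frac_of_max)
  if ("motifs" %in% config$stages) {
    proms <- extract_promoters(
      world$genome,
      world$models[world$models$gene_id %in% world$battery$gene_id, ],
      cfg$genes$promoter_len)
    km <- kmer_enrichment(as.character(proms), k = 6L)
    report$motifs <- list(
      n_xbox_intervals = nrow(xb$intervals),
      n_xbox_genes = length(xb$genes),
      top_kmer = km$kmer[1], top_kmer_q = km$q_value[1])
  }

  needs_peaks <- any(c("peaks", "positional") %in% config$stages)
  pk <- if (needs_peaks) synth_peaksets(cfg, world)
  reg <- if (needs_peaks) pk$truth$regulator
  ann_reg <- NULL
  if (needs_peaks) {
    summaries <- do.call(rbind, lapply(names(pk$peaksets), function(tf) {
      ann <- annotate_peaks(pk$peaksets[[tf]], world$models,
                            cfg$peaks$tss_window)
      if (tf == reg) ann_reg <<- ann
      battery_binding(ann, world$battery, tf_name = tf,
                      features = "promoter")
    }))
    if ("peaks" %in% config$stages) {
      pri <- prioritize_tfs(summaries)
      write_narrowpeak(pk$peaksets[[reg]],
                       file.path(out_dir, "regulator_peaks.narrowPeak"))
      files <- c(files, "regulator_peaks.narrowPeak")
      reg_row <- summaries[summaries$tf_name == reg, ]
      report$peaks <- list(
        n_tfs = nrow(summaries),
        regulator = reg,
        regulator_battery_fraction = reg_row$battery_fraction,
        regulator_core_fraction = reg_row$core_fraction,
        regulator_subtype_fraction = reg_row$subtype_fraction,
        top_ranked = pri$ranking$tf_name[1],
        flagged = pri$outliers$tf_name[pri$outliers$flag],
        feature_distribution = as.list(feature_distribution(ann_reg)))
    }
  }

  if ("positional" %in% config$stages) {
    win <- peak_windows(pk$peaksets[[reg]], world$genome)
    ce <- central_enrichment(pwm, win$sequences,
                             frac_of_max = config$scan$frac_of_max)
    xd <- xbox_peak_distance(xb$intervals, pk$peaksets[[reg]])
    bound_genes <- unique(ann_reg$gene_id[!is.na(ann_reg$gene_id)])
    sig <- classify_signatures(world$battery, xb$genes, bound_genes)
    report$positional <- list(
      match_fraction = ce$match_fraction,
      central_p = ce$central_p,
      xbox_fraction_within = xd$fraction_within,
      signature_counts = as.list(sig$counts))
  }

  if ("sc" %in% config$stages) {
    scd <- synth_sc_matrix(cfg)
    hits <- enrichment_screen(scd$matrix, scd$truth$target_class,
                              scd$gene_sets$candidates,
                              min_fold = config$screen$min_fold,
                              fdr = config$screen$fdr)
    prof <- expression_correlation(scd$matrix, scd$truth$regulator,
                                   scd$gene_sets[c("core", "ubiquitous",
                                                   "panneuronal")],
                                   cell_subset = scd$truth$target_class)
    report$sc <- list(
      n_hits = sum(hits$passes),
      hit_genes = hits$gene_id[hits$passes],
      regulator_recovered = scd$truth$regulator %in%
        hits$gene_id[hits$passes],
      core_median_R = prof$summary$median[prof$summary$set == "core"])
  }

  if ("synergy" %in% config$stages) {
    rep_data <- synth_reporter_counts(cfg)
    fc <- fold_changes(rep_data$groups, cfg$reporter$reference)
    st <- fc$stats
    em <- expected_multiplicative(st[st$genotype == "double_a", ],
                                  st[st$genotype == "double_b", ])
    sy <- synergy_test(rep_data$groups$triple,
                       rep_data$groups[[cfg$reporter$reference]],
                       em$E, em$sd_expected,
                       alpha = config$synergy$alpha)
    report$synergy <- list(
      expected_fc = em$E, sd_expected = em$sd_expected,
      observed_mean_fc = sy$observed_mean_fc,
      p_value = sy$p_value, verdict = sy$verdict)
  }

  if (length(files))
    report$input_checksums <- as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
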