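# End-to-end orchestration: simulate -> trim -> detect -> seed -> predict ->
# enrich, with plain-file stage outputs, per-stage read accounting, and a
# single seed governing every stochastic stage.

#' Pipeline configuration
#'
#' @param out_dir run directory (created; stage outputs are written under
#'   it in documented plain-text formats).
#' @param rng_seed single integer seed governing reference generation,
#'   cohort simulation, and synthetic downstream resources.
#' @param n_host,n_plant reference catalog sizes.
#' @param sim a [sim_config()]; its `rng_seed`, `adapter` and ubiquitous /
#'   sporadic defaults are filled in from this configuration when left at
#'   their defaults.
#' @param trim a [trim_config()].
#' @param detect a [detect_config()].
#' @param predict a [predict_config()].
#' @param enrich_mode "fisher" or "ease".
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, rng_seed = 1L, n_host = 30L,
                            n_plant = 10L, sim = NULL, trim = NULL,
                            detect = NULL, predict = NULL,
                            enrich_mode = c("fisher", "ease")) {
  enrich_mode <- match.arg(enrich_mode)
  if (is.null(sim)) {
    sim <- sim_config(n_samples = 5L, reads_per_sample = 10000L,
                      ubiquitous_mean_copies = 300,
                      rng_seed = rng_seed)
  }
  sim$rng_seed <- as.integer(rng_seed)
  if (is.null(trim)) trim <- trim_config(adapter = sim$adapter)
  if (is.null(detect)) detect <- detect_config()
  if (is.null(predict)) predict <- predict_config()
  structure(list(out_dir = out_dir, rng_seed = as.integer(rng_seed),
                 n_host = as.integer(n_host), n_plant = as.integer(n_plant),
                 sim = sim, trim = trim, detect = detect, predict = predict,
                 enrich_mode = enrich_mode),
            class = "pipeline_config")
}

run_stage <- function(name, log_path, expr) {
  cat(sprintf("[stage %s] start\n", name), file = log_path, append = TRUE)
  tryCatch(expr, error = function(e) {
    stop_data("stage ", name, " failed: ", conditionMessage(e))
  })
}

#' Run the full detection and target-inference pipeline
#'
#' Executes every stage on a synthetic cohort, writing plain-file outputs
#' under `cfg$out_dir`: reference FASTAs (`refs/`), per-sample FASTQ
#' (`fastq/`), trimmed FASTQ and trimming report (`trimmed/`), per-sample
#' count TSVs and cohort summary (`counts/`), seed report and matches
#' (`seed/`), transferred candidates and duplex predictions (`targets/`),
#' enrichment table (`enrich/`), and a per-miRNA summary report plus
#' per-stage read accounting (`report/`). Deterministic given
#' `cfg$rng_seed`; read counts are conserved at every stage boundary and
#' asserted in the accounting table.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with the key tables (`summary`, `accounting`,
#'   `cohort`, `matches`, `predictions`, `enrichment`) and `dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dirs <- file.path(cfg$out_dir, c("refs", "fastq", "trimmed", "counts",
                                   "seed", "targets", "enrich", "report"))
  for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  cat("xenomir pipeline, seed ", cfg$rng_seed, "\n", sep = "",
      file = log_path)

  refs <- run_stage("reference", log_path, {
    r <- make_reference_set(cfg$n_host, cfg$n_plant, cfg$rng_seed,
                            adapter = cfg$sim$adapter)
    write_seq_fasta(r$host$id, r$host$mature,
                    file.path(cfg$out_dir, "refs", "host_mature.fa"),
                    rna = TRUE)
    write_seq_fasta(r$plant$id, r$plant$mature,
                    file.path(cfg$out_dir, "refs", "plant_mature.fa"),
                    rna = TRUE)
    write_seq_fasta(r$plant$id, r$plant$precursor,
                    file.path(cfg$out_dir, "refs", "plant_precursor.fa"),
                    rna = TRUE)
    write_seq_fasta(r$decoys$id, r$decoys$sequence,
                    file.path(cfg$out_dir, "refs", "host_decoys.fa"))
    r
  })

  sim <- cfg$sim
  if (length(sim$ubiquitous_xeno_ids) == 0 && is.null(sim$sporadic_xeno_spec)) {
    sim$ubiquitous_xeno_ids <- refs$plant$id[1]
    if (nrow(refs$plant) >= 3) {
      sim$sporadic_xeno_spec <- data.frame(
        id = refs$plant$id[2:3], prevalence = c(0.3, 0.1),
        max_copies = c(4L, 4L), stringsAsFactors = FALSE)
    }
  }

  cohort <- run_stage("simulate", log_path,
                      make_cohort(refs, sim, file.path(cfg$out_dir, "fastq"),
                                  keep_read_truth = FALSE))

  trim_reports <- run_stage("trim", log_path, {
    reps <- lapply(cohort$fastq, function(fq) {
      preprocess_fastq(fq, file.path(cfg$out_dir, "trimmed", basename(fq)),
                       cfg$trim)
    })
    rep_df <- do.call(rbind, reps)
    write_tsv_file(rep_df, file.path(cfg$out_dir, "trimmed",
                                     "trim_report.tsv"))
    rep_df
  })

  contaminated <- adapter_contamination_check(
    data.frame(id = refs$plant$id, mature = refs$plant$mature),
    cfg$sim$adapter)
  plant_ok <- refs$plant[!contaminated[refs$plant$id], , drop = FALSE]

  profiles <- run_stage("detect", log_path, {
    plant_index <- build_index(plant_ok$id, plant_ok$mature, cfg$detect$k)
    host_index <- build_index(
      c(refs$host$id, refs$decoys$id),
      c(refs$host$mature, refs$decoys$sequence), cfg$detect$k,
      kingdom = c(rep("host", nrow(refs$host)),
                  rep("decoy", nrow(refs$decoys))))
    ps <- list()
    for (i in seq_along(cohort$fastq)) {
      sid <- sub("\\.fastq$", "", basename(cohort$fastq[i]))
      reads <- read_fastq(file.path(cfg$out_dir, "trimmed",
                                    basename(cohort$fastq[i])))
      p <- quantify(reads$seq, plant_index, host_index, cfg$detect, sid)
      write_count_profile(p, file.path(cfg$out_dir, "counts",
                                       paste0(sid, "_counts.tsv")))
      ps[[sid]] <- p
    }
    ps
  })
  cohort_tab <- cohort_summary(profiles, cfg$detect)
  write_tsv_file(cohort_tab, file.path(cfg$out_dir, "counts",
                                       "cohort_summary.tsv"))

  resources <- run_stage("resources", log_path, {
    res <- make_target_resources(plant_ok, derive_seed(cfg$rng_seed, 1001L))
    write_seq_fasta(res$human$id, res$human$mature,
                    file.path(cfg$out_dir, "refs", "synthetic_human_mature.fa"),
                    rna = TRUE)
    write_tsv_file(res$interactions,
                   file.path(cfg$out_dir, "refs",
                             "synthetic_interactions.tsv"))
    write_tsv_file(res$genes, file.path(cfg$out_dir, "refs",
                                        "synthetic_gene_regions.tsv"))
    write_gmt(res$term_sets, file.path(cfg$out_dir, "refs",
                                       "synthetic_terms.gmt"))
    res
  })

  seed_out <- run_stage("seed", log_path, {
    st <- seed_table(plant_ok)
    matches <- match_human(plant_ok, resources$human)
    matched <- vapply(st$id, function(pid)
      paste(sort(matches$human_id[matches$plant_id == pid]), collapse = ","),
      character(1), USE.NAMES = FALSE)
    st$matched_human_ids <- matched
    write_tsv_file(st, file.path(cfg$out_dir, "seed", "seed_report.tsv"))
    write_tsv_file(matches, file.path(cfg$out_dir, "seed", "matches.tsv"))
    list(table = st, matches = matches)
  })

  transfers <- run_stage("transfer", log_path, {
    tr <- transfer_targets(seed_out$matches, resources$interactions)
    write_tsv_file(tr, file.path(cfg$out_dir, "targets", "candidates.tsv"))
    tr
  })

  predictions <- run_stage("predict", log_path, {
    preds <- list()
    for (pid in unique(transfers$plant_id)) {
      genes <- transfers$gene_symbol[transfers$plant_id == pid]
      mat <- plant_ok$mature[plant_ok$id == pid]
      gsub <- resources$genes[resources$genes$gene_id %in% genes, ,
                              drop = FALSE]
      if (nrow(gsub) == 0) next
      res <- scan_genes(data.frame(id = pid, mature = mat,
                                   stringsAsFactors = FALSE),
                        gsub, cfg$predict)
      if (nrow(res) > 0) preds[[pid]] <- res
    }
    pred_df <- if (length(preds) > 0) do.call(rbind, preds) else
      scan_genes(data.frame(id = character(0), mature = character(0)),
                 resources$genes[0, ], cfg$predict)
    rownames(pred_df) <- NULL
    write_tsv_file(pred_df, file.path(cfg$out_dir, "targets",
                                      "predictions.tsv"))
    pred_df
  })

  enrichment <- run_stage("enrich", log_path, {
    rows <- list()
    for (pid in unique(predictions$mirna_id)) {
      q <- unique(predictions$gene_id[predictions$mirna_id == pid])
      e <- enrich_targets(q, resources$term_sets, mode = cfg$enrich_mode)
      if (nrow(e) > 0) rows[[pid]] <- cbind(mirna_id = pid, e)
    }
    e_df <- if (length(rows) > 0) do.call(rbind, rows) else
      cbind(mirna_id = character(0),
            enrich_targets(character(0),
                           resources$term_sets)[0, ])
    rownames(e_df) <- NULL
    write_tsv_file(e_df, file.path(cfg$out_dir, "enrich", "enrichment.tsv"))
    e_df
  })

  # Per-stage read accounting; conservation asserted at every boundary.
  accounting <- run_stage("report", log_path, {
    acc <- data.frame(
      sample_id = sub("\\.fastq$", "", basename(cohort$fastq)),
      reads_in = trim_reports$reads_in,
      rejected = trim_reports$rejected,
      kept = trim_reports$kept,
      dropped_too_short = trim_reports$dropped_too_short,
      dropped_too_long = trim_reports$dropped_too_long,
      dropped_low_quality = trim_reports$dropped_low_quality,
      assigned_host = vapply(profiles, function(p)
        as.integer(p$totals["host"]), integer(1)),
      assigned_plant = vapply(profiles, function(p)
        as.integer(p$totals["plant"]), integer(1)),
      unassigned = vapply(profiles, function(p)
        as.integer(p$totals["unassigned"]), integer(1)),
      stringsAsFactors = FALSE)
    conserved_trim <- acc$reads_in ==
      acc$rejected + acc$kept + acc$dropped_too_short +
      acc$dropped_too_long + acc$dropped_low_quality
    conserved_detect <- acc$kept ==
      acc$assigned_host + acc$assigned_plant + acc$unassigned
    if (!all(conserved_trim & conserved_detect))
      stop_data("read-count conservation violated in accounting")
    acc$conserved <- conserved_trim & conserved_detect
    write_tsv_file(acc, file.path(cfg$out_dir, "report", "accounting.tsv"))
    acc
  })

  summary_tab <- run_stage("summary", log_path, {
    rows <- lapply(seq_len(nrow(plant_ok)), function(i) {
      pid <- plant_ok$id[i]
      in_cohort <- cohort_tab[cohort_tab$mirna_id == pid, , drop = FALSE]
      data.frame(
        mirna_id = pid,
        n_samples_present = if (nrow(in_cohort)) in_cohort$n_samples_present
                            else 0L,
        max_count = if (nrow(in_cohort)) in_cohort$max_count else 0L,
        seed_matched_human = paste(
          sort(seed_out$matches$human_id[seed_out$matches$plant_id == pid]),
          collapse = ","),
        n_candidate_genes = sum(transfers$plant_id == pid),
        n_predicted_targets =
          length(unique(predictions$gene_id[predictions$mirna_id == pid])),
        top_enriched_term = {
          e <- enrichment[enrichment$mirna_id == pid, , drop = FALSE]
          if (nrow(e)) e$term[1] else ""
        },
        stringsAsFactors = FALSE)
    })
    s <- do.call(rbind, rows)
    write_tsv_file(s, file.path(cfg$out_dir, "report", "summary.tsv"))
    s
  })

  cat("[done]\n", file = log_path, append = TRUE)
  invisible(list(summary = summary_tab, accounting = accounting,
                 cohort = cohort_tab, matches = seed_out$matches,
                 predictions = predictions, enrichment = enrichment,
                 dir = cfg$out_dir))
}
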