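# Synthetic plasma small RNA-seq cohorts with per-read ground truth.
#
# The generator emulates the statistical regime reported for plant miRNAs in
# human plasma: a host-dominated read pool in which roughly 1% of trimmed
# reads are plant-alignable, one ubiquitous high-copy exogenous miRNA
# (Poisson, mean ~1e3 copies/sample), and sporadic low-copy exogenous miRNAs
# (<= 4 copies, present in a minority of samples).

DEFAULT_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"  # TruSeq small RNA 3' adapter

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults encode the study
#' regime the package targets: 50-nt single-end reads, ~1% background plant
#' fraction, a Poisson(1000) ubiquitous exogenous spike-in, and sporadic
#' spike-ins capped at 4 copies.
#'
#' @param n_samples number of samples in the cohort.
#' @param reads_per_sample reads per sample.
#' @param read_length fixed read length (nt).
#' @param adapter 3' adapter sequence appended after each insert.
#' @param seq_error_rate per-base substitution probability on the insert
#'   (must be < 0.05).
#' @param xeno_fraction_mean expected fraction of reads drawn from background
#'   plant miRNAs (spike-ins are drawn on top of this fraction).
#' @param ubiquitous_xeno_ids plant miRNA ids present in every sample at high
#'   copy (Poisson with mean `ubiquitous_mean_copies`).
#' @param ubiquitous_mean_copies Poisson mean for ubiquitous spike-ins.
#' @param sporadic_xeno_spec data.frame with columns `id`, `prevalence`,
#'   `max_copies`: each id is present in a sample with probability
#'   `prevalence`, at a copy number uniform on `1:max_copies`.
#' @param degraded_read_rate fraction of reads given a uniformly low quality
#'   string (mean Phred ~12), exercising the quality filter.
#' @param degraded_tail_len number of trailing cycles over which quality
#'   declines from the plateau (Q38) to Q20.
#' @param rng_seed master seed; every sample derives its own seed from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 20L,
                       reads_per_sample = 50000L,
                       read_length = 50L,
                       adapter = DEFAULT_ADAPTER,
                       seq_error_rate = 0.001,
                       xeno_fraction_mean = 0.01,
                       ubiquitous_xeno_ids = character(),
                       ubiquitous_mean_copies = 1000,
                       sporadic_xeno_spec = NULL,
                       degraded_read_rate = 0,
                       degraded_tail_len = 10L,
                       rng_seed = 1L) {
  if (seq_error_rate < 0 || seq_error_rate >= 0.05)
    stop_config("seq_error_rate must be in [0, 0.05)")
  if (xeno_fraction_mean < 0 || xeno_fraction_mean >= 0.5)
    stop_config("xeno_fraction_mean must be in [0, 0.5)")
  if (!is_valid_seq(adapter)) stop_config("adapter is not a DNA string")
  if (n_samples < 1 || reads_per_sample < 1)
    stop_config("n_samples and reads_per_sample must be >= 1")
  if (!is.null(sporadic_xeno_spec)) {
    s <- sporadic_xeno_spec
    if (!all(c("id", "prevalence", "max_copies") %in% names(s)))
      stop_config("sporadic_xeno_spec needs columns id, prevalence, max_copies")
    if (any(s$max_copies < 1)) stop_config("sporadic max_copies must be >= 1")
    if (any(s$prevalence <= 0 | s$prevalence > 1))
      stop_config("sporadic prevalence must be in (0, 1]")
  }
  structure(list(n_samples = as.integer(n_samples),
                 reads_per_sample = as.integer(reads_per_sample),
                 read_length = as.integer(read_length),
                 adapter = norm_seq(adapter),
                 seq_error_rate = seq_error_rate,
                 xeno_fraction_mean = xeno_fraction_mean,
                 ubiquitous_xeno_ids = ubiquitous_xeno_ids,
                 ubiquitous_mean_copies = ubiquitous_mean_copies,
                 sporadic_xeno_spec = sporadic_xeno_spec,
                 degraded_read_rate = degraded_read_rate,
                 degraded_tail_len = as.integer(degraded_tail_len),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# Smallest Hamming distance of q against any same-length window of t
# (q no longer than t); returns TRUE when every window is > max_mm away.
windows_far <- function(q, t, max_mm) {
  qi <- utf8ToInt(q)
  ti <- utf8ToInt(t)
  nq <- length(qi)
  if (nq > length(ti)) return(TRUE)
  for (off in 0:(length(ti) - nq)) {
    if (sum(qi != ti[(off + 1):(off + nq)]) <= max_mm) return(FALSE)
  }
  TRUE
}

# TRUE when cand is far (> max_mm at every substring placement, in either
# direction) from every sequence in pool.
far_from_all <- function(cand, pool, max_mm = 2L) {
  for (s in pool) {
    if (nchar(cand) <= nchar(s)) {
      if (!windows_far(cand, s, max_mm)) return(FALSE)
    } else {
      if (!windows_far(s, cand, max_mm)) return(FALSE)
    }
  }
  TRUE
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Generate a synthetic miRNA reference set
#'
#' Builds disjoint host and plant mature/precursor catalogs plus host decoy
#' sequences. Matures are 19-24 nt; every mature is embedded in its
#' precursor; all matures (and all plant-mature/decoy placements) are kept at
#' Hamming distance >= 3 from each other at every substring offset, so that
#' host exclusion and mismatch-tolerant assignment are unambiguous by
#' construction. One decoy carries the adapter sequence to exercise the
#' adapter-contamination check.
#'
#' @param n_host,n_plant number of host / plant miRNA records (>= 1).
#' @param rng_seed integer seed; identical seeds give identical catalogs.
#' @param n_decoys number of host decoy sequences (80 nt).
#' @param adapter adapter sequence embedded in the first decoy.
#' @param max_tries rejection-sampling retries per record before giving up
#'   (an error here signals the catalog is too large for the sequence space).
#' @return list with elements `host` and `plant` (data.frames: `id`,
#'   `species`, `kingdom`, `mature`, `precursor`) and `decoys` (data.frame:
#'   `id`, `sequence`), of class `mirna_reference_set`.
#' @export
make_reference_set <- function(n_host, n_plant, rng_seed = 1L,
                               n_decoys = 4L, adapter = DEFAULT_ADAPTER,
                               max_tries = 500L) {
  if (n_host < 1 || n_plant < 1) stop_config("n_host and n_plant must be >= 1")
  set.seed(as.integer(rng_seed))
  n_total <- n_host + n_plant
  matures <- character(0)
  for (i in seq_len(n_total)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- random_seq(sample(19:24, 1))
      if (far_from_all(cand, matures)) {
        matures <- c(matures, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop_data("could not draw ", n_total, " mutually distant ",
                       "matures; catalog too large for sequence space")
  }
  precursor_of <- function(m) {
    paste0(random_seq(sample(15:30, 1)), m, random_seq(sample(15:30, 1)))
  }
  precursors <- vapply(matures, precursor_of, character(1), USE.NAMES = FALSE)
  host_idx <- seq_len(n_host)
  plant_idx <- n_host + seq_len(n_plant)
  host <- data.frame(
    id = sprintf("hsa-mir-%04d", seq_len(n_host)),
    species = "host", kingdom = "host",
    mature = matures[host_idx], precursor = precursors[host_idx],
    stringsAsFactors = FALSE)
  plant <- data.frame(
    id = sprintf("pla-mir-%04d", seq_len(n_plant)),
    species = "plant", kingdom = "plant",
    mature = matures[plant_idx], precursor = precursors[plant_idx],
    stringsAsFactors = FALSE)
  adapter <- norm_seq(adapter)
  decoys <- character(0)
  for (d in seq_len(n_decoys)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- if (d == 1) {
        paste0(random_seq(25), adapter, random_seq(80 - 25 - nchar(adapter)))
      } else random_seq(80)
      if (all(vapply(plant$mature, function(m) windows_far(m, cand, 2L),
                     logical(1)))) {
        decoys <- c(decoys, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop_data("could not draw decoys distant from plant matures")
  }
  structure(list(host = host, plant = plant,
                 decoys = data.frame(id = sprintf("decoy-%02d",
                                                  seq_len(n_decoys)),
                                     sequence = decoys,
                                     stringsAsFactors = FALSE)),
            class = "mirna_reference_set")
}

#' Validate a reference set's structural invariants
#'
#' Checks mature lengths (19-24 nt), alphabet, mature-in-precursor embedding,
#' id uniqueness, and the mutual-distance guarantee between plant matures and
#' host sequences.
#'
#' @param refs a `mirna_reference_set`.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_reference_set <- function(refs) {
  recs <- rbind(refs$host, refs$plant)
  stopifnot(!anyDuplicated(recs$id))
  if (!all(nchar(recs$mature) >= 19 & nchar(recs$mature) <= 24))
    stop_data("mature length outside 19-24 nt")
  if (!all(is_valid_seq(recs$mature)))
    stop_data("mature sequence has non-ACGT characters")
  emb <- mapply(grepl, recs$mature, recs$precursor, MoreArgs = list(fixed = TRUE))
  if (!all(emb)) stop_data("mature not embedded in its precursor")
  hostside <- c(refs$host$mature, refs$decoys$sequence)
  for (m in refs$plant$mature) {
    if (!far_from_all(m, hostside, 2L))
      stop_data("plant mature within 2 mismatches of a host sequence")
  }
  invisible(TRUE)
}

quality_template <- function(read_length, tail_len) {
  plateau <- rep(38L, max(0L, read_length - tail_len))
  tail <- if (tail_len > 0)
    as.integer(round(seq(38, 20, length.out = tail_len))) else integer(0)
  intToUtf8(c(plateau, tail)[seq_len(read_length)] + 33L)
}

apply_errors <- function(inserts, rate) {
  n_err <- rbinom(length(inserts), nchar(inserts), rate)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    s <- strsplit(inserts[i], "", fixed = TRUE)[[1]]
    pos <- sample(length(s), n_err[i])
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    inserts[i] <- paste(s, collapse = "")
  }
  list(seq = inserts, n_errors = n_err)
}

#' Simulate one plasma small RNA-seq sample
#'
#' Draws per-miRNA copy numbers (ubiquitous spike-ins: Poisson; sporadic
#' spike-ins: Bernoulli presence then uniform copies; background plant reads:
#' binomial at `xeno_fraction_mean`; host reads fill the remainder), builds
#' 50-nt reads as insert + 3' adapter + poly-A pad with independent per-base
#' substitution errors on the insert, and records per-read ground truth.
#'
#' @param refs a `mirna_reference_set`.
#' @param config a [sim_config()].
#' @param sample_index 1-based sample number (determines the derived seed).
#' @return list with `reads` (data.frame `id`, `seq`, `qual`) and `truth`
#'   (list with `counts`: data.frame `mirna_id`, `true_count`; and `reads`:
#'   data.frame `read_id`, `mirna_id`, `insert_seq`, `adapter_start`,
#'   `n_errors`), of class `sim_sample`.
#' @export
simulate_sample <- function(refs, config, sample_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(refs$plant) + nrow(refs$host) == 0) stop_config("empty reference set")
  set.seed(derive_seed(config$rng_seed, sample_index))
  n <- config$reads_per_sample

  ubiq <- intersect(config$ubiquitous_xeno_ids, refs$plant$id)
  spor <- config$sporadic_xeno_spec
  spike_src <- character(0)
  for (id in ubiq) {
    spike_src <- c(spike_src, rep(id, rpois(1, config$ubiquitous_mean_copies)))
  }
  if (!is.null(spor)) {
    for (r in seq_len(nrow(spor))) {
      if (runif(1) <= spor$prevalence[r]) {
        copies <- sample.int(spor$max_copies[r], 1)
        spike_src <- c(spike_src, rep(spor$id[r], copies))
      }
    }
  }
  if (length(spike_src) > n)
    stop_config("spike-in copies exceed reads_per_sample")

  bg_ids <- setdiff(refs$plant$id, c(ubiq, if (!is.null(spor)) spor$id))
  n_bg <- if (length(bg_ids) > 0 && config$xeno_fraction_mean > 0)
    rbinom(1, n, config$xeno_fraction_mean) else 0L
  n_bg <- min(n_bg, n - length(spike_src))
  bg_src <- if (n_bg > 0) sample(bg_ids, n_bg, replace = TRUE) else character(0)

  n_host <- n - length(spike_src) - n_bg
  host_src <- if (n_host > 0) sample(refs$host$id, n_host, replace = TRUE)
              else character(0)

  src <- sample(c(spike_src, bg_src, host_src))  # interleave read order
  mature_by_id <- c(stats::setNames(refs$plant$mature, refs$plant$id),
                    stats::setNames(refs$host$mature, refs$host$id))
  err <- apply_errors(unname(mature_by_id[src]), config$seq_error_rate)
  inserts <- err$seq

  pad <- strrep("A", config$read_length)
  seqs <- substr(paste0(inserts, config$adapter, pad), 1, config$read_length)
  qual_ok <- quality_template(config$read_length, config$degraded_tail_len)
  qual_bad <- strrep(intToUtf8(12L + 33L), config$read_length)
  degraded <- runif(n) < config$degraded_read_rate
  quals <- ifelse(degraded, qual_bad, qual_ok)
  read_ids <- sprintf("S%03d_R%06d", sample_index, seq_len(n))

  counts <- as.data.frame(table(src), stringsAsFactors = FALSE)
  names(counts) <- c("mirna_id", "true_count")
  counts <- counts[order(counts$mirna_id), , drop = FALSE]
  rownames(counts) <- NULL

  structure(list(
    reads = data.frame(id = read_ids, seq = seqs, qual = quals,
                       stringsAsFactors = FALSE),
    truth = list(
      counts = counts,
      reads = data.frame(read_id = read_ids, mirna_id = src,
                         insert_seq = inserts,
                         adapter_start = nchar(inserts) + 1L,
                         n_errors = err$n_errors,
                         stringsAsFactors = FALSE))),
    class = "sim_sample")
}

#' Simulate a full cohort and write it to disk
#'
#' Applies [simulate_sample()] per sample with per-sample derived seeds,
#' writes one FASTQ per sample plus a ground-truth count TSV
#' (`truth_counts.tsv`: sample_id, mirna_id, true_count).
#'
#' @param refs a `mirna_reference_set`.
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param keep_read_truth also return the per-read ground-truth table.
#' @return list with `fastq` (paths), `truth_counts` (data.frame),
#'   `read_truth` (data.frame or NULL), and `dir`.
#' @export
make_cohort <- function(refs, config, out_dir, keep_read_truth = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(config$n_samples)
  tc <- vector("list", config$n_samples)
  rt <- if (keep_read_truth) vector("list", config$n_samples) else NULL
  for (i in seq_len(config$n_samples)) {
    s <- simulate_sample(refs, config, i)
    sid <- sprintf("sample_%03d", i)
    paths[i] <- file.path(out_dir, paste0(sid, ".fastq"))
    write_fastq(s$reads, paths[i])
    tc[[i]] <- cbind(sample_id = sid, s$truth$counts)
    if (keep_read_truth) rt[[i]] <- cbind(sample_id = sid, s$truth$reads)
  }
  truth_counts <- do.call(rbind, tc)
  write_tsv_file(truth_counts, file.path(out_dir, "truth_counts.tsv"))
  list(fastq = paths, truth_counts = truth_counts,
       read_truth = if (keep_read_truth) do.call(rbind, rt) else NULL,
       dir = out_dir)
}

#' Build synthetic downstream resources for target inference
#'
#' Constructs, around a plant catalog, the reference material the
#' target-inference stages need: a synthetic host miRNA catalog containing
#' planted seed-identical partners for the first plant miRNAs (one sharing
#' positions 2-7, one sharing positions 2-8), a curated-style interaction
#' table (miRNA id, gene symbol), per-gene region sequences (5UTR/CDS/3UTR)
#' with perfect-complement target sites planted for the first plant miRNA,
#' and annotation term sets containing a planted enriched term. All content
#' is synthetic and deterministic given the seed.
#'
#' @param plant plant catalog data.frame (`id`, `mature`).
#' @param rng_seed integer seed.
#' @param n_random_human extra host miRNAs with no seed identity to any
#'   plant mature.
#' @param targets_per_mirna curated targets per seed-matched host miRNA.
#' @param n_terms total annotation terms (one planted + background).
#' @return list with `human` (data.frame `id`, `mature`), `interactions`
#'   (data.frame `mirna_id`, `gene_symbol`), `genes` (data.frame `gene_id`,
#'   `region`, `sequence`), `term_sets` (named list of gene vectors), and
#'   `planted_term`.
#' @export
make_target_resources <- function(plant, rng_seed = 1L, n_random_human = 10L,
                                  targets_per_mirna = 5L, n_terms = 8L) {
  set.seed(as.integer(rng_seed))
  p1 <- norm_seq(plant$mature[1])
  seed67 <- substr(p1, 2, 7)
  seed28 <- substr(p1, 2, 8)
  mk_tail <- function(n) random_seq(n)
  human <- data.frame(
    id = c("hsa-mir-t001", "hsa-mir-t002"),
    mature = c(paste0("A", seed67, mk_tail(15)),   # shares positions 2-7
               paste0("A", seed28, mk_tail(14))),  # shares positions 2-8
    stringsAsFactors = FALSE)
  plant_seeds <- substr(norm_seq(plant$mature), 2, 7)
  while (nrow(human) < 2L + n_random_human) {
    cand <- random_seq(22)
    if (!(substr(cand, 2, 7) %in% plant_seeds)) {
      human <- rbind(human, data.frame(
        id = sprintf("hsa-mir-r%03d", nrow(human) - 1L),
        mature = cand, stringsAsFactors = FALSE))
    }
  }
  genes <- sprintf("GENE%03d", seq_len(2L * targets_per_mirna))
  # overlapping curated target lists for the two planted host miRNAs
  t1 <- genes[seq_len(targets_per_mirna)]
  t2 <- genes[(targets_per_mirna - 1L):(2L * targets_per_mirna - 2L)]
  interactions <- rbind(
    data.frame(mirna_id = "hsa-mir-t001", gene_symbol = t1,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = "hsa-mir-t002", gene_symbol = t2,
               stringsAsFactors = FALSE))
  site <- revcomp(p1)  # perfect-complement target site for plant miRNA 1
  region_len <- c(`5UTR` = 120L, CDS = 240L, `3UTR` = 180L)
  region_for_gene <- rep(c("3UTR", "CDS", "5UTR"), length.out = length(genes))
  gene_rows <- list()
  for (g in seq_along(genes)) {
    for (reg in names(region_len)) {
      s <- random_seq(region_len[[reg]])
      if (g <= targets_per_mirna && reg == region_for_gene[g]) {
        at <- 40L  # plant the site at a fixed internal offset
        substr(s, at, at + nchar(site) - 1L) <- site
      }
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = genes[g], region = reg, sequence = s,
        stringsAsFactors = FALSE)
    }
  }
  gene_df <- do.call(rbind, gene_rows)
  universe <- c(genes, sprintf("BGGENE%03d", seq_len(60)))
  term_sets <- list()
  term_sets[["TERM_PLANTED"]] <- unique(c(t1, sample(universe, 3)))
  for (k in seq_len(n_terms - 1L)) {
    term_sets[[sprintf("TERM_BG%02d", k)]] <- sample(universe,
                                                     sample(8:20, 1))
  }
  list(human = human, interactions = interactions, genes = gene_df,
       term_sets = term_sets, planted_term = "TERM_PLANTED")
}
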