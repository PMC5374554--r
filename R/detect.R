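# Read assignment against plant and host miRNA catalogs with host exclusion,
# per-sample quantification, presence calls, and cohort summaries.

#' Detection configuration
#'
#' @param max_mismatches mismatches tolerated between a read and a catalog
#'   sequence (<= 2).
#' @param min_reads_presence assigned reads needed to call a miRNA present in
#'   a sample (>= 1; the detection rule is "at least one read").
#' @param ambiguous_policy how reads matching both catalogs are resolved;
#'   only `"host_wins"` is defined: a read is exogenous only if it matches a
#'   plant mature and nothing host-side.
#' @param k k-mer size for the exact-seeding index. At lookup time k is
#'   clamped to `floor(L / (max_mismatches + 1))` for the shortest query of
#'   length L, which guarantees every qualifying match is seeded.
#' @return an object of class `detect_config`.
#' @export
detect_config <- function(max_mismatches = 1L, min_reads_presence = 1L,
                          ambiguous_policy = "host_wins", k = 12L) {
  if (max_mismatches < 0 || max_mismatches > 2)
    stop_config("max_mismatches must be in 0..2")
  if (min_reads_presence < 1) stop_config("min_reads_presence must be >= 1")
  if (!identical(ambiguous_policy, "host_wins"))
    stop_config("only the host_wins ambiguity policy is supported")
  structure(list(max_mismatches = as.integer(max_mismatches),
                 min_reads_presence = as.integer(min_reads_presence),
                 ambiguous_policy = ambiguous_policy,
                 k = as.integer(k)),
            class = "detect_config")
}

#' Build a sequence index over catalog records
#'
#' Records are sorted lexicographically by id (which also fixes the
#' tie-break order for equally good hits) and checked for duplicates.
#'
#' @param ids record identifiers (unique).
#' @param seqs sequences (matures and/or decoys; U/T-insensitive).
#' @param k k-mer size; must not exceed the shortest sequence.
#' @param kingdom optional per-record kingdom labels, carried along.
#' @return an object of class `mirna_index`.
#' @export
build_index <- function(ids, seqs, k = 12L, kingdom = NULL) {
  if (length(ids) == 0) stop_config("index needs at least one record")
  if (anyDuplicated(ids)) stop_config("duplicate ids in index records")
  seqs <- norm_seq(seqs)
  if (k > min(nchar(seqs)))
    stop_config("k exceeds the shortest indexed sequence")
  ord <- order(ids)
  structure(list(ids = ids[ord], seqs = seqs[ord],
                 kingdom = if (is.null(kingdom)) NULL else kingdom[ord],
                 k = as.integer(k)),
            class = "mirna_index")
}

effective_k <- function(index, queries, max_mm) {
  lmin <- min(nchar(queries))
  max(1L, min(index$k, lmin %/% (max_mm + 1L)))
}

#' All index hits for a set of queries
#'
#' Finds every placement of each query as a substring of an indexed sequence
#' with at most `max_mm` mismatches (exact k-mer seeding, full verification).
#'
#' @param index a [build_index()] object.
#' @param queries character vector of query sequences.
#' @param max_mm mismatch tolerance.
#' @return list (one element per query) of data.frames with columns `id`,
#'   `offset` (1-based within the indexed sequence), `mismatches`.
#' @export
index_lookup <- function(index, queries, max_mm = 1L) {
  queries <- norm_seq(queries)
  k_eff <- effective_k(index, queries, max_mm)
  raw <- kmer_match_all_cpp(queries, index$seqs, k_eff, max_mm)
  lapply(raw, function(h) {
    data.frame(id = index$ids[h[, 1]], offset = h[, 2],
               mismatches = h[, 3], stringsAsFactors = FALSE)
  })
}

index_best <- function(index, queries, max_mm = 1L) {
  queries <- norm_seq(queries)
  k_eff <- effective_k(index, queries, max_mm)
  hit <- kmer_match_best_cpp(queries, index$seqs, k_eff, max_mm)
  data.frame(id = ifelse(hit$target > 0, index$ids[pmax(hit$target, 1)], NA),
             mismatches = hit$mismatches, stringsAsFactors = FALSE)
}

#' Assign reads to host or plant catalogs
#'
#' Implements the conservative host-wins exclusion rule: a read matching any
#' host-side sequence (host mature or decoy) within `cfg$max_mismatches` is
#' host; otherwise a read matching a plant mature is plant (best id by
#' fewest mismatches, then lexicographic id); otherwise unassigned.
#'
#' @param seqs trimmed, filtered read sequences.
#' @param plant_index index over plant matures.
#' @param host_index index over host matures plus host decoys.
#' @param cfg a [detect_config()].
#' @return data.frame with columns `assignment` (host/plant/unassigned) and
#'   `mirna_id` (matched id; NA when unassigned).
#' @export
assign_reads <- function(seqs, plant_index, host_index,
                         cfg = detect_config()) {
  host <- index_best(host_index, seqs, cfg$max_mismatches)
  plant <- index_best(plant_index, seqs, cfg$max_mismatches)
  assignment <- ifelse(!is.na(host$id), "host",
                       ifelse(!is.na(plant$id), "plant", "unassigned"))
  mirna_id <- ifelse(!is.na(host$id), host$id, plant$id)
  data.frame(assignment = assignment, mirna_id = mirna_id,
             stringsAsFactors = FALSE)
}

#' Flag catalog records sharing sequence with sequencing adapters
#'
#' A record is flagged when any adapter, or its reverse complement, shares an
#' exact substring of at least `min_shared` nt with the mature sequence.
#' Flagged records are excluded from reporting as possible adapter
#' contamination rather than genuine exogenous miRNAs.
#'
#' @param records data.frame with columns `id`, `mature`.
#' @param adapters character vector of adapter sequences.
#' @param min_shared shared-substring length that triggers the flag.
#' @return named logical vector (TRUE = flagged).
#' @export
adapter_contamination_check <- function(records, adapters, min_shared = 10L) {
  stopifnot(length(adapters) > 0)
  probes <- unique(c(norm_seq(adapters), revcomp(adapters)))
  kmers <- unique(unlist(lapply(probes, function(a) {
    n <- nchar(a)
    if (n < min_shared) return(character(0))
    substring(a, 1:(n - min_shared + 1), min_shared:n)
  })))
  matures <- norm_seq(records$mature)
  flagged <- vapply(matures, function(m) {
    any(vapply(kmers, grepl, logical(1), x = m, fixed = TRUE))
  }, logical(1), USE.NAMES = FALSE)
  stats::setNames(flagged, records$id)
}

#' Quantify one sample
#'
#' Applies [assign_reads()] to every read and tallies per-miRNA counts.
#' Totals always conserve the input read count.
#'
#' @param seqs trimmed, filtered read sequences of one sample.
#' @param plant_index,host_index catalog indexes (see [assign_reads()]).
#' @param cfg a [detect_config()].
#' @param sample_id label carried into the profile.
#' @return an object of class `count_profile`: list with `sample_id`,
#'   `counts` (named integer vector over all indexed ids), `kingdom` (named,
#'   "plant"/"host"), and `totals` (input, host, plant, unassigned).
#' @export
quantify <- function(seqs, plant_index, host_index, cfg = detect_config(),
                     sample_id = "sample") {
  all_ids <- c(plant_index$ids, host_index$ids)
  host_kingdom <- if (!is.null(host_index$kingdom)) host_index$kingdom
                  else rep("host", length(host_index$ids))
  kingdom <- stats::setNames(c(rep("plant", length(plant_index$ids)),
                               host_kingdom), all_ids)
  counts <- stats::setNames(integer(length(all_ids)), all_ids)
  totals <- c(input = length(seqs), host = 0L, plant = 0L, unassigned = 0L)
  if (length(seqs) > 0) {
    asg <- assign_reads(seqs, plant_index, host_index, cfg)
    tab <- table(asg$mirna_id[!is.na(asg$mirna_id)])
    counts[names(tab)] <- as.integer(tab)
    totals["host"] <- sum(asg$assignment == "host")
    totals["plant"] <- sum(asg$assignment == "plant")
    totals["unassigned"] <- sum(asg$assignment == "unassigned")
  }
  structure(list(sample_id = sample_id, counts = counts, kingdom = kingdom,
                 totals = totals),
            class = "count_profile")
}

#' Plant miRNAs present in a sample
#'
#' @param profile a [quantify()] result.
#' @param cfg a [detect_config()]; presence needs at least
#'   `min_reads_presence` assigned reads.
#' @return character vector of plant miRNA ids called present.
#' @export
presence_call <- function(profile, cfg = detect_config()) {
  plant_ids <- names(profile$counts)[profile$kingdom[names(profile$counts)] ==
                                       "plant"]
  plant_ids[profile$counts[plant_ids] >= cfg$min_reads_presence]
}

#' Cohort-level summary of plant miRNA detection
#'
#' For every plant miRNA detected anywhere in the cohort: the number of
#' samples where it is called present, its maximum and median count over
#' those samples, and its relative abundance rank — the quantile of its
#' count within the pooled host-miRNA count distribution of the same sample
#' (median over present samples). A quantile near 1 means the exogenous
#' miRNA out-counts most host miRNAs in the samples where it appears.
#'
#' @param profiles list of [quantify()] results.
#' @param cfg a [detect_config()].
#' @return data.frame with columns `mirna_id`, `n_samples_present`,
#'   `max_count`, `median_count`, `median_host_quantile`, sorted by
#'   decreasing `n_samples_present` then id.
#' @export
cohort_summary <- function(profiles, cfg = detect_config()) {
  stopifnot(length(profiles) > 0)
  kingdom <- profiles[[1]]$kingdom
  plant_ids <- names(kingdom)[kingdom == "plant"]
  host_ids <- names(kingdom)[kingdom == "host"]
  rows <- list()
  for (id in sort(plant_ids)) {
    cnt <- vapply(profiles, function(p) p$counts[[id]], integer(1))
    present <- cnt >= cfg$min_reads_presence
    if (!any(present)) next
    qts <- vapply(which(present), function(s) {
      hc <- profiles[[s]]$counts[host_ids]
      mean(hc <= cnt[s])
    }, numeric(1))
    rows[[id]] <- data.frame(
      mirna_id = id, n_samples_present = sum(present),
      max_count = max(cnt), median_count = median(cnt[present]),
      median_host_quantile = median(qts), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(mirna_id = character(0),
                      n_samples_present = integer(0), max_count = integer(0),
                      median_count = numeric(0),
                      median_host_quantile = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_samples_present, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a count profile as TSV
#'
#' @param profile a [quantify()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_profile <- function(profile, path) {
  df <- data.frame(sample_id = profile$sample_id,
                   mirna_id = names(profile$counts),
                   kingdom = unname(profile$kingdom[names(profile$counts)]),
                   count = unname(profile$counts),
                   stringsAsFactors = FALSE)
  write_tsv_file(df[df$count > 0, , drop = FALSE], path)
}
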