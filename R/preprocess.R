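# Adapter trimming and read quality filtering (in-repo replacement for the
# external trimming/QC tools used in the original study design).

#' Trimming and quality-filter configuration
#'
#' @param adapter 3' adapter sequence to remove.
#' @param min_overlap smallest adapter overlap (nt) accepted at the 3' end;
#'   must be >= 3.
#' @param max_mismatch_rate highest tolerated mismatch fraction within the
#'   adapter overlap (0-0.2).
#' @param min_len,max_len kept-insert length window (nt).
#' @param min_mean_q smallest mean Phred score kept.
#' @return an object of class `trim_config`.
#' @export
trim_config <- function(adapter = DEFAULT_ADAPTER, min_overlap = 6L,
                        max_mismatch_rate = 0.1, min_len = 16L,
                        max_len = 28L, min_mean_q = 20) {
  if (min_overlap < 3) stop_config("min_overlap must be >= 3")
  if (max_mismatch_rate < 0 || max_mismatch_rate > 0.2)
    stop_config("max_mismatch_rate must be in [0, 0.2]")
  if (min_len >= max_len) stop_config("min_len must be < max_len")
  if (!is_valid_seq(adapter)) stop_config("adapter is not a DNA string")
  structure(list(adapter = norm_seq(adapter),
                 min_overlap = as.integer(min_overlap),
                 max_mismatch_rate = max_mismatch_rate,
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 min_mean_q = min_mean_q),
            class = "trim_config")
}

#' Trim the 3' adapter from reads
#'
#' Removes everything from the leftmost adapter occurrence onward. An
#' occurrence at offset i must overlap the adapter by at least
#' `cfg$min_overlap` bases (the adapter may run off the 3' end) with a
#' mismatch fraction at most `cfg$max_mismatch_rate`; leftmost wins, i.e.
#' the shortest plausible insert. Reads without a qualifying occurrence are
#' returned unchanged with `found = FALSE`. Reads with non-ACGTN characters
#' are rejected (`rejected = TRUE`) and left untouched.
#'
#' @param seqs character vector of read sequences.
#' @param quals matching quality strings (Phred+33).
#' @param cfg a [trim_config()].
#' @return list with `seq`, `qual` (trimmed), `found` (logical), and
#'   `rejected` (logical, alphabet violations).
#' @export
trim_adapter <- function(seqs, quals, cfg = trim_config()) {
  stopifnot(length(seqs) == length(quals), all(nzchar(seqs)))
  seqs <- norm_seq(seqs)
  rejected <- !is_valid_seq(seqs)
  off <- rep(-1L, length(seqs))
  keep <- !rejected
  if (any(keep)) {
    off[keep] <- adapter_offsets_cpp(seqs[keep], cfg$adapter,
                                     cfg$min_overlap, cfg$max_mismatch_rate)
  }
  found <- off >= 0
  out_seq <- seqs
  out_qual <- quals
  out_seq[found] <- substr(seqs[found], 1L, off[found])
  out_qual[found] <- substr(quals[found], 1L, off[found])
  list(seq = out_seq, qual = out_qual, found = found, rejected = rejected)
}

#' Keep/drop decision on trimmed reads
#'
#' Keeps a read iff `min_len <= length <= max_len` and its mean Phred score
#' is at least `min_mean_q`. Drop reasons, in precedence order:
#' `too_short`, `too_long`, `low_quality`.
#'
#' @param seqs trimmed read sequences.
#' @param quals matching quality strings.
#' @param cfg a [trim_config()].
#' @return list with `keep` (logical) and `reason` (character; "" when kept).
#' @export
quality_filter <- function(seqs, quals, cfg = trim_config()) {
  stopifnot(length(seqs) == length(quals),
            all(nchar(seqs) == nchar(quals)))
  len <- nchar(seqs)
  reason <- character(length(seqs))
  reason[len < cfg$min_len] <- "too_short"
  reason[reason == "" & len > cfg$max_len] <- "too_long"
  idx <- which(reason == "")
  if (length(idx) > 0) {
    lowq <- mean_phred(quals[idx]) < cfg$min_mean_q
    reason[idx[lowq]] <- "low_quality"
  }
  list(keep = reason == "", reason = reason)
}

#' Trim and filter one sample
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param cfg a [trim_config()].
#' @return list with `kept` (data.frame of surviving reads, trimmed) and
#'   `report` (one-row data.frame: reads_in, trimmed, kept, and per-reason
#'   drop counts; `rejected` counts alphabet violations).
#' @export
preprocess_sample <- function(reads, cfg = trim_config()) {
  tr <- trim_adapter(reads$seq, reads$qual, cfg)
  usable <- !tr$rejected
  qf <- quality_filter(tr$seq[usable], tr$qual[usable], cfg)
  kept_idx <- which(usable)[qf$keep]
  kept <- data.frame(id = reads$id[kept_idx], seq = tr$seq[kept_idx],
                     qual = tr$qual[kept_idx], stringsAsFactors = FALSE)
  report <- data.frame(
    reads_in = nrow(reads),
    rejected = sum(tr$rejected),
    trimmed = sum(tr$found),
    kept = length(kept_idx),
    dropped_too_short = sum(qf$reason == "too_short"),
    dropped_too_long = sum(qf$reason == "too_long"),
    dropped_low_quality = sum(qf$reason == "low_quality"))
  list(kept = kept, report = report)
}

#' Trim and filter a FASTQ file
#'
#' @param in_path input FASTQ.
#' @param out_path output FASTQ of kept, trimmed reads.
#' @param cfg a [trim_config()].
#' @return the per-file report row (see [preprocess_sample()]), invisibly
#'   annotated with the file paths.
#' @export
preprocess_fastq <- function(in_path, out_path, cfg = trim_config()) {
  reads <- read_fastq(in_path)
  res <- preprocess_sample(reads, cfg)
  write_fastq(res$kept, out_path)
  rep <- cbind(data.frame(input = in_path, output = out_path,
                          stringsAsFactors = FALSE), res$report)
  invisible(rep)
}
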