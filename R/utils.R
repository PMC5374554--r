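# Shared sequence and file helpers. Everything downstream works in the DNA
# alphabet with U folded into T; FASTA/FASTQ I/O goes through Biostrings.

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and converts U to T so that RNA and DNA spellings (and mixed
#' case) compare equal everywhere in the package.
#'
#' @param x character vector of sequences.
#' @return character vector in the A/C/G/T(/N) alphabet.
#' @export
norm_seq <- function(x) chartr("U", "T", toupper(x))

#' Reverse complement of DNA/RNA strings
#'
#' @param x character vector of sequences (U and T equivalent).
#' @return character vector of reverse complements, DNA alphabet.
#' @export
revcomp <- function(x) {
  x <- norm_seq(x)
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

is_valid_seq <- function(x) grepl("^[ACGTN]+$", norm_seq(x))

#' @noRd
stop_config <- function(...) {
  stop(structure(class = c("xenomir_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
stop_data <- function(...) {
  stop(structure(class = c("xenomir_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Derive a per-sample RNG seed from a master seed; kept below 2^31.
derive_seed <- function(rng_seed, index) {
  as.integer((as.numeric(rng_seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (Phred+33).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # suppress Biostrings' benign notice about dropped metadata columns
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a miRNA catalog FASTA
#'
#' Accepts RNA or DNA alphabet; sequences are normalized to DNA internally.
#'
#' @param path FASTA file of mature (or precursor) sequences.
#' @return data.frame with columns `id`, `seq`.
#' @export
read_mirna_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  data.frame(id = ids, seq = norm_seq(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param ids record identifiers.
#' @param seqs sequences (DNA alphabet; use `rna = TRUE` to emit U).
#' @param path output path.
#' @param rna write in the RNA alphabet.
#' @return `path`, invisibly.
#' @export
write_seq_fasta <- function(ids, seqs, path, rna = FALSE) {
  seqs <- norm_seq(seqs)
  if (rna) {
    x <- Biostrings::RNAStringSet(chartr("T", "U", seqs))
  } else {
    x <- Biostrings::DNAStringSet(seqs)
  }
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Mean Phred score of quality strings (Phred+33).
mean_phred <- function(quals) {
  vapply(quals, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}
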