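# Seed-anchored miRNA:mRNA target-site prediction: nearest-neighbor duplex
# minimum free energy (intermolecular only) plus a complementarity score,
# filtered at MFE <= -14 kcal/mol and score >= 140.

the_env <- new.env(parent = emptyenv())

PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Load the nearest-neighbor duplex energy model
#'
#' Reads the versioned stack-energy table shipped with the package
#' (`nn_stacks_v1.tsv`): Watson-Crick stack free energies from the published
#' nearest-neighbor parameter set, simplified generic values for
#' G:U-containing stacks, and affine interior-loop/bulge penalties
#' (open + per-unpaired-nt extension), all at 37 degrees C.
#'
#' @param path optional path to an alternative table with the same layout.
#' @return list with `stack` (6x6 matrix over pair types AU/UA/CG/GC/GU/UG,
#'   kcal/mol), `loop_open`, `loop_ext` (kcal/mol), `max_loop` (nt).
#' @export
energy_model <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the_env$model)) return(the_env$model)
    path <- system.file("extdata", "nn_stacks_v1.tsv", package = "xenomir")
    cache <- TRUE
  } else cache <- FALSE
  tab <- read_tsv_file(path)
  st <- tab[tab$kind == "stack", , drop = FALSE]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  stack[cbind(match(st$key1, PAIR_TYPES), match(st$key2, PAIR_TYPES))] <-
    st$value
  stopifnot(!anyNA(stack))
  model <- list(stack = stack,
                loop_open = tab$value[tab$kind == "loop_open"],
                loop_ext = tab$value[tab$kind == "loop_ext"],
                max_loop = as.integer(tab$value[tab$kind == "max_loop"]))
  if (cache) the_env$model <- model
  model
}

#' Target-site prediction configuration
#'
#' @param mfe_max duplex MFE threshold in kcal/mol (sites must be <= this;
#'   default -14).
#' @param score_min complementarity score threshold (sites must be >= this;
#'   default 140).
#' @param window target window length (nt) evaluated around each seed
#'   anchor.
#' @param weights scoring weights, see [score_weights()].
#' @return an object of class `predict_config`.
#' @export
predict_config <- function(mfe_max = -14, score_min = 140, window = 30L,
                           weights = score_weights()) {
  if (mfe_max >= 0) stop_config("mfe_max must be negative")
  if (score_min <= 0) stop_config("score_min must be positive")
  structure(list(mfe_max = mfe_max, score_min = score_min,
                 window = as.integer(window), weights = weights),
            class = "predict_config")
}

#' Complementarity score weights
#'
#' @param seed_wc points per Watson-Crick pair at miRNA positions 2-8.
#' @param other_wc points per Watson-Crick pair elsewhere.
#' @param gu points per G:U pair.
#' @param loop penalty per interior loop/bulge event (negative).
#' @return named list of weights.
#' @export
score_weights <- function(seed_wc = 15, other_wc = 5, gu = 2, loop = -3) {
  list(seed_wc = seed_wc, other_wc = other_wc, gu = gu, loop = loop)
}

#' Minimum free energy of an intermolecular RNA:RNA duplex
#'
#' Dynamic program over all antiparallel, non-crossing intermolecular pair
#' sets (no intramolecular pairs, no pseudoknots) under the nearest-neighbor
#' stack model with affine loop penalties. The empty structure has energy 0,
#' so the MFE is always <= 0.
#'
#' @param mirna miRNA sequence, 5'->3' (5-40 nt).
#' @param target target window sequence, 5'->3' (5-40 nt).
#' @param model an [energy_model()].
#' @return list with `mfe` (kcal/mol) and `pairs`, a data.frame with
#'   columns `i` (miRNA position), `j` (target position) and `wobble`
#'   (TRUE for G:U pairs) of the MFE structure (empty when mfe = 0).
#' @export
duplex_mfe <- function(mirna, target, model = energy_model()) {
  mirna <- norm_seq(mirna)
  target <- norm_seq(target)
  if (!is_valid_seq(mirna) || !is_valid_seq(target))
    stop_data("duplex sequences must be nucleotide strings")
  if (nchar(mirna) < 5 || nchar(mirna) > 40 ||
      nchar(target) < 5 || nchar(target) > 40)
    stop_data("duplex sequences must be 5-40 nt")
  res <- duplex_dp_cpp(mirna, target, model$stack, model$loop_open,
                       model$loop_ext, model$max_loop)
  pairs <- data.frame(i = res$i, j = res$j, wobble = res$wobble)
  if (res$mfe >= 0) pairs <- pairs[0, , drop = FALSE]
  list(mfe = res$mfe, pairs = pairs)
}

#' Complementarity score of a duplex structure
#'
#' `score = seed_wc * (WC pairs at miRNA positions 2-8) + other_wc * (WC
#' pairs elsewhere) + gu * (G:U pairs) + loop * (interior loop/bulge
#' events)`, where a loop event is any gap between consecutive pairs.
#'
#' @param pairs pair data.frame from [duplex_mfe()] (columns `i`, `j`,
#'   `wobble`).
#' @param weights a [score_weights()] list.
#' @return numeric score (0 for an empty pair list).
#' @export
complementarity_score <- function(pairs, weights = score_weights()) {
  if (nrow(pairs) == 0) return(0)
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  wc <- !pairs$wobble
  seed <- pairs$i >= 2 & pairs$i <= 8
  n_loops <- 0L
  if (nrow(pairs) > 1) {
    gx <- diff(pairs$i) - 1L
    gy <- -diff(pairs$j) - 1L
    n_loops <- sum(gx + gy > 0)
  }
  weights$seed_wc * sum(wc & seed) + weights$other_wc * sum(wc & !seed) +
    weights$gu * sum(pairs$wobble) + weights$loop * n_loops
}

site_class_at <- function(region_seq, start, sites) {
  len6 <- nchar(sites$site6)
  after1 <- substr(region_seq, start + len6, start + len6)
  m8_start <- start - 1L
  has_m8 <- m8_start >= 1 &&
    substr(region_seq, m8_start, m8_start + nchar(sites$site7m8) - 1L) ==
      sites$site7m8
  if (has_m8 && after1 == "A") return("8mer")
  if (has_m8) return("7mer-m8")
  if (after1 == "A") return("7mer-A1")
  "6mer"
}

#' Scan a gene's regions for target sites of one miRNA
#'
#' Anchors at every exact occurrence of the miRNA's 6mer seed site (or a
#' stronger class) in each annotated region (5UTR/CDS/3UTR), evaluates the
#' duplex MFE of the miRNA against a window extending upstream of the
#' anchor (where the miRNA 3' end pairs), scores the structure, and
#' reports the sites passing both thresholds. Overlapping passing sites are
#' all reported, with a flag marking overlap with the previous site.
#'
#' @param mirna_id identifier carried into the results.
#' @param mature mature miRNA sequence.
#' @param gene data.frame with columns `gene_id`, `region`
#'   (5UTR/CDS/3UTR), `sequence` — the regions of one gene.
#' @param cfg a [predict_config()].
#' @param model an [energy_model()].
#' @return data.frame with columns `mirna_id`, `gene_id`, `region`,
#'   `start`, `end` (1-based closed interval of the seed site within the
#'   region), `match_class`, `mfe`, `score`, `overlaps_previous`.
#' @export
scan_gene <- function(mirna_id, mature, gene, cfg = predict_config(),
                      model = energy_model()) {
  stopifnot(nrow(gene) > 0)
  mature <- norm_seq(mature)
  sites <- seed_sites(mature, mirna_id)
  out <- list()
  for (r in seq_len(nrow(gene))) {
    region_seq <- norm_seq(gene$sequence[r])
    hits <- gregexpr(sites$site6, region_seq, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    prev_end <- -1L
    for (start in as.integer(hits)) {
      end <- start + nchar(sites$site6) - 1L
      wend <- min(nchar(region_seq), end + 2L)
      wstart <- max(1L, wend - cfg$window + 1L)
      window_seq <- substr(region_seq, wstart, wend)
      if (nchar(window_seq) < 5) next
      dp <- duplex_mfe(mature, window_seq, model)
      sc <- complementarity_score(dp$pairs, cfg$weights)
      if (dp$mfe <= cfg$mfe_max && sc >= cfg$score_min) {
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = mirna_id, gene_id = gene$gene_id[r],
          region = gene$region[r], start = start, end = end,
          match_class = site_class_at(region_seq, start, sites),
          mfe = dp$mfe, score = sc,
          overlaps_previous = start <= prev_end,
          stringsAsFactors = FALSE)
        prev_end <- end
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      region = character(0), start = integer(0),
                      end = integer(0), match_class = character(0),
                      mfe = numeric(0), score = numeric(0),
                      overlaps_previous = logical(0)))
  }
  do.call(rbind, out)
}

#' Scan many genes for many miRNAs
#'
#' @param mirnas data.frame with columns `id`, `mature`.
#' @param genes data.frame with columns `gene_id`, `region`, `sequence`
#'   (possibly many genes).
#' @param cfg a [predict_config()].
#' @param model an [energy_model()].
#' @return row-bound [scan_gene()] results.
#' @export
scan_genes <- function(mirnas, genes, cfg = predict_config(),
                       model = energy_model()) {
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (g in unique(genes$gene_id)) {
      res <- scan_gene(mirnas$id[i], mirnas$mature[i],
                       genes[genes$gene_id == g, , drop = FALSE], cfg, model)
      if (nrow(res) > 0) out[[length(out) + 1L]] <- res
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      region = character(0), start = integer(0),
                      end = integer(0), match_class = character(0),
                      mfe = numeric(0), score = numeric(0),
                      overlaps_previous = logical(0)))
  }
  do.call(rbind, out)
}
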