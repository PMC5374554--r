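# Seed-derived target-site strings, cross-kingdom seed-identity matching,
# and curated-target transfer.
#
# Conventions: mature positions are 1-based from the 5' end; the seed is
# positions 2-7 (6mer) or 2-8 (7mer-m8). Site strings are written 5'->3' on
# the mRNA as reverse complements of the seed; the A of the 7mer-A1/8mer
# classes is the target-site position-1 adenosine appended 3' of the site.

#' Target-site seed strings of a mature miRNA
#'
#' @param mature mature miRNA sequence (RNA or DNA alphabet), >= 9 nt.
#' @param id optional identifier used in error messages.
#' @return an object of class `seed_sites`: list with `site6` (reverse
#'   complement of positions 2-7), `site7A1` (`site6` + "A"), `site7m8`
#'   (reverse complement of positions 2-8), and `site8` (`site7m8` + "A"),
#'   all in the DNA alphabet.
#' @examples
#' seed_sites("UAGUUGGAGAGGAAUUGAUCG")$site6  # "CCAACT"
#' @export
seed_sites <- function(mature, id = NULL) {
  m <- norm_seq(mature)
  if (nchar(m) < 9)
    stop_data("mature", if (!is.null(id)) paste0(" '", id, "'"),
              " is shorter than 9 nt; cannot derive seed sites")
  if (!is_valid_seq(m)) stop_data("mature has non-nucleotide characters")
  site6 <- revcomp(substr(m, 2, 7))
  site7m8 <- revcomp(substr(m, 2, 8))
  structure(list(site6 = site6,
                 site7A1 = paste0(site6, "A"),
                 site7m8 = site7m8,
                 site8 = paste0(site7m8, "A")),
            class = "seed_sites")
}

#' Seed-site table for a catalog
#'
#' @param records data.frame with columns `id`, `mature`.
#' @return data.frame with columns `id`, `site6`, `site7A1`, `site7m8`,
#'   `site8`.
#' @export
seed_table <- function(records) {
  sites <- lapply(seq_len(nrow(records)),
                  function(i) seed_sites(records$mature[i], records$id[i]))
  data.frame(id = records$id,
             site6 = vapply(sites, `[[`, character(1), "site6"),
             site7A1 = vapply(sites, `[[`, character(1), "site7A1"),
             site7m8 = vapply(sites, `[[`, character(1), "site7m8"),
             site8 = vapply(sites, `[[`, character(1), "site8"),
             stringsAsFactors = FALSE)
}

#' Host miRNAs with seed identity to plant miRNAs
#'
#' Reports all plant/host pairs whose site strings of the requested class
#' are identical (exact Watson-Crick identity; no wobble, no mismatches).
#' Because the A1 adenosine is appended to every site string, 7mer-A1
#' identity coincides with 6mer identity and 8mer identity with 7mer-m8
#' identity; each reported pair is labeled with its strongest class
#' ("8mer" when positions 2-8 agree, else "7mer-A1") and carries the full
#' list of classes it satisfies.
#'
#' @param plant,human catalog data.frames with columns `id`, `mature`.
#' @param class minimal match class required: "6mer" (positions 2-7, the
#'   default), "7mer-A1" (same sites as 6mer), "7mer-m8" or "8mer"
#'   (positions 2-8).
#' @return data.frame with columns `plant_id`, `human_id`, `match_class`
#'   (strongest), `classes` (comma-separated list of satisfied classes).
#' @export
match_human <- function(plant, human,
                        class = c("6mer", "7mer-A1", "7mer-m8", "8mer")) {
  class <- match.arg(class)
  stopifnot(nrow(plant) > 0, nrow(human) > 0)
  pt <- seed_table(plant)
  ht <- seed_table(human)
  rows <- list()
  for (i in seq_len(nrow(pt))) {
    m6 <- ht$site6 == pt$site6[i]
    m8 <- ht$site7m8 == pt$site7m8[i]
    hit <- if (class %in% c("6mer", "7mer-A1")) m6 else m8
    for (j in which(hit)) {
      classes <- c("6mer", "7mer-A1")[c(m6[j], m6[j])]
      if (m8[j]) classes <- c(classes, "7mer-m8", "8mer")
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = pt$id[i], human_id = ht$id[j],
        match_class = if (m8[j]) "8mer" else "7mer-A1",
        classes = paste(classes, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(plant_id = character(0), human_id = character(0),
                      match_class = character(0), classes = character(0)))
  }
  do.call(rbind, rows)
}

#' Transfer curated targets of seed-matched host miRNAs
#'
#' Candidate targets of a plant miRNA are the union of the curated target
#' genes of all host miRNAs sharing its seed, with provenance (which host
#' miRNA contributed each gene) retained. Matched host miRNAs absent from
#' the interaction table contribute nothing and trigger a warning.
#'
#' @param matches a [match_human()] result.
#' @param interactions data.frame with columns `mirna_id`, `gene_symbol`
#'   (curated miRNA-target table, e.g. a miRTarBase-style export).
#' @return data.frame with columns `plant_id`, `gene_symbol`, `source_human`
#'   (comma-separated contributing host miRNA ids); one row per unique
#'   (plant, gene) pair.
#' @export
transfer_targets <- function(matches, interactions) {
  stopifnot(all(c("mirna_id", "gene_symbol") %in% names(interactions)))
  empty <- data.frame(plant_id = character(0), gene_symbol = character(0),
                      source_human = character(0))
  if (nrow(matches) == 0) return(empty)
  missing <- setdiff(unique(matches$human_id), unique(interactions$mirna_id))
  if (length(missing) > 0) {
    warning("no curated interactions for: ", paste(missing, collapse = ", "))
  }
  rows <- list()
  for (pid in unique(matches$plant_id)) {
    humans <- matches$human_id[matches$plant_id == pid]
    sub <- interactions[interactions$mirna_id %in% humans, , drop = FALSE]
    if (nrow(sub) == 0) next
    prov <- vapply(split(sub$mirna_id, sub$gene_symbol),
                   function(h) paste(sort(unique(h)), collapse = ","),
                   character(1))
    rows[[pid]] <- data.frame(plant_id = pid,
                              gene_symbol = names(prov),
                              source_human = unname(prov),
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
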