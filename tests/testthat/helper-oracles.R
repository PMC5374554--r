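# Independent oracles used to cross-check the package's fast paths. These
# deliberately re-derive results by brute force (full scans, exhaustive
# enumeration) and share no code with the implementations they check.

# All placements of `query` inside any of `targets` with <= max_mm
# mismatches, by direct Hamming scan over every offset.
brute_hits <- function(query, targets, max_mm) {
  qi <- utf8ToInt(query)
  nq <- length(qi)
  rows <- list()
  for (t in seq_along(targets)) {
    ti <- utf8ToInt(targets[t])
    if (nq > length(ti)) next
    for (off in 0:(length(ti) - nq)) {
      mm <- sum(qi != ti[(off + 1):(off + nq)])
      if (mm <= max_mm) {
        rows[[length(rows) + 1L]] <- c(t, off + 1L, mm)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(target = integer(0), offset = integer(0),
                      mismatches = integer(0)))
  }
  m <- do.call(rbind, rows)
  data.frame(target = m[, 1], offset = m[, 2], mismatches = m[, 3])
}

# Host-wins assignment decision derived only from brute_hits.
brute_assign <- function(read, plant_ids, plant_seqs, host_seqs, max_mm) {
  if (nrow(brute_hits(read, host_seqs, max_mm)) > 0) return("host")
  h <- brute_hits(read, plant_seqs, max_mm)
  if (nrow(h) == 0) return("unassigned")
  h <- h[order(h$mismatches, plant_ids[h$target]), , drop = FALSE]
  plant_ids[h$target[1]]
}

# Exhaustive enumeration of all antiparallel non-crossing intermolecular
# pair sets, scored with the same energy tables as the DP but by direct
# recursion over structures.
enum_duplex_mfe <- function(x, y, model = xenomir::energy_model()) {
  to_rna <- function(s) chartr("T", "U", xenomir::norm_seq(s))
  xb <- strsplit(to_rna(x), "")[[1]]
  yb <- strsplit(to_rna(y), "")[[1]]
  types <- rownames(model$stack)
  ptype <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% types) key else NA_character_
  }
  m <- length(xb)
  n <- length(yb)
  best <- 0
  rec <- function(last_i, last_j, last_t, e) {
    if (e < best) best <<- e
    if (last_i >= m || last_j <= 1) return(invisible())
    for (i in (last_i + 1):m) {
      for (j in seq_len(last_j - 1)) {
        t <- ptype(xb[i], yb[j])
        if (is.na(t)) next
        if (is.null(last_t)) {
          cost <- 0
        } else {
          gx <- i - last_i - 1L
          gy <- last_j - j - 1L
          if (gx == 0 && gy == 0) {
            cost <- model$stack[last_t, t]
          } else if (gx + gy <= model$max_loop) {
            cost <- model$loop_open + model$loop_ext * (gx + gy)
          } else next
        }
        rec(i, j, t, e + cost)
      }
    }
    invisible()
  }
  rec(0L, length(yb) + 1L, NULL, 0)
  best
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws (N small).
enum_hyper_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # term genes are labeled 1..K
  mean(hits >= k)
}

# Direct BH step-up computation on a raw p-vector.
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
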