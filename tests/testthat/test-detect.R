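test_that("index lookup finds exact and 1-mismatch hits", {
  idx <- build_index("mir-a", "ACGTACGTACGTACGTACGT", k = 12)
  hit <- index_lookup(idx, "ACGTACGTACGTACGTACGT", max_mm = 1)[[1]]
  expect_equal(hit$id, "mir-a")
  expect_equal(hit$mismatches, 0)
  mut <- "ACGTACGTACTTACGTACGT"  # one substitution
  hit1 <- index_lookup(idx, mut, max_mm = 1)[[1]]
  expect_equal(hit1$mismatches, 1)
  expect_equal(nrow(index_lookup(idx, mut, max_mm = 0)[[1]]), 0)
  expect_error(build_index(c("a", "a"), c("ACGTACGTACGTA", "ACGTACGTACGTC")),
               class = "xenomir_config_error")
})

test_that("index hit sets equal a brute-force Hamming scan", {
  refs <- big_refs()
  all_seqs <- c(refs$host$mature, refs$plant$mature)
  idx <- build_index(sprintf("rec-%03d", seq_along(all_seqs)), all_seqs,
                     k = 12)
  set.seed(7)
  queries <- c(
    vapply(sample(all_seqs, 150, replace = TRUE), function(s) {
      v <- strsplit(s, "")[[1]]
      nmut <- sample(0:2, 1)
      for (p in sample(length(v), nmut))
        v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
      paste(v, collapse = "")
    }, character(1), USE.NAMES = FALSE),
    replicate(150, random_dna(sample(16:24, 1))))
  for (mm in 0:2) {
    got <- index_lookup(idx, queries, max_mm = mm)
    for (qi in seq_along(queries)) {
      want <- brute_hits(queries[qi], idx$seqs, mm)
      g <- got[[qi]][order(got[[qi]]$id, got[[qi]]$offset), , drop = FALSE]
      w <- data.frame(id = idx$ids[want$target], offset = want$offset,
                      mismatches = want$mismatches)
      w <- w[order(w$id, w$offset), , drop = FALSE]
      rownames(g) <- rownames(w) <- NULL
      expect_equal(g, w)
    }
  }
})

test_that("host-wins policy resolves ambiguous reads conservatively", {
  # hand-built catalogs: the plant mature also occurs inside a host decoy
  plant <- build_index("pla-x", "ACGTACGTAACCGGTTACGT", k = 8)
  decoy <- paste0("TTTTTTTTTT", "ACGTACGTAACCGGTTACGT", "GGGGGGGGGG")
  host <- build_index(c("hsa-y", "decoy-1"),
                      c("TGCATGCATGCATGCATGCA", decoy), k = 8)
  cfg <- detect_config()
  asg <- assign_reads(c("ACGTACGTAACCGGTTACGT",  # plant + decoy -> host
                        "TGCATGCATGCATGCATGCA",  # host mature
                        "CCCCCCCCGGGGGGGGAAAA"), # nothing
                      plant, host, cfg)
  expect_equal(asg$assignment, c("host", "host", "unassigned"))
  # without the decoy the same read is exogenous
  host2 <- build_index("hsa-y", "TGCATGCATGCATGCATGCA", k = 8)
  asg2 <- assign_reads("ACGTACGTAACCGGTTACGT", plant, host2, cfg)
  expect_equal(asg2$assignment, "plant")
  expect_equal(asg2$mirna_id, "pla-x")
})

test_that("ties among plant ids break by mismatches then lexicographic id", {
  plant <- build_index(c("pla-b", "pla-a"),
                       c("ACGTACGTAACCGGTTACGT", "ACGTACGTAACCGGTTACGA"),
                       k = 8)
  host <- build_index("hsa-z", "TGCATGCATGCATGCATGCA", k = 8)
  # read at 1 mm from both plant records: lexicographically first id wins
  read <- "ACGTACGTAACCGGTTACGC"
  asg <- assign_reads(read, plant, host, detect_config(max_mismatches = 1))
  expect_equal(asg$mirna_id, "pla-a")
  # read exactly equal to pla-b: 0 mm beats 1 mm
  asg2 <- assign_reads("ACGTACGTAACCGGTTACGT", plant, host,
                       detect_config(max_mismatches = 1))
  expect_equal(asg2$mirna_id, "pla-b")
})

test_that("adapter contamination flags shared substrings on either strand", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  recs <- data.frame(
    id = c("contains", "revcomp", "clean"),
    mature = c(paste0("AC", adapter),                       # verbatim
               paste0(revcomp(adapter), "TT"),              # reverse strand
               "ACGTACGTACGTACGTACGTA"),
    stringsAsFactors = FALSE)
  fl <- adapter_contamination_check(recs, adapter)
  expect_true(fl[["contains"]])
  expect_true(fl[["revcomp"]])
  expect_false(fl[["clean"]])
  # random catalog vs the standard adapter: nothing flagged
  refs <- small_refs()
  fl2 <- adapter_contamination_check(
    data.frame(id = refs$plant$id, mature = refs$plant$mature), adapter)
  expect_false(any(fl2))
})

test_that("quantification conserves totals and recovers ground truth", {
  refs <- small_refs()
  idx <- indexes_for(refs)
  cfg <- detect_config()
  # empty input: all-zero profile
  p0 <- quantify(character(0), idx$plant, idx$host, cfg, "empty")
  expect_true(all(p0$counts == 0))
  expect_equal(unname(p0$totals["input"]), 0L)
  # error-free sample: plant counts equal ground truth exactly
  scfg <- sim_config(n_samples = 1, reads_per_sample = 4000,
                     ubiquitous_xeno_ids = refs$plant$id[1],
                     ubiquitous_mean_copies = 80, seq_error_rate = 0,
                     rng_seed = 53)
  s <- simulate_sample(refs, scfg, 1)
  pp <- preprocess_sample(s$reads, trim_config(adapter = scfg$adapter))
  prof <- quantify(pp$kept$seq, idx$plant, idx$host, cfg, "s1")
  expect_equal(unname(sum(prof$totals[c("host", "plant", "unassigned")])),
               unname(prof$totals[["input"]]))
  truth <- s$truth$counts
  for (id in refs$plant$id) {
    want <- truth$true_count[truth$mirna_id == id]
    expect_equal(prof$counts[[id]], if (length(want)) want else 0L)
  }
  # host-only sample: zero plant assignments
  scfg0 <- sim_config(n_samples = 1, reads_per_sample = 3000,
                      xeno_fraction_mean = 0, rng_seed = 59)
  s0 <- simulate_sample(refs, scfg0, 1)
  pp0 <- preprocess_sample(s0$reads, trim_config(adapter = scfg0$adapter))
  prof0 <- quantify(pp0$kept$seq, idx$plant, idx$host, cfg, "s0")
  expect_equal(unname(prof0$totals[["plant"]]), 0L)
})

test_that("raising max_mismatches never lowers plant counts", {
  refs <- small_refs()
  idx <- indexes_for(refs)
  scfg <- sim_config(n_samples = 1, reads_per_sample = 3000,
                     ubiquitous_xeno_ids = refs$plant$id[1],
                     ubiquitous_mean_copies = 100,
                     seq_error_rate = 0.02, rng_seed = 61)
  s <- simulate_sample(refs, scfg, 1)
  pp <- preprocess_sample(s$reads, trim_config(adapter = scfg$adapter))
  counts <- lapply(0:2, function(mm) {
    p <- quantify(pp$kept$seq, idx$plant, idx$host,
                  detect_config(max_mismatches = mm), "s")
    p$counts[refs$plant$id]
  })
  expect_true(all(counts[[2]] >= counts[[1]]))
  expect_true(all(counts[[3]] >= counts[[2]]))
})

test_that("presence calls honor the read-count threshold", {
  refs <- small_refs()
  idx <- indexes_for(refs)
  prof <- quantify(refs$plant$mature[2], idx$plant, idx$host,
                   detect_config(), "one_read")
  expect_identical(presence_call(prof, detect_config(min_reads_presence = 1)),
                   refs$plant$id[2])
  expect_length(presence_call(prof, detect_config(min_reads_presence = 5)), 0)
  # count 4 misses a threshold of 5
  prof4 <- quantify(rep(refs$plant$mature[2], 4), idx$plant, idx$host,
                    detect_config(), "four_reads")
  expect_length(presence_call(prof4, detect_config(min_reads_presence = 5)), 0)
})

test_that("cohort summary reflects spike-in design and ranks abundance", {
  refs <- small_refs()
  idx <- indexes_for(refs)
  spor <- data.frame(id = refs$plant$id[2], prevalence = 0.4, max_copies = 3L)
  scfg <- sim_config(n_samples = 10, reads_per_sample = 2000,
                     ubiquitous_xeno_ids = refs$plant$id[1],
                     ubiquitous_mean_copies = 150, seq_error_rate = 0,
                     xeno_fraction_mean = 0, sporadic_xeno_spec = spor,
                     rng_seed = 67)
  profiles <- lapply(1:10, function(i) {
    s <- simulate_sample(refs, scfg, i)
    pp <- preprocess_sample(s$reads, trim_config(adapter = scfg$adapter))
    quantify(pp$kept$seq, idx$plant, idx$host, detect_config(),
             sprintf("s%02d", i))
  })
  tab <- cohort_summary(profiles, detect_config())
  ub <- tab[tab$mirna_id == refs$plant$id[1], ]
  expect_equal(ub$n_samples_present, 10L)
  # the high-copy spike-in out-counts most host miRNAs
  expect_gte(ub$median_host_quantile, 0.9)
  # miRNAs never simulated are absent from the table
  expect_false(refs$plant$id[5] %in% tab$mirna_id)
})
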