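pileup_fixture <- function(n_pairs = 4000, seed = 141) {
  gp <- fixture_genomes(20000, seed = seed)
  sim <- fixture_mixture(gp, n_pairs = n_pairs, host_fraction = 0,
                         error_rate = 0, seed = seed + 1)
  list(gp = gp, sim = sim)
}

test_that("pileup counts equal a brute-force per-read base extraction", {
  fx <- pileup_fixture(n_pairs = 1500, seed = 131)
  vars <- random_spike_variants(fx$gp, 2, vaf = 0.4, seed = 132)
  reads <- spike_variants(fx$gp, fx$sim$pairs, fx$sim$labels, vars, seed = 133)
  obs <- truth_alignments(list(pairs = reads, labels = fx$sim$labels))
  for (j in seq_len(nrow(vars))) {
    locus <- vars$position[j] + 1L
    pc <- pileup_allele_counts(obs, "graft", locus, min_base_q = 20)
    # brute force: walk every record, extract the covering base
    want <- matrix(0L, 5, 2, dimnames = list(c("A", "C", "G", "T", "N"),
                                             c("fwd", "rev")))
    for (i in seq_len(nrow(obs))) {
      if (!obs$mapped[i] || !obs$primary[i] || obs$duplicate[i]) next
      if (!obs$mapq_available[i] || !obs$proper_pair[i]) next
      off <- locus - obs$position[i] + 1L
      if (off < 1 || off > obs$width[i]) next
      b <- substr(obs$seq[i], off, off)
      if (utf8ToInt(substr(obs$qual[i], off, off)) - 33L < 20) next
      col <- if (obs$strand[i] == "+") "fwd" else "rev"
      want[b, col] <- want[b, col] + 1L
    }
    expect_equal(pc$counts, want)
    expect_equal(pc$depth_after_filters, sum(want))
  }
  # locus with no coverage yields a zero-depth result, not an error
  empty <- pileup_allele_counts(obs, "chrMissing", 50)
  expect_equal(empty$depth_after_filters, 0L)
})

test_that("pileup excludes MAPQ-unavailable, duplicate and low-quality bases", {
  obs <- data.frame(
    id = c("a", "b", "c", "d"), mate = 1L, mapped = TRUE,
    mapq = c(60L, 255L, 60L, 60L),
    mapq_available = c(TRUE, FALSE, TRUE, TRUE),
    proper_pair = TRUE, reference = "graft", position = 100L, strand = "+",
    primary = TRUE, duplicate = c(FALSE, FALSE, TRUE, FALSE), width = 5L,
    seq = c("AAAAA", "AAAAA", "AAAAA", "ACAAA"),
    qual = c("IIIII", "IIIII", "IIIII", "I!III"),  # '!' = Q0
    stringsAsFactors = FALSE)
  class(obs) <- c("xp_alignments", "data.frame")
  pc <- pileup_allele_counts(obs, "graft", 101L)
  # b excluded (MAPQ 255, tallied), c excluded (duplicate), d base below Q20
  expect_equal(pc$depth_after_filters, 1L)
  expect_equal(pc$excluded_mapq_unavailable, 1L)
  with_dup <- pileup_allele_counts(obs, "graft", 101L, use_dedup = FALSE)
  expect_equal(with_dup$depth_after_filters, 2L)
})

test_that("Fisher strand score matches stats::fisher.test and enumeration", {
  expect_equal(fisher_strand_phred(c(5, 5, 5, 5)), 0)
  for (k in c(1, 3, 10, 30)) expect_equal(fisher_strand_phred(rep(k, 4)), 0)

  enum <- naive_fisher_phred(c(10, 0, 0, 10))
  expect_equal(fisher_strand_phred(c(10, 0, 0, 10)), enum, tolerance = 1e-9)

  set.seed(21)
  for (i in 1:200) {
    tab <- rpois(4, sample(1:12, 1))
    if (sum(tab) == 0) next
    got <- fisher_strand_phred(tab)
    pref <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    want <- if (pref >= 1 - 1e-12) 0 else min(-10 * log10(pref), 10000)
    expect_equal(got, want, tolerance = 1e-6)
  }
  expect_error(fisher_strand_phred(c(0, 0, 0, 0)), "all-zero")
})

test_that("SNV cluster flagging matches a sliding enumeration oracle", {
  rec <- function(pos, chrom = "c1", ref = "A", alt = "G")
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  trio <- do.call(rbind, lapply(c(100, 104, 108), rec))
  expect_equal(flag_snp_clusters(trio, 3, 10), rep(TRUE, 3))
  duo <- do.call(rbind, lapply(c(100, 105), rec))
  expect_equal(flag_snp_clusters(duo, 3, 10), rep(FALSE, 2))
  spread <- do.call(rbind, lapply(c(100, 105, 110), rec))
  expect_equal(flag_snp_clusters(spread, 3, 10), rep(FALSE, 3))

  set.seed(23)
  pos <- sort(sample(1:2000, 120))
  recs <- do.call(rbind, lapply(pos, rec))
  got <- flag_snp_clusters(recs, 3, 10)
  want <- rep(FALSE, length(pos))
  for (j in seq_len(length(pos) - 2)) {
    if (pos[j + 2] - pos[j] < 10) want[j:(j + 2)] <- TRUE
  }
  expect_equal(got, want)
  expect_error(flag_snp_clusters(recs[c(2, 1), ], 3, 10), "sorted")
  # indels do not participate in the cluster rule
  indel <- rec(104); indel$ref <- "AT"
  mixed <- rbind(rec(100), indel, rec(108))
  expect_equal(flag_snp_clusters(mixed, 3, 10), rep(FALSE, 3))
})

random_variant_table <- function(n, seed) {
  set.seed(seed)
  pos <- sort(sample(1:50000, n))
  v <- variant_records(
    chrom = "c1", pos = pos,
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = sample(c("A", "C", "G", "T"), n, TRUE),
    qual = round(runif(n, 0, 200)),
    depth = sample(0:60, n, TRUE),
    ref_count = 0L, alt_count = 0L,
    ref_fwd = rpois(n, 6), ref_rev = rpois(n, 6),
    alt_fwd = rpois(n, 3), alt_rev = rpois(n, 3))
  same <- v$ref == v$alt
  v$alt[same] <- ifelse(v$ref[same] == "A", "G", "A")
  v$ref_count <- v$ref_fwd + v$ref_rev
  v$alt_count <- v$alt_fwd + v$alt_rev
  v$depth <- pmax(v$depth, v$ref_count + v$alt_count)
  v
}

test_that("hard filters match a brute-force rule reapplication and are idempotent", {
  v <- random_variant_table(300, seed = 27)
  cfg <- filter_config()
  out <- apply_hard_filters(v, cfg)
  expect_identical(out$chrom, v$chrom)

  clus <- flag_snp_clusters(v, cfg$cluster_count, cfg$cluster_window)
  for (i in seq_len(nrow(v))) {
    want <- character(0)
    if (v$depth[i] < 5) want <- c(want, "LowDepth")
    if (v$qual[i] < 50) want <- c(want, "LowQual")
    p <- fisher.test(matrix(c(v$ref_fwd[i], v$ref_rev[i],
                              v$alt_fwd[i], v$alt_rev[i]),
                            2, byrow = TRUE))$p.value
    fs <- if (p >= 1 - 1e-12) 0 else min(-10 * log10(p), 10000)
    if (fs >= 60) want <- c(want, "StrandBias")
    if (clus[i]) want <- c(want, "SnpCluster")
    expect_equal(out$filters[i], paste(want, collapse = ";"))
  }
  twice <- apply_hard_filters(out, cfg)
  expect_identical(twice$filters, out$filters)
  expect_error(apply_hard_filters(data.frame(chrom = "c1")), "missing")
})

test_that("germline subtraction and known-site annotation are exact key joins", {
  s <- random_variant_table(80, seed = 31)
  c0 <- s[0, ]
  expect_equal(nrow(subtract_germline(s, c0)), 80)
  ctl <- s[sample(80, 30), ]
  som <- subtract_germline(s, ctl)
  keys <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
  expect_setequal(keys(som), setdiff(keys(s), keys(ctl)))

  known_tab <- data.frame(chrom = som$chrom[1:10], pos = som$pos[1:10],
                          ref = som$ref[1:10], alt = som$alt[1:10])
  ann <- annotate_known(som, known_tab)
  expect_equal(ann$summary$n_known, 10)
  expect_equal(ann$summary$known_novel_ratio, 10 / (nrow(som) - 10))
  expect_true(all(ann$records$known[1:10]))

  none <- annotate_known(som, known_tab[0, ])
  expect_equal(none$summary$n_known, 0)
  expect_equal(none$summary$known_novel_ratio, 0)
})

test_that("mutation spectrum collapses strands and is complement-invariant", {
  one <- variant_records("c1", 10, "C", "T", 100, 20, 10, 10)
  sp <- mutation_spectrum(one)
  expect_equal(sp$count[sp$class == "G>A/C>T"], 1L)

  # all 12 raw substitutions once -> six classes at 1/6 each
  subs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]
  v12 <- variant_records("c1", seq_len(12) * 100, subs$ref, subs$alt,
                         100, 20, 10, 10)
  sp12 <- mutation_spectrum(v12)
  expect_equal(sp12$count, rep(2L, 6))
  expect_equal(sp12$proportion, rep(1 / 6, 6))

  # involution: complementing every record leaves class counts unchanged
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vc <- v12; vc$ref <- unname(comp[v12$ref]); vc$alt <- unname(comp[v12$alt])
  expect_equal(mutation_spectrum(vc)$count, sp12$count)

  expect_error(mutation_spectrum(variant_records("c1", 1, "A", "A",
                                                 1, 1, 0, 0)), "ref == alt")
})

fake_pileup <- function(depth, alt, alt_base = "G", ref_base = "A") {
  counts <- matrix(0L, 5, 2, dimnames = list(c("A", "C", "G", "T", "N"),
                                             c("fwd", "rev")))
  counts[ref_base, "fwd"] <- as.integer(depth - alt)
  counts[alt_base, "fwd"] <- as.integer(alt)
  structure(list(chrom = "c1", pos = 1L, depth_after_filters = sum(counts),
                 counts = counts, excluded_mapq_unavailable = 0L),
            class = "pileup_counts")
}

test_that("rescue classification follows the AF/depth rule table", {
  cfg <- filter_config()
  expect_equal(rescue_classify("G", fake_pileup(100, 5), cfg),
               "DETECTED_BELOW_THRESHOLD")
  expect_equal(rescue_classify("G", fake_pileup(8, 2), cfg),
               "NOT_DETECTED_LOW_DEPTH")
  expect_equal(rescue_classify("G", fake_pileup(50, 0), cfg),
               "NOT_DETECTED_NO_ALT")
  expect_equal(rescue_classify("G", fake_pileup(100, 30), cfg), "CALLED")

  # exhaustive check against the brute-force rule table
  for (depth in c(5, 9, 10, 11, 50, 100)) {
    for (alt in unique(pmin(depth, c(0, 1, 2, 19, 20, round(depth * 0.5))))) {
      got <- rescue_classify("G", fake_pileup(depth, alt), cfg)
      want <- if (depth < 10) "NOT_DETECTED_LOW_DEPTH"
        else if (alt == 0) "NOT_DETECTED_NO_ALT"
        else if (alt / depth >= 0.2) "CALLED"
        else "DETECTED_BELOW_THRESHOLD"
      expect_equal(got, want)
    }
  }
})

test_that("VCF records round-trip with filters, allele depths and known flags", {
  v <- random_variant_table(40, seed = 37)
  v <- apply_hard_filters(v, filter_config())
  v$known <- c(rep(TRUE, 5), rep(FALSE, 35))
  f <- tempfile(fileext = ".vcf")
  write_vcf_records(v, f)
  back <- read_vcf_records(f)
  expect_equal(back$pos, v$pos)
  expect_equal(back$depth, v$depth)
  expect_equal(back$ref_count, v$ref_count)
  expect_equal(back$alt_count, v$alt_count)
  expect_equal(back$ref_fwd, v$ref_fwd)
  expect_equal(back$filters, v$filters)
  unlink(f)
})

test_that("host-contamination window finds injected host reads exactly", {
  gp <- fixture_genomes(30000, seed = 151)
  sim <- fixture_mixture(gp, n_pairs = 1500, host_fraction = 0,
                         error_rate = 0.001, seed = 152)
  obs <- truth_alignments(sim)
  host_idx <- seed_index(gp$host, genome_id = "host")
  locus <- 15000L
  res <- host_window_check(obs, "graft", locus, host_idx, window = 1000)
  expect_gt(res$reads_examined, 0)
  expect_equal(res$reads_host_alignable, 0L)

  # inject k reads copied from the host genome at graft coordinates
  k <- 5
  injected <- obs[obs$position >= locus - 500 & obs$position <= locus + 500, ][1:k, ]
  injected$id <- paste0("HOSTREAD", seq_len(k))
  injected$seq <- substring(gp$host, injected$position,
                            injected$position + injected$width - 1L)
  both <- rbind(obs, injected)
  class(both) <- c("xp_alignments", "data.frame")
  res2 <- host_window_check(both, "graft", locus, host_idx, window = 1000)
  expect_equal(res2$reads_host_alignable, k)
  expect_equal(res2$reads_examined, res$reads_examined + k)

  empty <- host_window_check(obs, "graft", 10000000L, host_idx)
  expect_true(empty$empty_window)
})
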