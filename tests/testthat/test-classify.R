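test_that("partition algebra matches brute-force membership scanning", {
  expect_setequal(partition_ids(c("a", "b"), "a", character(0))$graft_specific, "a")
  expect_setequal(partition_ids(c("a", "b"), "a", "a")$common, "a")

  set.seed(3)
  universe <- sprintf("id%05d", 1:2000)
  g <- sample(universe, 900)
  h <- sample(universe, 700)
  part <- partition_ids(universe, g, h)
  for (id in universe) {
    ing <- id %in% g; inh <- id %in% h
    want <- if (ing && inh) "common" else if (ing) "graft_specific"
            else if (inh) "host_specific" else "unmapped"
    expect_true(id %in% part[[want]])
  }
  # disjoint cover
  expect_equal(sum(lengths(part[1:4])), 2000)
  expect_error(partition_ids(universe[1:10], "id99999", character(0)),
               "outside")
})

test_that("swapping graft and host inputs swaps the specific sets", {
  set.seed(4)
  universe <- sprintf("x%04d", 1:500)
  g <- sample(universe, 200); h <- sample(universe, 150)
  p1 <- partition_ids(universe, g, h)
  p2 <- partition_ids(universe, h, g)
  expect_setequal(p1$graft_specific, p2$host_specific)
  expect_setequal(p1$host_specific, p2$graft_specific)
  expect_setequal(p1$common, p2$common)
  expect_setequal(p1$unmapped, p2$unmapped)
})

make_obs <- function(id, mate, mapped = TRUE, mapq = 40L, proper = TRUE,
                     mapq_available = TRUE, primary = TRUE) {
  data.frame(id = id, mate = mate, mapped = mapped, mapq = mapq,
             mapq_available = mapq_available, proper_pair = proper,
             reference = ifelse(mapped, "ref", NA), position = 1L,
             strand = ifelse(mapped, "+", NA), primary = primary,
             duplicate = FALSE, width = 101L, stringsAsFactors = FALSE)
}

test_that("pair-unit mapping requires both mates to pass the MAPQ gate", {
  cfg <- classify_config(min_mapq = 20)
  both <- rbind(make_obs("p1", 1L, mapq = 40L), make_obs("p1", 2L, mapq = 42L))
  expect_equal(collect_mapped_ids(both, cfg), "p1")

  one_unmapped <- rbind(make_obs("p2", 1L),
                        make_obs("p2", 2L, mapped = FALSE, proper = FALSE))
  expect_equal(length(collect_mapped_ids(one_unmapped, cfg)), 0)

  low <- rbind(make_obs("p3", 1L, mapq = 19L), make_obs("p3", 2L, mapq = 50L))
  expect_equal(length(collect_mapped_ids(low, cfg)), 0)

  # MAPQ-unavailable handling is configurable
  unavail <- rbind(make_obs("p4", 1L, mapq = 255L, mapq_available = FALSE),
                   make_obs("p4", 2L, mapq = 50L))
  expect_equal(collect_mapped_ids(unavail, cfg), "p4")
  cfg2 <- classify_config(treat_mapq_unavailable_as = "unmapped")
  expect_equal(length(collect_mapped_ids(unavail, cfg2)), 0)

  # secondary records are ignored; >2 primary mate records is malformed
  with_secondary <- rbind(both, make_obs("p1", 1L, primary = FALSE))
  expect_equal(collect_mapped_ids(with_secondary, cfg), "p1")
  expect_error(collect_mapped_ids(rbind(both, make_obs("p1", 1L)), cfg),
               "malformed")
})

test_that("pair gating equals a record-wise reapplication of the filter", {
  set.seed(11)
  n <- 400
  obs <- do.call(rbind, lapply(1:n, function(i) {
    rbind(make_obs(sprintf("f%04d", i), 1L,
                   mapped = runif(1) < 0.9, mapq = sample(0:60, 1),
                   proper = runif(1) < 0.85),
          make_obs(sprintf("f%04d", i), 2L,
                   mapped = runif(1) < 0.9, mapq = sample(0:60, 1),
                   proper = runif(1) < 0.85))
  }))
  cfg <- classify_config(min_mapq = 20, require_proper_pair = TRUE)
  got <- sort(collect_mapped_ids(obs, cfg))
  want <- character(0)
  for (id in unique(obs$id)) {
    sub <- obs[obs$id == id, ]
    pass <- sub$mapped & sub$proper_pair & sub$mapq >= 20
    if (nrow(sub) == 2 && all(pass)) want <- c(want, id)
  }
  expect_equal(got, sort(want))
})

test_that("partition is invariant under permutation of alignment records", {
  gp <- fixture_genomes(20000, seed = 81)
  sim <- fixture_mixture(gp, n_pairs = 500, seed = 82)
  gi <- seed_index(gp$graft, genome_id = "graft")
  hi <- seed_index(gp$host, genome_id = "host")
  og <- micro_align_library(sim$pairs, gi)
  oh <- micro_align_library(sim$pairs, hi)
  cfg <- classify_config()
  p1 <- partition_ids(sim$pairs$id,
                      collect_mapped_ids(og, cfg), collect_mapped_ids(oh, cfg))
  set.seed(1)
  og2 <- og[sample(nrow(og)), ]
  oh2 <- oh[sample(nrow(oh)), ]
  p2 <- partition_ids(sim$pairs$id,
                      collect_mapped_ids(og2, cfg), collect_mapped_ids(oh2, cfg))
  for (s in c("graft_specific", "host_specific", "common", "unmapped"))
    expect_setequal(p1[[s]], p2[[s]])
})

test_that("sequential align/realign/subtract equals the direct set algebra", {
  gp <- fixture_genomes(25000, seed = 85)
  for (hf in c(0.05, 0.4)) {
    sim <- fixture_mixture(gp, n_pairs = 800, host_fraction = hf,
                           seed = 86 + round(100 * hf))
    og <- micro_align_library(sim$pairs, seed_index(gp$graft, genome_id = "graft"))
    oh <- micro_align_library(sim$pairs, seed_index(gp$host, genome_id = "host"))
    cfg <- classify_config()
    direct <- partition_ids(sim$pairs$id,
                            intersect(collect_mapped_ids(og, cfg), sim$pairs$id),
                            intersect(collect_mapped_ids(oh, cfg), sim$pairs$id))
    sequential <- partition_sequential(sim$pairs$id, og, oh, cfg)
    for (s in c("graft_specific", "host_specific", "common", "unmapped"))
      expect_setequal(direct[[s]], sequential[[s]])
  }
})

test_that("per-category FASTQ outputs conserve and reconstruct the universe", {
  gp <- fixture_genomes(20000, seed = 91)
  sim <- fixture_mixture(gp, n_pairs = 300, seed = 92)
  og <- micro_align_library(sim$pairs, seed_index(gp$graft, genome_id = "graft"))
  oh <- micro_align_library(sim$pairs, seed_index(gp$host, genome_id = "host"))
  res <- classify_library(sim$pairs, og, oh)
  outdir <- tempfile("split")
  counts <- split_reads(sim$pairs, res$partition, outdir)
  expect_equal(unname(counts),
               unname(vapply(res$partition[1:4], length, integer(1))))
  ids <- character(0)
  for (cat in names(counts)) {
    f1 <- file.path(outdir, paste0(cat, "_1.fastq"))
    back <- read_fastq_pairs(f1, sub("_1", "_2", f1))
    expect_setequal(back$id, res$partition[[cat]])
    ids <- c(ids, back$id)
  }
  expect_setequal(ids, sim$pairs$id)
  unlink(outdir, recursive = TRUE)
})

test_that("partition summaries report category percentages of the universe", {
  universe <- sprintf("u%03d", 1:100)
  part <- partition_ids(universe, universe[1:84], universe[81:95])
  s <- summarize_partition(part, "wgs")
  expect_equal(s$count, c(80L, 11L, 4L, 5L))
  expect_equal(s$percent, c(80.0, 11.0, 4.0, 5.0))
  expect_lt(abs(sum(s$percent) - 100), 0.2)
  expect_error(summarize_partition(partition_ids(character(0), character(0),
                                                 character(0))), "empty")
})

test_that("duplicate marking flags exact coordinate copies only", {
  gp <- fixture_genomes(20000, seed = 95)
  sim <- fixture_mixture(gp, n_pairs = 200, error_rate = 0, seed = 96)
  obs <- truth_alignments(sim)
  base <- mark_duplicates(obs)
  n_base <- length(unique(base$id[base$duplicate]))

  # inject exact copies of k fragments under fresh ids
  k <- 7
  set.seed(97)
  pick <- sample(unique(obs$id), k)
  copies <- obs[obs$id %in% pick, ]
  copies$id <- paste0(copies$id, "_dup")
  marked <- mark_duplicates(rbind(obs, copies))
  expect_equal(length(unique(marked$id[marked$duplicate])), n_base + k)

  # fragments at distinct coordinates stay unflagged
  distinct <- obs[obs$id %in% setdiff(unique(obs$id),
                                      unique(base$id[base$duplicate])), ]
  expect_false(any(mark_duplicates(distinct)$duplicate))
})
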