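# Deterministic fixtures shared across test files; everything is generated
# in code at test time.

fixture_genomes <- function(length = 20000, divergence = 0.12, seed = 101)
  evolve_genomes(length, divergence, seed = seed)

fixture_mixture <- function(gp, n_pairs = 2000, host_fraction = 0.2,
                            error_rate = 0, seed = 202, ...)
  simulate_mixture(gp, sim_params(n_pairs, host_fraction,
                                  error_rate = error_rate, seed = seed, ...))

# Perfect-alignment observations derived from simulator truth. The pileup,
# duplicate-marking and rescue layers consume alignment observations; building
# them straight from the truth labels decouples those tests from the aligner.
truth_alignments <- function(sim, origin = "GRAFT", reference = "graft") {
  keep <- sim$labels$origin == origin
  lab <- sim$labels[keep, , drop = FALSE]
  pr <- sim$pairs[keep, , drop = FALSE]
  rl <- nchar(pr$seq1[1])
  n <- nrow(lab)
  plus <- lab$source_strand == "+"
  left_pos <- lab$source_position
  right_pos <- lab$source_position + lab$insert - rl
  pos1 <- ifelse(plus, left_pos, right_pos)
  pos2 <- ifelse(plus, right_pos, left_pos)
  strand1 <- ifelse(plus, "+", "-")
  strand2 <- ifelse(plus, "-", "+")
  seq1 <- ifelse(plus, pr$seq1, revcomp(pr$seq1))
  seq2 <- ifelse(plus, revcomp(pr$seq2), pr$seq2)
  build <- function(mate, pos, strand, sq, qual)
    data.frame(id = pr$id, mate = mate, mapped = TRUE, mapq = 60L,
               mapq_available = TRUE, proper_pair = TRUE,
               reference = reference, position = as.integer(pos),
               strand = strand, primary = TRUE, duplicate = FALSE,
               width = rl, seq = sq, qual = qual, stringsAsFactors = FALSE)
  d1 <- build(1L, pos1, strand1, seq1, pr$qual1)
  d2 <- build(2L, pos2, strand2, seq2, pr$qual2)
  out <- rbind(d1, d2)[rep(seq_len(n), each = 2L) + c(0L, n), ]
  rownames(out) <- NULL
  class(out) <- c("xp_alignments", "data.frame")
  out
}

# Exhaustive left-to-right window scan, the independent trimming oracle.
naive_trim_point <- function(scores, window, min_q) {
  n <- length(scores)
  if (n >= window) {
    for (i in seq_len(n - window + 1L)) {
      if (mean(scores[i:(i + window - 1L)]) < min_q) return(i - 1L)
    }
  }
  n
}

# Random reads with a planted low-quality tail.
random_tailed_reads <- function(n, seed) {
  set.seed(seed)
  len <- sample(30:140, n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    good <- sample(0:len[i], 1L)
    q <- c(sample(25:40, good, replace = TRUE),
           sample(0:24, len[i] - good, replace = TRUE))
    list(seq = paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
                     collapse = ""),
         qual = intToUtf8(q + 33L), scores = q)
  })
}

# Average-rank (midrank) computed from first principles.
naive_average_rank <- function(v)
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))

# Two-sided Fisher p by explicit enumeration of every table with the
# observed margins, probabilities from binomial coefficients (independent of
# the package's stats::dhyper route).
naive_fisher_phred <- function(tab) {
  R <- tab[1] + tab[2]; A <- tab[3] + tab[4]; FW <- tab[1] + tab[3]
  N <- R + A
  if (R == 0 || A == 0 || FW == 0 || tab[2] + tab[4] == 0) return(0)
  ks <- max(0, FW - A):min(R, FW)
  prob <- choose(R, ks) * choose(A, FW - ks) / choose(N, FW)
  p_obs <- choose(R, tab[1]) * choose(A, FW - tab[1]) / choose(N, FW)
  p <- sum(prob[prob <= p_obs * (1 + 1e-7)])
  if (p >= 1 - 1e-12) return(0)
  min(-10 * log10(p), 10000)
}
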