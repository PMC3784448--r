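BASES <- c("A", "C", "G", "T")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# replacement base under a transition/transversion-weighted exchange model;
# transition_weight 1 gives the uniform (Jukes-Cantor-like) special case
draw_substitutions <- function(ref_chars, transition_weight = 1) {
  n <- length(ref_chars)
  if (!n) return(character(0))
  alts <- vapply(ref_chars, function(b) {
    others <- setdiff(BASES, b)
    w <- ifelse(others == TRANSITION[[b]], transition_weight, 1)
    sample(others, 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
  alts
}

#' Evolve a homologous graft/host genome pair from a common ancestor
#'
#' Draws a uniform-random ancestor and applies independent substitutions to
#' the two lineages such that the expected pairwise divergence at
#' corresponding sites equals `divergence` (under the uniform exchange
#' model). Optionally applies small indels (geometric lengths) to the host
#' lineage, tracked in the site-correspondence map. The pair is a
#' human/mouse-like stand-in at configurable divergence, not a biological
#' model.
#'
#' @param ancestor_length ancestor length in bp (>= 1000).
#' @param divergence expected pairwise divergence per site, in [0, 0.75).
#' @param indel_rate per-site probability of starting an indel in the host
#'   lineage (default 0).
#' @param seed integer seed; the result is a pure function of the arguments.
#' @param transition_weight relative weight of the transition substitution
#'   over each transversion (default 1 = uniform).
#' @return a `genome_pair` list: `graft`, `host` (strings), `divergence`,
#'   `correspondence` (integer vector mapping 0-based graft position to
#'   0-based host position, NA where deleted), `seed`.
#' @export
evolve_genomes <- function(ancestor_length, divergence, indel_rate = 0,
                           seed = 1L, transition_weight = 1) {
  if (ancestor_length < 1000L) stop("ancestor_length must be >= 1000")
  if (divergence < 0 || divergence >= 0.75)
    stop("divergence must be in [0, 0.75)")
  set.seed(seed)
  L <- as.integer(ancestor_length)
  anc <- sample(BASES, L, replace = TRUE)

  # per-lineage substitution probability q with pairwise divergence d:
  # d = 2 q (1 - q) + (2/3) q^2  =>  q = (2 - sqrt(4 - 16 d / 3)) / (8/3)
  q <- (2 - sqrt(4 - 16 * divergence / 3)) / (8 / 3)
  mutate_lineage <- function(chars) {
    hit <- which(runif(L) < q)
    chars[hit] <- draw_substitutions(chars[hit], transition_weight)
    chars
  }
  graft_chars <- mutate_lineage(anc)
  host_chars <- mutate_lineage(anc)

  if (indel_rate > 0) {
    is_del <- runif(L) < indel_rate / 2
    is_ins <- runif(L) < indel_rate / 2
    del_len <- integer(L); del_len[is_del] <- stats::rgeom(sum(is_del), 0.5) + 1L
    keep <- rep(TRUE, L)
    for (i in which(is_del)) {           # short deletions, may overlap ends
      keep[i:min(L, i + del_len[i] - 1L)] <- FALSE
    }
    ins_str <- character(L)
    n_ins <- sum(is_ins)
    if (n_ins) {
      lens <- stats::rgeom(n_ins, 0.5) + 1L
      ins_str[is_ins] <- vapply(lens, function(l)
        paste(sample(BASES, l, replace = TRUE), collapse = ""), character(1))
    }
    ins_len <- nchar(ins_str)
    kept_before <- cumsum(keep) - keep
    ins_upto <- cumsum(ins_len)          # insertions placed before site i
    corr <- ifelse(keep, kept_before + ins_upto, NA_integer_)
    host_seq <- paste(paste0(ins_str, ifelse(keep, host_chars, "")),
                      collapse = "")
  } else {
    corr <- 0:(L - 1L)
    host_seq <- paste(host_chars, collapse = "")
  }

  structure(list(graft = paste(graft_chars, collapse = ""),
                 host = host_seq,
                 divergence = divergence,
                 correspondence = as.integer(corr),
                 seed = seed),
            class = "genome_pair")
}

#' @export
print.genome_pair <- function(x, ...) {
  cat("genome_pair: graft", nchar(x$graft), "bp / host", nchar(x$host),
      "bp, divergence", x$divergence, "\n")
  invisible(x)
}

#' Simulation parameters for a mixed-species paired-end library
#'
#' Defaults follow a typical short-insert Illumina DNA library: 101 nt
#' paired reads on 200 bp fragments.
#'
#' @param n_pairs number of fragments to simulate.
#' @param host_fraction probability that a fragment originates from the host
#'   genome.
#' @param read_length read length in nt (default 101).
#' @param insert_mean,insert_sd fragment-length distribution (normal,
#'   truncated at `read_length`); defaults 200 and 30 nt.
#' @param error_rate independent per-base substitution error probability.
#' @param seed integer seed.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_pairs, host_fraction, read_length = 101L,
                       insert_mean = 200L, insert_sd = 30,
                       error_rate = 0.001, seed = 1L) {
  stopifnot(host_fraction >= 0, host_fraction <= 1,
            read_length <= insert_mean)
  structure(list(n_pairs = as.integer(n_pairs),
                 host_fraction = host_fraction,
                 read_length = as.integer(read_length),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = insert_sd, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "sim_params")
}

apply_sequencing_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  rl <- nchar(seqs)
  stopifnot(length(unique(rl)) <= 1L)
  rl <- rl[1]
  total <- length(seqs) * rl
  n_err <- rbinom(1L, total, error_rate)
  if (n_err == 0L) return(seqs)
  at <- sample.int(total, n_err)
  ridx <- (at - 1L) %/% rl + 1L
  off <- (at - 1L) %% rl + 1L
  for (j in seq_len(n_err)) {
    i <- ridx[j]
    cur <- substr(seqs[i], off[j], off[j])
    substr(seqs[i], off[j], off[j]) <- sample(setdiff(BASES, cur), 1L)
  }
  seqs
}

#' Simulate a mixed graft/host paired-end library with truth labels
#'
#' Each fragment's origin is Bernoulli(`host_fraction`); its start is
#' uniform on the source genome; insert length is normal truncated at the
#' read length; the two mates are read inward from the fragment ends
#' (forward-reverse orientation), with mate 1 at the fragment's 5' end on a
#' uniformly chosen fragment strand. Sequencing errors are independent
#' per-base substitutions. Fragment ids (`FRAG000001`, ...) encode nothing
#' about origin; truth is carried in the separate label table.
#'
#' @param pair a [evolve_genomes()] `genome_pair`.
#' @param params a [sim_params()].
#' @return list with `pairs` (an `xp_pairs` data.frame) and `labels`
#'   (data.frame: `fragment_id`, `origin` GRAFT/HOST, `source_position`
#'   1-based leftmost fragment coordinate, `source_strand`, `insert`).
#' @export
simulate_mixture <- function(pair, params) {
  set.seed(params$seed)
  n <- params$n_pairs
  rl <- params$read_length
  glen <- nchar(pair$graft)
  hlen <- nchar(pair$host)
  stopifnot(glen > params$insert_mean + 6 * params$insert_sd,
            hlen > params$insert_mean + 6 * params$insert_sd)

  origin <- ifelse(runif(n) < params$host_fraction, "HOST", "GRAFT")
  insert <- as.integer(round(rnorm(n, params$insert_mean, params$insert_sd)))
  insert <- pmax(insert, rl)
  src_len <- ifelse(origin == "HOST", hlen, glen)
  insert <- pmin(insert, src_len)
  start <- as.integer(floor(runif(n) * (src_len - insert + 1))) + 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)

  left <- character(n); right <- character(n)
  for (g in c("GRAFT", "HOST")) {
    idx <- which(origin == g)
    if (!length(idx)) next
    genome <- if (g == "GRAFT") pair$graft else pair$host
    s <- start[idx]; ins <- insert[idx]
    left[idx] <- substring(genome, s, s + rl - 1L)
    right[idx] <- substring(genome, s + ins - rl, s + ins - 1L)
  }
  # mate1 reads the fragment's 5' end: forward-left on '+', reverse-right on '-'
  seq1 <- ifelse(strand == "+", left, .xp_revcomp(right))
  seq2 <- ifelse(strand == "+", .xp_revcomp(right), left)
  seq1 <- apply_sequencing_errors(seq1, params$error_rate)
  seq2 <- apply_sequencing_errors(seq2, params$error_rate)

  qual <- strrep("D", rl)  # constant Phred 35
  ids <- sprintf("FRAG%06d", seq_len(n))
  labels <- data.frame(fragment_id = ids, origin = origin,
                       source_position = start, source_strand = strand,
                       insert = insert, stringsAsFactors = FALSE)
  list(pairs = new_read_pairs(ids, seq1, qual, seq2, qual), labels = labels)
}

#' Spike subclonal variants into simulated graft reads
#'
#' For each variant, every graft-origin fragment whose mates cover the site
#' carries the alternative allele with probability `vaf`; the carrier draw
#' is made once per fragment so both mates agree. Read bases are edited in
#' sequencing orientation (complemented on reverse-oriented mates).
#'
#' @param pair the source `genome_pair`.
#' @param reads `xp_pairs` from [simulate_mixture()].
#' @param labels matching truth labels.
#' @param variants data.frame with columns `position` (0-based graft
#'   coordinate), `ref_base`, `alt_base`, `vaf`.
#' @param seed integer seed for the carrier draws.
#' @return the edited `xp_pairs`.
#' @export
spike_variants <- function(pair, reads, labels, variants, seed = 1L) {
  set.seed(seed)
  rl <- nchar(reads$seq1[1])
  stopifnot(nrow(reads) == nrow(labels),
            all(reads$id == labels$fragment_id))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (v in seq_len(nrow(variants))) {
    P <- variants$position[v] + 1L  # 1-based
    ref <- variants$ref_base[v]; alt <- variants$alt_base[v]
    if (alt == ref) stop("alt_base equals ref_base")
    if (substr(pair$graft, P, P) != ref)
      stop("variant ref_base does not match graft genome at position ",
           variants$position[v])
    s <- labels$source_position; ins <- labels$insert
    in_left <- P >= s & P <= s + rl - 1L
    in_right <- P >= s + ins - rl & P <= s + ins - 1L
    cover <- which(labels$origin == "GRAFT" & (in_left | in_right))
    if (!length(cover)) next
    carrier <- cover[runif(length(cover)) < variants$vaf[v]]
    for (i in carrier) {
      # left window holds mate1 on '+' fragments (forward) and mate2 on '-'
      if (in_left[i]) {
        off <- P - s[i] + 1L
        if (labels$source_strand[i] == "+") {
          substr(reads$seq1[i], off, off) <- alt
        } else {
          substr(reads$seq2[i], off, off) <- alt
        }
      }
      if (in_right[i]) {
        off_rc <- (s[i] + ins[i] - 1L) - P + 1L
        if (labels$source_strand[i] == "+") {
          substr(reads$seq2[i], off_rc, off_rc) <- comp[[alt]]
        } else {
          substr(reads$seq1[i], off_rc, off_rc) <- comp[[alt]]
        }
      }
    }
  }
  reads
}

#' Draw a random set of spike-in variants
#'
#' Positions are sampled without replacement (with a minimum spacing so
#' variants do not interact); the alternative allele is the transition
#' partner of the reference with probability `transition_prob`, otherwise a
#' uniformly chosen transversion.
#'
#' @param genome graft genome string (or `genome_pair`).
#' @param n number of variants.
#' @param vaf allele fraction given to every variant (scalar or vector).
#' @param transition_prob probability the substitution is a transition.
#' @param min_spacing minimum distance between variant sites (default 200).
#' @param seed integer seed.
#' @return data.frame: `position` (0-based), `ref_base`, `alt_base`, `vaf`.
#' @export
random_spike_variants <- function(genome, n, vaf, transition_prob = 0.5,
                                  min_spacing = 200L, seed = 1L) {
  if (inherits(genome, "genome_pair")) genome <- genome$graft
  set.seed(seed)
  L <- nchar(genome)
  slots <- seq(min_spacing, L - min_spacing, by = min_spacing)
  if (length(slots) < n) stop("genome too short for ", n, " spaced variants")
  pos1 <- sort(sample(slots, n))          # 1-based
  ref <- substring(genome, pos1, pos1)
  is_ts <- runif(n) < transition_prob
  alt <- character(n)
  alt[is_ts] <- TRANSITION[ref[is_ts]]
  tv_choices <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
  alt[!is_ts] <- vapply(ref[!is_ts],
                        function(b) sample(tv_choices[[b]], 1L),
                        character(1), USE.NAMES = FALSE)
  data.frame(position = pos1 - 1L, ref_base = ref, alt_base = alt,
             vaf = vaf, stringsAsFactors = FALSE)
}

#' Generate a non-overlapping gene model
#'
#' Lays genes left to right with random intergenic gaps; each gene has a
#' random number of exons with random exon/intron lengths. Output is valid
#' BED12 territory: 0-based half-open, sorted non-overlapping blocks.
#'
#' @param genome_length length of the target sequence.
#' @param n_genes number of genes.
#' @param exons_per_gene length-2 integer range (default `c(1, 4)`).
#' @param exon_length,intron_length,intergenic length-2 ranges in nt.
#' @param chrom reference name (default "ref").
#' @param seed integer seed.
#' @return a `gene_model` data.frame: `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open gene span), `strand`, `exonic_length`, and
#'   list-columns `exon_starts`/`exon_ends` (0-based half-open, genome
#'   coordinates).
#' @export
generate_gene_model <- function(genome_length, n_genes,
                                exons_per_gene = c(1L, 4L),
                                exon_length = c(150L, 400L),
                                intron_length = c(60L, 200L),
                                intergenic = c(200L, 600L),
                                chrom = "ref", seed = 1L) {
  set.seed(seed)
  rint <- function(rng) {               # guard the length-1 sample() trap
    if (rng[1] == rng[2]) return(as.integer(rng[1]))
    sample(seq(rng[1], rng[2]), 1L)
  }
  cursor <- rint(intergenic)
  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    n_ex <- rint(exons_per_gene)
    ex_len <- vapply(seq_len(n_ex), function(i) rint(exon_length), integer(1))
    in_len <- if (n_ex > 1L)
      vapply(seq_len(n_ex - 1L), function(i) rint(intron_length), integer(1))
    else integer(0)
    starts <- cursor + cumsum(c(0L, head(ex_len, -1L) + in_len))
    ends <- starts + ex_len
    if (ends[n_ex] > genome_length)
      stop("gene model does not fit in genome of length ", genome_length)
    genes[[g]] <- list(gene_id = sprintf("GENE%04d", g), chrom = chrom,
                       start = starts[1], end = ends[n_ex],
                       strand = sample(c("+", "-"), 1L),
                       exon_starts = starts, exon_ends = ends)
    cursor <- ends[n_ex] + rint(intergenic)
  }
  model <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    chrom = chrom,
    start = vapply(genes, `[[`, numeric(1), "start"),
    end = vapply(genes, `[[`, numeric(1), "end"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  model$exon_starts <- lapply(genes, function(g) as.integer(g$exon_starts))
  model$exon_ends <- lapply(genes, function(g) as.integer(g$exon_ends))
  model$exonic_length <- vapply(seq_len(n_genes), function(g)
    sum(model$exon_ends[[g]] - model$exon_starts[[g]]), integer(1))
  class(model) <- c("gene_model", "data.frame")
  model
}

#' Simulate an exonic (RNA-seq-like) graft read library
#'
#' Fragments are drawn only from exonic intervals of the gene model, with
#' per-gene abundance weights (Dirichlet-drawn when not supplied). This is a
#' deliberately reduced transcript model — no splice junctions — sufficient
#' to exercise exon-overlap counting and RPKM.
#'
#' @param genome source genome string (or `genome_pair`, graft side used).
#' @param model a [generate_gene_model()] `gene_model`.
#' @param n_pairs number of fragments.
#' @param read_length,insert_mean,insert_sd,error_rate as [sim_params()],
#'   with shorter defaults suited to exon-sized intervals.
#' @param weights optional per-gene abundance weights (recycled/normalized).
#' @param seed integer seed.
#' @return list with `pairs`, `labels` (including `gene_id` truth), and
#'   `weights` used.
#' @export
simulate_rnaseq <- function(genome, model, n_pairs, read_length = 60L,
                            insert_mean = 120L, insert_sd = 10,
                            error_rate = 0, weights = NULL, seed = 1L) {
  if (inherits(genome, "genome_pair")) genome <- genome$graft
  set.seed(seed)
  n_genes <- nrow(model)
  if (is.null(weights)) weights <- rgamma(n_genes, shape = 1)
  weights <- weights / sum(weights)
  gene_idx <- sample.int(n_genes, n_pairs, replace = TRUE, prob = weights)
  insert <- pmax(as.integer(round(rnorm(n_pairs, insert_mean, insert_sd))),
                 read_length)
  start <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    g <- gene_idx[i]
    es <- model$exon_starts[[g]]; ee <- model$exon_ends[[g]]
    fit <- which(ee - es >= insert[i])
    if (!length(fit)) {          # shrink the fragment into the widest exon
      fit <- which.max(ee - es)
      insert[i] <- ee[fit] - es[fit]
    }
    e <- if (length(fit) > 1L) sample(fit, 1L) else fit
    start[i] <- es[e] + sample.int(ee[e] - es[e] - insert[i] + 1L, 1L)  # 1-based
  }
  strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
  left <- substring(genome, start, start + read_length - 1L)
  right <- substring(genome, start + insert - read_length, start + insert - 1L)
  seq1 <- ifelse(strand == "+", left, .xp_revcomp(right))
  seq2 <- ifelse(strand == "+", .xp_revcomp(right), left)
  seq1 <- apply_sequencing_errors(seq1, error_rate)
  seq2 <- apply_sequencing_errors(seq2, error_rate)
  qual <- strrep("D", read_length)
  ids <- sprintf("FRAG%06d", seq_len(n_pairs))
  labels <- data.frame(fragment_id = ids, origin = "GRAFT",
                       source_position = start, source_strand = strand,
                       insert = insert, gene_id = model$gene_id[gene_idx],
                       stringsAsFactors = FALSE)
  list(pairs = new_read_pairs(ids, seq1, qual, seq2, qual),
       labels = labels, weights = weights)
}

#' Write / read the simulator's text outputs
#'
#' FASTA goes through Biostrings; truth labels and spike-variant tables are
#' plain TSV.
#'
#' @param pair a `genome_pair`.
#' @param graft_path,host_path destination FASTA paths.
#' @return invisibly, the paths written.
#' @export
write_genome_pair <- function(pair, graft_path, host_path) {
  g <- Biostrings::DNAStringSet(c(graft = pair$graft))
  h <- Biostrings::DNAStringSet(c(host = pair$host))
  Biostrings::writeXStringSet(g, graft_path)
  Biostrings::writeXStringSet(h, host_path)
  invisible(c(graft_path, host_path))
}

#' @rdname write_genome_pair
#' @param labels a truth-label data.frame.
#' @param path destination TSV.
#' @export
write_truth_labels <- function(labels, path) {
  write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_pair
#' @export
read_truth_labels <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
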