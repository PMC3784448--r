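#' Write a gene model as BED12
#'
#' @param model a `gene_model` data.frame (see [generate_gene_model()]).
#' @param path destination BED12 path.
#' @return invisibly, the path.
#' @export
write_bed12 <- function(model, path) {
  lines <- vapply(seq_len(nrow(model)), function(i) {
    es <- model$exon_starts[[i]]; ee <- model$exon_ends[[i]]
    paste(model$chrom[i], format(model$start[i], scientific = FALSE),
          format(model$end[i], scientific = FALSE), model$gene_id[i], 0L,
          model$strand[i],
          format(model$start[i], scientific = FALSE),
          format(model$end[i], scientific = FALSE), "0",
          length(es),
          paste0(paste(ee - es, collapse = ","), ","),
          paste0(paste(es - model$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED12 gene model
#'
#' Parsed through rtracklayer; blocks become 0-based half-open exon
#' intervals in genome coordinates.
#'
#' @param path BED12 path.
#' @return a `gene_model` data.frame (same shape as
#'   [generate_gene_model()]).
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  n <- length(gr)
  start0 <- GenomicRanges::start(gr) - 1L
  blocks <- gr$blocks
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    b <- blocks[[i]]  # 1-based, relative to the gene start
    exon_starts[[i]] <- start0[i] + IRanges::start(b) - 1L
    exon_ends[[i]] <- start0[i] + IRanges::end(b)
  }
  model <- data.frame(
    gene_id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  model$strand[model$strand == "*"] <- "+"
  model$exon_starts <- exon_starts
  model$exon_ends <- exon_ends
  model$exonic_length <- vapply(seq_len(n), function(i)
    sum(exon_ends[[i]] - exon_starts[[i]]), integer(1))
  class(model) <- c("gene_model", "data.frame")
  model
}

model_exon_granges <- function(model) {
  n_ex <- lengths(model$exon_starts)
  GenomicRanges::GRanges(
    seqnames = rep(model$chrom, n_ex),
    ranges = IRanges::IRanges(
      start = unlist(model$exon_starts) + 1L,   # to 1-based closed
      end = unlist(model$exon_ends)),
    gene_id = rep(model$gene_id, n_ex))
}

fragment_spans <- function(alignments) {
  a <- alignments[alignments$primary & alignments$mapped, , drop = FALSE]
  if (!nrow(a))
    return(data.frame(id = character(), reference = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  ends <- a$position + a$width - 1L
  lo <- tapply(a$position, a$id, min)
  hi <- tapply(ends, a$id, max)
  ref <- tapply(a$reference, a$id, `[`, 1L)
  ids <- names(lo)
  data.frame(id = ids, reference = as.character(ref[ids]),
             start = as.integer(lo[ids]), end = as.integer(hi[ids]),
             stringsAsFactors = FALSE)
}

#' Assign fragments to genes by maximal exonic overlap
#'
#' A fragment (the span from its leftmost to rightmost aligned base) counts
#' once toward the single gene whose exonic intervals overlap it by the
#' most bases. Fragments overlapping no exon are unassigned; fragments
#' tying across genes are discarded as ambiguous. Strand is ignored
#' (non-directional libraries).
#'
#' @param alignments an `xp_alignments` table, already restricted to one
#'   species-specific category.
#' @param model a `gene_model`.
#' @return list with `counts` (named integer vector per gene),
#'   `n_fragments`, `n_assigned`, `n_unassigned`, `n_ambiguous`.
#' @export
assign_fragments <- function(alignments, model) {
  if (any(vapply(seq_len(nrow(model)), function(i)
    is.unsorted(model$exon_starts[[i]]) ||
      any(model$exon_ends[[i]] <= model$exon_starts[[i]]), logical(1))))
    stop("invalid gene model: exons unsorted or empty")
  frags <- fragment_spans(alignments)
  n_frag <- nrow(frags)
  counts <- setNames(integer(nrow(model)), model$gene_id)
  if (!n_frag)
    return(list(counts = counts, n_fragments = 0L, n_assigned = 0L,
                n_unassigned = 0L, n_ambiguous = 0L))
  fr_gr <- GenomicRanges::GRanges(frags$reference,
                                  IRanges::IRanges(frags$start, frags$end))
  ex_gr <- model_exon_granges(model)
  hits <- GenomicRanges::findOverlaps(fr_gr, ex_gr, ignore.strand = TRUE)
  if (!length(hits)) {
    return(list(counts = counts, n_fragments = n_frag, n_assigned = 0L,
                n_unassigned = n_frag, n_ambiguous = 0L))
  }
  ov <- IRanges::width(IRanges::pintersect(
    fr_gr[S4Vectors::queryHits(hits)], ex_gr[S4Vectors::subjectHits(hits)]))
  gene <- ex_gr$gene_id[S4Vectors::subjectHits(hits)]
  frag_i <- S4Vectors::queryHits(hits)
  # total exonic overlap per (fragment, gene)
  key <- paste(frag_i, gene, sep = "\r")
  tot <- tapply(ov, key, sum)
  kf <- as.integer(sub("\r.*$", "", names(tot)))
  kg <- sub("^[^\r]*\r", "", names(tot))
  best <- tapply(as.numeric(tot), kf, max)
  best_for <- best[as.character(kf)]
  is_best <- as.numeric(tot) == as.numeric(best_for)
  n_best <- tapply(is_best, kf, sum)
  amb_frags <- as.integer(names(n_best)[n_best > 1L])
  winner <- is_best & !(kf %in% amb_frags)
  tab <- table(kg[winner])
  counts[names(tab)] <- as.integer(tab)
  n_assigned <- sum(counts)
  n_ambiguous <- length(amb_frags)
  list(counts = counts, n_fragments = n_frag, n_assigned = n_assigned,
       n_unassigned = n_frag - n_assigned - n_ambiguous,
       n_ambiguous = n_ambiguous)
}

#' Reads/fragments per kilobase of exon model per million mapped reads
#'
#' `rpkm = 1e9 * count / (total_mapped * exonic_length)`.
#'
#' @param count fragment (or read) count for the gene.
#' @param exonic_length exon-union length in nt (>= 1).
#' @param total_mapped normalization denominator (>= 1).
#' @return numeric RPKM (vectorized).
#' @export
rpkm <- function(count, exonic_length, total_mapped) {
  if (any(exonic_length < 1) || any(total_mapped < 1))
    stop("exonic_length and total_mapped must be >= 1")
  1e9 * count / (as.numeric(total_mapped) * as.numeric(exonic_length))
}

#' Quantify a species-specific alignment set over a gene model
#'
#' Fragment counting by maximal exonic overlap followed by RPKM
#' normalization. The default denominator is the number of mapped fragments
#' in the category being quantified (quantification happens after species
#' separation); `denominator = "assigned"` restricts it to exon-assigned
#' fragments.
#'
#' @inheritParams assign_fragments
#' @param pseudocount added before the exported log2 transform (default 1).
#' @param denominator `"mapped"` (default) or `"assigned"`.
#' @return an `expression_table` data.frame: `gene_id`, `count`,
#'   `exonic_length`, `rpkm`, `log2_rpkm`; totals as attributes.
#' @export
quantify_expression <- function(alignments, model, pseudocount = 1,
                                denominator = c("mapped", "assigned")) {
  denominator <- match.arg(denominator)
  asg <- assign_fragments(alignments, model)
  total <- if (denominator == "mapped") asg$n_fragments else asg$n_assigned
  total <- max(total, 1L)
  out <- data.frame(gene_id = model$gene_id,
                    count = as.integer(asg$counts[model$gene_id]),
                    exonic_length = model$exonic_length,
                    stringsAsFactors = FALSE)
  out$rpkm <- rpkm(out$count, out$exonic_length, total)
  out$log2_rpkm <- log2(out$rpkm + pseudocount)
  attr(out, "total_mapped") <- total
  attr(out, "n_assigned") <- asg$n_assigned
  attr(out, "n_unassigned") <- asg$n_unassigned
  attr(out, "n_ambiguous") <- asg$n_ambiguous
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Spearman correlation of log2-transformed expression vectors
#'
#' Both vectors are log2(value + pseudocount) transformed before ranking
#' with average-tie handling. Spearman's correlation is invariant to the
#' monotone log transform; the transform is retained because the exported
#' matrices are on the log2 scale.
#'
#' @param x,y paired expression vectors over a shared gene set (length 3
#'   or more).
#' @param pseudocount added before the log transform (default 1).
#' @return Spearman correlation in `[-1, 1]`; `NA` with a warning when
#'   either vector is constant.
#' @export
spearman_log2 <- function(x, y, pseudocount = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  lx <- log2(x + pseudocount)
  ly <- log2(y + pseudocount)
  if (length(unique(lx)) == 1L || length(unique(ly)) == 1L) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(lx, ly, method = "spearman")
}

#' Write an expression table as TSV
#'
#' @param expr an `expression_table`.
#' @param path destination TSV.
#' @return invisibly, the path.
#' @export
write_expression <- function(expr, path) {
  write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
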