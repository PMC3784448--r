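#' Build a k-mer seed index over a reference sequence
#'
#' Records every forward-strand k-mer occurrence (2-bit packed, so k must be
#' at most 31; k-mers containing non-ACGT bases are skipped). The index
#' backs the seed-and-extend micro-aligner used for synthetic genomes and
#' the host-contamination window check; real libraries are expected to come
#' with externally produced SAM/BAM.
#'
#' @param genome nucleotide string (or a length-1 `DNAStringSet`).
#' @param k seed length (default 21).
#' @param genome_id reference name written into SAM output (default "ref").
#' @return a `seed_index` object.
#' @export
seed_index <- function(genome, k = 21L, genome_id = "ref") {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome[[1]])
  genome <- toupper(as.character(genome))
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (nchar(genome) < k) stop("genome shorter than k")
  structure(list(genome = genome, k = k, genome_id = genome_id,
                 ptr = .xp_index_build(genome, k)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index:", x$genome_id, "-", nchar(x$genome), "bp, k =", x$k, "\n")
  invisible(x)
}

#' Look up the occurrence positions of a k-mer
#'
#' @param index a [seed_index()].
#' @param kmer k-mer string of length `index$k`.
#' @return integer vector of 0-based forward-strand positions.
#' @export
seed_positions <- function(index, kmer) {
  .xp_index_lookup(index$ptr, toupper(kmer))
}

#' Reverse-complement nucleotide strings
#'
#' @param seqs character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seqs) .xp_revcomp(seqs)

hit_frame <- function(res, ids, mates) {
  data.frame(id = ids, mate = mates, position = res$position,
             strand = res$strand, mismatches = res$mismatches,
             mapq_like = res$mapq_like, stringsAsFactors = FALSE)
}

#' Align a single read against a seed index
#'
#' Seeds with non-overlapping k-mers from the read and its reverse
#' complement, extends every candidate placement ungapped, and returns the
#' placement with the fewest mismatches. `mapq_like` is
#' `min(60, 10 * (second_best - best))`, 0 when two equal-best placements
#' exist, 60 when no competing placement was seen; ties are broken by the
#' lowest coordinate. Indels are not modeled.
#'
#' @param sequence read sequence.
#' @param index a [seed_index()].
#' @param max_mismatch maximum allowed mismatches (default 5).
#' @return a one-row data.frame (`position` 1-based, `strand`, `mismatches`,
#'   `mapq_like`), or `NULL` when no placement is within `max_mismatch`.
#' @export
align_read <- function(sequence, index, max_mismatch = 5L) {
  res <- .xp_align_batch(index$ptr, toupper(sequence), as.integer(max_mismatch))
  if (is.na(res$position[1])) return(NULL)
  hit_frame(res, NA_character_, NA_integer_)
}

#' Align a read pair against a seed index
#'
#' A pair is proper when both mates align to the reference on opposite
#' strands in forward-reverse orientation with an inferred fragment length
#' inside `[insert_min, insert_max]`.
#'
#' @param seq1,seq2 mate sequences.
#' @param index a [seed_index()].
#' @param insert_min,insert_max accepted fragment-length window.
#' @param max_mismatch maximum allowed mismatches per mate.
#' @return list with `hit1`, `hit2` (each a one-row data.frame or `NULL`)
#'   and `proper_pair`.
#' @export
align_pair <- function(seq1, seq2, index, insert_min = 100L,
                       insert_max = 400L, max_mismatch = 5L) {
  h1 <- align_read(seq1, index, max_mismatch)
  h2 <- align_read(seq2, index, max_mismatch)
  proper <- FALSE
  if (!is.null(h1) && !is.null(h2)) {
    end1 <- h1$position + nchar(seq1) - 1L
    end2 <- h2$position + nchar(seq2) - 1L
    frag <- max(end1, end2) - min(h1$position, h2$position) + 1L
    fr <- (h1$strand == "+" && h2$strand == "-" && h1$position <= end2) ||
          (h1$strand == "-" && h2$strand == "+" && h2$position <= end1)
    proper <- fr && h1$strand != h2$strand &&
      frag >= insert_min && frag <= insert_max
  }
  list(hit1 = h1, hit2 = h2, proper_pair = proper)
}

reverse_strings <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Align a paired-end library and return alignment observations
#'
#' Batch interface over [align_pair()]: aligns every fragment of an
#' `xp_pairs` library and returns the same observation table that
#' [parse_sam()] produces, so the classifier treats the built-in aligner and
#' external aligners identically. Sequences and qualities are stored in
#' reference orientation (reverse-complemented for minus-strand placements),
#' matching SAM conventions.
#'
#' @param pairs an `xp_pairs` data.frame.
#' @param index a [seed_index()].
#' @inheritParams align_pair
#' @return an `xp_alignments` data.frame, two rows (mate 1 then mate 2) per
#'   fragment, id-major order.
#' @export
micro_align_library <- function(pairs, index, insert_min = 100L,
                                insert_max = 400L, max_mismatch = 5L) {
  n <- nrow(pairs)
  mm <- as.integer(max_mismatch)
  r1 <- .xp_align_batch(index$ptr, toupper(pairs$seq1), mm)
  r2 <- .xp_align_batch(index$ptr, toupper(pairs$seq2), mm)
  len1 <- nchar(pairs$seq1)
  len2 <- nchar(pairs$seq2)
  m1 <- !is.na(r1$position)
  m2 <- !is.na(r2$position)
  end1 <- r1$position + len1 - 1L
  end2 <- r2$position + len2 - 1L
  frag <- pmax(end1, end2) - pmin(r1$position, r2$position) + 1L
  fr <- (r1$strand == "+" & r2$strand == "-" & r1$position <= end2) |
        (r1$strand == "-" & r2$strand == "+" & r2$position <= end1)
  proper <- m1 & m2 & !is.na(fr) & fr & r1$strand != r2$strand &
    frag >= insert_min & frag <= insert_max
  proper[is.na(proper)] <- FALSE

  orient <- function(seqs, quals, res, mapped) {
    neg <- mapped & res$strand == "-"
    neg[is.na(neg)] <- FALSE
    seqs[neg] <- .xp_revcomp(seqs[neg])
    quals[neg] <- reverse_strings(quals[neg])
    list(seq = seqs, qual = quals)
  }
  o1 <- orient(pairs$seq1, pairs$qual1, r1, m1)
  o2 <- orient(pairs$seq2, pairs$qual2, r2, m2)

  build <- function(mate, res, mapped, len, o) {
    data.frame(id = pairs$id, mate = mate, mapped = mapped,
               mapq = ifelse(mapped, res$mapq_like, 0L),
               mapq_available = TRUE,
               proper_pair = proper,
               reference = ifelse(mapped, index$genome_id, NA_character_),
               position = res$position,
               strand = res$strand,
               primary = TRUE, duplicate = FALSE,
               width = ifelse(mapped, len, NA_integer_),
               seq = o$seq, qual = o$qual, stringsAsFactors = FALSE)
  }
  d1 <- build(1L, r1, m1, len1, o1)
  d2 <- build(2L, r2, m2, len2, o2)
  out <- rbind(d1, d2)[rep(seq_len(n), each = 2L) + c(0L, n), ]
  rownames(out) <- NULL
  class(out) <- c("xp_alignments", "data.frame")
  out
}

#' Write micro-aligner observations as a SAM file
#'
#' Renders the id-major observation table from [micro_align_library()] as
#' standard SAM text (FLAG, 1-based POS, full-length match CIGAR), suitable
#' for any downstream SAM consumer including [parse_sam()].
#'
#' @param obs output of [micro_align_library()].
#' @param path destination SAM path.
#' @param reference_name,reference_length `@SQ` header values; default taken
#'   from the observations.
#' @return invisibly, the number of records written.
#' @export
write_sam <- function(obs, path, reference_name = NULL,
                      reference_length = NULL) {
  n <- nrow(obs)
  if (n %% 2L != 0L) stop("expected an id-major mate1/mate2 table")
  i1 <- seq(1L, n, by = 2L)
  i2 <- i1 + 1L
  if (!all(obs$id[i1] == obs$id[i2]))
    stop("expected an id-major mate1/mate2 table")
  if (is.null(reference_name)) {
    refs <- unique(obs$reference[obs$mapped])
    reference_name <- if (length(refs)) refs[1] else "ref"
  }
  if (is.null(reference_length))
    reference_length <- max(c(1L, obs$position + obs$width - 1L), na.rm = TRUE)

  row_flags <- function(self, mate, first) {
    fl <- 1L + (if (first) 64L else 128L)
    fl <- fl + ifelse(self$mapped, 0L, 4L) + ifelse(mate$mapped, 0L, 8L)
    fl <- fl + ifelse(self$mapped & self$strand == "-", 16L, 0L)
    fl <- fl + ifelse(mate$mapped & mate$strand == "-", 32L, 0L)
    fl + ifelse(self$proper_pair & self$mapped & mate$mapped, 2L, 0L)
  }
  render <- function(self, mate, first) {
    flag <- row_flags(self, mate, first)
    both <- self$mapped & mate$mapped
    tlen <- integer(nrow(self))
    if (any(both)) {
      lo <- pmin(self$position[both], mate$position[both])
      hi <- pmax(self$position[both] + self$width[both],
                 mate$position[both] + mate$width[both]) - 1L
      span <- hi - lo + 1L
      tlen[both] <- ifelse(self$position[both] <= mate$position[both],
                           span, -span)
    }
    paste(obs$id[if (first) i1 else i2], flag,
          ifelse(self$mapped, reference_name, "*"),
          ifelse(self$mapped, self$position, 0L),
          ifelse(self$mapped, self$mapq, 0L),
          ifelse(self$mapped, paste0(nchar(self$seq), "M"), "*"),
          ifelse(mate$mapped, "=", "*"),
          ifelse(mate$mapped, mate$position, 0L),
          tlen, self$seq, self$qual, sep = "\t")
  }
  s1 <- obs[i1, , drop = FALSE]
  s2 <- obs[i2, , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", reference_name, "\tLN:", reference_length))
  lines <- character(n)
  lines[seq(1L, n, by = 2L)] <- render(s1, s2, TRUE)
  lines[seq(2L, n, by = 2L)] <- render(s2, s1, FALSE)
  writeLines(c(header, lines), path)
  invisible(n)
}
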