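#' Convert Phred+33 quality strings to integer scores
#'
#' @param qual character vector of Phred+33 encoded quality strings.
#' @return For `phred_to_int`, a list of integer vectors (one per string);
#'   for `int_to_phred`, a character vector.
#' @examples
#' phred_to_int("II5")[[1]]  # 40 40 20
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) {
    codes <- utf8ToInt(q)
    if (length(codes) && (min(codes) < 33L || max(codes) > 126L))
      stop("quality string contains bytes outside the Phred+33 range")
    codes - 33L
  })
}

#' @rdname phred_to_int
#' @param scores a list of integer vectors (or a single integer vector) of
#'   Phred scores.
#' @export
int_to_phred <- function(scores) {
  if (!is.list(scores)) scores <- list(scores)
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

#' Normalize a FASTQ header into a fragment id and mate number
#'
#' Strips the legacy `/1` and `/2` mate suffixes, truncates at the first
#' whitespace (Casava 1.8+ headers), and recovers the mate number either from
#' the suffix or from the first colon-delimited field of the comment when it
#' is `1:...` or `2:...`.
#'
#' @param raw_header header line, with or without the leading `@`.
#' @return list with elements `id` (string) and `mate` (1, 2, or NA).
#' @examples
#' normalize_read_id("READ7/2")
#' normalize_read_id("M01:55:ABC 1:N:0:ACGT")
#' @export
normalize_read_id <- function(raw_header) {
  if (length(raw_header) != 1L || is.na(raw_header) || !nzchar(raw_header))
    stop("malformed FASTQ header: empty")
  h <- sub("^@", "", raw_header)
  parts <- strsplit(h, "[ \t]+")[[1]]
  if (!length(parts) || !nzchar(parts[1]))
    stop("malformed FASTQ header: no id field")
  id <- parts[1]
  mate <- NA_integer_
  if (grepl("/[12]$", id)) {
    mate <- as.integer(substring(id, nchar(id)))
    id <- substring(id, 1L, nchar(id) - 2L)
  } else if (length(parts) >= 2L && grepl("^[12]:", parts[2])) {
    mate <- as.integer(substring(parts[2], 1L, 1L))
  }
  list(id = id, mate = mate)
}

fastq_connection <- function(path, open = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a FASTQ file
#'
#' Qualities are interpreted as Phred+33; gzip input is detected from the
#' `.gz` extension. Read ids are normalized with [normalize_read_id()].
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with columns `id`, `mate`, `sequence`, `quality`
#'   (quality kept as a Phred+33 string).
#' @export
read_fastq <- function(path) {
  con <- fastq_connection(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ file ", path, ": line count not a multiple of 4")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(), mate = integer(),
                      sequence = character(), quality = character(),
                      stringsAsFactors = FALSE))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(!startsWith(hdr, "@")))
    stop("FASTQ file ", path, ": header line missing '@'")
  if (any(nchar(seqs) != nchar(quals)))
    stop("FASTQ file ", path, ": sequence/quality length mismatch")
  # vectorized form of normalize_read_id for throughput
  h <- sub("^@", "", hdr)
  id <- sub("[ \t].*$", "", h)
  comment <- ifelse(grepl("[ \t]", h), sub("^[^ \t]+[ \t]+", "", h), "")
  mate <- rep(NA_integer_, n)
  sfx <- grepl("/[12]$", id)
  mate[sfx] <- as.integer(substring(id[sfx], nchar(id[sfx])))
  id[sfx] <- substring(id[sfx], 1L, nchar(id[sfx]) - 2L)
  cas <- !sfx & grepl("^[12]:", comment)
  mate[cas] <- as.integer(substring(comment[cas], 1L, 1L))
  data.frame(id = id, mate = mate,
             sequence = seqs, quality = quals, stringsAsFactors = FALSE)
}

new_read_pairs <- function(id, seq1, qual1, seq2, qual2) {
  df <- data.frame(id = id, seq1 = seq1, qual1 = qual1,
                   seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE)
  class(df) <- c("xp_pairs", "data.frame")
  df
}

#' Read a paired-end FASTQ file pair
#'
#' The two files must list the same fragments in the same order (the usual
#' `_1`/`_2` convention). Fragment ids are normalized so that legacy `/1`,
#' `/2` suffixes and Casava comments compare equal across files.
#'
#' @param in1,in2 mate-1 and mate-2 FASTQ paths (optionally gzipped).
#' @return an `xp_pairs` data.frame: `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(in1, in2) {
  r1 <- read_fastq(in1)
  r2 <- read_fastq(in2)
  if (nrow(r1) != nrow(r2))
    stop("mate files differ in record count (", nrow(r1), " vs ", nrow(r2), ")")
  if (!all(r1$id == r2$id))
    stop("mate files disagree on fragment ids")
  new_read_pairs(r1$id, r1$sequence, r1$quality, r2$sequence, r2$quality)
}

#' Write a paired-end FASTQ file pair
#'
#' Emits 4-line FASTQ records, mate-1 and mate-2 files in identical fragment
#' order; round-trips bit-exactly through [read_fastq_pairs()]. Output is
#' gzipped when the path ends in `.gz`.
#'
#' @param pairs an `xp_pairs` data.frame.
#' @param out1,out2 destination paths.
#' @return invisibly, the number of pairs written.
#' @export
write_fastq_pairs <- function(pairs, out1, out2) {
  write_one <- function(path, seqs, quals) {
    con <- fastq_connection(path, "wt")
    on.exit(close(con))
    if (nrow(pairs)) {
      lines <- as.vector(rbind(paste0("@", pairs$id), seqs, "+", quals))
      writeLines(lines, con)
    }
  }
  write_one(out1, pairs$seq1, pairs$qual1)
  write_one(out2, pairs$seq2, pairs$qual2)
  invisible(nrow(pairs))
}

#' Quality-trimming configuration
#'
#' Sliding-window trimming: scanning 5' to 3', the read is truncated before
#' the first window of `window` bases whose mean Phred quality drops below
#' `min_mean_quality`; reads shorter than `min_length` after truncation are
#' discarded. Defaults follow the common Trimmomatic-style recipe of a
#' 6-base window at mean quality 20 with a 50 nt length floor.
#'
#' @param window window width in bases (default 6).
#' @param min_mean_quality minimum mean Phred score per window (default 20).
#' @param min_length minimum surviving read length in nt (default 50).
#' @return a `trim_config` list.
#' @export
trim_config <- function(window = 6L, min_mean_quality = 20, min_length = 50L) {
  stopifnot(window >= 1L, min_length >= 1L)
  structure(list(window = as.integer(window),
                 min_mean_quality = min_mean_quality,
                 min_length = as.integer(min_length)),
            class = "trim_config")
}

# Kept prefix length for each quality string under the window rule.
# Reads shorter than the window have no window and are kept whole.
trim_points <- function(qual, window, min_mean_quality) {
  w <- as.integer(window)
  vapply(qual, function(q) {
    scores <- utf8ToInt(q) - 33L
    n <- length(scores)
    if (n < w) return(n)
    cs <- cumsum(c(0L, scores))
    means <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
    bad <- which(means < min_mean_quality)
    if (!length(bad)) n else bad[1] - 1L
  }, integer(1), USE.NAMES = FALSE)
}

#' Trim a single read by sliding-window quality
#'
#' @param sequence nucleotide string.
#' @param quality Phred+33 quality string of equal length.
#' @param cfg a [trim_config()].
#' @return list with `sequence`, `quality` (prefixes of the input) and
#'   `discarded` (TRUE when the trimmed read is shorter than
#'   `cfg$min_length`).
#' @export
sliding_window_trim <- function(sequence, quality, cfg = trim_config()) {
  stopifnot(nchar(sequence) == nchar(quality))
  keep <- trim_points(quality, cfg$window, cfg$min_mean_quality)
  if (keep < cfg$min_length)
    return(list(sequence = NULL, quality = NULL, discarded = TRUE))
  list(sequence = substr(sequence, 1L, keep),
       quality = substr(quality, 1L, keep), discarded = FALSE)
}

#' Trim a paired-end library
#'
#' Both mates are trimmed independently; if either mate falls below the
#' length floor the whole pair is dropped, since downstream classification
#' operates on fragments.
#'
#' @param pairs an `xp_pairs` data.frame.
#' @param cfg a [trim_config()].
#' @return list with `pairs` (surviving, trimmed pairs), `n_input`,
#'   `n_kept`, `n_discarded`.
#' @export
trim_pairs <- function(pairs, cfg = trim_config()) {
  if (!nrow(pairs))
    return(list(pairs = pairs, n_input = 0L, n_kept = 0L, n_discarded = 0L))
  k1 <- trim_points(pairs$qual1, cfg$window, cfg$min_mean_quality)
  k2 <- trim_points(pairs$qual2, cfg$window, cfg$min_mean_quality)
  keep <- k1 >= cfg$min_length & k2 >= cfg$min_length
  out <- pairs[keep, , drop = FALSE]
  out$seq1 <- substr(out$seq1, 1L, k1[keep])
  out$qual1 <- substr(out$qual1, 1L, k1[keep])
  out$seq2 <- substr(out$seq2, 1L, k2[keep])
  out$qual2 <- substr(out$qual2, 1L, k2[keep])
  rownames(out) <- NULL
  list(pairs = out, n_input = nrow(pairs), n_kept = sum(keep),
       n_discarded = sum(!keep))
}

#' Decode a SAM FLAG field
#'
#' @param flag integer vector of SAM FLAG values.
#' @return data.frame of logicals: `paired`, `proper_pair`, `unmapped`,
#'   `mate_unmapped`, `reverse`, `mate_reverse`, `first_in_pair`,
#'   `second_in_pair`, `secondary`, `qc_fail`, `duplicate`, `supplementary`.
#' @export
decode_sam_flag <- function(flag) {
  flag <- as.integer(flag)
  bit <- function(b) bitwAnd(flag, b) != 0L
  data.frame(paired = bit(0x1), proper_pair = bit(0x2), unmapped = bit(0x4),
             mate_unmapped = bit(0x8), reverse = bit(0x10),
             mate_reverse = bit(0x20), first_in_pair = bit(0x40),
             second_in_pair = bit(0x80), secondary = bit(0x100),
             qc_fail = bit(0x200), duplicate = bit(0x400),
             supplementary = bit(0x800))
}

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Parse SAM alignment records into alignment observations
#'
#' Reduces each SAM record to the fields the classifier and pileup layers
#' need. FLAG bits provide the mapped / mate / proper-pair / primary /
#' duplicate state; secondary and supplementary records are kept with
#' `primary = FALSE`; MAPQ 255 ("unavailable") is preserved as-is and
#' flagged via `mapq_available`.
#'
#' @param input path to a SAM file, or a character vector of SAM lines.
#' @param keep_seq keep the SEQ/QUAL columns (needed for pileup); default
#'   TRUE.
#' @return an `xp_alignments` data.frame with columns `id`, `mate`,
#'   `mapped`, `mapq`, `mapq_available`, `proper_pair`, `reference`,
#'   `position`, `strand`, `primary`, `duplicate`, `width`, and (optionally)
#'   `seq`, `qual`.
#' @export
parse_sam <- function(input, keep_seq = TRUE) {
  lines <- if (length(input) == 1L && !grepl("\n", input) &&
               file.exists(input)) readLines(input) else input
  body_idx <- which(!startsWith(lines, "@"))
  body <- lines[body_idx]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- body_idx[which(nf < 11L)[1]]
    stop("SAM line ", bad, ": fewer than 11 tab-separated fields")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(get(2))
  bits <- decode_sam_flag(flag)
  mapped <- !bits$unmapped
  mapq <- as.integer(get(5))
  pos <- as.integer(get(4))
  ref <- get(3)
  # QNAME contains no whitespace per the SAM spec; only the legacy mate
  # suffix needs stripping, vectorized here for throughput.
  ids <- sub("/[12]$", "", get(1))
  mate <- ifelse(bits$second_in_pair, 2L, 1L)
  out <- data.frame(
    id = ids,
    mate = mate,
    mapped = mapped,
    mapq = mapq,
    mapq_available = mapq != 255L,
    proper_pair = bits$proper_pair,
    reference = ifelse(mapped, ref, NA_character_),
    position = ifelse(mapped, pos, NA_integer_),
    strand = ifelse(mapped, ifelse(bits$reverse, "-", "+"), NA_character_),
    primary = !(bits$secondary | bits$supplementary),
    duplicate = bits$duplicate,
    width = ifelse(mapped, cigar_ref_width(get(6)), NA_integer_),
    stringsAsFactors = FALSE)
  if (keep_seq) {
    out$seq <- get(10)
    out$qual <- get(11)
  }
  class(out) <- c("xp_alignments", "data.frame")
  out
}

#' Read alignments from SAM or BAM
#'
#' SAM text is parsed directly; `.bam` input is decoded through Rsamtools
#' when available.
#'
#' @inheritParams parse_sam
#' @param path alignment file (`.sam` or `.bam`).
#' @return see [parse_sam()].
#' @export
read_alignments <- function(path, keep_seq = TRUE) {
  if (grepl("\\.bam$", path)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading BAM requires the Rsamtools package")
    bam <- Rsamtools::scanBam(path)[[1]]
    flag <- bam$flag
    bits <- decode_sam_flag(flag)
    mapped <- !bits$unmapped
    norm <- lapply(as.character(bam$qname), normalize_read_id)
    out <- data.frame(
      id = vapply(norm, `[[`, character(1), "id"),
      mate = ifelse(bits$second_in_pair, 2L, 1L),
      mapped = mapped,
      mapq = ifelse(is.na(bam$mapq), 255L, as.integer(bam$mapq)),
      mapq_available = !is.na(bam$mapq) & bam$mapq != 255L,
      proper_pair = bits$proper_pair,
      reference = ifelse(mapped, as.character(bam$rname), NA_character_),
      position = ifelse(mapped, bam$pos, NA_integer_),
      strand = ifelse(mapped, ifelse(bits$reverse, "-", "+"), NA_character_),
      primary = !(bits$secondary | bits$supplementary),
      duplicate = bits$duplicate,
      width = ifelse(mapped, cigar_ref_width(as.character(bam$cigar)),
                     NA_integer_),
      stringsAsFactors = FALSE)
    if (keep_seq) {
      out$seq <- as.character(bam$seq)
      out$qual <- as.character(bam$qual)
    }
    class(out) <- c("xp_alignments", "data.frame")
    return(out)
  }
  parse_sam(path, keep_seq = keep_seq)
}
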