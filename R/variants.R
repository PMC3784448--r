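#' Variant hard-filter and rescue configuration
#'
#' Defaults mirror a standard GATK-era exome hard-filter recipe: minimum
#' depth 5, minimum site quality 50, Fisher strand bias below 60
#' (Phred-scaled), SNP clusters of 3 or more SNVs within a 10 nt window,
#' and the rescue rule's allele-fraction threshold 0.2 at minimum usable
#' depth 10.
#'
#' @param min_depth minimum read depth.
#' @param min_qual minimum Phred-scaled site quality.
#' @param max_fs maximum Phred-scaled Fisher strand-bias score.
#' @param cluster_count,cluster_window SNP-cluster rule: `cluster_count` or
#'   more SNVs within `cluster_window` bases.
#' @param min_af_call allele fraction at or above which a variant counts as
#'   called in the counterpart sample.
#' @param rescue_min_depth minimum counterpart depth for a rescue verdict.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_depth = 5L, min_qual = 50, max_fs = 60,
                          cluster_count = 3L, cluster_window = 10L,
                          min_af_call = 0.2, rescue_min_depth = 10L) {
  stopifnot(min_depth >= 0, min_qual >= 0, max_fs >= 0, cluster_count >= 1,
            cluster_window >= 1, min_af_call >= 0, rescue_min_depth >= 0)
  structure(list(min_depth = as.integer(min_depth), min_qual = min_qual,
                 max_fs = max_fs, cluster_count = as.integer(cluster_count),
                 cluster_window = as.integer(cluster_window),
                 min_af_call = min_af_call,
                 rescue_min_depth = as.integer(rescue_min_depth)),
            class = "filter_config")
}

#' Construct a variant-record table
#'
#' The in-memory form of one called variant per row; the unit flowing
#' through the exome post-processing layer.
#'
#' @param chrom,pos,ref,alt variant key fields (`pos` 1-based).
#' @param qual Phred-scaled site quality.
#' @param depth total read depth.
#' @param ref_count,alt_count per-allele depths.
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev per-allele strand counts.
#' @param genotype `"het"` or `"hom"`.
#' @return a `variant_records` data.frame with empty `filters` and unset
#'   `known`.
#' @export
variant_records <- function(chrom, pos, ref, alt, qual, depth,
                            ref_count, alt_count,
                            ref_fwd = NA_integer_, ref_rev = NA_integer_,
                            alt_fwd = NA_integer_, alt_rev = NA_integer_,
                            genotype = "het") {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                   alt = alt, qual = qual, depth = as.integer(depth),
                   ref_count = as.integer(ref_count),
                   alt_count = as.integer(alt_count),
                   ref_fwd = as.integer(ref_fwd),
                   ref_rev = as.integer(ref_rev),
                   alt_fwd = as.integer(alt_fwd),
                   alt_rev = as.integer(alt_rev),
                   genotype = genotype, filters = "",
                   known = NA, stringsAsFactors = FALSE)
  bad <- which(df$ref_count + df$alt_count > df$depth)
  if (length(bad))
    stop("allele depths exceed total depth at record ", bad[1])
  class(df) <- c("variant_records", "data.frame")
  df
}

#' Read a VCF into a variant-record table
#'
#' Parsed through vcfR. Depth, allele depths and strand counts are taken
#' from the INFO fields `DP`, `AD` (ref,alt) and `SB`
#' (ref_fwd,ref_rev,alt_fwd,alt_rev) when present. Multi-allelic records
#' are split into bi-allelic records, allele depths carried per split
#' allele.
#'
#' @param path VCF path.
#' @return a `variant_records` data.frame.
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- t(fix)      # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info_field <- function(key) {
    has <- grepl(paste0("(^|;)", key, "="), fix$INFO)
    val <- rep(NA_character_, nrow(fix))
    val[has] <- sub(paste0(".*(?:^|;)", key, "=([^;]*).*"), "\\1",
                    fix$INFO[has], perl = TRUE)
    val
  }
  dp <- as.integer(info_field("DP"))
  ad <- info_field("AD")
  sb <- info_field("SB")
  gt <- info_field("GT")
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    adv <- if (is.na(ad[i])) rep(NA_integer_, length(alts) + 1L) else
      as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]])
    sbv <- if (is.na(sb[i])) rep(NA_integer_, 4L) else
      as.integer(strsplit(sb[i], ",", fixed = TRUE)[[1]])
    out[[i]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = fix$REF[i],
      alt = alts, qual = as.numeric(fix$QUAL[i]), depth = dp[i],
      ref_count = adv[1], alt_count = adv[seq_along(alts) + 1L],
      ref_fwd = sbv[1], ref_rev = sbv[2], alt_fwd = sbv[3], alt_rev = sbv[4],
      genotype = if (is.na(gt[i])) "het" else gt[i],
      filters = ifelse(fix$FILTER[i] %in% c(".", "PASS", NA), "",
                       fix$FILTER[i]),
      known = NA, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  class(df) <- c("variant_records", "data.frame")
  df
}

#' Write a variant-record table as VCF
#'
#' Filter tags go to the FILTER column (`PASS` when none); depth, allele
#' depths, strand counts, genotype and the known flag are emitted as INFO
#' fields `DP`, `AD`, `SB`, `GT`, `KNOWN`.
#'
#' @param records a `variant_records` data.frame.
#' @param path destination VCF path.
#' @return invisibly, the path.
#' @export
write_vcf_records <- function(records, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##INFO=<ID=SB,Number=4,Type=Integer,Description=\"Per-allele strand counts: ref_fwd,ref_rev,alt_fwd,alt_rev\">",
           "##INFO=<ID=GT,Number=1,Type=String,Description=\"het or hom\">",
           "##INFO=<ID=KNOWN,Number=0,Type=Flag,Description=\"Present in the known-sites catalogue\">",
           "##FILTER=<ID=LowDepth,Description=\"Depth below threshold\">",
           "##FILTER=<ID=LowQual,Description=\"Quality below threshold\">",
           "##FILTER=<ID=StrandBias,Description=\"Fisher strand bias above threshold\">",
           "##FILTER=<ID=SnpCluster,Description=\"SNV cluster\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- paste0(
    "DP=", records$depth,
    ";AD=", records$ref_count, ",", records$alt_count,
    ifelse(is.na(records$ref_fwd), "",
           paste0(";SB=", records$ref_fwd, ",", records$ref_rev, ",",
                  records$alt_fwd, ",", records$alt_rev)),
    ";GT=", records$genotype,
    ifelse(!is.na(records$known) & records$known, ";KNOWN", ""))
  filt <- ifelse(nzchar(records$filters), records$filters, "PASS")
  lines <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                 format(records$qual, trim = TRUE), filt, info, sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Count alleles at a locus from alignment observations
#'
#' Pileup restricted to usable evidence: primary, FLAG-mapped, properly
#' paired records whose mapping quality is available (MAPQ 255 excluded and
#' tallied), optionally excluding duplicate-flagged records, counting only
#' bases with base quality at or above `min_base_q`. Alignments are assumed
#' ungapped over their reference span (full-length match), which holds for
#' the built-in aligner.
#'
#' @param alignments an `xp_alignments` table with `seq`/`qual`.
#' @param chrom,pos locus (1-based).
#' @param min_base_q minimum base quality (default 20).
#' @param use_dedup exclude duplicate-flagged records (default TRUE).
#' @return a `pileup_counts` list: `chrom`, `pos`, `depth_after_filters`,
#'   `counts` (5 x 2 matrix, bases x fwd/rev strand),
#'   `excluded_mapq_unavailable`.
#' @export
pileup_allele_counts <- function(alignments, chrom, pos, min_base_q = 20L,
                                 use_dedup = TRUE) {
  a <- alignments
  over <- a$primary & a$mapped & !is.na(a$position) &
    a$reference == chrom & a$position <= pos & a$position + a$width - 1L >= pos
  over[is.na(over)] <- FALSE
  excluded_mq <- sum(over & !a$mapq_available)
  usable <- over & a$mapq_available & a$proper_pair
  if (use_dedup) usable <- usable & !a$duplicate
  counts <- matrix(0L, nrow = 5L, ncol = 2L,
                   dimnames = list(c("A", "C", "G", "T", "N"),
                                   c("fwd", "rev")))
  idx <- which(usable)
  for (i in idx) {
    off <- pos - a$position[i] + 1L
    base <- toupper(substr(a$seq[i], off, off))
    if (!base %in% rownames(counts)) base <- "N"
    bq <- utf8ToInt(substr(a$qual[i], off, off)) - 33L
    if (bq < min_base_q) next
    col <- if (a$strand[i] == "+") "fwd" else "rev"
    counts[base, col] <- counts[base, col] + 1L
  }
  structure(list(chrom = chrom, pos = pos,
                 depth_after_filters = sum(counts),
                 counts = counts,
                 excluded_mapq_unavailable = excluded_mq),
            class = "pileup_counts")
}

#' Phred-scaled two-sided Fisher's exact test for strand bias
#'
#' FisherStrand score on the 2x2 ref/alt by forward/reverse table:
#' `-10 * log10(p)` of the two-sided exact test, computed by full
#' hypergeometric enumeration of the conditional distribution (no mid-p),
#' capped at 10000.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev non-negative strand counts; the
#'   first argument may instead be a length-4 vector.
#' @return Phred-scaled score (0 for perfectly balanced tables).
#' @export
fisher_strand_phred <- function(ref_fwd, ref_rev = NULL, alt_fwd = NULL,
                                alt_rev = NULL) {
  if (is.null(ref_rev)) {
    stopifnot(length(ref_fwd) == 4L)
    tab <- as.integer(ref_fwd)
  } else {
    tab <- as.integer(c(ref_fwd, ref_rev, alt_fwd, alt_rev))
  }
  if (any(tab < 0)) stop("negative counts")
  if (sum(tab) < 1L) stop("all-zero strand table")
  n_ref <- tab[1] + tab[2]
  n_alt <- tab[3] + tab[4]
  n_fwd <- tab[1] + tab[3]
  if (n_ref == 0L || n_alt == 0L || n_fwd == 0L || tab[2] + tab[4] == 0L)
    return(0)            # degenerate margin: only one possible table
  supp <- max(0L, n_fwd - n_alt):min(n_ref, n_fwd)
  dens <- dhyper(supp, n_ref, n_alt, n_fwd)
  p_obs <- dhyper(tab[1], n_ref, n_alt, n_fwd)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  if (p >= 1 - 1e-12) return(0)   # all tables as extreme as observed
  if (p <= 0) return(10000)
  min(-10 * log10(p), 10000)
}

#' Flag SNV clusters
#'
#' Any record belonging to a run of `cluster_count` or more SNVs spanning
#' fewer than `cluster_window` bases receives the `SnpCluster` tag; dense
#' local runs of substitutions are a hallmark of alignment artifacts.
#' Indels are ignored by the rule.
#'
#' @param records a `variant_records` data.frame sorted by (chrom, pos).
#' @param cluster_count,cluster_window rule parameters (defaults 3 and 10).
#' @return logical vector, TRUE where the record is in a cluster.
#' @export
flag_snp_clusters <- function(records, cluster_count = 3L,
                              cluster_window = 10L) {
  ord <- order(records$chrom, records$pos)
  if (is.unsorted(ord)) stop("records must be sorted by (chrom, pos)")
  is_snv <- nchar(records$ref) == 1L & nchar(records$alt) == 1L &
    records$ref %in% BASES & records$alt %in% BASES
  tagged <- rep(FALSE, nrow(records))
  for (ch in unique(records$chrom)) {
    idx <- which(records$chrom == ch & is_snv)
    p <- records$pos[idx]
    k <- length(p)
    if (k < cluster_count) next
    for (j in seq_len(k - cluster_count + 1L)) {
      if (p[j + cluster_count - 1L] - p[j] < cluster_window)
        tagged[idx[j:(j + cluster_count - 1L)]] <- TRUE
    }
  }
  tagged
}

fs_scores <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    if (is.na(records$ref_fwd[i])) return(0)
    tab <- c(records$ref_fwd[i], records$ref_rev[i],
             records$alt_fwd[i], records$alt_rev[i])
    if (sum(tab) < 1L) return(0)
    fisher_strand_phred(tab)
  }, numeric(1))
}

#' Apply hard filters to variant records
#'
#' Tags per failing criterion — `LowDepth` (depth below `min_depth`),
#' `LowQual` (quality below `min_qual`), `StrandBias` (FisherStrand at or
#' above `max_fs`), `SnpCluster` (cluster rule) — written into `filters`
#' (`""` means PASS). Tags are recomputed from the record fields, so the
#' operation is idempotent; input order is preserved.
#'
#' @param records a `variant_records` data.frame sorted by (chrom, pos).
#' @param cfg a [filter_config()].
#' @return the records with updated `filters` and an `fs` column of
#'   FisherStrand scores.
#' @export
apply_hard_filters <- function(records, cfg = filter_config()) {
  need <- c("depth", "qual", "chrom", "pos", "ref", "alt")
  miss <- need[!need %in% names(records)]
  if (length(miss))
    stop("records missing required fields: ", paste(miss, collapse = ", "))
  fs <- fs_scores(records)
  cluster <- flag_snp_clusters(records, cfg$cluster_count, cfg$cluster_window)
  tags <- vapply(seq_len(nrow(records)), function(i) {
    t <- character(0)
    if (records$depth[i] < cfg$min_depth) t <- c(t, "LowDepth")
    if (records$qual[i] < cfg$min_qual) t <- c(t, "LowQual")
    if (fs[i] >= cfg$max_fs) t <- c(t, "StrandBias")
    if (cluster[i]) t <- c(t, "SnpCluster")
    paste(t, collapse = ";")
  }, character(1))
  records$filters <- tags
  records$fs <- fs
  records
}

variant_key <- function(records) {
  paste(records$chrom, records$pos, records$ref, records$alt, sep = "\r")
}

#' Subtract germline variants
#'
#' Somatic set = sample variants whose (chrom, pos, ref, alt) key is absent
#' from the matched-control call set; control-shared variants are treated
#' as germline and dropped.
#'
#' @param sample,control `variant_records` data.frames.
#' @return the somatic subset of `sample`.
#' @export
subtract_germline <- function(sample, control) {
  keep <- !(variant_key(sample) %in% variant_key(control))
  out <- sample[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a known-sites table
#'
#' dbSNP-like TSV with header columns `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path TSV path.
#' @return data.frame of known sites.
#' @export
read_known_sites <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, fill = TRUE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("known-sites table must have columns chrom, pos, ref, alt")
  bad <- which(is.na(tab$pos) | is.na(tab$chrom) | !nzchar(tab$ref) |
                 !nzchar(tab$alt))
  if (length(bad))
    stop("malformed known-sites row at line ", bad[1] + 1L)
  tab$pos <- as.integer(tab$pos)
  tab
}

#' Annotate variants against a known-sites catalogue
#'
#' Exact (chrom, pos, ref, alt) key match sets `known = TRUE`; the summary
#' reports the known-to-novel ratio.
#'
#' @param somatic a `variant_records` data.frame.
#' @param known_sites a [read_known_sites()] table (or equivalent).
#' @return list with `records` (annotated) and `summary`
#'   (`n_known`, `n_novel`, `known_novel_ratio`).
#' @export
annotate_known <- function(somatic, known_sites) {
  key <- paste(known_sites$chrom, known_sites$pos, known_sites$ref,
               known_sites$alt, sep = "\r")
  somatic$known <- variant_key(somatic) %in% key
  n_known <- sum(somatic$known)
  n_novel <- sum(!somatic$known)
  list(records = somatic,
       summary = list(n_known = n_known, n_novel = n_novel,
                      known_novel_ratio =
                        if (n_novel == 0L && n_known == 0L) 0
                        else if (n_novel == 0L) Inf
                        else n_known / n_novel))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

SPECTRUM_CLASSES <- c("G>A/C>T", "G>T/C>A", "G>C/C>G",
                      "A>G/T>C", "A>T/T>A", "A>C/T>G")

substitution_class <- function(ref, alt) {
  flip <- ref %in% c("C", "T")
  r <- ifelse(flip, COMPLEMENT[ref], ref)
  a <- ifelse(flip, COMPLEMENT[alt], alt)
  paste0(r, ">", a, "/", COMPLEMENT[r], ">", COMPLEMENT[a])
}

#' Mutation spectrum over the six strand-collapsed substitution classes
#'
#' Each SNV is mapped to its purine-reference class (e.g. C>T and G>A share
#' the class written `G>A/C>T`); complementing every record leaves the
#' class counts unchanged. Indel records are excluded from the spectrum and
#' counted separately.
#'
#' @param records a `variant_records` data.frame.
#' @return a `mutation_spectrum` data.frame (`class`, `count`,
#'   `proportion`), with `n_snvs` and `n_indels` attributes.
#' @export
mutation_spectrum <- function(records) {
  if (any(records$ref == records$alt))
    stop("record with ref == alt")
  is_snv <- nchar(records$ref) == 1L & nchar(records$alt) == 1L &
    records$ref %in% BASES & records$alt %in% BASES
  snv <- records[is_snv, , drop = FALSE]
  cls <- substitution_class(snv$ref, snv$alt)
  counts <- table(factor(cls, levels = SPECTRUM_CLASSES))
  n <- sum(counts)
  out <- data.frame(class = SPECTRUM_CLASSES, count = as.integer(counts),
                    proportion = if (n) as.numeric(counts) / n else
                      rep(0, length(SPECTRUM_CLASSES)),
                    stringsAsFactors = FALSE)
  attr(out, "n_snvs") <- n
  attr(out, "n_indels") <- sum(!is_snv)
  class(out) <- c("mutation_spectrum", "data.frame")
  out
}

#' Classify a discordant variant by direct pileup in the counterpart sample
#'
#' Re-examines a variant absent from one sample's call set: `CALLED` when
#' the counterpart's alt fraction reaches `min_af_call` at depth
#' `rescue_min_depth` or more; `DETECTED_BELOW_THRESHOLD` when alt reads
#' exist at adequate depth but the fraction is below threshold (subclonal
#' presence); `NOT_DETECTED_LOW_DEPTH` when the usable depth is below
#' `rescue_min_depth`; `NOT_DETECTED_NO_ALT` when depth is adequate and no
#' alt read is seen.
#'
#' @param alt_base the variant's alternative allele.
#' @param counterpart a [pileup_allele_counts()] result at the variant
#'   locus in the other sample.
#' @param cfg a [filter_config()].
#' @return one of `"CALLED"`, `"DETECTED_BELOW_THRESHOLD"`,
#'   `"NOT_DETECTED_LOW_DEPTH"`, `"NOT_DETECTED_NO_ALT"`.
#' @export
rescue_classify <- function(alt_base, counterpart, cfg = filter_config()) {
  depth <- counterpart$depth_after_filters
  alt <- sum(counterpart$counts[alt_base, ])
  if (depth < cfg$rescue_min_depth) return("NOT_DETECTED_LOW_DEPTH")
  if (alt == 0L) return("NOT_DETECTED_NO_ALT")
  if (alt / depth >= cfg$min_af_call) return("CALLED")
  "DETECTED_BELOW_THRESHOLD"
}

#' Host-contamination window check around a variant locus
#'
#' Extracts the reads whose alignments fall within `window` bases of the
#' locus and attempts to align each against the host genome with the
#' micro-aligner; any host-alignable read flags possible contamination at
#' the locus. The default mismatch budget of 2 is chosen for this detector
#' role: a genuine host read carries only sequencing errors (well under 2
#' mismatches at typical error rates over ~100 nt), while a graft read over
#' a homologous region at percent-scale divergence carries an order of
#' magnitude more, so the budget separates the two populations cleanly.
#'
#' @param graft_alignments `xp_alignments` with `seq` columns (graft
#'   alignment of the sample).
#' @param chrom,pos locus (1-based, graft coordinates).
#' @param host_index a [seed_index()] over the host genome.
#' @param window half-window in nt (default 1000).
#' @param max_mismatch micro-aligner mismatch budget (default 2).
#' @return list: `reads_examined`, `reads_host_alignable`, `empty_window`.
#' @export
host_window_check <- function(graft_alignments, chrom, pos, host_index,
                              window = 1000L, max_mismatch = 2L) {
  a <- graft_alignments
  lo <- pos - window; hi <- pos + window
  sel <- a$primary & a$mapped & !is.na(a$position) & a$reference == chrom &
    a$position <= hi & (a$position + a$width - 1L) >= lo
  sel[is.na(sel)] <- FALSE
  seqs <- a$seq[sel]
  if (!length(seqs))
    return(list(reads_examined = 0L, reads_host_alignable = 0L,
                empty_window = TRUE))
  res <- .xp_align_batch(host_index$ptr, toupper(seqs),
                         as.integer(max_mismatch))
  list(reads_examined = length(seqs),
       reads_host_alignable = sum(!is.na(res$position)),
       empty_window = FALSE)
}
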