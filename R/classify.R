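#' Classification configuration
#'
#' @param min_mapq minimum mapping quality for a record to count as mapped
#'   (default 20, the quality level at which a read-pair placement is
#'   treated as effectively unique; set 0 to disable the gate).
#' @param require_proper_pair require concordant pairs (default TRUE, the
#'   DNA workflow setting; RNA-seq libraries with spliced mates typically
#'   run with FALSE).
#' @param unit classification unit: `"pair"` (a fragment is mapped iff both
#'   mates pass) or `"single"`.
#' @param treat_mapq_unavailable_as how to treat MAPQ 255: `"mapped"`
#'   (default; the aligner asserted a location) or `"unmapped"`.
#' @return a `classify_config` list.
#' @export
classify_config <- function(min_mapq = 20L, require_proper_pair = TRUE,
                            unit = c("pair", "single"),
                            treat_mapq_unavailable_as = c("mapped", "unmapped")) {
  unit <- match.arg(unit)
  treat_mapq_unavailable_as <- match.arg(treat_mapq_unavailable_as)
  stopifnot(min_mapq >= 0L, min_mapq <= 60L)
  structure(list(min_mapq = as.integer(min_mapq),
                 require_proper_pair = require_proper_pair,
                 unit = unit,
                 treat_mapq_unavailable_as = treat_mapq_unavailable_as),
            class = "classify_config")
}

#' Collect the fragment ids that count as mapped to one genome
#'
#' Under `unit = "pair"` a fragment is mapped iff both primary mate records
#' are FLAG-mapped, (when required) properly paired, and the smaller of the
#' two MAPQs passes `min_mapq`. MAPQ 255 ("unavailable") passes or fails the
#' gate according to `treat_mapq_unavailable_as`.
#'
#' @param alignments an `xp_alignments` table from one genome.
#' @param cfg a [classify_config()].
#' @return character vector of mapped fragment ids.
#' @export
collect_mapped_ids <- function(alignments, cfg = classify_config()) {
  a <- alignments[alignments$primary, , drop = FALSE]
  if (cfg$unit == "pair" &&
      anyDuplicated(paste(a$id, a$mate, sep = "\r")))
    stop("malformed input: fragment with more than 2 primary mate records")
  mapq_eff <- a$mapq
  if (cfg$treat_mapq_unavailable_as == "mapped") {
    mapq_eff[!a$mapq_available] <- 60L
  } else {
    mapq_eff[!a$mapq_available] <- -1L
  }
  pass <- a$mapped & mapq_eff >= cfg$min_mapq
  if (cfg$require_proper_pair) pass <- pass & a$proper_pair
  if (cfg$unit == "single") return(unique(a$id[pass]))
  # both mates must pass
  n_pass <- tapply(pass, a$id, sum)
  n_rec <- tapply(rep(1L, nrow(a)), a$id, sum)
  names(n_pass)[n_pass == 2L & n_rec == 2L]
}

#' Partition a read universe into the four species-of-origin sets
#'
#' Pure set algebra on fragment ids: graft-specific ids mapped only to the
#' graft genome, host-specific only to the host, common to both, unmapped
#' to neither. The four sets are disjoint and cover the universe.
#'
#' @param universe all fragment ids in the library.
#' @param graft_mapped,host_mapped ids mapped to each genome (subsets of
#'   `universe`).
#' @return a `species_partition` list: `graft_specific`, `host_specific`,
#'   `common`, `unmapped` (character vectors), `universe_size`.
#' @export
partition_ids <- function(universe, graft_mapped, host_mapped) {
  universe <- unique(universe)
  graft_mapped <- unique(graft_mapped)
  host_mapped <- unique(host_mapped)
  stray <- setdiff(c(graft_mapped, host_mapped), universe)
  if (length(stray))
    stop("mapped ids outside the read universe: ",
         paste(head(stray, 5L), collapse = ", "),
         if (length(stray) > 5L) ", ..." else "")
  in_g <- universe %in% graft_mapped
  in_h <- universe %in% host_mapped
  part <- structure(list(graft_specific = universe[in_g & !in_h],
                         host_specific = universe[!in_g & in_h],
                         common = universe[in_g & in_h],
                         unmapped = universe[!in_g & !in_h],
                         universe_size = length(universe)),
                    class = "species_partition")
  validate_partition(part)
  part
}

validate_partition <- function(part) {
  sets <- part[c("graft_specific", "host_specific", "common", "unmapped")]
  all_ids <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("internal error: partition categories are not disjoint")
  if (length(all_ids) != part$universe_size)
    stop("internal error: partition does not cover the universe")
  invisible(part)
}

#' @export
print.species_partition <- function(x, ...) {
  cat("species_partition over", x$universe_size, "fragments:\n")
  for (s in c("graft_specific", "host_specific", "common", "unmapped"))
    cat(sprintf("  %-15s %d\n", s, length(x[[s]])))
  invisible(x)
}

#' Partition via the sequential align/realign/subtract recipe
#'
#' The stepwise workflow: a primary alignment to the graft genome splits the
#' universe into graft-mapped and graft-unmapped fragments; each subset is
#' then (re)examined against the host alignments — graft-mapped fragments
#' also mapped to the host form the common set, graft-unmapped fragments
#' mapped to the host form the host-specific set — and the common set is
#' subtracted from the primary graft-mapped set to leave the graft-specific
#' reads. Algebraically identical to [partition_ids()]; implemented
#' independently as the subset-restricted flow so the equivalence is a
#' checkable property rather than an assumption.
#'
#' @param universe fragment ids of the library.
#' @param graft_alignments,host_alignments `xp_alignments` tables against
#'   each genome.
#' @param cfg a [classify_config()].
#' @return a `species_partition`.
#' @export
partition_sequential <- function(universe, graft_alignments, host_alignments,
                                 cfg = classify_config()) {
  universe <- unique(universe)
  graft_mapped <- intersect(collect_mapped_ids(graft_alignments, cfg), universe)
  graft_unmapped <- setdiff(universe, graft_mapped)
  realign <- function(subset) {
    sub <- host_alignments[host_alignments$id %in% subset, , drop = FALSE]
    intersect(collect_mapped_ids(sub, cfg), subset)
  }
  common <- realign(graft_mapped)
  host_specific <- realign(graft_unmapped)
  graft_specific <- setdiff(graft_mapped, common)
  part <- structure(list(graft_specific = graft_specific,
                         host_specific = host_specific,
                         common = common,
                         unmapped = setdiff(graft_unmapped, host_specific),
                         universe_size = length(universe)),
                    class = "species_partition")
  validate_partition(part)
  part
}

#' Split a paired-end library into per-category FASTQ files
#'
#' @param pairs the `xp_pairs` universe.
#' @param partition a `species_partition` covering every pair id.
#' @param outdir output directory (created if needed); files are
#'   `<category>_1.fastq` / `<category>_2.fastq`.
#' @return named integer vector of written pair counts per category.
#' @export
split_reads <- function(pairs, partition, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cats <- c("graft_specific", "host_specific", "common", "unmapped")
  membership <- rep(NA_character_, nrow(pairs))
  for (cat in cats)
    membership[pairs$id %in% partition[[cat]]] <- cat
  if (anyNA(membership))
    stop("pairs not present in any partition category: ",
         paste(head(pairs$id[is.na(membership)], 5L), collapse = ", "))
  counts <- setNames(integer(length(cats)), cats)
  for (cat in cats) {
    sub <- pairs[membership == cat, , drop = FALSE]
    counts[cat] <- write_fastq_pairs(
      sub, file.path(outdir, paste0(cat, "_1.fastq")),
      file.path(outdir, paste0(cat, "_2.fastq")))
  }
  stopifnot(all(counts == vapply(partition[cats], length, integer(1))))
  counts
}

#' Summarize a species partition as counts and percentages
#'
#' @param partition a `species_partition`.
#' @param library_type tag recorded in the summary: `"wgs"`, `"exome"` or
#'   `"rnaseq"`.
#' @return a `partition_summary` data.frame: `category`, `count`, `percent`
#'   (of universe, 1 decimal), with the library tag as an attribute.
#' @export
summarize_partition <- function(partition,
                                library_type = c("wgs", "exome", "rnaseq")) {
  library_type <- match.arg(library_type)
  if (partition$universe_size == 0L) stop("empty read universe")
  cats <- c("graft_specific", "host_specific", "common", "unmapped")
  counts <- vapply(partition[cats], length, integer(1))
  out <- data.frame(category = cats, count = as.integer(counts),
                    percent = round(100 * counts / partition$universe_size, 1),
                    stringsAsFactors = FALSE)
  attr(out, "library_type") <- library_type
  class(out) <- c("partition_summary", "data.frame")
  out
}

#' Write a partition summary as TSV and JSON
#'
#' @param summary a [summarize_partition()] result.
#' @param tsv,json optional destination paths.
#' @return invisibly, the JSON string.
#' @export
write_partition_summary <- function(summary, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    write.table(summary, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  obj <- list(library_type = attr(summary, "library_type"),
              categories = summary)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(json)) writeLines(js, json)
  invisible(js)
}

#' Mark duplicate fragments by alignment coordinates
#'
#' Fragments sharing (mate-1 reference, mate-1 leftmost position, mate-1
#' strand, mate-2 reference, mate-2 position) form a duplicate group; the
#' member with the highest summed base quality stays unflagged, the rest
#' are flagged, with ties broken deterministically by fragment id. Intended
#' for the exome/WGS path; RNA-seq libraries are quantified without
#' de-duplication.
#'
#' @param alignments an `xp_alignments` table with `seq`/`qual` columns
#'   (qualities drive the kept-member choice; without them the first id
#'   wins).
#' @return the table with updated `duplicate` flags.
#' @export
mark_duplicates <- function(alignments) {
  a <- alignments
  prim <- a$primary & a$mapped
  m1 <- a[prim & a$mate == 1L, , drop = FALSE]
  m2 <- a[prim & a$mate == 2L, , drop = FALSE]
  both <- intersect(m1$id, m2$id)
  m1 <- m1[match(both, m1$id), , drop = FALSE]
  m2 <- m2[match(both, m2$id), , drop = FALSE]
  if (!length(both)) return(a)
  key <- paste(m1$reference, m1$position, m1$strand,
               m2$reference, m2$position, sep = "\r")
  qsum <- if (!is.null(a$qual)) {
    v1 <- vapply(m1$qual, function(q) sum(utf8ToInt(q)) - 33L * nchar(q),
                 numeric(1), USE.NAMES = FALSE)
    v2 <- vapply(m2$qual, function(q) sum(utf8ToInt(q)) - 33L * nchar(q),
                 numeric(1), USE.NAMES = FALSE)
    v1 + v2
  } else rep(0, length(both))
  ord <- order(key, -qsum, both)
  keep_first <- !duplicated(key[ord])
  dup_ids <- both[ord][!keep_first]
  a$duplicate <- a$duplicate | (a$id %in% dup_ids)
  a
}

#' Classify a paired-end library against two genomes end-to-end
#'
#' Convenience wrapper: collects mapped ids from both alignment sets,
#' partitions the universe, and summarizes.
#'
#' @param pairs the `xp_pairs` universe.
#' @param graft_alignments,host_alignments `xp_alignments` tables.
#' @param cfg a [classify_config()].
#' @param library_type tag for the summary.
#' @return list with `partition` and `summary`.
#' @export
classify_library <- function(pairs, graft_alignments, host_alignments,
                             cfg = classify_config(),
                             library_type = "wgs") {
  g <- collect_mapped_ids(graft_alignments, cfg)
  h <- collect_mapped_ids(host_alignments, cfg)
  universe <- unique(pairs$id)
  part <- partition_ids(universe, intersect(g, universe),
                        intersect(h, universe))
  list(partition = part,
       summary = summarize_partition(part, library_type))
}
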