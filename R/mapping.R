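# Read placement at a sequence-identity threshold and per-genome coverage
# summaries. The 95% default identity filter mirrors the conventional
# species demarcation boundary, so reads from another species' genome
# (ANI <= 95%) are mostly rejected.

#' Map reads onto a reference set
#'
#' Internal seed-and-extend placement: exact k-mer seeds at both read ends
#' locate candidate diagonals, the read is compared ungapped over its full
#' length on both strands, and the best-identity placement is kept (ties
#' broken by lowest global coordinate, then forward strand). Placements
#' with identity below `min_identity_pct` are suppressed. Reverse-strand
#' hits are reported in forward reference coordinates.
#'
#' @param reads A `read_set` from [simulate_metagenome()], a named
#'   character vector of sequences, or a data frame with columns `read_id`
#'   and `sequence`.
#' @param ref A [build_reference()] result.
#' @param min_identity_pct Minimum percent identity (default 95, the
#'   species demarcation threshold).
#' @param k Seed k-mer size (default 31; adequate for >= 95% identity at
#'   150 bp).
#' @return An `alignment_set` data frame: `read_id`, `genome_id`, `contig`,
#'   `start` (0-based), `aligned_length`, `matches`, `identity_pct`,
#'   `strand`.
#' @export
map_reads <- function(reads, ref, min_identity_pct = 95, k = 31L) {
  stopifnot(inherits(ref, "reference_set"))
  .check_number(min_identity_pct, "min_identity_pct", lower = 0,
                lower_open = TRUE, upper = 100)
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads) %||%
                          sprintf("read%06d", seq_along(reads)),
                        sequence = unname(reads), stringsAsFactors = FALSE)
  if (!NROW(reads)) .stopf("`reads` is empty")
  if (!all(c("read_id", "sequence") %in% names(reads)))
    .stopf("`reads` needs columns read_id and sequence")
  if (!nchar(ref$seq)) .stopf("reference is empty")

  hits <- cpp_map_reads(ref$seq, toupper(reads$sequence), as.integer(k),
                        min_identity_pct)
  if (!nrow(hits)) return(.empty_alignments())
  loc <- .globalize(ref, hits$start, hits$aligned_length)
  keep <- loc$ok
  out <- data.frame(
    read_id = reads$read_id[hits$read[keep]],
    genome_id = loc$genome_id[keep],
    contig = loc$contig[keep],
    start = loc$local_start[keep],
    aligned_length = hits$aligned_length[keep],
    matches = hits$matches[keep],
    strand = ifelse(hits$strand[keep] > 0, "+", "-"),
    stringsAsFactors = FALSE)
  out$identity_pct <- 100 * out$matches / out$aligned_length
  class(out) <- c("alignment_set", "data.frame")
  out
}

.empty_alignments <- function() {
  out <- data.frame(read_id = character(), genome_id = character(),
                    contig = integer(), start = integer(),
                    aligned_length = integer(), matches = integer(),
                    strand = character(), identity_pct = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("alignment_set", "data.frame")
  out
}

#' Import external alignments from SAM
#'
#' Lets an external mapper stand in for [map_reads()]. Reference sequence
#' names must follow the `"<genome_id>|<contig>"` dialect (a bare genome
#' id means contig 1). Unmapped, secondary and supplementary records are
#' ignored. Identity is computed from the `NM` tag when present
#' (`(aligned_length - NM) / aligned_length` with `aligned_length` the
#' number of M/=/X CIGAR bases), else from the substitution letters of the
#' `MD` tag; records carrying neither are skipped with a counted warning.
#' The same identity filter as in [map_reads()] is applied.
#'
#' @param sam Path to a SAM file, or a character vector of SAM lines.
#' @param ref A [build_reference()] result.
#' @param min_identity_pct Minimum percent identity (default 95).
#' @return An `alignment_set` data frame (see [map_reads()]).
#' @export
import_alignments <- function(sam, ref, min_identity_pct = 95) {
  stopifnot(inherits(ref, "reference_set"))
  rec <- read_sam_min(sam)
  if (!nrow(rec)) return(.empty_alignments())
  drop_flags <- bitwAnd(rec$flag, 0x4L) != 0L |
    bitwAnd(rec$flag, 0x100L) != 0L | bitwAnd(rec$flag, 0x800L) != 0L
  rec <- rec[!drop_flags, , drop = FALSE]
  if (!nrow(rec)) return(.empty_alignments())

  no_tag <- is.na(rec$nm) & is.na(rec$md)
  if (any(no_tag)) {
    warning(sprintf("%d SAM record(s) without NM or MD tag skipped",
                    sum(no_tag)), call. = FALSE)
    rec <- rec[!no_tag, , drop = FALSE]
    if (!nrow(rec)) return(.empty_alignments())
  }

  parts <- strsplit(rec$rname, "|", fixed = TRUE)
  gid <- vapply(parts, `[`, character(1), 1L)
  ctg <- vapply(parts, function(p) if (length(p) > 1L) as.integer(p[2]) else 1L,
                integer(1))
  known <- names(ref$genomes)
  if (length(setdiff(gid, known)))
    .stopf("SAM references unknown genome(s): %s",
           paste(unique(setdiff(gid, known)), collapse = ", "))

  aligned_length <- vapply(rec$cigar, .cigar_ref_consumed, integer(1),
                           USE.NAMES = FALSE)
  mismatches <- ifelse(is.na(rec$nm), .md_mismatches(rec$md), rec$nm)
  matches <- pmax(aligned_length - mismatches, 0L)
  out <- data.frame(
    read_id = rec$qname, genome_id = gid, contig = ctg,
    start = rec$pos - 1L,  # SAM is 1-based
    aligned_length = aligned_length, matches = matches,
    strand = ifelse(bitwAnd(rec$flag, 0x10L) != 0L, "-", "+"),
    stringsAsFactors = FALSE)
  out$identity_pct <- ifelse(out$aligned_length > 0,
                             100 * out$matches / out$aligned_length, 0)
  # bounds check against the reference
  for (i in seq_len(nrow(out))) {
    len <- nchar(ref$genomes[[out$genome_id[i]]]$contigs[out$contig[i]])
    if (out$start[i] < 0L || out$start[i] + out$aligned_length[i] > len)
      .stopf("SAM record '%s' extends beyond contig bounds", out$read_id[i])
  }
  out <- out[out$identity_pct >= min_identity_pct - 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alignment_set", "data.frame")
  out
}

# reference-consuming aligned bases: M, =, X
.cigar_ref_consumed <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(0L)
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  sum(n[op %in% c("M", "=", "X")])
}

# substitution count from an MD tag (deletion runs ^ACGT excluded)
.md_mismatches <- function(md) {
  vapply(md, function(x) {
    if (is.na(x)) return(NA_integer_)
    x <- gsub("\\^[ACGTN]+", "", x)
    sum(gregexpr("[ACGTN]", x)[[1]] > 0)
  }, integer(1), USE.NAMES = FALSE)
}

#' Compute per-genome coverage profiles
#'
#' Per-position depth is accumulated over the aligned spans, intersected
#' with the unmasked positions of each genome. Breadth is the percentage
#' of unmasked positions with depth >= `min_depth_for_breadth` (default 1;
#' the usual "covered at least once" notion), mean depth is total aligned
#' bases on unmasked positions divided by the unmasked length, and the
#' mapped-read percentage uses the total read count of the metagenome
#' before mapping as denominator.
#'
#' @param alignments An `alignment_set` from [map_reads()] or
#'   [import_alignments()].
#' @param ref The [build_reference()] result the alignments refer to.
#' @param total_reads Total number of input reads (>= number aligned).
#' @param min_depth_for_breadth Depth a position needs to count as covered.
#' @param keep_depth Keep the per-position depth vectors (over unmasked
#'   positions, contigs concatenated) in the result.
#' @return A named list of `coverage_profile` objects (one per reference
#'   genome, in reference order) with fields `genome_id`, `breadth_pct`,
#'   `mean_depth`, `mapped_reads`, `mapped_read_pct`, `unmasked_length`
#'   and optionally `depth`.
#' @export
compute_coverage <- function(alignments, ref, total_reads,
                             min_depth_for_breadth = 1L, keep_depth = FALSE) {
  stopifnot(inherits(ref, "reference_set"))
  .check_number(total_reads, "total_reads", lower = NROW(alignments))
  profiles <- list()
  for (gid in names(ref$genomes)) {
    g <- ref$genomes[[gid]]
    al <- alignments[alignments$genome_id == gid, , drop = FALSE]
    depth_sum <- 0
    covered <- 0L
    depth_all <- if (keep_depth) vector("list", length(g$contigs))
    for (ci in seq_along(g$contigs)) {
      len <- nchar(g$contigs[ci])
      sub <- al[al$contig == ci, , drop = FALSE]
      if (nrow(sub) &&
          any(sub$start < 0L | sub$start + sub$aligned_length > len))
        .stopf("alignment outside contig bounds (genome '%s' contig %d)",
               gid, ci)
      dense <- if (nrow(sub))
        as.integer(IRanges::coverage(IRanges::IRanges(sub$start + 1L,
                                                      width = sub$aligned_length),
                                     width = len))
      else integer(len)
      mi <- g$masked_intervals
      mi <- mi[mi$contig == ci, , drop = FALSE]
      unmasked <- rep(TRUE, len)
      for (j in seq_len(nrow(mi)))
        unmasked[(mi$start[j] + 1L):mi$end[j]] <- FALSE
      if (!any(unmasked)) next
      v <- dense[unmasked]
      depth_sum <- depth_sum + sum(as.numeric(v))
      covered <- covered + sum(v >= min_depth_for_breadth)
      if (keep_depth) depth_all[[ci]] <- v
    }
    ulen <- unname(ref$unmasked_length[gid])
    if (ulen == 0L) {
      warning(sprintf("genome '%s' is fully masked; breadth undefined, reported as 0",
                      gid), call. = FALSE)
      prof <- list(genome_id = gid, breadth_pct = 0, mean_depth = 0,
                   mapped_reads = nrow(al),
                   mapped_read_pct = 100 * nrow(al) / total_reads,
                   unmasked_length = 0L)
    } else {
      prof <- list(genome_id = gid,
                   breadth_pct = 100 * covered / ulen,
                   mean_depth = depth_sum / ulen,
                   mapped_reads = nrow(al),
                   mapped_read_pct = 100 * nrow(al) / total_reads,
                   unmasked_length = ulen)
    }
    if (keep_depth)
      prof$depth <- unlist(depth_all, use.names = FALSE) %||% integer()
    class(prof) <- "coverage_profile"
    profiles[[gid]] <- prof
  }
  profiles
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: breadth %.2f%%, mean depth %.3fx, %d reads (%.3f%%)\n",
              x$genome_id, x$breadth_pct, x$mean_depth, x$mapped_reads,
              x$mapped_read_pct))
  invisible(x)
}

#' Tabulate coverage profiles
#'
#' @param profiles List of `coverage_profile` objects.
#' @return Data frame with one row per genome.
#' @export
coverage_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(genome_id = p$genome_id, unmasked_length = p$unmasked_length,
               mapped_reads = p$mapped_reads,
               mapped_read_pct = p$mapped_read_pct,
               mean_depth = p$mean_depth, breadth_pct = p$breadth_pct,
               stringsAsFactors = FALSE, row.names = NULL)))
}
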