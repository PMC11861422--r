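# Synthetic community generator: genomes, divergent relatives, shared
# rRNA-operon-like repeats, and labelled shotgun reads. The generator
# provides the statistical structure the detection and taxonomy analyses
# assume: i.i.d. base composition, uniform read starts (Lander-Waterman
# coverage), i.i.d. substitution errors, and known genome-of-origin labels.

#' Construct a genome record
#'
#' A genome record holds the contig sequences of one (draft) genome
#' together with intervals to be masked during reference construction
#' (ribosomal-operon analogs). Intervals are 0-based, half-open, and are
#' normalized (sorted, merged) on construction.
#'
#' @param genome_id Single string identifying the genome.
#' @param contigs Character vector of contig sequences over A/C/G/T.
#' @param masked_intervals `NULL` or a data frame with columns `contig`
#'   (1-based contig index), `start`, `end` (0-based half-open).
#' @return An object of class `genome_record` with fields `genome_id`,
#'   `contigs`, `masked_intervals`, `total_length` and `gc_fraction`.
#' @export
genome_record <- function(genome_id, contigs, masked_intervals = NULL) {
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    .stopf("`genome_id` must be a non-empty string")
  if (!is.character(contigs) || length(contigs) < 1L)
    .stopf("`contigs` must be a non-empty character vector")
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGT]", contigs)
  if (any(bad))
    .stopf("contig %d of genome '%s' contains characters outside A/C/G/T",
           which(bad)[1], genome_id)
  lens <- nchar(contigs)
  masked_intervals <- .normalize_masks(masked_intervals, lens, genome_id)
  structure(list(
    genome_id = genome_id,
    contigs = unname(contigs),
    masked_intervals = masked_intervals,
    total_length = sum(lens),
    gc_fraction = .gc_fraction(contigs)
  ), class = "genome_record")
}

# Sort, bound-check and merge masked intervals. Returns a data frame with
# columns contig/start/end (0-based half-open), possibly zero rows.
.normalize_masks <- function(mi, contig_lengths, genome_id) {
  empty <- data.frame(contig = integer(), start = integer(), end = integer())
  if (is.null(mi) || NROW(mi) == 0L) return(empty)
  mi <- as.data.frame(mi)
  if (!all(c("contig", "start", "end") %in% names(mi)))
    .stopf("masked intervals need columns contig/start/end")
  mi$contig <- as.integer(mi$contig)
  mi$start <- as.integer(mi$start)
  mi$end <- as.integer(mi$end)
  if (any(mi$contig < 1L | mi$contig > length(contig_lengths)))
    .stopf("masked interval references an unknown contig of genome '%s'",
           genome_id)
  if (any(mi$start < 0L | mi$end > contig_lengths[mi$contig] | mi$start >= mi$end))
    .stopf("masked interval out of bounds in genome '%s'", genome_id)
  out <- lapply(sort(unique(mi$contig)), function(ci) {
    sub <- mi[mi$contig == ci, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
    data.frame(contig = ci, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %s bp, GC %.3f, %d masked interval(s)\n",
              x$genome_id, length(x$contigs), format(x$total_length, big.mark = ","),
              x$gc_fraction, nrow(x$masked_intervals)))
  invisible(x)
}

#' Generate a random genome
#'
#' Bases are drawn i.i.d. with P(G) + P(C) = `gc`, split evenly between G/C
#' and A/T, and the sequence is split into `n_contigs` near-equal contigs.
#'
#' @param length_bp Total genome length in bp (>= 1000).
#' @param gc Target GC fraction in \[0, 1\].
#' @param n_contigs Number of contigs (each at least 500 bp).
#' @param genome_id Identifier; default `"genome"`.
#' @param seed Optional integer seed; the same seed reproduces the genome
#'   bit-identically.
#' @return A [genome_record].
#' @examples
#' g <- generate_genome(10000, gc = 0.42, seed = 1)
#' g$gc_fraction
#' @export
generate_genome <- function(length_bp, gc, n_contigs = 1L, genome_id = "genome",
                            seed = NULL) {
  .check_number(length_bp, "length_bp", lower = 1000)
  .check_number(gc, "gc", lower = 0, upper = 1)
  .check_number(n_contigs, "n_contigs", lower = 1, upper = length_bp / 500)
  length_bp <- as.integer(length_bp)
  n_contigs <- as.integer(n_contigs)
  with_seed(seed, {
    base_len <- length_bp %/% n_contigs
    lens <- rep(base_len, n_contigs)
    extra <- length_bp - sum(lens)
    if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
    contigs <- vapply(lens, .rand_dna, character(1), gc = gc)
    genome_record(genome_id, contigs)
  })
}

#' Derive a divergent relative of a genome
#'
#' Each site is independently substituted with probability
#' `substitution_rate`, choosing uniformly among the three alternative
#' bases (no transition/transversion bias). Expected nucleotide identity
#' to the parent is `100 * (1 - substitution_rate)` percent. Masked
#' intervals are carried over unchanged.
#'
#' @param parent A [genome_record].
#' @param substitution_rate Per-site substitution probability in \[0, 0.35).
#' @param genome_id Identifier of the relative; defaults to
#'   `<parent id>_rel`.
#' @param seed Optional integer seed.
#' @return A [genome_record] with the same contig structure as `parent`.
#' @export
derive_relative <- function(parent, substitution_rate, genome_id = NULL,
                            seed = NULL) {
  stopifnot(inherits(parent, "genome_record"))
  .check_number(substitution_rate, "substitution_rate", lower = 0,
                upper = 0.35, upper_open = TRUE)
  genome_id <- genome_id %||% paste0(parent$genome_id, "_rel")
  with_seed(seed, {
    contigs <- vapply(parent$contigs, function(s) {
      r <- utf8ToInt(s)
      hit <- which(runif(length(r)) < substitution_rate)
      if (length(hit)) {
        cur <- match(r[hit], .BASE_CODES)
        # shift by 1..3 modulo 4: uniform over the three other bases
        new <- (cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L
        r[hit] <- .BASE_CODES[new]
      }
      intToUtf8(r)
    }, character(1), USE.NAMES = FALSE)
    genome_record(genome_id, contigs, parent$masked_intervals)
  })
}

#' Plant a shared repeat into every genome
#'
#' Inserts one common random repeat sequence (an rRNA-operon analog:
#' near-identical across otherwise divergent genomes) at random positions
#' into every genome, recording each insertion in `masked_intervals`.
#' Insertion points are drawn outside existing masked intervals so that
#' interval bookkeeping remains a simple shift.
#'
#' @param genomes List of [genome_record] objects.
#' @param repeat_length Length of the shared repeat (>= 100 bp).
#' @param copies_per_genome Number of insertions per genome (0 = no-op).
#' @param gc GC fraction of the repeat sequence.
#' @param seed Optional integer seed.
#' @return List of modified [genome_record] objects; every genome grows by
#'   `copies_per_genome * repeat_length` bp.
#' @export
plant_shared_repeat <- function(genomes, repeat_length, copies_per_genome = 1L,
                                gc = 0.5, seed = NULL) {
  if (!is.list(genomes) || length(genomes) == 0L ||
      !all(vapply(genomes, inherits, logical(1), "genome_record")))
    .stopf("`genomes` must be a non-empty list of genome_record objects")
  .check_number(repeat_length, "repeat_length", lower = 100)
  .check_number(copies_per_genome, "copies_per_genome", lower = 0)
  repeat_length <- as.integer(repeat_length)
  copies_per_genome <- as.integer(copies_per_genome)
  if (copies_per_genome == 0L) return(genomes)
  max_contig <- max(vapply(genomes, function(g) max(nchar(g$contigs)), numeric(1)))
  if (repeat_length > max_contig)
    .stopf("repeat_length (%d) exceeds the longest contig (%d)",
           repeat_length, max_contig)
  with_seed(seed, {
    rep_seq <- .rand_dna(repeat_length, gc)
    lapply(genomes, function(g) {
      contigs <- g$contigs
      mi <- g$masked_intervals
      for (i in seq_len(copies_per_genome)) {
        lens <- nchar(contigs)
        ci <- sample.int(length(contigs), 1L, prob = lens)
        # position outside existing masked intervals of that contig
        repeat {
          pos <- sample.int(lens[ci] + 1L, 1L) - 1L  # 0..len
          cur <- mi[mi$contig == ci, , drop = FALSE]
          if (!nrow(cur) || all(pos <= cur$start | pos >= cur$end)) break
        }
        contigs[ci] <- paste0(substr(contigs[ci], 1L, pos), rep_seq,
                              substr(contigs[ci], pos + 1L, lens[ci]))
        shift <- mi$contig == ci & mi$start >= pos
        mi$start[shift] <- mi$start[shift] + repeat_length
        mi$end[shift] <- mi$end[shift] + repeat_length
        mi <- rbind(mi, data.frame(contig = ci, start = pos,
                                   end = pos + repeat_length))
      }
      genome_record(g$genome_id, contigs, mi)
    })
  })
}

#' Describe a synthetic metagenome
#'
#' @param members Named numeric vector of relative abundances (genome id ->
#'   abundance); abundances must be positive and sum to 1.
#' @param n_reads Number of reads to simulate.
#' @param read_length Read length in bp (default 150, the common paired-end
#'   short-read length).
#' @param substitution_error_rate Per-base substitution error rate in
#'   \[0, 1).
#' @param seed Integer seed used by [simulate_metagenome()].
#' @return An object of class `community_design`.
#' @export
community_design <- function(members, n_reads, read_length = 150L,
                             substitution_error_rate = 0, seed = NULL) {
  if (!is.numeric(members) || is.null(names(members)) ||
      any(!nzchar(names(members))))
    .stopf("`members` must be a named numeric vector of abundances")
  if (any(members <= 0))
    .stopf("relative abundances must be positive")
  if (abs(sum(members) - 1) > 1e-6)
    .stopf("relative abundances must sum to 1 (got %.6f)", sum(members))
  .check_number(n_reads, "n_reads", lower = 1)
  .check_number(read_length, "read_length", lower = 20)
  .check_number(substitution_error_rate, "substitution_error_rate",
                lower = 0, upper = 1, upper_open = TRUE)
  structure(list(
    members = members,
    n_reads = as.integer(n_reads),
    read_length = as.integer(read_length),
    substitution_error_rate = substitution_error_rate,
    seed = seed
  ), class = "community_design")
}

#' Simulate a shotgun metagenome
#'
#' Read origins are drawn proportional to `abundance * genome_length`
#' (abundances are organism abundances, so sequence yield scales with
#' genome size), start positions are uniform within contigs (reads that
#' would run off a contig end are never produced: linear contigs), strands
#' are random, and substitution errors are i.i.d. per base. Truth labels
#' (genome, contig, 0-based forward start, strand) are recorded in the
#' returned table and encoded in the read identifiers
#' (`read000001|src=<genome>|ctg=<i>|pos=<p>|str=<+/->`) so external SAM
#' round-trips preserve them.
#'
#' @param design A [community_design].
#' @param genomes List of [genome_record]; every member id must resolve.
#' @return A `read_set`: data frame with columns `read_id`, `sequence`,
#'   `truth_genome_id`, `truth_contig`, `truth_position`, `truth_strand`.
#' @export
simulate_metagenome <- function(design, genomes) {
  stopifnot(inherits(design, "community_design"))
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  miss <- setdiff(names(design$members), ids)
  if (length(miss))
    .stopf("community member(s) not found among genomes: %s",
           paste(miss, collapse = ", "))
  gl <- setNames(vapply(genomes, function(g) g$total_length, numeric(1)), ids)
  rl <- design$read_length
  with_seed(design$seed, {
    w <- design$members * gl[names(design$members)]
    origin <- sample(names(design$members), design$n_reads, replace = TRUE,
                     prob = w)
    out <- vector("list", length(design$members))
    names(out) <- names(design$members)
    for (gid in names(design$members)) {
      n_g <- sum(origin == gid)
      if (n_g == 0L) next
      g <- genomes[[match(gid, ids)]]
      lens <- nchar(g$contigs)
      eligible <- pmax(lens - rl + 1L, 0L)
      if (all(eligible == 0L))
        .stopf("all contigs of genome '%s' are shorter than the read length", gid)
      ctg <- sample.int(length(lens), n_g, replace = TRUE, prob = eligible)
      start <- integer(n_g)
      for (ci in unique(ctg)) {
        sel <- ctg == ci
        start[sel] <- sample.int(eligible[ci], sum(sel), replace = TRUE) - 1L
      }
      seqs <- substring(g$contigs[ctg], start + 1L, start + rl)
      # i.i.d. substitution errors
      e <- design$substitution_error_rate
      if (e > 0) {
        n_err <- rbinom(n_g, rl, e)
        for (j in which(n_err > 0L)) {
          r <- utf8ToInt(seqs[j])
          pos <- sample.int(rl, n_err[j])
          cur <- match(r[pos], .BASE_CODES)
          new <- (cur - 1L + sample.int(3L, length(pos), replace = TRUE)) %% 4L + 1L
          r[pos] <- .BASE_CODES[new]
          seqs[j] <- intToUtf8(r)
        }
      }
      fwd <- runif(n_g) < 0.5
      seqs[!fwd] <- vapply(seqs[!fwd], .revcomp, character(1), USE.NAMES = FALSE)
      out[[gid]] <- data.frame(
        sequence = seqs, truth_genome_id = gid, truth_contig = ctg,
        truth_position = start, truth_strand = ifelse(fwd, "+", "-"),
        stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, out)
    rownames(reads) <- NULL
    # restore the sampling order of origins so read ids are stream-stable
    ord <- order(match(reads$truth_genome_id, names(design$members)))
    reads <- reads[ord, , drop = FALSE]
    reads$read_id <- sprintf("read%06d|src=%s|ctg=%d|pos=%d|str=%s",
                             seq_len(nrow(reads)), reads$truth_genome_id,
                             reads$truth_contig, reads$truth_position,
                             reads$truth_strand)
    reads <- reads[, c("read_id", "sequence", "truth_genome_id",
                       "truth_contig", "truth_position", "truth_strand")]
    class(reads) <- c("read_set", "data.frame")
    reads
  })
}

#' Parse truth labels back out of read identifiers
#'
#' Inverse of the identifier scheme used by [simulate_metagenome()]; lets
#' externally mapped reads (SAM round-trips) be audited against their true
#' genome of origin.
#'
#' @param read_ids Character vector of read identifiers.
#' @return Data frame with columns `read_id`, `truth_genome_id`,
#'   `truth_contig`, `truth_position`, `truth_strand` (`NA` where the id
#'   carries no labels).
#' @export
read_truth <- function(read_ids) {
  m <- regmatches(read_ids,
    regexec("\\|src=([^|]+)\\|ctg=(\\d+)\\|pos=(\\d+)\\|str=([+-])", read_ids))
  got <- lengths(m) == 5L
  data.frame(
    read_id = read_ids,
    truth_genome_id = ifelse(got, vapply(m, function(x) x[2] %||% NA_character_,
                                         character(1)), NA_character_),
    truth_contig = ifelse(got, as.integer(vapply(m, function(x) x[3] %||% NA,
                                                 character(1))), NA_integer_),
    truth_position = ifelse(got, as.integer(vapply(m, function(x) x[4] %||% NA,
                                                   character(1))), NA_integer_),
    truth_strand = ifelse(got, vapply(m, function(x) x[5] %||% NA_character_,
                                      character(1)), NA_character_),
    stringsAsFactors = FALSE)
}

#' Expected coverage breadth under the Lander-Waterman model
#'
#' Under Poisson-distributed coverage at mean depth d, the expected
#' fraction of positions covered at least once is `1 - exp(-d)`.
#'
#' @param mean_depth Non-negative mean coverage depth (vectorized).
#' @return Expected breadth in percent.
#' @examples
#' expected_breadth(1)   # 63.212
#' @export
expected_breadth <- function(mean_depth) {
  if (!is.numeric(mean_depth) || any(is.na(mean_depth)) || any(mean_depth < 0))
    .stopf("`mean_depth` must be non-negative")
  100 * (1 - exp(-mean_depth))
}
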