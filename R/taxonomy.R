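# Overall genome relatedness indices and the species demarcation rule:
# fragment-based average nucleotide identity (the classic 1020 bp /
# 70% identity / 70% coverage convention), a digital DNA-DNA
# hybridization estimate from the d4 statistic (1 - summed identities
# over high-scoring segment pairs divided by total HSP length), and
# terminal-gap-trimmed 16S rRNA identity. Two genomes belong to the same
# species iff ANI >= 95% and dDDH >= 70%; 16S identity >= 98.7% alone is
# never sufficient.

.as_genome_contigs <- function(x, default_id = "genome") {
  if (inherits(x, "genome_record")) return(x)
  if (is.character(x)) return(genome_record(default_id, x))
  .stopf("expected a genome_record or character sequence(s)")
}

# consecutive full-length fragments per contig (tail shorter than
# fragment_bp dropped)
.cut_fragments <- function(g, fragment_bp) {
  unlist(lapply(g$contigs, function(s) {
    n <- nchar(s)
    k <- n %/% fragment_bp
    if (k == 0L) return(character())
    st <- (seq_len(k) - 1L) * fragment_bp + 1L
    substring(s, st, st + fragment_bp - 1L)
  }), use.names = FALSE)
}

# contigs joined with an N spacer so fragments cannot match across junctions
.subject_string <- function(g, spacer = 50L) {
  paste(g$contigs, collapse = strrep("N", spacer))
}

.one_direction_hits <- function(query, subject, fragment_bp, k, seed_step) {
  frags <- .cut_fragments(query, fragment_bp)
  hits <- cpp_fragment_hits(frags, .subject_string(subject), as.integer(k),
                            as.integer(seed_step))
  hits$identity_pct <- ifelse(hits$found & hits$overlap > 0,
                              100 * hits$matches / hits$overlap, 0)
  hits$coverage <- ifelse(hits$found, hits$overlap / fragment_bp, 0)
  hits
}

#' Fragment-based average nucleotide identity
#'
#' The query genome is cut into consecutive `fragment_bp` fragments, each
#' fragment is placed on the subject by seed-and-extend on both strands,
#' and fragments aligning at >= `min_fragment_identity_pct` identity over
#' >= `min_fragment_cov` of their length are kept. ANI is the mean
#' identity of kept fragments, computed in both directions and averaged
#' (hence symmetric).
#'
#' @param a,b [genome_record] objects (or plain sequences), each at least
#'   `10 * fragment_bp` long.
#' @param fragment_bp Fragment size (default 1020).
#' @param min_fragment_identity_pct,min_fragment_cov Fragment filters
#'   (defaults 70 and 0.7).
#' @param k,seed_step Seed k-mer size and spacing used for placement.
#' @return An `ani_result`: `genome_a`, `genome_b`, `ani_pct`,
#'   `aligned_fraction`, `fragments_total`, `fragments_used`, `flagged`
#'   (`TRUE` when a direction retained no fragments, in which case
#'   `ani_pct` is reported as 0).
#' @export
fragment_ani <- function(a, b, fragment_bp = 1020L,
                         min_fragment_identity_pct = 70,
                         min_fragment_cov = 0.7, k = 15L, seed_step = 40L) {
  a <- .as_genome_contigs(a, "genome_a")
  b <- .as_genome_contigs(b, "genome_b")
  fragment_bp <- as.integer(fragment_bp)
  if (a$total_length < 10L * fragment_bp || b$total_length < 10L * fragment_bp)
    .stopf("both genomes must be at least 10 * fragment_bp = %d bp",
           10L * fragment_bp)
  dirs <- list(ab = .one_direction_hits(a, b, fragment_bp, k, seed_step),
               ba = .one_direction_hits(b, a, fragment_bp, k, seed_step))
  ani_dir <- frac_dir <- numeric(2)
  used <- total <- integer(2)
  for (i in 1:2) {
    h <- dirs[[i]]
    keep <- h$found & h$identity_pct >= min_fragment_identity_pct &
      h$coverage >= min_fragment_cov
    total[i] <- nrow(h)
    used[i] <- sum(keep)
    ani_dir[i] <- if (used[i]) mean(h$identity_pct[keep]) else NA_real_
    frac_dir[i] <- if (total[i]) used[i] / total[i] else 0
  }
  flagged <- any(used == 0L)
  structure(list(
    genome_a = a$genome_id, genome_b = b$genome_id,
    ani_pct = if (flagged) 0 else mean(ani_dir),
    aligned_fraction = mean(frac_dir),
    fragments_total = sum(total), fragments_used = sum(used),
    flagged = flagged), class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> %s vs %s: ANI %.2f%% (aligned fraction %.2f, %d/%d fragments)%s\n",
              x$genome_a, x$genome_b, x$ani_pct, x$aligned_fraction,
              x$fragments_used, x$fragments_total,
              if (x$flagged) " [flagged: no aligned fragments]" else ""))
  invisible(x)
}

#' Calibration of the d4 -> dDDH transform
#'
#' Logistic mapping `ddh_pct = 100 / (1 + exp(intercept + slope * d4))`
#' from the d4 distance (1 - summed identities over HSPs / total HSP
#' length) to a DNA-DNA hybridization percentage. This is the package's
#' own calibration: it is anchored so that d4 = 0 maps to ~99.9% and
#' d4 = 0.05 maps to 70%, i.e. the conventional 70% dDDH species boundary
#' coincides with the 95% ANI boundary.
#'
#' @format A list with elements `intercept` and `slope`.
#' @export
ddh_calibration <- list(intercept = -7, slope = 123.05)

.ddh_from_d4 <- function(d4, calibration = ddh_calibration) {
  100 / (1 + exp(calibration$intercept + calibration$slope * d4))
}

#' Digital DNA-DNA hybridization estimate (d4 statistic)
#'
#' High-scoring segment pairs are found by the same seeded ungapped
#' placement as [fragment_ani()] (fragments aligning at >= 70% identity
#' over >= 70% of their length, both directions). The distance is
#' `d4 = 1 - sum(identities) / sum(HSP lengths)` and is mapped to a DDH
#' percentage with the logistic transform in [ddh_calibration].
#'
#' @inheritParams fragment_ani
#' @return A `ddh_result`: `genome_a`, `genome_b`, `d4_distance`,
#'   `ddh_pct`, `n_hsps`, `flagged` (no HSPs: `ddh_pct` 0).
#' @export
gbdp_d4 <- function(a, b, fragment_bp = 1020L, k = 15L, seed_step = 40L) {
  a <- .as_genome_contigs(a, "genome_a")
  b <- .as_genome_contigs(b, "genome_b")
  if (a$total_length < fragment_bp || b$total_length < fragment_bp)
    .stopf("genomes must be at least one fragment long")
  dirs <- list(.one_direction_hits(a, b, fragment_bp, k, seed_step),
               .one_direction_hits(b, a, fragment_bp, k, seed_step))
  match_sum <- 0
  len_sum <- 0
  n_hsps <- 0L
  for (h in dirs) {
    keep <- h$found & h$identity_pct >= 70 & h$coverage >= 0.7
    match_sum <- match_sum + sum(h$matches[keep])
    len_sum <- len_sum + sum(h$overlap[keep])
    n_hsps <- n_hsps + sum(keep)
  }
  if (len_sum == 0) {
    return(structure(list(genome_a = a$genome_id, genome_b = b$genome_id,
                          d4_distance = NA_real_, ddh_pct = 0,
                          n_hsps = 0L, flagged = TRUE),
                     class = "ddh_result"))
  }
  d4 <- 1 - match_sum / len_sum
  structure(list(genome_a = a$genome_id, genome_b = b$genome_id,
                 d4_distance = d4, ddh_pct = .ddh_from_d4(d4),
                 n_hsps = n_hsps, flagged = FALSE),
            class = "ddh_result")
}

#' @export
print.ddh_result <- function(x, ...) {
  cat(sprintf("<ddh_result> %s vs %s: d4 %.4f, dDDH %.1f%%%s\n",
              x$genome_a, x$genome_b, x$d4_distance, x$ddh_pct,
              if (x$flagged) " [flagged: no HSPs]" else ""))
  invisible(x)
}

#' Pairwise 16S rRNA gene identity
#'
#' The two sequences are globally aligned with free end gaps and identity
#' is computed as matches over aligned columns, excluding terminal-gap
#' columns (the "align, then trim" convention for marker genes).
#'
#' @param seq_a,seq_b Nucleotide sequences of at least 500 bp.
#' @return Percent identity.
#' @export
pairwise_16s_identity <- function(seq_a, seq_b) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L)
    .stopf("`seq_a` and `seq_b` must be single sequences")
  if (nchar(seq_a) < 500L || nchar(seq_b) < 500L)
    .stopf("sequences must be at least 500 bp")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(seq_a)), Biostrings::DNAString(toupper(seq_b)),
    type = "overlap", substitutionMatrix = sm,
    gapOpening = 5, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / cols
}

#' Apply the species demarcation rule
#'
#' Two genomes are conspecific iff ANI >= `ani_threshold` (95%) and
#' dDDH >= `ddh_threshold` (70%). 16S identity is reported as supporting
#' evidence only: values at or above `s16_threshold` (98.7%) are
#' inconclusive (closely related species routinely share >98.7% 16S
#' identity), values below it indicate distinct species.
#'
#' @param ani An `ani_result` for the pair.
#' @param ddh A `ddh_result` for the same pair.
#' @param s16_pct Optional 16S identity in percent.
#' @param ani_threshold,ddh_threshold,s16_threshold Demarcation constants.
#' @return A `species_decision` with the verdict and an evidence table
#'   (criterion, threshold, value, verdict).
#' @export
species_demarcation <- function(ani, ddh, s16_pct = NULL,
                                ani_threshold = 95, ddh_threshold = 70,
                                s16_threshold = 98.7) {
  stopifnot(inherits(ani, "ani_result"), inherits(ddh, "ddh_result"))
  if (!setequal(c(ani$genome_a, ani$genome_b), c(ddh$genome_a, ddh$genome_b)))
    .stopf("ANI pair (%s, %s) does not match dDDH pair (%s, %s)",
           ani$genome_a, ani$genome_b, ddh$genome_a, ddh$genome_b)
  same <- ani$ani_pct >= ani_threshold && ddh$ddh_pct >= ddh_threshold
  ev <- data.frame(
    criterion = c("ani", "ddh"),
    threshold = c(ani_threshold, ddh_threshold),
    value = c(ani$ani_pct, ddh$ddh_pct),
    verdict = c(
      if (ani$ani_pct >= ani_threshold) "same" else "distinct",
      if (ddh$ddh_pct >= ddh_threshold) "same" else "distinct"),
    stringsAsFactors = FALSE)
  if (!is.null(s16_pct)) {
    ev <- rbind(ev, data.frame(
      criterion = "16s", threshold = s16_threshold, value = s16_pct,
      verdict = if (s16_pct >= s16_threshold)
        "inconclusive" else "distinct",
      stringsAsFactors = FALSE))
  }
  structure(list(genome_a = ani$genome_a, genome_b = ani$genome_b,
                 ani_pct = ani$ani_pct, ddh_pct = ddh$ddh_pct,
                 s16_identity_pct = s16_pct, same_species = same,
                 evidence = ev),
            class = "species_decision")
}

#' @export
print.species_decision <- function(x, ...) {
  cat(sprintf("<species_decision> %s vs %s: %s\n", x$genome_a, x$genome_b,
              if (x$same_species) "SAME species" else "DISTINCT species"))
  print(x$evidence, row.names = FALSE)
  invisible(x)
}
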