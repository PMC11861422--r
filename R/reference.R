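# Concatenated mapping reference: all genomes joined into one coordinate
# system with masked intervals (ribosomal-operon analogs) hard-masked to N,
# mirroring a reference "with all ribosomal operons removed". Contigs and
# genomes are separated by N spacers so reads can never align across a
# junction.

#' Build a concatenated, masked mapping reference
#'
#' Joins the contigs of all genomes into a single sequence with per-contig
#' global offsets. Masked intervals -- those embedded in the genome records
#' plus any supplied externally -- are merged per contig, hard-masked to
#' `N` in the concatenated sequence (so no read can seed or match there),
#' and excluded from the breadth/depth denominators.
#'
#' @param genomes A [genome_record] or list of them; genome ids must be
#'   unique.
#' @param masks Optional BED-style data frame with columns `chrom`
#'   (`"<genome_id>|<contig>"` dialect, or a bare genome id meaning contig
#'   1), `start`, `end` (0-based half-open), merged with the embedded
#'   intervals.
#' @param apply_masks If `FALSE`, intervals are recorded but not masked in
#'   the mapping sequence (cross-mapping of shared repeats then occurs, as
#'   it would without operon removal). Denominators still exclude them.
#' @param spacer Number of `N` characters inserted between contigs.
#' @return An object of class `reference_set` with the concatenated
#'   sequence, a contig table (genome_id, contig, global_start, length),
#'   per-genome masked intervals and unmasked lengths.
#' @export
build_reference <- function(genomes, masks = NULL, apply_masks = TRUE,
                            spacer = 200L) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  if (!is.list(genomes) || !length(genomes) ||
      !all(vapply(genomes, inherits, logical(1), "genome_record")))
    .stopf("`genomes` must be genome_record objects")
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) .stopf("genome ids must be unique")
  names(genomes) <- ids
  spacer <- as.integer(spacer)

  # merge external BED masks into the per-genome interval tables
  if (!is.null(masks) && NROW(masks)) {
    masks <- as.data.frame(masks)
    if (!all(c("chrom", "start", "end") %in% names(masks)))
      .stopf("`masks` needs columns chrom/start/end")
    parts <- strsplit(as.character(masks$chrom), "|", fixed = TRUE)
    gid <- vapply(parts, `[`, character(1), 1L)
    ctg <- vapply(parts, function(p) if (length(p) > 1L) as.integer(p[2]) else 1L,
                  integer(1))
    unknown <- setdiff(gid, ids)
    if (length(unknown))
      .stopf("mask references unknown genome(s): %s",
             paste(unique(unknown), collapse = ", "))
    for (i in seq_along(gid)) {
      g <- genomes[[gid[i]]]
      add <- data.frame(contig = ctg[i], start = masks$start[i],
                        end = masks$end[i])
      genomes[[gid[i]]] <- genome_record(g$genome_id, g$contigs,
                                         rbind(g$masked_intervals, add))
    }
  }

  # contig table with 0-based global offsets
  rows <- list()
  pieces <- list()
  offset <- 0L
  pad <- strrep("N", spacer)
  for (gid in ids) {
    g <- genomes[[gid]]
    for (ci in seq_along(g$contigs)) {
      s <- g$contigs[ci]
      if (apply_masks) {
        mi <- g$masked_intervals
        mi <- mi[mi$contig == ci, , drop = FALSE]
        if (nrow(mi)) {
          r <- utf8ToInt(s)
          for (j in seq_len(nrow(mi)))
            r[(mi$start[j] + 1L):mi$end[j]] <- 78L  # 'N'
          s <- intToUtf8(r)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, contig = ci, global_start = offset,
        length = nchar(g$contigs[ci]), stringsAsFactors = FALSE)
      pieces[[length(pieces) + 1L]] <- s
      offset <- offset + nchar(s) + spacer
    }
  }
  contig_table <- do.call(rbind, rows)
  masked_bp <- vapply(genomes, function(g) {
    if (!nrow(g$masked_intervals)) 0L
    else sum(g$masked_intervals$end - g$masked_intervals$start)
  }, integer(1))
  unmasked <- vapply(genomes, function(g) g$total_length, integer(1)) - masked_bp

  structure(list(
    genomes = genomes,
    contig_table = contig_table,
    seq = paste(unlist(pieces), collapse = pad),
    spacer = spacer,
    apply_masks = apply_masks,
    unmasked_length = unmasked
  ), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d genome(s), %d contig(s), %s bp concatenated (masks %s)\n",
              length(x$genomes), nrow(x$contig_table),
              format(nchar(x$seq), big.mark = ","),
              if (x$apply_masks) "applied" else "recorded only"))
  invisible(x)
}

# Map 0-based global coordinates to (genome, contig, local start); hits
# falling in spacers or crossing a contig end are dropped.
.globalize <- function(ref, start, len) {
  ct <- ref$contig_table
  row <- findInterval(start, ct$global_start)
  ok <- row >= 1L
  ok[ok] <- start[ok] + len[ok] <= ct$global_start[row[ok]] + ct$length[row[ok]]
  list(row = row, ok = ok,
       genome_id = ifelse(ok, ct$genome_id[row], NA_character_),
       contig = ifelse(ok, ct$contig[row], NA_integer_),
       local_start = ifelse(ok, start - ct$global_start[row], NA_integer_))
}
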