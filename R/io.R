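# File-format round-trips shared by the pipeline stages. FASTA/FASTQ go
# through Biostrings; Newick through ape; models and run logs are JSON;
# reports are TSV with a versioned schema header. BED is 0-based
# half-open; SAM positions are converted from 1-based on ingestion.

#' Read sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (ids truncated at the first whitespace).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, or a [genome_record] (contigs are
#'   written as `<genome_id>|<contig>`).
#' @param path Output path.
#' @param width Line wrap width (default 80).
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (inherits(seqs, "genome_record"))
    seqs <- setNames(seqs$contigs,
                     sprintf("%s|%d", seqs$genome_id, seq_along(seqs$contigs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}

#' Read reads from FASTQ
#'
#' @param path Path to a FASTQ file.
#' @return Named character vector of sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads to FASTQ (constant quality)
#'
#' @param reads A `read_set` or named character vector of sequences.
#' @param path Output path.
#' @param quality_char Single Phred+33 quality character applied to every
#'   base (default `"I"`, Q40).
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  if (is.data.frame(reads)) reads <- setNames(reads$sequence, reads$read_id)
  x <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), strrep,
                                        character(1), x = quality_char))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a 3-column BED file of mask intervals
#'
#' @param path Path to a BED file (0-based half-open intervals).
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- tryCatch(
    read.table(path, sep = "\t", comment.char = "#",
               col.names = c("chrom", "start", "end"),
               colClasses = c("character", "integer", "integer")),
    error = function(e) .stopf("malformed BED file '%s': %s", path,
                               conditionMessage(e)))
  if (any(bed$start < 0L | bed$end <= bed$start))
    .stopf("BED file '%s' contains invalid intervals", path)
  bed
}

#' Write a 3-column BED file
#'
#' @param bed Data frame with columns `chrom`, `start`, `end`, or a
#'   [genome_record] (masked intervals written as `<genome_id>|<contig>`).
#' @param path Output path.
#' @export
write_bed <- function(bed, path) {
  if (inherits(bed, "genome_record"))
    bed <- data.frame(chrom = sprintf("%s|%d", bed$genome_id,
                                      bed$masked_intervals$contig),
                      start = bed$masked_intervals$start,
                      end = bed$masked_intervals$end)
  write.table(bed[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Minimal SAM ingestion
#'
#' Parses the mandatory fields plus the `NM` and `MD` optional tags of a
#' SAM text stream; header lines are skipped. Used by
#' [import_alignments()].
#'
#' @param sam Path to a SAM file, or a character vector of SAM lines.
#' @return Data frame with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based), `cigar`, `nm`, `md` (`NA` where a tag is absent).
#' @export
read_sam_min <- function(sam) {
  lines <- if (length(sam) == 1L && !grepl("\t", sam) && file.exists(sam))
    readLines(sam) else sam
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      cigar = character(), nm = integer(), md = character(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short))
    .stopf("malformed SAM record at line %d (fewer than 11 fields)", short[1])
  get <- function(i) vapply(fields, `[`, character(1), i)
  tag_val <- function(prefix) {
    vapply(fields, function(f) {
      opt <- f[-(1:11)]
      hit <- opt[startsWith(opt, prefix)]
      if (length(hit)) sub(prefix, "", hit[1], fixed = TRUE) else NA_character_
    }, character(1))
  }
  data.frame(
    qname = get(1), flag = as.integer(get(2)), rname = get(3),
    pos = as.integer(get(4)), cigar = get(6),
    nm = suppressWarnings(as.integer(tag_val("NM:i:"))),
    md = tag_val("MD:Z:"), stringsAsFactors = FALSE)
}

#' Write a tree to Newick
#'
#' Branch lengths and internal-node support labels are preserved.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Serialize a threshold model to JSON
#'
#' @param model A [threshold_model].
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  jsonlite::write_json(
    list(a = model$a, b = model$b, c = model$c, source = model$source,
         fit_rmse = model$rmse, genome_id = model$genome_id),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a threshold model from JSON
#'
#' @param path Path to a model JSON file.
#' @return A [threshold_model].
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path)
  threshold_model(a = x$a, b = x$b, c = x$c,
                  source = x$source %||% "fitted",
                  rmse = x$fit_rmse %||% NA_real_,
                  genome_id = x$genome_id %||% NA_character_)
}

REPORT_SCHEMA_VERSION <- "0.1.0"

#' Write a report table as TSV with a schema header
#'
#' The first line is `#aquadetect=<version>`; the table follows with a
#' header row.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @export
write_report_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#aquadetect=%s", REPORT_SCHEMA_VERSION), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a report TSV written by [write_report_tsv()]
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_report_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}
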