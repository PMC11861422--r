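# Deterministic sequence helpers and small fixtures shared across tests.

BASE4 <- c(65L, 67L, 71L, 84L)  # utf8 codes of A C G T

# substitute at n random positions (cyclic base shift: always a change)
mutate_seq <- function(s, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- utf8ToInt(s)
  pos <- sample(length(r), n)
  cur <- match(r[pos], BASE4)
  r[pos] <- BASE4[(cur %% 4L) + 1L]
  intToUtf8(r)
}

# substitute at fixed positions
mutate_at <- function(s, positions) {
  r <- utf8ToInt(s)
  cur <- match(r[positions], BASE4)
  r[positions] <- BASE4[(cur %% 4L) + 1L]
  intToUtf8(r)
}

rand_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  intToUtf8(BASE4[sample.int(4L, n, replace = TRUE, prob = p)])
}

# four-taxon, two-clade nucleotide alignment with clear internal structure
clade_alignment <- function(n_cols = 600, seed = 2) {
  set.seed(seed)
  anc <- rand_dna(n_cols)
  clade_a <- mutate_seq(anc, round(n_cols * 0.07))
  clade_b <- mutate_seq(anc, round(n_cols * 0.07))
  multiple_alignment(c(
    A1 = mutate_seq(clade_a, 4), A2 = mutate_seq(clade_a, 5),
    B1 = mutate_seq(clade_b, 4), B2 = mutate_seq(clade_b, 6)))
}

# naive per-position coverage oracle: dense counting over one genome,
# masked positions excluded from depth vector and denominators
naive_coverage <- function(alignments, genome) {
  lens <- nchar(genome$contigs)
  depth <- lapply(lens, function(l) integer(l))
  al <- alignments[alignments$genome_id == genome$genome_id, , drop = FALSE]
  for (i in seq_len(nrow(al))) {
    ci <- al$contig[i]
    span <- (al$start[i] + 1L):(al$start[i] + al$aligned_length[i])
    depth[[ci]][span] <- depth[[ci]][span] + 1L
  }
  v <- unlist(lapply(seq_along(lens), function(ci) {
    keep <- rep(TRUE, lens[ci])
    mi <- genome$masked_intervals
    mi <- mi[mi$contig == ci, , drop = FALSE]
    for (j in seq_len(nrow(mi))) keep[(mi$start[j] + 1L):mi$end[j]] <- FALSE
    depth[[ci]][keep]
  }))
  list(depth = v, breadth_pct = 100 * mean(v >= 1L), mean_depth = mean(v))
}

make_ani <- function(a, b, pct, flagged = FALSE) {
  structure(list(genome_a = a, genome_b = b, ani_pct = pct,
                 aligned_fraction = 0.9, fragments_total = 100L,
                 fragments_used = 90L, flagged = flagged),
            class = "ani_result")
}

make_ddh <- function(a, b, pct) {
  structure(list(genome_a = a, genome_b = b, d4_distance = NA_real_,
                 ddh_pct = pct, n_hsps = 10L, flagged = FALSE),
            class = "ddh_result")
}

sam_line <- function(qname, rname, pos, seq, flag = 0L,
                     cigar = paste0(nchar(seq), "M"), tags = character()) {
  paste(c(qname, flag, rname, pos, 60L, cigar, "*", 0L, 0L, seq, "*", tags),
        collapse = "\t")
}
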