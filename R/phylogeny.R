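# Distance-based phylogenetics as configured for near-full-length 16S
# analyses of closely related freshwater bacteria: Kimura two-parameter
# distances (optionally gamma-corrected) with pairwise gap deletion,
# neighbour joining, bootstrap support, midpoint rooting; plus core-gene
# selection from pan-genomes and a conserved-block column filter for
# concatenated alignments.

#' Construct a multiple alignment
#'
#' @param rows Named character vector: taxon -> aligned sequence. All rows
#'   must have equal length; gaps are `-`.
#' @return An object of class `multiple_alignment` with fields `taxa`,
#'   `rows` and `length`.
#' @export
multiple_alignment <- function(rows) {
  if (!is.character(rows) || is.null(names(rows)) || anyDuplicated(names(rows)))
    .stopf("`rows` must be a named character vector with unique taxa")
  lens <- nchar(rows)
  if (length(unique(lens)) > 1L)
    .stopf("alignment rows differ in length")
  structure(list(taxa = names(rows), rows = toupper(rows),
                 length = unname(lens[1] %||% 0L)),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d taxa x %d columns\n",
              length(x$taxa), x$length))
  invisible(x)
}

# character matrix view (taxa x columns)
.aln_matrix <- function(aln) {
  if (aln$length == 0L)
    return(matrix(character(), nrow = length(aln$taxa), ncol = 0,
                  dimnames = list(aln$taxa, NULL)))
  m <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(m) <- aln$taxa
  m
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Transitions (A<->G, C<->T) and transversions are counted over sites
#' where both rows carry an unambiguous base; gaps and ambiguity codes are
#' pairwise-deleted. The distance is
#' `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with transition proportion P
#' and transversion proportion Q; with a gamma shape `a` the rate-
#' heterogeneous form
#' `d = a/2 ((1-2P-Q)^(-1/a) + (1-2Q)^(-1/a)/2 - 3/2)` is used.
#'
#' @param row_a,row_b Aligned sequences of equal length.
#' @param gamma_shape Optional gamma shape parameter (rate heterogeneity
#'   across sites); `NULL` for the uncorrected distance.
#' @param min_sites Minimum number of comparable sites (default 50).
#' @return The K2P distance (substitutions per site).
#' @examples
#' a <- strrep("ACGT", 25)
#' k2p_distance(a, a)  # 0
#' @export
k2p_distance <- function(row_a, row_b, gamma_shape = NULL, min_sites = 50L) {
  if (nchar(row_a) != nchar(row_b))
    .stopf("aligned rows must have equal length")
  a <- utf8ToInt(toupper(row_a))
  b <- utf8ToInt(toupper(row_b))
  ia <- match(a, .BASE_CODES)
  ib <- match(b, .BASE_CODES)
  ok <- !is.na(ia) & !is.na(ib)
  n <- sum(ok)
  if (n < min_sites)
    .stopf("only %d comparable sites after pairwise deletion (need >= %d)",
           n, min_sites)
  ia <- ia[ok]
  ib <- ib[ok]
  diff <- ia != ib
  # purines A,G are codes 1,3; pyrimidines C,T are 2,4: a transition keeps
  # parity of the base code
  transition <- diff & ((ia %% 2L) == (ib %% 2L))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    .stopf("K2P distance saturated (P = %.3f, Q = %.3f)", P, Q)
  if (is.null(gamma_shape)) {
    -0.5 * log(w1) - 0.25 * log(w2)
  } else {
    .check_number(gamma_shape, "gamma_shape", lower = 0, lower_open = TRUE)
    gamma_shape / 2 * (w1^(-1 / gamma_shape) + 0.5 * w2^(-1 / gamma_shape) - 1.5)
  }
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param aln A [multiple_alignment] with at least 3 taxa.
#' @inheritParams k2p_distance
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
distance_matrix <- function(aln, gamma_shape = NULL, min_sites = 50L) {
  stopifnot(inherits(aln, "multiple_alignment"))
  n <- length(aln$taxa)
  if (n < 3L) .stopf("need at least 3 taxa")
  d <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- tryCatch(
        k2p_distance(aln$rows[i], aln$rows[j], gamma_shape, min_sites),
        error = function(e)
          .stopf("distance between '%s' and '%s' failed: %s",
                 aln$taxa[i], aln$taxa[j], conditionMessage(e)))
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); negative intermediate branch
#' lengths are clamped to zero. The returned tree is unrooted.
#'
#' @param dm Symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @return An \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!is.matrix(dm) || nrow(dm) < 3L) .stopf("need a matrix over >= 3 taxa")
  if (any(!is.finite(dm))) .stopf("distance matrix contains non-finite entries")
  tr <- ape::nj(as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbour-joining tree with bootstrap support
#'
#' Alignment columns are resampled with replacement `n_replicates` times;
#' a replicate tree is built from each resampled alignment and the support
#' of every internal bipartition of the full-data tree is the percentage
#' of replicates containing it (stored as node labels). Replicates whose
#' distances saturate are dropped and counted; more than 5% dropped raises
#' a warning.
#'
#' @param aln A [multiple_alignment].
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @inheritParams k2p_distance
#' @param seed Optional integer seed; fixed seeds reproduce supports.
#' @return The full-data NJ `phylo` tree with percent support as
#'   `node.label` and attributes `n_effective` / `n_dropped`.
#' @export
bootstrap_support <- function(aln, n_replicates = 1000L, gamma_shape = NULL,
                              seed = NULL, min_sites = 50L) {
  stopifnot(inherits(aln, "multiple_alignment"))
  .check_number(n_replicates, "n_replicates", lower = 1)
  full <- nj_tree(distance_matrix(aln, gamma_shape, min_sites))
  m <- .aln_matrix(aln)
  with_seed(seed, {
    reps <- vector("list", n_replicates)
    dropped <- 0L
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rows <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
      rep_aln <- multiple_alignment(rows)
      tr <- tryCatch(nj_tree(distance_matrix(rep_aln, gamma_shape, min_sites)),
                     error = function(e) NULL)
      if (is.null(tr)) dropped <- dropped + 1L else reps[[r]] <- tr
    }
    reps <- reps[!vapply(reps, is.null, logical(1))]
    if (dropped > 0.05 * n_replicates)
      warning(sprintf("%d of %d bootstrap replicates dropped (saturation)",
                      dropped, n_replicates), call. = FALSE)
    if (!length(reps)) .stopf("all bootstrap replicates failed")
    counts <- ape::prop.clades(full, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    full$node.label <- round(100 * counts / length(reps), 1)
    attr(full, "n_effective") <- length(reps)
    attr(full, "n_dropped") <- dropped
    full
  })
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path
#' (via \pkg{phangorn}). All pairwise leaf path lengths are preserved.
#'
#' @param tree An unrooted `phylo` tree with >= 2 leaves.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) .stopf("need at least 2 leaves")
  if (is.null(tree$edge.length) || all(tree$edge.length == 0))
    .stopf("cannot midpoint-root a tree with all-zero branch lengths")
  phangorn::midpoint(tree)
}

# -- core-gene selection ------------------------------------------------

# percent identity of a global alignment: matches over aligned columns
.global_identity <- function(patterns, subject, type) {
  sm <- if (type == "protein") "BLOSUM62"
  else Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                baseOnly = FALSE)
  pat <- if (type == "protein") Biostrings::AAStringSet(patterns)
  else Biostrings::DNAStringSet(patterns)
  subj <- if (type == "protein") Biostrings::AAString(subject)
  else Biostrings::DNAString(subject)
  aln <- Biostrings::pairwiseAlignment(pat, subj, type = "global",
                                       substitutionMatrix = sm)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / cols
}

#' Select core gene families from per-genome gene sets
#'
#' Greedy centroid clustering: genes (longest first) join the first
#' existing family whose centroid they match at >= `min_identity_pct`
#' global identity, else found a new family. Families with at least one
#' member in 100% of genomes are core. One representative per genome per
#' core family (the first encountered) is aligned with the internal
#' center-star aligner and the family alignments are concatenated in
#' stable family order.
#'
#' @param gene_sets Named list (genome -> named character vector of
#'   protein sequences); >= 2 genomes, each with >= 1 gene.
#' @param min_identity_pct Clustering identity threshold (default 70, the
#'   usual blastp core-genome setting).
#' @return A list with `families` (data frame `family_id`,
#'   `n_genomes_present`, `n_members`, `core`), `membership` (data frame
#'   `family_id`, `genome`, `gene_id`), `n_core`, and `core_alignment`
#'   (a [multiple_alignment] of the concatenated core families, or `NULL`
#'   with a warning when no family is core).
#' @export
core_gene_selection <- function(gene_sets, min_identity_pct = 70) {
  if (!is.list(gene_sets) || length(gene_sets) < 2L ||
      is.null(names(gene_sets)))
    .stopf("`gene_sets` must be a named list of >= 2 genomes")
  if (any(vapply(gene_sets, length, integer(1)) == 0L))
    .stopf("every genome needs at least one gene")
  genomes <- names(gene_sets)
  genes <- do.call(rbind, lapply(genomes, function(g) {
    s <- gene_sets[[g]]
    data.frame(genome = g,
               gene_id = names(s) %||% sprintf("%s_g%03d", g, seq_along(s)),
               seq = toupper(unname(s)), stringsAsFactors = FALSE)
  }))
  genes <- genes[order(-nchar(genes$seq)), , drop = FALSE]

  centroids <- character()
  family <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (length(centroids)) {
      ident <- .global_identity(centroids, genes$seq[i], "protein")
      best <- which.max(ident)
      if (ident[best] >= min_identity_pct) {
        family[i] <- best
        next
      }
    }
    centroids <- c(centroids, genes$seq[i])
    family[i] <- length(centroids)
  }
  genes$family_id <- sprintf("fam%04d", family)

  fam_ids <- sort(unique(genes$family_id))
  present <- vapply(fam_ids, function(f)
    length(unique(genes$genome[genes$family_id == f])), integer(1))
  families <- data.frame(
    family_id = fam_ids, n_genomes_present = present,
    n_members = as.integer(table(genes$family_id)[fam_ids]),
    core = present == length(genomes), stringsAsFactors = FALSE,
    row.names = NULL)

  core_ids <- families$family_id[families$core]
  core_alignment <- NULL
  if (!length(core_ids)) {
    warning("no core families at the given identity threshold", call. = FALSE)
  } else {
    blocks <- lapply(core_ids, function(f) {
      sub <- genes[genes$family_id == f, , drop = FALSE]
      reps <- vapply(genomes, function(g) sub$seq[sub$genome == g][1],
                     character(1))
      star_align(reps, type = "protein")
    })
    rows <- vapply(genomes, function(g)
      paste(vapply(blocks, function(b) b$rows[match(g, b$taxa)], character(1)),
            collapse = ""), character(1))
    core_alignment <- multiple_alignment(rows)
  }
  list(families = families,
       membership = genes[, c("family_id", "genome", "gene_id")],
       n_core = length(core_ids), core_alignment = core_alignment)
}

#' Center-star multiple alignment
#'
#' Simple progressive alignment: the longest sequence is the center, all
#' others are globally aligned to it pairwise, and insertions relative to
#' the center are merged across the pairwise alignments ("once a gap,
#' always a gap").
#'
#' @param seqs Named character vector of sequences.
#' @param type `"protein"` or `"dna"`.
#' @return A [multiple_alignment].
#' @export
star_align <- function(seqs, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  seqs <- toupper(seqs)
  if (length(seqs) == 1L) return(multiple_alignment(seqs))
  center_i <- which.max(nchar(seqs))
  center <- seqs[center_i]
  others <- seqs[-center_i]
  nc <- nchar(center)

  sm <- if (type == "protein") "BLOSUM62"
  else Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                baseOnly = FALSE)
  mk <- if (type == "protein") Biostrings::AAString else Biostrings::DNAString

  # For each member: member characters per center position, plus the
  # insertion strings that fall after center position 0..nc.
  pieces <- lapply(others, function(s) {
    aln <- Biostrings::pairwiseAlignment(mk(s), mk(center), type = "global",
                                         substitutionMatrix = sm)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    at_pos <- character(nc)      # member char aligned to center position
    ins <- vector("list", nc + 1L)  # insertions after center position 0..nc
    for (x in seq_len(nc + 1L)) ins[[x]] <- character()
    cpos <- 0L
    for (col in seq_along(sa)) {
      if (sa[col] == "-") {
        ins[[cpos + 1L]] <- c(ins[[cpos + 1L]], pa[col])
      } else {
        cpos <- cpos + 1L
        at_pos[cpos] <- pa[col]
      }
    }
    list(at_pos = at_pos, ins_len = lengths(ins), ins = ins)
  })

  master_ins <- rep(0L, nc + 1L)
  for (p in pieces) master_ins <- pmax(master_ins, p$ins_len)

  expand_row <- function(at_pos, ins) {
    out <- character()
    for (x in 0:nc) {
      here <- if (is.null(ins)) character() else ins[[x + 1L]]
      out <- c(out, here, rep("-", master_ins[x + 1L] - length(here)))
      if (x < nc) out <- c(out, at_pos[x + 1L])
    }
    paste(out, collapse = "")
  }
  rows <- c(setNames(expand_row(strsplit(center, "")[[1]], NULL),
                     names(seqs)[center_i]),
            vapply(seq_along(pieces), function(i)
              expand_row(pieces[[i]]$at_pos, pieces[[i]]$ins), character(1)))
  names(rows) <- c(names(seqs)[center_i], names(others))
  multiple_alignment(rows[names(seqs)])
}

#' Filter an alignment down to conserved blocks
#'
#' Simplified conserved-block selection: columns whose gap fraction
#' exceeds `max_gap_fraction` are removed, and surviving runs of
#' consecutive kept columns shorter than `min_block_length` are removed
#' too.
#'
#' @param aln A [multiple_alignment].
#' @param max_gap_fraction Maximum tolerated per-column gap fraction.
#' @param min_block_length Minimum length of a kept block.
#' @return The filtered [multiple_alignment], with attributes
#'   `kept_positions` (original column indices) and `n_blocks`; empty
#'   output raises a warning.
#' @export
conserved_block_filter <- function(aln, max_gap_fraction = 0.5,
                                   min_block_length = 10L) {
  stopifnot(inherits(aln, "multiple_alignment"))
  m <- .aln_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  r <- rle(keep)
  r$values[r$values & r$lengths < min_block_length] <- FALSE
  keep <- inverse.rle(r)
  n_blocks <- sum(rle(keep)$values)
  if (!any(keep)) {
    warning("no columns survive the conserved-block filter", call. = FALSE)
    out <- multiple_alignment(setNames(rep("", length(aln$taxa)), aln$taxa))
  } else {
    rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
    out <- multiple_alignment(rows)
  }
  attr(out, "kept_positions") <- which(keep)
  attr(out, "n_blocks") <- n_blocks
  out
}
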