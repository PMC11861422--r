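# K2P distances, neighbour joining, bootstrap, midpoint rooting,
# core-gene selection and conserved-block filtering.

test_that("K2P distances match closed forms and an independent oracle", {
  a100 <- strrep("A", 100)
  expect_equal(k2p_distance(a100, a100), 0)
  # 10 transitions (A->G), no transversions: -0.5 ln(0.8)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_distance(a100, b), 0.1115718, tolerance = 1e-6)

  # gap and N columns are pairwise-deleted
  a_g <- paste0(a100, "----", "NNNN")
  b_g <- paste0(b, "CCCC", "TTTT")
  expect_equal(k2p_distance(a_g, b_g), k2p_distance(a100, b))

  # oracle: ape::dist.dna on constructed (P, Q) pairs, plain and gamma
  set.seed(71)
  for (i in 1:20) {
    n <- 1000L
    nP <- sample(0:150, 1)   # A->G transitions
    nQ <- sample(0:120, 1)   # A->C transversions
    row_a <- strrep("A", n)
    row_b <- paste0(strrep("G", nP), strrep("C", nQ), strrep("A", n - nP - nQ))
    m <- rbind(strsplit(tolower(row_a), "")[[1]],
               strsplit(tolower(row_b), "")[[1]])
    rownames(m) <- c("a", "b")
    bin <- ape::as.DNAbin(m)
    expect_equal(k2p_distance(row_a, row_b),
                 as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-9)
    expect_equal(k2p_distance(row_a, row_b, gamma_shape = 0.5),
                 as.numeric(ape::dist.dna(bin, model = "K80", gamma = 0.5)),
                 tolerance = 1e-9)
  }

  # saturation raises an error rather than returning infinity
  sat <- paste0(strrep("G", 60), strrep("C", 40))
  expect_error(k2p_distance(a100, sat), "saturated")
  expect_error(k2p_distance(substr(a100, 1, 30), substr(a100, 1, 30)),
               "comparable sites")
})

test_that("distance matrices are symmetric, permutable and oracle-equal", {
  aln <- clade_alignment(seed = 72)
  dm <- distance_matrix(aln)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
  # elementwise brute-force recomputation
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(dm[i, j], k2p_distance(aln$rows[i], aln$rows[j]))
  # permuting taxa permutes the matrix consistently
  perm <- c(3, 1, 4, 2)
  dm_p <- distance_matrix(multiple_alignment(aln$rows[perm]))
  expect_equal(dm_p, dm[perm, perm])
  # identical rows give the zero matrix
  same <- multiple_alignment(setNames(rep(strrep("ACGT", 30), 3),
                                      c("x", "y", "z")))
  expect_true(all(distance_matrix(same) == 0))
})

test_that("neighbour joining recovers additive trees exactly", {
  # 4-taxon additive matrix: topology and all path lengths recovered
  tr <- ape::read.tree(text = "((A:0.10,B:0.20):0.05,(C:0.15,D:0.30):0.07);")
  dm <- cophenetic(tr)
  njt <- nj_tree(dm)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), njt), 0)
  expect_equal(cophenetic(njt)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-9)

  # 3 taxa: closed-form three-point branch lengths
  dm3 <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nj3 <- nj_tree(dm3)
  expect_equal(sort(nj3$edge.length), c(0.1, 0.2, 0.4), tolerance = 1e-9)

  # ultrametric matrix: NJ topology equals UPGMA topology
  set.seed(73)
  ut <- ape::rcoal(8)
  dmu <- cophenetic(ut)
  upgma <- ape::as.phylo(stats::hclust(as.dist(dmu), method = "average"))
  expect_equal(phangorn::RF.dist(nj_tree(dmu), ape::unroot(upgma)), 0)

  # random additive matrices, exact recovery (subset; full 100 seeds in
  # the acceptance suite)
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:12, 1)
    rt <- ape::unroot(ape::rtree(n))
    rt$edge.length <- runif(nrow(rt$edge), 0.05, 1)
    expect_equal(phangorn::RF.dist(nj_tree(cophenetic(rt)), rt), 0)
  }

  dm_bad <- dm3
  dm_bad[1, 2] <- dm_bad[2, 1] <- Inf
  expect_error(nj_tree(dm_bad), "non-finite")
})

test_that("bootstrap supports separate clean clades and are reproducible", {
  aln <- clade_alignment(seed = 74)
  bt <- bootstrap_support(aln, n_replicates = 100, seed = 75)
  expect_true(all(bt$node.label >= 0 & bt$node.label <= 100))
  # the (A1,A2)|(B1,B2) split has many diagnostic columns
  expect_gte(min(bt$node.label), 95)
  bt2 <- bootstrap_support(aln, n_replicates = 100, seed = 75)
  expect_identical(bt$node.label, bt2$node.label)
  expect_identical(ape::write.tree(bt), ape::write.tree(bt2))

  # identical sequences: star-like tree, all branch lengths zero
  same <- multiple_alignment(setNames(rep(strrep("ACGT", 40), 4),
                                      c("p", "q", "r", "s")))
  st <- nj_tree(distance_matrix(same))
  expect_true(all(st$edge.length == 0))
})

test_that("midpoint rooting balances the longest path and preserves distances", {
  tr <- ape::read.tree(
    text = "((((A:1,B:1):1,C:1):1,D:1):1,E:10);")
  tr <- ape::unroot(tr)
  rooted <- midpoint_root(tr)
  expect_true(ape::is.rooted(rooted))
  # path lengths between leaves unchanged by re-rooting
  expect_equal(cophenetic(rooted)[tr$tip.label, tr$tip.label],
               cophenetic(tr)[tr$tip.label, tr$tip.label], tolerance = 1e-9)
  # both root children reach their deepest leaf at diameter/2
  depths <- ape::node.depth.edgelength(rooted)
  diameter <- max(cophenetic(tr))
  expect_equal(max(depths[seq_along(rooted$tip.label)]), diameter / 2,
               tolerance = 1e-9)

  zero <- tr
  zero$edge.length[] <- 0
  expect_error(midpoint_root(zero), "all-zero")
})

test_that("core-gene selection finds exactly the planted shared families", {
  set.seed(76)
  n_shared <- 15L
  shared <- replicate(n_shared, aquadetect:::.rand_protein(sample(80:120, 1)))
  mut_prot <- function(s, n) {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    r <- strsplit(s, "")[[1]]
    pos <- sample(length(r), n)
    r[pos] <- sample(aa, n, replace = TRUE)
    paste(r, collapse = "")
  }
  gene_sets <- lapply(setNames(nm = c("gA", "gB", "gC")), function(g) {
    fams <- vapply(shared, mut_prot, character(1), n = 3)
    priv <- replicate(4, aquadetect:::.rand_protein(sample(60: 100, 1)))
    setNames(c(fams, priv), sprintf("%s_gene%02d", g, seq_len(n_shared + 4)))
  })
  cg <- core_gene_selection(gene_sets)
  expect_equal(cg$n_core, n_shared)
  expect_equal(sum(cg$families$core), n_shared)
  # concatenation length is the sum of aligned family lengths and taxa
  # order is stable
  expect_identical(cg$core_alignment$taxa, c("gA", "gB", "gC"))
  expect_gte(cg$core_alignment$length, sum(vapply(shared, nchar, integer(1))))

  # dropping one family from one genome removes it from the core
  gs2 <- gene_sets
  gs2$gC <- gs2$gC[-1]
  expect_equal(core_gene_selection(gs2)$n_core, n_shared - 1L)

  # identical gene sets: every family is core
  gs3 <- list(x = gene_sets$gA, y = gene_sets$gA)
  cg3 <- core_gene_selection(gs3)
  expect_true(all(cg3$families$core))
})

test_that("the conserved-block filter drops gappy columns and short blocks", {
  clean <- multiple_alignment(c(a = strrep("ACGT", 10), b = strrep("ACGT", 10)))
  out <- conserved_block_filter(clean)
  expect_equal(out$length, 40L)
  expect_equal(attr(out, "n_blocks"), 1L)

  # a 5-column conserved island between gappy regions falls below the
  # minimum block length and is dropped
  island <- multiple_alignment(c(
    a = paste0(strrep("A-", 10), "CCCCC", strrep("-A", 10), strrep("G", 12)),
    b = paste0(strrep("-A", 10), "CCCCC", strrep("A-", 10), strrep("G", 12))))
  outi <- conserved_block_filter(island, max_gap_fraction = 0.4,
                                 min_block_length = 10)
  expect_equal(outi$length, 12L)  # only the trailing G block survives
  expect_equal(attr(outi, "n_blocks"), 1L)

  # an all-gap column can never survive
  gappy <- multiple_alignment(c(a = paste0(strrep("A", 20), "-"),
                                b = paste0(strrep("A", 20), "-")))
  expect_equal(conserved_block_filter(gappy)$length, 20L)

  all_gap <- multiple_alignment(c(a = strrep("-", 30), b = strrep("A", 30)))
  expect_warning(empty <- conserved_block_filter(all_gap,
                                                 max_gap_fraction = 0.2),
                 "no columns")
  expect_equal(empty$length, 0L)
})
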