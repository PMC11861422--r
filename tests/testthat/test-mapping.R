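# Read mapping, identity filtering, SAM ingestion and coverage
# computation.

test_that("error-free reads place on their genome of origin at full identity", {
  base <- generate_genome(60000, 0.45, genome_id = "spA", seed = 1)
  other <- derive_relative(base, 0.2, genome_id = "spB", seed = 2)
  ref <- build_reference(list(base, other))
  rs <- simulate_metagenome(
    community_design(c(spA = 0.5, spB = 0.5), n_reads = 2000, seed = 3),
    list(base, other))
  al <- map_reads(rs, ref)
  expect_gte(nrow(al) / nrow(rs), 0.99)
  expect_true(all(al$identity_pct == 100))
  truth <- read_truth(al$read_id)
  expect_gte(mean(al$genome_id == truth$truth_genome_id), 0.99)
  # placements are at the true coordinates
  same <- al$genome_id == truth$truth_genome_id
  expect_gte(mean(al$start[same] == truth$truth_position[same]), 0.99)
})

test_that("the identity filter boundary sits exactly at 95%", {
  g <- generate_genome(20000, 0.5, genome_id = "g", seed = 4)
  ref <- build_reference(list(g))
  window <- substr(g$contigs[1], 1001, 1150)  # 150 bp
  # mismatches kept away from the 31 bp seed regions at either end
  read7 <- mutate_at(window, seq(40, 112, by = 12))   # 7 mismatches: 95.33%
  read8 <- mutate_at(window, seq(40, 124, by = 12))   # 8 mismatches: 94.67%
  al <- map_reads(c(keep = read7, drop = read8), ref)
  expect_identical(al$read_id, "keep")
  expect_equal(al$matches, 143L)
  expect_equal(al$start, 1000L)
  # 1000 bp probe: 50 mismatches (95.0%) retained, 51 (94.9%) suppressed
  w2 <- substr(g$contigs[1], 5001, 6000)
  al2 <- map_reads(c(keep = mutate_at(w2, seq(50, by = 18, length.out = 50)),
                     drop = mutate_at(w2, seq(50, by = 18, length.out = 51))),
                   ref)
  expect_identical(al2$read_id, "keep")
  expect_equal(al2$identity_pct, 95)
})

test_that("reverse-strand reads are reported in forward coordinates", {
  g <- generate_genome(10000, 0.5, genome_id = "g", seed = 5)
  ref <- build_reference(list(g))
  fwd <- substr(g$contigs[1], 2001, 2150)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  al <- map_reads(c(r = rc), ref)
  expect_equal(al$start, 2000L)
  expect_identical(al$strand, "-")
  expect_equal(al$identity_pct, 100)
})

test_that("high sequencing error collapses the mapped fraction at the 95% filter", {
  g <- generate_genome(50000, 0.5, genome_id = "g", seed = 6)
  ref <- build_reference(list(g))
  mk <- function(err, seed) simulate_metagenome(
    community_design(c(g = 1), n_reads = 1000, read_length = 150,
                     substitution_error_rate = err, seed = seed), list(g))
  clean <- map_reads(mk(0, 7), ref)
  noisy <- map_reads(mk(0.10, 8), ref)
  expect_gte(nrow(clean) / 1000, 0.99)
  # P(Binom(150, 0.1) <= 7) ~ 1.2%: almost everything is filtered
  expect_lt(nrow(noisy) / 1000, 0.05)
})

test_that("SAM records are ingested with NM/MD identity and flag semantics", {
  g <- genome_record("g1", rand_dna(1000, seed = 9))
  ref <- build_reference(list(g))
  seq150 <- substr(g$contigs[1], 101, 250)
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:g1|1\tLN:1000",
    sam_line("perfect", "g1|1", 101, seq150, tags = "NM:i:0"),
    sam_line("low_id", "g1|1", 101, seq150, tags = "NM:i:8"),
    sam_line("borderline", "g1|1", 101, seq150, tags = "NM:i:7"),
    sam_line("secondary", "g1|1", 101, seq150, flag = 256L, tags = "NM:i:0"),
    sam_line("unmapped", "*", 0, seq150, flag = 4L, tags = "NM:i:0"),
    sam_line("md_only", "g1|1", 101, seq150, tags = "MD:Z:70A79"),
    sam_line("no_tags", "g1|1", 101, seq150))
  expect_warning(al <- import_alignments(sam, ref), "without NM or MD")
  expect_setequal(al$read_id, c("perfect", "borderline", "md_only"))
  expect_equal(al$identity_pct[al$read_id == "perfect"], 100)
  expect_equal(al$identity_pct[al$read_id == "borderline"],
               100 * 143 / 150, tolerance = 1e-9)
  expect_equal(al$start[al$read_id == "perfect"], 100L)  # 1-based -> 0-based
  expect_equal(al$identity_pct[al$read_id == "md_only"],
               100 * 149 / 150, tolerance = 1e-9)
})

test_that("coverage arithmetic matches hand-computed and naive-oracle values", {
  g <- genome_record("g", rand_dna(300, seed = 10))
  ref <- build_reference(list(g))
  reads <- c(r1 = substr(g$contigs[1], 1, 150),
             r2 = substr(g$contigs[1], 151, 300))
  al <- map_reads(reads, ref)
  pr <- compute_coverage(al, ref, total_reads = 2)
  expect_equal(pr$g$breadth_pct, 100)
  expect_equal(pr$g$mean_depth, 1)
  pr1 <- compute_coverage(al[al$read_id == "r1", ], ref, total_reads = 2)
  expect_equal(pr1$g$breadth_pct, 50)
  expect_equal(pr1$g$mean_depth, 0.5)
  expect_equal(pr1$g$mapped_read_pct, 50)

  # exact agreement with a naive counting oracle on a masked 8 kb genome
  gm <- genome_record("gm", rand_dna(8000, seed = 11),
                      data.frame(contig = 1, start = c(1000, 5000),
                                 end = c(1400, 5600)))
  refm <- build_reference(list(gm))
  rs <- simulate_metagenome(
    community_design(c(gm = 1), n_reads = 120, read_length = 100, seed = 12),
    list(gm))
  alm <- map_reads(rs, refm)
  got <- compute_coverage(alm, refm, total_reads = nrow(rs), keep_depth = TRUE)
  want <- naive_coverage(alm, gm)
  expect_identical(got$gm$depth, want$depth)
  expect_equal(got$gm$breadth_pct, want$breadth_pct)
  expect_equal(got$gm$mean_depth, want$mean_depth)
  # conservation: no more mapped reads than input reads
  expect_lte(got$gm$mapped_reads, nrow(rs))
})

test_that("shared repeats cross-map without masking and are excluded with it", {
  set.seed(13)
  gs <- plant_shared_repeat(
    list(generate_genome(20000, 0.5, genome_id = "first", seed = 14),
         generate_genome(20000, 0.5, genome_id = "second", seed = 15)),
    repeat_length = 2000, copies_per_genome = 1, seed = 16)
  # reads only from "second", including its repeat copy
  rs <- simulate_metagenome(
    community_design(c(second = 1), n_reads = 1500, read_length = 150,
                     seed = 17), gs)
  ref_on <- build_reference(gs, apply_masks = TRUE)
  ref_off <- build_reference(gs, apply_masks = FALSE)
  al_on <- map_reads(rs, ref_on)
  al_off <- map_reads(rs, ref_off)
  # masking on: nothing lands on the absent genome, and repeat reads are gone
  expect_equal(sum(al_on$genome_id == "first"), 0L)
  # masking off: repeat reads tie-break to the earlier genome -> cross-mapping
  expect_gt(sum(al_off$genome_id == "first"), 0L)
  # masked positions never contribute coverage
  pr_on <- compute_coverage(al_on, ref_on, total_reads = nrow(rs))
  expect_lte(pr_on$second$breadth_pct, 100)
  expect_equal(pr_on$first$mapped_reads, 0L)
})
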