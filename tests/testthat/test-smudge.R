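test_that("read k-mer counting matches hand enumeration and is additive", {
  c1 <- count_kmers_from_reads("ACGT", k = 3)
  df <- as.data.frame(c1)
  # both windows (ACG, CGT) canonicalize to ACG
  expect_equal(df$kmer, "ACG")
  expect_equal(df$count, 2L)
  c2 <- count_kmers_from_reads(c("ACGT", "ACGT"), k = 3)
  expect_equal(as.data.frame(c2)$count, 4L)
  # windows with N skipped; strand-independence
  c3 <- count_kmers_from_reads(c("ACGNACG", "CGT"), k = 3)
  df3 <- as.data.frame(c3)
  expect_equal(df3$kmer, "ACG")
  expect_equal(df3$count, 3L)
  expect_error(count_kmers_from_reads(character(0), 3), "no reads")
  expect_error(count_kmers_from_reads("AC", 3), "shorter than k")
})

test_that("modal read k-mer depth matches the expected k-mer coverage", {
  set.seed(31)
  g <- random_dna(10000, 0.5)
  reads <- simulate_reads(c(h = g), 1L, coverage_per_copy = 10,
                          read_len = 100L, error_rate = 0, seed = 8, k = 21L)
  lambda <- attr(reads, "kmer_coverage_per_copy")
  counts <- count_kmers_from_reads(reads, 21)
  h <- kmer_histogram(counts)
  modal <- h$depth[which.max(h$n_kmers)]
  expect_lt(abs(modal - lambda), 2.5)
})

test_that("depth cutoff honors the user value and finds the error valley", {
  counts <- fake_counts(c(AAACGTA = 25, AAACGTC = 30), 7)
  expect_identical(depth_cutoff(counts, user_cutoff = 20), 20L)
  # bimodal histogram: error tail from depth 1, genomic peak near 30
  set.seed(12)
  err <- round(5000 * exp(-(1:12) / 1.2))
  gen <- round(800 * exp(-(5:50 - 30)^2 / 50))
  depths <- c(rep(1:12, err), rep(5:50, gen))
  km <- extract_canonical_kmers(random_dna(200000, 0.5),
                                sketch_params(k = 21))[seq_along(depths)]
  counts2 <- fake_counts(setNames(depths, km), 21)
  L <- depth_cutoff(counts2)
  expect_gte(L, 3L)
  expect_lte(L, 15L)
  # strictly decreasing histogram: no valley exists
  counts3 <- fake_counts(setNames(c(rep(1, 50), rep(2, 20), rep(3, 5)),
                                  km[1:75]), 21)
  expect_error(depth_cutoff(counts3), "no local minimum")
})

test_that("het pairs require Hamming distance exactly one", {
  counts <- fake_counts(c(AAA = 30, AAC = 28), 3)
  pairs <- find_het_pairs(counts, 20L)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$covA, 30)
  expect_equal(pairs$covB, 28)
  expect_equal(pairs$total, 58)
  expect_equal(pairs$ratio, 28 / 58)
  # Hamming distance 3: no pair
  expect_equal(nrow(find_het_pairs(fake_counts(c(AAA = 30, CCC = 30), 3),
                                   20L)), 0L)
  # depth filter removes members below L
  expect_equal(nrow(find_het_pairs(fake_counts(c(AAA = 30, AAC = 10), 3),
                                   20L)), 0L)
})

test_that("k-mers participating in several pairs are discarded", {
  counts <- fake_counts(c(AAA = 30, AAC = 28, AAG = 26), 3)
  expect_equal(nrow(find_het_pairs(counts, 20L)), 0L)
})

test_that("pairs hidden by strand canonicalization are still found", {
  # find a 21-mer pair (SNP in the middle) whose canonical forms take
  # opposite orientations, then check the pair is detected
  set.seed(44)
  found <- FALSE
  for (i in 1:200) {
    w <- random_dna(21, 0.5)
    for (base in c("A", "C", "G", "T")) {
      w2 <- w
      substr(w2, 1, 1) <- base
      if (w2 == w) next
      cw <- min(w, oracle_revcomp(w))
      cw2 <- min(w2, oracle_revcomp(w2))
      opposite <- xor(cw == w, cw2 == w2)
      if (!opposite) next
      counts <- fake_counts(setNames(c(30, 25), c(cw, cw2)), 21)
      pairs <- find_het_pairs(counts, 20L)
      expect_equal(nrow(pairs), 1L)
      expect_equal(pairs$covA, 30)
      found <- TRUE
      break
    }
    if (found) break
  }
  expect_true(found)
})

test_that("every reported pair satisfies the coverage and ratio invariants", {
  set.seed(19)
  g <- random_dna(30000, 0.45)
  g2 <- evolve_sequence(g, 0.002, seed = 5)
  reads <- simulate_reads(c(a = g, b = g2), 1L, coverage_per_copy = 12,
                          error_rate = 0.002, seed = 6)
  counts <- count_kmers_from_reads(reads, 21)
  L <- depth_cutoff(counts)
  pairs <- find_het_pairs(counts, L)
  expect_gt(nrow(pairs), 50)
  expect_true(all(pairs$covB <= pairs$covA))
  expect_true(all(pairs$covA >= L & pairs$covB >= L))
  expect_true(all(pairs$ratio > 0 & pairs$ratio <= 0.5))
  expect_equal(anyDuplicated(c(pairs$kmer_major, pairs$kmer_minor)), 0L)
  # each isolated SNP contributes about k pairs (one per window)
  n_snp <- sum(utf8ToInt(g) != utf8ToInt(g2))
  expect_lt(abs(nrow(pairs) - 21 * n_snp) / (21 * n_snp), 0.25)
})

test_that("a homozygous read set yields essentially no het pairs", {
  set.seed(23)
  g <- random_dna(30000, 0.5)
  reads <- simulate_reads(c(a = g, b = g), 1L, coverage_per_copy = 12,
                          error_rate = 0.002, seed = 9)
  counts <- count_kmers_from_reads(reads, 21)
  pairs <- find_het_pairs(counts, depth_cutoff(counts))
  expect_lt(nrow(pairs), 10)
})

test_that("coverage estimation handles pure and mixed smudges", {
  # all pairs at (total = 30, ratio = 0.5): AB interpretation, c = 15
  pure <- fake_pairs(rep(15, 100), rep(15, 100))
  expect_equal(estimate_haploid_coverage(pure, L = 4, max_ploidy = 2L), 15,
               tolerance = 0.05)
  # all pairs at (total = 60, ratio = 0.5) with classes up to AABB: the
  # c = 30 (AB) and c = 15 (AABB) interpretations fit identically; the
  # documented tie rule prefers the smallest-multiplicity reading (c = 30)
  pure4 <- fake_pairs(rep(30, 100), rep(30, 100))
  expect_equal(estimate_haploid_coverage(pure4, L = 4, max_ploidy = 4L), 30,
               tolerance = 0.05)
  # two smudges at (2c, 0.5) and (4c, 0.5), c = 15: identifiable, and the
  # Poisson noise model recovers c within 10%
  set.seed(3)
  ab_a <- rpois(300, 15); ab_b <- rpois(300, 15)
  bb_a <- rpois(500, 30); bb_b <- rpois(500, 30)
  mixed <- fake_pairs(c(pmax(ab_a, ab_b), pmax(bb_a, bb_b)),
                      c(pmax(pmin(ab_a, ab_b), 4),
                        pmax(pmin(bb_a, bb_b), 4)))
  c_hat <- estimate_haploid_coverage(mixed, L = 4)
  expect_lt(abs(c_hat - 15) / 15, 0.10)
  expect_error(estimate_haploid_coverage(fake_pairs(c(10, 12), c(9, 8))),
               "insufficient pairs")
})

test_that("genotype classification maps coverage centers to their classes", {
  c <- 15
  pairs <- fake_pairs(c(rep(2 * c, 40), rep(c, 10)),
                      c(rep(2 * c, 40), rep(c, 10)))
  s <- classify_genotypes(pairs, c)
  expect_equal(s$assignments$genotype, c(rep("AABB", 40), rep("AB", 10)))
  expect_equal(s$modal_genotype, "AABB")
  expect_equal(sum(s$proportions), 1, tolerance = 1e-9)
  # AAAB: major three copies, minor one
  s2 <- classify_genotypes(fake_pairs(rep(3 * c, 20), rep(c, 20)), c)
  expect_equal(s2$modal_genotype, "AAAB")
})

test_that("smudge histogram bins cover every pair exactly once", {
  pairs <- fake_pairs(rpois(200, 20) + 5, rpois(200, 10) + 2)
  pairs$ratio <- pmin(pairs$ratio, 0.5)
  h <- smudge_histogram(pairs)
  expect_equal(sum(h$n), nrow(pairs))
  expect_true(all(h$ratio_bin <= 0.5))
})
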