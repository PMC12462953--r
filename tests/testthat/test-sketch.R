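test_that("sketch_params enforces odd k and positive sketch size", {
  expect_error(sketch_params(k = 2), "odd")
  expect_error(sketch_params(k = 20), "odd")
  expect_error(sketch_params(k = 33), "odd|31")
  expect_error(sketch_params(s = 0), "s must be")
  expect_silent(sketch_params(k = 3, s = Inf))
})

test_that("canonical k-mer extraction matches hand enumeration", {
  p3 <- sketch_params(k = 3)
  # windows ACG, CGT; revcomp(CGT) = ACG
  expect_equal(extract_canonical_kmers("ACGT", p3), "ACG")
  # repeated k-mer collapses to one entry; canonical of AAA vs TTT is AAA
  expect_equal(extract_canonical_kmers("AAAAA", p3), "AAA")
  # windows containing N are skipped
  expect_equal(extract_canonical_kmers("ACGNACG", p3), "ACG")
  # soft-masked lowercase folds to uppercase
  expect_equal(extract_canonical_kmers("acgt", p3), "ACG")
  # shorter than k: empty set, not an error
  expect_length(extract_canonical_kmers("AC", p3), 0)
  # non-IUPAC characters are a hard error naming the position
  expect_error(extract_canonical_kmers("ACGXACG", p3), "position 4")
})

test_that("extraction agrees with an independent R enumeration oracle", {
  set.seed(7)
  for (k in c(3L, 5L, 7L)) {
    p <- sketch_params(k = k)
    for (i in 1:5) {
      seq <- random_dna(200, runif(1, 0.2, 0.8))
      expect_setequal(extract_canonical_kmers(seq, p),
                      oracle_canonical_set(seq, k))
    }
  }
})

test_that("build_sketch keeps the s smallest hashes and is deterministic", {
  p <- sketch_params(k = 5)
  kmers <- extract_canonical_kmers("ACGTACGGTACCGTAAGGTTACGAT", p)
  full <- build_sketch(kmers, "x", sketch_params(k = 5, s = Inf))
  expect_equal(length(full$hashes), full$total_distinct)
  expect_false(is.unsorted(full$hashes, strictly = TRUE))
  # s above the distinct count keeps everything
  big <- build_sketch(kmers, "x", sketch_params(k = 5, s = 5000))
  expect_equal(big$hashes, full$hashes)
  # bottom-3 equals the 3 smallest of the full sorted hash list (oracle)
  s3 <- build_sketch(kmers, "x", sketch_params(k = 5, s = 3))
  expect_equal(s3$hashes, sort(full$hashes)[1:3])
  expect_equal(s3$total_distinct, full$total_distinct)
  # byte-identical under the same seed; different under another seed
  again <- build_sketch(kmers, "x", sketch_params(k = 5, s = 3))
  expect_identical(s3$hashes, again$hashes)
  other <- build_sketch(kmers, "x", sketch_params(k = 5, s = 3,
                                                  hash_seed = 99))
  expect_false(identical(s3$hashes, other$hashes))
  expect_error(build_sketch(character(0), "x", p), "no valid k-mers")
})

test_that("sketch_sequence equals build_sketch over extracted k-mers", {
  set.seed(21)
  p <- sketch_params(k = 7, s = 50)
  seq <- random_dna(2000, 0.5)
  a <- sketch_sequence(seq, "a", p)
  b <- build_sketch(extract_canonical_kmers(seq, p), "a", p)
  expect_identical(a$hashes, b$hashes)
  expect_identical(a$total_distinct, b$total_distinct)
  expect_error(sketch_sequence("NNNNNNNNNN", "n", p), "no valid k-mers")
})

test_that("mash distance satisfies identity, cap, and the j=1/3 value", {
  p <- sketch_params(k = 21, s = Inf)
  a <- sketch_sequence(random_dna(400, 0.5), "a", p)
  self <- mash_distance(a, a)
  expect_identical(self$distance, 0)
  expect_identical(self$jaccard_est, 1)
  # provably disjoint k-mer sets: distance capped at 1
  pa <- sketch_sequence(strrep("A", 50), "pa", sketch_params(k = 3, s = Inf))
  pc <- sketch_sequence(strrep("C", 50), "pc", sketch_params(k = 3, s = Inf))
  cap <- mash_distance(pa, pc)
  expect_identical(cap$distance, 1.0)
  expect_true(cap$capped)
  # constructed sketches with j = 1/3: D = ln(2)/21
  s1 <- fake_sketch("s1", c(1, 2, 3, 4), p)
  s2 <- fake_sketch("s2", c(1, 2, 5, 6), p)
  d <- mash_distance(s1, s2)
  expect_equal(d$jaccard_est, 1 / 3)
  expect_equal(d$distance, log(2) / 21, tolerance = 1e-12)
})

test_that("mash distance is symmetric and rejects incompatible sketches", {
  set.seed(3)
  p <- sketch_params(k = 9, s = 40)
  for (i in 1:10) {
    x <- sketch_sequence(random_dna(1500, 0.4), "x", p)
    y <- sketch_sequence(random_dna(1500, 0.6), "y", p)
    expect_identical(mash_distance(x, y)$distance,
                     mash_distance(y, x)$distance)
  }
  x <- sketch_sequence("ACGTACGTACGT", "x", sketch_params(k = 5))
  y <- sketch_sequence("ACGTACGTACGT", "y", sketch_params(k = 7))
  expect_error(mash_distance(x, y), "incomparable")
  z <- sketch_sequence("ACGTACGTACGT", "z", sketch_params(k = 5,
                                                          hash_seed = 7))
  expect_error(mash_distance(x, z), "incomparable")
})

test_that("jaccard_exact matches the independent enumeration oracle", {
  p5 <- sketch_params(k = 5)
  expect_identical(jaccard_exact("ACGTACGTAC", "ACGTACGTAC", p5), 1)
  p3 <- sketch_params(k = 3)
  expect_identical(jaccard_exact(strrep("A", 10), strrep("C", 10), p3), 0)
  set.seed(11)
  for (i in 1:10) {
    a <- random_dna(300, 0.3)
    b <- random_dna(300, 0.7)
    expect_equal(jaccard_exact(a, b, p5), oracle_jaccard(a, b, 5))
  }
})

test_that("exhaustive sketches reproduce the exact Jaccard index", {
  # with s >= union size the bottom-sketch estimate is exact
  set.seed(5)
  p <- sketch_params(k = 21, s = Inf)
  for (i in 1:8) {
    a <- random_dna(3000, 0.5)
    b <- evolve_sequence(a, runif(1, 0.005, 0.1), seed = i)
    d <- mash_distance(sketch_sequence(a, "a", p), sketch_sequence(b, "b", p))
    expect_equal(d$jaccard_est, jaccard_exact(a, b, p), tolerance = 1e-12)
    expect_equal(d$distance, mash_formula(d$jaccard_est, 21),
                 tolerance = 1e-12)
  }
})

test_that("sketch JSON round-trips exactly", {
  p <- sketch_params(k = 7, s = 25)
  sk <- sketch_sequence(random_dna(500, 0.5), "chr1", p)
  path <- tempfile(fileext = ".sketch.json")
  write_sketch(sk, path)
  back <- read_sketch(path)
  expect_identical(back$hashes, sk$hashes)
  expect_identical(back$name, sk$name)
  expect_identical(back$params$k, sk$params$k)
  expect_identical(back$total_distinct, sk$total_distinct)
  d <- mash_distance(sk, back)
  expect_identical(d$distance, 0)
})
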