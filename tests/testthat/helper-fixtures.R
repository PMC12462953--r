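# Shared fixtures, all generated in code.

# Independent canonical k-mer enumeration in plain R (no package C++ code):
# the oracle for extraction and exact-Jaccard checks.
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

oracle_canonical_set <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  unique(vapply(kmers, function(w) min(w, oracle_revcomp(w)), character(1),
                USE.NAMES = FALSE))
}

oracle_jaccard <- function(a, b, k) {
  sa <- oracle_canonical_set(a, k)
  sb <- oracle_canonical_set(b, k)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

mash_formula <- function(j, k) {
  if (j <= 0) 1.0 else -(1 / k) * log(2 * j / (1 + j))
}

# Fabricate an exact-mode sketch with chosen hash values.
fake_sketch <- function(name, hashes, params) {
  polyphase:::new_sketch(name, params, sort(as.numeric(hashes)),
                         length(hashes))
}

# Fabricate a distance_matrix from a numeric matrix (rows = refs,
# cols = queries), bypassing sketching.
fake_distance_matrix <- function(d) {
  recs <- expand.grid(ref = rownames(d), query = colnames(d),
                      stringsAsFactors = FALSE)
  recs$shared <- 0L
  recs$denom <- 1L
  recs$jaccard <- NA_real_
  recs$distance <- d[cbind(recs$ref, recs$query)]
  structure(list(ref_names = rownames(d), query_names = colnames(d),
                 params = sketch_params(), records = recs),
            class = "distance_matrix")
}

# Fabricate a kmer_counts object from a named count vector (names = k-mers).
fake_counts <- function(counts, k) {
  codes <- polyphase:::cpp_strings_to_canonical_codes(names(counts), k)
  ord <- order(codes)
  structure(list(k = as.integer(k), code = codes[ord],
                 count = as.numeric(counts)[ord]),
            class = "kmer_counts")
}

# Fabricate a het-pair table straight from (covA, covB) columns.
fake_pairs <- function(covA, covB, cutoff = 4L) {
  out <- data.frame(kmer_major = sprintf("K%04d", seq_along(covA)),
                    kmer_minor = sprintf("k%04d", seq_along(covA)),
                    covA = covA, covB = covB, total = covA + covB,
                    ratio = covB / (covA + covB), stringsAsFactors = FALSE)
  class(out) <- c("het_pairs", "data.frame")
  attr(out, "cutoff") <- cutoff
  out
}

# Exhaustive minimum-total-distance pairing (copies_per_ref = 2) by
# recursive enumeration; oracle for the greedy assignment.
exhaustive_pairing <- function(d) {
  refs <- rownames(d)
  qs <- colnames(d)
  best <- list(total = Inf, sel = NULL)
  recurse <- function(i, remaining, acc, total) {
    if (total >= best$total) return()
    if (i > length(refs)) {
      best <<- list(total = total, sel = acc)
      return()
    }
    cmb <- utils::combn(remaining, 2L, simplify = FALSE)
    for (pr in cmb) {
      recurse(i + 1L, setdiff(remaining, pr),
              c(acc, list(pr)),
              total + d[refs[i], pr[1]] + d[refs[i], pr[2]])
    }
  }
  recurse(1L, qs, list(), 0)
  names(best$sel) <- refs
  best
}

tiny_sim_params <- function(seed, n_chrom = 3L, chrom_len = 2e4) {
  sim_params(n_chrom = n_chrom, chrom_len = chrom_len, seed = seed)
}
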