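#' Sketching parameters
#'
#' Parameters shared by every sketch in a comparison. `k` must be odd so
#' that no k-mer equals its own reverse complement; the default `k = 21`
#' matches the value used throughout k-mer analyses of fish genomes.
#' `s` is the bottom-sketch size: the number of smallest hash values
#' retained. `s = Inf` keeps every hash ("exact" mode), which reproduces the
#' effectively exhaustive sketch obtained by setting the sketch size far
#' above the distinct k-mer count of any chromosome.
#'
#' @param k k-mer length in bases; odd, between 3 and 31.
#' @param s sketch size (count of retained smallest hashes), `>= 1` or `Inf`.
#' @param hash_seed integer seed of the 64-bit hash function.
#' @param fold_case treat lowercase (soft-masked) bases as their uppercase
#'   equivalents (default `TRUE`). Hard-masked (`N`) windows are always
#'   dropped.
#' @return An object of class `sketch_params`.
#' @examples
#' sketch_params()
#' sketch_params(k = 17, s = Inf)
#' @export
sketch_params <- function(k = 21L, s = 5000L, hash_seed = 42L,
                          fold_case = TRUE) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k > 31L || k %% 2L == 0L)
    stop("k must be odd and in [3, 31] (odd k avoids palindromic k-mers)")
  if (!is.infinite(s)) {
    s <- as.numeric(s)
    if (is.na(s) || s < 1 || s != floor(s)) stop("s must be >= 1 or Inf")
  }
  hash_seed <- as.numeric(hash_seed)
  if (is.na(hash_seed) || hash_seed < 0) stop("hash_seed must be >= 0")
  structure(list(k = k, s = s, hash_seed = hash_seed,
                 fold_case = as.logical(fold_case)),
            class = "sketch_params")
}

#' @export
print.sketch_params <- function(x, ...) {
  cat(sprintf("sketch_params: k=%d s=%s hash_seed=%s fold_case=%s\n",
              x$k, if (is.finite(x$s)) format(x$s) else "exact",
              format(x$hash_seed), x$fold_case))
  invisible(x)
}

params_compatible <- function(a, b) {
  identical(a$k, b$k) && identical(a$hash_seed, b$hash_seed) &&
    identical(a$s, b$s) && identical(a$fold_case, b$fold_case)
}

#' Extract the set of distinct canonical k-mers from a sequence
#'
#' A canonical k-mer is the lexicographic minimum of a k-mer and its reverse
#' complement, making the set strand-independent. Windows containing any
#' IUPAC ambiguity code (including `N`) are skipped; characters outside the
#' IUPAC alphabet raise an error naming the offending position. Lowercase
#' bases are folded to uppercase when `params$fold_case` is `TRUE`.
#'
#' @param seq a single nucleotide string.
#' @param params a [sketch_params()] object.
#' @return Character vector of distinct canonical k-mers (sorted). A
#'   sequence shorter than `k` yields an empty set.
#' @examples
#' extract_canonical_kmers("ACGT", sketch_params(k = 3))
#' @export
extract_canonical_kmers <- function(seq, params = sketch_params()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  if (!params$fold_case && grepl("[a-z]", seq))
    stop("lowercase bases present but fold_case = FALSE; ",
         "hard-mask them or enable case folding")
  codes <- cpp_canonical_kmer_codes(seq, params$k)
  cpp_codes_to_strings(codes, params$k)
}

new_sketch <- function(name, params, hashes, total_distinct) {
  structure(list(name = name, params = params, hashes = hashes,
                 total_distinct = total_distinct),
            class = "polyphase_sketch")
}

#' @export
print.polyphase_sketch <- function(x, ...) {
  cat(sprintf("polyphase_sketch '%s': %d/%s hashes (k=%d, seed=%s)\n",
              x$name, length(x$hashes), format(x$total_distinct),
              x$params$k, format(x$params$hash_seed)))
  invisible(x)
}

#' Build a bottom-s MinHash sketch from a k-mer set
#'
#' Hashes every k-mer with a seeded 64-bit mixing function and keeps the
#' `s` smallest distinct hash values. K-mers are canonicalized before
#' hashing, so the sketch is the same whichever strand was supplied.
#'
#' @param kmers character vector of k-mers (length `params$k` each).
#' @param name identifier for the sketched sequence.
#' @param params a [sketch_params()] object.
#' @return A `polyphase_sketch`: `name`, `params`, sorted ascending `hashes`
#'   (length `min(s, total_distinct)`), and `total_distinct`.
#' @export
build_sketch <- function(kmers, name, params = sketch_params()) {
  if (length(kmers) == 0L)
    stop("no valid k-mers for '", name,
         "' (input all-N, masked, or shorter than k?)")
  codes <- unique(cpp_strings_to_canonical_codes(kmers, params$k))
  hashes <- sort(cpp_hash_codes(codes, params$hash_seed))
  if (is.finite(params$s)) hashes <- head(hashes, params$s)
  new_sketch(name, params, hashes, as.numeric(length(codes)))
}

#' Sketch a single sequence
#'
#' Equivalent to `build_sketch(extract_canonical_kmers(seq, params), ...)`
#' but computed in one pass in C++.
#'
#' @inheritParams extract_canonical_kmers
#' @param name identifier for the sequence.
#' @return A `polyphase_sketch`.
#' @export
sketch_sequence <- function(seq, name, params = sketch_params()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence for '", name, "'")
  if (!params$fold_case && grepl("[a-z]", seq))
    stop("lowercase bases present but fold_case = FALSE")
  res <- cpp_sketch_sequence(seq, params$k, params$hash_seed)
  if (res$total_distinct == 0)
    stop("no valid k-mers for '", name,
         "' (input all-N, masked, or shorter than k?)")
  hashes <- res$hashes
  if (is.finite(params$s)) hashes <- head(hashes, params$s)
  new_sketch(name, params, hashes, res$total_distinct)
}

#' Sketch every chromosome of a genome
#'
#' @param genome a named character vector of sequences, or a path to a
#'   (optionally gzipped) FASTA file.
#' @param params a [sketch_params()] object.
#' @return Named list of `polyphase_sketch` objects. Chromosomes yielding no
#'   valid k-mers are dropped with a warning.
#' @export
sketch_genome <- function(genome, params = sketch_params()) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)))
    genome <- read_genome(genome) # a single unnamed string is a file path
  stopifnot(is.character(genome))
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome sequences must have unique names")
  out <- list()
  for (nm in names(genome)) {
    sk <- tryCatch(sketch_sequence(genome[[nm]], nm, params),
                   error = function(e) e)
    if (inherits(sk, "error")) {
      warning("excluding chromosome '", nm, "': ",
              conditionMessage(sk), call. = FALSE)
    } else out[[nm]] <- sk
  }
  if (length(out) == 0L) stop("no chromosome yielded a valid sketch")
  out
}

#' Mash distance between two sketches
#'
#' Merges the two bottom sketches, takes the `denom = min(s, |union|)`
#' smallest hash values of the union, and counts how many occur in both
#' sketches. The Jaccard estimate `j = shared/denom` is transformed to the
#' Mash distance `D = -(1/k) * log(2j / (1 + j))`, an estimate of per-base
#' divergence under a Poisson model of random site mutation. `j = 0` has an
#' undefined logarithm; the distance is then capped at 1 and flagged.
#'
#' @param a,b `polyphase_sketch` objects built with identical parameters.
#' @return A `mash_dist` record: `ref_name`, `query_name`, `shared`,
#'   `denom`, `jaccard_est`, `distance`, `capped`.
#' @examples
#' p <- sketch_params(k = 5, s = Inf)
#' a <- sketch_sequence("ACGTACGTACGTAA", "a", p)
#' mash_distance(a, a)$distance
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "polyphase_sketch"), inherits(b, "polyphase_sketch"))
  if (!params_compatible(a$params, b$params))
    stop("sketches are incomparable: k, s, or hash_seed differ ",
         "(a: k=", a$params$k, " seed=", a$params$hash_seed,
         "; b: k=", b$params$k, " seed=", b$params$hash_seed, ")")
  k <- a$params$k
  u <- sort(unique(c(a$hashes, b$hashes)))
  denom <- if (is.finite(a$params$s)) min(a$params$s, length(u)) else length(u)
  top <- u[seq_len(denom)]
  shared <- sum(top %in% a$hashes & top %in% b$hashes)
  j <- shared / denom
  if (j > 0) {
    d <- max(0, -(1 / k) * log(2 * j / (1 + j)))
    capped <- FALSE
  } else {
    d <- 1.0
    capped <- TRUE
  }
  structure(list(ref_name = a$name, query_name = b$name,
                 shared = as.integer(shared), denom = as.integer(denom),
                 jaccard_est = j, distance = d, capped = capped),
            class = "mash_dist")
}

#' @export
print.mash_dist <- function(x, ...) {
  cat(sprintf("mash_dist %s vs %s: j=%.6g (%d/%d) D=%.6g%s\n",
              x$ref_name, x$query_name, x$jaccard_est, x$shared, x$denom,
              x$distance, if (x$capped) " [capped]" else ""))
  invisible(x)
}

#' Exact Jaccard index between the canonical k-mer sets of two sequences
#'
#' Brute-force oracle: `|A intersect B| / |A union B|` over the full
#' canonical k-mer sets, with no hashing and no sketching. When the sketch
#' size is at least the union size, [mash_distance()]'s Jaccard estimate
#' equals this value exactly.
#'
#' @param seq_a,seq_b nucleotide strings.
#' @param params a [sketch_params()] object (only `k` and case policy used).
#' @return Jaccard index in `[0, 1]`.
#' @examples
#' jaccard_exact("ACGTACGT", "ACGTTGCA", sketch_params(k = 5))
#' @export
jaccard_exact <- function(seq_a, seq_b, params = sketch_params()) {
  ka <- cpp_canonical_kmer_codes(seq_a, params$k)
  kb <- cpp_canonical_kmer_codes(seq_b, params$k)
  if (length(ka) == 0L || length(kb) == 0L)
    stop("a sequence yields no valid k-mers")
  length(intersect(ka, kb)) / length(union(ka, kb))
}
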