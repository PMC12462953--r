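#' Count canonical k-mers in sequencing reads
#'
#' Canonical counting with the same convention as the sketching module:
#' the lexicographic minimum of each k-mer and its reverse complement is
#' counted, windows containing `N` (or any IUPAC ambiguity code) are
#' skipped, and characters outside the IUPAC alphabet raise an error.
#'
#' @param reads character vector of read sequences, or a path to a FASTQ
#'   file (optionally gzipped).
#' @param k k-mer length (default 21).
#' @return A `kmer_counts` object: `k`, `code` (numeric 2-bit encodings of
#'   the canonical k-mers), `count`.
#' @export
count_kmers_from_reads <- function(reads, k = 21L) {
  k <- as.integer(k)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  stopifnot(is.character(reads))
  if (length(reads) == 0L) stop("no reads supplied")
  if (all(nchar(reads) < k)) stop("all reads shorter than k")
  res <- cpp_count_kmers(reads, k)
  if (length(res$code) == 0L) stop("no valid k-mers in reads")
  structure(list(k = k, code = res$code, count = res$count),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("kmer_counts: %d distinct canonical %d-mers (max depth %d)\n",
              length(x$code), x$k, max(x$count)))
  invisible(x)
}

#' @method as.data.frame kmer_counts
#' @export
as.data.frame.kmer_counts <- function(x, ...) {
  data.frame(kmer = cpp_codes_to_strings(x$code, x$k),
             count = as.integer(x$count), stringsAsFactors = FALSE)
}

#' K-mer depth histogram
#'
#' @param counts a [count_kmers_from_reads()] object.
#' @return Data frame `depth`, `n_kmers` for depths `1..max`.
#' @export
kmer_histogram <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  tab <- tabulate(as.integer(counts$count))
  data.frame(depth = seq_along(tab), n_kmers = tab)
}

#' Depth cutoff separating error k-mers from genomic k-mers
#'
#' Sequencing errors produce a large peak of low-depth k-mers; genuine
#' genomic k-mers form peaks at multiples of the haploid coverage. The
#' cutoff is the depth of the first local minimum of the depth histogram
#' (smoothed by a width-3 moving average), i.e. the valley between the
#' error peak and the first genomic peak; k-mers below it are excluded
#' downstream. When the histogram has no leading error peak at all
#' (error-free data) the cutoff is 1; a strictly decreasing histogram
#' (no genomic peak) is an error asking for an explicit cutoff. An
#' explicit `user_cutoff` (e.g. the conventional 20 for deep short-read
#' data) overrides the automatic rule.
#'
#' @param counts a [count_kmers_from_reads()] object.
#' @param user_cutoff optional explicit cutoff.
#' @return Integer depth `L`; k-mers with `count < L` should be excluded.
#' @export
depth_cutoff <- function(counts, user_cutoff = NULL) {
  stopifnot(inherits(counts, "kmer_counts"))
  if (!is.null(user_cutoff)) {
    L <- as.integer(user_cutoff)
    if (is.na(L) || L < 1L) stop("user_cutoff must be a positive integer")
    return(L)
  }
  h <- kmer_histogram(counts)$n_kmers
  if (length(h) < 3L)
    stop("depth histogram too narrow for automatic cutoff; ",
         "supply user_cutoff explicitly")
  # width-3 moving average; endpoints keep their raw value
  s <- h
  mid <- 2:(length(h) - 1L)
  s[mid] <- (h[mid - 1L] + h[mid] + h[mid + 1L]) / 3
  for (d in mid) {
    if (s[d] <= s[d - 1L] && s[d] < s[d + 1L]) return(as.integer(d))
  }
  # no valley and no leading error peak (histogram rises into the genomic
  # peak): nothing to exclude
  if (s[1L] <= s[2L]) return(1L)
  stop("k-mer depth histogram has no local minimum (monotone); ",
       "supply user_cutoff explicitly")
}

#' Identify heterozygous k-mer pairs
#'
#' Finds unordered pairs of retained canonical k-mers that differ at
#' exactly one position. For each position the k-mers are bucketed by the
#' string with that position wildcarded, over *both* orientations of each
#' canonical k-mer, so strand canonicalization cannot hide a pair. K-mers
#' participating in more than one pair are discarded together with their
#' pairs, suppressing repeat-family artifacts. Each retained pair carries
#' the coverages of its two members ordered `covA >= covB`, their sum, and
#' the minor-fraction `ratio = covB/(covA+covB)` in `(0, 0.5]`.
#'
#' @param counts a [count_kmers_from_reads()] object.
#' @param L depth cutoff from [depth_cutoff()]; k-mers with `count < L` are
#'   excluded before pairing.
#' @return A `het_pairs` data frame: `kmer_major`, `kmer_minor`, `covA`,
#'   `covB`, `total`, `ratio`; attribute `cutoff = L`.
#' @export
find_het_pairs <- function(counts, L) {
  stopifnot(inherits(counts, "kmer_counts"))
  L <- as.integer(L)
  keep <- counts$count >= L
  code <- counts$code[keep]
  cnt <- counts$count[keep]
  empty <- data.frame(kmer_major = character(0), kmer_minor = character(0),
                      covA = numeric(0), covB = numeric(0),
                      total = numeric(0), ratio = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(code) < 2L) {
    class(empty) <- c("het_pairs", "data.frame")
    attr(empty, "cutoff") <- L
    return(empty)
  }
  idx <- cpp_find_het_pairs(code, counts$k)
  if (nrow(idx) == 0L) {
    class(empty) <- c("het_pairs", "data.frame")
    attr(empty, "cutoff") <- L
    return(empty)
  }
  # drop k-mers in more than one pair (ambiguous paralog/repeat signal)
  deg <- tabulate(c(idx[, 1L], idx[, 2L]), nbins = length(code))
  ok <- deg[idx[, 1L]] == 1L & deg[idx[, 2L]] == 1L
  idx <- idx[ok, , drop = FALSE]
  if (nrow(idx) == 0L) {
    class(empty) <- c("het_pairs", "data.frame")
    attr(empty, "cutoff") <- L
    return(empty)
  }
  c1 <- cnt[idx[, 1L]]
  c2 <- cnt[idx[, 2L]]
  major <- ifelse(c1 >= c2, idx[, 1L], idx[, 2L])
  minor <- ifelse(c1 >= c2, idx[, 2L], idx[, 1L])
  covA <- pmax(c1, c2)
  covB <- pmin(c1, c2)
  out <- data.frame(
    kmer_major = cpp_codes_to_strings(code[major], counts$k),
    kmer_minor = cpp_codes_to_strings(code[minor], counts$k),
    covA = covA, covB = covB, total = covA + covB,
    ratio = covB / (covA + covB), stringsAsFactors = FALSE)
  class(out) <- c("het_pairs", "data.frame")
  attr(out, "cutoff") <- L
  out
}

# Genotype center catalogue: multiplicity m and minor copy number b, with
# coverage-space centers (total = m*c, ratio = b/m).
genotype_centers <- function(max_ploidy) {
  m <- rep(2:max_ploidy, times = floor((2:max_ploidy) / 2))
  b <- unlist(lapply(2:max_ploidy, function(mm) seq_len(floor(mm / 2))))
  lab <- vapply(seq_along(m), function(i)
    paste0(strrep("A", m[i] - b[i]), strrep("B", b[i])), character(1))
  data.frame(m = m, b = b, label = lab, stringsAsFactors = FALSE)
}

# Per-pair log-likelihood matrix under one candidate coverage c: the
# ordered pair (covA >= covB) of a class with minor copy number b and major
# a = m - b is modelled as independent Poissons with means (a*c, b*c),
# summed over both assignments of the two alleles to the (major, minor)
# slots. Constants independent of c (the ordering factor) cancel.
class_loglik <- function(covA, covB, centers, c) {
  ll <- matrix(NA_real_, length(covA), nrow(centers))
  for (j in seq_len(nrow(centers))) {
    a <- centers$m[j] - centers$b[j]
    b <- centers$b[j]
    l1 <- stats::dpois(covA, a * c, log = TRUE) +
      stats::dpois(covB, b * c, log = TRUE)
    l2 <- stats::dpois(covA, b * c, log = TRUE) +
      stats::dpois(covB, a * c, log = TRUE)
    hi <- pmax(l1, l2)
    ll[, j] <- hi + log1p(exp(-abs(l1 - l2)))
  }
  ll
}

# Mean negative log-likelihood of the genotype-class mixture at coverage c,
# with mixture weights profiled out by EM. Per-pair log-likelihood is
# floored for robustness against stray (error/repeat) pairs.
mixture_negloglik <- function(covA, covB, centers, c, floor_ll = -15,
                              em_iter = 200L) {
  ll <- class_loglik(covA, covB, centers, c)
  K <- ncol(ll)
  w <- rep(1 / K, K)
  for (it in seq_len(em_iter)) {
    lw <- sweep(ll, 2L, log(w), "+")
    mx <- apply(lw, 1L, max)
    resp <- exp(lw - mx)
    resp <- resp / rowSums(resp)
    w_new <- colMeans(resp)
    if (max(abs(w_new - w)) < 1e-10) { w <- w_new; break }
    w <- w_new
  }
  lw <- sweep(ll, 2L, log(pmax(w, 1e-12)), "+")
  mx <- apply(lw, 1L, max)
  mix_ll <- mx + log(rowSums(exp(lw - mx)))
  -mean(pmax(mix_ll, floor_ll))
}

#' Estimate the haploid (1n) k-mer coverage from heterozygous pairs
#'
#' Models the member coverages `(covA, covB)` of every pair as an ordered
#' pair of independent Poisson counts with means `((m-b)*c, b*c)` for a
#' genotype class with allele multiplicity `m` and minor copy number `b`,
#' and fits a mixture over all classes up to `max_ploidy` by grid search
#' over the haploid coverage `c`, profiling the class weights out by EM at
#' every candidate. The mixture (rather than a best-class profile)
#' penalizes interpretations that shatter one coverage smudge across
#' several classes, which is what makes `c` identifiable. An exact `c`
#' versus `c/2` ambiguity (every occupied class having a
#' double-multiplicity counterpart within `max_ploidy`) yields
#' machine-identical likelihoods; such ties are resolved toward the
#' *largest* coverage, i.e. the smallest-multiplicity, most parsimonious
#' interpretation. The winning grid point is refined by golden-section
#' search.
#'
#' @param pairs a [find_het_pairs()] data frame.
#' @param L lower bound of the coverage grid; defaults to the pairs'
#'   `cutoff` attribute.
#' @param max_ploidy largest allele multiplicity hypothesized during
#'   estimation (default 4: classes AB through AABB).
#' @return Estimated haploid k-mer coverage (numeric scalar).
#' @export
estimate_haploid_coverage <- function(pairs, L = NULL, max_ploidy = 4L) {
  stopifnot(inherits(pairs, "data.frame"))
  if (nrow(pairs) < 5L)
    stop("insufficient pairs (", nrow(pairs), " < 5) to estimate coverage")
  if (is.null(L)) L <- attr(pairs, "cutoff")
  if (is.null(L)) L <- max(2, floor(min(pairs$covB) / 2))
  # deterministic thinning: the fit needs a few thousand pairs at most
  if (nrow(pairs) > 5000L) {
    ord <- order(pairs$total, pairs$ratio)
    pairs <- pairs[ord[seq(1L, nrow(pairs),
                           length.out = 5000L)], , drop = FALSE]
  }
  centers <- genotype_centers(max_ploidy)
  loss <- function(c)
    mixture_negloglik(pairs$covA, pairs$covB, centers, c)
  lo <- max(2, L)
  # stray high-coverage (repeat-derived) pairs would stretch the grid far
  # beyond any plausible 1n coverage; cap at the bulk of the distribution
  hi <- as.numeric(stats::quantile(pairs$total, 0.99))
  if (lo >= hi) stop("degenerate coverage grid: cutoff exceeds max total")
  grid <- seq(lo, hi, by = 0.5)
  losses <- vapply(grid, loss, numeric(1))
  # refine every competitive local basin, then break (numerically exact)
  # ties toward the largest c: the smallest-multiplicity interpretation
  locmin <- which(losses <= c(Inf, losses[-length(losses)]) &
                    losses <= c(losses[-1L], Inf))
  locmin <- locmin[order(losses[locmin])]
  locmin <- locmin[seq_len(min(6L, length(locmin)))]
  refined <- lapply(locmin, function(i)
    optimize(loss, lower = max(lo, grid[i] - 0.75),
             upper = min(hi, grid[i] + 0.75), tol = 1e-4))
  vals <- vapply(refined, `[[`, numeric(1), "objective")
  cs <- vapply(refined, `[[`, numeric(1), "minimum")
  # near-ties (within 0.01 nat/pair) are degenerate halving/doubling
  # interpretations of the same smudges; genuinely different coverages
  # separate by an order of magnitude more than this
  max(cs[vals <= min(vals) + 0.01])
}

#' Classify heterozygous k-mer pairs into genotype classes
#'
#' Assigns each pair to the genotype class `(m, b)` whose center
#' `(total = m*c, ratio = b/m)` best explains its member coverages under
#' the same ordered-Poisson model used for coverage estimation: `covA` and
#' `covB` are modelled as Poisson with means `((m-b)*c, b*c)` (both allele
#' assignments summed). Class labels follow the usual convention: AB
#' (`m=2`), AAB (`m=3`), AABB and AAAB (`m=4`), and so on up to
#' `max_ploidy`.
#'
#' @param pairs a [find_het_pairs()] data frame.
#' @param c haploid k-mer coverage (from [estimate_haploid_coverage()]).
#' @param max_ploidy largest allele multiplicity considered (default 8).
#' @return A `smudge_summary`: `haploid_coverage`, `proportions` (named
#'   numeric, sums to 1), `modal_genotype`, `n_pairs`, `assignments`
#'   (pairs with `genotype` column).
#' @export
classify_genotypes <- function(pairs, c, max_ploidy = 8L) {
  stopifnot(inherits(pairs, "data.frame"), c > 0)
  if (nrow(pairs) == 0L) stop("no pairs to classify")
  centers <- genotype_centers(max_ploidy)
  ll <- class_loglik(pairs$covA, pairs$covB, centers, c)
  # fit class weights by EM, then assign each pair to its maximum-posterior
  # class: the weights act as priors, so a minor class cannot soak up the
  # sampling tails of a dominant neighboring class
  w <- rep(1 / ncol(ll), ncol(ll))
  for (it in seq_len(50L)) {
    lw <- sweep(ll, 2L, log(pmax(w, 1e-12)), "+")
    mx <- apply(lw, 1L, max)
    resp <- exp(lw - mx)
    resp <- resp / rowSums(resp)
    w_new <- colMeans(resp)
    if (max(abs(w_new - w)) < 1e-8) { w <- w_new; break }
    w <- w_new
  }
  lw <- sweep(ll, 2L, log(pmax(w, 1e-12)), "+")
  which_c <- max.col(lw, ties.method = "first")
  genotype <- centers$label[which_c]
  prop <- table(factor(genotype, levels = unique(centers$label)))
  prop <- prop / sum(prop)
  prop <- prop[prop > 0]
  assignments <- pairs
  assignments$genotype <- genotype
  structure(list(haploid_coverage = c,
                 proportions = setNames(as.numeric(prop), names(prop)),
                 modal_genotype = names(prop)[which.max(prop)],
                 n_pairs = nrow(pairs),
                 assignments = assignments),
            class = "smudge_summary")
}

#' @export
print.smudge_summary <- function(x, ...) {
  cat(sprintf("smudge_summary: %d pairs, 1n coverage %.2f, modal %s\n",
              x$n_pairs, x$haploid_coverage, x$modal_genotype))
  p <- sort(x$proportions, decreasing = TRUE)
  for (nm in names(p)) cat(sprintf("  %-8s %5.1f%%\n", nm, 100 * p[[nm]]))
  invisible(x)
}

#' 2-D histogram of heterozygous pairs in (total, ratio) space
#'
#' A tabular stand-in for the usual smudge density plot, suitable for
#' external plotting.
#'
#' @param pairs a [find_het_pairs()] data frame.
#' @param total_binwidth bin width for total coverage.
#' @param ratio_bins number of bins on `(0, 0.5]`.
#' @return Data frame `total_bin`, `ratio_bin`, `n` (non-empty bins only).
#' @export
smudge_histogram <- function(pairs, total_binwidth = 5, ratio_bins = 25L) {
  stopifnot(inherits(pairs, "data.frame"))
  tb <- floor(pairs$total / total_binwidth) * total_binwidth
  rb <- pmin(ceiling(pairs$ratio * 2 * ratio_bins), ratio_bins) /
    (2 * ratio_bins)
  agg <- aggregate(list(n = rep(1L, nrow(pairs))),
                   by = list(total_bin = tb, ratio_bin = rb), FUN = sum)
  agg[order(agg$total_bin, agg$ratio_bin), ]
}

#' Full heterozygous k-mer-pair ploidy analysis of a read set
#'
#' Convenience wrapper: count k-mers, choose the depth cutoff, find pairs,
#' estimate the haploid coverage, and classify genotypes.
#'
#' @param reads character vector of reads or FASTQ path.
#' @param k k-mer length (default 21).
#' @param cutoff optional explicit depth cutoff (default: first local
#'   minimum of the depth histogram).
#' @param max_ploidy largest allele multiplicity for classification.
#' @param estimate_max_ploidy largest multiplicity hypothesized during
#'   coverage estimation.
#' @return A `smudge_summary` (see [classify_genotypes()]); the pair table
#'   is in `$assignments`.
#' @export
smudge_analysis <- function(reads, k = 21L, cutoff = NULL, max_ploidy = 8L,
                            estimate_max_ploidy = 4L) {
  counts <- count_kmers_from_reads(reads, k)
  L <- depth_cutoff(counts, cutoff)
  pairs <- find_het_pairs(counts, L)
  c_hat <- estimate_haploid_coverage(pairs, L = L,
                                     max_ploidy = estimate_max_ploidy)
  classify_genotypes(pairs, c_hat, max_ploidy = max_ploidy)
}
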