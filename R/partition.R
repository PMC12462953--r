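#' Partitioning parameters
#'
#' `tau` is the ambiguity threshold on the *relative* distance gap of a
#' homoeolog pair, `(d_high - d_low) / mean(d_low, d_high)`. A relative
#' (scale-free) gap is used so the same threshold works across reference
#' species at very different phylogenetic distances. Pairs whose relative
#' gap falls below `tau` are flagged ambiguous but still labeled.
#'
#' @param tau relative-gap ambiguity threshold, dimensionless, `>= 0`
#'   (default 0.05).
#' @param label_low,label_high subgenome labels for the less/more diverged
#'   member of each pair.
#' @return An object of class `partition_params`.
#' @export
partition_params <- function(tau = 0.05, label_low = "subA",
                             label_high = "subB") {
  tau <- as.numeric(tau)
  if (is.na(tau) || tau < 0) stop("tau must be >= 0")
  if (identical(label_low, label_high)) stop("labels must differ")
  structure(list(tau = tau, label_low = label_low, label_high = label_high),
            class = "partition_params")
}

#' Assign homoeologs to subgenomes by relative divergence
#'
#' The core decision rule: within each homoeologous pair, the member with
#' the smaller Mash distance to the reference has accumulated less variation
#' and is therefore closer to the ancestral state; it receives `label_low`,
#' the more diverged member `label_high`. Assignment is independent per
#' pair, exactly as per-chromosome divergence bar plots encode it, so a
#' single aberrant pair cannot cascade. A pair is flagged ambiguous when its
#' relative gap is below `tau`; exact ties (`d_low == d_high`) are flagged
#' ambiguous and broken by assigning the lexicographically smaller
#' chromosome name to `label_low`.
#'
#' @param pairs a `homoeolog_pairs` data frame
#'   ([infer_homoeolog_pairs()] / [load_pairs_file()]).
#' @param params a [partition_params()] object.
#' @return A `partition_result`: `assignments` (data frame with columns
#'   `chromosome`, `subgenome`, `ref_chrom`, `distance`, `abs_gap`,
#'   `rel_gap`, `ambiguous`), `pairs`, and `params`.
#' @export
assign_subgenomes <- function(pairs, params = partition_params()) {
  stopifnot(inherits(pairs, "data.frame"))
  if (nrow(pairs) == 0L) stop("empty pair list")
  need <- c("ref_chrom", "member_low", "d_low", "member_high", "d_high")
  stopifnot(all(need %in% names(pairs)))
  lo <- pairs$member_low
  hi <- pairs$member_high
  d_lo <- pairs$d_low
  d_hi <- pairs$d_high
  # member order in the input carries no information: reorder by distance
  flip <- d_lo > d_hi
  if (any(flip)) {
    tmp <- lo[flip]; lo[flip] <- hi[flip]; hi[flip] <- tmp
    tmpd <- d_lo[flip]; d_lo[flip] <- d_hi[flip]; d_hi[flip] <- tmpd
  }
  tie <- d_lo == d_hi
  # on an exact tie the low slot goes to the lexicographically smaller name
  swap <- tie & hi < lo
  tmp <- lo[swap]; lo[swap] <- hi[swap]; hi[swap] <- tmp
  mean_d <- (d_lo + d_hi) / 2
  abs_gap <- d_hi - d_lo
  rel_gap <- ifelse(mean_d > 0, abs_gap / mean_d, 0)
  ambiguous <- tie | rel_gap < params$tau
  assignments <- data.frame(
    chromosome = c(lo, hi),
    subgenome = rep(c(params$label_low, params$label_high),
                    each = nrow(pairs)),
    ref_chrom = rep(pairs$ref_chrom, 2L),
    distance = c(d_lo, d_hi),
    abs_gap = rep(abs_gap, 2L),
    rel_gap = rep(rel_gap, 2L),
    ambiguous = rep(ambiguous, 2L),
    stringsAsFactors = FALSE)
  assignments <- assignments[order(assignments$ref_chrom,
                                   assignments$subgenome), ]
  rownames(assignments) <- NULL
  structure(list(assignments = assignments, pairs = pairs, params = params),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  s <- summarize_partition(x)
  cat(sprintf("partition_result: %d pairs, %d ambiguous; verdict: %s\n",
              nrow(x$pairs), s$ambiguous_pairs, s$verdict))
  invisible(x)
}

#' Summarize a subgenome partition
#'
#' Per-subgenome chromosome counts and distance statistics, the number of
#' ambiguous pairs, and an overall verdict: `"partitioned"` when at most
#' half of the pairs are ambiguous, `"indeterminate"` otherwise (the
#' expected outcome for an autopolyploid or for subgenomes with
#' indistinguishable divergence, where the method is known to fail).
#'
#' @param r a `partition_result` from [assign_subgenomes()].
#' @return A list: `by_subgenome` (data frame with `subgenome`, `n_chrom`,
#'   `mean_distance`, `min_distance`, `max_distance`), `ambiguous_pairs`,
#'   `n_pairs`, `verdict`.
#' @export
summarize_partition <- function(r) {
  stopifnot(inherits(r, "partition_result"))
  a <- r$assignments
  by <- do.call(rbind, lapply(split(a, a$subgenome), function(g)
    data.frame(subgenome = g$subgenome[1], n_chrom = nrow(g),
               mean_distance = mean(g$distance),
               min_distance = min(g$distance),
               max_distance = max(g$distance),
               stringsAsFactors = FALSE)))
  rownames(by) <- NULL
  n_amb <- sum(tapply(a$ambiguous, a$ref_chrom, any))
  list(by_subgenome = by,
       ambiguous_pairs = as.integer(n_amb),
       n_pairs = nrow(r$pairs),
       verdict = if (n_amb > nrow(r$pairs) / 2) "indeterminate"
                 else "partitioned")
}

#' Consensus partition over several reference genomes
#'
#' When the distances to a single reference are nearly equal, testing
#' additional related species can restore resolution. Each reference yields
#' an independent partition; chromosomes are then given the majority label
#' across references, with per-chromosome agreement reported. Label
#' polarity is anchored on the first reference: for every subsequent
#' result, labels are flipped as a whole if that flip increases agreement
#' with the first (the two subgenome labels are arbitrary in isolation).
#'
#' @param results list of `partition_result` objects over the same polyploid
#'   chromosomes.
#' @return Data frame with `chromosome`, `subgenome` (majority label),
#'   `support` (fraction of references agreeing), `n_ref`.
#' @export
consensus_partition <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "partition_result")))
  base <- results[[1]]$assignments[, c("chromosome", "subgenome")]
  p <- results[[1]]$params
  labs <- lapply(results, function(r) {
    a <- r$assignments
    v <- setNames(a$subgenome, a$chromosome)[base$chromosome]
    agree <- mean(v == base$subgenome, na.rm = TRUE)
    if (!is.na(agree) && agree < 0.5) {
      v <- ifelse(v == p$label_low, p$label_high,
                  ifelse(v == p$label_high, p$label_low, v))
    }
    v
  })
  mat <- do.call(cbind, labs)
  maj <- apply(mat, 1L, function(row) {
    row <- row[!is.na(row)]
    tab <- sort(table(row), decreasing = TRUE)
    names(tab)[1]
  })
  support <- vapply(seq_len(nrow(mat)), function(i) {
    row <- mat[i, ][!is.na(mat[i, ])]
    mean(row == maj[i])
  }, numeric(1))
  data.frame(chromosome = base$chromosome, subgenome = maj,
             support = support, n_ref = length(results),
             stringsAsFactors = FALSE)
}
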