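#' Simulation parameters
#'
#' Conditions for the synthetic allotetraploid scenario: an ancestral
#' genome, two progenitor lineages diverging at different per-branch rates,
#' and a reference lineage. Defaults mirror a desk-scale cypriniform-like
#' setup: 10 chromosomes of 200 kb, GC ~ 40% (typical of fish genomes),
#' substitutions applied once per branch under a uniform (Jukes-Cantor
#' style) base exchange, and a light load of short indels.
#'
#' @param n_chrom number of ancestral chromosomes.
#' @param chrom_len chromosome length in bases (`>= 10000`).
#' @param gc GC fraction in `[0, 1]`.
#' @param sub_rate substitutions per site per branch, in `[0, 0.5]`.
#' @param indel_rate indel events per site, in `[0, 0.5]`.
#' @param indel_mean_len mean indel length in bases (geometric lengths).
#' @param repeat_fraction fraction of the genome covered by inserted repeat
#'   copies (used by [insert_repeats()]).
#' @param seed integer random seed; identical seeds give identical output.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_chrom = 10L, chrom_len = 2e5, gc = 0.4,
                       sub_rate = 0.02, indel_rate = 5e-4,
                       indel_mean_len = 3, repeat_fraction = 0,
                       seed = 1L) {
  stopifnot(n_chrom >= 1, chrom_len >= 1e4,
            gc >= 0, gc <= 1,
            sub_rate >= 0, sub_rate <= 0.5,
            indel_rate >= 0, indel_rate <= 0.5,
            indel_mean_len >= 1,
            repeat_fraction >= 0, repeat_fraction < 1)
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_len = as.integer(chrom_len), gc = gc,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_mean_len = indel_mean_len,
                 repeat_fraction = repeat_fraction,
                 seed = as.integer(seed)),
            class = "sim_params")
}

BASE_INTS <- c(65L, 67L, 71L, 84L) # UTF-8 codes of A, C, G, T

# sequences are manipulated as integer base codes 1..4 (NA = non-ACGT,
# preserved untouched) for speed; conversion via utf8ToInt/intToUtf8
seq_to_codes <- function(seq) {
  v <- utf8ToInt(seq)
  structure(match(v, BASE_INTS), ints = v)
}

codes_to_seq <- function(codes, orig_ints = NULL) {
  out <- BASE_INTS[codes]
  if (anyNA(out)) {
    if (!is.null(orig_ints) && length(orig_ints) == length(out)) {
      out[is.na(codes)] <- orig_ints[is.na(codes)]
    } else out[is.na(out)] <- 78L # N
  }
  intToUtf8(out)
}

#' Random DNA sequence with a target GC content
#'
#' @param n length in bases.
#' @param gc GC fraction.
#' @return A single DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 1, gc >= 0, gc <= 1)
  codes <- sample.int(4L, n, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  intToUtf8(BASE_INTS[codes])
}

#' Generate a random ancestral genome
#'
#' @param p a [sim_params()] object.
#' @param prefix chromosome name prefix.
#' @return Named character vector of `n_chrom` sequences
#'   (`<prefix>01`, `<prefix>02`, ...), deterministic per `p$seed`.
#' @export
random_genome <- function(p, prefix = "chr") {
  stopifnot(inherits(p, "sim_params"))
  with_seed(p$seed, {
    g <- vapply(seq_len(p$n_chrom), function(i) random_dna(p$chrom_len, p$gc),
                character(1))
    names(g) <- sprintf("%s%02d", prefix, seq_len(p$n_chrom))
    g
  })
}

evolve_codes <- function(codes, sub_rate, indel_rate, indel_mean_len) {
  n <- length(codes)
  if (sub_rate > 0) {
    idx <- which(runif(n) < sub_rate & !is.na(codes))
    if (length(idx) > 0L) {
      # shift by 1..3 (mod 4): uniformly random *different* base
      codes[idx] <- ((codes[idx] - 1L +
                        sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
    }
  }
  if (indel_rate > 0) {
    ev <- which(runif(n) < indel_rate)
    if (length(ev) > 0L) {
      lens <- rgeom(length(ev), prob = 1 / indel_mean_len) + 1L
      is_ins <- runif(length(ev)) < 0.5
      keep <- rep(TRUE, n)
      for (j in which(!is_ins)) {
        to <- min(n, ev[j] + lens[j] - 1L)
        keep[ev[j]:to] <- FALSE
      }
      ins_pos <- ev[is_ins]
      ins_seq <- lapply(lens[is_ins], function(l)
        sample.int(4L, l, replace = TRUE))
      new_idx <- cumsum(keep)
      codes <- codes[keep]
      if (length(ins_pos) > 0L) {
        # insert after the (surviving) base at each event position,
        # applied right-to-left so earlier indices stay valid
        ord <- order(ins_pos, decreasing = TRUE)
        for (j in ord) {
          at <- new_idx[ins_pos[j]]
          codes <- append(codes, ins_seq[[j]], after = at)
        }
      }
    }
  }
  codes
}

#' Evolve a sequence along one branch
#'
#' Applies independent per-site substitutions (probability `sub_rate` to a
#' uniformly random different base; no transition/transversion bias) and
#' indel events at rate `indel_rate` with geometric lengths (mean
#' `indel_mean_len`), insertions and deletions equiprobable. Rates are
#' per-branch expected events per site applied once, without multiple-hit
#' bookkeeping; at the rates used here (<= 0.1) the resulting bias is
#' negligible for divergence-ordering properties.
#'
#' @param seq a DNA string.
#' @param sub_rate substitution probability per site.
#' @param indel_rate indel event probability per site.
#' @param indel_mean_len mean indel length (geometric).
#' @param seed integer seed; the function is deterministic given it.
#' @return The derived DNA string.
#' @export
evolve_sequence <- function(seq, sub_rate, indel_rate = 0,
                            indel_mean_len = 3, seed = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L,
            sub_rate >= 0, sub_rate <= 0.5,
            indel_rate >= 0, indel_rate <= 0.5)
  with_seed(seed, {
    codes <- seq_to_codes(seq)
    orig <- attr(codes, "ints")
    out <- evolve_codes(as.integer(codes), sub_rate, indel_rate,
                        indel_mean_len)
    codes_to_seq(out, if (length(out) == length(orig)) orig else NULL)
  })
}

evolve_genome <- function(genome, sub_rate, indel_rate, indel_mean_len,
                          seed) {
  out <- genome
  for (i in seq_along(genome)) {
    out[[i]] <- evolve_sequence(genome[[i]], sub_rate, indel_rate,
                                indel_mean_len,
                                seed = seed + 131L * i)
  }
  out
}

#' Simulate an allotetraploid with a diploid reference and truth labels
#'
#' Builds an ancestral genome, evolves it independently into a reference
#' lineage (rate `r_ref`) and two progenitor lineages B and C (rates `r_B`,
#' `r_C`), and fuses the two progenitors into an allotetraploid whose
#' chromosomes are relabeled (and shuffled) so the truth is not encoded in
#' the names. With `r_B != r_C` the two subgenomes carry asymmetric
#' divergence and are partitionable; `r_B == r_C` emulates the
#' autopolyploid-like negative control in which the method is expected to
#' return an indeterminate verdict.
#'
#' @param p a [sim_params()] object (`sub_rate` unused; branch rates below).
#' @param r_ref,r_B,r_C per-branch substitution rates for the reference and
#'   the two progenitor lineages.
#' @return A list: `ref` (named character vector, `ref_chr*`), `poly`
#'   (named character vector, `poly_chr*`), `truth` (data frame
#'   `poly_chrom`, `progenitor` ("B"/"C"), `anc_chrom`, `ref_chrom`), and
#'   `params`.
#' @export
make_allotetraploid <- function(p, r_ref = 0.05, r_B = 0.02, r_C = 0.08) {
  stopifnot(inherits(p, "sim_params"))
  anc <- random_genome(p, prefix = "anc_chr")
  ref <- evolve_genome(anc, r_ref, p$indel_rate, p$indel_mean_len,
                       seed = p$seed + 1000L)
  names(ref) <- sub("^anc_", "ref_", names(anc))
  progB <- evolve_genome(anc, r_B, p$indel_rate, p$indel_mean_len,
                         seed = p$seed + 2000L)
  progC <- evolve_genome(anc, r_C, p$indel_rate, p$indel_mean_len,
                         seed = p$seed + 3000L)
  poly <- c(progB, progC)
  truth <- data.frame(
    poly_chrom = NA_character_,
    progenitor = rep(c("B", "C"), each = p$n_chrom),
    anc_chrom = rep(names(anc), 2L),
    ref_chrom = rep(names(ref), 2L),
    stringsAsFactors = FALSE)
  ord <- with_seed(p$seed + 4000L, sample.int(length(poly)))
  poly <- poly[ord]
  truth <- truth[ord, ]
  truth$poly_chrom <- sprintf("poly_chr%02d", seq_along(poly))
  names(poly) <- truth$poly_chrom
  rownames(truth) <- NULL
  list(ref = ref, poly = poly, truth = truth, params = p)
}

#' Insert mutated copies of a repeat monomer into a genome
#'
#' Emulates a transposon-like repeat load: a single random monomer is
#' copied into random positions (each copy independently mutated at 2% of
#' sites) until the requested fraction of the output genome is
#' repeat-derived. Every insertion is recorded as a 0-based half-open BED
#' interval in the coordinates of the returned genome, suitable for
#' hard-masking.
#'
#' @param genome named character vector of sequences.
#' @param repeat_len monomer length in bases.
#' @param repeat_fraction target fraction of the output genome covered by
#'   inserted copies (alternative to `copies`).
#' @param copies total number of copies to insert (overrides
#'   `repeat_fraction`).
#' @param seed integer seed.
#' @return A list: `genome` (with insertions), `bed` (data frame `chrom`,
#'   `start`, `end`), `monomer`.
#' @export
insert_repeats <- function(genome, repeat_len = 500L,
                           repeat_fraction = NULL, copies = NULL,
                           seed = 1L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  total_len <- sum(nchar(genome))
  if (is.null(copies)) {
    if (is.null(repeat_fraction))
      stop("give either copies or repeat_fraction")
    stopifnot(repeat_fraction >= 0, repeat_fraction < 1)
    # inserted/(L + inserted) = f  =>  inserted = f*L/(1-f)
    copies <- round(repeat_fraction * total_len /
                      (1 - repeat_fraction) / repeat_len)
  }
  copies <- as.integer(copies)
  if (copies == 0L)
    return(list(genome = genome,
                bed = data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0)),
                monomer = NA_character_))
  with_seed(seed, {
    monomer <- random_dna(repeat_len, gc = 0.5)
    lens <- nchar(genome)
    chrom_of <- sample(names(genome), copies, replace = TRUE,
                       prob = lens / sum(lens))
    bed_rows <- list()
    for (nm in names(genome)) {
      n_here <- sum(chrom_of == nm)
      if (n_here == 0L) next
      pos <- sort(sample.int(nchar(genome[[nm]]), n_here)) # insert after pos
      mono_codes <- as.integer(seq_to_codes(monomer))
      mut <- vapply(seq_len(n_here), function(i)
        codes_to_seq(evolve_codes(mono_codes, 0.02, 0, 1)), character(1))
      pieces <- substring(genome[[nm]], c(1L, pos + 1L),
                          c(pos, nchar(genome[[nm]])))
      out <- pieces[1]
      for (i in seq_len(n_here)) out <- paste0(out, mut[i], pieces[i + 1L])
      genome[[nm]] <- out
      shift <- (seq_len(n_here) - 1L) * repeat_len
      start0 <- pos + shift # 0-based start == bases preceding the insert
      bed_rows[[nm]] <- data.frame(chrom = nm, start = start0,
                                   end = start0 + repeat_len,
                                   stringsAsFactors = FALSE)
    }
    bed <- do.call(rbind, bed_rows)
    rownames(bed) <- NULL
    list(genome = genome, bed = bed, monomer = monomer)
  })
}

#' Hard-mask BED intervals of a genome with N
#'
#' @param genome named character vector of sequences.
#' @param bed data frame with `chrom`, `start`, `end` (0-based half-open).
#' @return The masked genome.
#' @export
hard_mask <- function(genome, bed) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  for (i in seq_len(nrow(bed))) {
    nm <- bed$chrom[i]
    if (!nm %in% names(genome)) stop("BED chromosome not in genome: ", nm)
    from <- bed$start[i] + 1L
    to <- bed$end[i]
    substr(genome[[nm]], from, to) <- paste(rep("N", to - from + 1L),
                                            collapse = "")
  }
  genome
}

#' Simulate error-prone short reads from haplotype copies
#'
#' Draws uniformly placed single-end reads from each haplotype, repeated
#' `multiplicity` times (an AB genome is two haplotypes at multiplicity 1;
#' an AABB genome two haplotypes at multiplicity 2), applies per-base
#' substitution errors, and reverse-complements a random half of the reads.
#'
#' The metadata attribute `kmer_coverage_per_copy` reports the expected
#' k-mer-space coverage contributed by a single copy,
#' `cov * (read_len - k + 1)/read_len * (1 - error_rate)^k`, which is the
#' "haploid coverage" the read-based ploidy module estimates.
#'
#' @param haplotypes named character vector of haplotype sequences.
#' @param multiplicity integer vector (recycled) of copies per haplotype.
#' @param coverage_per_copy mean per-base read depth per copy.
#' @param read_len read length in bases.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @param k k-mer length used for the reported k-mer coverage metadata.
#' @return Character vector of reads with attribute
#'   `kmer_coverage_per_copy`.
#' @export
simulate_reads <- function(haplotypes, multiplicity = 1L,
                           coverage_per_copy = 15, read_len = 150L,
                           error_rate = 0.005, seed = 1L, k = 21L) {
  stopifnot(is.character(haplotypes), length(haplotypes) >= 1L,
            read_len >= k, coverage_per_copy > 0,
            error_rate >= 0, error_rate < 1)
  multiplicity <- rep_len(as.integer(multiplicity), length(haplotypes))
  bases <- c("A", "C", "G", "T")
  reads <- with_seed(seed, {
    out <- list()
    for (h in seq_along(haplotypes)) {
      seqh <- haplotypes[[h]]
      L <- nchar(seqh)
      if (L < read_len) stop("haplotype shorter than read_len")
      n_reads <- round(L * coverage_per_copy * multiplicity[h] / read_len)
      starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
      r <- substring(seqh, starts, starts + read_len - 1L)
      # sequencing errors: global Binomial draw, then per-read placement
      n_err <- stats::rbinom(1L, n_reads * read_len, error_rate)
      if (n_err > 0L) {
        at_read <- sample.int(n_reads, n_err, replace = TRUE)
        at_pos <- sample.int(read_len, n_err, replace = TRUE)
        for (e in seq_len(n_err)) {
          cur <- substr(r[at_read[e]], at_pos[e], at_pos[e])
          newb <- bases[((match(cur, bases) - 1L + sample.int(3L, 1L)) %% 4L) + 1L]
          substr(r[at_read[e]], at_pos[e], at_pos[e]) <- newb
        }
      }
      flip <- runif(n_reads) < 0.5
      if (any(flip)) r[flip] <- revcomp(r[flip])
      out[[h]] <- r
    }
    unlist(out, use.names = FALSE)
  })
  names(reads) <- sprintf("read_%06d", seq_along(reads))
  attr(reads, "kmer_coverage_per_copy") <-
    coverage_per_copy * (read_len - k + 1) / read_len * (1 - error_rate)^k
  reads
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
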