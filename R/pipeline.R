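pkg_version <- function() {
  as.character(utils::packageVersion("polyphase"))
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

echo_config <- function(config, out_dir) {
  cfg <- config
  cfg$tool <- "polyphase"
  cfg$version <- pkg_version()
  jsonlite::write_json(cfg, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}

#' Run the full subgenome-partitioning pipeline
#'
#' Orchestrates sketch -> distance matrix -> homoeolog pairing ->
#' subgenome assignment for one polyploid assembly against one or more
#' diploid references, persisting every intermediate table as TSV in
#' `out_dir` together with a machine-readable echo of the configuration
#' and tool version. With several references a per-reference partition is
#' written and a majority consensus reported. Identical configuration and
#' seeds give byte-identical outputs.
#'
#' @param poly polyploid assembly: FASTA path or named character vector.
#' @param refs diploid reference assemblies: character vector of FASTA
#'   paths, or a named list of named character vectors.
#' @param out_dir output directory (created if needed).
#' @param sketch a [sketch_params()] object.
#' @param partition a [partition_params()] object.
#' @param pairs_file optional TSV fixing the homoeolog pairs
#'   (see [load_pairs_file()]); applied to the first reference only.
#' @return Invisibly, a list with `partitions` (per reference), `summaries`,
#'   and `consensus` (non-`NULL` when more than one reference was given).
#' @export
run_pipeline <- function(poly, refs, out_dir,
                         sketch = sketch_params(),
                         partition = partition_params(),
                         pairs_file = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(refs)) refs <- as.list(refs)
  if (is.null(names(refs)))
    names(refs) <- sprintf("ref%d", seq_along(refs))
  echo_config(list(
    subcommand = "partition",
    poly = if (is.character(poly) && length(poly) == 1L) poly else "<in-memory>",
    refs = vapply(refs, function(r)
      if (is.character(r) && length(r) == 1L && file.exists(r)) r
      else "<in-memory>", character(1)),
    k = sketch$k, s = sketch$s, hash_seed = sketch$hash_seed,
    tau = partition$tau,
    pairs_file = if (is.null(pairs_file)) NULL else pairs_file), out_dir)
  partitions <- list()
  summaries <- list()
  for (rn in names(refs)) {
    m <- distance_matrix(poly, refs[[rn]], sketch)
    write_tsv(m$records, file.path(out_dir, paste0("dist_", rn, ".tsv")))
    pairs <- if (!is.null(pairs_file) && rn == names(refs)[1])
      load_pairs_file(pairs_file, m) else infer_homoeolog_pairs(m)
    write_tsv(as.data.frame(pairs),
              file.path(out_dir, paste0("pairs_", rn, ".tsv")))
    res <- assign_subgenomes(pairs, partition)
    write_tsv(res$assignments,
              file.path(out_dir, paste0("partition_", rn, ".tsv")))
    s <- summarize_partition(res)
    write_tsv(cbind(s$by_subgenome, ambiguous_pairs = s$ambiguous_pairs,
                    n_pairs = s$n_pairs, verdict = s$verdict),
              file.path(out_dir, paste0("summary_", rn, ".tsv")))
    partitions[[rn]] <- res
    summaries[[rn]] <- s
  }
  consensus <- NULL
  if (length(partitions) > 1L) {
    consensus <- consensus_partition(partitions)
    write_tsv(consensus, file.path(out_dir, "consensus.tsv"))
  }
  invisible(list(partitions = partitions, summaries = summaries,
                 consensus = consensus))
}

#' Run the read-based ploidy analysis and persist its tables
#'
#' @param reads FASTQ path or character vector of reads.
#' @param out_dir output directory.
#' @param k k-mer length.
#' @param cutoff optional explicit depth cutoff.
#' @return Invisibly, the `smudge_summary`.
#' @export
run_smudge <- function(reads, out_dir, k = 21L, cutoff = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  echo_config(list(subcommand = "smudge",
                   reads = if (is.character(reads) && length(reads) == 1L)
                     reads else "<in-memory>",
                   k = k, cutoff = cutoff), out_dir)
  s <- smudge_analysis(reads, k = k, cutoff = cutoff)
  write_tsv(s$assignments, file.path(out_dir, "het_pairs.tsv"))
  write_tsv(smudge_histogram(s$assignments),
            file.path(out_dir, "smudge_hist.tsv"))
  write_tsv(data.frame(haploid_coverage = s$haploid_coverage,
                       modal_genotype = s$modal_genotype,
                       n_pairs = s$n_pairs),
            file.path(out_dir, "smudge_summary.tsv"))
  write_tsv(data.frame(genotype = names(s$proportions),
                       proportion = as.numeric(s$proportions)),
            file.path(out_dir, "genotype_proportions.tsv"))
  invisible(s)
}

#' Simulate the allotetraploid preset and persist FASTA/TSV artifacts
#'
#' @param out_dir output directory.
#' @param p a [sim_params()] object.
#' @param r_ref,r_B,r_C branch substitution rates.
#' @return Invisibly, the [make_allotetraploid()] result.
#' @export
run_simulate <- function(out_dir, p = sim_params(), r_ref = 0.05,
                         r_B = 0.02, r_C = 0.08) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  echo_config(list(subcommand = "simulate", seed = p$seed,
                   n_chrom = p$n_chrom, chrom_len = p$chrom_len,
                   r_ref = r_ref, r_B = r_B, r_C = r_C), out_dir)
  sim <- make_allotetraploid(p, r_ref = r_ref, r_B = r_B, r_C = r_C)
  write_genome(sim$ref, file.path(out_dir, "reference.fa"))
  write_genome(sim$poly, file.path(out_dir, "tetraploid.fa"))
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  invisible(sim)
}
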