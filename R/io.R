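#' Read a genome FASTA into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; accepts plain or
#' gzipped FASTA. Each record is treated as one chromosome. Record names are
#' truncated at the first whitespace, as is conventional for assemblies.
#'
#' @param path path to a FASTA (optionally `.gz`).
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("input FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no sequences in FASTA: ", path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write a named character vector of sequences to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  x <- Biostrings::DNAStringSet(genome)
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read sequencing reads from FASTQ
#'
#' @param path path to a FASTQ (optionally `.gz`).
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("input FASTQ not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  if (length(x) == 0L) stop("no reads in FASTQ: ", path)
  as.character(x)
}

#' Write reads to FASTQ with uniform placeholder qualities
#'
#' @param reads character vector of read sequences (names used as ids; made
#'   up as `read_<i>` when absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.character(reads), length(reads) > 0L)
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- if (is.null(names(reads)))
    sprintf("read_%d", seq_along(reads)) else names(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = q)
  invisible(path)
}

#' Save a sketch to a JSON container
#'
#' A plain, documented JSON format (name, parameters, hash list) rather than
#' a binary sketch file, so sketches are diffable and auditable.
#'
#' @param sketch a `polyphase_sketch` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sketch <- function(sketch, path) {
  stopifnot(inherits(sketch, "polyphase_sketch"))
  obj <- list(
    format = "polyphase-sketch-v1",
    hash_function = "splitmix64(code xor splitmix64(seed)), top 53 bits",
    name = sketch$name,
    k = sketch$params$k,
    s = if (is.finite(sketch$params$s)) sketch$params$s else "exact",
    hash_seed = sketch$params$hash_seed,
    fold_case = sketch$params$fold_case,
    total_distinct = sketch$total_distinct,
    hashes = sketch$hashes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a sketch from its JSON container
#'
#' @param path path written by [write_sketch()].
#' @return A `polyphase_sketch` object.
#' @export
read_sketch <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "polyphase-sketch-v1"))
    stop("not a polyphase sketch file: ", path)
  s <- if (identical(obj$s, "exact")) Inf else as.numeric(obj$s)
  params <- sketch_params(k = obj$k, s = s, hash_seed = obj$hash_seed,
                          fold_case = obj$fold_case)
  new_sketch(name = obj$name, params = params,
             hashes = as.numeric(obj$hashes),
             total_distinct = as.numeric(obj$total_distinct))
}
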