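#' All-pairs Mash distance matrix between a polyploid and a reference genome
#'
#' Sketches every chromosome of both genomes with shared parameters and
#' computes the Mash distance for every (reference, query) combination.
#' Chromosomes yielding no valid k-mers are excluded with a warning.
#'
#' @param poly_genome polyploid assembly: named character vector or FASTA
#'   path.
#' @param ref_genome diploid reference assembly: named character vector or
#'   FASTA path.
#' @param params a [sketch_params()] object.
#' @return A `distance_matrix` object: `ref_names`, `query_names`, `params`,
#'   and `records`, a data frame with columns `ref`, `query`, `shared`,
#'   `denom`, `jaccard`, `distance`.
#' @export
distance_matrix <- function(poly_genome, ref_genome,
                            params = sketch_params()) {
  ref_sk <- sketch_genome(ref_genome, params)
  qry_sk <- sketch_genome(poly_genome, params)
  grid <- expand.grid(ref = names(ref_sk), query = names(qry_sk),
                      stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    d <- mash_distance(ref_sk[[grid$ref[i]]], qry_sk[[grid$query[i]]])
    data.frame(ref = d$ref_name, query = d$query_name, shared = d$shared,
               denom = d$denom, jaccard = d$jaccard_est,
               distance = d$distance, stringsAsFactors = FALSE)
  })
  structure(list(ref_names = names(ref_sk), query_names = names(qry_sk),
                 params = params, records = do.call(rbind, recs)),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d ref x %d query chromosomes (k=%d, s=%s)\n",
              length(x$ref_names), length(x$query_names), x$params$k,
              if (is.finite(x$params$s)) format(x$params$s) else "exact"))
  invisible(x)
}

#' Matrix view of a distance_matrix
#'
#' @param x a `distance_matrix`.
#' @param ... unused.
#' @return Numeric matrix, rows = reference chromosomes, columns = query
#'   chromosomes.
#' @method as.matrix distance_matrix
#' @export
as.matrix.distance_matrix <- function(x, ...) {
  m <- matrix(NA_real_, length(x$ref_names), length(x$query_names),
              dimnames = list(x$ref_names, x$query_names))
  m[cbind(x$records$ref, x$records$query)] <- x$records$distance
  m
}

#' Infer homoeologous chromosome pairs by greedy distance assignment
#'
#' Iterates all (reference, query) records in ascending distance and binds a
#' query chromosome to a reference chromosome unless the query is already
#' bound or the reference already holds `copies_per_ref` members. For an
#' allotetraploid versus a diploid reference (`copies_per_ref = 2`) this
#' pairs each reference chromosome with its two homoeologs. Ties on equal
#' distance are broken lexicographically by (ref, query) name, so results do
#' not depend on input order. Leftover (unbound) chromosomes, e.g. from
#' fusions or count mismatches, are reported via a warning and the
#' `unbound` attribute, never silently dropped.
#'
#' @param m a [distance_matrix()].
#' @param copies_per_ref polyploid copies expected per reference chromosome
#'   (default 2, tetraploid).
#' @return For `copies_per_ref = 2`, a `homoeolog_pairs` data frame with
#'   columns `ref_chrom`, `member_low`, `d_low`, `member_high`, `d_high`
#'   (`d_low <= d_high`) and attribute `unbound`. For other copy numbers, a
#'   long-format data frame `ref_chrom`, `member`, `distance`, `rank`.
#' @export
infer_homoeolog_pairs <- function(m, copies_per_ref = 2L) {
  stopifnot(inherits(m, "distance_matrix"))
  copies_per_ref <- as.integer(copies_per_ref)
  if (copies_per_ref < 1L) stop("copies_per_ref must be >= 1")
  r <- m$records[order(m$records$distance, m$records$ref, m$records$query), ]
  if (length(m$query_names) != copies_per_ref * length(m$ref_names))
    warning(sprintf(
      "chromosome counts (%d query vs %d ref) do not match copies_per_ref=%d; returning partial pairing",
      length(m$query_names), length(m$ref_names), copies_per_ref),
      call. = FALSE)
  bound_q <- character(0)
  slots <- setNames(rep(0L, length(m$ref_names)), m$ref_names)
  keep <- logical(nrow(r))
  for (i in seq_len(nrow(r))) {
    if (r$query[i] %in% bound_q) next
    if (slots[[r$ref[i]]] >= copies_per_ref) next
    keep[i] <- TRUE
    bound_q <- c(bound_q, r$query[i])
    slots[[r$ref[i]]] <- slots[[r$ref[i]]] + 1L
  }
  sel <- r[keep, , drop = FALSE]
  unbound <- setdiff(m$query_names, sel$query)
  if (length(unbound) > 0L)
    warning("unbound polyploid chromosomes: ",
            paste(unbound, collapse = ", "), call. = FALSE)
  if (copies_per_ref != 2L) {
    sel <- sel[order(sel$ref, sel$distance, sel$query), ]
    out <- data.frame(ref_chrom = sel$ref, member = sel$query,
                      distance = sel$distance,
                      rank = stats::ave(sel$distance, sel$ref,
                                        FUN = seq_along),
                      stringsAsFactors = FALSE)
    attr(out, "unbound") <- unbound
    return(out)
  }
  refs <- intersect(m$ref_names, unique(sel$ref))
  rows <- lapply(refs, function(rc) {
    sub <- sel[sel$ref == rc, , drop = FALSE]
    if (nrow(sub) < 2L) return(NULL) # partially bound ref: reported unbound
    sub <- sub[order(sub$distance, sub$query), ]
    data.frame(ref_chrom = rc,
               member_low = sub$query[1], d_low = sub$distance[1],
               member_high = sub$query[2], d_high = sub$distance[2],
               stringsAsFactors = FALSE)
  })
  incomplete <- refs[vapply(rows, is.null, logical(1))]
  if (length(incomplete) > 0L)
    warning("reference chromosomes with fewer than 2 bound members: ",
            paste(incomplete, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) stop("no complete homoeolog pairs")
  rownames(out) <- NULL
  class(out) <- c("homoeolog_pairs", "data.frame")
  attr(out, "unbound") <- unbound
  out
}

#' Load a user-supplied homoeolog-pair table
#'
#' Lets users supply externally derived homology (e.g. from a collinearity
#' analysis) instead of the greedy distance assignment. The file must be a
#' TSV with header columns `ref_chrom`, `poly_chrom_1`, `poly_chrom_2`.
#' Distances are filled from the distance matrix and each pair is ordered so
#' `d_low <= d_high` regardless of the file's column order.
#'
#' @param path path to the TSV file.
#' @param m a [distance_matrix()] covering all ids in the file.
#' @return A `homoeolog_pairs` data frame as from [infer_homoeolog_pairs()].
#' @export
load_pairs_file <- function(path, m) {
  stopifnot(inherits(m, "distance_matrix"))
  if (!file.exists(path)) stop("pairs file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("ref_chrom", "poly_chrom_1", "poly_chrom_2")
  if (!all(need %in% names(tab)))
    stop("pairs file must have header columns: ",
         paste(need, collapse = ", "))
  dmat <- as.matrix(m)
  seen <- character(0)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    line <- i + 1L # header is line 1
    rc <- tab$ref_chrom[i]
    p1 <- tab$poly_chrom_1[i]
    p2 <- tab$poly_chrom_2[i]
    if (!rc %in% rownames(dmat))
      stop("line ", line, ": unknown reference chromosome '", rc, "'")
    for (p in c(p1, p2)) {
      if (!p %in% colnames(dmat))
        stop("line ", line, ": unknown polyploid chromosome '", p, "'")
      if (p %in% seen)
        stop("line ", line, ": polyploid chromosome '", p,
             "' appears in more than one pair")
    }
    if (p1 == p2)
      stop("line ", line, ": pair members must differ ('", p1, "')")
    seen <<- c(seen, p1, p2)
    d1 <- dmat[rc, p1]
    d2 <- dmat[rc, p2]
    swap <- d2 < d1 || (d2 == d1 && p2 < p1)
    data.frame(ref_chrom = rc,
               member_low = if (swap) p2 else p1,
               d_low = min(d1, d2),
               member_high = if (swap) p1 else p2,
               d_high = max(d1, d2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("homoeolog_pairs", "data.frame")
  attr(out, "unbound") <- setdiff(m$query_names,
                                  c(out$member_low, out$member_high))
  out
}
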