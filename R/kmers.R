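## k-mer counting and enrichment. Counting is delegated to Biostrings
## (C implementation, overlapping windows); the enrichment/Z logic and the
## site-level aggregation used by discovery live here.

#' Count all overlapping k-mers in a read set
#'
#' Every position window of every read is counted. Returns the counts for all
#' `4^k` k-mers in lexicographic A<C<G<T order as an unnamed integer vector
#' (use [kmer_names()] to label it; for k = 10 the names alone cost ~80 MB).
#'
#' @param reads Character vector or `DNAStringSet`.
#' @param k Window size (>= 1).
#' @return Integer vector of length `4^k`, with attribute `k`.
#' @export
count_kmers <- function(reads, k) {
  stopifnot(k >= 1L)
  if (!methods::is(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
  if (!length(reads)) stop("reads must be nonempty")
  cnt <- Biostrings::oligonucleotideFrequency(reads, width = k,
                                              simplify.as = "collapse")
  cnt <- unname(cnt)
  attr(cnt, "k") <- as.integer(k)
  cnt
}

#' @param k Window size.
#' @rdname count_kmers
#' @export
kmer_names <- function(k) Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)

#' Standardize enrichment values
#'
#' `Z = (R - mean(R)) / sd(R)` with the sample standard deviation, over all
#' k-mers.
#'
#' @param R Numeric vector of enrichment values.
#' @export
enrichment_z <- function(R) (R - mean(R)) / stats::sd(R)

#' Per-k-mer enrichment and Z-scores
#'
#' Enrichment of a k-mer is the ratio of its frequency in the bound library
#' over its frequency in the input pool; the Z-score standardizes enrichment
#' across all k-mers. A pseudocount (default 1) is added to both libraries'
#' counts before frequencies so that k-mers unobserved in the finite input
#' sample (4^10 ~ 1e6 k-mers) have finite enrichment.
#'
#' @param bound_counts,input_counts Integer vectors from [count_kmers()] at
#'   the same k.
#' @param pseudocount Added to every count in both libraries (default 1; use
#'   0 for exact frequency ratios on dense small-k tables).
#' @return An object of class `enrichment_table`: a list with unnamed vectors
#'   `count_bound`, `count_input`, `freq_bound`, `freq_input`, `R`, `Z` and
#'   scalar `k`.
#' @export
enrich_and_z <- function(bound_counts, input_counts, pseudocount = 1) {
  stopifnot(length(bound_counts) == length(input_counts))
  k <- attr(bound_counts, "k")
  if (is.null(k)) k <- as.integer(round(log(length(bound_counts), 4)))
  cb <- as.numeric(bound_counts) + pseudocount
  ci <- as.numeric(input_counts) + pseudocount
  fb <- cb / sum(cb)
  fi <- ci / sum(ci)
  R <- fb / fi
  structure(list(count_bound = as.integer(bound_counts),
                 count_input = as.integer(input_counts),
                 freq_bound = fb, freq_input = fi,
                 R = R, Z = enrichment_z(R), k = k,
                 pseudocount = pseudocount),
            class = "enrichment_table")
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table> k = %d, %d k-mers\n", x$k, length(x$R)))
  print(utils::head(top_kmers(x, 5L)))
  invisible(x)
}

#' Most enriched k-mers of an enrichment table
#'
#' @param tab An `enrichment_table`.
#' @param n Number of k-mers.
#' @return data.frame with columns kmer, count_bound, count_input, R, Z.
#' @export
top_kmers <- function(tab, n = 100L) {
  idx <- order(tab$R, decreasing = TRUE)[seq_len(min(n, length(tab$R)))]
  data.frame(kmer = index_to_kmer(idx, tab$k),
             index = idx,
             count_bound = tab$count_bound[idx],
             count_input = tab$count_input[idx],
             R = tab$R[idx], Z = tab$Z[idx],
             row.names = NULL)
}

#' Dump an enrichment table as TSV
#'
#' @param tab An `enrichment_table`.
#' @param path Output path.
#' @param n Restrict to the top n k-mers by R (default all; the full k = 10
#'   table is ~1e6 rows).
#' @export
write_enrichment_table <- function(tab, path, n = length(tab$R)) {
  utils::write.table(top_kmers(tab, n), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## Aggregate (site-level) enrichment over a member k-mer index set, using the
## same pseudocounted frequency normalization as the per-k-mer table.
aggregate_enrichment <- function(bound_counts, input_counts, idx,
                                 pseudocount = 1) {
  n <- length(bound_counts)
  cb <- sum(as.numeric(bound_counts[idx])) + pseudocount
  ci <- sum(as.numeric(input_counts[idx])) + pseudocount
  tb <- sum(as.numeric(bound_counts)) + n * pseudocount
  ti <- sum(as.numeric(input_counts)) + n * pseudocount
  (cb / tb) / (ci / ti)
}
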