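## Unique-site assignment of reads across a catalog.
##
## Each read's full search region is scanned for every catalog motif.
## Occurrences wholly contained in a longer occurrence are absorbed by it
## (a 6mer inside an 8mer is the same binding site, not a second site).
## Reads left with a single occurrence are counted to that site type; reads
## with several disjoint or partially overlapping occurrences are dropped
## and tallied; reads with no occurrence are "no-site".

#' Assign reads to unique site categories
#'
#' @param reads Character vector or `DNAStringSet` of preprocessed search
#'   regions (DNA).
#' @param catalog A [site_catalog()].
#' @param detail If `TRUE`, also return the per-match table for dropped
#'   reads (used by the simulator to resolve multi-site occupancy).
#' @return A list with `category` (character, per read: a site name,
#'   `"no-site"`, or `NA` for dropped multi/overlapping-site reads),
#'   `dropped_multi` (count), and when `detail = TRUE` a data.frame
#'   `matches` of (read, site) pairs for dropped reads.
#' @export
assign_sites <- function(reads, catalog, detail = FALSE) {
  if (!methods::is(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
  n <- length(reads)
  motifs <- catalog$motifs
  rid <- integer(0); st <- integer(0); en <- integer(0); site <- integer(0)
  for (j in seq_along(motifs)) {
    m <- Biostrings::vmatchPattern(motifs[[j]], reads)
    nm <- S4Vectors::elementNROWS(m)
    if (!sum(nm)) next
    ir <- unlist(m, use.names = FALSE)
    rid <- c(rid, rep.int(seq_len(n), nm))
    st <- c(st, IRanges::start(ir)); en <- c(en, IRanges::end(ir))
    site <- c(site, rep.int(j, sum(nm)))
  }
  category <- rep("no-site", n)
  if (!length(rid)) {
    return(list(category = category, dropped_multi = 0L,
                matches = if (detail) data.frame(read = integer(0), site = character(0))))
  }
  ## pack all reads into one coordinate space (reads are far shorter than 500)
  off <- (rid - 1L) * 500L
  ir <- IRanges::IRanges(st + off, en + off)
  w <- IRanges::width(ir)
  ov <- IRanges::findOverlaps(ir, ir, type = "within")
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  absorbed <- unique(q[w[q] < w[s]])
  keep <- setdiff(seq_along(ir), absorbed)
  n_surv <- tabulate(rid[keep], nbins = n)
  category[n_surv == 1L] <- names(motifs)[site[keep][match(which(n_surv == 1L), rid[keep])]]
  dropped <- which(n_surv >= 2L)
  category[dropped] <- NA_character_
  out <- list(category = category, dropped_multi = length(dropped))
  if (detail) {
    in_drop <- rid %in% dropped
    out$matches <- unique(data.frame(read = rid[in_drop],
                                     site = names(motifs)[site[in_drop]]))
  }
  out
}

#' Count reads per site category across libraries
#'
#' Builds the site-count matrix feeding K_D estimation: rows are site types
#' plus `"no-site"`, columns are libraries (input pool first), entries are
#' unique-site read counts. Dropped multi-site reads are tallied per library
#' and checked against a QC bound (they should be a trace fraction).
#'
#' @param libraries Named list of read vectors; must include an element
#'   named `"input"`.
#' @param catalog A [site_catalog()].
#' @param max_dropped_frac QC bound on dropped reads per library (default
#'   0.01); exceeding it raises a warning, not an error.
#' @return An object of class `site_count_matrix`: an integer matrix with
#'   attributes `dropped_multi` (per library) and `library_sizes`.
#' @export
assign_reads <- function(libraries, catalog, max_dropped_frac = 0.01) {
  stopifnot(is.list(libraries), "input" %in% names(libraries))
  sites <- c(names(catalog$motifs), "no-site")
  counts <- matrix(0L, nrow = length(sites), ncol = length(libraries),
                   dimnames = list(sites, names(libraries)))
  dropped <- integer(length(libraries)); names(dropped) <- names(libraries)
  sizes <- vapply(libraries, length, 0L)
  for (a in seq_along(libraries)) {
    asn <- assign_sites(libraries[[a]], catalog)
    tab <- table(factor(asn$category, levels = sites))
    counts[, a] <- as.integer(tab)
    dropped[a] <- asn$dropped_multi
    if (asn$dropped_multi / max(1L, sizes[a]) > max_dropped_frac) {
      warning(sprintf("library '%s': %.2f%% of reads dropped as multi-site (QC bound %.2f%%)",
                      names(libraries)[a], 100 * asn$dropped_multi / sizes[a],
                      100 * max_dropped_frac))
    }
  }
  structure(counts, dropped_multi = dropped, library_sizes = sizes,
            class = c("site_count_matrix", class(counts)))
}

#' @export
print.site_count_matrix <- function(x, ...) {
  cat("<site_count_matrix>\n")
  print(unclass(x))
  cat("dropped multi-site reads:", paste(attr(x, "dropped_multi"), collapse = " "), "\n")
  invisible(x)
}

#' Write a site-count matrix as TSV
#' @param counts A `site_count_matrix`.
#' @param path Output path.
#' @export
write_site_counts <- function(counts, path) {
  df <- data.frame(site = rownames(counts), unclass(counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
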