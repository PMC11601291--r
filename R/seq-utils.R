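## Low-level nucleic-acid string helpers shared by all modules.
## Reads are DNA (T); duplex logic is RNA (U). Conversion is explicit.

.RNA_ALPHABET <- c("A", "C", "G", "U")
.DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of a nucleic-acid string
#'
#' Antiparallel Watson-Crick complement, returned 5'->3'. The alphabet is
#' explicit: `"RNA"` complements A<->U, `"DNA"` complements A<->T.
#'
#' @param seq Character scalar, 5'->3'.
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return Character scalar, the reverse complement 5'->3'.
#' @examples
#' reverse_complement("GAGGUAG", "RNA") # "CUACCUC"
#' @export
reverse_complement <- function(seq, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  check_alphabet(seq, alphabet)
  if (alphabet == "RNA") {
    rev_chartr(seq, "ACGU", "UGCA")
  } else {
    rev_chartr(seq, "ACGT", "TGCA")
  }
}

rev_chartr <- function(seq, from, to) {
  x <- chartr(from, to, seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

## Reject with the 1-based position of the first offending character.
check_alphabet <- function(seq, alphabet) {
  allowed <- if (alphabet == "RNA") .RNA_ALPHABET else .DNA_ALPHABET
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% allowed)
  if (length(bad)) {
    stop(sprintf("non-%s character '%s' at position %d", alphabet, ch[bad[1L]], bad[1L]))
  }
  invisible(TRUE)
}

#' @rdname reverse_complement
#' @export
rna_to_dna <- function(seq) chartr("Uu", "Tt", seq)

#' @rdname reverse_complement
#' @export
dna_to_rna <- function(seq) chartr("Tt", "Uu", seq)

## Watson-Crick partner (RNA alphabet, single characters, vectorized)
wc_complement <- function(nt) chartr("ACGU", "UGCA", nt)

## TRUE if guide nt (RNA) : target nt (RNA) is a Watson-Crick pair
is_wc_pair <- function(guide_nt, target_nt) {
  wc_complement(guide_nt) == target_nt
}

## TRUE for a G:U wobble: guide G with target U, or guide U with target G
is_wobble_pair <- function(guide_nt, target_nt) {
  (guide_nt == "G" & target_nt == "U") | (guide_nt == "U" & target_nt == "G")
}

#' k-mer index arithmetic
#'
#' Conversion between DNA k-mers and their 1-based index in the
#' lexicographic A<C<G<T order used by [count_kmers()] (the ordering of
#' `Biostrings::oligonucleotideFrequency`): index = 1 + sum of base-4
#' digits with A=0, C=1, G=2, T=3. `kmers_containing()` enumerates the
#' indices of all k-mers holding `motif` as a substring (the member set of
#' a site motif, used for site-level aggregation in discovery).
#'
#' @param kmers Character vector of k-mers.
#' @param k Word size.
#' @param idx Integer indices.
#' @param motif DNA motif, `nchar(motif) <= k`.
#' @export
kmer_to_index <- function(kmers, k = nchar(kmers[1L])) {
  if (!length(kmers)) return(integer(0))
  stopifnot(all(nchar(kmers) == k))
  m <- matrix(utf8ToInt(paste(kmers, collapse = "")), nrow = k)
  digit <- integer(128)
  digit[utf8ToInt("A")] <- 0L; digit[utf8ToInt("C")] <- 1L
  digit[utf8ToInt("G")] <- 2L; digit[utf8ToInt("T")] <- 3L
  pow <- 4^((k - 1L):0)
  as.integer(colSums(matrix(digit[m], nrow = k) * pow)) + 1L
}

#' @rdname kmer_to_index
#' @export
index_to_kmer <- function(idx, k) {
  idx0 <- idx - 1L
  out <- character(length(idx))
  chars <- c("A", "C", "G", "T")
  m <- matrix("", nrow = k, ncol = length(idx))
  for (i in k:1) {
    m[i, ] <- chars[idx0 %% 4L + 1L]
    idx0 <- idx0 %/% 4L
  }
  apply(m, 2L, paste, collapse = "")
}

#' @rdname kmer_to_index
#' @export
kmers_containing <- function(motif, k) {
  m <- nchar(motif)
  if (m > k) return(integer(0))
  if (m == k) return(kmer_to_index(motif, k))
  nfree <- k - m
  flanks <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), nfree)
  out <- integer(0)
  for (p in 0:nfree) {
    left <- if (p > 0) substr(flanks, 1L, p) else ""
    right <- if (p < nfree) substr(flanks, p + 1L, nfree) else ""
    out <- c(out, kmer_to_index(unique(paste0(left, motif, right)), k))
  }
  unique(out)
}

## Random DNA sequences of fixed width (i.i.d. uniform ACGT), fast path
## used by the simulator. Returns a character vector.
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  mat <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
                nrow = n, ncol = width)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}
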