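## Read QC, structural filtering and adapter removal.
##
## A read is kept iff (i) the anchor trinucleotide (the first nucleotides of
## the 3' adapter, TGG) sits exactly at its expected 1-based window
## (positions 21-23 for a 20-nt insert), (ii) every base call has
## Phred >= min_phred, and (iii) no N calls. Anchor equality is exact - the
## filter is a literal containment test, not an alignment.

#' Filtering / trimming configuration
#'
#' @param anchor Anchor trinucleotide (default `"TGG"`).
#' @param anchor_start 1-based position where the anchor must begin
#'   (default 21, i.e. insert length + 1).
#' @param min_phred Minimum Phred score for every base (default 20).
#' @param adapter 3' adapter (default `TGGAATTCTCGGGTGCCAAGG`); its first
#'   nucleotides are the anchor.
#' @param flank5 5' constant sequence of the library molecule (used to
#'   reconstruct the search region's 5' side).
#' @param search_flank Constant nucleotides retained per side of the insert
#'   in the output search region: 0 without blocker oligos, 4 or 6 with
#'   blocker set #1 / #2 (experiment-specific; default 0).
#' @return A `filter_config` list.
#' @export
filter_config <- function(anchor = "TGG", anchor_start = 21L, min_phred = 20L,
                          adapter = "TGGAATTCTCGGGTGCCAAGG",
                          flank5 = "GGGAGTTCTACAGTCCGACGATC",
                          search_flank = 0L) {
  stopifnot(nzchar(adapter), nzchar(anchor), anchor_start >= 1L,
            search_flank %in% c(0L, 4L, 6L),
            substr(adapter, 1L, nchar(anchor)) == anchor,
            search_flank <= nchar(flank5))
  structure(list(anchor = anchor, anchor_start = as.integer(anchor_start),
                 min_phred = as.integer(min_phred), adapter = adapter,
                 flank5 = flank5, search_flank = as.integer(search_flank)),
            class = "filter_config")
}

#' Filter reads on anchor, quality and N calls
#'
#' @param seqs Character vector of read sequences (DNA).
#' @param quals Character vector of Phred+33 quality strings (same lengths).
#' @param cfg A [filter_config()].
#' @return A list: `keep` (logical) and `reason` (character: `"pass"`,
#'   `"too_short"`, `"anchor"`, `"N"`, `"quality"`). Per-read and
#'   order-independent; `sum(keep) +` per-reason drops `== length(seqs)`.
#' @export
filter_reads <- function(seqs, quals, cfg = filter_config()) {
  stopifnot(length(seqs) == length(quals), all(nchar(seqs) == nchar(quals)))
  a0 <- cfg$anchor_start
  a1 <- a0 + nchar(cfg$anchor) - 1L
  reason <- rep("pass", length(seqs))
  reason[substr(seqs, a0, a1) != cfg$anchor] <- "anchor"
  reason[grepl("N", seqs, fixed = TRUE)] <- "N"
  minq <- vapply(quals, function(q) min(utf8ToInt(q)) - 33L, 0L,
                 USE.NAMES = FALSE)
  reason[reason == "pass" & minq < cfg$min_phred] <- "quality"
  reason[nchar(seqs) < a1] <- "too_short"
  list(keep = reason == "pass", reason = reason)
}

#' Remove the 3' adapter and reconstruct the search region
#'
#' The read suffix beginning at the anchored adapter is removed; the
#' retained search region is the insert plus `search_flank` nucleotides of
#' constant sequence per side (5' side taken from `flank5`, 3' side from
#' the adapter itself, which is the molecule's 3' constant region).
#'
#' @param seqs Character vector of reads that passed [filter_reads()].
#' @param cfg A [filter_config()].
#' @return A list: `region` (character; `NA` for reads whose adapter prefix
#'   is absent at the anchor, which are dropped) and `dropped` (count).
#' @export
trim_adapter <- function(seqs, cfg = filter_config()) {
  a0 <- cfg$anchor_start
  ins <- substr(seqs, 1L, a0 - 1L)
  avail <- pmin(nchar(seqs) - a0 + 1L, nchar(cfg$adapter))
  ok <- avail > 0L &
    substr(seqs, a0, a0 + avail - 1L) == substr(cfg$adapter, 1L, avail)
  sf <- cfg$search_flank
  region <- if (sf == 0L) ins else {
    paste0(substr(cfg$flank5, nchar(cfg$flank5) - sf + 1L, nchar(cfg$flank5)),
           ins, substr(cfg$adapter, 1L, sf))
  }
  region[!ok] <- NA_character_
  list(region = region, dropped = sum(!ok))
}

#' Preprocess a FASTQ file into search regions
#'
#' Reads FASTQ (gzip transparently supported), applies [filter_reads()] and
#' [trim_adapter()], and optionally writes the kept search regions as FASTA
#' and a per-reason drop report as TSV.
#'
#' @param fastq Path to a FASTQ file.
#' @param cfg A [filter_config()].
#' @param out_fa,report Optional output paths.
#' @return A list: `regions` (kept search regions), `drops` (named counts
#'   by reason), `n_input`.
#' @export
preprocess_fastq <- function(fastq, cfg = filter_config(), out_fa = NULL,
                             report = NULL) {
  ## Biostrings warns about dropping its own metadata columns here; noise
  fq <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(fastq),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  seqs <- unname(as.character(fq))
  quals <- unname(as.character(Biostrings::quality(fq)))
  flt <- filter_reads(seqs, quals, cfg)
  trm <- trim_adapter(seqs[flt$keep], cfg)
  regions <- trm$region[!is.na(trm$region)]
  drops <- c(table(flt$reason[!flt$keep]),
             if (trm$dropped) c(adapter = trm$dropped))
  if (!is.null(out_fa)) {
    xs <- Biostrings::DNAStringSet(regions)
    names(xs) <- sprintf("read%07d", seq_along(xs))
    Biostrings::writeXStringSet(xs, out_fa)
  }
  if (!is.null(report)) {
    utils::write.table(
      data.frame(reason = names(drops), n = as.integer(drops)),
      report, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(regions = regions, drops = drops, n_input = length(seqs))
}
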