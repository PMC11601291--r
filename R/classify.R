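## Assignment of k-mers to site types via the pairing hierarchy used for
## de novo discovery. Interpretations are ranked by the number of paired
## guide positions P (longest first); within one P the tiers are, in order:
##   (0) perfect contiguous complementarity, preferring the variant with a
##       terminal adenosine opposite g1 (t1A; the A occupies the MID pocket
##       and is part of the site's printed length);
##   (1) contiguous complementarity allowing G:U wobble pairs;
##   (2) contiguous complementarity with a single internal bulged
##       (inserted) target run;
##   (3) contiguous complementarity over P guide positions with one internal
##       non-wobble mismatch (P-1 true pairs).
## Ranking by paired span rather than by window length keeps a perfect core
## from being rewritten as a longer bulged/mismatched window (e.g. a
## C-flanked seed match is a seed match, not a bulged-C site), and wobble
## precedes bulge so that the wobble-terminal types recovered de novo
## (8mer-w8, 7mer-w8) are reachable in degenerate registers.
## Remaining ambiguity is broken by fewer edits, the most 5'-proximal guide
## start, the leftmost window, and (for equivalent bulge registers, e.g. an
## inserted A next to a templated A) the smallest bulge slot, which names
## the nucleation bulge b5.6. Guide position g1 never base-pairs.

#' Classify a k-mer against a guide
#'
#' Returns the site type of the best pairing configuration of any window of
#' `kmer` against the guide, or `NULL` when no configuration with printed
#' site length of at least `min_len` exists ("no-site" is a value, not an
#' error).
#'
#' @param guide A [guide_rna()].
#' @param kmer Character scalar, 4-12 nt, DNA or RNA alphabet.
#' @param min_len Minimum printed site length (default 5, the shortest site
#'   type recovered de novo).
#' @param max_bulge_len Maximum bulged-insertion length (default 1).
#' @return A [site_spec()] or `NULL`.
#' @export
classify_kmer <- function(guide, kmer, min_len = 5L, max_bulge_len = 1L) {
  stopifnot(inherits(guide, "guide_rna"))
  k <- nchar(kmer)
  if (k < 4L || k > 12L) stop("kmer length must be in [4, 12], got ", k)
  kmer <- toupper(dna_to_rna(kmer))
  check_alphabet(kmer, "RNA")
  tch <- strsplit(kmer, "", fixed = TRUE)[[1L]]
  g <- guide$chars
  Lg <- guide$length
  Pmax <- min(k, Lg - 1L)
  if (Pmax < min_len - 1L) return(NULL)

  ## Match one window's paired chars (target 5'->3', char 1 pairs the span
  ## end) against guide span s..s+P-1 under one pairing mode.
  pair_span <- function(w, s, mode) {
    P <- length(w)
    e <- s + P - 1L
    if (e > Lg) return(NULL)
    gs <- g[e:s]
    wc <- w == wc_complement(gs)
    if (mode == "perfect") {
      if (all(wc)) return(list(n_edits = 0, args = list()))
    } else if (mode == "wobble") {
      wob <- is_wobble_pair(gs, w)
      if (all(wc | wob) && any(wob & !wc)) {
        return(list(n_edits = sum(wob & !wc),
                    args = list(wobbles = (e:s)[wob & !wc])))
      }
    } else if (mode == "mismatch") {
      if (sum(!wc) == 1L) {
        j <- which(!wc)
        if (j > 1L && j < P && !is_wobble_pair(gs[j], w[j])) {
          return(list(n_edits = 1,
                      args = list(mismatches = stats::setNames(w[j], e - j + 1L))))
        }
      }
    }
    NULL
  }

  best_of <- function(cands) {
    if (!length(cands)) return(NULL)
    slot <- vapply(cands, function(cc) {
      if (is.null(cc$args$bulges)) 0L else as.integer(names(cc$args$bulges))
    }, 0L)
    ord <- order(vapply(cands, `[[`, 0, "n_edits"),
                 vapply(cands, `[[`, 0L, "s"),
                 vapply(cands, `[[`, 0L, "p"),
                 slot)
    cc <- cands[[ord[1L]]]
    site_spec(cc$s, cc$e, t1A = cc$t1A,
              wobbles = cc$args$wobbles %||% integer(0),
              mismatches = cc$args$mismatches %||% character(0),
              bulges = cc$args$bulges %||% character(0))
  }

  ## Simple (non-bulge) tier at span P: t1A variant first, then plain.
  simple_tier <- function(P, mode) {
    for (variant in c("t1A", "plain")) {
      cands <- list()
      if (variant == "t1A") {
        if (P + 1L > k || P + 1L < min_len) next
        for (p in seq_len(k - P)) {        # window p..p+P, last char the A
          if (tch[p + P] != "A") next
          hit <- pair_span(tch[p:(p + P - 1L)], 2L, mode)
          if (!is.null(hit)) {
            cands[[length(cands) + 1L]] <-
              c(list(s = 2L, e = P + 1L, p = p, t1A = TRUE), hit)
          }
        }
      } else {
        if (P > k || P < min_len) next
        for (p in seq_len(k - P + 1L)) {
          w <- tch[p:(p + P - 1L)]
          for (s in 2L:(Lg - P + 1L)) {
            hit <- pair_span(w, s, mode)
            if (!is.null(hit)) {
              cands[[length(cands) + 1L]] <-
                c(list(s = s, e = s + P - 1L, p = p, t1A = FALSE), hit)
            }
          }
        }
      }
      res <- best_of(cands)
      if (!is.null(res)) return(res)
    }
    NULL
  }

  ## Bulge tier at span P: P paired positions plus an internal inserted run
  ## of length blen (window P + blen, plus one for the t1A variant).
  bulge_tier <- function(P) {
    if (P < max(min_len - 1L, 3L) || P > Lg - 2L) return(NULL)
    for (variant in c("t1A", "plain")) {
      cands <- list()
      for (blen in seq_len(max_bulge_len)) {
        Lw <- P + blen                     # paired + bulged chars
        win <- Lw + (variant == "t1A")
        if (win > k) next
        if (variant == "plain" && P < min_len) next
        if (variant == "t1A" && P + 1L < min_len) next
        spans <- if (variant == "t1A") 2L else 2L:(Lg - P + 1L)
        for (p in seq_len(k - win + 1L)) {
          if (variant == "t1A" && tch[p + win - 1L] != "A") next
          w <- tch[p:(p + Lw - 1L)]
          for (j in 2L:(Lw - blen)) {      # run occupies j..j+blen-1
            keep <- w[-(j:(j + blen - 1L))]
            for (s in spans) {
              e <- s + P - 1L
              if (e > Lg) next
              if (all(keep == wc_complement(g[e:s]))) {
                cands[[length(cands) + 1L]] <-
                  list(s = s, e = e, p = p, t1A = variant == "t1A",
                       n_edits = blen,
                       args = list(bulges = stats::setNames(
                         paste(w[j:(j + blen - 1L)], collapse = ""),
                         e - j + 1L)))
              }
            }
          }
        }
      }
      res <- best_of(cands)
      if (!is.null(res)) return(res)
    }
    NULL
  }

  for (P in seq(Pmax, max(min_len - 1L, 3L))) {
    for (tier in c("perfect", "wobble", "bulge", "mismatch")) {
      res <- if (tier == "bulge") bulge_tier(P) else simple_tier(P, tier)
      if (!is.null(res)) return(res)
    }
  }
  NULL
}
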