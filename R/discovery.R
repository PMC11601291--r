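## De novo binding-site discovery by iterative 10-mer enrichment with masking.
##
## Each iteration: (1) compute 10-mer enrichments on the current (masked)
## libraries; (2) classify the top_n most enriched 10-mers against the guide;
## (3) identify the most enriched site type by aggregating enrichment over
## every 10-mer containing the type's motif, after absorbing specific types
## into general ones (motif substring) that enrich equally; (4) test the
## site's Z-score,
## computed from the original (unmasked) enrichment values, against the
## percentile threshold of the iteration-0 Z distribution; (5) mask all reads
## containing the site motif in both libraries (every member 10-mer contains
## the canonical motif, so motif masking removes every member occurrence);
## (6) recount and repeat until the most enriched site falls below threshold.
##
## The site-level Z (aggregate over the member 10-mer set) rather than the
## single top 10-mer's Z is what makes the stopping rule well calibrated: the
## maximum of ~1e6 empirical Z values always exceeds their own 99.9th
## percentile, so a per-k-mer rule would accept a spurious site from any
## null library, whereas aggregation over a motif's member set has no
## selection bias and sits near Z = 0 under the null.

#' Remove reads containing any of a set of motifs
#'
#' @param reads Character vector or `DNAStringSet`.
#' @param motifs Character vector of motifs (exact substring match).
#' @return Reads with every read containing any motif removed (same class as
#'   the input).
#' @export
mask_reads <- function(reads, motifs) {
  xs <- if (methods::is(reads, "DNAStringSet")) reads else Biostrings::DNAStringSet(reads)
  hit <- rep(FALSE, length(xs))
  for (m in motifs) {
    hit <- hit | Biostrings::vcountPattern(m, xs) > 0L
  }
  reads[!hit]
}

#' De novo site discovery from the top-concentration bound library
#'
#' @param bound Reads from the binding reaction with the greatest RISC
#'   concentration (character vector or `DNAStringSet`).
#' @param input Reads from the input RNA pool.
#' @param guide A [guide_rna()].
#' @param k Motif length counted (default 10).
#' @param top_n Number of most enriched k-mers interrogated per iteration.
#' @param percentile Z-score significance percentile, computed once from the
#'   iteration-0 distribution (default 99.9).
#' @param min_len,max_bulge_len Passed to [classify_kmer()].
#' @param min_support Minimum effective member-occurrence count (counts
#'   divided by the register multiplicity) required in each library for a
#'   candidate site type to be considered estimable (default 20).
#' @param z_absorb A candidate whose motif contains another candidate's
#'   motif as a substring is absorbed into the more general type unless its
#'   aggregate enrichment is higher by more than `z_absorb` standard errors
#'   (default 2); this collapses flanking extensions and edit rewrites of a
#'   core motif that carry no independent evidence. See the methods
#'   vignette for what this implies for nested canonical types at
#'   saturating RISC concentrations.
#' @param max_iter Safety cap on iterations.
#' @return An object of class `discovery_result`: list with `accepted`
#'   (data.frame: iteration, name, motif, R_current, R_original, Z_original,
#'   percentile, n_member_kmers), `specs` (the accepted [site_spec()]s),
#'   `threshold`, `reason`, `k`.
#' @export
discover <- function(bound, input, guide, k = 10L, top_n = 100L,
                     percentile = 99.9, min_len = 5L, max_bulge_len = 1L,
                     min_support = 20, z_absorb = 2, max_iter = 10L) {
  bound <- as.character(bound); input <- as.character(input)
  cb0 <- count_kmers(bound, k); ci0 <- count_kmers(input, k)
  tab0 <- enrich_and_z(cb0, ci0)
  Rbar0 <- mean(tab0$R); S0 <- stats::sd(tab0$R)
  threshold <- stats::quantile(tab0$Z, percentile / 100, names = FALSE)

  site_z0 <- function(idx) {
    (aggregate_enrichment(cb0, ci0, idx) - Rbar0) / S0
  }

  cb <- cb0; ci <- ci0
  acc <- list(); specs <- list(); reason <- "max_iter"
  member_cache <- new.env(parent = emptyenv())
  members_of <- function(motif) {
    if (is.null(member_cache[[motif]])) {
      member_cache[[motif]] <- kmers_containing(motif, k)
    }
    member_cache[[motif]]
  }

  for (iter in seq_len(max_iter)) {
    R <- ((as.numeric(cb) + 1) / sum(as.numeric(cb) + 1)) /
         ((as.numeric(ci) + 1) / sum(as.numeric(ci) + 1))
    top_idx <- order(R, decreasing = TRUE)[seq_len(min(top_n, length(R)))]
    top_km <- index_to_kmer(top_idx, k)
    cls <- lapply(top_km, classify_kmer, guide = guide, min_len = min_len,
                  max_bulge_len = max_bulge_len)
    hit <- !vapply(cls, is.null, TRUE)
    if (!any(hit)) { reason <- "no_classifiable"; break }
    cls <- cls[hit]
    nm <- vapply(cls, `[[`, "", "name")
    cand <- cls[!duplicated(nm)]
    names(cand) <- nm[!duplicated(nm)]
    cinfo <- lapply(cand, function(sp) {
      motif <- motif_for_site(guide, sp, "DNA")
      if (nchar(motif) > k) return(NULL)      # cannot aggregate beyond k
      idx <- members_of(motif)
      mult <- k - nchar(motif) + 1L           # registers per occurrence
      B <- sum(as.numeric(cb[idx])); I <- sum(as.numeric(ci[idx]))
      list(spec = sp, motif = motif, idx = idx,
           R_cur = aggregate_enrichment(cb, ci, idx),
           eff_b = B / mult, eff_i = I / mult,
           se_rel = sqrt(1 / max(B / mult, 1) + 1 / max(I / mult, 1)))
    })
    cinfo <- Filter(Negate(is.null), cinfo)
    ## a candidate needs enough member-occurrence support in both libraries
    ## for its enrichment to be estimable at all
    cinfo <- Filter(function(ci_) ci_$eff_b >= min_support &&
                                  ci_$eff_i >= min_support, cinfo)
    if (!length(cinfo)) { reason <- "no_supported_candidate"; break }
    ## absorb specific types into general ones (motif substring) unless the
    ## specific type is more enriched by > z_absorb standard errors: a
    ## flanking extension or internal-edit rewrite of a core motif adds
    ## nothing unless its enrichment is significantly higher
    ord <- order(-vapply(cinfo, function(ci_) nchar(ci_$motif), 0L))
    absorbed <- rep(FALSE, length(cinfo))
    for (ii in ord) {
      Ti <- cinfo[[ii]]
      best_target <- NA_integer_; best_size <- -1L
      for (jj in seq_along(cinfo)) {
        if (jj == ii || absorbed[jj]) next
        Tj <- cinfo[[jj]]
        if (nchar(Tj$motif) >= nchar(Ti$motif)) next
        if (!grepl(Tj$motif, Ti$motif, fixed = TRUE)) next
        slack <- z_absorb * sqrt(Ti$se_rel^2 + Tj$se_rel^2) * Ti$R_cur
        if (Tj$R_cur >= Ti$R_cur - slack && length(Tj$idx) > best_size) {
          best_target <- jj; best_size <- length(Tj$idx)
        }
      }
      if (!is.na(best_target)) absorbed[ii] <- TRUE
    }
    cinfo <- cinfo[!absorbed]
    Rcur <- vapply(cinfo, `[[`, 0, "R_cur")
    pick <- cinfo[[which.max(Rcur)]]

    z0 <- site_z0(pick$idx)
    if (z0 < threshold) { reason <- "below_threshold"; break }

    acc[[length(acc) + 1L]] <- data.frame(
      iteration = iter, name = pick$spec$name, motif = pick$motif,
      R_current = pick$R_cur,
      R_original = aggregate_enrichment(cb0, ci0, pick$idx),
      Z_original = z0,
      percentile = 100 * mean(tab0$Z <= z0),
      n_member_kmers = length(pick$idx),
      n_top_kmers = sum(nm == pick$spec$name),
      row.names = NULL)
    specs[[pick$spec$name]] <- pick$spec

    bound <- as.character(mask_reads(bound, pick$motif))
    input <- as.character(mask_reads(input, pick$motif))
    if (!length(bound) || !length(input)) { reason <- "empty_library"; break }
    cb <- count_kmers(bound, k); ci <- count_kmers(input, k)
  }

  structure(list(
    accepted = if (length(acc)) do.call(rbind, acc) else
      data.frame(iteration = integer(0), name = character(0),
                 motif = character(0), R_current = numeric(0),
                 R_original = numeric(0), Z_original = numeric(0),
                 percentile = numeric(0), n_member_kmers = integer(0),
                 n_top_kmers = integer(0)),
    specs = specs, threshold = threshold, percentile = percentile,
    reason = reason, k = k), class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("<discovery_result> %d accepted site type(s); stop: %s (Z threshold %.2f = %.1f pct)\n",
              nrow(x$accepted), x$reason, x$threshold, x$percentile))
  if (nrow(x$accepted)) print(x$accepted)
  invisible(x)
}
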