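## Site accessibility from unpaired-probability profiles, and the flanking
## dinucleotide context partition of a site type.
##
## Accessibility profiles come from RNAplfold (an optional external tool):
## either its `_lunp` output, where column u of row i is the probability
## that the window of length u ending at position i is entirely unpaired,
## or a plain per-base TSV (position, probability unpaired). The core
## scoring consumes precomputed profiles, so no external binary is needed.

#' Read an accessibility profile
#'
#' Accepts RNAplfold `_lunp` format (header line starting with `#`, then
#' one row per position: position followed by unpaired probabilities for
#' window sizes 1..u) or a two-column TSV (position, probability).
#'
#' @param path File path.
#' @return A numeric matrix, rows = positions, columns = window sizes
#'   (a per-base TSV yields a single column), class `access_profile`.
#' @export
read_access_profile <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  ncol <- max(lengths(parts))
  m <- matrix(NA_real_, nrow = length(parts), ncol = ncol - 1L)
  pos <- integer(length(parts))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]]))
    pos[i] <- as.integer(v[1L])
    m[i, seq_len(length(v) - 1L)] <- v[-1L]
  }
  m <- m[order(pos), , drop = FALSE]
  structure(m, class = c("access_profile", class(m)))
}

#' Accessibility score of a site span
#'
#' Probability that the whole site is unpaired at thermodynamic
#' equilibrium. When the profile carries span-level window probabilities
#' (RNAplfold `_lunp` with a window column at least the span width), the
#' span-level value is used; otherwise the per-base probabilities are
#' multiplied as an independence fallback.
#'
#' @param profile Matrix from [read_access_profile()], or a numeric vector
#'   of per-base unpaired probabilities.
#' @param start,end 1-based span within the profiled sequence.
#' @return Score in `[0, 1]`.
#' @export
accessibility_score <- function(profile, start, end) {
  stopifnot(start >= 1L, end >= start)
  w <- end - start + 1L
  if (is.matrix(profile)) {
    if (end > nrow(profile)) stop("span outside profile")
    if (ncol(profile) >= w && !is.na(profile[end, w])) {
      return(profile[end, w])
    }
    p <- profile[start:end, 1L]
  } else {
    if (end > length(profile)) stop("span outside profile")
    p <- profile[start:end]
  }
  if (anyNA(p)) stop("profile has missing values over the span")
  prod(p)
}

#' Run RNAplfold on a sequence, if the binary is available
#'
#' Optional external interface: computes unpaired probabilities with
#' RNAplfold and returns the parsed `_lunp` profile. The core scoring
#' ([accessibility_score()]) consumes precomputed profiles, so nothing in
#' the package requires the binary.
#'
#' @param seq RNA or DNA sequence (character scalar).
#' @param winsize Folding window size (`-W`, default 80).
#' @param ulength Maximum unpaired-window length reported (`-u`,
#'   default 12, the motif ceiling).
#' @return An `access_profile` matrix (positions x window sizes).
#' @export
run_rnaplfold <- function(seq, winsize = 80L, ulength = 12L) {
  bin <- Sys.which("RNAplfold")
  if (!nzchar(bin)) {
    stop("RNAplfold binary not found on PATH; supply a precomputed ",
         "profile via read_access_profile() instead")
  }
  dir <- tempfile("plfold"); dir.create(dir)
  old <- setwd(dir); on.exit(setwd(old), add = TRUE)
  writeLines(c(">seq", dna_to_rna(seq)), "in.fa")
  status <- system2(bin, c("-W", winsize, "-u", ulength),
                    stdin = "in.fa", stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("RNAplfold exited with status ", status)
  read_access_profile("seq_lunp")
}

#' Flanking dinucleotide context panel of a site type
#'
#' Subdivides a site into `4^(2*flank)` context-specific sites according to
#' the `flank`-nucleotide sequences immediately 5' and 3' of the site motif
#' (the paper-scale analysis uses dinucleotides, flank = 2, i.e. 256
#' 12-nt sites for an 8mer).
#'
#' @param guide A [guide_rna()].
#' @param spec A [site_spec()] or site name.
#' @param flank Flanking width per side (default 2).
#' @return data.frame with columns name, flank5, flank3, motif (DNA).
#' @export
context_panel <- function(guide, spec, flank = 2L) {
  if (is.character(spec)) spec <- parse_site_name(spec)
  base <- motif_for_site(guide, spec, "DNA")
  fl <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), flank)
  grid <- expand.grid(flank5 = fl, flank3 = fl, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(name = sprintf("%s[%s/%s]", spec$name, grid$flank5, grid$flank3),
             flank5 = grid$flank5, flank3 = grid$flank3,
             motif = paste0(grid$flank5, base, grid$flank3),
             row.names = NULL)
}

#' Catalog of context-specific sites for K_D fitting
#'
#' Wraps [context_panel()] motifs as a catalog usable by [assign_reads()]
#' and [fit_kd()], so each flanking context becomes its own site type.
#' Reads where the base motif sits too close to the read edge for full
#' flanks match no context motif and fall into no-site.
#'
#' @inheritParams context_panel
#' @export
context_catalog <- function(guide, spec, flank = 2L) {
  panel <- context_panel(guide, spec, flank)
  if (any(nchar(panel$motif) > 12L)) {
    stop("context motifs exceed the 12-nt RBNS motif ceiling")
  }
  structure(list(guide = guide, specs = list(),
                 motifs = stats::setNames(panel$motif, panel$name),
                 alphabet = "DNA", panel = panel),
            class = "site_catalog")
}
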