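## Formal grammar of miRNA target-site types.
##
## Coordinates are 1-based guide positions g1..gL, 5'->3'. Target position tK
## is the nucleotide opposite gK. Motifs are written target 5'->3', so the
## nucleotide opposite the highest paired guide position comes first and the
## t1A adenosine (bound in the Argonaute MID pocket, never base-paired) is the
## motif's 3'-terminal character. Position g1 is reserved for the t1A pocket
## and never base-pairs, matching the structural role of the MID domain.

#' Construct a guide RNA object
#'
#' @param name Identifier (e.g. `"let-7"`).
#' @param sequence Guide sequence 5'->3' over `{A,C,G,U}`; T is accepted and
#'   transliterated to U. Length must be 18-30 nt.
#' @return An object of class `guide_rna` with fields `name`, `sequence`,
#'   `length` and the per-position character vector `chars`.
#' @export
guide_rna <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(dna_to_rna(sequence))
  check_alphabet(sequence, "RNA")
  len <- nchar(sequence)
  if (len < 18L || len > 30L) {
    stop("guide length must be between 18 and 30 nt, got ", len)
  }
  structure(
    list(name = name, sequence = sequence, length = len,
         chars = strsplit(sequence, "", fixed = TRUE)[[1L]]),
    class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  cat(sprintf("<guide_rna> %s (%d nt)\n  5'-%s-3'\n", x$name, x$length, x$sequence))
  invisible(x)
}

#' Construct a target-site specification
#'
#' A `site_spec` describes one target-site type: the inclusive paired guide
#' span `[g_start, g_end]`, whether an adenosine sits opposite g1 (`t1A`),
#' and edits relative to perfect complementarity: G:U wobbles, mismatched
#' target nucleotides, bulged (inserted) target nucleotides between adjacent
#' target positions, and target deletions.
#'
#' @param g_start,g_end Inclusive guide-position span; `g_start >= 2` (g1 is
#'   the unpaired A-pocket position).
#' @param t1A Logical; adenosine opposite g1. Requires `g_start == 2`.
#' @param wobbles Integer vector of guide positions carrying G:U pairs.
#' @param mismatches Named character vector: names are guide positions, values
#'   the target nucleotide (RNA letters; `"R"` = IUPAC purine is allowed).
#' @param bulges Named character vector: names are inter-position slots `k`
#'   (insertion between tK and tK+1), values the inserted nucleotide(s) 5'->3'.
#' @param deletions Integer vector of guide positions with no opposing target
#'   nucleotide.
#' @param name Optional canonical name; derived from the structure if missing.
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(g_start, g_end, t1A = FALSE, wobbles = integer(0),
                      mismatches = character(0), bulges = character(0),
                      deletions = integer(0), name = NULL) {
  g_start <- as.integer(g_start); g_end <- as.integer(g_end)
  wobbles <- sort(unique(as.integer(wobbles)))
  deletions <- sort(unique(as.integer(deletions)))
  if (g_start < 2L) stop("g_start must be >= 2: g1 is the unpaired A-pocket position")
  if (g_end < g_start) stop("empty span [", g_start, ", ", g_end, "]")
  if (t1A && g_start != 2L) stop("t1A requires g_start == 2")
  mpos <- as.integer(names(mismatches))
  bpos <- as.integer(names(bulges))
  inside <- function(p) all(p >= g_start & p <= g_end)
  if (!inside(wobbles) || !inside(mpos) || !inside(deletions)) {
    stop("edit position outside paired span [", g_start, ", ", g_end, "]")
  }
  if (length(bpos) && !all(bpos >= g_start & bpos < g_end)) {
    stop("bulge slot outside span interior")
  }
  if (any(duplicated(c(wobbles, mpos, deletions)))) {
    stop("conflicting edits at a single guide position")
  }
  if (length(mismatches)) {
    bad <- !toupper(mismatches) %in% c("A", "C", "G", "U", "R")
    if (any(bad)) stop("invalid mismatch nucleotide: ", mismatches[bad][1L])
    mismatches <- stats::setNames(toupper(as.character(mismatches)), mpos)
    mismatches <- mismatches[order(mpos)]
  }
  if (length(bulges)) {
    bulges <- stats::setNames(toupper(dna_to_rna(as.character(bulges))), bpos)
    for (b in bulges) check_alphabet(b, "RNA")
    bulges <- bulges[order(bpos)]
  }
  spec <- structure(
    list(g_start = g_start, g_end = g_end, t1A = isTRUE(t1A),
         wobbles = wobbles, mismatches = mismatches, bulges = bulges,
         deletions = deletions, name = ""),
    class = "site_spec")
  spec$name <- if (is.null(name)) format_site_name(spec) else name
  spec
}

#' @export
format.site_spec <- function(x, ...) x$name

#' @export
print.site_spec <- function(x, ...) {
  cat(sprintf("<site_spec> %s  span g%d-g%d%s\n", x$name, x$g_start, x$g_end,
              if (x$t1A) " +t1A" else ""))
  if (length(x$wobbles)) cat("  wobbles: g", paste(x$wobbles, collapse = ", g"), "\n", sep = "")
  if (length(x$mismatches)) cat("  mismatches: ",
    paste0("g", names(x$mismatches), "->", x$mismatches, collapse = ", "), "\n", sep = "")
  if (length(x$bulges)) cat("  bulges: ",
    paste0("t", names(x$bulges), "/t", as.integer(names(x$bulges)) + 1L, ":", x$bulges,
           collapse = ", "), "\n", sep = "")
  if (length(x$deletions)) cat("  deletions: g", paste(x$deletions, collapse = ", g"), "\n", sep = "")
  invisible(x)
}

## Canonical printed name. The base length counts paired guide positions plus
## the t1A adenosine; bulges and deletions modify the base site and do not
## change the printed length (e.g. "8mer-b5.6A").
format_site_name <- function(spec) {
  s <- spec$g_start; e <- spec$g_end
  len <- (e - s + 1L) + as.integer(spec$t1A)
  wob <- spec$wobbles
  ## compact seed forms
  if (spec$t1A && s == 2L && e == 8L) {
    base <- "8mer"
  } else if (spec$t1A && s == 2L) {
    base <- sprintf("%dmer-A1", len)
  } else if (!spec$t1A && s == 2L && e == 7L) {
    base <- "6mer"
  } else if (!spec$t1A && e == 8L && s %in% c(2L, 3L)) {
    base <- sprintf("%dmer-m8", len)
  } else {
    base <- sprintf("%dmer-m%d.%d", len, s, e)
  }
  ## the paper's compact wobble-at-m8 forms: "8mer-w8", "7mer-w8"
  if (s == 2L && e == 8L && 8L %in% wob) {
    base <- if (spec$t1A) "8mer-w8" else "7mer-w8"
    wob <- setdiff(wob, 8L)
  }
  sep <- if (grepl("-(m|A1|w)", base)) "," else "-"
  out <- base
  for (w in wob) { out <- paste0(out, sep, "w", w); sep <- "," }
  for (i in seq_along(spec$mismatches)) {
    out <- paste0(out, "-x", names(spec$mismatches)[i], spec$mismatches[i])
  }
  for (i in seq_along(spec$bulges)) {
    k <- as.integer(names(spec$bulges)[i])
    out <- paste0(out, "-b", k, ".", k + 1L, spec$bulges[i])
  }
  for (d in spec$deletions) out <- paste0(out, "-d", d)
  out
}

#' Parse a printed site name into a `site_spec`
#'
#' Accepts the full printed nomenclature: `"8mer"`, `"7mer-m8"`, `"7mer-A1"`,
#' `"6mer"`, `"6mer-m8"`, `"6mer-A1"`, `"5mer-A1"`, range forms
#' (`"5mer-m2.6"`, `"10mer-m13.22"`, `"11mer-m4.14"`), wobble forms
#' (`"8mer-w8"`, `"7mer-w8"`, `"7mer-m8,w2"`), mismatches (`"8mer-x4C"`,
#' `"8mer-x4R"`), bulges (`"8mer-b5.6A"`, `"8mer-b5.6CA"`) and deletions
#' (`"8mer-d4"`, a grammar extension). `print(parse(name)) == name`.
#'
#' @param name Site name.
#' @return A `site_spec`.
#' @export
parse_site_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec("^(\\d+)mer", name))[[1L]]
  if (!length(m)) stop("unparseable site name '", name, "': missing '<len>mer' prefix")
  len <- as.integer(m[2L])
  rest <- substr(name, nchar(m[1L]) + 1L, nchar(name))
  toks <- if (nzchar(rest)) {
    if (!substr(rest, 1L, 1L) %in% c("-", ",")) {
      stop("unparseable site name '", name, "': unexpected token '", rest, "'")
    }
    strsplit(substr(rest, 2L, nchar(rest)), "[-,]")[[1L]]
  } else character(0)

  t1A <- FALSE; g_start <- NA_integer_; g_end <- NA_integer_
  i <- 1L
  if (length(toks)) {
    t1 <- toks[1L]
    if (grepl("^m\\d+\\.\\d+$", t1)) {
      p <- as.integer(strsplit(substr(t1, 2L, nchar(t1)), ".", fixed = TRUE)[[1L]])
      g_start <- p[1L]; g_end <- p[2L]; i <- 2L
      if (len != g_end - g_start + 1L) {
        stop("length prefix ", len, "mer inconsistent with span in '", name, "'")
      }
    } else if (grepl("^m8$", t1)) {
      g_end <- 8L; g_start <- 8L - len + 1L; i <- 2L
    } else if (t1 == "A1") {
      t1A <- TRUE; g_start <- 2L; g_end <- len; i <- 2L
    } else if (grepl("^w\\d+$", t1) && !len %in% c(6L, 8L)) {
      ## compact "<len>mer-w<k>" (e.g. "7mer-w8"): span g2..gk, t1A iff len==k
      k <- as.integer(substr(t1, 2L, nchar(t1)))
      if (!len %in% c(k, k - 1L)) stop("unparseable site name '", name, "'")
      t1A <- len == k; g_start <- 2L; g_end <- k
      ## leave the wobble token for the edit pass
    }
  }
  if (is.na(g_start)) {  # plain "<len>mer" base
    if (len == 8L) { t1A <- TRUE; g_start <- 2L; g_end <- 8L }
    else if (len == 6L) { g_start <- 2L; g_end <- 7L }
    else stop("unparseable site name '", name, "': plain '", len,
              "mer' is only defined for 6mer and 8mer")
  }

  wobbles <- integer(0); mismatches <- character(0)
  bulges <- character(0); deletions <- integer(0)
  for (tk in toks[seq_along(toks) >= i]) {
    if (grepl("^w\\d+$", tk)) {
      wobbles <- c(wobbles, as.integer(substr(tk, 2L, nchar(tk))))
    } else if (grepl("^x\\d+[ACGURT]$", tk)) {
      pos <- sub("^x(\\d+).$", "\\1", tk)
      nt <- dna_to_rna(substr(tk, nchar(tk), nchar(tk)))
      mismatches <- c(mismatches, stats::setNames(nt, pos))
    } else if (grepl("^b\\d+\\.\\d+[ACGUT]+$", tk)) {
      mm <- regmatches(tk, regexec("^b(\\d+)\\.(\\d+)([ACGUT]+)$", tk))[[1L]]
      a <- as.integer(mm[2L]); b <- as.integer(mm[3L])
      if (b != a + 1L) stop("bulge slot must be adjacent positions in '", name, "'")
      bulges <- c(bulges, stats::setNames(mm[4L], a))
    } else if (grepl("^d\\d+$", tk)) {
      deletions <- c(deletions, as.integer(substr(tk, 2L, nchar(tk))))
    } else {
      stop("unparseable site name '", name, "': offending token '", tk, "'")
    }
  }
  spec <- site_spec(g_start, g_end, t1A = t1A, wobbles = wobbles,
                    mismatches = mismatches, bulges = bulges,
                    deletions = deletions)
  expect_len <- (g_end - g_start + 1L) + as.integer(t1A)
  if (len != expect_len) {
    stop("length prefix ", len, "mer inconsistent with structure of '", name, "'")
  }
  spec
}

#' Target motif for a site specification
#'
#' Builds the target motif, 5'->3', by reverse-complementing the paired guide
#' span and applying the spec's edits: wobbles replace the complement so the
#' pair is G:U, mismatches substitute the stated nucleotide, bulges insert
#' between the complements of the flanking guide positions, deletions remove
#' the complement, and a 3'-terminal A is appended for t1A sites.
#'
#' @param guide A `guide_rna`.
#' @param spec A `site_spec` or a site name understood by [parse_site_name()].
#' @param alphabet `"DNA"` (default, matching sequencing reads) or `"RNA"`.
#' @return Character scalar, the target motif 5'->3'.
#' @export
motif_for_site <- function(guide, spec, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(inherits(guide, "guide_rna"))
  if (is.character(spec)) spec <- parse_site_name(spec)
  if (spec$g_end > guide$length) {
    stop("span end g", spec$g_end, " exceeds guide length ", guide$length)
  }
  g <- guide$chars
  out <- character(0)
  for (k in spec$g_end:spec$g_start) {     # target 5'->3' = guide 3'->5'
    nt <- if (as.character(k) %in% names(spec$mismatches)) {
      spec$mismatches[[as.character(k)]]
    } else if (k %in% spec$deletions) {
      NA_character_
    } else if (k %in% spec$wobbles) {
      if (g[k] == "G") "U" else if (g[k] == "U") "G"
      else stop("wobble requested at g", k, " but guide has ", g[k],
                " which admits no G:U partner")
    } else {
      wc_complement(g[k])
    }
    if (!is.na(nt)) out <- c(out, nt)
    ## bulge in slot (k-1, k) goes after tK in target 5'->3' order
    slot <- as.character(k - 1L)
    if (slot %in% names(spec$bulges) && (k - 1L) >= spec$g_start) {
      out <- c(out, strsplit(spec$bulges[[slot]], "", fixed = TRUE)[[1L]])
    }
  }
  if (spec$t1A) out <- c(out, "A")
  motif <- paste(out, collapse = "")
  if (alphabet == "DNA") rna_to_dna(motif) else motif
}

#' Length of the motif implied by a site specification
#'
#' Equals span length + bulge insertions - deletions + (1 if t1A).
#' @param spec A `site_spec`.
#' @export
motif_length <- function(spec) {
  (spec$g_end - spec$g_start + 1L) +
    sum(nchar(spec$bulges)) - length(spec$deletions) + as.integer(spec$t1A)
}
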