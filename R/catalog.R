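## Site catalogs: an ordered set of site specs for one guide, with their
## target motifs (DNA by default, matching sequencing reads).

#' Build a site catalog
#'
#' @param guide A [guide_rna()].
#' @param specs A list of [site_spec()] objects and/or site names understood
#'   by [parse_site_name()].
#' @param alphabet Alphabet for the stored motifs, `"DNA"` (default) or `"RNA"`.
#' @return An object of class `site_catalog` with fields `guide`, `specs`
#'   (named list) and `motifs` (named character vector).
#' @export
site_catalog <- function(guide, specs, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(inherits(guide, "guide_rna"))
  specs <- lapply(specs, function(s) if (is.character(s)) parse_site_name(s) else s)
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate site names in catalog: ", nm[duplicated(nm)][1L])
  names(specs) <- nm
  motifs <- vapply(specs, function(s) motif_for_site(guide, s, alphabet), "")
  ml <- nchar(motifs)
  if (any(ml < 4L | ml > 12L)) {
    stop("motif length outside the 4-12 nt range supported by RBNS: ",
         paste(nm[ml < 4L | ml > 12L], collapse = ", "))
  }
  structure(list(guide = guide, specs = specs, motifs = motifs,
                 alphabet = alphabet),
            class = "site_catalog")
}

#' @export
print.site_catalog <- function(x, ...) {
  cat(sprintf("<site_catalog> guide %s, %d site types\n", x$guide$name,
              length(x$specs)))
  print(data.frame(name = names(x$motifs), motif = unname(x$motifs),
                   row.names = NULL))
  invisible(x)
}

#' Write / read a site catalog as TSV
#'
#' Columns: name, gStart, gEnd, t1A, edits, motif. The name encodes the full
#' structure and round-trips through [parse_site_name()]; the other columns
#' are provided for human inspection and checked on read.
#'
#' @param catalog A `site_catalog`.
#' @param path File path.
#' @export
write_site_catalog <- function(catalog, path) {
  specs <- catalog$specs
  df <- data.frame(
    name = names(specs),
    gStart = vapply(specs, `[[`, 0L, "g_start"),
    gEnd = vapply(specs, `[[`, 0L, "g_end"),
    t1A = vapply(specs, `[[`, TRUE, "t1A"),
    edits = vapply(specs, function(s) {
      paste(c(if (length(s$wobbles)) paste0("w", s$wobbles),
              if (length(s$mismatches)) paste0("x", names(s$mismatches), s$mismatches),
              if (length(s$bulges)) paste0("b", names(s$bulges), ".",
                                           as.integer(names(s$bulges)) + 1L, s$bulges),
              if (length(s$deletions)) paste0("d", s$deletions)),
            collapse = ";")
    }, ""),
    motif = unname(catalog$motifs))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param guide The guide the catalog was built for.
#' @param path File path.
#' @rdname write_site_catalog
#' @export
read_site_catalog <- function(path, guide) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(name = "character", motif = "character"))
  cat <- site_catalog(guide, as.list(df$name))
  if (!all(cat$motifs == df$motif)) {
    stop("catalog motifs in ", path, " do not match the supplied guide")
  }
  cat
}

#' Packaged Drosophila guide sequences
#'
#' Returns one of the four fly miRNA guides used throughout the package
#' examples and tests (miRBase-derived reference sequences shipped in
#' `inst/extdata/guides.fa`; guides are inputs to every analysis, so any
#' guide_rna can be used instead).
#'
#' @param name One of `"let-7"`, `"bantam"`, `"miR-184"`, `"miR-11"`.
#' @return A [guide_rna()].
#' @export
fly_guide <- function(name = c("let-7", "bantam", "miR-184", "miR-11")) {
  name <- match.arg(name)
  fa <- system.file("extdata", "guides.fa", package = "mirbns", mustWork = TRUE)
  seqs <- Biostrings::readRNAStringSet(fa)
  hit <- grep(paste0("^", name, "\\b"), names(seqs))
  guide_rna(name, as.character(seqs[[hit[1L]]]))
}

#' Canonical seed-site catalog for a guide
#'
#' The six canonical seed-matched site types plus no-site handling is left to
#' the assignment step; this helper just builds the catalog.
#'
#' @param guide A [guide_rna()].
#' @param names Site names (default the canonical six).
#' @export
canonical_catalog <- function(guide,
                              names = c("8mer", "7mer-m8", "7mer-A1", "6mer",
                                        "6mer-m8", "6mer-A1")) {
  site_catalog(guide, as.list(names))
}
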