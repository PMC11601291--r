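## Nearest-neighbor duplex free energies and predicted dissociation
## constants. The parameter set is a single published RNA/RNA table
## (Turner-2004 vintage, Watson-Crick block; see
## inst/extdata/nn_rna_turner2004.tsv) transcribed into a versioned data
## file whose identity is recorded in the returned attributes.

.nn_table_cache <- new.env(parent = emptyenv())

#' Load a nearest-neighbor parameter table
#'
#' @param path TSV with columns term, key, dg37_kcal_mol; defaults to the
#'   packaged Turner-2004-vintage Watson-Crick table.
#' @return A list: `stack` (named numeric), `init`, `term_au`, `symmetry`,
#'   `source`.
#' @export
nn_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_rna_turner2004.tsv",
                        package = "mirbns", mustWork = TRUE)
  }
  key <- normalizePath(path)
  if (!is.null(.nn_table_cache[[key]])) return(.nn_table_cache[[key]])
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  tab <- list(
    stack = stats::setNames(df$dg37_kcal_mol[df$term == "stack"],
                            df$key[df$term == "stack"]),
    init = df$dg37_kcal_mol[df$term == "init"][1L],
    term_au = df$dg37_kcal_mol[df$term == "term_au"][1L],
    symmetry = df$dg37_kcal_mol[df$term == "symmetry"][1L],
    source = basename(path))
  .nn_table_cache[[key]] <- tab
  tab
}

#' Nearest-neighbor free energy of a guide-span/target duplex
#'
#' Sum of stack terms plus duplex initiation, terminal A:U (or G:U)
#' penalties, and the self-complementarity symmetry term, for the RNA/RNA
#' duplex formed by a guide span and its target motif. Pairing must be
#' Watson-Crick except at guide positions declared as wobbles (which in
#' turn require a parameter table carrying G:U stack terms).
#'
#' @param guide_span Guide span sequence, RNA 5'->3'.
#' @param target_motif Target motif, RNA or DNA 5'->3' (antiparallel:
#'   its last base pairs the span's first).
#' @param wobbles Integer positions (1-based within `guide_span`) allowed
#'   to pair G:U.
#' @param table A [nn_table()].
#' @return dG at 37 C in kcal/mol, with attribute `source`.
#' @export
nn_duplex_dG <- function(guide_span, target_motif, wobbles = integer(0),
                         table = nn_table()) {
  g <- strsplit(toupper(dna_to_rna(guide_span)), "")[[1L]]
  t5 <- strsplit(toupper(dna_to_rna(target_motif)), "")[[1L]]
  L <- length(g)
  if (length(t5) != L) stop("span and motif lengths differ: no indels allowed here")
  if (L < 2L) stop("duplex must be at least 2 bp")
  t <- rev(t5)                       # t[i] pairs g[i]
  wc <- is_wc_pair(g, t)
  wob <- is_wobble_pair(g, t)
  bad <- which(!(wc | (wob & seq_len(L) %in% wobbles)))
  if (length(bad)) {
    stop("unpaired or undeclared non-WC position ", bad[1L],
         " (", g[bad[1L]], ":", t[bad[1L]], ")")
  }
  dg <- table$init
  for (i in seq_len(L - 1L)) {
    key <- paste0(g[i], g[i + 1L], "/", t[i], t[i + 1L])
    v <- unname(table$stack[match(key, names(table$stack))])
    if (is.na(v)) {
      stop("no stack parameter for ", key,
           " in table '", table$source,
           "' (the packaged table has no G:U wobble block)")
    }
    dg <- dg + v
  }
  for (i in c(1L, L)) {
    if (!(paste0(g[i], t[i]) %in% c("CG", "GC"))) dg <- dg + table$term_au
  }
  if (paste(g, collapse = "") == paste(t5, collapse = "")) {
    dg <- dg + table$symmetry
  }
  structure(dg, source = table$source)
}

#' Predicted dissociation constant from a duplex free energy
#'
#' `K_pred = exp(dG / (R T))` in molar, with R = 0.0019872 kcal/(mol K).
#'
#' @param dG Free energy (kcal/mol).
#' @param temperature Kelvin (default 310.15, i.e. 37 C, the reference
#'   temperature of the dG table; the binding assays run at 25 C, but a
#'   temperature-consistent offset cancels in log-scale correlations).
#' @export
predicted_kd <- function(dG, temperature = 310.15) {
  stopifnot(temperature > 0)
  exp(as.numeric(dG) / (0.0019872 * temperature))
}

#' Predicted K_D for a site of a guide
#'
#' Convenience wrapper: builds the guide-span sequence and target motif for
#' an edit-free, non-t1A site (the t1A adenosine is pocket-bound, not
#' paired, so sites with t1A have no defined duplex dG) and returns
#' `predicted_kd(nn_duplex_dG(...))`.
#'
#' @param guide A [guide_rna()].
#' @param spec A [site_spec()] or site name.
#' @param temperature Kelvin.
#' @param table A [nn_table()].
#' @export
site_predicted_kd <- function(guide, spec, temperature = 310.15,
                              table = nn_table()) {
  if (is.character(spec)) spec <- parse_site_name(spec)
  if (spec$t1A) stop("predicted K_D is defined for sites without t1A")
  if (length(spec$mismatches) || length(spec$bulges) || length(spec$deletions)) {
    stop("predicted K_D supports only contiguous (optionally wobbled) duplexes")
  }
  span <- substr(guide$sequence, spec$g_start, spec$g_end)
  motif <- motif_for_site(guide, spec, "RNA")
  wob <- spec$wobbles - spec$g_start + 1L
  predicted_kd(nn_duplex_dG(span, motif, wobbles = wob, table = table),
               temperature)
}

#' Pearson correlation between predicted and observed K_D
#'
#' Computed on log-transformed values; the p-value is two-sided from the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @param k_pred,k_obs Positive dissociation constants (>= 3 pairs).
#' @return A list: `r`, `p`, `n`.
#' @export
correlate_pred_obs <- function(k_pred, k_obs) {
  stopifnot(length(k_pred) == length(k_obs), length(k_pred) >= 3L,
            all(k_pred > 0), all(k_obs > 0))
  x <- log10(k_pred); y <- log10(k_obs)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                note = "zero variance: correlation undefined"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
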