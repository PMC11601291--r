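## Equilibrium-selection simulator for RBNS libraries.
##
## The generator reproduces the statistical structure the analysis assumes:
## a pool of molecules with 20-nt uniform-random inserts inside constant
## primer-binding flanks; equilibrium selection at each RISC concentration
## with per-molecule bound probability equal to fractional occupancy at the
## molecule's site-specific K_D, with free RISC limited by mass conservation
## over the whole library; multinomial sequencing sampling to a fixed depth;
## and a mock (no-RISC) library sampled uniformly from the pool. Bound reads
## are sampled with weights equal to occupancy without explicit molecule
## depletion: the library (100 nM) is in vast excess over RISC (<= 5.8 nM),
## so depletion of any one sequence is negligible while total RISC
## sequestration is not (hence the free-RISC solve).

#' Simulation configuration
#'
#' @param guide A [guide_rna()].
#' @param kd_map Named numeric vector of true K_D values (nM): one per site
#'   type (names understood by [parse_site_name()]) plus `"no-site"`.
#' @param insert_length Random-insert length (default 20).
#' @param n_pool Number of distinct pool molecules (default 1e6; a
#'   desk-scale stand-in for the experimental 1e12 diversity).
#' @param flank5,flank3 Constant primer-binding sequences (DNA). `flank3`
#'   doubles as the sequencing 3' adapter.
#' @param series Total active RISC concentrations (nM), highest first
#'   (default six 3.2-fold serial dilutions from 5 nM).
#' @param library_total RNA library concentration (nM, default 100).
#' @param depth Reads sequenced per library (default 1e6).
#' @param search_flank Constant nucleotides retained per side of the insert
#'   in the single-stranded search region (default 4, the blocker regime).
#' @param seed Integer seed; all randomness derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(guide, kd_map, insert_length = 20L, n_pool = 1e6,
                       flank5 = "GGGAGTTCTACAGTCCGACGATC",
                       flank3 = "TGGAATTCTCGGGTGCCAAGG",
                       series = 5 / 3.2^(0:5), library_total = 100,
                       depth = 1e6, search_flank = 4L, seed = 1L) {
  stopifnot(inherits(guide, "guide_rna"), "no-site" %in% names(kd_map),
            all(kd_map > 0), depth >= 1, insert_length >= 1)
  if (is.unsorted(rev(series), strictly = TRUE)) {
    stop("series must be strictly decreasing (serial dilutions)")
  }
  structure(list(guide = guide, kd_map = kd_map,
                 insert_length = as.integer(insert_length),
                 n_pool = as.integer(n_pool), flank5 = flank5, flank3 = flank3,
                 series = series, library_total = library_total,
                 depth = as.integer(depth),
                 search_flank = as.integer(search_flank),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Fractional occupancy of a single site at equilibrium
#'
#' @param a_free Free RISC concentration (nM), >= 0.
#' @param kd Dissociation constant (nM), > 0.
#' @return `a_free / (a_free + kd)`, in `[0, 1]`.
#' @export
occupancy <- function(a_free, kd) {
  if (any(kd <= 0)) stop("kd must be > 0")
  if (any(a_free < 0)) stop("a_free must be >= 0")
  a_free / (a_free + kd)
}

#' Simulate the input RNA pool
#'
#' @param cfg A [sim_config()].
#' @return An `rbns_pool`: list with `inserts` (character), `cfg`.
#' @export
simulate_pool <- function(cfg) {
  set.seed(cfg$seed)
  structure(list(inserts = random_dna(cfg$n_pool, cfg$insert_length),
                 cfg = cfg),
            class = "rbns_pool")
}

#' Single-stranded search region of each molecule
#'
#' Insert plus `search_flank` constant nucleotides per side (the part of the
#' molecule accessible for binding in the blocker regime, and the region
#' scanned by all downstream analyses).
#'
#' @param inserts Character vector of inserts.
#' @param cfg A [sim_config()] (or any list with `flank5`, `flank3`,
#'   `search_flank`).
#' @export
search_regions <- function(inserts, cfg) {
  sf <- cfg$search_flank
  if (sf == 0L) return(inserts)
  l5 <- substr(cfg$flank5, nchar(cfg$flank5) - sf + 1L, nchar(cfg$flank5))
  l3 <- substr(cfg$flank3, 1L, sf)
  paste0(l5, inserts, l3)
}

#' Simulate equilibrium selection across the concentration series
#'
#' @param pool An `rbns_pool` from [simulate_pool()].
#' @param cfg A [sim_config()] (defaults to the pool's).
#' @return An `rbns_libraries` object: list with `input`, `mock`, `bound`
#'   (named list of read vectors, names = formatted concentrations),
#'   `series` (named), `a_free` (per concentration), `catalog`,
#'   `truth` (the kd_map), `cfg`. All reads are search regions (DNA).
#' @export
simulate_selection <- function(pool, cfg = pool$cfg) {
  set.seed(cfg$seed + 1L)
  regions <- search_regions(pool$inserts, cfg)
  site_names <- setdiff(names(cfg$kd_map), "no-site")
  catalog <- site_catalog(cfg$guide, as.list(site_names))
  asn <- assign_sites(regions, catalog, detail = TRUE)
  cat_eff <- asn$category
  if (asn$dropped_multi > 0L) {
    ## multi-site molecules: occupancy dominated by the strongest site
    kd_of <- cfg$kd_map[asn$matches$site]
    best <- tapply(kd_of, asn$matches$read, min)
    cat_eff[as.integer(names(best))] <-
      names(cfg$kd_map)[match(best, cfg$kd_map)]
  }
  kd_read <- unname(cfg$kd_map[cat_eff])
  freq <- as.numeric(table(factor(cat_eff, levels = names(cfg$kd_map))))
  freq <- freq / sum(freq)
  n <- length(regions)
  labels <- sprintf("%.4g", cfg$series)
  bound <- vector("list", length(cfg$series)); names(bound) <- labels
  a_free <- stats::setNames(numeric(length(cfg$series)), labels)
  for (i in seq_along(cfg$series)) {
    af <- solve_free_ago(cfg$kd_map, freq, cfg$series[i], cfg$library_total)
    a_free[i] <- af
    w <- occupancy(af, kd_read)
    bound[[i]] <- regions[sample.int(n, cfg$depth, replace = TRUE, prob = w)]
  }
  input <- regions[sample.int(n, cfg$depth, replace = TRUE)]
  mock <- regions[sample.int(n, cfg$depth, replace = TRUE)]
  structure(list(input = input, mock = mock, bound = bound,
                 series = stats::setNames(cfg$series, labels),
                 a_free = a_free, catalog = catalog, truth = cfg$kd_map,
                 cfg = cfg),
            class = "rbns_libraries")
}

#' @export
print.rbns_libraries <- function(x, ...) {
  cat(sprintf("<rbns_libraries> %d bound libraries (%s nM), depth %d\n",
              length(x$bound), paste(names(x$bound), collapse = ", "),
              length(x$input)))
  invisible(x)
}

#' Write simulated libraries to FASTQ plus a manifest
#'
#' Sequenced reads are insert + 3' adapter with uniform high quality
#' (Phred 40); the pool is written as FASTA. A manifest TSV maps each file
#' to its role and RISC concentration, and the ground-truth kd_map is
#' written alongside for recovery tests.
#'
#' @param pool An `rbns_pool`.
#' @param libs An `rbns_libraries` from [simulate_selection()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_rbns_run <- function(pool, libs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- libs$cfg
  sf <- cfg$search_flank
  to_insert <- function(regions) {
    substr(regions, sf + 1L, sf + cfg$insert_length)
  }
  wr_fastq <- function(reads, path) {
    seqs <- Biostrings::DNAStringSet(paste0(to_insert(reads), cfg$flank3))
    names(seqs) <- sprintf("read%07d", seq_along(seqs))
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = qual)
  }
  manifest <- data.frame(file = character(0), role = character(0),
                         conc_nM = numeric(0))
  fa <- file.path(dir, "pool.fa")
  ps <- Biostrings::DNAStringSet(paste0(cfg$flank5, pool$inserts, cfg$flank3))
  names(ps) <- sprintf("mol%07d", seq_along(ps))
  Biostrings::writeXStringSet(ps, fa)
  wr_fastq(libs$input, file.path(dir, "input.fq"))
  manifest <- rbind(manifest, data.frame(file = "input.fq", role = "input",
                                         conc_nM = 0))
  wr_fastq(libs$mock, file.path(dir, "mock.fq"))
  manifest <- rbind(manifest, data.frame(file = "mock.fq", role = "mock",
                                         conc_nM = 0))
  for (i in seq_along(libs$bound)) {
    fn <- sprintf("bound_%02d.fq", i)
    wr_fastq(libs$bound[[i]], file.path(dir, fn))
    manifest <- rbind(manifest, data.frame(file = fn, role = "bound",
                                           conc_nM = libs$series[[i]]))
  }
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(site = names(libs$truth), kd_nM = unname(libs$truth)),
    file.path(dir, "truth_kd.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(mp)
}
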