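## Shared fixtures and independent oracles. Everything is generated in code;
## oracles deliberately use naive implementations (nested loops, substring
## scans) independent of the package's Biostrings-backed paths.

guide_let7 <- function() guide_rna("let-7", "UGAGGUAGUAGGUUGUAUAGUU")
guide_mir184 <- function() guide_rna("miR-184", "UGGACGGAGAACUGAUAAGGGC")
guide_mir11 <- function() guide_rna("miR-11", "CAUCACAGUCUGAGUUCUUGC")

## naive overlapping k-mer counter: nested loop over reads and positions
naive_count_kmers <- function(reads, k) {
  out <- new.env(parent = emptyenv())
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      km <- substr(r, i, i + k - 1L)
      out[[km]] <- (out[[km]] %||% 0L) + 1L
    }
  }
  unlist(as.list(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## naive substring-containment mask
naive_mask <- function(reads, motifs) {
  keep <- !vapply(reads, function(r) {
    any(vapply(motifs, function(m) grepl(m, r, fixed = TRUE), TRUE))
  }, TRUE, USE.NAMES = FALSE)
  reads[keep]
}

## numeric equilibrium solver oracle for the two-species quadratic:
## complex c solves (E-c)(S-c) = K c, fraction bound = c/S
oracle_binding_fraction <- function(E, S, K) {
  if (K == 0) return(min(E, S) / S)
  c <- stats::uniroot(function(c) (E - c) * (S - c) - K * c,
                      c(0, min(E, S)), tol = 1e-16)$root
  c / S
}

## small simulated RBNS run reused by several unit tests
small_sim <- function(kd_map = c("8mer" = 0.02, "7mer-m8" = 0.08,
                                 "6mer" = 0.5, "no-site" = 100),
                      n = 5e4, depth = 5e4, seed = 11,
                      series = 5 / 3.2^(0:3)) {
  g <- guide_let7()
  cfg <- sim_config(g, kd_map, n_pool = n, depth = depth, series = series,
                    seed = seed)
  pool <- simulate_pool(cfg)
  libs <- simulate_selection(pool, cfg)
  list(cfg = cfg, pool = pool, libs = libs, guide = g)
}

## write an in-memory FASTQ (plain text) for preprocess tests
write_test_fastq <- function(seqs, quals, path) {
  stopifnot(length(seqs) == length(quals))
  lines <- character(4L * length(seqs))
  for (i in seq_along(seqs)) {
    lines[4 * i - 3] <- paste0("@read", i)
    lines[4 * i - 2] <- seqs[i]
    lines[4 * i - 1] <- "+"
    lines[4 * i] <- quals[i]
  }
  writeLines(lines, path)
  path
}
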