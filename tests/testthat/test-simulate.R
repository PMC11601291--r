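test_that("occupancy is the single-site equilibrium fraction", {
  expect_equal(occupancy(2, 2), 0.5)      # half saturation at a_free = kd
  expect_equal(occupancy(0, 5), 0)
  expect_equal(occupancy(3, 1), 0.75)
  expect_error(occupancy(1, 0), "kd")
  expect_error(occupancy(-1, 1), "a_free")
})

test_that("simulate_pool draws i.i.d. uniform inserts, deterministically", {
  g <- guide_let7()
  cfg <- sim_config(g, c("6mer" = 1, "no-site" = 100), n_pool = 2e4,
                    depth = 100, seed = 5)
  pool <- simulate_pool(cfg)
  expect_length(pool$inserts, 2e4)
  expect_true(all(nchar(pool$inserts) == 20L))
  ## per-position base frequencies 0.25 within 3 sigma binomial
  first <- substr(pool$inserts, 1, 1)
  tol <- 3 * sqrt(0.25 * 0.75 / 2e4)
  expect_true(all(abs(table(first) / 2e4 - 0.25) < tol))
  ## same seed twice -> identical pools
  expect_identical(simulate_pool(cfg)$inserts, pool$inserts)
  ## n = 0 -> empty set
  cfg0 <- sim_config(g, c("6mer" = 1, "no-site" = 100), n_pool = 0,
                     depth = 1, seed = 5)
  expect_length(simulate_pool(cfg0)$inserts, 0)
})

test_that("series must be strictly decreasing and kd positive", {
  g <- guide_let7()
  expect_error(sim_config(g, c("no-site" = 100), series = c(1, 2)), "decreasing")
  expect_error(sim_config(g, c("6mer" = -1, "no-site" = 100)), "kd_map")
  expect_error(sim_config(g, c("6mer" = 1)), "no-site")
})

test_that("selection draws exactly `depth` reads and is seed-deterministic", {
  s <- small_sim(n = 2e4, depth = 1.5e4, series = c(5, 1.5625), seed = 21)
  expect_length(s$libs$input, 1.5e4)
  for (b in s$libs$bound) expect_length(b, 1.5e4)
  s2 <- small_sim(n = 2e4, depth = 1.5e4, series = c(5, 1.5625), seed = 21)
  expect_identical(s2$libs$bound[[1]], s$libs$bound[[1]])
  expect_identical(s2$libs$mock, s$libs$mock)
  ## free RISC never exceeds the total and decreases along the dilution
  expect_true(all(s$libs$a_free <= s$libs$series))
  expect_true(!is.unsorted(rev(s$libs$a_free)))
})

test_that("flat kd_map yields no selection signal (bound ~ pool)", {
  g <- guide_let7()
  cfg <- sim_config(g, c("8mer" = 1, "no-site" = 1), n_pool = 3e4,
                    depth = 3e4, series = c(5, 1.5625), seed = 8)
  libs <- simulate_selection(simulate_pool(cfg), cfg)
  cat <- canonical_catalog(g, "8mer")
  counts <- assign_reads(list(input = libs$input, top = libs$bound[[1]]), cat)
  p_in <- counts["8mer", "input"] / sum(counts[, "input"])
  p_b <- counts["8mer", "top"] / sum(counts[, "top"])
  se <- sqrt(p_in * (1 - p_in) * 2 / 3e4)
  expect_lt(abs(p_b - p_in), 4 * se + 1e-9)
})

test_that("selection composition matches a per-read Bernoulli oracle", {
  ## kd_map {8mer 0.01, no-site 100}: the multinomial sampler's class
  ## composition must match direct Bernoulli selection at the same weights
  g <- guide_let7()
  kd <- c("8mer" = 0.01, "no-site" = 100)
  cfg <- sim_config(g, kd, n_pool = 4e4, depth = 4e4,
                    series = c(5, 1.5625), seed = 13)
  pool <- simulate_pool(cfg)
  libs <- simulate_selection(pool, cfg)
  regions <- search_regions(pool$inserts, cfg)
  cat <- libs$catalog
  is8 <- assign_sites(regions, cat)$category == "8mer"
  for (i in seq_along(libs$series)) {
    af <- libs$a_free[i]
    w <- occupancy(af, ifelse(is8, kd[["8mer"]], kd[["no-site"]]))
    ## Bernoulli oracle: accept each read with prob w, conditioned to depth
    set.seed(1000 + i)
    acc <- runif(length(w)) < w
    oracle_share <- sum(is8 & acc) / sum(acc)
    got_share <- mean(assign_sites(libs$bound[[i]], cat)$category == "8mer")
    se <- sqrt(oracle_share * (1 - oracle_share) *
                 (1 / sum(acc) + 1 / cfg$depth))
    expect_lt(abs(got_share - oracle_share), 5 * se + 1e-6)
  }
  ## enrichment direction follows the occupancy ratio across concentrations
  sh <- vapply(libs$bound, function(b)
    mean(assign_sites(b, cat)$category == "8mer"), 0)
  occ_ratio <- occupancy(libs$a_free, kd[["8mer"]]) /
               occupancy(libs$a_free, kd[["no-site"]])
  expect_identical(order(sh), order(occ_ratio))
})

test_that("mock library shows no site-level enrichment (|Z| small)", {
  s <- small_sim(n = 3e4, depth = 3e4, series = c(5, 1.5625), seed = 31)
  cb <- count_kmers(s$libs$mock, 10)
  ci <- count_kmers(s$libs$input, 10)
  tab <- enrich_and_z(cb, ci)
  for (m in s$libs$catalog$motifs) {
    idx <- kmers_containing(m, 10L)
    z <- (aggregate_enrichment(cb, ci, idx) - mean(tab$R)) / sd(tab$R)
    expect_lt(abs(z), 4)
  }
})
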