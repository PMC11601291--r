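test_that("solve_free_ago matches limits and a fine-grid oracle", {
  ## no binding: all K_D huge -> A_free = A_total
  expect_equal(solve_free_ago(c(1e12, 1e12), c(0.5, 0.5), 5), 5,
               tolerance = 1e-6)
  ## empty library
  expect_equal(solve_free_ago(c(1, 10), c(0.5, 0.5), 5, library_total = 0), 5,
               tolerance = 1e-9)
  ## one site, L = 100 nM, K_D = 1 nM, A_total = 5 nM vs grid-scan oracle
  gfun <- function(a) a * (1 + 100 / (a + 1)) - 5
  grid <- seq(1e-6, 5, length.out = 2e6)
  oracle <- grid[which.min(abs(gfun(grid)))]
  got <- solve_free_ago(c(1), c(1), 5, 100)
  expect_equal(got, oracle, tolerance = 1e-4)   # grid resolution ~2.5e-6 nM
  expect_equal(gfun(got), 0, tolerance = 1e-6)
  expect_error(solve_free_ago(c(-1), c(1), 5), "kd")
})

## small count matrix builder at exact expected (noiseless) composition
expected_counts <- function(kd, f, series, total = 1e6, library_total = 100) {
  cols <- lapply(series, function(A) {
    af <- solve_free_ago(kd, f, A, library_total)
    q <- f * af / (af + kd)
    round(total * q / sum(q))
  })
  m <- cbind(input = round(total * f), do.call(cbind, cols))
  colnames(m) <- c("input", sprintf("%.4g", series))
  rownames(m) <- names(kd)
  storage.mode(m) <- "integer"
  m
}

test_that("negative_log_likelihood matches closed forms", {
  kd <- c(site = 0.01, `no-site` = 100)
  f <- c(site = 0.01, `no-site` = 0.99)
  counts <- matrix(c(1000, 99000, 600, 400), ncol = 2,
                   dimnames = list(names(kd), c("input", "5")))
  ## hand evaluation of the two-site toy at one concentration
  af <- solve_free_ago(kd, mirbns:::.pool_freq(counts), 5, 100)
  fps <- mirbns:::.pool_freq(counts) * af / (af + kd)
  q <- fps / sum(fps)
  hand <- -(600 * log(q[1]) + 400 * log(q[2]))
  expect_equal(negative_log_likelihood(kd, counts, c("5" = 5)), unname(hand))
  ## all K_D equal -> q = f: the multinomial entropy term
  kdeq <- c(site = 1, `no-site` = 1)
  fhat <- mirbns:::.pool_freq(counts)
  expect_equal(negative_log_likelihood(kdeq, counts, c("5" = 5)),
               -sum(counts[, "5"] * log(fhat)))
})

test_that("NLL is scale invariant: c*K_D with c*concentrations is unchanged", {
  kd <- c(a = 0.05, b = 2, `no-site` = 100)
  f <- c(a = 0.002, b = 0.01, `no-site` = 0.988)
  counts <- expected_counts(kd, f, c(5, 0.5), total = 1e5)
  ser <- setNames(c(5, 0.5), colnames(counts)[-1])
  ## every concentration scales: the series and the library concentration
  for (c_ in c(0.1, 3, 42)) {
    expect_equal(negative_log_likelihood(kd, counts, ser, library_total = 100),
                 negative_log_likelihood(kd * c_, counts, ser * c_,
                                         library_total = 100 * c_),
                 tolerance = 1e-8, label = paste("scale", c_))
  }
})

test_that("perturbing any K_D away from truth increases the NLL", {
  kd <- c(s1 = 0.02, s2 = 0.5, `no-site` = 100)
  f <- c(s1 = 3e-4, s2 = 3e-3, `no-site` = 0.9967)
  counts <- expected_counts(kd, f, 5 / 3.2^(0:3), total = 2e6)
  ser <- setNames(5 / 3.2^(0:3), colnames(counts)[-1])
  base <- negative_log_likelihood(kd, counts, ser)
  for (s in names(kd)) {
    for (fac in c(0.5, 2)) {
      kd2 <- kd; kd2[s] <- kd2[s] * fac
      expect_gt(negative_log_likelihood(kd2, counts, ser), base)
    }
  }
})

test_that("fit_kd recovers generating parameters from noiseless counts", {
  kd <- c(s1 = 0.02, s2 = 0.08, s3 = 0.5, `no-site` = 100)
  f <- c(s1 = 3e-4, s2 = 1e-3, s3 = 4e-3, `no-site` = 0.9947)
  series <- 5 / 3.2^(0:5)
  counts <- expected_counts(kd, f, series, total = 5e6)
  tab <- fit_kd(counts, setNames(series, colnames(counts)[-1]),
                bootstrap = 0, seed = 3)
  expect_equal(setNames(tab$kd, tab$site), kd, tolerance = 0.05)
  ## relative K_Ds survive a mis-calibrated stock (x2) up to a common factor
  tab2 <- fit_kd(counts, setNames(2 * series, colnames(counts)[-1]),
                 bootstrap = 0, seed = 3)
  ratio <- tab2$kd / tab$kd
  expect_lt(diff(range(ratio[tab$site != "no-site"])) / mean(ratio), 0.25)
})

test_that("bootstrap CIs bracket the estimate and behave on simulated data", {
  s <- small_sim(n = 4e4, depth = 4e4, seed = 17)
  counts <- assign_reads(c(list(input = s$libs$input), s$libs$bound),
                         s$libs$catalog)
  tab <- fit_kd(counts, s$libs$series, bootstrap = 50, seed = 9)
  expect_true(all(tab$ci_low <= tab$kd + 1e-12))
  expect_true(all(tab$ci_high >= tab$kd - 1e-12))
  expect_true(all(tab$ci_low > 0))
  ## point estimates within 3-fold of truth even at this small depth
  truth <- s$cfg$kd_map[tab$site]
  expect_true(all(tab$kd / truth < 3 & tab$kd / truth > 1 / 3))
  ## well-separated ranks (>= 5-fold apart in truth) are preserved; the
  ## 8mer/7mer pair is only 4-fold apart and needs acceptance-scale depth
  kdv <- setNames(tab$kd, tab$site)
  expect_lt(max(kdv["8mer"], kdv["7mer-m8"]), kdv["6mer"])
  expect_lt(kdv["6mer"], kdv["no-site"])
})
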