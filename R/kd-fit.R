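## Maximum-likelihood K_D estimation across a RISC concentration series.
##
## Model: the input pool carries site types s at frequencies f_s. In a
## binding reaction with total active RISC A_tot, the free concentration
## A_free solves mass conservation
##     A_tot = A_free * (1 + sum_s L_s / (A_free + K_D,s)),  L_s = L_tot * f_s,
## with L_tot the RNA library concentration (the 100 nM library greatly
## exceeds the <= 5.8 nM RISC, so depletion of any one sequence is
## negligible but total RISC sequestration is not). A molecule carrying site
## s is bound with probability p(s) = A_free / (A_free + K_D,s), so the
## sequenced bound library has composition
##     q(s) = f_s p(s) / sum_s' f_s' p(s'),
## and the counts are multinomial. The negative log likelihood over all
## bound libraries is minimized over log10 K_D (one per site type plus
## no-site).

#' Self-consistent free RISC concentration
#'
#' Unique root in (0, A_total] of the mass-conservation equation, found by
#' bisection to a relative tolerance of 1e-10.
#'
#' @param kd Numeric vector of dissociation constants (nM), one per site
#'   type (including no-site).
#' @param freq Pool frequency of each site type (sums to 1, aligned with
#'   `kd`).
#' @param A_total Total active RISC (nM).
#' @param library_total RNA library concentration (nM, default 100).
#' @param tol Relative tolerance.
#' @return Free RISC concentration (nM).
#' @export
solve_free_ago <- function(kd, freq, A_total, library_total = 100,
                           tol = 1e-10) {
  stopifnot(length(kd) == length(freq), all(kd > 0), A_total >= 0)
  if (A_total == 0) return(0)
  if (abs(sum(freq) - 1) > 1e-6) stop("site frequencies must sum to 1")
  L <- library_total * freq
  g <- function(a) a * (1 + sum(L / (a + kd))) - A_total
  lo <- 0; hi <- A_total
  if (g(hi) < 0) stop("no sign change on bracket (0, A_total]")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= tol * hi) break
  }
  (lo + hi) / 2
}

## Pool frequencies from the input column with a +1 pseudocount so that
## every site type has q > 0.
.pool_freq <- function(counts) {
  f <- counts[, "input"] + 1
  f / sum(f)
}

#' Negative log likelihood of a K_D model given site counts
#'
#' @param kd Named numeric vector of K_D (nM) covering every row of
#'   `counts` (site types plus `"no-site"`).
#' @param counts Site-count matrix from [assign_reads()] (rows: site types
#'   plus no-site; columns: `"input"` plus one per bound library).
#' @param series Named numeric vector: total active RISC (nM) for each bound
#'   library column of `counts`.
#' @param library_total RNA library concentration (nM).
#' @return Scalar negative log likelihood (multinomial, up to the
#'   count-permutation constant).
#' @export
negative_log_likelihood <- function(kd, counts, series, library_total = 100) {
  kd <- kd[rownames(counts)]
  if (anyNA(kd)) stop("kd must name every site category in counts")
  f <- .pool_freq(counts)
  nll <- 0
  for (a in names(series)) {
    afree <- solve_free_ago(kd, f, series[[a]], library_total)
    p <- afree / (afree + kd)
    q <- f * p / sum(f * p)
    n <- counts[, a]
    nll <- nll - sum(n[n > 0] * log(q[n > 0]))
  }
  nll
}

#' Fit per-site K_D values by maximum likelihood
#'
#' Minimizes the negative log likelihood over log10 K_D for all site types
#' (including no-site) by bounded quasi-Newton from multiple starts.
#' Confidence intervals are bootstrap percentiles: each library column is
#' resampled as a multinomial of its own size (equivalent to resampling
#' reads with replacement) and refit; the tabled estimate is the median of
#' the bootstrap estimates and the CI its 2.5/97.5 percentiles.
#'
#' @param counts Site-count matrix from [assign_reads()].
#' @param series Named numeric vector of total active RISC (nM), one per
#'   bound library column.
#' @param library_total RNA library concentration (nM, default 100).
#' @param bootstrap Number of bootstrap resamples B (default 200; 0 skips
#'   CIs and tables the MLE directly).
#' @param n_starts Multi-start count for the optimizer (default 5).
#' @param bounds log10 K_D bounds in nM (default 1e-5 to 1e4: K_D values
#'   span pM to uM).
#' @param fit_stock_scale Also fit one global scale factor on the
#'   concentration series (for an uncalibrated active-RISC stock). Default
#'   `FALSE`: active RISC is measured independently by titration.
#' @param seed Optional integer seed for the multi-start jitter and the
#'   bootstrap.
#' @return A `kd_table`: data.frame (site, kd, ci_low, ci_high, n_reads)
#'   with attributes `mle`, `nll`, `series`, `stock_scale`, `convergence`.
#' @export
fit_kd <- function(counts, series, library_total = 100, bootstrap = 200L,
                   n_starts = 5L, bounds = c(-5, 4),
                   fit_stock_scale = FALSE, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  stopifnot(length(series) >= 2L, "input" %in% colnames(counts))
  if (is.null(names(series))) {
    names(series) <- setdiff(colnames(counts), "input")
  }
  sites <- rownames(counts)
  npar <- length(sites) + as.integer(fit_stock_scale)

  obj <- function(par) {
    kd <- stats::setNames(10^par[seq_along(sites)], sites)
    ser <- if (fit_stock_scale) series * 10^par[npar] else series
    negative_log_likelihood(kd, counts, ser, library_total)
  }

  fit_once <- function(start) {
    stats::optim(start, obj, method = "L-BFGS-B",
                 lower = c(rep(bounds[1L], length(sites)),
                           if (fit_stock_scale) -2),
                 upper = c(rep(bounds[2L], length(sites)),
                           if (fit_stock_scale) 2),
                 control = list(maxit = 500L))
  }

  starts <- list(c(rep(0, length(sites)), if (fit_stock_scale) 0))
  for (i in seq_len(n_starts - 1L)) {
    starts[[i + 1L]] <- c(stats::runif(length(sites), -3, 3),
                          if (fit_stock_scale) stats::runif(1, -0.5, 0.5))
  }
  fits <- lapply(starts, function(s) tryCatch(fit_once(s), error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("K_D optimization failed from every start")
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  mle <- stats::setNames(10^best$par[seq_along(sites)], sites)
  scale <- if (fit_stock_scale) 10^best$par[npar] else 1

  est <- mle; lo <- rep(NA_real_, length(sites)); hi <- lo
  if (bootstrap > 0L) {
    bmat <- matrix(NA_real_, nrow = bootstrap, ncol = length(sites))
    for (b in seq_len(bootstrap)) {
      cb <- counts
      for (a in seq_len(ncol(counts))) {
        sz <- sum(counts[, a])
        cb[, a] <- as.integer(stats::rmultinom(1L, sz, counts[, a] / sz))
      }
      fb <- tryCatch(
        stats::optim(best$par, function(par) {
          kd <- stats::setNames(10^par[seq_along(sites)], sites)
          ser <- if (fit_stock_scale) series * 10^par[npar] else series
          negative_log_likelihood(kd, cb, ser, library_total)
        }, method = "L-BFGS-B",
        lower = c(rep(bounds[1L], length(sites)), if (fit_stock_scale) -2),
        upper = c(rep(bounds[2L], length(sites)), if (fit_stock_scale) 2),
        control = list(maxit = 500L)),
        error = function(e) NULL)
      if (!is.null(fb)) bmat[b, ] <- 10^fb$par[seq_along(sites)]
    }
    bmat <- bmat[stats::complete.cases(bmat), , drop = FALSE]
    if (nrow(bmat) >= 10L) {
      est <- apply(bmat, 2L, stats::median)
      lo <- apply(bmat, 2L, stats::quantile, 0.025)
      hi <- apply(bmat, 2L, stats::quantile, 0.975)
    } else {
      warning("too few successful bootstrap refits; tabling the MLE without CIs")
    }
  }

  out <- data.frame(site = sites, kd = unname(est), ci_low = unname(lo),
                    ci_high = unname(hi),
                    n_reads = unname(rowSums(counts[, names(series), drop = FALSE])),
                    row.names = NULL)
  structure(out, mle = mle, nll = best$value, series = series,
            library_total = library_total, stock_scale = scale,
            convergence = best$convergence,
            class = c("kd_table", "data.frame"))
}

#' Write a K_D table as TSV
#' @param kd_table A `kd_table` from [fit_kd()].
#' @param path Output path.
#' @export
write_kd_table <- function(kd_table, path) {
  utils::write.table(kd_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
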