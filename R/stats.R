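# Group statistics: independent-sample t-tests on discrete metrics and
# one-dimensional statistical parametric mapping (SPM) on 101-sample
# cycle curves, with suprathreshold-cluster reporting.

#' Independent two-sample t-test
#'
#' Pooled-variance two-sample t by default (Welch selectable), two-tailed.
#'
#' @param a,b Numeric samples (each n >= 2, finite).
#' @param alpha Significance level, default 0.05.
#' @param welch Use the Welch (unequal-variance) test.
#' @return List `t`, `df`, `p`, `flag` (p < alpha).
#' @export
ttest_independent <- function(a, b, alpha = 0.05, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2 || !all(is.finite(c(a, b)))) {
    stop_squatmech("each group needs >= 2 finite values", "invalid_samples")
  }
  if (!welch && stats::var(a) == 0 && stats::var(b) == 0) {
    stop_squatmech("zero pooled variance", "invalid_samples")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, flag = ht$p.value < alpha)
}

# Pointwise two-sample t-curve (pooled variance) for two groups of
# curves stored as rows of matrices A (nA x L) and B (nB x L).
.pointwise_t <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2, stats::var); vB <- apply(B, 2, stats::var)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
}

# Smoothness (FWHM, in samples) of the residual field, estimated from
# the gradients of the residual curves (Kiebel-style estimator).
estimate_fwhm <- function(R) {
  grad <- t(apply(R, 1, function(x) {
    n <- length(x)
    g <- numeric(n)
    g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
    g[1] <- x[2] - x[1]
    g[n] <- x[n] - x[n - 1]
    g
  }))
  ssq <- colSums(R^2)
  v <- colSums(grad^2) / pmax(ssq, .Machine$double.eps)
  resels_per_node <- sqrt(v / (4 * log(2)))
  1 / mean(resels_per_node)
}

# Expected Euler characteristic of a 1-D t-field of df nu thresholded at
# u, over a search region of `resels` resolution elements, plus the
# boundary (0-d) term; FWE p-value via the Poisson clump approximation.
.rft_t_pvalue <- function(u, nu, resels) {
  p0 <- stats::pt(u, nu, lower.tail = FALSE)
  p1 <- resels * sqrt(4 * log(2)) / (2 * pi) *
    (1 + u^2 / nu)^(-(nu - 1) / 2)
  1 - exp(-(p0 + p1))
}

# Critical threshold t* with P(max |t| > t*) ~ alpha (two-sided: alpha/2
# per tail on the t-field).
rft_threshold <- function(nu, fwhm, L = 101, alpha = 0.05,
                          two_sided = TRUE) {
  a <- if (two_sided) alpha / 2 else alpha
  resels <- (L - 1) / fwhm
  f <- function(u) .rft_t_pvalue(u, nu, resels) - a
  lo <- 0.1
  hi <- max(stats::qt(1 - a, nu), 10)
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 4
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Maximal runs where above[i] is TRUE, as [start, end] percent indices.
.clusters_from_logical <- function(above) {
  idx <- which(above)
  if (!length(idx)) return(list())
  breaks <- which(diff(idx) > 1)
  starts <- idx[c(1, breaks + 1)]
  ends <- idx[c(breaks, length(idx))]
  mapply(function(s, e) c(start_pct = s - 1L, end_pct = e - 1L),
         starts, ends, SIMPLIFY = FALSE)
}

#' SPM two-sample t-test on cycle curves
#'
#' Pointwise pooled-variance t-curve over the 101-sample cycle with a
#' family-wise critical threshold from 1-D random-field theory
#' (Euler-characteristic expectation at the residual-estimated FWHM
#' smoothness); a label-permutation threshold on max |t| is available as
#' a fallback.  Suprathreshold clusters are reported as percent-cycle
#' intervals.
#'
#' @param A,B Matrices of curves, one row per observation, 101 columns.
#' @param alpha Family-wise significance level, default 0.05.
#' @param method `"rft"` or `"perm"`.
#' @param n_perm Permutations for the fallback, default 10000.
#' @param seed Seed for the permutation fallback.
#' @return An `spm_result`: `t` (curve), `t_crit`, `alpha`, `fwhm`,
#'   `clusters` (list of `[start_pct, end_pct]`), `method`, `df`.
#' @export
spm_ttest_curves <- function(A, B, alpha = 0.05, method = c("rft", "perm"),
                             n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  if (ncol(A) != ncol(B)) {
    stop_squatmech("curve groups have mismatched lengths", "invalid_curves")
  }
  if (nrow(A) < 2 || nrow(B) < 2) {
    stop_squatmech("each group needs >= 2 curves", "invalid_samples")
  }
  L <- ncol(A)
  nu <- nrow(A) + nrow(B) - 2
  tcurve <- .pointwise_t(A, B)
  R <- rbind(sweep(A, 2, colMeans(A)), sweep(B, 2, colMeans(B)))
  fwhm <- estimate_fwhm(R)
  if (method == "rft") {
    t_crit <- rft_threshold(nu, fwhm, L, alpha)
  } else {
    n <- nrow(A) + nrow(B)
    X <- rbind(A, B)
    t_crit <- with_seed(seed, {
      maxs <- vapply(seq_len(n_perm), function(k) {
        idx <- sample.int(n, nrow(A))
        max(abs(.pointwise_t(X[idx, , drop = FALSE],
                             X[-idx, , drop = FALSE])))
      }, numeric(1))
      unname(stats::quantile(maxs, 1 - alpha, type = 8))
    })
  }
  structure(list(t = tcurve, t_crit = t_crit, alpha = alpha, fwhm = fwhm,
                 clusters = .clusters_from_logical(abs(tcurve) > t_crit),
                 method = method, df = nu),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("SPM{t} two-sample test: df = %d, FWHM = %.1f samples, t* = %.3f (%s, alpha = %g)\n",
              x$df, x$fwhm, x$t_crit, x$method, x$alpha))
  if (!length(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (cl in x$clusters) {
      cat(sprintf("  cluster: %d%%-%d%%\n", cl["start_pct"], cl["end_pct"]))
    }
  }
  invisible(x)
}

# Which result table each metric belongs to.
.metric_table <- function(metric) {
  if (grepl("moment_peak$", metric)) return("peak_moments")
  if (grepl("contact_peak$", metric)) return("contact_forces")
  if (grepl("_peak$", metric)) return("peak_angles")
  "rom"
}

#' Build group-comparison metrics tables
#'
#' From per-participant metrics (averaged over trials), builds the four
#' result tables (peak angles, ROM, peak moments, knee contact forces):
#' group mean and SD per load with an independent-t significance flag
#' per metric x load.
#'
#' @param metrics Long data frame with columns `participant`, `group`,
#'   `load`, `metric`, `value` (one row per participant x load x
#'   metric).
#' @param alpha Significance level, default 0.05.
#' @param welch Use Welch tests.
#' @return A `metrics_tables` data frame with columns `table`, `metric`,
#'   `load`, `mean_valgus`, `sd_valgus`, `mean_normal`, `sd_normal`,
#'   `t`, `p`, `flag`.
#' @export
build_tables <- function(metrics, alpha = 0.05, welch = FALSE) {
  need <- c("participant", "group", "load", "metric", "value")
  if (!all(need %in% names(metrics))) {
    stop_squatmech("metrics must have participant/group/load/metric/value",
                   "invalid_metrics")
  }
  combos <- unique(metrics[, c("metric", "load")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    m <- combos$metric[i]; ld <- combos$load[i]
    sub <- metrics[metrics$metric == m & metrics$load == ld, ]
    va <- sub$value[sub$group == "valgus"]
    no <- sub$value[sub$group == "normal"]
    if (length(va) < 2 || length(no) < 2) {
      stop_squatmech(sprintf(
        "metric '%s' at load %g has a group with fewer than 2 participants",
        m, ld), "invalid_samples")
    }
    ht <- ttest_independent(va, no, alpha = alpha, welch = welch)
    data.frame(table = .metric_table(m), metric = m, load = ld,
               mean_valgus = mean(va), sd_valgus = stats::sd(va),
               mean_normal = mean(no), sd_normal = stats::sd(no),
               t = ht$t, p = ht$p, flag = ht$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$table, out$metric, out$load), ]
  rownames(out) <- NULL
  class(out) <- c("metrics_tables", class(out))
  out
}
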