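#' Two-sided Fisher exact p-value for a pair of count/total libraries
#'
#' Tests whether a gene's read count is the same proportion of two library
#' totals, i.e. the 2x2 table `[[c_a, n_a - c_a], [c_b, n_b - c_b]]`. The
#' two-sided p-value follows the probability-mass convention: the sum of the
#' hypergeometric probabilities of every table with the same margins whose
#' probability does not exceed that of the observed table, with a relative
#' tie tolerance of 1e-7 (the convention of `stats::fisher.test`).
#'
#' All arguments are vectorised and recycled.
#'
#' @param c_a,c_b gene read counts in libraries A and B.
#' @param n_a,n_b library totals (positive).
#' @return Numeric vector of p-values in \[0, 1\].
#' @examples
#' fisher_exact_p(10, 1000, 10, 1000)  # identical proportions -> 1
#' fisher_exact_p(5, 100, 25, 100)
#' @export
fisher_exact_p <- function(c_a, n_a, c_b, n_b) {
  k <- max(length(c_a), length(n_a), length(c_b), length(n_b))
  c_a <- rep_len(c_a, k); n_a <- rep_len(n_a, k)
  c_b <- rep_len(c_b, k); n_b <- rep_len(n_b, k)
  if (any(c_a < 0 | c_b < 0)) stop("counts must be non-negative")
  if (any(n_a <= 0 | n_b <= 0)) stop("library totals must be positive")
  if (any(c_a > n_a | c_b > n_b)) stop("count exceeds its library total")
  rel <- 1 + 1e-7
  vapply(seq_len(k), function(i) {
    m <- c_a[i] + c_b[i]
    if (m == 0) return(1)
    lo <- max(0, m - n_b[i])
    hi <- min(m, n_a[i])
    d <- stats::dhyper(lo:hi, n_a[i], n_b[i], m)
    sel <- d <= d[c_a[i] - lo + 1L] * rel
    if (all(sel)) 1 else min(1, sum(d[sel]))
  }, numeric(1))
}

#' Likelihood-ratio G-test for a pair of count/total libraries
#'
#' Under the count-sampling model each library's gene count is Poisson with
#' mean proportional to the library total. With the pooled rate
#' `(c_a + c_b) / (n_a + n_b)` and expectations `E_a = n_a * p`, `E_b = n_b * p`,
#' the statistic is `G = 2 * (c_a * log(c_a / E_a) + c_b * log(c_b / E_b))`
#' (with the convention `0 * log 0 = 0`) and the p-value is the upper tail of
#' a chi-square distribution with one degree of freedom.
#'
#' @inheritParams fisher_exact_p
#' @return data.frame with columns `g_stat` and `p`.
#' @examples
#' lrt_p(50, 1000, 10, 1000)
#' lrt_p(10, 1000, 10, 1000)  # equal proportions -> G = 0, p = 1
#' @export
lrt_p <- function(c_a, n_a, c_b, n_b) {
  k <- max(length(c_a), length(n_a), length(c_b), length(n_b))
  c_a <- rep_len(c_a, k); n_a <- rep_len(n_a, k)
  c_b <- rep_len(c_b, k); n_b <- rep_len(n_b, k)
  if (any(c_a < 0 | c_b < 0)) stop("counts must be non-negative")
  if (any(n_a <= 0 | n_b <= 0)) stop("library totals must be positive")
  phat <- (c_a + c_b) / (n_a + n_b)
  term <- function(cc, e) ifelse(cc == 0, 0, cc * log(cc / e))
  g <- 2 * (term(c_a, n_a * phat) + term(c_b, n_b * phat))
  g <- pmax(g, 0)           # guard against -0 / rounding at the null
  g[c_a + c_b == 0] <- 0
  data.frame(g_stat = g, p = stats::pchisq(g, df = 1, lower.tail = FALSE))
}

#' Combine the two tests into a per-gene pair call
#'
#' A gene is significant when the combined rule rejects at `alpha`; by default
#' (`mode = "both"`) both the Fisher exact test and the likelihood-ratio test
#' must reject, an agreement-based integration of the two tests. Direction is
#' `up` when the normalised abundance `c_a / n_a` exceeds `c_b / n_b` in a
#' significant gene, `down` for the opposite, and `ns` otherwise (including
#' exactly equal proportions).
#'
#' @inheritParams fisher_exact_p
#' @param alpha significance level in (0, 1); the study uses 0.05.
#' @param mode `"both"`, `"either"`, `"fisher_only"` or `"lrt_only"`.
#' @param min_count optional expression-level threshold: genes whose larger
#'   count is below it are forced to `ns` (default 0, i.e. no filter).
#' @return data.frame with columns `c_a`, `n_a`, `c_b`, `n_b`, `p_fisher`,
#'   `p_lrt`, `g_stat`, `direction`.
#' @export
call_pair <- function(c_a, n_a, c_b, n_b, alpha = 0.05,
                      mode = c("both", "either", "fisher_only", "lrt_only"),
                      min_count = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single value in (0, 1)")
  p_f <- fisher_exact_p(c_a, n_a, c_b, n_b)
  lr <- lrt_p(c_a, n_a, c_b, n_b)
  sig <- switch(mode,
    both        = p_f < alpha & lr$p < alpha,
    either      = p_f < alpha | lr$p < alpha,
    fisher_only = p_f < alpha,
    lrt_only    = lr$p < alpha)
  k <- length(p_f)
  c_a <- rep_len(c_a, k); n_a <- rep_len(n_a, k)
  c_b <- rep_len(c_b, k); n_b <- rep_len(n_b, k)
  sig <- sig & pmax(c_a, c_b) >= min_count
  prop_a <- c_a / n_a
  prop_b <- c_b / n_b
  direction <- ifelse(!sig | prop_a == prop_b, "ns",
                      ifelse(prop_a > prop_b, "up", "down"))
  data.frame(c_a = c_a, n_a = n_a, c_b = c_b, n_b = n_b,
             p_fisher = p_f, p_lrt = lr$p, g_stat = lr$g_stat,
             direction = direction)
}

#' Per-gene, per-colony differential expression between two phases
#'
#' Pairs the two subclone libraries of each colony (one per phase) and runs
#' [call_pair()] gene by gene. Colonies lacking either phase are skipped with
#' a warning; they simply contribute no replicate for this comparison.
#'
#' @param experiment a [count_experiment()].
#' @param phase_a,phase_b phase labels; the comparison is "A vs B" and `up`
#'   means higher normalised abundance in A.
#' @inheritParams call_pair
#' @param adjust if `TRUE`, replace both p-values by Benjamini-Hochberg
#'   adjusted values within each colony before thresholding (off by default;
#'   the study thresholds raw p-values at 0.05).
#' @return data.frame of pair calls with columns `gene_id`, `colony_id`,
#'   `comparison` plus the [call_pair()] columns.
#' @export
test_comparison <- function(experiment, phase_a, phase_b, alpha = 0.05,
                            mode = "both", min_count = 0, adjust = FALSE) {
  stopifnot(inherits(experiment, "count_experiment"))
  smp <- experiment$samples
  if (!phase_a %in% smp$phase || !phase_b %in% smp$phase)
    stop("phase '", if (!phase_a %in% smp$phase) phase_a else phase_b,
         "' absent from every colony")
  colonies <- unique(smp$colony_id)
  res <- lapply(colonies, function(col) {
    sa <- smp$sample_id[smp$colony_id == col & smp$phase == phase_a]
    sb <- smp$sample_id[smp$colony_id == col & smp$phase == phase_b]
    if (length(sa) != 1 || length(sb) != 1) {
      warning("colony ", col, " lacks a unique sample for ",
              comparison_label(phase_a, phase_b), "; skipped", call. = FALSE)
      return(NULL)
    }
    calls <- call_pair(experiment$counts[, sa],
                       experiment$library_totals[[sa]],
                       experiment$counts[, sb],
                       experiment$library_totals[[sb]],
                       alpha = alpha, mode = mode, min_count = min_count)
    if (adjust) {
      p_f <- stats::p.adjust(calls$p_fisher, method = "BH")
      p_l <- stats::p.adjust(calls$p_lrt, method = "BH")
      sig <- switch(mode,
        both        = p_f < alpha & p_l < alpha,
        either      = p_f < alpha | p_l < alpha,
        fisher_only = p_f < alpha,
        lrt_only    = p_l < alpha)
      sig <- sig & pmax(calls$c_a, calls$c_b) >= min_count
      prop_a <- calls$c_a / calls$n_a
      prop_b <- calls$c_b / calls$n_b
      calls$p_fisher <- p_f
      calls$p_lrt <- p_l
      calls$direction <- ifelse(!sig | prop_a == prop_b, "ns",
                                ifelse(prop_a > prop_b, "up", "down"))
    }
    data.frame(gene_id = experiment$gene_ids, colony_id = col,
               comparison = comparison_label(phase_a, phase_b),
               calls, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Run every phase comparison of the design
#'
#' Convenience wrapper applying [test_comparison()] to each comparison pair,
#' by default the three cyclic comparisons preTO vs MC, TO vs preTO and
#' MC vs TO.
#'
#' @inheritParams test_comparison
#' @param comparisons list of `c(phase_a, phase_b)` pairs.
#' @return row-bound data.frame of pair calls across all comparisons.
#' @export
de_table <- function(experiment, comparisons = NULL, alpha = 0.05,
                     mode = "both", min_count = 0, adjust = FALSE) {
  if (is.null(comparisons))
    comparisons <- default_comparisons(unique(experiment$samples$phase))
  do.call(rbind, lapply(comparisons, function(cmp)
    test_comparison(experiment, cmp[1], cmp[2], alpha = alpha, mode = mode,
                    min_count = min_count, adjust = adjust)))
}
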