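#' Replicate-consensus call for one gene and comparison
#'
#' Collapses the per-colony calls of a single gene for a single phase
#' comparison into one status with the minimum-clues rule: the gene is `up`
#' when at least `min_clues` colonies call it up AND strictly more colonies
#' call up than down; symmetrically for `down`; otherwise `ns`. The study
#' requires confirmation by at least 3 of the 5 biological replicates.
#'
#' @param calls data.frame of pair calls for one gene and comparison (as one
#'   group of [test_comparison()] output); must contain `direction`, and
#'   `gene_id`/`comparison` if those are to be propagated.
#' @param min_clues minimum number of same-direction replicates (>= 1).
#' @return one-row data.frame with `gene_id`, `comparison`, `status`,
#'   `support_up`, `support_down`, `n_replicates`, `min_clues`.
#' @examples
#' calls <- data.frame(gene_id = "g1", comparison = "preTO_vs_MC",
#'                     direction = c("up", "up", "up", "ns", "down"))
#' consensus_call(calls, min_clues = 3)$status  # "up"
#' @export
consensus_call <- function(calls, min_clues = 3) {
  if (NROW(calls) == 0) stop("empty call list")
  if (min_clues < 1) stop("'min_clues' must be >= 1")
  if (!is.null(calls$gene_id) && length(unique(calls$gene_id)) > 1)
    stop("calls mix several genes")
  if (!is.null(calls$comparison) && length(unique(calls$comparison)) > 1)
    stop("calls mix several comparisons")
  up <- sum(calls$direction == "up")
  dn <- sum(calls$direction == "down")
  status <- if (up >= min_clues && up > dn) "up"
            else if (dn >= min_clues && dn > up) "down"
            else "ns"
  data.frame(
    gene_id = if (is.null(calls$gene_id)) NA_character_ else calls$gene_id[1],
    comparison = if (is.null(calls$comparison)) NA_character_
                 else calls$comparison[1],
    status = status, support_up = up, support_down = dn,
    n_replicates = NROW(calls), min_clues = min_clues)
}

#' Consensus table over all genes and comparisons
#'
#' Applies the minimum-clues rule to every (gene, comparison) group of a pair
#' call table, returning exactly one consensus call per group, ordered by
#' gene ID then comparison.
#'
#' @param calls data.frame of pair calls from [test_comparison()] /
#'   [de_table()].
#' @inheritParams consensus_call
#' @return data.frame of consensus calls (columns as [consensus_call()]).
#' @export
consensus_table <- function(calls, min_clues = 3) {
  if (min_clues < 1) stop("'min_clues' must be >= 1")
  key <- paste(calls$gene_id, calls$comparison, sep = "\r")
  up <- rowsum((calls$direction == "up") + 0L, key)
  dn <- rowsum((calls$direction == "down") + 0L, key)
  n <- rowsum(rep(1L, nrow(calls)), key)
  parts <- strsplit(rownames(up), "\r", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[`, "", 1L),
    comparison = vapply(parts, `[`, "", 2L),
    support_up = as.integer(up[, 1]),
    support_down = as.integer(dn[, 1]),
    n_replicates = as.integer(n[, 1]),
    min_clues = min_clues)
  out$status <- ifelse(
    out$support_up >= min_clues & out$support_up > out$support_down, "up",
    ifelse(out$support_down >= min_clues &
             out$support_down > out$support_up, "down", "ns"))
  # comparisons keep their design order (temporal succession), not an
  # alphabetical one
  cmp_order <- unique(calls$comparison)
  out <- out[order(out$gene_id, match(out$comparison, cmp_order)),
             c("gene_id", "comparison", "status", "support_up",
               "support_down", "n_replicates", "min_clues")]
  rownames(out) <- NULL
  out
}
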