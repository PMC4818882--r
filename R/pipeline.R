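#' Pipeline configuration
#'
#' Bundles input paths and every threshold the analysis applies. Defaults are
#' the study's printed values: raw p-value 0.05 with both tests required,
#' minimum clues 3 of 5, GRV/GNV threshold 0.9, ORF minimum 100 codons,
#' best-hit e-value 1e-5.
#'
#' @param counts,samples paths to the counts TSV and sample sheet TSV
#'   (required).
#' @param go_map path to the gene-to-GO TSV (required).
#' @param transcripts optional path to a transcripts FASTA; enables the
#'   ORF-classification stage.
#' @param hit_table optional path to a 13-column best-hit TSV; enables the
#'   taxonomy stage.
#' @param alpha per-test significance level.
#' @param mode test combination rule, see [call_pair()].
#' @param min_clues replicate-consensus threshold.
#' @param tau GRV/GNV selection threshold.
#' @param selection_rule `"or"` or `"and"`, see [category_dynamics()].
#' @param min_aa minimum ORF length in codons.
#' @param evalue_max best-hit significance threshold.
#' @param min_count optional expression-level threshold (default 0).
#' @param comparisons list of phase pairs, `NULL` for the cyclic default.
#' @param pairs list of consecutive comparison-label pairs, `NULL` for the
#'   default succession.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, samples, go_map, transcripts = NULL,
                            hit_table = NULL, alpha = 0.05, mode = "both",
                            min_clues = 3, tau = 0.9, selection_rule = "or",
                            min_aa = 100, evalue_max = 1e-5, min_count = 0,
                            comparisons = NULL, pairs = NULL,
                            out_dir = tempfile("blastodyn_run_")) {
  paths <- c(counts = counts, samples = samples, go_map = go_map,
             transcripts = transcripts, hit_table = hit_table)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (min_clues < 1) stop("'min_clues' must be >= 1")
  if (tau <= 0 || tau > 1) stop("'tau' must be in (0, 1]")
  if (min_aa < 1) stop("'min_aa' must be >= 1")
  if (evalue_max <= 0) stop("'evalue_max' must be positive")
  structure(list(counts = counts, samples = samples, go_map = go_map,
                 transcripts = transcripts, hit_table = hit_table,
                 alpha = alpha, mode = mode, min_clues = min_clues,
                 tau = tau, selection_rule = selection_rule,
                 min_aa = min_aa, evalue_max = evalue_max,
                 min_count = min_count, comparisons = comparisons,
                 pairs = pairs, out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Reads the inputs, runs pairwise differential expression, replicate
#' consensus, GO tallies and GRV/GNV dynamics — plus ORF classification and
#' taxonomy when sequence inputs are configured — and writes one TSV per
#' stage together with a JSON run log recording every applied parameter. The
#' pipeline itself is deterministic: identical inputs and configuration give
#' byte-identical tables. A failure in any stage aborts with a stage-tagged
#' error.
#'
#' @param config a [pipeline_config()].
#' @return data.frame manifest with columns `file`, `path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  experiment <- stage("read", read_counts(config$counts, config$samples))
  gomap <- stage("read", read_go_map(config$go_map))

  calls <- stage("pairwise_de",
    de_table(experiment, comparisons = config$comparisons,
             alpha = config$alpha, mode = config$mode,
             min_count = config$min_count))
  consensus <- stage("consensus",
    consensus_table(calls, min_clues = config$min_clues))
  tallies <- stage("go_dynamics", tally_categories(consensus, gomap))
  dynamics <- stage("go_dynamics",
    category_dynamics(tallies, pairs = config$pairs, tau = config$tau,
                      rule = config$selection_rule))

  p <- function(f) file.path(config$out_dir, f)
  manifest <- c(
    pair_calls = write_tsv(calls, p("pair_calls.tsv")),
    consensus = write_tsv(consensus, p("consensus.tsv")),
    category_tallies = write_tsv(tallies, p("category_tallies.tsv")),
    category_dynamics = write_tsv(dynamics, p("category_dynamics.tsv")))

  if (!is.null(config$transcripts)) {
    orfs <- stage("transcript_recovery",
      classify_transcripts(read_transcripts(config$transcripts),
                           min_aa = config$min_aa))
    manifest <- c(manifest,
                  orf_classes = write_tsv(orfs, p("orf_classes.tsv")))
  }
  if (!is.null(config$hit_table)) {
    assignments <- stage("transcript_recovery",
      assign_taxonomy(read_hit_table(config$hit_table),
                      evalue_max = config$evalue_max))
    summary <- summarize_taxonomy(assignments)
    manifest <- c(manifest,
                  taxonomy_assignments =
                    write_tsv(assignments, p("taxonomy_assignments.tsv")),
                  taxonomy_summary =
                    write_tsv(summary, p("taxonomy_summary.tsv")))
  }

  log <- list(inputs = list(counts = config$counts, samples = config$samples,
                            go_map = config$go_map,
                            transcripts = config$transcripts,
                            hit_table = config$hit_table),
              parameters = list(alpha = config$alpha, mode = config$mode,
                                min_clues = config$min_clues,
                                tau = config$tau,
                                selection_rule = config$selection_rule,
                                min_aa = config$min_aa,
                                evalue_max = config$evalue_max,
                                min_count = config$min_count),
              n_genes = length(experiment$gene_ids),
              n_samples = nrow(experiment$samples),
              outputs = as.list(manifest))
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  manifest <- c(manifest, run_log = p("run_log.json"))
  data.frame(file = names(manifest), path = unname(manifest),
             row.names = NULL)
}

#' Relative qPCR fold change by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,condition - Ct_reference,condition) -
#' (Ct_target,control - Ct_reference,control)`; the fold change of the
#' target gene relative to the housekeeping reference is `2^-ddCt`.
#'
#' Vectorised over replicate measurements.
#'
#' @param ct_target_condition,ct_reference_condition Ct values of target and
#'   reference gene in the condition of interest.
#' @param ct_target_control,ct_reference_control Ct values in the control
#'   condition.
#' @return numeric fold change(s).
#' @examples
#' ddct_fold_change(20, 18, 22, 18)  # ddCt = -2 -> fold 4
#' @export
ddct_fold_change <- function(ct_target_condition, ct_reference_condition,
                             ct_target_control, ct_reference_control) {
  vals <- c(ct_target_condition, ct_reference_condition,
            ct_target_control, ct_reference_control)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("Ct values must be finite and positive")
  ddct <- (ct_target_condition - ct_reference_condition) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' Compare ddCt fold changes between two replicate groups
#'
#' Two-sample Student's t-test on log2 fold changes, the usual presentation
#' of qPCR validation panels.
#'
#' @param fold_a,fold_b numeric vectors of per-replicate fold changes.
#' @return the `htest` object of [stats::t.test()] on `log2(fold)`.
#' @export
ddct_test <- function(fold_a, fold_b) {
  stats::t.test(log2(fold_a), log2(fold_b), var.equal = TRUE)
}

#' Overview table of the most represented GO categories
#'
#' For each comparison pair and GO domain, reports the `top_n` categories
#' ranked by total number of differentially expressed genes, with the D/U
#' counts of both comparisons, their down/up percentages (`D/(D+U)` and
#' `U/(D+U)`), GRV, GNV and the selection flag.
#'
#' @param dynamics data.frame from [category_dynamics()].
#' @param top_n categories to keep per (pair, domain) group (>= 1).
#' @return data.frame ordered by pair, domain, then total genes descending.
#' @export
render_overview <- function(dynamics, top_n = 10) {
  if (NROW(dynamics) == 0) stop("empty dynamics table")
  if (top_n < 1) stop("'top_n' must be >= 1")
  pct <- function(x, tot) ifelse(tot > 0, round(100 * x / tot, 1), NA_real_)
  out <- dynamics
  out$pct_down_1 <- pct(out$D1, out$D1 + out$U1)
  out$pct_up_1 <- pct(out$U1, out$D1 + out$U1)
  out$pct_down_2 <- pct(out$D2, out$D2 + out$U2)
  out$pct_up_2 <- pct(out$U2, out$D2 + out$U2)
  grp <- split(out, list(out$first, out$second, out$go_domain), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    g <- g[order(-g$total, g$go_code), ]
    utils::head(g, top_n)
  }))
  out <- out[order(out$first, out$second, out$go_domain, -out$total,
                   out$go_code), ]
  rownames(out) <- NULL
  out
}
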