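#' Build a count experiment
#'
#' Container for a gene x sample table of raw read counts together with the
#' sample metadata the blastogenetic-cycle design needs: which colony each
#' library comes from and which phase of the cycle (mid-cycle `MC`,
#' pre-take-over `preTO`, take-over `TO`) it was sampled at. Library totals
#' are always the observed column sums; they are the denominators of the
#' per-library proportions used by the pairwise tests.
#'
#' @param counts integer matrix (genes in rows, samples in columns) of
#'   non-negative raw read counts; rownames are gene IDs, colnames sample IDs.
#' @param samples data.frame with columns `sample_id`, `colony_id`, `phase`;
#'   one row per column of `counts`, matched by `sample_id`.
#' @return An object of class `count_experiment`: a list with elements
#'   `gene_ids`, `counts`, `samples` and `library_totals`.
#' @examples
#' m <- matrix(rpois(20, 50), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' sheet <- data.frame(sample_id = paste0("s", 1:5),
#'                     colony_id = "C1",
#'                     phase = c("MC", "preTO", "TO", "MC", "preTO"))
#' count_experiment(m, sheet)
#' @export
count_experiment <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) ||
      (nrow(counts) > 0 && is.null(rownames(counts))))
    stop("'counts' must carry gene IDs as rownames and sample IDs as colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers")
  storage.mode(counts) <- "integer"
  need <- c("sample_id", "colony_id", "phase")
  if (!all(need %in% names(samples)))
    stop("'samples' must have columns sample_id, colony_id, phase")
  samples <- as.data.frame(samples)[, need]
  samples[] <- lapply(samples, as.character)
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample sheet")
  if (!setequal(samples$sample_id, colnames(counts)))
    stop("sample sheet and count columns disagree")
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  rownames(samples) <- NULL
  structure(
    list(gene_ids = rownames(counts),
         counts = counts,
         samples = samples,
         library_totals = colSums(counts)),
    class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat("count_experiment:", length(x$gene_ids), "genes x",
      nrow(x$samples), "samples\n")
  cat("  phases: ", paste(unique(x$samples$phase), collapse = ", "), "\n")
  cat("  colonies:", length(unique(x$samples$colony_id)), "\n")
  cat("  library totals:",
      paste(format(range(x$library_totals), big.mark = ","), collapse = " - "),
      "\n")
  invisible(x)
}

#' Read a count experiment from TSV files
#'
#' `read_counts()` expects the counts table with `gene_id` as first column and
#' one column per sample, and a sample sheet with columns `sample_id`,
#' `colony_id`, `phase`.
#'
#' @param counts_path path to the gene x sample counts TSV.
#' @param samples_path path to the sample sheet TSV.
#' @return A [count_experiment()].
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("first column of the counts table must be 'gene_id'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  sheet <- utils::read.delim(samples_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  count_experiment(m, sheet)
}

#' Write a count experiment to TSV files
#'
#' @param experiment a [count_experiment()].
#' @param counts_path,samples_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(experiment, counts_path, samples_path) {
  tab <- data.frame(gene_id = experiment$gene_ids,
                    experiment$counts, check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(experiment$samples, samples_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Read a gene-to-GO annotation map
#'
#' @param path TSV with columns `gene_id`, `go_code`, `go_name`, `go_domain`.
#' @return data.frame with those four character columns.
#' @export
read_go_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "go_code", "go_name", "go_domain")
  if (!all(need %in% names(map)))
    stop("GO map must have columns gene_id, go_code, go_name, go_domain")
  map[, need]
}

#' Default cyclic phase comparisons
#'
#' The study compares consecutive phases in temporal succession and closes the
#' weekly cycle: `preTO vs MC`, `TO vs preTO`, `MC vs TO`. For an arbitrary
#' ordered phase vector this generalises to (phase\[i+1\] vs phase\[i\]) plus
#' the wrap-around pair.
#'
#' @param phases ordered character vector of phase labels.
#' @return list of length-2 character vectors `c(A, B)` meaning "A vs B".
#' @export
default_comparisons <- function(phases = c("MC", "preTO", "TO")) {
  p <- length(phases)
  if (p < 2) stop("need at least two phases")
  lapply(seq_len(p), function(i) c(phases[i %% p + 1L], phases[i]))
}

comparison_label <- function(phase_a, phase_b) paste0(phase_a, "_vs_", phase_b)
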