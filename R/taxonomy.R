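#' Read a tabular best-hit alignment file
#'
#' Parses the standard 12-column tab-separated hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bitscore) extended with a 13th column carrying the
#' subject's taxon label. Malformed lines (wrong field count, non-numeric
#' e-value or bitscore) are skipped with a warning; the number skipped is
#' attached as attribute `n_skipped`.
#'
#' @param path path to the hit table (no header line).
#' @return data.frame with columns `qseqid`, `sseqid`, `pident`, `length`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore`, `taxon`.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) == 13L
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore", "taxon")
  if (any(ok)) {
    m <- do.call(rbind, fields[ok])
    out <- as.data.frame(m, stringsAsFactors = FALSE)
    names(out) <- cols
    num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
             "sstart", "send", "evalue", "bitscore")
    out[num] <- suppressWarnings(lapply(out[num], as.numeric))
    bad <- is.na(out$evalue) | is.na(out$bitscore)
    if (any(bad)) out <- out[!bad, , drop = FALSE]
    n_skipped <- sum(!ok) + sum(bad)
  } else {
    out <- as.data.frame(matrix(character(), 0, 13,
                                dimnames = list(NULL, cols)),
                         stringsAsFactors = FALSE)
    n_skipped <- sum(!ok)
  }
  if (n_skipped > 0)
    warning(n_skipped, " malformed hit record(s) skipped", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Assign each transcript the taxon of its best significant hit
#'
#' Hits with e-value above `evalue_max` (default 1e-5, the study's
#' significance threshold) are discarded; each remaining transcript inherits
#' the taxon of its best hit — lowest e-value, ties broken by highest
#' bitscore, then first occurrence in the table. Transcripts with no
#' surviving hit are left unassigned (absent from the result).
#'
#' @param hits data.frame as returned by [read_hit_table()] (needs columns
#'   `qseqid`, `evalue`, `bitscore`, `taxon`).
#' @param evalue_max maximum e-value for a hit to count as significant.
#' @return data.frame with columns `transcript_id`, `taxon`, `evalue`,
#'   `bitscore`; one row per assigned transcript.
#' @export
assign_taxonomy <- function(hits, evalue_max = 1e-5) {
  need <- c("qseqid", "evalue", "bitscore", "taxon")
  if (!all(need %in% names(hits)))
    stop("hit table needs columns ", paste(need, collapse = ", "))
  keep <- hits[hits$evalue <= evalue_max, need, drop = FALSE]
  if (nrow(keep) == 0)
    return(data.frame(transcript_id = character(), taxon = character(),
                      evalue = numeric(), bitscore = numeric()))
  ord <- order(keep$qseqid, keep$evalue, -keep$bitscore,
               seq_len(nrow(keep)))
  keep <- keep[ord, ]
  best <- keep[!duplicated(keep$qseqid), ]
  out <- data.frame(transcript_id = best$qseqid, taxon = best$taxon,
                    evalue = best$evalue, bitscore = best$bitscore)
  rownames(out) <- NULL
  out
}

#' Summarize per-taxon assignment counts and proportions
#'
#' Accepts either per-transcript assignments (the output of
#' [assign_taxonomy()], or any data.frame with a `taxon` column and one row
#' per assigned transcript) or pre-tabulated per-taxon counts as a named
#' numeric vector — e.g. the printed counts of a published taxonomy table.
#'
#' @param assignments data.frame with a `taxon` column, or a named numeric
#'   vector of per-taxon counts.
#' @return data.frame with columns `taxon`, `count`, `proportion`, `percent`
#'   (percent rounded to whole numbers for reporting), sorted by count
#'   descending; total assigned transcripts = `sum(count)`, also attached as
#'   attribute `total`.
#' @export
summarize_taxonomy <- function(assignments) {
  if (is.data.frame(assignments)) {
    if (!"taxon" %in% names(assignments))
      stop("'assignments' needs a 'taxon' column")
    counts <- table(assignments$taxon)
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else if (is.numeric(assignments) && !is.null(names(assignments))) {
    if (any(assignments < 0)) stop("counts must be non-negative")
    counts <- assignments
  } else {
    stop("'assignments' must be a data.frame or a named count vector")
  }
  total <- sum(counts)
  out <- data.frame(taxon = if (is.null(names(counts))) character(0)
                            else names(counts),
                    count = as.numeric(counts))
  out$proportion <- if (total > 0) out$count / total else numeric(nrow(out))
  out$percent <- round(100 * out$proportion)
  if (nrow(out)) out <- out[order(-out$count, out$taxon), ]
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}
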