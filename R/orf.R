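STOP_CODONS <- c("TAA", "TAG", "TGA")

# Scan one frame of one strand: returns candidate ORFs as a data.frame.
# Segments are the codon runs between in-frame stop codons; a candidate needs
# either an ATG (complete / open at 3') or an unobstructed run from the 5'
# terminus (open at 5' / open at both ends). Interior start-less runs between
# two stops cannot be ORFs and are dropped.
scan_frame <- function(seq, frame, min_aa, strand = "+") {
  n <- nchar(seq)
  ncod <- (n - frame) %/% 3L
  if (ncod < 1L) return(NULL)
  starts_at <- frame + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(seq, starts_at, starts_at + 2L)
  is_stop <- codons %in% STOP_CODONS
  is_atg <- codons == "ATG"
  stop_idx <- which(is_stop)
  seg_lo <- c(1L, stop_idx + 1L)
  seg_hi <- c(stop_idx, ncod)
  res <- vector("list", length(seg_lo))
  for (i in seq_along(seg_lo)) {
    lo <- seg_lo[i]; hi <- seg_hi[i]
    if (lo > hi) next
    ends_at_stop <- is_stop[hi]
    at_5prime <- lo == 1L
    atg <- which(is_atg[lo:hi])
    if (length(atg)) {
      s0 <- lo + atg[1L] - 1L
      aa <- if (ends_at_stop) hi - s0 else hi - s0 + 1L
      compl <- if (ends_at_stop) "complete" else "open3"
      cand <- c(s0, hi, aa)
    } else if (at_5prime) {
      aa <- if (ends_at_stop) hi - lo else hi - lo + 1L
      compl <- if (ends_at_stop) "open5" else "open_both"
      cand <- c(lo, hi, aa)
    } else next
    if (cand[3] < min_aa) next
    res[[i]] <- data.frame(
      frame = frame, strand = strand,
      start = frame + 3L * (cand[1] - 1L),
      end = frame + 3L * cand[2],
      aa_length = cand[3],
      completeness = compl)
  }
  out <- do.call(rbind, res)
  out
}

#' Find candidate open reading frames in a transcript
#'
#' Scans the three reading frames of the forward strand (and, optionally, of
#' the reverse complement) for ORF candidates under the standard genetic code
#' (`ATG` start; `TAA`/`TAG`/`TGA` stop). Within a frame, candidates are the
#' maximal codon runs bounded by stop codons or the sequence termini:
#' `complete` (start and in-frame stop), `open3` (start, no stop before the
#' 3' terminus), `open5` (run from the 5' terminus, no start, ending at a
#' stop) and `open_both` (run spanning the frame with neither boundary
#' codon). Candidates shorter than `min_aa` codons are discarded — the
#' minimum-length proxy for significant coding potential.
#'
#' Coordinates are 0-based half-open on the scanned strand; the stop codon is
#' inside `[start, end)` but excluded from `aa_length`.
#'
#' @param sequence nucleotide string over `A C G T N` (case-insensitive), or
#'   anything coercible via `as.character()` (e.g. one element of a
#'   `Biostrings::DNAStringSet`).
#' @param min_aa minimum ORF length in codons, excluding the stop
#'   (default 100).
#' @param both_strands also scan the reverse complement (default `FALSE`:
#'   assembled transcripts are taken as oriented).
#' @return data.frame with columns `frame` (0/1/2), `strand`, `start`, `end`,
#'   `aa_length`, `completeness`; zero rows when nothing qualifies.
#' @examples
#' find_orfs("CCATGAAATAGCC", min_aa = 1)
#' @export
find_orfs <- function(sequence, min_aa = 100, both_strands = FALSE) {
  if (min_aa < 1) stop("'min_aa' must be >= 1")
  seq <- toupper(as.character(sequence))
  if (length(seq) != 1 || is.na(seq) || !nzchar(seq))
    stop("'sequence' must be a single non-empty nucleotide string")
  empty <- data.frame(frame = integer(), strand = character(),
                      start = integer(), end = integer(),
                      aa_length = integer(), completeness = character())
  if (nchar(seq) < 3) return(empty)
  cand <- do.call(rbind, lapply(0:2, scan_frame, seq = seq, min_aa = min_aa))
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    cand <- rbind(cand,
                  do.call(rbind, lapply(0:2, scan_frame, seq = rc,
                                        min_aa = min_aa, strand = "-")))
  }
  if (is.null(cand)) return(empty)
  rownames(cand) <- NULL
  cand
}

#' Classify a transcript by ORF completeness
#'
#' Picks the single best ORF candidate of [find_orfs()] — longest in amino
#' acids, ties broken by smaller start position, then smaller frame index
#' (forward strand preferred) — and labels the transcript with its
#' completeness class: `complete`, `open5`, `open3`, `open_both`, or `none`
#' when no candidate reaches `min_aa`.
#'
#' @inheritParams find_orfs
#' @return one-row data.frame with `frame`, `strand`, `start`, `end`,
#'   `aa_length`, `completeness` (`NA` coordinates for class `none`).
#' @export
classify_completeness <- function(sequence, min_aa = 100,
                                  both_strands = FALSE) {
  cand <- find_orfs(sequence, min_aa = min_aa, both_strands = both_strands)
  if (nrow(cand) == 0)
    return(data.frame(frame = NA_integer_, strand = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      aa_length = 0L, completeness = "none"))
  ord <- order(-cand$aa_length, cand$start,
               cand$strand != "+", cand$frame)
  cand[ord[1L], , drop = FALSE]
}

#' Classify a set of transcripts
#'
#' Applies [classify_completeness()] to every sequence of a FASTA-derived
#' set, returning one row per transcript.
#'
#' @param transcripts named character vector of sequences or a
#'   `Biostrings::DNAStringSet` (e.g. from [read_transcripts()]).
#' @inheritParams find_orfs
#' @return data.frame with `transcript_id` plus the
#'   [classify_completeness()] columns.
#' @export
classify_transcripts <- function(transcripts, min_aa = 100,
                                 both_strands = FALSE) {
  ids <- names(transcripts)
  seqs <- stats::setNames(as.character(transcripts), ids)
  if (is.null(ids)) stop("transcripts must be named")
  out <- do.call(rbind, lapply(seqs, classify_completeness,
                               min_aa = min_aa, both_strands = both_strands))
  data.frame(transcript_id = names(seqs), out, row.names = NULL)
}

#' Read transcripts from a FASTA file
#'
#' @param path FASTA file of nucleotide sequences.
#' @return a `Biostrings::DNAStringSet`, uppercase.
#' @export
read_transcripts <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  Biostrings::DNAStringSet(toupper(as.character(x)))
}
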