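#' Configuration for the synthetic study-design generator
#'
#' Captures the design of the real experiment — five colonies, each split
#' into one subclone per blastogenetic phase (MC, preTO, TO), sequenced to a
#' common expected depth — together with the parameters of the count model
#' and of the toy transcript/hit fixtures.
#'
#' Differential expression is generated cyclically: a DE gene has one phase
#' at which its log2 abundance is offset by `+/- delta` with `|delta|` drawn
#' uniformly from `log2fc_range`. Transition effects are differences of
#' phase offsets, so the log2 effects around the closed cycle sum to zero and
#' each DE gene is non-null on exactly two of the three transitions. The
#' per-gene DE probability is `de_fraction * n_phases / 2`, which makes the
#' expected non-null fraction of each single transition equal `de_fraction`.
#'
#' @param n_genes number of genes (> 0).
#' @param n_colonies number of colonies, i.e. biological replicates
#'   (default 5).
#' @param phases ordered phase labels (default `MC`, `preTO`, `TO`; at least
#'   two).
#' @param library_size expected reads per subclone library (default 1e6).
#' @param de_fraction expected fraction of genes differentially expressed on
#'   each single phase transition, in \[0, 1\].
#' @param log2fc_range interval for `|log2 fold change|` of DE genes; lower
#'   bound must be positive.
#' @param n_go_terms number of GO terms in the synthetic annotation.
#' @param coherent_term_fraction fraction of GO terms whose DE member genes
#'   all share one regulation pattern (same special phase and direction).
#' @param baseline_sdlog sdlog of the log-normal baseline relative abundance
#'   across genes (default 1, a typical RNA-seq abundance spread).
#' @param colony_sdlog sdlog of the mild log-normal per-gene colony effect
#'   shared by the three subclones of a colony (default 0.05).
#' @param n_per_class toy transcripts generated per ORF completeness class
#'   (default 10).
#' @param orf_min_aa designed minimum ORF length in codons for the toy
#'   transcripts (default 100, matching the classifier default).
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_colonies = 5,
                       phases = c("MC", "preTO", "TO"),
                       library_size = 1e6, de_fraction = 0.1,
                       log2fc_range = c(0.5, 3), n_go_terms = 150,
                       coherent_term_fraction = 0.2,
                       baseline_sdlog = 1, colony_sdlog = 0.05,
                       n_per_class = 10, orf_min_aa = 100, seed = 1) {
  if (n_genes < 1) stop("'n_genes' must be positive")
  if (n_colonies < 1) stop("'n_colonies' must be positive")
  if (length(phases) < 2) stop("need at least two phases")
  if (anyDuplicated(phases)) stop("duplicated phase labels")
  if (library_size <= 0) stop("'library_size' must be positive")
  if (de_fraction < 0 || de_fraction > 1)
    stop("'de_fraction' must be in [0, 1]")
  if (length(log2fc_range) != 2 || log2fc_range[1] <= 0 ||
      diff(log2fc_range) < 0)
    stop("'log2fc_range' must be an increasing interval with positive lower bound")
  if (de_fraction * length(phases) / 2 > 1)
    stop("'de_fraction' too large for a cyclic design with ",
         length(phases), " phases")
  if (n_go_terms < 1) stop("'n_go_terms' must be positive")
  if (coherent_term_fraction < 0 || coherent_term_fraction > 1)
    stop("'coherent_term_fraction' must be in [0, 1]")
  structure(list(
    n_genes = as.integer(n_genes), n_colonies = as.integer(n_colonies),
    phases = as.character(phases), library_size = library_size,
    de_fraction = de_fraction, log2fc_range = log2fc_range,
    n_go_terms = as.integer(n_go_terms),
    coherent_term_fraction = coherent_term_fraction,
    baseline_sdlog = baseline_sdlog, colony_sdlog = colony_sdlog,
    n_per_class = as.integer(n_per_class),
    orf_min_aa = as.integer(orf_min_aa), seed = as.integer(seed)),
    class = "sim_config")
}

GO_DOMAINS <- c("Biological Processes", "Molecular functions",
                "Cellular components")

#' Simulate a full synthetic dataset of the study design
#'
#' Draws a gene x sample count table with the statistical structure the
#' downstream analysis assumes: counts are Poisson with mean
#' `N_s * theta_g * 2^offset(g, phase(s)) * eps(g, colony(s))`, where
#' `theta_g` is a log-normal baseline relative abundance (normalised to sum
#' to one), the phase offsets implement cyclic differential expression (see
#' [sim_config()]) and `eps` is a mild log-normal colony effect shared by the
#' subclones of one colony — so within-colony phase comparisons stay exactly
#' valid under the null. Also generates a gene-to-GO annotation with a
#' controlled fraction of direction-coherent terms, the toy transcript set of
#' [simulate_transcripts()], and a best-hit table with known taxon truth.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_dataset` with elements `counts` (a
#'   [count_experiment()]), `truth_de` (gene x transition truth: `status`,
#'   `log2fc`), `truth_genes` (per-gene `theta`, DE pattern), `go_map`,
#'   `truth_go` (per-term coherence pattern), `transcripts`,
#'   `truth_transcripts`, `hit_table`, `truth_taxonomy`, and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_g <- config$n_genes
  phases <- config$phases
  n_p <- length(phases)
  gene_ids <- sprintf("g%05d", seq_len(n_g))

  # per-gene baseline and cyclic DE pattern
  theta <- stats::rlnorm(n_g, 0, config$baseline_sdlog)
  theta <- theta / sum(theta)
  p_de <- config$de_fraction * n_p / 2
  is_de <- stats::runif(n_g) < p_de
  special <- ifelse(is_de, sample(phases, n_g, replace = TRUE), NA)
  magnitude <- ifelse(is_de,
                      stats::runif(n_g, config$log2fc_range[1],
                                   config$log2fc_range[2]),
                      0)
  # Up/down signs are assigned so each phase's expected transcriptional mass
  # shift cancels (greedy signed balancing, largest contributions first):
  # the proportion-based tests downstream assume a constant total output per
  # library, and an unbalanced mass shift would bias every null gene's
  # proportion in that phase.
  sign_de <- rep(0, n_g)
  for (ph in phases) {
    idx <- which(is_de & special == ph)
    if (!length(idx)) next
    up_gain <- theta[idx] * (2^magnitude[idx] - 1)
    down_loss <- theta[idx] * (1 - 2^(-magnitude[idx]))
    ord <- idx[order(-pmax(up_gain, down_loss))]
    s <- 0
    for (j in seq_along(ord)) {
      g <- ord[j]
      gain <- theta[g] * (2^magnitude[g] - 1)
      loss <- theta[g] * (1 - 2^(-magnitude[g]))
      if (abs(s + gain) <= abs(s - loss)) {
        sign_de[g] <- 1; s <- s + gain
      } else {
        sign_de[g] <- -1; s <- s - loss
      }
    }
  }
  delta <- sign_de * magnitude
  offsets <- matrix(0, n_g, n_p, dimnames = list(gene_ids, phases))
  if (any(is_de))
    offsets[cbind(which(is_de), match(special[is_de], phases))] <-
      delta[is_de]

  # samples: one subclone per colony per phase
  colonies <- sprintf("C%d", seq_len(config$n_colonies))
  samples <- expand.grid(colony_id = colonies, phase = phases,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[order(samples$colony_id, match(samples$phase, phases)), ]
  samples$sample_id <- paste(samples$colony_id, samples$phase, sep = "_")
  samples <- samples[, c("sample_id", "colony_id", "phase")]
  rownames(samples) <- NULL
  n_s <- nrow(samples)

  lib_target <- config$library_size *
    stats::rlnorm(n_s, -config$colony_sdlog^2 / 2, config$colony_sdlog)
  eps <- matrix(stats::rlnorm(n_g * config$n_colonies,
                              -config$colony_sdlog^2 / 2,
                              config$colony_sdlog),
                n_g, config$n_colonies, dimnames = list(gene_ids, colonies))
  mu <- (theta * 2^offsets[, samples$phase, drop = FALSE]) *
    eps[, samples$colony_id, drop = FALSE]
  mu <- sweep(mu, 2, lib_target, `*`)
  counts <- matrix(stats::rpois(n_g * n_s, mu), n_g, n_s,
                   dimnames = list(gene_ids, samples$sample_id))
  experiment <- count_experiment(counts, samples)

  # transition truth: comparison (A vs B) has log2fc = offset_A - offset_B
  comparisons <- default_comparisons(phases)
  truth_de <- do.call(rbind, lapply(comparisons, function(cmp) {
    l2 <- offsets[, cmp[1]] - offsets[, cmp[2]]
    data.frame(gene_id = gene_ids,
               comparison = comparison_label(cmp[1], cmp[2]),
               status = ifelse(l2 > 0, "up", ifelse(l2 < 0, "down", "null")),
               log2fc = as.numeric(l2), row.names = NULL)
  }))
  truth_genes <- data.frame(gene_id = gene_ids, theta = theta,
                            is_de = is_de, special_phase = special,
                            delta = delta)

  # GO annotation: coherent terms sample members sharing one DE pattern
  n_terms <- config$n_go_terms
  go_codes <- sprintf("GO:%07d", seq_len(n_terms))
  go_names <- paste("synthetic category", seq_len(n_terms))
  go_domains <- sample(GO_DOMAINS, n_terms, replace = TRUE)
  n_coh <- round(config$coherent_term_fraction * n_terms)
  coherent <- seq_len(n_terms) <= n_coh
  base_pool <- which(!coherent)
  assign_rows <- list()
  if (length(base_pool) && n_g > 0) {
    k_terms <- sample(1:4, n_g, replace = TRUE)
    for (g in seq_len(n_g)) {
      tid <- sample(base_pool, min(k_terms[g], length(base_pool)))
      assign_rows[[g]] <- cbind(g, tid)
    }
  }
  coh_phase <- rep(NA_character_, n_terms)
  coh_sign <- rep(NA_integer_, n_terms)
  null_pool <- which(!is_de)
  for (t in which(coherent)) {
    ph <- sample(phases, 1)
    sg <- sample(c(-1L, 1L), 1)
    pool <- which(is_de & special == ph & sign_de == sg)
    if (length(pool) == 0) pool <- null_pool    # vacuously coherent
    if (length(pool) == 0) pool <- seq_len(n_g)
    if (length(pool) == 0) next
    members <- if (length(pool) > 10) sample(pool, 10) else pool
    coh_phase[t] <- ph
    coh_sign[t] <- sg
    assign_rows[[length(assign_rows) + 1L]] <- cbind(members, t)
  }
  # guarantee every term has at least one member gene
  amat <- if (length(assign_rows)) do.call(rbind, assign_rows) else
    matrix(integer(), 0, 2)
  if (n_g > 0) {
    orphan <- setdiff(seq_len(n_terms), unique(amat[, 2]))
    if (length(orphan))
      amat <- rbind(amat, cbind(sample(seq_len(n_g), length(orphan),
                                       replace = TRUE), orphan))
  }
  amat <- unique(amat)
  amat <- amat[order(amat[, 1], amat[, 2]), , drop = FALSE]
  go_map <- data.frame(gene_id = gene_ids[amat[, 1]],
                       go_code = go_codes[amat[, 2]],
                       go_name = go_names[amat[, 2]],
                       go_domain = go_domains[amat[, 2]])
  truth_go <- data.frame(go_code = go_codes, go_name = go_names,
                         go_domain = go_domains, coherent = coherent,
                         pattern_phase = coh_phase, pattern_sign = coh_sign)

  transcripts <- simulate_transcripts(config)
  hits <- simulate_hits(transcripts$records, config)

  structure(list(
    counts = experiment, truth_de = truth_de, truth_genes = truth_genes,
    go_map = go_map, truth_go = truth_go,
    transcripts = transcripts$records,
    truth_transcripts = transcripts$truth,
    hit_table = hits$hits, truth_taxonomy = hits$truth,
    config = config), class = "synthetic_dataset")
}

# codons over {C,G} only: no start or stop codon can arise in any frame,
# even across codon boundaries
SAFE_CODONS <- c("CCC", "CCG", "CGC", "CGG", "GCC", "GCG", "GGC", "GGG")
UTR_BLOCK <- "TAGATAGATAGA"   # stop codons in all three frames, no ATG

safe_run <- function(n) paste(sample(SAFE_CODONS, n, replace = TRUE),
                              collapse = "")

#' Simulate toy transcripts with known ORF completeness classes
#'
#' Builds `n_per_class` transcripts for each of the five classes: `complete`
#' (start and in-frame stop), `open5` (coding run from the 5' terminus ending
#' at a stop, no start codon), `open3` (start codon, no stop before the 3'
#' terminus), `open_both` (coding run spanning the transcript) and `none` (no
#' ORF reaching `orf_min_aa`). UTR filler is built from `TAGA` repeats —
#' stop codons in every frame, no start codon — and ORF interiors from
#' `C`/`G`-only codons, which cannot create a start or stop in any frame, so
#' the class labels hold by construction.
#'
#' @param config a [sim_config()]; uses `n_per_class`, `orf_min_aa`, `seed`.
#' @return list with `records` (named character vector of sequences) and
#'   `truth` (data.frame `transcript_id`, `class`).
#' @export
simulate_transcripts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  min_aa <- config$orf_min_aa
  classes <- c("complete", "open5", "open3", "open_both", "none")
  seqs <- character(0)
  truth <- character(0)
  for (cls in classes) {
    for (i in seq_len(config$n_per_class)) {
      shift <- strrep("C", sample(0:2, 1))
      k <- min_aa + sample(5:40, 1)       # designed ORF length in codons
      seq <- switch(cls,
        complete  = paste0(shift, UTR_BLOCK, "ATG", safe_run(k), "TAA",
                           UTR_BLOCK),
        open5     = paste0(safe_run(k), "TAA", UTR_BLOCK),
        open3     = paste0(shift, UTR_BLOCK, "ATG", safe_run(k)),
        open_both = safe_run(k),
        none      = paste0(UTR_BLOCK,
                           paste(replicate(3, paste0(
                             safe_run(sample(3:(min_aa - 2), 1)),
                             UTR_BLOCK)), collapse = "")))
      id <- sprintf("tx_%s_%02d", cls, i)
      seqs[id] <- seq
      truth <- c(truth, cls)
    }
  }
  list(records = seqs,
       truth = data.frame(transcript_id = names(seqs), class = truth,
                          row.names = NULL))
}

TAXON_POOL <- c("Ascidiacea", "Mammalia", "Actinopteri", "Aves", "Amphibia",
                "Insecta", "Gastropoda", "Echinoidea", "Hydrozoa",
                "Eurotiomycetes")
TAXON_WEIGHTS <- c(0.6, 0.08, 0.08, 0.04, 0.04, 0.04, 0.04, 0.04, 0.02, 0.02)

# best-hit table with planted truth: the true hit's e-value is strictly the
# smallest, decoys are orders of magnitude worse; some transcripts get only
# insignificant hits (truth NA), some none at all
simulate_hits <- function(records, config) {
  set.seed(config$seed + 1L)
  ids <- names(records)
  rows <- list()
  truth <- data.frame(transcript_id = ids, taxon = NA_character_)
  mk_row <- function(id, taxon, evalue, bitscore)
    data.frame(qseqid = id,
               sseqid = paste0("sbj_", substr(taxon, 1, 4), "_",
                               sample(1e4, 1)),
               pident = round(stats::runif(1, 40, 99), 1),
               length = sample(80:400, 1), mismatch = sample(0:60, 1),
               gapopen = sample(0:5, 1), qstart = 1,
               qend = sample(100:400, 1), sstart = 1,
               send = sample(100:400, 1),
               evalue = signif(evalue, 3), bitscore = round(bitscore, 1))
  for (i in seq_along(ids)) {
    r <- stats::runif(1)
    if (r < 0.10) next                      # no hits at all
    if (r < 0.20) {                         # only insignificant hits
      for (j in seq_len(sample(1:3, 1)))
        rows[[length(rows) + 1L]] <-
          cbind(mk_row(ids[i], sample(TAXON_POOL, 1),
                       10^stats::runif(1, -4.5, -1),
                       stats::runif(1, 30, 50)),
                taxon = sample(TAXON_POOL, 1))
      next
    }
    tax <- sample(TAXON_POOL, 1, prob = TAXON_WEIGHTS)
    truth$taxon[i] <- tax
    best_e <- 10^stats::runif(1, -50, -8)
    rows[[length(rows) + 1L]] <-
      cbind(mk_row(ids[i], tax, best_e, stats::runif(1, 100, 400)),
            taxon = tax)
    for (j in seq_len(sample(0:4, 1)))
      rows[[length(rows) + 1L]] <-
        cbind(mk_row(ids[i], sample(TAXON_POOL, 1),
                     best_e * 10^stats::runif(1, 1, 6),
                     stats::runif(1, 40, 120)),
              taxon = sample(TAXON_POOL, 1))
  }
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "taxon")
  hits <- if (length(rows)) do.call(rbind, rows)[, cols] else
    as.data.frame(stats::setNames(rep(list(character(0)), 13), cols))
  rownames(hits) <- NULL
  list(hits = hits, truth = truth)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits the six standard files — counts TSV, sample sheet TSV, GO map TSV,
#' truth TSV (transition truth), transcripts FASTA and hit table TSV — in
#' the exact formats the package readers consume, so a written dataset
#' round-trips losslessly.
#'
#' @param dataset a `synthetic_dataset` from [simulate_experiment()].
#' @param directory output directory (created if missing).
#' @return data.frame manifest with columns `file`, `path`, `bytes`.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  p <- function(f) file.path(directory, f)
  write_counts(dataset$counts, p("counts.tsv"), p("samples.tsv"))
  utils::write.table(dataset$go_map, p("go_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth_de, p("truth_de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", names(dataset$transcripts), "\n",
                    dataset$transcripts), p("transcripts.fasta"))
  utils::write.table(dataset$hit_table, p("hit_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  files <- c("counts.tsv", "samples.tsv", "go_map.tsv", "truth_de.tsv",
             "transcripts.fasta", "hit_table.tsv")
  data.frame(file = files, path = vapply(files, p, ""),
             bytes = file.size(vapply(files, p, "")), row.names = NULL)
}
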