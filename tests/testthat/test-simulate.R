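test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(library_size = -1), "library_size")
  expect_error(sim_config(de_fraction = 1.2), "de_fraction")
  expect_error(sim_config(log2fc_range = c(0, 2)), "log2fc_range")
  expect_error(sim_config(phases = "MC"), "two phases")
})

test_that("identical seeds give bit-identical datasets", {
  a <- simulate_experiment(sim_config(n_genes = 100, library_size = 1e4,
                                      n_per_class = 2, orf_min_aa = 20,
                                      seed = 7))
  b <- simulate_experiment(sim_config(n_genes = 100, library_size = 1e4,
                                      n_per_class = 2, orf_min_aa = 20,
                                      seed = 7))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$hit_table, b$hit_table)
  c <- simulate_experiment(sim_config(n_genes = 100, library_size = 1e4,
                                      n_per_class = 2, orf_min_aa = 20,
                                      seed = 8))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("de_fraction = 0 marks every gene null on every transition", {
  ds <- simulate_experiment(sim_config(n_genes = 150, library_size = 1e4,
                                       de_fraction = 0, n_per_class = 1,
                                       orf_min_aa = 20, seed = 2))
  expect_true(all(ds$truth_de$status == "null"))
  expect_true(all(ds$truth_de$log2fc == 0))
})

test_that("per-transition DE fraction sits in the binomial 99% band", {
  ds <- simulate_experiment(sim_config(n_genes = 2000, library_size = 1e4,
                                       de_fraction = 0.1, n_per_class = 1,
                                       orf_min_aa = 20, seed = 42))
  band <- qbinom(c(0.005, 0.995), 2000, 0.1) / 2000
  for (cmp in unique(ds$truth_de$comparison)) {
    frac <- mean(ds$truth_de$status[ds$truth_de$comparison == cmp] != "null")
    expect_gte(frac, band[1])
    expect_lte(frac, band[2])
  }
})

test_that("cyclic constraint: per-gene log2 effects sum to zero", {
  ds <- small_dataset()
  sums <- tapply(ds$truth_de$log2fc, ds$truth_de$gene_id, sum)
  expect_true(all(abs(sums) < 1e-12))
})

test_that("null-gene counts converge to N_s * theta_g", {
  # many replicate libraries of an all-null design, no colony noise
  ds <- simulate_experiment(sim_config(n_genes = 20, n_colonies = 3400,
                                       library_size = 1e5, de_fraction = 0,
                                       colony_sdlog = 0, n_per_class = 1,
                                       orf_min_aa = 20, seed = 5))
  n_draws <- nrow(ds$counts$samples)
  expect_gte(n_draws, 1e4)
  expected <- 1e5 * ds$truth_genes$theta
  observed <- rowMeans(ds$counts$counts)
  expect_true(all(abs(observed - expected) / expected < 0.05))
})

test_that("coherent GO terms only contain same-direction DE members", {
  ds <- simulate_experiment(sim_config(n_genes = 1000, library_size = 1e4,
                                       coherent_term_fraction = 0.4,
                                       n_per_class = 1, orf_min_aa = 20,
                                       seed = 13))
  de <- ds$truth_genes[ds$truth_genes$is_de, ]
  for (code in ds$truth_go$go_code[ds$truth_go$coherent]) {
    members <- ds$go_map$gene_id[ds$go_map$go_code == code]
    dirs <- unique(de[de$gene_id %in% members,
                      c("special_phase", "delta")])
    if (nrow(dirs) > 1) {
      expect_length(unique(dirs$special_phase), 1)
      expect_length(unique(sign(dirs$delta)), 1)
    } else succeed()
  }
  # every term has at least one member gene
  expect_true(all(ds$truth_go$go_code %in% ds$go_map$go_code))
})

test_that("written datasets round-trip losslessly through the readers", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_identical(nrow(manifest), 6L)
  expect_true(all(manifest$bytes > 0))
  back <- read_counts(file.path(dir, "counts.tsv"),
                      file.path(dir, "samples.tsv"))
  expect_identical(back$gene_ids, ds$counts$gene_ids)
  expect_identical(back$counts, ds$counts$counts)
  expect_identical(back$samples, ds$counts$samples)
  gm <- read_go_map(file.path(dir, "go_map.tsv"))
  expect_identical(gm, ds$go_map)
  tx <- read_transcripts(file.path(dir, "transcripts.fasta"))
  expect_identical(stats::setNames(as.character(tx), names(tx)),
                   ds$transcripts)
  ht <- read_hit_table(file.path(dir, "hit_table.tsv"))
  expect_equal(ht$evalue, ds$hit_table$evalue)
  expect_identical(ht$taxon, ds$hit_table$taxon)
})

test_that("a zero-gene dataset writes valid headers and no data rows", {
  ds <- simulate_experiment(sim_config(n_genes = 1, library_size = 10,
                                       n_per_class = 1, orf_min_aa = 20,
                                       seed = 1))
  # degenerate input handled at the reader level: header-only counts file
  dir <- withr::local_tempdir()
  writeLines(paste(c("gene_id", ds$counts$samples$sample_id),
                   collapse = "\t"),
             file.path(dir, "counts.tsv"))
  utils::write.table(ds$counts$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_counts(file.path(dir, "counts.tsv"),
                      file.path(dir, "samples.tsv"))
  expect_length(back$gene_ids, 0)
  expect_identical(unname(back$library_totals),
                   rep(0, nrow(ds$counts$samples)))
})

test_that("toy transcripts carry their designed class structure", {
  tr <- simulate_transcripts(sim_config(n_per_class = 10, orf_min_aa = 30,
                                        seed = 3))
  expect_length(tr$records, 50)
  expect_identical(as.integer(table(tr$truth$class)[c(
    "complete", "none", "open3", "open5", "open_both")]),
    rep(10L, 5))
  # a complete-class record contains an in-frame start and stop >= min_aa apart
  one <- tr$records[tr$truth$class == "complete"][1]
  m <- regexpr("ATG", one, fixed = TRUE)[1]
  rest <- substring(one, m)
  codons <- substring(rest, seq(1, nchar(rest) - 2, 3),
                      seq(3, nchar(rest), 3))
  stop_at <- which(codons %in% c("TAA", "TAG", "TGA"))[1]
  expect_gte(stop_at - 1, 30)
  expect_identical(simulate_transcripts(sim_config(seed = 3))$records,
                   simulate_transcripts(sim_config(seed = 3))$records)
})
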