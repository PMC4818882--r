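test_that("GRV and GNV reproduce the published worked examples", {
  # ATPase activity: 39 down / 0 up, then 1 down / 51 up
  expect_equal(grv(39, 0, 1, 51), 89 / 91)
  expect_equal(gnv(39, 0, 1, 51), 13 / 91)
  # microtubule-based movement: 39/0 then 2/79
  expect_equal(gnv(39, 0, 2, 79), 42 / 120)
  expect_equal(grv(5, 5, 5, 5), 0)
  for (n in c(1, 7, 40)) expect_equal(grv(n, 0, 0, n), 1)
  expect_equal(gnv(3, 4, 3, 4), 0)
  expect_equal(gnv(0, 0, 2, 5), 1)
  expect_true(is.na(grv(0, 0, 0, 0)))
  expect_true(is.na(gnv(0, 0, 0, 0)))
})

test_that("GRV/GNV sweep: bounds, antisymmetry, rational oracle", {
  q <- expand.grid(d1 = 0:20, u1 = 0:20, d2 = 0:20, u2 = 0:20)
  s <- q$d1 + q$u1 + q$d2 + q$u2
  q <- q[s > 0, ]; s <- s[s > 0]
  g_r <- grv(q$d1, q$u1, q$d2, q$u2)
  g_n <- gnv(q$d1, q$u1, q$d2, q$u2)
  expect_true(all(g_r >= -1 & g_r <= 1))
  expect_true(all(g_n >= -1 & g_n <= 1))
  # independent integer-arithmetic evaluation
  expect_identical(g_r, ((q$d1 - q$d2) + (q$u2 - q$u1)) / s)
  expect_identical(g_n, ((q$d2 + q$u2) - (q$d1 + q$u1)) / s)
  # swapping the two comparisons negates both statistics
  expect_equal(grv(q$d2, q$u2, q$d1, q$u1), -g_r)
  expect_equal(gnv(q$d2, q$u2, q$d1, q$u1), -g_n)
})

test_that("tallies count each annotated gene once per term", {
  cons <- data.frame(gene_id = c("g1", "g2", "g3"),
                     comparison = "preTO_vs_MC",
                     status = c("up", "down", "ns"))
  map <- data.frame(gene_id = c("g1", "g1", "g2", "g3", "g9"),
                    go_code = c("GO:1", "GO:2", "GO:1", "GO:1", "GO:3"),
                    go_name = "x", go_domain = "Molecular functions")
  tal <- tally_categories(cons, map)
  t1 <- tal[tal$go_code == "GO:1", ]
  expect_identical(t1$U, 1L)       # g1 counted once, g3 is ns
  expect_identical(t1$D, 1L)
  expect_identical(tal$U[tal$go_code == "GO:2"], 1L)  # multi-membership
  expect_identical(tal$D[tal$go_code == "GO:3"], 0L)  # unmatched gene g9
  expect_error(tally_categories(cons, map[0, ]), "empty")

  all_ns <- data.frame(gene_id = c("g1", "g2"), comparison = "a",
                       status = "ns")
  tns <- tally_categories(all_ns, map)
  expect_true(all(tns$D == 0 & tns$U == 0))
})

test_that("a coherent all-up term tallies U = members, D = 0", {
  ds <- simulate_experiment(sim_config(n_genes = 1500, library_size = 1e6,
                                       de_fraction = 0.1,
                                       log2fc_range = c(2, 3),
                                       coherent_term_fraction = 0.3,
                                       n_per_class = 1, orf_min_aa = 20,
                                       seed = 9))
  cons <- consensus_table(de_table(ds$counts), min_clues = 3)
  tal <- tally_categories(cons, ds$go_map)
  tg <- ds$truth_go
  # pick a coherent term whose members rise into their special phase
  cand <- tg[tg$coherent & !is.na(tg$pattern_phase) &
               tg$pattern_phase == "preTO" & !is.na(tg$pattern_sign) &
               tg$pattern_sign == 1, ]
  expect_gt(nrow(cand), 0)
  code <- cand$go_code[1]
  members <- unique(ds$go_map$gene_id[ds$go_map$go_code == code])
  de_members <- intersect(members,
                          ds$truth_genes$gene_id[ds$truth_genes$is_de])
  row <- tal[tal$go_code == code & tal$comparison == "preTO_vs_MC", ]
  expect_identical(row$D, 0L)
  expect_gte(row$U, length(de_members) - 1L)
  expect_lte(row$U, length(de_members))
})

test_that("category dynamics selects high-change categories", {
  tal <- data.frame(
    go_code = rep(c("GO:0016887", "GO:none"), each = 2),
    go_name = rep(c("ATPase activity", "empty"), each = 2),
    go_domain = "Molecular functions",
    comparison = rep(c("preTO_vs_MC", "TO_vs_preTO"), 2),
    D = c(39L, 1L, 0L, 0L), U = c(0L, 51L, 0L, 0L))
  dyn <- category_dynamics(tal, tau = 0.9)
  atp <- dyn[dyn$go_code == "GO:0016887", ]
  expect_equal(atp$GRV, 89 / 91)
  expect_true(atp$selected)
  none <- dyn[dyn$go_code == "GO:none", ]
  expect_true(is.na(none$GRV))
  expect_false(none$selected)
  # AND rule: the ATPase row fails because |GNV| = 13/91 < 0.9
  expect_false(category_dynamics(tal, tau = 0.9,
                                 rule = "and")$selected[
                                   dyn$go_code == "GO:0016887"][1])
  # strict threshold limit: tau = 1 can never be exceeded
  expect_true(all(!category_dynamics(tal, tau = 1)$selected))
  expect_error(category_dynamics(tal, pairs = list(c("a", "b"))), "unknown")
  # sorted by total gene number, descending
  expect_true(all(diff(dyn$total) <= 0))
})

test_that("a flipped coherent term attains GRV = 1 end to end", {
  ds <- simulate_experiment(sim_config(n_genes = 1500, library_size = 1e6,
                                       de_fraction = 0.1,
                                       log2fc_range = c(2, 3),
                                       coherent_term_fraction = 0.3,
                                       n_per_class = 1, orf_min_aa = 20,
                                       seed = 9))
  cons <- consensus_table(de_table(ds$counts), min_clues = 3)
  dyn <- category_dynamics(tally_categories(cons, ds$go_map), tau = 0.9)
  tg <- ds$truth_go
  # a term depressed in preTO flips all-down -> all-up across the pair
  flip <- tg$go_code[tg$coherent & !is.na(tg$pattern_phase) &
                       tg$pattern_phase == "preTO" & tg$pattern_sign == -1]
  expect_gt(length(flip), 0)
  row <- dyn[dyn$go_code == flip[1] & dyn$first == "preTO_vs_MC", ]
  expect_gt(row$total, 0)
  expect_equal(row$GRV, 1)
  expect_true(row$selected)
})
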