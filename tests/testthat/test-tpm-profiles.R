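test_that("TPM normalization matches hand arithmetic and sums to 1e6", {
  one <- data.frame(orf_id = "a", sample_id = "S1", length_bp = 900,
                    read_count = 7)
  expect_equal(compute_tpm(one)$tpm, 1e6)

  two <- data.frame(orf_id = c("a", "b"), sample_id = "S1",
                    length_bp = c(1000, 2000), read_count = c(10, 10))
  expect_equal(compute_tpm(two)$tpm, c(2e6 / 3, 1e6 / 3))

  eq <- data.frame(orf_id = letters[1:5], sample_id = "S1",
                   length_bp = 500, read_count = 3)
  expect_equal(compute_tpm(eq)$tpm, rep(2e5, 5))

  set.seed(4)
  many <- data.frame(orf_id = as.character(1:300),
                     sample_id = rep(c("S1", "S2", "S3"), each = 100),
                     length_bp = sample(300:2000, 300, TRUE),
                     read_count = rpois(300, 40))
  tpm <- compute_tpm(many)
  sums <- tapply(tpm$tpm, tpm$sample_id, sum)
  expect_equal(as.numeric(sums), rep(1e6, 3), tolerance = 1e-9)

  zero <- data.frame(orf_id = "a", sample_id = "S1", length_bp = 100,
                     read_count = 0)
  expect_warning(z <- compute_tpm(zero), "zero mapped")
  expect_equal(z$tpm, 0)
  expect_error(compute_tpm(data.frame(orf_id = "a", sample_id = "S1",
                                      length_bp = 0, read_count = 1)), "> 0")
})

test_that("nosZ clade votes follow strict majority with tie -> unassigned", {
  hits <- rbind(
    data.frame(orf_id = "all_I", hit_rank = 1:10, clade = "I"),
    data.frame(orf_id = "tie", hit_rank = 1:10, clade = rep(c("I", "II"), 5)),
    data.frame(orf_id = "six_four", hit_rank = 1:10,
               clade = c(rep("I", 6), rep("II", 4))),
    data.frame(orf_id = "short", hit_rank = 1:3, clade = c("II", "II", "I")))
  out <- split_nosz(hits)
  got <- setNames(out$assigned_clade, out$orf_id)
  expect_equal(got[["all_I"]], "nosZ_I")
  expect_equal(got[["tie"]], "unassigned")
  expect_equal(got[["six_four"]], "nosZ_I")
  expect_equal(got[["short"]], "nosZ_II")

  # permutation-invariant in hit order
  set.seed(9)
  shuffled <- hits[sample(nrow(hits)), ]
  out2 <- split_nosz(shuffled)
  expect_equal(out2[order(out2$orf_id), ], out[order(out$orf_id), ],
               ignore_attr = TRUE)
  expect_error(split_nosz(data.frame(orf_id = "x", clade = "III")), "clade")
})

test_that("taxon aggregation percentages follow share arithmetic and sum to 100", {
  # constructed fixture: {A: 30, B: 10} TPM -> {75 %, 25 %}
  orfs <- data.frame(orf_id = c("o1", "o2"), sample_id = "S1",
                     gene_label = "nirS",
                     taxon_lineage = c("d__B;p__A", "d__B;p__B"),
                     tpm = c(30, 10))
  agg <- aggregate_by_taxon(orfs)
  expect_equal(agg$relative_pct, c(75, 25))

  # single-taxon gene -> 100 %
  solo <- data.frame(orf_id = "o", sample_id = "S1", gene_label = "napA",
                     taxon_lineage = "d__B;p__OnlyOne", tpm = 5)
  expect_equal(aggregate_by_taxon(solo)$relative_pct, 100)

  # missing phylum annotation pools into unclassified bacteria
  un <- data.frame(orf_id = c("o1", "o2"), sample_id = "S1",
                   gene_label = "nirK",
                   taxon_lineage = c("d__Bacteria;p__", "d__Bacteria"),
                   tpm = c(1, 1))
  agg_un <- aggregate_by_taxon(un)
  expect_equal(agg_un$taxon, "unclassified bacteria")
  expect_equal(agg_un$relative_pct, 100)

  # field-like fixture: napA community with Proteobacteria at 69.58 %
  shares <- c(Proteobacteria = 0.6958, `unclassified bacteria` = 0.1339,
              Desulfobacterota = 0.1, Myxococcus = 0.0703)
  fx <- compute_tpm(orf_fixture_with_shares(shares))
  fx <- label_genes(fx)
  agg_fx <- aggregate_by_taxon(fx)
  expect_equal(
    agg_fx$relative_pct[agg_fx$taxon == "Proteobacteria"], 69.58,
    tolerance = 1e-9)
  expect_equal(sum(agg_fx$relative_pct), 100, tolerance = 1e-9)
})

test_that("gene-by-taxon matrix flags norB-without-nosZ imbalance exactly", {
  # 8 phyla, 3 constructed to carry norB with nosZ below 10 % of norB
  taxa <- paste0("P", 1:8)
  flagged <- c("P2", "P5", "P7")
  rows <- list()
  for (t in taxa) {
    norb <- 10
    nosz <- if (t %in% flagged) 0.5 else 12
    rows[[t]] <- data.frame(
      sample_id = "S1", gene_label = c("norB", "nosZ_I", "nosZ_II"),
      taxon = t, tpm = c(norb, nosz / 2, nosz / 2), relative_pct = NA)
  }
  gtm <- gene_taxon_matrix(do.call(rbind, rows))
  expect_equal(sort(names(which(gtm$flags))), sort(flagged))
  expect_equal(unname(gtm$matrix[, "norB"]), rep(10, 8))

  # nosZ >= norB never flags; zero nosZ with norB present always flags
  prof <- data.frame(sample_id = "S1",
                     gene_label = c("norB", "nosZ_II", "norB"),
                     taxon = c("A", "A", "B"), tpm = c(5, 5, 3),
                     relative_pct = NA)
  gtm2 <- gene_taxon_matrix(prof)
  expect_false(gtm2$flags[["A"]])
  expect_true(gtm2$flags[["B"]])
})

test_that("profiling chain is deterministic end to end", {
  cfg <- scenario_config(seed = 13, n_samples = 2, orfs_per_gene = 15,
                         depth = 2e4)
  g1 <- gen_orf_table(cfg)
  p1 <- profile_orfs(g1$orfs, g1$nosz_hits)
  g2 <- gen_orf_table(cfg)
  p2 <- profile_orfs(g2$orfs, g2$nosz_hits)
  expect_identical(p1$profile, p2$profile)
  expect_identical(p1$matrix, p2$matrix)
})
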