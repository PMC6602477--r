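toy <- toy_taxonomy()

test_that("clade-group selection honors membership, focus, and set semantics", {
  fx <- generate_trnas(fixture_spec(n_genes = 200, seed = 21))
  g <- fx$genes
  sel <- select_genes(g, toy, clades = c("Fungi", "Chordata"))
  expect_setequal(unique(sel$meta$species_taxid),
                  intersect(unique(g$meta$species_taxid),
                            c(subtree_species(toy, "Fungi"),
                              subtree_species(toy, "Chordata"))))
  ## overlapping members count each gene once
  sel2 <- select_genes(g, toy, clades = c("Eukaryota", "Fungi"))
  sel3 <- select_genes(g, toy, clades = "Eukaryota")
  expect_identical(sort(sel2$meta$gene_id), sort(sel3$meta$gene_id))
  ## monotone in clade containment
  expect_true(all(select_genes(g, toy, clades = "Fungi")$meta$gene_id %in%
                  sel3$meta$gene_id))
  ## half-open score focus: >= 55 excludes 54.9, includes 55.0
  g$meta$score_bits[1:2] <- c(54.9, 55.0)
  hi <- select_genes(g, toy, sel_focus = focus(score_min = 55))
  expect_false(g$meta$gene_id[1] %in% hi$meta$gene_id)
  expect_true(g$meta$gene_id[2] %in% hi$meta$gene_id)
  lo <- select_genes(g, toy, sel_focus = focus(score_max = 55))
  expect_identical(n_genes(hi) + n_genes(lo), n_genes(g))
  ## empty selection warns, not errors
  expect_warning(select_genes(g, toy,
                              sel_focus = focus(score_min = 1e6)), "empty")
})

test_that("position distributions count symbols and ordered pairs", {
  g <- mk_set(list(a = c("34" = "A"), b = c("34" = "G")),
              anticodon = "GCC")
  d <- suppressWarnings(position_distribution(g, "34"))
  expect_identical(d$counts[["A"]], 1L)
  expect_identical(d$counts[["G"]], 1L)
  expect_identical(d$n, 2L)
  ## pair target increments the ordered key
  g2 <- mk_set(list(a = c("3" = "G", "70" = "C")))
  d2 <- position_distribution(g2, "3:70")
  expect_identical(d2$counts[["G:C"]], 1L)
  expect_identical(sum(d2$counts), 1L)
  ## all-gap position
  d3 <- position_distribution(g2, "e1")
  expect_identical(d3$counts[["-"]], 1L)
  expect_error(position_distribution(g2, "badlabel"), "unknown Sprinzl")
})

test_that("frequencies normalize exactly and reject empty selections", {
  expect_identical(
    frequencies(as_position_distribution(c(A = 1, G = 1), "57"))[c("A", "G")],
    c(A = 0.5, G = 0.5))
  expect_identical(
    frequencies(as_position_distribution(c(`-` = 4), "17a"))[["-"]], 1)
  set.seed(1)
  for (k in 1:20) {
    cnt <- stats::setNames(sample(0:30, 5, replace = TRUE),
                           c("A", "C", "G", "U", "-"))
    if (sum(cnt) == 0) next
    expect_equal(sum(frequencies(as_position_distribution(cnt, "1"))), 1,
                 tolerance = 1e-9)
  }
  g0 <- mk_set(list(a = c("1" = "A")))[0]
  expect_error(frequencies(position_distribution(g0, "1")), "n = 0")
})

test_that("pair distributions marginalize to the single positions", {
  fx <- generate_trnas(fixture_spec(n_genes = 150, seed = 33))
  d <- position_distribution(fx$genes, "3:70")
  m5 <- position_distribution(fx$genes, "3")
  m3 <- position_distribution(fx$genes, "70")
  for (s in c("A", "C", "G", "U", "-")) {
    expect_identical(sum(d$counts[startsWith(names(d$counts),
                                             paste0(s, ":"))]),
                     m5$counts[[s]])
    expect_identical(sum(d$counts[endsWith(names(d$counts),
                                           paste0(":", s))]),
                     m3$counts[[s]])
  }
})

test_that("partition by clade group conserves per-position counts", {
  fx <- generate_trnas(fixture_spec(n_genes = 180, seed = 55))
  g <- fx$genes
  whole <- position_distribution(g, "34")$counts
  doms <- c("Eukaryota", "Bacteria", "Archaea")
  parts <- lapply(doms, function(d)
    position_distribution(suppressWarnings(
      select_genes(g, toy, clades = d)), "34")$counts)
  expect_identical(Reduce(`+`, parts), whole)
})

test_that("taxonomy summary reproduces the clade-share relation", {
  ## 25 fungal + 75 other eukaryotic genes -> Fungi contributes 25% of the
  ## domain's tRNAs
  fx <- generate_trnas(fixture_spec(
    n_genes = 100, seed = 3,
    species = c(rep("p1g1s1", 25), rep("p2g1s1", 75))))
  ts <- taxonomy_summary(fx$genes, toy, "Fungi")
  expect_identical(ts$count[ts$clade == "Fungi"], 25L)
  expect_identical(ts$fraction[ts$rank == "domain"], 0.25)
  ## clade = a domain: single row, fraction 1
  td <- taxonomy_summary(fx$genes, toy, "Eukaryota")
  expect_identical(nrow(td), 1L)
  expect_identical(td$fraction, 1)
  ## brute-force recount at every row
  ts2 <- taxonomy_summary(fx$genes, toy, "p1g1s1")
  for (r in seq_len(nrow(ts2))) {
    anc <- toy$taxid[match(ts2$clade[r], toy$name)]
    expect_identical(ts2$count[r],
      sum(vapply(fx$genes$meta$species_taxid, function(s)
        anc %in% lineage(toy, s), logical(1))))
  }
})

test_that("anticodon counts and score stats match direct recomputation", {
  fx <- generate_trnas(fixture_spec(n_genes = 90, seed = 8))
  ac <- anticodon_counts(fx$genes)
  expect_identical(sum(ac$count), 90L)
  expect_false(any(ac$count == 0))
  expect_identical(ac$isotype, sort(ac$isotype))
  for (r in sample(nrow(ac), 5)) {
    expect_identical(ac$count[r],
      sum(fx$genes$meta$isotype == ac$isotype[r] &
          fx$genes$meta$anticodon == ac$anticodon[r]))
  }
  ## score stats
  one <- mk_set(list(a = c("1" = "A")), score = 60)
  s1 <- score_stats(one, "isotype")
  expect_identical(s1$n, 1L)
  expect_true(all(s1[, c("min", "mean", "max")] == 60))
  two <- mk_set(list(a = c("1" = "A"), b = c("1" = "A")), score = 60)
  two$meta$score_bits <- c(50, 70)
  expect_identical(score_stats(two, "isotype")$mean, 60)
  ss <- score_stats(fx$genes, "isotype")
  for (r in sample(nrow(ss), 4)) {
    v <- fx$genes$meta$score_bits[fx$genes$meta$isotype == ss$group[r]]
    expect_equal(ss$mean[r], mean(v))
    expect_identical(ss$min[r], min(v))
    expect_identical(ss$max[r], max(v))
  }
  ## subclade grouping assigns genes to direct children
  sc <- score_stats(fx$genes, "subclade", tax = toy, clade = "Eukaryota")
  expect_setequal(sc$group, c("Fungi", "Chordata"))
  expect_identical(sum(sc$n),
                   sum(fx$genes$meta$species_taxid %in%
                       subtree_species(toy, "Eukaryota")))
})
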