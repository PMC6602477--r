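pd <- function(counts, target = "57") as_position_distribution(counts, target)

test_that("feature code base sets agree with the IUPAC truth table", {
  iupac <- list(R = c("A", "G"), Y = c("C", "U"), W = c("A", "U"),
                S = c("C", "G"), M = c("A", "C"), K = c("G", "U"),
                B = c("C", "G", "U"), D = c("A", "G", "U"),
                H = c("A", "C", "U"), V = c("A", "C", "G"))
  for (code in names(iupac)) {
    expect_setequal(code_base_set(code, "single"), iupac[[code]])
  }
  expect_identical(code_base_set("ABSENT"), "-")
  ## exhaustive pair truth table: PAIRED = the six zero-tier pairs,
  ## MISMATCHED = every other ordered non-gap pair
  all16 <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                           function(a, b) paste(a, b, sep = ":")))
  wc <- c("A:U", "U:A", "G:C", "C:G", "G:U", "U:G")
  expect_setequal(code_base_set("PAIRED"), wc)
  expect_setequal(code_base_set("MISMATCHED"), setdiff(all16, wc))
  expect_setequal(c(code_base_set("PAIRED"), code_base_set("MISMATCHED")),
                  all16)
})

test_that("classification reproduces the tiered threshold examples", {
  ## the R57 case: A and G each >= 5%, combined exactly 90%
  expect_identical(classify(pd(c(A = 46, G = 44, C = 5, U = 5)))$code, "R")
  expect_identical(classify(pd(c(A = 100)))$code, "A")
  ## within-tier order: R precedes M when both qualify
  expect_identical(classify(pd(c(A = 850, G = 80, C = 70)))$code, "R")
  ## high tier only
  expect_identical(classify(pd(c(A = 50, C = 30, G = 15, U = 5)))$code, "V")
  ## a minor base at 6% keeps W alive even though R/D/H all fail
  expect_identical(classify(pd(c(A = 850, G = 45, C = 45, U = 60)))$code, "W")
  ## no call: every candidate fails a component rule or the 90% total
  fc <- classify(pd(c(A = 850, G = 45, C = 45, U = 45, `-` = 15)))
  expect_identical(fc$code, "N")
  expect_identical(fc$tier, "none")
  ## gap-dominated position
  expect_identical(classify(pd(c(`-` = 95, A = 5), "17a"))$code, "ABSENT")
  ## paired: S:S aggregates both strong orientations
  expect_identical(
    classify(pd(c(`G:C` = 50, `C:G` = 45, `A:U` = 5), "3:70"))$code, "S:S")
  expect_error(classify(pd(c(A = 0))), "n = 0")
})

test_that("classification equals the brute-force oracle on random draws", {
  set.seed(2024)
  syms <- c("A", "C", "G", "U", "-")
  for (k in 1:400) {
    n <- sample(c(10, 20, 97, 100, 200), 1)
    cnt <- stats::setNames(as.vector(stats::rmultinom(
      1, n, prob = stats::runif(5)^sample(c(0.2, 1, 3), 1))), syms)
    d <- pd(cnt)
    expect_identical(classify(d)$code,
                     oracle_classify(d$counts, d$n, paired = FALSE),
                     info = paste(cnt, collapse = ","))
  }
  pk <- names(as_position_distribution(c(`A:U` = 1), "3:70")$counts)
  for (k in 1:400) {
    n <- sample(c(10, 50, 120), 1)
    cnt <- stats::setNames(as.vector(stats::rmultinom(
      1, n, prob = stats::runif(25)^sample(c(0.2, 1, 4), 1))), pk)
    d <- as_position_distribution(cnt, "3:70")
    expect_identical(classify(d)$code,
                     oracle_classify(d$counts, d$n, paired = TRUE),
                     info = paste(cnt, collapse = ","))
  }
})

test_that("tier soundness and threshold monotonicity hold", {
  set.seed(7)
  syms <- c("A", "C", "G", "U", "-")
  tier_rank <- c(zero = 1, partial = 2, high = 3, none = 4)
  for (k in 1:150) {
    cnt <- stats::setNames(as.vector(stats::rmultinom(1, 50,
                                                      stats::runif(5))), syms)
    d <- pd(cnt)
    fc <- classify(d)
    ## if any zero-tier code qualifies, the call is zero-tier
    zero_ok <- any(c(cnt[1:4] / 50 >= 0.9 - 1e-9, cnt[5] / 50 >= 0.9 - 1e-9))
    if (zero_ok) expect_identical(fc$tier, "zero")
    ## raising min_total never yields a more specific (lower) tier
    fc95 <- classify(d, min_total = 0.95)
    expect_gte(tier_rank[[fc95$tier]], tier_rank[[fc$tier]])
    ## determinism
    expect_identical(classify(d)$code, fc$code)
  }
})

test_that("consensus tables cover all positions and recover plans", {
  map <- mk_map("G", c("34" = "G", "35" = "C", "36" = "C"))
  g <- mk_uniform_set(100, map)
  ct <- consensus_table(g)
  expect_length(ct$single, 98)
  expect_true(all(ct$single_tier == "zero"))       # monomorphic columns
  expect_identical(unname(ct$single[["17a"]]), "ABSENT")
  expect_identical(unname(ct$single[["34"]]), "G")
  ## pairs of a monomorphic G/G set are G:G -> MISMATCHED except gaps
  expect_identical(unname(ct$paired[["1:72"]]), "MISMATCHED")
  expect_error(consensus_table(g[0]), "empty")
  ## planted consensus recovered from generated data
  fx <- generate_trnas(fixture_spec(
    n_genes = 300, seed = 17,
    planted_consensus = c("57" = "R", "20" = "Y", "6" = "ABSENT")))
  ct2 <- consensus_table(fx$genes)
  expect_identical(unname(ct2$single[c("57", "20", "6")]),
                   c("R", "Y", "ABSENT"))
})

test_that("tilemap splits by isotype and conserves gene counts", {
  fx <- generate_trnas(fixture_spec(n_genes = 80, seed = 12,
                                    isotypes = c("Gly", "Asn")))
  tm <- suppressMessages(tilemap(fx$genes))
  expect_setequal(names(tm), c("Gly", "Asn"))
  for (iso in names(tm)) {
    sub <- fx$genes[which(fx$genes$meta$isotype == iso)]
    expect_identical(tm[[iso]]$single, consensus_table(sub)$single)
  }
  expect_identical(sum(vapply(tm, `[[`, numeric(1), "n")),
                   as.numeric(n_genes(fx$genes)))
})

test_that("clade-versus-domain verdicts follow code specificity", {
  map <- mk_map("A", c("35" = "G", "36" = "C"))
  base <- mk_uniform_set(20, map, anticodon = "AGC", isotype = "Ala")
  ct_same <- consensus_table(base)
  v <- compare_to_domain(ct_same, ct_same)
  expect_true(all(v$verdict == "exact"))
  ## clade A vs domain R: more specific; R vs A: less specific or different
  clade <- base
  dom <- suppressWarnings(
    c(base, mk_uniform_set(15, mk_map("G", c("35" = "G", "36" = "C")),
                           anticodon = "AGC", isotype = "Ala",
                           species = "p1g1s2")))
  cv <- compare_to_domain(consensus_table(clade), consensus_table(dom))
  row1 <- cv[cv$position == "1" & cv$arity == "single", ]
  expect_identical(row1$clade_code, "A")
  expect_identical(row1$domain_code, "R")
  expect_identical(row1$verdict, "more_specific")
  rv <- compare_to_domain(consensus_table(dom), consensus_table(clade))
  expect_identical(rv$verdict[rv$position == "1" & rv$arity == "single"],
                   "less_specific_or_different")
  ## mismatched position sets are an error
  ct_small <- consensus_table(base, pair_table = data.frame(
    pos5 = "1", pos3 = "72", type = "secondary"))
  expect_error(compare_to_domain(ct_small, ct_same), "different position sets")
})
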