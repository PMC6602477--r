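ref_map <- mk_map("G", c("34" = "G", "35" = "C", "36" = "C",
                         "8" = "U", "9" = "A", "57" = "A", "62" = "C",
                         "19" = "G"))

test_that("profile bit values follow the smoothed log-odds closed forms", {
  one <- mk_uniform_set(1, ref_map)
  ## alpha -> 0 limit: modal symbol approaches log2(1 / 0.25) = 2 bits
  pr <- build_profile(one, alpha = 1e-9)
  expect_equal(unname(pr$r[["1"]]), 2, tolerance = 1e-6)
  ## hand computation at n = 97, count(G) = 94, alpha = 1
  g97 <- c(rep(list(ref_map), 94),
           rep(list(mk_map("A", c("34" = "G", "35" = "C", "36" = "C",
                                  "8" = "U", "9" = "A", "57" = "A",
                                  "62" = "C", "19" = "G"))), 3))
  set97 <- suppressWarnings(mk_set(g97))
  pr97 <- build_profile(set97, alpha = 1)
  expect_equal(unname(pr97$bits["G", "1"]), log2(((94 + 1) / (97 + 5)) / 0.25))
  expect_equal(unname(pr97$bits["A", "1"]), log2(((3 + 1) / (97 + 5)) / 0.25))
  expect_identical(unname(pr97$modal[["1"]]), "G")
  ## b <= r everywhere, r attained by the modal symbol
  expect_true(all(sweep(pr97$bits, 2, pr97$r) <= 1e-12))
  expect_error(build_profile(set97[0]), "empty reference")
})

test_that("penalties are zero at the modal symbol and bounded above by zero", {
  g <- mk_uniform_set(19, ref_map)
  pr <- build_profile(g)
  ## query identical to the modal sequence: all penalties zero
  p0 <- penalties(pr, g$aln[1, ])
  expect_true(all(p0 == 0))
  ## all-G column, query A: p = log2(1/24 * 4) - log2(20/24 * 4)
  qmap <- g$aln[1, ]; qmap["1"] <- "A"
  p <- penalties(pr, qmap)
  expect_equal(unname(p[["1"]]),
               log2((1 / 24) * 4) - log2((20 / 24) * 4))
  expect_true(all(p <= 0))
  ## uniform column: every base is modal-tied, penalty 0 for any base
  maps <- lapply(c("A", "C", "G", "U"), function(b)
    mk_map("G", c("5" = b, "34" = "G", "35" = "C", "36" = "C")))
  gu <- mk_set(maps)
  pru <- build_profile(gu)
  for (b in c("A", "C", "G", "U")) {
    qm <- gu$aln[1, ]; qm["5"] <- b
    expect_equal(unname(penalties(pru, qm)[["5"]]), 0)
  }
})

test_that("large pseudocounts shrink every penalty toward zero", {
  g <- mk_uniform_set(25, ref_map)
  q <- g$aln[1, ]; q["1"] <- "A"; q["8"] <- "C"
  p1 <- penalties(build_profile(g, alpha = 1), q)
  p10 <- penalties(build_profile(g, alpha = 10), q)
  p1e6 <- penalties(build_profile(g, alpha = 1e6), q)
  expect_true(all(p10 >= p1 - 1e-12))
  expect_true(all(abs(p1e6) < 1e-4))
})

test_that("query alignment recovers the modal numbering and deletions", {
  g <- mk_uniform_set(30, ref_map)
  pr <- build_profile(g)
  ms <- modal_sequence(pr)
  aq <- align_query(ms, pr)
  expect_identical(unname(aq[colnames(g$aln)]), unname(g$aln[1, ]))
  expect_identical(nrow(attr(aq, "insertions")), 0L)
  ## deletion placement: columns with distinct neighborhoods (cyclic
  ## A/C/G/U) pin the gap to exactly the deleted label
  cyc <- stats::setNames(rep(c("A", "C", "G", "U"), length.out = 76),
                         as.character(1:76))
  gc <- mk_uniform_set(25, cyc, anticodon = paste(cyc[34:36], collapse = ""))
  prc <- build_profile(gc)
  non_gap <- names(prc$modal)[prc$modal != "-"]
  del <- prc$modal[setdiff(non_gap, "17")]
  aq2 <- align_query(paste(del, collapse = ""), prc)
  expect_identical(unname(aq2[["17"]]), "-")
  same <- setdiff(non_gap, "17")
  expect_identical(aq2[same], gc$aln[1, same])
  ## determinism
  expect_identical(align_query(ms, pr), align_query(ms, pr))
  ## implausible lengths are rejected
  expect_error(align_query("ACGU", pr), "not a plausible mature tRNA")
  expect_error(align_query(strrep("ACGU", 40), pr), "not a plausible")
})

test_that("Gotoh alignment equals the exhaustive matching oracle", {
  set.seed(99)
  for (case in 1:40) {
    np <- sample(3:7, 1); nq <- sample(3:7, 1)
    bits <- matrix(stats::rnorm(5 * np, sd = 2), 5, np,
                   dimnames = list(c("A", "C", "G", "U", "-"), NULL))
    qs <- sample(c("A", "C", "G", "U"), nq, replace = TRUE)
    go <- stats::runif(1, 1, 6); ge <- stats::runif(1, 0.2, 2)
    got <- profile_align(bits, qs, gap_open = go, gap_extend = ge)
    want <- oracle_align_score(bits, match(qs, c("A", "C", "G", "U")), go, ge)
    expect_equal(got$score, want, tolerance = 1e-9,
                 info = sprintf("case %d (np=%d nq=%d)", case, np, nq))
    ## the reported alignment must itself achieve the reported score
    matched <- which(!is.na(got$assign))
    runs <- function(v) if (length(v) == 0) 0 else sum(diff(c(-9, v)) != 1)
    del <- which(is.na(got$assign))
    ins <- got$inserted
    realized <- sum(bits[cbind(match(qs, c("A", "C", "G", "U"))[
                                 got$assign[matched]], matched)]) +
      sum(bits[5, del]) -
      runs(ins) * go - length(ins) * ge
    expect_equal(realized, got$score, tolerance = 1e-9)
  }
})

test_that("group penalties average per position", {
  g <- mk_uniform_set(10, ref_map)
  pr <- build_profile(g)
  q1 <- g$aln[1, ]
  q2 <- g$aln[1, ]; q2["1"] <- "A"
  single <- group_penalties(pr, list(q1))
  expect_identical(single, penalties(pr, q1))
  both <- group_penalties(pr, list(q1, q2))
  expect_equal(unname(both[["1"]]),
               mean(c(penalties(pr, q1)[["1"]], penalties(pr, q2)[["1"]])))
  ## brute-force average over a generated fixture
  fx <- generate_trnas(fixture_spec(n_genes = 25, seed = 77))
  prf <- build_profile(fx$genes)
  gp <- group_penalties(prf, fx$genes)
  pm <- sapply(seq_len(25), function(i) penalties(prf, fx$genes$aln[i, ]))
  expect_equal(unname(gp), unname(rowMeans(pm)))
  expect_true(all(gp <= 0))
})

test_that("bitchart rows carry consensus, modal and per-group penalties", {
  g <- mk_uniform_set(40, ref_map)
  bc <- bitchart(g, list(self = g))
  expect_identical(unique(bc$row_type), c("consensus", "modal", "query"))
  self <- bc[bc$group == "self", ]
  ## monomorphic reference as its own query: penalties all zero
  expect_true(all(self$mean_penalty == 0))
  ## six-substitution query deviates at exactly six positions
  pr <- build_profile(g)
  mut <- mutate_modal(pr, c("8" = "G", "9" = "G", "19" = "A",
                            "57" = "G", "62" = "U", "34" = "U"))
  bc2 <- bitchart(g, list(q = mut, q2 = mut))
  qrow <- bc2[bc2$group == "q", ]
  expect_identical(sum(qrow$mean_penalty < 0), 6L)
  expect_setequal(qrow$position[qrow$mean_penalty < 0],
                  c("8", "9", "19", "57", "62", "34"))
  ## two identical groups produce identical rows
  q2row <- bc2[bc2$group == "q2", ]
  expect_identical(qrow$feature, q2row$feature)
  expect_identical(qrow$mean_penalty, q2row$mean_penalty)
  ## empty query groups are dropped with a warning
  expect_warning(bc3 <- bitchart(g, list(none = character(0))), "empty")
  expect_false("none" %in% bc3$group)
})
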