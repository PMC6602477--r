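## Shared builders and independent oracles for the test suite.

## A trna_set from explicit partial position maps (absent positions -> gap).
mk_set <- function(maps, isotype = "Gly", anticodon = "GCC",
                   species = "p1g1s1", score = 60) {
  n <- length(maps)
  if (is.null(names(maps))) names(maps) <- paste0(species, ".trna", seq_len(n))
  meta <- data.frame(
    gene_id = names(maps),
    species_taxid = rep_len(species, n),
    isotype = rep_len(isotype, n),
    anticodon = rep_len(anticodon, n),
    score_bits = rep_len(score, n),
    stringsAsFactors = FALSE)
  trna_set(meta, aligned_matrix(maps))
}

## n genes all carrying the same full-length sequence map.
mk_uniform_set <- function(n, map, ...) {
  mk_set(rep(list(map), n), ...)
}

## A full-length position map: every numeric position 1..76 set to `base`,
## insertions/e-arm left as gaps, with optional overrides.
mk_map <- function(base = "G", overrides = character(0)) {
  m <- stats::setNames(rep(base, 76), as.character(1:76))
  m[names(overrides)] <- overrides
  m
}

## ---- Independent classification oracle ------------------------------------
## Re-states the code tables and scan literally from their definitions,
## independent of the package's internal representation.
oracle_single_codes <- list(
  A = "A", C = "C", G = "G", U = "U", ABSENT = "-",
  R = c("A", "G"), Y = c("C", "U"), W = c("A", "U"), S = c("C", "G"),
  M = c("A", "C"), K = c("G", "U"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"))

oracle_paired_codes <- local({
  wc <- c("A:U", "U:A", "G:C", "C:G", "G:U", "U:G")
  all16 <- as.vector(t(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                             paste, sep = ":")))
  list(`A:U` = "A:U", `U:A` = "U:A", `G:C` = "G:C", `C:G` = "C:G",
       `G:U` = "G:U", `U:G` = "U:G",
       `R:Y` = c("A:U", "G:C", "G:U"), `Y:R` = c("U:A", "C:G", "U:G"),
       `S:S` = c("G:C", "C:G"), `W:W` = c("A:U", "U:A"),
       PAIRED = wc, MISMATCHED = setdiff(all16, wc))
})

## Brute-force scan over raw counts; total-only codes need no component rule.
oracle_classify <- function(counts, n, paired = FALSE,
                            minc = 0.05, mint = 0.90) {
  codes <- if (paired) oracle_paired_codes else oracle_single_codes
  for (code in names(codes)) {
    mem <- codes[[code]]
    f <- counts[mem] / n
    f[is.na(f)] <- 0
    comp_ok <- if (code %in% c("PAIRED", "MISMATCHED")) TRUE
               else all(f >= minc - 1e-9)
    if (comp_ok && sum(f) >= mint - 1e-9) return(code)
  }
  if (paired) "NN" else "N"
}

## ---- Independent alignment oracle ------------------------------------------
## Exhaustive enumeration over monotone match sets.  Deleted (unmatched)
## profile positions emit the gap-state score; unmatched query symbols
## form insertion runs, grouped between consecutive matches (the optimal
## arrangement), so the maximum over matchings equals the maximum over
## alignment paths.
oracle_align_score <- function(bits, qi, gap_open, gap_extend) {
  np <- ncol(bits); nq <- length(qi)
  ins_cost <- function(unmatched_sorted) {
    ## maximal blocks of consecutive unmatched indices, one opening each
    if (length(unmatched_sorted) == 0) return(0)
    runs <- sum(diff(c(-10, unmatched_sorted)) != 1)
    runs * gap_open + length(unmatched_sorted) * gap_extend
  }
  best <- -Inf
  for (k in 0:min(np, nq)) {
    pcomb <- if (k == 0) matrix(integer(0), nrow = 0, ncol = 1)
             else if (k == np) matrix(1:np, ncol = 1)
             else utils::combn(np, k)
    qcomb <- if (k == 0) matrix(integer(0), nrow = 0, ncol = 1)
             else if (k == nq) matrix(1:nq, ncol = 1)
             else utils::combn(nq, k)
    for (a in seq_len(ncol(pcomb))) {
      pi_ <- pcomb[, a]
      delscore <- sum(bits[5, setdiff(1:np, pi_)])
      for (b in seq_len(ncol(qcomb))) {
        qj <- qcomb[, b]
        sc <- sum(bits[cbind(qi[qj], pi_)]) + delscore -
          ins_cost(setdiff(1:nq, qj))
        if (sc > best) best <- sc
      }
    }
  }
  best
}
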