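## Feature-code tables.  Candidate order is the canonical scan order:
## tiers zero -> partial -> high, and within each tier the listed order.
## ABSENT is the zero-tier feature of gap-dominated positions; N / NN mark
## positions where no code qualifies.

.wc_pairs <- c("A:U", "U:A", "G:C", "C:G", "G:U", "U:G")
.all_base_pairs <- as.vector(t(outer(BASES, BASES, paste, sep = ":")))

.single_codes <- list(
  A = "A", C = "C", G = "G", U = "U", ABSENT = "-",
  R = c("A", "G"), Y = c("C", "U"), W = c("A", "U"), S = c("C", "G"),
  M = c("A", "C"), K = c("G", "U"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "U"))

.paired_codes <- list(
  `A:U` = "A:U", `U:A` = "U:A", `G:C` = "G:C", `C:G` = "C:G",
  `G:U` = "G:U", `U:G` = "U:G",
  ## partial pair codes cover only properly paired combinations, so the
  ## tiers nest: zero-tier pairs are subsets of partial codes, which are
  ## subsets of PAIRED
  `R:Y` = c("A:U", "G:C", "G:U"), `Y:R` = c("U:A", "C:G", "U:G"),
  `S:S` = c("G:C", "C:G"), `W:W` = c("A:U", "U:A"),
  PAIRED = .wc_pairs,
  MISMATCHED = setdiff(.all_base_pairs, .wc_pairs),
  NN = .all_base_pairs)

.code_tier <- c(
  stats::setNames(rep(c("zero", "partial", "high", "none"), c(5, 6, 4, 1)),
                  names(.single_codes)),
  stats::setNames(rep(c("zero", "partial", "high", "none"), c(6, 4, 2, 1)),
                  names(.paired_codes)))

#' The consensus feature-code vocabulary
#'
#' @param arity `"single"` or `"paired"`.
#' @return data.frame (code, tier, arity) in canonical scan order.
#' @export
feature_codes <- function(arity = c("single", "paired")) {
  arity <- match.arg(arity)
  codes <- if (arity == "single") names(.single_codes) else names(.paired_codes)
  data.frame(code = codes, tier = unname(.code_tier[codes]), arity = arity,
             stringsAsFactors = FALSE)
}

#' Symbols (or ordered symbol pairs) matched by a feature code
#' @param code A code such as `"R"`, `"ABSENT"`, `"S:S"`, `"PAIRED"`.
#' @param arity `"single"` or `"paired"` (needed to disambiguate; pair
#'   codes contain `":"` or are PAIRED/MISMATCHED/NN).
#' @return Character vector of symbols or `"X:Y"` pair keys.
#' @export
code_base_set <- function(code, arity = NULL) {
  if (is.null(arity)) {
    arity <- if (code %in% c("PAIRED", "MISMATCHED", "NN") ||
                 grepl(":", code, fixed = TRUE)) "paired" else "single"
  }
  tab <- if (arity == "single") .single_codes else .paired_codes
  if (is.null(tab[[code]])) stop("unknown ", arity, " feature code: ", code)
  tab[[code]]
}

.feature_code <- function(code, arity) {
  structure(list(code = code, tier = unname(.code_tier[code]), arity = arity,
                 base_set = code_base_set(code, arity)),
            class = "feature_code")
}

#' @export
print.feature_code <- function(x, ...) {
  cat(sprintf("feature %s (%s, %s tier): {%s}\n", x$code, x$arity, x$tier,
              paste(x$base_set, collapse = ", ")))
  invisible(x)
}

#' Classify a position distribution into a consensus feature
#'
#' Scans candidate codes tier by tier (zero, then partial, then high) in
#' the canonical within-tier order and returns the first code for which
#' every component base (or component base pair) has frequency at least
#' `min_component` and the components' combined frequency reaches
#' `min_total`.  Frequencies are counts over the full gene count `n`, so
#' gaps dilute base codes; gaps match only ABSENT (single) and never
#' contribute to a pair code.  PAIRED and MISMATCHED are treated as
#' single-component codes (combined threshold only).  If no code
#' qualifies, the no-call code `N` (single) or `NN` (paired) is returned
#' with tier `"none"`.
#'
#' Threshold comparisons are inclusive ("at least 5%", "reach 90%") and
#' evaluated with an absolute 1e-9 tolerance on the count ratios, so exact
#' boundary distributions classify as their rational values dictate.
#'
#' @param dist A `position_distribution` (single or paired target) with
#'   `n > 0`.
#' @param min_component Minimum per-component frequency (default 0.05).
#' @param min_total Minimum combined frequency (default 0.90).
#' @return A `feature_code`.
#' @examples
#' d <- structure(list(target = "57",
#'   counts = c(A = 46, C = 5, G = 44, U = 5, `-` = 0), n = 100),
#'   class = "position_distribution")
#' classify(d)$code   # "R"
#' @export
classify <- function(dist, min_component = 0.05, min_total = 0.90) {
  stopifnot(min_component > 0, min_component <= 1,
            min_total > 0, min_total <= 1)
  if (dist$n == 0) stop("cannot classify an empty distribution (n = 0)")
  paired <- grepl(":", dist$target, fixed = TRUE)
  freq <- dist$counts / dist$n
  codes <- if (paired) .paired_codes else .single_codes
  tol <- 1e-9
  for (code in names(codes)) {
    if (.code_tier[[code]] == "none") next
    members <- codes[[code]]
    f <- freq[members]
    total_only <- code %in% c("PAIRED", "MISMATCHED")
    if (!total_only && any(f < min_component - tol)) next
    if (sum(f) >= min_total - tol) {
      return(.feature_code(code, if (paired) "paired" else "single"))
    }
  }
  .feature_code(if (paired) "NN" else "N", if (paired) "paired" else "single")
}

#' Consensus feature table for a gene selection
#'
#' Applies [classify()] to every canonical Sprinzl position and to every
#' pair in the pair table.  Positions participating in a pair keep their
#' single-position entry as well.
#'
#' @param genes A non-empty `trna_set`.
#' @param pair_table data.frame of pairs (default [default_pair_table()]).
#' @param min_component,min_total Thresholds passed to [classify()].
#' @return An object of class `consensus_table`: list with `single`
#'   (named character vector of codes per position), `single_tier`,
#'   `paired`, `paired_tier` (named by `"pos5:pos3"`), `n`, `thresholds`.
#' @export
consensus_table <- function(genes, pair_table = default_pair_table(),
                            min_component = 0.05, min_total = 0.90) {
  if (n_genes(genes) == 0) stop("empty gene selection; no consensus to compute")
  pair_table <- validate_pair_table(pair_table)
  vocab <- sprinzl_positions()
  single <- character(length(vocab)); stier <- character(length(vocab))
  for (k in seq_along(vocab)) {
    fc <- classify(position_distribution(genes, vocab[k]),
                   min_component, min_total)
    single[k] <- fc$code; stier[k] <- fc$tier
  }
  pk <- paste(pair_table$pos5, pair_table$pos3, sep = ":")
  paired <- character(length(pk)); ptier <- character(length(pk))
  for (k in seq_along(pk)) {
    fc <- classify(position_distribution(genes, pk[k]),
                   min_component, min_total)
    paired[k] <- fc$code; ptier[k] <- fc$tier
  }
  structure(list(
    single = stats::setNames(single, vocab),
    single_tier = stats::setNames(stier, vocab),
    paired = stats::setNames(paired, pk),
    paired_tier = stats::setNames(ptier, pk),
    n = n_genes(genes),
    thresholds = c(min_component = min_component, min_total = min_total)),
    class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("consensus_table over %d gene(s)\n", x$n))
  cat(sprintf("  single: %d zero / %d partial / %d high / %d no-call\n",
              sum(x$single_tier == "zero"), sum(x$single_tier == "partial"),
              sum(x$single_tier == "high"), sum(x$single_tier == "none")))
  cat(sprintf("  paired: %d zero / %d partial / %d high / %d no-call\n",
              sum(x$paired_tier == "zero"), sum(x$paired_tier == "partial"),
              sum(x$paired_tier == "high"), sum(x$paired_tier == "none")))
  invisible(x)
}

#' @export
as.data.frame.consensus_table <- function(x, ...) {
  rbind(
    data.frame(position = names(x$single), arity = "single",
               code = unname(x$single), tier = unname(x$single_tier),
               stringsAsFactors = FALSE),
    data.frame(position = names(x$paired), arity = "paired",
               code = unname(x$paired), tier = unname(x$paired_tier),
               stringsAsFactors = FALSE))
}

#' Per-isotype consensus tables (tilemap)
#'
#' @param genes A `trna_set`.
#' @param pair_table,min_component,min_total As in [consensus_table()].
#' @return Named list of `consensus_table`, one per isotype present (in
#'   sorted isotype order); isotypes with zero genes are simply absent.
#' @export
tilemap <- function(genes, pair_table = default_pair_table(),
                    min_component = 0.05, min_total = 0.90) {
  isos <- sort(unique(genes$meta$isotype))
  out <- lapply(isos, function(iso)
    consensus_table(genes[which(genes$meta$isotype == iso)],
                    pair_table, min_component, min_total))
  names(out) <- isos
  absent <- setdiff(ISOTYPES, isos)
  if (length(absent) > 0) {
    message("tilemap: no genes for isotype(s): ", paste(absent, collapse = ", "))
  }
  out
}

.one_verdict <- function(clade_code, domain_code, arity) {
  if (clade_code == domain_code) return("exact")
  if (clade_code %in% c("N", "NN") || domain_code %in% c("N", "NN")) {
    return("less_specific_or_different")
  }
  cs <- code_base_set(clade_code, arity)
  ds <- code_base_set(domain_code, arity)
  if (all(cs %in% ds) && length(cs) < length(ds)) "more_specific"
  else "less_specific_or_different"
}

#' Compare a clade's consensus against its domain's
#'
#' Per position (and pair): `exact` when the codes are equal,
#' `more_specific` when the clade's base set is a strict subset of the
#' domain's, and `less_specific_or_different` otherwise (superset,
#' overlapping, disjoint, or a no-call on either side only).
#'
#' @param clade_table,domain_table `consensus_table`s over identical
#'   position and pair sets.
#' @return data.frame (position, arity, clade_code, domain_code, verdict).
#' @export
compare_to_domain <- function(clade_table, domain_table) {
  if (!identical(names(clade_table$single), names(domain_table$single)) ||
      !identical(names(clade_table$paired), names(domain_table$paired))) {
    stop("consensus tables cover different position sets")
  }
  cd <- as.data.frame(clade_table)
  dd <- as.data.frame(domain_table)
  out <- data.frame(position = cd$position, arity = cd$arity,
                    clade_code = cd$code, domain_code = dd$code,
                    stringsAsFactors = FALSE)
  out$verdict <- mapply(.one_verdict, out$clade_code, out$domain_code,
                        out$arity, USE.NAMES = FALSE)
  out
}
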