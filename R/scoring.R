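#' Build a position-specific reference profile
#'
#' From a set of Sprinzl-aligned reference tRNAs, computes per-position
#' log-odds bit values for each of the five symbols (the four bases and
#' the gap, which models a deleted position):
#' \deqn{b(x,i) = \log_2\frac{(c(x,i)+\alpha)/(n+5\alpha)}{0.25}}
#' with Laplace pseudocount `alpha` over the 5-symbol alphabet and a flat
#' 0.25 background.  `r_i` is the maximum attainable bit value at position
#' i (attained by the modal symbol), so penalty scores derived from the
#' profile are never positive.
#'
#' @param ref_genes A non-empty `trna_set`, already Sprinzl-aligned.
#' @param alpha Pseudocount (default 1).
#' @return An object of class `trna_profile`: list with `bits` (5 x 98
#'   matrix, rows `A,C,G,U,-`), `r`, `modal`, `n_ref`, `alpha`.
#' @export
build_profile <- function(ref_genes, alpha = 1.0) {
  if (n_genes(ref_genes) == 0) stop("empty reference set; cannot build profile")
  stopifnot(alpha > 0)
  vocab <- sprinzl_positions()
  counts <- vapply(vocab, function(p)
    tabulate(match(ref_genes$aln[, p], SYMBOLS), length(SYMBOLS)),
    integer(length(SYMBOLS)))
  dimnames(counts) <- list(SYMBOLS, vocab)
  n <- n_genes(ref_genes)
  bits <- log2(((counts + alpha) / (n + 5 * alpha)) / 0.25)
  modal_idx <- apply(bits, 2, which.max)   # ties: first in SYMBOLS order
  structure(list(
    bits = bits,
    r = stats::setNames(bits[cbind(modal_idx, seq_along(vocab))], vocab),
    modal = stats::setNames(SYMBOLS[modal_idx], vocab),
    n_ref = n, alpha = alpha),
    class = "trna_profile")
}

#' @export
print.trna_profile <- function(x, ...) {
  cat(sprintf("trna_profile: %d reference gene(s), alpha = %g\n",
              x$n_ref, x$alpha))
  cat(sprintf("  modal sequence (%d non-gap positions): %s...\n",
              sum(x$modal != GAP),
              substr(modal_sequence(x), 1, 40)))
  invisible(x)
}

#' Modal (most frequent) sequence of a profile
#' @param profile A `trna_profile`.
#' @return The concatenation of the modal symbols at non-gap-modal
#'   positions, 5' to 3'.
#' @export
modal_sequence <- function(profile) {
  paste(profile$modal[profile$modal != GAP], collapse = "")
}

#' Global profile-to-sequence alignment (Gotoh-style)
#'
#' Aligns a raw sequence to a series of profile positions, maximizing the
#' total emission score: `bits[symbol, position]` for a matched position,
#' the profile's own gap-state value `bits["-", position]` for a deleted
#' (skipped) position, and affine penalties (`gap_open + k * gap_extend`
#' for a run of k, terminal runs included) for query symbols inserted
#' between positions.  Scoring deletions through the gap state keeps the
#' aligner consistent with the penalty model, in which a deleted position
#' is a rare symbol, not a structural gap: positions that are usually
#' absent in the reference are then skipped at no cost, exactly as the
#' reference sequences themselves skip them.  Tie-break is deterministic:
#' match is preferred over a deletion, and a deletion over an insertion,
#' which places gaps leftmost along the profile.
#'
#' @param bits Numeric matrix, rows = `A,C,G,U,-`, columns = profile
#'   positions (the `-` row supplies the deletion scores).
#' @param seq_chars Character vector of query symbols (A/C/G/U).
#' @param gap_open,gap_extend Affine insertion parameters in bits
#'   (defaults 4 and 1).
#' @return list with `assign` (integer vector over profile columns: index
#'   of the query symbol matched there, or NA for a deletion), `inserted`
#'   (integer indices of query symbols not matched to any position) and
#'   `score`.
#' @export
profile_align <- function(bits, seq_chars, gap_open = 4, gap_extend = 1) {
  np <- ncol(bits); nq <- length(seq_chars)
  qi <- match(seq_chars, SYMBOLS[1:4])
  if (anyNA(qi)) stop("query contains non-ACGU symbol(s)")
  NEG <- -1e18
  gaprow <- match(GAP, SYMBOLS)
  ## M: position i matched to char j; X: i deleted (scored by the gap
  ## state, no run structure); Y: char j inserted (affine)
  M <- matrix(NEG, np + 1, nq + 1)
  X <- matrix(NEG, np + 1, nq + 1)
  Y <- matrix(NEG, np + 1, nq + 1)
  M[1, 1] <- 0
  if (np > 0) X[2:(np + 1), 1] <- cumsum(bits[gaprow, 1:np])
  if (nq > 0) Y[1, 2:(nq + 1)] <- -gap_open - (1:nq) * gap_extend
  for (i in seq_len(np)) {
    bi <- bits[, i]
    for (j in seq_len(nq)) {
      M[i + 1, j + 1] <- bi[qi[j]] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- bi[gaprow] + max(M[i, j + 1], X[i, j + 1],
                                          Y[i, j + 1])
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             X[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
    }
  }
  score <- max(M[np + 1, nq + 1], X[np + 1, nq + 1], Y[np + 1, nq + 1])
  ## traceback; preference order M > X > Y realizes the documented tie-break
  assign <- rep(NA_integer_, np)
  inserted <- integer(0)
  i <- np; j <- nq
  state <- which.max(c(M[np + 1, nq + 1], X[np + 1, nq + 1], Y[np + 1, nq + 1]))
  eps <- 1e-9
  while (i > 0 || j > 0) {
    if (state == 1) {            # match i<->j
      assign[i] <- j
      prev <- c(M[i, j], X[i, j], Y[i, j])
      target <- M[i + 1, j + 1] - bits[qi[j], i]
      i <- i - 1; j <- j - 1
      state <- which(prev >= target - eps)[1]
    } else if (state == 2) {     # deletion of position i
      prev <- c(M[i, j + 1], X[i, j + 1], Y[i, j + 1])
      target <- X[i + 1, j + 1] - bits[gaprow, i]
      i <- i - 1
      state <- which(prev >= target - eps)[1]
    } else {                     # insertion of char j
      inserted <- c(j, inserted)
      prev <- c(M[i + 1, j] - gap_open - gap_extend,
                X[i + 1, j] - gap_open - gap_extend,
                Y[i + 1, j] - gap_extend)
      target <- Y[i + 1, j + 1]
      j <- j - 1
      state <- which(prev >= target - eps)[1]
    }
    if (i == 0 && j == 0) break
    if (i == 0 && state != 3) state <- 3
    if (j == 0 && state != 2 && i > 0) state <- 2
  }
  list(assign = assign, inserted = inserted, score = score)
}

#' Align and number a query tRNA against a reference profile
#'
#' Globally aligns a raw query sequence to the profile's Sprinzl position
#' series (see [profile_align()]) and returns a total position map:
#' deleted positions hold the gap symbol; query symbols inserted between
#' positions carry no Sprinzl label and are reported in the
#' `"insertions"` attribute.
#'
#' @param raw_seq A string over A/C/G/U (T accepted), length 50-120.
#' @param profile A `trna_profile`.
#' @param gap_open,gap_extend Affine insertion parameters (see
#'   [profile_align()]).  By default `gap_open` is derived from the
#'   profile: one bit more than the largest per-position substitution
#'   loss (`max_i (r_i - min_x b(x,i))`), so that relabelling a
#'   substituted base as an insertion can never pay; substitutions then
#'   stay at their Sprinzl position and only genuine extra residues
#'   become insertions.
#' @return Named character vector `label -> symbol` over the full
#'   canonical vocabulary, with attributes `"insertions"` (data.frame
#'   after_position, symbol) and `"score"`.
#' @export
align_query <- function(raw_seq, profile, gap_open = NULL, gap_extend = 1) {
  chars <- normalize_symbols(raw_seq, split = TRUE)
  if (any(chars == GAP)) stop("query sequence must be ungapped")
  if (length(chars) < 50 || length(chars) > 120) {
    stop("query length ", length(chars),
         " outside 50-120; not a plausible mature tRNA sequence")
  }
  if (is.null(gap_open)) {
    gap_open <- max(profile$r - apply(profile$bits, 2, min)) +
      1 - gap_extend
  }
  al <- profile_align(profile$bits, chars, gap_open, gap_extend)
  vocab <- sprinzl_positions()
  out <- stats::setNames(rep(GAP, length(vocab)), vocab)
  matched <- !is.na(al$assign)
  out[vocab[matched]] <- chars[al$assign[matched]]
  ins <- if (length(al$inserted) > 0) {
    after <- vapply(al$inserted, function(j) {
      prior <- which(matched & al$assign < j)
      if (length(prior) == 0) "" else vocab[max(prior)]
    }, character(1))
    data.frame(after_position = after, symbol = chars[al$inserted],
               stringsAsFactors = FALSE)
  } else {
    data.frame(after_position = character(0), symbol = character(0),
               stringsAsFactors = FALSE)
  }
  if (nrow(ins) > 0) {
    message(nrow(ins), " query symbol(s) inserted relative to the profile; ",
            "insertions carry no Sprinzl label and are excluded from ",
            "per-position penalties")
  }
  attr(out, "insertions") <- ins
  attr(out, "score") <- al$score
  out
}

#' Per-position penalty scores p = q - r
#'
#' For each Sprinzl position, the query's positional bit value
#' `q = b(query symbol, i)` minus the reference's maximal positional bit
#' value `r_i`.  The highest penalty a position can receive is zero, when
#' the query carries the modal reference symbol (or ties its bit value);
#' deleted positions are scored through the gap symbol's bit value, like
#' any rare symbol.
#'
#' @param profile A `trna_profile`.
#' @param aligned_query Named symbol vector over the canonical vocabulary
#'   (from [align_query()], or a row of a `trna_set` alignment).
#' @return Named numeric vector of penalties, all `<= 0`.
#' @export
penalties <- function(profile, aligned_query) {
  vocab <- sprinzl_positions()
  q <- profile$bits[cbind(match(aligned_query[vocab], SYMBOLS),
                          seq_along(vocab))]
  stats::setNames(q - unname(profile$r), vocab)
}

#' Mean penalties over a query group
#'
#' @param profile A `trna_profile`.
#' @param queries A `trna_set` (members used as aligned), or a list of
#'   aligned symbol vectors, or a character vector of raw sequences (each
#'   aligned with [align_query()] first).
#' @return Named numeric vector: arithmetic mean penalty per position.
#' @export
group_penalties <- function(profile, queries) {
  maps <- .query_maps(profile, queries)
  if (length(maps) == 0) stop("query group is empty")
  pm <- vapply(maps, function(m) penalties(profile, m),
               numeric(length(sprinzl_positions())))
  stats::setNames(rowMeans(pm), sprinzl_positions())
}

.query_maps <- function(profile, queries) {
  if (inherits(queries, "trna_set")) {
    lapply(seq_len(n_genes(queries)), function(i) queries$aln[i, ])
  } else if (is.character(queries)) {
    lapply(queries, align_query, profile = profile)
  } else {
    queries
  }
}

.modal_symbol <- function(symbols) {
  tb <- tabulate(match(symbols, SYMBOLS), length(SYMBOLS))
  SYMBOLS[which.max(tb)]
}

#' Bitchart rows: reference consensus, reference modal, query groups
#'
#' Row 1 carries the reference selection's consensus feature per position,
#' row 2 its most common symbol; each further row is one query group, with
#' the group's most common symbol at each position and the group's mean
#' penalty there.
#'
#' @param ref_genes A non-empty `trna_set` (the reference selection).
#' @param query_groups Named list; each element a `trna_set`, a character
#'   vector of raw sequences, or a list of aligned maps.  Empty groups are
#'   omitted with a warning.
#' @param min_component,min_total Consensus thresholds for row 1.
#' @param alpha Profile pseudocount.
#' @return data.frame (row_type, group, position, feature, mean_penalty)
#'   in canonical position order; `mean_penalty` is NA for the consensus
#'   and modal rows.
#' @export
bitchart <- function(ref_genes, query_groups = list(),
                     min_component = 0.05, min_total = 0.90, alpha = 1.0) {
  if (n_genes(ref_genes) == 0) stop("empty reference selection")
  vocab <- sprinzl_positions()
  profile <- build_profile(ref_genes, alpha)
  cons <- consensus_table(ref_genes, min_component = min_component,
                          min_total = min_total)
  rows <- list(
    data.frame(row_type = "consensus", group = "reference", position = vocab,
               feature = unname(cons$single), mean_penalty = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(row_type = "modal", group = "reference", position = vocab,
               feature = unname(profile$modal), mean_penalty = NA_real_,
               stringsAsFactors = FALSE))
  for (nm in names(query_groups)) {
    maps <- .query_maps(profile, query_groups[[nm]])
    if (length(maps) == 0) {
      warning("query group '", nm, "' is empty; row omitted")
      next
    }
    sym <- vapply(vocab, function(p)
      .modal_symbol(vapply(maps, function(m) m[[p]], character(1))),
      character(1))
    rows[[length(rows) + 1]] <- data.frame(
      row_type = "query", group = nm, position = vocab,
      feature = unname(sym),
      mean_penalty = unname(group_penalties(profile, maps)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
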