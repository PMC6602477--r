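#' A focus: annotation predicate on tRNA genes
#'
#' Restricts a selection by isotype, anticodon and/or a bit-score interval.
#' The score interval is half-open, `[score_min, score_max)`, so
#' complementary foci (e.g. ">= 55 bits" and "< 55 bits") partition a gene
#' set exactly.
#'
#' @param isotype,anticodon Optional exact-match values.
#' @param score_min,score_max Optional score bounds in bits.
#' @return An object of class `trna_focus`.
#' @export
focus <- function(isotype = NULL, anticodon = NULL,
                  score_min = NULL, score_max = NULL) {
  if (!is.null(score_min) && !is.null(score_max) && score_min > score_max) {
    stop("score_min must be <= score_max")
  }
  if (!is.null(anticodon)) {
    anticodon <- paste(normalize_symbols(anticodon, split = TRUE), collapse = "")
  }
  structure(list(isotype = isotype, anticodon = anticodon,
                 score_min = score_min, score_max = score_max),
            class = "trna_focus")
}

#' @export
print.trna_focus <- function(x, ...) {
  cat("focus:", focus_label(x), "\n")
  invisible(x)
}

#' Deterministic string form of a focus (for grouping and report keys)
#' @param f A `trna_focus`.
#' @return A single string.
#' @export
focus_label <- function(f) {
  parts <- c(
    if (!is.null(f$isotype)) paste0("isotype=", f$isotype),
    if (!is.null(f$anticodon)) paste0("anticodon=", f$anticodon),
    if (!is.null(f$score_min)) paste0("score>=", f$score_min),
    if (!is.null(f$score_max)) paste0("score<", f$score_max))
  if (length(parts) == 0) "all" else paste(parts, collapse = ",")
}

.matches_focus <- function(meta, f) {
  ok <- rep(TRUE, nrow(meta))
  if (!is.null(f$isotype)) ok <- ok & meta$isotype == f$isotype
  if (!is.null(f$anticodon)) ok <- ok & meta$anticodon == f$anticodon
  if (!is.null(f$score_min)) ok <- ok & meta$score_bits >= f$score_min
  if (!is.null(f$score_max)) ok <- ok & meta$score_bits < f$score_max
  ok
}

#' Select genes by clade group and focus
#'
#' A gene is included iff its species is a descendant of (or equal to) any
#' member clade and it satisfies the focus.  Overlapping member clades
#' (e.g. a clade and its subclade) never duplicate genes.
#'
#' @param genes A `trna_set`.
#' @param tax A `trna_taxonomy`.
#' @param clades Character vector of clade names or taxids (the members of
#'   one clade group); `NULL` selects all genes.
#' @param sel_focus A [focus()] (default: no restriction).
#' @return A `trna_set` (possibly empty, with a warning).
#' @export
select_genes <- function(genes, tax, clades = NULL, sel_focus = focus()) {
  keep <- .matches_focus(genes$meta, sel_focus)
  if (!is.null(clades)) {
    ok_sp <- unique(unlist(lapply(clades, function(cl)
      descendants(tax, find_clade(tax, cl)))))
    keep <- keep & genes$meta$species_taxid %in% ok_sp
  }
  if (!any(keep)) {
    warning("selection is empty (clades: ",
            if (is.null(clades)) "all" else paste(clades, collapse = "+"),
            "; focus: ", focus_label(sel_focus), ")")
  }
  genes[which(keep)]
}

.pair_keys <- function() {
  as.vector(t(outer(SYMBOLS, SYMBOLS, paste, sep = ":")))
}

.parse_target <- function(target) {
  if (length(target) == 1 && grepl(":", target, fixed = TRUE)) {
    target <- strsplit(target, ":", fixed = TRUE)[[1]]
  }
  target <- as.character(target)
  sprinzl_index(target)
  if (!(length(target) %in% 1:2)) stop("target must be one label or a pair")
  target
}

#' Symbol counts at a Sprinzl position or position pair
#'
#' For a single position, counts of the five symbols (gap included); for a
#' pair, counts of the 25 ordered symbol pairs keyed `"X:Y"` (5' base :
#' 3' base).  Counts always sum to the number of genes.
#'
#' @param genes A `trna_set`.
#' @param target A label (`"34"`), a pair (`c("3","70")` or `"3:70"`).
#' @return An object of class `position_distribution`: list with `target`,
#'   `counts` (named integer vector over all keys), `n`.
#' @export
position_distribution <- function(genes, target) {
  target <- .parse_target(target)
  if (length(target) == 1) {
    obs <- genes$aln[, target]
    keys <- SYMBOLS
  } else {
    obs <- paste(genes$aln[, target[1]], genes$aln[, target[2]], sep = ":")
    keys <- .pair_keys()
  }
  counts <- stats::setNames(tabulate(match(obs, keys), length(keys)), keys)
  structure(list(target = paste(target, collapse = ":"),
                 counts = counts, n = length(obs)),
            class = "position_distribution")
}

#' Build a position distribution from explicit counts
#'
#' Convenience constructor for synthetic distributions (threshold sweeps,
#' classification tests) without materializing genes.  Keys absent from
#' `counts` are zero-filled.
#'
#' @param counts Named non-negative integer vector over symbols (single
#'   target) or `"X:Y"` pair keys (paired target).
#' @param target Label or pair the distribution describes.
#' @return A `position_distribution` with `n = sum(counts)`.
#' @export
as_position_distribution <- function(counts, target) {
  target <- .parse_target(target)
  keys <- if (length(target) == 1) SYMBOLS else .pair_keys()
  bad <- setdiff(names(counts), keys)
  if (length(bad) > 0) stop("invalid count key(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("counts must be non-negative")
  full <- stats::setNames(rep(0L, length(keys)), keys)
  full[names(counts)] <- as.integer(round(counts))
  structure(list(target = paste(target, collapse = ":"),
                 counts = full, n = sum(full)),
            class = "position_distribution")
}

#' @export
print.position_distribution <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat(sprintf("position %s (n=%d): %s\n", x$target, x$n,
              paste(sprintf("%s=%d", names(nz), nz), collapse = " ")))
  invisible(x)
}

#' Relative frequencies of a position distribution
#' @param dist A `position_distribution` (n must be positive).
#' @return Named numeric vector summing to 1.
#' @export
frequencies <- function(dist) {
  if (dist$n == 0) stop("empty distribution (n = 0); nothing to normalize")
  dist$counts / dist$n
}

#' Gene counts of a clade relative to its ancestors
#'
#' One row per ancestor from the selected clade up to its domain.  `count`
#' is the number of genes whose species lies in that ancestor; `fraction`
#' is the selected clade's share of the ancestor's count (1 at the clade
#' itself; at the domain row, the clade's contribution to the domain).
#'
#' @param genes A `trna_set`.
#' @param tax A `trna_taxonomy`.
#' @param clade Clade name or taxid.
#' @return data.frame with columns clade, rank, count, fraction.
#' @export
taxonomy_summary <- function(genes, tax, clade) {
  cl <- find_clade(tax, clade)
  anc <- lineage(tax, cl)
  counts <- vapply(anc, function(a)
    sum(genes$meta$species_taxid %in% descendants(tax, a)), integer(1))
  data.frame(
    clade = tax$name[match(anc, tax$taxid)],
    rank = tax$rank[match(anc, tax$taxid)],
    count = unname(counts),
    fraction = if (counts[1] == 0) rep(NA_real_, length(anc))
               else unname(counts[1] / counts),
    stringsAsFactors = FALSE)
}

#' Anticodon counts by isotype
#'
#' @param genes A `trna_set`.
#' @return data.frame (isotype, anticodon, count), sorted by isotype then
#'   anticodon; zero cells omitted.
#' @export
anticodon_counts <- function(genes) {
  m <- genes$meta
  tb <- as.data.frame(table(isotype = m$isotype, anticodon = m$anticodon),
                      stringsAsFactors = FALSE)
  names(tb)[3] <- "count"
  tb <- tb[tb$count > 0, , drop = FALSE]
  tb <- tb[order(tb$isotype, tb$anticodon), , drop = FALSE]
  rownames(tb) <- NULL
  tb$count <- as.integer(tb$count)
  tb
}

#' Bit-score summary statistics by group
#'
#' @param genes A `trna_set`.
#' @param group_by `"isotype"`, `"anticodon"` or `"subclade"` (direct
#'   children of `clade`; genes are assigned to the child whose subtree
#'   contains their species).
#' @param tax,clade Required for `group_by = "subclade"`.
#' @return data.frame (group, n, min, mean, max); empty groups omitted,
#'   sorted by group.
#' @export
score_stats <- function(genes, group_by = c("isotype", "anticodon", "subclade"),
                        tax = NULL, clade = NULL) {
  group_by <- match.arg(group_by)
  m <- genes$meta
  if (group_by == "subclade") {
    if (is.null(tax) || is.null(clade)) {
      stop("group_by = 'subclade' needs tax and clade")
    }
    cl <- find_clade(tax, clade)
    kids <- tax$taxid[tax$parent_taxid == cl]
    g <- rep(NA_character_, nrow(m))
    for (k in kids) {
      g[m$species_taxid %in% descendants(tax, k)] <-
        tax$name[match(k, tax$taxid)]
    }
    keep <- !is.na(g)
    m <- m[keep, , drop = FALSE]; g <- g[keep]
  } else {
    g <- m[[group_by]]
  }
  if (nrow(m) == 0) {
    return(data.frame(group = character(0), n = integer(0), min = numeric(0),
                      mean = numeric(0), max = numeric(0)))
  }
  sp <- split(m$score_bits, g)
  out <- data.frame(
    group = names(sp),
    n = vapply(sp, length, integer(1)),
    min = vapply(sp, min, numeric(1)),
    mean = vapply(sp, mean, numeric(1)),
    max = vapply(sp, max, numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
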