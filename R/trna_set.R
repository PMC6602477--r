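## The 20 standard isotypes and a representative anticodon for each,
## used by the synthetic generator when only an isotype is assigned.
ISOTYPES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val")

ISOTYPE_ANTICODON <- c(
  Ala = "AGC", Arg = "ACG", Asn = "GUU", Asp = "GUC", Cys = "GCA",
  Gln = "UUG", Glu = "UUC", Gly = "GCC", His = "GUG", Ile = "AAU",
  Leu = "CAG", Lys = "CUU", Met = "CAU", Phe = "GAA", Pro = "AGG",
  Ser = "AGA", Thr = "AGU", Trp = "CCA", Tyr = "GUA", Val = "AAC")

FLAG_COLS <- c("pseudogene", "truncated", "numt", "chordate_non_high_confidence")

#' Build an aligned symbol matrix from partial position maps
#'
#' Positions not mentioned for a gene are filled with the gap symbol, so the
#' result is always total over the canonical Sprinzl vocabulary.
#'
#' @param maps Named list (one element per gene) of named character vectors
#'   `label -> symbol`.
#' @return Character matrix, rows = genes, columns = [sprinzl_positions()].
#' @export
aligned_matrix <- function(maps) {
  vocab <- sprinzl_positions()
  m <- matrix(GAP, nrow = length(maps), ncol = length(vocab),
              dimnames = list(names(maps), vocab))
  for (i in seq_along(maps)) {
    mp <- maps[[i]]
    if (length(mp) == 0) next
    sprinzl_index(names(mp))
    m[i, names(mp)] <- normalize_symbols(unname(mp))
  }
  m
}

#' A set of annotated, Sprinzl-aligned tRNA genes
#'
#' The central container of the package.  `meta` is one row per gene with
#' identity, taxonomy and annotation columns; `aln` is the aligned sequence
#' matrix over the full canonical Sprinzl vocabulary (gap symbol `-` at
#' absent positions).
#'
#' @param meta data.frame with columns `gene_id`, `species_taxid`,
#'   `isotype`, `anticodon`, `score_bits`, the logical flag columns
#'   `pseudogene`, `truncated`, `numt`, `chordate_non_high_confidence`
#'   (missing flag columns are filled with `FALSE`) and optionally `domain`.
#' @param aln Character matrix of symbols, rows matching `meta$gene_id`,
#'   columns exactly [sprinzl_positions()]; or a named list of partial
#'   position maps (see [aligned_matrix()]).
#' @return An object of class `trna_set`.
#' @details Anticodons are annotations, not re-derived from sequence: if a
#'   gene's anticodon disagrees with its aligned positions 34-36 (all
#'   non-gap), a warning is raised but the annotation is kept.
#' @export
trna_set <- function(meta, aln) {
  stopifnot(is.data.frame(meta))
  req <- c("gene_id", "species_taxid", "isotype", "anticodon", "score_bits")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0) stop("meta lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$gene_id)) {
    stop("duplicate gene_id(s): ",
         paste(unique(meta$gene_id[duplicated(meta$gene_id)]), collapse = ", "))
  }
  meta$gene_id <- as.character(meta$gene_id)
  meta$species_taxid <- as.character(meta$species_taxid)
  for (fc in FLAG_COLS) {
    if (is.null(meta[[fc]])) meta[[fc]] <- FALSE
    meta[[fc]] <- as.logical(meta[[fc]])
  }
  if (is.null(meta$domain)) meta$domain <- NA_character_
  bad <- setdiff(unique(meta$isotype), ISOTYPES)
  if (length(bad) > 0) stop("unknown isotype(s): ", paste(bad, collapse = ", "))
  meta$anticodon <- vapply(meta$anticodon, function(a)
    paste(normalize_symbols(a, split = TRUE), collapse = ""), character(1))
  if (any(nchar(meta$anticodon) != 3L) || any(grepl("-", meta$anticodon, fixed = TRUE))) {
    stop("anticodons must be 3 bases over A/C/G/U")
  }
  if (is.list(aln) && !is.matrix(aln)) aln <- aligned_matrix(aln)
  stopifnot(is.matrix(aln))
  if (!identical(colnames(aln), sprinzl_positions())) {
    stop("alignment columns must be exactly the canonical Sprinzl vocabulary")
  }
  if (nrow(aln) != nrow(meta)) stop("meta and aln disagree on gene count")
  rownames(aln) <- meta$gene_id
  aln[] <- normalize_symbols(c(aln))
  ac_obs <- apply(aln[, c("34", "35", "36"), drop = FALSE], 1, paste, collapse = "")
  full <- !grepl("-", ac_obs, fixed = TRUE)
  dis <- full & ac_obs != meta$anticodon
  if (any(dis)) {
    warning("annotated anticodon differs from aligned positions 34-36 for: ",
            paste(utils::head(meta$gene_id[dis], 5), collapse = ", "),
            if (sum(dis) > 5) sprintf(" (+%d more)", sum(dis) - 5) else "")
  }
  rownames(meta) <- NULL
  structure(list(meta = meta, aln = aln), class = "trna_set")
}

#' @export
print.trna_set <- function(x, ...) {
  cat(sprintf("trna_set: %d gene(s), %d Sprinzl positions\n",
              nrow(x$meta), ncol(x$aln)))
  iso <- sort(table(x$meta$isotype), decreasing = TRUE)
  cat("isotypes:", paste(sprintf("%s(%d)", names(iso), iso), collapse = " "), "\n")
  if (nrow(x$meta) > 0) {
    cat(sprintf("score_bits: %.1f-%.1f (mean %.1f)\n",
                min(x$meta$score_bits), max(x$meta$score_bits),
                mean(x$meta$score_bits)))
  }
  invisible(x)
}

#' @export
`[.trna_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$gene_id)
  structure(list(meta = x$meta[i, , drop = FALSE],
                 aln = x$aln[i, , drop = FALSE]),
            class = "trna_set")
}

#' @export
length.trna_set <- function(x) nrow(x$meta)

#' Number of genes in a trna_set
#' @param x A `trna_set`.
#' @return Integer count.
#' @export
n_genes <- function(x) nrow(x$meta)

#' Combine tRNA sets
#' @param ... `trna_set` objects with disjoint gene ids.
#' @return A `trna_set`.
#' @export
c.trna_set <- function(...) {
  parts <- list(...)
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  aln <- do.call(rbind, lapply(parts, `[[`, "aln"))
  rownames(meta) <- NULL
  trna_set(meta, aln)
}

#' Assemble a trna_set from parsed inputs
#'
#' Joins a Sprinzl alignment (from [read_stockholm()]), gene annotations
#' (from [read_trnascan_table()]) and a taxonomy into one `trna_set`.
#' Species are taken from `species`, or, by default, from the gene-id
#' convention `<taxid>.trna<N>` used by the fixture writer.  The `domain`
#' column is derived from the taxonomy.
#'
#' @param aligned Named list of position maps or an aligned matrix.
#' @param annotations data.frame from [read_trnascan_table()].
#' @param taxonomy A `trna_taxonomy`.
#' @param species Optional named character vector `gene_id -> taxid`.
#' @return A `trna_set`.
#' @export
assemble_trna_set <- function(aligned, annotations, taxonomy, species = NULL) {
  if (is.list(aligned) && !is.matrix(aligned)) aligned <- aligned_matrix(aligned)
  ids <- rownames(aligned)
  ann <- annotations[match(ids, annotations$gene_id), , drop = FALSE]
  if (anyNA(ann$gene_id)) {
    stop("aligned gene(s) missing from annotation table: ",
         paste(ids[is.na(ann$gene_id)], collapse = ", "))
  }
  if (is.null(species)) {
    species <- stats::setNames(sub("\\.trna[0-9]+$", "", ids), ids)
  }
  ann$species_taxid <- unname(species[ids])
  ann$domain <- vapply(ann$species_taxid, function(tx)
    domain_of(taxonomy, tx), character(1))
  trna_set(ann, aligned)
}
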