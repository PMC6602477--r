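#' Curation-filter rule order
#'
#' The six curation rules, in the fixed order used for attribution when a
#' gene trips more than one: (i) Chordata genes outside the high-confidence
#' set, (ii) predicted pseudogenes, (iii) predicted truncations, (iv) fungal
#' genes below the fungal score cutoff, (v) all other genes below the
#' general score cutoff, (vi) NUMT-derived predictions.
#'
#' @return Character vector `c("i","ii","iii","iv","v","vi")`.
#' @export
rule_order <- function() c("i", "ii", "iii", "iv", "v", "vi")

#' Apply the six-rule curation filter
#'
#' Removes genes unlikely to act in cytosolic translation: (i) Chordata
#' genes flagged `chordate_non_high_confidence`; (ii) pseudogenes; (iii)
#' truncated genes; (iv) fungal genes with `score_bits` strictly below
#' `fungal_min_score`; (v) non-fungal genes strictly below
#' `other_min_score`; (vi) NUMT-flagged genes.  "Below" is a strict
#' inequality, so a fungal gene at exactly the fungal cutoff is kept.
#' Chordata and Fungi membership is resolved by walking each species'
#' lineage in `tax`; a gene whose taxid does not resolve is an error (the
#' filter never guesses lineage).  A gene matching several rules is
#' attributed to the first in [rule_order()].
#'
#' @param genes A `trna_set`.
#' @param tax A `trna_taxonomy` resolving every gene's species.
#' @param fungal_min_score Fungal cutoff in bits (default 50).
#' @param other_min_score General cutoff in bits (default 25).
#' @param fungal_clade,chordate_clade Clade names looked up in `tax`; if a
#'   name is absent from the taxonomy no gene is considered a member.
#' @return A list with elements `kept` (a `trna_set`) and `report` (a
#'   `filter_report`: input_count, kept_count, removed per rule,
#'   per_gene_outcome).
#' @export
apply_filters <- function(genes, tax, fungal_min_score = 50,
                          other_min_score = 25, fungal_clade = "Fungi",
                          chordate_clade = "Chordata") {
  m <- genes$meta
  unresolved <- m$gene_id[!(m$species_taxid %in% tax$taxid)]
  if (length(unresolved) > 0) {
    stop("species taxid unresolvable in taxonomy for gene(s): ",
         paste(unresolved, collapse = ", "))
  }
  member <- function(clade) {
    if (!(clade %in% tax$taxid || clade %in% tax$name))
      return(rep(FALSE, nrow(m)))
    sp <- unique(m$species_taxid)
    hit <- stats::setNames(in_clade(tax, sp, clade), sp)
    unname(hit[m$species_taxid])
  }
  fungal <- member(fungal_clade)
  chordate <- member(chordate_clade)
  hits <- cbind(
    i   = chordate & m$chordate_non_high_confidence,
    ii  = m$pseudogene,
    iii = m$truncated,
    iv  = fungal & m$score_bits < fungal_min_score,
    v   = !fungal & m$score_bits < other_min_score,
    vi  = m$numt)
  first <- apply(hits, 1, function(h) {
    w <- which(h)
    if (length(w) == 0) "kept" else rule_order()[w[1]]
  })
  kept_idx <- which(first == "kept")
  removed <- vapply(rule_order(), function(r) sum(first == r), integer(1))
  report <- structure(list(
    input_count = nrow(m),
    kept_count = length(kept_idx),
    removed = removed,
    per_gene_outcome = stats::setNames(first, m$gene_id)),
    class = "filter_report")
  list(kept = genes[kept_idx], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in, %d kept, %d removed\n",
              x$input_count, x$kept_count, sum(x$removed)))
  for (r in names(x$removed)) {
    if (x$removed[[r]] > 0) cat(sprintf("  rule %-3s removed %d\n", r, x$removed[[r]]))
  }
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(rule = names(x$removed), removed = unname(x$removed),
             stringsAsFactors = FALSE)
}
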