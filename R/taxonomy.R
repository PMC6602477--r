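RANKS <- c("domain", "kingdom", "phylum", "class", "order", "family",
           "genus", "species", "assembly")

#' Construct a validated taxonomy tree
#'
#' Parent links must form a tree rooted at a single virtual root (`ROOT`)
#' whose children are the domains.  Orphans (a parent taxid absent from the
#' table), duplicate taxids and cycles are errors.
#'
#' @param df data.frame with character columns `taxid`, `name`, `rank`,
#'   `parent_taxid` (`ROOT` marks a domain row).
#' @return An object of class `trna_taxonomy` (the validated data.frame).
#' @export
taxonomy <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("taxid", "name", "rank", "parent_taxid") %in% names(df)))
  df <- df[, c("taxid", "name", "rank", "parent_taxid")]
  for (cc in names(df)) df[[cc]] <- as.character(df[[cc]])
  if (anyDuplicated(df$taxid)) {
    stop("duplicate taxid(s): ",
         paste(unique(df$taxid[duplicated(df$taxid)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$rank), RANKS)
  if (length(bad) > 0) stop("unknown rank(s): ", paste(bad, collapse = ", "))
  roots <- df$taxid[df$parent_taxid == "ROOT"]
  if (length(roots) == 0) stop("no domain rows (parent ROOT) found")
  if (any(df$rank[df$parent_taxid == "ROOT"] != "domain")) {
    stop("rows with parent ROOT must have rank 'domain'")
  }
  orphan <- df$taxid[df$parent_taxid != "ROOT" &
                     !(df$parent_taxid %in% df$taxid)]
  if (length(orphan) > 0) {
    stop("orphan row(s), parent not in table: ", paste(orphan, collapse = ", "))
  }
  ## cycle check: every node must reach ROOT
  parent <- stats::setNames(df$parent_taxid, df$taxid)
  for (tx in df$taxid) {
    seen <- character(0); cur <- tx
    while (cur != "ROOT") {
      if (cur %in% seen) stop("cycle detected involving taxid ", cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("trna_taxonomy", "data.frame"))
}

#' @export
print.trna_taxonomy <- function(x, ...) {
  cat(sprintf("trna_taxonomy: %d node(s), %d domain(s)\n",
              nrow(x), sum(x$parent_taxid == "ROOT")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Resolve a clade by taxid or name
#' @param tax A `trna_taxonomy`.
#' @param clade Taxid or unique clade name.
#' @return The clade's taxid.
#' @export
find_clade <- function(tax, clade) {
  clade <- as.character(clade)
  if (clade %in% tax$taxid) return(clade)
  hit <- tax$taxid[tax$name == clade]
  if (length(hit) == 0) stop("clade not found in taxonomy: ", clade)
  if (length(hit) > 1) stop("clade name is ambiguous: ", clade)
  hit
}

#' Lineage of a node
#' @param tax A `trna_taxonomy`.
#' @param taxid Node taxid.
#' @return Character vector of taxids from the node up to its domain.
#' @export
lineage <- function(tax, taxid) {
  parent <- stats::setNames(tax$parent_taxid, tax$taxid)
  if (!(taxid %in% tax$taxid)) stop("taxid not in taxonomy: ", taxid)
  out <- character(0); cur <- taxid
  while (cur != "ROOT") {
    out <- c(out, cur)
    cur <- parent[[cur]]
  }
  out
}

#' Descendant taxids of a clade (including itself)
#' @param tax A `trna_taxonomy`.
#' @param taxid Clade taxid.
#' @return Character vector of taxids.
#' @export
descendants <- function(tax, taxid) {
  if (!(taxid %in% tax$taxid)) stop("taxid not in taxonomy: ", taxid)
  out <- taxid
  frontier <- taxid
  while (length(frontier) > 0) {
    kids <- tax$taxid[tax$parent_taxid %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Species/assembly leaves under a clade
#' @param tax A `trna_taxonomy`.
#' @param clade Taxid or name.
#' @return Taxids of rank species or assembly under (or equal to) the clade.
#' @export
subtree_species <- function(tax, clade) {
  cl <- find_clade(tax, clade)
  d <- descendants(tax, cl)
  d[tax$rank[match(d, tax$taxid)] %in% c("species", "assembly")]
}

#' Domain of a species
#' @param tax A `trna_taxonomy`.
#' @param taxid Any node taxid.
#' @return The domain name (e.g. "Eukaryota").
#' @export
domain_of <- function(tax, taxid) {
  lin <- lineage(tax, taxid)
  tax$name[match(lin[length(lin)], tax$taxid)]
}

#' Is a species inside a clade?
#' @param tax A `trna_taxonomy`.
#' @param taxid Node taxid(s).
#' @param clade Clade taxid or name.
#' @return Logical vector.
#' @export
in_clade <- function(tax, taxid, clade) {
  cl <- find_clade(tax, clade)
  vapply(taxid, function(tx) cl %in% lineage(tax, tx), logical(1))
}

#' Read a taxonomy TSV
#'
#' Expects tab-separated columns `taxid`, `name`, `rank`, `parent_taxid`
#' with a header row; domain rows carry parent `ROOT`.
#'
#' @param path File path.
#' @return A `trna_taxonomy`.
#' @export
read_taxonomy_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "#")
  taxonomy(df)
}

#' Write a taxonomy TSV
#' @param tax A `trna_taxonomy`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_tsv <- function(tax, path) {
  utils::write.table(as.data.frame(tax), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.newick_quote <- function(x) {
  if (grepl("[][():;,'\" \t]", x)) {
    paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  } else x
}

#' Export a clade subtree as Newick
#'
#' Builds a Newick string for the subtree rooted at `clade`: leaves are the
#' species/assembly descendants, internal nodes are labelled with clade
#' names (reserved characters quoted).
#'
#' @param tax A `trna_taxonomy`.
#' @param clade Clade taxid or name.
#' @return A single Newick string, terminated by `;`.
#' @export
write_newick <- function(tax, clade) {
  cl <- find_clade(tax, clade)
  rec <- function(tx) {
    nm <- .newick_quote(tax$name[match(tx, tax$taxid)])
    kids <- tax$taxid[tax$parent_taxid == tx]
    if (length(kids) == 0) return(nm)
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
           ")", nm)
  }
  body <- rec(cl)
  kids <- tax$taxid[tax$parent_taxid == cl]
  ## a clade that is itself a leaf still yields a valid one-leaf tree
  if (length(kids) == 0) body <- paste0("(", body, ")")
  paste0(body, ";")
}
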