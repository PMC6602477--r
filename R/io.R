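#' Read a Sprinzl-dialect Stockholm alignment
#'
#' The dialect carries exactly one per-column reference-annotation line
#' (`#=GC RF`) in which `x` marks a match column and `.` an insert column.
#' The k-th match column maps to the k-th canonical Sprinzl label, so the
#' match-column count must equal the vocabulary length; anything else is a
#' dialect error naming both counts.  Residues falling in insert columns
#' are not part of any position map; they are collected in the
#' `"insertions"` attribute and reported.
#'
#' @param path Stockholm file (single or interleaved blocks).
#' @return Named list of total position maps (`label -> symbol`), one per
#'   sequence, with attribute `"insertions"` (data.frame gene_id, column,
#'   symbol).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  seqs <- list()
  rf <- character(0)
  block_ids <- character(0)   # ids seen in the current interleaved block
  for (ln in lines) {
    if (ln == "" || ln == "//") { block_ids <- character(0); next }
    if (startsWith(ln, "#=GC RF")) {
      rf <- c(rf, sub("^#=GC RF\\s+", "", ln))
      next
    }
    if (startsWith(ln, "#")) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) != 2) stop("malformed Stockholm sequence line: ", ln)
    if (f[1] %in% block_ids) stop("duplicate sequence id: ", f[1])
    block_ids <- c(block_ids, f[1])
    seqs[[f[1]]] <- c(seqs[[f[1]]], f[2])
  }
  if (length(rf) == 0) stop("no #=GC RF match-column annotation line found")
  rf <- strsplit(paste(rf, collapse = ""), "")[[1]]
  vocab <- sprinzl_positions()
  match_cols <- which(rf == "x")
  if (length(match_cols) != length(vocab)) {
    stop(sprintf(
      "Sprinzl dialect error: %d match columns in file, %d canonical labels expected",
      length(match_cols), length(vocab)))
  }
  ins <- list()
  out <- lapply(names(seqs), function(id) {
    chars <- strsplit(paste(seqs[[id]], collapse = ""), "")[[1]]
    if (length(chars) != length(rf)) {
      stop(sprintf("sequence %s has %d columns, annotation has %d",
                   id, length(chars), length(rf)))
    }
    chars <- normalize_symbols(chars)
    insv <- which(rf != "x" & chars != GAP)
    if (length(insv) > 0) {
      ins[[id]] <<- data.frame(gene_id = id, column = insv,
                               symbol = chars[insv], stringsAsFactors = FALSE)
    }
    stats::setNames(chars[match_cols], vocab)
  })
  names(out) <- names(seqs)
  insdf <- if (length(ins) > 0) do.call(rbind, ins) else
    data.frame(gene_id = character(0), column = integer(0),
               symbol = character(0), stringsAsFactors = FALSE)
  rownames(insdf) <- NULL
  if (nrow(insdf) > 0) {
    message(nrow(insdf), " insert-column residue(s) recorded outside the ",
            "Sprinzl position maps")
  }
  attr(out, "insertions") <- insdf
  out
}

#' Write a Sprinzl-dialect Stockholm alignment
#' @param genes A `trna_set` (or an aligned matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(genes, path) {
  aln <- if (inherits(genes, "trna_set")) genes$aln else genes
  if (nrow(aln) == 0) stop("refusing to write an empty alignment")
  ids <- rownames(aln)
  w <- max(nchar(ids)) + 2L
  lines <- c("# STOCKHOLM 1.0",
             sprintf("%-*s%s", w, ids, apply(aln, 1, paste, collapse = "")),
             sprintf("%-*s%s", w, "#=GC RF",
                     paste(rep("x", ncol(aln)), collapse = "")),
             "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a tRNAscan-SE tabular output file
#'
#' Parses the classic tab-delimited format (header lines, then columns
#' name, tRNA#, begin, end, isotype, anticodon, intron begin, intron end,
#' score, note).  Anticodons are T-to-U normalized.  Flags are parsed from
#' the note field by case-insensitive substring: `pseudo` -> pseudogene,
#' `trunc` -> truncated, `numt` -> numt, `not high confidence` ->
#' chordate_non_high_confidence; NUMTs may alternatively be supplied as a
#' sidecar id list.  Records with an isotype outside `allowed_isotypes`
#' are skipped with a warning.
#'
#' @param path File path.
#' @param numt_ids Optional character vector of gene ids to flag as NUMT.
#' @param allowed_isotypes Isotype vocabulary (defaults to the 20 standard
#'   amino-acid names; extend to accept e.g. SeC or iMet rows).
#' @return data.frame with columns gene_id, isotype, anticodon, begin, end,
#'   score_bits, note and the four logical flag columns.
#' @export
read_trnascan_table <- function(path, numt_ids = NULL,
                                allowed_isotypes = ISOTYPES) {
  lines <- readLines(path)
  keep <- !grepl("^(Sequence|Name|-----|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t")
  recs <- vector("list", length(rows))
  skipped <- character(0)
  for (k in seq_along(rows)) {
    f <- trimws(rows[[k]])
    if (length(f) < 9) stop("line ", lineno[k], ": expected >= 9 tab-separated fields")
    score <- suppressWarnings(as.numeric(f[9]))
    if (is.na(score)) stop("line ", lineno[k], ": unparseable score '", f[9], "'")
    iso <- f[5]
    if (!(iso %in% allowed_isotypes)) {
      skipped <- c(skipped, sprintf("%s (isotype %s, line %d)", f[1], iso, lineno[k]))
      next
    }
    note <- if (length(f) >= 10) tolower(f[10]) else ""
    id <- paste0(f[1], ".trna", f[2])
    recs[[k]] <- data.frame(
      gene_id = id,
      isotype = iso,
      anticodon = paste(normalize_symbols(f[6], split = TRUE), collapse = ""),
      begin = as.integer(f[3]), end = as.integer(f[4]),
      score_bits = score,
      pseudogene = grepl("pseudo", note, fixed = TRUE),
      truncated = grepl("trunc", note, fixed = TRUE),
      numt = grepl("numt", note, fixed = TRUE) || (id %in% numt_ids),
      chordate_non_high_confidence = grepl("not high confidence", note, fixed = TRUE),
      note = note, stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0) {
    warning("skipped record(s) with unknown isotype: ",
            paste(skipped, collapse = "; "))
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(gene_id = character(0))
  rownames(out) <- NULL
  out
}

#' Write a tRNAscan-SE-style tabular file
#' @param genes A `trna_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trnascan_table <- function(genes, path) {
  m <- genes$meta
  sp <- sub("\\.trna[0-9]+$", "", m$gene_id)
  num <- sub("^.*\\.trna", "", m$gene_id)
  note <- mapply(function(p, t, n, h)
    paste(c(if (p) "pseudo", if (t) "trunc", if (n) "numt",
            if (h) "not high confidence"), collapse = ","),
    m$pseudogene, m$truncated, m$numt, m$chordate_non_high_confidence)
  len <- rowSums(genes$aln != GAP)
  hdr <- c(paste("Sequence", "tRNA", "Bounds", "Bounds", "tRNA", "Anti",
                 "Intron", "Intron", "Inf", "", sep = "\t"),
           paste("Name", "#", "Begin", "End", "Type", "Codon", "Begin",
                 "End", "Score", "Note", sep = "\t"),
           paste(rep("--------", 10), collapse = "\t"))
  body <- paste(sp, num, 1L, len, m$isotype, chartr("U", "T", m$anticodon),
                0L, 0L, sprintf("%.1f", m$score_bits), note, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read query tRNA sequences from FASTA
#'
#' T is normalized to U; any other non-ACGU character is an error naming
#' the offending record.
#'
#' @param path FASTA file.
#' @return Named character vector of RNA sequences, in file order.
#' @export
read_fasta_trna <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop("non-ACGT/U character(s) in FASTA record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  ## Biostrings keeps full header lines as names; use the first token
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  seqs
}

.format_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15, format(x, scientific = FALSE, trim = TRUE),
                formatC(x, digits = 6, format = "g")))
}

#' Export tables as TSV or JSON
#'
#' Deterministic export: column order is preserved as given, floats are
#' serialized with 6 significant digits, and repeated calls on the same
#' input produce byte-identical files.  The JSON layout (an object with a
#' `meta` header and a `tables` map of row arrays) is described by the
#' schema shipped at `inst/extdata/export-schema.json`.
#'
#' @param tables A data.frame, or a named list of data.frames.
#' @param format `"tsv"` or `"json"`.  TSV output of a multi-table list
#'   concatenates the tables, each preceded by a `## table:` marker line.
#' @param path Output path.
#' @param meta Optional named character vector recorded as a provenance
#'   header (comment lines for TSV, `meta` object for JSON).
#' @return `path`, invisibly.
#' @export
write_export <- function(tables, format = c("tsv", "json"), path, meta = NULL) {
  format <- match.arg(format)
  if (is.data.frame(tables)) tables <- list(table = tables)
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  fmt_df <- function(df) {
    for (cc in names(df)) {
      if (is.numeric(df[[cc]]) && !is.integer(df[[cc]])) {
        df[[cc]] <- .format_num(df[[cc]])
      }
    }
    df
  }
  if (format == "tsv") {
    con <- file(path, open = "wb")  # binary: stable newlines across platforms
    on.exit(close(con))
    wl <- function(x) writeLines(x, con, sep = "\n")
    for (nm in names(meta)) wl(sprintf("# %s: %s", nm, meta[[nm]]))
    for (nm in names(tables)) {
      if (length(tables) > 1) wl(paste0("## table: ", nm))
      df <- fmt_df(tables[[nm]])
      wl(paste(names(df), collapse = "\t"))
      if (nrow(df) > 0) {
        wl(do.call(paste, c(lapply(df, as.character), sep = "\t")))
      }
    }
  } else {
    obj <- list(meta = as.list(meta),
                tables = lapply(tables, function(df) {
                  for (cc in names(df)) {
                    if (is.numeric(df[[cc]]) && !is.integer(df[[cc]]))
                      df[[cc]] <- signif(df[[cc]], 6)
                  }
                  df
                }))
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Check an exported JSON file against the shipped schema
#'
#' A minimal structural validator (required keys and JSON types) for the
#' export layout; see `inst/extdata/export-schema.json`.
#'
#' @param path JSON file written by [write_export()].
#' @param schema_path Schema file; defaults to the shipped schema.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_export_json <- function(path,
    schema_path = system.file("extdata", "export-schema.json",
                              package = "trnafeat")) {
  schema <- jsonlite::read_json(schema_path)
  obj <- jsonlite::read_json(path)
  for (req in unlist(schema$required)) {
    if (is.null(obj[[req]])) stop("export JSON lacks required key: ", req)
  }
  if (!is.list(obj$tables)) stop("'tables' must be a JSON object")
  if (length(obj$tables) > 0 && is.null(names(obj$tables))) {
    stop("'tables' must be keyed by table name")
  }
  for (nm in names(obj$tables)) {
    tb <- obj$tables[[nm]]
    if (!is.list(tb)) stop("table '", nm, "' must be an array of row objects")
    for (row in tb) {
      if (!is.list(row) || (length(row) > 0 && is.null(names(row)))) {
        stop("table '", nm, "' contains a non-object row")
      }
    }
  }
  invisible(TRUE)
}
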