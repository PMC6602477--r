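#' Toy taxonomy used by the synthetic generator
#'
#' A fixed small tree: three domains, two phyla each (Eukaryota carries
#' Fungi and Chordata so the curation filter's lineage rules are
#' exercisable), two genera per phylum, two species per genus.
#'
#' @return A `trna_taxonomy` with 45 nodes (42 below the domains).
#' @export
toy_taxonomy <- function() {
  rows <- list(c("d1", "Eukaryota", "domain", "ROOT"),
               c("d2", "Bacteria", "domain", "ROOT"),
               c("d3", "Archaea", "domain", "ROOT"))
  phyla <- list(d1 = c("Fungi", "Chordata"),
                d2 = c("Proteobacteria", "Firmicutes"),
                d3 = c("Euryarchaeota", "Crenarchaeota"))
  pk <- 0
  for (d in names(phyla)) {
    for (ph in phyla[[d]]) {
      pk <- pk + 1
      pid <- paste0("p", pk)
      rows[[length(rows) + 1]] <- c(pid, ph, "phylum", d)
      for (g in 1:2) {
        gid <- paste0(pid, "g", g)
        rows[[length(rows) + 1]] <- c(gid, paste0(ph, "_genus", g), "genus", pid)
        for (s in 1:2) {
          sid <- paste0(gid, "s", s)
          rows[[length(rows) + 1]] <-
            c(sid, paste0(ph, "_sp", g, s), "species", gid)
        }
      }
    }
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("taxid", "name", "rank", "parent_taxid")
  taxonomy(df)
}

## Default per-position symbol distributions: a generic cytosolic tRNA
## modal sequence held at 91% with the three alternative bases at 3% each;
## insertion labels (17a/20a/20b) and the variable arm are gap-dominated.
.default_modal <- function() {
  vocab <- sprinzl_positions()
  m <- stats::setNames(rep(NA_character_, length(vocab)), vocab)
  core <- c(
    "1" = "G", "2" = "G", "3" = "G", "4" = "G", "5" = "A", "6" = "U",
    "7" = "U", "8" = "U", "9" = "A", "10" = "G", "11" = "C", "12" = "U",
    "13" = "C", "14" = "A", "15" = "G", "16" = "U", "17" = "U",
    "18" = "G", "19" = "G", "20" = "U", "21" = "A", "22" = "G", "23" = "A",
    "24" = "G", "25" = "C", "26" = "G", "27" = "G", "28" = "C", "29" = "U",
    "30" = "C", "31" = "A", "32" = "C", "33" = "U", "34" = "G", "35" = "C",
    "36" = "A", "37" = "A", "38" = "A", "39" = "U", "40" = "G", "41" = "A",
    "42" = "G", "43" = "C", "44" = "U", "45" = "G", "46" = "G", "47" = "U",
    "48" = "C", "49" = "G", "50" = "G", "51" = "U", "52" = "U", "53" = "C",
    "54" = "U", "55" = "U", "56" = "C", "57" = "A", "58" = "A", "59" = "U",
    "60" = "U", "61" = "G", "62" = "C", "63" = "A", "64" = "C", "65" = "C",
    "66" = "A", "67" = "A", "68" = "U", "69" = "C", "70" = "C", "71" = "C",
    "72" = "C", "73" = "A", "74" = "C", "75" = "C", "76" = "A")
  m[names(core)] <- core
  m[is.na(m)] <- GAP     # 17a, 20a, 20b and the variable arm default absent
  m
}

.default_position_probs <- function() {
  modal <- .default_modal()
  lapply(modal, function(b) {
    p <- stats::setNames(rep(0, 5), SYMBOLS)
    if (b == GAP) {
      p[GAP] <- 0.97
      p[BASES] <- 0.0075
    } else {
      p[b] <- 0.91
      p[setdiff(BASES, b)] <- 0.03
    }
    p
  })
}

.plant_probs <- function(code, floor_total = 0.96) {
  members <- code_base_set(code, "single")
  p <- stats::setNames(rep(0, 5), SYMBOLS)
  p[members] <- floor_total / length(members)
  rest <- setdiff(SYMBOLS, members)
  p[rest] <- (1 - floor_total) / length(rest)
  p
}

#' Specification for a synthetic tRNA gene set
#'
#' Defines the study conditions the generator reproduces: per-position
#' symbol distributions (defaulting to a generic tRNA modal sequence held
#' at 91%), uniform isotype assignment with the isotype's representative
#' anticodon written at positions 34-36, bit scores from a normal
#' truncated at zero (mean 60, sd 10, the realistic range of cytosolic
#' tRNA gene scores), uniform species assignment over the toy taxonomy,
#' and optional per-flag rates.  `planted_consensus` replaces the stated
#' positions' distributions with ones realizing the given feature codes
#' (components sharing `planted_total`, every non-member below the 5%
#' component threshold); realizability is validated at spec time by
#' classifying the exact target distribution.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed; every sampling step derives from it.
#' @param position_probs Named list `label -> named prob vector` over
#'   `A,C,G,U,-` (missing labels fall back to the default distribution).
#' @param isotypes Isotype pool to sample from.
#' @param score_mean,score_sd Normal parameters for bit scores (bits).
#' @param scores Optional explicit score vector (length `n_genes`),
#'   overriding the normal draw.
#' @param species Optional explicit species taxid vector (length
#'   `n_genes` or recycled), overriding uniform sampling.
#' @param flag_rates Named numeric rates in `[0,1]` for `pseudogene`,
#'   `truncated`, `numt`, `chordate_non_high_confidence`.
#' @param planted_consensus Optional named character vector
#'   `label -> single-position feature code`.
#' @param planted_total Combined frequency given to a planted code's
#'   components (default 0.96).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 200, seed = 1,
                         position_probs = list(),
                         isotypes = ISOTYPES,
                         score_mean = 60, score_sd = 10,
                         scores = NULL, species = NULL,
                         flag_rates = c(pseudogene = 0, truncated = 0,
                                        numt = 0,
                                        chordate_non_high_confidence = 0),
                         planted_consensus = NULL,
                         planted_total = 0.96) {
  stopifnot(n_genes >= 1, planted_total > 0, planted_total <= 1)
  probs <- .default_position_probs()
  for (nm in names(position_probs)) {
    sprinzl_index(nm)
    p <- position_probs[[nm]][SYMBOLS]
    p[is.na(p)] <- 0
    if (abs(sum(p) - 1) > 1e-6) stop("probabilities at ", nm, " do not sum to 1")
    probs[[nm]] <- stats::setNames(as.numeric(p), SYMBOLS)
  }
  if (!is.null(planted_consensus)) {
    for (nm in names(planted_consensus)) {
      code <- planted_consensus[[nm]]
      p <- .plant_probs(code, planted_total)
      ## realizability check on the exact target distribution
      d <- structure(list(target = nm,
                          counts = stats::setNames(round(p * 1e6), SYMBOLS),
                          n = 1e6), class = "position_distribution")
      got <- classify(d)$code
      if (got != code) {
        stop("planted consensus ", code, " at ", nm,
             " is not realizable under the classification thresholds ",
             "(exact distribution classifies as ", got, ")")
      }
      probs[[nm]] <- p
    }
  }
  fr <- c(pseudogene = 0, truncated = 0, numt = 0,
          chordate_non_high_confidence = 0)
  fr[names(flag_rates)] <- flag_rates
  if (!is.null(scores) && length(scores) != n_genes) {
    stop("scores must have length n_genes")
  }
  structure(list(n_genes = n_genes, seed = as.integer(seed),
                 position_probs = probs, isotypes = isotypes,
                 score_mean = score_mean, score_sd = score_sd,
                 scores = scores, species = species, flag_rates = fr,
                 planted_consensus = planted_consensus),
            class = "fixture_spec")
}

#' Generate a synthetic, annotated, Sprinzl-aligned tRNA gene set
#'
#' Deterministic given the spec's seed: symbols are drawn per position
#' from the spec's categorical distributions, species uniformly over the
#' toy taxonomy (unless given), isotypes uniformly with the representative
#' anticodon written at positions 34-36, scores from the truncated normal
#' rounded to 0.1 bit (the precision tRNAscan-SE reports), and flags as
#' independent Bernoulli draws.
#'
#' @param spec A [fixture_spec()].
#' @return list with `genes` (a `trna_set`) and `taxonomy` (the toy tree).
#' @export
generate_trnas <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  tax <- toy_taxonomy()
  n <- spec$n_genes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  vocab <- sprinzl_positions()
  aln <- matrix(GAP, n, length(vocab), dimnames = list(NULL, vocab))
  for (p in vocab) {
    aln[, p] <- sample(SYMBOLS, n, replace = TRUE, prob = spec$position_probs[[p]])
  }
  if (!is.null(spec$species)) {
    species <- rep_len(as.character(spec$species), n)
  } else {
    pool <- sort(unlist(lapply(tax$taxid[tax$parent_taxid == "ROOT"],
                               function(d) subtree_species(tax, d))))
    species <- sample(pool, n, replace = TRUE)
  }
  isotype <- sample(spec$isotypes, n, replace = TRUE)
  anticodon <- unname(ISOTYPE_ANTICODON[isotype])
  for (k in 1:3) {
    aln[, c("34", "35", "36")[k]] <- substr(anticodon, k, k)
  }
  if (!is.null(spec$scores)) {
    score <- round(spec$scores, 1)
  } else {
    score <- stats::rnorm(n, spec$score_mean, spec$score_sd)
    while (any(score < 0)) {
      score[score < 0] <- stats::rnorm(sum(score < 0), spec$score_mean,
                                       spec$score_sd)
    }
    score <- round(score, 1)
  }
  flags <- lapply(spec$flag_rates, function(r)
    if (r <= 0) rep(FALSE, n) else stats::runif(n) < r)
  meta <- data.frame(
    gene_id = paste0(species, ".trna", stats::ave(seq_len(n), species,
                                                  FUN = seq_along)),
    species_taxid = species, isotype = isotype, anticodon = anticodon,
    score_bits = score,
    pseudogene = flags$pseudogene, truncated = flags$truncated,
    numt = flags$numt,
    chordate_non_high_confidence = flags$chordate_non_high_confidence,
    domain = vapply(species, function(s) domain_of(tax, s), character(1)),
    stringsAsFactors = FALSE)
  list(genes = trna_set(meta, aln), taxonomy = tax)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Mutate the modal sequence of a profile or reference set
#'
#' Builds a raw query sequence from the modal sequence with exactly the
#' stated substitutions, for construction of test queries with a known
#' number of deviant positions.  Substituting a base equal to the modal
#' base, or at a position whose modal state is the gap, is an error (it
#' would silently weaken any downstream count of deviant positions).
#'
#' @param x A `trna_profile` or a `trna_set` (profile built with defaults).
#' @param substitutions Named character vector `label -> new symbol`.
#' @return The mutated raw sequence (one string).
#' @export
mutate_modal <- function(x, substitutions = character(0)) {
  profile <- if (inherits(x, "trna_profile")) x else build_profile(x)
  modal <- profile$modal
  if (anyDuplicated(names(substitutions))) stop("duplicate substitution positions")
  for (nm in names(substitutions)) {
    sprinzl_index(nm)
    sym <- normalize_symbols(substitutions[[nm]])
    if (modal[[nm]] == GAP) {
      stop("position ", nm, " is gap-modal; cannot substitute in the raw sequence")
    }
    if (sym == modal[[nm]]) {
      stop("substitution at ", nm, " equals the modal base ", sym)
    }
    modal[nm] <- sym
  }
  paste(modal[modal != GAP], collapse = "")
}

#' Write a fixture corpus to disk
#'
#' Emits the three files the readers consume: `alignment.sto` (Sprinzl
#' Stockholm dialect), `genes.tsv` (tRNAscan-SE-style table) and
#' `taxonomy.tsv`.  Reading them back with [read_fixture()] reproduces
#' the input exactly.
#'
#' @param genes A non-empty `trna_set`.
#' @param tax A `trna_taxonomy`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(genes, tax, dir) {
  if (n_genes(genes) == 0) stop("refusing to write an empty fixture")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stockholm(genes, file.path(dir, "alignment.sto"))
  write_trnascan_table(genes, file.path(dir, "genes.tsv"))
  write_taxonomy_tsv(tax, file.path(dir, "taxonomy.tsv"))
  invisible(dir)
}

#' Read a fixture corpus back into a trna_set
#' @param dir Directory written by [write_fixture()].
#' @return list with `genes` and `taxonomy`.
#' @export
read_fixture <- function(dir) {
  tax <- read_taxonomy_tsv(file.path(dir, "taxonomy.tsv"))
  aligned <- read_stockholm(file.path(dir, "alignment.sto"))
  ann <- read_trnascan_table(file.path(dir, "genes.tsv"))
  list(genes = assemble_trna_set(aligned, ann, tax), taxonomy = tax)
}
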