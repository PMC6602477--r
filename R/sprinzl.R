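#' @keywords internal
"_PACKAGE"

## Canonical Sprinzl vocabulary, built once at load time.  Positions 1-76
## with the inserted D-loop labels 17a/20a/20b and the variable-arm labels:
## 5' strand e11-e17, loop e1-e5, 3' strand e27 down to e21 (so that e1k
## pairs e2k across the variable stem).  98 labels in total.
.sprinzl_vocab <- local({
  v <- character(0)
  for (i in 1:17) v <- c(v, as.character(i))
  v <- c(v, "17a", "18", "19", "20", "20a", "20b")
  for (i in 21:45) v <- c(v, as.character(i))
  v <- c(v, paste0("e", 11:17), paste0("e", 1:5), paste0("e", 27:21))
  for (i in 46:76) v <- c(v, as.character(i))
  v
})

#' Canonical Sprinzl position labels
#'
#' Returns the fixed, ordered vocabulary of Sprinzl position labels used by
#' every alignment, distribution and consensus computation in the package:
#' positions 1-76, the inserted D-loop labels `17a`, `20a`, `20b`, and the
#' variable-arm labels `e11`-`e17`, `e1`-`e5`, `e27`-`e21` (in 5' to 3'
#' order).  The order of the returned vector defines the total order on
#' labels.
#'
#' @return Character vector of 98 labels, 5' to 3'.
#' @examples
#' head(sprinzl_positions())
#' length(sprinzl_positions())
#' @export
sprinzl_positions <- function() .sprinzl_vocab

#' Index of a Sprinzl label in the canonical order
#'
#' @param label Character vector of labels.
#' @return Integer indices (1-based) into [sprinzl_positions()].
#' @export
sprinzl_index <- function(label) {
  idx <- match(label, .sprinzl_vocab)
  if (anyNA(idx)) {
    stop("unknown Sprinzl label(s): ",
         paste(label[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Normalize nucleotide symbols
#'
#' Uppercases, converts T to U and maps `.` to the gap character `-`.
#' Any character outside `A`, `C`, `G`, `U`, `-` is an error.
#'
#' @param x Character vector of single-character symbols (or strings when
#'   `split = TRUE`, which are split into characters first).
#' @param split Split multi-character strings into single symbols?
#' @return Character vector of normalized symbols.
#' @export
normalize_symbols <- function(x, split = FALSE) {
  if (split) x <- strsplit(paste(x, collapse = ""), "")[[1]]
  x <- toupper(x)
  x[x == "T"] <- "U"
  x[x == "."] <- GAP
  bad <- setdiff(unique(x), SYMBOLS)
  if (length(bad) > 0) {
    stop("invalid nucleotide symbol(s): ", paste(bad, collapse = ", "))
  }
  x
}

#' Canonical cloverleaf base pairs and tertiary interactions
#'
#' The default pair table: the four cloverleaf stems (acceptor 1:72-7:66,
#' D-stem 10:25-13:22, anticodon stem 27:43-31:39, T-stem 49:65-53:61) plus
#' the variable-arm stem (e11:e21 ... e17:e27) as secondary pairs, and the
#' classic tertiary interactions (8:14, 9:23, 10:45, 15:48, 18:55, 19:56,
#' 22:46, 26:44, 54:58).  Pair orientation is (5' position, 3' position);
#' a pair code X:Y reads 5' base : 3' base.
#'
#' @return A data.frame with columns `pos5`, `pos3`, `type`
#'   (`"secondary"` or `"tertiary"`).
#' @examples
#' pt <- default_pair_table()
#' subset(pt, type == "tertiary")
#' @export
default_pair_table <- function() {
  sec5 <- c(as.character(1:7),            # acceptor
            as.character(10:13),          # D-stem
            as.character(27:31),          # anticodon stem
            as.character(49:53),          # T-stem
            paste0("e", 11:17))           # variable arm
  sec3 <- c(as.character(72:66),
            as.character(25:22),
            as.character(43:39),
            as.character(65:61),
            paste0("e", 21:27))
  ter5 <- c("8", "9", "10", "15", "18", "19", "22", "26", "54")
  ter3 <- c("14", "23", "45", "48", "55", "56", "46", "44", "58")
  out <- data.frame(
    pos5 = c(sec5, ter5),
    pos3 = c(sec3, ter3),
    type = rep(c("secondary", "tertiary"), c(length(sec5), length(ter5))),
    stringsAsFactors = FALSE)
  stopifnot(all(c(out$pos5, out$pos3) %in% .sprinzl_vocab))
  out
}

#' Validate a user pair table
#' @param pairs data.frame with columns pos5, pos3 (and optionally type).
#' @return The validated data.frame (type filled with "secondary").
#' @keywords internal
validate_pair_table <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("pos5", "pos3") %in% names(pairs)))
  pairs$pos5 <- as.character(pairs$pos5)
  pairs$pos3 <- as.character(pairs$pos3)
  sprinzl_index(pairs$pos5); sprinzl_index(pairs$pos3)
  if (is.null(pairs$type)) pairs$type <- "secondary"
  sec <- pairs[pairs$type == "secondary", ]
  lab <- c(sec$pos5, sec$pos3)
  if (anyDuplicated(lab)) {
    stop("label(s) appear twice in secondary pairs: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  }
  pairs
}

## Arm annotation per canonical label.
.sprinzl_arm <- local({
  v <- .sprinzl_vocab
  arm <- character(length(v))
  num <- suppressWarnings(as.integer(sub("[ab]$", "", v)))
  evar <- grepl("^e", v)
  arm[evar] <- "variable"
  arm[!evar & num <= 9] <- "acceptor"
  arm[!evar & num >= 10 & num <= 26] <- "d_arm"
  arm[!evar & num >= 27 & num <= 43] <- "anticodon"
  arm[!evar & num >= 44 & num <= 48] <- "variable"
  arm[!evar & num >= 49 & num <= 65] <- "t_arm"
  arm[!evar & num >= 66] <- "acceptor"
  stats::setNames(arm, v)
})

#' Arm annotation for Sprinzl labels
#' @param label Character vector of canonical labels.
#' @return Character vector over acceptor, d_arm, anticodon, variable, t_arm.
#' @export
sprinzl_arm <- function(label = sprinzl_positions()) {
  sprinzl_index(label)
  unname(.sprinzl_arm[label])
}

## Arc helper: k points on a circle between two angles (degrees).
.arc <- function(cx, cy, r, from, to, k) {
  th <- seq(from, to, length.out = k) * pi / 180
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Cloverleaf layout coordinates
#'
#' Deterministic 2D coordinates for every canonical Sprinzl label in an
#' abstract unit frame, suitable for plotting consensus features on the
#' classic cloverleaf.  Paired positions of every stem in
#' [default_pair_table()] sit exactly one unit apart.
#'
#' @return data.frame with columns `position`, `x`, `y`, `arm`.
#' @export
cloverleaf_layout <- function() {
  xy <- matrix(NA_real_, length(.sprinzl_vocab), 2,
               dimnames = list(.sprinzl_vocab, c("x", "y")))
  put <- function(labels, x, y) xy[labels, ] <<- cbind(x, y)
  ## acceptor stem: 5' strand 1-7 down the left, 3' strand 72-66 beside it
  put(as.character(1:7), 0, 13:7)
  put(as.character(72:66), 1, 13:7)
  put(as.character(73:76), 1, 14:17)
  put(c("8", "9"), c(-0.4, -1.0), c(6.2, 5.6))
  ## D-arm (horizontal, loop to the left)
  put(as.character(10:13), -(2:5), 5)
  put(as.character(25:22), -(2:5), 4)
  dl <- c("14", "15", "16", "17", "17a", "18", "19", "20", "20a", "20b", "21")
  xy[dl, ] <- .arc(-6, 4.5, 1.6, 80, 280, length(dl))
  put("26", -1, 3.4)
  ## anticodon arm (vertical, loop at the bottom)
  put(as.character(27:31), 0, 3:-1)
  put(as.character(43:39), 1, 3:-1)
  al <- as.character(32:38)
  xy[al, ] <- .arc(0.5, -1.6, 1.4, 160, 380, length(al))
  ## variable region and arm (diagonal stem, unit-offset strands)
  put(c("44", "45"), c(1.8, 2.4), c(3.6, 4.0))
  d <- c(0.9, -0.9) / sqrt(2)         # stem direction
  p <- c(1, 1) / sqrt(2)              # unit perpendicular (strand offset)
  a0 <- c(3.2, 4.2)
  for (k in 1:7) {
    put(paste0("e", 10 + k), a0[1] + (k - 1) * d[1], a0[2] + (k - 1) * d[2])
    put(paste0("e", 20 + k),
        a0[1] + p[1] + (k - 1) * d[1], a0[2] + p[2] + (k - 1) * d[2])
  }
  el <- paste0("e", 1:5)
  cen <- a0 + 6.8 * d + p / 2
  xy[el, ] <- .arc(cen[1], cen[2], 0.9, -120, 120, length(el))
  put(c("46", "47", "48"), c(2.1, 2.0, 1.9), c(4.8, 5.5, 6.2))
  ## T-arm (horizontal, loop to the right)
  put(as.character(49:53), 2:6, 2)
  put(as.character(65:61), 2:6, 1)
  tl <- as.character(54:60)
  xy[tl, ] <- .arc(7, 1.5, 1.6, 100, -100, length(tl))
  data.frame(position = .sprinzl_vocab,
             x = unname(xy[, 1]), y = unname(xy[, 2]),
             arm = unname(.sprinzl_arm), stringsAsFactors = FALSE)
}
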