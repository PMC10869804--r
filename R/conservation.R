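#' Residue class sets used for conservation flagging
#'
#' Nonpolar, acidic and basic classes as commonly coloured in consensus
#' plots. His is excluded from the basic set by default (its charge is
#' pH-dependent); the sets are arguments everywhere they are used, so
#' sensitivity to the membership choice can be checked directly.
#'
#' @return named list of character vectors of 1-letter codes.
#' @export
residue_classes <- function() {
  list(nonpolar = c("A", "V", "L", "I", "M", "F", "W", "P", "G"),
       acidic = c("D", "E"),
       basic = c("K", "R"))
}

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a multiple sequence alignment from FASTA
#'
#' @param path aligned FASTA file.
#' @return list of class `msa`: `ids`, `matrix` (sequences x columns,
#'   uppercase characters, `-` for gaps), `width`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) < 2L) stop("an alignment needs at least 2 sequences")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in alignment: ", ids[duplicated(ids)][1])
  }
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(w), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  mat[mat %in% c(".", "*")] <- "-"
  rownames(mat) <- ids
  structure(list(ids = ids, matrix = mat, width = w[1]), class = "msa")
}

msa_from_strings <- function(ids, strings) {
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(paste0(">", ids, "\n", strings), tmp)
  read_alignment(tmp)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa: %d sequences x %d columns>\n", length(x$ids), x$width))
  invisible(x)
}

#' Per-column conservation statistics
#'
#' For every alignment column: residue frequencies and class fractions with
#' gaps counted in the denominator (a heavily gapped column can then never
#' be called conserved), the gap fraction, and the information content
#' `log2(20) - H` where `H` is the Shannon entropy of the gap-renormalised
#' residue distribution. Columns are mapped to the reference sequence's
#' (native) numbering by skipping reference gaps.
#'
#' @param msa an [read_alignment()] object.
#' @param reference_id id of the reference row used for numbering.
#' @param classes class sets, see [residue_classes()].
#' @return data.frame with one row per column: `column`, `native_num` (NA
#'   where the reference is gapped), `gap_fraction`, `information`,
#'   `freq_<aa>` for the 20 residues and `class_<name>` fractions.
#' @export
column_stats <- function(msa, reference_id, classes = residue_classes()) {
  stopifnot(inherits(msa, "msa"))
  if (!reference_id %in% msa$ids) stop("reference id '", reference_id, "' not in alignment")
  mat <- msa$matrix
  n <- nrow(mat)
  ref <- mat[reference_id, ]
  native <- cumsum(ref != "-")
  native[ref == "-"] <- NA_integer_
  freq <- vapply(.aa20, function(a) colMeans(mat == a), numeric(msa$width))
  if (msa$width == 1L) freq <- matrix(freq, nrow = 1, dimnames = list(NULL, .aa20))
  gapf <- colMeans(mat == "-")
  ## information content of the gap-renormalised residue distribution
  info <- vapply(seq_len(msa$width), function(j) {
    p <- freq[j, ]
    tot <- sum(p)
    if (tot <= 0) return(NA_real_)
    p <- p[p > 0] / tot
    log2(20) + sum(p * log2(p))
  }, numeric(1))
  out <- data.frame(column = seq_len(msa$width), native_num = native,
                    gap_fraction = gapf, information = info)
  for (a in .aa20) out[[paste0("freq_", a)]] <- freq[, a]
  for (cl in names(classes)) {
    out[[paste0("class_", cl)]] <- rowSums(freq[, classes[[cl]], drop = FALSE])
  }
  ## residues outside all declared classes (plus nonstandard letters)
  out$class_other <- pmax(0, 1 - gapf -
    Reduce(`+`, lapply(names(classes), function(cl) out[[paste0("class_", cl)]])))
  out
}

#' Flag conserved columns by residue class
#'
#' A column is flagged when a single class fraction strictly exceeds the
#' threshold (default 0.80, matching a "> 80%" consensus-plot rule). By
#' default only the coloured classes (nonpolar, acidic, basic) are eligible;
#' with `mode = "residue"` a column is instead flagged when a single residue
#' frequency exceeds the threshold.
#'
#' @param stats a [column_stats()] result.
#' @param threshold fraction in (0, 1], strict inequality.
#' @param mode `"class"` or `"residue"`.
#' @param classes class names eligible for flagging in class mode.
#' @return data.frame with `column`, `native_num`, `class` (or the residue),
#'   `fraction` for each flagged column.
#' @export
flag_conserved <- function(stats, threshold = 0.80,
                           mode = c("class", "residue"),
                           classes = c("nonpolar", "acidic", "basic")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold <= 1)
  if (mode == "class") {
    cols <- paste0("class_", classes)
    labels <- classes
  } else {
    cols <- paste0("freq_", .aa20)
    labels <- .aa20
  }
  fr <- as.matrix(stats[, cols, drop = FALSE])
  best <- max.col(fr, ties.method = "first")
  bestf <- fr[cbind(seq_len(nrow(fr)), best)]
  hit <- bestf > threshold
  data.frame(column = stats$column[hit], native_num = stats$native_num[hit],
             class = labels[best[hit]], fraction = bestf[hit],
             stringsAsFactors = FALSE)
}

#' Majority-rule consensus sequence
#'
#' Per column the most frequent non-gap residue, ties broken alphabetically;
#' columns with a gap fraction above 0.5 are emitted in lowercase.
#'
#' @param msa an [read_alignment()] object.
#' @return single consensus string.
#' @export
consensus <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  mat <- msa$matrix
  out <- vapply(seq_len(msa$width), function(j) {
    col <- mat[, j]
    res <- col[col != "-"]
    if (!length(res)) return("-")
    tab <- table(res)                      # table() is alphabetical: ties -> first
    best <- names(tab)[which.max(tab)]
    if (mean(col == "-") > 0.5) tolower(best) else best
  }, character(1))
  paste(out, collapse = "")
}
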