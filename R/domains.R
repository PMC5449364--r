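#' Detect S-/D-type EUL protein architecture
#'
#' One EUL-domain hit makes an S-type protein, two non-overlapping hits a
#' D-type whose linker is the stretch between the domains; the N-terminal
#' region is everything before the first domain. Zero hits reject the
#' protein (not an EUL); more than two hits are flagged unsupported and
#' reported raw.
#'
#' @param protein_id identifier
#' @param protein_length length of the protein in residues
#' @param hits data.frame of EUL-domain intervals on the protein:
#'   \code{start}, \code{end} (1-based inclusive, aa)
#' @return an \code{architecture_call}: list with \code{protein_id},
#'   \code{type} ("S", "D" or "unsupported"), \code{domains} (ordered
#'   intervals), \code{n_term_length}, \code{linker} (start, end, length;
#'   D-type only)
#' @export
detect_architecture <- function(protein_id, protein_length, hits) {
  if (!nrow(hits))
    stop_structural("protein ", protein_id, " has no EUL domain hit; rejected")
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$start <- as.integer(hits$start); hits$end <- as.integer(hits$end)
  if (any(hits$start > hits$end) || any(hits$end > protein_length))
    stop_structural("domain interval outside protein ", protein_id)
  call <- list(protein_id = protein_id, domains = hits[, c("start", "end")],
               n_term_length = hits$start[1] - 1L, linker = NULL)
  if (nrow(hits) == 1L) {
    call$type <- "S"
  } else if (nrow(hits) == 2L) {
    if (hits$start[2] <= hits$end[1])
      stop_structural("overlapping domains in ", protein_id)
    call$type <- "D"
    call$linker <- list(start = hits$end[1] + 1L, end = hits$start[2] - 1L,
                        length = hits$start[2] - hits$end[1] - 1L)
  } else {
    call$type <- "unsupported"
    warning("protein ", protein_id, " has ", nrow(hits),
            " EUL domain hits; flagged unsupported")
  }
  structure(call, class = "architecture_call")
}

#' @export
print.architecture_call <- function(x, ...) {
  cat(x$protein_id, ": ", x$type, "-type, N-terminal region ",
      x$n_term_length, " aa", sep = "")
  if (!is.null(x$linker)) cat(", linker", x$linker$length, "aa")
  cat("\n")
  invisible(x)
}

# positive-scoring residue pairs under BLOSUM62 define the similarity groups
blosum62_positive <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62 > 0
    }
    cache
  }
})

#' Percent identity and similarity of an aligned sequence pair
#'
#' Columns where both sequences are gapped are excluded from the
#' denominator; single-gap columns count as mismatches. Identity counts
#' exact residue matches; similarity additionally counts substitutions with
#' a positive BLOSUM62 score (the conventional "similar residue" groups).
#'
#' @param a,b equal-length aligned sequences (characters; gaps as \code{-})
#' @param digits rounding of the percentages (default 1)
#' @return named numeric: \code{identity}, \code{similarity}
#' @export
pairwise_identity_similarity <- function(a, b, digits = 1) {
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(va) != length(vb)) stop_structural("aligned sequences differ in length")
  keep <- !(va == "-" & vb == "-")
  if (!any(keep)) stop_structural("alignment has only dual-gap columns")
  va <- va[keep]; vb <- vb[keep]
  ident <- va == vb & va != "-"
  pos <- blosum62_positive()
  simil <- ident
  both <- va != "-" & vb != "-" & !ident &
    va %in% rownames(pos) & vb %in% colnames(pos)
  simil[both] <- pos[cbind(va[both], vb[both])]
  c(identity = round_half_up(100 * sum(ident) / length(va), digits),
    similarity = round_half_up(100 * sum(simil) / length(va), digits))
}

#' Pairwise identity/similarity matrix over an MSA
#'
#' @param msa named character vector of equal-length aligned sequences
#' @param digits rounding (default 1)
#' @return a \code{similarity_matrix}: list of two symmetric matrices
#'   \code{identity} and \code{similarity} with 100 on the diagonal
#' @export
similarity_matrix <- function(msa, digits = 1) {
  n <- length(msa)
  ids <- names(msa) %||% paste0("seq", seq_len(n))
  idm <- smm <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- pairwise_identity_similarity(msa[[i]], msa[[j]], digits)
    idm[i, j] <- idm[j, i] <- v[["identity"]]
    smm[i, j] <- smm[j, i] <- v[["similarity"]]
  }
  structure(list(identity = idm, similarity = smm), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  n <- nrow(x$identity)
  off <- x$identity[upper.tri(x$identity)]
  cat("similarity_matrix over", n, "domains")
  if (length(off))
    cat("; identity range", min(off), "-", max(off))
  cat("\n")
  invisible(x)
}

# landmark positions in the 151-residue EUL-domain frame (1-based)
eul_landmarks <- function() {
  list(QxW1 = c(34, 36), D116 = 116, FL118 = 118, W136 = 136,
       N143 = 143, Q144 = 144)
}

#' Conservation profile of an EUL-domain alignment
#'
#' Per-column residue frequencies over non-gap symbols, per-column
#' information content IC = log2(20) - H (H the Shannon entropy in bits of
#' the non-gap composition; no small-sample correction by default), and a
#' landmark report for the positions that define the EUL domain: the QxW
#' motif at 34-36 (Q at 34 and W at 36, any residue between), the
#' carbohydrate-binding triad D116/N143/Q144, the stacking residues F or L
#' at 118 (both fractions reported) and W at 136.
#'
#' @param msa named character vector of aligned domain sequences; columns
#'   must be the 151-residue EUL frame, or \code{column_map} must give, for
#'   each of the 151 frame positions, the corresponding MSA column
#' @param column_map optional integer vector of length 151
#' @param small_sample_correction subtract the (e-1)/(2 ln2 n) entropy bias
#'   term (off by default)
#' @return a \code{domain_profile}: list with \code{frequencies} (20 x
#'   ncol), \code{information_content} (bits per column), \code{landmarks}
#'   (named fractions in [0,1]; \code{FL118_F}/\code{FL118_L} split the
#'   118 mix), \code{n_sequences}
#' @export
conservation_profile <- function(msa, column_map = NULL,
                                 small_sample_correction = FALSE) {
  if (!length(msa)) stop_structural("empty MSA")
  mat <- do.call(rbind, strsplit(toupper(unname(unlist(msa))), "", fixed = TRUE))
  if (is.null(column_map)) {
    if (ncol(mat) != 151)
      stop_structural("MSA has ", ncol(mat),
                      " columns; supply column_map to locate the 151-residue frame")
    column_map <- seq_len(151L)
  }
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  freq <- apply(mat, 2, function(col) {
    col <- col[col %in% aas]
    if (!length(col)) return(stats::setNames(rep(NA_real_, 20), aas))
    tabulate(factor(col, levels = aas), 20) / length(col)
  })
  rownames(freq) <- aas
  ic <- apply(freq, 2, function(f) {
    if (any(is.na(f))) return(NA_real_)
    nz <- f[f > 0]
    log2(20) - (-sum(nz * log2(nz)))
  })
  if (small_sample_correction)
    ic <- pmax(0, ic - (20 - 1) / (2 * log(2) * nrow(mat)))
  col_of <- function(pos) mat[, column_map[pos]]
  frac <- function(v, residues) mean(v %in% residues)
  lm <- c(
    QxW = mean(col_of(34) == "Q" & col_of(36) == "W"),
    D116 = frac(col_of(116), "D"),
    FL118 = frac(col_of(118), c("F", "L")),
    FL118_F = frac(col_of(118), "F"),
    FL118_L = frac(col_of(118), "L"),
    W136 = frac(col_of(136), "W"),
    N143 = frac(col_of(143), "N"),
    Q144 = frac(col_of(144), "Q")
  )
  structure(list(frequencies = freq, information_content = ic,
                 landmarks = lm, n_sequences = nrow(mat)),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("domain_profile:", x$n_sequences, "sequences,",
      length(x$information_content), "columns\n")
  cat("landmarks:\n")
  print(round(x$landmarks, 3))
  invisible(x)
}

#' @export
#' @method plot domain_profile
plot.domain_profile <- function(x, ...) {
  graphics::barplot(x$information_content, border = NA,
                    xlab = "EUL-domain position", ylab = "information content (bits)",
                    ...)
  invisible(x)
}
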