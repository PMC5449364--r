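#' Chromosomal gene-order index
#'
#' Ranks ALL annotated genes (not only lectins) along each chromosome by
#' start position, with consecutive 0-based ranks. Tandem calling counts
#' intervening genes on this index.
#'
#' @param models gene models
#' @return data.frame gene_id, chromosome, start, rank
#' @export
gene_order_index <- function(models) {
  g <- gene_table(models)
  g <- g[order(g$chromosome, g$start), ]
  g$rank <- as.integer(stats::ave(seq_len(nrow(g)), g$chromosome, FUN = seq_along)) - 1L
  rownames(g) <- NULL
  g[, c("gene_id", "chromosome", "start", "rank")]
}

#' Call tandem duplication blocks
#'
#' Two genes are tandem-linked iff they belong to the same lectin family,
#' lie on the same chromosome, and are separated by at most
#' \code{max_intervening} other genes (rank difference minus one; the
#' boundary is inclusive, so exactly ten intervening genes still links).
#' Blocks are the connected components of this relation — three genes each
#' linked to the next form one block even if the outer pair exceeds the gap.
#'
#' @param order gene-order index from [gene_order_index()]
#' @param assignments classification table ([classify_lectin_genes()]); a
#'   multi-family gene participates in each of its families
#' @param max_intervening maximum number of intervening genes (default 10)
#' @return data.frame with one row per block: \code{family},
#'   \code{chromosome}, \code{members} (comma-joined gene ids in chromosomal
#'   order), \code{size}, \code{max_gap} (largest intervening count between
#'   consecutive members)
#' @export
call_tandem_duplications <- function(order, assignments, max_intervening = 10L) {
  pairs <- assignment_pairs(assignments)
  missing <- setdiff(unique(pairs$gene_id), order$gene_id)
  if (length(missing))
    stop_structural("assigned gene(s) missing from gene order: ",
                    paste(missing, collapse = ", "))
  rk <- order[match(pairs$gene_id, order$gene_id), ]
  pairs$chromosome <- rk$chromosome
  pairs$rank <- rk$rank
  blocks <- list()
  for (key in unique(paste(pairs$family, pairs$chromosome, sep = "\r"))) {
    sub <- pairs[paste(pairs$family, pairs$chromosome, sep = "\r") == key, ]
    sub <- sub[order(sub$rank), ]
    if (nrow(sub) < 2) next
    # consecutive same-family genes along the chromosome: a new block starts
    # whenever the gap to the previous family member exceeds the limit
    gaps <- diff(sub$rank) - 1L
    grp <- cumsum(c(0L, gaps > max_intervening))
    for (g in split(seq_len(nrow(sub)), grp)) {
      if (length(g) < 2) next
      blocks[[length(blocks) + 1L]] <- data.frame(
        family = sub$family[1], chromosome = sub$chromosome[1],
        members = paste(sub$gene_id[g], collapse = ","),
        size = length(g),
        max_gap = as.integer(max(gaps[g[-length(g)]])),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(blocks))
    return(data.frame(family = character(), chromosome = character(),
                      members = character(), size = integer(),
                      max_gap = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, blocks)
  out[order(out$chromosome, out$family), , drop = FALSE]
}

#' Filter segmental (collinear) duplication blocks
#'
#' Retains blocks whose synonymous substitution rate does not exceed
#' \code{ks_max} (blocks with Ks strictly above the cutoff are omitted as
#' saturated) and in which at least one anchor gene carries a lectin family
#' label; retained blocks are annotated with the linked families.
#'
#' @param blocks data.frame block_id, gene_a, gene_b, ks
#' @param assignments classification table
#' @param ks_max Ks cutoff (default 1.0; Ks equal to the cutoff is retained)
#' @return the retained subset of \code{blocks} with an added
#'   \code{families} column
#' @export
filter_segmental_blocks <- function(blocks, assignments, ks_max = 1.0) {
  if (!all(c("block_id", "gene_a", "gene_b", "ks") %in% names(blocks)))
    stop_structural("blocks need columns block_id, gene_a, gene_b, ks")
  if (any(blocks$ks < 0)) stop_structural("negative Ks value")
  fam_of <- stats::setNames(assignments$families, assignments$gene_id)
  fa <- fam_of[blocks$gene_a]
  fb <- fam_of[blocks$gene_b]
  keep <- blocks$ks <= ks_max & (!is.na(fa) | !is.na(fb))
  out <- blocks[keep, , drop = FALSE]
  lab <- function(a, b) paste(sort(unique(unlist(strsplit(c(a, b)[!is.na(c(a, b))], ",")))),
                              collapse = ",")
  out$families <- mapply(lab, fa[keep], fb[keep], USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}
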