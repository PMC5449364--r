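#' Gene model tables
#'
#' Gene models are kept as a plain feature table with one row per feature:
#' columns \code{gene_id}, \code{chromosome}, \code{strand} (\code{"+"} or
#' \code{"-"}), \code{type} (one of \code{"gene"}, \code{"exon"},
#' \code{"CDS"}) and 1-based inclusive \code{start}/\code{end} coordinates
#' (the GFF3 convention at the file boundary). Internally, promoter and match
#' coordinates are 0-based half-open; conversion happens only at I/O.
#'
#' @param features data.frame with columns \code{gene_id}, \code{chromosome},
#'   \code{strand}, \code{type}, \code{start}, \code{end}.
#' @return A \code{gene_models} object (a validated data.frame).
#' @export
gene_models <- function(features) {
  need <- c("gene_id", "chromosome", "strand", "type", "start", "end")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop_structural("gene model table lacks columns: ", paste(miss, collapse = ", "))
  features <- as.data.frame(features)[, need]
  if (any(features$start > features$end))
    stop_structural("feature with start > end")
  if (!all(features$strand %in% c("+", "-")))
    stop_structural("strand must be '+' or '-'")
  if (!all(features$type %in% c("gene", "exon", "CDS")))
    stop_structural("feature type must be gene/exon/CDS")
  class(features) <- c("gene_models", "data.frame")
  features
}

#' @export
print.gene_models <- function(x, ...) {
  g <- unique(x$gene_id[x$type == "gene"])
  cat("gene_models:", length(g), "genes,", nrow(x), "features on",
      length(unique(x$chromosome)), "chromosome(s)\n")
  invisible(x)
}

#' Extract the gene-level table (one row per gene)
#' @param models a \code{gene_models} object
#' @return data.frame with gene_id, chromosome, strand, start, end
#' @export
gene_table <- function(models) {
  g <- models[models$type == "gene", c("gene_id", "chromosome", "strand", "start", "end")]
  rownames(g) <- NULL
  g
}

# Per-gene feature intervals of a given type, sorted by genomic start.
feature_intervals <- function(models, gene_id, type) {
  f <- models[models$gene_id == gene_id & models$type == type, , drop = FALSE]
  f[order(f$start), , drop = FALSE]
}

#' Read gene models from a GFF3 file
#'
#' Uses \pkg{rtracklayer}; features are matched to genes through the
#' \code{ID}/\code{Parent} attributes, collapsing transcript-level parents to
#' their gene.
#' @param path GFF3 file
#' @return a \code{gene_models} object
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  id <- as.character(df$ID)
  parent <- vapply(df$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
                   character(1))
  # map transcript ids to their gene parent so exon/CDS rows resolve to genes
  tx_parent <- stats::setNames(parent[df$type == "mRNA"], id[df$type == "mRNA"])
  gene_of <- function(i) {
    if (df$type[i] == "gene") return(id[i])
    p <- parent[i]
    if (!is.na(p) && p %in% names(tx_parent)) p <- tx_parent[[p]]
    p
  }
  keep <- df$type %in% c("gene", "exon", "CDS")
  out <- data.frame(
    gene_id = vapply(which(keep), gene_of, character(1)),
    chromosome = as.character(df$seqnames)[keep],
    strand = as.character(df$strand)[keep],
    type = as.character(df$type)[keep],
    start = df$start[keep],
    end = df$end[keep],
    stringsAsFactors = FALSE
  )
  gene_models(out)
}

#' Write gene models to GFF3
#' @param models a \code{gene_models} object
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_gene_models_gff3 <- function(models, path) {
  df <- as.data.frame(models)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chromosome,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand,
    type = df$type
  )
  is_gene <- df$type == "gene"
  gr$ID <- ifelse(is_gene, df$gene_id, paste0(df$gene_id, ":", df$type, ":", seq_len(nrow(df))))
  gr$Parent <- ifelse(is_gene, NA_character_, df$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
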