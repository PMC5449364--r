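#' The twelve plant lectin families and their Pfam domain accessions
#'
#' Mapping from Pfam-style domain accessions to the twelve recognised plant
#' lectin families: ABA (Agaricus bisporus agglutinin), amaranthin, CRA
#' (chitinase-related agglutinin), cyanovirin, EUL (Euonymus-related lectin),
#' GNA (Galanthus nivalis agglutinin), hevein, JRL (jacalin-related), legume,
#' LysM, nictaba and ricin-B.
#'
#' @return data.frame with columns \code{accession} and \code{family}
#' @export
lectin_family_map <- function() {
  data.frame(
    accession = c("PF07367", "PF07468", "PF00704", "PF08881", "PF14200",
                  "PF01453", "PF00187", "PF01419", "PF00139", "PF01476",
                  "PF14299", "PF00652"),
    family = c("ABA", "amaranthin", "CRA", "cyanovirin", "EUL",
               "GNA", "hevein", "JRL", "legume", "LysM",
               "nictaba", "ricin-B"),
    stringsAsFactors = FALSE
  )
}

#' Classify genes into lectin families from domain annotations
#'
#' Genes carrying at least one domain whose accession maps to a lectin family
#' are retained; all others are excluded. A gene whose domains map to several
#' families carries every label and is flagged multi-family. Accessions absent
#' from the map are ignored with a warning.
#'
#' @param annotations data.frame with columns \code{gene_id},
#'   \code{domain_id}, \code{aa_start}, \code{aa_end} (1-based inclusive
#'   residue coordinates), InterProScan-style.
#' @param map accession-to-family map; defaults to [lectin_family_map()].
#' @return data.frame with \code{gene_id}, \code{families} (comma-joined,
#'   sorted), \code{n_families}, \code{multi_family}.
#' @export
classify_lectin_genes <- function(annotations, map = lectin_family_map()) {
  need <- c("gene_id", "domain_id")
  if (!all(need %in% names(annotations)))
    stop_structural("annotations need columns gene_id, domain_id")
  if (all(c("aa_start", "aa_end") %in% names(annotations)) &&
      any(annotations$aa_start > annotations$aa_end))
    stop_structural("domain annotation with aa_start > aa_end")
  if (anyDuplicated(map$accession))
    stop_config("family map accessions must be unique")
  fam <- stats::setNames(map$family, map$accession)
  unknown <- setdiff(unique(annotations$domain_id), names(fam))
  if (length(unknown))
    warning("ignoring unknown domain accession(s): ", paste(unknown, collapse = ", "))
  hit <- annotations[annotations$domain_id %in% names(fam), , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(gene_id = character(), families = character(),
                      n_families = integer(), multi_family = logical(),
                      stringsAsFactors = FALSE))
  }
  fam_by_gene <- lapply(split(fam[hit$domain_id], hit$gene_id),
                        function(f) sort(unique(unname(f))))
  data.frame(
    gene_id = names(fam_by_gene),
    families = vapply(fam_by_gene, paste, character(1), collapse = ","),
    n_families = lengths(fam_by_gene),
    multi_family = lengths(fam_by_gene) > 1L,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# expand a classification table to long (gene_id, family) pairs
assignment_pairs <- function(assignments) {
  if (!nrow(assignments))
    return(data.frame(gene_id = character(), family = character()))
  fams <- strsplit(assignments$families, ",", fixed = TRUE)
  data.frame(gene_id = rep(assignments$gene_id, lengths(fams)),
             family = unlist(fams), stringsAsFactors = FALSE)
}

#' Family census table
#'
#' Counts genes per lectin family and reports each family's percentage of the
#' total, the way genome-wide lectin censuses are tabulated: per-family counts
#' (a multi-family gene counts once in each of its families), the number of
#' distinct genes, percentages rounded half-up to one decimal, the largest and
#' smallest non-zero families, and how many of the twelve families are
#' represented (count >= 1).
#'
#' @param x either a classification table from [classify_lectin_genes()], or a
#'   named numeric vector of per-family gene counts.
#' @param families the family universe; defaults to the twelve plant lectin
#'   families.
#' @return A \code{lectin_census} object: data.frame (family, count, percent)
#'   with attributes \code{total_genes}, \code{total_assignments},
#'   \code{n_represented}, \code{largest}, \code{smallest}.
#' @examples
#' cts <- c(CRA = 2, EUL = 5, GNA = 134, hevein = 10, JRL = 30,
#'          legume = 104, LysM = 20, nictaba = 20, `ricin-B` = 4)
#' family_census(cts)
#' @export
family_census <- function(x, families = lectin_family_map()$family) {
  if (is.numeric(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop_config("count vector must be fully named by family")
    bad <- setdiff(names(x), families)
    if (length(bad)) stop_config("unknown family name(s): ", paste(bad, collapse = ", "))
    if (any(x < 0) || any(x != floor(x))) stop_config("counts must be non-negative integers")
    counts <- stats::setNames(numeric(length(families)), families)
    counts[names(x)] <- x
    total_genes <- sum(x)          # counts given per family are distinct genes
    total_assign <- sum(x)
  } else {
    pairs <- assignment_pairs(x)
    bad <- setdiff(unique(pairs$family), families)
    if (length(bad)) stop_config("assignment outside family universe: ", paste(bad, collapse = ", "))
    counts <- stats::setNames(numeric(length(families)), families)
    tab <- table(pairs$family)
    counts[names(tab)] <- as.numeric(tab)
    total_genes <- length(unique(pairs$gene_id))
    total_assign <- nrow(pairs)
  }
  percent <- if (total_genes > 0) round_half_up(100 * counts / total_genes, 1) else counts * 0
  out <- data.frame(family = families, count = as.integer(counts),
                    percent = percent, row.names = NULL, stringsAsFactors = FALSE)
  nz <- out[out$count > 0, , drop = FALSE]
  attr(out, "total_genes") <- as.integer(total_genes)
  attr(out, "total_assignments") <- as.integer(total_assign)
  attr(out, "n_represented") <- nrow(nz)
  attr(out, "largest") <- if (nrow(nz)) nz$family[which.max(nz$count)] else NA_character_
  attr(out, "smallest") <- if (nrow(nz)) nz$family[which.min(nz$count)] else NA_character_
  class(out) <- c("lectin_census", "data.frame")
  out
}

#' @export
print.lectin_census <- function(x, ...) {
  cat("Lectin family census:", attr(x, "total_genes"), "distinct genes,",
      attr(x, "n_represented"), "of", nrow(x), "families represented\n")
  shown <- as.data.frame(x)
  print(shown[shown$count > 0 | nrow(shown) <= 12, ], row.names = FALSE)
  if (!is.na(attr(x, "largest")))
    cat("largest:", attr(x, "largest"), " smallest (non-zero):", attr(x, "smallest"), "\n")
  invisible(x)
}

#' Per-chromosome ordered map of classified genes
#'
#' @param models gene models
#' @param assignments classification table ([classify_lectin_genes()])
#' @return list with \code{placed} (data.frame gene_id, chromosome, start,
#'   strand, families, ordered by start within chromosome) and
#'   \code{unplaced} (gene ids with no model).
#' @export
chromosome_map <- function(models, assignments) {
  genes <- gene_table(models)
  m <- merge(assignments, genes, by = "gene_id", all.x = TRUE)
  unplaced <- m$gene_id[is.na(m$start)]
  placed <- m[!is.na(m$start), c("gene_id", "chromosome", "start", "strand", "families")]
  placed <- placed[order(placed$chromosome, placed$start), ]
  rownames(placed) <- NULL
  list(placed = placed, unplaced = unplaced)
}

#' Exon/intron structure summary of one gene
#'
#' Intron i spans the gap between exon i and exon i+1 in transcript
#' orientation; sizes are in bp. UTR extents are derived from the exon span
#' not covered by CDS when CDS features are present.
#'
#' @param models gene models
#' @param gene_id gene to summarise
#' @return list: \code{n_exons}, \code{n_introns}, \code{exon_sizes},
#'   \code{intron_sizes} (transcript orientation), \code{utr5}, \code{utr3}
#'   (bp, NA when no CDS annotated).
#' @export
gene_structure_summary <- function(models, gene_id) {
  ex <- feature_intervals(models, gene_id, "exon")
  if (!nrow(ex)) stop_structural("gene ", gene_id, " has no exon features")
  if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
    stop_structural("overlapping exons in gene ", gene_id)
  strand <- ex$strand[1]
  sizes <- ex$end - ex$start + 1L
  introns <- if (nrow(ex) > 1) ex$start[-1] - ex$end[-nrow(ex)] - 1L else integer(0)
  if (strand == "-") { sizes <- rev(sizes); introns <- rev(introns) }
  cds <- feature_intervals(models, gene_id, "CDS")
  utr5 <- utr3 <- NA_integer_
  if (nrow(cds)) {
    # bp of exon sequence before the first / after the last CDS base
    left <- sum(pmax(0L, pmin(ex$end, min(cds$start) - 1L) - ex$start + 1L))
    right <- sum(pmax(0L, ex$end - pmax(ex$start, max(cds$end) + 1L) + 1L))
    left <- as.integer(left); right <- as.integer(right)
    if (strand == "+") { utr5 <- left; utr3 <- right } else { utr5 <- right; utr3 <- left }
  }
  list(gene_id = gene_id, n_exons = nrow(ex), n_introns = length(introns),
       exon_sizes = as.integer(sizes), intron_sizes = as.integer(introns),
       utr5 = utr5, utr3 = utr3)
}
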