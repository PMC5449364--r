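#' Classify the consequence of a single-nucleotide variant against a gene model
#'
#' Maps the variant position to a feature (intergenic, UTR, intron, exon-CDS)
#' and, for CDS hits, substitutes the affected codon base (strand-aware, so a
#' genomic allele on a minus-strand gene is complemented first) and translates
#' with the standard genetic code: an unchanged amino acid is a silent
#' mutation, anything else is missense with the amino-acid change recorded.
#'
#' @param models gene models
#' @param gene_id gene against which to classify (use \code{NA} for a variant
#'   outside any gene: it is returned as intergenic)
#' @param cds_sequence the gene's spliced CDS, 5'->3' in transcript
#'   orientation (character or \code{Biostrings::DNAString}); length must be
#'   a multiple of 3
#' @param chromosome,position variant locus; \code{position} is 1-based
#'   genomic (VCF convention)
#' @param ref,alt reference and alternate bases on the forward genomic strand
#' @return a one-row data.frame: chromosome, position, ref, alt, gene_id,
#'   feature, consequence (\code{none}/\code{silent}/\code{missense}),
#'   aa_ref, aa_pos, aa_alt, codon_ref, codon_alt
#' @export
classify_snp <- function(models, gene_id, cds_sequence, chromosome, position,
                         ref, alt) {
  if (identical(ref, alt)) stop_structural("alt base equals ref base")
  if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T"))
    stop_structural("ref/alt must be single A/C/G/T bases")
  rec <- data.frame(chromosome = chromosome, position = position, ref = ref,
                    alt = alt, gene_id = NA_character_, feature = "intergenic",
                    consequence = "none", aa_ref = NA_character_,
                    aa_pos = NA_integer_, aa_alt = NA_character_,
                    codon_ref = NA_character_, codon_alt = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.na(gene_id)) return(rec)
  g <- gene_table(models)
  g <- g[g$gene_id == gene_id, ]
  if (!nrow(g)) stop_structural("gene ", gene_id, " not in models")
  if (g$chromosome != chromosome || position < g$start || position > g$end)
    return(rec)
  rec$gene_id <- gene_id
  ex <- feature_intervals(models, gene_id, "exon")
  cds <- feature_intervals(models, gene_id, "CDS")
  in_iv <- function(iv) nrow(iv) && any(position >= iv$start & position <= iv$end)
  if (in_iv(cds)) {
    rec$feature <- "exon-CDS"
    cs <- as.character(cds_sequence)
    if (nchar(cs) %% 3 != 0)
      stop_structural("CDS length not divisible by 3 for ", gene_id)
    if (nchar(cs) != sum(cds$end - cds$start + 1L))
      stop_structural("CDS sequence length does not match CDS intervals for ", gene_id)
    strand <- g$strand
    # offset of the variant within the spliced CDS, in transcript orientation
    if (strand == "+") {
      prior <- sum(pmax(0L, pmin(cds$end, position - 1L) - cds$start + 1L))
    } else {
      prior <- sum(pmax(0L, cds$end - pmax(cds$start, position + 1L) + 1L))
    }
    cds_pos <- prior + 1L                       # 1-based transcript coordinate
    refc <- if (strand == "+") ref else comp_base[[ref]]
    altc <- if (strand == "+") alt else comp_base[[alt]]
    if (substr(cs, cds_pos, cds_pos) != refc)
      stop_structural("reference base mismatch at CDS position ", cds_pos,
                      " of ", gene_id)
    aa_pos <- (cds_pos - 1L) %/% 3L + 1L
    codon_start <- (aa_pos - 1L) * 3L + 1L
    codon_ref <- substr(cs, codon_start, codon_start + 2L)
    codon_alt <- codon_ref
    substr(codon_alt, cds_pos - codon_start + 1L, cds_pos - codon_start + 1L) <- altc
    aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
    aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
    rec$consequence <- if (aa_ref == aa_alt) "silent" else "missense"
    rec$aa_ref <- aa_ref; rec$aa_alt <- aa_alt; rec$aa_pos <- as.integer(aa_pos)
    rec$codon_ref <- codon_ref; rec$codon_alt <- codon_alt
  } else if (in_iv(ex)) {
    rec$feature <- "UTR"
  } else {
    rec$feature <- "intron"
  }
  rec
}

#' Reference-allele percentage matrix per subpopulation
#'
#' For every SNP locus and subpopulation, the percentage of accessions whose
#' (haploid) call equals the reference allele, computed over non-missing
#' genotypes only; the denominator is kept alongside. A cell with no
#' non-missing call is NA.
#'
#' @param genotypes character matrix, loci x accessions, entries the called
#'   base or NA for missing
#' @param subpop_table data.frame accession, subpopulation (every accession
#'   exactly once)
#' @param loci data.frame with at least \code{locus_id} and \code{ref},
#'   rows aligned with \code{genotypes}
#' @return an \code{allele_frequency_matrix}: numeric matrix (loci x
#'   subpopulations, percentages in [0,100]) with a \code{denominator}
#'   attribute of the same shape
#' @export
reference_allele_matrix <- function(genotypes, subpop_table, loci) {
  if (nrow(genotypes) != nrow(loci))
    stop_structural("genotype rows must align with loci table")
  acc <- colnames(genotypes)
  unassigned <- setdiff(acc, subpop_table$accession)
  if (length(unassigned))
    stop_structural("accession(s) without subpopulation: ",
                    paste(unassigned, collapse = ", "))
  sp <- stats::setNames(subpop_table$subpopulation, subpop_table$accession)[acc]
  pops <- unique(subpop_table$subpopulation)
  m <- matrix(NA_real_, nrow(genotypes), length(pops),
              dimnames = list(loci$locus_id, pops))
  den <- m
  for (p in pops) {
    cols <- genotypes[, sp == p, drop = FALSE]
    nm <- rowSums(!is.na(cols))
    refn <- rowSums(cols == loci$ref, na.rm = TRUE)
    den[, p] <- nm
    m[, p] <- ifelse(nm > 0, 100 * refn / nm, NA_real_)
  }
  attr(m, "denominator") <- den
  class(m) <- c("allele_frequency_matrix", class(m))
  m
}

#' RMSD distance between allele-frequency profiles
#'
#' d(a,b) = sqrt(mean over loci of (x_a - x_b)^2) computed on allele
#' fractions (0-1); loci where either profile is NA are dropped pairwise.
#'
#' @param mat allele-frequency matrix (percentages, loci x subpopulations)
#' @return a \code{dist} object over subpopulations
#' @export
rmsd_distance <- function(mat) {
  x <- unclass(mat) / 100
  n <- ncol(x)
  if (n < 2) stop_structural("need at least 2 subpopulations")
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(x[, i]) & !is.na(x[, j])
    if (!any(ok)) stop_structural("no pairwise-complete loci for ",
                                  colnames(x)[i], " vs ", colnames(x)[j])
    d[i, j] <- d[j, i] <- sqrt(mean((x[ok, i] - x[ok, j])^2))
  }
  stats::as.dist(d)
}

#' UPGMA dendrogram of subpopulations from reference-allele usage
#'
#' Agglomerates subpopulations by average linkage (UPGMA) on RMSD distances
#' between their reference-allele fraction profiles; the result is an
#' ultrametric rooted tree. Columns that are entirely NA are excluded with a
#' warning.
#'
#' @param mat allele-frequency matrix from [reference_allele_matrix()]
#' @return an \code{upgma_dendrogram}: list with \code{hclust} (merge
#'   heights = cophenetic distances), \code{phylo} (ultrametric
#'   \pkg{ape} tree, branch lengths = heights/2), \code{newick} string
#' @export
upgma_rmsd <- function(mat) {
  allna <- apply(unclass(mat), 2, function(col) all(is.na(col)))
  if (any(allna)) {
    warning("excluding all-NA subpopulation column(s): ",
            paste(colnames(mat)[allna], collapse = ", "))
    mat <- mat[, !allna, drop = FALSE]
  }
  d <- rmsd_distance(mat)
  hc <- stats::hclust(d, method = "average")
  ph <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = ph, newick = ape::write.tree(ph)),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram over", length(x$hclust$labels), "subpopulations\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' @export
#' @method plot upgma_dendrogram
plot.upgma_dendrogram <- function(x, ...) plot(x$hclust, ...)

#' The two subpopulation groups separated at the dendrogram root
#' @param dend an \code{upgma_dendrogram}
#' @return list of two character vectors of subpopulation names
#' @export
root_bipartition <- function(dend) {
  k <- stats::cutree(dend$hclust, k = 2)
  unname(split(names(k), k))
}
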