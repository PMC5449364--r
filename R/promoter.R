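#' Extract promoter sequences upstream of the translation start
#'
#' The promoter of a gene is the \code{length} bases of genomic sequence
#' immediately upstream of its translation start (the first CDS base, i.e.
#' the A of the ATG) in transcript orientation: for a plus-strand gene the
#' genomic window \code{[atg - length, atg)}; for a minus-strand gene the
#' reverse complement of \code{[atg, atg + length)}. Windows running off the
#' chromosome are clipped and flagged. Genes without CDS are skipped with a
#' warning. The anchor can be switched to the transcript start (first exon
#' base) with \code{anchor = "tss"}.
#'
#' @param models gene models
#' @param genome named list or \code{Biostrings::DNAStringSet} of chromosome
#'   sequences
#' @param length promoter length in bp (default 2000)
#' @param anchor \code{"atg"} (first CDS base, default) or \code{"tss"}
#' @return a \code{promoter_set}: list with \code{sequences} (named character
#'   vector, promoter 5'->3' ending just before the anchor) and \code{info}
#'   (data.frame gene_id, chromosome, strand, genomic start/end of the
#'   window, clipped flag)
#' @export
extract_promoters <- function(models, genome, length = 2000L, anchor = c("atg", "tss")) {
  anchor <- match.arg(anchor)
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  genes <- gene_table(models)
  seqs <- character(0); info <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    iv <- feature_intervals(models, gid, if (anchor == "atg") "CDS" else "exon")
    if (!nrow(iv)) {
      warning("gene ", gid, " has no ", if (anchor == "atg") "CDS" else "exon",
              " feature; skipped")
      next
    }
    chrom <- genes$chromosome[i]
    chrseq <- genome[[chrom]]
    if (is.null(chrseq)) stop_structural("chromosome ", chrom, " absent from genome")
    clen <- nchar(chrseq)
    if (genes$strand[i] == "+") {
      atg <- min(iv$start)                       # 1-based first coding base
      from <- max(1L, atg - length); to <- atg - 1L
      clipped <- from > atg - length
      s <- if (to >= from) substr(chrseq, from, to) else ""
    } else {
      atg <- max(iv$end)
      from <- atg + 1L; to <- min(clen, atg + length)
      clipped <- to < atg + length
      s <- if (to >= from) revcomp_chr(substr(chrseq, from, to)) else ""
    }
    seqs[gid] <- s
    info[[gid]] <- data.frame(gene_id = gid, chromosome = chrom,
                              strand = genes$strand[i],
                              genomic_start = from, genomic_end = to,
                              length = nchar(s), clipped = clipped,
                              stringsAsFactors = FALSE)
  }
  info <- if (length(info)) do.call(rbind, c(info, list(make.row.names = FALSE)))
          else data.frame(gene_id = character(), chromosome = character(),
                          strand = character(), genomic_start = integer(),
                          genomic_end = integer(), length = integer(),
                          clipped = logical(), stringsAsFactors = FALSE)
  structure(list(sequences = seqs, info = info), class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("promoter_set:", length(x$sequences), "promoters,",
      sum(x$info$clipped), "clipped\n")
  invisible(x)
}

# 5-symbol encoding: A C G T -> 1:4, anything else (N, separators) -> 5
encode_dna <- function(s) {
  lut <- rep(5L, 256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt(s)]
}

#' Scan promoters with a PWM library (log-odds, both strands)
#'
#' Per-position log-odds score in bits: sum over motif columns of
#' log2(p_col(base)/bg(base)). Both strands are scanned; a minus-strand match
#' at promoter interval [s, s+w) means the reverse complement of that window
#' matches the motif. Windows overlapping an N score -Inf and are never
#' reported. Every window scoring at or above the threshold is reported
#' (individual matches, no cluster-level aggregation).
#'
#' @param promoters a \code{promoter_set}, or a named character vector of
#'   sequences
#' @param pwms a [pwm_library()]
#' @param score_threshold_bits report matches with score >= this (default 6)
#' @return data.frame: motif_id, gene_id, start, end (0-based half-open
#'   promoter coordinates), strand, score
#' @export
scan_motifs <- function(promoters, pwms, score_threshold_bits = 6) {
  if (inherits(promoters, "promoter_set")) promoters <- promoters$sequences
  if (is.null(names(promoters)) || any(!nzchar(names(promoters))))
    stop_structural("promoters must be named by gene id")
  if (!inherits(pwms, "pwm_library")) stop_config("pwms must be a pwm_library")
  if (!is.finite(score_threshold_bits)) stop_config("threshold must be finite")
  lens <- nchar(promoters)
  # one concatenated scan per motif x strand: promoters joined by an N
  # sentinel, so any window crossing a boundary scores -Inf automatically
  codes <- encode_dna(paste(promoters, collapse = "N"))
  n <- length(codes)
  offset <- c(0L, cumsum(lens + 1L))[seq_along(promoters)]  # concat pos of base 1 minus 1
  prom_at <- function(pos) findInterval(pos, offset + 1L)
  out <- list()
  for (m in pwms) {
    w <- ncol(m$matrix)
    L <- rbind(log2(m$matrix / m$background[c("A", "C", "G", "T")]),
               `N` = rep(-Inf, w))
    Lminus <- L[c(4:1, 5), rev(seq_len(w)), drop = FALSE]   # revcomp scan
    for (strand in c("+", "-")) {
      M <- if (strand == "+") L else Lminus
      if (n < w) next
      s <- numeric(n - w + 1L)
      for (j in seq_len(w)) s <- s + M[, j][codes[j:(n - w + j)]]
      hit <- which(s >= score_threshold_bits)
      if (!length(hit)) next
      pi <- prom_at(hit)
      start0 <- hit - offset[pi] - 1L           # 0-based within promoter
      out[[length(out) + 1L]] <- data.frame(
        motif_id = m$id, gene_id = names(promoters)[pi],
        start = start0, end = start0 + w, strand = strand,
        score = s[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif_id = character(), gene_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$motif_id, res$gene_id, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Filter motif matches by functional regions
#'
#' Keeps a match iff at least \code{min_fraction} of its length overlaps one
#' single merged functional region (conserved non-coding sequence or open
#' chromatin): regions are first merged (union of overlapping or book-ended
#' intervals), then overlap is measured against individual merged regions, so
#' a match straddling two regions separated by a gap is judged on its best
#' single-region overlap — the \code{intersectBed -f} semantics.
#'
#' @param matches data.frame from [scan_motifs()]
#' @param regions data.frame gene_id, start, end (0-based half-open promoter
#'   coordinates), e.g. from [read_regions_bed()]
#' @param min_fraction minimum overlap fraction of the match length
#'   (default 0.5)
#' @return the retained subset of \code{matches}
#' @export
filter_by_functional_regions <- function(matches, regions, min_fraction = 0.5) {
  if (!nrow(matches)) return(matches)
  if (!all(c("gene_id", "start", "end") %in% names(regions)))
    stop_structural("regions need columns gene_id, start, end")
  if (any(regions$end < regions$start)) stop_structural("region with end < start")
  if (!nrow(regions)) return(matches[0, , drop = FALSE])
  rgr <- GenomicRanges::GRanges(regions$gene_id,
                                IRanges::IRanges(regions$start + 1L, regions$end))
  rgr <- GenomicRanges::reduce(rgr)             # merges overlapping + book-ended
  mgr <- GenomicRanges::GRanges(matches$gene_id,
                                IRanges::IRanges(matches$start + 1L, matches$end))
  ov <- GenomicRanges::findOverlaps(mgr, rgr)
  if (!length(ov)) return(matches[0, , drop = FALSE])
  inter <- IRanges::width(IRanges::pintersect(mgr[S4Vectors::queryHits(ov)],
                                              rgr[S4Vectors::subjectHits(ov)]))
  best <- tapply(inter, S4Vectors::queryHits(ov), max)
  keep_idx <- as.integer(names(best))[best >= min_fraction * IRanges::width(mgr)[as.integer(names(best))]]
  out <- matches[sort(keep_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read promoter functional regions from BED
#'
#' BED is 0-based half-open; the chrom column names the promoter (gene id).
#' @param path BED file
#' @return data.frame gene_id, start, end (0-based half-open)
#' @export
read_regions_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(gene_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Write promoter functional regions to BED
#' @param regions data.frame gene_id, start, end (0-based half-open)
#' @param path output file
#' @return \code{path}, invisibly
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(regions$gene_id,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Build a co-expression regulon around a focal gene
#'
#' Pearson correlation between the focal gene's expression profile and every
#' other gene across all samples; the \code{top_n} most positively
#' correlated genes are selected ("co-expressed" is taken as positive
#' co-variation). When an id map is supplied, members whose id has no
#' mapping are dropped and the post-mapping size recorded — mirroring the
#' shrinkage seen when converting between annotation namespaces.
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples)
#' @param focal_gene row name of the focal gene
#' @param top_n regulon size cap (default 200)
#' @param id_map optional data.frame gene_id, mapped_id (NA = unmapped)
#' @return a \code{regulon}: list with \code{focal}, \code{members}
#'   (data.frame gene_id, r, mapped_id, sorted by descending r) and
#'   \code{size}
#' @export
build_regulon <- function(expr, focal_gene, top_n = 200L, id_map = NULL) {
  if (!focal_gene %in% rownames(expr)) stop_structural("focal gene not in matrix")
  if (ncol(expr) < 3) stop_structural("need >= 3 samples")
  f <- expr[focal_gene, ]
  if (stats::sd(f) == 0) stop_structural("zero-variance focal profile: correlation undefined")
  others <- expr[rownames(expr) != focal_gene, , drop = FALSE]
  sds <- apply(others, 1, stats::sd)
  r <- rep(NA_real_, nrow(others)); names(r) <- rownames(others)
  r[sds > 0] <- as.vector(stats::cor(f, t(others[sds > 0, , drop = FALSE])))
  ord <- order(r, decreasing = TRUE, na.last = TRUE)
  sel <- ord[seq_len(min(top_n, sum(!is.na(r))))]
  members <- data.frame(gene_id = names(r)[sel], r = unname(r[sel]),
                        mapped_id = names(r)[sel], stringsAsFactors = FALSE)
  if (!is.null(id_map)) {
    members$mapped_id <- id_map$mapped_id[match(members$gene_id, id_map$gene_id)]
    members <- members[!is.na(members$mapped_id), , drop = FALSE]
  }
  rownames(members) <- NULL
  structure(list(focal = focal_gene, members = members, size = nrow(members)),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat("regulon of", x$focal, "-", x$size, "members; top r =",
      signif(x$members$r[1], 3), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: q_i = min over j with rank >= rank(i) of
#' m * p_(j) / j, capped at 1.
#' @param p_values vector of p-values in (0, 1]
#' @return q-values in the input order
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop_structural("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric motif enrichment over a regulon
#'
#' For each motif, presence/absence (>= 1 retained match) defines k regulon
#' promoters and K background promoters carrying the motif out of n regulon
#' and N background promoters; p is the upper-tail hypergeometric probability
#' P(X >= k), q the BH adjustment across the motif library. The final
#' \code{enriched} flag additionally requires the motif to be present in the
#' focal gene's own promoter.
#'
#' @param regulon a [build_regulon()] result or character vector of regulon
#'   gene ids (promoter namespace)
#' @param matches retained matches (after any functional-region filtering)
#' @param background character vector of all gene ids with extracted
#'   promoters (the sampling universe; must contain the regulon)
#' @param focal_gene focal gene id; defaults to \code{regulon$focal}
#' @param q_threshold significance cutoff on q (default 0.05)
#' @return an \code{enrichment_result} data.frame: motif_id, k, n, K, N, p,
#'   q, present_in_focal, enriched
#' @export
hypergeom_enrichment <- function(regulon, matches, background,
                                 focal_gene = NULL, q_threshold = 0.05) {
  if (inherits(regulon, "regulon")) {
    if (is.null(focal_gene)) focal_gene <- regulon$focal
    regulon <- regulon$members$mapped_id
  }
  regulon <- unique(regulon)
  background <- unique(background)
  out_of_frame <- setdiff(regulon, background)
  if (length(out_of_frame))
    stop_structural("regulon gene(s) absent from background: ",
                    paste(utils::head(out_of_frame, 5), collapse = ", "))
  n <- length(regulon); N <- length(background)
  motifs <- unique(matches$motif_id)
  rows <- lapply(motifs, function(mid) {
    present <- unique(matches$gene_id[matches$motif_id == mid])
    present <- intersect(present, background)
    k <- length(intersect(present, regulon))
    K <- length(present)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(motif_id = mid, k = k, n = n, K = K, N = N, p = p,
               present_in_focal = !is.null(focal_gene) && focal_gene %in% present,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(motif_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      present_in_focal = logical(), stringsAsFactors = FALSE)
  res$q <- if (nrow(res)) bh_fdr(res$p) else numeric(0)
  res$enriched <- res$q < q_threshold & res$present_in_focal
  res <- res[, c("motif_id", "k", "n", "K", "N", "p", "q",
                 "present_in_focal", "enriched")]
  class(res) <- c("enrichment_result", "data.frame")
  res
}
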