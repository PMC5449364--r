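#' Stress/hormone fold-change profile per gene
#'
#' Per transcript and stratum (tissue x timepoint x treatment condition) the
#' fold change is (treated + pseudocount)/(control + pseudocount); per gene
#' the arithmetic mean over its transcripts (genes with several
#' representative transcripts behave very similarly, so the mean is the
#' reported profile). A stratum lacking a control measurement is an error
#' naming the stratum; a zero-expression control is rescued by the
#' pseudocount and the record flagged.
#'
#' @param expr long-format data.frame: gene_id, transcript_id, tissue,
#'   condition, timepoint, value, and optionally fdr (a q-value per
#'   treated record)
#' @param pseudocount added to numerator and denominator (default 1e-6)
#' @param control_label condition name of the control (default
#'   \code{"control"})
#' @return data.frame per gene x tissue x condition x timepoint:
#'   \code{fold_change} (mean over transcripts), \code{n_transcripts},
#'   \code{zero_control} flag, and \code{fdr}/\code{stars} when fdr was
#'   supplied (minimum q over transcripts)
#' @export
fold_change_profile <- function(expr, pseudocount = 1e-6,
                                control_label = "control") {
  need <- c("gene_id", "transcript_id", "tissue", "condition", "timepoint", "value")
  if (!all(need %in% names(expr)))
    stop_structural("expression table needs columns ", paste(need, collapse = ", "))
  if (any(expr$value < 0)) stop_structural("negative expression value")
  has_fdr <- "fdr" %in% names(expr)
  ctrl <- expr[expr$condition == control_label, ]
  trt <- expr[expr$condition != control_label, ]
  ckey <- paste(ctrl$transcript_id, ctrl$tissue, ctrl$timepoint, sep = "\r")
  cval <- stats::setNames(ctrl$value, ckey)
  tkey <- paste(trt$transcript_id, trt$tissue, trt$timepoint, sep = "\r")
  missing <- !(tkey %in% ckey)
  if (any(missing)) {
    ex <- trt[which(missing)[1], ]
    stop_structural("no control for stratum transcript=", ex$transcript_id,
                    " tissue=", ex$tissue, " timepoint=", ex$timepoint)
  }
  trt$fc <- (trt$value + pseudocount) / (cval[tkey] + pseudocount)
  trt$zero_control <- cval[tkey] == 0
  gkey <- paste(trt$gene_id, trt$tissue, trt$condition, trt$timepoint, sep = "\r")
  agg <- function(x, f) as.vector(tapply(x, factor(gkey, levels = unique(gkey)), f))
  out <- trt[!duplicated(gkey), c("gene_id", "tissue", "condition", "timepoint")]
  out$fold_change <- agg(trt$fc, mean)
  out$n_transcripts <- agg(trt$transcript_id, function(v) length(unique(v)))
  out$zero_control <- agg(trt$zero_control, any)
  if (has_fdr) {
    out$fdr <- agg(trt$fdr, min)
    out$stars <- significance_stars(out$fdr)
  }
  rownames(out) <- NULL
  out
}

#' Significance stars for an FDR q-value
#'
#' Two-tier annotation: \code{"***"} for q below the lower tier (default
#' 0.001), \code{"**"} for q below the upper tier (default 0.05) but at or
#' above the lower one, empty otherwise. An optional third, single-star tier
#' can be enabled by supplying three decreasing cutoffs, but is off by
#' default because the common one/two-star boundaries overlap the two-star
#' definition.
#'
#' @param q numeric vector of q-values in [0, 1]
#' @param tiers decreasing cutoffs, outermost first (default
#'   \code{c(0.05, 0.001)} giving "**" and "***")
#' @return character vector of star strings
#' @export
significance_stars <- function(q, tiers = c(0.05, 0.001)) {
  if (any(is.na(q)) || any(q < 0) || any(q > 1))
    stop_structural("q-values must lie in [0, 1]")
  if (is.unsorted(rev(tiers), strictly = TRUE))
    stop_config("tiers must be strictly decreasing")
  base_stars <- 3L - length(tiers)  # 2 tiers -> ** and ***, 3 tiers -> * ** ***
  n_below <- vapply(q, function(qi) sum(qi < tiers), integer(1))
  vapply(n_below, function(k) {
    if (k == 0) "" else strrep("*", base_stars + k)
  }, character(1))
}

#' Replicate-based significance of stress responses
#'
#' For synthetic or replicate-level tables where no external q-values exist:
#' per gene x tissue x condition x timepoint, a two-sample t-test of treated
#' versus control replicate values, with BH correction across all strata.
#' A stand-in for database-supplied FDR values, labelled as such.
#'
#' @param expr long-format table as in [fold_change_profile()] with a
#'   \code{replicate} column
#' @param control_label control condition name
#' @return data.frame gene_id, tissue, condition, timepoint, p, fdr
#' @export
replicate_significance <- function(expr, control_label = "control") {
  trt <- expr[expr$condition != control_label, ]
  key <- unique(trt[, c("gene_id", "tissue", "condition", "timepoint")])
  p <- vapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    a <- trt$value[trt$gene_id == k$gene_id & trt$tissue == k$tissue &
                   trt$condition == k$condition & trt$timepoint == k$timepoint]
    b <- expr$value[expr$gene_id == k$gene_id & expr$tissue == k$tissue &
                    expr$condition == control_label & expr$timepoint == k$timepoint]
    if (length(a) < 2 || length(b) < 2) return(1)
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else .Machine$double.xmin)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  key$p <- p
  key$fdr <- bh_fdr(p)
  rownames(key) <- NULL
  key
}
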