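# Independent brute-force oracles used by the property and acceptance tests.
# These deliberately share no code with the package implementations.

# --- tandem calling: all-pairs linkage + union-find ------------------------
naive_tandem_blocks <- function(order, fam_pairs, max_intervening = 10L) {
  df <- merge(fam_pairs, order, by = "gene_id")
  key <- paste(df$gene_id, df$family)
  parent <- stats::setNames(seq_along(key), key)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n <- nrow(df)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (df$family[i] == df$family[j] &&
        df$chromosome[i] == df$chromosome[j] &&
        abs(df$rank[i] - df$rank[j]) - 1L <= max_intervening) {
      ri <- find(i); rj <- find(j)
      parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, numeric(1))
  comps <- split(seq_len(n), roots)
  comps <- Filter(function(ix) length(ix) >= 2, comps)
  blocks <- vapply(comps, function(ix) {
    ix <- ix[order(df$rank[ix])]
    paste(df$family[ix[1]], df$chromosome[ix[1]],
          paste(df$gene_id[ix], collapse = ","))
  }, character(1))
  sort(unname(blocks))
}

# package result in the same canonical form
canon_tandem_blocks <- function(blocks) {
  if (!nrow(blocks)) return(character(0))
  sort(paste(blocks$family, blocks$chromosome, blocks$members))
}

# --- hypergeometric upper tail by full enumeration (N <= 12) ---------------
enum_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)     # items 1..K are the marked ones
  mean(marked >= k)
}

# --- PWM scanning by per-offset loops --------------------------------------
brute_scan <- function(seqs, motif, threshold, bg = c(A = .25, C = .25, G = .25, T = .25)) {
  mat <- motif$matrix
  w <- ncol(mat)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_window <- function(win) {
    s <- 0
    for (j in seq_len(w)) {
      b <- substr(win, j, j)
      if (!b %in% c("A", "C", "G", "T")) return(-Inf)
      s <- s + log2(mat[b, j] / bg[[b]])
    }
    s
  }
  out <- list()
  for (g in names(seqs)) {
    sq <- seqs[[g]]
    n <- nchar(sq)
    if (n < w) next
    for (off in 0:(n - w)) {
      win <- substr(sq, off + 1, off + w)
      rcwin <- paste(rev(comp[strsplit(win, "")[[1]]]), collapse = "")
      for (str in c("+", "-")) {
        s <- score_window(if (str == "+") win else rcwin)
        if (s >= threshold)
          out[[length(out) + 1]] <- data.frame(
            motif_id = motif$id, gene_id = g, start = off, end = off + w,
            strand = str, score = s, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(motif_id = character(), gene_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric()))
  res <- do.call(rbind, out)
  res[order(res$motif_id, res$gene_id, res$start, res$strand), ]
}

# --- UPGMA agglomeration from first principles -----------------------------
# returns the cophenetic distance matrix (merge height of each pair)
naive_upgma_cophenetic <- function(D) {
  labs <- labels(D)
  Dm <- as.matrix(D)
  clusters <- as.list(labs)
  coph <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1):length(clusters)) {
        d <- mean(Dm[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    i <- best[2]; j <- best[3]
    for (a in clusters[[i]]) for (b in clusters[[j]])
      coph[a, b] <- coph[b, a] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# --- per-column information content ----------------------------------------
naive_column_ic <- function(residues) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  residues <- residues[residues %in% aas]
  if (!length(residues)) return(NA_real_)
  p <- table(factor(residues, levels = aas)) / length(residues)
  p <- p[p > 0]
  log2(20) + sum(p * log2(p))
}

# --- Benjamini-Hochberg step-up by hand ------------------------------------
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(scaled)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# --- small builders --------------------------------------------------------
# gene models laid out on one or more chromosomes from a compact spec:
# data.frame(gene_id, chromosome, start) with fixed-size single-exon genes
toy_models <- function(genes, width = 100L, strand = "+") {
  rows <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    data.frame(gene_id = g$gene_id, chromosome = g$chromosome,
               strand = strand, type = c("gene", "exon", "CDS"),
               start = g$start, end = g$start + width - 1L,
               stringsAsFactors = FALSE)
  }))
  gene_models(rows)
}

rownames_key <- function(df) paste(df$gene_id, df$start, df$end)

# assignment table in the classify_lectin_genes output format
toy_assignments <- function(gene_id, family) {
  data.frame(gene_id = gene_id, families = family,
             n_families = 1L, multi_family = FALSE, stringsAsFactors = FALSE)
}
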