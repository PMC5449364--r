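# Promoter extraction, PWM scanning, functional-region filtering, regulon
# construction and hypergeometric enrichment.

test_that("promoters are the 2 kb upstream of the ATG, strand-aware, clipped", {
  chrom <- random_seq <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE),
                               collapse = "")
  genome <- list(chr1 = chrom)
  m <- gene_models(data.frame(
    gene_id = c("plus", "clipped", "minus"),
    chromosome = "chr1", strand = c("+", "+", "-"),
    type = "gene", start = c(5001, 1501, 7001), end = c(5600, 2100, 8000)))
  m <- gene_models(rbind(as.data.frame(m), data.frame(
    gene_id = c("plus", "clipped", "minus"), chromosome = "chr1",
    strand = c("+", "+", "-"), type = "CDS",
    start = c(5001, 1501, 7001), end = c(5600, 2100, 8000))))
  ps <- extract_promoters(m, genome, length = 2000)
  # + strand, ATG at genomic 5001 (0-based 5000): promoter = [3000, 5000)
  expect_identical(ps$sequences[["plus"]], substr(chrom, 3001, 5000))
  expect_false(ps$info$clipped[ps$info$gene_id == "plus"])
  # ATG at 0-based 1500: clipped to [0, 1500)
  expect_identical(nchar(ps$sequences[["clipped"]]), 1500L)
  expect_identical(ps$sequences[["clipped"]], substr(chrom, 1, 1500))
  expect_true(ps$info$clipped[ps$info$gene_id == "clipped"])
  # - strand, first CDS base at 0-based 7999: revcomp of [8000, 10000)
  want <- chartr("ACGT", "TGCA", substr(chrom, 8001, 10000))
  want <- paste(rev(strsplit(want, "")[[1]]), collapse = "")
  expect_identical(ps$sequences[["minus"]], want)
})

test_that("genes without CDS are skipped with a warning", {
  genome <- list(chr1 = strrep("ACGT", 1000))
  m <- gene_models(data.frame(gene_id = "nocds", chromosome = "chr1",
                              strand = "+", type = "gene",
                              start = 3000, end = 3500))
  expect_warning(ps <- extract_promoters(m, genome), "nocds")
  expect_length(ps$sequences, 0)
})

test_that("a background-equal PWM scores zero everywhere; a sharp PWM scores 2 bits per matched column", {
  flat <- pwm_library(list(list(id = "flat",
                                matrix = matrix(0.25, 4, 4))), pseudocount = 0)
  hits <- scan_motifs(c(g = "ACGTACGTAC"), flat, score_threshold_bits = 0)
  expect_true(all(hits$score == 0))
  expect_identical(nrow(scan_motifs(c(g = "ACGTACGTAC"), flat,
                                    score_threshold_bits = 0.1)), 0L)

  sharp <- pwm_library(list(list(id = "sharp", matrix = local({
    m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(1:4, 1:4)] <- 1      # consensus ACGT
    m
  }))), pseudocount = 0)
  hits <- scan_motifs(c(g = "TTACGTTT"), sharp, score_threshold_bits = 7.9)
  plus <- hits[hits$strand == "+", ]
  expect_identical(plus$start, 2L)
  expect_equal(plus$score, 8, tolerance = 1e-9)  # 4 x log2(4)
})

test_that("windows containing N are never reported", {
  sharp <- pwm_library(list(list(id = "m", matrix = local({
    m <- matrix(1e-9, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(c(1, 2, 3), 1:3)] <- 1
    m
  }))))
  hits <- scan_motifs(c(g = "ACGNACG"), sharp, score_threshold_bits = 1)
  expect_true(all(hits$start %in% c(0L, 4L)))
  expect_false(any(hits$start %in% 1:3))
})

test_that("scan scores equal exhaustive per-offset enumeration on short promoters", {
  set.seed(12)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:15) {
    seqs <- stats::setNames(
      vapply(1:4, function(i) paste(sample(c(bases, "N"), sample(10:50, 1),
                                           TRUE, prob = c(rep(.24, 4), .04)),
                                    collapse = ""), character(1)),
      paste0("p", 1:4))
    w <- sample(3:8, 1)
    counts <- matrix(stats::rpois(4 * w, 5), 4,
                     dimnames = list(bases, NULL))
    lib <- pwm_library(list(list(id = "m", matrix = counts)))
    thr <- stats::runif(1, -10, 4)
    got <- scan_motifs(seqs, lib, thr)
    want <- brute_scan(seqs, lib$m, thr)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("region filtering uses best single merged-region overlap at 50%", {
  mk_match <- function(start, end) data.frame(
    motif_id = "m", gene_id = "g", start = start, end = end, strand = "+",
    score = 10, stringsAsFactors = FALSE)
  # 10-bp match [10,20): 5-bp overlap retained, 4-bp dropped
  reg5 <- data.frame(gene_id = "g", start = 15, end = 40)
  expect_identical(nrow(filter_by_functional_regions(mk_match(10, 20), reg5)), 1L)
  reg4 <- data.frame(gene_id = "g", start = 16, end = 40)
  expect_identical(nrow(filter_by_functional_regions(mk_match(10, 20), reg4)), 0L)
  # 3 bp + 3 bp across a 1-bp gap: no single region reaches 50%
  straddle <- data.frame(gene_id = "g", start = c(7, 14), end = c(13, 17))
  expect_identical(nrow(filter_by_functional_regions(mk_match(10, 20), straddle)), 0L)
  # book-ended regions merge first, so 3+3 contiguous bp count as 6... still
  # short of 5? no: merged [7,20) overlap is full 10 -> retained
  bookend <- data.frame(gene_id = "g", start = c(7, 13), end = c(13, 20))
  expect_identical(nrow(filter_by_functional_regions(mk_match(10, 20), bookend)), 1L)
})

test_that("filtered sets match a naive per-base computation on random intervals", {
  set.seed(77)
  naive_keep <- function(matches, regions, min_fraction) {
    merged_by_gene <- lapply(split(regions, regions$gene_id), function(r) {
      cov <- rep(FALSE, 500)
      for (i in seq_len(nrow(r))) if (r$end[i] > r$start[i])
        cov[(r$start[i] + 1):r$end[i]] <- TRUE
      # split covered bases into maximal runs
      rl <- rle(cov)
      ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
      cbind(starts[rl$values], ends[rl$values])
    })
    keep <- logical(nrow(matches))
    for (i in seq_len(nrow(matches))) {
      runs <- merged_by_gene[[matches$gene_id[i]]]
      if (is.null(runs) || !nrow(runs)) next
      a <- matches$start[i] + 1; b <- matches$end[i]
      ov <- pmax(0, pmin(b, runs[, 2]) - pmax(a, runs[, 1]) + 1)
      keep[i] <- max(ov) >= min_fraction * (b - a + 1)
    }
    which(keep)
  }
  for (rep in 1:25) {
    n_m <- sample(5:40, 1); n_r <- sample(1:30, 1)
    genes <- paste0("g", 1:3)
    w <- sample(4:12, n_m, replace = TRUE)
    st <- sample(0:(480), n_m, replace = TRUE)
    matches <- data.frame(motif_id = "m", gene_id = sample(genes, n_m, TRUE),
                          start = st, end = st + w, strand = "+", score = 1,
                          stringsAsFactors = FALSE)
    rs <- sample(0:480, n_r, replace = TRUE)
    regions <- data.frame(gene_id = sample(genes, n_r, TRUE),
                          start = rs, end = rs + sample(1:40, n_r, TRUE))
    frac <- sample(c(0.3, 0.5, 0.8), 1)
    got <- filter_by_functional_regions(matches, regions, frac)
    want <- matches[naive_keep(matches, regions, frac), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("adding regions can only grow, and raising min_fraction only shrink, the retained set", {
  set.seed(5)
  st <- sample(0:90, 30, TRUE)
  matches <- data.frame(motif_id = "m", gene_id = "g", start = st,
                        end = st + 8, strand = "+", score = 1)
  r1 <- data.frame(gene_id = "g", start = c(10, 40), end = c(30, 60))
  r2 <- rbind(r1, data.frame(gene_id = "g", start = 70, end = 95))
  k1 <- filter_by_functional_regions(matches, r1)
  k2 <- filter_by_functional_regions(matches, r2)
  expect_true(all(rownames_key(k1) %in% rownames_key(k2)))
  k_strict <- filter_by_functional_regions(matches, r1, min_fraction = 0.9)
  expect_true(all(rownames_key(k_strict) %in% rownames_key(k1)))
})

test_that("regulons select top positive correlations and shrink through the id map", {
  set.seed(3)
  profile <- c(1, 5, 2, 8, 3, 9, 4, 7, 2, 6)
  expr <- rbind(
    focal = profile,
    twin = profile * 2,                        # r = 1, noiseless copy
    anti = -profile,
    matrix(rnorm(300 * 10), 300, dimnames = list(paste0("bg", 1:300), NULL)))
  reg <- build_regulon(expr, "focal", top_n = 50)
  expect_identical(reg$members$gene_id[1], "twin")
  expect_equal(reg$members$r[1], 1)
  expect_false("anti" %in% reg$members$gene_id)  # signed r, not |r|
  expect_identical(reg$size, 50L)

  id_map <- data.frame(gene_id = rownames(expr),
                       mapped_id = rownames(expr), stringsAsFactors = FALSE)
  id_map$mapped_id[id_map$gene_id %in% reg$members$gene_id[1:10]] <- NA
  reg2 <- build_regulon(expr, "focal", top_n = 50, id_map = id_map)
  expect_identical(reg2$size, 40L)               # 50 selected, 10 unmapped

  flat <- expr; flat["focal", ] <- 1
  expect_error(build_regulon(flat, "focal"), "zero-variance")
})

test_that("hypergeometric p-values match closed cases and BH behaves as hand-computed", {
  matches <- data.frame(motif_id = "m", gene_id = c("g1", "g2"),
                        start = 0, end = 5, strand = "+", score = 9)
  # N=5, K=2, n=2, k=2 -> 1/10
  er <- hypergeom_enrichment(c("g1", "g2"), matches, paste0("g", 1:5),
                             focal_gene = "g1")
  expect_equal(er$p, 0.1)
  expect_true(er$present_in_focal)
  # k = 0 -> p = 1
  er0 <- hypergeom_enrichment(c("g3", "g4"), matches, paste0("g", 1:5))
  expect_equal(er0$p, 1)
  expect_false(er0$enriched)
  expect_error(hypergeom_enrichment(c("g1", "zz"), matches, paste0("g", 1:5)),
               "zz")

  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  expect_error(bh_fdr(c(0.5, 0)), "p-values")
  set.seed(9)
  for (rep in 1:10) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_fdr(p), hand_bh(p))
  }
})

test_that("a significant motif absent from the focal promoter is not flagged enriched", {
  matches <- data.frame(motif_id = "m", gene_id = paste0("g", 1:10),
                        start = 0, end = 5, strand = "+", score = 9)
  bg <- paste0("g", 1:100)
  er <- hypergeom_enrichment(paste0("g", 1:10), matches, bg,
                             focal_gene = "g99", q_threshold = 0.05)
  expect_lt(er$q, 0.05)
  expect_false(er$present_in_focal)
  expect_false(er$enriched)
})
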