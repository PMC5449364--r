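# The generators must be deterministic under a fixed seed, emit every planted
# feature in their truth manifests, and respect their degenerate-input
# contracts.

small_cfg <- function(seed = 11, ...) {
  defaults <- list(
    seed = seed, n_chromosomes = 2, genes_per_chromosome = 30,
    n_genes_expression = 120, n_snps = 10, promoter_length = 300,
    module_spec = list(list(module_id = "M1", size = 20, members = NULL,
                            baseline = 10, noise_sd = 0.5,
                            fold_changes = c(drought = 4, osmotic = 2,
                                             ABA = 1.5, JA = 1))),
    tandem_array_spec = data.frame(family = "EUL", size = 3,
                                   chromosome = "chr2"))
  over <- list(...)
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  do.call(simulation_config, defaults)
}

test_that("configuration validation rejects degenerate inputs", {
  expect_error(simulation_config(genes_per_chromosome = 0), "positive")
  expect_error(simulation_config(tandem_array_spec = data.frame(
    family = "EUL", size = 3, chromosome = "chr99")), "unknown chromosome")
  expect_error(small_cfg(subpop_spec = data.frame(
    name = "A", n_accessions = 5, ref_fraction = 1.2)), "\\[0, 1\\]")
  expect_error(small_cfg(motif_plant_spec = list(
    motif_id = "X", in_module = -0.1, background = 0.1)), "probabilities")
  expect_error(small_cfg(motif_width = 400), "longer than promoter")
  expect_error(small_cfg(eul_spec = list(n_S = 2, n_D = 3,
                                         substitution_prob = 1, f118_F = 0.5)),
               "substitution")
})

test_that("identical seed and config give identical outputs across generators", {
  cfg <- small_cfg()
  a <- simulate_genome(cfg); b <- simulate_genome(cfg)
  expect_identical(a, b)
  expect_identical(simulate_population_snps(cfg, a$models),
                   simulate_population_snps(cfg, a$models))
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  ids <- rownames(simulate_expression(cfg)$matrix)[1:50]
  expect_identical(simulate_promoters_and_motifs(cfg, ids, ids[1:10]),
                   simulate_promoters_and_motifs(cfg, ids, ids[1:10]))
  expect_identical(simulate_eul_proteins(cfg), simulate_eul_proteins(cfg))
  # and a different seed actually changes the data
  expect_false(identical(simulate_genome(small_cfg(seed = 12))$genome, a$genome))
})

test_that("simulated genes are non-overlapping, ordered, with in-frame CDS", {
  sim <- simulate_genome(small_cfg())
  g <- gene_table(sim$models)
  for (ch in unique(g$chromosome)) {
    gg <- g[g$chromosome == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
  for (gid in g$gene_id[1:10]) {
    cds <- extract_cds(sim$models, sim$genome, gid)
    expect_identical(nchar(cds) %% 3L, 0L)
  }
})

test_that("planted tandem arrays appear exactly once in the manifest", {
  sim <- simulate_genome(small_cfg())
  tr <- sim$truth$tandem_arrays
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$family, "EUL")
  expect_identical(tr$chromosome, "chr2")
  members <- strsplit(tr$members, ",")[[1]]
  expect_length(members, 3)
  expect_false(anyDuplicated(members) > 0)
  # members carry the planted family in the annotation table
  fam <- classify_lectin_genes(sim$annotations)
  expect_true(all(members %in% fam$gene_id[fam$families == "EUL"]))
})

test_that("SNP genotypes honour extreme reference fractions and zero-SNP input", {
  cfg1 <- small_cfg(subpop_spec = data.frame(
    name = c("P1", "P2"), n_accessions = 20, ref_fraction = c(1, 0)))
  sim <- simulate_genome(cfg1)
  snp <- simulate_population_snps(cfg1, sim$models)
  p1 <- snp$subpopulations$accession[snp$subpopulations$subpopulation == "P1"]
  p2 <- setdiff(snp$subpopulations$accession, p1)
  expect_true(all(snp$genotypes[, p1] == snp$snps$ref))
  expect_true(all(snp$genotypes[, p2] == snp$snps$alt))

  cfg0 <- small_cfg(n_snps = 0)
  empty <- simulate_population_snps(cfg0, sim$models)
  expect_identical(nrow(empty$snps), 0L)
  expect_identical(nrow(empty$genotypes), 0L)
})

test_that("zero-noise modules give exact fold changes and perfect correlation", {
  cfg <- small_cfg(module_spec = list(list(
    module_id = "M1", size = 5, members = NULL, baseline = 10, noise_sd = 0,
    fold_changes = c(drought = 4, osmotic = 2, ABA = 1.5, JA = 1))))
  ex <- simulate_expression(cfg)
  mem <- ex$truth$modules$M1$members
  s <- ex$samples
  for (tp in unique(s$timepoint)) {
    trt <- s$sample_id[s$condition == "drought" & s$timepoint == tp][1]
    ctl <- s$sample_id[s$condition == "control" & s$timepoint == tp][1]
    expect_equal(unname(ex$matrix[mem, trt] / ex$matrix[mem, ctl]),
                 rep(4, length(mem)))
  }
  expect_equal(stats::cor(ex$matrix[mem[1], ], ex$matrix[mem[2], ]), 1)
})

test_that("member vs non-member correlation is centred at zero", {
  rs <- vapply(1:300, function(s) {
    cfg <- small_cfg(seed = s, n_genes_expression = 40,
                     module_spec = list(list(module_id = "M1", size = 3,
                                             members = NULL, baseline = 10,
                                             noise_sd = 0.5,
                                             fold_changes = c(drought = 4,
                                                              osmotic = 2,
                                                              ABA = 1.5, JA = 1))))
    ex <- simulate_expression(cfg)
    mem <- ex$truth$modules$M1$members[1]
    non <- setdiff(rownames(ex$matrix), ex$truth$modules$M1$members)[1]
    stats::cor(ex$matrix[mem, ], ex$matrix[non, ])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("motif planting respects probabilities and records coordinates in range", {
  ids <- sprintf("G%03d", 1:60)
  cfg <- small_cfg(motif_plant_spec = list(motif_id = "SYNMOT01",
                                           in_module = 1, background = 0))
  pm <- simulate_promoters_and_motifs(cfg, ids, module_members = ids[1:25])
  planted <- pm$truth$planted
  expect_setequal(unique(planted$gene_id), ids[1:25])   # all members, no bg
  expect_true(all(planted$start >= 0 & planted$end <= cfg$promoter_length))
  # the exact consensus sits at every recorded coordinate
  cons <- pwm_consensus(pm$pwms$SYNMOT01)
  ok <- vapply(seq_len(nrow(planted)), function(i) {
    substr(pm$promoters[[planted$gene_id[i]]],
           planted$start[i] + 1, planted$end[i]) == cons
  }, logical(1))
  expect_true(all(ok))
})

test_that("functional regions cover the configured promoter fraction", {
  ids <- sprintf("G%03d", 1:40)
  cfg <- small_cfg(region_coverage = 0.25, motif_plant_spec = list(
    motif_id = "SYNMOT01", in_module = 0, background = 0))
  pm <- simulate_promoters_and_motifs(cfg, ids)
  cov <- tapply(pm$regions$end - pm$regions$start, pm$regions$gene_id, sum)
  expect_true(all(abs(cov / cfg$promoter_length - 0.25) < 0.1))
})

test_that("EUL protein sets have the configured architectures and landmarks", {
  cfg <- small_cfg(eul_spec = list(n_S = 2, n_D = 3, substitution_prob = 0.05,
                                   f118_F = 0.63))
  eu <- simulate_eul_proteins(cfg)
  expect_identical(sum(eu$architecture$type == "S"), 2L)
  expect_identical(sum(eu$architecture$type == "D"), 3L)
  expect_true(all(nchar(eu$msa) == 151))
  expect_true(all(substr(eu$msa, 34, 34) == "Q" & substr(eu$msa, 36, 36) == "W"))
  expect_true(all(substr(eu$msa, 116, 116) == "D"))
  expect_true(all(substr(eu$msa, 143, 144) == "NQ"))
  expect_true(all(substr(eu$msa, 118, 118) %in% c("F", "L")))
  expect_true(all(eu$architecture$n_term_length >= 19 &
                    eu$architecture$n_term_length <= 117))
  lk <- eu$architecture$linker_length[eu$architecture$type == "D"]
  expect_true(all(lk >= 18 & lk <= 76))
})

test_that("the position-118 F/L mix matches its planted probability", {
  # pool domains over seeds for a reasonable binomial sample
  l_frac <- unlist(lapply(1:40, function(s) {
    eu <- simulate_eul_proteins(small_cfg(
      seed = s, eul_spec = list(n_S = 3, n_D = 3, substitution_prob = 0,
                                f118_F = 0.63)))
    substr(eu$msa, 118, 118) == "L"
  }))
  n <- length(l_frac)                      # 40 seeds x 9 domains
  p_hat <- mean(l_frac)
  expect_lt(abs(p_hat - 0.37), 3 * sqrt(0.37 * 0.63 / n))
})

test_that("zero substitution probability reproduces the consensus exactly", {
  eu <- simulate_eul_proteins(small_cfg(eul_spec = list(
    n_S = 2, n_D = 2, substitution_prob = 0, f118_F = 1)))
  expect_true(all(eu$msa == eu$truth$consensus))
})
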