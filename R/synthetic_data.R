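#' Configuration for the synthetic-data generators
#'
#' One configuration object drives all five generators, so a single seed
#' reproduces an entire synthetic study byte for byte. The defaults encode
#' the study conditions the pipeline is validated under: a japonica/indica-like
#' two-cluster panel (reference-allele fractions 0.95 vs 0.05, 50 accessions
#' per subpopulation, 20 SNP loci), one planted 150-gene co-expression module
#' among 2000 genes with stress fold changes (drought 4x, osmotic 2x, ABA
#' 1.5x, JA 1x), a promoter motif planted at frequency 0.6 inside the module
#' versus 0.1 in the background, functional regions covering 25% of promoter
#' bases, and an EUL protein set of 2 S-type and 3 D-type proteins (the rice
#' counts) with the F/L mix at domain position 118 set to 0.63/0.37.
#'
#' @param seed integer RNG seed
#' @param n_chromosomes,genes_per_chromosome genome layout (both positive)
#' @param family_labels lectin families available for background labelling
#' @param family_fraction fraction of genes given a background family label
#' @param tandem_array_spec data.frame \code{family}, \code{size},
#'   \code{chromosome}: tandem arrays to plant
#' @param subpop_spec data.frame \code{name}, \code{n_accessions},
#'   \code{ref_fraction}: per-subpopulation reference-allele fraction,
#'   applied to every SNP
#' @param n_snps number of SNP loci to simulate
#' @param missing_rate per-genotype missing-call probability
#' @param n_genes_expression size of the expression gene universe
#' @param module_spec list of module descriptions: \code{module_id},
#'   \code{size} (or explicit \code{members}), \code{baseline},
#'   \code{fold_changes} (named by condition), \code{noise_sd}
#' @param conditions,timepoints,replicates expression design (conditions in
#'   addition to the control)
#' @param motif_plant_spec list \code{motif_id}, \code{in_module},
#'   \code{background}: planting probabilities for the focal motif
#' @param n_motifs,motif_width PWM library size and motif width
#' @param promoter_length promoter length in bp (default 2000)
#' @param region_coverage fraction of promoter bases covered by functional
#'   regions
#' @param region_cover_planted fraction of planted motif instances that get
#'   a covering functional region
#' @param eul_spec list \code{n_S}, \code{n_D}, \code{substitution_prob}
#'   (per non-landmark site, in [0,1)), \code{f118_F} (probability of F over
#'   L at position 118)
#' @param id_unmapped_fraction fraction of expression gene ids left without
#'   a mapping in the id-conversion table (drives regulon shrinkage)
#' @return a \code{simulation_config} object
#' @export
simulation_config <- function(
    seed = 1L,
    n_chromosomes = 3L,
    genes_per_chromosome = 60L,
    family_labels = c("EUL", "GNA", "legume"),
    family_fraction = 0.1,
    tandem_array_spec = data.frame(family = "EUL", size = 3L, chromosome = "chr3",
                                   stringsAsFactors = FALSE),
    subpop_spec = data.frame(
      name = c("Trop", "Subtrop", "Temp", "Ind1A", "Ind1B", "Ind2"),
      n_accessions = 50L,
      ref_fraction = c(0.95, 0.95, 0.95, 0.05, 0.05, 0.05),
      stringsAsFactors = FALSE),
    n_snps = 20L,
    missing_rate = 0,
    n_genes_expression = 2000L,
    module_spec = list(list(module_id = "M1", size = 150L, members = NULL,
                            baseline = 10, noise_sd = 0.5,
                            fold_changes = c(drought = 4, osmotic = 2,
                                             ABA = 1.5, JA = 1))),
    conditions = c("drought", "osmotic", "ABA", "JA"),
    timepoints = 3L,
    replicates = 2L,
    motif_plant_spec = list(motif_id = "SYNMOT01", in_module = 0.6,
                            background = 0.1),
    n_motifs = 5L,
    motif_width = 10L,
    promoter_length = 2000L,
    region_coverage = 0.25,
    region_cover_planted = 1,
    eul_spec = list(n_S = 2L, n_D = 3L, substitution_prob = 0.05, f118_F = 0.63),
    id_unmapped_fraction = 0.25) {
  if (n_chromosomes < 1) stop_config("n_chromosomes must be positive")
  if (genes_per_chromosome < 1) stop_config("genes_per_chromosome must be positive")
  chroms <- paste0("chr", seq_len(n_chromosomes))
  if (nrow(tandem_array_spec) && !all(tandem_array_spec$chromosome %in% chroms))
    stop_config("tandem array on unknown chromosome: ",
                paste(setdiff(tandem_array_spec$chromosome, chroms), collapse = ", "))
  if (nrow(tandem_array_spec) && any(tandem_array_spec$size < 2))
    stop_config("tandem arrays need size >= 2")
  if (!nrow(subpop_spec)) stop_config("subpop_spec must be non-empty")
  if (any(subpop_spec$ref_fraction < 0 | subpop_spec$ref_fraction > 1))
    stop_config("reference fractions must lie in [0, 1]")
  if (n_snps < 0) stop_config("n_snps must be >= 0")
  for (m in module_spec) {
    if (is.null(m$members) && is.null(m$size))
      stop_config("module needs members or size")
    if (!is.null(m$noise_sd) && m$noise_sd < 0) stop_config("noise sd must be >= 0")
  }
  pp <- c(motif_plant_spec$in_module, motif_plant_spec$background)
  if (any(pp < 0 | pp > 1)) stop_config("plant probabilities must lie in [0, 1]")
  if (motif_width > promoter_length)
    stop_config("motif longer than promoter")
  if (eul_spec$n_S < 0 || eul_spec$n_D < 0) stop_config("EUL counts must be >= 0")
  if (eul_spec$substitution_prob < 0 || eul_spec$substitution_prob >= 1)
    stop_config("substitution probability must lie in [0, 1)")
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config (seed ", x$seed, "): ", x$n_chromosomes, " chromosomes x ",
      x$genes_per_chromosome, " genes, ", nrow(x$subpop_spec), " subpopulations, ",
      length(x$module_spec), " expression module(s)\n", sep = "")
  invisible(x)
}

# ---- genome, gene models, tandem arrays -----------------------------------

#' Simulate a genome with gene models, planted tandem arrays and domain
#' annotations
#'
#' Lays out non-overlapping, ordered genes along each chromosome (random
#' strand, 2-4 exons, CDS length a multiple of 3, UTR margins on the outer
#' exons) over an i.i.d. uniform A/C/G/T genome. Tandem arrays from the
#' configuration are planted as runs of same-family genes separated by at
#' most three intervening genes; background family labels are placed so that
#' no two same-family labelled genes fall within eleven ranks of each other,
#' so the planted arrays are exactly the tandem blocks present. Each
#' labelled gene receives one InterProScan-style domain annotation with its
#' family's Pfam accession.
#'
#' @param config a [simulation_config()]
#' @return list: \code{genome} (named character vector of chromosome
#'   sequences), \code{models} (gene models), \code{annotations}
#'   (data.frame gene_id, domain_id, aa_start, aa_end), \code{truth} (list:
#'   \code{tandem_arrays}, \code{families})
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    fam_acc <- stats::setNames(lectin_family_map()$accession, lectin_family_map()$family)
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    feats <- list(); gene_rows <- list()
    for (ci in seq_along(chroms)) {
      pos <- 1L
      for (gi in seq_len(config$genes_per_chromosome)) {
        gid <- sprintf("LOC_Os%02dg%05d", ci, gi * 10L)
        n_ex <- sample(2:4, 1)
        ex_len <- sample(seq(150L, 300L, by = 3L), n_ex, replace = TRUE)
        in_len <- sample(50:200, max(0, n_ex - 1), replace = TRUE)
        u5 <- sample(10:40, 1); u3 <- sample(10:40, 1)
        # trim the last exon so the spliced CDS length is a multiple of 3
        cds_len <- sum(ex_len) - u5 - u3
        ex_len[n_ex] <- ex_len[n_ex] - cds_len %% 3L
        pos <- pos + sample(200:1000, 1)
        starts <- pos + c(0L, cumsum(ex_len[-n_ex] + in_len))
        ends <- starts + ex_len - 1L
        strand <- sample(c("+", "-"), 1)
        g_start <- starts[1]; g_end <- ends[n_ex]
        # CDS trims u5 from the transcript 5' end, u3 from the 3' end
        if (strand == "+") { c_from <- starts[1] + u5; c_to <- ends[n_ex] - u3 }
        else { c_from <- starts[1] + u3; c_to <- ends[n_ex] - u5 }
        cds <- data.frame(start = pmax(starts, c_from), end = pmin(ends, c_to))
        cds <- cds[cds$start <= cds$end, ]
        feats[[length(feats) + 1L]] <- data.frame(
          gene_id = gid, chromosome = chroms[ci], strand = strand,
          type = c("gene", rep("exon", n_ex), rep("CDS", nrow(cds))),
          start = c(g_start, starts, cds$start),
          end = c(g_end, ends, cds$end), stringsAsFactors = FALSE)
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = gid, chromosome = chroms[ci], rank = gi - 1L,
          stringsAsFactors = FALSE)
        pos <- g_end
      }
    }
    models <- gene_models(do.call(rbind, feats))
    genes <- do.call(rbind, gene_rows)

    # plant tandem arrays, then scatter background labels far from them
    fam_of <- stats::setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
    arrays <- list()
    blocked <- list()  # per family: ranks (chrom-qualified) already claimed
    claim <- function(fam, chrom, ranks) {
      blocked[[fam]] <<- c(blocked[[fam]], paste(chrom, ranks))
    }
    near <- function(fam, chrom, rank, halo = 11L) {
      any(paste(chrom, (rank - halo):(rank + halo)) %in% blocked[[fam]])
    }
    spec <- config$tandem_array_spec
    for (i in seq_len(nrow(spec))) {
      fam <- spec$family[i]; chrom <- spec$chromosome[i]; size <- spec$size[i]
      cand <- genes[genes$chromosome == chrom, ]
      gaps <- sample(0:3, size - 1, replace = TRUE)
      span <- size + sum(gaps)
      if (span > nrow(cand))
        stop_config("tandem array does not fit on ", chrom)
      ok <- FALSE
      for (try in 1:50) {
        start_rank <- sample(0:(nrow(cand) - span), 1)
        ranks <- start_rank + cumsum(c(0L, gaps + 1L))
        if (!any(vapply(ranks, function(r) near(fam, chrom, r), logical(1)))) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop_config("could not place tandem array ", i, " without collision")
      ids <- cand$gene_id[ranks + 1L]
      fam_of[ids] <- fam
      claim(fam, chrom, ranks)
      arrays[[length(arrays) + 1L]] <- data.frame(
        family = fam, chromosome = chrom, size = size,
        members = paste(ids, collapse = ","), stringsAsFactors = FALSE)
    }
    n_bg <- round(config$family_fraction * nrow(genes))
    pool <- genes[is.na(fam_of[genes$gene_id]), ]
    pool <- pool[sample(nrow(pool)), ]
    placed <- 0L
    for (j in seq_len(nrow(pool))) {
      if (placed >= n_bg) break
      fam <- sample(config$family_labels, 1)
      if (near(fam, pool$chromosome[j], pool$rank[j])) next
      fam_of[pool$gene_id[j]] <- fam
      claim(fam, pool$chromosome[j], pool$rank[j])
      placed <- placed + 1L
    }

    labelled <- names(fam_of)[!is.na(fam_of)]
    annotations <- data.frame(
      gene_id = labelled,
      domain_id = unname(fam_acc[fam_of[labelled]]),
      aa_start = 5L,
      aa_end = 60L,
      stringsAsFactors = FALSE)

    gl <- gene_table(models)
    chrom_len <- vapply(chroms, function(ch) max(gl$end[gl$chromosome == ch]) + 500L,
                        numeric(1))
    genome <- vapply(chrom_len, function(n) random_dna(n), character(1))
    names(genome) <- chroms

    list(genome = genome, models = models, annotations = annotations,
         truth = list(
           tandem_arrays = if (length(arrays)) do.call(rbind, arrays) else
             data.frame(family = character(), chromosome = character(),
                        size = integer(), members = character()),
           families = data.frame(gene_id = labelled,
                                 family = unname(fam_of[labelled]),
                                 stringsAsFactors = FALSE)))
  })
}

#' Spliced CDS sequence of a gene from a simulated (or real) genome
#'
#' Concatenates the CDS intervals and reverse complements for minus-strand
#' genes, yielding the coding sequence 5'->3' in transcript orientation.
#' @param models gene models
#' @param genome named character vector of chromosome sequences
#' @param gene_id gene
#' @return character CDS sequence
#' @export
extract_cds <- function(models, genome, gene_id) {
  cds <- feature_intervals(models, gene_id, "CDS")
  if (!nrow(cds)) stop_structural("gene ", gene_id, " has no CDS")
  chrseq <- genome[[cds$chromosome[1]]]
  pieces <- substring(chrseq, cds$start, cds$end)
  s <- paste(pieces, collapse = "")
  if (cds$strand[1] == "-") s <- revcomp_chr(s)
  s
}

# ---- population SNPs -------------------------------------------------------

#' Simulate a SNP panel over subpopulations with known allele fractions
#'
#' Places SNP loci inside randomly chosen genes, draws one haploid call per
#' accession at its subpopulation's true reference-allele fraction, and
#' returns the truth alongside.
#'
#' @param config a [simulation_config()]
#' @param models gene models (loci are placed within gene spans)
#' @return list: \code{snps} (locus_id, chromosome, position, ref, alt,
#'   gene_id), \code{genotypes} (character matrix loci x accessions, called
#'   base or NA), \code{subpopulations} (accession, subpopulation),
#'   \code{truth} (matrix of true reference fractions, loci x
#'   subpopulations)
#' @export
simulate_population_snps <- function(config, models) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 1L, {
    sp <- config$subpop_spec
    acc <- data.frame(
      accession = sprintf("ACC%04d", seq_len(sum(sp$n_accessions))),
      subpopulation = rep(sp$name, sp$n_accessions),
      stringsAsFactors = FALSE)
    if (config$n_snps == 0) {
      return(list(
        snps = data.frame(locus_id = character(), chromosome = character(),
                          position = integer(), ref = character(),
                          alt = character(), gene_id = character()),
        genotypes = matrix(character(), 0, nrow(acc),
                           dimnames = list(NULL, acc$accession)),
        subpopulations = acc,
        truth = matrix(numeric(), 0, nrow(sp), dimnames = list(NULL, sp$name))))
    }
    g <- gene_table(models)
    host <- g[sample(nrow(g), config$n_snps, replace = TRUE), ]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, config$n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    snps <- data.frame(
      locus_id = sprintf("SNP%03d", seq_len(config$n_snps)),
      chromosome = host$chromosome,
      position = host$start + vapply(host$end - host$start, function(w)
        sample.int(w + 1L, 1) - 1L, integer(1)),
      ref = ref, alt = unname(alt), gene_id = host$gene_id,
      stringsAsFactors = FALSE)
    truth <- matrix(rep(sp$ref_fraction, each = config$n_snps),
                    nrow = config$n_snps,
                    dimnames = list(snps$locus_id, sp$name))
    frac_of_acc <- truth[, acc$subpopulation, drop = FALSE]
    is_ref <- matrix(stats::runif(length(frac_of_acc)) < frac_of_acc,
                     nrow = config$n_snps)
    geno <- ifelse(is_ref, snps$ref, snps$alt)
    if (config$missing_rate > 0)
      geno[stats::runif(length(geno)) < config$missing_rate] <- NA
    dimnames(geno) <- list(snps$locus_id, acc$accession)
    list(snps = snps, genotypes = geno, subpopulations = acc, truth = truth)
  })
}

# ---- expression ------------------------------------------------------------

#' Simulate an expression matrix with planted co-expression modules
#'
#' Samples are a full design of control plus treatment conditions x
#' timepoints x replicates. Module members share a common profile —
#' baseline x timepoint shape x condition fold change — scaled per gene,
#' plus independent Gaussian noise, so at zero noise the treated/control
#' ratio equals the planted fold change exactly and member pairs correlate
#' perfectly. Non-members are uncorrelated log-normal noise around the
#' baseline. An id-conversion map with a configured unmapped fraction is
#' generated alongside (module members always mappable, so mapping losses
#' thin the background the way annotation-namespace conversion does).
#'
#' @param config a [simulation_config()]
#' @return list: \code{matrix} (genes x samples), \code{samples}
#'   (sample_id, condition, timepoint, replicate), \code{id_map} (gene_id,
#'   mapped_id with NA = unmapped), \code{truth} (list of modules with
#'   members, baseline, fold_changes, noise_sd)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 2L, {
    ids <- sprintf("GENE%05d", seq_len(config$n_genes_expression))
    samples <- expand.grid(replicate = seq_len(config$replicates),
                           timepoint = seq_len(config$timepoints),
                           condition = c("control", config$conditions),
                           stringsAsFactors = FALSE)
    samples$sample_id <- sprintf("%s_t%d_r%d", samples$condition,
                                 samples$timepoint, samples$replicate)
    shape <- stats::runif(config$timepoints, 0.5, 2)   # shared timepoint shape
    mat <- matrix(NA_real_, length(ids), nrow(samples),
                  dimnames = list(ids, samples$sample_id))
    taken <- character(0)
    modules <- list()
    for (m in config$module_spec) {
      members <- m$members
      if (is.null(members)) {
        avail <- setdiff(ids, taken)
        members <- sort(sample(avail, m$size))
      }
      unknown <- setdiff(members, ids)
      if (length(unknown))
        stop_config("module member(s) not in gene universe: ",
                    paste(utils::head(unknown, 5), collapse = ", "))
      taken <- c(taken, members)
      fc <- c(control = 1, m$fold_changes[config$conditions])
      names(fc) <- c("control", config$conditions)
      profile <- fc[samples$condition] * shape[samples$timepoint]
      scale_g <- stats::runif(length(members), 0.5, 2)
      vals <- outer(scale_g * m$baseline, profile) +
        matrix(stats::rnorm(length(members) * nrow(samples), 0, m$noise_sd),
               length(members))
      mat[members, ] <- pmax(0, vals)
      modules[[m$module_id]] <- list(module_id = m$module_id, members = members,
                                     baseline = m$baseline,
                                     fold_changes = m$fold_changes,
                                     noise_sd = m$noise_sd)
    }
    rest <- setdiff(ids, taken)
    bg_baseline <- if (length(config$module_spec))
      config$module_spec[[1]]$baseline else 10
    mat[rest, ] <- matrix(
      stats::rlnorm(length(rest) * nrow(samples),
                    meanlog = log(bg_baseline), sdlog = 0.5),
      length(rest))
    unmapped <- sample(rest, round(config$id_unmapped_fraction * length(ids)))
    id_map <- data.frame(gene_id = ids,
                         mapped_id = ifelse(ids %in% unmapped, NA_character_,
                                            sub("GENE", "MSU", ids)),
                         stringsAsFactors = FALSE)
    list(matrix = mat,
         samples = samples[, c("sample_id", "condition", "timepoint", "replicate")],
         id_map = id_map,
         truth = list(modules = modules))
  })
}

# ---- promoters, motifs, functional regions --------------------------------

#' Simulate promoters with planted motif instances and functional regions
#'
#' Promoter sequences are i.i.d. uniform over A/C/G/T (chance-hit rates are
#' then analytically checkable). A library of sharp synthetic PWMs is
#' generated; the focal motif's exact consensus is inserted at a recorded
#' coordinate with the in-module probability for module genes and the
#' background probability elsewhere. Functional regions cover the configured
#' fraction of each promoter's bases, and a configurable fraction of planted
#' instances additionally receives a region covering it entirely.
#'
#' @param config a [simulation_config()]
#' @param gene_ids promoters to simulate (character vector); module
#'   membership is looked up in \code{module_members}
#' @param module_members gene ids forming the module (default: members of
#'   the first configured expression module that appear in \code{gene_ids})
#' @return list: \code{promoters} (named character vector), \code{pwms}
#'   ([pwm_library()]), \code{regions} (data.frame gene_id, start, end;
#'   0-based half-open), \code{truth} (list: \code{planted} data.frame
#'   gene_id, motif_id, start, end; \code{module_members})
#' @export
simulate_promoters_and_motifs <- function(config, gene_ids,
                                          module_members = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 3L, {
    L <- config$promoter_length
    w <- config$motif_width
    bases <- c("A", "C", "G", "T")
    all_chars <- sample(bases, length(gene_ids) * L, replace = TRUE)
    proms <- substring(paste(all_chars, collapse = ""),
                       seq(1L, by = L, length.out = length(gene_ids)),
                       seq(L, by = L, length.out = length(gene_ids)))
    names(proms) <- gene_ids
    mk_motif <- function(id) {
      cons <- sample(bases, w, replace = TRUE)
      mat <- matrix(0.01, 4, w, dimnames = list(bases, NULL))
      mat[cbind(match(cons, bases), seq_len(w))] <- 0.97
      list(id = id, matrix = mat)
    }
    ids <- c(config$motif_plant_spec$motif_id,
             sprintf("SYNBG%02d", seq_len(config$n_motifs - 1L)))
    pwms <- pwm_library(lapply(ids, mk_motif))
    consensus <- pwm_consensus(pwms[[config$motif_plant_spec$motif_id]])
    if (is.null(module_members)) {
      mm <- if (length(config$module_spec)) {
        m1 <- config$module_spec[[1]]
        m1$members %||% character(0)
      } else character(0)
      module_members <- intersect(gene_ids, mm)
    }
    p_of <- ifelse(gene_ids %in% module_members,
                   config$motif_plant_spec$in_module,
                   config$motif_plant_spec$background)
    plant <- stats::runif(length(gene_ids)) < p_of
    planted <- data.frame(gene_id = character(), motif_id = character(),
                          start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
    for (i in which(plant)) {
      s0 <- sample.int(L - w + 1L, 1) - 1L       # 0-based insertion offset
      substr(proms[i], s0 + 1L, s0 + w) <- consensus
      planted <- rbind(planted, data.frame(
        gene_id = gene_ids[i], motif_id = config$motif_plant_spec$motif_id,
        start = s0, end = s0 + w, stringsAsFactors = FALSE))
    }
    # functional regions: disjoint 100-bp tiles chosen per promoter until the
    # requested base coverage is reached (exact when L is a tile multiple)
    tw <- min(100L, L)
    nt <- L %/% tw
    k <- min(nt, ceiling(config$region_coverage * L / tw))
    regions <- if (k > 0) {
      do.call(rbind, lapply(gene_ids, function(g) {
        chosen <- sort(sample.int(nt, k))
        data.frame(gene_id = g, start = (chosen - 1L) * tw,
                   end = pmin(chosen * tw, L), stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(gene_id = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    }
    # ... plus guaranteed cover for the configured share of planted instances
    if (nrow(planted)) {
      covered_idx <- which(stats::runif(nrow(planted)) < config$region_cover_planted)
      if (length(covered_idx))
        regions <- rbind(regions, data.frame(
          gene_id = planted$gene_id[covered_idx],
          start = planted$start[covered_idx],
          end = planted$end[covered_idx], stringsAsFactors = FALSE))
    }
    list(promoters = proms, pwms = pwms, regions = regions,
         truth = list(planted = planted, module_members = module_members))
  })
}

# ---- EUL proteins ----------------------------------------------------------

# invariant landmark residues of the 151-aa EUL-domain frame
eul_landmark_residues <- function() {
  c(`34` = "Q", `36` = "W", `116` = "D", `136` = "W", `143` = "N", `144` = "Q")
}

#' Simulate EUL protein sets with conserved landmarks
#'
#' Every domain is 151 aa on a common consensus: Q-x-W at positions 34-36,
#' the carbohydrate-binding triad D116/N143/Q144, W136, and F or L at 118
#' drawn at the configured mix. All other positions substitute independently
#' with the configured probability. S-type proteins are an N-terminal region
#' (19-117 aa) plus one domain; D-type proteins carry two domains joined by
#' an 18-76 aa linker.
#'
#' @param config a [simulation_config()]
#' @return list: \code{proteins} (named character vector),
#'   \code{architecture} (protein_id, type, n_term_length, linker_length,
#'   domain coordinates), \code{domain_hits} (protein_id, start, end; one
#'   row per domain, InterProScan-style), \code{msa} (named character
#'   vector of 151-aa domain sequences), \code{truth} (consensus sequence,
#'   position-118 residue per domain)
#' @export
simulate_eul_proteins <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  es <- config$eul_spec
  with_seed(config$seed + 4L, {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    lm <- eul_landmark_residues()
    consensus <- sample(aas, 151, replace = TRUE)
    consensus[as.integer(names(lm))] <- lm
    consensus[118] <- "F"
    free <- setdiff(seq_len(151L), c(as.integer(names(lm)), 118L))
    mk_domain <- function() {
      d <- consensus
      sub <- free[stats::runif(length(free)) < es$substitution_prob]
      d[sub] <- vapply(d[sub], function(a) sample(setdiff(aas, a), 1), character(1))
      d[118] <- if (stats::runif(1) < es$f118_F) "F" else "L"
      paste(d, collapse = "")
    }
    proteins <- character(0); arch <- list(); hits <- list(); msa <- character(0)
    f118 <- character(0)
    add_domain <- function(pid, k) {
      dom <- mk_domain()
      msa[paste0(pid, "_", k)] <<- dom
      f118[paste0(pid, "_", k)] <<- substr(dom, 118, 118)
      dom
    }
    for (i in seq_len(es$n_S)) {
      pid <- sprintf("EULS%d", i)
      nt <- sample(19:117, 1)
      dom <- add_domain(pid, 1L)
      proteins[pid] <- paste0(random_protein(nt, aas), dom)
      arch[[pid]] <- data.frame(protein_id = pid, type = "S", n_term_length = nt,
                                linker_length = NA_integer_,
                                dom1_start = nt + 1L, dom1_end = nt + 151L,
                                dom2_start = NA_integer_, dom2_end = NA_integer_,
                                stringsAsFactors = FALSE)
      hits[[length(hits) + 1L]] <- data.frame(protein_id = pid, start = nt + 1L,
                                              end = nt + 151L)
    }
    for (i in seq_len(es$n_D)) {
      pid <- sprintf("EULD%d", i)
      nt <- sample(19:117, 1); lk <- sample(18:76, 1)
      d1 <- add_domain(pid, 1L); d2 <- add_domain(pid, 2L)
      proteins[pid] <- paste0(random_protein(nt, aas), d1,
                              random_protein(lk, aas), d2)
      s2 <- nt + 151L + lk + 1L
      arch[[pid]] <- data.frame(protein_id = pid, type = "D", n_term_length = nt,
                                linker_length = lk,
                                dom1_start = nt + 1L, dom1_end = nt + 151L,
                                dom2_start = s2, dom2_end = s2 + 150L,
                                stringsAsFactors = FALSE)
      hits[[length(hits) + 1L]] <- data.frame(protein_id = pid,
                                              start = c(nt + 1L, s2),
                                              end = c(nt + 151L, s2 + 150L))
    }
    list(proteins = proteins,
         architecture = do.call(rbind, c(arch, list(make.row.names = FALSE))),
         domain_hits = do.call(rbind, c(hits, list(make.row.names = FALSE))),
         msa = msa,
         truth = list(consensus = paste(consensus, collapse = ""),
                      f118 = f118))
  })
}

random_protein <- function(n, aas) paste(sample(aas, n, replace = TRUE), collapse = "")
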