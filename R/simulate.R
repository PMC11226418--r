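#' Simulation configuration
#'
#' Describes a complete synthetic mutagenesis study: a reference genome with
#' placed chromosomes and unplaced scaffolds, gene models, a panel of
#' wild-type controls descended from a line diverged from the reference, and
#' a panel of EMS-treated mutants each carrying private induced mutations.
#'
#' Defaults mirror the study design this pipeline targets: 18 placed
#' chromosomes, five wild types, nine mutants, an EMS substitution spectrum
#' dominated by C/G>T/A transitions (transition fraction 0.6, of which 0.7
#' are C/G>T/A), per-mutant mutation counts drawn log-uniformly to mimic
#' strong count heterogeneity between mutants, and a homozygous fraction of
#' 1/3 (the expected fraction of homozygotes among selfed-progeny carriers of
#' a heterozygous induced allele).
#'
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param chrom_lengths Lengths (bp) of the placed chromosomes.
#' @param unplaced_lengths Lengths (bp) of unplaced scaffolds.
#' @param n_wildtype,n_mutant Panel sizes.
#' @param background_rate Per-bp rate of fixed divergence between the
#'   wild-type line and the reference (homozygous alternate in every sample).
#' @param wt_noise_rate Per-bp rate of sites where one wild type differs from
#'   the others (individual heterogeneity; removed by the cascade).
#' @param ems_counts Optional integer vector (length `n_mutant`) of planted
#'   EMS mutations per mutant; if `NULL`, counts are drawn log-uniformly from
#'   `ems_count_range`.
#' @param ems_count_range Range for log-uniform per-mutant counts.
#' @param transition_fraction Fraction of planted EMS mutations that are
#'   transitions.
#' @param cg_ta_fraction Fraction of planted transitions that are C/G>T/A
#'   (the EMS-preferred class) rather than T/A>C/G.
#' @param transversion_weights Relative weights of the four transversion
#'   classes (C/G>A/T, T/A>A/T, T/A>G/C, C/G>G/C); the last is depressed by
#'   default, matching the empirically rare C/G>G/C class.
#' @param homozygous_fraction Probability a planted EMS mutation is
#'   homozygous in its carrier.
#' @param missing_rate Per-genotype probability of replacement by missing.
#' @param shared_mutant_sites Number of sites carried identically by every
#'   mutant (exercises the shared-among-mutants filter step).
#' @param unplaced_mutant_sites Number of mutant-private sites planted on
#'   unplaced scaffolds (exercises the placed-chromosome filter step).
#' @param gene_density Genes per Mb on placed chromosomes.
#' @param mean_cds_length Mean CDS length in bp (rounded to codons).
#' @param intron_fraction Fraction of genes with a single intron.
#' @param mean_intron_length Mean intron length (bp).
#' @param n_go_terms Number of GO terms in the synthetic ontology.
#' @param mean_terms_per_gene Mean GO terms per gene (Poisson).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = rep(1e6, 18),
                       unplaced_lengths = rep(1e5, 2),
                       n_wildtype = 5L,
                       n_mutant = 9L,
                       background_rate = 5e-4,
                       wt_noise_rate = 5e-5,
                       ems_counts = NULL,
                       ems_count_range = c(500, 5000),
                       transition_fraction = 0.6,
                       cg_ta_fraction = 0.7,
                       transversion_weights = c(1, 1, 1, 1 / 3),
                       homozygous_fraction = 1 / 3,
                       missing_rate = 0.01,
                       shared_mutant_sites = 0L,
                       unplaced_mutant_sites = 50L,
                       gene_density = 30,
                       mean_cds_length = 900,
                       intron_fraction = 0.5,
                       mean_intron_length = 300,
                       n_go_terms = 40L,
                       mean_terms_per_gene = 2) {
  rates <- c(background_rate, wt_noise_rate, transition_fraction,
             cg_ta_fraction, homozygous_fraction, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(chrom_lengths <= 0) || any(unplaced_lengths < 0))
    stop("lengths must be positive")
  if (!is.null(ems_counts) && length(ems_counts) != n_mutant)
    stop("ems_counts must have one entry per mutant")
  if (length(transversion_weights) != 4 || any(transversion_weights < 0))
    stop("transversion_weights must be 4 non-negative numbers")
  cfg <- list(seed = as.integer(seed),
              chrom_lengths = chrom_lengths,
              unplaced_lengths = unplaced_lengths,
              n_wildtype = as.integer(n_wildtype),
              n_mutant = as.integer(n_mutant),
              background_rate = background_rate,
              wt_noise_rate = wt_noise_rate,
              ems_counts = ems_counts,
              ems_count_range = ems_count_range,
              transition_fraction = transition_fraction,
              cg_ta_fraction = cg_ta_fraction,
              transversion_weights = transversion_weights,
              homozygous_fraction = homozygous_fraction,
              missing_rate = missing_rate,
              shared_mutant_sites = as.integer(shared_mutant_sites),
              unplaced_mutant_sites = as.integer(unplaced_mutant_sites),
              gene_density = gene_density,
              mean_cds_length = mean_cds_length,
              intron_fraction = intron_fraction,
              mean_intron_length = mean_intron_length,
              n_go_terms = as.integer(n_go_terms),
              mean_terms_per_gene = mean_terms_per_gene)
  class(cfg) <- "sim_config"
  cfg
}

sim_sample_names <- function(config) {
  # mutants R2..R(n+1), wild types numbered after them
  mut <- paste0("R", seq_len(config$n_mutant) + 1L)
  wt <- paste0("R", seq_len(config$n_wildtype) + 1L + config$n_mutant)
  sample_roles(stats::setNames(c(rep("mutant", length(mut)),
                                 rep("wildtype", length(wt))),
                               c(mut, wt)))
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a reference genome with gene models
#'
#' Chromosome sequences are i.i.d. uniform over A/C/G/T except within CDS,
#' which is rewritten as a valid open reading frame (ATG start, no internal
#' stop, terminal stop; reverse-complemented onto minus-strand genes). Genes
#' are placed without overlap; each is single-intron with probability
#' `intron_fraction`, otherwise intronless.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` ([ems_genome]) and `models`
#'   ([gene_models], with synthetic GO terms attached).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pl <- length(config$chrom_lengths)
  chroms <- sprintf("Chr%02d", seq_len(n_pl))
  scaffolds <- if (length(config$unplaced_lengths))
    sprintf("scaffold_%03d", seq_along(config$unplaced_lengths)) else character(0)
  ids <- c(chroms, scaffolds)
  lens <- c(config$chrom_lengths, config$unplaced_lengths)

  seqs <- vector("list", length(ids))
  names(seqs) <- ids
  genes_list <- list(); cds_list <- list()
  gi <- 0L

  for (ci in seq_along(ids)) {
    L <- lens[ci]
    s <- sample(BASES, L, replace = TRUE)
    if (ci <= n_pl && config$gene_density > 0) {
      n_genes <- round(config$gene_density * L / 1e6)
      if (n_genes > 0) {
        n_codons <- pmax(30L, rpois(n_genes, config$mean_cds_length / 3))
        has_intron <- runif(n_genes) < config$intron_fraction
        intron_len <- ifelse(has_intron,
                             pmax(60L, rpois(n_genes, config$mean_intron_length)),
                             0L)
        span <- 3L * n_codons + intron_len
        free <- L - sum(span)
        if (free < n_genes + 1L)
          stop("gene placement impossible at requested density; lower gene_density")
        gaps <- as.vector(rmultinom(1, free - (n_genes + 1L),
                                    rep(1, n_genes + 1L))) + 1L
        # start_k = all gaps up to and incl. gap_k + all earlier gene spans + 1
        starts <- cumsum(gaps[seq_len(n_genes)]) +
          c(0L, cumsum(span))[seq_len(n_genes)] + 1L
        strands <- sample(c("+", "-"), n_genes, replace = TRUE)
        for (k in seq_len(n_genes)) {
          gi <- gi + 1L
          gid <- sprintf("gene%04d", gi)
          codons <- random_orf(n_codons[k])
          # split CDS around an intron at a codon boundary (if any)
          if (has_intron[k]) {
            brk <- sample(seq_len(n_codons[k] - 1L), 1L) * 3L
            ex1 <- c(starts[k], starts[k] + brk - 1L)
            ex2 <- c(ex1[2] + intron_len[k] + 1L,
                     ex1[2] + intron_len[k] + (3L * n_codons[k] - brk))
            ex <- rbind(ex1, ex2)
          } else {
            ex <- rbind(c(starts[k], starts[k] + 3L * n_codons[k] - 1L))
          }
          # write ORF into the chromosome 5'->3' on the gene strand
          cds_pos <- unlist(lapply(seq_len(nrow(ex)),
                                   function(e) ex[e, 1]:ex[e, 2]))
          orf <- strsplit(paste(codons, collapse = ""), "")[[1]]
          if (strands[k] == "-") {
            s[rev(cds_pos)] <- dna_complement(orf)
          } else {
            s[cds_pos] <- orf
          }
          genes_list[[gi]] <- data.frame(
            gene_id = gid, tx_id = paste0(gid, ".t1"), chrom = ids[ci],
            strand = strands[k], span_start = min(ex), span_end = max(ex),
            cds_len = 3L * n_codons[k])
          cds_list[[gi]] <- data.frame(
            gene_id = gid, chrom = ids[ci], strand = strands[k],
            start = ex[, 1], end = ex[, 2])
        }
      }
    }
    seqs[[ci]] <- paste(s, collapse = "")
  }

  genome <- ems_genome(unlist(seqs), placed = chroms)
  if (gi > 0) {
    genes <- do.call(rbind, genes_list)
    cds <- do.call(rbind, cds_list)
    go <- simulate_go(genes$gene_id, config)
    models <- gene_models(genes, cds, go)
  } else {
    models <- gene_models(
      genes = data.frame(gene_id = character(0), tx_id = character(0),
                         chrom = character(0), strand = character(0),
                         span_start = integer(0), span_end = integer(0),
                         cds_len = integer(0)),
      cds = data.frame(gene_id = character(0), chrom = character(0),
                       strand = character(0), start = integer(0),
                       end = integer(0)))
  }
  list(genome = genome, models = models)
}

# codon sequence: ATG, stop-free middle, terminal stop
random_orf <- function(n_codons) {
  all_codons <- names(Biostrings::GENETIC_CODE)
  sense <- setdiff(all_codons, STOP_CODONS)
  c("ATG", sample(sense, n_codons - 2L, replace = TRUE),
    sample(STOP_CODONS, 1L))
}

dna_complement <- function(x) c(A = "T", C = "G", G = "C", T = "A")[x]

simulate_go <- function(gene_ids, config) {
  if (config$n_go_terms == 0 || length(gene_ids) == 0) return(list())
  terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  n <- pmin(rpois(length(gene_ids), config$mean_terms_per_gene),
            config$n_go_terms)
  go <- lapply(n, function(k) if (k > 0) sample(terms, k) else character(0))
  names(go) <- gene_ids
  go[lengths(go) > 0]
}

# substitution class -> (ref base family, alt for each family member)
CLASS_SUBS <- list(
  "C/G>T/A" = c(C = "T", G = "A"),
  "T/A>C/G" = c(T = "C", A = "G"),
  "C/G>A/T" = c(C = "A", G = "T"),
  "T/A>A/T" = c(T = "A", A = "T"),
  "T/A>G/C" = c(T = "G", A = "C"),
  "C/G>G/C" = c(C = "G", G = "C"))

#' Simulate the study population
#'
#' Plants four disjoint classes of variant sites on the simulated genome:
#' fixed background divergence (same homozygous alternate genotype in every
#' sample), wild-type individual noise (one wild type deviates), per-mutant
#' private EMS mutations with the configured substitution spectrum and
#' zygosity, and (optionally) sites shared by all mutants or private sites on
#' unplaced scaffolds. Missing genotypes are then injected uniformly at the
#' configured rate.
#'
#' @param genome An [ems_genome] from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A list of class `ems_study` with elements `sites`
#'   ([variant_table]), `roles`, `truth` (lists of planted site tables:
#'   `ems`, `background`, `wt_noise`, `shared`, `unplaced`) and `config`.
#' @export
simulate_population <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  if (sum(genome$lengths) == 0) stop("genome is empty")
  set.seed(config$seed + 1000L)
  roles <- sim_sample_names(config)
  mut <- mutant_ids(roles); wt <- wildtype_ids(roles)
  samples <- names(roles)

  ids <- names(genome$seq)
  placed <- genome$placed
  unplaced <- setdiff(ids, placed)

  # per-mutant EMS counts
  ems_n <- config$ems_counts
  if (is.null(ems_n)) {
    r <- config$ems_count_range
    ems_n <- round(exp(runif(config$n_mutant, log(r[1]), log(r[2]))))
  }
  names(ems_n) <- mut

  # spectrum class probabilities
  tvw <- config$transversion_weights / sum(config$transversion_weights)
  class_p <- c(config$transition_fraction * config$cg_ta_fraction,
               config$transition_fraction * (1 - config$cg_ta_fraction),
               (1 - config$transition_fraction) * tvw)
  names(class_p) <- SPECTRUM_CLASSES

  # plan per-chromosome site budgets
  plan <- list()
  for (id in ids) {
    L <- genome$lengths[[id]]
    plan[[id]] <- list(
      background = rbinom(1, L, config$background_rate),
      wt_noise = rbinom(1, L, config$wt_noise_rate))
  }
  # allocate EMS sites to placed chromosomes proportional to length
  pl_len <- genome$lengths[placed]
  ems_chrom <- lapply(mut, function(m)
    sample(placed, ems_n[[m]], replace = TRUE, prob = pl_len))
  names(ems_chrom) <- mut
  shared_chrom <- if (config$shared_mutant_sites > 0)
    sample(placed, config$shared_mutant_sites, replace = TRUE, prob = pl_len)
  else character(0)
  unpl_chrom <- if (config$unplaced_mutant_sites > 0 && length(unplaced))
    sample(unplaced, config$unplaced_mutant_sites, replace = TRUE,
           prob = genome$lengths[unplaced])
  else character(0)

  # sample disjoint positions per chromosome, split by base family as needed
  rows <- list()  # each: chrom,pos,ref,alt,kind,mutant,zygosity
  for (id in ids) {
    L <- genome$lengths[[id]]
    n_ems_here <- sum(vapply(mut, function(m) sum(ems_chrom[[m]] == id), 0L)) +
      sum(shared_chrom == id) + sum(unpl_chrom == id)
    n_other <- plan[[id]]$background + plan[[id]]$wt_noise
    tot <- n_ems_here + n_other
    if (tot == 0) next
    if (tot > L) stop("requested mutation count exceeds available positions on ", id)
    # overdraw candidates so both base families are well represented
    n_cand <- min(L, max(4L * tot, 200L))
    cand <- sample.int(L, n_cand)
    base <- genome_base(genome, id, cand)
    pool <- list("CG" = which(base %in% c("C", "G")),
                 "TA" = which(base %in% c("T", "A")))
    take <- function(family, k) {
      avail <- pool[[family]]
      if (length(avail) < k)
        stop("requested mutation count exceeds available positions on ", id)
      got <- avail[seq_len(k)]
      pool[[family]] <<- avail[-seq_len(k)]
      got
    }
    draw_spectrum_sites <- function(k, kind, mutant = NA_character_) {
      if (k == 0) return(NULL)
      cls <- sample(SPECTRUM_CLASSES, k, replace = TRUE, prob = class_p)
      fam <- ifelse(startsWith(cls, "C/G"), "CG", "TA")
      idx <- integer(k)
      for (f in c("CG", "TA")) {
        sel <- which(fam == f)
        if (length(sel)) idx[sel] <- take(f, length(sel))
      }
      refb <- base[idx]
      altb <- vapply(seq_len(k), function(i) CLASS_SUBS[[cls[i]]][[refb[i]]],
                     character(1))
      data.frame(chrom = id, pos = cand[idx], ref = refb, alt = altb,
                 kind = kind, mutant = mutant, stringsAsFactors = FALSE)
    }
    draw_any_sites <- function(k, kind) {
      if (k == 0) return(NULL)
      # any reference base; alternate drawn uniformly among the other three
      n_cg <- min(length(pool[["CG"]]), k)
      idx <- c(if (n_cg) take("CG", n_cg), if (k - n_cg) take("TA", k - n_cg))
      refb <- base[idx]
      altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1), "")
      data.frame(chrom = id, pos = cand[idx], ref = refb, alt = altb,
                 kind = kind, mutant = NA_character_, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- draw_any_sites(plan[[id]]$background, "background")
    rows[[length(rows) + 1L]] <- draw_any_sites(plan[[id]]$wt_noise, "wt_noise")
    for (m in mut)
      rows[[length(rows) + 1L]] <-
        draw_spectrum_sites(sum(ems_chrom[[m]] == id), "ems", m)
    rows[[length(rows) + 1L]] <-
      draw_spectrum_sites(sum(shared_chrom == id), "shared")
    if (length(unpl_chrom)) {
      k <- sum(unpl_chrom == id)
      if (k > 0) {
        u <- draw_spectrum_sites(k, "unplaced")
        u$mutant <- sample(mut, k, replace = TRUE)
        rows[[length(rows) + 1L]] <- u
      }
    }
  }
  site_df <- do.call(rbind, rows)
  if (is.null(site_df))
    site_df <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          kind = character(0), mutant = character(0))
  site_df <- site_df[order(site_df$chrom, site_df$pos), ]
  n <- nrow(site_df)

  # genotypes
  gt <- matrix(NA_character_, n, length(samples),
               dimnames = list(NULL, samples))
  hom_ref <- gt_hom(site_df$ref)
  hom_alt <- gt_hom(site_df$alt)
  het <- gt_pair(site_df$ref, site_df$alt)
  for (s in samples) gt[, s] <- hom_ref

  is_bg <- site_df$kind == "background"
  gt[is_bg, ] <- hom_alt[is_bg]

  is_noise <- which(site_df$kind == "wt_noise")
  if (length(is_noise)) {
    noisy_wt <- sample(wt, length(is_noise), replace = TRUE)
    noisy_gt <- ifelse(runif(length(is_noise)) < 0.5,
                       het[is_noise], hom_alt[is_noise])
    gt[cbind(is_noise, match(noisy_wt, samples))] <- noisy_gt
  }

  is_shared <- site_df$kind == "shared"
  gt[is_shared, mut] <- hom_alt[is_shared]

  carrier <- which(site_df$kind %in% c("ems", "unplaced"))
  zyg <- rep(NA_character_, n)
  if (length(carrier)) {
    hom <- runif(length(carrier)) < config$homozygous_fraction
    zyg[carrier] <- ifelse(hom, "hom", "het")
    gt[cbind(carrier, match(site_df$mutant[carrier], samples))] <-
      ifelse(hom, hom_alt[carrier], het[carrier])
  }
  site_df$zygosity <- zyg

  # inject missing genotypes
  if (config$missing_rate > 0) {
    miss <- runif(length(gt)) < config$missing_rate
    gt[miss] <- NA_character_
  }

  sites <- variant_table(site_df$chrom, site_df$pos, site_df$ref,
                         site_df$alt, gt)
  attr(sites, "roles") <- roles

  truth_cols <- c("mutant", "chrom", "pos", "ref", "alt", "zygosity")
  pick <- function(kind) {
    d <- site_df[site_df$kind == kind, intersect(truth_cols, names(site_df)),
                 drop = FALSE]
    rownames(d) <- NULL
    d
  }
  truth <- list(ems = pick("ems"), background = pick("background"),
                wt_noise = pick("wt_noise"), shared = pick("shared"),
                unplaced = pick("unplaced"))
  structure(list(sites = sites, roles = roles, truth = truth,
                 config = config),
            class = "ems_study")
}

#' Simulate a complete study
#'
#' Convenience wrapper: [simulate_genome()] then [simulate_population()].
#'
#' @param config A [sim_config()].
#' @return An `ems_study` list with `genome`, `models`, `sites`, `roles`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  g <- simulate_genome(config)
  pop <- simulate_population(g$genome, config)
  pop$genome <- g$genome
  pop$models <- g$models
  pop
}

#' @export
print.ems_study <- function(x, ...) {
  cat(sprintf(paste0("<ems_study> %d sites x %d samples ",
                     "(%d mutants, %d wild types)\n"),
              nrow(x$sites), length(x$roles),
              length(mutant_ids(x$roles)), length(wildtype_ids(x$roles))))
  cat(sprintf("  planted: %d EMS, %d background, %d WT-noise, %d shared, %d unplaced\n",
              nrow(x$truth$ems), nrow(x$truth$background),
              nrow(x$truth$wt_noise), nrow(x$truth$shared),
              nrow(x$truth$unplaced)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits `study.vcf`, `genome.fa`, `genes.gff3`, `gene2go.tsv`,
#' `samples.tsv` and `truth.json` into a directory; all files are re-readable
#' with the package's readers.
#'
#' @param study An `ems_study` from [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  paths <- c(vcf = file.path(dir, "study.vcf"),
             fasta = file.path(dir, "genome.fa"),
             gff = file.path(dir, "genes.gff3"),
             gene2go = file.path(dir, "gene2go.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(study$sites, paths[["vcf"]], genome = study$genome)
  write_genome(study$genome, paths[["fasta"]])
  write_gff(study$models, paths[["gff"]])
  write_gene2go(study$models$go, paths[["gene2go"]])
  write.table(data.frame(sample = names(study$roles), role = study$roles),
              paths[["samples"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(c(list(schema = "emsift-truth/1",
                              placed = study$genome$placed),
                         study$truth),
                       paths[["truth"]], dataframe = "columns", digits = NA)
  invisible(paths)
}

#' Read a ground-truth file written by [write_study()]
#'
#' @param path Path to `truth.json`.
#' @return List of planted-site tables (`ems`, `background`, `wt_noise`,
#'   `shared`, `unplaced`).
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("ems", "background", "wt_noise", "shared", "unplaced"))
    x[[k]] <- as.data.frame(x[[k]])
  x
}
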