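# hand-built genome: one plus-strand and one minus-strand gene with known
# ORFs, placed > 5 kb apart so their flank windows do not overlap.
# Chr01: positions 11-22 hold the plus-strand ORF  ATG CAA GGT TAA
# Chr01: positions 8000-8011 hold the minus-strand ORF (genomic TTAACCTTGCAT)
annot_fixture <- function(chrom_len = 25000) {
  pad <- function(n) paste(rep("A", n), collapse = "")
  seqs <- paste0(pad(10), "ATGCAAGGTTAA", pad(7977), "TTAACCTTGCAT",
                 pad(chrom_len - 8011))
  genome <- ems_genome(c(Chr01 = seqs), placed = "Chr01")
  genes <- data.frame(
    gene_id = c("gplus", "gminus"), tx_id = c("gplus.t1", "gminus.t1"),
    chrom = "Chr01", strand = c("+", "-"),
    span_start = c(11L, 8000L), span_end = c(22L, 8011L), cds_len = 12L)
  cds <- data.frame(gene_id = c("gplus", "gminus"), chrom = "Chr01",
                    strand = c("+", "-"), start = c(11L, 8000L),
                    end = c(22L, 8011L))
  list(genome = genome, models = gene_models(genes, cds))
}

test_that("coding changes classify by codon translation", {
  fx <- annot_fixture()
  # codon 2 (positions 14-16) CAA -> TAA : glutamine to stop
  e <- classify_site("Chr01", 14, "C", "T", fx$models, fx$genome)
  expect_equal(e$category, "stop_gain")
  expect_equal(e$codon_ref, "CAA")
  expect_equal(e$codon_alt, "TAA")
  # codon 3 (positions 17-19) GGT -> GGC : glycine synonymous
  e <- classify_site("Chr01", 19, "T", "C", fx$models, fx$genome)
  expect_equal(e$category, "synonymous")
  expect_equal(e$aa_ref, e$aa_alt)
  # codon 3 GGT -> GAT : glycine to aspartate
  e <- classify_site("Chr01", 18, "G", "A", fx$models, fx$genome)
  expect_equal(e$category, "non_synonymous")
  expect_equal(c(e$aa_ref, e$aa_alt), c("G", "D"))
})

test_that("minus-strand codons are reverse-complemented before translation", {
  fx <- annot_fixture()
  # ORF position 4 (codon 2 base 1, 'C') is genomic 8008 on the minus gene;
  # genomic G>A reads as C>T on the coding strand: CAA -> TAA
  expect_equal(genome_base(fx$genome, "Chr01", 8008), "G")
  e <- classify_site("Chr01", 8008, "G", "A", fx$models, fx$genome)
  expect_equal(e$category, "stop_gain")
  expect_equal(e$codon_ref, "CAA")
  expect_equal(e$codon_alt, "TAA")
  # third position of minus-strand codon 1 (ORF pos 3 'G' = genomic 8009 'C')
  e <- classify_site("Chr01", 8009, "C", "T", fx$models, fx$genome)
  expect_equal(e$codon_ref, "ATG")   # start codon: any change is missense-like
  expect_equal(e$category, "non_synonymous")
})

test_that("intron, flank and intergenic calls follow the window rule", {
  fx <- annot_fixture()
  # two-exon gene with an intron at 107..154
  genes2 <- data.frame(gene_id = "g2x", tx_id = "g2x.t1", chrom = "Chr01",
                       strand = "+", span_start = 101L, span_end = 160L,
                       cds_len = 12L)
  cds2 <- data.frame(gene_id = "g2x", chrom = "Chr01", strand = "+",
                     start = c(101L, 155L), end = c(106L, 160L))
  m2 <- gene_models(genes2, cds2)
  e <- classify_site("Chr01", 120, "A", "G", m2, fx$genome)
  expect_equal(e$category, "intron")
  expect_equal(e$gene_id, "g2x")
  # strand-aware flanks: 50 bp before a plus gene is upstream
  e <- classify_site("Chr01", 95, "A", "G", m2, fx$genome, window = 50)
  expect_equal(e$category, "upstream")
  e <- classify_site("Chr01", 170, "A", "G", m2, fx$genome, window = 50)
  expect_equal(e$category, "downstream")
  # minus-strand gene: positions after span_end are upstream
  fxm <- annot_fixture()
  e <- classify_site("Chr01", 8014, "A", "G", fxm$models, fxm$genome,
                     window = 5)
  expect_equal(e$category, "upstream")
  expect_equal(e$gene_id, "gminus")
  # far from every gene: intergenic
  e <- classify_site("Chr01", 20000, "A", "G", fxm$models, fxm$genome,
                     window = 5000)
  expect_equal(e$category, "intergenic")
  expect_true(is.na(e$gene_id))
})

test_that("positions beyond the chromosome are rejected", {
  fx <- annot_fixture()
  expect_error(classify_site("Chr01", 10^9, "A", "G", fx$models, fx$genome),
               "beyond chromosome")
})

test_that("severity reduction picks the most severe category", {
  expect_equal(reduce_severity(c("intergenic", "synonymous", "upstream")),
               "synonymous")
  expect_equal(reduce_severity(c("non_synonymous", "stop_gain")), "stop_gain")
  expect_equal(reduce_severity("intron"), "intron")
  expect_equal(reduce_severity(c("downstream", "upstream")), "upstream")
})

test_that("annotated call sets carry one severity-reduced category per SNP", {
  cfg <- sim_config(seed = 31, chrom_lengths = rep(1e5, 3),
                    unplaced_lengths = numeric(0), gene_density = 60,
                    ems_count_range = c(80, 200), missing_rate = 0,
                    unplaced_mutant_sites = 0L)
  st <- simulate_study(cfg)
  out <- run_cascade(st$sites, st$roles, st$genome)
  ann <- annotate_callsets(out, st$models, st$genome)
  for (m in names(ann$calls)) {
    d <- ann$calls[[m]]
    expect_false(any(is.na(d$category)))
    expect_true(all(d$category %in%
                      c("stop_gain", "non_synonymous", "synonymous", "intron",
                        "upstream", "downstream", "intergenic")))
    # every attributed SNP receives at least one effect call
    expect_setequal(unique(ann$effects[[m]]$site), seq_len(nrow(d)))
  }
  ab <- annotation_abundance(ann)
  expect_equal(unname(colSums(ab)), rep(1, ncol(ab)))
})

test_that("genes_with_category dedups genes per mutant and per category", {
  fx <- annot_fixture()
  calls <- list(R2 = data.frame(chrom = "Chr01", pos = c(14L, 18L, 8008L),
                                ref = c("C", "G", "G"), alt = c("A", "A", "T"),
                                genotype = "x", zygosity = "het"),
                R3 = data.frame(chrom = character(0), pos = integer(0),
                                ref = character(0), alt = character(0),
                                genotype = character(0),
                                zygosity = character(0)))
  cs <- structure(list(calls = calls,
                       roles = sample_roles(c(R2 = "mutant", R3 = "mutant",
                                              R11 = "wildtype"))),
                  class = "ems_callsets")
  ann <- annotate_callsets(cs, fx$models, fx$genome)
  ns <- genes_with_category(ann, "non_synonymous")
  # pos 14 C>A: CAA->AAA (Q->K), pos 18 G>A: GGT->GAT (G->D), same gene once;
  # pos 8008 G>T is coding C>A on gminus: CAA->AAA, also non-synonymous
  expect_setequal(ns$R2, c("gplus", "gminus"))
  expect_equal(ns$R3, character(0))
  sg <- genes_with_category(ann, "stop_gain")
  # none of the three changes creates a stop codon
  expect_true(all(vapply(sg, length, 0L) == 0))
  expect_error(genes_with_category(cs, "non_synonymous"), "not annotated")
})
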