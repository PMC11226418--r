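test_that("substitutions pool into the six strand-symmetric classes", {
  expect_equal(classify_substitution("G", "A"), "C/G>T/A")
  expect_equal(classify_substitution("C", "T"), "C/G>T/A")
  expect_equal(classify_substitution("A", "G"), "T/A>C/G")
  expect_equal(classify_substitution("A", "T"), "T/A>A/T")
  expect_equal(classify_substitution("G", "C"), "C/G>G/C")
  expect_equal(classify_substitution("C", "A"), "C/G>A/T")
  expect_equal(classify_substitution("T", "G"), "T/A>G/C")
  expect_true(is_transition("G", "A"))
  expect_false(is_transition("A", "T"))
  # every complementary pair maps to the same class
  for (r in c("A", "C", "G", "T")) for (a in setdiff(c("A", "C", "G", "T"), r)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    expect_equal(classify_substitution(r, a),
                 classify_substitution(comp[[r]], comp[[a]]))
  }
  expect_error(classify_substitution("A", "A"), "differ")
})

test_that("spectrum counts conserve totals and proportions sum to one", {
  calls <- data.frame(ref = rep("G", 10), alt = rep("A", 10))
  s <- spectrum(calls)
  expect_equal(s$transition_proportion, 1)
  expect_equal(sum(s$counts), 10L)
  expect_equal(sum(s$proportions), 1, tolerance = 1e-12)

  set.seed(1)
  refs <- sample(c("A", "C", "G", "T"), 500, TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  s <- spectrum(data.frame(ref = refs, alt = alts))
  expect_equal(sum(s$counts), 500L)
  expect_equal(sum(s$proportions), 1, tolerance = 1e-12)

  expect_error(spectrum(data.frame(ref = character(0), alt = character(0))),
               "empty")
})

test_that("frequency table divides counts by exact Mb lengths", {
  genome <- ems_genome(c(Chr01 = paste(rep("A", 100), collapse = "")),
                       placed = "Chr01")
  genome$lengths["Chr01"] <- 2.5e6   # pretend a 2.5 Mb chromosome
  calls <- list(R2 = data.frame(chrom = rep("Chr01", 50), pos = 1:50,
                                ref = "C", alt = "T", genotype = "C/T",
                                zygosity = "het"),
                R3 = data.frame(chrom = character(0), pos = integer(0),
                                ref = character(0), alt = character(0),
                                genotype = character(0), zygosity = character(0)))
  cs <- structure(list(calls = calls), class = "ems_callsets")
  ft <- frequency_table(cs, genome)
  expect_equal(ft["Chr01", "R2"], 20)   # 50 / 2.5 Mb
  expect_equal(ft["Chr01", "R3"], 0)    # zero SNPs still contribute a row
  cnt <- frequency_table(cs, genome, what = "count")
  expect_equal(cnt["Chr01", "R2"], 50L)
})

test_that("frequencies halve when every chromosome length doubles", {
  st <- simulate_study(sim_config(seed = 17, chrom_lengths = rep(5e4, 3),
                                  unplaced_lengths = numeric(0),
                                  gene_density = 0,
                                  ems_count_range = c(30, 80),
                                  unplaced_mutant_sites = 0L,
                                  missing_rate = 0))
  out <- run_cascade(st$sites, st$roles, st$genome)
  f1 <- frequency_table(out, st$genome)
  g2 <- st$genome
  g2$lengths <- g2$lengths * 2
  f2 <- frequency_table(out, g2)
  mcols <- names(out$calls)
  expect_equal(as.matrix(f2[, mcols]), as.matrix(f1[, mcols]) / 2)
})

test_that("per-chromosome counts conserve the per-mutant totals", {
  st <- simulate_study(sim_config(seed = 19, chrom_lengths = rep(6e4, 4),
                                  unplaced_lengths = 2e4,
                                  ems_count_range = c(40, 120),
                                  missing_rate = 0))
  out <- run_cascade(st$sites, st$roles, st$genome)
  cnt <- frequency_table(out, st$genome, what = "count")
  for (m in names(out$calls))
    expect_equal(sum(cnt[[m]]), nrow(out$calls[[m]]))
})

test_that("summary rows implement Sum, Average = Sum/n, Min, Max", {
  m <- matrix(2, nrow = 18, ncol = 3,
              dimnames = list(paste0("Chr", 1:18), c("A", "B", "C")))
  s <- summarize_table(m)
  expect_equal(unlist(s["Sum", ]), c(A = 36, B = 36, C = 36))
  expect_equal(unlist(s["Average", ]), c(A = 2, B = 2, C = 2))
  expect_equal(unlist(s["Min", ]), unlist(s["Max", ]))

  set.seed(4)
  r <- matrix(runif(36), 18, 2)
  s <- summarize_table(r)
  expect_equal(unlist(s["Average", ]), colSums(r) / 18, ignore_attr = TRUE)
})

test_that("zygosity counts respect their inequalities", {
  calls <- data.frame(zygosity = c("hom", "hom", "hom", "het", "het"),
                      category = c("non_synonymous", "synonymous", "intron",
                                   "non_synonymous", "upstream"))
  z <- zygosity_counts(calls)
  expect_equal(unname(z), c(5, 3, 2, 1))
  expect_lte(z[["homozygous"]], z[["total"]])
  expect_lte(z[["hom_non_synonymous"]],
             min(z[["homozygous"]], z[["non_synonymous"]]))
  empty <- calls[0, ]
  expect_equal(unname(zygosity_counts(empty)), c(0, 0, 0, 0))
})

test_that("a one-SNP-per-category call set gives uniform abundance", {
  cats <- c("stop_gain", "non_synonymous", "synonymous", "intron",
            "upstream", "downstream", "intergenic")
  calls <- list(R2 = data.frame(chrom = "Chr01", pos = 1:7, ref = "C",
                                alt = "T", genotype = "C/T", zygosity = "het",
                                category = cats, gene_id = NA))
  cs <- structure(list(calls = calls), class = "ems_callsets")
  ab <- annotation_abundance(cs)
  expect_equal(ab$R2, rep(1 / 7, 7))
})

test_that("packaged frequency fixture reproduces its printed summary rows", {
  t1 <- read.table(system.file("extdata", "table1.tsv", package = "emsift"),
                   header = TRUE, sep = "\t", row.names = 1)
  s <- summarize_table(t1)
  expect_equal(unlist(s["Sum", ]),
               c(R2 = 3663.6, R3 = 2040.4, R4 = 583.2, R5 = 3542.4,
                 R6 = 1208.7, R7 = 81.5, R8 = 269.3, R9 = 2281.5,
                 R10 = 1098.7),
               tolerance = 1e-9)
  printed_avg <- c(203.5, 113.4, 32.4, 196.8, 67.1, 4.5, 15.0, 126.7, 61.0)
  expect_true(all(abs(unlist(s["Average", ]) - printed_avg) <= 0.05 + 1e-9))
})
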