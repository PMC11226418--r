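# hand-built site helper: genotypes given per sample, defaults to hom-ref
mk_site <- function(roles, ref = "C", alt = "T", chrom = "Chr01", pos = 100L,
                    ...) {
  over <- list(...)
  gt <- matrix(paste(ref, ref, sep = "/"), 1, length(roles),
               dimnames = list(NULL, names(roles)))
  for (s in names(over)) gt[, s] <- over[[s]]
  variant_table(chrom, pos, ref, alt, gt)
}

roles9 <- toy_roles()
wt <- wildtype_ids(roles9)
mut <- mutant_ids(roles9)

test_that("wild-type consensus certifies unanimous non-missing genotypes", {
  s_ok <- mk_site(roles9)
  r <- wt_consensus(s_ok, wt)
  expect_equal(nrow(r$kept), 1)
  expect_equal(r$kept$consensus, "C/C")

  args <- stats::setNames(list("C/T"), wt[1])
  s_diff <- do.call(mk_site, c(list(roles9), args))
  r <- wt_consensus(s_diff, wt)
  expect_equal(nrow(r$kept), 0)   # individual difference among controls

  args <- stats::setNames(list(NA_character_), wt[2])
  s_na <- do.call(mk_site, c(list(roles9), args))
  r <- wt_consensus(s_na, wt)
  expect_equal(nrow(r$kept), 0)   # missing control blocks certification
})

test_that("background divergence from the reference is dropped", {
  s <- mk_site(roles9)
  s$consensus <- "T/T"
  expect_equal(nrow(drop_background(s)$kept), 0)
  s$consensus <- "C/C"
  expect_equal(nrow(drop_background(s)$kept), 1)
  s$consensus <- "C/T"    # heterozygous consensus is still divergence
  expect_equal(nrow(drop_background(s)$kept), 0)
})

test_that("sites shared identically by all mutants are removed", {
  all_alt <- stats::setNames(as.list(rep("T/T", length(mut))), mut)
  s <- do.call(mk_site, c(list(roles9), all_alt))
  expect_equal(nrow(drop_shared_mutant(s, mut)$kept), 0)

  eight <- stats::setNames(as.list(rep("T/T", length(mut) - 1)), mut[-1])
  s <- do.call(mk_site, c(list(roles9), eight))   # one mutant stays hom-ref
  expect_equal(nrow(drop_shared_mutant(s, mut)$kept), 1)

  s <- mk_site(roles9)                            # all mutants reference
  expect_equal(nrow(drop_shared_mutant(s, mut)$kept), 1)
})

test_that("unplaced scaffolds are excluded", {
  genome <- toy_genome()
  s <- rbind(mk_site(roles9, chrom = "Chr03", pos = 7L),
             mk_site(roles9, chrom = "scaffold_001", pos = 7L))
  r <- drop_unplaced(s, genome)
  expect_equal(r$kept$chrom, "Chr03")
  expect_equal(r$removed$chrom, "scaffold_001")
  all_placed <- mk_site(roles9)
  expect_equal(nrow(drop_unplaced(all_placed, genome)$removed), 0)
})

test_that("uniqueness keeps sites where some mutant differs from all others", {
  one <- stats::setNames(list("A/A"), mut[1])
  s <- do.call(mk_site, c(list(roles9, ref = "C", alt = "A"), one))
  expect_equal(nrow(uniqueness_filter(s, mut)$kept), 1)

  two <- stats::setNames(list("A/A", "A/C"), mut[1:2])
  s <- do.call(mk_site, c(list(roles9, ref = "C", alt = "A"), two))
  expect_equal(nrow(uniqueness_filter(s, mut)$kept), 1)

  # genotypes split 5 vs 4 into two identical groups: nothing unique
  grp <- stats::setNames(as.list(c(rep("A/A", 5), rep("C/C", 4))), mut)
  s <- do.call(mk_site, c(list(roles9, ref = "C", alt = "A"), grp))
  expect_equal(nrow(uniqueness_filter(s, mut)$kept), 0)
})

test_that("attribution assigns non-consensus, non-missing genotypes with zygosity", {
  args <- stats::setNames(list("T/T", "C/T", NA_character_), mut[1:3])
  s <- do.call(mk_site, c(list(roles9), args))
  s$consensus <- "C/C"
  calls <- attribute_to_mutants(s, mut)
  expect_equal(nrow(calls[[mut[1]]]), 1)
  expect_equal(calls[[mut[1]]]$zygosity, "hom")
  expect_equal(calls[[mut[2]]]$zygosity, "het")
  expect_equal(nrow(calls[[mut[3]]]), 0)   # missing is never attributed
  for (m in mut[4:9]) expect_equal(nrow(calls[[m]]), 0)
})

test_that("trace conserves sites at every step", {
  genome <- toy_genome()
  sites <- random_sites(300, genome, roles9, seed = 42)
  out <- run_cascade(sites, roles9, genome)
  expect_equal(out$trace$n_out, out$trace$n_in - out$trace$n_removed)
  expect_equal(out$trace$n_in[-1], out$trace$n_out[-5])
  expect_equal(out$trace$n_in[1], nrow(sites))
})

test_that("cascade equals the naive per-site rule evaluator", {
  genome <- toy_genome()
  for (seed in c(1, 2, 3)) {
    sites <- random_sites(200, genome, roles9, seed = seed)
    fast <- run_cascade(sites, roles9, genome)
    slow <- naive_cascade(sites, roles9, genome)
    expect_equal(sum(slow$kept), fast$trace$n_out[5])
    expect_equal(call_keys(fast), slow$calls)
  }
})

test_that("steps 3, 4, 5 commute pairwise", {
  genome <- toy_genome()
  sites <- random_sites(250, genome, roles9, seed = 77)
  ops <- list(
    s3 = function(s) drop_shared_mutant(s, mut)$kept,
    s4 = function(s) drop_unplaced(s, genome)$kept,
    s5 = function(s) uniqueness_filter(s, mut)$kept)
  key <- function(s) sort(paste(s$chrom, s$pos))
  for (a in names(ops)) for (b in names(ops)) {
    if (a == b) next
    expect_equal(key(ops[[b]](ops[[a]](sites))),
                 key(ops[[a]](ops[[b]](sites))),
                 info = paste(a, b))
  }
})

test_that("a wild type that always matches consensus never changes output", {
  genome <- toy_genome()
  sites <- random_sites(200, genome, roles9, seed = 13)
  base <- run_cascade(sites, roles9, genome)

  cons <- wt_consensus(sites, wt)
  extra <- sites
  extra$R99 <- NA_character_
  idx <- match(paste(cons$kept$chrom, cons$kept$pos),
               paste(sites$chrom, sites$pos))
  extra$R99[idx] <- cons$kept$consensus
  # where consensus is undefined the site is already removed at step 1;
  # give the new control the first WT's genotype there
  extra$R99[is.na(extra$R99)] <- extra[[wt[1]]][is.na(extra$R99)]
  roles10 <- sample_roles(c(roles9, R99 = "wildtype"))
  aug <- run_cascade(extra, roles10, genome)
  expect_equal(call_keys(aug), call_keys(base))
})

test_that("a study with only background sites yields empty call sets", {
  cfg <- sim_config(seed = 2, chrom_lengths = rep(5e4, 3),
                    unplaced_lengths = numeric(0), gene_density = 0,
                    ems_counts = rep(0L, 9), wt_noise_rate = 0,
                    unplaced_mutant_sites = 0L, missing_rate = 0)
  st <- simulate_study(cfg)
  expect_gt(nrow(st$truth$background), 0)
  out <- run_cascade(st$sites, st$roles, st$genome)
  expect_true(all(vapply(out$calls, nrow, 0L) == 0))
  # everything is removed as background divergence
  expect_equal(out$trace$n_removed[2], nrow(st$truth$background))
})

test_that("cascade recovers planted truth exactly on a clean study", {
  cfg <- sim_config(seed = 8, chrom_lengths = rep(8e4, 4),
                    unplaced_lengths = 2e4, gene_density = 10,
                    ems_count_range = c(40, 150), missing_rate = 0)
  st <- simulate_study(cfg)
  out <- run_cascade(st$sites, st$roles, st$genome)
  sc <- score_against_truth(out, st$truth)
  overall <- sc[sc$mutant == "overall", ]
  expect_equal(overall$precision, 1)
  expect_equal(overall$recall, 1)
})

test_that("a hand fixture covering every removal reason matches the oracle", {
  genome <- toy_genome()
  hr <- "C/C"; ha <- "T/T"; het <- "C/T"
  rows <- list(
    mk_site(roles9, pos = 1L,
            R11 = het),                                 # WT individual diff
    do.call(mk_site, c(list(roles9, pos = 2L),
                       stats::setNames(as.list(rep(NA_character_, 1)), wt[1]))),
    do.call(mk_site, c(list(roles9, pos = 3L),
                       stats::setNames(as.list(rep(ha, 14)),
                                       c(mut, wt)))),   # background divergence
    do.call(mk_site, c(list(roles9, pos = 4L),
                       stats::setNames(as.list(rep(ha, 9)), mut))),  # shared
    do.call(mk_site, c(list(roles9, chrom = "scaffold_001", pos = 5L),
                       stats::setNames(list(ha), mut[1]))),          # unplaced
    do.call(mk_site, c(list(roles9, pos = 6L),
                       stats::setNames(as.list(c(rep(ha, 5), rep(hr, 4))),
                                       mut))),          # 5v4, nothing unique
    do.call(mk_site, c(list(roles9, pos = 7L),
                       stats::setNames(list(ha), mut[3]))),          # kept hom
    do.call(mk_site, c(list(roles9, pos = 8L),
                       stats::setNames(list(het), mut[5]))),         # kept het
    mk_site(roles9, pos = 9L))   # all-reference: survives step 3 but has no
  sites <- do.call(rbind, rows)  # unique mutant, so step 5 removes it
  fast <- run_cascade(sites, roles9, genome)
  slow <- naive_cascade(sites, roles9, genome)
  expect_equal(call_keys(fast), slow$calls)
  expect_equal(fast$trace$n_removed, c(2L, 1L, 1L, 1L, 2L))
  expect_equal(nrow(fast$calls[[mut[3]]]), 1)
  expect_equal(fast$calls[[mut[3]]]$zygosity, "hom")
  expect_equal(fast$calls[[mut[5]]]$zygosity, "het")
})
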