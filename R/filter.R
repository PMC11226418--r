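#' Five-step EMS SNP filtering cascade
#'
#' The cascade reduces a raw multi-sample SNP table to per-mutant sets of
#' EMS-attributable mutations:
#'
#' 1. **Wild-type consensus** ([wt_consensus()]): keep sites where all
#'    wild-type controls carry the same, non-missing genotype (removes
#'    individual differences among controls).
#' 2. **Background divergence** ([drop_background()]): keep sites whose
#'    wild-type consensus is homozygous reference (removes fixed divergence
#'    between the wild-type line and the reference genome).
#' 3. **Shared among mutants** ([drop_shared_mutant()]): remove sites where
#'    every mutant carries the same non-reference genotype (cannot be
#'    independent induced mutations).
#' 4. **Placed chromosomes** ([drop_unplaced()]): remove sites on unplaced
#'    scaffolds.
#' 5. **Uniqueness** ([uniqueness_filter()]): keep sites where at least one
#'    mutant's non-missing genotype differs from every other mutant's.
#'
#' [attribute_to_mutants()] then assigns each surviving site to every mutant
#' whose genotype differs from the wild-type consensus and is not missing
#' (one site may be attributed to more than one mutant).
#'
#' @param sites An `ems_variants` table (see [variant_table()]).
#' @param roles Named character vector of sample roles.
#' @param genome An [ems_genome] defining the placed chromosomes.
#' @return [run_cascade()] returns an object of class `ems_callsets`: a list
#'   with `calls` (named list of per-mutant data.frames with columns `chrom`,
#'   `pos`, `ref`, `alt`, `genotype`, `zygosity`), `trace` (the
#'   [filter_trace()] data.frame), `sites` (surviving sites with their
#'   consensus), and `roles`.
#' @name ems_cascade
NULL

#' Step 1: certify the wild-type consensus genotype
#'
#' @param sites An `ems_variants` table.
#' @param wt Character vector of wild-type sample ids.
#' @return List with `kept` (sites gaining a `consensus` column) and
#'   `removed`.
#' @export
wt_consensus <- function(sites, wt) {
  if (length(wt) < 1) stop("need at least one wild-type sample")
  g <- vt_gt(sites, wt)
  consistent <- !is.na(g[, 1])
  if (ncol(g) > 1) {
    for (j in 2:ncol(g))
      consistent <- consistent & !is.na(g[, j]) & g[, j] == g[, 1]
  }
  consistent[is.na(consistent)] <- FALSE
  kept <- sites[consistent, , drop = FALSE]
  kept$consensus <- g[consistent, 1]
  list(kept = kept, removed = sites[!consistent, , drop = FALSE])
}

#' Step 2: drop background divergence from the reference
#'
#' @param sites Sites with a `consensus` column (from [wt_consensus()]).
#' @return List with `kept` (consensus is homozygous reference) and
#'   `removed`.
#' @export
drop_background <- function(sites) {
  if (is.null(sites$consensus)) stop("sites lack a consensus column")
  keep <- sites$consensus == gt_hom(sites$ref)
  list(kept = sites[keep, , drop = FALSE],
       removed = sites[!keep, , drop = FALSE])
}

#' Step 3: drop sites shared identically by all mutants
#'
#' @param sites An `ems_variants` table.
#' @param mut Character vector of mutant sample ids.
#' @return List with `kept` and `removed` (all mutants identical, non-missing
#'   and non-reference).
#' @export
drop_shared_mutant <- function(sites, mut) {
  if (length(mut) < 2) stop("need at least two mutants")
  g <- vt_gt(sites, mut)
  same <- !is.na(g[, 1])
  for (j in seq_len(ncol(g))[-1])
    same <- same & !is.na(g[, j]) & g[, j] == g[, 1]
  same[is.na(same)] <- FALSE
  shared <- same & g[, 1] != gt_hom(sites$ref)
  list(kept = sites[!shared, , drop = FALSE],
       removed = sites[shared, , drop = FALSE])
}

#' Step 4: drop sites on unplaced scaffolds
#'
#' @param sites An `ems_variants` table.
#' @param genome An [ems_genome]; its `placed` set defines the chromosomes.
#' @return List with `kept` and `removed`.
#' @export
drop_unplaced <- function(sites, genome) {
  keep <- sites$chrom %in% genome$placed
  list(kept = sites[keep, , drop = FALSE],
       removed = sites[!keep, , drop = FALSE])
}

#' Step 5: keep sites unique to at least one mutant
#'
#' A site is kept if some mutant's genotype is non-missing and equals no
#' other mutant's genotype (missing genotypes in other mutants do not block
#' uniqueness).
#'
#' @inheritParams drop_shared_mutant
#' @return List with `kept` and `removed`.
#' @export
uniqueness_filter <- function(sites, mut) {
  g <- vt_gt(sites, mut)
  kept <- rep(FALSE, nrow(g))
  for (j in seq_len(ncol(g))) {
    eq <- g == g[, j]
    eq[is.na(eq)] <- FALSE
    kept <- kept | (!is.na(g[, j]) & rowSums(eq) == 1L)
  }
  list(kept = sites[kept, , drop = FALSE],
       removed = sites[!kept, , drop = FALSE])
}

#' Attribute surviving sites to individual mutants
#'
#' A site is attributed to a mutant when that mutant's genotype is not
#' missing and differs from the wild-type consensus; its zygosity is `hom`
#' when both alleles equal the alternate allele, `het` otherwise. A site may
#' be attributed to several mutants.
#'
#' @param sites Sites with a `consensus` column that passed steps 1-5.
#' @param mut Character vector of mutant sample ids.
#' @return Named list (one per mutant) of call data.frames.
#' @export
attribute_to_mutants <- function(sites, mut) {
  g <- vt_gt(sites, mut)
  out <- list()
  for (m in mut) {
    sel <- !is.na(g[, m]) & g[, m] != sites$consensus
    d <- data.frame(chrom = sites$chrom[sel], pos = sites$pos[sel],
                    ref = sites$ref[sel], alt = sites$alt[sel],
                    genotype = g[sel, m], stringsAsFactors = FALSE)
    d$zygosity <- if (nrow(d)) ifelse(gt_is_hom(d$genotype), "hom", "het")
                  else character(0)
    rownames(d) <- NULL
    out[[m]] <- d
  }
  out
}

#' Construct a filter trace
#'
#' @param steps Character vector of step names.
#' @param n_in,n_removed Integer vectors of per-step input and removed site
#'   counts.
#' @return data.frame with columns `step`, `n_in`, `n_removed`, `n_out`;
#'   conservation (`n_out = n_in - n_removed`) is checked.
#' @export
filter_trace <- function(steps, n_in, n_removed) {
  out <- data.frame(step = steps, n_in = n_in, n_removed = n_removed,
                    n_out = n_in - n_removed)
  if (any(out$n_out < 0)) stop("removed more sites than were present")
  out
}

#' @rdname ems_cascade
#' @export
run_cascade <- function(sites, roles, genome) {
  roles <- sample_roles(roles)
  mut <- mutant_ids(roles); wt <- wildtype_ids(roles)

  s1 <- wt_consensus(sites, wt)
  s2 <- drop_background(s1$kept)
  s3 <- drop_shared_mutant(s2$kept, mut)
  s4 <- drop_unplaced(s3$kept, genome)
  s5 <- uniqueness_filter(s4$kept, mut)

  trace <- filter_trace(
    steps = c("wt_consensus", "background_divergence", "shared_among_mutants",
              "unplaced_scaffolds", "uniqueness"),
    n_in = c(nrow(sites), nrow(s1$kept), nrow(s2$kept), nrow(s3$kept),
             nrow(s4$kept)),
    n_removed = c(nrow(s1$removed), nrow(s2$removed), nrow(s3$removed),
                  nrow(s4$removed), nrow(s5$removed)))

  calls <- attribute_to_mutants(s5$kept, mut)
  structure(list(calls = calls, trace = trace, sites = s5$kept,
                 roles = roles),
            class = "ems_callsets")
}

#' @export
print.ems_callsets <- function(x, ...) {
  cat("<ems_callsets>\n")
  cat(sprintf("  %d sites passed the cascade (from %d)\n",
              x$trace$n_out[nrow(x$trace)], x$trace$n_in[1]))
  n <- vapply(x$calls, nrow, 0L)
  cat("  attributed per mutant:\n")
  print(n)
  invisible(x)
}

#' @export
summary.ems_callsets <- function(object, ...) {
  n <- vapply(object$calls, nrow, 0L)
  hom <- vapply(object$calls, function(d) sum(d$zygosity == "hom"), 0L)
  out <- data.frame(mutant = names(object$calls), total = n,
                    homozygous = hom, heterozygous = n - hom)
  rownames(out) <- NULL
  out
}

#' Compare attributed calls with planted ground truth
#'
#' @param callsets An `ems_callsets`.
#' @param truth A truth list (element `ems`) from [simulate_study()] or
#'   [read_truth()].
#' @return data.frame of per-mutant and overall precision/recall.
#' @export
score_against_truth <- function(callsets, truth) {
  key <- function(m, c, p) paste(m, c, p, sep = ":")
  truth_keys <- key(truth$ems$mutant, truth$ems$chrom, truth$ems$pos)
  call_keys <- unlist(lapply(names(callsets$calls), function(m) {
    d <- callsets$calls[[m]]
    if (nrow(d)) key(m, d$chrom, d$pos) else character(0)
  }))
  per <- lapply(names(callsets$calls), function(m) {
    tk <- truth_keys[truth$ems$mutant == m]
    ck <- call_keys[startsWith(call_keys, paste0(m, ":"))]
    tp <- sum(ck %in% tk)
    data.frame(mutant = m, n_called = length(ck), n_true = length(tk),
               precision = if (length(ck)) tp / length(ck) else NA_real_,
               recall = if (length(tk)) tp / length(tk) else NA_real_)
  })
  per <- do.call(rbind, per)
  tp <- sum(call_keys %in% truth_keys)
  rbind(per, data.frame(mutant = "overall", n_called = length(call_keys),
                        n_true = length(truth_keys),
                        precision = if (length(call_keys)) tp / length(call_keys) else NA_real_,
                        recall = if (length(truth_keys)) tp / length(truth_keys) else NA_real_))
}
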