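#' Classify a substitution into the six strand-symmetric classes
#'
#' Substitutions are pooled by strand symmetry (a G>A change is the same
#' event as C>T observed on the other strand), giving six classes:
#' `C/G>T/A` and `T/A>C/G` (transitions), `C/G>A/T`, `T/A>A/T`, `T/A>G/C`
#' and `C/G>G/C` (transversions).
#'
#' @param ref,alt Character vectors of single-nucleotide alleles.
#' @return Character vector of class labels with attribute-free values from
#'   `spectrum_classes()`.
#' @export
classify_substitution <- function(ref, alt) {
  if (any(ref == alt)) stop("ref and alt must differ")
  if (!all(c(ref, alt) %in% BASES)) stop("alleles must be A, C, G or T")
  # lookup over the 12 ordered pairs, pooled by strand symmetry
  key <- paste0(ref, alt)
  map <- c(CT = "C/G>T/A", GA = "C/G>T/A",
           TC = "T/A>C/G", AG = "T/A>C/G",
           CA = "C/G>A/T", GT = "C/G>A/T",
           TA = "T/A>A/T", AT = "T/A>A/T",
           TG = "T/A>G/C", AC = "T/A>G/C",
           CG = "C/G>G/C", GC = "C/G>G/C")
  unname(map[key])
}

#' Is a substitution a transition?
#'
#' @inheritParams classify_substitution
#' @return Logical vector; `TRUE` for purine-purine or
#'   pyrimidine-pyrimidine changes.
#' @export
is_transition <- function(ref, alt) {
  classify_substitution(ref, alt) %in% SPECTRUM_CLASSES[1:2]
}

#' The six substitution class labels
#' @return Character vector, transitions first.
#' @export
spectrum_classes <- function() SPECTRUM_CLASSES

#' Substitution spectrum of a call set
#'
#' @param calls A per-mutant call data.frame (columns `ref`, `alt`), e.g. one
#'   element of `ems_callsets$calls`.
#' @return Object of class `substitution_spectrum`: list with `counts` and
#'   `proportions` (named by class, transitions first) and
#'   `transition_proportion`.
#' @export
spectrum <- function(calls) {
  if (nrow(calls) == 0)
    stop("empty call set: spectrum proportions are undefined")
  cls <- factor(classify_substitution(calls$ref, calls$alt),
                levels = SPECTRUM_CLASSES)
  counts <- table(cls)
  counts <- stats::setNames(as.integer(counts), names(counts))
  props <- counts / sum(counts)
  structure(list(counts = counts, proportions = props,
                 transition_proportion = sum(props[1:2])),
            class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat("<substitution_spectrum>\n")
  print(round(x$proportions, 4))
  cat(sprintf("  transitions: %.1f%%\n", 100 * x$transition_proportion))
  invisible(x)
}

#' Per-chromosome mutation counts or frequencies
#'
#' Builds the chromosome-by-mutant table of SNP counts or frequencies
#' (SNPs/Mb, count divided by exact chromosome length in bp / 1e6).
#'
#' @param callsets An `ems_callsets`.
#' @param genome An [ems_genome]; rows are its placed chromosomes in order.
#' @param what `"frequency"` (SNPs/Mb, default) or `"count"`.
#' @return data.frame of class `chrom_stat_table`, rows = placed
#'   chromosomes, columns = mutants, plus a `length_mb` column.
#' @export
frequency_table <- function(callsets, genome, what = c("frequency", "count")) {
  what <- match.arg(what)
  chroms <- genome$placed
  len_mb <- genome$lengths[chroms] / 1e6
  out <- data.frame(row.names = chroms, length_mb = unname(len_mb))
  for (m in names(callsets$calls)) {
    d <- callsets$calls[[m]]
    cnt <- vapply(chroms, function(c) sum(d$chrom == c), 0L)
    out[[m]] <- if (what == "frequency") cnt / len_mb else cnt
  }
  class(out) <- c("chrom_stat_table", "data.frame")
  out
}

#' Append Sum/Average/Min/Max summary rows to a statistics table
#'
#' Arithmetic is exact; the `Average` row is the unweighted mean over
#' chromosome rows (so `Average = Sum / n_rows`), matching the convention of
#' per-chromosome frequency tables. Rounding, if any, is applied only at
#' presentation.
#'
#' @param x Numeric matrix or data.frame (rows = chromosomes).
#' @param digits Optional rounding for presentation; `NULL` keeps full
#'   precision.
#' @return data.frame with the original rows plus `Sum`, `Average`, `Min`,
#'   `Max` rows.
#' @export
summarize_table <- function(x, digits = NULL) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("x must be numeric")
  summ <- rbind(Sum = colSums(m), Average = colMeans(m),
                Min = apply(m, 2, min), Max = apply(m, 2, max))
  out <- rbind(m, summ)
  if (!is.null(digits)) out <- round(out, digits)
  as.data.frame(out)
}

#' Zygosity and effect summary counts for one mutant
#'
#' @param calls An annotated per-mutant call data.frame (columns `zygosity`
#'   and, for the non-synonymous counts, `category`).
#' @return Named integer vector: `total`, `homozygous`, `non_synonymous`,
#'   `hom_non_synonymous`.
#' @export
zygosity_counts <- function(calls) {
  hom <- calls$zygosity == "hom"
  ns <- if (!is.null(calls$category)) calls$category == "non_synonymous"
        else rep(FALSE, nrow(calls))
  c(total = nrow(calls), homozygous = sum(hom),
    non_synonymous = sum(ns), hom_non_synonymous = sum(hom & ns))
}

#' Relative abundance of effect categories per mutant
#'
#' Uses the severity-reduced single category per SNP; per-mutant abundances
#' sum to one.
#'
#' @param callsets An annotated `ems_callsets`.
#' @return data.frame, rows = the seven effect categories, columns = mutants.
#' @export
annotation_abundance <- function(callsets) {
  if (is.null(callsets$calls[[1]]$category))
    stop("callsets are not annotated; run annotate_callsets() first")
  out <- data.frame(row.names = EFFECT_LEVELS)
  for (m in names(callsets$calls)) {
    d <- callsets$calls[[m]]
    cnt <- table(factor(d$category, levels = EFFECT_LEVELS))
    out[[m]] <- if (nrow(d)) as.numeric(cnt) / nrow(d) else as.numeric(cnt)
  }
  out
}
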