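#' Run the full characterization pipeline
#'
#' Orchestrates filter, annotate, statistics, chromosome-length scaling and
#' GO enrichment on a study given either as in-memory objects (an
#' `ems_study` from [simulate_study()]) or as files on disk. All stages are
#' deterministic given the inputs.
#'
#' @param study Optional `ems_study`; if supplied, `vcf`/`fasta`/`gff` are
#'   ignored.
#' @param vcf,fasta,gff Paths to the study VCF, reference FASTA and GFF3 gene
#'   models (used when `study` is `NULL`).
#' @param roles Named character vector of sample roles (required with file
#'   input).
#' @param gene2go Optional path to a gene-to-GO TSV or a named list; when
#'   absent and the study carries no GO annotation, enrichment is skipped
#'   with a message.
#' @param out_dir Optional output directory; when given, all result tables
#'   are written as TSV (plus per-mutant VCFs, Newick dendrograms and a JSON
#'   manifest).
#' @param window Annotation window (bp) for upstream/downstream calls.
#' @param min_term_size,alpha Enrichment parameters (see [enrich()]).
#' @param entanglement_L Norm exponent for [entanglement()].
#' @param truth Optional ground-truth list (from a simulated study or
#'   [read_truth()]); when given, precision/recall against the planted EMS
#'   sites is computed.
#' @param placed Optional placed-chromosome ids for file input (see
#'   [read_genome()]).
#' @return Object of class `ems_run`: list with `callsets`, `trace`,
#'   `frequencies`, `counts`, `spectra`, `abundance`, `zygosity`, `fits`,
#'   `dendrograms`, `entanglement`, `enrichment`, `truth_scores`, `params`.
#' @export
run_pipeline <- function(study = NULL, vcf = NULL, fasta = NULL, gff = NULL,
                         roles = NULL, gene2go = NULL, out_dir = NULL,
                         window = 5000, min_term_size = 3, alpha = 0.05,
                         entanglement_L = 1.5, truth = NULL, placed = NULL) {
  if (!is.null(study)) {
    stopifnot(inherits(study, "ems_study"))
    sites <- study$sites; roles <- study$roles
    genome <- study$genome; models <- study$models
    if (is.null(truth)) truth <- study$truth
    if (is.null(gene2go) && length(models$go)) gene2go <- models$go
  } else {
    if (is.null(vcf) || is.null(fasta) || is.null(gff) || is.null(roles))
      stop("file input requires vcf, fasta, gff and roles")
    genome <- read_genome(fasta, placed = placed)
    models <- read_gff(gff)
    sites <- read_vcf(vcf, roles)
  }
  if (is.character(gene2go)) gene2go <- read_gene2go(gene2go)

  callsets <- run_cascade(sites, roles, genome)
  callsets <- annotate_callsets(callsets, models, genome, window = window)

  counts <- frequency_table(callsets, genome, what = "count")
  freqs <- frequency_table(callsets, genome, what = "frequency")
  spectra <- lapply(callsets$calls, function(d)
    if (nrow(d)) spectrum(d) else NULL)
  abundance <- annotation_abundance(callsets)
  zyg <- t(vapply(callsets$calls, zygosity_counts, numeric(4)))
  zyg <- data.frame(mutant = rownames(zyg), zyg, row.names = NULL)

  lengths_mb <- genome$lengths[genome$placed] / 1e6
  fits <- list(); dendros <- list(); ent <- list()
  d_len <- if (length(lengths_mb) >= 2) build_dendrogram(lengths_mb) else NULL
  for (m in names(callsets$calls)) {
    cnt <- stats::setNames(counts[[m]], rownames(counts))
    fits[[m]] <- tryCatch(fit_count_vs_length(cnt, unname(lengths_mb)),
                          error = function(e) NULL)
    if (!is.null(d_len) && stats::var(cnt) > 0) {
      dendros[[m]] <- build_dendrogram(cnt)
      raw <- entanglement(d_len, dendros[[m]], L = entanglement_L)
      unt <- untangle(d_len, dendros[[m]], L = entanglement_L)
      ent[[m]] <- data.frame(mutant = m, raw = raw$value,
                             untangled = unt$score$value,
                             L = entanglement_L)
    }
  }
  fit_tab <- do.call(rbind, lapply(names(fits), function(m) {
    f <- fits[[m]]
    if (is.null(f)) return(NULL)
    data.frame(mutant = m, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, p_value = f$p_value, n = f$n)
  }))
  ent_tab <- if (length(ent)) do.call(rbind, ent) else NULL

  enrichment <- NULL
  if (is.null(gene2go) || length(gene2go) == 0) {
    message("no gene-to-GO annotation: enrichment skipped")
  } else {
    enrichment <- list()
    for (cat in c("non_synonymous", "stop_gain")) {
      gsets <- genes_with_category(callsets, cat)
      enrichment[[cat]] <- lapply(gsets, function(g)
        if (length(g)) enrich(g, gene2go, min_term_size, alpha) else NULL)
    }
  }

  truth_scores <- if (!is.null(truth) && !is.null(truth$ems) &&
                      nrow(truth$ems))
    score_against_truth(callsets, truth) else NULL

  run <- structure(
    list(callsets = callsets, trace = callsets$trace, counts = counts,
         frequencies = freqs, spectra = spectra, abundance = abundance,
         zygosity = zyg, fits = fits, fit_table = fit_tab,
         dendrograms = c(list(length = d_len), dendros),
         entanglement = ent_tab, enrichment = enrichment,
         truth_scores = truth_scores,
         params = list(window = window, min_term_size = min_term_size,
                       alpha = alpha, entanglement_L = entanglement_L)),
    class = "ems_run")
  if (!is.null(out_dir)) write_run(run, out_dir, genome)
  run
}

#' @export
print.ems_run <- function(x, ...) {
  cat("<ems_run>\n")
  print(x$trace)
  if (!is.null(x$truth_scores)) {
    cat("\nrecovery vs planted truth:\n")
    print(x$truth_scores[x$truth_scores$mutant == "overall", ])
  }
  invisible(x)
}

write_tsv <- function(d, path, rn = FALSE) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = rn,
              col.names = if (rn) NA else TRUE)
}

# write all pipeline outputs as diffable plain text
write_run <- function(run, out_dir, genome) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_tsv(run$trace, file.path(out_dir, "filter_trace.tsv"))
  write_tsv(run$counts, file.path(out_dir, "counts.tsv"), rn = TRUE)
  write_tsv(summarize_table(run$frequencies),
            file.path(out_dir, "frequencies.tsv"), rn = TRUE)
  write_tsv(run$abundance, file.path(out_dir, "abundance.tsv"), rn = TRUE)
  write_tsv(run$zygosity, file.path(out_dir, "zygosity.tsv"))
  spec_tab <- do.call(rbind, lapply(names(run$spectra), function(m) {
    s <- run$spectra[[m]]
    if (is.null(s)) return(NULL)
    data.frame(mutant = m, class = names(s$counts), count = s$counts,
               proportion = s$proportions, row.names = NULL)
  }))
  if (!is.null(spec_tab))
    write_tsv(spec_tab, file.path(out_dir, "spectrum.tsv"))
  if (!is.null(run$fit_table))
    write_tsv(run$fit_table, file.path(out_dir, "regression.tsv"))
  if (!is.null(run$entanglement))
    write_tsv(run$entanglement, file.path(out_dir, "entanglement.tsv"))
  for (m in names(run$dendrograms)) {
    d <- run$dendrograms[[m]]
    if (!is.null(d))
      writeLines(to_newick(d),
                 file.path(out_dir, sprintf("dendrogram_%s.nwk", m)))
  }
  if (!is.null(run$enrichment)) {
    for (cat in names(run$enrichment)) {
      tab <- do.call(rbind, lapply(names(run$enrichment[[cat]]), function(m) {
        e <- run$enrichment[[cat]][[m]]
        if (is.null(e) || nrow(e) == 0) return(NULL)
        cbind(mutant = m, as.data.frame(e))
      }))
      if (!is.null(tab))
        write_tsv(tab, file.path(out_dir, sprintf("enrichment_%s.tsv", cat)))
    }
  }
  if (!is.null(run$truth_scores))
    write_tsv(run$truth_scores, file.path(out_dir, "truth_scores.tsv"))
  # per-mutant call sets as single-sample VCFs
  for (m in names(run$callsets$calls)) {
    d <- run$callsets$calls[[m]]
    gt <- matrix(d$genotype, ncol = 1, dimnames = list(NULL, m))
    vt <- variant_table(d$chrom, d$pos, d$ref, d$alt, gt)
    write_vcf(vt, file.path(out_dir, sprintf("calls_%s.vcf", m)),
              genome = genome)
  }
  manifest <- list(package = "emsift",
                   version = as.character(packageVersion("emsift")),
                   params = run$params,
                   n_sites_in = run$trace$n_in[1],
                   n_sites_out = run$trace$n_out[nrow(run$trace)])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
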