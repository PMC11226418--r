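#' Classify one SNP against the gene models
#'
#' Assigns one effect call per gene model near the site: a hit inside a CDS
#' is classified by codon translation (strand-aware) as `stop_gain`,
#' `non_synonymous` or `synonymous`; a hit inside the gene span but outside
#' the CDS is `intron`; a site within `window` bp 5' of the gene start
#' (strand-aware) is `upstream`, within `window` bp 3' of the gene end
#' `downstream`. If no gene is within the window a single `intergenic` call
#' is returned.
#'
#' @param chrom,pos,ref,alt The SNP (single nucleotides, 1-based position).
#' @param models A [gene_models] object.
#' @param genome An [ems_genome] (needed to build codons).
#' @param window Upstream/downstream window in bp (default 5000, the
#'   conventional annotation default).
#' @return data.frame with columns `category`, `gene_id`, `codon_ref`,
#'   `codon_alt`, `aa_ref`, `aa_alt` (codon/aa fields `NA` outside CDS).
#' @export
classify_site <- function(chrom, pos, ref, alt, models, genome,
                          window = 5000) {
  stopifnot(length(pos) == 1, window > 0)
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  if (pos < 1 || pos > genome$lengths[[chrom]])
    stop("position beyond chromosome length")
  if (!alt %in% BASES || !ref %in% BASES || ref == alt)
    stop("ref and alt must be distinct single nucleotides")

  calls <- empty_effects()
  genes <- models$genes[models$genes$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (pos >= g$span_start && pos <= g$span_end) {
      cds <- models$cds[models$cds$gene_id == g$gene_id, , drop = FALSE]
      in_cds <- any(pos >= cds$start & pos <= cds$end)
      if (in_cds) {
        calls <- rbind(calls, coding_effect(g, cds, pos, alt, genome))
      } else {
        calls <- rbind(calls, effect_row("intron", g$gene_id))
      }
    } else {
      before <- pos < g$span_start && pos >= g$span_start - window
      after <- pos > g$span_end && pos <= g$span_end + window
      if (before || after) {
        upstream <- if (g$strand == "+") before else after
        calls <- rbind(calls,
                       effect_row(if (upstream) "upstream" else "downstream",
                                  g$gene_id))
      }
    }
  }
  if (nrow(calls) == 0) calls <- effect_row("intergenic", NA_character_)
  rownames(calls) <- NULL
  calls
}

empty_effects <- function() {
  data.frame(category = character(0), gene_id = character(0),
             codon_ref = character(0), codon_alt = character(0),
             aa_ref = character(0), aa_alt = character(0),
             stringsAsFactors = FALSE)
}

effect_row <- function(category, gene_id, codon_ref = NA_character_,
                       codon_alt = NA_character_, aa_ref = NA_character_,
                       aa_alt = NA_character_) {
  data.frame(category = category, gene_id = gene_id, codon_ref = codon_ref,
             codon_alt = codon_alt, aa_ref = aa_ref, aa_alt = aa_alt,
             stringsAsFactors = FALSE)
}

# translate the affected codon on the coding strand and classify
coding_effect <- function(gene, cds, pos, alt, genome) {
  cds <- cds[order(cds$start), , drop = FALSE]
  # genomic positions of the CDS in translation (5'->3') order
  txpos <- unlist(lapply(seq_len(nrow(cds)),
                         function(i) cds$start[i]:cds$end[i]))
  if (gene$strand == "-") txpos <- rev(txpos)
  i <- match(pos, txpos)
  codon_idx <- (i - 1L) %/% 3L
  offset <- (i - 1L) %% 3L + 1L
  cpos <- txpos[(3L * codon_idx + 1L):(3L * codon_idx + 3L)]
  bases <- genome_base(genome, gene$chrom, cpos)
  if (gene$strand == "-") bases <- dna_complement(bases)
  codon_ref <- paste(bases, collapse = "")
  alt_coding <- if (gene$strand == "-") dna_complement(alt) else alt
  bases[offset] <- alt_coding
  codon_alt <- paste(bases, collapse = "")
  aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  category <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*" && aa_ref != "*") "stop_gain"
    else "non_synonymous"  # includes stop/start loss
  effect_row(category, gene$gene_id, codon_ref, codon_alt, aa_ref, aa_alt)
}

#' Reduce effect calls to a single per-SNP category
#'
#' Severity order: stop_gain > non_synonymous > synonymous > intron >
#' upstream > downstream > intergenic (upstream and downstream are equal in
#' severity; the tie is broken in favour of upstream for determinism).
#'
#' @param categories Character vector of effect categories for one SNP.
#' @return The single most severe category.
#' @export
reduce_severity <- function(categories) {
  EFFECT_LEVELS[min(match(categories, EFFECT_LEVELS))]
}

#' Annotate attributed call sets with effect categories
#'
#' Classifies every attributed SNP of every mutant. Each mutant's call table
#' gains `category` and `gene_id` columns holding the severity-reduced single
#' call; the full per-gene effect tables are kept in an `effects` element.
#'
#' @param callsets An `ems_callsets` from [run_cascade()].
#' @param models A [gene_models] object.
#' @param genome An [ems_genome].
#' @inheritParams classify_site
#' @return The annotated `ems_callsets` (gains element `effects`: named list
#'   of data.frames with one row per (SNP, gene) effect call).
#' @export
annotate_callsets <- function(callsets, models, genome, window = 5000) {
  idx <- effect_index(models, genome, window)
  callsets$effects <- list()
  for (m in names(callsets$calls)) {
    d <- callsets$calls[[m]]
    eff <- annotate_sites(d, models, genome, idx, window)
    callsets$effects[[m]] <- eff
    if (nrow(d)) {
      top <- vapply(split(eff, eff$site), function(e) {
        k <- which.min(match(e$category, EFFECT_LEVELS))
        paste(e$category[k], e$gene_id[k] %||% NA, sep = "\r")
      }, character(1))
      top <- top[as.character(seq_len(nrow(d)))]
      parts <- strsplit(top, "\r", fixed = TRUE)
      d$category <- vapply(parts, `[`, "", 1L)
      d$gene_id <- vapply(parts, function(p) p[2], "")
      d$gene_id[d$gene_id == "NA"] <- NA_character_
    } else {
      d$category <- character(0); d$gene_id <- character(0)
    }
    callsets$calls[[m]] <- d
  }
  callsets
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# precomputed GRanges for vectorized overlap queries
effect_index <- function(models, genome, window) {
  if (nrow(models$genes) == 0) return(NULL)
  g <- models$genes
  lens <- genome$lengths
  span <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(g$span_start, g$span_end),
                                 gene = g$gene_id)
  cds <- GenomicRanges::GRanges(models$cds$chrom,
                                IRanges::IRanges(models$cds$start,
                                                 models$cds$end),
                                gene = models$cds$gene_id)
  up_start <- ifelse(g$strand == "+", g$span_start - window, g$span_end + 1)
  up_end <- ifelse(g$strand == "+", g$span_start - 1, g$span_end + window)
  dn_start <- ifelse(g$strand == "+", g$span_end + 1, g$span_start - window)
  dn_end <- ifelse(g$strand == "+", g$span_end + window, g$span_start - 1)
  # clamp flanks to the chromosome; inverted ranges collapse to width zero
  flank <- function(st, en, chrom) {
    st <- pmax(1, st)
    en <- pmin(unname(lens[chrom]), en)
    IRanges::IRanges(st, pmax(en, st - 1))
  }
  up <- GenomicRanges::GRanges(g$chrom, flank(up_start, up_end, g$chrom),
                               gene = g$gene_id)
  dn <- GenomicRanges::GRanges(g$chrom, flank(dn_start, dn_end, g$chrom),
                               gene = g$gene_id)
  list(span = span, cds = cds, up = up, dn = dn)
}

# one effect table for a call data.frame; `site` column indexes rows of d
annotate_sites <- function(d, models, genome, idx, window) {
  out <- cbind(site = integer(0), empty_effects())
  if (nrow(d) == 0) return(out)
  if (is.null(idx)) {
    out <- cbind(site = seq_len(nrow(d)),
                 effect_row("intergenic", NA_character_)[rep(1, nrow(d)), ])
    rownames(out) <- NULL
    return(out)
  }
  q <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, d$pos))
  rows <- list()

  # coding hits: per-site codon work
  ov <- GenomicRanges::findOverlaps(q, idx$cds)
  for (h in seq_along(ov)) {
    si <- S4Vectors::queryHits(ov)[h]
    gid <- S4Vectors::mcols(idx$cds)$gene[S4Vectors::subjectHits(ov)[h]]
    gene <- models$genes[models$genes$gene_id == gid, ]
    cds <- models$cds[models$cds$gene_id == gid, , drop = FALSE]
    rows[[length(rows) + 1L]] <-
      cbind(site = si, coding_effect(gene, cds, d$pos[si], d$alt[si], genome))
  }
  coding_pairs <- if (length(ov))
    paste(S4Vectors::queryHits(ov),
          S4Vectors::mcols(idx$cds)$gene[S4Vectors::subjectHits(ov)]) else character(0)

  # intron: within span but not within CDS of the same gene
  ov <- GenomicRanges::findOverlaps(q, idx$span)
  if (length(ov)) {
    si <- S4Vectors::queryHits(ov)
    gid <- S4Vectors::mcols(idx$span)$gene[S4Vectors::subjectHits(ov)]
    isec <- !paste(si, gid) %in% coding_pairs
    if (any(isec))
      rows[[length(rows) + 1L]] <-
        cbind(site = si[isec],
              effect_row("intron", NA)[rep(1, sum(isec)), ] |>
                transform(gene_id = gid[isec]))
  }

  # upstream / downstream flanks (exclude sites inside the gene span)
  for (what in c("up", "dn")) {
    ov <- GenomicRanges::findOverlaps(q, idx[[what]])
    if (length(ov)) {
      si <- S4Vectors::queryHits(ov)
      gid <- S4Vectors::mcols(idx[[what]])$gene[S4Vectors::subjectHits(ov)]
      gspan <- models$genes[match(gid, models$genes$gene_id), ]
      outside <- d$pos[si] < gspan$span_start | d$pos[si] > gspan$span_end
      if (any(outside))
        rows[[length(rows) + 1L]] <-
          cbind(site = si[outside],
                effect_row(if (what == "up") "upstream" else "downstream",
                           NA)[rep(1, sum(outside)), ] |>
                  transform(gene_id = gid[outside]))
    }
  }

  eff <- if (length(rows)) do.call(rbind, rows) else out
  hit <- unique(eff$site)
  nohit <- setdiff(seq_len(nrow(d)), hit)
  if (length(nohit))
    eff <- rbind(eff, cbind(site = nohit,
                            effect_row("intergenic",
                                       NA_character_)[rep(1, length(nohit)), ]))
  eff <- eff[order(eff$site), ]
  rownames(eff) <- NULL
  eff
}

#' Genes hit by a given effect category, per mutant
#'
#' Each gene is counted once per mutant regardless of how many qualifying
#' SNPs hit it.
#'
#' @param callsets An annotated `ems_callsets` (see [annotate_callsets()]).
#' @param category One of the effect categories (e.g. `"non_synonymous"`,
#'   `"stop_gain"`).
#' @return Named list mapping mutant id to a character vector of gene ids.
#' @export
genes_with_category <- function(callsets, category) {
  if (is.null(callsets$effects))
    stop("callsets are not annotated; run annotate_callsets() first")
  category <- match.arg(category, EFFECT_LEVELS)
  lapply(callsets$effects, function(e)
    sort(unique(e$gene_id[e$category == category & !is.na(e$gene_id)])))
}
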