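#' Gene model container
#'
#' Holds protein-coding gene models at the resolution the effect annotator
#' needs: one selected transcript per gene (the longest CDS), its CDS
#' intervals in genomic order, strand, and optional GO annotations.
#'
#' @param genes data.frame with columns `gene_id`, `tx_id`, `chrom`, `strand`
#'   (`"+"` or `"-"`), `span_start`, `span_end`, `cds_len`.
#' @param cds data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (1-based inclusive, ascending `start` within gene; non-overlapping).
#' @param go Named list mapping gene id to GO term ids (optional).
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, cds, go = list()) {
  stopifnot(all(c("gene_id", "tx_id", "chrom", "strand",
                  "span_start", "span_end", "cds_len") %in% names(genes)),
            all(c("gene_id", "chrom", "strand", "start", "end") %in% names(cds)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  # CDS intervals within a gene must not overlap
  for (g in split(cds, cds$gene_id)) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)]))
      stop("overlapping CDS intervals in gene ", g$gene_id[1])
  }
  structure(list(genes = genes, cds = cds, go = go), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d CDS segments, %d with GO terms\n",
              nrow(x$genes), nrow(x$cds), length(x$go)))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Imports `gene`/`mRNA`/`CDS` features and keeps, for every gene, the
#' transcript with the longest total CDS. Coordinates stay 1-based inclusive.
#' CDS features whose parent transcript cannot be resolved to a gene are
#' skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models] object (GO annotations empty; see
#'   [read_gene2go()]).
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  empty <- gene_models(
    genes = data.frame(gene_id = character(0), tx_id = character(0),
                       chrom = character(0), strand = character(0),
                       span_start = integer(0), span_end = integer(0),
                       cds_len = integer(0)),
    cds = data.frame(gene_id = character(0), chrom = character(0),
                     strand = character(0), start = integer(0),
                     end = integer(0)))
  if (nrow(df) == 0) return(empty)
  df$Parent1 <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))

  mrna <- df[df$type == "mRNA", ]
  tx2gene <- stats::setNames(mrna$Parent1, mrna$ID)
  cds <- df[df$type == "CDS", ]
  if (nrow(cds) == 0) return(empty)
  cds$tx_id <- cds$Parent1
  cds$gene_id <- tx2gene[cds$tx_id]
  orphan <- is.na(cds$gene_id)
  if (any(orphan)) {
    warning(sum(orphan), " CDS feature(s) without a resolvable parent gene skipped")
    cds <- cds[!orphan, ]
  }
  if (nrow(cds) == 0) return(empty)

  # longest-CDS transcript per gene
  tx_len <- tapply(cds$width, cds$tx_id, sum)
  tx_tab <- data.frame(tx_id = names(tx_len), len = as.integer(tx_len),
                       gene_id = tx2gene[names(tx_len)])
  tx_tab <- tx_tab[order(tx_tab$gene_id, -tx_tab$len, tx_tab$tx_id), ]
  keep_tx <- tx_tab$tx_id[!duplicated(tx_tab$gene_id)]
  cds <- cds[cds$tx_id %in% keep_tx, ]
  cds <- cds[order(cds$gene_id, cds$start), ]

  genes <- do.call(rbind, lapply(split(cds, cds$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], tx_id = g$tx_id[1],
               chrom = as.character(g$seqnames[1]),
               strand = as.character(g$strand[1]),
               span_start = min(g$start), span_end = max(g$end),
               cds_len = sum(g$width))
  }))
  rownames(genes) <- NULL
  gene_models(genes,
              data.frame(gene_id = cds$gene_id,
                         chrom = as.character(cds$seqnames),
                         strand = as.character(cds$strand),
                         start = cds$start, end = cds$end))
}

#' Write gene models to GFF3
#'
#' @param models A [gene_models] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    cds <- models$cds[models$cds$gene_id == g$gene_id, , drop = FALSE]
    lines <- c(lines,
      paste(g$chrom, "emsift", "gene", g$span_start, g$span_end, ".",
            g$strand, ".", sprintf("ID=%s", g$gene_id), sep = "\t"),
      paste(g$chrom, "emsift", "mRNA", g$span_start, g$span_end, ".",
            g$strand, ".", sprintf("ID=%s;Parent=%s", g$tx_id, g$gene_id),
            sep = "\t"),
      paste(cds$chrom, "emsift", "CDS", cds$start, cds$end, ".",
            cds$strand, "0",
            sprintf("ID=%s.cds;Parent=%s", cds$gene_id, g$tx_id), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Attach GO annotations to gene models
#'
#' @param models A [gene_models] object.
#' @param gene2go Named list from [read_gene2go()].
#' @return `models` with its `go` slot replaced.
#' @export
attach_go <- function(models, gene2go) {
  models$go <- gene2go[names(gene2go) %in% models$genes$gene_id]
  models
}
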