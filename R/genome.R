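#' Genome container
#'
#' Bundles chromosome sequences with the set of sequence ids that count as
#' placed chromosomes. Only placed chromosomes contribute to per-chromosome
#' statistics; sites on unplaced scaffolds are removed by the filtering
#' cascade.
#'
#' @param seq A named [Biostrings::DNAStringSet] (or named character vector)
#'   of chromosome/scaffold sequences.
#' @param placed Character vector of sequence ids regarded as placed
#'   chromosomes. Defaults to every id that does not look like a scaffold
#'   (case-insensitive prefix `scaffold`, `contig`, `ctg` or `un`).
#' @return An object of class `ems_genome` with elements `seq` (DNAStringSet),
#'   `placed` (character) and `lengths` (named numeric, bp).
#' @export
ems_genome <- function(seq, placed = NULL) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(seq)
  if (!methods::is(seq, "DNAStringSet"))
    stop("`seq` must be a DNAStringSet or named character vector")
  if (is.null(names(seq)) || anyDuplicated(names(seq)))
    stop("sequences must have unique names")
  ids <- names(seq)
  if (is.null(placed)) {
    placed <- ids[!grepl("^(scaffold|contig|ctg|un)", ids, ignore.case = TRUE)]
  }
  if (!all(placed %in% ids))
    stop("placed ids not present in sequences: ",
         paste(setdiff(placed, ids), collapse = ", "))
  structure(
    list(seq = seq, placed = placed,
         lengths = stats::setNames(as.numeric(Biostrings::width(seq)), ids)),
    class = "ems_genome"
  )
}

#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @inheritParams ems_genome
#' @return An `ems_genome`.
#' @export
read_genome <- function(path, placed = NULL) {
  ems_genome(Biostrings::readDNAStringSet(path), placed = placed)
}

#' Write a genome to FASTA
#'
#' @param genome An `ems_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}

#' @export
print.ems_genome <- function(x, ...) {
  cat(sprintf("<ems_genome> %d sequences (%d placed), %.2f Mb total\n",
              length(x$seq), length(x$placed), sum(x$lengths) / 1e6))
  invisible(x)
}

#' Reference bases at 1-based positions of one chromosome
#' @param genome An `ems_genome`.
#' @param chrom Chromosome id.
#' @param pos Integer vector of positions.
#' @return Character vector of bases.
#' @export
genome_base <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  L <- genome$lengths[[chrom]]
  if (any(pos < 1L | pos > L))
    stop("position beyond chromosome length on ", chrom)
  as.character(Biostrings::extractAt(genome$seq[[chrom]],
                                     IRanges::IRanges(pos, pos)))
}
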