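#' Variant site table
#'
#' The central container for multi-sample SNP records. Each row is one
#' biallelic site; genotypes are stored one column per sample as an unordered
#' allele pair (`"C/T"`, alleles sorted alphabetically) or `NA` for missing
#' ("N" / `./.`). Multiallelic input records are decomposed into one row per
#' alternate allele before they reach this container.
#'
#' @param chrom Character vector of chromosome ids.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Single-nucleotide reference and alternate alleles.
#' @param gt Character matrix of genotypes (rows = sites, named columns =
#'   samples), each entry a sorted allele pair or `NA`.
#' @return A data.frame of class `ems_variants` with columns `chrom`, `pos`,
#'   `ref`, `alt` and one genotype column per sample.
#' @export
variant_table <- function(chrom, pos, ref, alt, gt) {
  stopifnot(is.matrix(gt), !is.null(colnames(gt)))
  n <- length(chrom)
  if (length(pos) != n || length(ref) != n || length(alt) != n ||
      nrow(gt) != n)
    stop("chrom, pos, ref, alt and gt must describe the same number of sites")
  if (any(pos < 1)) stop("positions must be >= 1")
  bad <- which(ref == alt)
  if (length(bad)) stop("ref == alt at row ", bad[1])
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(gt))) df[[colnames(gt)[j]]] <- gt[, j]
  class(df) <- c("ems_variants", "data.frame")
  df
}

# sample columns of a variant table
vt_samples <- function(sites) setdiff(names(sites), c("chrom", "pos", "ref",
                                                      "alt", "consensus"))

# genotype matrix (sites x samples)
vt_gt <- function(sites, samples = vt_samples(sites)) {
  as.matrix(sites[, samples, drop = FALSE])
}

# canonical unordered genotype string from two alleles
gt_pair <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

gt_hom <- function(allele) paste(allele, allele, sep = "/")

# split "A/C" -> c("A","C")
gt_alleles <- function(g) strsplit(g, "/", fixed = TRUE)

gt_is_hom <- function(g) {
  al <- matrix(unlist(gt_alleles(g)), ncol = 2, byrow = TRUE)
  al[, 1] == al[, 2]
}

#' Validate sample roles
#'
#' @param roles Named character vector mapping sample id to `"mutant"` or
#'   `"wildtype"`.
#' @return `roles`, normalized.
#' @export
sample_roles <- function(roles) {
  if (is.null(names(roles)) || any(names(roles) == ""))
    stop("roles must be a named vector (sample id -> role)")
  if (!all(roles %in% c("mutant", "wildtype")))
    stop("roles must be 'mutant' or 'wildtype'")
  if (!any(roles == "mutant") || !any(roles == "wildtype"))
    stop("need at least one mutant and one wildtype sample")
  roles
}

#' Sample ids by role
#' @param roles Named role vector (see [sample_roles()]).
#' @return Character vector of sample ids.
#' @export
mutant_ids <- function(roles) names(roles)[roles == "mutant"]

#' @rdname mutant_ids
#' @export
wildtype_ids <- function(roles) names(roles)[roles == "wildtype"]

#' Read SNPs from a multi-sample VCF
#'
#' Parses a VCF 4.x file, keeps SNP records only (indels are skipped and
#' counted), decomposes multiallelic records into one biallelic site per
#' alternate allele, and normalizes genotypes to unordered allele pairs.
#' At a decomposed site, a genotype that references a different alternate
#' allele becomes missing; half-calls and `./.` are missing; phasing is
#' ignored.
#'
#' @param path Path to a VCF file.
#' @param roles Named character vector of sample roles (see [sample_roles()]).
#'   Every named sample must be present in the VCF.
#' @return An `ems_variants` table with attributes `roles` and
#'   `skipped_indels` (number of non-SNP records dropped).
#' @export
read_vcf <- function(path, roles) {
  roles <- sample_roles(roles)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  missing_samples <- setdiff(names(roles), colnames(gt_raw))
  if (length(missing_samples))
    stop("declared sample(s) absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  gt_raw <- gt_raw[, names(roles), drop = FALSE]

  chrom <- character(0); pos <- integer(0)
  ref <- character(0); alt <- character(0)
  gt <- matrix(character(0), ncol = length(roles),
               dimnames = list(NULL, names(roles)))
  skipped <- 0L

  for (i in seq_len(nrow(fix))) {
    r <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    snp_alts <- which(nchar(alts) == 1L & alts %in% c("A", "C", "G", "T"))
    if (nchar(r) != 1L || !r %in% c("A", "C", "G", "T") ||
        length(snp_alts) == 0L) {
      skipped <- skipped + 1L
      next
    }
    codes <- decode_gt_row(gt_raw[i, ], line = i)
    for (a in snp_alts) {
      g <- vapply(codes, function(cd) {
        if (anyNA(cd) || any(!cd %in% c(0L, a))) return(NA_character_)
        al <- ifelse(cd == 0L, r, alts[a])
        gt_pair(al[1], al[2])
      }, character(1))
      chrom <- c(chrom, fix[i, "CHROM"])
      pos <- c(pos, as.integer(fix[i, "POS"]))
      ref <- c(ref, r); alt <- c(alt, alts[a])
      gt <- rbind(gt, g)
    }
  }
  if (skipped > 0)
    message(skipped, " non-SNP record(s) skipped")
  out <- variant_table(chrom, pos, ref, alt, gt)
  attr(out, "roles") <- roles
  attr(out, "skipped_indels") <- skipped
  out
}

# parse one record's GT strings into integer allele-code pairs (NA = missing)
decode_gt_row <- function(gts, line) {
  lapply(seq_along(gts), function(j) {
    g <- gts[j]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    parts <- strsplit(g, "[/|]")[[1]]
    if (length(parts) != 2L) {
      if (length(parts) == 1L && grepl("^[0-9]+$", parts)) {
        parts <- c(parts, parts)  # haploid call treated as homozygous
      } else {
        stop("malformed GT '", g, "' for sample ", names(gts)[j],
             " at record ", line)
      }
    }
    if (any(parts == ".")) return(NA_integer_)  # half-call -> missing
    if (!all(grepl("^[0-9]+$", parts)))
      stop("malformed GT '", g, "' for sample ", names(gts)[j],
           " at record ", line)
    as.integer(parts)
  })
}

#' Write a variant table to VCF
#'
#' Emits a minimal VCF 4.2 file with GT-only genotype columns, suitable for
#' re-reading with [read_vcf()].
#'
#' @param sites An `ems_variants` table.
#' @param path Output path.
#' @param genome Optional `ems_genome`; when given, `##contig` header lines
#'   are written with lengths.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path, genome = NULL) {
  samples <- vt_samples(sites)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=emsift")
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$seq), as.integer(genome$lengths)))
  } else {
    hdr <- c(hdr, sprintf("##contig=<ID=%s>", unique(sites$chrom)))
  }
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt <- vt_gt(sites, samples)
  enc <- matrix("./.", nrow = nrow(gt), ncol = ncol(gt))
  for (j in seq_len(ncol(gt))) {
    g <- gt[, j]
    ok <- !is.na(g)
    if (!any(ok)) next
    al <- matrix(unlist(gt_alleles(g[ok])), ncol = 2, byrow = TRUE)
    code <- matrix("0", nrow(al), 2)
    code[al == matrix(sites$alt[ok], nrow(al), 2)] <- "1"
    # order codes so hets are always 0/1
    enc[ok, j] <- paste(pmin(code[, 1], code[, 2]),
                        pmax(code[, 1], code[, 2]), sep = "/")
  }
  body <- if (nrow(sites) == 0) character(0) else
    paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
          "PASS", ".", "GT",
          apply(enc, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a gene-to-GO annotation table
#'
#' @param path Path to a two-column TSV (gene id, GO term id), one pair per
#'   line. Duplicate pairs are deduplicated.
#' @return Named list mapping gene id to a character vector of GO term ids.
#'   Genes without terms are absent.
#' @export
read_gene2go <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(stats::setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("malformed gene2go line ", which(nf != 2L)[1], ": expected 2 columns")
  gene <- vapply(parts, `[`, "", 1L)
  term <- vapply(parts, `[`, "", 2L)
  lapply(split(term, gene), unique)
}

#' Write a gene-to-GO annotation table
#'
#' @param gene2go Named list mapping gene id to GO term ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene2go <- function(gene2go, path) {
  gene <- rep(names(gene2go), lengths(gene2go))
  writeLines(if (length(gene)) paste(gene, unlist(gene2go), sep = "\t")
             else character(0), path)
  invisible(path)
}
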