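#' Read unphased biallelic genotypes
#'
#' Reads a genotype matrix of minor-allele counts (0/1/2) either from a TSV
#' file (first column subject id, remaining columns one variant each, with a
#' header of variant names) or from a VCF (biallelic sites, `GT` field;
#' requires the `vcfR` package). The alternate allele of the VCF is taken as
#' the counted (minor) allele.
#'
#' @param file Path to a `.tsv`/`.txt` count table or a `.vcf` file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return An integer matrix, subjects in rows (rownames = subject ids),
#'   variants in columns (colnames = variant names). The per-variant allele
#'   labels, when known, are attached as attribute `"alleles"`, a data.frame
#'   with columns `minor` and `major`.
#' @export
read_genotypes <- function(file, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", file, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") return(read_genotypes_vcf(file))
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  G <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- as.character(tab[[1L]])
  bad <- G[!is.na(G)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype counts must be 0, 1 or 2 (or missing)")
  G
}

read_genotypes_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- vcfR::getALT(v)
  ref <- vcfR::getREF(v)
  if (any(grepl(",", alt)))
    stop("multiallelic sites are not supported; split or drop them first")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x)
    parts <- strsplit(gsub("\\|", "/", x[ok]), "/", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) sum(p == "1"), integer(1L))
    out
  }
  G <- t(apply(gt, 1L, count_alt))
  G <- t(G)  # subjects x variants
  storage.mode(G) <- "integer"
  colnames(G) <- rownames(gt)
  rownames(G) <- colnames(gt)
  attr(G, "alleles") <- data.frame(minor = alt, major = ref,
                                   row.names = rownames(gt),
                                   stringsAsFactors = FALSE)
  G
}
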