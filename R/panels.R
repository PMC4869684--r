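#' Packaged haplotype reference panels
#'
#' Loads one of the two reference panels shipped with the package: four
#' coding variants in *G6PC2* (chromosome 2) or five variants in *JAZF1*
#' (chromosome 7), each with the haplotypes observed in 6,561 Framingham
#' Heart Study participants and their EM-estimated frequencies. Allele
#' letters follow the strand used in the haplotype tables. Frequencies
#' printed as "<0.001" are transcribed as 0.001; the frequency column is
#' renormalized to sum to one (the printed values sum to 1 within rounding).
#'
#' @param gene `"G6PC2"` or `"JAZF1"`.
#' @return A list of class `reference_panel`: `gene`; `variants`
#'   (data.frame: name, chr, pos, rsid, minor, major, maf as printed);
#'   `haplotypes` (data.frame: label, raw_frequency, frequency);
#'   `bits` (K x q 0/1 matrix of minor-allele indicators); `maf`
#'   (panel-derived minor allele frequencies, `colSums(bits * frequency)`).
#' @export
reference_panel <- function(gene = c("G6PC2", "JAZF1")) {
  gene <- match.arg(gene)
  pfx <- tolower(gene)
  vfile <- system.file("extdata", paste0(pfx, "_variants.tsv"),
                       package = "haplometa", mustWork = TRUE)
  hfile <- system.file("extdata", paste0(pfx, "_haplotypes.tsv"),
                       package = "haplometa", mustWork = TRUE)
  variants <- utils::read.table(vfile, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  haps <- utils::read.table(hfile, header = TRUE, sep = "\t",
                            colClasses = c("character", "numeric"))
  raw <- haps$frequency
  if (abs(sum(raw) - 1) > 1e-3)
    stop("panel frequencies sum to ", sum(raw), "; transcription error?")
  freq <- raw / sum(raw)
  q <- nrow(variants)
  bits <- t(vapply(strsplit(haps$haplotype, ""), function(ch) {
    bad <- ch != variants$minor & ch != variants$major
    if (any(bad)) stop("panel haplotype allele inconsistent with variants")
    as.integer(ch == variants$minor)
  }, integer(q)))
  rownames(bits) <- haps$haplotype
  colnames(bits) <- variants$name
  structure(list(gene = gene, variants = variants,
                 haplotypes = data.frame(label = haps$haplotype,
                                         raw_frequency = raw,
                                         frequency = freq,
                                         stringsAsFactors = FALSE),
                 bits = bits,
                 maf = colSums(bits * freq)),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel", x$gene, "-", nrow(x$variants), "variants,",
      nrow(x$haplotypes), "haplotypes\n")
  print(x$haplotypes, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Simulation study designs
#'
#' The ten multi-cohort study designs used in the type-I error and power
#' studies. Cohort units are NF2 (nuclear family, two offspring), NFv
#' (nuclear family, Uniform{1..4} offspring) or U (unrelated singletons).
#'
#' @param id Optional design id (1-10); if given, only that design's cohort
#'   table is returned.
#' @return Data frame with columns `design`, `cohort`, `unit`, `n_units`.
#' @export
study_designs <- function(id = NULL) {
  file <- system.file("extdata", "study_designs.tsv",
                      package = "haplometa", mustWork = TRUE)
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!is.null(id)) {
    if (!id %in% d$design) stop("unknown study design: ", id)
    d <- d[d$design == id, , drop = FALSE]
  }
  d
}
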