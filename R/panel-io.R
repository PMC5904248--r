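#' Write a genotype panel as plain-text tables
#'
#' `dosages.tsv` (samples x SNPs integer matrix, `NA` for missing),
#' `snps.tsv` and `samples.tsv` metadata; the simulation truth, when
#' present, goes to `truth_geno.json`.
#'
#' @param panel A `geno_panel`.
#' @param directory Output directory.
#' @export
write_panel <- function(panel, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(sample_id = panel$samples$id, panel$dosages, check.names = FALSE),
    file.path(directory, "dosages.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(panel$snp, file.path(directory, "snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$samples, file.path(directory, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(panel$truth)) {
    tr <- panel$truth
    tr$config <- unclass(tr$config)
    tr$beta <- as.data.frame(tr$beta)
    jsonlite::write_json(tr, file.path(directory, "truth_geno.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(directory)
}

#' Read a genotype panel written by [write_panel()]
#'
#' @param directory Directory holding `dosages.tsv`, `snps.tsv`,
#'   `samples.tsv` (truth is not reloaded).
#' @return A `geno_panel`.
#' @export
read_panel <- function(directory) {
  rd <- function(f) {
    path <- file.path(directory, f)
    if (!file.exists(path)) stop_config("missing panel file: %s", f)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  d <- rd("dosages.tsv")
  G <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- d$sample_id
  structure(list(dosages = G, snp = rd("snps.tsv"), samples = rd("samples.tsv"),
                 truth = NULL), class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("Genotype panel: %d samples x %d SNPs (%d cases, %d controls, %d batch(es))\n",
              nrow(x$dosages), ncol(x$dosages),
              sum(x$samples$status == 1), sum(x$samples$status == 0),
              length(unique(x$samples$batch))))
  invisible(x)
}

#' Export a genotype panel as VCF
#'
#' Minimal VCFv4.2 with one ALT allele per record and GT fields derived
#' from the dosage of `a1` (the counted allele); missing dosages become
#' `./.`.
#'
#' @param panel A `geno_panel`.
#' @param path Output file path.
#' @export
write_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ehrgenval",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples$id), collapse = "\t")),
             con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(panel$dosages))) {
    g <- panel$dosages[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1L])
    writeLines(paste(c(panel$snp$chrom[j], panel$snp$pos[j], panel$snp$id[j],
                       panel$snp$a2[j], panel$snp$a1[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
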