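fmt12 <- function(x) sprintf("%.12g", x)

#' Write / read GWAS summary statistics
#'
#' Tab-delimited with header `CHR POS ID EA OA BETA SE P N DESIGN`; numeric
#' columns are written with 12 significant digits, so a round-trip is
#' lossless to that precision.
#'
#' @param stats A `sumstats` data frame.
#' @param path File path.
#' @return `write_sumstats` returns `path` invisibly; `read_sumstats`
#'   returns a `sumstats` data frame.
#' @export
write_sumstats <- function(stats, path) {
  out <- data.frame(CHR = stats$chr, POS = stats$pos, ID = stats$id,
                    EA = stats$ea, OA = stats$oa,
                    BETA = fmt12(stats$beta), SE = fmt12(stats$se),
                    P = fmt12(stats$p), N = stats$n, DESIGN = stats$design,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c(CHR = "integer", POS = "integer",
                                 ID = "character", EA = "character",
                                 OA = "character", BETA = "numeric",
                                 SE = "numeric", P = "numeric",
                                 N = "integer", DESIGN = "character"),
                  stringsAsFactors = FALSE)
  out <- data.frame(chr = d$CHR, pos = d$POS, id = d$ID, ea = d$EA,
                    oa = d$OA, beta = d$BETA, se = d$SE, p = d$P, n = d$N,
                    design = d$DESIGN, stringsAsFactors = FALSE)
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Write / read a polygenic score file
#'
#' Tab-delimited `ID EA WEIGHT` (plink `--score 1 2 3` column order), 12
#' significant digits.
#'
#' @param model A [build_score_model()] object.
#' @param path File path.
#' @return `write_score_model` returns `path` invisibly; `read_score_model`
#'   returns a `score_model` (with unknown `p_threshold`/`source_design`
#'   unless present in `attr`-style comment-free files).
#' @export
write_score_model <- function(model, path) {
  out <- data.frame(ID = model$entries$snp_id,
                    EA = model$entries$effect_allele,
                    WEIGHT = fmt12(model$entries$weight),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c(ID = "character", EA = "character",
                                 WEIGHT = "numeric"),
                  stringsAsFactors = FALSE)
  entries <- data.frame(snp_id = d$ID, effect_allele = d$EA,
                        weight = d$WEIGHT, stringsAsFactors = FALSE)
  structure(list(entries = entries, p_threshold = NA_real_,
                 source_design = NA_character_, n_snps = nrow(entries)),
            class = "score_model")
}

#' Write / read a genotype matrix as tab-delimited text
#'
#' First column `IID`, then one column per SNP (header = SNP ids), one row
#' per individual, entries are effect-allele counts in \{0, 1, 2\}.
#'
#' @param genotypes A `geno_matrix`.
#' @param path File path.
#' @param panel A `snp_panel` to attach on reading (optional).
#' @return `write_genotypes` returns `path` invisibly; `read_genotypes`
#'   returns a `geno_matrix` (without haplotypes).
#' @export
write_genotypes <- function(genotypes, path) {
  counts <- as_counts(genotypes)
  out <- data.frame(IID = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, panel = NULL) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  counts <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- d$IID
  new_geno_matrix(panel, counts, NULL, d$IID)
}

#' Write a phenotype/covariate table
#'
#' Tab-delimited with columns `individual_id, y, y_binary, sex, age,
#' stratum, family_id` (missing fields written as empty).
#'
#' @param pheno A data frame from [assemble_phenotype()] or
#'   [simulate_cohort()]'s `pheno` element.
#' @param path File path.
#' @export
write_phenotypes <- function(pheno, path) {
  cols <- c("individual_id", "y", "y_binary", "sex", "age", "stratum",
            "family_id")
  out <- pheno
  for (cn in setdiff(cols, names(out))) out[[cn]] <- NA
  out <- out[, cols]
  out$y <- fmt12(out$y)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Export genotypes as VCF 4.2
#'
#' Minimal single-sample-column-per-individual VCF: the panel's effect
#' allele is written as ALT (so genotype dosages count ALT alleles), the
#' other allele as REF. Unphased `GT` is derived from counts
#' (`0/0`, `0/1`, `1/1`); when the `geno_matrix` retains haplotypes, phased
#' `GT` (`a|b`) is written instead. Positions are 1-based.
#'
#' @param genotypes A `geno_matrix` with a panel.
#' @param path File path.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "geno_matrix"),
            inherits(genotypes$panel, "snp_panel"))
  panel <- genotypes$panel
  counts <- genotypes$counts
  n <- nrow(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pgsport",
               sprintf("##contig=<ID=%d>", unique(panel$chrom)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(counts)), collapse = "\t"),
             con)
  phased <- !is.null(genotypes$haplotypes)
  gt_unphased <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(panel))) {
    gt <- if (phased) {
      h1 <- as.integer(genotypes$haplotypes[seq(1L, 2L * n, 2L), j])
      h2 <- as.integer(genotypes$haplotypes[seq(2L, 2L * n, 2L), j])
      paste0(h1, "|", h2)
    } else gt_unphased[counts[, j] + 1L]
    writeLines(paste(c(panel$chrom[j], panel$pos[j], panel$snp_id[j],
                       panel$other_allele[j], panel$effect_allele[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' The YAML file holds one or both of the top-level sections `sibcompare`
#' and `stratified`, each a mapping of the fields of [sibcompare_config()] /
#' [stratified_config()] (the `strata` field as a list of records), plus an
#' optional top-level `seed`. Unset fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A list with elements among `sibcompare` (a `sibcompare_config`),
#'   `stratified` (a `stratified_config`) and `seed`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$sibcompare))
    out$sibcompare <- do.call(sibcompare_config, coerce_cfg(raw$sibcompare))
  if (!is.null(raw$stratified)) {
    sc <- coerce_cfg(raw$stratified)
    if (!is.null(sc$strata))
      sc$strata <- do.call(rbind, lapply(sc$strata, as.data.frame))
    out$stratified <- do.call(stratified_config, sc)
  }
  out$seed <- raw$seed
  out
}

coerce_cfg <- function(x) {
  if (!is.null(x$thresholds)) x$thresholds <- as.numeric(x$thresholds)
  if (!is.null(x$nstar_grid)) x$nstar_grid <- as.integer(x$nstar_grid)
  x
}
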