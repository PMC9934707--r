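# File interfaces: VCF genotypes (DS dosage FORMAT), tab-delimited summary
# statistics, phenotypes and clump tables.

#' Write genotypes to VCF with dosages in a DS FORMAT field
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path; `.vcf.gz` is appended semantics-wise by vcfR
#'   (pass a path ending in `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  info <- if ("info" %in% names(v) && !all(is.na(v$info)))
    sprintf("II=%g", v$info) else rep(".", nrow(v))
  fix <- cbind(CHROM = as.character(v$chr), POS = as.character(v$pos),
               ID = v$id, REF = v$oa, ALT = v$ea, QUAL = ".",
               FILTER = "PASS", INFO = info)
  gt <- cbind(FORMAT = "DS",
              t(matrix(sprintf("%g", genotypes$dosage),
                       nrow = nrow(genotypes$dosage),
                       dimnames = list(genotypes$ids, v$id))))
  colnames(gt) <- c("FORMAT", genotypes$ids)
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=II,Number=1,Type=Float,Description=\"Imputation INFO score\">",
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">")
  vcf <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read genotypes from VCF (DS dosages or GT calls)
#'
#' Dosages are taken from the DS FORMAT field when present, otherwise
#' counted from GT calls. The effect allele is ALT; the INFO score is read
#' from an `II=` INFO key when present.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(vcf@gt[, "FORMAT"])
  if (any(grepl("DS", fmt))) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1]]))
    })
  }
  info_raw <- vcf@fix[, "INFO"]
  info <- suppressWarnings(as.numeric(sub("^.*II=([0-9.eE+-]+).*$", "\\1",
                                          info_raw)))
  dosage <- t(ds)
  variants <- data.frame(
    id = vcf@fix[, "ID"], chr = as.integer(vcf@fix[, "CHROM"]),
    pos = as.integer(vcf@fix[, "POS"]),
    ea = vcf@fix[, "ALT"], oa = vcf@fix[, "REF"],
    eaf = colMeans(dosage) / 2, info = info,
    stringsAsFactors = FALSE
  )
  genotype_matrix(rownames(dosage), variants, dosage)
}

#' Write / read summary statistics in the package's TSV dialect
#'
#' Tab-delimited with header `SNP CHR BP EA OA EAF BETA SE P N` plus
#' optional `INFO` and `OK` columns.
#'
#' @param stats A [sumstats()] table.
#' @param path File path.
#' @return `path` (write) or a [sumstats()] table (read), with the trait
#'   and kind supplied by the caller on read.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "sumstats"))
  utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @param trait,kind Trait label and kind to attach on read.
#' @export
read_sumstats <- function(path, trait, kind = c("quantitative", "binary")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sumstats(df, trait = trait, kind = match.arg(kind))
}

#' Write / read a phenotype table
#'
#' Tab-delimited with the fixed analysis-facing columns `iid,
#' child_bmi_true, adult_bmi, recall, outcome, sex, age, centre` (plus any
#' added reconstruction columns). The hidden confounder is never written.
#'
#' @param phenotypes Phenotype data frame from [simulate_phenotypes()].
#' @param path File path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  df <- phenotypes[, setdiff(names(phenotypes), "confounder"), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a clump result as a tab-delimited index table
#'
#' @param clump A [ld_clump()] result.
#' @param path File path.
#' @export
write_clump <- function(clump, path) {
  stopifnot(inherits(clump, "clump_result"))
  df <- as.data.frame(clump)
  members <- attr(clump, "members")
  df$members <- vapply(df$SNP, function(s)
    paste(members[[s]], collapse = ","), character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
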