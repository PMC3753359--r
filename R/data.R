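#' One-locus dataset with ordered genotypes
#'
#' A dataset couples a phenotype (quantitative trait values, or 0/1 disease
#' status) with the ordered genotype of each individual at one diallelic
#' locus, stored as the maternal and paternal variant-allele counts.
#'
#' @param phenotype numeric vector; for `trait_kind = "binary"` only 0/1.
#' @param n_m,n_f maternal / paternal variant-allele counts (0 or 1).
#' @param sample_id optional identifiers; defaults to `s1, s2, ...`.
#' @param trait_kind `"quantitative"`, `"binary"`, or `"auto"` (binary iff all
#'   phenotype values are 0/1).
#' @return a data.frame of class `"poe_data"` with columns `sample_id`,
#'   `phenotype`, `n_m`, `n_f` and attribute `trait_kind`.
#' @examples
#' poe_data(phenotype = c(92.7, 88.1), n_m = c(0, 1), n_f = c(1, 1))
#' @export
poe_data <- function(phenotype, n_m, n_f, sample_id = NULL,
                     trait_kind = c("auto", "quantitative", "binary")) {
  trait_kind <- match.arg(trait_kind)
  n <- length(phenotype)
  if (n < 1L) stop("dataset must contain at least one individual")
  if (length(n_m) != n || length(n_f) != n)
    stop("genotypes and phenotype must have equal length")
  if (!all(n_m %in% 0:1) || !all(n_f %in% 0:1))
    stop("parental allele counts must be 0 or 1")
  if (!is.numeric(phenotype) || anyNA(phenotype))
    stop("phenotype must be numeric without missing values")
  is01 <- all(phenotype %in% c(0, 1))
  if (trait_kind == "auto") trait_kind <- if (is01) "binary" else "quantitative"
  if (trait_kind == "binary" && !is01)
    stop("binary phenotypes must contain only 0/1")
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n))
  out <- data.frame(sample_id = as.character(sample_id),
                    phenotype = as.numeric(phenotype),
                    n_m = as.integer(n_m), n_f = as.integer(n_f),
                    stringsAsFactors = FALSE)
  structure(out, trait_kind = trait_kind, class = c("poe_data", "data.frame"))
}

#' @export
print.poe_data <- function(x, ...) {
  cat(sprintf("poe_data: %d individuals, %s trait\n", nrow(x), trait_kind(x)))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' Trait kind of a dataset
#' @param data a [poe_data()] object.
#' @return `"quantitative"` or `"binary"`.
#' @export
trait_kind <- function(data) attr(data, "trait_kind")

#' Read / write one-locus datasets as TSV
#'
#' The TSV dialect is tab-separated UTF-8 with a header. Two genotype layouts
#' are accepted: a single `genotype` column with ordered codes 11/12/21/22
#' (first digit maternal), or two columns `maternal` and `paternal` with
#' variant-allele counts 0/1. A `phenotype` column is required; `sample_id`
#' is optional. Rows with missing genotype or phenotype are dropped with a
#' message. Writing always uses the `genotype`-code layout and enough digits
#' for quantitative phenotypes to round-trip (15 significant digits).
#'
#' @param path file path.
#' @param trait_kind as in [poe_data()].
#' @return `read_poe_tsv` returns a [poe_data()]; `write_poe_tsv` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' d <- poe_data(phenotype = c(92.7, 88.1), n_m = c(0, 1), n_f = c(1, 1))
#' write_poe_tsv(d, f)
#' read_poe_tsv(f)
#' @export
read_poe_tsv <- function(path, trait_kind = c("auto", "quantitative", "binary")) {
  trait_kind <- match.arg(trait_kind)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!"phenotype" %in% names(tab)) stop("missing phenotype column")
  has_code <- "genotype" %in% names(tab)
  has_pair <- all(c("maternal", "paternal") %in% names(tab))
  if (!has_code && !has_pair)
    stop("need a 'genotype' column or 'maternal'/'paternal' columns")
  pheno <- suppressWarnings(as.numeric(tab$phenotype))
  if (has_code) {
    gt <- tab$genotype
    miss <- is.na(pheno) | is.na(gt) | gt == "" | gt == "NA"
  } else {
    nm <- suppressWarnings(as.integer(tab$maternal))
    nf <- suppressWarnings(as.integer(tab$paternal))
    miss <- is.na(pheno) | is.na(nm) | is.na(nf)
  }
  if (any(miss)) {
    message(sum(miss), " row(s) with missing genotype or phenotype dropped")
    tab <- tab[!miss, , drop = FALSE]
    pheno <- pheno[!miss]
  }
  if (nrow(tab) == 0L) stop("no complete rows in ", path)
  if (has_code) {
    pg <- parse_genotype_code(tab$genotype)
  } else {
    pg <- list(n_m = as.integer(tab$maternal), n_f = as.integer(tab$paternal))
    if (!all(pg$n_m %in% 0:1) || !all(pg$n_f %in% 0:1))
      stop("maternal/paternal columns must be 0 or 1")
  }
  id <- if ("sample_id" %in% names(tab)) tab$sample_id else NULL
  poe_data(pheno, pg$n_m, pg$n_f, sample_id = id, trait_kind = trait_kind)
}

#' @rdname read_poe_tsv
#' @param data a [poe_data()] dataset.
#' @export
write_poe_tsv <- function(data, path) {
  stopifnot(inherits(data, "poe_data"))
  pheno <- if (trait_kind(data) == "binary") {
    format(as.integer(data$phenotype))
  } else {
    format(data$phenotype, digits = 15, scientific = FALSE, trim = TRUE)
  }
  out <- data.frame(sample_id = data$sample_id, phenotype = pheno,
                    genotype = genotype_code(data$n_m, data$n_f),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ordered genotypes from a phased VCF
#'
#' Reads a single biallelic site from a VCF file whose GT fields are phased
#' (`|` separator); unphased genotypes are rejected because parental origin
#' is then unknown. The VCF format itself does not say which haplotype is
#' maternal; by convention the *left* allele of each phased genotype is taken
#' as maternal, overridable via `maternal = "right"`. This reader is an
#' interoperability convenience for data already phased by pedigree or
#' haplotype methods. Requires the `vcfR` package.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param phenotype numeric phenotype vector, one value per VCF sample, in
#'   the VCF's sample order.
#' @param maternal which side of the phased genotype is the maternal allele.
#' @param which row index of the variant to use when the file has several.
#' @inheritParams poe_data
#' @return a [poe_data()] dataset.
#' @export
read_poe_vcf <- function(path, phenotype, maternal = c("left", "right"),
                         which = 1L,
                         trait_kind = c("auto", "quantitative", "binary")) {
  maternal <- match.arg(maternal)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_poe_vcf requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) < which) stop("VCF has fewer than ", which, " variants")
  gt <- vcfR::extract.gt(v, element = "GT")[which, ]
  alt <- v@fix[which, "ALT"]
  if (is.na(alt) || grepl(",", alt)) stop("site must be biallelic")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype ('/' separator); parental origin requires phased GT")
  parts <- strsplit(gt, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed GT field")
  left <- as.integer(vapply(parts, `[`, "", 1L))
  right <- as.integer(vapply(parts, `[`, "", 2L))
  if (anyNA(left) || anyNA(right) || any(left > 1L) || any(right > 1L))
    stop("GT alleles must be 0 or 1 for a biallelic site")
  n_m <- if (maternal == "left") left else right
  n_f <- if (maternal == "left") right else left
  poe_data(phenotype, n_m, n_f, sample_id = names(gt), trait_kind = trait_kind)
}
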