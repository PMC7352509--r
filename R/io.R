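# File-format helpers: GMT gene sets (plain and weighted), minimal VCF 4.2.

#' Read a GMT gene-set file
#'
#' @param path GMT file (set name, description, then member genes,
#'   tab-separated).
#' @return named list: set name -> character vector of genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read weighted signature centroids from GMT-with-weights
#'
#' Each member field is `gene:weight`; one line per class.
#'
#' @param path file path.
#' @return named list of named numeric centroid vectors.
#' @export
read_signature_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sigs <- lapply(parts, function(p) {
    kv <- strsplit(p[-(1:2)], ":", fixed = TRUE)
    setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
             vapply(kv, `[[`, character(1), 1))
  })
  names(sigs) <- vapply(parts, `[[`, character(1), 1)
  sigs
}

#' Write weighted signature centroids as GMT-with-weights
#'
#' @param sigs named list of named numeric vectors, or a centroid matrix
#'   (genes x classes).
#' @param path output file.
#' @export
write_signature_gmt <- function(sigs, path) {
  if (is.matrix(sigs)) {
    sigs <- setNames(lapply(seq_len(ncol(sigs)), function(j) {
      setNames(sigs[, j], rownames(sigs))
    }), colnames(sigs))
  }
  lines <- vapply(names(sigs), function(nm) {
    v <- sigs[[nm]]
    paste(c(nm, "na", sprintf("%s:%.10g", names(v), unname(v))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a variant call set as a minimal VCF 4.2 file
#'
#' Gene, functional class and VAF go into the INFO column (`GENE=`,
#' `CLASS=`, `VAF=`).
#'
#' @param calls variant data frame (`chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `class`, `vaf`).
#' @param path output file.
#' @export
write_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Annotated gene\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tGENE=%s;CLASS=%s;VAF=%.4f",
                  calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
                  calls$gene, calls$class, calls$vaf)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF 4.2 variant file
#'
#' Parses the fixed columns (via `vcfR`) and the `GENE`/`CLASS`/`VAF` INFO
#' keys written by [write_vcf()] (or an equivalent annotated VCF).
#'
#' @param path VCF file.
#' @param sample optional sample id attached to every row.
#' @return variant data frame.
#' @export
read_vcf_variants <- function(path, sample = NA_character_) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (!nrow(fix)) {
    return(data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), gene = character(0),
                      class = character(0), vaf = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(sample = sample,
             chrom = unname(fix[, "CHROM"]),
             pos = as.integer(fix[, "POS"]),
             ref = unname(fix[, "REF"]),
             alt = unname(fix[, "ALT"]),
             gene = unname(vcfR::extract.info(vcf, "GENE")),
             class = unname(vcfR::extract.info(vcf, "CLASS")),
             vaf = as.numeric(vcfR::extract.info(vcf, "VAF")),
             stringsAsFactors = FALSE)
}
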