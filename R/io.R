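#' Read and write the package's tabular formats
#'
#' All tables are tab-separated with a header row. Missing values are "NA".
#' `read_subjects()` validates id uniqueness and runs the sum-Z consistency
#' check; `read_genotypes()` validates that dosages are 0/1/2/NA.
#'
#' @param path File path.
#' @return A tibble (readers) or `path`, invisibly (writers).
#' @name hbm_io
NULL

tsv_cols <- function(...) readr::cols(...)

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  na = "NA", show_col_types = FALSE)
}

#' @rdname hbm_io
#' @export
read_subjects <- function(path) {
  hdr <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE, show_col_types = FALSE))
  spec <- c(
    lapply(setNames(nm = intersect(c("id", "cohort"), hdr)),
           function(.) readr::col_character()),
    lapply(setNames(nm = intersect(c("dna_available", "genotyped", "carrier"),
                                   hdr)),
           function(.) readr::col_logical()),
    list(.default = readr::col_double())
  )
  x <- read_tsv_quiet(path, do.call(readr::cols, spec))
  if (anyDuplicated(x$id)) abort("duplicate subject ids in subject table.")
  ensure_sum_z(x)
}

#' @rdname hbm_io
#' @param subjects Subject tibble.
#' @export
write_subjects <- function(subjects, path) {
  readr::write_tsv(subjects, path, na = "NA")
  invisible(path)
}

#' @rdname hbm_io
#' @export
read_effect_table <- function(path) {
  x <- read_tsv_quiet(path, tsv_cols(
    rsid = readr::col_character(), effect_allele = readr::col_character(),
    other_allele = readr::col_character(), beta = readr::col_double(),
    maf = readr::col_double()
  ))
  if (anyDuplicated(x$rsid)) abort("duplicate rsids in effect table.")
  if (any(x$beta <= 0))
    abort("effect sizes must be strictly positive (risk-allele orientation).")
  x
}

#' @rdname hbm_io
#' @param effects Effect tibble.
#' @export
write_effect_table <- function(effects, path) {
  readr::write_tsv(effects, path, na = "NA")
  invisible(path)
}

#' @rdname hbm_io
#' @export
read_genotypes <- function(path) {
  x <- read_tsv_quiet(path, tsv_cols(
    id = readr::col_character(), .default = readr::col_integer()
  ))
  genotype_matrix(x) # validates
  x
}

#' @rdname hbm_io
#' @param genotypes Wide genotype tibble (`id` + one dosage column per rsid).
#' @export
write_genotypes <- function(genotypes, path) {
  readr::write_tsv(genotypes, path, na = "NA")
  invisible(path)
}

#' @rdname hbm_io
#' @export
read_pedigree <- function(path) {
  x <- read_tsv_quiet(path, tsv_cols(
    id = readr::col_character(), relation = readr::col_character(),
    sum_z = readr::col_double(), carrier = readr::col_character()
  ))
  bad <- setdiff(unique(x$carrier), c("carrier", "non-carrier", "unknown"))
  if (length(bad))
    abort(paste("carrier status must be carrier/non-carrier/unknown, got:",
                paste(bad, collapse = ", ")))
  x
}

#' @rdname hbm_io
#' @param pedigree Pedigree tibble.
#' @export
write_pedigree <- function(pedigree, path) {
  readr::write_tsv(pedigree, path, na = "NA")
  invisible(path)
}

#' @rdname hbm_io
#' @export
read_ct_panel <- function(path) {
  read_tsv_quiet(path, tsv_cols(
    gene = readr::col_character(), sample = readr::col_character(),
    replicate = readr::col_integer(), ct = readr::col_double()
  ))
}

#' @rdname hbm_io
#' @param panel Long Ct tibble (`gene`, `sample`, `replicate`, `ct`).
#' @export
write_ct_panel <- function(panel, path) {
  readr::write_tsv(panel, path, na = "NA")
  invisible(path)
}

#' Minimal VCF export/import of a dosage matrix
#'
#' `write_genotypes_vcf()` writes a minimal VCFv4.2 file with a GT FORMAT
#' field only: biallelic sites, unphased diploid genotypes, dosage counted on
#' the effect allele (REF = other allele, ALT = effect allele; dosage 2 =
#' `1/1`, missing = `./.`). Positions are synthetic (1..n on chromosome "1")
#' since the panel is positionless. `read_genotypes_vcf()` parses such a file
#' back to the wide dosage tibble via the vcfR package.
#'
#' @param genotypes Wide genotype tibble.
#' @param effects Matching effect table (allele columns).
#' @param path Output/input file path.
#' @return The path (writer) or a wide genotype tibble (reader).
#' @export
write_genotypes_vcf <- function(genotypes, effects, path) {
  m <- genotype_matrix(genotypes)
  if (!setequal(colnames(m), effects$rsid))
    abort("genotype columns and effect-table rsids do not match.")
  m <- m[, effects$rsid, drop = FALSE]
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(m)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(m)), function(j) {
    gt <- ifelse(is.na(m[, j]), "./.", gt_code[as.character(m[, j])])
    paste(c("1", j, effects$rsid[j], effects$other_allele[j],
            effects$effect_allele[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  out <- t(dos)
  bind_cols(tibble(id = rownames(out)),
            as_tibble(out))
}
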