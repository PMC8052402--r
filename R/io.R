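# Standard-format I/O. Coordinates are 0-based half-open internally;
# BED is native, VCF positions are converted at the boundary (1-based).

#' Write genotypes to a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT genotypes (unphased), per-variant MAF and
#' INFO score in the INFO column; missing dosages become `./.`.
#'
#' @param geno A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geno_vcf <- function(geno, path) {
  v <- geno$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  G <- geno$dosage
  gt <- matrix("./.", nrow = ncol(G), ncol = nrow(G))
  for (j in seq_len(nrow(G))) {
    gj <- G[j, ]
    gt[!is.na(gj), j] <- gt_code[as.character(gj[!is.na(gj)])]
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation INFO score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                sprintf("MAF=%.6g;INFO=%.4g", v$maf, v$info), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses GT fields into alternate-allele dosages (0/1/2, `NA` for missing)
#' and recovers MAF/INFO annotations when present.
#'
#' @param path VCF file path.
#' @return A [geno_matrix()] (without kinship; use
#'   [realized_relatedness()]).
#' @export
read_geno_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    alleles <- strsplit(gsub("\\|", "/", x[ok]), "/")
    out[ok] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
    out
  }
  dosage <- t(apply(gt, 1, count_alt))
  colnames(dosage) <- colnames(gt)
  dosage <- t(dosage)  # donors x variants
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  get_info <- function(key, default) {
    m <- regmatches(fix$INFO, regexpr(paste0(key, "=[^;]+"), fix$INFO))
    vals <- rep(default, nrow(fix))
    hit <- grepl(paste0(key, "="), fix$INFO)
    vals[hit] <- as.numeric(sub(paste0(key, "="), "", m))
    vals
  }
  variants <- tibble(
    variant_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    maf = get_info("MAF", NA_real_),
    info = get_info("INFO", 1)
  )
  colnames(dosage) <- variants$variant_id
  geno_matrix(dosage, variants)
}

#' Write intervals to BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional `name`
#'   / `score` columns (0-based half-open, BED native).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- as_tibble(intervals)
  gr <- GenomicRanges_from_tibble(intervals)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

GenomicRanges_from_tibble <- function(df) {
  gr <- IRanges::IRanges(start = df$start + 1L, end = df$end)
  out <- GenomicRanges::GRanges(seqnames = df$chrom, ranges = gr)
  if ("name" %in% names(df)) names(out) <- df$name
  if ("score" %in% names(df)) out$score <- df$score
  out
}

#' Read intervals from BED
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open) plus
#'   `name`/`score` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  nm <- names(gr) %||% gr$name
  if (!is.null(nm)) out$name <- nm
  if (!is.null(gr$score)) out$score <- gr$score
  out
}

#' Write a signal matrix to TSV with a stage header
#'
#' The first line records the pipeline stage (`#stage=`), followed by a
#' feature-by-donor table with interval columns.
#'
#' @param signal A `signal_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_tsv <- function(signal, path) {
  writeLines(paste0("#stage=", signal$stage), path)
  df <- dplyr::bind_cols(signal$features,
                         as_tibble(signal$values, .name_repair = "minimal"))
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a signal matrix written by [write_signal_tsv()]
#'
#' @param path TSV path.
#' @return A `signal_matrix` at the recorded stage.
#' @export
read_signal_tsv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#stage=")) abort_invalid("missing #stage= header.")
  stage <- sub("#stage=", "", first)
  df <- readr::read_tsv(path, skip = 1, show_col_types = FALSE)
  feat_cols <- intersect(c("feature_id", "chrom", "start", "end", "assay",
                           "cell_type"), names(df))
  features <- df[feat_cols]
  vals <- as.matrix(df[setdiff(names(df), feat_cols)])
  rownames(vals) <- features$feature_id
  signal_matrix(vals, features, stage = stage)
}

#' Write / read generic result tables
#'
#' Thin wrappers around TSV serialisation used for QTL records, allelic
#' counts, interactions, summary statistics and catalogues.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
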