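#' Read a genotype region from a VCF or dosage TSV
#'
#' VCF files are read with \pkg{vcfR}; dosages are taken from the `DS` FORMAT
#' field when present, otherwise hard genotype calls (`GT`) are converted to
#' additive 0/1/2 counts. Per-SNP imputation quality is parsed from the INFO
#' keys `IQ` or `R2` and defaults to 1 (genotyped) when absent. Multi-allelic
#' records are skipped with a warning, and SNPs with imputation quality below
#' `iq_min` are dropped.
#'
#' A dosage TSV has one row per SNP with header columns `chrom`, `pos`,
#' optionally `id` and `iq`, followed by one dosage column per sample.
#'
#' @param path Path to a `.vcf`/`.vcf.gz` or tab-separated dosage file.
#' @param chrom,start,end Optional region restriction (1-based inclusive).
#' @param iq_min Minimum imputation quality retained (default 0.8).
#' @return A `"ws_region"` object; sample identifiers are kept as rownames of
#'   the dosage matrix.
#' @export
read_genotypes <- function(path, chrom = NULL, start = NULL, end = NULL,
                           iq_min = 0.8) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_genotypes_vcf(path, chrom, start, end, iq_min)
  } else {
    read_genotypes_tsv(path, chrom, start, end, iq_min)
  }
}

read_genotypes_vcf <- function(path, chrom, start, end, iq_min) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  pos <- as.numeric(fix$POS)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(chrom)) keep <- keep & fix$CHROM == as.character(chrom)
  if (!is.null(start)) keep <- keep & pos >= start
  if (!is.null(end)) keep <- keep & pos <= end
  multi <- !is.na(fix$ALT) & grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi & keep)) {
    warning(sum(multi & keep), " multi-allelic site(s) skipped", call. = FALSE)
    keep <- keep & !multi
  }
  if (!any(keep)) stop("no SNPs in the requested region", call. = FALSE)

  iq <- parse_info_iq(fix$INFO)
  low <- keep & iq < iq_min
  keep <- keep & iq >= iq_min
  if (!any(keep)) stop("no SNPs left after the imputation-quality filter", call. = FALSE)

  gt <- vcf@gt
  fmt <- strsplit(gt[, 1], ":", fixed = TRUE)
  has_ds <- all(vapply(fmt, function(f) "DS" %in% f, logical(1)))
  extract <- function(field) {
    m <- vcfR::extract.gt(vcf, element = field, as.numeric = field == "DS")
    m
  }
  if (has_ds) {
    dos <- extract("DS")
  } else {
    gtm <- extract("GT")
    dos <- apply(gtm, c(1, 2), gt_to_dosage)
  }
  dos <- dos[keep, , drop = FALSE]
  dos[is.na(dos)] <- 0
  dos <- pmin(pmax(dos, 0), 2)

  genotype_region(
    dosages = t(dos),
    positions = pos[keep],
    iq = iq[keep],
    chrom = if (is.null(chrom)) fix$CHROM[keep][1] else as.character(chrom),
    lb = start %||% pos[keep][1],
    ub = end %||% pos[keep][length(pos[keep])]
  )
}

gt_to_dosage <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1]]
  sum(alleles == "1")
}

parse_info_iq <- function(info) {
  vapply(info, function(s) {
    if (is.na(s)) return(1)
    m <- regmatches(s, regexec("(?:^|;)(?:IQ|R2)=([0-9.eE+-]+)", s))[[1]]
    if (length(m) == 2) as.numeric(m[2]) else 1
  }, numeric(1), USE.NAMES = FALSE)
}

read_genotypes_tsv <- function(path, chrom, start, end, iq_min) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("chrom", "pos", "id", "iq"), names(tab))
  if (!all(c("chrom", "pos") %in% meta_cols)) {
    stop("dosage TSV needs 'chrom' and 'pos' columns", call. = FALSE)
  }
  sample_cols <- setdiff(names(tab), meta_cols)
  if (!length(sample_cols)) stop("dosage TSV has no sample columns", call. = FALSE)
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(chrom)) keep <- keep & tab$chrom == chrom
  if (!is.null(start)) keep <- keep & tab$pos >= start
  if (!is.null(end)) keep <- keep & tab$pos <= end
  iq <- if ("iq" %in% meta_cols) tab$iq else rep(1, nrow(tab))
  keep <- keep & iq >= iq_min
  if (!any(keep)) stop("no SNPs left after region/IQ filtering", call. = FALSE)
  dos <- t(as.matrix(tab[keep, sample_cols, drop = FALSE]))
  genotype_region(
    dosages = dos,
    positions = tab$pos[keep],
    iq = iq[keep],
    chrom = if (is.null(chrom)) tab$chrom[keep][1] else as.character(chrom),
    lb = start %||% tab$pos[keep][1],
    ub = end %||% max(tab$pos[keep])
  )
}

#' Write a genotype region as a dosage TSV
#'
#' Inverse of the TSV branch of [read_genotypes()].
#'
#' @param region A `"ws_region"` object.
#' @param path Output path.
#' @param sample_ids Optional sample identifiers (default `ind1..indK` or
#'   dosage rownames).
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(region, path, sample_ids = NULL) {
  stopifnot(inherits(region, "ws_region"))
  K <- nrow(region$dosages)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(region$dosages) %||% paste0("ind", seq_len(K))
  }
  tab <- data.frame(
    chrom = region$chrom,
    pos = region$positions,
    iq = region$iq,
    t(region$dosages),
    check.names = FALSE
  )
  names(tab)[-(1:3)] <- sample_ids
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype (or covariate) TSV
#'
#' Expects a header row `sample_id` followed by one or more numeric columns;
#' returns a tibble.
#'
#' @param path File path.
#' @return Tibble with a `sample_id` column and numeric value columns.
#' @export
read_phenotype_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) {
    stop("phenotype TSV needs a 'sample_id' column", call. = FALSE)
  }
  tibble::as_tibble(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
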