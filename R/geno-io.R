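#' Genotype matrix objects
#'
#' A `geno_matrix` is an individuals x markers matrix of biallelic SNP
#' dosages coded 0/1/2 (`NA` = missing call, real-valued dosages after mean
#' imputation), with unique row (individual) and column (marker) ids and an
#' optional genetic map aligned to the columns.
#'
#' @param calls Numeric matrix, individuals x markers, values in `[0, 2]` or
#'   `NA`, with rownames and colnames set (or supplied via `individual_ids` /
#'   `marker_ids`).
#' @param map Optional [as_genetic_map()] covering the marker columns.
#' @param individual_ids,marker_ids Optional dimension ids.
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(calls, map = NULL, individual_ids = NULL,
                        marker_ids = NULL) {
  calls <- as.matrix(calls)
  if (!is.null(individual_ids)) rownames(calls) <- individual_ids
  if (!is.null(marker_ids)) colnames(calls) <- marker_ids
  assert_that(!is.null(rownames(calls)) &&
                (ncol(calls) == 0L || !is.null(colnames(calls))),
              "genotype matrix needs individual and marker ids")
  assert_that(!anyDuplicated(rownames(calls)), "duplicated individual ids")
  assert_that(!anyDuplicated(colnames(calls)), "duplicated marker ids")
  if (length(calls) > 0 && !all(is.na(calls))) {
    rng <- range(calls, na.rm = TRUE)
    assert_that(rng[1] >= 0 && rng[2] <= 2, "calls must lie in [0, 2]")
  }
  if (!is.null(map)) {
    map <- as_genetic_map(map)
    assert_that(all(colnames(calls) %in% map$marker_id),
                "map must cover every marker column")
    map <- map[match(colnames(calls), map$marker_id), ]
  }
  structure(list(calls = calls, map = map), class = "geno_matrix")
}

#' @exportS3Method base::print
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d markers (%.2f%% missing)%s\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls)),
              if (is.null(x$map)) "" else ", mapped"))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Summarise markers of a genotype matrix
#'
#' @param g A [geno_matrix()].
#' @return A tibble with one row per marker: allele frequency of the counted
#'   allele (`mean(calls)/2` over non-missing calls), minor-allele frequency
#'   and missing fraction.
#' @export
marker_stats <- function(g) {
  calls <- g$calls
  freq <- colMeans(calls, na.rm = TRUE) / 2
  tibble(marker_id = colnames(calls),
         freq = freq,
         maf = pmin(freq, 1 - freq),
         missing_frac = colMeans(is.na(calls)))
}

#' Read genotypes from VCF or a delimited dosage matrix
#'
#' The VCF dialect uses only the GT field; multi-allelic records are skipped
#' with a reported count, and `./.` becomes a missing call. The matrix dialect
#' is tab-delimited with marker ids as the header and individual ids in the
#' first column, values 0/1/2/NA.
#'
#' @param path File to read.
#' @param dialect `"vcf"` or `"matrix"`.
#' @param map Optional genetic map to attach.
#' @return A [geno_matrix()]. The number of skipped multi-allelic VCF records
#'   is attached as attribute `"skipped_multiallelic"`.
#' @export
read_genotypes <- function(path, dialect = c("vcf", "matrix"), map = NULL) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), paste("no such file:", path))
  if (dialect == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    alt <- fix[, "ALT"]
    multi <- grepl(",", alt)
    n_skip <- sum(multi)
    if (n_skip > 0) {
      inform(sprintf("skipped %d multi-allelic record(s) in %s", n_skip, path))
      v <- v[!multi, ]
      fix <- vcfR::getFIX(v)
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- apply(gt, c(1, 2), function(x) {
      if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]))
    })
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
    assert_that(!anyDuplicated(ids), paste("duplicated marker ids in", path))
    assert_that(!anyDuplicated(colnames(dose)), paste("duplicated sample ids in", path))
    out <- geno_matrix(t(dose), map = map, marker_ids = ids)
    attr(out, "skipped_multiallelic") <- n_skip
    out
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, row.names = 1)
    geno_matrix(as.matrix(tab), map = map)
  }
}

#' Write genotypes to VCF or a delimited dosage matrix
#'
#' The VCF written is a minimal VCF 4.2 with GT fields only (missing calls as
#' `./.`); dosage 1 is written as the unphased het `0/1`. Writing then reading
#' either dialect round-trips calls and ids exactly for integer dosages.
#'
#' @param g A [geno_matrix()].
#' @param path Output file.
#' @param dialect `"vcf"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, dialect = c("vcf", "matrix")) {
  dialect <- match.arg(dialect)
  calls <- g$calls
  if (dialect == "matrix") {
    df <- data.frame(id = rownames(calls), calls, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  assert_that(all(calls %in% c(0, 1, 2) | is.na(calls)),
              "VCF output requires integer 0/1/2 dosages (write before imputing)")
  map <- g$map
  chrom <- if (is.null(map)) rep(1L, ncol(calls)) else map$linkage_group
  pos <- if (is.null(map)) seq_len(ncol(calls)) else
    pmax(1L, as.integer(round(map$pos_mb * 1e6)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(ncol(calls)), function(j) {
    gts <- calls[, j]
    gt <- ifelse(is.na(gts), "./.", gt_code[as.character(gts)])
    paste(c(chrom[j], pos[j], colnames(calls)[j], "A", "C", ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(calls)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Marker quality control
#'
#' Removes markers with minor-allele frequency strictly below `maf_min` or a
#' missing-call fraction strictly above `max_missing`. Both rules are applied
#' to the original matrix, so filtering is order-independent and boundary
#' values (MAF exactly `maf_min`, missingness exactly `max_missing`) are
#' retained. MAF is computed on non-missing calls. For transparency the
#' report also carries the MAF recomputed after dropping high-missing markers
#' (`maf_after_missing_rule`), which under these per-marker rules is identical.
#'
#' @param g A [geno_matrix()].
#' @param maf_min Minimum minor-allele frequency kept (default 0.05).
#' @param max_missing Maximum missing fraction kept (default 0.05).
#' @return A list: `genotypes` (filtered [geno_matrix()]) and `report`
#'   (tibble: `marker_id`, `maf`, `missing_frac`, `removed_by` in
#'   `{"kept", "maf", "missing", "maf+missing"}`).
#' @export
qc_filter <- function(g, maf_min = 0.05, max_missing = 0.05) {
  assert_that(ncol(g$calls) > 0 && nrow(g$calls) > 0, "empty genotype matrix")
  st <- marker_stats(g)
  by_maf <- st$maf < maf_min & !is.nan(st$maf)
  by_maf[is.nan(st$maf)] <- TRUE            # all-missing marker: no MAF
  by_miss <- st$missing_frac > max_missing
  removed_by <- dplyr::case_when(
    by_maf & by_miss ~ "maf+missing",
    by_maf ~ "maf",
    by_miss ~ "missing",
    TRUE ~ "kept")
  keep <- removed_by == "kept"
  if (!any(keep)) warn("QC removed every marker")
  report <- tibble(marker_id = st$marker_id, maf = st$maf,
                   missing_frac = st$missing_frac, removed_by = removed_by)
  report$maf_after_missing_rule <- ifelse(by_miss, NA_real_, st$maf)
  gm <- geno_matrix(g$calls[, keep, drop = FALSE],
                    map = if (is.null(g$map)) NULL else g$map[keep, ])
  list(genotypes = gm, report = report)
}

#' Mean imputation of missing genotype calls
#'
#' Replaces each missing call with twice the allele frequency of that marker
#' among its non-missing calls, leaving observed calls untouched. Imputed
#' dosages are real-valued in `[0, 2]`; downstream models accept dosages.
#'
#' @param g A [geno_matrix()] in which every marker has at least one
#'   non-missing call.
#' @return A [geno_matrix()] with no missing values.
#' @export
impute_mean <- function(g) {
  calls <- g$calls
  nmiss <- colSums(is.na(calls))
  assert_that(all(nmiss < nrow(calls)),
              "all-missing marker present; run qc_filter first")
  if (any(nmiss > 0)) {
    freq2 <- colMeans(calls, na.rm = TRUE)   # = 2 x allele frequency
    idx <- which(is.na(calls), arr.ind = TRUE)
    calls[idx] <- freq2[idx[, 2]]
  }
  geno_matrix(calls, map = g$map)
}

#' Write a genetic map to a 4-column tab-delimited file
#' @param map A [as_genetic_map()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genetic map written by [write_genetic_map()]
#' @param path File to read.
#' @return A `genetic_map` tibble.
#' @export
read_genetic_map <- function(path) {
  as_genetic_map(utils::read.table(path, header = TRUE, sep = "\t"))
}
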