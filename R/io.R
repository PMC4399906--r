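#' Read a genotype matrix from VCF or a plain delimited file
#'
#' VCF input (via the \pkg{vcfR} parser) uses the GT field of bi-allelic
#' records; multi-allelic records are skipped with a message (or cause an
#' error with `multiallelic = "error"`). Matrix input expects a delimited
#' file with a header row of variant identifiers, subject identifiers in
#' the first column, and entries 0/1/2 (or the missing code). In both
#' cases columns are oriented so entries count the allele that is minor in
#' the full sample ([orient_minor()]), and missing genotypes are imputed
#' to 0 copies with a recorded per-variant missingness rate
#' ([impute_missing()]).
#'
#' @param path input file.
#' @param format `"auto"` (by extension: `.vcf` / `.vcf.gz` versus
#'   anything else), `"vcf"`, or `"matrix"`.
#' @param multiallelic `"skip"` or `"error"` for multi-allelic VCF records.
#' @param missing_code string encoding missing entries in matrix input.
#' @param sep field separator for matrix input (default whitespace/tab).
#' @return numeric subjects x variants matrix of minor-allele counts with
#'   row/column names; VCF input additionally carries a `variants`
#'   attribute (data frame with `chrom`, `pos` (1-based, as in the file),
#'   `ref`, `alt`) and both carry the `flipped` orientation attribute.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix"),
                           multiallelic = c("skip", "error"),
                           missing_code = "NA", sep = "") {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "matrix"
  }
  if (format == "vcf") {
    read_genotypes_vcf(path, multiallelic)
  } else {
    read_genotypes_matrix(path, missing_code, sep)
  }
}

read_genotypes_vcf <- function(path, multiallelic) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (any(!bi)) {
    if (multiallelic == "error") {
      stop(sum(!bi), " multi-allelic record(s) in ", path,
           " (first at row ", which(!bi)[1], "); split them or pass multiallelic = 'skip'")
    }
    message("skipping ", sum(!bi), " multi-allelic record(s)")
    v <- v[bi, ]
  }
  fx <- vcfR::getFIX(v)
  if (!is.matrix(fx)) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- unname(fx[, "ID"])
  ids[is.na(ids) | ids == "."] <- paste0(fx[, "CHROM"], ":", fx[, "POS"])[is.na(ids) | ids == "."]
  # count ALT alleles from the GT string; any ploidy other than 2 is an error
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2L) stop("non-diploid genotype '", g, "' in ", path)
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  G <- t(matrix(vapply(gt, count_alt, numeric(1)), nrow = nrow(gt)))
  dimnames(G) <- list(colnames(gt), ids)
  G <- impute_missing(G)
  rate <- attr(G, "missing_rate")
  G <- orient_minor(G)
  attr(G, "missing_rate") <- rate
  attr(G, "variants") <- data.frame(
    chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
    ref = fx[, "REF"], alt = fx[, "ALT"],
    row.names = ids, stringsAsFactors = FALSE)
  G
}

read_genotypes_matrix <- function(path, missing_code, sep) {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = missing_code, check.names = FALSE,
                           row.names = 1, stringsAsFactors = FALSE)
  G <- as.matrix(tab)
  if (!is.numeric(G)) stop("non-numeric genotype entries in ", path)
  bad <- !(G %in% c(0, 1, 2) | is.na(G))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("genotype entry ", G[i], " outside {0,1,2} in ", path,
         " (subject ", rownames(G)[(i - 1) %% nrow(G) + 1], ")")
  }
  G <- impute_missing(G)
  rate <- attr(G, "missing_rate")
  G <- orient_minor(G)
  attr(G, "missing_rate") <- rate
  G
}

#' Write a genotype matrix as a delimited file
#'
#' Tab-separated, variant identifiers as the header, subject identifiers
#' in the first column -- the format [read_genotypes()] reads back.
#'
#' @param genotypes subjects x variants matrix.
#' @param path output file.
#' @export
write_genotypes <- function(genotypes, path) {
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("s%04d", seq_len(nrow(genotypes)))
  }
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- sprintf("v%02d", seq_len(ncol(genotypes)))
  }
  df <- data.frame(subject = rownames(genotypes), genotypes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export genotypes to a minimal VCF (v4.2)
#'
#' Writes bi-allelic records with GT-only genotype columns on one pseudo-
#' chromosome with synthetic positions -- enough for end-to-end testing of
#' VCF-driven pipelines with simulated data. Entries are taken to count
#' the ALT allele.
#'
#' @param genotypes subjects x variants matrix of allele counts (0/1/2).
#' @param path output file (plain text).
#' @param chrom pseudo-chromosome name.
#' @param pos per-variant positions (1-based); default 1000, 2000, ...
#' @export
write_vcf <- function(genotypes, path, chrom = "chrS", pos = NULL) {
  check_genotypes(genotypes)
  n <- nrow(genotypes); k <- ncol(genotypes)
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- sprintf("v%02d", seq_len(k))
  }
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("s%04d", seq_len(n))
  }
  if (is.null(pos)) pos <- 1000L * seq_len(k)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  body <- vapply(seq_len(k), function(j) {
    paste(c(chrom, pos[j], colnames(genotypes)[j], "A", "T", ".", "PASS",
            ".", "GT", gt_code[as.character(genotypes[, j])]),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a phenotype file
#'
#' Two delimited columns -- subject identifier, disease status 0/1 -- with
#' or without a header. Anything else is rejected.
#'
#' @param path input file.
#' @return named 0/1 vector (names = subject identifiers).
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 2) {
    stop("phenotype file must have exactly two columns (subject id, 0/1); got ",
         ncol(tab))
  }
  if (!all(tab[[2]] %in% c(0, 1))) {
    # tolerate a header line, nothing more
    if (nrow(tab) > 1 && all(tab[-1, 2] %in% c("0", "1"))) {
      tab <- tab[-1, , drop = FALSE]
    } else {
      stop("phenotype status column must contain only 0 and 1")
    }
  }
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Read a region (gene) grouping file
#'
#' Two delimited columns -- region identifier, variant identifier -- mapping
#' each variant to the region it belongs to. Variant order within a
#' region follows file order.
#'
#' @param path input file.
#' @return named list of character vectors of variant identifiers.
#' @export
read_regions <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 2) {
    stop("region file must have two columns (region id, variant id)")
  }
  split(as.character(tab[[2]]), factor(tab[[1]], levels = unique(tab[[1]])))
}

#' Test every region of a genotype matrix
#'
#' Subjects are intersected between the genotype matrix and the phenotype
#' vector (mismatches are reported), optional region filters are applied,
#' and each surviving region is tested with each requested method. A
#' region whose variants are all monomorphic in the analysed subjects is
#' degenerate: its statistic carries no information, the p-value is
#' reported as 1 and a warning is emitted.
#'
#' @param genotypes subjects x variants matrix (row/column names required),
#'   e.g. from [read_genotypes()].
#' @param phenotype named 0/1 vector, e.g. from [read_phenotypes()].
#' @param regions named list of variant-id vectors, e.g. from
#'   [read_regions()]; `NULL` tests the whole matrix as one region.
#' @param methods character vector of GWSS method names.
#' @param B permutations per test.
#' @param seed master seed; each region derives a child seed.
#' @param min_variants drop regions with fewer variants present.
#' @param require_rv_cv if `TRUE`, keep only regions containing at least
#'   one rare and one common variant at the `maf_cut` boundary (sample
#'   MAF), mirroring the usual mixed-region screening protocol.
#' @param maf_cut rare/common MAF boundary for `require_rv_cv`.
#' @param theta,theta_set passed to [gwss_test_set()].
#' @return data frame with one row per (region, method): `region`,
#'   `method`, `n_variants`, `statistic`, `selected_theta`, `B`,
#'   `p_value`.
#' @export
run_region_tests <- function(genotypes, phenotype, regions = NULL,
                             methods = "VDWSS-t", B = 1000, seed = NULL,
                             min_variants = 1, require_rv_cv = FALSE,
                             maf_cut = 0.01, theta = Inf,
                             theta_set = "observed") {
  if (is.null(rownames(genotypes))) {
    stop("genotype matrix needs subject row names to match the phenotype")
  }
  common <- intersect(rownames(genotypes), names(phenotype))
  if (length(common) == 0) stop("no subjects shared by genotypes and phenotype")
  dropped <- length(union(rownames(genotypes), names(phenotype))) - length(common)
  if (dropped > 0) {
    message(dropped, " subject(s) present in only one input were dropped")
  }
  G <- genotypes[common, , drop = FALSE]
  D <- phenotype[common]
  if (is.null(regions)) regions <- list(all = colnames(G))

  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(.Machine$integer.max, length(regions))
  rows <- list()
  for (i in seq_along(regions)) {
    rid <- names(regions)[i]
    vars <- intersect(regions[[i]], colnames(G))
    if (length(vars) < min_variants) {
      message("region '", rid, "' skipped: ", length(vars),
              " variant(s) present, fewer than min_variants = ", min_variants)
      next
    }
    Gr <- G[, vars, drop = FALSE]
    maf <- colMeans(Gr) / 2
    maf <- pmin(maf, 1 - maf)
    if (require_rv_cv && !(any(maf > 0 & maf <= maf_cut) && any(maf > maf_cut))) {
      message("region '", rid, "' skipped: needs >= 1 rare and >= 1 common variant at MAF cut ",
              maf_cut)
      next
    }
    if (all(maf == 0)) {
      warning("region '", rid, "' is monomorphic; p-value reported as 1")
      rows[[length(rows) + 1L]] <- data.frame(
        region = rid, method = methods, n_variants = length(vars),
        statistic = NA_real_, selected_theta = NA_real_, B = B, p_value = 1,
        stringsAsFactors = FALSE)
      next
    }
    res <- gwss_test_set(Gr, D, methods = methods, B = B, seed = child[i],
                         theta = theta, theta_set = theta_set)
    rows[[length(rows) + 1L]] <- data.frame(
      region = rid, method = res$method, n_variants = length(vars),
      statistic = res$statistic, selected_theta = res$selected_theta,
      B = res$n_permutations, p_value = res$p_value,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(), method = character(),
               n_variants = integer(), statistic = numeric(),
               selected_theta = numeric(), B = integer(),
               p_value = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a results table as tab-separated text
#'
#' @param results data frame (e.g. from [run_region_tests()] or
#'   [run_study()]).
#' @param path output file.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
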