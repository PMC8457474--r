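# File formats: cohort TSV round-trip, delimited and VCF genotype matrices,
# and result tables with the PPLD display-precision rule.

#' Write / read a cohort as tab-separated text
#'
#' The cohort format has a header row `sample_id genotype covariate time
#' event` preceded by one `#`-comment metadata line recording the generating
#' model and seed (or `real-data`).
#'
#' @param cohort A cohort tibble (see [sim_cohort()]).
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   a validated cohort tibble with provenance attributes.
#' @export
write_cohort <- function(cohort, path) {
  model_id <- attr(cohort, "model_id") %||% "real-data"
  seed <- attr(cohort, "seed")
  meta <- sprintf("# model=%s seed=%s", model_id,
                  if (is.null(seed)) "NA" else seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(cohort, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1)
  meta <- if (startsWith(first, "#")) first else NULL
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "covariate", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort file lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad_time <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_time)) stop("non-positive time at row ", bad_time[1],
                             call. = FALSE)
  bad_event <- which(!df$event %in% c(0, 1))
  if (length(bad_event)) stop("event not in {0,1} at row ", bad_event[1],
                              call. = FALSE)
  if ("genotype" %in% names(df)) {
    bad_g <- which(!df$genotype %in% c(0:2, NA))
    if (length(bad_g)) stop("genotype not in {0,1,2} at row ", bad_g[1],
                            call. = FALSE)
  }
  bad_cov <- which(!df$covariate %in% 1:2)
  if (length(bad_cov)) stop("covariate not in {1,2} at row ", bad_cov[1],
                            call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids", call. = FALSE)
  out <- tibble::as_tibble(df)
  if (!is.null(meta)) {
    m <- regmatches(meta, regexec("model=(\\S+) seed=(\\S+)", meta))[[1]]
    if (length(m) == 3) {
      attr(out, "model_id") <- m[2]
      attr(out, "seed") <- suppressWarnings(as.integer(m[3]))
    }
  }
  out
}

#' Read a delimited genotype matrix
#'
#' Expects a TSV with a `sample_id` column followed by one column per SNP of
#' minor-allele counts (0/1/2, `NA` for missing). Rows are reordered to match
#' `sample_order` when given; absent samples are an error.
#'
#' @param path File path.
#' @param sample_order Optional character vector of sample ids.
#' @return A numeric matrix, samples x SNPs, with `sample_id` rownames.
#' @export
read_genotypes_tsv <- function(path, sample_order = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("no sample_id column", call. = FALSE)
  G <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(G) <- df$sample_id
  if (!all(G %in% c(0:2, NA))) stop("genotype entries must be 0/1/2 or NA",
                                    call. = FALSE)
  if (!is.null(sample_order)) {
    absent <- setdiff(sample_order, rownames(G))
    if (length(absent)) stop("samples absent from genotype file: ",
                             paste(utils::head(absent, 5), collapse = ", "),
                             call. = FALSE)
    G <- G[sample_order, , drop = FALSE]
  }
  G
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Extracts GT fields and converts them to minor-allele counts; the minor
#' allele is defined per SNP from the loaded samples. Multi-allelic and
#' non-SNP records are skipped (a count is reported via message); missing
#' genotypes become `NA`.
#'
#' @param path VCF path (plain or gzipped).
#' @param sample_order Optional sample ids to select/order columns.
#' @return A numeric matrix, samples x SNPs, with per-SNP MAF in attribute
#'   `"maf"`.
#' @export
read_genotypes_vcf <- function(path, sample_order = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  is_snp <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"])
  n_skip <- sum(!is_snp)
  if (n_skip > 0) message(n_skip, " multi-allelic/non-SNP records skipped")
  gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  ids <- fix[is_snp, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[is_snp, "CHROM"], ":",
                                         fix[is_snp, "POS"])[is.na(ids) | ids == "."]
  alt_count <- function(x) {
    x <- sub("\\|", "/", x)
    ifelse(is.na(x) | x %in% c("./.", "."), NA_real_,
           as.numeric(substr(x, 1, 1) == "1") + as.numeric(substr(x, 3, 3) == "1"))
  }
  G <- t(apply(gt, 1, alt_count))
  colnames(G) <- colnames(gt)
  # orient to minor-allele counts per SNP
  flip <- rowMeans(G, na.rm = TRUE) / 2 > 0.5
  G[flip, ] <- 2 - G[flip, , drop = FALSE]
  G <- t(G)
  colnames(G) <- ids
  if (!is.null(sample_order)) {
    absent <- setdiff(sample_order, rownames(G))
    if (length(absent)) stop("samples absent from VCF: ",
                             paste(utils::head(absent, 5), collapse = ", "),
                             call. = FALSE)
    G <- G[sample_order, , drop = FALSE]
  }
  attr(G, "maf") <- colMeans(G, na.rm = TRUE) / 2
  G
}

#' Format a PPLD for display
#'
#' PPLDs are reported to 2 decimal places when `>= 0.01` and to 4 decimal
#' places below that, so that very small values can still be compared with
#' the prior probability.
#'
#' @param ppld Numeric PPLD values.
#' @return Character vector.
#' @export
format_ppld <- function(ppld) {
  ifelse(is.na(ppld), NA_character_,
         ifelse(ppld >= 0.01, sprintf("%.2f", ppld), sprintf("%.4f", ppld)))
}

#' Write a result table as TSV
#'
#' Writes a tab-separated file with a fixed column order; any `ppld` column
#' is rendered with the display-precision rule of [format_ppld()]. Output is
#' byte-identical for identical input.
#'
#' @param table A result tibble (e.g. from [ppld_scan()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  out <- as.data.frame(table)
  if ("ppld" %in% names(out)) out$ppld <- format_ppld(out$ppld)
  for (j in names(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 6,
                                                  format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
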