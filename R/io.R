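#' Construct a genotype matrix
#'
#' Container for effect-allele dosages with the variant annotation needed for
#' allele harmonization. Dosages count the `ref` allele of the accompanying
#' SNP table (the counted allele); `NA` marks missing calls. Pseudo-haploid
#' samples carry only dosages 0 and 2.
#'
#' @param dosage Integer matrix, samples in rows and variants in columns, with
#'   values in \{0, 1, 2, NA\}; dimnames give sample and variant ids.
#' @param snp Data frame with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per dosage column, in column order.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` and `snp`.
#' @export
genotype_matrix <- function(dosage, snp) {
  stopifnot(is.matrix(dosage))
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snp))) {
    stop("snp table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(snp) != ncol(dosage)) {
    stop("snp table rows (", nrow(snp), ") do not match dosage columns (",
         ncol(dosage), ")", call. = FALSE)
  }
  if (anyDuplicated(snp$variant_id)) {
    stop("duplicate variant_id in snp table", call. = FALSE)
  }
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- snp$variant_id
  snp$chrom <- as.character(snp$chrom)
  rownames(snp) <- NULL
  structure(list(dosage = dosage, snp = snp), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "variants;", sprintf("%.1f%%", 100 * mean(is.na(x$dosage))),
      "missing\n")
  invisible(x)
}

#' Subset a genotype matrix by samples and/or variants
#'
#' @param g A `genotype_matrix`.
#' @param samples,variants Character vectors of ids (or NULL to keep all).
#' @return A `genotype_matrix` restricted to the requested ids, in the
#'   requested order.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosage
  snp <- g$snp
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(dos))
    if (length(miss)) stop("unknown sample ids: ",
                           paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    dos <- dos[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    idx <- match(variants, snp$variant_id)
    if (anyNA(idx)) stop("unknown variant ids", call. = FALSE)
    dos <- dos[, idx, drop = FALSE]
    snp <- snp[idx, , drop = FALSE]
    rownames(snp) <- NULL
  }
  genotype_matrix(dos, snp)
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a header-ed delimited file into a validated summary-statistics table.
#' Rows whose numeric fields (position, beta, p-value) fail to parse, or whose
#' p-value lies outside (0, 1], are dropped and counted; the count is reported
#' with a message and recorded in the `n_dropped` attribute. Allele-content
#' filters (bi-allelic, ambiguous pairs) are deliberately NOT applied here —
#' that is harmonization's job.
#'
#' @param path Path to the delimited text file.
#' @param column_map Named character vector mapping the required canonical
#'   names (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta`, `p_value`) to the file's column names.
#' @param sep Field separator (default tab).
#' @param trait_name Trait label stored on the returned table.
#' @return A data frame of class `sumstats` with the canonical columns, and
#'   attributes `trait_name` and `n_dropped`.
#' @export
read_summary_stats <- function(path,
                               column_map = NULL,
                               sep = "\t",
                               trait_name = "trait") {
  canon <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
             "beta", "p_value")
  if (is.null(column_map)) column_map <- stats::setNames(canon, canon)
  if (!all(canon %in% names(column_map))) {
    stop("schema error: column_map must name all of: ",
         paste(canon, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character",
                           comment.char = "", quote = "")
  missing_cols <- setdiff(unname(column_map[canon]), names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    variant_id    = raw[[column_map[["variant_id"]]]],
    chrom         = raw[[column_map[["chrom"]]]],
    pos           = suppressWarnings(as.numeric(raw[[column_map[["pos"]]]])),
    effect_allele = toupper(raw[[column_map[["effect_allele"]]]]),
    other_allele  = toupper(raw[[column_map[["other_allele"]]]]),
    beta          = suppressWarnings(as.numeric(raw[[column_map[["beta"]]]])),
    p_value       = suppressWarnings(as.numeric(raw[[column_map[["p_value"]]]])),
    stringsAsFactors = FALSE
  )
  ok <- !is.na(out$pos) & !is.na(out$beta) & !is.na(out$p_value) &
    out$p_value > 0 & out$p_value <= 1
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message("read_summary_stats: dropped ", n_dropped,
            " row(s) with unparseable or out-of-range numeric fields")
  }
  out <- out[ok, , drop = FALSE]
  if (anyDuplicated(out$variant_id)) {
    dup <- duplicated(out$variant_id)
    warning("read_summary_stats: dropped ", sum(dup),
            " row(s) with duplicate variant_id (kept first occurrence)")
    out <- out[!dup, , drop = FALSE]
    n_dropped <- n_dropped + sum(dup)
  }
  if (nrow(out) == 0L) {
    stop("empty-input error: no usable summary-statistic rows in ", path,
         call. = FALSE)
  }
  out$pos <- as.integer(out$pos)
  rownames(out) <- NULL
  structure(out, class = c("sumstats", "data.frame"),
            trait_name = trait_name, n_dropped = n_dropped)
}

#' Read EIGENSTRAT geno/snp/ind text triplet
#'
#' Decodes the three-file text genotype representation used by the Reich-lab
#' ancient-DNA releases: `.geno` has one row per SNP and one digit per sample
#' (0/1/2 count of the `.snp` reference-column allele, 9 = missing), `.snp`
#' has one row per variant (id, chromosome, genetic position, physical
#' position, ref, alt) and `.ind` one row per sample (id, sex, population).
#' Digit 9 is mapped to `NA`. No filtering happens here; all-missing samples
#' or variants are retained for downstream QC.
#'
#' @param geno_path,snp_path,ind_path Paths to the three files.
#' @return A `genotype_matrix` (samples x variants) whose counted allele is
#'   the `.snp` reference column, with the `.ind` population column attached
#'   as attribute `population`.
#' @export
read_eigenstrat <- function(geno_path, snp_path, ind_path) {
  snp <- utils::read.table(snp_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(snp) < 6L) {
    stop("format error: .snp file must have 6 columns ",
         "(id, chrom, genetic pos, physical pos, ref, alt)", call. = FALSE)
  }
  snp <- snp[, 1:6]
  names(snp) <- c("variant_id", "chrom", "genetic_pos", "pos", "ref", "alt")
  ind <- utils::read.table(ind_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(ind) < 3L) {
    stop("format error: .ind file must have 3 columns (id, sex, population)",
         call. = FALSE)
  }
  names(ind)[1:3] <- c("sample_id", "sex", "population")

  lines <- readLines(geno_path)
  if (length(lines) != nrow(snp)) {
    stop("format error: .geno has ", length(lines), " rows but .snp has ",
         nrow(snp), call. = FALSE)
  }
  n_samp <- nrow(ind)
  bad_len <- which(nchar(lines) != n_samp)
  if (length(bad_len)) {
    stop("format error: .geno line ", bad_len[1], " has ",
         nchar(lines[bad_len[1]]), " characters but .ind lists ", n_samp,
         " samples", call. = FALSE)
  }
  chars <- strsplit(lines, "", fixed = TRUE)
  m <- matrix(as.integer(unlist(chars, use.names = FALSE)),
              nrow = nrow(snp), ncol = n_samp, byrow = TRUE)
  bad <- !(m %in% c(0L, 1L, 2L, 9L))
  if (any(bad)) {
    stop("format error: .geno contains digits other than 0/1/2/9",
         call. = FALSE)
  }
  m[m == 9L] <- NA_integer_
  dos <- t(m)
  rownames(dos) <- ind$sample_id
  g <- genotype_matrix(dos, snp[, c("variant_id", "chrom", "pos",
                                    "ref", "alt")])
  attr(g, "population") <- stats::setNames(ind$population, ind$sample_id)
  g
}

#' Read sample metadata
#'
#' Parses a tab-separated table keyed by `sample_id` with carbon-dated age
#' (years before 1950), geographic coordinates and an optional explicit
#' period label. Missing ages are allowed (such samples are removed later by
#' the QC filters); an age of exactly 0 forces the Modern period.
#'
#' @param path Path to the tab-separated metadata file. Must contain columns
#'   `sample_id` and `age_bp`; `latitude`, `longitude`, `period` and
#'   `is_ancient` are optional.
#' @return Data frame with columns `sample_id`, `age_bp`, `latitude`,
#'   `longitude`, `period`, `is_ancient`.
#' @export
read_metadata <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (!all(c("sample_id", "age_bp") %in% names(raw))) {
    stop("schema error: metadata must have columns sample_id and age_bp",
         call. = FALSE)
  }
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         raw$sample_id[duplicated(raw$sample_id)][1], call. = FALSE)
  }
  out <- data.frame(
    sample_id = as.character(raw$sample_id),
    age_bp    = suppressWarnings(as.numeric(raw$age_bp)),
    latitude  = if ("latitude" %in% names(raw))
      suppressWarnings(as.numeric(raw$latitude)) else NA_real_,
    longitude = if ("longitude" %in% names(raw))
      suppressWarnings(as.numeric(raw$longitude)) else NA_real_,
    period    = if ("period" %in% names(raw))
      as.character(raw$period) else NA_character_,
    stringsAsFactors = FALSE
  )
  known <- c(period_levels(), NA_character_)
  bad_period <- !is.na(out$period) & !(out$period %in% period_levels())
  if (any(bad_period)) {
    stop("unknown period label(s): ",
         paste(unique(out$period[bad_period]), collapse = ", "),
         call. = FALSE)
  }
  # age 0 <=> Modern, by definition
  modern <- !is.na(out$age_bp) & out$age_bp == 0
  out$period[modern] <- "Modern"
  if ("is_ancient" %in% names(raw)) {
    out$is_ancient <- as.logical(raw$is_ancient)
  } else {
    out$is_ancient <- !modern
  }
  out
}

#' Write result tables as tab-separated text
#'
#' @param tables Named list of data frames; names become file names
#'   (`<name>.tsv`).
#' @param out_dir Output directory (created if needed).
#' @param overwrite Refuse to clobber existing files unless TRUE.
#' @return Invisibly, the vector of written paths.
#' @export
write_results <- function(tables, out_dir, overwrite = FALSE) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  paths <- file.path(out_dir, paste0(names(tables), ".tsv"))
  exists <- file.exists(paths)
  if (any(exists) && !overwrite) {
    stop("refusing to overwrite existing file(s): ",
         paste(basename(paths[exists]), collapse = ", "),
         " (set overwrite = TRUE)", call. = FALSE)
  }
  for (i in seq_along(tables)) {
    write_tsv(tables[[i]], paths[i])
  }
  invisible(paths)
}

# Deterministic TSV writer: fixed column order as given, no quoting, NA as
# "NA", full-precision numerics so read-back reproduces doubles exactly.
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
}
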