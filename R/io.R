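phenotype_columns <- c("genotype_id", "parent1", "parent2", "year", "block",
                       "countertop", "treatment", "trait", "value")

#' Read a phenotype table
#'
#' Reads the canonical long phenotype CSV (columns `genotype_id`,
#' `parent1`, `parent2`, `year`, `block`, `countertop`, `treatment`,
#' `trait`, `value`). Empty strings and `"NA"` in `value` are
#' missing-coded; design factor columns must be complete.
#'
#' @param path CSV file path.
#' @return tibble with typed columns; number of rows and missing values is
#'   reported via `message()`.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    genotype_id = readr::col_character(), parent1 = readr::col_character(),
    parent2 = readr::col_character(), year = readr::col_character(),
    block = readr::col_character(), countertop = readr::col_character(),
    treatment = readr::col_character(), trait = readr::col_character(),
    value = readr::col_double()
  ), na = c("", "NA"))
  miss <- setdiff(phenotype_columns, names(df))
  if (length(miss) > 0) {
    stop("phenotype file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fac <- c("genotype_id", "year", "block", "countertop", "treatment", "trait")
  if (anyNA(df[fac])) {
    stop("missing values in design factor columns", call. = FALSE)
  }
  message(sprintf("read_phenotypes: %d rows, %d missing values",
                  nrow(df), sum(is.na(df$value))))
  df
}

#' Write a phenotype table
#'
#' @param phenotypes phenotype tibble.
#' @param path output CSV path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes[, phenotype_columns], path, na = "NA")
  invisible(path)
}

#' Read genotypes as a dosage matrix
#'
#' Reads either a CSV dosage matrix (first column genotype ID, remaining
#' columns markers on the 0--2 scale, empty cells missing) or a VCF with GT
#' calls (via vcfR; diploid biallelic sites only, `./.` missing,
#' multi-allelic sites skipped with a count).
#'
#' @param path input file.
#' @param format `"csv"` or `"vcf"` (guessed from the extension by default).
#' @return a [marker_matrix()]; for VCF input the number of skipped
#'   multi-allelic sites is attached as attribute `n_multiallelic`.
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "csv"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_double(),
      genotype_id = readr::col_character()
    ), na = c("", "NA"))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$genotype_id
    return(marker_matrix(m))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_multi <- sum(!bi)
  if (n_multi > 0) v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  ploidy_bad <- grepl("^[0-9]+([/|][0-9]+){2,}$", gt)
  if (any(ploidy_bad, na.rm = TRUE)) {
    stop("non-diploid GT calls found", call. = FALSE)
  }
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dose[gt %in% c("1/1", "1|1")] <- 2
  out <- marker_matrix(t(dose))
  attr(out, "n_multiallelic") <- n_multi
  out
}

#' Write genotypes as a CSV dosage matrix
#'
#' @param M a [marker_matrix()].
#' @param path output CSV path.
#' @export
write_genotypes_csv <- function(M, path) {
  stopifnot(inherits(M, "marker_matrix"))
  df <- tibble::as_tibble(M$dosages, rownames = "genotype_id")
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Write genotypes as plain-text VCF
#'
#' Emits a minimal VCFv4.2 file with GT calls: dosage 0 as `0/0`, 1 as
#' `0/1`, 2 as `1/1`, missing as `./.`. Markers are placed on a single
#' synthetic contig at consecutive positions.
#'
#' @param M a [marker_matrix()] (integer dosages).
#' @param path output `.vcf` path.
#' @export
write_genotypes_vcf <- function(M, path) {
  stopifnot(inherits(M, "marker_matrix"))
  d <- M$dosages
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", M$ids), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(d)), function(j) {
    paste(c("1", j, colnames(d)[j], "A", "T", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed and package version of an analysis run.
#'
#' @param config named list of run parameters.
#' @param path output `.json` path.
#' @export
write_manifest <- function(config, path) {
  payload <- list(
    package = "diallelGP",
    version = as.character(utils::packageVersion("diallelGP")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    config_hash = rlang::hash(config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Generate an on-disk miniature study for tests and examples
#'
#' Writes a deterministic 6-parent, 10-cross, 200-marker, 2-year,
#' 2-treatment synthetic study: parental and hybrid genotypes (CSV dosage
#' and VCF), phenotypes (CSV) and a JSON manifest.
#'
#' @param dir output directory (created if absent).
#' @param seed integer seed.
#' @return invisibly, a named list of the file paths.
#' @export
make_fixtures <- function(dir, seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(n_parents = 6, n_markers = 200, n_crosses = 10,
                    n_years = 2, n_blocks = 2, seed = seed)
  study <- simulate_study(cfg, include_parents = TRUE)
  paths <- list(
    parents_csv = file.path(dir, "parents.csv"),
    parents_vcf = file.path(dir, "parents.vcf"),
    hybrids_csv = file.path(dir, "hybrids.csv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_genotypes_csv(study$parents, paths$parents_csv)
  write_genotypes_vcf(study$parents, paths$parents_vcf)
  write_genotypes_csv(study$hybrids, paths$hybrids_csv)
  write_phenotypes(study$phenotypes, paths$phenotypes)
  jsonlite::write_json(
    list(package = "diallelGP", seed = seed,
         n_parents = cfg$n_parents, n_markers = cfg$n_markers,
         n_crosses = cfg$n_crosses, n_years = cfg$n_years,
         treatments = cfg$treatments),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
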