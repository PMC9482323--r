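# Readers and writers for the delimited interchange formats. Everything is
# tab-delimited text with a header row; gene annotation travels as BED
# (0-based, half-open).

#' Read and write the delimited study tables
#'
#' All tables are tab-delimited with a header row. Methylation and genotype
#' tables carry one marker per row with metadata columns first
#' (`cpg_id, chrom, pos` and `snp_id, maf, imputation_quality,
#' is_multiallelic` respectively) followed by one column per sample. Weight
#' tables must provide `marker_id`, `effect`, `p`.
#'
#' @param path file path.
#' @param x the tibble to write.
#' @return the tibble read, or (for writers) the input invisibly.
#' @name study_io
NULL

#' @rdname study_io
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname study_io
#' @export
write_phenotypes <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname study_io
#' @export
read_methylation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("cpg_id", "chrom", "pos")
  if (!all(need %in% names(x))) {
    abort(sprintf("methylation table must start with columns %s.",
                  paste(need, collapse = ", ")),
          class = "epimediate_data_error")
  }
  x
}

#' @rdname study_io
#' @export
write_methylation <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname study_io
#' @export
read_weight_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("marker_id", "effect", "p")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(sprintf("weight table lacks required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "epimediate_data_error")
  }
  if (anyDuplicated(x$marker_id)) {
    abort("duplicate marker ids in weight table.",
          class = "epimediate_data_error")
  }
  if (any(x$p <= 0 | x$p > 1)) {
    abort("weight-table p-values must lie in (0, 1].",
          class = "epimediate_data_error")
  }
  x
}

#' @rdname study_io
#' @export
write_weight_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname study_io
#' @export
read_genotypes <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("snp_id", "maf", "imputation_quality", "is_multiallelic")
  if (!all(need %in% names(x))) {
    abort(sprintf("genotype table must start with columns %s.",
                  paste(need, collapse = ", ")),
          class = "epimediate_data_error")
  }
  x
}

#' @rdname study_io
#' @export
write_genotypes <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' Read and write gene annotation as BED
#'
#' BED is 0-based and half-open; at least four columns
#' (chrom, start, end, name) are required. Malformed lines raise an error
#' naming the line number.
#'
#' @param path file path.
#' @param genes tibble with `chrom`, `start`, `end`, `gene_id`.
#' @return tibble with `chrom`, `start`, `end`, `gene_id`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 4 || is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3])))) {
      abort(sprintf("malformed BED record at line %d of %s.", i, path),
            class = "epimediate_data_error")
    }
  }
  tibble::tibble(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.integer(vapply(parts, `[`, character(1), 2)),
    end = as.integer(vapply(parts, `[`, character(1), 3)),
    gene_id = vapply(parts, `[`, character(1), 4)
  )
}

#' @rdname read_bed
#' @export
write_bed <- function(genes, path) {
  stopifnot(all(c("chrom", "start", "end", "gene_id") %in% names(genes)))
  readr::write_tsv(genes[, c("chrom", "start", "end", "gene_id")], path,
                   col_names = FALSE)
  invisible(genes)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir directory containing the delimited study tables.
#' @return a list shaped like [simulate_study()]'s output (without the
#'   `config` element; the truth table is included when present).
#' @export
read_study <- function(dir) {
  need <- file.path(dir, c("phenotypes.tsv", "methylation_baseline.tsv"))
  if (!all(file.exists(need))) {
    abort(sprintf("`%s` is not a study directory (missing %s).", dir,
                  basename(need[!file.exists(need)])[1]),
          class = "epimediate_data_error")
  }
  wfiles <- list.files(dir, pattern = "^weights_.*\\.tsv$",
                       full.names = TRUE)
  weights <- lapply(wfiles, read_weight_table)
  names(weights) <- sub("^weights_(.*)\\.tsv$", "\\1", basename(wfiles))
  fu <- file.path(dir, "methylation_followup.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  structure(
    list(cohort = read_phenotypes(file.path(dir, "phenotypes.tsv")),
         methylation_baseline =
           read_methylation(file.path(dir, "methylation_baseline.tsv")),
         methylation_followup =
           if (file.exists(fu)) read_methylation(fu) else NULL,
         weight_tables = weights,
         annotation = if (file.exists(file.path(dir, "genes.bed"))) {
           read_bed(file.path(dir, "genes.bed"))
         } else NULL,
         genotypes = if (file.exists(file.path(dir, "genotypes.tsv"))) {
           read_genotypes(file.path(dir, "genotypes.tsv"))
         } else NULL,
         snp_weights = if (file.exists(file.path(dir,
                                                 "snp_weights.tsv"))) {
           read_weight_table(file.path(dir, "snp_weights.tsv"))
         } else NULL,
         truth = if (file.exists(truth_path)) {
           readr::read_tsv(truth_path, show_col_types = FALSE)
         } else NULL),
    class = "epimediate_study"
  )
}

#' Write every table of a simulated study to a directory
#'
#' Emits the phenotype table, both methylation matrices, all weight tables,
#' the gene annotation (BED), the genotype matrix with its weights, and the
#' ground-truth ledger as delimited text files.
#'
#' @param study an `epimediate_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return the vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "epimediate_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    phenotypes = file.path(dir, "phenotypes.tsv"),
    methylation_baseline = file.path(dir, "methylation_baseline.tsv"),
    methylation_followup = file.path(dir, "methylation_followup.tsv"),
    annotation = file.path(dir, "genes.bed"),
    genotypes = file.path(dir, "genotypes.tsv"),
    snp_weights = file.path(dir, "snp_weights.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_phenotypes(study$cohort, paths[["phenotypes"]])
  write_methylation(study$methylation_baseline,
                    paths[["methylation_baseline"]])
  write_methylation(study$methylation_followup,
                    paths[["methylation_followup"]])
  write_bed(study$annotation, paths[["annotation"]])
  write_genotypes(study$genotypes, paths[["genotypes"]])
  write_weight_table(study$snp_weights, paths[["snp_weights"]])
  readr::write_tsv(tibble::as_tibble(study$truth), paths[["truth"]])
  for (nm in names(study$weight_tables)) {
    p <- file.path(dir, paste0("weights_", nm, ".tsv"))
    write_weight_table(study$weight_tables[[nm]], p)
    paths[[paste0("weights_", nm)]] <- p
  }
  invisible(paths)
}
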