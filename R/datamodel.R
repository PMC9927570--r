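#' @importFrom data.table fread fwrite as.data.table
#' @importFrom stats pchisq predict sd setNames coef
#' @importFrom utils head
NULL

#' Construct a case-control genotype dataset
#'
#' Bundles a subjects x variants genotype matrix (alternate-allele counts
#' coded 0/1/2, `NA` for missing) with an aligned binary phenotype vector
#' (1 = case, 0 = control) and validates the pairing.
#'
#' @param genotypes Integer matrix, subjects in rows and variants in columns,
#'   with `dimnames` giving subject and variant identifiers. Values must be
#'   in `{0, 1, 2}` or `NA`.
#' @param phenotype Vector of 0/1 labels, one per subject (row of
#'   `genotypes`).
#' @param subject_ids,variant_ids Optional identifier vectors; default to the
#'   dimnames of `genotypes` or generated `S1..`, `V1..` labels.
#' @return An object of class `geno_dataset`: a list with elements
#'   `genotypes` (integer matrix with dimnames) and `phenotype` (named
#'   integer vector).
#' @export
geno_dataset <- function(genotypes, phenotype, subject_ids = NULL,
                         variant_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(genotypes)
    if (is.null(subject_ids)) subject_ids <- sprintf("S%d", seq_len(nrow(genotypes)))
  }
  if (is.null(variant_ids)) {
    variant_ids <- colnames(genotypes)
    if (is.null(variant_ids)) variant_ids <- sprintf("V%d", seq_len(ncol(genotypes)))
  }
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (anyDuplicated(variant_ids)) stop("duplicate variant ids")
  if (length(subject_ids) != nrow(genotypes))
    stop("subject_ids length does not match genotype rows")
  if (length(variant_ids) != ncol(genotypes))
    stop("variant_ids length does not match genotype columns")
  storage.mode(genotypes) <- "integer"
  bad <- which(!is.na(genotypes) & !(genotypes %in% 0:2))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(genotypes)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(genotypes)) + 1L
    stop(sprintf(
      "invalid genotype code %s for subject '%s', variant '%s' (must be 0, 1, 2 or NA)",
      genotypes[bad[1]], subject_ids[i], variant_ids[j]))
  }
  dimnames(genotypes) <- list(subject_ids, variant_ids)
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length does not match number of subjects")
  if (anyNA(phenotype) || !all(phenotype %in% 0:1))
    stop("phenotype must be coded 0 (control) / 1 (case) with no missing values")
  names(phenotype) <- subject_ids
  structure(list(genotypes = genotypes, phenotype = phenotype),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat(sprintf("geno_dataset: %d subjects x %d variants (%d cases / %d controls)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$phenotype == 1L), sum(x$phenotype == 0L)))
  nmiss <- sum(is.na(x$genotypes))
  if (nmiss) cat(sprintf("  %d missing genotype calls\n", nmiss))
  invisible(x)
}

#' @export
dim.geno_dataset <- function(x) dim(x$genotypes)

n_subjects <- function(dataset) nrow(dataset$genotypes)
n_variants <- function(dataset) ncol(dataset$genotypes)
subject_ids <- function(dataset) rownames(dataset$genotypes)
variant_ids <- function(dataset) colnames(dataset$genotypes)

#' Subset a dataset by subjects and/or variants
#'
#' @param dataset A [geno_dataset].
#' @param subjects,variants Index, logical or character selectors; `NULL`
#'   keeps everything.
#' @param check_classes If `TRUE` (default) require both phenotype classes to
#'   remain non-empty.
#' @return A [geno_dataset].
#' @export
subset_dataset <- function(dataset, subjects = NULL, variants = NULL,
                           check_classes = FALSE) {
  g <- dataset$genotypes
  ph <- dataset$phenotype
  if (!is.null(subjects)) {
    g <- g[subjects, , drop = FALSE]
    ph <- ph[subjects]
  }
  if (!is.null(variants)) g <- g[, variants, drop = FALSE]
  if (check_classes && length(unique(ph)) < 2L)
    stop("subset leaves a single phenotype class")
  geno_dataset(g, ph)
}

normalise_missing <- function(x) {
  x[x %in% c(-1)] <- NA
  x
}

#' Read a case-control genotype dataset from delimited text
#'
#' Supports a plain delimited layout (subjects in rows, one column per
#' variant named by its rsID, plus a phenotype column coded 0/1) and the
#' PLINK `.raw` dosage dialect (whitespace-delimited with leading
#' FID/IID/PAT/MAT/SEX/PHENOTYPE columns, phenotype coded 1 = control /
#' 2 = case). Missing genotypes may be written `NA` or `-1` and are stored
#' as `NA`.
#'
#' @param path Path to the genotype table.
#' @param format One of `"csv"`, `"tsv"`, `"plink_raw"`.
#' @param phenotype_col Name of the phenotype column for csv/tsv input.
#' @return A [geno_dataset].
#' @export
read_dataset <- function(path, format = c("csv", "tsv", "plink_raw"),
                         phenotype_col = "phenotype") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "plink_raw") return(read_plink_raw(path))
  sep <- if (format == "csv") "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, na.strings = c("NA", ""))
  if (!phenotype_col %in% names(dt))
    stop("phenotype column '", phenotype_col, "' not found in ", path)
  id_col <- intersect(c("subject_id", "IID", "id"), names(dt))[1]
  if (!is.na(id_col)) {
    sid <- as.character(dt[[id_col]])
    dt[[id_col]] <- NULL
  } else {
    sid <- sprintf("S%d", seq_len(nrow(dt)))
  }
  ph <- dt[[phenotype_col]]
  dt[[phenotype_col]] <- NULL
  g <- normalise_missing(as.matrix(dt))
  if (is.character(g)) stop("non-numeric genotype values in ", path)
  rownames(g) <- sid
  geno_dataset(g, ph)
}

read_plink_raw <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(lead %in% names(dt)[1:6]))
    stop("not a PLINK .raw file (expected leading columns ",
         paste(lead, collapse = "/"), "): ", path)
  ph <- dt$PHENOTYPE
  if (all(ph %in% c(1, 2))) ph <- ph - 1  # PLINK 1/2 -> 0/1
  if (anyNA(ph) || !all(ph %in% 0:1))
    stop("PLINK phenotype must be a complete 1/2 (or 0/1) binary vector")
  sid <- as.character(dt$IID)
  g <- dt[, setdiff(names(dt), lead), drop = FALSE]
  # .raw headers carry the counted allele as a suffix (rs123_A); strip it
  colnames(g) <- sub("_[A-Za-z0-9]+$", "", colnames(g))
  g <- normalise_missing(as.matrix(g))
  rownames(g) <- sid
  geno_dataset(g, ph)
}

#' Write a genotype or transformed-feature table to delimited text
#'
#' Writes subjects in rows with a `subject_id` column, one column per
#' variant, and a `phenotype` column when available, so that
#' [read_dataset()] (for `geno_dataset`) or [read_table()] (for plain
#' matrices) recovers the object exactly.
#'
#' @param x A [geno_dataset] or a numeric matrix with dimnames (for example
#'   a delta-degree transformed matrix).
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_table <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  if (inherits(x, "geno_dataset")) {
    df <- data.frame(subject_id = rownames(x$genotypes),
                     x$genotypes,
                     phenotype = unname(x$phenotype),
                     check.names = FALSE)
  } else {
    x <- as.matrix(x)
    df <- data.frame(subject_id = rownames(x), x, check.names = FALSE)
  }
  data.table::fwrite(df, path, sep = sep, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a plain feature matrix written by [write_table()]
#'
#' @param path Input path.
#' @param format `"csv"` or `"tsv"`.
#' @return A numeric matrix with subject ids as rownames.
#' @export
read_table <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  sid <- as.character(dt$subject_id)
  dt$subject_id <- NULL
  m <- as.matrix(dt)
  rownames(m) <- sid
  m
}
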