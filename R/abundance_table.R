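#' Construct an abundance table
#'
#' The canonical container for ASV/taxon count data: a non-negative integer
#' matrix in samples x taxa orientation with unique, aligned sample and taxon
#' identifiers. All downstream statistics (occupancy, diversity, neutral-model
#' fitting) consume this orientation.
#'
#' @param counts numeric matrix, samples as rows and taxa as columns. Values
#'   must be non-negative and exactly integral (a tolerance of 1e-8 is allowed
#'   before coercion to integer storage fails).
#' @param sample_ids character vector of unique sample identifiers; defaults to
#'   `rownames(counts)`.
#' @param taxon_ids character vector of unique taxon identifiers; defaults to
#'   `colnames(counts)`.
#' @return An object of class `abundance_table`: the counts matrix with
#'   dimnames set, carrying its identifiers in `rownames`/`colnames`.
#' @export
abundance_table <- function(counts, sample_ids = rownames(counts),
                            taxon_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != nrow(counts))
    stop("sample_ids length does not match number of rows")
  if (length(taxon_ids) != ncol(counts))
    stop("taxon_ids length does not match number of columns")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon identifiers: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts contain negative entries")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts contain non-integral entries")
  counts <- round(counts)
  storage.mode(counts) <- "double"   # doubles hold exact integers beyond .Machine$integer.max
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(counts, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa, %s total reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Sample identifiers of an abundance table
#' @param table an `abundance_table`
#' @return character vector
#' @export
sample_ids <- function(table) rownames(table)

#' Taxon identifiers of an abundance table
#' @param table an `abundance_table`
#' @return character vector
#' @export
taxon_ids <- function(table) colnames(table)

#' Per-sample read depths
#' @param table an `abundance_table`
#' @return named numeric vector of per-sample totals
#' @export
sample_depths <- function(table) rowSums(unclass(table))

as_matrix <- function(table) {
  m <- unclass(table)
  class(m) <- NULL
  attr(m, "class") <- NULL
  m
}

#' Read an abundance table from disk
#'
#' Supports plain TSV (first column = identifiers, header = the other margin's
#' identifiers) and BIOM (via the biomformat package). BIOM stores taxa as
#' rows; the table is transposed into the package's canonical samples x taxa
#' orientation on read. For TSV the on-disk orientation is declared with
#' `orientation`.
#'
#' @param path file path
#' @param format `"tsv"` or `"biom"`
#' @param orientation for TSV only: `"samples_as_rows"` (default) or
#'   `"taxa_as_rows"`
#' @return an [abundance_table()]
#' @export
read_abundance_table <- function(path,
                                 format = c("tsv", "biom"),
                                 orientation = c("samples_as_rows", "taxa_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))   # taxa x samples per BIOM convention
    return(abundance_table(t(m)))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("abundance TSV needs an identifier column plus data")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    bad <- which(is.na(suppressWarnings(as.numeric(m[, j]))) & !is.na(m[, j]))
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   ids[bad[1]], colnames(m)[j]))
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "taxa_as_rows") m <- t(m)
  abundance_table(m)
}

#' Write an abundance table as TSV
#'
#' Writes samples as rows with a leading `sample_id` column; re-reading with
#' [read_abundance_table()] round-trips counts and labels exactly.
#'
#' @param table an `abundance_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_abundance_table <- function(table, path) {
  df <- data.frame(sample_id = sample_ids(table),
                   as_matrix(table), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with a header row and one sample per line; the first column (or the
#' column named `sample_id`) holds sample identifiers. All other columns are
#' treated as categorical covariates and stored as character. A logical column
#' `is_negative_control` is recognised if present (values TRUE/FALSE, 1/0,
#' yes/no); otherwise every sample is taken to be a true sample.
#'
#' @param path file path
#' @return data.frame with rownames = sample ids, covariate columns as
#'   character, and a logical `is_negative_control` column
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- if ("sample_id" %in% names(df)) "sample_id" else names(df)[1]
  ids <- as.character(df[[idcol]])
  if (anyDuplicated(ids))
    stop("duplicate sample identifiers in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- df[, setdiff(names(df), idcol), drop = FALSE]
  rownames(df) <- ids
  for (nm in names(df)) {
    if (nm == "is_negative_control") {
      v <- df[[nm]]
      if (is.character(v)) v <- tolower(v) %in% c("true", "1", "yes", "t")
      df[[nm]] <- as.logical(v)
    } else {
      df[[nm]] <- as.character(df[[nm]])
    }
  }
  if (!"is_negative_control" %in% names(df))
    df$is_negative_control <- FALSE
  df
}

#' Read a 7-rank taxonomy table
#'
#' TSV with a taxon identifier column followed either by seven rank columns
#' (Kingdom..Species) or by a single semicolon-delimited lineage column.
#' SILVA-style rank prefixes (`k__`, `p__`, ..., `D_0__`) are stripped.
#' Unknown ranks are stored as empty strings, never dropped.
#'
#' @param path file path
#' @return data.frame with rownames = taxon ids and columns Kingdom, Phylum,
#'   Class, Order, Family, Genus, Species (character, "" = unassigned)
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate taxon identifiers in taxonomy")
  body <- df[, -1, drop = FALSE]
  ranks <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus", "Species")
  if (ncol(body) == 1) {
    parts <- strsplit(as.character(body[[1]]), ";", fixed = TRUE)
    m <- t(vapply(parts, function(p) {
      p <- trimws(p)
      length(p) <- 7
      p
    }, character(7)))
  } else {
    m <- as.matrix(body)[, seq_len(min(7, ncol(body))), drop = FALSE]
    if (ncol(m) < 7) m <- cbind(m, matrix("", nrow(m), 7 - ncol(m)))
  }
  m[is.na(m)] <- ""
  m <- sub("^[dkpcofgs]__", "", m)
  m <- sub("^D_[0-6]__", "", m)
  m <- trimws(m)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- ranks
  rownames(out) <- ids
  out
}
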