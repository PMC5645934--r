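## Tabular data model: validated containers and TSV readers/writers.
##
## One tabular dialect throughout: UTF-8, tab-separated, '.' decimal point.
## Matrices are written features-in-rows with a named id column first and
## sample ids as the header row.

#' Construct a validated count table
#'
#' A count table holds the number of reads mapped to each catalogue gene
#' (rows) in each sample (columns). Counts must be non-negative integers;
#' gene and sample identifiers must be unique.
#'
#' @param counts numeric matrix, genes x samples, with dimnames; or an
#'   unnamed matrix with `gene_ids`/`sample_ids` supplied.
#' @param gene_ids,sample_ids optional character vectors overriding dimnames.
#' @return an integer matrix of class `count_table`.
#' @export
count_table <- function(counts, gene_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("count_table requires gene and sample identifiers")
  if (length(gene_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions")
  .check_unique(gene_ids, "gene id")
  .check_unique(sample_ids, "sample id")
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-finite count at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  nonint <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(nonint) > 0)
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 gene_ids[nonint[1, 1]], sample_ids[nonint[1, 2]]))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, sample_ids)
  class(counts) <- c("count_table", class(counts))
  counts
}

.check_unique <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d) > 0)
    stop(sprintf("duplicated %s: %s", what,
                 paste(utils::head(d, 5), collapse = ", ")))
  invisible(TRUE)
}

#' Read / write a count table
#'
#' TSV with a header row of sample ids; the first column holds gene ids.
#' Reading validates the table (unique ids, non-negative integer counts);
#' writing round-trips bitwise for an integer matrix.
#'
#' @param path file path.
#' @return `read_count_table` returns a [count_table()].
#' @export
read_count_table <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  count_table(m)
}

#' @rdname read_count_table
#' @param x a count table.
#' @export
write_count_table <- function(x, path) {
  write_matrix_tsv(unclass(x), path, id_col = "gene_id")
}

#' Construct a relative-abundance matrix
#'
#' Feature x sample matrix of relative abundances in percent of the total
#' mapped signal (0-100). Column sums equal 100 for a complete matrix and
#' may be smaller after subsetting, never larger.
#'
#' @param values numeric matrix with dimnames, entries in \[0, 100\].
#' @param level abundance level: `"gene"`, `"species"`, `"genus"`, `"ko"` or
#'   `"vf_gene"`.
#' @return a numeric matrix of class `abundance_matrix` with a `level`
#'   attribute.
#' @export
abundance_matrix <- function(values,
                             level = c("gene", "species", "genus", "ko",
                                       "vf_gene")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(colnames(values)) ||
      (nrow(values) > 0 && is.null(rownames(values))))
    stop("abundance_matrix requires feature and sample identifiers")
  if (nrow(values) == 0) rownames(values) <- character(0)
  .check_unique(rownames(values), "feature id")
  .check_unique(colnames(values), "sample id")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 100 + 1e-6))
    stop("abundances must lie in [0, 100]")
  cs <- colSums(values)
  if (any(cs > 100 + 1e-6))
    stop(sprintf("column sum exceeds 100%% for sample '%s'",
                 colnames(values)[which.max(cs)]))
  structure(values, level = level,
            class = c("abundance_matrix", class(values)))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance matrix (%s level): %d features x %d samples\n",
              attr(x, "level"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE]))
  invisible(x)
}

#' Abundance level accessor
#' @param x an `abundance_matrix`.
#' @return the level label.
#' @export
abundance_level <- function(x) attr(x, "level")

#' Read / write an abundance matrix
#'
#' @param path file path.
#' @param level abundance level label, see [abundance_matrix()].
#' @return `read_abundance` returns an [abundance_matrix()].
#' @export
read_abundance <- function(path, level = "species") {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  abundance_matrix(m, level = level)
}

#' @rdname read_abundance
#' @param x an abundance matrix.
#' @export
write_abundance <- function(x, path) {
  write_matrix_tsv(unclass(x), path, id_col = "feature_id")
}

#' Construct sample metadata with the study's factor encoding
#'
#' Each sample carries a group label (`ADS`, `ALC` or `Control`) and two
#' binary clinical factors derived from it when absent: alcohol dependence
#' and liver cirrhosis. The encoding is fixed: ADS is (yes, no), ALC is
#' (yes, yes), Control is (no, no). Supplying factor columns that conflict
#' with this encoding is an error.
#'
#' @param df data.frame with columns `sample_id`, `group`, and optionally
#'   `dependence`, `cirrhosis` (\"yes\"/\"no\"), `gender` (\"F\"/\"M\"),
#'   `age` (years).
#' @return a data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata requires columns sample_id and group")
  df$sample_id <- as.character(df$sample_id)
  .check_unique(df$sample_id, "sample id")
  df$group <- as.character(df$group)
  bad <- setdiff(unique(df$group), c("ADS", "ALC", "Control"))
  if (length(bad) > 0)
    stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")))
  enc <- list(ADS = c("yes", "no"), ALC = c("yes", "yes"),
              Control = c("no", "no"))
  dep <- vapply(df$group, function(g) enc[[g]][1], character(1))
  cir <- vapply(df$group, function(g) enc[[g]][2], character(1))
  for (col in c("dependence", "cirrhosis")) {
    want <- if (col == "dependence") dep else cir
    if (col %in% names(df)) {
      got <- tolower(as.character(df[[col]]))
      if (!all(got %in% c("yes", "no")))
        stop(sprintf("column '%s' must be yes/no", col))
      if (!all(got == want))
        stop(sprintf("column '%s' conflicts with the group encoding", col))
    }
    df[[col]] <- unname(want)
  }
  if ("gender" %in% names(df)) {
    df$gender <- toupper(as.character(df$gender))
    if (!all(df$gender %in% c("F", "M")))
      stop("gender must be F or M")
  }
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read / write sample metadata
#' @param path file path.
#' @return `read_metadata` returns a [sample_metadata()] data.frame.
#' @export
read_metadata <- function(path) {
  sample_metadata(read_tsv(path))
}

#' @rdname read_metadata
#' @param x a `sample_metadata` data.frame.
#' @export
write_metadata <- function(x, path) {
  write_df_tsv(as.data.frame(x), path)
}

#' Construct a gene annotation table
#'
#' One row per catalogue gene: length in bp (for length normalization),
#' optional KO label and optional taxonomic labels. Every gene present in a
#' count table must be annotated; normalization needs each mapped gene's
#' length.
#'
#' @param df data.frame with columns `gene_id`, `length_bp` and optionally
#'   `ko`, `taxon_species`, `taxon_genus` (empty string or NA = unlabeled).
#' @return a data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(df)))
    stop("annotation requires columns gene_id and length_bp")
  df$gene_id <- as.character(df$gene_id)
  .check_unique(df$gene_id, "gene id")
  df$length_bp <- as.numeric(df$length_bp)
  if (any(!is.finite(df$length_bp)) || any(df$length_bp < 1))
    stop("gene lengths must be >= 1 bp")
  for (col in c("ko", "taxon_species", "taxon_genus"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read / write gene annotations
#' @param path file path.
#' @return `read_gene_annotation` returns a [gene_annotation()] data.frame.
#' @export
read_gene_annotation <- function(path) {
  gene_annotation(read_tsv(path))
}

#' @rdname read_gene_annotation
#' @param x a `gene_annotation` data.frame.
#' @export
write_gene_annotation <- function(x, path) {
  write_df_tsv(as.data.frame(x), path)
}

#' Construct a homology hit table
#'
#' Tabular homology hits of catalogue genes against virulence-factor
#' reference genes, in BLAST outfmt-6-like column order with an explicit
#' alignment-coverage column (fraction of the reference gene length).
#'
#' @param df data.frame with columns `catalogue_gene_id`, `vf_gene_id`,
#'   `evalue`, `percent_identity`, `coverage_fraction`.
#' @return a data.frame of class `hit_table`.
#' @export
hit_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("catalogue_gene_id", "vf_gene_id", "evalue", "percent_identity",
            "coverage_fraction")
  if (!all(need %in% names(df)))
    stop(sprintf("hit table requires columns: %s", paste(need, collapse = ", ")))
  df <- df[, need]
  df$catalogue_gene_id <- as.character(df$catalogue_gene_id)
  df$vf_gene_id <- as.character(df$vf_gene_id)
  for (col in c("evalue", "percent_identity", "coverage_fraction"))
    df[[col]] <- as.numeric(df[[col]])
  if (any(df$evalue < 0)) stop("e-values must be >= 0")
  if (any(df$percent_identity < 0 | df$percent_identity > 100))
    stop("percent identity must lie in [0, 100]")
  if (any(df$coverage_fraction < 0 | df$coverage_fraction > 1))
    stop("coverage fraction must lie in [0, 1]")
  rownames(df) <- NULL
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Read / write homology hit tables
#' @param path file path.
#' @return `read_hits` returns a [hit_table()] data.frame.
#' @export
read_hits <- function(path) {
  hit_table(read_tsv(path))
}

#' @rdname read_hits
#' @param x a `hit_table` data.frame.
#' @export
write_hits <- function(x, path) {
  write_df_tsv(as.data.frame(x), path)
}

## -- internal TSV plumbing ---------------------------------------------------

read_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

write_df_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_df_tsv(df, path)
}
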