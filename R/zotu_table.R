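#' ZOTU read-count tables
#'
#' A `zotu_table` holds non-negative integer read counts for zero-radius OTUs
#' (ZOTUs; exact amplicon sequence variants) across sequencing replicates or
#' individuals, together with one taxonomy lineage string per ZOTU. Rows are
#' always ZOTUs and columns are always samples.
#'
#' Lineage strings are ordered domain to genus and separated by `lineage_sep`
#' (default `","`); unassigned ranks are empty fields, and an optional
#' single-letter rank prefix (`d:`, `p:`, `c:`, `o:`, `f:`, `g:`) is tolerated
#' and stripped on parsing.
#'
#' @param counts non-negative integer matrix, ZOTUs in rows, samples in
#'   columns; both dimensions must be named.
#' @param taxonomy character vector of lineage strings, one per row of
#'   `counts` (recycled names are taken from `counts` row names when unnamed).
#' @return An object of class `zotu_table`: a list with elements `counts`
#'   (named integer matrix) and `taxonomy` (named character vector).
#' @examples
#' m <- matrix(c(0L, 5L, 20L, 0L), 2, 2,
#'             dimnames = list(c("Zotu1", "Zotu2"), c("s1", "s2")))
#' zt <- zotu_table(m, c("Bacteria,Proteobacteria,Gammaproteobacteria,,,",
#'                       "Bacteria,Firmicutes,Bacilli,,,"))
#' zt
#' @export
zotu_table <- function(counts, taxonomy) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    # an empty table (e.g. everything filtered away) is valid
    dimnames(counts) <- list(
      if (is.null(rownames(counts))) character(0) else rownames(counts),
      if (is.null(colnames(counts))) character(0) else colnames(counts))
  } else if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must have row (ZOTU) and column (sample) names")
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate ZOTU id: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  if (!is.numeric(counts))
    stop("'counts' must be numeric")
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative count at ZOTU '%s', sample '%s'",
                 rownames(counts)[neg[1L, 1L]], colnames(counts)[neg[1L, 2L]]))
  storage.mode(counts) <- "integer"
  taxonomy <- as.character(taxonomy)
  if (length(taxonomy) != nrow(counts))
    stop("'taxonomy' must have one entry per ZOTU")
  names(taxonomy) <- rownames(counts)
  structure(list(counts = counts, taxonomy = taxonomy), class = "zotu_table")
}

#' @export
print.zotu_table <- function(x, ...) {
  cat(sprintf("ZOTU count table: %d ZOTUs x %d samples, %s reads total\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.zotu_table <- function(x) dim(x$counts)

#' Total reads in a count table
#' @param x a [zotu_table()].
#' @return Total read count as a double.
#' @export
total_reads <- function(x) sum(as.numeric(x$counts))

#' Read a ZOTU count table from TSV
#'
#' Expects one row per ZOTU with an id column, a taxonomy column and one
#' numeric column per replicate. Column names are configurable through
#' `columns` so that differently-labelled deposited tables can be read without
#' editing the file.
#'
#' @param path path to a tab-separated table.
#' @param columns named list mapping the roles `zotu_id` and `taxonomy` to
#'   column names in the file.
#' @param sep field separator (default tab).
#' @return A [zotu_table()].
#' @export
read_zotu_table <- function(path,
                            columns = list(zotu_id = "zotu_id",
                                           taxonomy = "taxonomy"),
                            sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (role in c("zotu_id", "taxonomy")) {
    if (!columns[[role]] %in% names(df))
      stop("column '", columns[[role]], "' (", role, ") not found in ", path)
  }
  ids <- as.character(df[[columns$zotu_id]])
  tax <- as.character(df[[columns$taxonomy]])
  keep <- setdiff(names(df), c(columns$zotu_id, columns$taxonomy))
  counts <- as.matrix(df[, keep, drop = FALSE])
  rownames(counts) <- ids
  zotu_table(counts, tax)
}

#' Write a ZOTU count table as TSV
#'
#' @param x a [zotu_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zotu_table <- function(x, path) {
  df <- data.frame(zotu_id = rownames(x$counts),
                   taxonomy = unname(x$taxonomy),
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' The metadata maps each sequencing replicate to an individual host and host
#' species and flags negative controls. Required columns:
#' `replicate_id`, `individual_id`, `host_species`, `control_kind`
#' (`"extraction"`, `"pcr"` or `"none"`).
#'
#' @param path path to a CSV file.
#' @return A data frame of class `sample_metadata` with an added logical
#'   column `is_control`.
#' @export
read_sample_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Construct and validate sample metadata
#'
#' @param df data frame with columns `replicate_id`, `individual_id`,
#'   `host_species`, `control_kind`.
#' @return The validated data frame with class `sample_metadata` and a derived
#'   `is_control` column.
#' @export
sample_metadata <- function(df) {
  req <- c("replicate_id", "individual_id", "host_species", "control_kind")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$replicate_id))
    stop("duplicate replicate_id: ",
         df$replicate_id[duplicated(df$replicate_id)][1L])
  bad <- setdiff(unique(df$control_kind), c("extraction", "pcr", "none"))
  if (length(bad) > 0)
    stop("unknown control_kind: ", paste(bad, collapse = ", "))
  df$is_control <- df$control_kind != "none"
  smp <- df[!df$is_control, , drop = FALSE]
  tab <- table(smp$individual_id)
  if (any(tab != 2L))
    stop("each individual must have exactly 2 replicates; offending: ",
         paste(names(tab)[tab != 2L], collapse = ", "))
  nsp <- tapply(smp$host_species, smp$individual_id,
                function(z) length(unique(z)))
  if (any(nsp > 1L))
    stop("individual mapped to more than one host species: ",
         paste(names(nsp)[nsp > 1L], collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read a count table together with its metadata
#'
#' Reads both files and reconciles them: every metadata replicate must appear
#' in the table and vice versa.
#'
#' @param path path to the count TSV (see [read_zotu_table()]).
#' @param metadata_path path to the metadata CSV (see
#'   [read_sample_metadata()]).
#' @inheritParams read_zotu_table
#' @return A list with elements `table` ([zotu_table()]) and `metadata`
#'   (`sample_metadata`).
#' @export
read_zotu_data <- function(path, metadata_path,
                           columns = list(zotu_id = "zotu_id",
                                          taxonomy = "taxonomy"),
                           sep = "\t") {
  tab <- read_zotu_table(path, columns = columns, sep = sep)
  md <- read_sample_metadata(metadata_path)
  reconcile_metadata(tab, md)
  list(table = tab, metadata = md)
}

reconcile_metadata <- function(table, metadata) {
  in_tab <- colnames(table$counts)
  in_md <- metadata$replicate_id
  miss <- setdiff(in_md, in_tab)
  if (length(miss) > 0)
    stop("replicate '", miss[1L], "' in metadata is absent from the table")
  extra <- setdiff(in_tab, in_md)
  if (length(extra) > 0)
    stop("replicate '", extra[1L], "' in table is absent from the metadata")
  invisible(TRUE)
}

# Split lineage strings into a ZOTU x rank character matrix
# (domain, phylum, class, order, family, genus); optional "x:" prefixes are
# stripped; absent trailing ranks become "".
lineage_ranks <- function(taxonomy, lineage_sep = ",") {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  parts <- strsplit(as.character(taxonomy), lineage_sep, fixed = TRUE)
  out <- matrix("", nrow = length(parts), ncol = 6L,
                dimnames = list(names(taxonomy), ranks))
  for (i in seq_along(parts)) {
    p <- sub("^[dpcofg]:", "", trimws(parts[[i]]))
    n <- min(length(p), 6L)
    if (n > 0) out[i, seq_len(n)] <- p[seq_len(n)]
  }
  out
}
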