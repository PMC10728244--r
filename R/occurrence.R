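#' Binary ZOTU occurrence matrices
#'
#' An `occurrence` object is a binary ZOTU x individual incidence matrix plus
#' a host-species partition of the individuals. It is the substrate of all
#' richness and null-model statistics. All-zero rows and columns are dropped
#' at construction with a warning, so row sums and column sums are always
#' positive.
#'
#' @param presence matrix with entries in \{0, 1\} (ZOTU rows, individual
#'   columns), with dimnames.
#' @param species host species of each individual: a character or factor
#'   vector either named by individual id or in column order of `presence`.
#' @return An object of class `occurrence`: list with `presence` (integer 0/1
#'   matrix) and `species` (factor named by individual id).
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("z1", "z2"), c("i1", "i2")))
#' occurrence(m, c(i1 = "A", i2 = "B"))
#' @export
occurrence <- function(presence, species) {
  presence <- as.matrix(presence)
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop("'presence' must have row and column names")
  if (!all(presence %in% c(0, 1)))
    stop("'presence' must be binary (0/1)")
  storage.mode(presence) <- "integer"
  if (!is.null(names(species))) {
    miss <- setdiff(colnames(presence), names(species))
    if (length(miss) > 0)
      stop("no host species for individual '", miss[1L], "'")
    species <- species[colnames(presence)]
  } else {
    if (length(species) != ncol(presence))
      stop("'species' must have one entry per individual")
    names(species) <- colnames(presence)
  }
  zr <- rowSums(presence) == 0L
  zc <- colSums(presence) == 0L
  if (any(zr) || any(zc)) {
    warning(sprintf("dropping %d all-zero ZOTU row(s) and %d all-zero individual column(s)",
                    sum(zr), sum(zc)))
    presence <- presence[!zr, !zc, drop = FALSE]
    species <- species[colnames(presence)]
  }
  if (nrow(presence) == 0L || ncol(presence) == 0L)
    stop("occurrence matrix is empty after dropping all-zero rows/columns")
  species <- factor(as.character(species))
  names(species) <- colnames(presence)
  structure(list(presence = presence, species = species),
            class = "occurrence")
}

#' @export
print.occurrence <- function(x, ...) {
  cat(sprintf("Occurrence matrix: %d ZOTUs x %d individuals, %d host species (%s)\n",
              nrow(x$presence), ncol(x$presence), nlevels(x$species),
              paste(levels(x$species), collapse = ", ")))
  cat(sprintf("Fill: %d presences (%.1f%%)\n", sum(x$presence),
              100 * mean(x$presence)))
  invisible(x)
}

#' @export
dim.occurrence <- function(x) dim(x$presence)

#' Convert a per-individual count table to presence/absence
#'
#' Read counts are binarised as strictly positive after quality control: any
#' count threshold belongs to the QC cascade, not here. Columns of the table
#' must already be individuals (i.e. the replicate filter has been applied);
#' the host species of each individual is looked up in the metadata.
#'
#' @param table a [zotu_table()] with one column per individual.
#' @param metadata a `sample_metadata` object (see [read_sample_metadata()]).
#' @return An [occurrence()] object; all-zero rows/columns are dropped with a
#'   warning.
#' @export
to_occurrence <- function(table, metadata) {
  smp <- metadata[!metadata$is_control, , drop = FALSE]
  lut <- tapply(smp$host_species, smp$individual_id,
                function(z) unique(z)[1L])
  miss <- setdiff(colnames(table$counts), names(lut))
  if (length(miss) > 0)
    stop("individual '", miss[1L], "' not present in metadata")
  presence <- (table$counts > 0L) * 1L
  occurrence(presence, lut[colnames(presence)])
}

#' Relative read abundances
#'
#' Divides each column (individual) of a count table by its column total, so
#' RRAs of retained ZOTUs sum to one per individual.
#'
#' @param table a [zotu_table()].
#' @return A numeric matrix of class `rra` with values in `[0, 1]` and unit
#'   column sums.
#' @export
to_rra <- function(table) {
  tot <- colSums(table$counts)
  if (any(tot == 0))
    stop("zero-total column: ", colnames(table$counts)[tot == 0][1L])
  out <- sweep(table$counts, 2L, tot, "/")
  class(out) <- c("rra", "matrix")
  out
}
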