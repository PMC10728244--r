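#' Quality-control filter cascade for replicated ZOTU tables
#'
#' These functions implement the post-denoising cleaning steps for replicated
#' amplicon count tables: a negative-control filter, taxonomic collapsing,
#' a paired-replicate concordance filter, a proportional tag-jump filter, a
#' target-taxon filter and a rare-occurrence filter, applied in that order by
#' [run_cascade()] with a per-stage audit report.
#'
#' Stages operate by zeroing cells; rows or columns that become all-zero are
#' only dropped at the end of the cascade so the audit report can attribute
#' removals to stages. Boundary semantics are strict `<` everywhere: ties with
#' a threshold survive.
#'
#' @name qc_filters
NULL

#' Negative-control filter
#'
#' For each ZOTU, takes a summary (default the maximum, the most conservative
#' choice) of its counts across all extraction and PCR control replicates, and
#' zeroes any sample cell whose count is strictly smaller. Control columns are
#' dropped afterwards. With no control replicates the table is returned
#' unchanged with a warning.
#'
#' @param table a [zotu_table()] whose columns are replicates.
#' @param metadata matching `sample_metadata`.
#' @param stat how to aggregate a ZOTU's counts over the controls: `"max"`
#'   (default) or `"min"`.
#' @return A filtered [zotu_table()] without control columns.
#' @export
control_filter <- function(table, metadata, stat = c("max", "min")) {
  stat <- match.arg(stat)
  ctrl <- intersect(metadata$replicate_id[metadata$is_control],
                    colnames(table$counts))
  if (length(ctrl) == 0L) {
    warning("no control replicates present; control filter skipped")
    return(table)
  }
  keep <- setdiff(colnames(table$counts), ctrl)
  cmat <- table$counts[, ctrl, drop = FALSE]
  thr <- apply(cmat, 1L, stat)
  counts <- table$counts[, keep, drop = FALSE]
  counts[counts < thr] <- 0L   # thr recycled down columns: per-ZOTU threshold
  zotu_table(counts, table$taxonomy)
}

#' Collapse rows assigned to the same taxon
#'
#' Rows with an identical full lineage are merged by summing their counts; a
#' merged row takes the lineage string as its id, while rows whose lineage is
#' unique keep their original id. Rows unassigned at every rank are kept
#' distinct under their original ids.
#'
#' @inheritParams control_filter
#' @param lineage_sep separator inside lineage strings.
#' @return A [zotu_table()] with one row per distinct taxon.
#' @export
collapse_taxa <- function(table, lineage_sep = ",") {
  ranks <- lineage_ranks(table$taxonomy, lineage_sep)
  unassigned <- rowSums(ranks != "") == 0L
  key <- unname(table$taxonomy)
  singleton <- !(key %in% key[duplicated(key)])
  key[unassigned | singleton] <- rownames(table$counts)[unassigned | singleton]
  counts <- rowsum(table$counts, group = key, reorder = FALSE)
  tax <- tapply(unname(table$taxonomy), key, `[`, 1L)[rownames(counts)]
  zotu_table(counts, tax)
}

#' Paired-replicate concordance filter
#'
#' Each individual was amplified in two separately tagged reactions. Taxa with
#' a positive count in only one of the two replicates of an individual are
#' zeroed; surviving counts are summed over the pair, leaving one column per
#' individual.
#'
#' @inheritParams control_filter
#' @return A [zotu_table()] with one column per individual.
#' @export
replicate_filter <- function(table, metadata) {
  smp <- metadata[!metadata$is_control, , drop = FALSE]
  miss <- setdiff(smp$replicate_id, colnames(table$counts))
  if (length(miss) > 0)
    stop("replicate '", miss[1L], "' missing from table")
  inds <- unique(smp$individual_id)
  out <- matrix(0L, nrow(table$counts), length(inds),
                dimnames = list(rownames(table$counts), inds))
  for (ind in inds) {
    reps <- smp$replicate_id[smp$individual_id == ind]
    if (length(reps) != 2L)
      stop("individual '", ind, "' has ", length(reps),
           " replicates; exactly 2 required")
    a <- table$counts[, reps[1L]]
    b <- table$counts[, reps[2L]]
    s <- a + b
    s[a == 0L | b == 0L] <- 0L
    out[, ind] <- s
  }
  zotu_table(out, table$taxonomy)
}

#' Proportional tag-jump filter
#'
#' Zeroes any cell holding strictly less than `threshold` (default 0.05%) of
#' its sample's total reads, the standard mitigation for cross-sample tag
#' jumping. Denominators are the column totals at stage entry and are not
#' recomputed as cells are removed.
#'
#' @inheritParams control_filter
#' @param threshold minimum within-sample read proportion (default `5e-4`).
#' @return A filtered [zotu_table()].
#' @export
tag_jump_filter <- function(table, threshold = 0.0005) {
  counts <- table$counts
  tot <- colSums(counts)
  nz <- tot > 0
  if (any(nz)) {
    sub <- counts[, nz, drop = FALSE]
    prop <- sweep(sub, 2L, tot[nz], "/")
    sub[prop < threshold] <- 0L
    counts[, nz] <- sub
  }
  zotu_table(counts, table$taxonomy)
}

#' Target-taxon filter
#'
#' Removes rows whose domain is neither Bacteria nor Archaea and rows whose
#' class is Chloroplast. Rows with an unassigned domain are kept unless
#' `drop_unassigned_domain` is set.
#'
#' @inheritParams collapse_taxa
#' @param drop_unassigned_domain also remove rows with no domain assignment?
#' @return A filtered [zotu_table()].
#' @export
target_filter <- function(table, drop_unassigned_domain = FALSE,
                          lineage_sep = ",") {
  ranks <- lineage_ranks(table$taxonomy, lineage_sep)
  dom_ok <- ranks[, "domain"] %in% c("Bacteria", "Archaea")
  if (!drop_unassigned_domain)
    dom_ok <- dom_ok | ranks[, "domain"] == ""
  keep <- dom_ok & ranks[, "class"] != "Chloroplast"
  zotu_table(table$counts[keep, , drop = FALSE], table$taxonomy[keep])
}

#' Rare-occurrence filter
#'
#' Zeroes cells with a positive count strictly below `min_count`
#' (default 20 reads).
#'
#' @inheritParams control_filter
#' @param min_count minimum surviving read count per cell.
#' @return A filtered [zotu_table()].
#' @export
rare_filter <- function(table, min_count = 20) {
  counts <- table$counts
  counts[counts > 0L & counts < min_count] <- 0L
  zotu_table(counts, table$taxonomy)
}

n_occurrences <- function(table) sum(table$counts > 0L)

# taxon x individual pairs with a positive count in at least one replicate
n_union_occurrences <- function(table, metadata) {
  smp <- metadata[!metadata$is_control, , drop = FALSE]
  inds <- unique(smp$individual_id)
  tot <- 0L
  for (ind in inds) {
    reps <- intersect(smp$replicate_id[smp$individual_id == ind],
                      colnames(table$counts))
    if (length(reps) == 0L) next
    tot <- tot + sum(rowSums(table$counts[, reps, drop = FALSE] > 0L) > 0L)
  }
  tot
}

#' Run the full QC cascade
#'
#' Applies, in order: control filter, taxonomic collapsing, replicate filter,
#' tag-jump filter, target filter and rare filter (the tag-jump filter can
#' optionally run before replicate summation instead). All-zero rows and
#' columns are dropped at the end. A `filter_report` records reads retained
#' and positive cells (occurrences) removed per stage.
#'
#' @inheritParams control_filter
#' @inheritParams tag_jump_filter
#' @inheritParams rare_filter
#' @inheritParams target_filter
#' @param control_stat aggregation over control replicates, see
#'   [control_filter()].
#' @param tag_jump_before_replicate apply the tag-jump filter to replicate
#'   columns before replicate summation instead of after (default `FALSE`).
#' @return A list with elements `table` (final per-individual [zotu_table()])
#'   and `report` (a `filter_report` data frame).
#' @export
run_cascade <- function(table, metadata,
                        min_count = 20,
                        tag_jump = 0.0005,
                        drop_unassigned_domain = FALSE,
                        control_stat = "max",
                        tag_jump_before_replicate = FALSE,
                        lineage_sep = ",") {
  stages <- list()
  stages$control <- function(x) control_filter(x, metadata, stat = control_stat)
  stages$collapse <- function(x) collapse_taxa(x, lineage_sep = lineage_sep)
  if (tag_jump_before_replicate) {
    stages$tag_jump <- function(x) tag_jump_filter(x, threshold = tag_jump)
    stages$replicate <- function(x) replicate_filter(x, metadata)
  } else {
    stages$replicate <- function(x) replicate_filter(x, metadata)
    stages$tag_jump <- function(x) tag_jump_filter(x, threshold = tag_jump)
  }
  stages$target <- function(x)
    target_filter(x, drop_unassigned_domain = drop_unassigned_domain,
                  lineage_sep = lineage_sep)
  stages$rare <- function(x) rare_filter(x, min_count = min_count)

  rep_stage <- data.frame(stage = "input",
                          reads = total_reads(table),
                          occurrences_removed = 0,
                          stringsAsFactors = FALSE)
  cur <- table
  for (nm in names(stages)) {
    # the replicate stage merges column pairs and the control stage drops
    # control columns; count so that neither mechanical change is booked
    # as an occurrence removal
    occ_before <- if (nm == "replicate") {
      n_union_occurrences(cur, metadata)
    } else if (nm == "control") {
      smp_cols <- intersect(colnames(cur$counts),
                            metadata$replicate_id[!metadata$is_control])
      sum(cur$counts[, smp_cols, drop = FALSE] > 0L)
    } else n_occurrences(cur)
    cur <- stages[[nm]](cur)
    rep_stage <- rbind(rep_stage, data.frame(
      stage = nm,
      reads = total_reads(cur),
      occurrences_removed = max(occ_before - n_occurrences(cur), 0),
      stringsAsFactors = FALSE))
  }
  keep_r <- rowSums(cur$counts) > 0L
  keep_c <- colSums(cur$counts) > 0L
  final <- zotu_table(cur$counts[keep_r, keep_c, drop = FALSE],
                      cur$taxonomy[keep_r])
  report <- structure(rep_stage,
                      initial_reads = rep_stage$reads[1L],
                      final_reads = total_reads(final),
                      dropped_zotus = sum(!keep_r),
                      dropped_individuals = sum(!keep_c),
                      class = c("filter_report", "data.frame"))
  list(table = final, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("QC filter cascade report\n")
  df <- as.data.frame(x)
  df$reads <- format(df$reads, big.mark = ",")
  print(df, row.names = FALSE)
  cat(sprintf("Dropped at end: %d all-zero ZOTUs, %d empty individuals\n",
              attr(x, "dropped_zotus"), attr(x, "dropped_individuals")))
  invisible(x)
}

#' Serialise a filter report as JSON
#'
#' @param report a `filter_report` from [run_cascade()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  obj <- list(stages = as.data.frame(report),
              initial_reads = attr(report, "initial_reads"),
              final_reads = attr(report, "final_reads"),
              dropped_zotus = attr(report, "dropped_zotus"),
              dropped_individuals = attr(report, "dropped_individuals"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
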