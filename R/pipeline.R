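#' Run the complete occurrence-analysis pipeline
#'
#' Applies the QC cascade, converts to presence/absence, and runs the
#' richness summary, the fixed-fixed null-model comparison and the
#' community-level tests (dissimilarity, PERMANOVA, dispersion homogeneity,
#' core ZOTUs, class composition). Stage seeds are derived deterministically
#' from `seed`, so a rerun with the same inputs and seed is byte-identical.
#'
#' @param table replicate-level [zotu_table()].
#' @param metadata matching `sample_metadata`.
#' @param min_count,tag_jump,drop_unassigned_domain,control_stat QC cascade
#'   parameters, see [run_cascade()].
#' @param n_rand null-model randomizations (default 1000).
#' @param n_perm PERMANOVA permutations (default 10000).
#' @param B BCa bootstrap resamples (default 10000).
#' @param k number of core ZOTUs (default 50; capped at the ZOTU total).
#' @param mass HDCI mass (default 0.95).
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, writes
#'   `filter_report.json`, `richness_summary.tsv`, `null_summary.json`,
#'   `community.json` and `provenance.json`.
#' @return An object of class `sharedzotu_run`: list with `filter_report`,
#'   `occurrence`, `richness`, `null`, `community` (list with `dissimilarity`,
#'   `permanova`, `dispersion`, `core`, `class_composition`), `params`.
#' @export
run_pipeline <- function(table, metadata,
                         min_count = 20, tag_jump = 0.0005,
                         drop_unassigned_domain = FALSE,
                         control_stat = "max",
                         n_rand = 1000, n_perm = 10000, B = 10000,
                         k = 50, mass = 0.95, seed = 1,
                         out_dir = NULL) {
  seeds <- derive_seeds(seed, 4L)
  qc <- run_cascade(table, metadata, min_count = min_count,
                    tag_jump = tag_jump,
                    drop_unassigned_domain = drop_unassigned_domain,
                    control_stat = control_stat)
  occ <- to_occurrence(qc$table, metadata)
  rra <- to_rra(qc$table)
  rich <- richness_summary(occ, B = B, seed = seeds[1L])
  nullc <- null_compare(occ, n_rand = n_rand, mass = mass, seed = seeds[2L])
  diss <- sorensen(occ)
  perm <- permanova(diss, occ$species, n_perm = n_perm, seed = seeds[3L])
  disp <- dispersion_test(diss, occ$species)
  core <- core_zotus(rra[rownames(occ$presence), colnames(occ$presence),
                         drop = FALSE],
                     occ, k = min(k, nrow(occ$presence)))
  comp <- class_composition(rra[rownames(occ$presence), colnames(occ$presence),
                                drop = FALSE],
                            qc$table$taxonomy, occ)
  params <- list(min_count = min_count, tag_jump = tag_jump,
                 drop_unassigned_domain = drop_unassigned_domain,
                 control_stat = control_stat, n_rand = n_rand,
                 n_perm = n_perm, B = B, k = k, mass = mass, seed = seed,
                 stage_seeds = seeds)
  res <- structure(list(filter_report = qc$report, table = qc$table,
                        occurrence = occ, richness = rich, null = nullc,
                        community = list(dissimilarity = diss,
                                         permanova = perm,
                                         dispersion = disp,
                                         core = core,
                                         class_composition = comp),
                        params = params),
                   class = "sharedzotu_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

# deterministic small positive stage seeds derived from one master seed
derive_seeds <- function(seed, n) {
  (as.integer(seed) * 7919L + 104729L * seq_len(n)) %% 2147483629L + 1L
}

#' @export
print.sharedzotu_run <- function(x, ...) {
  cat("== Shared-ZOTU occurrence analysis ==\n\n")
  print(x$filter_report); cat("\n")
  print(x$occurrence); cat("\n")
  print(x$richness); cat("\n")
  print(x$null); cat("\n")
  print(x$community$permanova)
  print(x$community$dispersion)
  invisible(x)
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_filter_report(res$filter_report,
                      file.path(out_dir, "filter_report.json"))
  write.table(as.data.frame(res$richness),
              file.path(out_dir, "richness_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_null_summary(res$null, file.path(out_dir, "null_summary.json"))
  comm <- res$community
  jsonlite::write_json(
    list(permanova = comm$permanova[c("pseudo_F", "R2", "p", "n_perm",
                                      "g", "N")],
         dispersion = comm$dispersion[c("F", "df1", "df2", "p")],
         core_zotus = comm$core,
         class_composition = as.data.frame(as.table(
           comm$class_composition))),
    file.path(out_dir, "community.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  jsonlite::write_json(
    list(package = "sharedzotu",
         version = as.character(utils::packageVersion("sharedzotu")),
         params = res$params),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the pipeline from a configuration file or list
#'
#' The configuration (YAML file or list) names the input `table` and
#' `metadata` paths, an `out_dir`, and any parameter of [run_pipeline()].
#' A missing seed is generated and recorded in the provenance output.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return The `sharedzotu_run` object, invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("table", "metadata"))
    if (is.null(config[[field]]))
      stop("config is missing required field '", field, "'")
  dat <- read_zotu_data(config$table, config$metadata)
  if (is.null(config$seed)) config$seed <- sample.int(1e6, 1L)
  args <- config[intersect(names(config),
                           setdiff(names(formals(run_pipeline)),
                                   c("table", "metadata")))]
  invisible(do.call(run_pipeline,
                    c(list(table = dat$table, metadata = dat$metadata),
                      args)))
}
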