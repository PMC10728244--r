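#' Configuration for the synthetic faecal-microbiome generator
#'
#' Defines the study conditions emulated by [generate_occurrence()] and
#' [generate_counts()]: a small community of host species sampled as
#' individuals, a minority of "core" ZOTUs shared across species at moderate
#' per-species prevalence, and a majority of species-specific incidental
#' ZOTUs seen in about one individual each. One species can carry a surfeit
#' of specific ZOTUs (`specific_excess`), emulating a host with an excess of
#' incidental taxa. Counts are generated on top of the occupancy layer with
#' lognormal sequencing depths, Dirichlet-style within-sample abundance
#' weights (cores drawn with a larger gamma shape, so cores tend to dominate
#' reads), paired technical replicates whose discrepancy is governed by
#' `replicate_cv`, and negative controls receiving low-level contamination.
#'
#' Default dimensions are kept small (4 species x 10 individuals, ~400 ZOTUs)
#' so that complete analyses run in seconds; `paper_scale = TRUE` switches to
#' the full field-study dimensions (48/46/46/45 individuals, ~1512 ZOTUs)
#' with per-species prevalences rescaled so that mean incidences stay in the
#' same range (shared ZOTUs ~3-4.5 individuals, specific ZOTUs ~1).
#'
#' @param n_species number of host species.
#' @param individuals_per_species scalar or per-species vector.
#' @param n_core number of shared core ZOTUs.
#' @param core_prevalence range (length 2) of per-ZOTU-per-species presence
#'   probabilities for cores.
#' @param core_prevalence_mode `"per_species"` (default) draws an independent
#'   prevalence for every core ZOTU x species pair, giving cores mild host
#'   affinities as seen in field data; `"shared"` draws one prevalence per
#'   core ZOTU used for every species, which (with `n_specific = 0`) yields a
#'   community with no species structure at all, i.e. one drawn from the
#'   hypothesis the fixed-fixed null model tests.
#' @param n_specific number of species-specific ZOTUs per species.
#' @param specific_prevalence presence probability of a specific ZOTU within
#'   its species; default `NULL` means `1 / N_s` (expected incidence 1).
#' @param specific_excess multiplier on `n_specific` for `excess_species`.
#' @param excess_species index of the species carrying the excess.
#' @param read_depth_log_mean,read_depth_log_sd lognormal parameters of the
#'   per-individual total read depth.
#' @param replicate_cv coefficient of variation of the per-replicate gamma
#'   multipliers; the default (0.5) is calibrated so the median paired
#'   replicate read-count discrepancy is about 50%.
#' @param dirichlet_shape_core,dirichlet_shape_specific gamma shapes of the
#'   within-sample abundance weights.
#' @param n_extraction_controls,n_pcr_controls numbers of control replicates.
#' @param control_contamination_rate per-cell probability that a ZOTU leaks
#'   into a control replicate.
#' @param n_contaminants number of contaminant-only ZOTUs (present in
#'   controls and sporadically in samples, absent from the occupancy truth).
#' @param empty what to do with ZOTUs that receive no presence: `"drop"`
#'   (default) or `"resample"`.
#' @param paper_scale use the full field-study dimensions (see Details).
#' @param seed default seed used by the generators when none is passed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 4,
                             individuals_per_species = 10,
                             n_core = 80,
                             core_prevalence = c(0.05, 0.5),
                             core_prevalence_mode = c("per_species", "shared"),
                             n_specific = 80,
                             specific_prevalence = NULL,
                             specific_excess = 1,
                             excess_species = 1,
                             read_depth_log_mean = log(56000),
                             read_depth_log_sd = 0.5,
                             replicate_cv = 0.5,
                             dirichlet_shape_core = 4,
                             dirichlet_shape_specific = 1,
                             n_extraction_controls = 2,
                             n_pcr_controls = 2,
                             control_contamination_rate = 0.01,
                             n_contaminants = 5,
                             empty = c("drop", "resample"),
                             paper_scale = FALSE,
                             seed = NULL) {
  empty <- match.arg(empty)
  core_prevalence_mode <- match.arg(core_prevalence_mode)
  if (paper_scale) {
    if (missing(individuals_per_species))
      individuals_per_species <- c(48, 46, 46, 45)
    if (missing(n_core)) n_core <- 600
    if (missing(n_specific)) n_specific <- 228
    if (missing(core_prevalence))
      core_prevalence <- c(0.05, 0.5) * 10 / mean(individuals_per_species)
  }
  if (length(individuals_per_species) == 1L)
    individuals_per_species <- rep(individuals_per_species, n_species)
  stopifnot(length(individuals_per_species) == n_species,
            n_species >= 2, all(individuals_per_species >= 2),
            all(core_prevalence >= 0 & core_prevalence <= 1),
            specific_excess >= 0, excess_species %in% seq_len(n_species))
  cfg <- list(n_species = n_species,
              individuals_per_species = individuals_per_species,
              n_core = n_core, core_prevalence = core_prevalence,
              core_prevalence_mode = core_prevalence_mode,
              n_specific = n_specific,
              specific_prevalence = specific_prevalence,
              specific_excess = specific_excess,
              excess_species = excess_species,
              read_depth_log_mean = read_depth_log_mean,
              read_depth_log_sd = read_depth_log_sd,
              replicate_cv = replicate_cv,
              dirichlet_shape_core = dirichlet_shape_core,
              dirichlet_shape_specific = dirichlet_shape_specific,
              n_extraction_controls = n_extraction_controls,
              n_pcr_controls = n_pcr_controls,
              control_contamination_rate = control_contamination_rate,
              n_contaminants = n_contaminants,
              empty = empty, paper_scale = paper_scale, seed = seed)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic occurrence matrix with ground truth
#'
#' Presence is sampled independently per ZOTU x individual: core ZOTUs get a
#' per-species probability drawn uniformly from `core_prevalence`, specific
#' ZOTUs occur only within their own species at `specific_prevalence`.
#' Deterministic for a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return A list with `occurrence` (an [occurrence()] object) and `truth`
#'   (data frame with `zotu_id`, `class` ("core"/"specific"), `species`,
#'   plus attributes `probs` and `true_richness`).
#' @export
generate_occurrence <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  S <- config$n_species
  ns <- config$individuals_per_species
  sp_names <- paste0("sp", seq_len(S))
  species <- rep(sp_names, ns)
  ind_ids <- unlist(lapply(seq_len(S), function(s)
    sprintf("%s_i%02d", sp_names[s], seq_len(ns[s]))))
  names(species) <- ind_ids
  n_spec <- rep(config$n_specific, S)
  n_spec[config$excess_species] <-
    round(n_spec[config$excess_species] * config$specific_excess)
  zotu_ids <- c(sprintf("core%04d", seq_len(config$n_core)),
                unlist(lapply(seq_len(S), function(s)
                  sprintf("%s_spec%04d", sp_names[s], seq_len(n_spec[s])))))
  truth <- data.frame(
    zotu_id = zotu_ids,
    class = rep(c("core", "specific"), c(config$n_core, sum(n_spec))),
    species = c(rep(NA_character_, config$n_core), rep(sp_names, n_spec)),
    stringsAsFactors = FALSE)
  spv <- if (is.null(config$specific_prevalence)) 1 / ns else
    rep(config$specific_prevalence, length.out = S)
  # per-ZOTU x species presence probabilities
  probs <- matrix(0, length(zotu_ids), S, dimnames = list(zotu_ids, sp_names))
  ncore <- config$n_core
  if (ncore > 0) {
    if (identical(config$core_prevalence_mode, "shared")) {
      p1 <- runif(ncore, config$core_prevalence[1L], config$core_prevalence[2L])
      probs[seq_len(ncore), ] <- matrix(p1, ncore, S)
    } else {
      probs[seq_len(ncore), ] <- runif(ncore * S, config$core_prevalence[1L],
                                       config$core_prevalence[2L])
    }
  }
  for (s in seq_len(S)) {
    sel <- !is.na(truth$species) & truth$species == sp_names[s]
    probs[sel, s] <- spv[s]
  }
  draw <- function() {
    p_cell <- probs[, match(species, sp_names), drop = FALSE]
    matrix(rbinom(length(p_cell), 1L, p_cell), nrow = nrow(probs),
           dimnames = list(zotu_ids, ind_ids))
  }
  pres <- draw()
  if (config$empty == "resample") {
    for (rep_i in 1:50) {
      zero <- rowSums(pres) == 0L
      if (!any(zero)) break
      p_cell <- probs[zero, match(species, sp_names), drop = FALSE]
      pres[zero, ] <- matrix(rbinom(length(p_cell), 1L, p_cell),
                             nrow = sum(zero))
    }
  }
  keep <- rowSums(pres) > 0L
  if (!any(keep)) stop("configuration yielded an empty occurrence matrix")
  occ <- suppressWarnings(occurrence(pres[keep, , drop = FALSE], species))
  truth <- truth[truth$zotu_id %in% rownames(occ$presence), , drop = FALSE]
  attr(truth, "probs") <- probs
  attr(truth, "true_richness") <- length(zotu_ids)
  list(occurrence = occ, truth = truth)
}

# weighted lineage pool used for synthetic taxonomy; each ZOTU gets its own
# genus label so taxonomic collapsing keeps distinct ZOTUs distinct (as in
# post-assignment tables where near-identical variants were already merged)
synthetic_lineage <- function(ids) {
  classes <- c("Gammaproteobacteria", "Bacilli", "Alphaproteobacteria",
               "Betaproteobacteria", "Actinobacteria", "Mollicutes",
               "Negativicutes", "Sphingobacteriia", "Cytophagia")
  phyla <- c("Proteobacteria", "Firmicutes", "Proteobacteria",
             "Proteobacteria", "Actinobacteria", "Tenericutes",
             "Firmicutes", "Bacteroidetes", "Bacteroidetes")
  w <- c(0.45, 0.20, 0.10, 0.07, 0.07, 0.04, 0.03, 0.02, 0.02)
  n <- length(ids)
  k <- sample.int(length(classes), n, replace = TRUE, prob = w)
  sprintf("Bacteria,%s,%s,,,Genus_%s", phyla[k], classes[k], ids)
}

#' Generate replicated counts (and controls) on top of an occurrence matrix
#'
#' Each individual gets a lognormal total read depth split evenly over its
#' two replicates; within-sample expected shares are Dirichlet-weighted over
#' the present ZOTUs (cores with a larger gamma shape); each replicate draws
#' multinomial counts with an independent per-ZOTU gamma multiplier of
#' coefficient of variation `replicate_cv`. Extraction and PCR control
#' replicates receive Poisson contamination at `control_contamination_rate`,
#' and `n_contaminants` contaminant-only ZOTUs appear in controls and
#' sporadically (at low counts) in sample replicates.
#'
#' @inheritParams generate_occurrence
#' @param occ an [occurrence()] object (typically from
#'   [generate_occurrence()]).
#' @param truth optional ground-truth data frame (used to give core ZOTUs
#'   their larger abundance shape); without it all ZOTUs use the specific
#'   shape.
#' @return A list with `table` (a replicate-level [zotu_table()] including
#'   control columns) and `metadata` (`sample_metadata`).
#' @export
generate_counts <- function(config, occ, truth = NULL, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed + 1L)
  pres <- occ$presence
  inds <- colnames(pres)
  nz <- nrow(pres)
  shapes <- rep(config$dirichlet_shape_specific, nz)
  if (!is.null(truth)) {
    is_core <- rownames(pres) %in% truth$zotu_id[truth$class == "core"]
    shapes[is_core] <- config$dirichlet_shape_core
  }
  cv <- config$replicate_cv
  gshape <- if (cv > 0) 1 / cv^2 else Inf
  rep_ids <- as.vector(t(outer(inds, c("_r1", "_r2"), paste0)))
  counts <- matrix(0L, nz, length(rep_ids),
                   dimnames = list(rownames(pres), rep_ids))
  for (i in seq_along(inds)) {
    present <- which(pres[, i] > 0L)
    if (length(present) == 0L) next
    w <- rgamma(length(present), shape = shapes[present], rate = 1)
    w[w <= 0] <- 1e-12
    depth <- round(rlnorm(1L, config$read_depth_log_mean,
                          config$read_depth_log_sd) / 2)
    for (r in 1:2) {
      mult <- if (is.finite(gshape))
        rgamma(length(present), shape = gshape, rate = gshape) else 1
      pr <- w * mult
      counts[present, 2L * (i - 1L) + r] <-
        rmultinom(1L, size = depth, prob = pr / sum(pr))[, 1L]
    }
  }
  taxonomy <- synthetic_lineage(rownames(pres))
  names(taxonomy) <- rownames(pres)
  # control replicates + contaminant-only ZOTUs
  ctrl_ids <- c(if (config$n_extraction_controls > 0)
    sprintf("ctrl_ext%d", seq_len(config$n_extraction_controls)),
    if (config$n_pcr_controls > 0)
      sprintf("ctrl_pcr%d", seq_len(config$n_pcr_controls)))
  ncont <- config$n_contaminants
  if (ncont > 0) {
    cont_ids <- sprintf("contam%02d", seq_len(ncont))
    cont_tax <- c("Viridiplantae,Streptophyta,,,,",
                  "Bacteria,Cyanobacteria,Chloroplast,,,",
                  synthetic_lineage(cont_ids[-(1:2)][seq_len(max(ncont - 2L, 0L))])
                  )[seq_len(ncont)]
    names(cont_tax) <- cont_ids
    extra <- matrix(0L, ncont, ncol(counts),
                    dimnames = list(cont_ids, colnames(counts)))
    # sporadic low-count presence of contaminants in sample replicates
    hit <- matrix(rbinom(length(extra), 1L, 0.3), nrow = ncont)
    extra[hit == 1L] <- rpois(sum(hit), 8) + 1L
    counts <- rbind(counts, extra)
    taxonomy <- c(taxonomy, cont_tax)
  }
  if (length(ctrl_ids) > 0) {
    cmat <- matrix(0L, nrow(counts), length(ctrl_ids),
                   dimnames = list(rownames(counts), ctrl_ids))
    leak <- matrix(rbinom(length(cmat), 1L,
                          config$control_contamination_rate),
                   nrow = nrow(cmat))
    cmat[leak == 1L] <- rpois(sum(leak), 25) + 1L
    if (ncont > 0) {
      # contaminants are reliably in the controls, at counts exceeding
      # their sporadic sample-level counts
      sub <- matrix(rbinom(ncont * length(ctrl_ids), 1L, 0.9) *
                      (rpois(ncont * length(ctrl_ids), 40) + 1L),
                    nrow = ncont)
      cmat[nrow(cmat) - ncont + seq_len(ncont), ] <- sub
    }
    counts <- cbind(counts, cmat)
  }
  md <- data.frame(
    replicate_id = colnames(counts),
    individual_id = c(rep(inds, each = 2L), ctrl_ids),
    host_species = c(rep(as.character(occ$species), each = 2L),
                     rep(NA_character_, length(ctrl_ids))),
    control_kind = c(rep("none", 2L * length(inds)),
                     rep(c("extraction", "pcr"),
                         c(config$n_extraction_controls,
                           config$n_pcr_controls))),
    stringsAsFactors = FALSE)
  list(table = zotu_table(counts, taxonomy), metadata = sample_metadata(md))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_occurrence()] then
#' [generate_counts()].
#'
#' @inheritParams generate_occurrence
#' @return List with `table`, `metadata`, `occurrence`, `truth`.
#' @export
generate_dataset <- function(config, seed = config$seed) {
  og <- generate_occurrence(config, seed = seed)
  gc_ <- generate_counts(config, og$occurrence, og$truth, seed = seed)
  list(table = gc_$table, metadata = gc_$metadata,
       occurrence = og$occurrence, truth = og$truth)
}

#' Median paired-replicate read-count discrepancy
#'
#' For every ZOTU x individual cell where both technical replicates have a
#' positive count, computes `|c1 - c2| / mean(c1, c2)` and returns the
#' median — the statistic whose field value motivates presence/absence
#' analysis (about 50% in deeply multiplexed faecal data).
#'
#' @param table a replicate-level [zotu_table()].
#' @param metadata matching `sample_metadata`.
#' @return The median discrepancy (scalar in `[0, 2]`).
#' @export
replicate_discrepancy <- function(table, metadata) {
  smp <- metadata[!metadata$is_control, , drop = FALSE]
  inds <- unique(smp$individual_id)
  vals <- lapply(inds, function(ind) {
    reps <- smp$replicate_id[smp$individual_id == ind]
    a <- table$counts[, reps[1L]]
    b <- table$counts[, reps[2L]]
    sel <- a > 0L & b > 0L
    2 * abs(a[sel] - b[sel]) / (a[sel] + b[sel])
  })
  stats::median(unlist(vals))
}
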