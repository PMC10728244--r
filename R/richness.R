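#' Incidence frequency counts for one host species
#'
#' Restricts the occurrence matrix to one species' individuals and the ZOTUs
#' observed there, and counts the inputs of incidence-based richness
#' extrapolation: observed richness `S_obs`, the numbers of ZOTUs present in
#' exactly one (`Q1`) and exactly two (`Q2`) individuals, and the number of
#' individuals `N`.
#'
#' @param x an [occurrence()] object.
#' @param species one of `levels(x$species)`.
#' @return An object of class `incidence_freq`: list with `S_obs`, `Q1`,
#'   `Q2`, `N`, the per-ZOTU incidence vector `incidence`, and
#'   `singletons_per_individual` (needed for the jackknife variance).
#' @export
incidence_frequencies <- function(x, species) {
  if (!species %in% levels(x$species))
    stop("unknown species '", species, "'")
  sub <- x$presence[, x$species == species, drop = FALSE]
  inc <- rowSums(sub)
  sub <- sub[inc > 0L, , drop = FALSE]
  inc <- inc[inc > 0L]
  structure(list(S_obs = length(inc),
                 Q1 = sum(inc == 1L),
                 Q2 = sum(inc == 2L),
                 N = ncol(sub),
                 incidence = inc,
                 singletons_per_individual =
                   colSums(sub[inc == 1L, , drop = FALSE])),
            class = "incidence_freq")
}

#' Chao2 incidence-based richness estimate
#'
#' Bias-corrected Chao2 with the small-sample factor `(N-1)/N`:
#' `S_obs + ((N-1)/N) * Q1^2 / (2 Q2)` when `Q2 > 0` and
#' `S_obs + ((N-1)/N) * Q1 (Q1-1) / 2` when `Q2 = 0`, with the classical
#' Chao (1987) variance. Set `smallsample = FALSE` for the uncorrected form.
#'
#' @param freq an `incidence_freq` from [incidence_frequencies()].
#' @param smallsample apply the `(N-1)/N` correction (default `TRUE`)?
#' @return List with `estimate` and `se`.
#' @examples
#' f <- structure(list(S_obs = 10, Q1 = 4, Q2 = 2, N = 5),
#'                class = "incidence_freq")
#' chao2(f)$estimate  # 13.2
#' @export
chao2 <- function(freq, smallsample = TRUE) {
  with(freq, {
    if (N < 2L) stop("Chao2 requires at least 2 individuals")
    ssc <- if (smallsample) (N - 1) / N else 1
    if (Q2 > 0) {
      est <- S_obs + ssc * Q1^2 / (2 * Q2)
      r <- Q1 / Q2
      v <- Q1 * ssc * (0.5 + ssc * (1 + r / 4) * r) * r
    } else {
      est <- S_obs + ssc * Q1 * (Q1 - 1) / 2
      v <- ssc * (ssc * (Q1 * (2 * Q1 - 1)^2 / 4 - Q1^4 / est / 4) +
                    Q1 * (Q1 - 1) / 2)
    }
    list(estimate = est, se = sqrt(max(v, 0)))
  })
}

#' First-order jackknife richness estimate
#'
#' `S_obs + Q1 * (N-1)/N`, with the standard variance based on the counts of
#' singletons per individual.
#'
#' @inheritParams chao2
#' @return List with `estimate` and `se`.
#' @export
jackknife1 <- function(freq) {
  with(freq, {
    if (N < 2L) stop("jackknife1 requires at least 2 individuals")
    est <- S_obs + Q1 * (N - 1) / N
    v <- if (Q1 > 0 && !is.null(singletons_per_individual)) {
      jf <- table(singletons_per_individual[singletons_per_individual > 0])
      (sum(as.numeric(names(jf))^2 * jf) - Q1 / N) * (N - 1) / N
    } else 0
    list(estimate = est, se = sqrt(max(v, 0)))
  })
}

#' Sample-based ZOTU accumulation curves
#'
#' Cumulative count of distinct ZOTUs as one species' individuals are added
#' in random order, over `n_rand` random orderings, with the pointwise mean
#' curve.
#'
#' @inheritParams incidence_frequencies
#' @param n_rand number of random orderings (default 200).
#' @param seed optional integer seed.
#' @return An object of class `accumulation_curve`: list with `curves`
#'   (`n_rand` x `N` matrix), `mean` (length-`N` vector), `S_obs`, `species`.
#' @export
accumulation <- function(x, species, n_rand = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sub <- x$presence[, x$species == species, drop = FALSE]
  sub <- sub[rowSums(sub) > 0L, , drop = FALSE]
  n <- ncol(sub)
  curves <- matrix(0L, n_rand, n)
  for (r in seq_len(n_rand)) {
    ord <- sample.int(n)
    seen <- logical(nrow(sub))
    cum <- integer(n)
    tot <- 0L
    for (k in seq_len(n)) {
      new <- !seen & (sub[, ord[k]] > 0L)
      tot <- tot + sum(new)
      seen <- seen | new
      cum[k] <- tot
    }
    curves[r, ] <- cum
  }
  structure(list(curves = curves, mean = colMeans(curves),
                 S_obs = nrow(sub), species = species),
            class = "accumulation_curve")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("Accumulation curve for %s: %d individuals, S_obs = %d, %d randomizations\n",
              x$species, length(x$mean), x$S_obs, nrow(x$curves)))
  invisible(x)
}

#' @export
plot.accumulation_curve <- function(x, col = "grey70", mean_col = "red", ...) {
  n <- length(x$mean)
  graphics::matplot(seq_len(n), t(x$curves), type = "l", lty = 1,
                    col = grDevices::adjustcolor(col, alpha.f = 0.15),
                    xlab = "Individuals sampled", ylab = "Cumulative ZOTU richness",
                    main = x$species, ...)
  graphics::lines(seq_len(n), x$mean, col = mean_col, lwd = 2)
  invisible(x)
}

#' Species span of each ZOTU and unique/shared tallies
#'
#' A ZOTU's span is the set of host species in which it was detected; ZOTUs
#' with span size one are "unique" to that species, all others are "shared".
#'
#' @param x an [occurrence()] object with at least two species.
#' @return A list with `span_size` (integer per ZOTU), `unique` (logical per
#'   ZOTU), `owner` (species name for unique ZOTUs, `NA` otherwise), and
#'   `per_species` (data frame with `species`, `S_obs`, `n_unique`,
#'   `n_shared`, `prop_unique`).
#' @export
unique_shared <- function(x) {
  if (nlevels(x$species) < 2L) stop("need at least 2 host species")
  ind <- species_indicator(x)
  per_sp <- (x$presence %*% ind) > 0
  span <- as.integer(rowSums(per_sp))
  names(span) <- rownames(per_sp)
  uniq <- span == 1L
  owner <- rep(NA_character_, nrow(per_sp))
  owner[uniq] <- colnames(per_sp)[max.col(per_sp[uniq, , drop = FALSE])]
  per_species <- data.frame(
    species = colnames(per_sp),
    S_obs = as.integer(colSums(per_sp)),
    n_unique = vapply(colnames(per_sp),
                      function(s) sum(uniq & per_sp[, s]), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  per_species$n_shared <- per_species$S_obs - per_species$n_unique
  per_species$prop_unique <- per_species$n_unique / per_species$S_obs
  list(span_size = span, unique = uniq, owner = owner,
       per_species = per_species)
}

species_indicator <- function(x) {
  sp <- levels(x$species)
  ind <- matrix(0L, ncol(x$presence), length(sp),
                dimnames = list(colnames(x$presence), sp))
  ind[cbind(seq_along(x$species), as.integer(x$species))] <- 1L
  ind
}

#' Mean incidence of unique or shared ZOTUs with a BCa interval
#'
#' For ZOTUs of one class (unique to the species or shared with others),
#' the mean number of that species' individuals in which a ZOTU was detected,
#' with a BCa bootstrap interval resampling ZOTUs.
#'
#' @inheritParams incidence_frequencies
#' @param which `"unique"` or `"shared"`.
#' @param B bootstrap resamples (default 10000).
#' @param conf confidence level.
#' @param seed optional integer seed.
#' @return List with `mean`, `lower`, `upper`, `n_zotus`, `which`, `species`.
#' @export
mean_incidence <- function(x, species, which = c("unique", "shared"),
                           B = 10000, conf = 0.95, seed = NULL) {
  which <- match.arg(which)
  if (!is.null(seed)) set.seed(seed)
  us <- unique_shared(x)
  sub <- x$presence[, x$species == species, drop = FALSE]
  inc <- rowSums(sub)
  sel <- inc > 0L & (if (which == "unique") us$unique else !us$unique)
  if (sum(sel) == 0L)
    stop("no ", which, " ZOTUs observed for species '", species, "'")
  vals <- inc[sel]
  if (length(vals) < 2L) {
    return(list(mean = mean(vals), lower = mean(vals), upper = mean(vals),
                n_zotus = length(vals), which = which, species = species))
  }
  ci <- bca_ci(vals, B = B, conf = conf)
  list(mean = ci$estimate, lower = ci$lower, upper = ci$upper,
       n_zotus = length(vals), which = which, species = species)
}

#' Per-species richness summary table
#'
#' One row per host species: number of individuals, observed ZOTU richness,
#' number and proportion of species-unique ZOTUs, Chao2 and first-order
#' jackknife extrapolations with standard errors, and mean incidences of
#' unique and shared ZOTUs with BCa intervals.
#'
#' @param x an [occurrence()] object.
#' @param B bootstrap resamples for the BCa intervals.
#' @param conf confidence level.
#' @param seed optional integer seed.
#' @return A data frame of class `richness_summary`.
#' @export
richness_summary <- function(x, B = 10000, conf = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  us <- unique_shared(x)
  rows <- lapply(levels(x$species), function(sp) {
    f <- incidence_frequencies(x, sp)
    ch <- chao2(f)
    j1 <- jackknife1(f)
    mu <- mean_incidence(x, sp, "unique", B = B, conf = conf)
    ms <- mean_incidence(x, sp, "shared", B = B, conf = conf)
    psp <- us$per_species[us$per_species$species == sp, ]
    data.frame(species = sp, n = f$N, S_obs = f$S_obs,
               n_unique = psp$n_unique, prop_unique = psp$prop_unique,
               chao2 = ch$estimate, chao2_se = ch$se,
               jack1 = j1$estimate, jack1_se = j1$se,
               unique_mean = mu$mean, unique_lo = mu$lower,
               unique_hi = mu$upper,
               shared_mean = ms$mean, shared_lo = ms$lower,
               shared_hi = ms$upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("richness_summary", "data.frame")
  out
}

#' @export
print.richness_summary <- function(x, digits = 2, ...) {
  cat("Per-species ZOTU richness summary\n")
  df <- data.frame(
    species = x$species, n = x$n, richness = x$S_obs,
    prop.unique = round(x$prop_unique, digits),
    chao = sprintf("%.2f (%.2f)", x$chao2, x$chao2_se),
    jackknife = sprintf("%.2f (%.2f)", x$jack1, x$jack1_se),
    unique.incidence = sprintf("%.2f (%.2f-%.2f)", x$unique_mean,
                               x$unique_lo, x$unique_hi),
    shared.incidence = sprintf("%.2f (%.2f-%.2f)", x$shared_mean,
                               x$shared_lo, x$shared_hi),
    stringsAsFactors = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
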