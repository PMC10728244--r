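#' Presence/absence (Sorensen / binary Bray-Curtis) dissimilarity
#'
#' Pairwise dissimilarity between individuals,
#' `d = (A + B - 2J) / (A + B)`, where `A` and `B` are the ZOTU richnesses of
#' the two individuals and `J` the number of ZOTUs they share.
#'
#' @param x an [occurrence()] object with at least 2 individuals.
#' @return An object of class `pa_dissim`: list with `d` (symmetric matrix,
#'   zero diagonal, values in `[0, 1]`), `A` (per-individual richness) and
#'   `J` (pairwise shared-ZOTU count matrix).
#' @export
sorensen <- function(x) {
  if (ncol(x$presence) < 2L) stop("need at least 2 individuals")
  A <- colSums(x$presence)
  J <- crossprod(x$presence)
  AB <- outer(A, A, "+")
  d <- (AB - 2 * J) / AB
  diag(d) <- 0
  structure(list(d = d, A = A, J = J), class = "pa_dissim")
}

#' @export
print.pa_dissim <- function(x, ...) {
  cat(sprintf("Presence/absence dissimilarity over %d individuals (mean %.3f)\n",
              ncol(x$d), mean(x$d[lower.tri(x$d)])))
  invisible(x)
}

#' @export
as.matrix.pa_dissim <- function(x, ...) x$d

#' @export
as.dist.pa_dissim <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$d, diag = diag, upper = upper)

dist_matrix <- function(d) {
  if (inherits(d, "pa_dissim")) return(d$d)
  if (inherits(d, "dist")) return(as.matrix(d))
  as.matrix(d)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components and tests the pseudo-F statistic by random
#' permutation of group labels. `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `pseudo_F = (SS_among / (g-1)) / (SS_within / (N-g))`,
#' `R2 = SS_among / SS_total`, and
#' `p = (1 + #\{F* >= F\}) / (1 + n_perm)` (add-one convention).
#'
#' @param d a `pa_dissim`, `dist` or square matrix of dissimilarities.
#' @param groups factor (or named factor) of group labels, one per sample.
#' @param n_perm number of label permutations (default 10000).
#' @param seed optional integer seed.
#' @return An object of class `permanova`: list with `pseudo_F`, `R2`, `p`,
#'   `n_perm`, `g`, `N`, `SS` (total/among/within).
#' @export
permanova <- function(d, groups, n_perm = 10000, seed = NULL) {
  D <- dist_matrix(d)
  N <- nrow(D)
  if (!is.null(names(groups)) && !is.null(rownames(D)))
    groups <- groups[rownames(D)]
  groups <- factor(as.character(groups))
  if (length(groups) != N) stop("'groups' must have one label per sample")
  g <- nlevels(groups)
  D2 <- D^2
  ss_total <- sum(D2[lower.tri(D2)]) / N
  if (g < 2L) {
    return(structure(list(pseudo_F = NA_real_, R2 = 0, p = NA_real_,
                          n_perm = 0L, g = g, N = N,
                          SS = c(total = ss_total, among = 0,
                                 within = ss_total)),
                     class = "permanova"))
  }
  tab <- table(groups)
  if (any(tab < 2L)) stop("every group needs at least 2 members")
  ss_within_for <- function(lab) {
    sw <- 0
    for (lv in levels(lab)) {
      idx <- which(lab == lv)
      sw <- sw + sum(D2[idx, idx]) / (2 * length(idx))
    }
    sw
  }
  ss_w <- ss_within_for(groups)
  ss_a <- ss_total - ss_w
  f_of <- function(sw) {
    if (sw == 0) return(Inf)
    ((ss_total - sw) / (g - 1)) / (sw / (N - g))
  }
  f_obs <- f_of(ss_w)
  r2 <- if (ss_total > 0) ss_a / ss_total else 0
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    lab <- groups[sample.int(N)]
    if (f_of(ss_within_for(lab)) >= f_obs) count <- count + 1L
  }
  p <- (1 + count) / (1 + n_perm)
  structure(list(pseudo_F = f_obs, R2 = r2, p = p, n_perm = n_perm,
                 g = g, N = N,
                 SS = c(total = ss_total, among = ss_a, within = ss_w)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.4f, p = %.4g (%d permutations, %d groups, N = %d)\n",
              x$pseudo_F, x$R2, x$p, x$n_perm, x$g, x$N))
  invisible(x)
}

# Principal-coordinates embedding of a distance matrix, keeping axes with
# negative eigenvalues separately (real/imaginary split, no correction).
pcoa_axes <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  list(pos = sweep(e$vectors[, pos, drop = FALSE], 2L,
                   sqrt(e$values[pos]), "*"),
       neg = sweep(e$vectors[, neg, drop = FALSE], 2L,
                   sqrt(-e$values[neg]), "*"))
}

spatial_median <- function(xy, tol = 1e-8, maxit = 200) {
  m <- colMeans(xy)
  for (it in seq_len(maxit)) {
    dd <- sqrt(rowSums(sweep(xy, 2L, m)^2))
    dd[dd < tol] <- tol
    m_new <- colSums(xy / dd) / sum(1 / dd)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Homogeneity of multivariate dispersions
#'
#' Embeds the dissimilarity matrix by principal coordinates (keeping
#' negative-eigenvalue axes separately), computes each sample's distance to
#' its group centre as `sqrt(d_real^2 - d_imag^2)` (negative squared
#' distances clamped to zero with a warning), and applies a one-way ANOVA F
#' test with `(g-1, N-g)` degrees of freedom. The group centre is the
#' centroid by default; `type = "median"` uses the spatial (geometric)
#' median, computed per embedding block by Weiszfeld iteration.
#'
#' @inheritParams permanova
#' @param type `"centroid"` (default) or `"median"`.
#' @return An object of class `dispersion_test`: list with `F`, `df1`, `df2`,
#'   `p`, `group_means` (mean distance to centre per group) and `distances`.
#' @export
dispersion_test <- function(d, groups, type = c("centroid", "median")) {
  type <- match.arg(type)
  D <- dist_matrix(d)
  N <- nrow(D)
  if (!is.null(names(groups)) && !is.null(rownames(D)))
    groups <- groups[rownames(D)]
  groups <- factor(as.character(groups))
  if (length(groups) != N) stop("'groups' must have one label per sample")
  g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 members")
  ax <- pcoa_axes(D)
  d2 <- numeric(N)
  for (lv in levels(groups)) {
    idx <- which(groups == lv)
    centre <- function(xy) {
      if (ncol(xy) == 0L) return(numeric(0L))
      if (type == "centroid") colMeans(xy[idx, , drop = FALSE])
      else spatial_median(xy[idx, , drop = FALSE])
    }
    cp <- centre(ax$pos); cn <- centre(ax$neg)
    dp <- rowSums(sweep(ax$pos[idx, , drop = FALSE], 2L, cp)^2)
    dn <- if (ncol(ax$neg) > 0L)
      rowSums(sweep(ax$neg[idx, , drop = FALSE], 2L, cn)^2) else 0
    d2[idx] <- dp - dn
  }
  if (any(d2 < 0)) {
    warning(sum(d2 < 0), " negative squared distance(s) clamped to 0")
    d2[d2 < 0] <- 0
  }
  z <- sqrt(d2)
  zbar <- mean(z)
  zg <- tapply(z, groups, mean)
  ng <- tabulate(groups)
  ssb <- sum(ng * (zg - zbar)^2)
  ssw <- sum((z - zg[groups])^2)
  df1 <- g - 1L
  df2 <- N - g
  f <- (ssb / df1) / (ssw / df2)
  structure(list(F = f, df1 = df1, df2 = df2,
                 p = pf(f, df1, df2, lower.tail = FALSE),
                 group_means = c(zg), distances = z, type = type),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("Multivariate dispersion homogeneity (%s): F_%d,%d = %.3f, p = %.4g\n",
              x$type, x$df1, x$df2, x$F, x$p))
  cat("Mean distance to group centre:\n")
  print(round(x$group_means, 4))
  invisible(x)
}

#' Rank core ZOTUs by overall prevalence
#'
#' ZOTUs ranked by the fraction of all individuals in which they were
#' detected; prevalence ties are broken by total relative read abundance
#' (descending), then by id.
#'
#' @param rra an `rra` matrix from [to_rra()].
#' @param x an [occurrence()] object (defines prevalence).
#' @param k number of core ZOTUs to return (default 50).
#' @return Data frame with `zotu_id`, `prevalence`, `total_rra`, in rank
#'   order.
#' @export
core_zotus <- function(rra, x, k = 50) {
  if (k > nrow(x$presence)) stop("'k' exceeds the number of ZOTUs")
  prev <- rowMeans(x$presence)
  tot_rra <- rowSums(rra)[names(prev)]
  tot_rra[is.na(tot_rra)] <- 0
  ord <- order(-prev, -tot_rra, names(prev))
  out <- data.frame(zotu_id = names(prev)[ord],
                    prevalence = unname(prev[ord]),
                    total_rra = unname(tot_rra[ord]),
                    stringsAsFactors = FALSE)
  out[seq_len(k), , drop = FALSE]
}

#' Mean class-level composition per host species
#'
#' Sums relative read abundances by bacterial class within each individual
#' (ZOTUs without a class assignment pooled as `"unclassified"`), then
#' averages over each species' individuals. Shares are reported in percent
#' and sum to 100 per species.
#'
#' @param rra an `rra` matrix (ZOTU x individual).
#' @param taxonomy lineage strings named by ZOTU id (rows of `rra`).
#' @param partition host species per individual: named factor/character, or
#'   an [occurrence()] object whose `species` is used.
#' @param lineage_sep separator inside lineage strings.
#' @return Matrix of mean percentages, species x class.
#' @export
class_composition <- function(rra, taxonomy, partition, lineage_sep = ",") {
  if (inherits(partition, "occurrence")) partition <- partition$species
  partition <- partition[colnames(rra)]
  if (anyNA(partition)) stop("missing host species for some individuals")
  cls <- lineage_ranks(taxonomy[rownames(rra)], lineage_sep)[, "class"]
  cls[cls == ""] <- "unclassified"
  by_class <- rowsum(unclass(rra), group = cls)   # class x individual
  sp <- factor(as.character(partition))
  means <- t(rowsum(t(by_class), group = sp) / as.vector(table(sp)))
  t(means) * 100
}
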