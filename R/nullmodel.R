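#' Fixed-fixed randomization of a binary occurrence matrix
#'
#' Samples a binary matrix with exactly the row sums (per-ZOTU incidence) and
#' column sums (per-individual richness) of the input. The default
#' `"quasiswap"` method draws an independent matrix per call: an integer
#' matrix with the target marginals is filled by Patefield's algorithm
#' ([r2dtable()]) and reduced to binary by random 2x2 quasi-swap moves. The
#' `"curveball"` method instead starts from the observed matrix and applies
#' `burnin` random curveball trades (default `5 * max(nr, nc) * log(nr)`).
#'
#' @param x an [occurrence()] object or a binary matrix.
#' @param method `"quasiswap"` (default) or `"curveball"`.
#' @param burnin number of curveball trades (curveball method only).
#' @param seed optional integer seed.
#' @return An object of the same type as `x` with identical marginals.
#' @export
quasi_swap <- function(x, method = c("quasiswap", "curveball"),
                       burnin = NULL, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  is_occ <- inherits(x, "occurrence")
  m <- if (is_occ) x$presence else as.matrix(x)
  if (!all(m %in% c(0L, 1L))) stop("input matrix must be binary")
  storage.mode(m) <- "integer"
  out <- perm_matrix(m, method, burnin)
  dimnames(out) <- dimnames(m)
  if (is_occ) {
    res <- x
    res$presence <- out
    res
  } else out
}

perm_matrix <- function(m, method, burnin = NULL) {
  if (method == "quasiswap") {
    fill <- r2dtable(1L, rowSums(m), colSums(m))[[1L]]
    storage.mode(fill) <- "integer"
    cpp_quasiswap(fill)
  } else {
    if (is.null(burnin))
      burnin <- ceiling(5 * max(dim(m)) * log(nrow(m)))
    cpp_curveball(m + 0L, as.integer(burnin))  # m + 0L forces a copy
  }
}

#' Sharedness profile of an occurrence matrix
#'
#' Counts ZOTUs by the number of host species in which they occur
#' (`span_counts`, k = 1..S) and by the exact species combination
#' (`venn_counts`, one count per non-empty subset of species, labelled with
#' species names joined by `"&"`).
#'
#' @param x an [occurrence()] object.
#' @return An object of class `sharedness_profile`: list with `span_counts`,
#'   `venn_counts`, `total` and `species`.
#' @export
sharedness <- function(x) {
  ind <- species_indicator(x)
  per_sp <- (x$presence %*% ind) > 0
  prof <- sharedness_from_per_sp(per_sp, levels(x$species))
  prof
}

venn_subsets <- function(sp) {
  S <- length(sp)
  codes <- seq_len(2^S - 1L)
  labs <- vapply(codes, function(cd) {
    paste(sp[bitwAnd(cd, 2^(seq_len(S) - 1L)) > 0], collapse = "&")
  }, character(1L))
  sizes <- vapply(codes, function(cd) sum(bitwAnd(cd, 2^(seq_len(S) - 1L)) > 0),
                  integer(1L))
  list(codes = codes, labels = labs, sizes = sizes)
}

sharedness_from_per_sp <- function(per_sp, sp) {
  S <- length(sp)
  vs <- venn_subsets(sp)
  code <- as.integer(per_sp %*% 2^(seq_len(S) - 1L))
  venn <- tabulate(code, nbins = 2^S - 1L)
  names(venn) <- vs$labels
  span <- vapply(seq_len(S), function(k) sum(venn[vs$sizes == k]), numeric(1L))
  names(span) <- as.character(seq_len(S))
  structure(list(span_counts = span, venn_counts = venn,
                 total = sum(venn), species = sp),
            class = "sharedness_profile")
}

#' @export
print.sharedness_profile <- function(x, ...) {
  cat(sprintf("Sharedness of %d ZOTUs across %d host species\n",
              x$total, length(x$species)))
  cat("ZOTUs by number of species occupied:\n")
  print(x$span_counts)
  invisible(x)
}

#' Highest density continuous interval of an empirical sample
#'
#' The shortest contiguous interval `[x_(i), x_(j)]` over the sorted sample
#' containing at least `ceiling(mass * n)` points; width ties are broken by
#' the smallest lower endpoint.
#'
#' @param values numeric vector.
#' @param mass probability mass to cover (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' hdci(1:100)  # c(1, 95)
#' @export
hdci <- function(values, mass = 0.95) {
  values <- sort(as.numeric(values))
  n <- length(values)
  if (n == 0L) stop("empty input")
  k <- min(max(ceiling(mass * n), 1L), n)
  nwin <- n - k + 1L
  widths <- values[k:n] - values[seq_len(nwin)]
  i <- which.min(widths)  # leftmost minimum = smallest lower endpoint
  c(values[i], values[i + k - 1L])
}

#' Compare observed sharedness to a fixed-fixed null ensemble
#'
#' Randomizes the occurrence matrix `n_rand` times under fixed row and column
#' sums, recomputes the sharedness profile for each draw, and summarizes every
#' span and species-combination (Venn) statistic with its null mean, highest
#' density continuous interval, and a flag for whether the observed value
#' falls outside the interval. Span statistics are also reported as
#' proportions of the (fixed) ZOTU total.
#'
#' @param x an [occurrence()] object.
#' @param n_rand number of null matrices (default 1000).
#' @param mass interval mass (default 0.95).
#' @param seed optional integer seed (recorded in the result).
#' @param method randomization algorithm, see [quasi_swap()].
#' @return An object of class `null_compare`: a data frame with columns
#'   `statistic`, `type` (`"span"`/`"venn"`), `observed`, `null_mean`,
#'   `lower`, `upper`, `exceeds`, plus attributes `n_rand`, `seed`, `mass`,
#'   `method`, `total` and the raw `null_draws` matrix.
#' @export
null_compare <- function(x, n_rand = 1000, mass = 0.95, seed = NULL,
                         method = c("quasiswap", "curveball")) {
  method <- match.arg(method)
  if (n_rand < 1L) stop("n_rand must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  ind <- species_indicator(x)
  sp <- levels(x$species)
  obs <- sharedness(x)
  stat_names <- c(paste0("span_", names(obs$span_counts)),
                  names(obs$venn_counts))
  obs_vec <- c(obs$span_counts, obs$venn_counts)
  draws <- matrix(0, n_rand, length(obs_vec),
                  dimnames = list(NULL, stat_names))
  m <- x$presence
  for (r in seq_len(n_rand)) {
    perm <- perm_matrix(m, method)
    per_sp <- (perm %*% ind) > 0
    prof <- sharedness_from_per_sp(per_sp, sp)
    draws[r, ] <- c(prof$span_counts, prof$venn_counts)
  }
  ints <- apply(draws, 2L, hdci, mass = mass)
  out <- data.frame(
    statistic = stat_names,
    type = rep(c("span", "venn"),
               c(length(obs$span_counts), length(obs$venn_counts))),
    observed = unname(obs_vec),
    null_mean = unname(colMeans(draws)),
    lower = ints[1L, ],
    upper = ints[2L, ],
    stringsAsFactors = FALSE, row.names = NULL)
  out$exceeds <- out$observed < out$lower | out$observed > out$upper
  structure(out, n_rand = n_rand, seed = seed, mass = mass, method = method,
            total = obs$total, null_draws = draws,
            class = c("null_compare", "data.frame"))
}

#' @export
print.null_compare <- function(x, ...) {
  cat(sprintf("Fixed-fixed null model (%s, %d randomizations, %g%% HDCIs)\n",
              attr(x, "method"), attr(x, "n_rand"), 100 * attr(x, "mass")))
  df <- as.data.frame(x)
  df$null_mean <- round(df$null_mean, 2)
  df$flag <- ifelse(df$exceeds,
                    ifelse(df$observed > df$upper, "above", "below"), "")
  print(df[, c("statistic", "type", "observed", "null_mean", "lower",
               "upper", "flag")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.null_compare <- function(x, type = "span", ...) {
  df <- as.data.frame(x)[as.data.frame(x)$type == type, ]
  tot <- attr(x, "total")
  n <- nrow(df)
  ylim <- range(0, df$observed, df$upper) / tot
  graphics::plot(seq_len(n), df$null_mean / tot, ylim = ylim, pch = 16,
                 xaxt = "n", xlab = "", ylab = "Proportion of ZOTUs",
                 main = sprintf("Observed vs null (%s)", type), ...)
  graphics::axis(1, at = seq_len(n), labels = df$statistic, las = 2,
                 cex.axis = 0.7)
  graphics::arrows(seq_len(n), df$lower / tot, seq_len(n), df$upper / tot,
                   angle = 90, code = 3, length = 0.04)
  graphics::points(seq_len(n) + 0.15, df$observed / tot, pch = 17,
                   col = "red")
  invisible(x)
}

#' Serialise a null-model comparison as JSON
#'
#' @param x a `null_compare` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_null_summary <- function(x, path) {
  obj <- list(n_rand = attr(x, "n_rand"),
              seed = attr(x, "seed"),
              mass = attr(x, "mass"),
              method = attr(x, "method"),
              total_zotus = attr(x, "total"),
              statistics = as.data.frame(x))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
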