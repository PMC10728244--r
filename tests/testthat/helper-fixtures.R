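# Shared deterministic builders for the test suite.

# A small replicate-level table + metadata engineered so that every QC stage
# removes at least one occurrence: Zc falls to the control filter, Zm1/Zm2
# merge at the collapse stage, Zr is replicate-discordant, Zt is below the
# tag-jump proportion, Zx is non-target (plant), Zq is rare (< 20 reads).
# Zbig is a large backbone ZOTU keeping all columns populated.
qc_fixture <- function() {
  reps <- c("a_r1", "a_r2", "b_r1", "b_r2", "c_r1", "c_r2",
            "d_r1", "d_r2", "ctrl1")
  zotus <- c("Zbig", "Zc", "Zm1", "Zm2", "Zr", "Zt", "Zx", "Zq")
  counts <- matrix(0L, length(zotus), length(reps),
                   dimnames = list(zotus, reps))
  counts["Zbig", 1:8] <- 5000L
  counts["Zc", c("a_r1", "ctrl1")] <- c(30L, 50L)
  counts["Zm1", c("b_r1", "b_r2")] <- c(100L, 100L)
  counts["Zm2", c("b_r1", "b_r2")] <- c(50L, 60L)
  counts["Zr", "c_r1"] <- 500L
  counts["Zt", c("d_r1", "d_r2")] <- c(2L, 2L)
  counts["Zx", c("a_r1", "a_r2")] <- c(100L, 100L)
  counts["Zq", c("b_r1", "b_r2")] <- c(10L, 9L)
  tax <- c(Zbig = "Bacteria,Firmicutes,Bacilli,,,Genus_big",
           Zc   = "Bacteria,Proteobacteria,Gammaproteobacteria,,,Genus_c",
           Zm1  = "Bacteria,Firmicutes,Bacilli,,,Genus_m",
           Zm2  = "Bacteria,Firmicutes,Bacilli,,,Genus_m",
           Zr   = "Bacteria,Proteobacteria,Gammaproteobacteria,,,Genus_r",
           Zt   = "Bacteria,Proteobacteria,Gammaproteobacteria,,,Genus_t",
           Zx   = "Viridiplantae,Streptophyta,,,,",
           Zq   = "Bacteria,Proteobacteria,Gammaproteobacteria,,,Genus_q")
  md <- sample_metadata(data.frame(
    replicate_id = reps,
    individual_id = c("a", "a", "b", "b", "c", "c", "d", "d", "ctrl1"),
    host_species = c("A", "A", "A", "A", "B", "B", "B", "B", NA),
    control_kind = c(rep("none", 8), "extraction"),
    stringsAsFactors = FALSE))
  list(table = zotu_table(counts, tax), metadata = md)
}

# Random binary occurrence object with a species partition.
rand_occ <- function(nz = 60, ni = 12, S = 3, fill = 0.25, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(nz * ni, 1L, fill), nz, ni,
              dimnames = list(sprintf("z%03d", seq_len(nz)),
                              sprintf("i%02d", seq_len(ni))))
  sp <- rep(paste0("sp", seq_len(S)), length.out = ni)
  suppressWarnings(occurrence(m, stats::setNames(sp, colnames(m))))
}

# Exhaustive enumeration of all binary matrices with the given row and
# column sums (small cases only) -- the brute-force oracle for the
# fixed-fixed null model.
enum_fixed_fixed <- function(rs, cs) {
  nr <- length(rs)
  out <- list()
  m <- matrix(0L, nr, length(cs))
  rec <- function(i, rem) {
    if (i > nr) {
      if (all(rem == 0L)) out[[length(out) + 1L]] <<- m
      return(invisible(NULL))
    }
    if (rs[i] == 0L) {
      rec(i + 1L, rem)
      return(invisible(NULL))
    }
    cols <- which(rem > 0L)
    if (length(cols) < rs[i]) return(invisible(NULL))
    for (sel in utils::combn(cols, rs[i], simplify = FALSE)) {
      m[i, ] <<- 0L
      m[i, sel] <<- 1L
      rem2 <- rem
      rem2[sel] <- rem2[sel] - 1L
      rec(i + 1L, rem2)
    }
    m[i, ] <<- 0L
    invisible(NULL)
  }
  rec(1L, as.integer(cs))
  out
}

key_mat <- function(m) paste(m, collapse = "")

# Brute-force shortest-window HDCI used as an oracle for hdci().
hdci_brute <- function(values, mass = 0.95) {
  v <- sort(values)
  n <- length(v)
  k <- min(max(ceiling(mass * n), 1L), n)
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - k + 1L)) {
    w <- v[i + k - 1L] - v[i]
    if (w < best[1L]) best <- c(w, v[i], v[i + k - 1L])
  }
  best[2:3]
}
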