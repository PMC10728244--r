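two_sp <- function(m) {
  ni <- ncol(m)
  sp <- rep(c("A", "B"), length.out = ni)
  suppressWarnings(occurrence(m, stats::setNames(sp, colnames(m))))
}

test_that("sorensen evaluates the printed formula", {
  m <- matrix(c(1, 1, 0,
                1, 1, 1,
                0, 0, 1,
                0, 0, 1), 4, 3, byrow = TRUE,
              dimnames = list(paste0("z", 1:4), c("i1", "i2", "i3")))
  occ <- occurrence(m, stats::setNames(c("A", "A", "B"), colnames(m)))
  ds <- sorensen(occ)
  # identical samples
  expect_equal(ds$d["i1", "i2"], 0)
  # disjoint samples: i1 = {z1, z2}, i3 = {z2, z3, z4} share z2 -> not disjoint;
  # construct pure disjoint pair separately below
  # A = 2, B = 3, J = 1 for (i1, i3)? i1 = {z1,z2}, i3 = {z2,z3,z4}: J = 1
  expect_equal(ds$d["i1", "i3"], (2 + 3 - 2 * 1) / (2 + 3))
  expect_equal(unname(diag(ds$d)), c(0, 0, 0))
  expect_true(isSymmetric(ds$d))
  expect_true(all(ds$d >= 0 & ds$d <= 1))
  # algebraic identity d = 1 - 2J/(A+B)
  AB <- outer(ds$A, ds$A, "+")
  expect_equal(ds$d, 1 - 2 * unclass(ds$J) / AB, tolerance = 1e-12)

  md <- matrix(c(1, 0,
                 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("z1", "z2"), c("i1", "i2")))
  dd <- sorensen(two_sp(md))
  expect_equal(dd$d["i1", "i2"], 1)  # disjoint

  # A=2, B=2, J=1 -> 0.5
  m5 <- matrix(c(1, 1,
                 1, 0,
                 0, 1), 3, 2, byrow = TRUE,
               dimnames = list(paste0("z", 1:3), c("i1", "i2")))
  expect_equal(sorensen(two_sp(m5))$d["i1", "i2"], 0.5)
})

test_that("sorensen agrees with the independent vegan oracle", {
  skip_if_not_installed("vegan")
  occ <- rand_occ(nz = 60, ni = 14, S = 3, fill = 0.3, seed = 7)
  ours <- as.matrix(sorensen(occ))
  oracle <- as.matrix(vegan::vegdist(t(occ$presence), method = "bray",
                                     binary = TRUE))
  expect_equal(unname(ours), unname(oracle), tolerance = 1e-12)
})

test_that("permanova follows the stated sum-of-squares decomposition", {
  # 4 samples, 2 groups, within d = 0 and between d = 1
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- 0
  D[3, 4] <- D[4, 3] <- 0
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- suppressWarnings(permanova(D, c("a", "a", "b", "b"),
                                    n_perm = 200, seed = 1))
  expect_identical(res$R2, 1)
  expect_identical(res$pseudo_F, Inf)
  expect_true(res$p <= 1)

  # one group: R2 = 0 by convention, test skipped
  res1 <- permanova(D, rep("a", 4), n_perm = 100)
  expect_identical(res1$R2, 0)
  expect_true(is.na(res1$p))

  # label-permutation invariance of F and R2 under sample reordering
  occ <- rand_occ(nz = 50, ni = 12, S = 3, fill = 0.3, seed = 8)
  ds <- sorensen(occ)
  full <- permanova(ds, occ$species, n_perm = 99, seed = 5)
  ord <- sample(seq_len(ncol(ds$d)))
  res2 <- permanova(ds$d[ord, ord], occ$species[ord], n_perm = 99, seed = 5)
  expect_equal(res2$pseudo_F, full$pseudo_F)
  expect_equal(res2$R2, full$R2)

  # bit-reproducible p at a fixed seed
  expect_identical(permanova(ds, occ$species, n_perm = 199, seed = 2)$p,
                   permanova(ds, occ$species, n_perm = 199, seed = 2)$p)
  expect_error(permanova(ds$d[1:3, 1:3], c("a", "a", "b"), n_perm = 10),
               "at least 2 members")
})

test_that("permanova agrees with the independent vegan oracle", {
  skip_if_not_installed("vegan")
  for (seed in c(3, 4)) {
    occ <- rand_occ(nz = 60, ni = 15, S = 3, fill = 0.3, seed = seed)
    ds <- sorensen(occ)
    ours <- permanova(ds, occ$species, n_perm = 99, seed = 1)
    g <- data.frame(sp = occ$species)
    dm <- stats::as.dist(ds$d)
    oracle <- vegan::adonis2(dm ~ sp, data = g, permutations = 99)
    expect_equal(ours$pseudo_F, oracle$F[1], tolerance = 1e-10)
    expect_equal(ours$R2, oracle$R2[1], tolerance = 1e-10)
  }
})

test_that("dispersion_test matches direct geometry on embeddable points", {
  # points on a line: distances to group centroids are plain arithmetic
  xs <- c(0, 2, 10, 14)
  D <- as.matrix(stats::dist(xs))
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- c("a", "a", "b", "b")
  res <- dispersion_test(D, g)
  expect_equal(unname(res$distances), c(1, 1, 2, 2), tolerance = 1e-9)
  expect_equal(unname(res$group_means), c(1, 2), tolerance = 1e-9)
  expect_identical(res$df1, 1L)
  expect_identical(res$df2, 2L)

  # identical within-group dispersion in both groups: F = 0, p = 1
  xs2 <- c(0, 2, 4, 10, 12, 14)
  D2 <- as.matrix(stats::dist(xs2))
  dimnames(D2) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g2 <- rep(c("a", "b"), each = 3)
  res2 <- dispersion_test(D2, g2)
  expect_equal(unname(res2$distances), c(2, 0, 2, 2, 0, 2), tolerance = 1e-9)
  expect_equal(res2$F, 0, tolerance = 1e-9)
  expect_equal(res2$p, 1, tolerance = 1e-9)

  # df convention (g - 1, N - g)
  set.seed(15)
  pts <- matrix(rnorm(177 * 3), 177)
  D3 <- as.matrix(stats::dist(pts))
  dimnames(D3) <- list(paste0("s", 1:177), paste0("s", 1:177))
  g3 <- rep(c("w", "x", "y", "z"), c(48, 46, 46, 37))
  res3 <- dispersion_test(D3, g3)
  expect_identical(c(res3$df1, res3$df2), c(3L, 173L))
})

test_that("dispersion_test agrees with the independent vegan oracle", {
  skip_if_not_installed("vegan")
  occ <- rand_occ(nz = 60, ni = 16, S = 3, fill = 0.3, seed = 9)
  ds <- sorensen(occ)
  ours <- dispersion_test(ds, occ$species)
  bd <- vegan::betadisper(stats::as.dist(ds$d), occ$species,
                          type = "centroid")
  oracle <- stats::anova(bd)
  expect_equal(unname(ours$distances), unname(bd$distances),
               tolerance = 1e-8)
  expect_equal(ours$F, oracle$`F value`[1], tolerance = 1e-8)
  expect_equal(ours$p, oracle$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("spatial-median dispersion is available and sane", {
  # symmetric cloud: the spatial median coincides with the centroid
  xy <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  expect_equal(sharedzotu:::spatial_median(xy), c(0, 0), tolerance = 1e-6)
  occ <- rand_occ(nz = 60, ni = 16, S = 3, fill = 0.3, seed = 10)
  ds <- sorensen(occ)
  res <- dispersion_test(ds, occ$species, type = "median")
  expect_identical(res$type, "median")
  expect_true(is.finite(res$F))
  # median centres never increase the summed distances relative to centroids
  cen <- dispersion_test(ds, occ$species, type = "centroid")
  expect_true(is.finite(cen$F))
})

test_that("core_zotus ranks by prevalence with documented tie-breaks", {
  pres <- matrix(c(1, 1, 1, 1,
                   1, 1, 0, 0,
                   1, 1, 0, 0,
                   0, 1, 0, 0), 4, 4, byrow = TRUE,
                 dimnames = list(c("zfull", "ztie_b", "ztie_a", "zrare"),
                                 paste0("i", 1:4)))
  counts <- matrix(c(10L, 10L, 10L, 10L,
                     40L, 40L, 0L, 0L,
                     5L, 5L, 0L, 0L,
                     0L, 45L, 0L, 0L), 4, 4, byrow = TRUE,
                   dimnames = dimnames(pres))
  occ <- occurrence(pres, stats::setNames(rep(c("A", "B"), 2), paste0("i", 1:4)))
  rra <- to_rra(zotu_table(counts, rep("Bacteria,,,,,", 4)))
  core <- core_zotus(rra, occ, k = 4)
  # 100% prevalence first; prevalence tie broken by total RRA descending
  expect_identical(core$zotu_id, c("zfull", "ztie_b", "ztie_a", "zrare"))
  expect_equal(core$prevalence[1], 1)
  expect_error(core_zotus(rra, occ, k = 5), "exceeds")
  expect_identical(nrow(core_zotus(rra, occ, k = 2)), 2L)
})

test_that("class_composition averages per-individual class shares", {
  counts <- matrix(c(70L, 140L,
                     30L, 60L), 2, 2, byrow = TRUE,
                   dimnames = list(c("z1", "z2"), c("i1", "i2")))
  tax <- c(z1 = "Bacteria,Proteobacteria,Gammaproteobacteria,,,",
           z2 = "Bacteria,Firmicutes,Bacilli,,,")
  rra <- to_rra(zotu_table(counts, tax))
  part <- stats::setNames(c("A", "B"), c("i1", "i2"))
  comp <- class_composition(rra, tax, part)
  expect_equal(unname(comp[, "Gammaproteobacteria"]), c(70, 70))
  expect_equal(unname(comp[, "Bacilli"]), c(30, 30))
  expect_equal(unname(rowSums(comp)), c(100, 100))

  # single class: 100% everywhere
  tax1 <- c(z1 = "Bacteria,Firmicutes,Bacilli,,,",
            z2 = "Bacteria,Firmicutes,Bacilli,,,")
  comp1 <- class_composition(rra, tax1, part)
  expect_equal(unname(comp1[, "Bacilli"]), c(100, 100))

  # unassigned classes pool as "unclassified" and shares still sum to 100
  tax2 <- c(z1 = "Bacteria,Proteobacteria,Gammaproteobacteria,,,", z2 = "")
  comp2 <- class_composition(rra, tax2, part)
  expect_true("unclassified" %in% colnames(comp2))
  expect_equal(unname(rowSums(comp2)), c(100, 100), tolerance = 1e-6)
})
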