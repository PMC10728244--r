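make_md <- function(reps, inds, sp, kind = NULL) {
  if (is.null(kind)) kind <- rep("none", length(reps))
  sample_metadata(data.frame(replicate_id = reps, individual_id = inds,
                             host_species = sp, control_kind = kind,
                             stringsAsFactors = FALSE))
}

test_that("control_filter zeroes cells strictly below the control maximum", {
  counts <- matrix(c(9L, 10L, 11L, 0L, 10L,
                     10L, 0L, 0L, 0L, 0L), 2, 5, byrow = TRUE,
                   dimnames = list(c("z1", "z2"),
                                   c("r1", "r2", "r3", "r4", "c1")))
  md <- make_md(c("r1", "r2", "r3", "r4", "c1"),
                c("i1", "i1", "i2", "i2", "c1"),
                c("A", "A", "A", "A", NA),
                c("none", "none", "none", "none", "extraction"))
  out <- control_filter(zotu_table(counts, c("t", "t")), md)
  # boundary: ties with the control count survive ("fewer than")
  expect_identical(unname(out$counts["z1", ]), c(0L, 10L, 11L, 0L))
  # a ZOTU absent from the controls (c = 0) is untouched
  expect_identical(unname(out$counts["z2", ]), c(10L, 0L, 0L, 0L))
  expect_false("c1" %in% colnames(out$counts))

  # no controls: unchanged with a warning
  md2 <- make_md(c("r1", "r2", "r3", "r4"),
                 c("i1", "i1", "i2", "i2"), rep("A", 4))
  zt <- zotu_table(counts[, 1:4], c("t", "t"))
  expect_warning(out2 <- control_filter(zt, md2), "skipped")
  expect_identical(out2$counts, zt$counts)

  # stat = "min" uses the per-ZOTU minimum over controls
  counts3 <- cbind(counts, c2 = c(4L, 0L))
  md3 <- make_md(c("r1", "r2", "r3", "r4", "c1", "c2"),
                 c("i1", "i1", "i2", "i2", "c1", "c2"),
                 c("A", "A", "A", "A", NA, NA),
                 c(rep("none", 4), "extraction", "pcr"))
  out3 <- control_filter(zotu_table(counts3, c("t", "t")), md3, stat = "min")
  expect_identical(unname(out3$counts["z1", ]), c(9L, 10L, 11L, 0L))
})

test_that("collapse_taxa merges identical lineages and keeps ids otherwise", {
  counts <- matrix(c(5L, 3L,
                     2L, 0L,
                     7L, 1L,
                     4L, 4L,
                     6L, 2L), 5, 2, byrow = TRUE,
                   dimnames = list(paste0("z", 1:5), c("s1", "s2")))
  tax <- c("Bacteria,Proteobacteria,,,,Acinetobacter",
           "Bacteria,Proteobacteria,,,,Acinetobacter",
           "Bacteria,Firmicutes,Bacilli,,,",
           "", "")
  out <- collapse_taxa(zotu_table(counts, tax))
  # duplicated lineage: one row, summed, id = lineage string
  merged <- "Bacteria,Proteobacteria,,,,Acinetobacter"
  expect_true(merged %in% rownames(out$counts))
  expect_identical(unname(out$counts[merged, ]), c(7L, 3L))
  # unique lineage keeps its original id
  expect_true("z3" %in% rownames(out$counts))
  # fully unassigned rows stay distinct under their own ids
  expect_true(all(c("z4", "z5") %in% rownames(out$counts)))
  expect_identical(nrow(out$counts), 4L)

  # all lineages unique: identity
  tax2 <- sprintf("Bacteria,,,,,G%d", 1:5)
  out2 <- collapse_taxa(zotu_table(counts, tax2))
  expect_identical(out2$counts, counts)
})

test_that("replicate_filter keeps only concordant pairs and sums them", {
  counts <- matrix(c(30L, 0L,
                     30L, 1L,
                     0L, 0L), 3, 2, byrow = TRUE,
                   dimnames = list(c("z1", "z2", "z3"), c("i1_r1", "i1_r2")))
  md <- make_md(c("i1_r1", "i1_r2"), c("i1", "i1"), c("A", "A"))
  out <- replicate_filter(zotu_table(counts, rep("t", 3)), md)
  expect_identical(colnames(out$counts), "i1")
  expect_identical(unname(out$counts[, "i1"]), c(0L, 31L, 0L))

  md3 <- make_md(c("i1_r1", "i1_r2", "i2_r1", "i2_r2"),
                 c("i1", "i1", "i2", "i2"), rep("A", 4))
  expect_error(replicate_filter(zotu_table(counts, rep("t", 3)), md3),
               "replicate 'i2_r1' missing")
})

test_that("tag_jump_filter applies a strict per-column proportion threshold", {
  counts <- matrix(c(4L, 5L, 9991L), 3, 1,
                   dimnames = list(c("z1", "z2", "z3"), "s1"))
  out <- tag_jump_filter(zotu_table(counts, rep("t", 3)), threshold = 0.0005)
  # column total 10,000: 4 (0.04%) removed, 5 (0.05%) kept
  expect_identical(unname(out$counts[, 1]), c(0L, 5L, 9991L))

  # threshold 0: identity
  out0 <- tag_jump_filter(zotu_table(counts, rep("t", 3)), threshold = 0)
  expect_identical(out0$counts, counts)

  # denominators are frozen at the stage-entry column totals, so the filter
  # is one-pass idempotent, and a count exactly at the threshold survives
  counts2 <- matrix(c(800L, 6L, 9194L), 3, 1,
                    dimnames = list(c("z1", "z2", "z3"), "s1"))
  zt2 <- zotu_table(counts2, rep("t", 3))
  once <- tag_jump_filter(zt2, threshold = 0.08)
  expect_identical(unname(once$counts[, 1]), c(800L, 0L, 9194L))
  expect_identical(tag_jump_filter(once, threshold = 0.08)$counts, once$counts)
})

test_that("target_filter keeps Bacteria/Archaea and drops Chloroplast", {
  counts <- matrix(1L, 5, 1, dimnames = list(paste0("z", 1:5), "s1"))
  tax <- c("Viridiplantae,Streptophyta,,,,",
           "Bacteria,Cyanobacteria,Chloroplast,,,",
           "Bacteria,Firmicutes,Bacilli,,,",
           "Archaea,Euryarchaeota,,,,",
           "")
  out <- target_filter(zotu_table(counts, tax))
  expect_identical(rownames(out$counts), c("z3", "z4", "z5"))
  out2 <- target_filter(zotu_table(counts, tax), drop_unassigned_domain = TRUE)
  expect_identical(rownames(out2$counts), c("z3", "z4"))
})

test_that("rare_filter zeroes positive counts strictly below min_count", {
  counts <- matrix(c(19L, 20L, 0L, 1L), 4, 1,
                   dimnames = list(paste0("z", 1:4), "s1"))
  out <- rare_filter(zotu_table(counts, rep("t", 4)), min_count = 20)
  expect_identical(unname(out$counts[, 1]), c(0L, 20L, 0L, 0L))
  out1 <- rare_filter(zotu_table(counts, rep("t", 4)), min_count = 1)
  expect_identical(out1$counts, counts)
  # idempotent
  expect_identical(rare_filter(out, min_count = 20)$counts, out$counts)
})

test_that("run_cascade applies all stages in order with a faithful report", {
  fx <- qc_fixture()
  res <- run_cascade(fx$table, fx$metadata)
  rep_df <- as.data.frame(res$report)
  expect_identical(rep_df$stage,
                   c("input", "control", "collapse", "replicate",
                     "tag_jump", "target", "rare"))
  # reads can only decrease
  expect_true(all(diff(rep_df$reads) <= 0))
  # every stage of the engineered fixture removes at least one occurrence
  expect_true(all(rep_df$occurrences_removed[-1] >= 1))
  expect_identical(rep_df$occurrences_removed[-1], c(1, 2, 1, 1, 1, 1))
  # survivors: the backbone ZOTU and the merged pair
  expect_setequal(rownames(res$table$counts),
                  c("Zbig", "Bacteria,Firmicutes,Bacilli,,,Genus_m"))
  expect_identical(colnames(res$table$counts), c("a", "b", "c", "d"))
  expect_identical(attr(res$report, "dropped_zotus"), 4L)
  expect_identical(attr(res$report, "dropped_individuals"), 0L)
  expect_identical(attr(res$report, "initial_reads"), total_reads(fx$table))
  expect_identical(attr(res$report, "final_reads"), total_reads(res$table))
})

test_that("the cascade survives a table that empties completely", {
  counts <- matrix(c(5L, 3L, 0L, 0L), 1, 4,
                   dimnames = list("z1", c("i1_r1", "i1_r2", "i2_r1", "i2_r2")))
  md <- make_md(c("i1_r1", "i1_r2", "i2_r1", "i2_r2"),
                c("i1", "i1", "i2", "i2"), rep("A", 4))
  expect_warning(res <- run_cascade(zotu_table(counts, "Bacteria,,,,,"), md),
                 "skipped")  # no controls
  # 5 + 3 = 8 reads < 20: rare filter empties the table
  expect_identical(dim(res$table$counts), c(0L, 0L))
  expect_identical(attr(res$report, "final_reads"), 0)
  expect_identical(nrow(as.data.frame(res$report)), 7L)
})

test_that("tag-jump placement relative to replicate summation matters", {
  # replicate counts (3, 9) in a deep column: summed first they pass the
  # 0.05% threshold, but filtered per replicate the 3 is removed and the
  # pair becomes discordant
  counts <- matrix(c(3L, 9L,
                     9997L, 9991L), 2, 2, byrow = TRUE,
                   dimnames = list(c("z1", "zbig"), c("i1_r1", "i1_r2")))
  md <- make_md(c("i1_r1", "i1_r2"), c("i1", "i1"), c("A", "A"))
  zt <- zotu_table(counts, c("Bacteria,,,,,G1", "Bacteria,,,,,G2"))
  after <- suppressWarnings(
    run_cascade(zt, md, min_count = 1))
  before <- suppressWarnings(
    run_cascade(zt, md, min_count = 1, tag_jump_before_replicate = TRUE))
  expect_true("z1" %in% rownames(after$table$counts))
  expect_false("z1" %in% rownames(before$table$counts))
  expect_identical(unname(after$table$counts["z1", "i1"]), 12L)
})

test_that("filter reports serialise to JSON", {
  fx <- qc_fixture()
  res <- run_cascade(fx$table, fx$metadata)
  path <- tempfile(fileext = ".json")
  write_filter_report(res$report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$stages$stage,
                   c("input", "control", "collapse", "replicate",
                     "tag_jump", "target", "rare"))
  expect_equal(back$dropped_zotus, 4L)
  expect_equal(back$final_reads, attr(res$report, "final_reads"))
})
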