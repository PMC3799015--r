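test_that("expression study TSVs round-trip and validate", {
  study <- tiny_study(n_genes = 5, n_contrasts = 2)
  mp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_expression_study(study, mp, ap, header_lines = "demo")
  back <- read_expression_study(mp, ap)
  expect_equal(back$exprs, study$exprs, tolerance = 1e-12)
  expect_equal(back$samples$sample_id, study$samples$sample_id)
  expect_equal(back$samples$state, study$samples$state)

  # 2x2 hand-written table
  writeLines(c("feature_id\ts1\ts2", "Cd86\t1.5\t2.5", "Il6\t3\t4"), mp)
  ann <- data.frame(sample_id = c("s1", "s2"), subset = "pDC",
                    state = c("quiescent", "activated"), species = "mouse",
                    contrast = "c1", replicate = 1)
  write.table(ann, ap, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- read_expression_study(mp, ap)
  expect_equal(unname(st$exprs["Cd86", ]), c(1.5, 2.5))
})

test_that("expression study readers fail loudly on malformed input", {
  mp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  ann <- data.frame(sample_id = c("s1", "s2"), subset = "pDC",
                    state = c("quiescent", "activated"), species = "mouse",
                    contrast = "c1", replicate = 1)
  write.table(ann, ap, sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(c("feature_id\ts1\ts2", "Cd86\t1\t2", "Cd86\t3\t4"), mp)
  expect_error(read_expression_study(mp, ap), "Cd86")

  writeLines(c("feature_id\ts1\ts2", "Cd86\t1\tabc"), mp)
  expect_error(read_expression_study(mp, ap), "Cd86.*s2")

  writeLines(c("feature_id\ts1\ts3", "Cd86\t1\t2"), mp)
  expect_error(read_expression_study(mp, ap), "s3|s2")
})

test_that("generator output parses back with the expected shape", {
  gen <- generate_study(n_genes = 100, n_mouse_contrasts = 3,
                        n_human_contrasts = 2, seed = 7,
                        truth_params = list(n_core_up = 5, n_core_down = 5,
                                            n_fingerprint = 3,
                                            n_condition_specific = 2,
                                            n_discovery = 3))
  mp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_expression_study(gen$mouse, mp, ap)
  back <- read_expression_study(mp, ap)
  expect_equal(dim(back$exprs), c(100, 12))
})

test_that("GMT files round-trip with direction and validate", {
  path <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(coreUP = gene_set("coreUP", c("A", "B", "C"), "up"))
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_setequal(back$coreUP$genes, c("A", "B", "C"))
  expect_equal(back$coreUP$direction, "up")

  writeLines("s1\tdesc\tCCL2\tCXCL10", path)
  expect_length(read_gmt(path)$s1$genes, 2)

  writeLines(c("ok\td\tG1", "bad\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 2")
  writeLines("empty\td\t\t", path)
  expect_error(read_gmt(path), "empty")
})

test_that("Venn-area gene sets from a DE run are pairwise disjoint", {
  gen <- generate_study(n_genes = 400, seed = 11,
                        truth_params = list(n_core_up = 20, n_core_down = 15,
                                            n_fingerprint = 10,
                                            n_condition_specific = 4))
  model <- fit_error_model(gen$mouse)
  up <- list(); down <- list()
  for (cid in c("m01", "m02", "m03")) {
    de <- differential_test(gen$mouse, cid, model)
    lab <- gen$mouse$samples$subset[gen$mouse$samples$contrast == cid][1]
    up[[lab]] <- de$gene[de$call == "up"]
    down[[lab]] <- de$gene[de$call == "down"]
  }
  sets <- venn_gene_sets(venn_partition(up, down))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  ups <- lapply(Filter(function(s) s$direction == "up", back), `[[`, "genes")
  for (i in seq_along(ups)) for (j in seq_along(ups)) {
    if (i < j) expect_length(intersect(ups[[i]], ups[[j]]), 0)
  }
})

test_that("PWM count blocks normalise exactly and reject bad blocks", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">toy", "A [ 2 0 ]", "C [ 0 2 ]", "G [ 0 0 ]", "T [ 0 0 ]"),
             path)
  p0 <- read_pwm_counts(path, pseudocount = 0)$toy
  expect_equal(unname(p0$mat[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(p0$mat[, 2]), c(0, 1, 0, 0))
  p1 <- read_pwm_counts(path, pseudocount = 1)$toy
  expect_equal(unname(p1$mat[, 1]), c(3, 1, 1, 1) / 6)

  writeLines(c(">zero", "A [ 2 0 ]", "C [ 0 0 ]", "G [ 0 0 ]", "T [ 0 0 ]"),
             path)
  expect_error(read_pwm_counts(path, pseudocount = 0), "all-zero")
  writeLines(c(">short", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]"), path)
  expect_error(read_pwm_counts(path), "4 nucleotide rows")

  # fixture of 3 PWMs round-trips lengths
  pwms <- list(random_pwm("a", 4), random_pwm("b", 6), random_pwm("c", 9))
  names(pwms) <- c("a", "b", "c")
  write_pwm_counts(pwms, path)
  back <- read_pwm_counts(path, pseudocount = 0)
  expect_length(back, 3)
  expect_equal(vapply(back, function(p) ncol(p$mat), integer(1)),
               c(a = 4L, b = 6L, c = 9L))
  expect_equal(back$b$mat, pwms$b$mat, tolerance = 1e-6)
})

test_that("FASTA and BED readers enforce their conventions", {
  fp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">CCL2", "ACGT"), fp)
  ps <- read_fasta(fp)
  expect_length(ps$seqs, 1)
  expect_equal(nchar(ps$seqs[["CCL2"]]), 4)

  writeLines(c(">CCL2", "ACGT", ">CCL2", "GGGG"), fp)
  expect_error(read_fasta(fp), "duplicate")

  bp <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t101\tg1\t.\t+", bp)
  bed <- read_bed_intervals(bp)
  expect_equal(bed$end - bed$start, 1L)
  writeLines("chr1\t101\t100\tg1\t.\t+", bp)
  expect_error(read_bed_intervals(bp), "start >= end")

  # generator-written promoter FASTA keeps count and length
  prom <- generate_promoters(sprintf("G%02d", 1:50), length = 801, seed = 5)
  write_fasta(prom$promoters, fp)
  back <- read_fasta(fp)
  expect_length(back$seqs, 50)
  expect_true(all(nchar(back$seqs) == 801))
})

test_that("ortholog tables parse and reject duplicates and blanks", {
  op <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mouse\thuman", "Cd86\tCD86", "Il6\tIL6"), op)
  tab <- read_ortholog_table(op)
  expect_equal(tab[["Cd86"]], "CD86")
  writeLines(c("mouse\thuman", "Cd86\tCD86", "Cd86\tOTHER"), op)
  expect_error(read_ortholog_table(op), "duplicate")
  writeLines(c("mouse\thuman", "Cd86\t"), op)
  expect_error(read_ortholog_table(op), "empty")
})

test_that("probe collapse keeps the max-mean probe per gene", {
  study <- tiny_study(n_genes = 6, n_contrasts = 1)
  pm <- data.frame(probe = rownames(study$exprs)[1:4],
                   gene = c("Cd86", "Cd86", "Il6", "Il6"))
  means <- rowMeans(study$exprs)[1:4]
  out <- collapse_probes(study, pm)
  expect_setequal(rownames(out$exprs), c("Cd86", "Il6"))
  expect_equal(unname(rowMeans(out$exprs)["Cd86"]),
               unname(max(means[1:2])))
  expect_equal(attr(out, "n_unmapped"), 2L)
})
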