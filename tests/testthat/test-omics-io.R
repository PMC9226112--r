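# Readers and writers: round-trip identity and contract violations.

test_that("matrix containers round-trip through TSV", {
  dir <- withr::local_tempdir()
  em <- make_expr(n_genes = 3, n_tumor = 2, n_normal = 2, seed = 2)
  write_matrix(em, file.path(dir, "e.tsv"), file.path(dir, "g.tsv"))
  back <- read_matrix(file.path(dir, "e.tsv"), file.path(dir, "g.tsv"),
                      "expression")
  expect_equal(back$values, em$values)
  expect_identical(back$group, em$group)

  beta <- matrix(c(0.1, 0.5, 0.9, 0.25), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  mm <- methylation_matrix(beta, c(s1 = "tumor", s2 = "normal"))
  write_matrix(mm, file.path(dir, "m.tsv"), file.path(dir, "mg.tsv"))
  back <- read_matrix(file.path(dir, "m.tsv"), file.path(dir, "mg.tsv"),
                      "methylation")
  expect_equal(back$beta, mm$beta)
})

test_that("matrix parse errors name the offending gene and line", {
  dir <- withr::local_tempdir()
  writeLines(c("gene\ts1\ts2", "gA\t1\t2", "gA\t3\t4"),
             file.path(dir, "dup.tsv"))
  writeLines(c("sample\tgroup", "s1\ttumor", "s2\tnormal"),
             file.path(dir, "g.tsv"))
  expect_error(read_matrix(file.path(dir, "dup.tsv"), file.path(dir, "g.tsv")),
               "gA")
  writeLines(c("gene\ts1\ts2", "gA\t1\tx"), file.path(dir, "bad.tsv"))
  expect_error(read_matrix(file.path(dir, "bad.tsv"), file.path(dir, "g.tsv")),
               "line 2.*gA.*s2")
  writeLines(c("gene\ts1\ts2", "gA\t0.5\t1.2"), file.path(dir, "beta.tsv"))
  expect_error(read_matrix(file.path(dir, "beta.tsv"), file.path(dir, "g.tsv"),
                           "methylation"),
               "beta outside \\[0,1\\].*gA.*s2")
})

test_that("CNA calls round-trip and reject out-of-range calls", {
  dir <- withr::local_tempdir()
  call <- matrix(c(-2L, 0L, 1L, 2L), 2, 2,
                 dimnames = list(c("g1", "g2"), c("t1", "t2")))
  cna <- cna_calls(call, amp_genes = "g2", del_genes = "g1")
  write_cna(cna, file.path(dir, "c.tsv"), file.path(dir, "a.txt"),
            file.path(dir, "d.txt"))
  back <- read_cna(file.path(dir, "c.tsv"), file.path(dir, "a.txt"),
                   file.path(dir, "d.txt"))
  expect_equal(back$call, cna$call)
  expect_identical(back$amp_genes, cna$amp_genes)
  expect_identical(back$del_genes, cna$del_genes)

  writeLines(c("gene\tt1", "g1\t3"), file.path(dir, "bad.tsv"))
  expect_error(read_cna(file.path(dir, "bad.tsv"), file.path(dir, "a.txt"),
                        file.path(dir, "d.txt")),
               "outside \\{-2\\.\\.2\\}")
  expect_error(cna_calls(call, amp_genes = "g1", del_genes = "g1"),
               "both amplified and deleted")
})

test_that("MAF-like mutation files map silent classes and round-trip", {
  dir <- withr::local_tempdir()
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
               "TP53\ts1\tMissense_Mutation",
               "TP53\ts2\tSilent",
               "KRAS\ts1\t3'UTR"),
             file.path(dir, "m.tsv"))
  mut <- read_mutations(file.path(dir, "m.tsv"))
  expect_identical(mut$variant_class, c("nonsilent", "silent", "nonsilent"))
  # a configurable silent vocabulary reclassifies UTR records
  mut2 <- read_mutations(file.path(dir, "m.tsv"),
                         silent_classes = c("Silent", "3'UTR"))
  expect_identical(mut2$variant_class, c("nonsilent", "silent", "silent"))
  write_mutations(mut, file.path(dir, "out.tsv"))
  back <- read_mutations(file.path(dir, "out.tsv"))
  expect_identical(as.data.frame(back), as.data.frame(mut))
})

test_that("clinical files round-trip; unknown category strings are mapped with a warning", {
  dir <- withr::local_tempdir()
  cl <- clinical_table(data.frame(
    sample = c("t1", "t2"), os_time = c(100.5, 2000), os_event = c(1L, 0L),
    age_group = c("young", "old"), er = c("pos", "unknown"),
    pr = c("neg", "pos"), stage = c("early", "late"),
    stringsAsFactors = FALSE
  ))
  write_clinical(cl, file.path(dir, "cl.tsv"))
  back <- read_clinical(file.path(dir, "cl.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(cl))

  writeLines(c("sample\tos_time\tos_event\tage_group\ter\tpr\tstage",
               "t1\t10\t1\tyoung\tPositive\tneg\tearly"),
             file.path(dir, "odd.tsv"))
  expect_warning(odd <- read_clinical(file.path(dir, "odd.tsv")), "er")
  expect_identical(odd$er, "unknown")
})

test_that("network files reject duplicate undirected edges and bad weights", {
  dir <- withr::local_tempdir()
  writeLines(c("from\tto\tweight", "A\tB\t0.9", "B\tA\t0.9"),
             file.path(dir, "dup.tsv"))
  expect_error(read_network(file.path(dir, "dup.tsv")), "duplicate undirected edge")
  writeLines(c("from\tto\tweight", "A\tA\t0.5"), file.path(dir, "loop.tsv"))
  expect_error(read_network(file.path(dir, "loop.tsv")), "self-loop")
  writeLines(c("from\tto\tweight", "A\tB\t1.5"), file.path(dir, "w.tsv"))
  expect_error(read_network(file.path(dir, "w.tsv")), "\\(0, 1\\]")

  net <- functional_network(data.frame(from = c("B", "C"), to = c("A", "A"),
                                       weight = c(0.9, 0.4)),
                            nodes = c("A", "B", "C", "D"))
  write_network(net, file.path(dir, "n.tsv"), file.path(dir, "nodes.txt"))
  back <- read_network(file.path(dir, "n.tsv"),
                       nodes = readLines(file.path(dir, "nodes.txt")))
  expect_equal(back$edges, net$edges)
  expect_identical(back$nodes, net$nodes)
})

test_that("DRG annotation and truth labels round-trip", {
  dir <- withr::local_tempdir()
  drg <- drg_annotation(data.frame(gene = c("g1", "g2"),
                                   drug = c("tamoxifen", "olaparib")))
  write_drg(drg, file.path(dir, "drg.tsv"))
  expect_equal(as.data.frame(read_drg(file.path(dir, "drg.tsv"))),
               as.data.frame(drg))
  expect_error(drg_annotation(data.frame(gene = character(),
                                         drug = character())),
               "at least one")

  sim <- generate_cohort(small_cohort_config(seed = 2L))
  write_truth_labels(sim$truth, file.path(dir, "truth.json"))
  back <- read_truth_labels(file.path(dir, "truth.json"))
  expect_setequal(back$mut_driven, sim$truth$mut_driven)
  expect_setequal(back$de_genes_up, sim$truth$de_genes_up)
  expect_identical(back$surv_pair, sim$truth$surv_pair)
  expect_equal(back$surv_beta_true, sim$truth$surv_beta_true)
  expect_equal(sort(names(back$module_assignment)),
               sort(names(sim$truth$module_assignment)))
})
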