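test_that("ortholog mapping collapses many-to-one and reports unmapped", {
  tab <- data.frame(bee_gene_id = c("b1", "b2", "b3", "b3"),
                    fly_gene_id = c("f1", "f1", "f2", "f2"))
  res <- map_orthologs(c("b1", "b2", "b4"), tab)
  expect_equal(res$mapped, "f1")
  expect_equal(res$unmapped, "b4")
  expect_equal(map_orthologs(character(0), tab),
               list(mapped = character(0), unmapped = character(0)))
})

test_that("chi-square equals the closed form and the stats oracle", {
  # 2x2 table (10, 10 / 10, 70) from marginals: targets 20 (10 in-term),
  # background 100 (20 in-term)
  ann <- data.frame(
    gene_id = sprintf("g%03d", 1:20),  # the 20 in-term genes
    go_id = "GO:1", go_name = "term one")
  targets <- sprintf("g%03d", c(1:10, 21:30))     # 10 in, 10 out
  background <- sprintf("g%03d", 1:100)
  enr <- enrich_chisq(targets, background, ann)
  O <- matrix(c(10, 10, 10, 70), 2)
  E <- outer(rowSums(O), colSums(O)) / 100
  expect_equal(enr$chi2, sum((O - E)^2 / E), tolerance = 1e-9)
  # independent oracle: stats::chisq.test without continuity correction
  grp <- factor(background %in% targets)
  interm <- factor(background %in% ann$gene_id)
  ct <- suppressWarnings(stats::chisq.test(table(interm, grp),
                                           correct = FALSE))
  expect_equal(enr$chi2, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(enr$p, ct$p.value, tolerance = 1e-9)
  expect_true(enr$enriched)  # 50% in targets vs 20% overall
})

test_that("identical proportions give chi-square zero and p one", {
  ann <- data.frame(gene_id = c("g1", "g2", "g5", "g6"),
                    go_id = "GO:9", go_name = "flat term")
  # targets: 2 of 4 in-term; background 8 with 4 in-term
  enr <- enrich_chisq(c("g1", "g5", "g3", "g7"),
                      sprintf("g%d", 1:8), ann)
  expect_equal(enr$chi2, 0, tolerance = 1e-12)
  expect_equal(enr$p, 1)
  expect_false(enr$enriched)
})

test_that("degenerate terms are skipped with a reason, with guards on input", {
  ann <- data.frame(gene_id = c("g1", "g2", "g1", "g2", "g3"),
                    go_id = c("GO:all", "GO:all", "GO:ok", "GO:ok", "GO:ok"),
                    go_name = c("everything", "everything", "fine", "fine",
                                "fine"))
  # GO:all covers the whole 2-gene... use a background where GO:all = all
  enr <- enrich_chisq(c("g1"), c("g1", "g2"), ann[1:2, ])
  expect_equal(nrow(enr), 0)
  expect_match(attr(enr, "skipped"), "zero expected cell")
  expect_error(enrich_chisq("gX", c("g1", "g2"), ann), "subset")
  expect_error(enrich_chisq("g1", "g1", ann), ">= 2")
})

test_that("development terms constructed as enriched are flagged enriched", {
  bee <- sprintf("bee%03d", 1:120)
  targets <- sprintf("bee%03d", 1:12)
  sim <- gen_annotations(bee, targets, n_terms = 10, n_dev_terms = 6,
                         seed = 42)
  mp <- map_orthologs(targets, sim$orthologs)
  bg <- map_orthologs(bee, sim$orthologs)$mapped
  enr <- enrich_chisq(mp$mapped, bg, sim$annotations)
  dev_terms <- unique(sim$annotations$go_name[
    sim$annotations$go_id %in% enr$go_id[enr$enriched]])
  dev_names <- c("imaginal disc development", "ovarian follicle development",
                 "larval development", "metamorphosis",
                 "body morphogenesis", "oogenesis")
  # the construction makes the development terms the enriched ones
  expect_setequal(enr$go_name[enr$enriched], dev_names)
  expect_equal(sum(enr$enriched), 6)
})

test_that("null targets produce the nominal false-positive rate", {
  set.seed(7)
  bg <- sprintf("g%03d", 1:400)
  ann <- do.call(rbind, lapply(1:10, function(t)
    data.frame(gene_id = sample(bg, 80), go_id = sprintf("GO:%d", t),
               go_name = sprintf("term %d", t))))
  hits <- 0L; total <- 0L
  for (r in 1:300) {
    tg <- sample(bg, 100)
    enr <- enrich_chisq(tg, bg, ann)
    hits <- hits + sum(enr$p < 0.05)
    total <- total + nrow(enr)
  }
  rate <- hits / total
  # 3000 term-tests; allow generous Monte-Carlo + approximation slack
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("network export computes Jaccard weights from shared genes", {
  enr <- data.frame(go_id = c("A", "B", "C"),
                    go_name = c("a", "b", "c"),
                    p = c(0.001, 0.01, 0.04),
                    enriched = TRUE)
  ann <- data.frame(
    gene_id = c("g1", "g2", "g3", "g2", "g3", "g4", "g9"),
    go_id = c("A", "A", "A", "B", "B", "B", "C"),
    go_name = c("a", "a", "a", "b", "b", "b", "c"))
  net <- export_network(enr, ann, targets = c("g1", "g2", "g3", "g4", "g9"))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(net$nodes$size, -log10(enr$p))
  # A = {g1,g2,g3}, B = {g2,g3,g4}: Jaccard 2/4; C = {g9} disjoint
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 0.5)
  # identical gene sets give weight 1
  net2 <- export_network(enr[1:2, ],
                         data.frame(gene_id = c("g1", "g1"),
                                    go_id = c("A", "B"),
                                    go_name = c("a", "b")),
                         targets = "g1")
  expect_equal(net2$edges$weight, 1)
  expect_error(export_network(transform(enr, enriched = FALSE), ann, "g1"),
               "no enriched")
})
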