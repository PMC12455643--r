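test_that("absent observations become zeros in the frequency matrix", {
  iso <- tibble::tibble(isolate_id = c("iso1", "iso2"),
                        group = c("parental", "evolved"))
  recs <- tibble::tibble(mutation_id = "m1", type = "SNP", seq_id = "chr1",
                         position = 10L, detail = "G>A",
                         isolate_id = "iso1", frequency = 0.745)
  fm <- build_matrix(recs, iso)
  expect_equal(unname(fm$mat), matrix(c(0.745, 0), 1, 2))
  expect_equal(rownames(fm$mat), "m1")
})

test_that("the partially segregated deletion row reproduces its group means", {
  # 27-bp deletion seen in two of three evolved isolates at 74.5% and 100%
  iso <- panel_33()
  recs <- tibble::tibble(
    mutation_id = "del27", type = "DEL", seq_id = "chr1", position = 100L,
    detail = "27", isolate_id = c("EMP_1", "EMP_3"),
    frequency = c(0.745, 1.0)
  )
  fm <- build_matrix(recs, iso)
  enr <- enrichment(fm)
  expect_equal(enr$mean_parental, 0)
  expect_equal(enr$mean_evolved, (0.745 + 0 + 1.0) / 3, tolerance = 1e-12)
  expect_true(enr$increasing)
})

test_that("duplicate observations and unknown isolates are rejected", {
  iso <- tibble::tibble(isolate_id = c("iso1", "iso2"),
                        group = c("parental", "evolved"))
  recs <- tibble::tibble(mutation_id = c("m1", "m1"), type = "SNP",
                         seq_id = "chr1", position = 10L, detail = "G>A",
                         isolate_id = c("iso1", "iso1"),
                         frequency = c(0.5, 0.6))
  expect_error(build_matrix(recs, iso), "duplicate observation")
  recs2 <- recs[1, ]
  recs2$isolate_id <- "ghost"
  expect_error(build_matrix(recs2, iso), "not in the panel")
  expect_error(build_matrix(recs[1, ],
                            tibble::tibble(isolate_id = "iso1",
                                           group = "parental")),
               "parental and.*evolved")
})

test_that("a single varying mutation captures all variance on PC1", {
  mat <- rbind(m1 = c(0, 0, 0, 1, 1, 1),
               m2 = rep(0.4, 6),
               m3 = rep(0.9, 6))
  colnames(mat) <- panel_33()$isolate_id
  fm <- fm_from_matrix(mat, panel_33()$group)
  pca <- run_pca(fm)
  expect_equal(pca$variance_fraction[1], 1.0, tolerance = 1e-12)
  expect_equal(abs(pca$loadings["m1", 1]), 1.0, tolerance = 1e-12)
  # sign convention: the dominant loading is positive
  expect_gt(pca$loadings["m1", 1], 0)
})

test_that("an all-constant matrix is a degenerate PCA input", {
  mat <- matrix(0.5, 3, 6, dimnames = list(paste0("m", 1:3),
                                           panel_33()$isolate_id))
  fm <- fm_from_matrix(mat, panel_33()$group)
  expect_error(run_pca(fm), "degenerate")
})

test_that("PCA matches covariance eigendecomposition on random matrices", {
  set.seed(7)
  for (rep in 1:50) {
    mat <- matrix(runif(20 * 6), nrow = 20,
                  dimnames = list(sprintf("m%02d", 1:20),
                                  panel_33()$isolate_id))
    fm <- fm_from_matrix(mat, panel_33()$group)
    pca <- run_pca(fm)
    want <- oracle_cov_pca(mat)
    expect_equal(pca$variance_fraction, want$variance_fraction,
                 tolerance = 1e-8)
    expect_equal(abs(unname(pca$loadings)), abs(want$loadings),
                 tolerance = 1e-8)
    expect_lte(sum(pca$variance_fraction), 1 + 1e-9)
    # loadings are unit norm
    expect_equal(unname(colSums(pca$loadings^2)),
                 rep(1, ncol(pca$loadings)), tolerance = 1e-10)
  }
})

test_that("group-separating components are selected, mixed ones are not", {
  mat <- rbind(m1 = c(0, 0, 0, 1, 1, 1),          # clean group split
               m2 = c(0.9, 0.1, 0.5, 0.5, 0.1, 0.9)) # interleaved
  colnames(mat) <- panel_33()$isolate_id
  fm <- fm_from_matrix(mat, panel_33()$group)
  pca <- run_pca(fm)
  sel <- select_discriminating_pcs(pca, tau = 1)
  grp <- panel_33()$group
  # the selected component(s) really separate the groups; zero within-group
  # spread with distinct means counts as infinite separation
  for (j in seq_len(ncol(pca$scores))) {
    s <- pca$scores[, j]
    d <- abs(mean(s[grp == "evolved"]) - mean(s[grp == "parental"]))
    pooled <- sqrt((stats::var(s[grp == "evolved"]) +
                      stats::var(s[grp == "parental"])) / 2)
    stat <- if (pooled == 0) ifelse(d > 0, Inf, 0) else d / pooled
    expect_equal(j %in% sel, stat >= 1)
  }
  expect_true(1 %in% sel)
})

test_that("identical group means mean no selection", {
  mat <- rbind(m1 = c(0.9, 0.1, 0.5, 0.9, 0.1, 0.5),
               m2 = c(0.2, 0.8, 0.5, 0.2, 0.8, 0.5))
  colnames(mat) <- panel_33()$isolate_id
  fm <- fm_from_matrix(mat, panel_33()$group)
  pca <- run_pca(fm)
  expect_length(select_discriminating_pcs(pca, tau = 1), 0)
})

test_that("top loadings rank by absolute value with lexicographic ties", {
  pca <- structure(list(
    loadings = matrix(c(0.9, -0.95, 0.1), ncol = 1,
                      dimnames = list(c("m1", "m2", "m3"), "PC1")),
    variance_fraction = 1,
    scores = matrix(0, 2, 1),
    isolates = tibble::tibble(isolate_id = c("a", "b"),
                              group = c("parental", "evolved"))
  ), class = "ale_pca")
  expect_equal(top_loadings(pca, 1, 2), c("m2", "m1"))
  expect_equal(top_loadings(pca, 1, 10), c("m2", "m1", "m3"))
  tie <- pca
  tie$loadings[, 1] <- c(0.5, -0.5, 0.1)
  expect_equal(top_loadings(tie, 1, 1), "m1")
  expect_error(top_loadings(pca, 1, 0), "k must be")
})

test_that("enrichment uses strict inequalities for the increasing mark", {
  mat <- rbind(same = rep(0.4, 6),
               down = c(1, 1, 1, 0, 0, 0))
  colnames(mat) <- panel_33()$isolate_id
  fm <- fm_from_matrix(mat, panel_33()$group)
  enr <- enrichment(fm)
  expect_equal(enr$delta[enr$mutation_id == "same"], 0)
  expect_false(enr$increasing[enr$mutation_id == "same"])
  expect_equal(enr$delta[enr$mutation_id == "down"], -1)
  expect_false(enr$increasing[enr$mutation_id == "down"])
})

test_that("gene exclusion removes whole tainted genes but not intergenic", {
  enr <- tibble::tibble(
    mutation_id = c("a1", "a2", "b1", "c1", "c2", "i1"),
    delta = c(0.5, -0.1, 0.5, 0.3, 0.0, -0.2)
  )
  gmap <- tibble::tibble(
    mutation_id = enr$mutation_id,
    gene_id = c("geneA", "geneA", "geneB", "geneC", "geneC", "intergenic")
  )
  kept <- gene_exclusion_filter(enr, gmap)
  # geneA has a decreasing mutation -> both removed; zero is not decreasing;
  # the intergenic decrease is out of this rule's scope
  expect_equal(kept, c("b1", "c1", "c2", "i1"))
  expect_error(gene_exclusion_filter(enr, gmap[-1, ]), "gene assignment")
})

test_that("gene exclusion equals exhaustive set logic on random patterns", {
  set.seed(5)
  for (rep in 1:200) {
    n <- sample(2:9, 1)
    ids <- sprintf("m%02d", seq_len(n))
    gmap <- tibble::tibble(
      mutation_id = ids,
      gene_id = sample(c("g1", "g2", "g3", "intergenic"), n, replace = TRUE)
    )
    enr <- tibble::tibble(mutation_id = ids,
                          delta = sample(c(-0.5, 0, 0.5), n, replace = TRUE))
    expect_equal(gene_exclusion_filter(enr, gmap),
                 oracle_gene_filter(ids, enr$delta, gmap$gene_id))
  }
})

test_that("candidate combination requires both channels under intersection", {
  enr <- tibble::tibble(
    mutation_id = c("d1", "d2", "n1"),
    mean_parental = c(0, 0.8, 0.2),
    mean_evolved = c(1, 0.2, 0.3),
    delta = c(1, -0.6, 0.1),
    increasing = c(TRUE, FALSE, TRUE)
  )
  gmap <- tibble::tibble(mutation_id = c("d1", "d2", "n1"),
                         gene_id = c("pnp", "rpoB", "sigA"))
  hits <- tibble::tibble(mutation_id = c("d1", "d2"), pc = 1L,
                         loading = c(0.9, -0.8))
  rep1 <- combine_candidates(hits, retained_increasing = c("d1", "n1"),
                             gmap, enr)
  # pnp: top loading + increasing retained -> in; rpoB: loading only -> out;
  # sigA: enrichment only -> out under intersection
  expect_equal(rep1$genes$gene_id, "pnp")
  expect_equal(rep1$genes$max_delta, 1)
  expect_equal(rep1$genes$source_pc, 1L)
  rep2 <- combine_candidates(hits, c("d1", "n1"), gmap, enr,
                             combine = "union")
  expect_setequal(rep2$genes$gene_id, c("pnp", "rpoB", "sigA"))
  # union ranks by max delta then loading
  expect_equal(rep2$genes$gene_id[1], "pnp")
  expect_warning(
    empty <- combine_candidates(hits[0, ], character(0), gmap, enr),
    "no candidate"
  )
  expect_equal(empty$status, "empty")
  expect_equal(nrow(tidy(empty)), 0)
})

test_that("candidate reports are invariant to isolate and record order", {
  set.seed(31)
  sim <- simulate_ale(ale_config(seed = 31, n_transfers = 8))
  panel <- sample_isolates(sim, seed = 1)
  obs <- emulate_sequencing(panel, seed = 2)
  iso <- attr(obs, "isolates")
  gmap <- assign_genes(obs, sim$annotation)
  ref <- prioritize_mutations(obs, iso, gene_map = gmap)

  perm_iso <- iso[sample(nrow(iso)), ]
  perm_obs <- obs[sample(nrow(obs)), ]
  shuffled <- prioritize_mutations(perm_obs, perm_iso, gene_map = gmap)
  expect_equal(shuffled$genes$gene_id, ref$genes$gene_id)
  expect_equal(shuffled$genes$max_delta, ref$genes$max_delta)
  expect_equal(shuffled$genes$max_abs_loading, ref$genes$max_abs_loading,
               tolerance = 1e-10)
})

test_that("adding a constant to a mutation row changes neither loading nor delta", {
  set.seed(13)
  mat <- matrix(runif(10 * 6, 0, 0.5), nrow = 10,
                dimnames = list(sprintf("m%02d", 1:10),
                                panel_33()$isolate_id))
  fm1 <- fm_from_matrix(mat, panel_33()$group)
  mat2 <- mat
  mat2[4, ] <- mat2[4, ] + 0.3
  fm2 <- fm_from_matrix(mat2, panel_33()$group)
  p1 <- run_pca(fm1); p2 <- run_pca(fm2)
  expect_equal(abs(p1$loadings), abs(p2$loadings), tolerance = 1e-10)
  expect_equal(enrichment(fm1)$delta, enrichment(fm2)$delta,
               tolerance = 1e-12)
})
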