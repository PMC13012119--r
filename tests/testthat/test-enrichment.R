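two_organ_atlas <- function(values) {
  # values: named list organ -> stage vector of rpkm
  rows <- do.call(rbind, lapply(names(values), function(o) {
    v <- values[[o]]
    data.frame(gene = "g1", organ = o,
               stage = c("E12.5", "P0", "P63")[seq_along(v)], rpkm = v)
  }))
  make_atlas(rows)
}

test_that("organ means average available stages only", {
  atlas <- make_atlas(data.frame(
    gene = "g1", organ = c(rep("cerebellum", 3), rep("liver", 2)),
    stage = c("E12.5", "P0", "P63", "E12.5", "P63"),
    rpkm = c(10, 10, 10, 4, 8)))
  prof <- organ_mean_profile(atlas, "g1")
  expect_equal(prof$mean_rpkm[prof$organ == "cerebellum"], 10)
  expect_equal(prof$mean_rpkm[prof$organ == "liver"], 6)  # missing P0 skipped
  expect_error(organ_mean_profile(atlas, "nope"), "unknown gene")
})

test_that("single-organ expression and uniform expression call as expected", {
  single <- two_organ_atlas(list(cerebellum = c(10, 10, 10),
                                 brain = c(0, 0, 0), liver = c(0, 0, 0)))
  call1 <- call_enrichment(single)
  expect_equal(call1$organ, "cerebellum")
  expect_equal(call1$score, (10 + 0.1) / (0 + 0.1))

  uniform <- two_organ_atlas(list(cerebellum = c(5, 5), brain = c(5, 5)))
  expect_true(is.na(call_enrichment(uniform)$organ))

  expect_error(call_enrichment(two_organ_atlas(list(brain = c(1, 2)))),
               ">= 2 organs")
})

test_that("enrichment calls match a brute-force oracle on random atlases", {
  for (seed in 1:4) {
    atlas <- random_atlas(seed, n_genes = 60,
                          organs = c("brain", "cerebellum", "heart", "liver"))
    calls <- call_enrichment(atlas)
    oracle <- oracle_enrichment(atlas)
    merged <- merge(as.data.frame(calls)[, c("gene", "organ", "score")],
                    oracle, by = "gene")
    expect_identical(merged$organ.x, merged$organ.y)
    expect_equal(merged$score.x, merged$score.y, tolerance = 1e-12)
    # mean columns re-derive from the atlas
    g <- sample(unique(atlas$gene), 1)
    prof <- organ_mean_profile(atlas, g)
    row <- calls[calls$gene == g, ]
    for (i in seq_len(nrow(prof))) {
      expect_equal(row[[paste0("mean_", prof$organ[i])]], prof$mean_rpkm[i])
    }
  }
})

test_that("every gene gets exactly one call and thresholds are monotone", {
  atlas <- random_atlas(9, n_genes = 80)
  calls <- call_enrichment(atlas)
  expect_setequal(calls$gene, unique(atlas$gene))
  expect_equal(anyDuplicated(calls$gene), 0)

  base_set <- calls$gene[!is.na(calls$organ)]
  for (cfg in list(enrichment_config(fold_min = 3),
                   enrichment_config(expr_floor = 10),
                   enrichment_config(fold_min = 4, expr_floor = 5))) {
    stricter <- call_enrichment(atlas, cfg)
    expect_true(all(stricter$gene[!is.na(stricter$organ)] %in% base_set))
  }
})

test_that("planted organ-enriched genes are recovered exactly", {
  sim <- simulate_atlas(atlas_sim_config(seed = 5, n_genes = 400,
                                         n_enriched_per_organ = 10))
  calls <- call_enrichment(sim$atlas)
  called <- calls[!is.na(calls$organ), c("gene", "organ")]
  truth <- sim$truth$enriched
  merged <- merge(called, truth, by = "gene", all = TRUE)
  expect_equal(nrow(called), nrow(truth))          # no false discoveries
  expect_true(all(merged$organ.x == merged$organ.y))  # every planting found
})

test_that("heatmap table is organ-grouped, mean-sorted and tie-broken by gene", {
  atlas <- make_atlas(expand.grid(
    gene = c("a", "b", "c", "d"), organ = c("brain", "liver"),
    stage = c("P0", "P63"), stringsAsFactors = FALSE) |>
      dplyr::mutate(rpkm = c(20, 20, 9, 1, 0.1, 0.1, 0.1, 9,
                             20, 20, 9, 1, 0.1, 0.1, 0.1, 9)))
  calls <- call_enrichment(atlas)
  heat <- grouped_heatmap_table(calls, atlas)
  expect_equal(names(heat)[1:2], c("gene", "organ"))
  expect_equal(names(heat)[-(1:2)],
               c("brain|P0", "brain|P63", "liver|P0", "liver|P63"))
  # organ-contiguous rows, ties (a and b both mean 20 in brain) lexicographic
  expect_identical(heat$organ, sort(heat$organ))
  brain_rows <- heat$gene[heat$organ == "brain"]
  expect_identical(brain_rows, c("a", "b", "c"))

  # random calls: row order equals the stated sort key
  a2 <- random_atlas(13, n_genes = 40)
  c2 <- call_enrichment(a2)
  h2 <- grouped_heatmap_table(c2, a2)
  enr <- as.data.frame(c2)[!is.na(c2$organ), ]
  own <- sapply(seq_len(nrow(enr)),
                function(i) enr[[paste0("mean_", enr$organ[i])]][i])
  ord <- order(match(enr$organ, atlas_organs(a2)), -own, enr$gene)
  expect_identical(h2$gene, enr$gene[ord])
})
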