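tiny_counts <- function() {
  m <- Matrix::Matrix(rbind(
    gA = c(0, 1, 2, 0, 5, 0),
    gB = c(0, 0, 0, 0, 1, 1)), sparse = TRUE)
  colnames(m) <- sprintf("c%d", 1:6)
  meta <- tibble::tibble(cell = colnames(m), cluster = "GNP",
                         stage = rep(c("E12", "P0"), each = 3),
                         species = "mouse")
  cell_counts(m, meta)
}

test_that("dot-plot summary computes exact fractions and means per group", {
  cc <- tiny_counts()
  s <- summarize_dotplot(cc, c("gA", "gB"))
  a_e12 <- s[s$gene == "gA" & s$stage == "E12", ]
  expect_equal(a_e12$fraction_expressing, 2 / 3)
  expect_equal(a_e12$mean_expression, 1)
  b_e12 <- s[s$gene == "gB" & s$stage == "E12", ]
  expect_equal(b_e12$fraction_expressing, 0)   # all-zero group
  expect_equal(b_e12$mean_expression, 0)
  expect_error(summarize_dotplot(cc, "ghost"), "unknown gene")
})

test_that("summary matches a per-group loop oracle on random counts", {
  withr::with_seed(401, {
    n_cells <- 500
    m <- Matrix::Matrix(matrix(rpois(4 * n_cells, 0.7), nrow = 4), sparse = TRUE)
    dimnames(m) <- list(sprintf("g%d", 1:4), sprintf("c%03d", 1:n_cells))
    meta <- tibble::tibble(cell = colnames(m),
                           cluster = sample(c("GNP", "GN"), n_cells, TRUE),
                           stage = sample(c("E12", "P0", "P7"), n_cells, TRUE),
                           species = "mouse")
    cc <- cell_counts(m, meta)
    s <- summarize_dotplot(cc, rownames(m))
    oracle <- oracle_dotplot(cc, rownames(m))
    merged <- merge(as.data.frame(s), oracle, by = c("gene", "cluster", "stage"))
    expect_equal(nrow(merged), nrow(s))
    expect_equal(merged$fraction_expressing.x, merged$fraction_expressing.y)
    expect_equal(merged$mean_expression.x, merged$mean_expression.y)
    # fraction depends only on zero/nonzero: scaling counts changes nothing
    cc2 <- cell_counts(m * 7L, meta)
    s2 <- summarize_dotplot(cc2, rownames(m))
    expect_equal(s2$fraction_expressing, s$fraction_expressing)
  })
})

test_that("window extraction is an envelope with reported dips", {
  s <- tibble::tibble(
    gene = "g", cluster = "GNP", species = "mouse",
    stage = c("E10", "E12", "E14", "P0", "P4", "P10", "P14"),
    n_cells = 100,
    fraction_expressing = c(0.05, 0.5, 0.6, 0.3, 0.25, 0.21, 0.1),
    mean_expression = 1)
  w <- extract_window(s, "g", "GNP", min_fraction = 0.2)
  expect_equal(w$first_stage, "E12")
  expect_equal(w$last_stage, "P10")
  expect_equal(w$n_dips, 0)

  dip <- s
  dip$fraction_expressing[4] <- 0.1  # interior dip at P0
  wd <- extract_window(dip, "g", "GNP", min_fraction = 0.2)
  expect_equal(c(wd$first_stage, wd$last_stage), c("E12", "P10"))
  expect_equal(wd$n_dips, 1)

  none <- extract_window(s, "g", "GNP", min_fraction = 0.9)
  expect_equal(nrow(none), 0)

  single <- extract_window(s, "g", "GNP", min_fraction = 0.55)
  expect_equal(c(single$first_stage, single$last_stage), c("E14", "E14"))
})

test_that("duration normalisation follows the species timeline", {
  tl <- species_timeline("mouse", gestation_days = 19, lifespan_days = 730)
  w <- tibble::tibble(gene = "Tox3", cluster = "GNP", species = "mouse",
                      first_stage = "E12", last_stage = "P10", n_dips = 0L)
  nd <- normalize_duration(w, tl)
  expect_equal(nd$duration_days, 17)            # (19 + 10) - 12
  expect_equal(nd$normalized_duration, 17 / 730, tolerance = 1e-12)

  zero <- normalize_duration(
    dplyr::mutate(w, last_stage = "E12"), tl)
  expect_equal(zero$normalized_duration, 0)

  # doubling lifespan halves the normalised duration exactly
  tl2 <- species_timeline("mouse", 19, 1460)
  expect_equal(normalize_duration(w, tl2)$normalized_duration,
               nd$normalized_duration / 2)

  # widening the window never decreases normalised duration
  wider <- normalize_duration(dplyr::mutate(w, first_stage = "E10"), tl)
  expect_gte(wider$normalized_duration, nd$normalized_duration)

  expect_error(normalize_duration(
    dplyr::mutate(w, last_stage = "P99"), species_timeline(
      "mouse", 19, 730, stage_map = tibble::tibble(
        stage = c("E12", "P10"), age_days = c(12, 29)))), "P99")
})

test_that("MTX bundle round trip preserves counts and metadata", {
  cc <- tiny_counts()
  dir <- withr::local_tempdir()
  paths <- write_cluster_counts(cc, dir)
  back <- read_cluster_counts(paths$mtx, paths$genes, paths$cells, paths$meta)
  expect_equal(as.matrix(back$counts), as.matrix(cc$counts))
  expect_equal(back$cell_meta, cc$cell_meta)
})
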