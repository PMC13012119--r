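small_cfg <- function(seed = 1) {
  atlas_sim_config(seed = seed, n_genes = 240, n_enriched_per_organ = 8,
                   organs = c("brain", "cerebellum", "liver"),
                   stages = c("E12.5", "E15.5", "P0", "P14", "P63"))
}

test_that("atlas generator is bit-reproducible and respects the noiseless limit", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_atlas(simulate_atlas(small_cfg())$atlas, p1)
  write_expression_atlas(simulate_atlas(small_cfg())$atlas, p2)
  expect_identical(readLines(p1), readLines(p2))

  noiseless <- simulate_atlas(atlas_sim_config(
    seed = 3, n_genes = 60, n_enriched_per_organ = 5,
    organs = c("brain", "cerebellum"), noise_cv = 0, missing_rate = 0,
    perinatal_peak_fraction = 0))
  means <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(noiseless$atlas), gene, organ),
    m = mean(rpkm), .groups = "drop")
  tr <- noiseless$truth$enriched
  for (i in seq_len(nrow(tr))) {
    own <- means$m[means$gene == tr$gene[i] & means$organ == tr$organ[i]]
    other <- means$m[means$gene == tr$gene[i] & means$organ != tr$organ[i]]
    expect_equal(own / other, 8, tolerance = 1e-12)  # exact planted fold
  }
})

test_that("planted temporal genes carry the planted boundary-stage ratio", {
  sim <- simulate_atlas(atlas_sim_config(
    seed = 4, n_genes = 100, n_enriched_per_organ = 10,
    organs = c("brain", "cerebellum"), noise_cv = 0, missing_rate = 0))
  atl <- tibble::as_tibble(sim$atlas)
  tp <- sim$truth$temporal_pass
  expect_gt(nrow(tp), 0)
  for (i in seq_len(nrow(tp))) {
    sub <- atl[atl$gene == tp$gene[i] & atl$organ == tp$organ[i], ]
    ratio <- sub$rpkm[sub$stage == "P0"] / sub$rpkm[sub$stage == "P63"]
    expect_equal(ratio, 40, tolerance = 1e-9)
  }
})

test_that("generator rejects inconsistent configurations", {
  expect_error(atlas_sim_config(n_genes = 10, n_enriched_per_organ = 5),
               "exceeds n_genes")
  expect_error(atlas_sim_config(noise_cv = -1), "noise_cv")
  expect_error(atlas_sim_config(stages = c("P0", "P63"),
                                perinatal_peak_fraction = 0.5,
                                n_genes = 2000),
               NA)  # P0/P63 present: fine
  expect_error(atlas_sim_config(stages = c("E12.5", "P0")),
               "requires stages P0 and P63")
  expect_error(simulate_peaks(n_a = 100, n_b = 10, co_fraction = 0.5),
               "exceeds n_b")
  expect_error(simulate_peaks(genome_length = 1e4), "infeasible packing")
  expect_error(simulate_cluster_counts(
    stages = "P0", genes = "g",
    planted_windows = tibble::tibble(gene = "g", first_stage = "P0",
                                     last_stage = "P0"),
    p_in = 0.1, p_out = 0.2), "p_in must exceed")
})

test_that("peak generator plants the co-occupancy fraction exactly", {
  pk <- simulate_peaks(seed = 11, n_a = 200, n_b = 220, co_fraction = 0.35,
                       window = 500)
  flags <- proximity_overlap(pk$peaks_a, pk$peaks_b, 500)
  expect_equal(attr(flags, "fraction_near"), round(0.35 * 200) / 200)
  expect_identical(flags$near, pk$truth$co_occupied)
  # non-co-occupied peaks stay beyond twice the window
  far <- proximity_overlap(pk$peaks_a, pk$peaks_b, 2 * 500)
  expect_identical(far$near, pk$truth$co_occupied)
})

test_that("single-cell generator: degenerate and null regimes behave as stated", {
  w <- tibble::tibble(gene = "g", first_stage = "E12", last_stage = "P0")
  one <- simulate_cluster_counts(seed = 5, stages = c("E12", "P0"),
                                 n_cells_per_stage = 1, genes = "g",
                                 planted_windows = w)
  s <- summarize_dotplot(one$counts, "g")
  expect_true(all(s$fraction_expressing %in% c(0, 1)))

  # determinism at the emitted-text level
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    cc <- simulate_cluster_counts(seed = 6, stages = c("E12", "P0"),
                                  n_cells_per_stage = 20, genes = c("g", "h"),
                                  planted_windows = w)
    write_cluster_counts(cc$counts, d)
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("fixture directory parses through every reader", {
  dir <- withr::local_tempdir()
  simulate_fixture(dir, seed = 2, atlas_config = small_cfg())
  atlas <- read_expression_atlas(file.path(dir, "atlas.tsv"))
  expect_s3_class(atlas, "expr_atlas")
  catalog <- read_regulator_catalog(file.path(dir, "catalog.tsv"))
  expect_setequal(catalog$gene, atlas_genes(atlas))
  ev <- read_ortholog_evidence(file.path(dir, "evidence.tsv"))
  expect_gt(nrow(ev), 0)
  gmt <- read_gmt(file.path(dir, "terms.gmt"))
  expect_true(all(c("term", "name", "gene") %in% names(gmt)))
  expect_gt(nrow(read_bed(file.path(dir, "peaks_a.bed"))), 0)
  expect_gt(nrow(read_bed(file.path(dir, "peaks_b.bed"))), 0)
  expect_gt(nrow(read_gene_anchors(file.path(dir, "anchors.tsv"))), 0)
  fa <- read_enhancer_fasta(file.path(dir, "enhancers.synthetic.fasta"))
  expect_true("lamprey" %in% names(fa))
  tls <- read_species_timelines(file.path(dir, "timelines.tsv"),
                                file.path(dir, "stage_map.tsv"))
  expect_setequal(names(tls), c("zebrafish", "mouse", "human"))
  cc <- read_cluster_counts(file.path(dir, "counts.mtx"),
                            file.path(dir, "counts_genes.tsv"),
                            file.path(dir, "counts_cells.tsv"),
                            file.path(dir, "counts_cell_meta.tsv"))
  expect_s3_class(cc, "cell_counts")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 2)
})
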