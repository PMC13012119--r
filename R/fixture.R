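#' Emit a complete synthetic fixture directory
#'
#' Generates every input the pipeline consumes — atlas TSV, regulator
#' catalog, ortholog-evidence table, GMT annotations, two BED peak sets with
#' gene anchors, per-species enhancer FASTA, a MatrixMarket count bundle and
#' species timelines — together with `truth.json` recording the planted
#' ground truth. All files are plain text and bit-reproducible given the
#' seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed driving every generator.
#' @param atlas_config An [atlas_sim_config()]; its own `seed` field is
#'   overridden by `seed`.
#' @param co_fraction Planted peak co-occupancy fraction.
#' @param window Peak proximity window in bases.
#' @return Named list of written paths plus the `truth` list, invisibly.
#' @export
simulate_fixture <- function(dir, seed = 1L,
                             atlas_config = atlas_sim_config(),
                             co_fraction = 0.6, window = 1000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atlas_config$seed <- as.integer(seed)
  sim <- simulate_atlas(atlas_config)
  atlas <- sim$atlas
  truth <- sim$truth
  genes <- atlas_genes(atlas)

  paths <- list(atlas = file.path(dir, "atlas.tsv"),
                catalog = file.path(dir, "catalog.tsv"),
                evidence = file.path(dir, "evidence.tsv"),
                gmt = file.path(dir, "terms.gmt"),
                bed_a = file.path(dir, "peaks_a.bed"),
                bed_b = file.path(dir, "peaks_b.bed"),
                anchors = file.path(dir, "anchors.tsv"),
                fasta = file.path(dir, "enhancers.synthetic.fasta"),
                timeline = file.path(dir, "timelines.tsv"),
                stage_map = file.path(dir, "stage_map.tsv"),
                truth = file.path(dir, "truth.json"))

  write_expression_atlas(atlas, paths$atlas)

  withr::with_seed(seed + 1L, {
    catalog <- tibble(
      gene = genes,
      class = sample(c("transcription_factor", "cofactor"), length(genes),
                     replace = TRUE, prob = c(0.7, 0.3))
    )
    write_tsv_atomic(catalog, paths$catalog)

    status_map <- c(type_I = "related_nonortholog", type_II = "absent",
                    conserved = "ortholog")
    evidence <- tibble(gene = truth$evo_category$gene,
                       outgroup_taxon = "sea_lamprey",
                       status = unname(status_map[truth$evo_category$category]))
    write_tsv_atomic(arrange(evidence, .data$gene), paths$evidence)

    organs <- atlas_config$organs
    gmt_lines <- vapply(organs, function(o) {
      members <- truth$enriched$gene[truth$enriched$organ == o]
      extra <- sample(setdiff(genes, members), 20)
      paste(c(paste0("DEV_", toupper(o)), paste0(o, " development"),
              sort(c(members, extra))), collapse = "\t")
    }, character(1))
    rand_lines <- vapply(1:10, function(i) {
      paste(c(sprintf("RAND_%02d", i), sprintf("random set %d", i),
              sort(sample(genes, sample(15:60, 1)))), collapse = "\t")
    }, character(1))
    write_atomic(function(p) readr::write_lines(c(gmt_lines, rand_lines), p),
                 paths$gmt)
  })

  pk <- simulate_peaks(seed = seed + 2L, co_fraction = co_fraction,
                       window = window)
  write_bed(pk$peaks_a, paths$bed_a)
  write_bed(pk$peaks_b, paths$bed_b)
  withr::with_seed(seed + 3L, {
    n_anchor <- 100L
    anchors <- tibble(
      gene = sort(sample(genes, n_anchor)),
      chrom = "chrS",
      anchor = sort(sample.int(2e7, n_anchor)),
      strand = sample(c("+", "-"), n_anchor, replace = TRUE)
    )
    write_tsv_atomic(anchors, paths$anchors)
  })

  fa <- simulate_enhancers(seed + 4L)
  write_atomic(function(p) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(fa$seqs), p)
  }, paths$fasta)

  timelines <- tibble(
    species = c("zebrafish", "mouse", "human"),
    gestation_days = c(0, 19, 280),
    lifespan_days = c(1095, 730, 29200)
  )
  write_tsv_atomic(timelines, paths$timeline)
  stage_map <- bind_rows(
    tibble(species = "zebrafish", stage = c("1dpf", "2dpf", "5dpf"),
           age_days = c(1, 2, 5)),
    tibble(species = "mouse",
           stage = c("E10", "E12", "E14", "E17", "P0", "P4", "P7", "P10"),
           age_days = c(10, 12, 14, 17, 19, 23, 26, 29)),
    tibble(species = "human",
           stage = c("9wpc", "17wpc", "newborn", "infant", "adult"),
           age_days = c(63, 119, 280, 645, 7580))
  )
  write_tsv_atomic(stage_map, paths$stage_map)

  mouse_stages <- c("E10", "E12", "E14", "E17", "P0", "P4", "P7", "P10")
  planted_windows <- tibble(
    gene = c("Tox3", "Atoh1", "Mki67"),
    first_stage = c("E12", "E12", "E10"),
    last_stage = c("P10", "P10", "P10")
  )
  cc <- simulate_cluster_counts(seed = seed + 5L, species = "mouse",
                                stages = mouse_stages,
                                genes = c("Tox3", "Atoh1", "Mki67", "Neurod1"),
                                planted_windows = planted_windows)
  count_paths <- write_cluster_counts(cc$counts, dir)

  truth_json <- list(
    seed = seed,
    enriched_counts = as.list(table(factor(truth$enriched$organ,
                                           levels = atlas_config$organs))),
    enriched = truth$enriched,
    temporal_pass = truth$temporal_pass,
    evo_counts = as.list(table(truth$evo_category$category)),
    evo_category = truth$evo_category,
    co_occupancy = list(fraction = pk$truth$fraction, window = window,
                        n_a = nrow(pk$peaks_a), n_b = nrow(pk$peaks_b)),
    motif_presence = fa$presence,
    planted_windows = planted_windows
  )
  write_json_atomic(truth_json, paths$truth)

  invisible(c(paths, count_paths, list(truth = truth_json)))
}

# Per-species synthetic enhancer sequences: E-box-free random background
# with a consensus E-box planted in every species except lamprey.
simulate_enhancers <- function(seed, length_bp = 600L,
                               species = c("zebrafish", "frog", "lizard",
                                           "mouse", "human", "lamprey"),
                               ablated = "lamprey", motif = "CAGCTG") {
  withr::with_seed(seed, {
    seqs <- vapply(species, function(sp) {
      s <- paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
                 collapse = "")
      scrub_ebox(s)
    }, character(1))
    insert_at <- as.integer(length_bp / 2)
    planted <- !species %in% ablated
    seqs[planted] <- vapply(seqs[planted], function(s) {
      paste0(substr(s, 1, insert_at), motif,
             substr(s, insert_at + nchar(motif) + 1, nchar(s)))
    }, character(1))
    list(seqs = seqs,
         presence = setNames(as.list(planted), species))
  })
}

# Remove every canonical E-box (CANNTG, palindromic consensus) by mutating
# the leading C; iterate until the sequence is motif-free on both strands.
scrub_ebox <- function(s) {
  repeat {
    hits <- scan_motif(s, motif_query("CANNTG"))
    if (nrow(hits) == 0) return(s)
    pos <- hits$position[1] + 1L
    substr(s, pos, pos) <- "T"
  }
}
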