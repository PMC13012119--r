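#' Synthetic atlas configuration
#'
#' Conditions for the planted-truth atlas generator. Defaults emulate the
#' structure of a seven-organ developmental atlas: 2,000 regulator genes,
#' 14 stages per organ from mid-gestation to adulthood, 50 planted
#' organ-enriched genes per organ at 8-fold enrichment over background, and
#' a log-normal multiplicative noise with 20% coefficient of variation.
#' A `perinatal_peak_fraction` of each organ's enriched genes additionally
#' receives a perinatal-high temporal profile whose planted birth/adult
#' (P0/P63) mean ratio is `planted_ratio` — far above the screen's threshold
#' so recovery tests are sharp.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes.
#' @param organs Organ labels.
#' @param stages Stage labels shared by all organs (must contain `"P0"` and
#'   `"P63"` when `perinatal_peak_fraction > 0`).
#' @param n_enriched_per_organ Planted enriched genes per organ.
#' @param enrichment_fold Planted fold of the target organ over background
#'   (> 1).
#' @param perinatal_peak_fraction Fraction of each organ's enriched genes
#'   given the perinatal-high profile.
#' @param planted_ratio Planted P0/P63 mean ratio of temporal genes.
#' @param baseline_rpkm Background mean RPKM scale.
#' @param noise_cv Log-normal coefficient of variation (>= 0; 0 = noiseless).
#' @param missing_rate Fraction of atlas cells dropped as unavailable, in
#'   `[0, 1)`. Cells that define the planted temporal truth (the P0 and P63
#'   measurements of temporal genes in their organ) are never dropped, so the
#'   planted labels stay consistent with the emitted data.
#' @return An `atlas_sim_config` list.
#' @export
atlas_sim_config <- function(seed = 1L, n_genes = 2000L,
                             organs = c("brain", "cerebellum", "heart",
                                        "kidney", "liver", "ovary", "testis"),
                             stages = c("E10.5", "E11.5", "E12.5", "E13.5",
                                        "E14.5", "E15.5", "E16.5", "E17.5",
                                        "P0", "P3", "P7", "P14", "P28", "P63"),
                             n_enriched_per_organ = 50L,
                             enrichment_fold = 8,
                             perinatal_peak_fraction = 0.4,
                             planted_ratio = 40,
                             baseline_rpkm = 5,
                             noise_cv = 0.2,
                             missing_rate = 0.02) {
  if (length(stages) > 14) abort("at most 14 stages per organ")
  if (n_enriched_per_organ * length(organs) > n_genes) {
    abort("n_enriched_per_organ x organs exceeds n_genes")
  }
  if (enrichment_fold <= 1) abort("enrichment_fold must be > 1")
  if (perinatal_peak_fraction < 0 || perinatal_peak_fraction > 1) {
    abort("perinatal_peak_fraction must lie in [0, 1]")
  }
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)")
  }
  if (perinatal_peak_fraction > 0 && !all(c("P0", "P63") %in% stages)) {
    abort("temporal planting requires stages P0 and P63")
  }
  parse_stage(stages)
  structure(as.list(environment()), class = "atlas_sim_config")
}

#' Simulate a developmental expression atlas with planted truth
#'
#' Deterministic planted means with log-normal multiplicative noise:
#' background genes are flat across organs and stages at a gene-specific
#' baseline; each planted enriched gene has its target-organ means raised
#' `enrichment_fold`-fold; planted temporal genes additionally follow a
#' perinatal-peak stage profile (embryonic ramp to a birth peak, then decay
#' to `1/planted_ratio` of the peak by P63), rescaled so the organ mean is
#' unchanged. Output is bit-reproducible given the seed.
#'
#' @param config An [atlas_sim_config()].
#' @return List with elements `atlas` (an `expr_atlas`) and `truth` (a list
#'   with tibbles `enriched` (`gene`, `organ`), `temporal_pass`
#'   (`gene`, `organ`), `evo_category` (`gene`, `category`) and the config).
#' @export
simulate_atlas <- function(config = atlas_sim_config()) {
  stopifnot(inherits(config, "atlas_sim_config"))
  withr::with_seed(config$seed, simulate_atlas_impl(config))
}

simulate_atlas_impl <- function(cfg) {
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  organs <- cfg$organs
  stages <- cfg$stages
  n_org <- length(organs)
  n_stg <- length(stages)

  base <- exp(rnorm(cfg$n_genes, 0, 0.5) - 0.125)
  enriched_idx <- sample.int(cfg$n_genes, cfg$n_enriched_per_organ * n_org)
  base[enriched_idx] <- pmax(base[enriched_idx], 0.25)
  enriched <- tibble(
    gene = genes[enriched_idx],
    organ = rep(organs, each = cfg$n_enriched_per_organ)
  )
  n_temporal <- round(cfg$perinatal_peak_fraction * cfg$n_enriched_per_organ)
  temporal <- enriched |>
    group_by(.data$organ) |>
    slice(sort(sample.int(n(), n_temporal))) |>
    ungroup() |>
    select("gene", "organ")

  # perinatal-peak stage shape, planted numerator/denominator ratio fixed
  shape <- vapply(stages, function(s) {
    ph <- stage_phase(s)
    v <- stage_days(s)
    if (ph == "embryonic") 0.3 + 0.7 * min(v / 18, 1)
    else cfg$planted_ratio^(-v / stage_days("P63"))
  }, numeric(1))
  shape <- shape / mean(shape)

  grid <- tidyr::crossing(gene = genes, organ = organs, stage = stages) |>
    arrange(match(.data$gene, genes), match(.data$organ, organs),
            match(.data$stage, stages))
  gi <- match(grid$gene, genes)
  si <- match(grid$stage, stages)
  mean_val <- cfg$baseline_rpkm * base[gi]
  target <- paste(enriched$gene, enriched$organ)
  is_target <- paste(grid$gene, grid$organ) %in% target
  mean_val[is_target] <- mean_val[is_target] * cfg$enrichment_fold
  is_temporal <- paste(grid$gene, grid$organ) %in%
    paste(temporal$gene, temporal$organ)
  mean_val[is_temporal] <- mean_val[is_temporal] * shape[si[is_temporal]]

  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  noise <- if (cfg$noise_cv == 0) rep(1, nrow(grid)) else
    exp(rnorm(nrow(grid), 0, sdlog) - sdlog^2 / 2)
  rpkm <- mean_val * noise

  protected <- is_temporal & grid$stage %in% c("P0", "P63")
  drop <- runif(nrow(grid)) < cfg$missing_rate & !protected
  atlas <- expr_atlas(mutate(grid, rpkm = rpkm)[!drop, ])

  evo_levels <- c("type_I", "type_II", "conserved")
  evo_probs <- c(12, 10, 4) / 26
  evo <- tibble(
    gene = temporal$gene,
    category = sample(evo_levels, nrow(temporal), replace = TRUE,
                      prob = evo_probs)
  )
  list(atlas = atlas,
       truth = list(enriched = enriched, temporal_pass = temporal,
                    evo_category = evo, config = cfg))
}

#' Simulate two peak sets with a planted co-occupancy fraction
#'
#' Places peaks in disjoint genomic slots sized so that exactly
#' `round(co_fraction * n_a)` A peaks have a B peak within `window` bases
#' (gap drawn uniformly in `[0, window]`) and every other A peak is farther
#' than `2 * window` from any B peak. The realised co-occupancy fraction
#' under [proximity_overlap()] at the same window is therefore exact.
#'
#' @param seed Integer RNG seed.
#' @param n_a,n_b Number of A and B peaks.
#' @param co_fraction Planted fraction of co-occupied A peaks in `[0, 1]`.
#' @param genome_length Length of the simulated chromosome in bases.
#' @param window Proximity window in bases.
#' @param chrom Chromosome label.
#' @return List with tibbles `peaks_a`, `peaks_b` and a `truth` list
#'   (`n_co`, `fraction`, `window`, per-A `co_occupied` flags).
#' @export
simulate_peaks <- function(seed = 1L, n_a = 500L, n_b = 500L,
                           co_fraction = 0.6, genome_length = 2e7,
                           window = 1000L, chrom = "chrS") {
  if (co_fraction < 0 || co_fraction > 1) abort("co_fraction must be in [0, 1]")
  n_co <- round(co_fraction * n_a)
  if (n_co > n_b) abort("infeasible: co_fraction * n_a exceeds n_b")
  max_len <- 400L
  slot <- 2L * max_len + 6L * max(window, 100L)
  n_slots <- n_a + (n_b - n_co)
  if (as.numeric(n_slots) * slot > genome_length) {
    abort("infeasible packing: genome_length too small for requested peaks")
  }
  withr::with_seed(seed, {
    starts <- sample.int(n_slots, n_slots) - 1L
    starts <- starts * slot
    lens <- function(n) sample(150:max_len, n, replace = TRUE)
    a_slots <- starts[seq_len(n_a)]
    b_only <- starts[seq_len(n_b - n_co) + n_a]
    la <- lens(n_a)
    a <- tibble(chrom = chrom, start = a_slots, end = a_slots + la,
                name = sprintf("A_%04d", seq_len(n_a)))
    co <- seq_len(n_co)
    gap <- if (n_co > 0) floor(runif(n_co, 0, window + 1)) else integer(0)
    gap <- pmin(gap, window)
    lb_co <- lens(n_co)
    b_co <- tibble(chrom = chrom, start = a$end[co] + gap,
                   end = a$end[co] + gap + lb_co)
    lb_only <- lens(n_b - n_co)
    b_lone <- tibble(chrom = chrom, start = b_only, end = b_only + lb_only)
    b <- bind_rows(b_co, b_lone) |>
      mutate(name = sprintf("B_%04d", row_number()))
    truth <- list(n_co = n_co, fraction = if (n_a > 0) n_co / n_a else 0,
                  window = window,
                  co_occupied = seq_len(n_a) %in% co)
    list(peaks_a = a, peaks_b = b, truth = truth)
  })
}

#' Simulate cluster counts with planted expression windows
#'
#' For each gene, cells whose stage lies inside the gene's planted window
#' express it (count drawn as `1 + Poisson(lambda)`) with probability
#' `p_in`; cells outside express with probability `p_out`. All cells carry
#' one cluster label: clustering is upstream of this package and the
#' generator emulates its output, not its mechanism.
#'
#' @param seed Integer RNG seed.
#' @param species Species label.
#' @param stages Ordered stage labels.
#' @param n_cells_per_stage Cells per stage.
#' @param genes Gene identifiers.
#' @param planted_windows Tibble `gene`, `first_stage`, `last_stage` (subset
#'   of `genes`; genes without a row never express above `p_out`).
#' @param p_in,p_out Expression probabilities inside/outside the window
#'   (`p_in > p_out`).
#' @param cluster Cluster label.
#' @param lambda Poisson mean of the positive count component.
#' @return List with `counts` (a [cell_counts()]) and `truth`
#'   (the planted windows).
#' @export
simulate_cluster_counts <- function(seed = 1L, species = "mouse",
                                    stages, n_cells_per_stage = 500L,
                                    genes, planted_windows,
                                    p_in = 0.5, p_out = 0.02,
                                    cluster = "GNP", lambda = 1.5) {
  if (p_in <= p_out) abort("p_in must exceed p_out")
  planted_windows <- as_tibble(planted_windows)
  bad <- setdiff(c(planted_windows$first_stage, planted_windows$last_stage),
                 stages)
  if (length(bad) > 0) abort(sprintf("planted stage not in stages: %s", bad[1]))
  withr::with_seed(seed, {
    n_cells <- n_cells_per_stage * length(stages)
    cell_stage <- rep(stages, each = n_cells_per_stage)
    cells <- sprintf("cell_%05d", seq_len(n_cells))
    rows <- lapply(seq_along(genes), function(g) {
      w <- dplyr::filter(planted_windows, .data$gene == genes[g])
      stage_idx <- match(cell_stage, stages)
      inside <- if (nrow(w) == 1) {
        stage_idx >= match(w$first_stage, stages) &
          stage_idx <= match(w$last_stage, stages)
      } else rep(FALSE, n_cells)
      p <- ifelse(inside, p_in, p_out)
      expressed <- runif(n_cells) < p
      counts <- integer(n_cells)
      counts[expressed] <- 1L + rpois(sum(expressed), lambda)
      counts
    })
    m <- methods::as(Matrix::Matrix(do.call(rbind, rows), sparse = TRUE),
                     "CsparseMatrix")
    dimnames(m) <- list(genes, cells)
    meta <- tibble(cell = cells, cluster = cluster, stage = cell_stage,
                   species = species)
    list(counts = cell_counts(m, meta),
         truth = planted_windows)
  })
}
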