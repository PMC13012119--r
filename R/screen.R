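#' Temporal candidate-screen configuration
#'
#' The candidate filter keeps organ-enriched genes that are both expressed
#' (mean RPKM strictly above `min_mean_rpkm` over the organ's stages) and
#' perinatally dynamic (expression ratio between a numerator stage, birth by
#' default, and a denominator stage, adulthood by default, strictly above
#' `min_ratio`). Both inequalities are strict. A small pseudocount guards the
#' ratio against zero denominators.
#'
#' @param min_mean_rpkm Mean-expression threshold (default 1, strict `>`).
#' @param min_ratio Stage-ratio threshold (default 8, strict `>`).
#' @param numerator_stage Stage label for the ratio numerator (default "P0").
#' @param denominator_stage Stage label for the denominator (default "P63").
#' @param ratio_pseudocount RPKM added to both ratio terms (default 0.01).
#' @param stages Optional character vector restricting the averaging window
#'   to a stage subset; `NULL` (default) averages over all available stages.
#' @return A `screen_config` list.
#' @export
screen_config <- function(min_mean_rpkm = 1, min_ratio = 8,
                          numerator_stage = "P0", denominator_stage = "P63",
                          ratio_pseudocount = 0.01, stages = NULL) {
  if (min_mean_rpkm <= 0 || min_ratio <= 0 || ratio_pseudocount <= 0) {
    abort("screen thresholds and pseudocount must be positive")
  }
  if (identical(numerator_stage, denominator_stage)) {
    abort("numerator and denominator stages must differ")
  }
  parse_stage(c(numerator_stage, denominator_stage))
  structure(list(min_mean_rpkm = min_mean_rpkm, min_ratio = min_ratio,
                 numerator_stage = numerator_stage,
                 denominator_stage = denominator_stage,
                 ratio_pseudocount = ratio_pseudocount, stages = stages),
            class = "screen_config")
}

#' Screen organ-enriched genes for perinatal candidates
#'
#' Applies the two-predicate temporal filter to a gene set within one organ
#' of the atlas. Every input gene yields a record; genes missing the
#' numerator or denominator stage (or all data for the organ) are emitted
#' with `passes = FALSE` and a flagged `reason` rather than dropped.
#'
#' @param atlas An `expr_atlas`.
#' @param organ Organ label present in the atlas.
#' @param genes Non-empty character vector of gene identifiers (must be
#'   atlas genes).
#' @param config A [screen_config()].
#' @return A `screen_candidates` tibble with columns `gene`, `mean_rpkm`,
#'   `numerator_value`, `denominator_value`, `ratio`, `passes`, `reason`,
#'   sorted by descending ratio (`NA` ratios last, ties by gene id).
#' @examples
#' atlas <- expr_atlas(tibble::tibble(
#'   gene = "Tox3", organ = "cerebellum",
#'   stage = c("E13.5", "P0", "P63"), rpkm = c(12, 16, 1.9)))
#' screen_candidates(atlas, "cerebellum", "Tox3")
#' @export
screen_candidates <- function(atlas, organ, genes, config = screen_config()) {
  if (!organ %in% atlas_organs(atlas)) {
    abort(sprintf("organ not in atlas: %s", organ))
  }
  genes <- unique(as.character(genes))
  if (length(genes) == 0) abort("empty gene set")
  unknown <- setdiff(genes, unique(atlas$gene))
  if (length(unknown) > 0) {
    abort(sprintf("gene not in atlas: %s", unknown[1]))
  }
  eps <- config$ratio_pseudocount
  sub <- dplyr::filter(as_tibble(atlas), .data$organ == !!organ,
                       .data$gene %in% genes)
  msub <- if (is.null(config$stages)) sub else
    dplyr::filter(sub, .data$stage %in% config$stages)

  means <- msub |>
    group_by(.data$gene) |>
    summarise(mean_rpkm = mean(.data$rpkm), .groups = "drop")
  pick <- function(stage_label, col) {
    sub |>
      dplyr::filter(.data$stage == stage_label) |>
      select("gene", !!col := "rpkm")
  }
  out <- tibble(gene = genes) |>
    left_join(means, by = "gene") |>
    left_join(pick(config$numerator_stage, "numerator_value"), by = "gene") |>
    left_join(pick(config$denominator_stage, "denominator_value"), by = "gene") |>
    mutate(
      ratio = (.data$numerator_value + eps) / (.data$denominator_value + eps),
      passes = !is.na(.data$mean_rpkm) & !is.na(.data$ratio) &
        .data$mean_rpkm > config$min_mean_rpkm & .data$ratio > config$min_ratio,
      reason = dplyr::case_when(
        is.na(.data$mean_rpkm) ~ "no data for organ",
        is.na(.data$numerator_value) ~
          paste("missing numerator stage", config$numerator_stage),
        is.na(.data$denominator_value) ~
          paste("missing denominator stage", config$denominator_stage),
        .data$passes ~ "ok",
        TRUE ~ "below threshold"
      )
    ) |>
    arrange(desc(.data$ratio), .data$gene)
  structure(out, organ = organ, config = config,
            class = c("screen_candidates", class(out)))
}

#' Flag perinatally high-expressed candidates
#'
#' Adds a `high_expression` column: `TRUE` iff `mean_rpkm` strictly exceeds
#' `floor` (default 10 RPKM), the conventional bar for calling a candidate
#' highly expressed in the perinatal organ.
#'
#' @param records A `screen_candidates` tibble.
#' @param floor RPKM floor (default 10, strict `>`).
#' @return `records` with a logical `high_expression` column appended.
#' @export
high_expression_flag <- function(records, floor = 10) {
  mutate(records,
         high_expression = !is.na(.data$mean_rpkm) & .data$mean_rpkm > floor)
}

#' @method glance screen_candidates
#' @export
glance.screen_candidates <- function(x, ...) {
  tibble(organ = attr(x, "organ"), n_screened = nrow(x),
         n_pass = sum(x$passes), n_flagged = sum(x$reason != "ok" &
                                                   x$reason != "below threshold"))
}
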