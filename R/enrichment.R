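#' Organ-enrichment configuration
#'
#' Parameters of the organ-enrichment rule. A gene is called enriched in its
#' top organ when that organ's mean developmental expression clears an
#' absolute floor and exceeds the second-highest organ mean by a pseudocounted
#' fold change. The pseudocount appears in both numerator and denominator, so
#' it avoids division by zero and caps scores for near-silent backgrounds.
#'
#' @param expr_floor Minimum mean RPKM in the top organ (default 1).
#' @param fold_min Minimum fold over the second-highest organ mean
#'   (default 2, must be >= 1).
#' @param pseudocount RPKM added to numerator and denominator (default 0.1).
#' @return An `enrichment_config` list.
#' @export
enrichment_config <- function(expr_floor = 1, fold_min = 2, pseudocount = 0.1) {
  if (expr_floor <= 0 || pseudocount <= 0) abort("parameters must be positive")
  if (fold_min < 1) abort("fold_min must be >= 1")
  structure(list(expr_floor = expr_floor, fold_min = fold_min,
                 pseudocount = pseudocount), class = "enrichment_config")
}

#' Per-organ mean developmental expression of one gene
#'
#' Arithmetic mean of the gene's RPKM over the stages actually measured in
#' each organ; an organ with no available stage for the gene is absent from
#' the result (missing data are skipped, never treated as zero).
#'
#' @param atlas An `expr_atlas`.
#' @param gene A single gene identifier present in the atlas.
#' @return Tibble with columns `organ`, `mean_rpkm`, in declared organ order.
#' @export
organ_mean_profile <- function(atlas, gene) {
  stopifnot(length(gene) == 1L)
  sub <- dplyr::filter(as_tibble(atlas), .data$gene == !!gene)
  if (nrow(sub) == 0) abort(sprintf("unknown gene: %s", gene))
  sub |>
    group_by(organ = .data$organ) |>
    summarise(mean_rpkm = mean(.data$rpkm), .groups = "drop") |>
    arrange(match(.data$organ, atlas_organs(atlas)))
}

#' Call organ enrichment for every gene in an atlas
#'
#' For each gene, let `m1` be the highest per-organ mean and `m2` the second
#' highest (0 when only one organ was measured). The score is
#' `(m1 + pseudocount) / (m2 + pseudocount)`; the gene is called enriched in
#' the argmax organ iff `m1 >= expr_floor` and `score >= fold_min`, otherwise
#' its organ is `NA`. Each gene receives exactly one call, so the enriched
#' organs partition the enriched gene set.
#'
#' @param atlas An `expr_atlas` with at least two organs.
#' @param config An [enrichment_config()].
#' @return An `enrichment_calls` tibble with columns `gene`, `organ` (`NA`
#'   for not enriched), `score`, and one `mean_<organ>` column per organ.
#'   Enriched rows come first, grouped by organ in declared order and sorted
#'   by descending mean in the called organ (ties broken by gene id);
#'   unenriched rows follow, sorted by gene id.
#' @examples
#' atlas <- expr_atlas(tidyr::crossing(
#'   gene = "Tox3", organ = c("cerebellum", "liver"), stage = c("P0", "P63")
#' ) |> dplyr::mutate(rpkm = c(16, 4, 0.2, 0.1)))
#' call_enrichment(atlas)
#' @export
call_enrichment <- function(atlas, config = enrichment_config()) {
  organs <- atlas_organs(atlas)
  if (length(organs) < 2) abort("atlas must contain >= 2 organs")
  means <- as_tibble(atlas) |>
    group_by(.data$gene, .data$organ) |>
    summarise(mean_rpkm = mean(.data$rpkm), .groups = "drop")

  ranked <- means |>
    group_by(.data$gene) |>
    arrange(desc(.data$mean_rpkm), match(.data$organ, organs),
            .by_group = TRUE) |>
    summarise(
      top_organ = .data$organ[1],
      m1 = .data$mean_rpkm[1],
      m2 = ifelse(n() > 1, .data$mean_rpkm[2], 0),
      .groups = "drop"
    ) |>
    mutate(
      score = (.data$m1 + config$pseudocount) / (.data$m2 + config$pseudocount),
      enriched = .data$m1 >= config$expr_floor & .data$score >= config$fold_min,
      organ = ifelse(.data$enriched, .data$top_organ, NA_character_)
    )

  wide <- means |>
    mutate(organ = paste0("mean_", .data$organ)) |>
    tidyr::pivot_wider(names_from = "organ", values_from = "mean_rpkm")
  for (o in paste0("mean_", organs)) if (!o %in% names(wide)) wide[[o]] <- NA_real_
  wide <- wide[, c("gene", paste0("mean_", organs))]

  out <- ranked |>
    select("gene", "organ", "score", "m1") |>
    left_join(wide, by = "gene") |>
    arrange(is.na(.data$organ), match(.data$organ, organs),
            desc(.data$m1), .data$gene) |>
    select(-"m1")
  structure(out, organs = organs, config = config,
            class = c("enrichment_calls", class(out)))
}

#' Heatmap-ready table of enriched genes
#'
#' Restricts to enriched genes, groups rows by called organ in declared organ
#' order, sorts within organ by descending mean expression in that organ
#' (ties broken lexicographically by gene id), and lays out one value column
#' per (organ, stage) cell of the atlas, `NA` where unmeasured.
#'
#' @param calls An `enrichment_calls` tibble from [call_enrichment()].
#' @param atlas The `expr_atlas` the calls were produced from.
#' @return Tibble with columns `gene`, `organ`, then `<organ>|<stage>` value
#'   columns in declared organ and developmental stage order.
#' @export
grouped_heatmap_table <- function(calls, atlas) {
  organs <- atlas_organs(atlas)
  stages <- atlas_stages(atlas)
  enr <- dplyr::filter(as_tibble(calls), !is.na(.data$organ))
  enr$own_mean <- vapply(seq_len(nrow(enr)), function(i) {
    enr[[paste0("mean_", enr$organ[i])]][i]
  }, numeric(1))
  enr <- enr |>
    arrange(match(.data$organ, organs), desc(.data$own_mean), .data$gene) |>
    select("gene", "organ")

  cells <- tibble(
    organ = rep(names(stages), lengths(stages)),
    stage = unlist(stages, use.names = FALSE)
  ) |> mutate(col = paste0(.data$organ, "|", .data$stage))
  long <- as_tibble(atlas) |>
    semi_join(enr, by = "gene") |>
    mutate(col = paste0(.data$organ, "|", .data$stage)) |>
    select("gene", "col", "rpkm")
  wide <- tidyr::pivot_wider(long, names_from = "col", values_from = "rpkm")
  for (cl in cells$col) if (!cl %in% names(wide)) wide[[cl]] <- NA_real_
  enr |> left_join(wide[, c("gene", cells$col)], by = "gene")
}

#' @method glance enrichment_calls
#' @export
glance.enrichment_calls <- function(x, ...) {
  organs <- attr(x, "organs")
  counts <- table(factor(x$organ, levels = organs))
  tibble(
    n_genes = nrow(x),
    n_enriched = sum(!is.na(x$organ)),
    !!!setNames(as.list(as.integer(counts)), paste0("n_", organs))
  )
}

#' @method tidy enrichment_calls
#' @export
tidy.enrichment_calls <- function(x, ...) {
  as_tibble(x) |> select("gene", "organ", "score")
}
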