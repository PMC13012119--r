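#' Cell-by-gene count container
#'
#' Bundles a sparse genes x cells integer count matrix with per-cell
#' metadata (cluster, stage, species). Cluster labels are inputs: clustering
#' and integration happen upstream of this package.
#'
#' @param counts A genes x cells matrix (coercible to `Matrix::dgCMatrix`)
#'   with gene rownames and cell colnames; non-negative integer counts.
#' @param cell_meta Tibble with columns `cell`, `cluster`, `stage`,
#'   `species` covering every matrix column.
#' @return A `cell_counts` list.
#' @export
cell_counts <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have gene rownames and cell colnames")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    abort("counts must be non-negative integers")
  }
  cell_meta <- as_tibble(cell_meta)
  stopifnot(all(c("cell", "cluster", "stage", "species") %in% names(cell_meta)))
  missing <- setdiff(colnames(counts), cell_meta$cell)
  if (length(missing) > 0) {
    abort(sprintf("cell without metadata: %s", missing[1]))
  }
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell), ]
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("<cell_counts> %d genes x %d cells (%d clusters, %d stages)\n",
              nrow(x$counts), ncol(x$counts),
              dplyr::n_distinct(x$cell_meta$cluster),
              dplyr::n_distinct(x$cell_meta$stage)))
  invisible(x)
}

#' Read a MatrixMarket count bundle
#'
#' Expects a genes x cells MTX matrix plus one-column gene and cell files
#' (no header) and a cell metadata TSV `cell`, `cluster`, `stage`, `species`.
#'
#' @param mtx_path,genes_path,cells_path,meta_path File paths.
#' @return A [cell_counts()] object.
#' @export
read_cluster_counts <- function(mtx_path, genes_path, cells_path, meta_path) {
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- readr::read_lines(genes_path, progress = FALSE)
  cells <- readr::read_lines(cells_path, progress = FALSE)
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    abort("matrix dimensions do not match gene/cell files")
  }
  dimnames(m) <- list(genes, cells)
  meta <- read_tsv_strict(meta_path, c("cell", "cluster", "stage", "species"),
                          col_types = readr::cols(.default = readr::col_character()))
  cell_counts(m, meta)
}

#' Write a count bundle to disk
#'
#' @param counts A [cell_counts()] object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named list of written paths, invisibly.
#' @export
write_cluster_counts <- function(counts, dir, prefix = "counts") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    mtx = file.path(dir, paste0(prefix, ".mtx")),
    genes = file.path(dir, paste0(prefix, "_genes.tsv")),
    cells = file.path(dir, paste0(prefix, "_cells.tsv")),
    meta = file.path(dir, paste0(prefix, "_cell_meta.tsv"))
  )
  Matrix::writeMM(counts$counts, paths$mtx)
  readr::write_lines(rownames(counts$counts), paths$genes)
  readr::write_lines(colnames(counts$counts), paths$cells)
  readr::write_tsv(counts$cell_meta, paths$meta, progress = FALSE)
  invisible(paths)
}

#' Dot-plot summary: fraction expressing and mean expression per group
#'
#' For each requested gene and each (cluster, stage, species) cell group,
#' reports the number of cells, the fraction of cells with count > 0
#' ("expressing" means any detected transcript; no magnitude threshold), and
#' the mean raw count over all cells of the group — the two quantities a
#' single-cell dot plot encodes.
#'
#' @param counts A [cell_counts()] object.
#' @param genes Character vector of genes present in the matrix.
#' @return A `dotplot_summary` tibble with columns `gene`, `cluster`,
#'   `stage`, `species`, `n_cells`, `fraction_expressing`, `mean_expression`.
#' @export
summarize_dotplot <- function(counts, genes) {
  stopifnot(inherits(counts, "cell_counts"))
  genes <- unique(as.character(genes))
  unknown <- setdiff(genes, rownames(counts$counts))
  if (length(unknown) > 0) abort(sprintf("unknown gene: %s", unknown[1]))
  meta <- counts$cell_meta
  grp <- meta |>
    mutate(.idx = row_number()) |>
    group_by(.data$cluster, .data$stage, .data$species) |>
    summarise(idx = list(.data$.idx), .groups = "drop")
  sub <- counts$counts[genes, , drop = FALSE]
  out <- purrr::pmap_dfr(grp, function(cluster, stage, species, idx) {
    block <- sub[, idx, drop = FALSE]
    tibble(gene = genes, cluster = cluster, stage = stage, species = species,
           n_cells = length(idx),
           fraction_expressing = unname(Matrix::rowSums(block > 0)) / length(idx),
           mean_expression = unname(Matrix::rowMeans(block)))
  })
  out <- arrange(out, .data$gene, .data$cluster, .data$species,
                 stage_key_safe(.data$stage))
  structure(out, class = c("dotplot_summary", class(out)))
}

# Order stages developmentally when they follow the E/P grammar, otherwise
# fall back to input order (cross-species labels are ordered by the caller).
stage_key_safe <- function(label) {
  ok <- grepl("^[EP][0-9]+(\\.[0-9]+)?$", label)
  if (all(ok)) stage_key(label) else seq_along(label)
}

#' Extract a gene's expression window across stages
#'
#' The window is the envelope from the FIRST to the LAST stage at which the
#' fraction of expressing cells reaches `min_fraction`. Interior stages that
#' dip below the threshold do not split the window — stage sampling is sparse,
#' especially across species — but are counted and reported as `n_dips`.
#'
#' @param summary A `dotplot_summary` tibble.
#' @param gene,cluster Gene and cluster selecting one dot-plot row series.
#' @param min_fraction Fraction-expressing threshold in `(0, 1]`; the default
#'   0.2 mirrors the conventional "over 20% of cells" bar, with 0.4 the
#'   stricter variant.
#' @param stage_levels Optional character vector fixing stage order for
#'   species whose labels are not `E<d>`/`P<d>`.
#' @return A one-row `expression_window` tibble (`gene`, `cluster`,
#'   `species`, `first_stage`, `last_stage`, `n_dips`), or a zero-row tibble
#'   when no stage qualifies.
#' @export
extract_window <- function(summary, gene, cluster, min_fraction = 0.2,
                           stage_levels = NULL) {
  if (min_fraction <= 0 || min_fraction > 1) {
    abort("min_fraction must lie in (0, 1]")
  }
  rows <- as_tibble(summary) |>
    dplyr::filter(.data$gene == !!gene, .data$cluster == !!cluster)
  empty <- tibble(gene = character(0), cluster = character(0),
                  species = character(0), first_stage = character(0),
                  last_stage = character(0), n_dips = integer(0))
  class(empty) <- c("expression_window", class(empty))
  if (nrow(rows) == 0) return(empty)
  if (is.null(stage_levels)) {
    rows <- arrange(rows, stage_key_safe(.data$stage))
  } else {
    idx <- match(rows$stage, stage_levels)
    if (anyNA(idx)) abort(sprintf("stage '%s' not in stage_levels",
                                  rows$stage[which(is.na(idx))[1]]))
    rows <- rows[order(idx), ]
  }
  qual <- which(rows$fraction_expressing >= min_fraction)
  if (length(qual) == 0) return(empty)
  first <- min(qual)
  last <- max(qual)
  inner <- setdiff(seq(first, last), qual)
  out <- tibble(gene = gene, cluster = cluster,
                species = rows$species[1],
                first_stage = rows$stage[first], last_stage = rows$stage[last],
                n_dips = length(inner))
  structure(out, min_fraction = min_fraction,
            class = c("expression_window", class(out)))
}

#' Lifespan-normalised window duration
#'
#' Completes an expression window with its absolute duration in days
#' (`stage age of last - stage age of first` under the species timeline) and
#' the dimensionless duration as a fraction of average lifespan, the scale
#' on which expression persistence is compared across species.
#'
#' @param window An `expression_window` tibble (one or more rows).
#' @param timeline A [species_timeline()] for the window's species.
#' @return `window` with `duration_days` and `normalized_duration` appended.
#' @examples
#' tl <- species_timeline("mouse", gestation_days = 19, lifespan_days = 730)
#' w <- tibble::tibble(gene = "Tox3", cluster = "GNP", species = "mouse",
#'                     first_stage = "E12", last_stage = "P10", n_dips = 0L)
#' normalize_duration(w, tl)
#' @export
normalize_duration <- function(window, timeline) {
  stopifnot(inherits(timeline, "species_timeline"))
  w <- as_tibble(window)
  if (nrow(w) == 0) return(window)
  dur <- stage_age(timeline, w$last_stage) - stage_age(timeline, w$first_stage)
  out <- mutate(w, duration_days = dur,
                normalized_duration = dur / timeline$lifespan_days)
  structure(out, class = unique(c("expression_window", class(out))))
}
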