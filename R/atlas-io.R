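#' Read a developmental expression atlas
#'
#' The atlas is a long-format TSV with header `gene`, `organ`, `stage`,
#' `rpkm`: one row per measured (gene, organ, stage) cell. Long format makes
#' per-organ stage sets irregular without padding, and missing measurements
#' are simply absent rows — distinguishable from an expression value of 0,
#' and never imputed.
#'
#' @param path Path to the TSV (UTF-8, `#`-prefixed comment lines allowed).
#' @return An `expr_atlas`: a tibble with columns `gene`, `organ`, `stage`,
#'   `rpkm`, whose `organs` attribute records organ order of first appearance.
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\torgan\tstage\trpkm",
#'              "Tox3\tcerebellum\tP0\t16",
#'              "Tox3\tcerebellum\tP63\t1.9"), path)
#' read_expression_atlas(path)
#' @export
read_expression_atlas <- function(path) {
  df <- read_tsv_strict(path, c("gene", "organ", "stage", "rpkm"),
                        col_types = readr::cols(
                          gene = readr::col_character(),
                          organ = readr::col_character(),
                          stage = readr::col_character(),
                          rpkm = readr::col_double()
                        ))
  expr_atlas(df)
}

#' Construct an expression atlas from a data frame
#'
#' @param df Data frame with columns `gene`, `organ`, `stage`, `rpkm`.
#' @return An `expr_atlas` tibble.
#' @export
expr_atlas <- function(df) {
  df <- as_tibble(df)[, c("gene", "organ", "stage", "rpkm")]
  if (nrow(df) == 0) abort("no records")
  neg <- which(is.na(df$rpkm) | df$rpkm < 0)
  if (length(neg) > 0) {
    abort(sprintf("negative or missing rpkm at row %d (gene %s)",
                  neg[1], df$gene[neg[1]]))
  }
  key <- paste(df$gene, df$organ, df$stage, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf("duplicate (gene, organ, stage) row: (%s, %s, %s)",
                  df$gene[dup[1]], df$organ[dup[1]], df$stage[dup[1]]))
  }
  parse_stage(unique(df$stage))  # validates the stage grammar
  structure(df, organs = unique(df$organ),
            class = c("expr_atlas", class(df)))
}

#' @export
print.expr_atlas <- function(x, ...) {
  cat(sprintf("<expr_atlas> %d genes x %d organs, %d measured cells\n",
              dplyr::n_distinct(x$gene), length(atlas_organs(x)), nrow(x)))
  NextMethod()
}

#' Atlas axes
#'
#' @param atlas An `expr_atlas`.
#' @return `atlas_organs()`: organ labels in declared (first-appearance)
#'   order. `atlas_genes()`: sorted unique gene identifiers.
#'   `atlas_stages()`: per-organ stage labels in developmental order.
#' @export
atlas_organs <- function(atlas) {
  attr(atlas, "organs") %||% unique(atlas$organ)
}

#' @rdname atlas_organs
#' @export
atlas_genes <- function(atlas) sort(unique(atlas$gene))

#' @rdname atlas_organs
#' @export
atlas_stages <- function(atlas) {
  sts <- dplyr::distinct(as_tibble(atlas), .data$organ, .data$stage)
  out <- lapply(split(sts$stage, sts$organ), function(s) s[order(stage_key(s))])
  out[atlas_organs(atlas)]
}

#' Write an expression atlas to TSV
#'
#' Rows are emitted sorted by (gene, organ order, stage order) so that a
#' write/read round trip is byte-stable.
#'
#' @param atlas An `expr_atlas`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_atlas <- function(atlas, path) {
  organs <- atlas_organs(atlas)
  out <- as_tibble(atlas) |>
    arrange(.data$gene, match(.data$organ, organs), stage_key(.data$stage))
  write_tsv_atomic(out, path)
  invisible(path)
}

#' Read a transcription-regulator catalog
#'
#' Two-column TSV `gene`, `class` with class one of `transcription_factor`
#' or `cofactor`. Exact duplicate rows are deduplicated; a gene listed with
#' two different classes is an error.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene`, `class`.
#' @export
read_regulator_catalog <- function(path) {
  df <- read_tsv_strict(path, c("gene", "class"),
                        col_types = readr::cols(.default = readr::col_character()))
  regulator_catalog(df)
}

#' @rdname read_regulator_catalog
#' @param df Data frame with columns `gene`, `class`.
#' @export
regulator_catalog <- function(df) {
  df <- as_tibble(df)[, c("gene", "class")]
  ok <- c("transcription_factor", "cofactor")
  bad <- which(!df$class %in% ok)
  if (length(bad) > 0) {
    abort(sprintf("unknown regulator class '%s' for gene %s",
                  df$class[bad[1]], df$gene[bad[1]]))
  }
  df <- dplyr::distinct(df)
  dup <- which(duplicated(df$gene))
  if (length(dup) > 0) {
    abort(sprintf("gene %s listed with conflicting classes", df$gene[dup[1]]))
  }
  df
}

#' Restrict an atlas to catalogued regulators
#'
#' Keeps exactly the genes present in both the atlas and the catalog;
#' surviving values are untouched.
#'
#' @param atlas An `expr_atlas`.
#' @param catalog A regulator catalog tibble (`gene`, `class`).
#' @return The restricted `expr_atlas`.
#' @export
restrict_to_catalog <- function(atlas, catalog) {
  keep <- intersect(unique(atlas$gene), catalog$gene)
  if (length(keep) == 0) abort("no regulators present in atlas")
  out <- dplyr::filter(as_tibble(atlas), .data$gene %in% keep)
  organs <- atlas_organs(atlas)
  structure(out, organs = organs[organs %in% out$organ],
            class = c("expr_atlas", class(out)))
}
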