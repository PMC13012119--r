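#' Read genomic intervals from a BED file
#'
#' Accepts the BED3/BED6 dialect (tab-separated; optional `name`, `score`,
#' `strand` columns). Coordinates are kept 0-based half-open, as in the file.
#' Input row order is preserved.
#'
#' @param path Path to the BED file.
#' @return A `genomic_intervals` tibble with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand` (the last three `NA` when absent).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(parts) == 0) abort(sprintf("%s: no records", path))
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 3)) {
    abort(sprintf("%s: fewer than 3 fields on line %d", path,
                  lineno[which(nf < 3)[1]]))
  }
  get <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, character(1))
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric coordinates on line %d", path, lineno[bad[1]]))
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid interval (start >= end) on line %d", path,
                  lineno[bad[1]]))
  }
  strand <- get(6)
  strand[startsWith(strand, "−")] <- "-"  # tolerate typographic minus
  badstrand <- which(!is.na(strand) & !strand %in% c("+", "-", "."))
  if (length(badstrand) > 0) {
    abort(sprintf("%s: invalid strand on line %d", path, lineno[badstrand[1]]))
  }
  out <- tibble(chrom = get(1), start = start, end = end,
                name = get(4),
                score = suppressWarnings(as.numeric(get(5))),
                strand = strand)
  structure(out, class = c("genomic_intervals", class(out)))
}

#' Write intervals to BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- as_tibble(intervals)
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(df) && any(!is.na(df$name))) {
    df$name[is.na(df$name)] <- "."
    df$score <- if (!"score" %in% names(df)) 0 else
      ifelse(is.na(df$score), 0, df$score)
    df$strand <- if (!"strand" %in% names(df)) "." else
      ifelse(is.na(df$strand), ".", df$strand)
    cols <- c(cols, "name", "score", "strand")
  }
  write_atomic(function(p) {
    readr::write_tsv(df[, cols], p, col_names = FALSE, progress = FALSE)
  }, path)
  invisible(path)
}

#' Proximity co-occupancy between two peak sets
#'
#' Flags each interval of `set_a` that has a same-chromosome interval of
#' `set_b` within `window` bases, where the gap between half-open intervals
#' `a` and `b` is `max(0, b_start - a_end, a_start - b_end)` (0 for touching
#' or overlapping intervals). The fraction of flagged A peaks is the
#' co-occupancy fraction. Implemented as a per-chromosome sorted sweep
#' (sorted B starts with a running maximum of B ends), so the result is
#' independent of input order.
#'
#' @param set_a,set_b Interval tibbles (`chrom`, `start`, `end`).
#' @param window Maximum gap in bases (>= 0).
#' @return `set_a` with a logical `near` column appended, carrying attributes
#'   `fraction_near` and `window`; class `cooccupancy_flags`.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 210, end = 220)
#' attr(proximity_overlap(a, b, window = 10), "fraction_near")
#' @export
proximity_overlap <- function(set_a, set_b, window) {
  if (!is.numeric(window) || window < 0) abort("window must be >= 0")
  a <- as_tibble(set_a)
  b <- as_tibble(set_b)
  if (nrow(a) == 0) abort("empty A set: fraction undefined")
  near <- logical(nrow(a))
  for (chr in unique(a$chrom)) {
    ai <- which(a$chrom == chr)
    bi <- which(b$chrom == chr)
    if (length(bi) == 0) next
    bs <- b$start[bi]
    be <- b$end[bi]
    o <- order(bs)
    bs <- bs[o]
    run_max_end <- cummax(be[o])
    # b is near a iff b.start <= a.end + window AND b.end >= a.start - window
    idx <- findInterval(a$end[ai] + window, bs)
    hit <- idx > 0 & run_max_end[pmax(idx, 1)] >= a$start[ai] - window
    near[ai] <- hit
  }
  out <- mutate(a, near = near)
  structure(out, fraction_near = mean(near), window = window,
            class = c("cooccupancy_flags", class(out)))
}

#' @method glance cooccupancy_flags
#' @export
glance.cooccupancy_flags <- function(x, ...) {
  tibble(n_a = nrow(x), n_near = sum(x$near),
         fraction_near = attr(x, "fraction_near"),
         window = attr(x, "window"))
}

#' Read a gene anchor table
#'
#' TSV with columns `gene`, `chrom`, `anchor`, `strand`: one anchor
#' coordinate per gene (by convention the translation start site, but any
#' per-gene anchor such as the transcription start can be supplied).
#'
#' @param path Path to the TSV.
#' @return Tibble with one row per gene.
#' @export
read_gene_anchors <- function(path) {
  df <- read_tsv_strict(path, c("gene", "chrom", "anchor", "strand"))
  if (anyDuplicated(df$gene)) {
    abort(sprintf("duplicate anchor for gene %s",
                  df$gene[which(duplicated(df$gene))[1]]))
  }
  if (any(df$anchor < 0)) abort("anchor positions must be >= 0")
  df
}

#' Assign each peak to its nearest gene anchor
#'
#' For each peak, the same-chromosome gene whose anchor minimises the
#' absolute distance to the peak midpoint (`floor((start + end) / 2)`); ties
#' are broken lexicographically by gene id. Peaks on chromosomes without any
#' anchor map to `NA`.
#'
#' @param peaks Interval tibble (`chrom`, `start`, `end`).
#' @param anchors Anchor tibble (`gene`, `chrom`, `anchor`).
#' @return `peaks` with `midpoint`, `gene` and `distance` columns appended.
#' @export
nearest_gene <- function(peaks, anchors) {
  anchors <- as_tibble(anchors)
  if (nrow(anchors) == 0) abort("anchor table is empty")
  peaks <- as_tibble(peaks)
  mid <- floor((peaks$start + peaks$end) / 2)
  gene <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chr)
    ai <- which(anchors$chrom == chr)
    if (length(ai) == 0) next
    pos <- anchors$anchor[ai]
    ids <- anchors$gene[ai]
    d <- abs(outer(mid[pi], pos, "-"))
    best <- apply(d, 1, min)
    pickbest <- function(i) {
      tied <- which(d[i, ] == best[i])
      tied[order(ids[tied])][1]
    }
    sel <- vapply(seq_along(pi), pickbest, integer(1))
    gene[pi] <- ids[sel]
    dist[pi] <- best
  }
  mutate(peaks, midpoint = mid, gene = gene, distance = dist)
}

#' Shared targets of two factors
#'
#' Exact intersection of two target-gene sets, with the co-targeting
#' fraction `|A intersect B| / |A|` attached.
#'
#' @param targets_a,targets_b Character vectors of target genes.
#' @return A `shared_targets` tibble with a sorted `gene` column; attribute
#'   `cotargeting_fraction`.
#' @export
shared_targets <- function(targets_a, targets_b) {
  a <- unique(as.character(targets_a))
  shared <- sort(intersect(a, unique(as.character(targets_b))))
  frac <- if (length(a) == 0) 0 else length(shared) / length(a)
  structure(tibble(gene = shared), cotargeting_fraction = frac,
            class = c("shared_targets", "tbl_df", "tbl", "data.frame"))
}

#' @method glance shared_targets
#' @export
glance.shared_targets <- function(x, ...) {
  tibble(n_shared = nrow(x),
         cotargeting_fraction = attr(x, "cotargeting_fraction"))
}
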