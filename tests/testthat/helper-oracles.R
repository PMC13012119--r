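# Independent brute-force oracles and tiny fixture builders. These are
# deliberately written as plain loops, separate from the package's
# vectorised implementations, so the two routes can disagree.

make_atlas <- function(df) expr_atlas(tibble::as_tibble(df))

# A small random atlas: every (gene, organ, stage) cell present with
# probability 1 - missing_rate.
random_atlas <- function(seed, n_genes = 30, organs = c("brain", "cerebellum", "liver"),
                         stages = c("E12.5", "E16.5", "P0", "P14", "P63"),
                         missing_rate = 0.1, max_rpkm = 50) {
  withr::with_seed(seed, {
    grid <- expand.grid(gene = sprintf("g%03d", seq_len(n_genes)),
                        organ = organs, stage = stages,
                        stringsAsFactors = FALSE)
    grid$rpkm <- round(runif(nrow(grid), 0, max_rpkm), 3)
    keep <- runif(nrow(grid)) >= missing_rate
    # guarantee at least one row per gene so every gene stays in the atlas
    first <- !duplicated(grid$gene)
    make_atlas(grid[keep | first, ])
  })
}

# Loop-based re-derivation of per-gene organ means and enrichment calls.
oracle_enrichment <- function(atlas, cfg = enrichment_config()) {
  df <- as.data.frame(atlas)
  genes <- unique(df$gene)
  out <- list()
  for (g in genes) {
    sub <- df[df$gene == g, ]
    organs <- unique(sub$organ)
    means <- sapply(organs, function(o) mean(sub$rpkm[sub$organ == o]))
    ord <- order(-means, match(organs, atlas_organs(atlas)))
    m1 <- means[ord[1]]
    m2 <- if (length(means) > 1) means[ord[2]] else 0
    score <- (m1 + cfg$pseudocount) / (m2 + cfg$pseudocount)
    enriched <- m1 >= cfg$expr_floor && score >= cfg$fold_min
    out[[g]] <- data.frame(gene = g,
                           organ = if (enriched) organs[ord[1]] else NA_character_,
                           score = score)
  }
  do.call(rbind, out)
}

# Loop-based re-derivation of the two-predicate temporal screen.
oracle_screen <- function(atlas, organ, genes, cfg = screen_config()) {
  df <- as.data.frame(atlas)
  out <- list()
  for (g in genes) {
    sub <- df[df$gene == g & df$organ == organ, ]
    mean_rpkm <- if (nrow(sub) == 0) NA_real_ else mean(sub$rpkm)
    num <- sub$rpkm[sub$stage == cfg$numerator_stage]
    den <- sub$rpkm[sub$stage == cfg$denominator_stage]
    ratio <- if (length(num) == 1 && length(den) == 1) {
      (num + cfg$ratio_pseudocount) / (den + cfg$ratio_pseudocount)
    } else NA_real_
    passes <- !is.na(mean_rpkm) && !is.na(ratio) &&
      mean_rpkm > cfg$min_mean_rpkm && ratio > cfg$min_ratio
    out[[g]] <- data.frame(gene = g, mean_rpkm = mean_rpkm,
                           ratio = ratio, passes = passes)
  }
  do.call(rbind, out)
}

# Exhaustive enumeration of hypergeometric draws: every size-n subset of
# 1..N, counting those with >= k members among the first K.
oracle_hypergeom_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Literal step-up BH on the sorted sequence.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- m * ps / seq_len(m)
  for (i in rev(seq_len(m - 1))) qs[i] <- min(qs[i], qs[i + 1])
  q <- numeric(m)
  q[o] <- pmin(qs, 1)
  q
}

iv <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

random_intervals <- function(seed, n, chroms = c("chr1", "chr2"),
                             span = 100000) {
  withr::with_seed(seed, {
    start <- sample.int(span, n, replace = TRUE)
    iv(sample(chroms, n, replace = TRUE), start,
       start + sample(50:500, n, replace = TRUE))
  })
}

# Quadratic all-pairs proximity flags with the stated gap definition.
oracle_proximity <- function(a, b, window) {
  flags <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      gap <- max(0, b$start[j] - a$end[i], a$start[i] - b$end[j])
      if (gap <= window) {
        flags[i] <- TRUE
        break
      }
    }
  }
  flags
}

# Per-peak loop over every anchor, explicit distance and tie rule.
oracle_nearest <- function(peaks, anchors) {
  genes <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    cand <- anchors[anchors$chrom == peaks$chrom[i], ]
    if (nrow(cand) == 0) {
      genes[i] <- NA_character_
      next
    }
    d <- abs(cand$anchor - mid)
    tied <- cand$gene[d == min(d)]
    genes[i] <- sort(tied)[1]
  }
  genes
}

# Naive sliding-window IUPAC scan over both strands; ambiguity codes
# intersect on both pattern and subject.
IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
           W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
           V = "ACG", N = "ACGT")
iupac_compatible <- function(a, b) {
  any(strsplit(IUPAC[[a]], "")[[1]] %in% strsplit(IUPAC[[b]], "")[[1]])
}
revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B", D = "H",
            H = "D")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}
oracle_scan <- function(seq, pattern, both_strands = TRUE) {
  seq <- toupper(seq)
  pats <- list(`+` = pattern)
  if (both_strands) pats$`-` <- revcomp_chr(pattern)
  m <- nchar(pattern)
  hits <- list()
  for (strand in names(pats)) {
    pc <- strsplit(pats[[strand]], "")[[1]]
    for (pos in seq_len(max(nchar(seq) - m + 1, 0))) {
      win <- strsplit(substr(seq, pos, pos + m - 1), "")[[1]]
      if (all(mapply(iupac_compatible, win, pc))) {
        hits[[length(hits) + 1]] <- data.frame(position = pos - 1L,
                                               strand = strand)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(position = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

# Per-group loops for the dot-plot summary.
oracle_dotplot <- function(counts, genes) {
  meta <- counts$cell_meta
  m <- as.matrix(counts$counts)
  out <- list()
  for (g in genes) {
    for (cl in unique(meta$cluster)) {
      for (st in unique(meta$stage[meta$cluster == cl])) {
        cells <- meta$cell[meta$cluster == cl & meta$stage == st]
        v <- m[g, cells]
        out[[length(out) + 1]] <- data.frame(
          gene = g, cluster = cl, stage = st,
          fraction_expressing = sum(v > 0) / length(v),
          mean_expression = mean(v))
      }
    }
  }
  do.call(rbind, out)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
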