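test_that("hypergeometric tail is exact on closed-form cases", {
  expect_identical(hypergeom_upper_tail(0, 5, 5, 10), 1)
  # all five annotated genes drawn: C(5,5)C(5,0)/C(10,5) = 1/252
  expect_equal(hypergeom_upper_tail(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(3, 11, 5, 10), "K <= N")
  expect_error(hypergeom_upper_tail(6, 5, 5, 10), "min\\(K, n\\)")
})

test_that("hypergeometric tail matches full enumeration for small N", {
  withr::with_seed(101, {
    for (rep in 1:15) {
      N <- sample(5:20, 1)
      K <- sample(0:N, 1)
      n <- sample(0:min(N, 9), 1)
      k <- if (min(K, n) > 0) sample(0:min(K, n), 1) else 0
      expect_equal(hypergeom_upper_tail(k, K, n, N),
                   oracle_hypergeom_enum(k, K, n, N), tolerance = 1e-12)
    }
  })
})

test_that("hypergeometric tail agrees with phyper at atlas scale", {
  withr::with_seed(102, {
    for (rep in 1:20) {
      N <- sample(100:10000, 1)
      K <- sample(1:(N %/% 2), 1)
      n <- sample(1:(N %/% 2), 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(hypergeom_upper_tail(k, K, n, N),
                   stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  })
})

test_that("BH step-up matches hand computation and reference routines", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  withr::with_seed(103, {
    for (rep in 1:10) {
      p <- runif(sample(1:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
      # q order statistics are monotone in p order statistics
      expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
  })
})

test_that("term enrichment reproduces the exact combinatorial case", {
  universe <- sprintf("u%02d", 1:10)
  ann <- tibble::tibble(term = "T1", name = "term one",
                        gene = universe[1:5])
  res <- enrich_terms(universe[1:5], ann, universe)
  expect_equal(res$p, 1 / 252, tolerance = 1e-12)
  expect_equal(res$k, 5)

  disjoint <- enrich_terms(universe[6:10], ann, universe)
  expect_equal(disjoint$k, 0)
  expect_equal(disjoint$p, 1)
  expect_error(enrich_terms(character(0), ann, universe), "non-empty")
  expect_error(enrich_terms("ghost", ann, universe), "not in universe")
})

test_that("full result tables match a per-term oracle on random GMTs", {
  withr::with_seed(104, {
    universe <- sprintf("u%03d", 1:200)
    for (rep in 1:3) {
      ann <- purrr::map_dfr(1:15, function(i) {
        tibble::tibble(term = sprintf("T%02d", i), name = sprintf("term %d", i),
                       gene = sample(universe, sample(5:50, 1)))
      })
      query <- sample(universe, 25)
      res <- enrich_terms(query, ann, universe)
      # loop oracle
      for (tm in unique(ann$term)) {
        members <- ann$gene[ann$term == tm]
        k <- length(intersect(members, query))
        p <- hypergeom_upper_tail(k, length(members), 25, 200)
        expect_equal(res$p[res$term == tm], p, tolerance = 1e-12)
        expect_equal(res$k[res$term == tm], k)
      }
      expect_equal(res$q, bh_adjust(res$p))
      expect_false(is.unsorted(res$p))
    }
  })
})

test_that("adding an annotated gene to the query never raises the term's p", {
  withr::with_seed(105, {
    universe <- sprintf("u%03d", 1:100)
    ann <- tibble::tibble(term = "T1", name = "t", gene = universe[1:30])
    query <- sample(universe[31:100], 10)
    p0 <- enrich_terms(query, ann, universe)$p
    for (g in sample(universe[1:30], 5)) {
      p1 <- enrich_terms(c(query, g), ann, universe)$p
      expect_lte(p1, p0 + 1e-15)
      query <- c(query, g)
      p0 <- p1
    }
  })
})

test_that("GMT parsing yields long annotations and top-N is deterministic", {
  path <- write_lines_tmp(c("T1\tfirst term\ta\tb\tc",
                            "T2\tsecond term\tb\td"), ext = ".gmt")
  gmt <- read_gmt(path)
  expect_equal(nrow(gmt), 5)
  expect_setequal(gmt$gene[gmt$term == "T2"], c("b", "d"))
  expect_error(read_gmt(write_lines_tmp("T1\tno genes", ext = ".gmt")),
               "no genes")

  res <- enrich_terms(c("a", "b", "c"), gmt, c("a", "b", "c", "d", "e"))
  expect_equal(nrow(top_terms(res, 1)), 1)
  expect_equal(top_terms(res, 1)$term, "T1")
})
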