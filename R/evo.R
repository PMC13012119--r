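#' Read an outgroup ortholog-evidence table
#'
#' TSV with columns `gene`, `outgroup_taxon`, `status`, where `status` is one
#' of `ortholog`, `related_nonortholog`, `absent`. The evidence is an input:
#' any upstream orthology inference (similarity search, synteny, curated
#' orthology databases) can produce it.
#'
#' @param path Path to the TSV (`#` comments allowed).
#' @return Tibble with columns `gene`, `outgroup_taxon`, `status`.
#' @export
read_ortholog_evidence <- function(path) {
  df <- read_tsv_strict(path, c("gene", "outgroup_taxon", "status"),
                        col_types = readr::cols(.default = readr::col_character()))
  ok <- c("ortholog", "related_nonortholog", "absent")
  bad <- which(!df$status %in% ok)
  if (length(bad) > 0) {
    abort(sprintf("unknown ortholog status '%s' for gene %s",
                  df$status[bad[1]], df$gene[bad[1]]))
  }
  df
}

#' Classify candidates by outgroup ortholog evidence
#'
#' Maps each candidate gene to an evolutionary category as a pure function of
#' its outgroup evidence: a true outgroup ortholog means `conserved`; an
#' evolutionarily related but non-orthologous outgroup counterpart means
#' `type_I`; no similar outgroup gene means `type_II`; a candidate without an
#' evidence record is `unclassified`. Consistent duplicate evidence rows are
#' tolerated; conflicting ones are an error.
#'
#' @param candidates Character vector of candidate gene identifiers.
#' @param evidence Evidence tibble (`gene`, `outgroup_taxon`, `status`), e.g.
#'   from [read_ortholog_evidence()].
#' @return An `evo_classes` tibble with columns `gene`, `category`
#'   (factor with levels conserved, type_I, type_II, unclassified), one row
#'   per candidate in input order.
#' @examples
#' ev <- tibble::tibble(gene = c("Tox3", "Atoh1"),
#'                      outgroup_taxon = "sea_lamprey",
#'                      status = c("related_nonortholog", "absent"))
#' classify_candidates(c("Tox3", "Atoh1", "Pax6"), ev)
#' @export
classify_candidates <- function(candidates, evidence) {
  candidates <- as.character(candidates)
  ev <- dplyr::distinct(as_tibble(evidence), .data$gene, .data$status)
  dup <- which(duplicated(ev$gene))
  if (length(dup) > 0) {
    abort(sprintf("conflicting evidence rows for gene %s", ev$gene[dup[1]]))
  }
  map <- c(ortholog = "conserved", related_nonortholog = "type_I",
           absent = "type_II")
  status <- ev$status[match(candidates, ev$gene)]
  category <- ifelse(is.na(status), "unclassified", unname(map[status]))
  out <- tibble(
    gene = candidates,
    category = factor(category,
                      levels = c("conserved", "type_I", "type_II", "unclassified"))
  )
  structure(out, class = c("evo_classes", class(out)))
}

#' @method glance evo_classes
#' @export
glance.evo_classes <- function(x, ...) {
  counts <- table(x$category)
  tibble(n_candidates = nrow(x),
         !!!setNames(as.list(as.integer(counts)),
                     paste0("n_", names(counts))))
}

#' Category count summary
#'
#' @param classes An `evo_classes` tibble.
#' @return Named list of category counts (sums to the candidate count),
#'   suitable for JSON serialisation.
#' @export
evo_category_counts <- function(classes) {
  counts <- table(classes$category)
  as.list(setNames(as.integer(counts), names(counts)))
}
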