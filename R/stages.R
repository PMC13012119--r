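#' Developmental stage labels
#'
#' Bulk developmental atlases label their samples `E<days>` (embryonic, days
#' post conception) or `P<days>` (postnatal, days after birth). `parse_stage()`
#' turns such labels into a `dev_stage` vector that sorts developmentally:
#' every embryonic stage precedes every postnatal stage, and stages within a
#' phase are ordered by their day value. Formatting a parsed canonical label
#' reproduces it exactly.
#'
#' Species-specific stage units (e.g. zebrafish `dpf`, human `wpc`) are
#' deliberately not part of this grammar; cross-species work maps stage labels
#' to absolute ages through a [species_timeline()] instead.
#'
#' @param x Character vector of stage labels such as `"E13.5"` or `"P0"`.
#' @return A `dev_stage` record vector with fields `phase`
#'   (`"embryonic"`/`"postnatal"`) and `value` (days, non-negative).
#' @examples
#' s <- parse_stage(c("P63", "E10.5", "P0", "E16.5"))
#' format(sort(s))
#' parse_stage("E16.5") < parse_stage("P0")
#' @export
parse_stage <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^([EP])([0-9]+(?:\\.[0-9]+)?)$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(sprintf(
      "malformed stage label %s: expected 'E<number>' or 'P<number>'",
      paste0("'", x[which(bad)[1]], "'")
    ), class = "regdiscover_parse_error")
  }
  phase <- ifelse(vapply(m, `[`, character(1), 2) == "E", "embryonic", "postnatal")
  value <- as.numeric(vapply(m, `[`, character(1), 3))
  new_dev_stage(phase, value)
}

new_dev_stage <- function(phase = character(), value = double()) {
  vctrs::new_rcrd(list(phase = phase, value = value), class = "regdiscover_stage")
}

#' @export
format.regdiscover_stage <- function(x, ...) {
  phase <- vctrs::field(x, "phase")
  value <- vctrs::field(x, "value")
  paste0(ifelse(phase == "embryonic", "E", "P"),
         vapply(value, function(v) format(v, scientific = FALSE, trim = TRUE),
                character(1)))
}

#' @export
vec_proxy_compare.regdiscover_stage <- function(x, ...) {
  data.frame(
    phase = match(vctrs::field(x, "phase"), c("embryonic", "postnatal")),
    value = vctrs::field(x, "value")
  )
}

#' @rdname parse_stage
#' @param label Character vector of stage labels.
#' @return `stage_key()` returns a numeric sort key consistent with the
#'   `dev_stage` total order (useful inside `dplyr::arrange()`).
#' @export
stage_key <- function(label) {
  s <- parse_stage(label)
  phase <- vctrs::field(s, "phase")
  value <- vctrs::field(s, "value")
  ifelse(phase == "postnatal", 1e6 + value, value)
}

#' @rdname parse_stage
#' @return `stage_phase()` and `stage_days()` return the parsed components.
#' @export
stage_phase <- function(label) vctrs::field(parse_stage(label), "phase")

#' @rdname parse_stage
#' @export
stage_days <- function(label) vctrs::field(parse_stage(label), "value")

#' Species timeline for lifespan-normalised durations
#'
#' Maps the stage labels of one species onto absolute age in days so that
#' expression-window durations can be compared across species on a common
#' scale (fraction of average lifespan). Embryonic stages map to their
#' days-post-conception value; postnatal stages map to gestation plus days
#' after birth. Non `E`/`P` labels (zebrafish `dpf`, human `wpc`, ...) must be
#' supplied through an explicit `stage_map`.
#'
#' @param species Species label.
#' @param gestation_days Gestation length in days (>= 0).
#' @param lifespan_days Average lifespan in days (> gestation).
#' @param stage_map Optional tibble with columns `stage`, `age_days` giving
#'   the absolute age of each stage label. When `NULL`, ages are derived from
#'   the `E`/`P` grammar on demand.
#' @return A `species_timeline` object (a list).
#' @examples
#' tl <- species_timeline("mouse", gestation_days = 19, lifespan_days = 730)
#' stage_age(tl, c("E12", "P10"))
#' @export
species_timeline <- function(species, gestation_days, lifespan_days,
                             stage_map = NULL) {
  stopifnot(is.character(species), length(species) == 1L)
  if (!is.numeric(gestation_days) || gestation_days < 0) {
    abort("gestation_days must be a non-negative number of days")
  }
  if (!is.numeric(lifespan_days) || lifespan_days <= gestation_days) {
    abort("lifespan_days must exceed gestation_days")
  }
  if (!is.null(stage_map)) {
    stage_map <- as_tibble(stage_map)
    stopifnot(all(c("stage", "age_days") %in% names(stage_map)))
    if (anyDuplicated(stage_map$stage)) abort("duplicate stage in stage_map")
  }
  structure(
    list(species = species, gestation_days = as.numeric(gestation_days),
         lifespan_days = as.numeric(lifespan_days), stage_map = stage_map),
    class = "species_timeline"
  )
}

#' @export
print.species_timeline <- function(x, ...) {
  cat(sprintf("<species_timeline> %s: gestation %g d, lifespan %g d, %s\n",
              x$species, x$gestation_days, x$lifespan_days,
              if (is.null(x$stage_map)) "E/P-derived stage map"
              else sprintf("%d mapped stages", nrow(x$stage_map))))
  invisible(x)
}

#' Absolute age of stage labels under a timeline
#'
#' @param timeline A [species_timeline()].
#' @param label Character vector of stage labels.
#' @return Numeric vector of ages in days.
#' @export
stage_age <- function(timeline, label) {
  stopifnot(inherits(timeline, "species_timeline"))
  label <- as.character(label)
  if (!is.null(timeline$stage_map)) {
    idx <- match(label, timeline$stage_map$stage)
    if (anyNA(idx)) {
      abort(sprintf("stage '%s' missing from timeline for %s",
                    label[which(is.na(idx))[1]], timeline$species))
    }
    return(timeline$stage_map$age_days[idx])
  }
  s <- parse_stage(label)
  phase <- vctrs::field(s, "phase")
  value <- vctrs::field(s, "value")
  ifelse(phase == "postnatal", timeline$gestation_days + value, value)
}

#' Read species timelines from TSV
#'
#' `timeline_path` holds one row per species with columns
#' `species`, `gestation_days`, `lifespan_days`; the optional
#' `stage_map_path` holds `species`, `stage`, `age_days` rows. Lines starting
#' with `#` are comments.
#'
#' @param timeline_path Path to the timeline TSV.
#' @param stage_map_path Optional path to the stage-map TSV.
#' @return Named list of [species_timeline()] objects.
#' @export
read_species_timelines <- function(timeline_path, stage_map_path = NULL) {
  tl <- read_tsv_strict(timeline_path,
                        c("species", "gestation_days", "lifespan_days"))
  maps <- NULL
  if (!is.null(stage_map_path)) {
    maps <- read_tsv_strict(stage_map_path, c("species", "stage", "age_days"))
  }
  out <- purrr::map(seq_len(nrow(tl)), function(i) {
    sp <- tl$species[i]
    sm <- if (!is.null(maps)) {
      m <- dplyr::filter(maps, .data$species == sp)
      if (nrow(m) > 0) dplyr::select(m, "stage", "age_days") else NULL
    }
    species_timeline(sp, as.numeric(tl$gestation_days[i]),
                     as.numeric(tl$lifespan_days[i]), stage_map = sm)
  })
  setNames(out, tl$species)
}
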