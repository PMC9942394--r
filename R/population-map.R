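#' Read a population map
#'
#' A whitespace/tab-delimited file with one line per sample: sample id,
#' population label, altitude (m above sea level). Lines of the form
#' `group = POP1,POP2,...` define named unions of populations (e.g. a
#' pooled low-altitude control group). Comment lines start with `#`.
#'
#' @param path Path to the map file.
#' @return A `pop_map`: a tibble with columns `sample`, `population`,
#'   `altitude`, carrying a `groups` attribute (named list of population
#'   vectors).
#' @export
read_population_map <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty population map: ", path, call. = FALSE)
  is_group <- grepl("=", lines, fixed = TRUE)
  groups <- list()
  for (g in lines[is_group]) {
    parts <- strsplit(g, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed group line: ", g, call. = FALSE)
    groups[[trimws(parts[1])]] <- trimws(strsplit(parts[2], ",")[[1]])
  }
  rows <- lines[!is_group]
  if (!length(rows)) stop("population map has no sample lines", call. = FALSE)
  fields <- strsplit(rows, "[ \t]+")
  n_f <- lengths(fields)
  if (any(n_f < 3L)) {
    stop("population map line ", which(n_f < 3L)[1],
         " has fewer than 3 fields", call. = FALSE)
  }
  alt <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(alt)) {
    stop("non-numeric altitude on population map line ",
         which(is.na(alt))[1], call. = FALSE)
  }
  tbl <- tibble::tibble(
    sample = vapply(fields, `[`, "", 1L),
    population = vapply(fields, `[`, "", 2L),
    altitude = alt
  )
  if (anyDuplicated(tbl$sample)) {
    warning("duplicate sample assignments; keeping the last", call. = FALSE)
    tbl <- dplyr::slice_tail(dplyr::group_by(tbl, .data$sample), n = 1L)
    tbl <- dplyr::ungroup(tbl)
  }
  population_map(tbl, groups)
}

#' Construct a population map from a data frame
#'
#' @param assignments Data frame with columns `sample`, `population` and
#'   optionally `altitude`.
#' @param groups Named list mapping group names to character vectors of
#'   population labels (unions of populations).
#' @return A `pop_map` tibble.
#' @export
population_map <- function(assignments, groups = list()) {
  tbl <- tibble::as_tibble(assignments)
  stopifnot(all(c("sample", "population") %in% names(tbl)))
  if (!"altitude" %in% names(tbl)) tbl$altitude <- NA_real_
  unknown <- setdiff(unlist(groups), tbl$population)
  if (length(unknown)) {
    stop("group references unknown population(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tbl <- tbl[, c("sample", "population", "altitude")]
  attr(tbl, "groups") <- groups
  class(tbl) <- c("pop_map", class(tbl))
  tbl
}

#' Resolve a population, group or sample set to sample identifiers
#'
#' `who` may be a population label, a group name defined in the map, a
#' character vector mixing several of them, or (as a fallback) sample ids
#' themselves.
#'
#' @param popmap A `pop_map`.
#' @param who Character vector of population labels, group names or samples.
#' @return Character vector of sample ids (order of the map).
#' @export
resolve_samples <- function(popmap, who) {
  groups <- attr(popmap, "groups") %||% list()
  pops <- unique(unlist(lapply(who, function(w) {
    if (w %in% names(groups)) groups[[w]] else w
  })))
  hit_pop <- pops %in% popmap$population
  hit_sample <- pops %in% popmap$sample
  if (any(!hit_pop & !hit_sample)) {
    stop("unknown population/group/sample: ",
         paste(pops[!hit_pop & !hit_sample], collapse = ", "), call. = FALSE)
  }
  unique(c(popmap$sample[popmap$population %in% pops[hit_pop]],
           pops[hit_sample & !hit_pop]))
}

#' Populations ordered by altitude
#'
#' @param popmap A `pop_map`.
#' @return Tibble of `population`, `altitude` sorted by increasing altitude.
#' @export
altitude_order <- function(popmap) {
  out <- dplyr::distinct(tibble::as_tibble(popmap)[, c("population", "altitude")])
  if (anyNA(out$altitude)) {
    stop("altitude undefined for population(s): ",
         paste(out$population[is.na(out$altitude)], collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(out, .data$altitude, .data$population)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
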