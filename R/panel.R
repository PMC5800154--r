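#' Construct a validated counts panel
#'
#' A counts panel holds binomial case counts and denominators on a complete
#' gender x region x wave grid. Waves are calendar years (the survey waves
#' are unequally spaced, so all temporal computation uses years, never wave
#' indices).
#'
#' @param regions character vector of region labels (length N).
#' @param waves strictly increasing integer vector of calendar years (length T).
#' @param genders character vector of group labels, length 1 (pooled) or 2.
#'   When length 2 the first label is group j = 1 (male) and the second
#'   j = 2 (female).
#' @param Y integer array of cases, dim c(J, N, T).
#' @param n integer array of denominators, dim c(J, N, T).
#' @return An object of class \code{counts_panel}: a list with fields
#'   \code{regions}, \code{waves}, \code{genders}, \code{Y}, \code{n}.
#' @export
counts_panel <- function(regions, waves, genders, Y, n) {
  regions <- as.character(regions)
  waves <- as.integer(waves)
  genders <- as.character(genders)
  J <- length(genders); N <- length(regions); Tn <- length(waves)
  if (J < 1L || J > 2L) stop("genders must have length 1 or 2")
  if (anyDuplicated(regions)) stop("duplicate region labels")
  if (Tn >= 2L && any(diff(waves) <= 0L)) stop("waves must be strictly increasing")
  Y <- array(as.numeric(Y), dim = c(J, N, Tn))
  n <- array(as.numeric(n), dim = c(J, N, Tn))
  dimnames(Y) <- dimnames(n) <- list(genders, regions, waves)
  if (anyNA(Y) || anyNA(n)) stop("missing cells: Y and n must be complete")
  if (any(Y != round(Y)) || any(n != round(n))) stop("Y and n must be integers")
  if (any(n < 0)) stop("denominators must be non-negative")
  if (any(Y < 0) || any(Y > n)) {
    bad <- which(Y > n | Y < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("cases outside [0, n] at gender=%s region=%s year=%s",
                 genders[bad[1]], regions[bad[2]], waves[bad[3]]))
  }
  structure(list(regions = regions, waves = waves, genders = genders,
                 Y = Y, n = n),
            class = "counts_panel")
}

#' @export
print.counts_panel <- function(x, ...) {
  cat(sprintf("<counts_panel> %d gender(s) x %d regions x %d waves (%d-%d)\n",
              length(x$genders), length(x$regions), length(x$waves),
              min(x$waves), max(x$waves)))
  cat(sprintf("  total cases %d / %d observations\n", sum(x$Y), sum(x$n)))
  invisible(x)
}

#' Read a counts panel from a long-format CSV
#'
#' Canonical format: one row per gender-region-wave cell with columns
#' \code{region, year, gender, cases, n} (header required). The grid must be
#' complete; missing cells and duplicate rows are errors, never imputed.
#'
#' @param path CSV file path.
#' @param schema optional named list remapping column names, e.g.
#'   \code{list(cases = "events")}, and/or \code{gender_levels} giving the
#'   group order (default: order of first appearance, or
#'   \code{c("male","female")} when both are present).
#' @return A \code{\link{counts_panel}}.
#' @export
read_panel <- function(path, schema = list()) {
  cols <- list(region = "region", year = "year", gender = "gender",
               cases = "cases", n = "n")
  cols[names(schema)[names(schema) %in% names(cols)]] <-
    schema[names(schema) %in% names(cols)]
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("no rows in panel file ", path)
  miss <- setdiff(unlist(cols), names(d))
  if (length(miss)) stop("panel file missing columns: ", paste(miss, collapse = ", "))
  d <- data.frame(region = as.character(d[[cols$region]]),
                  year = as.integer(d[[cols$year]]),
                  gender = as.character(d[[cols$gender]]),
                  cases = d[[cols$cases]], n = d[[cols$n]])
  key <- paste(d$region, d$year, d$gender, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- d[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate row for region=%s year=%d gender=%s",
                 dup$region, dup$year, dup$gender))
  }
  bad <- which(d$cases > d$n)
  if (length(bad)) stop(sprintf("cases > n at region=%s year=%d gender=%s",
                                d$region[bad[1]], d$year[bad[1]], d$gender[bad[1]]))
  regions <- unique(d$region)
  waves <- sort(unique(d$year))
  genders <- unique(d$gender)
  if (!is.null(schema$gender_levels)) {
    if (!setequal(genders, schema$gender_levels))
      stop("gender_levels do not match genders present in file")
    genders <- schema$gender_levels
  } else if (setequal(genders, c("male", "female"))) {
    genders <- c("male", "female")
  }
  full <- expand.grid(gender = genders, region = regions, year = waves,
                      stringsAsFactors = FALSE)
  fkey <- paste(full$region, full$year, full$gender, sep = "\r")
  absent <- setdiff(fkey, key)
  if (length(absent)) {
    stop("missing cells (region|year|gender): ",
         paste(gsub("\r", "|", utils::head(absent, 10L)), collapse = ", "),
         if (length(absent) > 10L) sprintf(" ... and %d more", length(absent) - 10L))
  }
  idx <- match(fkey, key)
  J <- length(genders); N <- length(regions); Tn <- length(waves)
  counts_panel(regions, waves, genders,
               Y = array(d$cases[idx], c(J, N, Tn)),
               n = array(d$n[idx], c(J, N, Tn)))
}

#' Write a counts panel to long-format CSV
#'
#' Inverse of \code{\link{read_panel}}: \code{read_panel(write_panel(p))}
#' reproduces \code{p}.
#'
#' @param panel a \code{counts_panel}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "counts_panel"))
  g <- expand.grid(gender = panel$genders, region = panel$regions,
                   year = panel$waves, stringsAsFactors = FALSE)
  d <- data.frame(region = g$region, year = g$year, gender = g$gender,
                  cases = as.integer(panel$Y), n = as.integer(panel$n))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pool the two gender groups of a panel
#'
#' Sums cases and denominators over gender, returning a single-group panel
#' (group label "all"). Totals are conserved exactly.
#'
#' @param panel a two-gender \code{counts_panel}.
#' @return A single-group \code{counts_panel}.
#' @export
pool_genders <- function(panel) {
  stopifnot(inherits(panel, "counts_panel"))
  if (length(panel$genders) != 2L) stop("pool_genders requires two genders")
  counts_panel(panel$regions, panel$waves, "all",
               Y = colSums(panel$Y), n = colSums(panel$n))
}
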