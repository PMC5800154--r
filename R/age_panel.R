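#' Construct an age-stratified counts panel
#'
#' Adds an age-group axis to the gender x region x wave grid, carrying the
#' inputs of indirect standardization. Marginalizing over age reproduces a
#' valid \code{\link{counts_panel}}.
#'
#' @param regions,waves,genders as in \code{\link{counts_panel}}.
#' @param age_groups character vector of age-group labels (length A).
#' @param Y,n integer arrays of dim c(J, N, T, A).
#' @return An object of class \code{age_stratified_panel}.
#' @export
age_stratified_panel <- function(regions, waves, genders, age_groups, Y, n) {
  regions <- as.character(regions); waves <- as.integer(waves)
  genders <- as.character(genders); age_groups <- as.character(age_groups)
  J <- length(genders); N <- length(regions)
  Tn <- length(waves); A <- length(age_groups)
  Y <- array(as.numeric(Y), c(J, N, Tn, A))
  n <- array(as.numeric(n), c(J, N, Tn, A))
  dn <- list(genders, regions, waves, age_groups)
  dimnames(Y) <- dimnames(n) <- dn
  if (anyNA(Y) || anyNA(n)) stop("missing cells in age-stratified panel")
  if (any(Y < 0) || any(n < 0) || any(Y > n)) stop("need 0 <= Y <= n in every stratum")
  obj <- structure(list(regions = regions, waves = waves, genders = genders,
                        age_groups = age_groups, Y = Y, n = n),
                   class = "age_stratified_panel")
  # marginalizing over age must give a valid counts panel
  as_counts_panel(obj)
  obj
}

#' Collapse an age-stratified panel over age
#'
#' @param age_panel an \code{\link{age_stratified_panel}}.
#' @return The implied \code{\link{counts_panel}}.
#' @export
as_counts_panel <- function(age_panel) {
  stopifnot(inherits(age_panel, "age_stratified_panel"))
  counts_panel(age_panel$regions, age_panel$waves, age_panel$genders,
               Y = apply(age_panel$Y, c(1L, 2L, 3L), sum),
               n = apply(age_panel$n, c(1L, 2L, 3L), sum))
}

#' Read an age-stratified panel from long-format CSV
#'
#' Same layout as \code{\link{read_panel}} plus an \code{age_group} column.
#'
#' @param path CSV path with columns region, year, gender, age_group, cases, n.
#' @param gender_levels optional explicit gender order.
#' @return An \code{\link{age_stratified_panel}}.
#' @export
read_age_panel <- function(path, gender_levels = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("no rows in age panel file")
  need <- c("region", "year", "gender", "age_group", "cases", "n")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("age panel missing columns: ", paste(miss, collapse = ", "))
  regions <- unique(d$region); waves <- sort(unique(d$year))
  genders <- if (!is.null(gender_levels)) gender_levels else unique(d$gender)
  ages <- unique(d$age_group)
  full <- expand.grid(gender = genders, region = regions, year = waves,
                      age_group = ages, stringsAsFactors = FALSE)
  key <- paste(d$gender, d$region, d$year, d$age_group, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate stratum rows in age panel")
  fkey <- paste(full$gender, full$region, full$year, full$age_group, sep = "\r")
  idx <- match(fkey, key)
  if (anyNA(idx)) stop("missing strata in age panel: ",
                       paste(gsub("\r", "|", utils::head(fkey[is.na(idx)], 5L)),
                             collapse = ", "))
  J <- length(genders); N <- length(regions)
  age_stratified_panel(regions, waves, genders, ages,
                       Y = array(d$cases[idx], c(J, N, length(waves), length(ages))),
                       n = array(d$n[idx], c(J, N, length(waves), length(ages))))
}

#' Assign ages to age-group labels
#'
#' Two conventions are supported: fixed-width bins (default 4 years, last
#' group open-ended) as used for reference-rate construction, and the
#' coarse preset (12-29, 30-44, 45-59, 60+) used for describing the age
#' mix of survey participants.
#'
#' @param ages numeric vector of ages in years.
#' @param width bin width in years for \code{preset = "width"}.
#' @param min_age,max_age range covered by the width-based bins; ages at or
#'   beyond \code{max_age} fall into the open-ended last group.
#' @param preset \code{"width"} (fixed-width bins) or \code{"coarse"}.
#' @return Factor of age-group labels (levels in age order).
#' @export
age_bins <- function(ages, width = 4, min_age = 12, max_age = 60,
                     preset = c("width", "coarse")) {
  preset <- match.arg(preset)
  if (any(ages < 0)) stop("negative ages")
  if (preset == "coarse") {
    breaks <- c(12, 30, 45, 60, Inf)
    labels <- c("12-29", "30-44", "45-59", "60-100")
  } else {
    lo <- seq(min_age, max_age - width, by = width)
    breaks <- c(lo, max_age, Inf)
    labels <- c(paste(lo, lo + width - 1, sep = "-"), paste0(max_age, "+"))
  }
  if (any(ages < breaks[1L]))
    stop("ages below the first bin (", breaks[1L], ")")
  cut(ages, breaks = breaks, labels = labels, right = FALSE)
}
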