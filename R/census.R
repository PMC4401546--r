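#' Rectangular observation window
#'
#' Defines the rectangular plot window, in metres, inside which all stems
#' must lie. Stems exactly on the border are accepted (closed window).
#'
#' @param x_min,x_max,y_min,y_max Window limits in metres.
#' @return An object of class `"isar_window"`: a list with the four limits,
#'   plus `width`, `height` and `area` (m^2).
#' @examples
#' w <- isar_window(0, 500, 0, 500)  # 25 ha
#' w$area
#' @export
isar_window <- function(x_min, x_max, y_min, y_max) {
  stopifnot(is.numeric(x_min), is.numeric(x_max),
            is.numeric(y_min), is.numeric(y_max))
  if (x_max <= x_min || y_max <= y_min)
    stop("invalid window: need x_max > x_min and y_max > y_min")
  structure(list(x_min = as.numeric(x_min), x_max = as.numeric(x_max),
                 y_min = as.numeric(y_min), y_max = as.numeric(y_max),
                 width = as.numeric(x_max - x_min),
                 height = as.numeric(y_max - y_min),
                 area = as.numeric((x_max - x_min) * (y_max - y_min))),
            class = "isar_window")
}

#' @export
print.isar_window <- function(x, ...) {
  cat(sprintf("window [%g, %g] x [%g, %g] m (%.4g ha)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$area / 1e4))
  invisible(x)
}

in_window <- function(x, y, window) {
  x >= window$x_min & x <= window$x_max &
    y >= window$y_min & y <= window$y_max
}

#' Marked point pattern of a mapped plant community
#'
#' Bundles a stem table (one row per mapped individual: identifier, species
#' code, planar coordinates in metres, DBH in cm) with its observation
#' window. This is the community pattern every other function consumes.
#'
#' @param stems A data frame with columns `stem_id`, `species`, `x`, `y`,
#'   `dbh` (and optionally `size_class`).
#' @param window An [isar_window()].
#' @param validate Check invariants (coordinates inside the window,
#'   `dbh >= 1`, non-empty species codes)? Default `TRUE`.
#' @return An object of class `"isar_community"`: the stem data frame with
#'   the window attached as attribute `"window"`.
#' @seealso [read_census()], [stratify_by_size()], [select_targets()]
#' @export
community <- function(stems, window, validate = TRUE) {
  stopifnot(is.data.frame(stems), inherits(window, "isar_window"))
  needed <- c("stem_id", "species", "x", "y", "dbh")
  missing_cols <- setdiff(needed, names(stems))
  if (length(missing_cols))
    stop("census table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  stems <- as.data.frame(stems, stringsAsFactors = FALSE)
  stems$species <- as.character(stems$species)
  stems$x <- as.numeric(stems$x)
  stems$y <- as.numeric(stems$y)
  stems$dbh <- as.numeric(stems$dbh)
  if (validate) {
    if (anyNA(stems$x) || anyNA(stems$y))
      stop("non-numeric or missing coordinates")
    bad <- !in_window(stems$x, stems$y, window)
    if (any(bad))
      stop("stem(s) outside the window: ",
           paste(utils::head(stems$stem_id[bad], 5), collapse = ", "))
    if (anyNA(stems$dbh) || any(stems$dbh < 1))
      stop("dbh must be numeric and >= 1 cm (census threshold); offending stem(s): ",
           paste(utils::head(stems$stem_id[is.na(stems$dbh) | stems$dbh < 1], 5),
                 collapse = ", "))
    if (any(!nzchar(stems$species)) || anyNA(stems$species))
      stop("species codes must be non-empty")
  }
  structure(stems, window = window, class = c("isar_community", "data.frame"))
}

#' @export
print.isar_community <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("mapped community: %d stems, %d species in a %.4g ha window\n",
              nrow(x), length(unique(x$species)), w$area / 1e4))
  if ("size_class" %in% names(x)) {
    tab <- table(x$size_class)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.isar_community <- function(x, cex = 0.3, ...) {
  w <- attr(x, "window")
  sp <- factor(x$species)
  graphics::plot(x$x, x$y, col = as.integer(sp), pch = 16, cex = cex,
                 xlim = c(w$x_min, w$x_max), ylim = c(w$y_min, w$y_max),
                 xlab = "x (m)", ylab = "y (m)", asp = 1, ...)
  graphics::rect(w$x_min, w$y_min, w$x_max, w$y_max, border = "grey40")
  invisible(x)
}

#' Read a plot-census CSV
#'
#' Reads a stem table with header `stem_id,species,x,y,dbh` (decimal point,
#' UTF-8, no thousands separators) and validates it against the window.
#' Row order is irrelevant to all downstream results.
#'
#' @param path Path to the CSV file.
#' @param window An [isar_window()]; passed explicitly, never inferred from
#'   the data.
#' @return An `"isar_community"`.
#' @export
read_census <- function(path, window) {
  if (!file.exists(path)) stop("census file not found: ", path)
  stems <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(species = "character"))
  community(stems, window)
}

#' Write a community to the standard census CSV
#'
#' @param x An `"isar_community"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(x, path) {
  stopifnot(inherits(x, "isar_community"))
  cols <- intersect(c("stem_id", "species", "x", "y", "dbh", "size_class"),
                    names(x))
  utils::write.csv(as.data.frame(x)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Stratify stems into adults and saplings by DBH
#'
#' Splits every stem into exactly one size class: adults have
#' `dbh > adult_threshold_cm`, saplings have `1 <= dbh <= adult_threshold_cm`
#' (a stem of exactly 10 cm is a sapling; the sapling interval is closed).
#'
#' @param points An `"isar_community"`.
#' @param adult_threshold_cm Threshold in cm; default 10.
#' @return The community with a `size_class` column (`"adult"`/`"sapling"`).
#' @export
stratify_by_size <- function(points, adult_threshold_cm = 10) {
  stopifnot(inherits(points, "isar_community"))
  if (any(points$dbh < 1)) stop("dbh below the 1 cm census threshold")
  points$size_class <- ifelse(points$dbh > adult_threshold_cm,
                              "adult", "sapling")
  points
}

#' Select target species by adult abundance
#'
#' Target species are those whose adult abundance is strictly greater than
#' `min_abundance` (a species with exactly `min_abundance` adults is
#' excluded). Results are ranked by descending abundance, rank 1 = most
#' abundant; ties are broken by lexicographic species code so reports are
#' deterministic.
#'
#' @param points An `"isar_community"` with `size_class` assigned
#'   (see [stratify_by_size()]).
#' @param min_abundance Strict lower abundance bound; default 50.
#' @param count_on Which stems are counted towards abundance: `"adult"`
#'   (default; targets are adult individuals of major species) or `"all"`.
#' @return A data frame (`species`, `abundance`, `rank`), possibly empty.
#' @export
select_targets <- function(points, min_abundance = 50,
                           count_on = c("adult", "all")) {
  stopifnot(inherits(points, "isar_community"))
  count_on <- match.arg(count_on)
  if (count_on == "adult") {
    if (!"size_class" %in% names(points))
      stop("size_class not assigned; call stratify_by_size() first")
    pool <- points[points$size_class == "adult", , drop = FALSE]
  } else pool <- points
  counts <- table(pool$species)
  counts <- counts[counts > min_abundance]
  if (!length(counts))
    return(data.frame(species = character(), abundance = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  out <- data.frame(species = names(counts),
                    abundance = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$species), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
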