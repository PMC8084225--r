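#' Forest dynamics plot census objects
#'
#' An `fdp` object holds a rectangular mapped plot and its repeated stem
#' censuses: one row per tree, with per-census diameter-at-breast-height
#' (dbh, cm, stems of multi-stemmed trees joined by `";"`) and status
#' columns.  All analysis functions in eaaforest consume this object.
#'
#' Statuses follow the life cycle `prior* -> recruit -> alive* -> dead`,
#' with `dead` absorbing.  A dbh is recorded exactly when the status is
#' `recruit` or `alive`, and every recorded dbh is at least 1 cm (the
#' census threshold at 1.3 m height).  Coordinates live in the half-open
#' rectangle `[0, width) x [0, height)` in meters.
#'
#' @param trees A data frame with columns `tree_id`, `species`, `x`, `y`
#'   and per-census columns `dbh_1 ... dbh_k` (numeric, or character with
#'   semicolon-joined stem diameters) and optionally `status_1 ... status_k`.
#'   When status columns are absent they are inferred: the first census with
#'   a dbh is a `recruit`, later censuses with dbh are `alive`, censuses
#'   after the last dbh are `dead`, censuses before the first are `prior`.
#' @param width,height Plot dimensions in meters.
#' @param interval_years Nominal census interval in years (default 5).
#' @return An object of class `fdp`: a list with the validated `trees`
#'   tibble, parsed numeric matrices `dbh` (equivalent single-stem diameter,
#'   cm), `ba` (basal area, cm^2) and a character `status` matrix, plus
#'   `width`, `height`, `n_censuses`, `interval_years` and `species`.
#'   Records rejected for out-of-bounds coordinates are counted in
#'   `attr(, "n_rejected")` and reported with a warning.
#' @examples
#' trees <- tibble::tibble(
#'   tree_id = c("a", "b", "c"), species = c("sp1", "sp1", "sp2"),
#'   x = c(1, 2, 3), y = c(1, 1, 2),
#'   dbh_1 = c(NA, 2.0, 5.0), dbh_2 = c(1.2, 2.5, NA)
#' )
#' plt <- fdp_census(trees, width = 10, height = 10)
#' plt
#' @export
fdp_census <- function(trees, width, height, interval_years = 5) {
  stopifnot(is.data.frame(trees), width > 0, height > 0)
  trees <- tibble::as_tibble(trees)
  need <- c("tree_id", "species", "x", "y")
  if (!all(need %in% names(trees))) {
    stop("`trees` must have columns ", paste(need, collapse = ", "))
  }
  dbh_cols <- grep("^dbh_[0-9]+$", names(trees), value = TRUE)
  k <- length(dbh_cols)
  if (k < 1) stop("no dbh_<census> columns found")
  dbh_cols <- paste0("dbh_", seq_len(k))
  if (!all(dbh_cols %in% names(trees))) stop("dbh_<census> columns must be consecutive from 1")
  status_cols <- paste0("status_", seq_len(k))
  has_status <- all(status_cols %in% names(trees))

  trees$tree_id <- as.character(trees$tree_id)
  trees$species <- as.character(trees$species)
  if (anyDuplicated(trees$tree_id)) stop("duplicated tree_id")

  ## bounds rule: half-open rectangle, offending records rejected with a count
  ok <- trees$x >= 0 & trees$x < width & trees$y >= 0 & trees$y < height &
    !is.na(trees$x) & !is.na(trees$y)
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warning(n_rejected, " record(s) outside the plot rectangle rejected")
    trees <- trees[ok, , drop = FALSE]
  }

  ## canonicalize dbh columns to semicolon-joined character
  for (cc in dbh_cols) {
    v <- trees[[cc]]
    if (is.numeric(v)) v <- ifelse(is.na(v), NA_character_, format_dbh(v))
    trees[[cc]] <- as.character(v)
  }
  stems <- lapply(dbh_cols, function(cc) parse_stems(trees[[cc]]))
  n <- nrow(trees)
  ba <- dbh <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    ba[, j] <- vapply(stems[[j]], function(d) if (length(d)) sum(pi * (d / 2)^2) else NA_real_, 0)
    dbh[, j] <- vapply(stems[[j]], function(d) if (length(d)) sqrt(sum(d^2)) else NA_real_, 0)
  }
  all_d <- unlist(stems)
  if (any(all_d < 1 - 1e-9)) stop("recorded dbh below the 1 cm census threshold")
  if (any(all_d < 0)) stop("negative dbh")

  if (has_status) {
    status <- vapply(status_cols, function(cc) as.character(trees[[cc]]), character(n))
    status <- matrix(status, n, k)
    bad <- setdiff(unique(as.vector(status)), c("prior", "recruit", "alive", "dead"))
    bad <- bad[!is.na(bad)]
    if (length(bad)) stop("unknown status token(s): ", paste(bad, collapse = ", "))
    if (anyNA(status)) stop("missing status values")
  } else {
    status <- infer_status(!is.na(dbh))
    for (j in seq_len(k)) trees[[status_cols[j]]] <- status[, j]
  }
  validate_status(status, !is.na(dbh))

  ## column order: ids, coords, dbh_*, status_*
  trees <- trees[, c(need, dbh_cols, status_cols)]
  out <- structure(
    list(
      trees = trees, dbh = dbh, ba = ba, status = status,
      width = as.numeric(width), height = as.numeric(height),
      n_censuses = k, interval_years = as.numeric(interval_years),
      species = sort(unique(trees$species))
    ),
    class = "fdp"
  )
  attr(out, "n_rejected") <- n_rejected
  out
}

format_dbh <- function(x) vapply(x, function(v) format(v, digits = 12, scientific = FALSE, trim = TRUE), "")

parse_stems <- function(chr) {
  lapply(chr, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

## statuses from dbh presence: first presence = recruit, then alive,
## absence after presence = dead (absorbing), before = prior
infer_status <- function(present) {
  k <- ncol(present)
  t(apply(present, 1, function(p) {
    first <- match(TRUE, p)
    if (is.na(first)) stop("tree with no dbh in any census")
    last <- max(which(p))
    if (!all(p[first:last])) stop("dbh gap within a tree's record; cannot infer status")
    s <- rep("prior", k)
    s[first] <- "recruit"
    if (last > first) s[(first + 1):last] <- "alive"
    if (last < k) s[(last + 1):k] <- "dead"
    s
  }))
}

validate_status <- function(status, present) {
  ord <- c(prior = 1L, recruit = 2L, alive = 3L, dead = 4L)
  num <- matrix(ord[status], nrow(status), ncol(status))
  for (i in seq_len(nrow(status))) {
    s <- num[i, ]
    if (is.unsorted(s)) stop("non-monotone status sequence for tree row ", i)
    if (sum(s == 2L) > 1L) stop("multiple recruit events for tree row ", i)
  }
  measurable <- status %in% c("recruit", "alive")
  if (any(measurable != as.vector(present))) {
    stop("dbh must be present exactly when status is recruit or alive")
  }
  invisible(TRUE)
}

#' @export
print.fdp <- function(x, ...) {
  cat(sprintf(
    "<fdp> %g x %g m, %d censuses (%g-yr intervals), %d trees, %d species\n",
    x$width, x$height, x$n_censuses, x$interval_years, nrow(x$trees),
    length(x$species)
  ))
  cat(sprintf("  stem density %.3f trees/m2 (census 1)\n",
              sum(!is.na(x$dbh[, 1])) / (x$width * x$height)))
  invisible(x)
}

#' Per-census snapshot of a plot
#'
#' Returns one row per tree with its state at a single census: equivalent
#' single-stem diameter (cm), basal area (cm^2, stems summed) and status.
#'
#' @param plot An [fdp_census()] object.
#' @param census Census index (1-based).
#' @return A tibble with columns `.idx` (row index into the plot), `tree_id`,
#'   `species`, `x`, `y`, `dbh`, `ba`, `status`.
#' @export
census_state <- function(plot, census) {
  stopifnot(inherits(plot, "fdp"), census >= 1, census <= plot$n_censuses)
  tibble::tibble(
    .idx = seq_len(nrow(plot$trees)),
    tree_id = plot$trees$tree_id,
    species = plot$trees$species,
    x = plot$trees$x, y = plot$trees$y,
    dbh = plot$dbh[, census], ba = plot$ba[, census],
    status = plot$status[, census]
  )
}

#' Read and write census tables
#'
#' The canonical dialect is a CSV with a comment header carrying the plot
#' metadata (`# plot_width: 100` etc.), one row per tree, and wide
#' per-census `dbh_<j>` / `status_<j>` columns; multi-stem diameters are
#' semicolon-joined within a cell.  `write_census()` followed by
#' `read_census()` is a lossless round trip.
#'
#' @param path File path.
#' @param width,height,interval_years Plot metadata; taken from the file
#'   header when `NULL`.
#' @return `read_census()` returns an [fdp_census()] object; `write_census()`
#'   returns `path` invisibly.
#' @export
read_census <- function(path, width = NULL, height = NULL, interval_years = NULL) {
  lines <- readr::read_lines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([a-z_]+)\\s*:\\s*(\\S+)", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- as.numeric(m[3])
  }
  width <- width %||% meta$plot_width
  height <- height %||% meta$plot_height
  interval_years <- interval_years %||% meta$interval_years %||% 5
  if (is.null(width) || is.null(height)) {
    stop("plot dimensions not found in file header and not supplied")
  }
  trees <- readr::read_csv(I(lines[!grepl("^#", lines)]),
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      tree_id = "c", species = "c", x = "d", y = "d", .default = "c"
    )
  )
  fdp_census(trees, width = width, height = height, interval_years = interval_years)
}

#' @rdname read_census
#' @param plot An [fdp_census()] object.
#' @export
write_census <- function(plot, path) {
  stopifnot(inherits(plot, "fdp"))
  hdr <- c(
    sprintf("# plot_width: %.10g", plot$width),
    sprintf("# plot_height: %.10g", plot$height),
    sprintf("# interval_years: %.10g", plot$interval_years)
  )
  readr::write_lines(hdr, path)
  readr::write_csv(plot$trees, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
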