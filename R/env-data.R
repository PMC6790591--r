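#' Construct a raster grid
#'
#' A minimal regular lon/lat grid: `values[1, 1]` is the top-left (north-west)
#' cell, rows run north to south and columns west to east.
#'
#' @param values numeric matrix of cell values (rows = north to south).
#' @param origin numeric length-2: (minimum longitude, maximum latitude) of
#'   the grid, i.e. the outer corner of the top-left cell.
#' @param cellsize numeric length-2 cell size in degrees (x, y), both > 0.
#' @param name variable name.
#' @param nodata sentinel value marking missing cells (converted to `NA`).
#' @return Object of class `RasterGrid`.
#' @export
raster_grid <- function(values, origin, cellsize, name = "env",
                        nodata = NULL) {
  values <- as.matrix(values)
  stopifnot(length(origin) == 2L, length(cellsize) == 2L,
            all(cellsize > 0), nrow(values) > 0, ncol(values) > 0)
  if (!is.null(nodata)) values[values == nodata] <- NA_real_
  structure(list(name = name, origin = as.numeric(origin),
                 cellsize = as.numeric(cellsize), values = values),
            class = "RasterGrid")
}

#' Read an ESRI ASCII grid (.asc)
#'
#' Plain-text raster format with a 6-line header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`) followed by rows of values, north first. This is the only
#' raster format supported: no GDAL-backed reader is available in the stack,
#' and GeoTIFF is a binary format. `gdal_translate -of AAIGrid` converts.
#'
#' @param path file path.
#' @param name variable name; default is the file stem.
#' @return A `RasterGrid`.
#' @export
read_esri_ascii <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", trimws(lines[i]))) {
    kv <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("missing header field ", k, " in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("value count mismatch in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  raster_grid(m, origin = c(xll, yll + hdr$nrows * hdr$cellsize),
              cellsize = c(hdr$cellsize, hdr$cellsize), name = name,
              nodata = hdr$nodata_value)
}

#' Extract raster values at point locations
#'
#' Nearest-cell rule (the value of the cell containing the point; no
#' interpolation). Points outside the grid extent, or falling on a nodata
#' cell, yield `NA`.
#'
#' @param r RasterGrid.
#' @param pts two-column matrix or data.frame of (lon, lat).
#' @return Numeric vector, one value per point.
#' @export
extract_at_points <- function(r, pts) {
  pts <- as.matrix(pts)
  stopifnot(inherits(r, "RasterGrid"), ncol(pts) == 2L)
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((pts[, 1L] - r$origin[1L]) / r$cellsize[1L]) + 1
  row <- floor((r$origin[2L] - pts[, 2L]) / r$cellsize[2L]) + 1
  out <- rep(NA_real_, nrow(pts))
  ok <- !is.na(col) & !is.na(row) & col >= 1 & col <= nc & row >= 1 & row <= nr
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Construct an environment table
#'
#' Samples x environmental variables, with WGS84 coordinates. Population
#' -structure columns (added by [add_structure_columns()]) are tracked by
#' name and treated specially by [prune_correlated()] and the scan engine.
#'
#' @param ids character sample IDs (order must match the genotype file).
#' @param lon,lat numeric coordinates in degrees (WGS84).
#' @param variables data.frame of named numeric columns.
#' @param pop_vars character vector naming the population-structure columns
#'   among `variables`.
#' @return Object of class `EnvTable` (a data.frame with columns `ID`,
#'   `lon`, `lat`, then variables; attribute `pop_vars`).
#' @export
env_table <- function(ids, lon, lat, variables, pop_vars = character()) {
  variables <- as.data.frame(variables)
  stopifnot(length(ids) == length(lon), length(lon) == length(lat),
            nrow(variables) == length(ids))
  if (anyDuplicated(ids)) stop("duplicate sample IDs")
  if (!all(pop_vars %in% names(variables)))
    stop("pop_vars not found among variables")
  if (!all(vapply(variables, is.numeric, logical(1L))))
    stop("all environmental variables must be numeric")
  df <- data.frame(ID = as.character(ids), lon = as.numeric(lon),
                   lat = as.numeric(lat), variables, check.names = FALSE,
                   stringsAsFactors = FALSE)
  structure(df, pop_vars = pop_vars, class = c("EnvTable", "data.frame"))
}

#' Variable names of an environment table
#' @param env EnvTable.
#' @param which `"env"`, `"pop"` or `"all"`.
#' @return Character vector of column names.
#' @export
env_variables <- function(env, which = c("env", "pop", "all")) {
  which <- match.arg(which)
  vars <- setdiff(names(env), c("ID", "lon", "lat"))
  pop <- attr(env, "pop_vars")
  switch(which, all = vars, pop = pop, env = setdiff(vars, pop))
}

#' Prune mutually correlated environmental variables
#'
#' Greedy scan in column order: a variable is dropped when its squared
#' Pearson correlation (pairwise-complete) with any already-retained variable
#' exceeds `r2_threshold`; the earlier column wins. Population-structure
#' columns are never dropped and never cause a drop. Constant columns are
#' dropped. Also computes the retention curve (# variables retained at each
#' threshold on a 0.05-step grid), the offline stand-in for an interactive
#' threshold-selection graph.
#'
#' @param env EnvTable.
#' @param r2_threshold squared-correlation ceiling, in (0, 1\].
#' @return Pruned `EnvTable` with attribute `pruning_curve` (data.frame:
#'   `threshold`, `n_retained`).
#' @export
prune_correlated <- function(env, r2_threshold = 0.9) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  keep <- .greedy_prune(env, r2_threshold)
  grid <- seq(0.05, 1, by = 0.05)
  curve <- data.frame(threshold = grid,
                      n_retained = vapply(grid, function(th)
                        length(.greedy_prune(env, th)), integer(1L)))
  out <- env[, c("ID", "lon", "lat", keep), drop = FALSE]
  structure(out, pop_vars = attr(env, "pop_vars"),
            pruning_curve = curve, class = class(env))
}

.greedy_prune <- function(env, r2_threshold) {
  vars <- env_variables(env, "env")
  pop <- env_variables(env, "pop")
  retained <- character()
  for (v in vars) {
    x <- env[[v]]
    if (sd(x, na.rm = TRUE) == 0 || all(is.na(x))) next
    ok <- TRUE
    for (w in retained) {
      r <- suppressWarnings(cor(x, env[[w]], use = "pairwise.complete.obs"))
      if (!is.na(r) && r * r > r2_threshold) { ok <- FALSE; break }
    }
    if (ok) retained <- c(retained, v)
  }
  c(retained, pop)
}

#' Write / read the environment CSV
#'
#' RFC-4180 CSV with columns `ID`, `lon`, `lat`, then variables. The
#' population-structure columns are recognised on read by the `pop` name
#' prefix convention (`pop1`, `pop2`, ...), or pass `pop_vars` explicitly.
#'
#' @param env EnvTable.
#' @param path file path.
#' @param pop_vars population-structure column names (read).
#' @return `write_env_csv()` returns `path` invisibly; `read_env_csv()`
#'   returns an `EnvTable`.
#' @export
write_env_csv <- function(env, path) {
  write.csv(as.data.frame(env), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_env_csv
#' @export
read_env_csv <- function(path, pop_vars = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("ID", "lon", "lat")
  if (!all(req %in% names(df)))
    stop("environment CSV must have columns ID, lon, lat")
  if (anyDuplicated(df$ID)) stop("duplicate sample IDs in ", path)
  vars <- setdiff(names(df), req)
  if (is.null(pop_vars)) pop_vars <- grep("^pop[0-9]+$", vars, value = TRUE)
  env_table(df$ID, df$lon, df$lat, df[, vars, drop = FALSE],
            pop_vars = pop_vars)
}
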