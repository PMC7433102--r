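#' Read and validate a Newick phylogeny
#'
#' Wraps [ape::read.tree()] with the checks the pipeline relies on: parseable
#' Newick, branch lengths present and positive (zero-length terminal branches
#' rejected), unique tip labels.
#'
#' @param path Newick file.
#' @return a `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stop("unparseable Newick file: ", path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] <= 0))
    stop("zero- or negative-length terminal branches in ", path)
  if (any(tree$edge.length < 0)) stop("negative branch lengths in ", path)
  tree
}

#' Write a phylogeny as Newick
#' @param tree a `phylo` object.
#' @param path output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read and validate a species trait table
#'
#' CSV with required columns `species`, `sds`, `reproductive_mode`,
#' `breed_start`, `breed_end`, `family`; extra columns are kept. Codings are
#' validated (0/1 for the binary traits, months in 1..12); a blank or missing
#' `breed_end` is closed at December ([resolve_open_window()]). Species
#' absent from `tree` (when given) are listed in the exclusion report rather
#' than being fatal.
#'
#' @param path CSV file.
#' @param tree optional `phylo` to cross-check species labels.
#' @return data.frame with attribute `exclusions` (species not in the tree).
#' @export
read_traits <- function(path, tree = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "sds", "reproductive_mode", "breed_start",
                "breed_end", "family")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("trait table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$species))
    stop("duplicate species rows in trait table")
  for (cn in c("sds", "reproductive_mode")) {
    bad <- which(!df[[cn]] %in% c(0, 1))
    if (length(bad) > 0)
      stop(sprintf("invalid %s coding (must be 0/1) at row(s): %s", cn,
                   paste(bad, collapse = ", ")))
  }
  bad <- which(!df$breed_start %in% 1:12)
  if (length(bad) > 0)
    stop("breed_start outside 1..12 at row(s): ", paste(bad, collapse = ", "))
  open_end <- is.na(df$breed_end)
  df$breed_end[open_end] <- 12L
  bad <- which(!df$breed_end %in% 1:12)
  if (length(bad) > 0)
    stop("breed_end outside 1..12 at row(s): ", paste(bad, collapse = ", "))
  exclusions <- character(0)
  if (!is.null(tree)) exclusions <- setdiff(df$species, tree$tip.label)
  rownames(df) <- df$species
  attr(df, "exclusions") <- exclusions
  df
}

#' Write a trait table as CSV
#' @param traits data.frame.
#' @param path output file.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE)
  invisible(path)
}

#' Write a climate grid as long-format CSV plus a JSON manifest
#'
#' One CSV per variable with columns `year, month, row, col, value`, plus
#' `manifest.json` recording dimensions, latitudes, longitudes and years.
#'
#' @param grid a `climate_grid`.
#' @param dir output directory (created if needed).
#' @export
write_climate_csv <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(grid$temperature)
  idx <- expand.grid(year = grid$years, month = 1:12, row = seq_len(d[3]),
                     col = seq_len(d[4]))
  for (v in c("temperature", "precipitation")) {
    df <- cbind(idx, value = as.vector(grid[[v]]))
    utils::write.csv(df, file.path(dir, paste0(v, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(
    list(variables = c("temperature", "precipitation"),
         years = grid$years, lat = grid$lat, lon = grid$lon,
         dims = d),
    file.path(dir, "manifest.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read a climate grid from long-format CSVs
#'
#' Reads the encoding written by [write_climate_csv()], optionally cropping
#' to an inclusive year period, and errors if any (year, month) combination
#' in the period is missing.
#'
#' @param dir directory with `manifest.json` and per-variable CSVs.
#' @param period optional `c(first_year, last_year)`, inclusive on both ends.
#' @return a `climate_grid`.
#' @export
read_climate_csv <- function(dir, period = NULL) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  years <- man$years
  if (!is.null(period)) {
    if (period[1] > period[2]) stop("period start must not exceed end")
    years <- years[years >= period[1] & years <= period[2]]
    if (length(years) == 0) stop("no years within the requested period")
  }
  nr <- man$dims[3]; nc <- man$dims[4]
  grid <- list(lat = man$lat, lon = man$lon, years = years)
  for (v in man$variables) {
    df <- utils::read.csv(file.path(dir, paste0(v, ".csv")))
    df <- df[df$year %in% years, ]
    have <- unique(df[, c("year", "month")])
    want <- expand.grid(year = years, month = 1:12)
    miss <- !paste(want$year, want$month) %in% paste(have$year, have$month)
    if (any(miss))
      stop("missing climate months: ",
           paste(paste0(want$year[miss], "-", want$month[miss]),
                 collapse = ", "))
    arr <- array(NA_real_, c(length(years), 12, nr, nc))
    yi <- match(df$year, years)
    arr[cbind(yi, df$month, df$row, df$col)] <- df$value
    if (anyNA(arr)) stop("incomplete climate grid for variable ", v)
    grid[[v]] <- arr
  }
  structure(grid[c("temperature", "precipitation", "lat", "lon", "years")],
            class = "climate_grid")
}

#' Write range masks as a CSV cell list
#' @param masks named list of (row, col) matrices.
#' @param path output CSV.
#' @export
write_ranges_csv <- function(masks, path) {
  df <- do.call(rbind, lapply(names(masks), function(sp)
    data.frame(species = sp, row = masks[[sp]][, 1], col = masks[[sp]][, 2])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read range masks from a CSV cell list
#'
#' CSV with columns `species, row, col`. Cells must fall inside the grid
#' when one is given; species with no cells are simply absent.
#'
#' @param path CSV file.
#' @param grid optional `climate_grid` for bounds checking.
#' @return named list of (row, col) matrices.
#' @export
read_ranges_csv <- function(path, grid = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "row", "col") %in% names(df)))
    stop("range CSV needs columns species, row, col")
  if (!is.null(grid)) {
    d <- dim(grid$temperature)
    if (any(df$row < 1 | df$row > d[3] | df$col < 1 | df$col > d[4]))
      stop("range cells fall outside the climate grid")
  }
  lapply(split(df, df$species), function(s)
    matrix(c(s$row, s$col), ncol = 2, dimnames = list(NULL, c("row", "col"))))
}

# even-odd ray-casting point-in-polygon test
.point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

#' Rasterize GeoJSON range polygons onto the climate grid
#'
#' Reads a GeoJSON FeatureCollection whose features carry a `species`
#' property and Polygon/MultiPolygon geometry in (lon, lat), and marks a grid
#' cell as inside a range when its center falls inside any polygon ring
#' (even-odd rule). Species whose polygons catch no cell center are flagged
#' via the `empty` attribute.
#'
#' @param path GeoJSON file.
#' @param grid a `climate_grid` (provides cell-center lat/lon).
#' @return named list of (row, col) matrices; attribute `empty` lists
#'   species with no covered cell.
#' @export
read_ranges_geojson <- function(path, grid) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  centers <- expand.grid(row = seq_along(grid$lat), col = seq_along(grid$lon))
  masks <- list()
  empty <- character(0)
  for (feat in gj$features) {
    sp <- feat$properties$species
    if (is.null(sp)) stop("feature without a species property")
    geom <- feat$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    hit <- rep(FALSE, nrow(centers))
    for (poly in polys) {
      ring <- do.call(rbind, lapply(poly[[1]], function(pt)
        c(pt[[1]], pt[[2]])))
      for (k in seq_len(nrow(centers))) {
        if (!hit[k] && .point_in_polygon(grid$lon[centers$col[k]],
                                         grid$lat[centers$row[k]], ring))
          hit[k] <- TRUE
      }
    }
    if (!any(hit)) {
      empty <- c(empty, sp)
    } else {
      masks[[sp]] <- as.matrix(centers[hit, c("row", "col")])
      dimnames(masks[[sp]]) <- list(NULL, c("row", "col"))
    }
  }
  attr(masks, "empty") <- empty
  masks
}

#' Write a full synthetic study to disk as plain-text files
#'
#' Newick tree, CSV trait table, long-format climate CSVs, CSV range masks
#' and a JSON sidecar with the true generator parameters.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tree(study$tree, file.path(dir, "tree.nwk"))
  write_traits(study$traits, file.path(dir, "traits.csv"))
  write_climate_csv(study$grid, file.path(dir, "climate"))
  write_ranges_csv(study$masks, file.path(dir, "ranges.csv"))
  truth <- study$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a study written by [write_study()]
#' @param dir directory.
#' @return a `synthetic_study`-shaped list.
#' @export
read_study <- function(dir) {
  tree <- read_tree(file.path(dir, "tree.nwk"))
  traits <- read_traits(file.path(dir, "traits.csv"), tree)
  grid <- read_climate_csv(file.path(dir, "climate"))
  masks <- read_ranges_csv(file.path(dir, "ranges.csv"), grid)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(tree = tree, traits = traits, grid = grid, masks = masks,
                 truth = truth), class = "synthetic_study")
}
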