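# Plain-text readers/writers for every object the pipeline exchanges:
# outline CSV, OFF-style meshes, cell-map CSV, growth/zone TSV, and
# PNG images with a JSON sidecar carrying the pixel size.

#' Write / read a leaf outline as CSV
#'
#' Columns `x_mm`, `y_mm` in boundary order; metadata columns
#' `genotype` and `node` are carried when present.
#' @param outline a `leaf_outline`.
#' @param path file path.
#' @export
write_outline_csv <- function(outline, path) {
  stopifnot(inherits(outline, "leaf_outline"))
  df <- data.frame(x_mm = outline$vertices[, 1], y_mm = outline$vertices[, 2])
  if (any(outline$is_cut)) df$is_cut <- outline$is_cut
  if (!is.null(outline$genotype)) df$genotype <- outline$genotype
  if (!is.null(outline$node)) df$node <- outline$node
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outline_csv
#' @export
read_outline_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("x_mm", "y_mm") %in% names(df)))
    stop("outline CSV needs columns `x_mm` and `y_mm`")
  new_leaf_outline(cbind(df$x_mm, df$y_mm),
                   genotype = if ("genotype" %in% names(df)) df$genotype[1],
                   node = if ("node" %in% names(df)) df$node[1],
                   is_cut = if ("is_cut" %in% names(df)) df$is_cut)
}

#' Write / read a surface mesh in OFF format
#'
#' Standard ASCII OFF: an `OFF` header line, a counts line, then vertex
#' coordinates and 1-per-line face records (`3 i j k`, zero-based).
#' @param mesh a `leaf_mesh`.
#' @param path file path.
#' @export
write_mesh_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "leaf_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    sprintf("%.9g %.9g %.9g", v[1], v[2], v[3])), con)
  writeLines(apply(mesh$faces - 1L, 1, function(f)
    sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (toupper(trimws(ln[1])) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- do.call(rbind, lapply(ln[2 + seq_len(nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(ln[2 + nv + seq_len(nf)], function(s) {
    v <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    if (v[1] != 3L) stop("only triangle faces are supported")
    v[2:4] + 1L
  }))
  new_leaf_mesh(vtx, fc)
}

#' Write / read a cell map as CSV
#'
#' One row per cell: `cell_id`, `centroid_x_um`, `centroid_y_um`,
#' `area_um2`, `gus_status` (0/1, empty when unassigned). Cell polygon
#' geometry is not round-tripped -- downstream profile and zone
#' operations use centroids, areas, and status only.
#' @param map a `cell_map`.
#' @param path file path.
#' @export
write_cell_map_csv <- function(map, path) {
  stopifnot(inherits(map, "cell_map"))
  df <- data.frame(cell_id = map$cells$cell_id,
                   centroid_x_um = map$cells$x_um,
                   centroid_y_um = map$cells$y_um,
                   area_um2 = map$cells$area_um2,
                   gus_status = as.integer(map$cells$gus))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_map_csv
#' @param width_um,height_um domain extent; inferred from the centroid
#'   range when omitted.
#' @export
read_cell_map_csv <- function(path, width_um = NULL, height_um = NULL) {
  df <- read.csv(path)
  need <- c("cell_id", "centroid_x_um", "centroid_y_um", "area_um2")
  if (!all(need %in% names(df))) stop("cell map CSV needs columns ",
                                      paste(need, collapse = ", "))
  gus <- if ("gus_status" %in% names(df)) df$gus_status == 1 else NA
  cells <- data.frame(cell_id = df$cell_id, x_um = df$centroid_x_um,
                      y_um = df$centroid_y_um, area_um2 = df$area_um2,
                      gus = gus)
  structure(list(cells = cells, polygons = NULL,
                 width_um = width_um %||% max(df$centroid_x_um),
                 height_um = height_um %||% max(df$centroid_y_um),
                 target_cell_area_um2 = NA, seed = NA, jitter = NA,
                 front = NULL),
            class = "cell_map")
}

#' Write / read a rendered stain image as PNG plus JSON sidecar
#'
#' The sidecar (`<path>.json`) records the pixel size and render seed
#' so an image file alone is a complete measurement input.
#' @param image a `gus_image`.
#' @param path PNG file path.
#' @export
write_gus_image_png <- function(image, path) {
  stopifnot(inherits(image, "gus_image"))
  png::writePNG(image$pixels, path)
  jsonlite::write_json(list(pixel_size_um = image$pixel_size_um,
                            seed = image$seed, noise_sd = image$noise_sd),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gus_image_png
#' @export
read_gus_image_png <- function(path) {
  px <- png::readPNG(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (is.null(meta$pixel_size_um))
    stop("sidecar JSON with `pixel_size_um` not found for ", path)
  structure(list(pixels = px, pixel_size_um = meta$pixel_size_um,
                 truth_mask = NULL, cell_labels = NULL,
                 n_gus_cells = NA_integer_, stain_color = NULL,
                 noise_sd = meta$noise_sd %||% NA_real_,
                 seed = meta$seed %||% NULL),
            class = "gus_image")
}

#' Write / read growth and zone series as TSV
#' @param series a `growth_series` or `zone_series` data frame.
#' @param path file path.
#' @export
write_series_tsv <- function(series, path) {
  write.table(as.data.frame(series), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_growth_tsv <- function(path) {
  df <- read.delim(path)
  if (!all(c("day", "width_mm") %in% names(df)))
    stop("growth TSV needs columns `day` and `width_mm`")
  class(df) <- c("growth_series", "data.frame")
  df
}

#' @rdname write_series_tsv
#' @export
read_zone_tsv <- function(path) {
  df <- read.delim(path)
  if (!all(c("leaf_length_mm", "zone_length_mm") %in% names(df)))
    stop("zone TSV needs columns `leaf_length_mm` and `zone_length_mm`")
  class(df) <- c("zone_series", "data.frame")
  df
}
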