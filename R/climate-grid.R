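#' Gridded climate field for one epoch and one variable
#'
#' Lightweight container for a rectangular gridded climate field: a numeric
#' matrix (`NA` marks missing cells), the cell edge length in metres, and
#' epoch/variable labels. Values are in the variable's natural units (degrees C
#' for mean annual temperature, mm/yr for annual precipitation).
#'
#' @param values numeric matrix; `NA` = missing, never silently zero.
#' @param cell_size_m cell edge length in metres (> 0).
#' @param epoch epoch label, e.g. `"lgm"`, `"present"`, `"lig"`.
#' @param variable variable label, e.g. `"temperature"`, `"precipitation"`.
#' @return object of class `climate_grid`.
#' @export
climate_grid <- function(values, cell_size_m, epoch = "present",
                         variable = "temperature") {
  if (!is.matrix(values) || !is.numeric(values)) {
    mp_stop("values must be a numeric matrix", "invalid_config")
  }
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1 || cell_size_m <= 0) {
    mp_stop("cell_size_m must be a single positive number", "invalid_config")
  }
  structure(
    list(values = values, cell_size_m = as.numeric(cell_size_m),
         epoch = as.character(epoch), variable = as.character(variable)),
    class = "climate_grid"
  )
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %s [%s]: %d x %d cells, %.0f m/cell, %d missing\n",
              x$variable, x$epoch, nrow(x$values), ncol(x$values),
              x$cell_size_m, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) dim(x$values)

check_congruent <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$cell_size_m, b$cell_size_m))) {
    mp_stop("grids are not congruent (shape or cell size differs)",
            "congruence_error")
  }
  invisible(TRUE)
}

#' Read / write a plain-text climate grid
#'
#' Text raster format used for synthetic-mode interchange: a 6-line header
#' (`ncols`, `nrows`, `cell_size_m`, `epoch`, `variable`, `nodata`) followed by
#' `nrows` whitespace-separated rows of values.
#'
#' @param path file path.
#' @return `read_grid_txt()` returns a [climate_grid]; `write_grid_txt()`
#'   returns `path` invisibly.
#' @export
read_grid_txt <- function(path) {
  if (!file.exists(path)) {
    mp_stop(sprintf("grid file not found: %s", path), "io_error")
  }
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "[[:space:]]+")
  key <- vapply(hdr, `[`, "", 1)
  val <- vapply(hdr, `[`, "", 2)
  names(val) <- tolower(key)
  nc <- as.integer(val[["ncols"]]); nr <- as.integer(val[["nrows"]])
  nodata <- as.numeric(val[["nodata"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  climate_grid(m, as.numeric(val[["cell_size_m"]]),
               epoch = val[["epoch"]], variable = val[["variable"]])
}

#' @rdname read_grid_txt
#' @param grid a [climate_grid].
#' @param nodata numeric sentinel written for missing cells.
#' @export
write_grid_txt <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "climate_grid"))
  m <- grid$values
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("cell_size_m", format(grid$cell_size_m, scientific = FALSE)),
           paste("epoch", grid$epoch), paste("variable", grid$variable),
           paste("nodata", nodata))
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
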