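#' Electrode montages on the unit sphere
#'
#' A montage is a tibble with one row per electrode and columns `label`,
#' `x`, `y`, `z` (unit-sphere Cartesian coordinates: x right, y anterior,
#' z superior), carrying the head radius in metres as an attribute.
#' All spherical-spline computations (see [csd_transform()]) and all
#' component topographies in the forward model use these positions.
#'
#' @param labels Character vector of electrode labels.
#' @param x,y,z Cartesian coordinates; each row is normalised to unit length.
#' @param head_radius Head radius in metres used to scale Laplacian output.
#' @return A `montage` tibble with columns `label`, `x`, `y`, `z`.
#' @export
montage <- function(labels, x, y, z, head_radius = 0.09) {
  assert_that(!anyDuplicated(labels), "montage labels must be unique")
  n <- sqrt(x^2 + y^2 + z^2)
  assert_that(all(n > 0), "montage coordinates must be nonzero")
  out <- tibble(label = as.character(labels), x = x / n, y = y / n, z = z / n)
  attr(out, "head_radius") <- head_radius
  class(out) <- c("montage", class(out))
  out
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage: %d electrodes, head radius %.3f m>\n",
              nrow(x), attr(x, "head_radius")))
  NextMethod()
}

head_radius <- function(mont) attr(mont, "head_radius") %||% 0.09

# Row/column layout of the 61-channel extended 10-20 cap. Each electrode is
# placed by an anterior-posterior arc angle (degrees from the vertex, positive
# anterior) and a lateral arc angle (positive right).
.montage61_layout <- function() {
  rows <- list(
    Fp = 72, AF = 54, F = 36, FC = 18, C = 0,
    CP = -18, P = -36, PO = -54, O = -72
  )
  cols <- list(
    Fp = c("1" = -18, "z" = 0, "2" = 18),
    AF = c("7" = -72, "3" = -36, "z" = 0, "4" = 36, "8" = 72),
    F  = c("7" = -72, "5" = -54, "3" = -36, "1" = -18, "z" = 0,
           "2" = 18, "4" = 36, "6" = 54, "8" = 72),
    FC = c("T7" = -72, "5" = -54, "3" = -36, "1" = -18, "z" = 0,
           "2" = 18, "4" = 36, "6" = 54, "T8" = 72),
    C  = c("T7" = -90, "5" = -54, "3" = -36, "1" = -18, "z" = 0,
           "2" = 18, "4" = 36, "6" = 54, "T8" = 90),
    CP = c("T7" = -72, "5" = -54, "3" = -36, "1" = -18, "z" = 0,
           "2" = 18, "4" = 36, "6" = 54, "T8" = 72),
    P  = c("7" = -72, "5" = -54, "3" = -36, "1" = -18, "z" = 0,
           "2" = 18, "4" = 36, "6" = 54, "8" = 72),
    PO = c("7" = -72, "3" = -36, "z" = 0, "4" = 36, "8" = 72),
    O  = c("1" = -18, "z" = 0, "2" = 18)
  )
  out <- list()
  for (row in names(rows)) {
    for (col in names(cols[[row]])) {
      lab <- switch(col,
        "T7" = paste0(sub("C", "T", row, fixed = TRUE), "7"),
        "T8" = paste0(sub("C", "T", row, fixed = TRUE), "8"),
        paste0(row, col)
      )
      # C row lateral extremes are the true temporal electrodes T7/T8
      if (row == "C" && col == "T7") lab <- "T7"
      if (row == "C" && col == "T8") lab <- "T8"
      if (row == "FC" && col == "T7") lab <- "FT7"
      if (row == "FC" && col == "T8") lab <- "FT8"
      if (row == "CP" && col == "T7") lab <- "TP7"
      if (row == "CP" && col == "T8") lab <- "TP8"
      out[[lab]] <- c(rows[[row]], cols[[row]][[col]])
    }
  }
  out
}

#' Packaged 61-channel extended 10-20 montage
#'
#' Returns the template montage used throughout the package: 61 scalp
#' positions (including FCz and Cz) on the unit sphere, constructed from the
#' anterior-posterior and lateral arc angles of the extended 10-20 layout.
#' The coordinates are an idealised spherical cap, adequate for the forward
#' model and the surface Laplacian; they are not digitised head positions.
#'
#' @inheritParams montage
#' @return A `montage` tibble with 61 rows.
#' @export
montage_61 <- function(head_radius = 0.09) {
  lay <- .montage61_layout()
  a <- vapply(lay, `[`, numeric(1), 1) * pi / 180  # anterior-posterior
  l <- vapply(lay, `[`, numeric(1), 2) * pi / 180  # lateral
  montage(names(lay),
          x = cos(a) * sin(l),
          y = sin(a),
          z = cos(a) * cos(l),
          head_radius = head_radius)
}

#' Read a montage from a TSV file
#'
#' The file must have a header row and either Cartesian columns
#' (`label`, `x`, `y`, `z`) or spherical columns (`label`, `theta`, `phi`,
#' both in degrees: `theta` = inclination from the vertex, `phi` = azimuth
#' counter-clockwise from the right ear). Coordinates are normalised onto
#' the unit sphere.
#'
#' @param path Path to the TSV file.
#' @param head_radius Head radius in metres.
#' @param require Labels that must be present (e.g. `c("FCz", "Cz")`);
#'   a validation error is raised otherwise.
#' @return A `montage` tibble.
#' @export
read_montage <- function(path, head_radius = 0.09, require = character()) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("x", "y", "z") %in% names(tab))) {
    out <- montage(tab$label, tab$x, tab$y, tab$z, head_radius = head_radius)
  } else if (all(c("theta", "phi") %in% names(tab))) {
    th <- tab$theta * pi / 180
    ph <- tab$phi * pi / 180
    out <- montage(tab$label,
                   x = sin(th) * cos(ph),
                   y = sin(th) * sin(ph),
                   z = cos(th),
                   head_radius = head_radius)
  } else {
    abort("montage file must have columns label,x,y,z or label,theta,phi")
  }
  missing <- setdiff(require, out$label)
  assert_that(length(missing) == 0,
              paste0("montage is missing required electrodes: ",
                     paste(missing, collapse = ", ")))
  out
}

#' Write a montage to a TSV file
#'
#' @param mont A `montage` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(mont, path) {
  readr::write_tsv(as_tibble(mont)[, c("label", "x", "y", "z")], path,
                   progress = FALSE)
  invisible(path)
}

# Pairwise cosine of the angular distance between electrodes.
montage_cosines <- function(mont, labels = mont$label) {
  m <- as.matrix(as_tibble(mont)[match(labels, mont$label), c("x", "y", "z")])
  cosmat <- m %*% t(m)
  pmin(pmax(cosmat, -1), 1)
}
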