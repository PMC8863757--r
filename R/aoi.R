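#' Build an AOI scheme
#'
#' An AOI scheme maps named screen regions to single uppercase letters.
#' Fixations falling into no region are assigned the whitespace letter
#' (default `"W"`), mirroring the common scanpath convention of building-area
#' / bricks / manual style schemes with a whitespace fallback.
#'
#' Region geometry is either an axis-aligned rectangle,
#' `list(type = "rect", x0 =, y0 =, x1 =, y1 =)`, with half-open membership
#' (`[x0, x1) x [y0, y1)`) so shared edges are never double-assigned, or a
#' polygon, `list(type = "polygon", x = c(...), y = c(...))`, with even-odd
#' membership and boundary points counted as inside. Scheme order resolves
#' overlaps: the first listed region containing a point wins.
#'
#' @param regions List of regions; each is
#'   `list(letter = "A", name = "building area", geometry = <rect|polygon>)`.
#' @param whitespace_letter Single character for the fallback region,
#'   default `"W"`; must not collide with any region letter.
#' @return An object of class `aoi_scheme`.
#' @export
#' @examples
#' scheme <- aoi_scheme(list(
#'   list(letter = "A", name = "building area",
#'        geometry = list(type = "rect", x0 = 0, y0 = 0, x1 = 100, y1 = 100)),
#'   list(letter = "B", name = "bricks",
#'        geometry = list(type = "rect", x0 = 100, y0 = 0, x1 = 200, y1 = 100))
#' ))
#' assign_aoi(c(50, 150, 500), c(50, 50, 50), scheme)
aoi_scheme <- function(regions, whitespace_letter = "W") {
  stopifnot(is.character(whitespace_letter), nchar(whitespace_letter) == 1)
  letters_seen <- character()
  for (r in regions) {
    if (is.null(r$letter) || nchar(r$letter) != 1 || !grepl("[A-Z]", r$letter)) {
      stop("aoi_scheme(): each region needs a single uppercase letter",
           call. = FALSE)
    }
    if (r$letter == whitespace_letter) {
      stop("aoi_scheme(): region letter '", r$letter,
           "' collides with the whitespace letter", call. = FALSE)
    }
    if (r$letter %in% letters_seen) {
      stop("aoi_scheme(): duplicate region letter '", r$letter, "'",
           call. = FALSE)
    }
    letters_seen <- c(letters_seen, r$letter)
    g <- r$geometry
    if (is.null(g$type)) stop("aoi_scheme(): geometry needs a type", call. = FALSE)
    if (g$type == "rect") {
      if (!(g$x1 > g$x0 && g$y1 > g$y0)) {
        stop("aoi_scheme(): degenerate rectangle for region '", r$letter, "'",
             call. = FALSE)
      }
    } else if (g$type == "polygon") {
      if (length(g$x) < 3 || length(g$x) != length(g$y)) {
        stop("aoi_scheme(): polygon for region '", r$letter,
             "' needs >= 3 vertices with matching x/y", call. = FALSE)
      }
    } else {
      stop("aoi_scheme(): unknown geometry type '", g$type, "'", call. = FALSE)
    }
  }
  structure(list(regions = regions, whitespace_letter = whitespace_letter),
            class = "aoi_scheme")
}

#' @export
print.aoi_scheme <- function(x, ...) {
  cat("<aoi_scheme> ", length(x$regions), " regions, whitespace '",
      x$whitespace_letter, "'\n", sep = "")
  for (r in x$regions) {
    cat("  ", r$letter, ": ", r$name %||% "", " (", r$geometry$type, ")\n",
        sep = "")
  }
  invisible(x)
}

#' Read an AOI scheme from YAML or JSON
#'
#' Expected structure: a top-level `whitespace_letter` (optional) and a
#' `regions` list, each region carrying `letter`, `name`, and either
#' `rect: [x0, y0, x1, y1]` or `polygon: [[x, y], ...]`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [aoi_scheme()] object.
#' @export
read_aoi_scheme <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  regions <- lapply(doc$regions, function(r) {
    geometry <- if (!is.null(r$rect)) {
      v <- unlist(r$rect)
      list(type = "rect", x0 = v[1], y0 = v[2], x1 = v[3], y1 = v[4])
    } else if (!is.null(r$polygon)) {
      m <- do.call(rbind, lapply(r$polygon, unlist))
      list(type = "polygon", x = m[, 1], y = m[, 2])
    } else {
      stop("read_aoi_scheme(): region '", r$letter,
           "' has neither rect nor polygon", call. = FALSE)
    }
    list(letter = r$letter, name = r$name, geometry = geometry)
  })
  aoi_scheme(regions, whitespace_letter = doc$whitespace_letter %||% "W")
}

# even-odd ray casting; boundary points count as inside
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # on-edge check: collinear and within segment bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) < 1e-9 &&
        px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
        py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9) {
      return(TRUE)
    }
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

.point_in_region <- function(px, py, g) {
  if (g$type == "rect") {
    px >= g$x0 && px < g$x1 && py >= g$y0 && py < g$y1
  } else {
    .point_in_polygon(px, py, g$x, g$y)
  }
}

#' Assign AOI letters to fixation positions
#'
#' Returns, for each point, the letter of the first scheme region (in scheme
#' order) containing it, or the scheme's whitespace letter if no region does.
#'
#' @param x,y Numeric vectors of fixation positions (scene coordinates,
#'   origin top-left, y down).
#' @param scheme An [aoi_scheme()].
#' @return Character vector of AOI letters, same length as `x`.
#' @export
assign_aoi <- function(x, y, scheme) {
  stopifnot(inherits(scheme, "aoi_scheme"), length(x) == length(y))
  vapply(seq_along(x), function(i) {
    if (is.na(x[i]) || is.na(y[i])) {
      stop("assign_aoi(): fixation ", i, " has no position", call. = FALSE)
    }
    for (r in scheme$regions) {
      if (.point_in_region(x[i], y[i], r$geometry)) return(r$letter)
    }
    scheme$whitespace_letter
  }, character(1))
}

#' Label a fixation table with AOI letters
#'
#' Fills the `label` column of a fixation tibble from fixation positions.
#' Rows that already carry a label are returned unchanged (pre-labeled input
#' bypasses geometry entirely). Order is preserved.
#'
#' @param fixations Canonical fixation tibble (see [read_fixations()]).
#' @param scheme An [aoi_scheme()]; may be `NULL` if every row is already
#'   labeled.
#' @return The fixation tibble with a complete `label` column.
#' @export
label_fixations <- function(fixations, scheme = NULL) {
  if (nrow(fixations) == 0) return(fixations)
  if (!"label" %in% names(fixations)) fixations$label <- NA_character_
  todo <- is.na(fixations$label)
  if (!any(todo)) return(fixations)
  if (is.null(scheme)) {
    stop("label_fixations(): ", sum(todo),
         " fixations lack labels and no AOI scheme was given", call. = FALSE)
  }
  bad <- todo & (is.na(fixations$x) | is.na(fixations$y))
  if (any(bad)) {
    stop("label_fixations(): fixation row ", which(bad)[1],
         " has neither a label nor a position", call. = FALSE)
  }
  fixations$label[todo] <- assign_aoi(fixations$x[todo], fixations$y[todo],
                                      scheme)
  fixations
}

#' Alphabet of an AOI scheme
#'
#' @param scheme An [aoi_scheme()].
#' @param include_whitespace Include the whitespace letter (default `TRUE`).
#' @return Character vector of letters.
#' @export
aoi_alphabet <- function(scheme, include_whitespace = TRUE) {
  letters <- vapply(scheme$regions, function(r) r$letter, character(1))
  if (include_whitespace) c(letters, scheme$whitespace_letter) else letters
}

`%||%` <- function(a, b) if (is.null(a)) b else a
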