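# Contour-stack I/O: the CSV dialect carrying stacked short-axis endocardial
# and epicardial contours, and the demographics table.
#
# Conventions (fixed for the whole package):
#   * coordinates in millimetres, right-handed patient frame, +z from apex
#     toward base;
#   * slice_index is 0-based with 0 = most basal slice, so z is strictly
#     decreasing with slice_index;
#   * contour polylines are closed (first point not repeated) and oriented
#     counter-clockwise when viewed from the basal (+z) side.

# ---- polygon primitives ------------------------------------------------

#' Signed area of a closed 2D polyline (shoelace)
#'
#' Positive for counter-clockwise orientation when viewed from +z.
#' @param xy two-column matrix of vertices, first point not repeated.
#' @return signed area in mm^2.
#' @keywords internal
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area centroid of a simple closed polygon
#' @keywords internal
polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

#' Point-in-polygon test (even-odd rule), vectorized over query points
#' @keywords internal
points_in_polygon <- function(pts, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  nxt <- c(seq_len(nrow(poly))[-1], 1L)
  inside <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1]; y <- pts[i, 2]
    crosses <- (py > y) != (py[nxt] > y)
    if (!any(crosses)) { inside[i] <- FALSE; next }
    j <- which(crosses)
    xint <- px[j] + (y - py[j]) / (py[nxt][j] - py[j]) * (px[nxt][j] - px[j])
    inside[i] <- (sum(xint > x) %% 2L) == 1L
  }
  inside
}

# Segment-pair intersection test for polyline simplicity. O(n^2); contours
# carry at most a few hundred points so this is cheap.
#' @keywords internal
polyline_is_simple <- function(xy) {
  n <- nrow(xy)
  p2 <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE])
  segs_intersect <- function(a1, a2, b1, b2) {
    d1 <- a2 - a1; d2 <- b2 - b1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(FALSE)  # parallel: treat as non-crossing
    t <- ((b1[1] - a1[1]) * d2[2] - (b1[2] - a1[2]) * d2[1]) / den
    u <- ((b1[1] - a1[1]) * d1[2] - (b1[2] - a1[2]) * d1[1]) / den
    t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) break
      if (segs_intersect(xy[i, ], p2[i, ], xy[j, ], p2[j, ])) return(FALSE)
    }
  }
  TRUE
}

# ---- SliceContour ------------------------------------------------------

#' Construct a single-slice contour
#'
#' A closed 2D polyline (first point not repeated) lying on one short-axis
#' slice. Orientation is normalized to counter-clockwise as viewed from the
#' basal (+z) side.
#'
#' @param slice_index 0-based slice index, 0 = most basal.
#' @param z slice position in mm (+z toward base).
#' @param surface `"endo"` or `"epi"`.
#' @param phase `"ED"` or `"ES"`.
#' @param points n x 2 matrix of (x, y) mm.
#' @param check validate simplicity (default TRUE; disable only for dense
#'   resampled contours already known simple).
#' @return an object of class `lv_slice_contour`.
#' @export
slice_contour <- function(slice_index, z, surface = c("endo", "epi"),
                          phase = c("ED", "ES"), points, check = TRUE) {
  surface <- match.arg(surface)
  phase <- match.arg(phase)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L)
    stop_lv("contour_io", "contour points must be an n x 2 matrix")
  if (nrow(points) < 8L)
    stop_lv("contour_io", "contour needs >= 8 points, got ", nrow(points))
  if (anyNA(points))
    stop_lv("contour_io", "contour contains NA coordinates")
  if (check && !polyline_is_simple(points))
    stop_lv("contour_io", "contour polyline is self-intersecting (slice ",
            slice_index, ", ", surface, ")")
  if (polygon_signed_area(points) < 0)
    points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  structure(list(slice_index = as.integer(slice_index), z = as.numeric(z),
                 surface = surface, phase = phase, points = points),
            class = "lv_slice_contour")
}

# ---- ContourStack ------------------------------------------------------

#' Construct a contour stack for one subject-phase
#'
#' @param subject_id subject identifier.
#' @param phase `"ED"` or `"ES"`.
#' @param slices list of `list(endo = , epi = )` pairs of [slice_contour()],
#'   ordered base to apex.
#' @param slice_spacing nominal slice spacing in mm (computed from z if NULL).
#' @return an object of class `lv_contour_stack`.
#' @export
contour_stack <- function(subject_id, phase = c("ED", "ES"), slices,
                          slice_spacing = NULL) {
  phase <- match.arg(phase)
  if (length(slices) < 3L)
    stop_lv("contour_io", "contour stack needs >= 3 slices, got ",
            length(slices))
  z <- vapply(slices, function(s) s$endo$z, numeric(1))
  ze <- vapply(slices, function(s) s$epi$z, numeric(1))
  if (max(abs(z - ze)) > 1e-9)
    stop_lv("contour_io", "endo and epi z differ within a slice")
  dz <- diff(z)
  if (any(dz >= 0))
    stop_lv("contour_io",
            "slice z must be strictly decreasing from base to apex")
  spacing <- slice_spacing %||% mean(-dz)
  if (max(abs(-dz - spacing)) > 0.05 * spacing)
    stop_lv("contour_io", "slice spacing non-uniform beyond 5% of nominal (",
            signif(spacing, 4), " mm)")
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    a_endo <- abs(polygon_signed_area(s$endo$points))
    a_epi <- abs(polygon_signed_area(s$epi$points))
    if (a_endo >= a_epi ||
        !all(points_in_polygon(s$endo$points, s$epi$points)))
      stop_lv("contour_io", "endocardium not strictly inside epicardium ",
              "on slice ", s$endo$slice_index)
  }
  structure(list(subject_id = as.character(subject_id), phase = phase,
                 slices = slices, slice_spacing = spacing),
            class = "lv_contour_stack")
}

#' @export
print.lv_contour_stack <- function(x, ...) {
  cat("<lv_contour_stack> subject", x$subject_id, "phase", x$phase, "\n")
  cat("  ", length(x$slices), "slices, spacing",
      signif(x$slice_spacing, 4), "mm, z",
      signif(x$slices[[1]]$endo$z, 4), "to",
      signif(x$slices[[length(x$slices)]]$endo$z, 4), "mm\n")
  invisible(x)
}

#' Slice z positions of a stack (base to apex)
#' @export
stack_z <- function(stack) {
  vapply(stack$slices, function(s) s$endo$z, numeric(1))
}

# ---- CSV dialect -------------------------------------------------------

#' Write a contour stack to the CSV dialect
#'
#' One row per contour point, header
#' `subject,phase,slice,surface,point_index,x,y,z`. z is constant within a
#' slice; `point_index` is 0-based along the closed polyline.
#'
#' @param stack an `lv_contour_stack`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contour_stack <- function(stack, path) {
  rows <- lapply(stack$slices, function(s) {
    do.call(rbind, lapply(list(s$endo, s$epi), function(ct) {
      n <- nrow(ct$points)
      data.frame(subject = stack$subject_id, phase = stack$phase,
                 slice = ct$slice_index, surface = ct$surface,
                 point_index = seq_len(n) - 1L,
                 x = ct$points[, 1], y = ct$points[, 2], z = ct$z)
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a contour stack from the CSV dialect
#'
#' @param path CSV file with header
#'   `subject,phase,slice,surface,point_index,x,y,z`.
#' @param subject_id subject to extract.
#' @param phase `"ED"` or `"ES"`.
#' @return a validated [contour_stack()], contours ordered by `point_index`
#'   and orientation normalized.
#' @export
read_contour_stack <- function(path, subject_id, phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  if (!file.exists(path))
    stop_lv("contour_io", "file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop_lv("contour_io", "cannot parse ", path, ": ",
                           conditionMessage(e)))
  need <- c("subject", "phase", "slice", "surface", "point_index",
            "x", "y", "z")
  if (!all(need %in% names(df)))
    stop_lv("contour_io", "missing columns: ",
            paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!stats::complete.cases(df[, c("slice", "point_index",
                                             "x", "y", "z")]))
  if (length(bad))
    stop_lv("contour_io", "malformed row(s) at line ",
            paste(head(bad + 1L, 5), collapse = ", "),
            " (1-based, after header)")
  df <- df[df$subject == subject_id & df$phase == phase, , drop = FALSE]
  if (!nrow(df))
    stop_lv("contour_io", "no rows for subject ", subject_id,
            " phase ", phase)
  if (!all(df$surface %in% c("endo", "epi")))
    stop_lv("contour_io", "surface must be 'endo' or 'epi'")
  slice_ids <- sort(unique(df$slice))
  slices <- lapply(slice_ids, function(k) {
    sk <- df[df$slice == k, , drop = FALSE]
    one <- function(surf) {
      ss <- sk[sk$surface == surf, , drop = FALSE]
      if (!nrow(ss))
        stop_lv("contour_io", "slice ", k, " lacks ", surf, " contour")
      ss <- ss[order(ss$point_index), , drop = FALSE]
      if (length(unique(ss$z)) != 1L)
        stop_lv("contour_io", "z not constant within slice ", k)
      slice_contour(k, ss$z[1], surf, phase,
                    cbind(ss$x, ss$y))
    }
    list(endo = one("endo"), epi = one("epi"))
  })
  contour_stack(subject_id, phase, slices)
}

# ---- demographics ------------------------------------------------------

#' Body surface area (Mosteller)
#'
#' BSA = sqrt(height_cm * weight_kg / 3600), in m^2.
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  sqrt(height_cm * weight_kg / 3600)
}

#' Assign the study age categories
#'
#' Categories: `<=44`, `45-64`, `65-74`, `75-84` years.
#' @param age numeric vector of ages in years.
#' @return factor with the four category levels.
#' @export
age_category <- function(age) {
  cut(age, breaks = c(-Inf, 44, 64, 74, 84),
      labels = c("<=44", "45-64", "65-74", "75-84"), right = TRUE)
}

#' Read a demographics table
#'
#' CSV with header
#' `subject_id,age,gender,height,weight,sbp,dbp,heart_rate,cohort`.
#' Computes Mosteller BSA and the age category.
#'
#' @param path CSV file.
#' @return tibble, one row per subject.
#' @export
read_demographics <- function(path) {
  if (!file.exists(path))
    stop_lv("contour_io", "file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "gender", "height", "weight",
            "sbp", "dbp", "heart_rate")
  if (!all(need %in% names(df)))
    stop_lv("contour_io", "missing columns: ",
            paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop_lv("contour_io", "duplicated subject_id")
  if (any(df$age < 0)) stop_lv("contour_io", "negative age")
  if (any(df$sbp <= df$dbp) || any(df$dbp <= 0))
    stop_lv("contour_io", "require sbp > dbp > 0")
  if (!all(df$gender %in% c("M", "F")))
    stop_lv("contour_io", "gender must be 'M' or 'F'")
  df$bsa <- bsa_mosteller(df$height, df$weight)
  df$age_category <- age_category(df$age)
  if (is.null(df$cohort)) df$cohort <- "control"
  tibble::as_tibble(df)
}
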