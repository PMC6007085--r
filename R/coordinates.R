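# unit registry: factors to metres; exponents kept separately so that
# conversions scale by an exactly representable integer power of ten
.unit_factors <- c(m = 1, cm = 0.01, mm = 0.001)
.unit_exponents <- c(m = 0L, cm = -2L, mm = -3L)

unit_factor <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L ||
      !unit %in% names(.unit_factors)) {
    stop("unknown coordinate unit '", unit, "' (use m, cm or mm)",
         call. = FALSE)
  }
  .unit_factors[[unit]]
}

#' Convert point coordinates between length units
#'
#' Exact power-of-ten scaling between `m`, `cm` and `mm`.
#'
#' @param points Numeric 3-vector or n-by-3 matrix.
#' @param from,to Unit tokens.
#' @return Rescaled points, same shape as the input.
#' @export
#' @examples
#' convert_units(c(0.1, 0, 0), "m", "mm")  # 100 0 0
convert_units <- function(points, from, to) {
  unit_factor(from); unit_factor(to)
  k <- .unit_exponents[[from]] - .unit_exponents[[to]]
  # scale one decade at a time: a chained conversion (m -> cm -> mm) then
  # performs the identical operation sequence as the direct one (m -> mm),
  # so compositions are bit-exact, not merely close
  while (k > 0L) { points <- points * 10; k <- k - 1L }
  while (k < 0L) { points <- points / 10; k <- k + 1L }
  points
}

#' Registered head coordinate frame conventions
#'
#' The closed registry of `MEGCoordinateSystem` tokens. `CTF` and `KIT`
#' systems use an ALS frame (+x anterior through the nasion, +y left, +z
#' superior, origin midway between the pre-auricular points);
#' `ElektaNeuromag` uses RAS (+x right through the ears, +y anterior
#' through the nasion, +z superior). `Other` is the escape hatch and
#' requires a free-text `MEGCoordinateSystemDescription`; no canonical
#' frame construction exists for it.
#'
#' @return Data frame with columns `name` and `axes`.
#' @export
frame_conventions <- function() {
  data.frame(name = c("CTF", "ElektaNeuromag", "KIT", "Other"),
             axes = c("ALS", "RAS", "ALS", NA),
             stringsAsFactors = FALSE)
}

convention_axes <- function(convention) {
  reg <- frame_conventions()
  i <- match(convention, reg$name)
  if (is.na(i)) {
    stop("unknown coordinate system convention '", convention, "'",
         call. = FALSE)
  }
  ax <- reg$axes[i]
  if (is.na(ax)) {
    stop("convention 'Other' has no canonical frame construction",
         call. = FALSE)
  }
  ax
}

check_vec3 <- function(v, what) {
  if (!is.numeric(v) || length(v) != 3L || !all(is.finite(v))) {
    stop(what, " must be a finite numeric 3-vector", call. = FALSE)
  }
  as.numeric(v)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))
vunit <- function(v) v / vnorm(v)

#' Anatomical fiducials
#'
#' The three anatomical landmarks defining the head coordinate frame:
#' nasion (NAS) and left/right pre-auricular points (LPA, RPA). The
#' triangle they span must be non-degenerate (area above 1e-12 m^2 after
#' unit normalisation), otherwise no frame can be constructed.
#'
#' @param nas,lpa,rpa Numeric 3-vectors.
#' @param units Unit token (`m`, `cm`, `mm`).
#' @return Object of class `fiducials`.
#' @export
fiducials <- function(nas, lpa, rpa, units = "m") {
  nas <- check_vec3(nas, "nas"); lpa <- check_vec3(lpa, "lpa")
  rpa <- check_vec3(rpa, "rpa")
  unit_factor(units)
  f <- unit_factor(units)
  area <- 0.5 * vnorm(cross3((lpa - nas) * f, (rpa - nas) * f))
  if (area <= 1e-12) {
    stop("degenerate fiducial geometry: nasion, LPA and RPA are collinear",
         call. = FALSE)
  }
  structure(list(nas = nas, lpa = lpa, rpa = rpa, units = units),
            class = "fiducials")
}

#' @export
print.fiducials <- function(x, ...) {
  cat("<fiducials> (", x$units, ")\n",
      "  NAS: ", paste(signif(x$nas, 4), collapse = " "), "\n",
      "  LPA: ", paste(signif(x$lpa, 4), collapse = " "), "\n",
      "  RPA: ", paste(signif(x$rpa, 4), collapse = " "), "\n", sep = "")
  invisible(x)
}

fiducials_in_m <- function(fid) {
  f <- unit_factor(fid$units)
  list(nas = fid$nas * f, lpa = fid$lpa * f, rpa = fid$rpa * f)
}

#' Construct a rigid transform
#'
#' `y = scale * (rotation %*% x) + translation`. The rotation must be
#' orthonormal with determinant +1 (within 1e-9); scale is for unit
#' conversion only and must be positive.
#'
#' @param rotation 3x3 matrix.
#' @param translation 3-vector.
#' @param scale Positive scalar.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- as.matrix(rotation)
  stopifnot(identical(dim(rotation), c(3L, 3L)))
  translation <- check_vec3(translation, "translation")
  if (!is_scalar_number(scale) || scale <= 0) {
    stop("scale must be a positive number", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation is not orthonormal within 1e-9", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation determinant must be +1 (no reflections)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation,
                 scale = scale),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> scale ", format(x$scale), "\n", sep = "")
  print(signif(x$rotation, 6))
  cat("  translation: ", paste(signif(x$translation, 6), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to points
#' @param transform A [rigid_transform()].
#' @param points 3-vector or n-by-3 matrix.
#' @return Transformed points, same shape.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3L)
    out <- transform$scale * (points %*% t(transform$rotation))
    sweep(out, 2L, transform$translation, `+`)
  } else {
    pts <- check_vec3(points, "points")
    as.numeric(transform$scale * (transform$rotation %*% pts) +
                 transform$translation)
  }
}

#' Compose two rigid transforms
#' @param a,b Transforms; the result applies `b` first, then `a`.
#' @return `a` composed with `b` as a [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(rotation = a$rotation %*% b$rotation,
                  translation = a$scale * as.numeric(a$rotation %*%
                                                       b$translation) +
                    a$translation,
                  scale = a$scale * b$scale)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  rt <- t(transform$rotation)
  rigid_transform(rotation = rt,
                  translation = -as.numeric(rt %*% transform$translation) /
                    transform$scale,
                  scale = 1 / transform$scale)
}

#' Head frame from fiducials
#'
#' Builds the rigid transform mapping points in the fiducials' native space
#' (in metres) into the convention's head frame (metres).
#'
#' ALS (CTF/KIT style): origin is the midpoint of LPA and RPA; x axis is
#' the unit vector from the origin through the nasion; z is the unit
#' vector along `x cross (lpa - rpa)` (superior); y completes the
#' right-handed frame (left).
#'
#' RAS (Elekta/Neuromag style): x is the unit vector from LPA to RPA; the
#' origin is the orthogonal projection of the nasion onto that ear-to-ear
#' line; y points from the origin through the nasion; z completes the
#' frame (superior).
#'
#' @param fid A [fiducials()] object (any supported unit; converted to
#'   metres internally).
#' @param convention Registry token (`CTF`, `ElektaNeuromag`, `KIT`).
#' @return A [rigid_transform()]; apply it to points expressed in metres in
#'   the fiducials' native space.
#' @export
frame_from_fiducials <- function(fid, convention = "CTF") {
  stopifnot(inherits(fid, "fiducials"))
  axes <- convention_axes(convention)
  p <- fiducials_in_m(fid)
  if (axes == "ALS") {
    origin <- (p$lpa + p$rpa) / 2
    xhat <- vunit(p$nas - origin)
    zhat <- vunit(cross3(xhat, p$lpa - p$rpa))
    yhat <- cross3(zhat, xhat)
  } else {  # RAS
    xhat <- vunit(p$rpa - p$lpa)
    origin <- p$lpa + sum((p$nas - p$lpa) * xhat) * xhat
    yhat <- vunit(p$nas - origin)
    zhat <- cross3(xhat, yhat)
  }
  basis <- rbind(xhat, yhat, zhat)
  rownames(basis) <- NULL
  rigid_transform(rotation = basis,
                  translation = -as.numeric(basis %*% origin))
}

#' Transform between two head frame conventions
#'
#' Composes `frame(to)` with the inverse of `frame(from)` for the same
#' fiducial set: points expressed in the `from` convention's head frame
#' map into the `to` convention's head frame.
#'
#' @param fid A [fiducials()] object.
#' @param from,to Convention tokens.
#' @return A [rigid_transform()].
#' @export
between_frames <- function(fid, from, to) {
  if (identical(from, to)) {
    convention_axes(from)
    return(rigid_transform())
  }
  compose_transforms(frame_from_fiducials(fid, to),
                     invert_transform(frame_from_fiducials(fid, from)))
}
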