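#' Dorsal surface-area model
#'
#' The dorsal surface of the animal is approximated by two plane figures
#' driven by two field measurements. The umbilicus girth G (body
#' circumference at the navel, cm) sets a radius r = G / (2 * pi). The tail
#' dorsum is a circle of that radius, area G^2 / (4 * pi). The body dorsum
#' is an ellipse with semi-minor axis a = r and semi-major axis b = L / 2,
#' where L is the curvilinear total length (cm), area pi * a * b = G * L / 4.
#' Total dorsal area is body + tail, exactly additive.
#'
#' @name surface-area-model
NULL

#' Girth to radius
#'
#' @param girth_cm umbilicus girth G, cm (> 0).
#' @return radius r = G / (2 * pi), cm.
#' @examples
#' girth_to_radius(2 * pi)  # 1
#' @export
girth_to_radius <- function(girth_cm) {
  if (any(!is.finite(girth_cm)) || any(girth_cm <= 0))
    stop("girth must be positive", call. = FALSE)
  girth_cm / (2 * pi)
}

#' Dorsal tail area
#'
#' Circle of radius G / (2 * pi): area G^2 / (4 * pi), cm^2.
#'
#' @inheritParams girth_to_radius
#' @export
tail_dorsal_area <- function(girth_cm) {
  pi * girth_to_radius(girth_cm)^2
}

#' Dorsal body area
#'
#' Ellipse with semi-minor axis G / (2 * pi) and semi-major axis L / 2:
#' area G * L / 4, cm^2.
#'
#' @inheritParams girth_to_radius
#' @param length_cm curvilinear total length L, cm (> 0).
#' @export
body_dorsal_area <- function(girth_cm, length_cm) {
  if (any(!is.finite(length_cm)) || any(length_cm <= 0))
    stop("length must be positive", call. = FALSE)
  pi * girth_to_radius(girth_cm) * (length_cm / 2)
}

#' Per-individual surface areas
#'
#' @inheritParams body_dorsal_area
#' @param scale optional multiplicative factor applied to both component
#'   areas (sensitivity analysis; 1 = the plain full-figure reading).
#' @return data frame with columns \code{radius_cm}, \code{semi_major_cm},
#'   \code{body_area_cm2}, \code{tail_area_cm2}, \code{total_area_cm2}.
#' @examples
#' surface_areas(girth_cm = 2 * pi, length_cm = 4)
#' @export
surface_areas <- function(girth_cm, length_cm, scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  body <- scale * body_dorsal_area(girth_cm, length_cm)
  tail <- scale * tail_dorsal_area(girth_cm)
  data.frame(radius_cm = girth_to_radius(girth_cm),
             semi_major_cm = length_cm / 2,
             body_area_cm2 = body, tail_area_cm2 = tail,
             total_area_cm2 = body + tail)
}

#' Per-sex cohort mean areas
#'
#' Computes surface areas per individual, then averages within sex (mean of
#' areas, not area of mean measurements: the area formulas are nonlinear in
#' girth, so the two orders differ for variable cohorts).
#'
#' @param morphometrics per-individual data frame as returned by
#'   \code{\link{read_morphometrics}} or \code{\link{simulate_hosts}}.
#' @param scale passed to \code{\link{surface_areas}}.
#' @return data frame with one row per sex: \code{sex}, \code{n},
#'   \code{curvilinear_length_cm}, \code{tail_length_cm} (if available),
#'   \code{body_area_cm2}, \code{tail_area_cm2}, \code{total_area_cm2}
#'   (cohort means).
#' @export
cohort_areas <- function(morphometrics, scale = 1) {
  m <- as.data.frame(morphometrics)
  required <- c("sex", "curvilinear_length_cm", "umbilicus_girth_cm")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("morphometrics must have column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(m) == 0L) stop("no individuals supplied", call. = FALSE)
  a <- surface_areas(m$umbilicus_girth_cm, m$curvilinear_length_cm, scale)
  sexes <- unique(m$sex)
  out <- do.call(rbind, lapply(sexes, function(s) {
    i <- m$sex == s
    data.frame(sex = s, n = sum(i),
               curvilinear_length_cm = mean(m$curvilinear_length_cm[i]),
               tail_length_cm = if ("tail_length_cm" %in% names(m))
                 mean(m$tail_length_cm[i]) else NA_real_,
               body_area_cm2 = mean(a$body_area_cm2[i]),
               tail_area_cm2 = mean(a$tail_area_cm2[i]),
               total_area_cm2 = mean(a$total_area_cm2[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
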