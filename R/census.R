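#' Whole-animal load from density and area
#'
#' Multiplies a total skin-surface density by a dorsal area. The unrounded
#' product is returned; rounding to whole nematodes is a reporting concern.
#'
#' @param density_total total nematode density, nematodes/cm^2 (>= 0).
#' @param area_cm2 dorsal area, cm^2 (>= 0).
#' @return expected number of nematodes (unrounded).
#' @examples
#' total_load(1, 100)  # 100
#' @export
total_load <- function(density_total, area_cm2) {
  if (any(density_total < 0) || any(area_cm2 < 0))
    stop("density and area must be non-negative", call. = FALSE)
  density_total * area_cm2
}

#' Multiplier-adjusted load range
#'
#' Deep resampling of the same skin patch yields roughly 3-4 times the
#' superficial count, so a superficial-census baseline load understates the
#' full skin-column population. The baseline is first rounded to a reporting
#' quantum (default 10,000 nematodes), then multiplied by the low and high
#' multipliers.
#'
#' @param baseline baseline load, nematodes (>= 0).
#' @param multipliers numeric length-2, \code{c(low, high)} with
#'   \code{1 <= low <= high}. Preset \code{"deep"} = c(3, 4) corresponds to
#'   the deeper-sampling yield; \code{"wide"} = c(1, 4) spans from the
#'   superficial baseline itself to the deep extreme.
#' @param quantum rounding quantum applied to the baseline before
#'   multiplication, nematodes (> 0).
#' @return named numeric \code{c(low, high)}.
#' @examples
#' load_range(30633, c(3, 4))         # 90,000  120,000
#' load_range(156452, "deep")         # 480,000 640,000
#' @export
load_range <- function(baseline, multipliers = c(3, 4), quantum = 10000) {
  if (is.character(multipliers))
    multipliers <- switch(match.arg(multipliers, c("deep", "wide")),
                          deep = c(3, 4), wide = c(1, 4))
  if (length(multipliers) != 2L || any(multipliers < 1) ||
      multipliers[1] > multipliers[2])
    stop("multipliers must be c(low, high) with 1 <= low <= high",
         call. = FALSE)
  if (any(baseline < 0)) stop("baseline must be non-negative", call. = FALSE)
  b <- round_to_quantum(baseline, quantum)
  c(low = b * multipliers[1], high = b * multipliers[2])
}

#' Fit a nematode skin census
#'
#' The package's central estimator. From an ordinal scrape survey and per-sex
#' dorsal areas it estimates per-morphospecies skin densities (two-stage:
#' within host, then unweighted across hosts), community composition,
#' prevalence, per-sex baseline loads on the tail dorsum and the whole
#' dorsum, and multiplier-adjusted load ranges accounting for the depth of
#' the inhabited skin column. If the survey contains sequentially resampled
#' areas, the observed depth-yield multipliers are summarised alongside.
#'
#' @param survey a \code{"scrape_survey"} data frame
#'   (\code{\link{read_sample_table}}, \code{\link{load_fixture}}, or
#'   \code{\link{simulate_survey}}).
#' @param areas per-sex areas: a data frame with columns \code{sex},
#'   \code{tail_area_cm2}, \code{total_area_cm2} (e.g.
#'   \code{load_fixture("morphometrics")} or \code{\link{cohort_areas}}
#'   output).
#' @param mapping a \code{\link{category_mapping}}; default is the published
#'   0/10/50/100 convention.
#' @param rule inclusion rule for the density estimate, see
#'   \code{\link{inclusion_mask}}.
#' @param exclude_hosts host ids dropped before estimation.
#' @param multipliers depth multipliers for \code{\link{load_range}}.
#' @param quantum baseline rounding quantum for \code{\link{load_range}}.
#' @return an object of class \code{"nematode_census"}; see
#'   \code{\link{summary.nematode_census}}. Key components:
#'   \code{estimate} (the \code{"density_estimate"}), \code{areas},
#'   \code{loads} (per-sex data frame of unrounded tail/total baselines),
#'   \code{ranges} (per-sex low/high for tail and total), \code{prevalence},
#'   \code{depth} (a \code{"depth_yield"} or NULL).
#' @examples
#' cs <- nematode_census(load_fixture(2018), load_fixture("morphometrics"))
#' cs
#' coef(cs)
#' @export
nematode_census <- function(survey, areas,
                            mapping = category_mapping(),
                            rule = "nonsequential",
                            exclude_hosts = NULL,
                            multipliers = c(3, 4),
                            quantum = 10000) {
  areas <- as.data.frame(areas)
  need <- c("sex", "tail_area_cm2", "total_area_cm2")
  missing <- setdiff(need, names(areas))
  if (length(missing))
    stop("'areas' must have column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  est <- population_mean_density(survey, mapping, rule, exclude_hosts)
  D <- sum(est$densities)
  loads <- data.frame(
    sex = areas$sex,
    tail_load = total_load(D, areas$tail_area_cm2),
    total_load = total_load(D, areas$total_area_cm2),
    stringsAsFactors = FALSE)
  if (is.character(multipliers))
    multipliers <- switch(match.arg(multipliers, c("deep", "wide")),
                          deep = c(3, 4), wide = c(1, 4))
  ranges <- lapply(seq_len(nrow(loads)), function(i) {
    list(tail = load_range(loads$tail_load[i], multipliers, quantum),
         total = load_range(loads$total_load[i], multipliers, quantum))
  })
  names(ranges) <- loads$sex
  depth <- tryCatch(depth_yield(survey, mapping), error = function(e) NULL)
  structure(list(
    call = match.call(),
    estimate = est,
    total_density = D,
    areas = areas,
    loads = loads,
    ranges = ranges,
    multipliers = multipliers,
    quantum = quantum,
    prevalence = prevalence_summary(survey),
    depth = depth
  ), class = "nematode_census")
}

#' @export
coef.nematode_census <- function(object, ...) object$estimate$densities

#' @export
print.nematode_census <- function(x, ...) {
  cat("Nematode skin census\n\n")
  print(x$estimate)
  cat(sprintf("\nTotal density: %.4f nematodes/cm^2\n", x$total_density))
  cat(sprintf("Prevalence: %d of %d hosts positive for all morphospecies\n",
              x$prevalence$n_hosts_all_species, x$prevalence$n_hosts))
  for (i in seq_len(nrow(x$loads))) {
    s <- x$loads$sex[i]
    cat(sprintf("%s: tail %s, dorsum %s nematodes (x%g-%g depth range: tail %s-%s, dorsum %s-%s)\n",
                s,
                format(round_half_up(x$loads$tail_load[i]), big.mark = ","),
                format(round_half_up(x$loads$total_load[i]), big.mark = ","),
                x$multipliers[1], x$multipliers[2],
                format(x$ranges[[s]]$tail["low"], big.mark = ","),
                format(x$ranges[[s]]$tail["high"], big.mark = ","),
                format(x$ranges[[s]]$total["low"], big.mark = ","),
                format(x$ranges[[s]]$total["high"], big.mark = ",")))
  }
  invisible(x)
}

#' Summarise a nematode census
#'
#' @param object a \code{"nematode_census"}.
#' @param ... unused.
#' @return the object, invisibly, after printing densities, composition,
#'   per-host means, prevalence, loads, ranges and (if present) the
#'   depth-yield summary.
#' @export
summary.nematode_census <- function(object, ...) {
  print(object)
  cat("\nPer-host mean densities (nematodes/cm^2):\n")
  print(round(object$estimate$by_host, 3))
  if (!is.null(object$depth)) {
    cat("\n")
    print(object$depth)
  }
  invisible(object)
}

#' Predict loads for new animals
#'
#' Applies the fitted total density (and depth multipliers) to new
#' morphometrics: either per-individual measurements (columns
#' \code{umbilicus_girth_cm}, \code{curvilinear_length_cm}) from which areas
#' are computed, or precomputed areas (columns \code{tail_area_cm2},
#' \code{total_area_cm2}).
#'
#' @param object a \code{"nematode_census"}.
#' @param newdata data frame of individuals or areas; defaults to the areas
#'   the census was fitted with.
#' @param ... unused.
#' @return data frame with baseline tail/total loads and the
#'   multiplier-adjusted ranges per row of \code{newdata}.
#' @export
predict.nematode_census <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$areas
  nd <- as.data.frame(newdata)
  if (!all(c("tail_area_cm2", "total_area_cm2") %in% names(nd))) {
    if (!all(c("umbilicus_girth_cm", "curvilinear_length_cm") %in% names(nd)))
      stop("newdata needs either areas or girth+length columns", call. = FALSE)
    a <- surface_areas(nd$umbilicus_girth_cm, nd$curvilinear_length_cm)
    nd$tail_area_cm2 <- a$tail_area_cm2
    nd$total_area_cm2 <- a$total_area_cm2
  }
  D <- object$total_density
  out <- data.frame(
    tail_load = total_load(D, nd$tail_area_cm2),
    total_load = total_load(D, nd$total_area_cm2))
  rng <- t(vapply(seq_len(nrow(out)), function(i) {
    c(load_range(out$tail_load[i], object$multipliers, object$quantum),
      load_range(out$total_load[i], object$multipliers, object$quantum))
  }, numeric(4)))
  colnames(rng) <- c("tail_low", "tail_high", "total_low", "total_high")
  cbind(nd[setdiff(names(nd), names(out))], out, as.data.frame(rng))
}

#' Plot per-host densities
#'
#' Grouped bar plot of host-level mean densities per morphospecies.
#'
#' @param x a \code{"nematode_census"}.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.nematode_census <- function(x, ...) {
  m <- t(x$estimate$by_host)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "nematodes / cm^2", xlab = "host",
                    las = 2, ...)
  invisible(x)
}

#' Write a census report
#'
#' Emits a machine-readable JSON report and a human-readable text summary.
#' The JSON body is deterministic for identical inputs and configuration
#' (no timestamps), and carries a provenance block recording the mapping,
#' inclusion rule, multipliers and quantum used.
#'
#' @param census a \code{"nematode_census"}.
#' @param dir output directory (created if needed).
#' @param basename file stem; writes \code{<basename>.json} and
#'   \code{<basename>.txt}.
#' @return named character vector of the two paths, invisibly.
#' @export
write_census_report <- function(census, dir, basename = "census") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  est <- census$estimate
  body <- list(
    provenance = list(
      package = "nemacensus",
      version = as.character(utils::packageVersion("nemacensus")),
      mapping = as.list(unclass(est$mapping)),
      inclusion_rule = est$rule,
      multipliers = census$multipliers,
      quantum = census$quantum),
    densities_per_cm2 = as.list(est$densities),
    densities_rounded = as.list(round_half_up(est$densities, 2)),
    composition_percent = as.list(round_half_up(100 * est$composition, 0)),
    total_density_per_cm2 = census$total_density,
    n_hosts = est$n_hosts,
    n_samples = est$n_samples,
    prevalence = list(
      n_hosts = census$prevalence$n_hosts,
      n_hosts_all_species = census$prevalence$n_hosts_all_species),
    areas_cm2 = census$areas,
    loads = transform(census$loads,
                      tail_load_rounded = round_half_up(tail_load),
                      total_load_rounded = round_half_up(total_load)),
    ranges = census$ranges,
    depth_yield = if (!is.null(census$depth))
      list(per_host = census$depth$per_host,
           summary = as.list(census$depth$summary)) else NULL)
  json_path <- file.path(dir, paste0(basename, ".json"))
  txt_path <- file.path(dir, paste0(basename, ".txt"))
  jsonlite::write_json(body, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  writeLines(utils::capture.output(summary(census)), txt_path)
  invisible(c(json = json_path, txt = txt_path))
}
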