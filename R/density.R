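#' Sample inclusion rules
#'
#' Which plates enter the density estimate. \code{"nonsequential"} (the
#' default, matching the published 2018 analysis) drops resample plates —
#' repeated higher-pressure scrapes of an already-sampled area — and keeps
#' every first-pass plate, including first passes of sequentially sampled
#' areas. \code{"first_pass"} keeps plates with \code{pass_index == 1}
#' (identical to \code{"nonsequential"} whenever the data are consistent,
#' since non-resamples are pass 1 by construction). \code{"all"} keeps every
#' plate. A function taking the survey and returning a logical vector may be
#' supplied instead.
#'
#' @param survey a \code{"scrape_survey"} data frame.
#' @param rule \code{"nonsequential"}, \code{"first_pass"}, \code{"all"}, or
#'   a predicate function.
#' @return logical vector marking included rows.
#' @export
inclusion_mask <- function(survey, rule = "nonsequential") {
  if (is.function(rule)) {
    m <- rule(survey)
    if (!is.logical(m) || length(m) != nrow(survey))
      stop("inclusion rule function must return one logical per row",
           call. = FALSE)
    return(m)
  }
  switch(match.arg(rule, c("nonsequential", "first_pass", "all")),
         nonsequential = !survey$is_resample,
         first_pass = survey$pass_index == 1L,
         all = rep(TRUE, nrow(survey)))
}

#' Per-host mean density
#'
#' Converts each included plate's ordinal category to a representative count
#' and averages count/area over that host's plates, per morphospecies:
#' nematodes per cm^2 of skin surface.
#'
#' @param survey a \code{"scrape_survey"} data frame for one host.
#' @param mapping a \code{\link{category_mapping}}.
#' @param rule inclusion rule, see \code{\link{inclusion_mask}}.
#' @return named numeric vector of densities (nematodes/cm^2) per species.
#' @export
host_mean_density <- function(survey, mapping = category_mapping(),
                              rule = "nonsequential") {
  survey <- as_scrape_survey(as.data.frame(survey))
  if (length(unique(survey$host_id)) != 1L)
    stop("host_mean_density() expects samples from a single host; use ",
         "population_mean_density() for a survey", call. = FALSE)
  keep <- inclusion_mask(survey, rule)
  s <- survey[keep, , drop = FALSE]
  if (nrow(s) == 0L)
    stop("no included samples for host ", survey$host_id[1],
         " under the given inclusion rule", call. = FALSE)
  d <- category_to_count(s$level, mapping) / s$area_cm2
  out <- tapply(d, s$species, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Two-stage population mean density
#'
#' The density estimator behind the census: per-species plate densities are
#' first averaged within each host, then the host means are averaged without
#' weighting, so hosts with different numbers of plates contribute equally.
#'
#' @param survey a \code{"scrape_survey"} data frame (any number of hosts).
#' @param mapping a \code{\link{category_mapping}}.
#' @param rule inclusion rule, see \code{\link{inclusion_mask}}.
#' @param exclude_hosts optional character vector of host ids to drop before
#'   estimation.
#' @return an object of class \code{"density_estimate"}: a list with
#'   \code{densities} (named per-species means, nematodes/cm^2),
#'   \code{by_host} (hosts x species matrix of host means),
#'   \code{composition} (fractions of the total density),
#'   \code{n_hosts}, \code{n_samples}, \code{rule} and \code{mapping}.
#' @examples
#' est <- population_mean_density(load_fixture(2018))
#' round(est$densities, 2)
#' @export
population_mean_density <- function(survey, mapping = category_mapping(),
                                    rule = "nonsequential",
                                    exclude_hosts = NULL) {
  survey <- as_scrape_survey(as.data.frame(survey))
  if (!is.null(exclude_hosts))
    survey <- survey[!survey$host_id %in% exclude_hosts, , drop = FALSE]
  hosts <- unique(survey$host_id)
  if (length(hosts) == 0L) stop("survey contains no hosts", call. = FALSE)
  species <- unique(survey$species)
  by_host <- matrix(NA_real_, length(hosts), length(species),
                    dimnames = list(hosts, species))
  for (h in hosts) {
    hd <- host_mean_density(survey[survey$host_id == h, , drop = FALSE],
                            mapping, rule)
    by_host[h, ] <- hd[species]
  }
  densities <- colMeans(by_host)
  keep <- inclusion_mask(survey, rule)
  structure(list(
    densities = densities,
    by_host = by_host,
    composition = if (sum(densities) > 0) densities / sum(densities) else
      stats::setNames(rep(NA_real_, length(densities)), names(densities)),
    n_hosts = length(hosts),
    n_samples = length(unique(paste(survey$host_id[keep],
                                    survey$sample_label[keep]))),
    rule = if (is.function(rule)) "custom" else rule,
    mapping = if (inherits(mapping, "category_mapping")) mapping else
      category_mapping(mapping)
  ), class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("Two-stage density estimate (%d hosts, %d plates, rule = %s)\n",
              x$n_hosts, x$n_samples, x$rule))
  tab <- rbind(`nematodes/cm^2` = round_half_up(x$densities, digits),
               `composition %` = round_half_up(100 * x$composition, 0))
  print(tab)
  invisible(x)
}

#' Composition fractions of a density estimate
#'
#' Each species' share of the summed density. Undefined (error) when every
#' density is zero.
#'
#' @param x a \code{"density_estimate"} or a non-negative numeric vector of
#'   densities.
#' @return named numeric vector of fractions summing to 1.
#' @export
composition_fractions <- function(x) {
  d <- if (inherits(x, "density_estimate")) x$densities else as.numeric(x)
  if (any(d < 0)) stop("densities must be non-negative", call. = FALSE)
  tot <- sum(d)
  if (tot == 0)
    stop("composition undefined: all densities are zero", call. = FALSE)
  d / tot
}

#' Prevalence summary
#'
#' A species is present on a host if any of the host's plates scores level
#' \code{+} or higher for it. Reports the per-host presence map, per-host
#' positive-plate counts, and how many hosts carry every species.
#'
#' @param survey a \code{"scrape_survey"} data frame.
#' @return a list with \code{presence} (hosts x species logical matrix),
#'   \code{positive_samples} (hosts x species counts of positive plates),
#'   \code{n_hosts}, and \code{n_hosts_all_species}.
#' @examples
#' prevalence_summary(load_fixture(2018))$n_hosts_all_species  # 7
#' @export
prevalence_summary <- function(survey) {
  survey <- as.data.frame(survey)
  if (nrow(survey) == 0L)
    return(list(presence = matrix(logical(0), 0, 0),
                positive_samples = matrix(integer(0), 0, 0),
                n_hosts = 0L, n_hosts_all_species = 0L))
  survey <- as_scrape_survey(survey)
  pos <- tapply(survey$level >= 1L, list(survey$host_id, survey$species), sum)
  pos[is.na(pos)] <- 0L
  presence <- pos > 0L
  list(presence = presence,
       positive_samples = pos,
       n_hosts = nrow(presence),
       n_hosts_all_species = sum(apply(presence, 1, all)))
}

#' Depth-resampling yield multiplier
#'
#' For each host with a sequentially resampled area (the same 5 x 5 cm patch
#' scraped repeatedly with increasing pressure, indexing depth into the
#' biofouling and dead-skin layer), the ratio of the total mapped count
#' across all passes to the mapped count of the superficial first pass.
#' Counts are summed over species within a pass before the ratio is formed.
#' Hosts whose first-pass total is zero have an undefined multiplier and are
#' flagged and excluded from the summary.
#'
#' @param survey a \code{"scrape_survey"} data frame.
#' @param mapping a \code{\link{category_mapping}}.
#' @return an object of class \code{"depth_yield"}: a list with
#'   \code{per_host} (data frame of host, pass-1 count, total count,
#'   multiplier, defined flag) and \code{summary} (min/median/max over
#'   defined hosts).
#' @examples
#' depth_yield(load_fixture(2019))
#' @export
depth_yield <- function(survey, mapping = category_mapping()) {
  survey <- as_scrape_survey(as.data.frame(survey))
  survey$area_letter <- sub("-.*$", "", survey$sample_label)
  grp <- paste(survey$host_id, survey$area_letter, sep = "\r")
  npass <- tapply(survey$pass_index, grp, function(p) length(unique(p)))[grp]
  seq_rows <- survey[npass > 1L, , drop = FALSE]
  if (nrow(seq_rows) == 0L)
    stop("no sequentially sampled areas in this survey", call. = FALSE)
  seq_rows$count <- category_to_count(seq_rows$level, mapping)
  hosts <- unique(seq_rows$host_id)
  per_host <- do.call(rbind, lapply(hosts, function(h) {
    x <- seq_rows[seq_rows$host_id == h, , drop = FALSE]
    p1 <- sum(x$count[x$pass_index == 1L])
    tot <- sum(x$count)
    data.frame(host_id = h, pass1_count = p1, total_count = tot,
               multiplier = if (p1 > 0) tot / p1 else NA_real_,
               defined = p1 > 0, stringsAsFactors = FALSE)
  }))
  m <- per_host$multiplier[per_host$defined]
  structure(list(per_host = per_host,
                 summary = c(min = if (length(m)) min(m) else NA_real_,
                             median = if (length(m)) stats::median(m) else NA_real_,
                             max = if (length(m)) max(m) else NA_real_)),
            class = "depth_yield")
}

#' @export
print.depth_yield <- function(x, ...) {
  cat(sprintf("Depth-resampling yield over %d sequentially sampled host(s)\n",
              nrow(x$per_host)))
  print(x$per_host, row.names = FALSE)
  cat(sprintf("multiplier min/median/max: %.2f / %.2f / %.2f\n",
              x$summary["min"], x$summary["median"], x$summary["max"]))
  if (any(!x$per_host$defined))
    cat("hosts with zero first-pass count excluded from summary:",
        paste(x$per_host$host_id[!x$per_host$defined], collapse = ", "), "\n")
  invisible(x)
}
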