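#' Configuration for the survey simulator
#'
#' Defines the synthetic study conditions: a winter cohort of hosts with
#' correlated length/girth morphometrics, per-host latent skin densities per
#' morphospecies (lognormal across hosts), 25 cm^2 scrape plates, a
#' depth-availability profile per species (fraction of a species' density
#' reachable at each sequential pass), negative-binomial plate counts, and
#' ordinal binning of those counts. Defaults emulate the shape of the 2018
#' adult survey: 7 hosts, 4-9 pseudoreplicate plates each, single
#' superficial pass, three morphospecies at a few nematodes per cm^2.
#'
#' @param n_hosts number of hosts.
#' @param sex_ratio probability a host is female.
#' @param length_mean,length_sd curvilinear total length distribution per
#'   sex, cm (named \code{c(female=, male=)} means).
#' @param girth_mean,girth_sd umbilicus girth distribution per sex, cm.
#' @param length_girth_cor correlation between length and girth.
#' @param tail_length_mean mean tail length per sex, cm (carried in the data
#'   model; unused by the area formulas).
#' @param species character vector of morphospecies names.
#' @param density_meanlog,density_sdlog per-species lognormal parameters of
#'   the latent across-host density (nematodes/cm^2); \code{density_meanlog}
#'   may be a named vector per species, \code{density_sdlog} a scalar or
#'   per-species vector.
#' @param availability named list: per species, a numeric vector of
#'   availability fractions by pass index (last value recycled for deeper
#'   passes). Defaults to full availability everywhere. See
#'   \code{\link{depth_profile}} for the biofilm-avoider preset.
#' @param dispersion negative-binomial size parameter k (variance
#'   m + m^2/k); \code{Inf} gives Poisson counts.
#' @param bin_edges ordinal bin lower edges, see
#'   \code{\link{count_to_category}}.
#' @param plates_range \code{c(min, max)} pseudoreplicate plates per host.
#' @param n_passes sequential passes on the first sampled area (1 = no
#'   sequential resampling).
#' @param juvenile_fraction probability a host is a juvenile.
#' @param juvenile_attenuation multiplicative density attenuation for
#'   juveniles (sparse fauna on young animals).
#' @param area_cm2 plate area, cm^2.
#' @param skin_remnant_prob probability of visible skin remnants at pass 1;
#'   increases by \code{skin_remnant_gain} per deeper pass (capped at 1).
#' @param skin_remnant_gain see above.
#' @return an object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(n_hosts = 7,
                       sex_ratio = 0.5,
                       length_mean = c(female = 262, male = 310),
                       length_sd = 15,
                       girth_mean = c(female = 217, male = 208),
                       girth_sd = 15,
                       length_girth_cor = 0.7,
                       tail_length_mean = c(female = 64, male = 66),
                       species = c("C_manati", "LT", "ST"),
                       density_meanlog = log(c(C_manati = 2.0, LT = 2.8,
                                               ST = 2.4)),
                       density_sdlog = 0.6,
                       availability = NULL,
                       dispersion = 5,
                       bin_edges = c(1, 21, 100),
                       plates_range = c(4, 9),
                       n_passes = 1,
                       juvenile_fraction = 0,
                       juvenile_attenuation = 0.1,
                       area_cm2 = 25,
                       skin_remnant_prob = 0.4,
                       skin_remnant_gain = 0.2) {
  cfg <- list(n_hosts = as.integer(n_hosts), sex_ratio = sex_ratio,
              length_mean = length_mean, length_sd = length_sd,
              girth_mean = girth_mean, girth_sd = girth_sd,
              length_girth_cor = length_girth_cor,
              tail_length_mean = tail_length_mean,
              species = species,
              density_meanlog = density_meanlog,
              density_sdlog = rep_len(density_sdlog, length(species)),
              availability = availability,
              dispersion = dispersion, bin_edges = bin_edges,
              plates_range = as.integer(plates_range),
              n_passes = as.integer(n_passes),
              juvenile_fraction = juvenile_fraction,
              juvenile_attenuation = juvenile_attenuation,
              area_cm2 = area_cm2,
              skin_remnant_prob = skin_remnant_prob,
              skin_remnant_gain = skin_remnant_gain)
  stopifnot(cfg$n_hosts >= 0,
            cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
            all(cfg$length_sd >= 0), all(cfg$girth_sd >= 0),
            abs(cfg$length_girth_cor) <= 1,
            length(cfg$density_meanlog) == length(cfg$species),
            all(cfg$density_sdlog >= 0),
            cfg$dispersion > 0,
            length(cfg$plates_range) == 2L,
            cfg$plates_range[1] >= 1L,
            cfg$plates_range[1] <= cfg$plates_range[2],
            cfg$n_passes >= 1L,
            cfg$juvenile_fraction >= 0, cfg$juvenile_fraction <= 1,
            cfg$juvenile_attenuation >= 0, cfg$juvenile_attenuation <= 1,
            cfg$area_cm2 > 0,
            cfg$skin_remnant_prob >= 0, cfg$skin_remnant_prob <= 1,
            cfg$skin_remnant_gain >= 0)
  count_to_category(0, cfg$bin_edges)  # validates the edges
  if (!is.null(cfg$availability)) {
    stopifnot(is.list(cfg$availability),
              all(names(cfg$availability) %in% cfg$species))
    lapply(cfg$availability, function(a)
      stopifnot(all(a >= 0), all(a <= 1), length(a) >= 1))
  }
  structure(cfg, class = "sim_config")
}

#' Biofilm-avoider depth-availability profile
#'
#' The qualitative depth pattern seen in sequential sampling: one species is
#' absent from the superficial biofilm layer (pass 1) but fully available
#' once dead skin is scraped at deeper passes.
#'
#' @param species name of the depth-restricted species.
#' @return availability list suitable for \code{\link{sim_config}}.
#' @examples
#' cfg <- sim_config(availability = depth_profile("C_manati"), n_passes = 4)
#' @export
depth_profile <- function(species = "C_manati") {
  stats::setNames(list(c(0, 1)), species)
}

.availability_at <- function(cfg, species, pass) {
  prof <- cfg$availability[[species]]
  if (is.null(prof)) return(rep(1, length(pass)))
  prof[pmin(pass, length(prof))]
}

#' Simulate host morphometrics
#'
#' Draws sexes, correlated (length, girth) pairs from a bivariate normal per
#' sex (truncated at positive values), tail lengths, and juvenile flags.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed; the full output stream is reproducible given it.
#' @return data frame with columns \code{id}, \code{sex},
#'   \code{curvilinear_length_cm}, \code{umbilicus_girth_cm},
#'   \code{tail_length_cm}, \code{is_juvenile}.
#' @export
simulate_hosts <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_hosts
  if (n == 0L)
    return(data.frame(id = character(0), sex = character(0),
                      curvilinear_length_cm = numeric(0),
                      umbilicus_girth_cm = numeric(0),
                      tail_length_cm = numeric(0),
                      is_juvenile = logical(0)))
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")
  rho <- config$length_girth_cor
  Sigma <- matrix(c(config$length_sd^2,
                    rho * config$length_sd * config$girth_sd,
                    rho * config$length_sd * config$girth_sd,
                    config$girth_sd^2), 2, 2)
  lg <- t(vapply(sex, function(s) {
    mu <- c(config$length_mean[[s]], config$girth_mean[[s]])
    repeat {
      x <- MASS::mvrnorm(1, mu = mu, Sigma = Sigma)
      if (all(x > 0)) return(x)
    }
  }, numeric(2)))
  juv <- stats::runif(n) < config$juvenile_fraction
  data.frame(id = sprintf("SIM-%02d", seq_len(n)),
             sex = sex,
             curvilinear_length_cm = lg[, 1],
             umbilicus_girth_cm = lg[, 2],
             tail_length_cm = vapply(sex, function(s)
               config$tail_length_mean[[s]], numeric(1)),
             is_juvenile = juv,
             row.names = NULL, stringsAsFactors = FALSE)
}

.rcount <- function(n, mu, size) {
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- if (is.infinite(size)) stats::rpois(sum(pos), mu[pos])
                else stats::rnbinom(sum(pos), mu = mu[pos], size = size)
  }
  out
}

#' Simulate scrape samples for a host cohort
#'
#' Draws per-host latent densities per species (lognormal across hosts,
#' attenuated for juveniles), then for every plate and species a
#' negative-binomial count with mean density x plate area x availability at
#' that depth pass, binned to an ordinal category. Each host receives a
#' random number of pseudoreplicate first-pass plates; when
#' \code{n_passes > 1} the first area is additionally resampled at deeper
#' passes (labels A, A-1, A-2, ... for passes 1, 2, 3, ...). Skin remnants
#' become more likely at deeper passes.
#'
#' @param hosts data frame from \code{\link{simulate_hosts}}.
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @return a \code{"scrape_survey"} data frame with attribute
#'   \code{"latent_density"}: the hosts x species matrix of latent densities
#'   (after juvenile attenuation) that generated it.
#' @export
simulate_samples <- function(hosts, config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  sp <- config$species
  nh <- nrow(hosts)
  lat <- matrix(stats::rlnorm(nh * length(sp),
                              meanlog = rep(config$density_meanlog, each = nh),
                              sdlog = rep(config$density_sdlog, each = nh)),
                nrow = nh, dimnames = list(hosts$id, sp))
  if (any(hosts$is_juvenile))
    lat[hosts$is_juvenile, ] <- lat[hosts$is_juvenile, , drop = FALSE] *
      config$juvenile_attenuation
  rows <- vector("list", nh)
  for (i in seq_len(nh)) {
    plate_choices <- seq(config$plates_range[1], config$plates_range[2])
    n_plates <- if (length(plate_choices) == 1L) plate_choices
                else sample(plate_choices, 1)
    labels <- LETTERS[seq_len(n_plates)]
    passes <- rep(1L, n_plates)
    resample <- rep(FALSE, n_plates)
    if (config$n_passes > 1L) {
      extra <- seq_len(config$n_passes - 1L)
      labels <- c(labels, paste0("A-", extra))
      passes <- c(passes, extra + 1L)
      resample <- c(resample, rep(TRUE, length(extra)))
    }
    np <- length(labels)
    plate <- data.frame(host_id = rep(hosts$id[i], np * length(sp)),
                        year = NA_integer_,
                        sample_label = rep(labels, each = length(sp)),
                        pass_index = rep(passes, each = length(sp)),
                        is_resample = rep(resample, each = length(sp)),
                        area_cm2 = config$area_cm2,
                        species = rep(sp, np),
                        stringsAsFactors = FALSE)
    avail <- mapply(function(s, p) .availability_at(config, s, p),
                    plate$species, plate$pass_index)
    mu <- lat[i, plate$species] * config$area_cm2 * avail
    cnt <- .rcount(nrow(plate), mu, config$dispersion)
    plate$category <- format_abundance_level(
      count_to_category(cnt, config$bin_edges))
    p_remnant <- pmin(1, config$skin_remnant_prob +
                        config$skin_remnant_gain * (passes - 1L))
    remn <- ifelse(stats::rbinom(np, 1, p_remnant) == 1, "P", "A")
    plate$skin_remnants <- rep(remn, each = length(sp))
    rows[[i]] <- plate
  }
  out <- as_scrape_survey(do.call(rbind, rows))
  attr(out, "latent_density") <- lat
  out
}

#' Simulate a full survey
#'
#' Convenience wrapper: hosts plus samples, with seeds derived from one
#' master seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer master seed.
#' @return list with \code{hosts}, \code{samples} and \code{latent_density}.
#' @export
simulate_survey <- function(config = sim_config(), seed = 1) {
  hosts <- simulate_hosts(config, seed)
  samples <- simulate_samples(hosts, config, seed + 1L)
  list(hosts = hosts, samples = samples,
       latent_density = attr(samples, "latent_density"))
}

#' Expected value of the mapped-count density estimator
#'
#' Numerical oracle for parameter-recovery experiments. Binning a count to
#' an ordinal class and replacing the class by a fixed representative count
#' is a biased estimator of the latent density; the relevant ground truth
#' for recovery is therefore the estimator's own expectation under the
#' simulator. For a first-pass plate of a host with latent density d, the
#' expected mapped count is
#' sum over levels of (representative count x P(count in bin | mean =
#' d * area * availability)), with negative-binomial counts; this is
#' integrated over the lognormal across-host density law.
#'
#' @param config a \code{\link{sim_config}}.
#' @param mapping a \code{\link{category_mapping}}.
#' @param pass pass index of the plates entering the estimator (default 1,
#'   matching the non-sequential inclusion rule).
#' @return named numeric vector: expected estimated density per species,
#'   nematodes/cm^2.
#' @export
expected_mapped_density <- function(config = sim_config(),
                                    mapping = category_mapping(),
                                    pass = 1L) {
  stopifnot(inherits(config, "sim_config"))
  map <- unclass(if (inherits(mapping, "category_mapping")) mapping
                 else category_mapping(mapping))
  e <- config$bin_edges
  emap <- function(mu) {  # E[mapped count | NB mean mu]
    vapply(mu, function(m) {
      if (m == 0) return(map[1])
      pr <- if (is.infinite(config$dispersion)) {
        c(stats::ppois(e[1] - 1, m),
          stats::ppois(e[2] - 1, m) - stats::ppois(e[1] - 1, m),
          stats::ppois(e[3] - 1, m) - stats::ppois(e[2] - 1, m),
          1 - stats::ppois(e[3] - 1, m))
      } else {
        k <- config$dispersion
        c(stats::pnbinom(e[1] - 1, mu = m, size = k),
          stats::pnbinom(e[2] - 1, mu = m, size = k) -
            stats::pnbinom(e[1] - 1, mu = m, size = k),
          stats::pnbinom(e[3] - 1, mu = m, size = k) -
            stats::pnbinom(e[2] - 1, mu = m, size = k),
          1 - stats::pnbinom(e[3] - 1, mu = m, size = k))
      }
      sum(map * pr)
    }, numeric(1))
  }
  out <- vapply(seq_along(config$species), function(j) {
    s <- config$species[j]
    a <- .availability_at(config, s, pass)
    ml <- config$density_meanlog[j]
    sl <- config$density_sdlog[j]
    if (sl == 0) return(emap(exp(ml) * config$area_cm2 * a) / config$area_cm2)
    f <- function(d) emap(d * config$area_cm2 * a) *
      stats::dlnorm(d, meanlog = ml, sdlog = sl)
    stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value / config$area_cm2
  }, numeric(1))
  stats::setNames(out, config$species)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a survey and runs the two-stage density estimator,
#' then compares the replicate mean against the estimator's numerically
#' computed expectation under the same configuration
#' (\code{\link{expected_mapped_density}}). Bias relative to the latent
#' density mean is also reported, but only as information: ordinal binning
#' with fixed representative counts does not target the latent mean.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer master seed; replicate r uses \code{seed + 2 * r}.
#' @param n_reps number of simulated surveys (>= 1).
#' @param mapping a \code{\link{category_mapping}}.
#' @param rule inclusion rule passed to the estimator.
#' @return an object of class \code{"recovery_experiment"}: data frame
#'   \code{per_species} with columns \code{species}, \code{expected}
#'   (numerical oracle), \code{mean_estimate}, \code{sd_estimate},
#'   \code{mc_se}, \code{bias}, \code{latent_mean},
#'   \code{bias_vs_latent}; plus \code{n_reps} and \code{estimates}
#'   (replicates x species matrix).
#' @export
recovery_experiment <- function(config = sim_config(), seed = 1, n_reps = 50,
                                mapping = category_mapping(),
                                rule = "nonsequential") {
  stopifnot(n_reps >= 1)
  ests <- t(vapply(seq_len(n_reps), function(r) {
    sv <- simulate_survey(config, seed + 2L * r)
    population_mean_density(sv$samples, mapping, rule)$densities[config$species]
  }, stats::setNames(numeric(length(config$species)), config$species)))
  expected <- expected_mapped_density(config, mapping)
  latent <- exp(config$density_meanlog + config$density_sdlog^2 / 2)
  per <- data.frame(species = config$species,
                    expected = as.numeric(expected),
                    mean_estimate = colMeans(ests),
                    sd_estimate = apply(ests, 2, stats::sd),
                    stringsAsFactors = FALSE)
  per$mc_se <- per$sd_estimate / sqrt(n_reps)
  per$bias <- per$mean_estimate - per$expected
  per$latent_mean <- as.numeric(latent)
  per$bias_vs_latent <- per$mean_estimate - per$latent_mean
  rownames(per) <- NULL
  structure(list(per_species = per, n_reps = n_reps, estimates = ests),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("Estimator recovery over %d simulated surveys\n", x$n_reps))
  print(x$per_species, row.names = FALSE, digits = 4)
  invisible(x)
}
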