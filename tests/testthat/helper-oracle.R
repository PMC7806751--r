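# Independent brute-force oracle for the two-stage density estimator:
# explicit double loop over hosts and plates, no shared code with the
# implementation (which uses tapply/vapply over a validated frame).
brute_force_two_stage <- function(df, map_counts, include) {
  species <- unique(df$species)
  hosts <- unique(df$host_id)
  acc <- matrix(0, length(hosts), length(species),
                dimnames = list(hosts, species))
  for (h in hosts) {
    for (s in species) {
      vals <- c()
      for (i in seq_len(nrow(df))) {
        if (df$host_id[i] == h && df$species[i] == s && include[i]) {
          lev <- match(trimws(df$category[i]), c("0", "+", "++", "+++")) - 1
          vals <- c(vals, map_counts[lev + 1] / df$area_cm2[i])
        }
      }
      acc[h, s] <- sum(vals) / length(vals)
    }
  }
  out <- numeric(length(species))
  names(out) <- species
  for (s in species) out[s] <- sum(acc[, s]) / length(hosts)
  out
}

# Random small ordinal survey: <= n_hosts hosts x <= n_plates plates,
# 3 species, optional resample plates at deeper passes.
random_survey <- function(n_hosts = 5, n_plates = 6, p_resample = 0.3) {
  hosts <- paste0("H", seq_len(sample(n_hosts, 1)))
  sp <- c("spA", "spB", "spC")
  rows <- list()
  for (h in hosts) {
    np <- sample(n_plates, 1)
    for (j in seq_len(np)) {
      res <- j > 1 && runif(1) < p_resample
      rows[[length(rows) + 1]] <- data.frame(
        host_id = h, year = 2020,
        sample_label = if (res) paste0("A-", j) else LETTERS[j],
        pass_index = if (res) j else 1L,
        is_resample = res, area_cm2 = 25,
        species = sp,
        category = c("0", "+", "++", "+++")[sample(4, 3, replace = TRUE)],
        skin_remnants = sample(c("P", "A"), 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

paper_mapping <- category_mapping(c(0, 10, 50, 100))
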