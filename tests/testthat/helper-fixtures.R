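# Shared fixtures and oracles for the test suite.  Everything is generated
# in code; no data files.

# A tiny fully deterministic pedigree: one family, phase-known sire and dam
# (hom x het patterns chosen so every transmission is deducible), genotypes
# written directly rather than simulated.
tiny_pedigree_genotypes <- function(genotypes, sire_geno, dam_geno,
                                    markers = colnames(genotypes)) {
  n_off <- nrow(genotypes)
  ids <- sprintf("o%02d", seq_len(n_off))
  rownames(genotypes) <- ids
  g <- rbind(S = sire_geno, D = dam_geno, genotypes)
  storage.mode(g) <- "integer"
  colnames(g) <- markers
  ped <- data.frame(
    id = c("S", "D", ids),
    sire = c(NA, NA, rep("S", n_off)),
    dam = c(NA, NA, rep("D", n_off)),
    sex = c("male", "female", rep(NA, n_off)),
    family = "fam1", stringsAsFactors = FALSE)
  structure(list(pedigree = ped, genotypes = g, markers = markers,
                 truth = NULL, truth_map = NULL),
            class = "pedigree_genotypes")
}

# Brute-force oracle: maximize the exact phase-mixture likelihood for
# per-parent counts (r, n) over a theta grid.
theta_grid_oracle <- function(r, n, resolution = 1e-4) {
  grid <- seq(0, 0.5, by = resolution)
  ll <- vapply(grid, function(th) {
    th <- min(max(th, 1e-12), 1 - 1e-12)
    sum(log(0.5 * th^r * (1 - th)^(n - r) + 0.5 * th^(n - r) * (1 - th)^r))
  }, 0)
  list(theta = grid[which.max(ll)], loglik = max(ll))
}

# Random per-parent count sets emulating small families.
random_counts <- function(theta, n_parents, meioses_range = c(4L, 20L)) {
  n <- sample(meioses_range[1]:meioses_range[2], n_parents, replace = TRUE)
  # each parent has a random phase; counts are recorded under coupling
  r <- stats::rbinom(n_parents, n, theta)
  flip <- stats::runif(n_parents) < 0.5
  r[flip] <- n[flip] - r[flip]
  list(r = r, n = n)
}

# Map table built directly from positions (one group), bypassing estimation.
toy_map_table <- function(group, female, male = female * 0.4,
                          ids = sprintf("%s_m%02d", group, seq_along(female)),
                          specific = FALSE) {
  data.frame(marker_id = ids, linkage_group = group,
             order_index = seq_along(female),
             female_cM = female - female[1L], male_cM = male - male[1L],
             n_meioses = 100L, accession = "",
             population_specific = rep_len(specific, length(female)),
             stringsAsFactors = FALSE)
}

# Query group carrying a planted fusion of two reference groups, built
# directly in map-table form.  Reference groups are A (length la) and B
# (length lb); "head_to_head" reverses A so the proximal ends meet.
planted_fusion_tables <- function(geometry = c("head_to_head", "tail_to_head"),
                                  la = 50, lb = 40, m = 11,
                                  male_profile = function(u) {
                                    karyomapr::male_crossover_position_cdf(u)
                                  }) {
  geometry <- match.arg(geometry)
  fa <- seq(0, la, length.out = m)
  fb <- seq(0, lb, length.out = m)
  mapA <- rbind(toy_map_table("refA", fa), toy_map_table("refB", fb))
  if (geometry == "head_to_head") {
    # query: reversed A then B
    q_female <- c(la - rev(fa), la + fb)
    q_ids <- c(rev(mapA$marker_id[1:m]), mapA$marker_id[(m + 1):(2 * m)])
  } else {
    # query: A forward (tail at junction) then B
    q_female <- c(fa, la + fb)
    q_ids <- mapA$marker_id
  }
  lq <- la + lb
  q_male <- 40 * male_profile(q_female / lq)
  mapB <- data.frame(marker_id = q_ids, linkage_group = "Q1",
                     order_index = seq_along(q_ids),
                     female_cM = q_female, male_cM = q_male - q_male[1L],
                     n_meioses = 100L, accession = "",
                     population_specific = FALSE, stringsAsFactors = FALSE)
  list(mapA = mapA, mapB = mapB)
}
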