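test_that("male crossover density is a valid, piecewise-uniform density", {
  # derived value: window 0.1, mass 0.9 -> interior density 0.1/0.8 = 0.125
  expect_equal(male_crossover_position_density(0.5, 0.1, 0.9), 0.125)
  expect_equal(male_crossover_position_density(0.05, 0.1, 0.9), 4.5)
  # uniform limit: mass = 2 * window
  expect_equal(male_crossover_position_density(c(0.02, 0.5, 0.97), 0.25, 0.5),
               rep(1, 3))
  # numeric integral = 1 for random valid parameters
  set.seed(7)
  for (i in 1:10) {
    w <- runif(1, 0.01, 0.49)
    mass <- runif(1, 0.05, 1)
    x <- seq(0, 1, length.out = 20001)
    integral <- mean(male_crossover_position_density(x, w, mass))
    expect_equal(integral, 1, tolerance = 1e-3)
    expect_equal(male_crossover_position_cdf(1, w, mass), 1, tolerance = 1e-12)
    expect_equal(male_crossover_position_cdf(0, w, mass), 0)
  }
  expect_error(male_crossover_position_density(0.5, 0.6, 0.9),
               "telomere_window")
  expect_error(male_crossover_position_density(0.5, 0.1, 1.4),
               "telomere_mass")
})

test_that("truth maps satisfy their invariants and are deterministic", {
  sim <- simulate_truth_maps(n_chromosomes = 4, markers_per_chromosome = 12,
                             shared_fraction = 0.8, seed = 5)
  sim2 <- simulate_truth_maps(n_chromosomes = 4, markers_per_chromosome = 12,
                              shared_fraction = 0.8, seed = 5)
  expect_identical(sim$query, sim2$query)
  expect_identical(sim$reference, sim2$reference)

  for (m in list(sim$reference, sim$query)) {
    for (g in unique(m$chromosome)) {
      d <- m[m$chromosome == g, ]
      expect_true(all(diff(d$female_cM) > 0))
      expect_true(all(diff(d$male_cM) > 0))
    }
  }
  # shared markers form a bijection between the two maps
  expect_setequal(sim$reference$marker, sim$query$marker[sim$query$shared])
  # shared_fraction = 1 -> every marker shared
  all_shared <- simulate_truth_maps(n_chromosomes = 2,
                                    markers_per_chromosome = 8,
                                    shared_fraction = 1, seed = 1)
  expect_true(all(all_shared$query$shared))
  expect_error(simulate_truth_maps(shared_fraction = 1.2), "shared_fraction")
})

test_that("shared fraction is honoured at scale", {
  sim <- simulate_truth_maps(n_chromosomes = 27, markers_per_chromosome = 24,
                             shared_fraction = 0.83, seed = 3)
  frac <- mean(sim$query$shared)
  # binomial sampling bound: 648 markers, 3.5 sigma
  expect_lt(abs(frac - 0.83), 3.5 * sqrt(0.83 * 0.17 / nrow(sim$query)))
})

test_that("meiosis simulator recovers crossover statistics", {
  sim <- simulate_truth_maps(n_chromosomes = 1, female_lengths_cM = 100,
                             male_lengths_cM = 50,
                             markers_per_chromosome = 30,
                             shared_fraction = 1, seed = 2)
  tm <- sim$reference
  hap <- rbind(rep(1L, nrow(tm)), rep(0L, nrow(tm)))  # fully informative

  # female: mean crossovers ~ Poisson(1) for a 100 cM chromosome.  Only
  # parity changes between markers are visible; their exact expectation is
  # the sum of Haldane probabilities over the marker intervals (~0.94 here).
  g <- simulate_meiosis(hap, tm, "female", n = 4000, seed = 11)
  ori <- attr(g, "origins")
  switches <- rowSums(ori[, -1] != ori[, -ncol(ori)])
  expected <- sum((1 - exp(-2 * diff(tm$female_cM) / 100)) / 2)
  expect_lt(abs(mean(switches) - expected),
            3 * sqrt(expected / 4000) + 0.01)
  expect_lt(abs(mean(switches) - 1), 0.12)

  # male: >= 85% of crossovers in terminal windows with telomere_mass 0.9
  gm <- simulate_meiosis(hap, tm, "male", n = 4000, seed = 12)
  om <- attr(gm, "origins")
  cross_idx <- which(abs(diff(t(om))) > 0, arr.ind = TRUE)
  u_at <- tm$u[cross_idx[, 1L]]   # interval left endpoint
  in_window <- u_at < 0.1 | u_at > 0.9 - 1 / 30
  expect_gte(mean(in_window), 0.85)

  # 0 cM chromosome: unrecombined parental haplotype
  tm0 <- sim$reference
  attr(tm0, "group_info")$female_length <- 1e-9
  g0 <- simulate_meiosis(hap, tm0, "female", n = 50, seed = 13)
  expect_true(all(apply(attr(g0, "origins"), 1, function(x)
    length(unique(x)) == 1L)))
})

test_that("pedigree genotypes are Mendelian and deterministic", {
  sim <- simulate_truth_maps(n_chromosomes = 2, markers_per_chromosome = 10,
                             shared_fraction = 1, seed = 4)
  pg <- simulate_pedigree_genotypes(sim$reference, n_families = 8,
                                    offspring_per_family = 10,
                                    half_sib_fraction = 0.25,
                                    missing_rate = 0, seed = 6)
  expect_identical(check_mendelian(pg), 1)
  pg2 <- simulate_pedigree_genotypes(sim$reference, n_families = 8,
                                     offspring_per_family = 10,
                                     half_sib_fraction = 0.25,
                                     missing_rate = 0, seed = 6)
  expect_identical(pg$genotypes, pg2$genotypes)
  expect_identical(pg$pedigree, pg2$pedigree)

  # half-sib families have one parent blanked in the pedigree and withheld
  # from the genotype matrix
  hs <- pg$truth$half_sib_families
  expect_length(hs, 2L)
  for (f in hs) {
    off <- pg$pedigree[pg$pedigree$family == f & !is.na(pg$pedigree$family) &
                         grepl("_o", pg$pedigree$id), ]
    expect_true(any(is.na(off$sire)) || any(is.na(off$dam)))
  }

  # monomorphic marker: all genotypes identical
  pg0 <- simulate_pedigree_genotypes(sim$reference, n_families = 4,
                                     offspring_per_family = 6,
                                     half_sib_fraction = 0, missing_rate = 0,
                                     maf = rep(0, nrow(sim$reference)),
                                     seed = 7)
  expect_true(all(pg0$genotypes == 0L))

  # missing rate is honoured
  pgm <- simulate_pedigree_genotypes(sim$reference, n_families = 10,
                                     offspring_per_family = 10,
                                     half_sib_fraction = 0,
                                     missing_rate = 0.1, seed = 8)
  expect_lt(abs(mean(is.na(pgm$genotypes)) - 0.1), 0.02)
})

test_that("recombinant fraction between close markers matches the map", {
  # markers 1 cM apart: observed recombinant fraction ~ 0.01
  sim <- simulate_truth_maps(n_chromosomes = 1, female_lengths_cM = 9,
                             male_lengths_cM = 9,
                             markers_per_chromosome = 10,
                             shared_fraction = 1, seed = 9,
                             telomere_mass = 0.2, telomere_window = 0.1)
  pg <- simulate_pedigree_genotypes(sim$reference, n_families = 60,
                                    offspring_per_family = 30,
                                    half_sib_fraction = 0, missing_rate = 0,
                                    seed = 10)
  oris <- rbind(pg$truth$origin_sire, pg$truth$origin_dam)
  recfrac <- mean(oris[, 1] != oris[, 2])
  n <- nrow(oris)
  expect_lt(abs(recfrac - 0.01), 3 * sqrt(0.01 * 0.99 / n) + 1e-3)
})

test_that("planted events rearrange the query truth map and karyotype", {
  events <- list(
    rearrangement_event("whole_arm_translocation", c("chr01p", "chr05")),
    rearrangement_event("robertsonian_fusion", c("chr03", "chr04")),
    rearrangement_event("tandem_fusion", c("chr02", "chr06"))
  )
  sim <- simulate_truth_maps(n_chromosomes = 6, markers_per_chromosome = 10,
                             shared_fraction = 1, seed = 21,
                             metacentric = c("chr01", "chr02"),
                             events = events)
  qg <- unique(sim$query$chromosome)
  expect_setequal(qg, c("chr01p/05", "chr01q", "chr03/04", "chr02/06"))
  s <- karyotype_summary(sim$query_karyotype)
  expect_identical(s$n_pairs, 4L)
  # arm mass (= female cM here) conserved through all events
  expect_equal(s$total_arm_length,
               karyotype_summary(sim$reference_karyotype)$total_arm_length)
  # marker content conserved
  expect_setequal(sim$query$marker,
                  paste0(rep(sprintf("chr%02d", 1:6), each = 10), "_m",
                         sprintf("%03d", rep(1:10, 6))))
  # each query group's positions still strictly increase
  for (g in qg) {
    d <- sim$query[sim$query$chromosome == g, ]
    expect_true(all(diff(d$female_cM) > 0))
    expect_true(all(diff(d$male_cM) > 0))
  }
})

test_that("fish probe counts follow the zygosity state", {
  out <- simulate_fish_counts(c(f1 = "hom_fused", f2 = "het",
                                f3 = "hom_unfused"))
  expect_identical(out$co_located, c(2L, 1L, 0L))
  expect_identical(out$separate, c(0L, 2L, 2L))
  expect_error(simulate_fish_counts(c(f1 = "weird")), "invalid state")
  expect_error(simulate_fish_counts("het"), "named")
})
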