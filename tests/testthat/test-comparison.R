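test_that("shared-marker matching reports intersections and uniques", {
  mapA <- rbind(toy_map_table("g1", c(0, 5, 10)),
                toy_map_table("g2", c(0, 7), ids = c("u1", "u2")))
  mapB <- rbind(toy_map_table("g1", c(0, 5, 10)),
                toy_map_table("g3", c(0, 3), ids = c("v1", "v2")))
  p <- match_shared_markers(mapA, mapB)
  expect_identical(nrow(p$shared), 3L)
  expect_setequal(p$only_a, c("u1", "u2"))
  expect_setequal(p$only_b, c("v1", "v2"))
  # self comparison: everything shared
  ps <- match_shared_markers(mapA, mapA)
  expect_identical(nrow(ps$shared), 5L)
  expect_length(ps$only_a, 0L)
  # disjoint maps: empty pairing
  p0 <- match_shared_markers(toy_map_table("a", c(0, 1), ids = c("p", "q")),
                             toy_map_table("b", c(0, 1), ids = c("r", "s")))
  expect_identical(nrow(p0$shared), 0L)
  # duplicates rejected
  dup <- rbind(toy_map_table("g1", c(0, 5)),
               toy_map_table("g1b", c(0, 5), ids = c("g1_m01", "g1_m02")))
  expect_error(match_shared_markers(dup, mapB), "duplicate marker id")
})

test_that("correspondence graph weights, prunes and orients edges", {
  mapA <- toy_map_table("g1", seq(0, 50, by = 5))
  # reversed copy: same positions, marker identity runs the other way
  mapB <- toy_map_table("h1", seq(0, 50, by = 5),
                        ids = rev(mapA$marker_id))
  g <- build_correspondence(match_shared_markers(mapA, mapB), mapA, mapB)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$n_shared, 11L)
  expect_lt(g$edges$rho, 0)

  # identical maps: rho +1
  gs <- build_correspondence(match_shared_markers(mapA, mapA), mapA, mapA)
  expect_equal(gs$edges$rho, 1)

  # stray shared markers below min_shared are pruned
  stray <- toy_map_table("g2", c(0, 4), ids = c("s1", "s2"))
  mapA2 <- rbind(mapA, stray)
  mapB2 <- mapB
  mapB2 <- rbind(mapB2, within(stray, linkage_group <- "h1")[0, ])
  extra <- stray; extra$linkage_group <- "h2"
  mapB2 <- rbind(mapB2, extra)
  g2 <- build_correspondence(match_shared_markers(mapA2, mapB2), mapA2, mapB2,
                             min_shared = 3)
  expect_identical(nrow(g2$edges), 1L)   # g2-h2 edge (2 markers) pruned
})

test_that("self-comparison yields only conserved events", {
  mapA <- rbind(toy_map_table("g1", seq(0, 40, by = 4)),
                toy_map_table("g2", seq(0, 30, by = 3)))
  cmp <- compare_maps(mapA, mapA)
  expect_true(all(vapply(cmp$events, function(e) e$type, "") == "conserved"))
  expect_identical(length(cmp$events), 2L)
})

test_that("planted head-to-head fusion is detected with junction and geometry", {
  tabs <- planted_fusion_tables("head_to_head")
  cmp <- compare_maps(tabs$mapA, tabs$mapB)
  ev <- Filter(function(e) e$type == "fusion", cmp$events)
  expect_length(ev, 1L)
  ev <- ev[[1]]
  expect_setequal(ev$reference_groups, c("refA", "refB"))
  expect_identical(ev$geometry, "head_to_head")
  # junction interval sits between the two blocks (true junction at 50)
  expect_lt(ev$junction[1], 50 + 1e-9)
  expect_gt(ev$junction[2], 50 - 1e-9)
  # per-block orientation: the reversed block is 'reverse'
  expect_setequal(unname(ev$orientation), c("forward", "reverse"))
})

test_that("planted tail-to-head fusion and duality with fission", {
  tabs <- planted_fusion_tables("tail_to_head")
  cmp <- compare_maps(tabs$mapA, tabs$mapB)
  ev <- Filter(function(e) e$type == "fusion", cmp$events)[[1]]
  expect_identical(ev$geometry, "tail_to_head")
  # duality: with the query as reference the same component is a fission
  cmp_rev <- compare_maps(tabs$mapB, tabs$mapA)
  ev_rev <- Filter(function(e) e$type == "fission", cmp_rev$events)
  expect_length(ev_rev, 1L)
  expect_identical(ev_rev[[1]]$reference_groups, "Q1")
  expect_setequal(ev_rev[[1]]$query_groups, c("refA", "refB"))
})

test_that("translocation plus fission is classified with its residue", {
  # reference: big group gA (p block 0-30, q block 30-80) and acrocentric gB
  fa <- seq(0, 80, by = 4)            # 21 markers
  fb <- seq(0, 40, by = 4)            # 11 markers
  mapA <- rbind(toy_map_table("gA", fa), toy_map_table("gB", fb))
  ids_a <- mapA$marker_id[mapA$linkage_group == "gA"]
  ids_b <- mapA$marker_id[mapA$linkage_group == "gB"]
  p_block <- fa < 30                  # moved arm
  # product: p block (forward, distal at 0) then gB offset by arm length
  prod_female <- c(fa[p_block], 30 + fb)
  prod_ids <- c(ids_a[p_block], ids_b)
  prod <- data.frame(marker_id = prod_ids, linkage_group = "qP",
                     order_index = seq_along(prod_ids),
                     female_cM = prod_female,
                     male_cM = 30 * male_crossover_position_cdf(
                       prod_female / max(prod_female)),
                     n_meioses = 100L, accession = "",
                     population_specific = FALSE)
  prod$male_cM <- prod$male_cM - prod$male_cM[1]
  resid_f <- fa[!p_block] - 30
  resid <- data.frame(marker_id = ids_a[!p_block], linkage_group = "qR",
                      order_index = seq_along(resid_f), female_cM = resid_f,
                      male_cM = 20 * male_crossover_position_cdf(
                        resid_f / max(resid_f)),
                      n_meioses = 100L, accession = "",
                      population_specific = FALSE)
  resid$male_cM <- resid$male_cM - resid$male_cM[1]
  mapB <- rbind(prod, resid)

  ref_k <- karyotype_from_arms(data.frame(
    chromosome = c("gA", "gA", "gB"), arm = c("gAp", "gAq", "gBq"),
    length = c(30, 50, 40)))
  cmp <- compare_maps(mapA, mapB, reference_karyotype = ref_k)
  ev <- Filter(function(e) e$type == "translocation_plus_fission", cmp$events)
  expect_length(ev, 1L)
  ev <- ev[[1]]
  expect_identical(ev$detail$donor, "gA")
  expect_identical(ev$detail$intact, "gB")
  expect_identical(ev$detail$moved_side, "low")
  expect_identical(unname(ev$query_groups["product"]), "qP")
  expect_identical(unname(ev$query_groups["residue"]), "qR")
  expect_identical(ev$architecture, "centromere_to_centromere")
  # karyotype prediction: translocation leaves pairs and NF unchanged
  s <- karyotype_summary(cmp$predicted_karyotype)
  expect_identical(s$n_pairs, 2L)
  expect_identical(s$nf, 6L)
  expect_identical(s$metacentric, 1L)
})

test_that("male telomere statistic behaves at its limits", {
  # uniform male map, dense markers -> about 2 * terminal_fraction
  rows <- toy_map_table("g", seq(0, 100, length.out = 201),
                        male = seq(0, 40, length.out = 201))
  expect_equal(male_telomere_statistic(rows, 0.1), 0.2, tolerance = 0.02)
  # all male recombination in the outermost intervals -> 1
  rows2 <- toy_map_table("g", c(0, 10, 50, 90, 100),
                         male = c(0, 18, 18, 18, 36))
  expect_equal(male_telomere_statistic(rows2, 0.1), 1)
  # telomere-concentrated profile -> high share
  u <- seq(0.025, 0.975, length.out = 39)
  rows3 <- toy_map_table("g", u * 100,
                         male = 40 * male_crossover_position_cdf(u))
  expect_gte(male_telomere_statistic(rows3, 0.1), 0.8)
  # zero male length -> NA
  rows4 <- toy_map_table("g", c(0, 5, 10), male = c(0, 0, 0))
  expect_true(is.na(male_telomere_statistic(rows4)))
  expect_error(male_telomere_statistic(rows4[1:2, ]), "3 markers")
})

test_that("architecture inference follows junction coldness and classes", {
  cls <- c(refA = "acrocentric", refB = "acrocentric")
  tabs <- planted_fusion_tables("head_to_head")
  cmp <- compare_maps(tabs$mapA, tabs$mapB)
  ev <- Filter(function(e) e$type == "fusion", cmp$events)[[1]]
  expect_identical(infer_architecture(ev, tabs$mapB, cls),
                   "centromere_to_centromere")
  # same geometry but one metacentric participant -> undetermined
  cls2 <- c(refA = "metacentric", refB = "acrocentric")
  expect_identical(infer_architecture(ev, tabs$mapB, cls2), "undetermined")

  # tandem: tail-side metacentric donor
  tabs2 <- planted_fusion_tables("tail_to_head")
  cmp2 <- compare_maps(tabs2$mapA, tabs2$mapB)
  ev2 <- Filter(function(e) e$type == "fusion", cmp2$events)[[1]]
  expect_identical(infer_architecture(ev2, tabs2$mapB, cls2), "tandem")

  # junction at a male hotspot (each constituent keeps its own telomeric
  # profile, so the junction sits between two hot ends) -> undetermined
  two_profiles <- function(u) {
    0.5 * male_crossover_position_cdf(pmin(2 * u, 1)) +
      0.5 * (u > 0.5) *
        male_crossover_position_cdf(pmin(pmax(2 * u - 1, 0), 1))
  }
  tabs3 <- planted_fusion_tables("head_to_head", male_profile = two_profiles)
  cmp3 <- compare_maps(tabs3$mapA, tabs3$mapB)
  ev3 <- Filter(function(e) e$type == "fusion", cmp3$events)[[1]]
  expect_identical(infer_architecture(ev3, tabs3$mapB, cls), "undetermined")

  con <- karyomapr:::new_detected_event("conserved", "refA", "Q1")
  expect_error(infer_architecture(con, tabs$mapB, cls), "fusion-like")
  expect_error(infer_architecture(ev, tabs$mapB, cls["refA"]), "cover")
})

test_that("events_to_karyotype maps detections onto karyotype operations", {
  ref <- karyotype_from_arms(data.frame(
    chromosome = c("c1", "c2", "c3", "c3"),
    arm = c("c1q", "c2q", "c3p", "c3q"), length = c(1, 1, 1, 1)))
  rob <- karyomapr:::new_detected_event(
    "fusion", c("c1", "c2"), "q1", junction = c(10, 12),
    orientation = c(c1 = "reverse", c2 = "forward"),
    geometry = "head_to_head", architecture = "centromere_to_centromere")
  out <- events_to_karyotype(list(rob), ref)
  s <- karyotype_summary(out)
  expect_identical(s$n_pairs, 2L)
  expect_identical(s$nf, 8L)
  expect_identical(s$metacentric, 2L)

  tan <- rob
  tan$reference_groups <- c("c3", "c1")
  tan$architecture <- "tandem"
  out2 <- events_to_karyotype(list(tan), ref)
  expect_identical(karyotype_summary(out2)$nf, 8L - 2L)

  und <- rob; und$architecture <- "undetermined"
  expect_error(events_to_karyotype(list(und), ref), "undetermined architecture")
  cpx <- karyomapr:::new_detected_event("complex", "c1", "q9")
  expect_error(events_to_karyotype(list(cpx), ref), "complex event")
  # conserved-only events leave the reference unchanged
  con <- karyomapr:::new_detected_event("conserved", "c1", "q1")
  out3 <- events_to_karyotype(list(con), ref)
  expect_identical(out3$arm, ref$arm)
  expect_identical(karyotype_summary(out3), karyotype_summary(ref))
})
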