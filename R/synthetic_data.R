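# Synthetic data -------------------------------------------------------------
#
# Generates the world the mapping pipeline assumes: truth maps for two
# populations sharing markers, a karyotype per population (the query one
# transformed by planted rearrangement events), pedigrees of full-/half-sib
# families, and meioses with sex-specific crossover distributions (female
# crossovers evenly spread, male crossovers concentrated at the telomeres).
#
# Coordinate conventions (shared with the comparison module): within a
# linkage group, position 0 of an acrocentric is its centromeric (proximal)
# end; a metacentric group runs p-distal (0) -> centromere (arm_split) ->
# q-distal (1).  Crossovers are a Poisson process without interference, so
# Haldane's map function is exact for these simulations.

#' Male crossover position density
#'
#' Piecewise-uniform density on relative chromosome position `[0, 1]` placing
#' `telomere_mass` of the crossover probability inside the two terminal
#' windows of width `telomere_window`, with the remainder uniform over the
#' interior.  Models the male-specific concentration of recombination at the
#' telomeres; females use the uniform density.
#'
#' @param x relative positions in `[0, 1]`.
#' @param telomere_window width of each terminal window, in `(0, 0.5)`.
#' @param telomere_mass total probability assigned to the two windows, in
#'   `(0, 1]`.  `telomere_mass == 2 * telomere_window` recovers the uniform
#'   density.
#' @return Density values at `x`; integrates to 1.
#' @export
#' @examples
#' male_crossover_position_density(c(0.05, 0.5), 0.1, 0.9)
male_crossover_position_density <- function(x, telomere_window = 0.1,
                                            telomere_mass = 0.9) {
  check_telomere_profile(telomere_window, telomere_mass)
  stopifnot(all(x >= 0 & x <= 1))
  in_window <- x < telomere_window | x > 1 - telomere_window
  ifelse(in_window,
         telomere_mass / (2 * telomere_window),
         (1 - telomere_mass) / (1 - 2 * telomere_window))
}

#' @rdname male_crossover_position_density
#' @export
male_crossover_position_cdf <- function(x, telomere_window = 0.1,
                                        telomere_mass = 0.9) {
  check_telomere_profile(telomere_window, telomere_mass)
  stopifnot(all(x >= 0 & x <= 1))
  w <- telomere_window
  dw <- telomere_mass / (2 * w)
  di <- (1 - telomere_mass) / (1 - 2 * w)
  ifelse(x < w, x * dw,
         ifelse(x <= 1 - w,
                w * dw + (x - w) * di,
                w * dw + (1 - 2 * w) * di + (x - (1 - w)) * dw))
}

check_telomere_profile <- function(telomere_window, telomere_mass) {
  if (!(telomere_window > 0 && telomere_window < 0.5)) {
    stop("telomere_window must lie in (0, 0.5)")
  }
  if (!(telomere_mass > 0 && telomere_mass <= 1)) {
    stop("telomere_mass must lie in (0, 1]")
  }
  invisible(TRUE)
}

new_truth_map <- function(df, group_info, telomere_window, telomere_mass) {
  rownames(df) <- NULL
  structure(df,
            group_info = group_info,
            telomere_window = telomere_window,
            telomere_mass = telomere_mass,
            class = c("truth_map", "data.frame"))
}

#' Group lengths of a truth map
#' @param truth_map a `truth_map` object.
#' @return Data frame with columns `chromosome`, `female_length`,
#'   `male_length`, `centromere_cM`.
#' @export
truth_map_groups <- function(truth_map) attr(truth_map, "group_info")

#' Simulate a pair of truth maps (reference and query population)
#'
#' Builds a reference genome of `n_chromosomes` linkage groups with markers at
#' random positions, flags a `shared_fraction` subset as typed in both
#' populations, and derives the query genome by applying an optional list of
#' planted rearrangement events (the query karyotype is obtained with
#' [apply_event_set()], so event accounting is shared with the karyotype
#' model).  Female positions are proportional to "physical" position; male
#' positions follow the telomere-concentrated crossover profile.
#'
#' @param n_chromosomes number of reference chromosomes.
#' @param female_lengths_cM,male_lengths_cM per-chromosome map lengths in cM
#'   (recycled if scalar).
#' @param markers_per_chromosome markers per chromosome (>= 2).
#' @param shared_fraction probability that a marker is typed in both
#'   populations.
#' @param seed optional RNG seed.
#' @param events optional list of [rearrangement_event()]s applied to the
#'   query genome; participants use chromosome names `chr01`, `chr02`, ...
#'   (arm names `chr01p`/`chr01q` for metacentrics).
#' @param metacentric character vector of chromosomes to make metacentric.
#' @param arm_split relative position of the centromere on metacentrics.
#' @param marker_spacing `"even"` (default) places markers at the centres of
#'   `markers_per_chromosome` equal intervals, emulating an evenly designed
#'   array panel whose adjacent bins are resolvable at desk scale;
#'   `"random"` draws positions uniformly, which produces arbitrarily tight
#'   marker pairs whose true order no finite pedigree can recover.
#' @param telomere_window,telomere_mass male crossover profile (see
#'   [male_crossover_position_density()]).
#' @return A list of class `truth_sim` with elements `reference`, `query`
#'   (truth maps), `reference_karyotype`, `query_karyotype`, `events`.
#' @export
#' @examples
#' sim <- simulate_truth_maps(n_chromosomes = 3, markers_per_chromosome = 10,
#'                            seed = 1)
#' head(sim$reference)
simulate_truth_maps <- function(n_chromosomes = 27,
                                female_lengths_cM = 80,
                                male_lengths_cM = 36,
                                markers_per_chromosome = 24,
                                shared_fraction = 0.83,
                                seed = NULL,
                                events = NULL,
                                metacentric = character(0),
                                arm_split = 0.45,
                                marker_spacing = c("even", "random"),
                                telomere_window = 0.1,
                                telomere_mass = 0.9) {
  marker_spacing <- match.arg(marker_spacing)
  stopifnot(n_chromosomes >= 1, markers_per_chromosome >= 2)
  if (!(shared_fraction >= 0 && shared_fraction <= 1)) {
    stop("shared_fraction must lie in [0, 1]")
  }
  female_lengths_cM <- rep_len(female_lengths_cM, n_chromosomes)
  male_lengths_cM <- rep_len(male_lengths_cM, n_chromosomes)
  if (any(female_lengths_cM <= 0) || any(male_lengths_cM <= 0)) {
    stop("map lengths must be > 0")
  }
  if (!(arm_split > 0 && arm_split < 1)) stop("arm_split must lie in (0, 1)")
  check_telomere_profile(telomere_window, telomere_mass)
  if (!is.null(seed)) set.seed(seed)

  chroms <- sprintf("chr%02d", seq_len(n_chromosomes))
  metacentric <- as.character(metacentric)
  unknown <- setdiff(metacentric, chroms)
  if (length(unknown) > 0L) {
    stop("metacentric chromosome(s) not simulated: ",
         paste(unknown, collapse = ", "))
  }

  # reference karyotype; arm lengths proportional to female map length
  arm_rows <- lapply(seq_along(chroms), function(i) {
    ch <- chroms[i]
    lf <- female_lengths_cM[i]
    if (ch %in% metacentric) {
      data.frame(chromosome = ch, arm = paste0(ch, c("p", "q")),
                 length = c(arm_split, 1 - arm_split) * lf)
    } else {
      data.frame(chromosome = ch, arm = paste0(ch, "q"), length = lf)
    }
  })
  ref_karyotype <- karyotype_from_arms(do.call(rbind, arm_rows),
                                       label = "simulated reference")

  glist <- list()   # per group: data.frame(marker, pos [female cM], shared)
  ginfo <- list()   # per group: list(Lf, Lm, centromere)
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    u <- if (marker_spacing == "even") {
      (seq_len(markers_per_chromosome) - 0.5) / markers_per_chromosome
    } else {
      sort(stats::runif(markers_per_chromosome))
    }
    glist[[ch]] <- data.frame(
      marker = sprintf("%s_m%03d", ch, seq_len(markers_per_chromosome)),
      pos = u * female_lengths_cM[i],
      shared = stats::runif(markers_per_chromosome) < shared_fraction,
      stringsAsFactors = FALSE)
    ginfo[[ch]] <- list(Lf = female_lengths_cM[i], Lm = male_lengths_cM[i],
                        centromere = if (ch %in% metacentric)
                          arm_split * female_lengths_cM[i] else 0)
  }

  assemble <- function(glist, ginfo) {
    dfs <- lapply(names(glist), function(g) {
      d <- glist[[g]]
      o <- order(d$pos)
      d <- d[o, , drop = FALSE]
      inf <- ginfo[[g]]
      u <- d$pos / inf$Lf
      data.frame(marker = d$marker, chromosome = g, u = u,
                 female_cM = d$pos,
                 male_cM = inf$Lm * male_crossover_position_cdf(
                   u, telomere_window, telomere_mass),
                 shared = d$shared, stringsAsFactors = FALSE)
    })
    gi <- data.frame(
      chromosome = names(glist),
      female_length = vapply(ginfo[names(glist)], function(x) x$Lf, 0),
      male_length = vapply(ginfo[names(glist)], function(x) x$Lm, 0),
      centromere_cM = vapply(ginfo[names(glist)], function(x) x$centromere, 0),
      stringsAsFactors = FALSE)
    new_truth_map(do.call(rbind, dfs), gi, telomere_window, telomere_mass)
  }

  reference_all <- assemble(glist, ginfo)
  reference <- reference_all[reference_all$shared, , drop = FALSE]
  reference <- new_truth_map(reference, truth_map_groups(reference_all),
                             telomere_window, telomere_mass)

  query_karyotype <- ref_karyotype
  if (!is.null(events) && length(events) > 0L) {
    for (ev in events) {
      res <- plant_event(glist, ginfo, ev, query_karyotype)
      glist <- res$glist
      ginfo <- res$ginfo
      query_karyotype <- apply_event(query_karyotype, ev)
    }
    attr(query_karyotype, "label") <- "simulated query"
  }
  query <- assemble(glist, ginfo)

  structure(list(reference = reference, query = query,
                 reference_karyotype = ref_karyotype,
                 query_karyotype = query_karyotype,
                 events = events %||% list()),
            class = "truth_sim")
}

# Apply one rearrangement event to the truth-map group structure.  Fragment
# male lengths are split from the parent group proportionally to female
# length, so total male map length is conserved.
plant_event <- function(glist, ginfo, event, karyotype) {
  stopifnot(inherits(event, "rearrangement_event"))
  get_group <- function(name) {
    if (!name %in% names(glist)) {
      stop(sprintf("planted event participant '%s' is not a simulated group", name))
    }
    glist[[name]]
  }
  drop_groups <- function(names_) {
    glist[setdiff(names(glist), names_)]
  }

  type <- event$event_type
  if (type == "robertsonian_fusion") {
    p <- event$participants
    a <- get_group(p[1]); b <- get_group(p[2])
    ia <- ginfo[[p[1]]]; ib <- ginfo[[p[2]]]
    newname <- event$product %||% compose_product_name(p[1], p[2])
    # head to head: proximal (position 0) ends meet at the junction
    a$pos <- ia$Lf - a$pos
    b$pos <- ia$Lf + b$pos
    glist <- drop_groups(p)
    ginfo <- ginfo[setdiff(names(ginfo), p)]
    glist[[newname]] <- rbind(a, b)
    ginfo[[newname]] <- list(Lf = ia$Lf + ib$Lf, Lm = ia$Lm + ib$Lm,
                             centromere = ia$Lf)
  } else if (type == "tandem_fusion") {
    p <- event$participants
    a <- get_group(p[1]); b <- get_group(p[2])
    ia <- ginfo[[p[1]]]; ib <- ginfo[[p[2]]]
    newname <- event$product %||% compose_product_name(p[1], p[2])
    # tail (distal q end of the donor) to head (proximal end of the other)
    b$pos <- ia$Lf + b$pos
    glist <- drop_groups(p)
    ginfo <- ginfo[setdiff(names(ginfo), p)]
    glist[[newname]] <- rbind(a, b)
    ginfo[[newname]] <- list(Lf = ia$Lf + ib$Lf, Lm = ia$Lm + ib$Lm,
                             centromere = ia$centromere)
  } else if (type == "fission") {
    p <- event$participants[1]
    g <- get_group(p); inf <- ginfo[[p]]
    if (inf$centromere <= 0 || inf$centromere >= inf$Lf) {
      stop(sprintf("fission of '%s': group has no interior centromere", p))
    }
    cpos <- inf$centromere
    is_p <- g$pos < cpos
    gp <- g[is_p, , drop = FALSE]; gq <- g[!is_p, , drop = FALSE]
    gp$pos <- cpos - gp$pos          # p arm reversed: centromere at 0
    gq$pos <- gq$pos - cpos
    name_p <- paste0(p, "p"); name_q <- paste0(p, "q")
    glist <- drop_groups(p)
    ginfo <- ginfo[setdiff(names(ginfo), p)]
    frac <- cpos / inf$Lf
    glist[[name_p]] <- gp
    ginfo[[name_p]] <- list(Lf = cpos, Lm = inf$Lm * frac, centromere = 0)
    glist[[name_q]] <- gq
    ginfo[[name_q]] <- list(Lf = inf$Lf - cpos, Lm = inf$Lm * (1 - frac),
                            centromere = 0)
  } else if (type == "whole_arm_translocation") {
    arm <- event$participants[1]
    recipient <- event$participants[2]
    donor <- sub("[pq]$", "", arm)
    which_arm <- substring(arm, nchar(arm))
    if (!which_arm %in% c("p", "q")) {
      stop(sprintf("translocated arm '%s' must end in 'p' or 'q'", arm))
    }
    g <- get_group(donor); inf <- ginfo[[donor]]
    b <- get_group(recipient); ib <- ginfo[[recipient]]
    if (inf$centromere <= 0 || inf$centromere >= inf$Lf) {
      stop(sprintf("translocation from '%s': group has no interior centromere", donor))
    }
    cpos <- inf$centromere
    in_arm <- if (which_arm == "p") g$pos < cpos else g$pos >= cpos
    moved <- g[in_arm, , drop = FALSE]
    resid <- g[!in_arm, , drop = FALSE]
    if (which_arm == "p") {
      L_arm <- cpos                      # distal end already at 0
      resid$pos <- resid$pos - cpos      # residue q arm, centromere at 0
      resid_name <- paste0(donor, "q")
    } else {
      L_arm <- inf$Lf - cpos
      moved$pos <- inf$Lf - moved$pos    # reverse so distal end is at 0
      resid$pos <- cpos - resid$pos      # residue p arm reversed
      resid_name <- paste0(donor, "p")
    }
    newname <- event$product %||% compose_product_name(arm, recipient)
    b$pos <- L_arm + b$pos               # centromere-to-centromere junction
    frac <- L_arm / inf$Lf
    glist <- drop_groups(c(donor, recipient))
    ginfo <- ginfo[setdiff(names(ginfo), c(donor, recipient))]
    glist[[newname]] <- rbind(moved, b)
    ginfo[[newname]] <- list(Lf = L_arm + ib$Lf, Lm = inf$Lm * frac + ib$Lm,
                             centromere = L_arm)
    glist[[resid_name]] <- resid
    ginfo[[resid_name]] <- list(Lf = inf$Lf - L_arm,
                                Lm = inf$Lm * (1 - frac), centromere = 0)
  } else {
    stop("unsupported event type: ", type)
  }
  list(glist = glist, ginfo = ginfo)
}

#' Simulate meioses of one parent
#'
#' Crossover counts per linkage group are Poisson with mean equal to the
#' sex-specific map length in Morgans (no interference); crossover positions
#' are uniform on the sex-specific map coordinate, which for males is
#' equivalent to drawing positions from the telomere-concentrated density on
#' physical coordinates.
#'
#' @param parent_haplotypes 2 x M matrix of phased alleles (rows = the two
#'   haplotypes, columns = markers in `truth_map` row order).
#' @param truth_map a `truth_map` covering the same markers.
#' @param parent_sex `"female"` or `"male"`.
#' @param n number of gametes to draw.
#' @param seed optional RNG seed.
#' @return An `n x M` matrix of gamete alleles with attribute `"origins"`
#'   (matrix of 1/2 haplotype origins, from which crossovers can be counted).
#' @export
simulate_meiosis <- function(parent_haplotypes, truth_map,
                             parent_sex = c("female", "male"),
                             n = 1L, seed = NULL) {
  parent_sex <- match.arg(parent_sex)
  stopifnot(inherits(truth_map, "truth_map"))
  parent_haplotypes <- as.matrix(parent_haplotypes)
  if (nrow(parent_haplotypes) != 2L ||
      ncol(parent_haplotypes) != nrow(truth_map)) {
    stop("parent_haplotypes must be a 2 x n_markers matrix matching truth_map")
  }
  if (!is.null(seed)) set.seed(seed)
  gi <- truth_map_groups(truth_map)
  M <- nrow(truth_map)
  gamete <- matrix(NA_real_, n, M)
  origins <- matrix(NA_integer_, n, M)
  colnames(gamete) <- colnames(origins) <- truth_map$marker
  pos_col <- if (parent_sex == "female") "female_cM" else "male_cM"
  len_col <- if (parent_sex == "female") "female_length" else "male_length"

  for (g in unique(truth_map$chromosome)) {
    jidx <- which(truth_map$chromosome == g)
    mpos <- truth_map[[pos_col]][jidx]
    L <- gi[[len_col]][match(g, gi$chromosome)]
    m <- length(jidx)
    k <- stats::rpois(n, L / 100)
    start <- sample.int(2L, n, replace = TRUE) - 1L
    before <- matrix(0L, n, m)
    total <- sum(k)
    if (total > 0L) {
      mei <- rep.int(seq_len(n), k)
      xpos <- stats::runif(total, 0, L)
      iv <- findInterval(xpos, mpos)            # 0..m crossovers after marker iv
      cnt <- matrix(tabulate((mei - 1L) * (m + 1L) + iv + 1L,
                             nbins = n * (m + 1L)),
                    nrow = n, byrow = TRUE)
      # crossovers strictly before marker j = those with findInterval <= j-1,
      # i.e. the cumulative sum of cnt columns 1..j
      before <- if (m == 1L) {
        cnt[, 1L, drop = FALSE]
      } else {
        t(apply(cnt[, seq_len(m), drop = FALSE], 1L, cumsum))
      }
    }
    orig <- (matrix(start, n, m) + before) %% 2L + 1L
    origins[, jidx] <- orig
    gamete[, jidx] <- matrix(
      parent_haplotypes[cbind(as.vector(orig),
                              rep(jidx, each = n))], n, m)
  }
  attr(gamete, "origins") <- origins
  gamete
}

#' Simulate pedigree SNP genotypes over a truth map
#'
#' Founder haplotypes are drawn in linkage equilibrium with per-marker minor
#' allele frequencies from `maf` (default Uniform(0.1, 0.5)); offspring
#' combine one maternal and one paternal gamete from [simulate_meiosis()].
#' In half-sib families one parent is generated (so the offspring are real
#' mosaics) but its genotypes are withheld from the output matrix and its id
#' is blanked in the pedigree.  Genotypes are unphased 0/1/2 with
#' `missing_rate` masking.
#'
#' @param truth_map a `truth_map` (one population's genome).
#' @param n_families,offspring_per_family pedigree dimensions.
#' @param half_sib_fraction fraction of families with one untyped parent.
#' @param missing_rate genotype missingness rate in `[0, 1]`.
#' @param maf numeric vector of minor allele frequencies (length = markers),
#'   a function of the marker count, or `NULL` for Uniform(0.1, 0.5).
#' @param seed optional RNG seed.
#' @return A list of class `pedigree_genotypes`: `pedigree` (id, sire, dam,
#'   sex, family), `genotypes` (individuals x markers, NA = missing),
#'   `markers`, and `truth` (haplotype origins and parent haplotypes for
#'   validation against the simulation).
#' @export
simulate_pedigree_genotypes <- function(truth_map,
                                        n_families = 40L,
                                        offspring_per_family = 20L,
                                        half_sib_fraction = 0.15,
                                        missing_rate = 0.02,
                                        maf = NULL,
                                        seed = NULL) {
  stopifnot(inherits(truth_map, "truth_map"),
            n_families >= 1, offspring_per_family >= 1)
  if (!(half_sib_fraction >= 0 && half_sib_fraction <= 1) ||
      !(missing_rate >= 0 && missing_rate <= 1)) {
    stop("half_sib_fraction and missing_rate must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  M <- nrow(truth_map)
  p <- if (is.null(maf)) {
    stats::runif(M, 0.1, 0.5)
  } else if (is.function(maf)) {
    maf(M)
  } else {
    rep_len(as.numeric(maf), M)
  }
  if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]")

  fam_ids <- sprintf("fam%03d", seq_len(n_families))
  n_half <- round(half_sib_fraction * n_families)
  half_fams <- if (n_half > 0) sample(fam_ids, n_half) else character(0)

  parent_haps <- list()
  geno_rows <- list()
  ped_rows <- list()
  origin_sire <- list()
  origin_dam <- list()
  off_ids_all <- character(0)

  for (f in fam_ids) {
    sire <- paste0(f, "_S"); dam <- paste0(f, "_D")
    hs <- matrix(stats::rbinom(2L * M, 1L, rep(p, each = 2L)), 2L, M)
    hd <- matrix(stats::rbinom(2L * M, 1L, rep(p, each = 2L)), 2L, M)
    parent_haps[[sire]] <- hs
    parent_haps[[dam]] <- hd
    gs <- simulate_meiosis(hs, truth_map, "male", n = offspring_per_family)
    gd <- simulate_meiosis(hd, truth_map, "female", n = offspring_per_family)
    off <- sprintf("%s_o%03d", f, seq_len(offspring_per_family))
    off_ids_all <- c(off_ids_all, off)
    og <- unclass(gs) + unclass(gd)
    rownames(og) <- off
    origin_sire[[f]] <- structure(attr(gs, "origins"), dimnames = list(off, NULL))
    origin_dam[[f]] <- structure(attr(gd, "origins"), dimnames = list(off, NULL))

    withheld <- if (f %in% half_fams) sample(c("sire", "dam"), 1L) else "none"
    sire_typed <- withheld != "sire"
    dam_typed <- withheld != "dam"
    pg <- rbind(if (sire_typed) matrix(colSums(hs), 1L,
                                       dimnames = list(sire, NULL)),
                if (dam_typed) matrix(colSums(hd), 1L,
                                      dimnames = list(dam, NULL)))
    geno_rows[[f]] <- rbind(pg, og)
    ped_rows[[f]] <- rbind(
      if (sire_typed) data.frame(id = sire, sire = NA, dam = NA,
                                 sex = "male", family = f),
      if (dam_typed) data.frame(id = dam, sire = NA, dam = NA,
                                sex = "female", family = f),
      data.frame(id = off,
                 sire = if (sire_typed) sire else NA_character_,
                 dam = if (dam_typed) dam else NA_character_,
                 sex = NA_character_, family = f))
  }

  genotypes <- do.call(rbind, geno_rows)
  colnames(genotypes) <- truth_map$marker
  storage.mode(genotypes) <- "integer"
  if (missing_rate > 0) {
    mask <- stats::runif(length(genotypes)) < missing_rate
    genotypes[mask] <- NA_integer_
  }
  pedigree <- do.call(rbind, ped_rows)
  rownames(pedigree) <- NULL

  structure(list(
    pedigree = pedigree,
    genotypes = genotypes,
    markers = truth_map$marker,
    maf = p,
    truth = list(parent_haplotypes = parent_haps,
                 origin_sire = do.call(rbind, origin_sire),
                 origin_dam = do.call(rbind, origin_dam),
                 half_sib_families = half_fams),
    truth_map = truth_map
  ), class = "pedigree_genotypes")
}

#' @export
print.pedigree_genotypes <- function(x, ...) {
  cat(sprintf("Pedigree genotypes: %d individuals x %d markers, %d families (%d half-sib)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$pedigree$family)),
              length(x$truth$half_sib_families)))
  invisible(x)
}

#' Check Mendelian consistency of trios
#'
#' For every offspring genotype with at least one typed parent, checks that
#' the genotype is reachable from the parental genotypes.  Used as an
#' invariant on the simulator and as a sanity check on input data.
#'
#' @param pg a `pedigree_genotypes` object.
#' @return Fraction of checkable (non-missing) offspring genotype calls that
#'   are Mendelian-consistent.
#' @export
check_mendelian <- function(pg) {
  stopifnot(inherits(pg, "pedigree_genotypes"))
  ped <- pg$pedigree
  g <- pg$genotypes
  off <- ped[!is.na(ped$sire) | !is.na(ped$dam), ]
  n_ok <- 0; n_tot <- 0
  contrib <- function(gp) {
    lo <- ifelse(is.na(gp), 0L, as.integer(gp == 2L))
    hi <- ifelse(is.na(gp), 1L, as.integer(gp >= 1L))
    list(lo = lo, hi = hi)
  }
  for (i in seq_len(nrow(off))) {
    go <- g[off$id[i], ]
    gs <- if (!is.na(off$sire[i]) && off$sire[i] %in% rownames(g))
      g[off$sire[i], ] else rep(NA_integer_, length(go))
    gd <- if (!is.na(off$dam[i]) && off$dam[i] %in% rownames(g))
      g[off$dam[i], ] else rep(NA_integer_, length(go))
    cs <- contrib(gs); cd <- contrib(gd)
    ok <- go >= cs$lo + cd$lo & go <= cs$hi + cd$hi
    keep <- !is.na(go)
    n_ok <- n_ok + sum(ok[keep])
    n_tot <- n_tot + sum(keep)
  }
  if (n_tot == 0L) return(NA_real_)
  n_ok / n_tot
}

#' Probe co-location counts for a fusion genotype
#'
#' Abstracts a two-probe FISH experiment on a fusion event: for each
#' individual state it reports how many chromosomes carry both probes
#' together (`co_located`) and how many carry a single probe (`separate`).
#' A fusion heterozygote shows the probes joined on the one fused chromosome
#' and separately on the two unfused homologs.
#'
#' @param states named character vector/list mapping event labels to one of
#'   `"hom_fused"`, `"het"`, `"hom_unfused"`.
#' @return Data frame with columns `event`, `state`, `co_located`,
#'   `separate`.
#' @export
#' @examples
#' simulate_fish_counts(c("ssa26/28" = "het", "ssa08/29" = "hom_unfused"))
simulate_fish_counts <- function(states) {
  states <- unlist(states)
  if (is.null(names(states)) || any(!nzchar(names(states)))) {
    stop("states must be named by event")
  }
  valid <- c("hom_fused", "het", "hom_unfused")
  bad <- setdiff(states, valid)
  if (length(bad) > 0L) {
    stop("invalid state(s): ", paste(unique(bad), collapse = ", "))
  }
  counts <- list(hom_fused = c(2L, 0L), het = c(1L, 2L), hom_unfused = c(0L, 2L))
  out <- data.frame(event = names(states), state = unname(states),
                    co_located = vapply(states, function(s) counts[[s]][1], 0L),
                    separate = vapply(states, function(s) counts[[s]][2], 0L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
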