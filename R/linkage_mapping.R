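# Linkage mapping ------------------------------------------------------------
#
# Two-point linkage from pedigree genotypes.  For every meiosis of a
# heterozygous parent we first deduce, marker by marker, which allele the
# parent transmitted (possible when the offspring is homozygous, or
# heterozygous with a homozygous other parent).  A marker pair then yields
# per-parent counts (r, n): n informative meioses and r recombinants under an
# arbitrary phase assignment.  Because parental phase is unknown, the
# likelihood per parent is the symmetric mixture
#   L(theta) = 0.5 * theta^r (1-theta)^(n-r) + 0.5 * theta^(n-r) (1-theta)^r
# maximized over theta in [0, 0.5] by EM: the E-step weighs the two phases
# from the parent's own offspring, the M-step sets theta to the expected
# recombinant fraction.  Sex-specific estimates use only meioses of parents
# of that sex; ambiguous transmissions (e.g. het x het -> het) are treated as
# uninformative rather than frequency-weighted.

# Deduce transmitted alleles for every meiosis with a typed parent.
# Returns, per sex, a meiosis x marker matrix T in {0, 1, NA} plus an integer
# parent index per row.
build_transmissions <- function(pg) {
  stopifnot(inherits(pg, "pedigree_genotypes"))
  g <- pg$genotypes
  ped <- pg$pedigree
  out <- list()
  for (sex in c("female", "male")) {
    pcol <- if (sex == "male") "sire" else "dam"
    ocol <- if (sex == "male") "dam" else "sire"
    off <- ped[!is.na(ped[[pcol]]) & ped[[pcol]] %in% rownames(g), ]
    if (nrow(off) == 0L) {
      out[[sex]] <- list(T = matrix(NA_integer_, 0L, ncol(g)),
                         parent = integer(0), parent_ids = character(0))
      next
    }
    O <- g[off$id, , drop = FALSE]
    P <- g[off[[pcol]], , drop = FALSE]
    other <- off[[ocol]]
    Q <- matrix(NA_integer_, nrow(off), ncol(g))
    has_other <- !is.na(other) & other %in% rownames(g)
    if (any(has_other)) Q[has_other, ] <- g[other[has_other], , drop = FALSE]
    T <- matrix(NA_integer_, nrow(off), ncol(g))
    T[which(P == 1L & O == 0L)] <- 0L
    T[which(P == 1L & O == 2L)] <- 1L
    T[which(P == 1L & O == 1L & Q == 0L)] <- 1L
    T[which(P == 1L & O == 1L & Q == 2L)] <- 0L
    pid <- match(off[[pcol]], unique(off[[pcol]]))
    out[[sex]] <- list(T = T, parent = pid, parent_ids = unique(off[[pcol]]))
  }
  out$informative_per_marker <-
    colSums(!is.na(out$female$T)) + colSums(!is.na(out$male$T))
  out
}

# Per-parent (r, n) counts for one marker pair within one sex.
pair_counts <- function(trans_sex, j, k) {
  Tj <- trans_sex$T[, j]
  Tk <- trans_sex$T[, k]
  known <- !is.na(Tj) & !is.na(Tk)
  np <- length(trans_sex$parent_ids)
  if (np == 0L || !any(known)) return(list(r = integer(0), n = integer(0)))
  d <- known & (Tj != Tk)
  n <- tabulate(trans_sex$parent[known], nbins = np)
  r <- tabulate(trans_sex$parent[d], nbins = np)
  keep <- n > 0L
  list(r = r[keep], n = n[keep])
}

# Sex-specific estimates rest on few parents; a parent contributing fewer
# informative meioses than this cannot have its phase resolved two-point
# and its mixture contribution is pure noise, so it is excluded from the
# sex-specific (but not the pooled) estimates.
MIN_PHASE_MEIOSES <- 5L

filter_phaseable <- function(counts, min_n = MIN_PHASE_MEIOSES) {
  keep <- counts$n >= min_n
  list(r = counts$r[keep], n = counts$n[keep])
}

# Observed-data log-likelihood of the phase-mixture model.
phase_mixture_loglik <- function(theta, r, n) {
  theta <- min(max(theta, 1e-9), 1 - 1e-9)
  l1 <- r * log(theta) + (n - r) * log1p(-theta)
  l2 <- (n - r) * log(theta) + r * log1p(-theta)
  hi <- pmax(l1, l2)
  sum(log(0.5) + hi + log1p(exp(-abs(l1 - l2))))
}

# EM for the recombination fraction on per-parent counts.  The iteration
# trace (used by the monotonicity tests) is only recorded on request.
em_theta <- function(r, n, init = 0.25, tol = 1e-6, max_iter = 200L,
                     trace = FALSE) {
  N <- sum(n)
  if (N == 0L) {
    return(list(theta = 0.5, loglik = 0, lod = 0, trace = numeric(0),
                n_meioses = 0L, iterations = 0L))
  }
  theta <- init
  keep_trace <- isTRUE(trace)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    if (keep_trace) trace <- c(trace, phase_mixture_loglik(theta, r, n))
    th <- min(max(theta, 1e-9), 1 - 1e-9)
    l1 <- r * log(th) + (n - r) * log1p(-th)
    l2 <- (n - r) * log(th) + r * log1p(-th)
    w <- 1 / (1 + exp(l2 - l1))               # posterior of the phase behind l1
    exp_rec <- sum(w * r + (1 - w) * (n - r))
    theta_new <- min(exp_rec / N, 0.5)
    done <- abs(theta_new - theta) < tol
    theta <- theta_new
    if (done) break
  }
  ll <- phase_mixture_loglik(theta, r, n)
  ll0 <- phase_mixture_loglik(0.5, r, n)
  if (ll0 >= ll) {
    # the maximum sits on the boundary; EM only approaches it asymptotically
    theta <- 0.5
    ll <- ll0
  }
  if (keep_trace) trace <- c(trace, ll)
  list(theta = theta, loglik = ll, lod = max((ll - ll0) / log(10), 0),
       trace = trace, n_meioses = N, iterations = it)
}

#' Two-point recombination fraction between two markers
#'
#' Maximum-likelihood recombination fraction by EM over unknown parental
#' phases (see the package vignette for the model).  The combined estimate
#' pools the meioses of all doubly-informative parents; `theta_female` /
#' `theta_male` use dam / sire meioses only.  A pair with no informative
#' meioses returns `theta = 0.5` with `lod = 0` rather than an error.
#'
#' @param pg a `pedigree_genotypes` object.
#' @param marker1,marker2 marker ids.
#' @param trans optional precomputed transmissions (internal reuse).
#' @param tol,max_iter EM convergence controls.
#' @return A list of class `two_point_estimate`: `theta`, `theta_female`,
#'   `theta_male`, `lod`, `n_female`, `n_male`, `n_meioses`, and the EM
#'   log-likelihood `trace`.
#' @export
estimate_theta <- function(pg, marker1, marker2, trans = NULL,
                           tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(pg, "pedigree_genotypes"))
  j <- match(marker1, pg$markers)
  k <- match(marker2, pg$markers)
  if (is.na(j)) stop(sprintf("unknown marker id '%s'", marker1))
  if (is.na(k)) stop(sprintf("unknown marker id '%s'", marker2))
  if (is.null(trans)) trans <- build_transmissions(pg)
  cf <- pair_counts(trans$female, j, k)
  cm <- pair_counts(trans$male, j, k)
  fit <- em_theta(c(cf$r, cm$r), c(cf$n, cm$n), tol = tol, max_iter = max_iter,
                  trace = TRUE)
  ff <- filter_phaseable(cf)
  fm <- filter_phaseable(cm)
  fit_f <- em_theta(ff$r, ff$n, tol = tol, max_iter = max_iter)
  fit_m <- em_theta(fm$r, fm$n, tol = tol, max_iter = max_iter)
  structure(list(marker1 = marker1, marker2 = marker2,
                 theta = fit$theta, theta_female = fit_f$theta,
                 theta_male = fit_m$theta, lod = fit$lod,
                 n_female = sum(ff$n), n_male = sum(fm$n),
                 n_meioses = fit$n_meioses, trace = fit$trace),
            class = "two_point_estimate")
}

#' @export
print.two_point_estimate <- function(x, ...) {
  cat(sprintf("theta(%s, %s) = %.4f (female %.4f / male %.4f), LOD %.2f, n = %d\n",
              x$marker1, x$marker2, x$theta, x$theta_female, x$theta_male,
              x$lod, x$n_meioses))
  invisible(x)
}

#' All-pairs two-point linkage with conservative screening
#'
#' Computes exact EM estimates for every marker pair that survives a cheap
#' phase-best screen.  The screen accumulates, over parents, the per-parent
#' best-phase recombinant counts `min(r, n - r)`; pairs whose pooled
#' best-phase recombination fraction exceeds `screen_theta_max` are far from
#' linkage and are omitted (the estimate collection is sparse, which the
#' grouping step accepts).  Linked pairs are never screened out: the
#' best-phase fraction is a lower bound on the EM estimate.
#'
#' @param pg a `pedigree_genotypes` object.
#' @param screen_theta_max pairs with pooled best-phase recombination
#'   fraction above this are skipped.
#' @param tol,max_iter EM controls.
#' @return A list with `estimates` (data frame: marker1, marker2, theta,
#'   theta_female, theta_male, lod, n_female, n_male), the transmissions
#'   `trans`, and `markers`.
#' @export
pairwise_linkage <- function(pg, screen_theta_max = 0.35,
                             tol = 1e-6, max_iter = 200L) {
  stopifnot(inherits(pg, "pedigree_genotypes"))
  trans <- build_transmissions(pg)
  M <- length(pg$markers)
  Rmin <- matrix(0, M, M)
  N <- matrix(0, M, M)
  for (sex in c("female", "male")) {
    ts <- trans[[sex]]
    if (length(ts$parent) == 0L) next
    for (p in seq_along(ts$parent_ids)) {
      Tp <- ts$T[ts$parent == p, , drop = FALSE]
      known <- !is.na(Tp)
      A <- (Tp == 1L) & known
      B <- (Tp == 0L) & known
      storage.mode(A) <- "double"; storage.mode(B) <- "double"
      n_p <- crossprod(A + B)
      r_p <- crossprod(A, B)
      r_p <- r_p + t(r_p)
      Rmin <- Rmin + pmin(r_p, n_p - r_p)
      N <- N + n_p
    }
  }
  cand <- which(upper.tri(N) & N > 0 & (Rmin / pmax(N, 1)) <= screen_theta_max,
                arr.ind = TRUE)
  est <- estimate_pairs(pg, trans, cand[, 1L], cand[, 2L],
                        tol = tol, max_iter = max_iter)
  list(estimates = est, trans = trans, markers = pg$markers)
}

# Exact EM estimates for a vector of marker-index pairs.  Sex-specific
# estimates (needed only for adjacent pairs when building maps) are
# computed when `sexes = TRUE`; the pooled estimate and LOD always are.
estimate_pairs <- function(pg, trans, jj, kk, tol = 1e-6, max_iter = 200L,
                           sexes = FALSE) {
  n_pairs <- length(jj)
  theta <- lod <- numeric(n_pairs)
  theta_f <- theta_m <- rep(NA_real_, n_pairs)
  n_f <- n_m <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    cf <- pair_counts(trans$female, jj[i], kk[i])
    cm <- pair_counts(trans$male, jj[i], kk[i])
    fit <- em_theta(c(cf$r, cm$r), c(cf$n, cm$n), tol = tol,
                    max_iter = max_iter)
    theta[i] <- fit$theta
    lod[i] <- fit$lod
    if (sexes) {
      ff <- filter_phaseable(cf)
      fm <- filter_phaseable(cm)
      theta_f[i] <- em_theta(ff$r, ff$n, tol = tol, max_iter = max_iter)$theta
      theta_m[i] <- em_theta(fm$r, fm$n, tol = tol, max_iter = max_iter)$theta
      n_f[i] <- sum(ff$n)
      n_m[i] <- sum(fm$n)
    } else {
      n_f[i] <- sum(cf$n)
      n_m[i] <- sum(cm$n)
    }
  }
  data.frame(marker1 = pg$markers[jj], marker2 = pg$markers[kk],
             theta = theta, theta_female = theta_f, theta_male = theta_m,
             lod = lod, n_female = n_f, n_male = n_m,
             stringsAsFactors = FALSE)
}

#' Partition markers into linkage groups
#'
#' Single-linkage transitive closure over marker pairs with `lod >=
#' lod_threshold`.  Deterministic: groups are sorted by decreasing size, then
#' by their lexicographically first marker, and renamed `LG01`, `LG02`, ...
#'
#' @param estimates data frame as returned by [pairwise_linkage()] (sparse
#'   collections are fine).
#' @param lod_threshold LOD score required for an edge (default 10; see the vignette).
#' @param markers optional character vector of all markers considered, so
#'   that markers absent from `estimates` are reported as singletons.
#' @return A list with `groups` (named list of marker id vectors) and
#'   `singletons` (markers in no group of size >= 2).
#' @export
group_markers <- function(estimates, lod_threshold = 10, markers = NULL) {
  if (is.null(markers)) {
    markers <- unique(c(estimates$marker1, estimates$marker2))
  }
  if (length(markers) == 0L) {
    return(list(groups = list(), singletons = character(0)))
  }
  edges <- estimates[estimates$lod >= lod_threshold, c("marker1", "marker2"),
                     drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = markers))
  comp <- igraph::components(g)
  member <- split(markers, comp$membership[markers])
  sizes <- lengths(member)
  singles <- unlist(member[sizes == 1L], use.names = FALSE)
  groups <- member[sizes >= 2L]
  if (length(groups) > 0L) {
    first <- vapply(groups, function(m) sort(m)[1L], "")
    ord <- order(-lengths(groups), first)
    groups <- groups[ord]
    # keep markers in input order within each group
    groups <- lapply(groups, function(m) markers[markers %in% m])
    names(groups) <- sprintf("LG%02d", seq_along(groups))
  } else {
    groups <- list()
  }
  list(groups = groups, singletons = sort(singles %||% character(0)))
}

#' Order the markers of one linkage group
#'
#' Seriation minimizing the sum of adjacent recombination fractions: markers
#' are first collapsed into co-segregating bins (transitive closure of pairs
#' with `theta <= theta_zero`), a greedy nearest-neighbour chain is grown
#' from one endpoint of the most distal bin pair, and 2-opt segment reversals
#' are applied until no improvement.  Within a bin the data carry no order
#' information, so bin members are ordered by `reference_order` when
#' supplied, else by input order.  When a reference is supplied the whole
#' order is also flipped, if needed, so shared-marker positions correlate
#' positively with the reference.
#'
#' @param group character vector of marker ids.
#' @param estimates estimate data frame ([pairwise_linkage()]); pairs absent
#'   from it are treated as unlinked (`theta = 0.5`).
#' @param reference_order optional character vector of marker ids in
#'   reference order (used for bin tie-breaking and orientation).
#' @param theta_zero recombination fraction at or below which two markers
#'   co-segregate.
#' @return Character vector: the group's markers in map order.
#' @export
order_markers <- function(group, estimates, reference_order = NULL,
                          theta_zero = 1e-6) {
  if (length(group) == 0L) stop("group must contain at least one marker")
  if (length(group) == 1L) return(group)

  m <- length(group)
  th <- matrix(0.5, m, m, dimnames = list(group, group))
  nn <- matrix(0, m, m)
  diag(th) <- 0
  sel <- estimates$marker1 %in% group & estimates$marker2 %in% group
  es <- estimates[sel, , drop = FALSE]
  if (nrow(es) > 0L) {
    i1 <- match(es$marker1, group); i2 <- match(es$marker2, group)
    th[cbind(i1, i2)] <- es$theta
    th[cbind(i2, i1)] <- es$theta
    n_pair <- es$n_female + es$n_male
    nn[cbind(i1, i2)] <- n_pair
    nn[cbind(i2, i1)] <- n_pair
  }

  # co-segregating bins: theta of (essentially) zero backed by enough
  # meioses, including female ones -- male meioses cannot separate interior
  # markers at any distance, so a handful of them must not merge a bin
  zi <- es$theta <= theta_zero & es$n_female >= 10L &
    (es$n_female + es$n_male) >= 20L
  g <- igraph::graph_from_data_frame(
    data.frame(from = es$marker1[zi], to = es$marker2[zi]),
    directed = FALSE, vertices = data.frame(name = group))
  bin_of <- igraph::components(g)$membership[group]
  bins <- split(group, bin_of)
  names(bins) <- vapply(bins, function(x) sort(x)[1L], "")
  bins <- bins[order(names(bins))]
  nb <- length(bins)

  if (nb > 1L) {
    # bin-level distances: mean available theta between members, plus the
    # total meiosis support behind each bin pair
    bth <- matrix(0.5, nb, nb)
    bnn <- matrix(0, nb, nb)
    for (a in seq_len(nb - 1L)) {
      ia <- match(bins[[a]], group)
      for (b in (a + 1L):nb) {
        ib <- match(bins[[b]], group)
        bth[a, b] <- bth[b, a] <- mean(th[ia, ib, drop = FALSE])
        bnn[a, b] <- bnn[b, a] <- sum(nn[ia, ib, drop = FALSE])
      }
    }
    diag(bth) <- 0
    ref_init <- NULL
    if (!is.null(reference_order)) {
      # published-order start: bins sorted by the minimum reference
      # position of their members (reference-free bins last, input order);
      # the data objective still decides between this and the data-driven
      # starts after polishing
      ref_pos <- vapply(bins, function(mm) {
        p <- match(mm, reference_order)
        if (all(is.na(p))) Inf else min(p, na.rm = TRUE)
      }, 0)
      ref_init <- order(ref_pos, match(names(bins), names(bins)))
    }
    ord <- seriate_bins(bth, names(bins), ref_init = ref_init,
                        support = bnn)
    bins <- bins[ord]
  }

  out <- unlist(lapply(bins, function(members) {
    if (length(members) == 1L) return(members)
    if (!is.null(reference_order)) {
      pos <- match(members, reference_order)
      members[order(is.na(pos), pos, match(members, group))]
    } else {
      members[order(match(members, group))]
    }
  }), use.names = FALSE)

  if (!is.null(reference_order)) {
    pos <- match(out, reference_order)
    keep <- !is.na(pos)
    if (sum(keep) >= 2L) {
      rho <- stats::cor(seq_along(out)[keep], pos[keep], method = "spearman")
      if (!is.na(rho) && rho < 0) out <- rev(out)
    }
  }
  out
}

# Seriation of co-segregating bins.  Two-point estimates are only reliable
# at short range (distant pairs saturate near theta = 0.5 and their
# phase-mixture estimates are biased), so the global layout is built from
# shortest-path (additive) distances over the graph of short, reliable
# links, embedded on one principal coordinate; a greedy nearest-neighbour
# chain from the most distal pair is kept as an alternative start.  Both
# orders are polished by 2-opt segment reversals on the sum of adjacent
# thetas and the better result is kept.
seriate_bins <- function(bth, labels, reliable_theta = 0.2,
                         ref_init = NULL, support = NULL,
                         min_support = 40) {
  nb <- nrow(bth)
  if (nb <= 2L) return(order(labels)[seq_len(nb)])
  d <- -50 * log(1 - 2 * pmin(bth, 0.49))
  diag(d) <- 0
  pc_order <- tryCatch({
    w <- d
    w[bth > reliable_theta] <- NA
    # a short-range link needs real meiosis support: small-sample
    # phase-mixture estimates near zero would otherwise create spurious
    # shortcuts that fold the embedding
    if (!is.null(support)) w[support < min_support] <- NA
    g <- igraph::graph_from_adjacency_matrix(
      ifelse(is.na(w), 0, pmax(w, 1e-6)), mode = "undirected",
      weighted = TRUE, diag = FALSE)
    sp <- igraph::distances(g)
    sp[!is.finite(sp)] <- d[!is.finite(sp)]   # disconnected: raw distance
    xy <- stats::cmdscale(sp, k = 1L)
    order(xy[, 1L], labels)
  }, error = function(e) NULL)
  cand <- list(greedy = seriate_chain(bth, labels))
  if (!is.null(pc_order)) cand$pcoa <- pc_order
  if (!is.null(ref_init)) cand$reference <- ref_init
  cand <- lapply(cand, polish_order, d = bth)
  cost <- vapply(cand, function(o) sum(bth[cbind(o[-nb], o[-1L])]), 0)
  best <- cand[[which.min(cost)]]
  # deterministic orientation of the bare chain: smaller label first
  if (match(labels[best[1L]], sort(labels)) >
      match(labels[best[nb]], sort(labels))) best <- rev(best)
  best
}

# Greedy nearest-neighbour chain on a symmetric distance matrix.
# Ties are broken by the lexicographic order of `labels`.
seriate_chain <- function(d, labels) {
  nb <- nrow(d)
  if (nb <= 2L) return(order(labels)[seq_len(nb)])
  lex <- order(labels)
  # start from one endpoint of the most distal pair
  far <- which(d == max(d), arr.ind = TRUE)
  far <- far[order(pmin(match(far[, 1L], lex), match(far[, 2L], lex))), ,
             drop = FALSE]
  current <- far[1L, 1L]
  chain <- current
  remaining <- setdiff(seq_len(nb), current)
  while (length(remaining) > 0L) {
    dd <- d[current, remaining]
    best <- remaining[which(dd == min(dd))]
    nxt <- best[order(match(best, lex))][1L]
    chain <- c(chain, nxt)
    remaining <- setdiff(remaining, nxt)
    current <- nxt
  }
  chain
}

# Local search: alternate 2-opt segment reversals and or-opt single-element
# relocations until neither improves the sum of adjacent distances.
polish_order <- function(chain, d) {
  repeat {
    c2 <- two_opt(chain, d)
    c3 <- or_opt(c2, d)
    if (identical(c3, chain)) return(c3)
    chain <- c3
  }
}

# or-opt: relocate segments of length 1..max_seg (either orientation) to
# their best position elsewhere in the chain.  Catches displaced runs that
# 2-opt segment reversal cannot repair.
or_opt <- function(chain, d, max_seg = 4L) {
  nb <- length(chain)
  if (nb <= 3L) return(chain)
  path_cost <- function(o) sum(d[cbind(o[-length(o)], o[-1L])])
  improved <- TRUE
  guard <- 0L
  while (improved && guard < 50L) {
    improved <- FALSE
    guard <- guard + 1L
    base <- path_cost(chain)
    for (L in seq_len(min(max_seg, nb - 2L))) {
      i <- 1L
      while (i + L - 1L <= nb) {
        seg <- chain[i:(i + L - 1L)]
        rest <- chain[-(i:(i + L - 1L))]
        nr <- length(rest)
        cost_rest <- path_cost(rest)
        # try every insertion slot (0 = before the first element)
        best_cost <- base
        best <- NULL
        for (j in 0:nr) {
          lft <- if (j >= 1L) rest[j] else NA
          rgt <- if (j < nr) rest[j + 1L] else NA
          gap <- if (!is.na(lft) && !is.na(rgt)) d[lft, rgt] else 0
          for (orient in 1:2) {
            s <- if (orient == 1L) seg else rev(seg)
            add <- (if (!is.na(lft)) d[lft, s[1L]] else 0) +
              (if (!is.na(rgt)) d[s[L], rgt] else 0)
            cand_cost <- cost_rest - gap + add +
              (if (L > 1L) sum(d[cbind(s[-L], s[-1L])]) else 0)
            if (cand_cost < best_cost - 1e-12) {
              best_cost <- cand_cost
              best <- append(rest, s, after = j)
            }
          }
        }
        if (!is.null(best)) {
          chain <- best
          base <- best_cost
          improved <- TRUE
        } else {
          i <- i + 1L
        }
      }
    }
  }
  chain
}

# 2-opt: reverse segments while the sum of adjacent distances decreases.
two_opt <- function(chain, d) {
  nb <- length(chain)
  if (nb <= 2L) return(chain)
  improved <- TRUE
  guard <- 0L
  while (improved && guard < 200L) {
    improved <- FALSE
    guard <- guard + 1L
    for (a in 1:(nb - 1L)) {
      for (b in (a + 1L):nb) {
        left <- if (a > 1L) d[chain[a - 1L], chain[a]] else 0
        right <- if (b < nb) d[chain[b], chain[b + 1L]] else 0
        new_left <- if (a > 1L) d[chain[a - 1L], chain[b]] else 0
        new_right <- if (b < nb) d[chain[a], chain[b + 1L]] else 0
        if (new_left + new_right < left + right - 1e-12) {
          chain[a:b] <- rev(chain[a:b])
          improved <- TRUE
        }
      }
    }
  }
  chain
}

#' Convert a recombination fraction to map distance
#'
#' Haldane: `d = -50 * ln(1 - 2 theta)`; Kosambi:
#' `d = 25 * ln((1 + 2 theta) / (1 - 2 theta))` (cM).
#'
#' @param theta recombination fraction(s) in `[0, 0.5)`.
#' @param mapping_function `"haldane"` or `"kosambi"`.
#' @return Distance(s) in centimorgans.
#' @export
map_distance_cM <- function(theta, mapping_function = c("kosambi", "haldane")) {
  mapping_function <- match.arg(mapping_function)
  if (any(theta < 0 | theta >= 0.5)) {
    stop("theta must lie in [0, 0.5) for a finite map distance")
  }
  switch(mapping_function,
         haldane = -50 * log(1 - 2 * theta),
         kosambi = 25 * log((1 + 2 * theta) / (1 - 2 * theta)))
}

#' Build the map-table rows of one ordered linkage group
#'
#' Converts sex-specific recombination fractions into cM positions with the
#' chosen map function.  Positions are fitted by inverse-variance weighted
#' least squares over every adequately supported pair available in
#' `estimates` (not just adjacent ones), with non-negative inter-marker
#' gaps; when only adjacent-pair estimates are supplied this reduces
#' exactly to the cumulative sum of adjacent distances.  Pooling bracketing
#' pairs stops the map-length inflation that adjacent-only accumulation
#' suffers when single estimates are noisy.  An adjacent *combined*
#' recombination fraction of 0.5 resting on at least 20 informative
#' meioses means the ordering/grouping was inconsistent and raises an
#' error; an interval with no usable information contributes zero length.
#'
#' @param ordered_markers markers in map order ([order_markers()]).
#' @param estimates estimate data frame covering at least the adjacent
#'   pairs (sex-specific columns may be `NA` for pairs estimated without
#'   them).
#' @param mapping_function `"kosambi"` (default) or `"haldane"`.
#' @param group_name linkage-group label for the rows.
#' @param n_meioses optional named vector of informative meiosis counts.
#' @param population_specific optional named logical: markers absent from
#'   the comparison population's map.
#' @param accession optional named character of marker accessions.
#' @return Data frame with the map-table columns (`marker_id`,
#'   `linkage_group`, `order_index`, `female_cM`, `male_cM`, `n_meioses`,
#'   `accession`, `population_specific`).
#' @export
build_map <- function(ordered_markers, estimates,
                      mapping_function = c("kosambi", "haldane"),
                      group_name = "LG01", n_meioses = NULL,
                      population_specific = NULL, accession = NULL) {
  mapping_function <- match.arg(mapping_function)
  k <- length(ordered_markers)
  if (k == 0L) stop("ordered_markers is empty")
  d_f <- d_m <- numeric(0)
  if (k > 1L) {
    key_fwd <- paste(ordered_markers[-k], ordered_markers[-1L])
    key_rev <- paste(ordered_markers[-1L], ordered_markers[-k])
    ekey <- paste(estimates$marker1, estimates$marker2)
    idx <- match(key_fwd, ekey)
    idx[is.na(idx)] <- match(key_rev, ekey)[is.na(idx)]
    if (anyNA(idx)) {
      stop("no estimate available for adjacent pair ",
           key_fwd[which(is.na(idx))[1L]],
           " (ordering/grouping inconsistency)")
    }
    adj <- estimates[idx, ]
    n_adj <- adj$n_female + adj$n_male
    unlinked <- adj$theta >= 0.5 - 1e-9
    if (any(unlinked & n_adj >= 20L)) {
      bad <- which(unlinked & n_adj >= 20L)[1L]
      stop(sprintf("adjacent markers %s / %s are unlinked (theta = 0.5): ordering/grouping inconsistency",
                   adj$marker1[bad], adj$marker2[bad]))
    }
    # all within-group pairs feed the weighted gap fit; duplicated pair
    # rows keep their first occurrence (sexed estimates are placed first)
    sel <- estimates$marker1 %in% ordered_markers &
      estimates$marker2 %in% ordered_markers
    es <- estimates[sel, , drop = FALSE]
    ia <- match(es$marker1, ordered_markers)
    ib <- match(es$marker2, ordered_markers)
    swap <- ia > ib
    tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
    keep <- ia != ib & !duplicated(paste(ia, ib))
    es <- es[keep, , drop = FALSE]
    ia <- ia[keep]; ib <- ib[keep]
    d_f <- fit_gap_distances(k, ia, ib, es$theta_female, es$n_female,
                             es$theta, mapping_function)
    d_m <- fit_gap_distances(k, ia, ib, es$theta_male, es$n_male,
                             es$theta, mapping_function)
  }
  nm <- if (is.null(n_meioses)) rep(0L, k) else {
    v <- n_meioses[ordered_markers]; v[is.na(v)] <- 0L; as.integer(v)
  }
  ps <- if (is.null(population_specific)) rep(FALSE, k) else {
    v <- population_specific[ordered_markers]; v[is.na(v)] <- FALSE; as.logical(v)
  }
  acc <- if (is.null(accession)) rep("", k) else {
    v <- accession[ordered_markers]; v[is.na(v)] <- ""; as.character(v)
  }
  data.frame(marker_id = ordered_markers,
             linkage_group = group_name,
             order_index = seq_len(k),
             female_cM = cumsum(c(0, d_f)),
             male_cM = cumsum(c(0, d_m)),
             n_meioses = nm,
             accession = acc,
             population_specific = ps,
             stringsAsFactors = FALSE)
}

# Profile-consistency QC on near-zero estimates.  If markers a and b are
# truly co-located, their recombination fractions to every third marker
# must agree; a near-zero estimate whose profiles disagree is a
# small-sample artefact (P(zero recombinants) is not negligible at a few
# dozen meioses) and would otherwise create false co-segregation bins,
# false adjacencies and compressed position fits.  Returns row indices of
# `estimates` (restricted to `group`) that should be discarded.
flag_inconsistent_pairs <- function(group, estimates, theta_max = 0.1,
                                    profile_tol = 0.12, min_common = 5L) {
  m <- length(group)
  th <- matrix(0.5, m, m)
  avail <- matrix(FALSE, m, m)
  sel <- which(estimates$marker1 %in% group & estimates$marker2 %in% group)
  if (length(sel) == 0L) return(integer(0))
  i1 <- match(estimates$marker1[sel], group)
  i2 <- match(estimates$marker2[sel], group)
  th[cbind(i1, i2)] <- th[cbind(i2, i1)] <- estimates$theta[sel]
  avail[cbind(i1, i2)] <- avail[cbind(i2, i1)] <- TRUE
  bad <- logical(length(sel))
  cand <- which(estimates$theta[sel] <= theta_max)
  for (ci in cand) {
    a <- i1[ci]; b <- i2[ci]
    cols <- which(avail[a, ] & avail[b, ])
    cols <- setdiff(cols, c(a, b))
    if (length(cols) < min_common) next
    v <- mean(abs(th[a, cols] - th[b, cols]))
    if (v > profile_tol) bad[ci] <- TRUE
  }
  sel[bad]
}

# Weighted non-negative least-squares fit of inter-marker gaps for one sex.
#
# Observations are pair distances d(ia, ib) = sum of the gaps between the
# two markers.  A sex-specific estimate is usable when it exists, rests on
# at least 25 informative meioses of phaseable parents, and is compatible
# with linkage (theta < 0.35); weakly informed *adjacent* pairs fall back
# to the pooled-sex estimate (capped, low weight) so that every interval
# can be covered.  Weights are inverse delta-method variances of the
# mapped distance.  Solved by cyclic coordinate descent with gaps clamped
# at zero; with only adjacent observations the solution is exactly the
# adjacent distances.
fit_gap_distances <- function(k, ia, ib, theta_sex, n_sex, theta_comb,
                              mapping_function) {
  usable <- !is.na(theta_sex) & n_sex >= 25L & theta_sex < 0.35
  th <- theta_sex[usable]
  nn <- n_sex[usable]
  oa <- ia[usable]; ob <- ib[usable]
  # fallback pseudo-observations for uncovered adjacent pairs
  adj_missing <- which(ib == ia + 1L & !usable)
  if (length(adj_missing) > 0L) {
    th <- c(th, pmin(theta_comb[adj_missing], 0.35))
    nn <- c(nn, rep(10, length(adj_missing)))
    oa <- c(oa, ia[adj_missing]); ob <- c(ob, ib[adj_missing])
  }
  if (length(th) == 0L) return(rep(0, k - 1L))
  th <- pmin(th, 0.4499)
  d <- map_distance_cM(th, mapping_function)
  deriv <- switch(mapping_function,
                  haldane = 100 / (1 - 2 * th),
                  kosambi = 100 / (1 - 4 * th^2))
  # theta floored in the variance so that downward fluctuations of small
  # estimates do not earn outsized weight (which would bias lengths down)
  th_var <- pmax(th, 0.02)
  w <- nn / (deriv^2 * (th_var * (1 - th_var) + 1e-4))

  g <- rep(0, k - 1L)
  adj_obs <- which(ob == oa + 1L)
  g[oa[adj_obs]] <- d[adj_obs]
  cover <- lapply(seq_len(k - 1L), function(i) which(oa <= i & ob > i))
  for (sweep in seq_len(100L)) {
    changed <- FALSE
    P <- cumsum(c(0, g))
    for (i in seq_len(k - 1L)) {
      cv <- cover[[i]]
      if (length(cv) == 0L) next
      pred <- P[ob[cv]] - P[oa[cv]]
      delta <- sum(w[cv] * (d[cv] - pred)) / sum(w[cv])
      g_new <- max(0, g[i] + delta)
      if (abs(g_new - g[i]) > 1e-8) {
        shift <- g_new - g[i]
        g[i] <- g_new
        P[(i + 1L):k] <- P[(i + 1L):k] + shift
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  g
}

#' Summarize a linkage-map table
#'
#' @param map a map table (see [build_map()] / [read_map_table()]).
#' @return List with `n_markers`, `n_groups`, `female_length_cM` and
#'   `male_length_cM` (sums of per-group maxima), `n_population_specific`
#'   and `n_shared`.
#' @export
map_summary <- function(map) {
  if (is.null(map) || nrow(map) == 0L) {
    return(list(n_markers = 0L, n_groups = 0L, female_length_cM = 0,
                male_length_cM = 0, n_population_specific = 0L,
                n_shared = 0L))
  }
  fl <- tapply(map$female_cM, map$linkage_group, max)
  ml <- tapply(map$male_cM, map$linkage_group, max)
  nps <- sum(map$population_specific)
  list(n_markers = nrow(map),
       n_groups = length(unique(map$linkage_group)),
       female_length_cM = sum(fl),
       male_length_cM = sum(ml),
       n_population_specific = nps,
       n_shared = nrow(map) - nps)
}

#' Full mapping pipeline: genotypes to sex-specific linkage maps
#'
#' Runs [pairwise_linkage()], [group_markers()], completes the estimate set
#' within each group, orders each group with [order_markers()] (using the
#' reference map, when given, for co-segregating bins and orientation) and
#' accumulates positions with [build_map()].
#'
#' @param pg a `pedigree_genotypes` object.
#' @param lod_threshold grouping LOD threshold (default 5).
#' @param mapping_function `"kosambi"` (default) or `"haldane"`.
#' @param reference optional reference map table; its marker order supplies
#'   bin tie-breaking and orientation, and markers absent from it are
#'   flagged population-specific.
#' @param min_group_size groups smaller than this are reported as
#'   singletons, not mapped.
#' @param screen_theta_max see [pairwise_linkage()].
#' @return List of class `linkage_map_result`: `map` (the combined table),
#'   `estimates`, `groups`, `singletons`.
#' @export
build_linkage_maps <- function(pg, lod_threshold = 10,
                               mapping_function = c("kosambi", "haldane"),
                               reference = NULL, min_group_size = 2L,
                               screen_theta_max = 0.35) {
  mapping_function <- match.arg(mapping_function)
  pl <- pairwise_linkage(pg, screen_theta_max = screen_theta_max)
  grp <- group_markers(pl$estimates, lod_threshold, markers = pg$markers)
  groups <- grp$groups
  small <- lengths(groups) < min_group_size
  singletons <- sort(c(grp$singletons, unlist(groups[small], use.names = FALSE)))
  groups <- groups[!small]
  if (length(groups) > 0L) names(groups) <- sprintf("LG%02d", seq_along(groups))

  estimates <- pl$estimates
  ref_order <- if (!is.null(reference)) {
    reference$marker_id[order(reference$linkage_group, reference$order_index)]
  } else NULL
  n_inf <- stats::setNames(pl$trans$informative_per_marker, pg$markers)
  pop_spec <- if (!is.null(reference)) {
    stats::setNames(!(pg$markers %in% reference$marker_id), pg$markers)
  } else NULL

  rows <- list()
  for (gname in names(groups)) {
    members <- groups[[gname]]
    # make sure every within-group pair has an exact estimate
    have <- estimates$marker1 %in% members & estimates$marker2 %in% members
    idx <- match(members, pg$markers)
    all_pairs <- utils::combn(idx, 2L)
    ekey <- paste(estimates$marker1[have], estimates$marker2[have])
    pkey1 <- paste(pg$markers[all_pairs[1L, ]], pg$markers[all_pairs[2L, ]])
    pkey2 <- paste(pg$markers[all_pairs[2L, ]], pg$markers[all_pairs[1L, ]])
    miss <- !(pkey1 %in% ekey) & !(pkey2 %in% ekey)
    if (any(miss)) {
      extra <- estimate_pairs(pg, pl$trans,
                              all_pairs[1L, miss], all_pairs[2L, miss])
      estimates <- rbind(estimates, extra)
    }
    # drop near-zero estimates whose recombination profiles contradict
    # co-location before they can distort ordering, bins or positions
    bad <- flag_inconsistent_pairs(members, estimates)
    est_group <- if (length(bad) > 0L) estimates[-bad, , drop = FALSE] else
      estimates
    ordered <- order_markers(members, est_group, reference_order = ref_order)
    # sex-specific estimates are needed for the position fit: all reliably
    # linked within-group pairs plus every adjacent pair of the final order
    have2 <- est_group$marker1 %in% members & est_group$marker2 %in% members
    near <- est_group[have2 & est_group$theta < 0.30, , drop = FALSE]
    jj <- c(match(near$marker1, pg$markers),
            match(ordered[-length(ordered)], pg$markers))
    kk <- c(match(near$marker2, pg$markers),
            match(ordered[-1L], pg$markers))
    dup <- duplicated(paste(pmin(jj, kk), pmax(jj, kk)))
    sexed <- estimate_pairs(pg, pl$trans, jj[!dup], kk[!dup], sexes = TRUE)
    rows[[gname]] <- build_map(ordered, rbind(sexed, est_group),
                               mapping_function = mapping_function,
                               group_name = gname, n_meioses = n_inf,
                               population_specific = pop_spec)
  }
  map <- if (length(rows) > 0L) do.call(rbind, rows) else
    build_empty_map_table()
  rownames(map) <- NULL
  structure(list(map = map, estimates = estimates, groups = groups,
                 singletons = singletons),
            class = "linkage_map_result")
}

build_empty_map_table <- function() {
  data.frame(marker_id = character(0), linkage_group = character(0),
             order_index = integer(0), female_cM = numeric(0),
             male_cM = numeric(0), n_meioses = integer(0),
             accession = character(0), population_specific = logical(0),
             stringsAsFactors = FALSE)
}

#' @export
print.linkage_map_result <- function(x, ...) {
  s <- map_summary(x$map)
  cat(sprintf("Linkage maps: %d markers on %d groups (%d unplaced); female %.1f cM, male %.1f cM\n",
              s$n_markers, s$n_groups, length(x$singletons),
              s$female_length_cM, s$male_length_cM))
  invisible(x)
}
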