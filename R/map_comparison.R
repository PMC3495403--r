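# Comparative map analysis ---------------------------------------------------
#
# Aligns two linkage-map tables on shared markers, builds a bipartite
# correspondence graph between linkage groups, classifies rearrangement
# events from the component structure, and infers fusion architecture
# (centromere-to-centromere vs tandem) from the male recombination profile:
# a fusion junction that falls in the male-recombination-cold interior while
# both distal ends recombine in males behaves like a centromere.
#
# Orientation convention: position 0 of an acrocentric group is its
# centromeric (proximal) end -- its "head"; the distal telomeric end is the
# "tail".  Events are labelled relative to the reference map A.

#' Match shared markers between two map tables
#'
#' @param mapA,mapB map tables (see [build_map()] / [read_map_table()]).
#' @return List with `shared` (data frame: marker, group/position/order in
#'   each map), `only_a`, `only_b` (marker ids unique to one map).
#' @export
match_shared_markers <- function(mapA, mapB) {
  for (nm in c("A", "B")) {
    m <- if (nm == "A") mapA else mapB
    dup <- m$marker_id[duplicated(m$marker_id)]
    if (length(dup) > 0L) {
      stop(sprintf("duplicate marker id(s) in map %s: %s", nm,
                   paste(unique(dup), collapse = ", ")))
    }
  }
  ids <- intersect(mapA$marker_id, mapB$marker_id)
  ia <- match(ids, mapA$marker_id)
  ib <- match(ids, mapB$marker_id)
  shared <- data.frame(marker = ids,
                       group_a = mapA$linkage_group[ia],
                       pos_a = mapA$female_cM[ia],
                       order_a = mapA$order_index[ia],
                       group_b = mapB$linkage_group[ib],
                       pos_b = mapB$female_cM[ib],
                       order_b = mapB$order_index[ib],
                       stringsAsFactors = FALSE)
  list(shared = shared,
       only_a = setdiff(mapA$marker_id, ids),
       only_b = setdiff(mapB$marker_id, ids))
}

#' Build the linkage-group correspondence graph
#'
#' Bipartite graph between the linkage groups of two maps; an edge connects
#' groups sharing at least `min_shared` markers and carries the shared count
#' and the Spearman rank correlation of the shared-marker positions (its
#' sign is the relative orientation of the two groups).
#'
#' @param pairing result of [match_shared_markers()].
#' @param mapA,mapB the two map tables.
#' @param min_shared minimum shared markers for an edge (default 3).
#' @return A list of class `correspondence_graph`: `edges` (group_a,
#'   group_b, n_shared, rho), `nodes_a`, `nodes_b`, `shared`, `min_shared`.
#' @export
build_correspondence <- function(pairing, mapA, mapB, min_shared = 3L) {
  sh <- pairing$shared
  if (nrow(sh) > 0L) {
    key <- paste(sh$group_a, sh$group_b, sep = "\r")
    cells <- split(sh, key)
    edges <- do.call(rbind, lapply(cells, function(d) {
      data.frame(group_a = d$group_a[1L], group_b = d$group_b[1L],
                 n_shared = nrow(d),
                 rho = if (nrow(d) >= 2L)
                   suppressWarnings(stats::cor(d$pos_a, d$pos_b,
                                               method = "spearman"))
                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    edges <- edges[edges$n_shared >= min_shared, , drop = FALSE]
    rownames(edges) <- NULL
    edges <- edges[order(edges$group_a, edges$group_b), , drop = FALSE]
  } else {
    edges <- data.frame(group_a = character(0), group_b = character(0),
                        n_shared = integer(0), rho = numeric(0))
  }
  structure(list(edges = edges,
                 nodes_a = unique(mapA$linkage_group),
                 nodes_b = unique(mapB$linkage_group),
                 shared = sh, min_shared = min_shared),
            class = "correspondence_graph")
}

#' @export
print.correspondence_graph <- function(x, ...) {
  cat(sprintf("Correspondence graph: %d x %d groups, %d edges (min_shared = %d)\n",
              length(x$nodes_a), length(x$nodes_b), nrow(x$edges),
              x$min_shared))
  invisible(x)
}

new_detected_event <- function(type, reference_groups, query_groups,
                               junction = NULL, orientation = NULL,
                               geometry = "not_applicable",
                               architecture = "undetermined",
                               detail = list()) {
  structure(list(type = type, reference_groups = reference_groups,
                 query_groups = query_groups, junction = junction,
                 orientation = orientation, geometry = geometry,
                 architecture = architecture, detail = detail),
            class = "detected_event")
}

#' @export
print.detected_event <- function(x, ...) {
  cat(sprintf("%s: %s -> %s%s%s%s\n", x$type,
              paste(x$reference_groups, collapse = " + "),
              paste(x$query_groups, collapse = " + "),
              if (!is.null(x$junction))
                sprintf(" junction (%.1f, %.1f) cM", x$junction[1], x$junction[2])
              else "",
              if (x$geometry != "not_applicable") paste0(" ", x$geometry) else "",
              if (x$architecture != "undetermined")
                paste0(" [", x$architecture, "]") else ""))
  invisible(x)
}

# Split an ordered two-label sequence at the cut minimizing misplacements.
# Returns NULL when more than max_interlopers markers sit on the wrong side.
best_two_block_cut <- function(labels, max_interlopers = 5L) {
  n <- length(labels)
  ulab <- unique(labels)
  if (length(ulab) != 2L) return(NULL)
  is1 <- labels == ulab[1L]
  cum1 <- cumsum(is1)
  tot1 <- sum(is1)
  best <- list(cost = Inf)
  for (cut in 0:n) {
    left1 <- if (cut == 0L) 0L else cum1[cut]
    # label 1 left of the cut, label 2 right
    cost_a <- (cut - left1) + (tot1 - left1)
    # label 2 left, label 1 right
    cost_b <- left1 + ((n - cut) - (tot1 - left1))
    if (cost_a < best$cost) best <- list(cost = cost_a, cut = cut,
                                         left = ulab[1L], right = ulab[2L])
    if (cost_b < best$cost) best <- list(cost = cost_b, cut = cut,
                                         left = ulab[2L], right = ulab[1L])
  }
  if (best$cost > max_interlopers || best$cut == 0L || best$cut == n) {
    return(NULL)
  }
  best
}

# Orientation and junction-end type of one reference block inside a query
# group.  rho > 0 means reference position increases along the query group.
block_geometry <- function(pos_a, pos_b, junction_side) {
  rho <- if (length(pos_a) >= 2L)
    suppressWarnings(stats::cor(pos_a, pos_b, method = "spearman")) else NA_real_
  orientation <- if (!is.na(rho) && rho < 0) "reverse" else "forward"
  # junction_side "right": the block's junction end is its max-pos_b end
  at_junction_max_a <- (junction_side == "right") == (orientation == "forward")
  list(orientation = orientation,
       junction_end = if (at_junction_max_a) "tail" else "head",
       rho = rho)
}

#' Classify rearrangement events from the correspondence graph
#'
#' Works per connected component, relative to reference map A:
#' one-to-one components are `conserved`; two A groups joined in one B group
#' with (quasi-)contiguous blocks are a `fusion` with a junction interval and
#' per-block orientation; one A group split over several B groups is a
#' `fission`; one A group split over two B groups where one fragment shares
#' its B group with a second, intact A group is a `translocation_plus_fission`
#' (the pure fragment is the fission residue).  Anything else is `complex` --
#' never an error.  Blocks may carry up to `max_interlopers` misplaced
#' markers, tolerating single-marker ordering noise.
#'
#' @param graph a [build_correspondence()] result.
#' @param mapA,mapB the two map tables.
#' @param max_interlopers misplaced markers tolerated per block boundary.
#' @return List of `detected_event` objects.
#' @export
classify_events <- function(graph, mapA, mapB, max_interlopers = 5L) {
  edges <- graph$edges
  if (nrow(edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("A\r", edges$group_a),
               to = paste0("B\r", edges$group_b)),
    directed = FALSE)
  comp <- igraph::components(g)
  events <- list()
  for (ci in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == ci]
    a_groups <- sort(sub("^A\r", "", nodes[startsWith(nodes, "A\r")]))
    b_groups <- sort(sub("^B\r", "", nodes[startsWith(nodes, "B\r")]))
    ev <- classify_component(a_groups, b_groups, graph, max_interlopers)
    events[[length(events) + 1L]] <- ev
  }
  events[order(vapply(events, function(e) e$reference_groups[1L], ""))]
}

classify_component <- function(a_groups, b_groups, graph, max_interlopers) {
  edges <- graph$edges
  sh <- graph$shared
  # shared markers restricted to pairs that are actual edges
  ekey <- paste(edges$group_a, edges$group_b)
  sh <- sh[paste(sh$group_a, sh$group_b) %in% ekey &
             sh$group_a %in% a_groups & sh$group_b %in% b_groups, ,
           drop = FALSE]

  complex_event <- function(why) {
    new_detected_event("complex", a_groups, b_groups,
                       detail = list(reason = why))
  }

  if (length(a_groups) == 1L && length(b_groups) == 1L) {
    d <- sh
    rho <- if (nrow(d) >= 2L)
      suppressWarnings(stats::cor(d$pos_a, d$pos_b, method = "spearman"))
    else NA_real_
    return(new_detected_event("conserved", a_groups, b_groups,
                              orientation = stats::setNames(
                                if (!is.na(rho) && rho < 0) "reverse" else "forward",
                                a_groups),
                              detail = list(n_shared = nrow(d))))
  }

  if (length(a_groups) == 2L && length(b_groups) == 1L) {
    # co-positioned markers (bins) have no meaningful internal order; sort
    # ties by reference group so they cannot masquerade as interlopers
    d <- sh[order(sh$pos_b, sh$group_a, sh$order_b), , drop = FALSE]
    cut <- best_two_block_cut(d$group_a, max_interlopers)
    if (is.null(cut)) return(complex_event("blocks in the query group are not contiguous"))
    left <- d[d$group_a == cut$left, , drop = FALSE]
    right <- d[d$group_a == cut$right, , drop = FALSE]
    gl <- block_geometry(left$pos_a, left$pos_b, "right")
    gr <- block_geometry(right$pos_a, right$pos_b, "left")
    ends <- c(gl$junction_end, gr$junction_end)
    geometry <- if (all(ends == "head")) "head_to_head"
    else if (all(ends == "tail")) "tail_to_tail"
    else "tail_to_head"
    junction <- c(d$pos_b[cut$cut], d$pos_b[cut$cut + 1L])
    return(new_detected_event(
      "fusion", c(cut$left, cut$right), b_groups,
      junction = junction,
      orientation = stats::setNames(c(gl$orientation, gr$orientation),
                                    c(cut$left, cut$right)),
      geometry = geometry,
      detail = list(junction_ends = stats::setNames(ends, c(cut$left, cut$right)),
                    n_shared = stats::setNames(c(nrow(left), nrow(right)),
                                               c(cut$left, cut$right)))))
  }

  if (length(a_groups) == 1L && length(b_groups) >= 2L) {
    # clean fission: the fragments partition the A group into blocks
    frag_rng <- lapply(b_groups, function(bg) {
      range(sh$pos_a[sh$group_b == bg])
    })
    ord <- order(vapply(frag_rng, function(r) mean(r), 0))
    overlap_markers <- 0L
    for (i in seq_along(ord)[-1L]) {
      hi_prev <- frag_rng[[ord[i - 1L]]][2L]
      lo_this <- frag_rng[[ord[i]]][1L]
      if (lo_this < hi_prev) {
        overlap_markers <- overlap_markers +
          sum(sh$pos_a >= lo_this & sh$pos_a <= hi_prev)
      }
    }
    if (overlap_markers > max_interlopers) {
      return(complex_event("fission fragments overlap on the reference group"))
    }
    return(new_detected_event("fission", a_groups, b_groups[ord],
                              detail = list(fragment_ranges = frag_rng[ord])))
  }

  if (length(a_groups) == 2L && length(b_groups) == 2L) {
    deg_a <- vapply(a_groups, function(a) sum(edges$group_a == a &
                                                edges$group_b %in% b_groups), 0L)
    deg_b <- vapply(b_groups, function(b) sum(edges$group_b == b &
                                                edges$group_a %in% a_groups), 0L)
    if (all(sort(deg_a) == c(1L, 2L)) && all(sort(deg_b) == c(1L, 2L))) {
      donor <- a_groups[deg_a == 2L]       # the A group that was split
      intact <- a_groups[deg_a == 1L]
      product <- b_groups[deg_b == 2L]     # carries fragment + intact group
      residue <- b_groups[deg_b == 1L]
      if (!any(edges$group_a == intact & edges$group_b == product)) {
        return(complex_event("edge pattern does not match a translocation"))
      }
      dp <- sh[sh$group_b == product, , drop = FALSE]
      dp <- dp[order(dp$pos_b, dp$group_a, dp$order_b), , drop = FALSE]
      cut <- best_two_block_cut(dp$group_a, max_interlopers)
      if (is.null(cut)) {
        return(complex_event("blocks in the product group are not contiguous"))
      }
      left <- dp[dp$group_a == cut$left, , drop = FALSE]
      right <- dp[dp$group_a == cut$right, , drop = FALSE]
      gl <- block_geometry(left$pos_a, left$pos_b, "right")
      gr <- block_geometry(right$pos_a, right$pos_b, "left")
      ends <- c(gl$junction_end, gr$junction_end)
      geometry <- if (all(ends == "head")) "head_to_head"
      else if (all(ends == "tail")) "tail_to_tail"
      else "tail_to_head"
      junction <- c(dp$pos_b[cut$cut], dp$pos_b[cut$cut + 1L])
      frag_rng <- range(sh$pos_a[sh$group_a == donor & sh$group_b == product])
      resid_rng <- range(sh$pos_a[sh$group_a == donor & sh$group_b == residue])
      moved_side <- if (mean(frag_rng) < mean(resid_rng)) "low" else "high"
      return(new_detected_event(
        "translocation_plus_fission", c(donor, intact),
        c(product = product, residue = residue),
        junction = junction,
        orientation = stats::setNames(c(gl$orientation, gr$orientation),
                                      c(cut$left, cut$right)),
        geometry = geometry,
        detail = list(donor = donor, intact = intact,
                      moved_side = moved_side,
                      junction_ends = stats::setNames(ends,
                                                      c(cut$left, cut$right)),
                      fragment_range = frag_rng, residue_range = resid_rng)))
    }
    return(complex_event("two-by-two component without a translocation pattern"))
  }

  complex_event(sprintf("component joins %d reference and %d query groups",
                        length(a_groups), length(b_groups)))
}

#' Share of a group's male map length in its terminal windows
#'
#' The terminal windows are the first and last `terminal_fraction` of the
#' group's female span (female positions proxy physical position, since
#' female recombination is evenly distributed).  An adjacent-marker interval
#' contributes its male cM when it overlaps a terminal window.  With dense
#' markers and male recombination proportional to female this tends to
#' `2 * terminal_fraction`; male recombination concentrated at the telomeres
#' drives it towards 1.
#'
#' @param group_rows map-table rows of one linkage group (>= 3 markers).
#' @param terminal_fraction window width as a fraction of the female span.
#' @return Share in `[0, 1]`, or `NA` when the male map length is zero.
#' @export
male_telomere_statistic <- function(group_rows, terminal_fraction = 0.1) {
  if (!(terminal_fraction > 0 && terminal_fraction < 0.5)) {
    stop("terminal_fraction must lie in (0, 0.5)")
  }
  d <- group_rows[order(group_rows$order_index), , drop = FALSE]
  if (nrow(d) < 3L) stop("group must have at least 3 markers")
  total_male <- max(d$male_cM) - min(d$male_cM)
  if (total_male <= 0) return(NA_real_)
  span <- max(d$female_cM) - min(d$female_cM)
  f0 <- min(d$female_cM)
  lo_hi <- f0 + terminal_fraction * span
  hi_lo <- f0 + (1 - terminal_fraction) * span
  f1 <- d$female_cM[-nrow(d)]
  f2 <- d$female_cM[-1L]
  dm <- diff(d$male_cM)
  in_terminal <- (f1 < lo_hi) | (f2 > hi_lo)
  sum(dm[in_terminal]) / total_male
}

#' Infer the architecture of a fusion-like event
#'
#' A fusion junction behaves like a centromere when it is
#' male-recombination-cold (male cM accumulated inside the junction window
#' is below `interior_male_max` of the group's male length) while both
#' distal ends of the fused group recombine in males.  Under that condition,
#' a head-to-head fusion of two acrocentric reference groups is called
#' `centromere_to_centromere`; a tail-to-head fusion whose tail-side
#' participant is metacentric (the centromere donor) is called `tandem`;
#' everything else, or a junction near a male hotspot, is `undetermined`.
#' For a translocation the moved fragment is an arm: its junction end must
#' be the arm's centromeric end and the recipient must be acrocentric.
#'
#' @param event a fusion-like `detected_event`.
#' @param query_map map table of the query population (contains the fused
#'   group).
#' @param reference_classes named character vector of centromere classes
#'   (`"metacentric"` / `"acrocentric"`) for the reference groups, e.g.
#'   `centromere_class(reference_karyotype)`.
#' @param terminal_fraction,junction_window,interior_male_max calibration
#'   thresholds (fractions of female span / male length).
#' @return The architecture label: `"centromere_to_centromere"`,
#'   `"tandem"`, or `"undetermined"`.
#' @export
infer_architecture <- function(event, query_map, reference_classes,
                               terminal_fraction = 0.1,
                               junction_window = 0.1,
                               interior_male_max = 0.15) {
  if (!inherits(event, "detected_event") ||
      !event$type %in% c("fusion", "translocation_plus_fission")) {
    stop("infer_architecture applies to fusion-like events only")
  }
  product <- if (event$type == "fusion") event$query_groups[1L]
  else event$query_groups[["product"]]
  d <- query_map[query_map$linkage_group == product, , drop = FALSE]
  d <- d[order(d$order_index), , drop = FALSE]
  if (nrow(d) < 3L) return("undetermined")
  total_male <- max(d$male_cM) - min(d$male_cM)
  if (total_male <= 0) return("undetermined")
  span <- max(d$female_cM) - min(d$female_cM)
  male_at <- function(f) {
    stats::approx(d$female_cM, d$male_cM, xout = f, ties = max, rule = 2)$y
  }
  jm <- mean(event$junction)
  male_in_window <- male_at(jm + junction_window * span) -
    male_at(jm - junction_window * span)
  f0 <- min(d$female_cM)
  left_male <- male_at(f0 + terminal_fraction * span) - male_at(f0)
  right_male <- male_at(max(d$female_cM)) -
    male_at(f0 + (1 - terminal_fraction) * span)
  cold_junction <- male_in_window < interior_male_max * total_male
  ends_recombine <- left_male > 0 && right_male > 0
  if (!cold_junction || !ends_recombine) return("undetermined")

  cls <- reference_classes[event$reference_groups]
  if (anyNA(cls)) {
    stop("reference_classes must cover: ",
         paste(event$reference_groups, collapse = ", "))
  }
  ends <- event$detail$junction_ends

  if (event$type == "fusion") {
    if (event$geometry == "head_to_head" && all(cls == "acrocentric")) {
      return("centromere_to_centromere")
    }
    if (event$geometry == "tail_to_head" && sum(cls == "metacentric") == 1L) {
      tail_group <- names(ends)[ends == "tail"]
      if (length(tail_group) == 1L &&
          cls[tail_group] == "metacentric") {
        return("tandem")
      }
    }
    return("undetermined")
  }

  # translocation: the fragment's centromeric end is the end nearest the
  # centromere of the donor metacentric (the high end of a low/"p" fragment)
  donor <- event$detail$donor
  intact <- event$detail$intact
  if (cls[donor] != "metacentric" || cls[intact] != "acrocentric") {
    return("undetermined")
  }
  frag_centromeric_end <- if (event$detail$moved_side == "low") "tail" else "head"
  if (identical(unname(ends[donor]), frag_centromeric_end) &&
      identical(unname(ends[intact]), "head")) {
    return("centromere_to_centromere")
  }
  "undetermined"
}

#' Map detected events onto a reference karyotype
#'
#' Converts detected events into [rearrangement_event()]s
#' (centromere-to-centromere fusion -> Robertsonian fusion; tandem fusion ->
#' tandem fusion with the metacentric participant donating the centromere;
#' translocation_plus_fission -> whole-arm translocation, whose residue is
#' the fission product; fission -> fission) and applies them with
#' [apply_event_set()].  Conserved events are ignored.  Complex events, and
#' fusions whose architecture could not be determined, are refused with an
#' error: they have no deterministic karyotype interpretation.
#'
#' @param events list of `detected_event` objects (architectures filled in
#'   via [infer_architecture()]).
#' @param reference the reference `karyotype`; detected reference group
#'   names must match its chromosome names.
#' @return The predicted `karyotype`.
#' @export
events_to_karyotype <- function(events, reference) {
  stopifnot(inherits(reference, "karyotype"))
  cls <- centromere_class(reference)
  res <- list()
  for (ev in events) {
    if (ev$type == "conserved") next
    if (ev$type == "complex") {
      stop("complex event involving ", paste(ev$reference_groups, collapse = ", "),
           " cannot be mapped to a karyotype operation (",
           ev$detail$reason %||% "no clean block structure", ")")
    }
    if (ev$type == "fusion") {
      if (ev$architecture == "centromere_to_centromere") {
        res[[length(res) + 1L]] <- rearrangement_event(
          "robertsonian_fusion", ev$reference_groups)
      } else if (ev$architecture == "tandem") {
        meta <- ev$reference_groups[cls[ev$reference_groups] == "metacentric"]
        other <- setdiff(ev$reference_groups, meta)
        if (length(meta) != 1L) {
          stop("tandem fusion of ", paste(ev$reference_groups, collapse = ", "),
               ": expected exactly one metacentric centromere donor")
        }
        res[[length(res) + 1L]] <- rearrangement_event(
          "tandem_fusion", c(meta, other))
      } else {
        stop("fusion of ", paste(ev$reference_groups, collapse = ", "),
             " has undetermined architecture; cannot infer its NF effect")
      }
    } else if (ev$type == "translocation_plus_fission") {
      donor <- ev$detail$donor
      arm <- paste0(donor, if (ev$detail$moved_side == "low") "p" else "q")
      if (!arm %in% reference$arm) {
        stop(sprintf("translocated arm '%s' is not an arm of the reference karyotype", arm))
      }
      res[[length(res) + 1L]] <- rearrangement_event(
        "whole_arm_translocation", c(arm, ev$detail$intact))
    } else if (ev$type == "fission") {
      res[[length(res) + 1L]] <- rearrangement_event(
        "fission", ev$reference_groups)
    } else {
      stop("unknown detected event type: ", ev$type)
    }
  }
  out <- apply_event_set(reference, res)
  attr(out, "label") <- "predicted query"
  out
}

#' Relabel recovered linkage groups after a published reference map
#'
#' Renames each linkage group of `map` to the `reference_map` group sharing
#' the most markers with it (published maps carry chromosome nomenclature;
#' recovered maps carry arbitrary `LG` labels).  Groups without a shared
#' majority keep their name.
#'
#' @param map a map table with arbitrary group labels.
#' @param reference_map a map table carrying the target nomenclature.
#' @return `map` with `linkage_group` relabelled.
#' @export
relabel_groups <- function(map, reference_map) {
  ref_group <- stats::setNames(reference_map$linkage_group,
                               reference_map$marker_id)
  new_names <- character(0)
  for (g in unique(map$linkage_group)) {
    ids <- map$marker_id[map$linkage_group == g]
    hits <- ref_group[ids]
    hits <- hits[!is.na(hits)]
    nm <- if (length(hits) > 0L) names(sort(table(hits), decreasing = TRUE))[1L]
    else g
    new_names[g] <- nm
  }
  if (anyDuplicated(new_names[unique(map$linkage_group)])) {
    stop("relabelling is ambiguous: two groups map to the same reference group")
  }
  map$linkage_group <- unname(new_names[map$linkage_group])
  map
}

#' Convert a truth map to a map table
#'
#' Represents a simulated truth map in the linkage-map-table layout
#' (positions shifted so each group starts at 0 cM), e.g. to serve as the
#' published reference map in comparisons.  Markers not shared with the
#' other population are flagged population-specific.
#'
#' @param truth_map a `truth_map`.
#' @return A map table data frame.
#' @export
truth_to_map_table <- function(truth_map) {
  stopifnot(inherits(truth_map, "truth_map"))
  rows <- lapply(unique(truth_map$chromosome), function(g) {
    d <- truth_map[truth_map$chromosome == g, , drop = FALSE]
    d <- d[order(d$female_cM), , drop = FALSE]
    data.frame(marker_id = d$marker,
               linkage_group = g,
               order_index = seq_len(nrow(d)),
               female_cM = d$female_cM - d$female_cM[1L],
               male_cM = d$male_cM - d$male_cM[1L],
               n_meioses = 0L,
               accession = "",
               population_specific = !d$shared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two linkage maps end to end
#'
#' Matches shared markers, builds the correspondence graph, classifies
#' events, infers fusion architectures (when a reference karyotype provides
#' centromere classes) and, if all non-conserved events are interpretable,
#' predicts the query karyotype.
#'
#' @param mapA reference map table; @param mapB query map table.
#' @param reference_karyotype optional `karyotype` whose chromosome names
#'   match `mapA`'s group labels.
#' @param min_shared,max_interlopers,terminal_fraction,junction_window,interior_male_max
#'   calibration parameters (see the individual functions).
#' @return A list of class `map_comparison`: `pairing`, `graph`, `events`,
#'   `predicted_karyotype` (or `NULL`), `prediction_error` (message if the
#'   prediction was refused).
#' @export
compare_maps <- function(mapA, mapB, reference_karyotype = NULL,
                         min_shared = 3L, max_interlopers = 5L,
                         terminal_fraction = 0.1, junction_window = 0.1,
                         interior_male_max = 0.15) {
  pairing <- match_shared_markers(mapA, mapB)
  graph <- build_correspondence(pairing, mapA, mapB, min_shared = min_shared)
  events <- classify_events(graph, mapA, mapB,
                            max_interlopers = max_interlopers)
  if (!is.null(reference_karyotype)) {
    cls <- centromere_class(reference_karyotype)
    events <- lapply(events, function(ev) {
      if (ev$type %in% c("fusion", "translocation_plus_fission") &&
          all(ev$reference_groups %in% names(cls))) {
        ev$architecture <- infer_architecture(
          ev, mapB, cls, terminal_fraction = terminal_fraction,
          junction_window = junction_window,
          interior_male_max = interior_male_max)
      }
      ev
    })
  }
  predicted <- NULL
  prediction_error <- NULL
  if (!is.null(reference_karyotype)) {
    predicted <- tryCatch(events_to_karyotype(events, reference_karyotype),
                          error = function(e) {
                            prediction_error <<- conditionMessage(e)
                            NULL
                          })
  }
  structure(list(pairing = pairing, graph = graph, events = events,
                 predicted_karyotype = predicted,
                 prediction_error = prediction_error),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  types <- vapply(x$events, function(e) e$type, "")
  cat(sprintf("Map comparison: %d shared markers, %d events (%s)\n",
              nrow(x$pairing$shared), length(x$events),
              paste(sprintf("%d %s", as.integer(table(types)),
                            names(table(types))), collapse = ", ")))
  for (e in x$events[types != "conserved"]) print(e)
  if (!is.null(x$predicted_karyotype)) print(karyotype_summary(x$predicted_karyotype))
  invisible(x)
}

#' Dual-map plot of one detected event
#'
#' Draws the query group as a vertical bar beside the contributing reference
#' groups (coloured distinctly) with connecting lines for shared markers --
#' the classic comparative-map figure for a composite chromosome.
#'
#' @param event a fusion-like or conserved `detected_event`.
#' @param mapA,mapB the two map tables.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the shared-marker table used.
#' @export
plot_detected_event <- function(event, mapA, mapB, ...) {
  product <- if (event$type == "translocation_plus_fission")
    event$query_groups[["product"]] else event$query_groups[1L]
  sh <- match_shared_markers(mapA, mapB)$shared
  sh <- sh[sh$group_b == product & sh$group_a %in% event$reference_groups, ,
           drop = FALSE]
  cols <- stats::setNames(
    grDevices::hcl.colors(max(2L, length(event$reference_groups)), "Dark 3")[
      seq_along(event$reference_groups)],
    event$reference_groups)
  ymax <- max(sh$pos_b, sh$pos_a)
  graphics::plot(NA, xlim = c(0, 3), ylim = c(ymax, 0), axes = FALSE,
                 xlab = "", ylab = "female cM",
                 main = sprintf("%s (%s)", product, event$type), ...)
  graphics::axis(2)
  graphics::segments(0.9, 0, 0.9, max(sh$pos_b), lwd = 8, col = "grey70")
  offs <- seq(2, 2.4, length.out = length(event$reference_groups))
  for (i in seq_along(event$reference_groups)) {
    ga <- event$reference_groups[i]
    d <- sh[sh$group_a == ga, ]
    graphics::segments(offs[i], min(d$pos_a), offs[i], max(d$pos_a),
                       lwd = 8, col = cols[ga])
    graphics::segments(0.9, d$pos_b, offs[i], d$pos_a, col = cols[ga],
                       lwd = 0.5)
    graphics::text(offs[i], max(d$pos_a), ga, pos = 1, cex = 0.7)
  }
  invisible(sh)
}
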