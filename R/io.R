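# File formats ---------------------------------------------------------------
#
# Everything is tab-delimited UTF-8 text with "." as the decimal mark.
# The linkage-map table uses the 8-column supplementary layout: marker id,
# linkage group, order of the marker within its group (1-based), female map
# position in cM, male map position in cM, number of informative meioses,
# accession (free text) and a population-specific flag serialized as a
# literal "x" (specific) or empty.

MAP_TABLE_COLUMNS <- c("marker_id", "linkage_group", "order_index",
                       "female_cM", "male_cM", "n_meioses", "accession",
                       "population_specific")

#' Read a linkage-map table
#'
#' Reads the 8-column layout described above.  A header line is
#' auto-detected (its order/position fields are not numeric).  The table is
#' validated: within each group `order_index` must be a permutation of
#' `1..k`, positions must be non-decreasing along the order and the first
#' marker must sit at 0 cM.
#'
#' @param path file path.
#' @param validate logical; skip validation when reading non-map layouts.
#' @return A map table data frame (`population_specific` as logical).
#' @export
read_map_table <- function(path, validate = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(build_empty_map_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  first <- fields[[1L]]
  has_header <- length(first) >= 5L &&
    !(is_num(first[3L]) && is_num(first[4L]) && is_num(first[5L]))
  start <- if (has_header) 2L else 1L
  if (start > length(lines)) return(build_empty_map_table())
  rows <- vector("list", length(lines) - start + 1L)
  for (i in start:length(lines)) {
    f <- fields[[i]]
    if (length(f) %in% 6:7) f <- c(f, rep("", 8L - length(f)))
    if (length(f) != 8L) {
      stop(sprintf("%s: malformed row at line %d (%d fields, expected 8)",
                   path, i, length(fields[[i]])))
    }
    if (!all(is_num(f[3:6]))) {
      stop(sprintf("%s: malformed row at line %d (non-numeric position/order field)",
                   path, i))
    }
    flag <- trimws(f[8L])
    if (!flag %in% c("", "x")) {
      stop(sprintf("%s: malformed row at line %d (flag must be 'x' or empty, got '%s')",
                   path, i, flag))
    }
    rows[[i - start + 1L]] <- f
  }
  m <- do.call(rbind, rows)
  out <- data.frame(marker_id = m[, 1L], linkage_group = m[, 2L],
                    order_index = as.integer(as.numeric(m[, 3L])),
                    female_cM = as.numeric(m[, 4L]),
                    male_cM = as.numeric(m[, 5L]),
                    n_meioses = as.integer(as.numeric(m[, 6L])),
                    accession = m[, 7L],
                    population_specific = trimws(m[, 8L]) == "x",
                    stringsAsFactors = FALSE)
  if (validate) validate_map_table(out, path)
  out
}

#' Validate the invariants of a map table
#'
#' @param map a map-table data frame.
#' @param context label used in error messages.
#' @return The table, invisibly; errors name the offending group.
#' @export
validate_map_table <- function(map, context = "map table") {
  miss <- setdiff(MAP_TABLE_COLUMNS, names(map))
  if (length(miss) > 0L) {
    stop(context, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  dup <- map$marker_id[duplicated(map$marker_id)]
  if (length(dup) > 0L) {
    stop(context, ": duplicated marker id(s): ",
         paste(unique(dup), collapse = ", "))
  }
  for (g in unique(map$linkage_group)) {
    d <- map[map$linkage_group == g, , drop = FALSE]
    if (!identical(sort(d$order_index), seq_len(nrow(d)))) {
      stop(sprintf("%s: order_index of group %s is not a permutation of 1..%d",
                   context, g, nrow(d)))
    }
    d <- d[order(d$order_index), , drop = FALSE]
    if (any(diff(d$female_cM) < -1e-9) || any(diff(d$male_cM) < -1e-9)) {
      stop(sprintf("%s: positions of group %s decrease along the marker order",
                   context, g))
    }
    if (abs(d$female_cM[1L]) > 1e-6 || abs(d$male_cM[1L]) > 1e-6) {
      stop(sprintf("%s: first marker of group %s is not at 0 cM", context, g))
    }
  }
  invisible(map)
}

#' Write a linkage-map table
#'
#' Columns in the documented order, positions to 3 decimals, the
#' population-specific flag as a literal `"x"` or empty.
#' `read_map_table(write_map_table(m))` round-trips (up to the 3-decimal
#' position precision).
#'
#' @param map a map-table data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_map_table <- function(map, path) {
  validate_map_table(map)
  lines <- c(paste(MAP_TABLE_COLUMNS, collapse = "\t"),
             if (nrow(map) > 0L)
               paste(map$marker_id, map$linkage_group, map$order_index,
                     sprintf("%.3f", map$female_cM),
                     sprintf("%.3f", map$male_cM),
                     map$n_meioses, map$accession,
                     ifelse(map$population_specific, "x", ""),
                     sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write / read a genotype matrix as TSV
#'
#' Individuals in rows (first column `id`), markers in columns, genotypes
#' in {0, 1, 2, NA}.
#'
#' @param genotypes integer matrix with individual row names.
#' @param path file path.
#' @return `path` invisibly / the genotype matrix.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  g <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- df$id
  g
}

#' Write / read a pedigree as TSV
#'
#' Columns: `id`, `sire`, `dam`, `sex`, `family`; missing parents as `NA`.
#'
#' @param pedigree pedigree data frame.
#' @param path file path.
#' @return `path` invisibly / the pedigree data frame.
#' @export
write_pedigree_tsv <- function(pedigree, path) {
  utils::write.table(pedigree[, c("id", "sire", "dam", "sex", "family")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Assemble a `pedigree_genotypes` object from files
#'
#' @param genotypes_path,pedigree_path TSVs written by
#'   [write_genotypes_tsv()] / [write_pedigree_tsv()].
#' @return A `pedigree_genotypes` object (without simulation truth).
#' @export
read_pedigree_genotypes <- function(genotypes_path, pedigree_path) {
  g <- read_genotypes_tsv(genotypes_path)
  ped <- read_pedigree_tsv(pedigree_path)
  missing_ids <- setdiff(ped$id, rownames(g))
  if (length(missing_ids) > 0L) {
    stop("pedigree individual(s) missing from the genotype matrix: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  }
  structure(list(pedigree = ped, genotypes = g, markers = colnames(g),
                 truth = NULL, truth_map = NULL),
            class = "pedigree_genotypes")
}

#' Write a truth map in the map-table layout plus a truth column
#'
#' @param truth_map a `truth_map`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth_map_tsv <- function(truth_map, path) {
  tab <- truth_to_map_table(truth_map)
  tab$true_u <- truth_map$u[match(tab$marker_id, truth_map$marker)]
  lines <- c(paste(c(MAP_TABLE_COLUMNS, "true_u"), collapse = "\t"),
             paste(tab$marker_id, tab$linkage_group, tab$order_index,
                   sprintf("%.3f", tab$female_cM),
                   sprintf("%.3f", tab$male_cM),
                   tab$n_meioses, tab$accession,
                   ifelse(tab$population_specific, "x", ""),
                   sprintf("%.6f", tab$true_u),
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Flatten detected events into a table
#'
#' @param events list of `detected_event` objects.
#' @return Data frame: type, reference_groups, query_groups, junction
#'   bounds, orientation, geometry, architecture.
#' @export
events_table <- function(events) {
  if (length(events) == 0L) {
    return(data.frame(type = character(0), reference_groups = character(0),
                      query_groups = character(0), junction_lo = numeric(0),
                      junction_hi = numeric(0), orientation = character(0),
                      geometry = character(0), architecture = character(0)))
  }
  do.call(rbind, lapply(events, function(e) {
    data.frame(type = e$type,
               reference_groups = paste(e$reference_groups, collapse = "+"),
               query_groups = paste(e$query_groups, collapse = "+"),
               junction_lo = if (is.null(e$junction)) NA_real_ else e$junction[1L],
               junction_hi = if (is.null(e$junction)) NA_real_ else e$junction[2L],
               orientation = if (is.null(e$orientation)) "" else
                 paste(sprintf("%s:%s", names(e$orientation), e$orientation),
                       collapse = ","),
               geometry = e$geometry,
               architecture = e$architecture,
               stringsAsFactors = FALSE)
  }))
}

# Pipeline configuration ------------------------------------------------------

CONFIG_RANGES <- list(
  seed = c(1, 2^31 - 1),
  n_chromosomes = c(1, 200),
  markers_per_chromosome = c(2, 10000),
  female_length_cM = c(1e-6, 1e4),
  male_length_cM = c(1e-6, 1e4),
  shared_fraction = c(0, 1),
  telomere_window = c(1e-9, 0.5),
  telomere_mass = c(1e-9, 1),
  arm_split = c(1e-9, 1),
  n_families = c(1, 1e6),
  offspring_per_family = c(1, 1e6),
  half_sib_fraction = c(0, 1),
  missing_rate = c(0, 1),
  lod_threshold = c(0, 1e3),
  em_tol = c(1e-12, 1e-2),
  em_max_iter = c(1, 1e5),
  screen_theta_max = c(0, 0.5),
  min_shared = c(1, 1e6),
  max_interlopers = c(0, 1e3),
  terminal_fraction = c(1e-9, 0.5),
  junction_window = c(1e-9, 0.5),
  interior_male_max = c(0, 1)
)

#' Default pipeline configuration
#'
#' Flat key-value list covering simulation, mapping and comparison
#' parameters; see the vignette for the meaning and rationale of each
#' default.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(seed = 1L,
       n_chromosomes = 27L,
       markers_per_chromosome = 24L,
       female_length_cM = 80,
       male_length_cM = 36,
       shared_fraction = 0.83,
       telomere_window = 0.1,
       telomere_mass = 0.9,
       arm_split = 0.45,
       n_families = 40L,
       offspring_per_family = 20L,
       half_sib_fraction = 0.15,
       missing_rate = 0.02,
       lod_threshold = 10,
       mapping_function = "kosambi",
       em_tol = 1e-6,
       em_max_iter = 200L,
       screen_theta_max = 0.35,
       min_shared = 3L,
       max_interlopers = 5L,
       terminal_fraction = 0.1,
       junction_window = 0.1,
       interior_male_max = 0.15)
}

#' Read a pipeline configuration file
#'
#' Flat `key = value` lines (`#` comments allowed).  Unknown keys are
#' rejected; every threshold is checked against its documented valid range.
#'
#' @param path config file, or `NULL` for the defaults.
#' @param overrides named list applied on top of the file (e.g. CLI flags).
#' @return Validated configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("malformed config line: ", ln)
      cfg[trimws(kv[1L])] <- list(trimws(kv[2L]))
    }
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  validate_config(cfg)
}

#' @rdname read_config
#' @param config configuration list to validate and type-coerce.
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(config)) {
    v <- config[[k]]
    if (k == "mapping_function") {
      v <- match.arg(as.character(v), c("kosambi", "haldane"))
    } else {
      v <- suppressWarnings(as.numeric(v))
      if (is.na(v)) stop(sprintf("config key %s: not a number", k))
      rng <- CONFIG_RANGES[[k]]
      if (v < rng[1L] || v > rng[2L]) {
        stop(sprintf("config key %s = %s outside valid range [%g, %g]",
                     k, config[[k]], rng[1L], rng[2L]))
      }
      if (is.integer(defaults[[k]])) v <- as.integer(v)
    }
    config[[k]] <- v
  }
  config
}

# Small stable hash (FNV-1a) used only to fingerprint configs in logs.
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x) paste(format(x), collapse = ","), ""),
             sep = "=", collapse = ";")
  h <- 216613626
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}
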