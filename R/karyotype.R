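# Karyotype model ------------------------------------------------------------
#
# A karyotype is represented as a data frame with one row per chromosome arm
# (columns: chromosome, arm, length).  A chromosome with one arm is
# acrocentric, with two arms metacentric; anything else is rejected.  Arm
# lengths are relative (unit by default) and conserved by every rearrangement
# operator, which makes "total arm mass" a useful invariant for testing.

EVENT_TYPES <- c("robertsonian_fusion", "tandem_fusion", "fission",
                 "whole_arm_translocation")
ORIENTATIONS <- c("head_to_head", "tail_to_head", "not_applicable")

#' Create a karyotype from a table of chromosome arms
#'
#' @param arms data frame with columns `chromosome`, `arm` and `length`.
#'   Row order within a chromosome is meaningful: the first arm is the p
#'   (short) arm of a metacentric, the last the q arm.
#' @param label free-text label (e.g. `"European reference"`).
#'
#' @return An object of class `karyotype`: the validated arm table with the
#'   label stored as an attribute.
#' @export
#' @examples
#' k <- karyotype_from_arms(
#'   data.frame(chromosome = c("c1", "c1", "c2"),
#'              arm = c("c1p", "c1q", "c2q"),
#'              length = 1),
#'   label = "toy")
#' karyotype_summary(k)
karyotype_from_arms <- function(arms, label = "") {
  stopifnot(is.data.frame(arms))
  need <- c("chromosome", "arm", "length")
  missing_cols <- setdiff(need, names(arms))
  if (length(missing_cols) > 0L) {
    stop("arm table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  k <- as.data.frame(arms[, need])
  rownames(k) <- NULL
  k$chromosome <- as.character(k$chromosome)
  k$arm <- as.character(k$arm)
  k$length <- as.numeric(k$length)
  attr(k, "label") <- as.character(label)[1L]
  class(k) <- c("karyotype", "data.frame")
  validate_karyotype(k)
  k
}

validate_karyotype <- function(k) {
  if (nrow(k) == 0L) return(invisible(k))
  if (any(!is.finite(k$length)) || any(k$length <= 0)) {
    stop("all arm lengths must be finite and > 0")
  }
  dup <- k$arm[duplicated(k$arm)]
  if (length(dup) > 0L) {
    stop("duplicated arm name(s): ", paste(unique(dup), collapse = ", "))
  }
  ac <- table(k$chromosome)
  bad <- names(ac)[!(ac %in% 1:2)]
  if (length(bad) > 0L) {
    stop("chromosome(s) with arm count outside {1, 2}: ",
         paste(bad, collapse = ", "))
  }
  # chromosome rows must be contiguous so that p/q row order is well defined
  rle_chr <- rle(k$chromosome)$values
  if (anyDuplicated(rle_chr)) {
    stop("rows of a chromosome must be contiguous in the arm table")
  }
  invisible(k)
}

#' @export
print.karyotype <- function(x, ...) {
  s <- karyotype_summary(x)
  lab <- attr(x, "label")
  cat(sprintf("Karyotype%s: %d pairs (2n = %d), NF = %d, %d metacentric + %d acrocentric\n",
              if (nzchar(lab)) paste0(" '", lab, "'") else "",
              s$n_pairs, s$two_n, s$nf, s$metacentric, s$acrocentric))
  invisible(x)
}

#' Centromere class of each chromosome
#'
#' @param k a `karyotype` object.
#' @return Named character vector: `"metacentric"` (two arms) or
#'   `"acrocentric"` (one arm) per chromosome.
#' @export
centromere_class <- function(k) {
  ac <- table(k$chromosome)
  out <- ifelse(as.integer(ac) == 2L, "metacentric", "acrocentric")
  names(out) <- names(ac)
  out
}

#' Summarize a karyotype
#'
#' Reports the numbers cytogeneticists quote: number of chromosome pairs,
#' diploid number 2n, fundamental number NF (diploid arm count; a metacentric
#' pair contributes 4 arms, an acrocentric pair 2), and the metacentric /
#' acrocentric pair counts.
#'
#' @param karyotype a [karyotype_from_arms()] object.
#' @return A list of class `karyotype_summary` with elements `n_pairs`,
#'   `two_n`, `nf`, `metacentric`, `acrocentric`, `total_arm_length`.
#' @export
karyotype_summary <- function(karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  cls <- centromere_class(karyotype)
  structure(list(
    n_pairs = length(cls),
    two_n = 2L * length(cls),
    nf = 2L * nrow(karyotype),
    metacentric = sum(cls == "metacentric"),
    acrocentric = sum(cls == "acrocentric"),
    total_arm_length = sum(karyotype$length)
  ), class = "karyotype_summary")
}

#' @export
summary.karyotype <- function(object, ...) karyotype_summary(object)

#' @export
print.karyotype_summary <- function(x, ...) {
  cat(sprintf("n_pairs: %d   2n: %d   NF: %d   metacentric: %d   acrocentric: %d\n",
              x$n_pairs, x$two_n, x$nf, x$metacentric, x$acrocentric))
  invisible(x)
}

#' The European Atlantic salmon reference karyotype
#'
#' Builds the standard European karyotype: 29 chromosome pairs, 8 metacentric
#' (ssa01-ssa08, each with p and q arms) and 21 acrocentric (ssa09-ssa29),
#' giving 2n = 58 and NF = 74.  Which chromosomes besides ssa01 and ssa08 are
#' metacentric is a labelling convention here; only the counts and the
#' identities of the rearrangement participants matter downstream.
#'
#' @param arm_lengths optional named numeric vector of relative arm lengths
#'   (names are arm names such as `"ssa01p"`); unnamed arms keep length 1.
#' @return A `karyotype` object.
#' @export
#' @examples
#' karyotype_summary(build_european_reference())
build_european_reference <- function(arm_lengths = NULL) {
  chrom <- sprintf("ssa%02d", 1:29)
  meta <- chrom[1:8]
  rows <- lapply(chrom, function(ch) {
    if (ch %in% meta) {
      data.frame(chromosome = ch, arm = paste0(ch, c("p", "q")), length = 1)
    } else {
      data.frame(chromosome = ch, arm = paste0(ch, "q"), length = 1)
    }
  })
  arms <- do.call(rbind, rows)
  if (!is.null(arm_lengths)) {
    if (is.null(names(arm_lengths))) stop("arm_lengths must be named by arm")
    unknown <- setdiff(names(arm_lengths), arms$arm)
    if (length(unknown) > 0L) {
      stop("unknown arm(s) in arm_lengths: ", paste(unknown, collapse = ", "))
    }
    idx <- match(names(arm_lengths), arms$arm)
    arms$length[idx] <- as.numeric(arm_lengths)
  }
  karyotype_from_arms(arms, label = "European reference")
}

#' Describe a chromosomal rearrangement event
#'
#' @param event_type one of `"robertsonian_fusion"`, `"tandem_fusion"`,
#'   `"fission"`, `"whole_arm_translocation"`.
#' @param participants character vector of participants.  Fusions take two
#'   chromosome names (for a tandem fusion the first listed donates the
#'   centromere); fission takes one metacentric chromosome;
#'   whole-arm translocation takes `c(arm, recipient_chromosome)`.
#' @param orientation junction geometry; defaults to `"head_to_head"` for a
#'   Robertsonian fusion, `"tail_to_head"` for a tandem fusion and
#'   `"not_applicable"` otherwise.
#' @param polymorphic logical; whether the event segregates in the population
#'   (annotation only -- it does not change how the event is applied).
#' @param product optional name for the product chromosome; by default
#'   participants are concatenated with `/` (e.g. `ssa26/28`).
#' @return An object of class `rearrangement_event`.
#' @export
rearrangement_event <- function(event_type, participants,
                                orientation = NULL, polymorphic = FALSE,
                                product = NULL) {
  event_type <- match.arg(event_type, EVENT_TYPES)
  participants <- as.character(participants)
  n_expected <- if (event_type == "fission") 1L else 2L
  if (length(participants) != n_expected) {
    stop(sprintf("'%s' takes %d participant(s), got %d",
                 event_type, n_expected, length(participants)))
  }
  if (is.null(orientation)) {
    orientation <- switch(event_type,
                          robertsonian_fusion = "head_to_head",
                          tandem_fusion = "tail_to_head",
                          "not_applicable")
  }
  orientation <- match.arg(orientation, ORIENTATIONS)
  structure(list(event_type = event_type,
                 participants = participants,
                 orientation = orientation,
                 polymorphic = isTRUE(polymorphic),
                 product = product),
            class = "rearrangement_event")
}

#' @export
print.rearrangement_event <- function(x, ...) {
  cat(sprintf("%s(%s)%s%s\n", x$event_type,
              paste(x$participants, collapse = ", "),
              if (x$orientation != "not_applicable")
                paste0(" [", x$orientation, "]") else "",
              if (x$polymorphic) " (polymorphic)" else ""))
  invisible(x)
}

# Compose "a/b" product names: the shared leading alphabetic prefix of the
# second participant is dropped, so ssa26 + ssa28 -> "ssa26/28" and
# ssa01p + ssa23 -> "ssa01p/23".
compose_product_name <- function(a, b) {
  pref_a <- sub("[^A-Za-z].*$", "", a)
  pref_b <- sub("[^A-Za-z].*$", "", b)
  b_short <- if (nzchar(pref_b) && identical(pref_a, pref_b)) {
    substring(b, nchar(pref_b) + 1L)
  } else {
    b
  }
  paste0(a, "/", b_short)
}

#' Apply a rearrangement event to a karyotype
#'
#' Pure transformation: the input karyotype is never modified.  Effects on the
#' summary numbers are: Robertsonian fusion joins two acrocentrics centromere
#' to centromere (pairs -1, NF unchanged, product metacentric); tandem fusion
#' joins one chromosome end-to-end onto another's q arm (pairs -1, diploid NF
#' -2, product class inherited from the first-listed, centromere-donating
#' participant); fission splits a metacentric into two acrocentrics (pairs +1,
#' NF unchanged); whole-arm translocation moves one arm between chromosomes
#' (pairs and NF unchanged, centromere classes recomputed).  Total arm length
#' is conserved by every event.
#'
#' @param karyotype a `karyotype` object.
#' @param event a [rearrangement_event()].
#' @return A new `karyotype`.
#' @export
#' @examples
#' eu <- build_european_reference()
#' na <- apply_event(eu, rearrangement_event("robertsonian_fusion",
#'                                           c("ssa26", "ssa28")))
#' karyotype_summary(na)
apply_event <- function(karyotype, event) {
  stopifnot(inherits(karyotype, "karyotype"),
            inherits(event, "rearrangement_event"))
  arms <- as.data.frame(karyotype)
  arms$..ord <- seq_len(nrow(arms))
  cls <- centromere_class(karyotype)

  check_chrom <- function(name) {
    if (!name %in% arms$chromosome) {
      stop(sprintf("unknown participant '%s' (not a chromosome of karyotype '%s')",
                   name, attr(karyotype, "label")))
    }
  }

  out <- switch(
    event$event_type,
    robertsonian_fusion = {
      p <- event$participants
      check_chrom(p[1]); check_chrom(p[2])
      if (p[1] == p[2]) stop("fusion participants must differ")
      not_acro <- p[cls[p] != "acrocentric"]
      if (length(not_acro) > 0L) {
        stop(sprintf("robertsonian_fusion requires two acrocentric participants; '%s' is metacentric",
                     not_acro[1]))
      }
      newname <- event$product %||% compose_product_name(p[1], p[2])
      ia <- which(arms$chromosome == p[1])
      ib <- which(arms$chromosome == p[2])
      merged <- arms[c(ia, ib), ]
      merged$chromosome <- newname
      merged$..ord <- min(arms$..ord[c(ia, ib)])
      rbind(arms[-c(ia, ib), ], merged)
    },
    tandem_fusion = {
      p <- event$participants
      check_chrom(p[1]); check_chrom(p[2])
      if (p[1] == p[2]) stop("fusion participants must differ")
      if (cls[p[2]] != "acrocentric") {
        # joining through a metacentric's interior would strand its second
        # arm without a centromere and change NF by more than two
        stop(sprintf("tandem_fusion requires an acrocentric attached participant; '%s' is metacentric",
                     p[2]))
      }
      newname <- event$product %||% compose_product_name(p[1], p[2])
      id <- which(arms$chromosome == p[1])   # centromere donor
      it <- which(arms$chromosome == p[2])   # attached chromosome
      donor <- arms[id, ]
      attached <- arms[it, ]
      merged_len <- donor$length[nrow(donor)] + sum(attached$length)
      kept <- donor[-nrow(donor), , drop = FALSE]
      merged <- data.frame(chromosome = newname,
                           arm = paste0(newname, "q"),
                           length = merged_len,
                           ..ord = min(arms$..ord[c(id, it)]))
      if (nrow(kept) > 0L) {
        kept$chromosome <- newname
        kept$..ord <- merged$..ord
      }
      rbind(arms[-c(id, it), ], kept, merged)
    },
    fission = {
      p <- event$participants[1]
      check_chrom(p)
      if (cls[p] != "metacentric") {
        stop(sprintf("fission requires a metacentric chromosome; '%s' is acrocentric", p))
      }
      ii <- which(arms$chromosome == p)
      split_rows <- arms[ii, ]
      split_rows$chromosome <- split_rows$arm
      rbind(arms[-ii, ], split_rows)
    },
    whole_arm_translocation = {
      arm_name <- event$participants[1]
      recipient <- event$participants[2]
      if (!arm_name %in% arms$arm) {
        stop(sprintf("unknown participant '%s' (not an arm of karyotype '%s')",
                     arm_name, attr(karyotype, "label")))
      }
      check_chrom(recipient)
      donor <- arms$chromosome[arms$arm == arm_name]
      if (donor == recipient) stop("arm cannot be translocated onto its own chromosome")
      if (sum(arms$chromosome == donor) < 2L) {
        stop(sprintf("whole_arm_translocation would leave '%s' without arms; use a fusion instead",
                     donor))
      }
      if (cls[recipient] != "acrocentric") {
        stop(sprintf("recipient '%s' is already metacentric; gaining an arm would exceed two arms",
                     recipient))
      }
      newname <- event$product %||% compose_product_name(arm_name, recipient)
      im <- which(arms$arm == arm_name)
      ir <- which(arms$chromosome == recipient)
      moved <- arms[im, ]
      moved$chromosome <- newname
      moved$..ord <- min(arms$..ord[ir]) - 0.5  # moved arm becomes the p arm
      rec_rows <- arms[ir, ]
      rec_rows$chromosome <- newname
      rest <- arms[-c(im, ir), ]
      # donor remnant: if a single arm is left, rename the chromosome to it
      left <- which(rest$chromosome == donor)
      if (length(left) == 1L) rest$chromosome[left] <- rest$arm[left]
      rbind(rest, moved, rec_rows)
    }
  )

  out <- out[order(out$..ord, match(out$arm, arms$arm)), ]
  out$..ord <- NULL
  karyotype_from_arms(out, label = attr(karyotype, "label"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply an ordered list of rearrangement events
#'
#' @param karyotype a `karyotype` object.
#' @param events list of [rearrangement_event()] objects, applied in order.
#' @return The transformed `karyotype`; an empty list returns the input
#'   unchanged.
#' @export
#' @examples
#' karyotype_summary(apply_event_set(build_european_reference(),
#'                                   na_standard_events()))
apply_event_set <- function(karyotype, events) {
  stopifnot(inherits(karyotype, "karyotype"), is.list(events))
  Reduce(apply_event, events, init = karyotype)
}

#' The three rearrangements separating the standard karyotypes
#'
#' The bundled event set that converts the European reference karyotype into
#' the standard North American one: (1) whole-arm translocation of ssa01p onto
#' ssa23, leaving the acrocentric residue ssa01q; (2) Robertsonian
#' (centromere-to-centromere) fusion of ssa26 with ssa28; (3) tandem fusion of
#' ssa29 onto the q arm of ssa08, with ssa08 donating the centromere.  The two
#' fusions segregate in North American populations and are flagged
#' polymorphic.
#'
#' @return List of three [rearrangement_event()] objects.
#' @export
na_standard_events <- function() {
  list(
    rearrangement_event("whole_arm_translocation", c("ssa01p", "ssa23")),
    rearrangement_event("robertsonian_fusion", c("ssa26", "ssa28"),
                        polymorphic = TRUE),
    rearrangement_event("tandem_fusion", c("ssa08", "ssa29"),
                        polymorphic = TRUE)
  )
}

#' Read / write a karyotype as TSV
#'
#' One row per chromosome with comma-separated arm names and lengths, plus the
#' derived centromere class.  `read_karyotype_tsv(write_karyotype_tsv(k))`
#' round-trips.
#'
#' @param karyotype a `karyotype` object.
#' @param path file path.
#' @return `write_karyotype_tsv` returns `path` invisibly;
#'   `read_karyotype_tsv` returns a `karyotype`.
#' @export
write_karyotype_tsv <- function(karyotype, path) {
  stopifnot(inherits(karyotype, "karyotype"))
  chroms <- unique(karyotype$chromosome)
  rows <- lapply(chroms, function(ch) {
    sub <- karyotype[karyotype$chromosome == ch, ]
    data.frame(chromosome = ch,
               arms = paste(sub$arm, collapse = ","),
               arm_lengths = paste(format(sub$length, trim = TRUE, digits = 12),
                                   collapse = ","),
               class = if (nrow(sub) == 2L) "metacentric" else "acrocentric")
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_karyotype_tsv
#' @param label label for the karyotype read from `path`.
#' @export
read_karyotype_tsv <- function(path, label = "") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("chromosome", "arms", "arm_lengths")
  if (!all(need %in% names(tab))) {
    stop("karyotype TSV must have columns chromosome, arms, arm_lengths, class")
  }
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    arm_names <- strsplit(tab$arms[i], ",", fixed = TRUE)[[1]]
    lens <- as.numeric(strsplit(tab$arm_lengths[i], ",", fixed = TRUE)[[1]])
    if (length(arm_names) != length(lens)) {
      stop(sprintf("row %d: arm name and length counts differ", i))
    }
    data.frame(chromosome = tab$chromosome[i], arm = arm_names, length = lens)
  })
  karyotype_from_arms(do.call(rbind, rows), label = label)
}
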