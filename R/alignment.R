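#' Construct an alignment from named sequences
#'
#' An alignment is a set of equal-length nucleotide rows keyed by unique tip
#' identifiers. Rows are stored upper-cased with `U` mapped to `T`; gaps
#' (`-`), `?`, `N` and IUPAC ambiguity codes are kept verbatim and handled at
#' distance time by pairwise deletion.
#'
#' @param x a named character vector of sequence strings (or a character
#'   matrix with one row per tip, one column per site).
#' @return an object of class `"alignment"` with elements `tip_ids`, `seq`
#'   (character matrix, tips x sites) and `n_sites`.
#' @export
alignment <- function(x) {
  if (is.matrix(x)) {
    mat <- x
  } else {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("sequences must be named by tip id")
    }
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      bad <- names(x)[lens != lens[1]][1]
      stop("ragged alignment: record '", bad, "' has length ", nchar(x[bad]),
           ", expected ", lens[1])
    }
    mat <- do.call(rbind, lapply(x, function(s) seq_chars(s)))
    rownames(mat) <- names(x)
  }
  if (is.null(rownames(mat))) stop("alignment rows must be named by tip id")
  mat[] <- toupper(mat)
  mat[mat == "U"] <- "T"
  ids <- rownames(mat)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate tip ids: ", paste(dup, collapse = ", "))
  }
  if (ncol(mat) < 1L) stop("alignment must have at least one site")
  structure(
    list(tip_ids = ids, seq = mat, n_sites = ncol(mat)),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, ...) {
  cat("Alignment:", length(x$tip_ids), "sequences x", x$n_sites, "sites\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment in FASTA format. All records must have
#' the same length and unique identifiers; sequences are upper-cased and `U`
#' is mapped to `T`.
#'
#' @param path path to an aligned FASTA file.
#' @return an [alignment] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                       as.string = TRUE, set.attributes = FALSE),
    error = function(e) stop("not readable as FASTA: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  if (length(seqs) < 1L) stop("no FASTA records in ", path)
  alignment(unlist(seqs))
}

#' Write an alignment to FASTA
#'
#' @param aln an [alignment] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  rows <- apply(aln$seq, 1L, paste, collapse = "")
  seqinr::write.fasta(as.list(rows), names = aln$tip_ids,
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' Construct a tip-to-species map
#'
#' @param tip_ids character vector of tip identifiers.
#' @param species character vector of species names, parallel to `tip_ids`.
#' @return a data frame of class `"species_map"` with columns `tip_id` and
#'   `species`.
#' @export
species_map <- function(tip_ids, species) {
  stopifnot(length(tip_ids) == length(species))
  tip_ids <- as.character(tip_ids)
  dup <- unique(tip_ids[duplicated(tip_ids)])
  if (length(dup)) stop("duplicate tip ids in species map: ",
                        paste(dup, collapse = ", "))
  out <- data.frame(tip_id = tip_ids, species = as.character(species),
                    stringsAsFactors = FALSE)
  class(out) <- c("species_map", "data.frame")
  out
}

#' Read a species map from TSV
#'
#' Expects a tab-separated file with a header line `tip_id<TAB>species`.
#'
#' @param path path to the TSV file.
#' @return a [species_map] data frame.
#' @export
read_species_map <- function(path) {
  if (!file.exists(path)) stop("species map not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("tip_id", "species") %in% names(df))) {
    stop("species map must have columns 'tip_id' and 'species'")
  }
  species_map(df$tip_id, df$species)
}

#' Write a species map to TSV
#' @param sm a [species_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_map <- function(sm, path) {
  utils::write.table(as.data.frame(sm)[, c("tip_id", "species")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Sites where either symbol is not an unambiguous `A`/`C`/`G`/`T` (gap, `?`,
#' `N`, or any IUPAC ambiguity code) are excluded pairwise; the distance is
#' the fraction of mismatches among the remaining comparable sites. No
#' multiple-hit correction is applied.
#'
#' @param a,b sequences of equal length, as strings or character vectors.
#' @return a list with `fraction` (in `[0, 1]`, or `NA` when no site is
#'   comparable) and `comparable_sites` (integer count).
#' @export
p_distance <- function(a, b) {
  a <- seq_chars(a)
  b <- seq_chars(b)
  if (length(a) != length(b)) {
    stop("sequence length mismatch: ", length(a), " vs ", length(b))
  }
  ok <- (a %in% DNA_BASES) & (b %in% DNA_BASES)
  n <- sum(ok)
  if (n == 0L) {
    return(list(fraction = NA_real_, comparable_sites = 0L))
  }
  list(fraction = sum(a[ok] != b[ok]) / n, comparable_sites = as.integer(n))
}

#' Pairwise p-distance matrix for an alignment
#'
#' Computes uncorrected p-distances under pairwise deletion for every pair of
#' rows. Pairs with no comparable sites get an `NA` distance (never 0) and a
#' warning; pairs with fewer than `min_comparable` comparable sites also
#' trigger a warning because percent distances become unstable.
#'
#' @param aln an [alignment] with at least 2 rows.
#' @param min_comparable warn when a pair has fewer comparable sites than
#'   this (default 50). Set to 0 to disable.
#' @return an object of class `"p_distance_matrix"`: `tip_ids`, `p`
#'   (symmetric numeric matrix of fractions, zero diagonal) and
#'   `comparable_sites` (symmetric integer matrix).
#' @export
distance_matrix <- function(aln, min_comparable = 50L) {
  stopifnot(inherits(aln, "alignment"))
  if (length(aln$tip_ids) < 2L) stop("need at least 2 sequences")
  X <- aln$seq
  OK <- matrix(X %in% DNA_BASES, nrow = nrow(X))
  storage.mode(OK) <- "numeric"
  C <- OK %*% t(OK)
  M <- matrix(0, nrow(X), nrow(X))
  for (b in DNA_BASES) {
    Ib <- (X == b) * 1
    M <- M + Ib %*% t(Ib)
  }
  P <- ifelse(C > 0, (C - M) / C, NA_real_)
  diag(P) <- 0
  dimnames(P) <- dimnames(C) <- list(aln$tip_ids, aln$tip_ids)
  n_missing <- sum(C[upper.tri(C)] == 0)
  if (n_missing > 0) {
    warning(n_missing, " pair(s) with no comparable sites: distance set to NA")
  }
  if (min_comparable > 0) {
    n_low <- sum(C[upper.tri(C)] > 0 & C[upper.tri(C)] < min_comparable)
    if (n_low > 0) {
      warning(n_low, " pair(s) with fewer than ", min_comparable,
              " comparable sites; percent distances may be unstable")
    }
  }
  structure(
    list(tip_ids = aln$tip_ids, p = P,
         comparable_sites = matrix(as.integer(C), nrow(C),
                                   dimnames = dimnames(C))),
    class = "p_distance_matrix"
  )
}

#' @export
print.p_distance_matrix <- function(x, ...) {
  cat("Uncorrected p-distance matrix:", length(x$tip_ids), "tips\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Write a p-distance matrix as CSV (full precision fractions)
#' @param dm a [distance_matrix] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.csv(as.data.frame(dm$p), path, row.names = TRUE)
  invisible(path)
}

# Collect the vector of p-distances between two sets of tips, excluding
# self-pairs and double counting. Returns fractions (may contain NA).
cross_pair_values <- function(dm, tips_a, tips_b) {
  if (identical(sort(tips_a), sort(tips_b))) {
    sub <- dm$p[tips_a, tips_a, drop = FALSE]
    sub[upper.tri(sub)]
  } else {
    as.vector(dm$p[tips_a, tips_b, drop = FALSE])
  }
}

#' Species-pair percent-distance ranges
#'
#' Summarises a p-distance matrix into per-species-pair ranges of percent
#' distance over all cross-individual comparisons, in the style of a
#' barcoding distance table: for each pair of species, the minimum and
#' maximum of `100 * p`, rounded half-away-from-zero to `decimals` places.
#' Within-species ranges are reported for species with at least two
#' individuals. Missing (NA) distances are excluded with a message.
#'
#' @param dm a [distance_matrix] result.
#' @param sm a [species_map] covering every tip in `dm`.
#' @param decimals decimal places for the displayed percent values
#'   (default 1).
#' @return a data frame of class `"pair_range_table"` with columns
#'   `species_a`, `species_b`, `min_percent`, `max_percent` (rounded, for
#'   display), `min_percent_raw`, `max_percent_raw` (full precision, used by
#'   downstream calibration), `n_comparisons` and `type` (`"between"` or
#'   `"within"`).
#' @export
species_pair_ranges <- function(dm, sm, decimals = 1L) {
  stopifnot(inherits(dm, "p_distance_matrix"))
  unmapped <- setdiff(dm$tip_ids, sm$tip_id)
  if (length(unmapped)) {
    stop("tips not in species map: ", paste(unmapped, collapse = ", "))
  }
  sp_of <- stats::setNames(sm$species, sm$tip_id)
  tips_by_sp <- split(dm$tip_ids, sp_of[dm$tip_ids])
  species <- names(tips_by_sp)
  rows <- list()
  n_dropped <- 0L
  for (i in seq_along(species)) {
    for (j in i:length(species)) {
      a <- species[i]; b <- species[j]
      within <- identical(a, b)
      if (within && length(tips_by_sp[[a]]) < 2L) next
      vals <- cross_pair_values(dm, tips_by_sp[[a]], tips_by_sp[[b]])
      n_dropped <- n_dropped + sum(is.na(vals))
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      pct <- round_half_up(100 * vals, decimals)
      rows[[length(rows) + 1L]] <- data.frame(
        species_a = a, species_b = b,
        min_percent = min(pct), max_percent = max(pct),
        min_percent_raw = 100 * min(vals), max_percent_raw = 100 * max(vals),
        n_comparisons = length(vals),
        type = if (within) "within" else "between",
        stringsAsFactors = FALSE
      )
    }
  }
  if (n_dropped > 0) {
    message(n_dropped, " missing pairwise distance(s) excluded from ranges")
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pair_range_table", "data.frame")
  out
}

#' Format a pair-range table as a square character matrix
#'
#' Cells contain `"min-max"` percent ranges, collapsed to a single value when
#' the rounded endpoints coincide; the diagonal holds within-species ranges
#' where available.
#'
#' @param ranges a [species_pair_ranges] result.
#' @return a square character matrix with species names as dimnames.
#' @export
format_range_matrix <- function(ranges) {
  species <- sort(unique(c(ranges$species_a, ranges$species_b)))
  out <- matrix("", length(species), length(species),
                dimnames = list(species, species))
  fmt <- function(lo, hi) {
    if (lo == hi) format(lo, trim = TRUE) else
      paste0(format(lo, trim = TRUE), "-", format(hi, trim = TRUE))
  }
  for (k in seq_len(nrow(ranges))) {
    a <- ranges$species_a[k]; b <- ranges$species_b[k]
    cell <- fmt(ranges$min_percent[k], ranges$max_percent[k])
    out[a, b] <- cell
    out[b, a] <- cell
  }
  out
}

#' Write a pair-range table as a Table-style CSV matrix
#' @param ranges a [species_pair_ranges] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_ranges <- function(ranges, path) {
  utils::write.csv(format_range_matrix(ranges), path, row.names = TRUE)
  invisible(path)
}

#' Within-species percent divergence
#'
#' Range of percent p-distance among conspecific individuals of one species,
#' with a comparison against a reference conspecific-divergence interval
#' (default 0.2--0.9 percent, a typical 16S conspecific range in the study
#' group).
#'
#' @param dm a [distance_matrix] result.
#' @param sm a [species_map].
#' @param species species name with at least 2 individuals.
#' @param reference numeric length-2 reference interval in percent.
#' @return a list with `min_percent`, `max_percent`, `n_comparisons`,
#'   `reference`, `inside_reference` (logical) and `relation` (one of
#'   `"inside"`, `"below"`, `"above"`, `"overlapping"`).
#' @export
within_species_divergence <- function(dm, sm, species,
                                      reference = c(0.2, 0.9)) {
  tips <- sm$tip_id[sm$species == species]
  tips <- intersect(tips, dm$tip_ids)
  if (!length(tips)) stop("species not found: ", species)
  if (length(tips) < 2L) stop("species '", species,
                              "' has fewer than 2 individuals")
  vals <- cross_pair_values(dm, tips, tips)
  vals <- 100 * vals[!is.na(vals)]
  if (!length(vals)) stop("no comparable within-species pairs for ", species)
  lo <- min(vals); hi <- max(vals)
  relation <-
    if (lo >= reference[1] && hi <= reference[2]) "inside"
    else if (hi < reference[1]) "below"
    else if (lo > reference[2]) "above"
    else "overlapping"
  list(min_percent = lo, max_percent = hi, n_comparisons = length(vals),
       reference = reference, inside_reference = relation == "inside",
       relation = relation)
}
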