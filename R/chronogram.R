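#' Create a chronogram from an ape phylogeny
#'
#' A chronogram is a rooted ultrametric tree with branch lengths in millions
#' of years (My). Node ages are computed as tree height minus root-to-node
#' path length; tip ages within `tol * height` of zero are snapped to 0.
#' A tree whose root-to-tip paths disagree by more than the tolerance is
#' accepted but flagged with a warning (ages remain defined relative to the
#' deepest tip path).
#'
#' @param phy an [ape::phylo] object with branch lengths on all edges.
#' @param tol relative ultrametricity tolerance (default `1e-6`).
#' @return an object of class `"chronogram"`: elements `phy`, `node_age`
#'   (ages for all tips and internal nodes, in My), `height` (root age),
#'   `spread_rel` (max relative spread of root-to-tip paths) and `tol`.
#' @export
as_chronogram <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("expected an ape 'phylo' tree")
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length)) {
    stop("chronogram requires branch lengths on all edges")
  }
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed")
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup)) stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  root_children <- sum(phy$edge[, 1] == root)
  if (root_children > 3L) {
    warning("basal polytomy of degree ", root_children,
            ": tree may be unrooted")
  }
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth[seq_len(ntip)])
  if (height <= 0) stop("tree height must be positive")
  age <- height - depth
  spread_rel <- (height - min(depth[seq_len(ntip)])) / height
  if (spread_rel > tol) {
    warning(sprintf(
      "tree is not ultrametric: relative root-to-tip spread %.3g exceeds %.3g",
      spread_rel, tol))
  }
  tip_age <- age[seq_len(ntip)]
  tip_age[abs(tip_age) <= tol * height] <- 0
  age[seq_len(ntip)] <- tip_age
  structure(
    list(phy = phy, node_age = age, height = height,
         spread_rel = spread_rel, tol = tol),
    class = "chronogram"
  )
}

#' Parse an ultrametric Newick time tree
#'
#' Accepts Newick text or a file path. Quoted labels, internal node labels
#' and support values are tolerated and ignored for age computation;
#' exponent-format branch lengths are accepted.
#'
#' @param newick Newick text (a string containing `(` ) or a file path.
#' @param tol relative ultrametricity tolerance, see [as_chronogram()].
#' @return a `"chronogram"` object.
#' @export
parse_chronogram <- function(newick, tol = 1e-6) {
  phy <- if (grepl("(", newick[1], fixed = TRUE)) {
    tryCatch(ape::read.tree(text = newick),
             error = function(e) NULL, warning = function(w) NULL)
  } else {
    if (!file.exists(newick)) stop("newick file not found: ", newick)
    tryCatch(ape::read.tree(newick),
             error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(phy)) stop("malformed Newick input")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  as_chronogram(phy, tol = tol)
}

#' @export
print.chronogram <- function(x, ...) {
  cat("Chronogram:", ape::Ntip(x$phy), "tips, height",
      format(x$height), "My",
      if (x$spread_rel <= x$tol) "(ultrametric)" else
        sprintf("(NOT ultrametric, spread %.3g)", x$spread_rel), "\n")
  invisible(x)
}

#' Check ultrametricity of a chronogram
#'
#' @param chr a [parse_chronogram()] result.
#' @param tol relative tolerance; defaults to the tolerance stored in `chr`.
#' @return a list with `height`, `max_tip_depth`, `min_tip_depth`,
#'   `spread_rel` and `pass`.
#' @export
check_ultrametric <- function(chr, tol = chr$tol) {
  stopifnot(inherits(chr, "chronogram"))
  depth <- ape::node.depth.edgelength(chr$phy)
  ntip <- ape::Ntip(chr$phy)
  tips <- depth[seq_len(ntip)]
  list(height = max(tips), max_tip_depth = max(tips),
       min_tip_depth = min(tips),
       spread_rel = (max(tips) - min(tips)) / max(tips),
       pass = (max(tips) - min(tips)) / max(tips) <= tol)
}

#' Divergence time of a pair of tips
#'
#' Returns the age (My) of the most recent common ancestor of two distinct
#' tips on the chronogram.
#'
#' @param chr a chronogram.
#' @param a,b tip labels (must differ).
#' @return divergence time in My.
#' @export
pair_time <- function(chr, a, b) {
  stopifnot(inherits(chr, "chronogram"))
  if (identical(a, b)) stop("pair_time requires two distinct tips")
  labs <- chr$phy$tip.label
  missing <- setdiff(c(a, b), labs)
  if (length(missing)) stop("unknown tip label(s): ",
                            paste(missing, collapse = ", "))
  m <- ape::getMRCA(chr$phy, c(a, b))
  unname(chr$node_age[m])
}

# Age of the MRCA of an arbitrary tip set (single tip -> its own age).
mrca_age <- function(chr, tips) {
  if (length(tips) == 1L) {
    return(unname(chr$node_age[match(tips, chr$phy$tip.label)]))
  }
  unname(chr$node_age[ape::getMRCA(chr$phy, tips)])
}

#' Table of pairwise divergence times
#'
#' Computes the MRCA age for every unordered pair of tips, or of species
#' when a species map is supplied (species-level time = age of the MRCA of
#' the union of the two species' tips). Species whose tips are not
#' monophyletic trigger a warning; their MRCA age is still used, which can
#' only overestimate (never underestimate) pair times.
#'
#' @param chr a chronogram.
#' @param sm optional [species_map]; tree tips without an entry are treated
#'   as species of their own.
#' @param cherries_only if `TRUE`, keep only pairs that form a cherry: the
#'   MRCA of the two species' tips has no other descendants.
#' @return a data frame of class `"pair_times"` with columns `species_a`,
#'   `species_b`, `time_my`.
#' @export
pair_time_table <- function(chr, sm = NULL, cherries_only = FALSE) {
  stopifnot(inherits(chr, "chronogram"))
  phy <- chr$phy
  labs <- phy$tip.label
  if (is.null(sm)) {
    sp_of <- stats::setNames(labs, labs)
  } else {
    sp_of <- stats::setNames(sm$species, sm$tip_id)[labs]
    sp_of[is.na(sp_of)] <- labs[is.na(sp_of)]
    names(sp_of) <- labs
  }
  tips_by_sp <- split(labs, sp_of)
  # species in the map with no tips in the tree are simply not in the table
  species <- sort(names(tips_by_sp))
  for (sp in species) {
    tips <- tips_by_sp[[sp]]
    if (length(tips) > 1L &&
        !ape::is.monophyletic(phy, tips)) {
      warning("species '", sp, "' is not monophyletic; using MRCA of its tips")
    }
  }
  desc_count <- function(tips) {
    if (length(tips) == ape::Ntip(phy)) return(ape::Ntip(phy))
    m <- if (length(tips) == 1L) match(tips, labs) else ape::getMRCA(phy, tips)
    if (m <= ape::Ntip(phy)) 1L else
      length(phangorn::Descendants(phy, m, type = "tips")[[1]])
  }
  rows <- list()
  if (length(species) < 2L) stop("need at least 2 species in the tree")
  for (i in seq_len(length(species) - 1L)) {
    for (j in (i + 1L):length(species)) {
      a <- species[i]; b <- species[j]
      tips <- c(tips_by_sp[[a]], tips_by_sp[[b]])
      t_ab <- mrca_age(chr, tips)
      if (cherries_only && desc_count(tips) != length(tips)) next
      rows[[length(rows) + 1L]] <- data.frame(
        species_a = a, species_b = b, time_my = t_ab,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pair_times", "data.frame")
  out
}

#' Write a pair-time table as CSV
#' @param times a [pair_time_table()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_times <- function(times, path) {
  utils::write.csv(as.data.frame(times), path, row.names = FALSE)
  invisible(path)
}
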