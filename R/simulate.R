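#' Expected p-distance under a strict Jukes-Cantor clock
#'
#' For two lineages whose MRCA lies `pair_time` My in the past, evolving at
#' `mu` substitutions/site/My, the expected uncorrected p-distance is
#' `0.75 * (1 - exp(-(8/3) * mu * pair_time))`: monotone increasing in both
#' arguments and saturating at 0.75.
#'
#' @param mu substitution rate (substitutions/site/My), `>= 0`.
#' @param pair_time MRCA age in My, `>= 0`.
#' @return expected p-distance fraction in `[0, 0.75)`.
#' @export
expected_p_jc <- function(mu, pair_time) {
  stopifnot(all(mu >= 0), all(pair_time >= 0))
  0.75 * (1 - exp(-(8 / 3) * mu * pair_time))
}

#' Simulate a Yule (pure-birth) chronogram
#'
#' Simulates a pure-birth tree with `n_species` tips; if `crown_age` is
#' given, branch lengths are rescaled so the crown (root) age equals it
#' exactly. The result is ultrametric by construction. Tips are labelled
#' `sp01`, `sp02`, ...
#'
#' @param n_species number of tip species (>= 2).
#' @param birth_rate speciation rate per lineage per My (default 0.2).
#' @param crown_age target crown age in My, or `NULL` to keep the simulated
#'   depth.
#' @param seed optional integer seed; fixes the topology and branch lengths.
#' @return a `"chronogram"`.
#' @export
simulate_yule_chronogram <- function(n_species, birth_rate = 0.2,
                                     crown_age = NULL, seed = NULL) {
  if (n_species < 2L) stop("need at least 2 species")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  phy$tip.label <- sprintf("sp%02d", seq_len(n_species))
  if (!is.null(crown_age)) {
    if (crown_age <= 0) stop("crown_age must be > 0")
    h <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * (crown_age / h)
  }
  as_chronogram(phy, tol = 1e-9)
}

# Write a Newick string for `phy`, expanding each species tip into a star
# polytomy of its individuals at the given within-species depth. Returns the
# extended tree and its tip-to-species map.
expand_individuals <- function(phy, k, depth) {
  ntip <- ape::Ntip(phy)
  labs <- phy$tip.label
  if (length(k) == 1L) k <- stats::setNames(rep(k, ntip), labs)
  if (is.null(names(k))) stop("per-species individual counts must be named")
  if (any(k < 1L)) stop("individuals_per_species must be >= 1")
  edge_below <- stats::setNames(
    phy$edge.length[match(seq_len(ntip), phy$edge[, 2])], labs)
  d_eff <- stats::setNames(pmin(depth, edge_below / 2), labs)
  if (depth > 0 && any(d_eff < depth)) {
    warning("intraspecific depth reduced to half the terminal branch for ",
            sum(d_eff < depth), " species")
  }
  children <- split(phy$edge[, 2], phy$edge[, 1])
  elen <- stats::setNames(phy$edge.length, phy$edge[, 2])
  build <- function(node) {
    if (node <= ntip) {
      sp <- labs[node]
      kk <- k[[sp]]
      inds <- sprintf("%s_%d", sp, seq_len(kk))
      if (kk == 1L || d_eff[[sp]] == 0) {
        if (kk == 1L) {
          return(sprintf("%s:%.12g", inds[1], elen[[as.character(node)]]))
        }
        # zero depth with several individuals: polytomy directly at the tip
        d <- 0
      } else {
        d <- d_eff[[sp]]
      }
      sub <- paste(sprintf("%s:%.12g", inds, d), collapse = ",")
      return(sprintf("(%s):%.12g", sub, elen[[as.character(node)]] - d))
    }
    sub <- paste(vapply(children[[as.character(node)]], build, ""),
                 collapse = ",")
    len <- elen[as.character(node)]
    if (is.na(len)) sprintf("(%s)", sub)          # root
    else sprintf("(%s):%.12g", sub, len)
  }
  nwk <- paste0(build(ntip + 1L), ";")
  ext <- ape::read.tree(text = nwk)
  sm <- species_map(
    ext$tip.label,
    sub("_[0-9]+$", "", ext$tip.label)
  )
  list(phy = ext, species_map = sm)
}

#' Simulate a strict-clock Jukes-Cantor alignment on a chronogram
#'
#' Draws a root sequence uniform over A/C/G/T and evolves it along the tree
#' under the Jukes-Cantor model at rate `mu` substitutions/site/My (per-site
#' change probability `(3/4)(1 - exp(-4*mu*b/3))` on a branch of length `b`
#' My). Conspecific individuals are attached as a shallow star polytomy of
#' age `intraspecific_depth` below each species tip.
#'
#' @param chr a `"chronogram"` of species.
#' @param mu substitution rate (substitutions/site/My), `>= 0`.
#' @param n_sites alignment length in sites.
#' @param individuals_per_species a single count or a vector named by
#'   species (default 1).
#' @param intraspecific_depth age (My) of the within-species polytomy
#'   (default 0; capped at half the terminal branch).
#' @param seed optional integer seed.
#' @return a list with `alignment` (tips named `<species>_<i>`),
#'   `species_map`, and `tree` (the extended individual-level chronogram).
#' @export
simulate_alignment_jc <- function(chr, mu, n_sites,
                                  individuals_per_species = 1L,
                                  intraspecific_depth = 0,
                                  seed = NULL) {
  stopifnot(inherits(chr, "chronogram"))
  if (mu < 0) stop("mu must be >= 0")
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (intraspecific_depth < 0) stop("intraspecific_depth must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ext <- expand_individuals(chr$phy, individuals_per_species,
                            intraspecific_depth)
  sim <- phangorn::simSeq(ext$phy, l = n_sites, type = "DNA", rate = mu)
  mat <- toupper(as.character(sim))
  rownames(mat) <- names(sim)
  aln <- alignment(mat)
  # keep alignment rows in species-map order for reproducible output
  ord <- match(ext$species_map$tip_id, aln$tip_ids)
  aln$seq <- aln$seq[ord, , drop = FALSE]
  aln$tip_ids <- rownames(aln$seq)
  list(alignment = aln, species_map = ext$species_map,
       tree = as_chronogram(ext$phy, tol = 1e-6))
}

#' Simulate a focal-holdout placement scenario
#'
#' Generates a full chronogram and strict-clock alignment, picks a non-basal
#' species as the focal taxon, records its true divergence time `T*` (the
#' age of the node where it attaches, i.e. the MRCA age with its nearest
#' non-focal clade), and prunes it from the chronogram copy handed to the
#' placement pipeline. The focal species remains in the alignment and
#' species map, emulating a newly sequenced taxon absent from the published
#' time tree.
#'
#' @param n_species number of species (>= 4).
#' @param individuals_per_species individuals per species (default 2).
#' @param birth_rate Yule speciation rate per My (default 0.25).
#' @param crown_age crown age in My (default 30).
#' @param mu substitution rate per site per My (default 5e-4).
#' @param n_sites alignment length (default 2000).
#' @param intraspecific_depth within-species polytomy age in My; default
#'   `0.05 * crown_age`.
#' @param seed integer seed fixing all randomness.
#' @return an object of class `"synthetic_scenario"`: `chronogram` (focal
#'   pruned), `full_chronogram`, `alignment`, `species_map`, `focal`,
#'   `true_time_my`, and `config`.
#' @export
simulate_focal_holdout <- function(n_species = 10L,
                                   individuals_per_species = 2L,
                                   birth_rate = 0.25,
                                   crown_age = 30,
                                   mu = 5e-4,
                                   n_sites = 2000L,
                                   intraspecific_depth = NULL,
                                   seed = NULL) {
  if (n_species < 4L) stop("need at least 4 species for a holdout scenario")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(intraspecific_depth)) intraspecific_depth <- 0.05 * crown_age
  chr <- simulate_yule_chronogram(n_species, birth_rate = birth_rate,
                                  crown_age = crown_age, seed = NULL)
  phy <- chr$phy
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  parent <- phy$edge[match(seq_len(ntip), phy$edge[, 2]), 1]
  eligible <- which(parent != root)
  focal_tip <- phy$tip.label[sample(eligible, 1L)]
  true_time <- unname(chr$node_age[parent[match(focal_tip, phy$tip.label)]])
  pruned <- as_chronogram(ape::drop.tip(phy, focal_tip), tol = chr$tol)
  sim <- simulate_alignment_jc(chr, mu = mu, n_sites = n_sites,
                               individuals_per_species = individuals_per_species,
                               intraspecific_depth = intraspecific_depth,
                               seed = NULL)
  structure(
    list(chronogram = pruned,
         full_chronogram = chr,
         alignment = sim$alignment,
         species_map = sim$species_map,
         focal = focal_tip,
         true_time_my = true_time,
         config = list(n_species = n_species,
                       individuals_per_species = individuals_per_species,
                       birth_rate = birth_rate, crown_age = crown_age,
                       mu = mu, n_sites = n_sites,
                       intraspecific_depth = intraspecific_depth,
                       seed = seed)),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic placement scenario: focal '", x$focal, "', true time ",
      format(x$true_time_my), " My, ",
      length(x$alignment$tip_ids), " sequences x ", x$alignment$n_sites,
      " sites\n", sep = "")
  invisible(x)
}

#' Write a synthetic scenario to disk
#'
#' Writes `alignment.fasta`, `chronogram.nwk` (focal pruned),
#' `full_chronogram.nwk`, `species_map.tsv` and `truth.json` (focal name,
#' true time, config echo) into `dir`, the exact formats the pipeline reads.
#'
#' @param scenario a [simulate_focal_holdout()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(scenario$alignment, file.path(dir, "alignment.fasta"))
  ape::write.tree(scenario$chronogram$phy, file.path(dir, "chronogram.nwk"))
  ape::write.tree(scenario$full_chronogram$phy,
                  file.path(dir, "full_chronogram.nwk"))
  write_species_map(scenario$species_map, file.path(dir, "species_map.tsv"))
  truth <- list(focal = scenario$focal,
                true_time_my = scenario$true_time_my,
                config = scenario$config)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "truth.json"))
  invisible(dir)
}
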