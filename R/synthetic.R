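#' Default host phylogeny for synthetic datasets
#'
#' A fixed six-taxon African-ape-like host tree: three chimpanzee
#' subspecies and the bonobo under genus \emph{Pan}, and western and eastern
#' gorillas under genus \emph{Gorilla}. Branch lengths are documented
#' constants chosen so the two genera are far apart (patristic distance 4.0)
#' relative to within-genus splits (0.3-1.2), mimicking the deep Pan-Gorilla
#' divergence versus recent subspecies splits.
#'
#' @return A \code{phylo} object with 6 tips.
#' @export
default_host_tree <- function() {
  parse_newick_text(paste0(
    "(((Pan_tro_verus:0.30,(Pan_tro_troglodytes:0.15,",
    "Pan_tro_schweinfurthii:0.15):0.15):0.20,Pan_paniscus:0.50):1.50,",
    "(Gorilla_gorilla:0.60,Gorilla_beringei:0.60):1.40);"))
}

#' Genus of each default host taxon
#' @return Named character vector mapping host taxon id to host genus.
#' @export
default_host_genera <- function() {
  c(Pan_tro_verus = "Pan", Pan_tro_troglodytes = "Pan",
    Pan_tro_schweinfurthii = "Pan", Pan_paniscus = "Pan",
    Gorilla_gorilla = "Gorilla", Gorilla_beringei = "Gorilla")
}

#' Default site table for synthetic datasets
#'
#' Seventeen sampling sites spread across equatorial Africa, with
#' coordinates loosely modelled on long-term ape field sites (west African
#' sites for western chimpanzees through east African sites for eastern
#' gorillas).
#'
#' @return Data frame with columns site_id, latitude, longitude.
#' @export
default_sites <- function() {
  data.frame(
    site_id = sprintf("S%02d", 1:17),
    latitude = c(12.70, 7.65, 5.75, -1.90, 2.20, 3.00, 2.30, 0.20, -2.70,
                 -4.70, 0.50, 1.75, 1.40, 2.36, -1.05, -2.30, 2.50),
    longitude = c(-12.20, -8.50, -7.12, 9.30, 16.50, 13.00, 10.00, 22.50,
                  20.40, 29.60, 30.40, 31.50, 28.60, 16.20, 29.70, 28.70,
                  16.90),
    stringsAsFactors = FALSE
  )
}

#' Default geographic ranges of the host taxa
#'
#' Assigns each host taxon the subset of sites where it occurs. Sites S04,
#' S05 and S07 host both a \emph{Pan} and a \emph{Gorilla} taxon, and S13
#' hosts the eastern pair — the sympatric heterogeneric sites the fidelity
#' test depends on.
#'
#' @return Named list mapping host taxon id to a character vector of site
#'   ids.
#' @export
default_host_ranges <- function() {
  list(
    Pan_tro_verus = c("S01", "S02", "S03"),
    Pan_tro_troglodytes = c("S04", "S05", "S06", "S07"),
    Pan_tro_schweinfurthii = c("S10", "S11", "S12", "S13"),
    Pan_paniscus = c("S08", "S09"),
    Gorilla_gorilla = c("S04", "S05", "S07", "S14", "S17"),
    Gorilla_beringei = c("S13", "S15", "S16")
  )
}

#' Configuration for the synthetic cophylogeny generator
#'
#' The generator emulates the sampling design the scan is built for: a
#' six-taxon two-genus host clade sampled at 17 sites (several sympatric),
#' with bacterial clades produced under three regimes — \code{codiv}
#' (clade topology mirrors the host tree: partner fidelity), \code{geo}
#' (clade topology follows a site-distance tree: isolation by distance) and
#' \code{random} (no structure; null control).
#'
#' @param n_codiv_clades,n_geo_clades,n_random_clades Clades per regime
#'   (defaults 20/20/20).
#' @param strains_per_host_taxon Strains contributed per host taxon (codiv
#'   regime) and used to size the other regimes' clades (default 3, i.e. 18
#'   tips per clade).
#' @param within_taxon_noise_sd SD of the |Normal| branch-length noise
#'   attached to each strain tip, in units of the clade diameter (default
#'   0.05, i.e. 5 percent of the clade's maximum tip-to-tip distance).
#' @param geo_tree_noise_sd SD (km) of the symmetric noise added to the
#'   site-to-site haversine matrix before building the geo-regime site tree
#'   (default 50 km).
#' @param clade_diameter Target maximum tip-to-tip distance within each
#'   simulated clade (default 1.0; an arbitrary unit — only ratios matter).
#' @param backbone_scale Length of the backbone stem edge carrying each
#'   clade. Must exceed 10 times the clade diameter so that every simulated
#'   clade falls inside the distal tenth of the assembled tree and no
#'   backbone-spanning node qualifies (default 12).
#' @param host_tree,host_genera,sites,host_ranges The host clade and
#'   sampling design; defaults as documented above.
#' @param phyla Pool of bacterial phylum labels cycled across clades.
#' @param seed Master RNG seed; per-clade streams are derived from it by
#'   stable hashing of the clade id.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_codiv_clades = 20,
                             n_geo_clades = 20,
                             n_random_clades = 20,
                             strains_per_host_taxon = 3,
                             within_taxon_noise_sd = 0.05,
                             geo_tree_noise_sd = 50,
                             clade_diameter = 1.0,
                             backbone_scale = 12,
                             host_tree = default_host_tree(),
                             host_genera = default_host_genera(),
                             sites = default_sites(),
                             host_ranges = default_host_ranges(),
                             phyla = c("Bacteroidota", "Firmicutes_A",
                                       "Firmicutes", "Proteobacteria",
                                       "Actinobacteriota",
                                       "Verrucomicrobiota"),
                             seed = 1L) {
  stopifnot(n_codiv_clades >= 0, n_geo_clades >= 0, n_random_clades >= 0,
            strains_per_host_taxon >= 1,
            within_taxon_noise_sd >= 0, geo_tree_noise_sd >= 0,
            clade_diameter > 0, backbone_scale > 0)
  stopifnot(all(host_tree$tip.label %in% names(host_genera)),
            all(names(host_ranges) %in% host_tree$tip.label),
            all(unlist(host_ranges) %in% sites$site_id))
  structure(list(
    n_codiv_clades = as.integer(n_codiv_clades),
    n_geo_clades = as.integer(n_geo_clades),
    n_random_clades = as.integer(n_random_clades),
    strains_per_host_taxon = as.integer(strains_per_host_taxon),
    within_taxon_noise_sd = within_taxon_noise_sd,
    geo_tree_noise_sd = geo_tree_noise_sd,
    clade_diameter = clade_diameter,
    backbone_scale = backbone_scale,
    host_tree = host_tree,
    host_genera = host_genera,
    sites = sites,
    host_ranges = host_ranges,
    phyla = phyla,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

fmt_len <- function(x) formatC(x, format = "g", digits = 12)

# Replace each named tip token of a newick string with a multifurcating
# group of strain tips attached at that point, ":len" suffixes preserved.
graft_strains <- function(nwk, groups) {
  for (tax in names(groups)) {
    g <- groups[[tax]]
    rep_txt <- if (length(g$labels) == 1 && is.null(g$lengths)) {
      g$labels
    } else {
      paste0("(", paste0(g$labels, ":", fmt_len(g$lengths), collapse = ","),
             ")")
    }
    nwk <- sub(paste0(tax, ":"), paste0(rep_txt, ":"), nwk, fixed = TRUE)
  }
  nwk
}

rescale_to_diameter <- function(phy, target) {
  d <- clade_table(phy)$tree_diameter
  if (d <= 0) stop("degenerate tree: zero diameter", call. = FALSE)
  phy$edge.length <- phy$edge.length * (target / d)
  phy
}

strain_labels <- function(clade_id, n) sprintf("%s_t%02d", clade_id, seq_len(n))

#' Simulate one co-diversifying (partner-fidelity) clade
#'
#' The clade's backbone is the host tree rescaled to the target clade
#' diameter, so between-host-taxon strain distances are proportional to host
#' patristic distances. Each host taxon contributes
#' \code{strains_per_host_taxon} strain tips attached at the taxon's
#' position with branch lengths |Normal(0, within_taxon_noise_sd)| (in
#' clade-diameter units). Each strain is sampled at a site drawn uniformly
#' from its host taxon's range. With zero noise and one strain per taxon the
#' clade's patristic matrix equals the host matrix up to a positive scale,
#' so the scan's r_phylo is exactly 1.
#'
#' @param config A [synthetic_config()] list.
#' @param clade_seed Integer seed for this clade's RNG stream.
#' @param clade_id Label prefix for the clade's tips.
#' @return List with \code{tree} (\code{phylo}) and \code{metadata} rows for
#'   the clade's tips (without phylum/genus, filled by
#'   [assemble_dataset()]).
#' @export
simulate_codiv_clade <- function(config, clade_seed, clade_id = "codiv") {
  with_seed(clade_seed, {
    host <- rescale_to_diameter(config$host_tree, config$clade_diameter)
    nwk <- ape::write.tree(host, digits = 12)
    k <- config$strains_per_host_taxon
    groups <- list()
    md <- list()
    for (tax in host$tip.label) {
      labs <- paste0(clade_id, "_", tax, sprintf("_t%02d", seq_len(k)))
      lens <- abs(stats::rnorm(k, 0, config$within_taxon_noise_sd *
                                 config$clade_diameter))
      range <- config$host_ranges[[tax]]
      tip_sites <- sample(range, k, replace = TRUE)
      groups[[tax]] <- list(labels = labs, lengths = lens)
      md[[tax]] <- data.frame(
        tip_id = labs,
        host_taxon_id = tax,
        host_genus = unname(config$host_genera[tax]),
        site_id = tip_sites,
        stringsAsFactors = FALSE
      )
    }
    tree <- ape::collapse.singles(parse_newick_text(graft_strains(nwk, groups)))
    list(tree = tree, metadata = do.call(rbind, c(md, make.row.names = FALSE)))
  })
}

#' Simulate one geography-driven (isolation-by-distance) clade
#'
#' A site-level tree is built by average-linkage agglomeration of the
#' site-to-site haversine matrix perturbed by symmetric Normal noise
#' (\code{geo_tree_noise_sd} km), then rescaled to the clade diameter.
#' Strains attach at their site's tip, and each strain's host taxon is drawn
#' uniformly from the taxa whose range includes that site — so at sympatric
#' sites, strains from the two host genera are each other's closest
#' relatives and host taxon is decoupled from the tree. This makes the geo
#' regime a true negative control for partner fidelity.
#'
#' @inheritParams simulate_codiv_clade
#' @return As [simulate_codiv_clade()].
#' @export
simulate_geo_clade <- function(config, clade_seed, clade_id = "geo") {
  if (nrow(config$sites) < 3) stop("need >= 3 sites", call. = FALSE)
  with_seed(clade_seed, {
    sites <- config$sites
    m <- nrow(sites)
    D <- geo_site_distances(sites)
    noise <- matrix(stats::rnorm(m * m, 0, config$geo_tree_noise_sd), m, m)
    noise <- (noise + t(noise)) / 2
    diag(noise) <- 0
    Dn <- pmax(D + noise, 0)
    site_tree <- ape::as.phylo(stats::hclust(stats::as.dist(Dn),
                                             method = "average"))
    n_strains <- config$strains_per_host_taxon * length(config$host_tree$tip.label)
    occupied <- sites$site_id[vapply(sites$site_id, function(s) {
      any(vapply(config$host_ranges, function(r) s %in% r, logical(1)))
    }, logical(1))]
    repeat {
      strain_sites <- sample(occupied, n_strains, replace = TRUE)
      if (length(unique(strain_sites)) >= 3) break
    }
    used <- sort(unique(strain_sites))
    site_tree <- ape::keep.tip(site_tree, used)
    site_tree <- rescale_to_diameter(site_tree, config$clade_diameter)
    nwk <- ape::write.tree(site_tree, digits = 12)
    groups <- list()
    md <- list()
    counter <- 0L
    for (s in used) {
      idx <- which(strain_sites == s)
      labs <- paste0(clade_id, "_", s, sprintf("_t%02d", seq_along(idx)))
      lens <- abs(stats::rnorm(length(idx), 0,
                               config$within_taxon_noise_sd *
                                 config$clade_diameter))
      occupants <- names(config$host_ranges)[vapply(config$host_ranges,
                                                    function(r) s %in% r,
                                                    logical(1))]
      taxa <- sample(occupants, length(idx), replace = TRUE)
      groups[[s]] <- list(labels = labs, lengths = lens)
      md[[s]] <- data.frame(
        tip_id = labs,
        host_taxon_id = taxa,
        host_genus = unname(config$host_genera[taxa]),
        site_id = s,
        stringsAsFactors = FALSE
      )
      counter <- counter + length(idx)
    }
    tree <- ape::collapse.singles(parse_newick_text(graft_strains(nwk, groups)))
    list(tree = tree, metadata = do.call(rbind, c(md, make.row.names = FALSE)))
  })
}

#' Simulate one unstructured (null) clade
#'
#' A random bifurcating topology with exponential branch lengths, rescaled
#' to the clade diameter; each tip's host taxon is uniform over the host
#' taxa and its site uniform over that taxon's range. Strain distances carry
#' no information about either reference, so scan p-values on these clades
#' are approximately uniform.
#'
#' @inheritParams simulate_codiv_clade
#' @return As [simulate_codiv_clade()].
#' @export
simulate_random_clade <- function(config, clade_seed, clade_id = "random") {
  with_seed(clade_seed, {
    n <- config$strains_per_host_taxon * length(config$host_tree$tip.label)
    tree <- ape::rtree(n, br = function(k) stats::rexp(k, rate = 1))
    tree <- rescale_to_diameter(tree, config$clade_diameter)
    labs <- strain_labels(clade_id, n)
    tree$tip.label <- labs[as.integer(sub("^t", "", tree$tip.label))]
    taxa <- sample(names(config$host_ranges), n, replace = TRUE)
    tip_sites <- vapply(taxa, function(tax) {
      r <- config$host_ranges[[tax]]
      r[sample.int(length(r), 1)]
    }, character(1))
    md <- data.frame(
      tip_id = labs,
      host_taxon_id = taxa,
      host_genus = unname(config$host_genera[taxa]),
      site_id = unname(tip_sites),
      stringsAsFactors = FALSE
    )
    list(tree = tree, metadata = md)
  })
}

#' Assemble a complete synthetic dataset
#'
#' Simulates all configured clades and grafts them, each on its own long
#' backbone stem (length \code{backbone_scale}), onto a single root — a star
#' backbone, so the only node spanning backbone edges is the root, whose
#' diameter is the whole tree's. The stem length guarantees every simulated
#' clade's diameter is at most 10 percent of the full-tree diameter (checked; a
#' violating clade raises a configuration error naming it). Bacterial
#' phylum labels are cycled across clades and each clade receives its own
#' genus label, so taxon-level summaries are exercised.
#'
#' @param config A [synthetic_config()] list.
#' @return An object of class \code{codiv_dataset}: list with \code{tree},
#'   \code{metadata}, \code{sites}, \code{host_tree}, \code{host_genera},
#'   and \code{truth} (data frame clade_id, regime, node_id, seed).
#' @export
assemble_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  specs <- list()
  add <- function(regime, n) {
    for (i in seq_len(n)) {
      id <- sprintf("%s%03d", regime, i)
      specs[[length(specs) + 1L]] <<- list(regime = regime, clade_id = id)
    }
  }
  add("codiv", config$n_codiv_clades)
  add("geo", config$n_geo_clades)
  add("random", config$n_random_clades)

  if (length(specs) == 0) {
    empty_md <- data.frame(tip_id = character(0), host_taxon_id = character(0),
                           host_genus = character(0), site_id = character(0),
                           phylum = character(0), genus = character(0),
                           stringsAsFactors = FALSE)
    return(structure(list(tree = NULL, metadata = empty_md,
                          sites = config$sites, host_tree = config$host_tree,
                          host_genera = config$host_genera,
                          truth = data.frame(clade_id = character(0),
                                             regime = character(0),
                                             node_id = character(0),
                                             seed = integer(0),
                                             stringsAsFactors = FALSE),
                          config = config),
                     class = "codiv_dataset"))
  }

  clades <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    seed_j <- hash_fold(config$seed, sp$clade_id)
    sim <- switch(sp$regime,
                  codiv = simulate_codiv_clade(config, seed_j, sp$clade_id),
                  geo = simulate_geo_clade(config, seed_j, sp$clade_id),
                  random = simulate_random_clade(config, seed_j, sp$clade_id))
    sim$regime <- sp$regime
    sim$clade_id <- sp$clade_id
    sim$seed <- seed_j
    clades[[j]] <- sim
  }

  subs <- vapply(clades, function(cl) {
    sub(";$", "", ape::write.tree(cl$tree, digits = 12))
  }, character(1))
  full_nwk <- paste0("(", paste0(subs, ":", fmt_len(config$backbone_scale),
                                 collapse = ","), ");")
  tree <- parse_newick_text(full_nwk)

  info <- clade_table(tree)
  max_allowed <- 0.1 * info$tree_diameter
  md_all <- list()
  truth <- list()
  for (j in seq_along(clades)) {
    cl <- clades[[j]]
    d <- clade_table(cl$tree)$tree_diameter
    if (d > max_allowed + 1e-9) {
      stop("backbone_scale too small: clade ", cl$clade_id,
           " has diameter ", format(d), " > 10% of tree diameter (",
           format(info$tree_diameter), ")", call. = FALSE)
    }
    md <- cl$metadata
    md$phylum <- config$phyla[((j - 1) %% length(config$phyla)) + 1]
    md$genus <- paste0("g_", cl$clade_id)
    md_all[[j]] <- md
    truth[[j]] <- data.frame(clade_id = cl$clade_id, regime = cl$regime,
                             node_id = clade_node_id(cl$tree$tip.label),
                             seed = cl$seed, stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, c(md_all, make.row.names = FALSE))
  if (anyDuplicated(metadata$tip_id)) {
    stop("internal error: duplicate synthetic tip labels", call. = FALSE)
  }
  structure(list(
    tree = tree,
    metadata = metadata,
    sites = config$sites,
    host_tree = config$host_tree,
    host_genera = config$host_genera,
    truth = do.call(rbind, c(truth, make.row.names = FALSE)),
    config = config
  ), class = "codiv_dataset")
}

#' @export
print.codiv_dataset <- function(x, ...) {
  cat("Synthetic co-diversification dataset\n")
  cat("  strains:", nrow(x$metadata),
      " clades:", nrow(x$truth),
      " (", paste(names(table(x$truth$regime)),
                  table(x$truth$regime), collapse = ", "), ")\n")
  cat("  host taxa:", length(x$host_tree$tip.label),
      " sites:", nrow(x$sites), "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits \code{strains.nwk}, \code{tips.tsv}, \code{sites.tsv},
#' \code{host.nwk} and \code{truth.tsv} (all UTF-8, TSV with header).
#'
#' @param dataset A \code{codiv_dataset} object.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "codiv_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(dataset$tree, file.path(dir, "strains.nwk"))
  write_newick(dataset$host_tree, file.path(dir, "host.nwk"))
  write_tsv(dataset$metadata, file.path(dir, "tips.tsv"))
  write_tsv(dataset$sites, file.path(dir, "sites.tsv"))
  write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = NA, comment.char = "", quote = "",
                    encoding = "UTF-8")
}
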