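#' Assign a scanned clade to a bacterial taxon at a given rank
#'
#' A clade belongs to a taxon when all of its tips share that taxon label at
#' the requested rank; clades mixing taxa at the rank are unassigned and are
#' excluded from that rank's summaries.
#'
#' @param tips Character vector of the clade's tip labels.
#' @param metadata Tip metadata with \code{phylum} and \code{genus} columns.
#' @param rank \code{"phylum"} or \code{"genus"}.
#' @return The shared taxon label, or \code{NA_character_} if mixed.
#' @export
assign_clade_taxon <- function(tips, metadata, rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  vals <- metadata[[rank]][match(tips, metadata$tip_id)]
  if (anyNA(vals)) stop("metadata does not cover all clade tips", call. = FALSE)
  u <- unique(vals)
  if (length(u) == 1) u else NA_character_
}

#' Branch-length-weighted centroids of Mantel correlations per taxon
#'
#' For each taxon, the weighted mean of the clade-level Mantel correlations
#' with host phylogeny and geography, weighting each tested node by its clade
#' branch length. Nodes with an undefined correlation on a side are omitted
#' from that side's mean; taxa with no usable node on either side are
#' dropped.
#'
#' @param results Data frame with columns \code{r_phylo}, \code{r_geo},
#'   \code{delta} (rows = tested nodes).
#' @param weights Numeric vector of node weights (clade branch lengths).
#' @param taxa Character vector of taxon assignments per node
#'   (\code{NA} = unassigned, dropped).
#' @return Data frame, one row per taxon: \code{taxon}, \code{n_nodes},
#'   \code{weight}, \code{weighted_mean_r_phylo}, \code{weighted_mean_r_geo},
#'   \code{weighted_mean_delta}.
#' @export
weighted_centroids <- function(results, weights, taxa) {
  stopifnot(nrow(results) == length(weights), length(weights) == length(taxa))
  keep <- !is.na(taxa)
  results <- results[keep, , drop = FALSE]
  weights <- weights[keep]
  taxa <- taxa[keep]
  wmean <- function(x, w) {
    ok <- !is.na(x) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  rows <- lapply(split(seq_along(taxa), taxa), function(idx) {
    data.frame(
      taxon = taxa[idx[1]],
      n_nodes = length(idx),
      weight = sum(weights[idx]),
      weighted_mean_r_phylo = wmean(results$r_phylo[idx], weights[idx]),
      weighted_mean_r_geo = wmean(results$r_geo[idx], weights[idx]),
      weighted_mean_delta = wmean(results$delta[idx], weights[idx]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  keep <- !(is.na(out$weighted_mean_r_phylo) & is.na(out$weighted_mean_r_geo))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact sign test
#'
#' Exact binomial tail under the fair-coin null, used to test whether more
#' taxa show a stronger Mantel correlation with host phylogeny than with
#' geography than expected by chance. One-sided (greater) by default.
#'
#' @param successes Number of successes (e.g. taxa with
#'   \code{r_phylo > r_geo}).
#' @param n Number of trials.
#' @param alternative \code{"greater"} (default) for the upper tail
#'   P(X >= successes), or \code{"two.sided"} for the exact two-sided test.
#' @return The p-value.
#' @export
sign_test <- function(successes, n, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n < 1 || successes < 0 || successes > n) {
    stop("require 0 <= successes <= n and n >= 1", call. = FALSE)
  }
  if (alternative == "greater") {
    stats::pbinom(successes - 1, n, 0.5, lower.tail = FALSE)
  } else {
    stats::binom.test(successes, n, 0.5, alternative = "two.sided")$p.value
  }
}

#' Weighted Welch t-test
#'
#' Welch-type two-sample t-test on weighted means and weighted variances,
#' with effective sample sizes \eqn{n_{eff} = (\sum w)^2 / \sum w^2} and
#' Satterthwaite degrees of freedom. With equal weights it reduces exactly to
#' the ordinary Welch t-test, and rescaling all weights within a group leaves
#' the result unchanged (weights act as reliability weights).
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param weights_a,weights_b Positive weights of matching length.
#' @return List with \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{mean_a}, \code{mean_b}.
#' @export
weighted_t_test <- function(values_a, weights_a, values_b, weights_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 entries", call. = FALSE)
  }
  stopifnot(length(values_a) == length(weights_a),
            length(values_b) == length(weights_b))
  if (any(c(weights_a, weights_b) < 0) ||
      sum(weights_a) <= 0 || sum(weights_b) <= 0) {
    stop("weights must be non-negative with positive total", call. = FALSE)
  }
  moments <- function(x, w) {
    sw <- sum(w)
    m <- sum(w * x) / sw
    neff <- sw^2 / sum(w^2)
    v <- sum(w * (x - m)^2) / sw * neff / (neff - 1)
    list(m = m, v = v, neff = neff)
  }
  a <- moments(values_a, weights_a)
  b <- moments(values_b, weights_b)
  se2 <- a$v / a$neff + b$v / b$neff
  if (se2 == 0) {
    t <- if (a$m == b$m) 0 else sign(a$m - b$m) * Inf
    return(list(t = t, df = a$neff + b$neff - 2,
                p = if (t == 0) 1 else 0, mean_a = a$m, mean_b = b$m))
  }
  t <- (a$m - b$m) / sqrt(se2)
  df <- se2^2 / ((a$v / a$neff)^2 / (a$neff - 1) +
                   (b$v / b$neff)^2 / (b$neff - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_a = a$m, mean_b = b$m)
}

#' Total branch length of the minimal subtree spanning a set of tips
#'
#' The "unique branch length" of a taxon: the sum of branch lengths of edges
#' lying on a path between two of the taxon's tips, each edge counted once.
#'
#' @param tree A \code{phylo} object.
#' @param tips Tip labels (>= 1; a single tip spans no edges, length 0).
#' @return Total spanning-subtree branch length.
#' @export
unique_branch_length <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tip label(s)", call. = FALSE)
  if (length(idx) < 2) return(0)
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  count <- integer(ntot)
  count[idx] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  L <- po$edge.length
  total <- length(idx)
  # an edge is on a tip-tip path iff its child subtree holds some but not all
  # of the tips
  len <- 0
  for (k in seq_len(nrow(E))) {
    p <- E[k, 1]; ch <- E[k, 2]
    if (count[ch] > 0L && count[ch] < total) len <- len + L[k]
    count[p] <- count[p] + count[ch]
  }
  len
}

#' Simulation-based phylogenetic analysis of variance
#'
#' One-way ANOVA of a continuous trait across groups of taxa, with the null
#' distribution of the F statistic generated by Brownian-motion simulation of
#' the trait along the taxon phylogeny (rate estimated from the observed
#' trait by maximum likelihood under BM), so phylogenetic covariance among
#' taxa is accounted for. On a star phylogeny the simulations reduce to
#' i.i.d. normals and the p-value converges to the ordinary ANOVA p.
#'
#' @param taxon_tree Phylogeny whose tips are the taxa (\code{phylo}).
#' @param trait Named numeric vector of trait values (names = tips).
#' @param groups Named character/factor vector of group labels (names = tips).
#' @param n_simulations Number of BM simulations (default 1000).
#' @param seed Optional integer seed.
#' @return List with \code{F}, \code{p}, \code{n_simulations},
#'   \code{sigma2} (ML Brownian rate).
#' @export
phylogenetic_anova <- function(taxon_tree, trait, groups,
                               n_simulations = 1000, seed = NULL) {
  stopifnot(inherits(taxon_tree, "phylo"))
  tips <- taxon_tree$tip.label
  if (!all(tips %in% names(trait)) || !all(tips %in% names(groups))) {
    stop("trait and groups must be named by the tree's tips", call. = FALSE)
  }
  x <- as.numeric(trait[tips])
  g <- factor(as.character(groups[tips]))
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  n <- length(x)
  k <- nlevels(g)
  f_stat <- function(v) {
    gm <- tapply(v, g, mean)
    ni <- tabulate(g)
    grand <- mean(v)
    ssb <- sum(ni * (gm - grand)^2)
    ssw <- sum((v - gm[g])^2)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  if (stats::var(x) == 0) {
    return(list(F = 0, p = 1, n_simulations = as.integer(n_simulations),
                sigma2 = 0))
  }
  f_obs <- f_stat(x)
  C <- ape::vcv(taxon_tree)[tips, tips]
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric(crossprod(one, Ci %*% x) / crossprod(one, Ci %*% one))
  sigma2 <- as.numeric(crossprod(x - mu, Ci %*% (x - mu))) / n  # ML rate
  Lc <- chol(C)
  f_sim <- with_seed(seed, {
    z <- matrix(stats::rnorm(n * n_simulations), n, n_simulations)
    xs <- crossprod(Lc, z) * sqrt(sigma2)
    apply(xs, 2, f_stat)
  })
  p <- (1 + sum(f_sim >= f_obs)) / (1 + n_simulations)
  list(F = f_obs, p = p, n_simulations = as.integer(n_simulations),
       sigma2 = sigma2)
}

#' Taxon-level summaries of a co-diversification scan
#'
#' Builds the branch-length-weighted (r_geo, r_phylo) centroid per taxon at
#' the requested rank (see [weighted_centroids()]) and the sign test for an
#' excess of taxa with stronger host-phylogeny than geography association.
#'
#' @param scan A \code{codiv_scan} object.
#' @param metadata Tip metadata.
#' @param rank \code{"phylum"} or \code{"genus"}.
#' @return List with \code{summaries} (the centroid data frame, plus a
#'   \code{max_delta} column: the maximum delta over the taxon's nodes),
#'   \code{n_phylo_greater}, \code{n_taxa}, \code{sign_test_p}.
#' @export
taxon_summaries <- function(scan, metadata, rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  taxa <- vapply(scan$clades, function(cl) {
    val <- assign_clade_taxon(cl$tips, metadata, rank)
    if (is.na(val)) NA_character_ else val
  }, character(1))
  weights <- vapply(scan$clades, `[[`, numeric(1), "clade_branch_length")
  cents <- weighted_centroids(scan$results, weights, taxa)
  max_delta <- vapply(cents$taxon, function(tx) {
    d <- scan$results$delta[!is.na(taxa) & taxa == tx]
    if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE)
  }, numeric(1))
  cents$max_delta <- max_delta
  comparable <- !is.na(cents$weighted_mean_r_phylo) &
    !is.na(cents$weighted_mean_r_geo)
  succ <- sum(cents$weighted_mean_r_phylo[comparable] >
                cents$weighted_mean_r_geo[comparable])
  ntax <- sum(comparable)
  list(
    summaries = cents,
    n_phylo_greater = succ,
    n_taxa = ntax,
    sign_test_p = if (ntax >= 1) sign_test(succ, ntax) else NA_real_
  )
}

#' Pairwise phylum comparisons of per-genus delta, weighted by genus branch
#' length
#'
#' For each pair of phyla containing at least \code{min_genera} genera,
#' compares the per-genus weighted-mean \code{delta = r_phylo - r_geo} values
#' between the phyla with a weighted Welch t-test, weighting each genus by
#' its unique branch length on the strain phylogeny; p-values are
#' Holm-corrected across all pairs.
#'
#' @param scan A \code{codiv_scan} object.
#' @param tree The strain phylogeny.
#' @param metadata Tip metadata (needs \code{phylum} and \code{genus}).
#' @param min_genera Minimum genera per phylum for inclusion (default 5).
#' @return Data frame: phylum_a, phylum_b, n_genera_a, n_genera_b, t, df,
#'   p, p_holm.
#' @export
phylum_pairwise_tests <- function(scan, tree, metadata, min_genera = 5) {
  gen <- taxon_summaries(scan, metadata, rank = "genus")$summaries
  gen <- gen[!is.na(gen$weighted_mean_delta), , drop = FALSE]
  if (nrow(gen) == 0) return(empty_pairwise_df())
  genus_phylum <- tapply(metadata$phylum, metadata$genus,
                         function(p) if (length(unique(p)) == 1) p[1] else NA)
  gen$phylum <- as.character(genus_phylum[gen$taxon])
  gen <- gen[!is.na(gen$phylum), , drop = FALSE]
  gen$ubl <- vapply(gen$taxon, function(gname) {
    unique_branch_length(tree, metadata$tip_id[metadata$genus == gname])
  }, numeric(1))
  gen <- gen[gen$ubl > 0, , drop = FALSE]
  counts <- table(gen$phylum)
  phyla <- sort(names(counts)[counts >= min_genera])
  if (length(phyla) < 2) return(empty_pairwise_df())
  pairs <- utils::combn(phyla, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    pa <- pairs[1, j]; pb <- pairs[2, j]
    ga <- gen[gen$phylum == pa, ]
    gb <- gen[gen$phylum == pb, ]
    tt <- weighted_t_test(ga$weighted_mean_delta, ga$ubl,
                          gb$weighted_mean_delta, gb$ubl)
    data.frame(phylum_a = pa, phylum_b = pb,
               n_genera_a = nrow(ga), n_genera_b = nrow(gb),
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_correction(pmin(out$p, 1))
  out
}

empty_pairwise_df <- function() {
  data.frame(phylum_a = character(0), phylum_b = character(0),
             n_genera_a = integer(0), n_genera_b = integer(0),
             t = numeric(0), df = numeric(0), p = numeric(0),
             p_holm = numeric(0), stringsAsFactors = FALSE)
}

#' Phylogenetic ANOVA of lifestyle traits on per-genus maximum delta
#'
#' Tests whether the maximum \code{r_phylo - r_geo} attained by a genus's
#' clades differs between lifestyle categories (e.g. aerobes vs anaerobes,
#' spore formers vs non-spore-formers) after accounting for bacterial
#' phylogenetic history, via [phylogenetic_anova()] on a genus-level tree.
#'
#' @param scan A \code{codiv_scan} object.
#' @param tree Strain phylogeny (used to derive a genus-level tree by keeping
#'   one representative tip per genus).
#' @param metadata Tip metadata.
#' @param traits Data frame with columns \code{genus} plus one or more trait
#'   columns (e.g. \code{oxygen_class}, \code{spore_forming}).
#' @param trait_cols Which trait columns to test (default: all but genus).
#' @param n_simulations,seed Passed to [phylogenetic_anova()].
#' @return Data frame: trait, F, p, n_genera.
#' @export
trait_anova <- function(scan, tree, metadata, traits,
                        trait_cols = setdiff(names(traits), "genus"),
                        n_simulations = 1000, seed = NULL) {
  gen <- taxon_summaries(scan, metadata, rank = "genus")$summaries
  gen <- gen[!is.na(gen$max_delta), , drop = FALSE]
  merged <- merge(gen, traits, by.x = "taxon", by.y = "genus")
  if (nrow(merged) < 4) {
    stop("too few genera with both scan results and trait data", call. = FALSE)
  }
  # genus-level tree: one representative tip per genus, relabeled
  rep_tips <- vapply(merged$taxon, function(gname) {
    metadata$tip_id[metadata$genus == gname][1]
  }, character(1))
  gtree <- ape::keep.tip(tree, rep_tips)
  gtree$tip.label <- merged$taxon[match(gtree$tip.label, rep_tips)]
  rows <- lapply(trait_cols, function(tc) {
    grp <- stats::setNames(as.character(merged[[tc]]), merged$taxon)
    ok <- !is.na(grp)
    tab <- table(grp[ok])
    if (length(tab) < 2 || any(tab < 2)) {
      return(data.frame(trait = tc, F = NA_real_, p = NA_real_,
                        n_genera = sum(ok), stringsAsFactors = FALSE))
    }
    sub <- ape::keep.tip(gtree, names(grp)[ok])
    res <- phylogenetic_anova(
      sub,
      stats::setNames(merged$max_delta, merged$taxon)[sub$tip.label],
      grp[sub$tip.label],
      n_simulations = n_simulations,
      seed = if (is.null(seed)) NULL else hash_fold(seed, tc)
    )
    data.frame(trait = tc, F = res$F, p = res$p, n_genera = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
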