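#' Mantel correlation between two labeled distance matrices
#'
#' Pearson correlation over the strictly-upper-triangle entries, the standard
#' Mantel statistic. The second matrix is re-ordered to the label order of the
#' first before comparison.
#'
#' @param d1,d2 Labeled symmetric distance matrices over the same label set.
#' @return The correlation in \[-1, 1\], or \code{NA_real_} when either upper
#'   triangle has zero variance (undefined correlation, not an error).
#' @export
mantel_r <- function(d1, d2) {
  labs <- rownames(d1)
  if (!setequal(labs, rownames(d2))) {
    stop("matrices do not share a label set", call. = FALSE)
  }
  d2 <- d2[labs, labs, drop = FALSE]
  x <- upper_vals(d1)
  y <- upper_vals(d2)
  if (length(x) < 1) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Mantel permutation test
#'
#' Tests for positive association between a symbiont (strain) patristic
#' distance matrix and a reference (host-phylogenetic or geographic) distance
#' matrix. The observed Mantel correlation is compared with a null
#' distribution obtained by jointly permuting the rows and columns of the
#' reference matrix; the p-value is one-tailed (greater), with the +1
#' correction in numerator and denominator so p is never exactly 0, and
#' permuted correlations tying the observed one count as at least as extreme.
#'
#' @param symbiont_D Strain patristic distance matrix (labeled, symmetric).
#' @param reference_D Reference distance matrix over the same labels.
#' @param n_permutations Number of random permutations (default 1000).
#' @param seed Optional integer seed; identical seed gives identical p.
#' @return A list with elements \code{r} (observed correlation or \code{NA}),
#'   \code{p} (permutation p-value or \code{NA}), \code{n} (matrix dimension),
#'   \code{n_permutations}, and \code{untestable} (\code{TRUE} when either
#'   triangle is constant, in which case no test is performed).
#' @export
mantel_permutation_test <- function(symbiont_D, reference_D,
                                    n_permutations = 1000, seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  labs <- rownames(symbiont_D)
  if (!setequal(labs, rownames(reference_D))) {
    stop("matrices do not share a label set", call. = FALSE)
  }
  reference_D <- reference_D[labs, labs, drop = FALSE]
  n <- nrow(symbiont_D)
  ut <- upper.tri(symbiont_D)
  x <- symbiont_D[ut]
  y <- reference_D[ut]
  out <- list(r = NA_real_, p = NA_real_, n = n,
              n_permutations = as.integer(n_permutations), untestable = TRUE)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(out)
  r_obs <- stats::cor(x, y)
  eps <- 1e-9
  hits <- with_seed(seed, {
    h <- 0L
    for (i in seq_len(n_permutations)) {
      perm <- sample.int(n)
      yp <- reference_D[perm, perm][ut]
      if (stats::cor(x, yp) >= r_obs - eps) h <- h + 1L
    }
    h
  })
  out$r <- r_obs
  out$p <- (1 + hits) / (1 + n_permutations)
  out$untestable <- FALSE
  out
}

# Exact permutation p by full enumeration of all n! joint relabelings of the
# reference matrix. Tractable for <= 7 or 8 labels; used as the oracle the
# sampling estimator is checked against.
mantel_exact_p <- function(symbiont_D, reference_D) {
  labs <- rownames(symbiont_D)
  reference_D <- reference_D[labs, labs, drop = FALSE]
  n <- nrow(symbiont_D)
  if (n > 8) stop("exact enumeration limited to <= 8 labels", call. = FALSE)
  ut <- upper.tri(symbiont_D)
  x <- symbiont_D[ut]
  r_obs <- stats::cor(x, reference_D[ut])
  eps <- 1e-9
  perms <- all_permutations(n)
  hits <- 0L
  for (k in seq_len(nrow(perms))) {
    perm <- perms[k, ]
    yp <- reference_D[perm, perm][ut]
    if (stats::cor(x, yp) >= r_obs - eps) hits <- hits + 1L
  }
  list(r = r_obs, p = hits / nrow(perms), n_permutations = nrow(perms))
}

# All permutations of 1..n as rows of a matrix (recursive construction).
all_permutations <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  row <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    block <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up BH adjusted p-values (wrapper over [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted values, each >= its raw p and <= 1; empty in, empty out.
#' @export
adjust_bh <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Holm family-wise-error adjustment
#'
#' Standard step-down Holm adjusted p-values (wrapper over
#' [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted values, monotone and capped at 1.
#' @export
holm_correction <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}
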