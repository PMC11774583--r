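# Internal helpers: deterministic string hashing for per-node RNG streams,
# seed-scoped evaluation, and distance-matrix validation.

# 31-fold string hash modulo 2^31 - 1. Used to derive per-node / per-clade
# RNG seeds from a master seed and a stable identifier, so results do not
# depend on iteration order.
hash_fold <- function(...) {
  parts <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(parts)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

# Stable identifier for a clade: hex hash of its sorted tip-label set.
# Invariant under re-ordering of tips in the input files.
clade_node_id <- function(tip_labels) {
  sprintf("c%08x", hash_fold(paste(sort(tip_labels), collapse = "|")))
}

assert_distance_matrix <- function(m, what = "distance matrix",
                                   tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(m) != ncol(m)) stop(what, " must be square", call. = FALSE)
  labs <- rownames(m)
  if (is.null(labs) || is.null(colnames(m))) {
    stop(what, " must carry row and column labels", call. = FALSE)
  }
  if (!identical(labs, colnames(m))) {
    stop(what, ": row and column labels differ", call. = FALSE)
  }
  if (anyDuplicated(labs)) stop(what, ": duplicate labels", call. = FALSE)
  if (any(!is.finite(m))) stop(what, ": non-finite entries", call. = FALSE)
  if (any(m < -tol)) stop(what, ": negative entries", call. = FALSE)
  if (max(abs(m - t(m))) > tol) stop(what, ": not symmetric", call. = FALSE)
  if (max(abs(diag(m))) > tol) stop(what, ": non-zero diagonal", call. = FALSE)
  invisible(m)
}

upper_vals <- function(m) m[upper.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
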