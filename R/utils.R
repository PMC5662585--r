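## Internal helpers: seeding, small utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

`%|na|%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

## Set the RNG seed, returning a restore function, so package functions
## never clobber the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

## Stable 31-bit hash of a character key, folded with a master seed.
## Used to give every pig (and every pipeline stage) its own substream so
## that adding pigs or stages never perturbs existing draws.
substream_seed <- function(master, key) {
  h <- 0
  for (cp in utf8ToInt(paste0(key, ":", as.integer(master))))
    h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

## Drop aliased (rank-deficient) columns of a design matrix, keeping the
## 'assign' attribute in step.
drop_aliased <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank == ncol(X)) return(X)
  keep <- sort(qr_x$pivot[seq_len(qr_x$rank)])
  Xk <- X[, keep, drop = FALSE]
  attr(Xk, "assign") <- attr(X, "assign")[keep]
  attr(Xk, "contrasts") <- attr(X, "contrasts")
  Xk
}

## Compact letter display: levels share a letter iff they are not
## significantly different. Greedy clique cover of the "not different"
## graph over levels in estimate order.
letter_groups <- function(levels, pairs_p, alpha = 0.05) {
  k <- length(levels)
  if (k == 1) return(stats::setNames("a", levels))
  ns <- matrix(TRUE, k, k, dimnames = list(levels, levels))
  for (i in seq_len(nrow(pairs_p))) {
    a <- pairs_p$level1[i]; b <- pairs_p$level2[i]
    ns[a, b] <- ns[b, a] <- pairs_p$p[i] >= alpha
  }
  groups <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(ns[i, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- i
  }
  ## absorb groups fully contained in another
  keep <- rep(TRUE, length(groups))
  for (g in seq_along(groups)) for (h in seq_along(groups))
    if (g != h && keep[h] && all(groups[[g]] %in% groups[[h]])) keep[g] <- FALSE
  groups <- groups[keep]
  out <- stats::setNames(rep("", k), levels)
  for (g in seq_along(groups))
    out[groups[[g]]] <- paste0(out[groups[[g]]], letters[g])
  out
}
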