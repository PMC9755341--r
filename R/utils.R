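#' @keywords internal
"_PACKAGE"

# Deterministic seed streams.  All stochastic operations in the package draw
# their seed from a master seed plus a path of integer indices, so adding a
# subject (or rater, or replicate) never perturbs the draws of earlier ones.

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with a path of integer indices through a fixed
#' congruential scheme.  The result is always in `[1, 2^31 - 2]` and is a pure
#' function of its arguments.
#'
#' @param seed Master seed (single integer-valued number).
#' @param ... Integer indices identifying the stream (e.g. subject, rater,
#'   method, replicate).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(seed) %% m
  # fold each index in; constants chosen < 2^21 so products stay < 2^53
  for (k in seq_along(idx)) {
    s <- (s * 69069 + 12345) %% m
    s <- (s + (as.numeric(idx[k]) %% m) * 1103515) %% m
    s <- (s * 40692) %% m
  }
  as.integer(s %% (m - 2L) + 1)
}

# run code under a local RNG seed without touching the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stop_mibg <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "mibg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# mean filter with a k x k box, edge-normalised (divides by the number of
# in-image pixels under the window)
box_smooth <- function(m, k = 3L) {
  if (k <= 1L) return(m)
  stopifnot(k %% 2L == 1L)
  ones <- matrix(1, nrow(m), ncol(m))
  run1 <- function(a, k) {
    # running sum along rows (dim 1) with half-window h
    h <- (k - 1L) %/% 2L
    n <- nrow(a)
    cs <- apply(a, 2L, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
    upper <- pmin(seq_len(n) + h, n)
    lower <- seq_len(n) - h - 1L
    out <- cs[upper, , drop = FALSE]
    has <- lower >= 1L
    if (any(has)) {
      out[has, ] <- out[has, , drop = FALSE] - cs[lower[has], , drop = FALSE]
    }
    out
  }
  num <- t(run1(t(run1(m, k)), k))
  den <- t(run1(t(run1(ones, k)), k))
  num / den
}

# connected components of a logical matrix, 4-connectivity.
# Returns an integer matrix of labels (0 = background), labelled in
# decreasing component size order (label 1 is the largest).
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  unvisited <- mask
  sizes <- integer(0)
  nextlab <- 0L
  idx_all <- which(unvisited)
  for (start in idx_all) {
    if (!unvisited[start]) next
    nextlab <- nextlab + 1L
    frontier <- start
    unvisited[start] <- FALSE
    lab[start] <- nextlab
    size <- 1L
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      up <- frontier[r > 1L] - 1L
      dn <- frontier[r < nr] + 1L
      lf <- frontier[frontier > nr] - nr
      rt <- frontier[frontier <= nr * (nc - 1L)] + nr
      nb <- c(up, dn, lf, rt)
      nb <- nb[unvisited[nb]]
      nb <- unique(nb)
      unvisited[nb] <- FALSE
      lab[nb] <- nextlab
      size <- size + length(nb)
      frontier <- nb
    }
    sizes[nextlab] <- size
  }
  if (nextlab > 1L) {
    ord <- order(sizes, decreasing = TRUE)
    remap <- integer(nextlab)
    remap[ord] <- seq_len(nextlab)
    nz <- lab != 0L
    lab[nz] <- remap[lab[nz]]
    sizes <- sizes[ord]
  }
  attr(lab, "sizes") <- sizes
  lab
}
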