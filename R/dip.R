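#' Hartigan's dip statistic
#'
#' The dip of a sample is the maximum difference, over all real x, between
#' its empirical CDF and the closest unimodal (convex-then-concave) CDF —
#' a measure of departure from unimodality (Hartigan & Hartigan 1985,
#' Annals of Statistics). Computed with the classical iterative
#' greatest-convex-minorant / least-concave-majorant algorithm over a
#' shrinking modal interval; `O(n log n)` from the sort. The convention
#' with lower bound `1/(2n)` is used (a two-point sample has dip exactly
#' 0.25; a sample of identical values has dip `1/(2n)`).
#'
#' @param x numeric vector (NAs removed).
#' @return The dip statistic, a scalar in `[1/(2n), 0.25]`.
#' @seealso [dip_test()]
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x[!is.na(x)]))
  n <- length(x)
  if (n < 1L) stop("empty sample")
  if (n == 1L) return(0)
  if (x[n] == x[1L]) return(1 / (2 * n))

  # mn[i]: previous touch point of the greatest convex minorant ending at i;
  # mj[i]: next touch point of the least concave majorant starting at i.
  mn <- integer(n)
  mj <- integer(n)
  mn[1L] <- 1L
  for (i in 2:n) {
    mn[i] <- i - 1L
    repeat {
      mnj <- mn[i]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[i] - x[mnj]) * (mnj - mnmnj) < (x[mnj] - x[mnmnj]) * (i - mnj)) break
      mn[i] <- mnmnj
    }
  }
  mj[n] <- n
  for (i in (n - 1L):1L) {
    mj[i] <- i + 1L
    repeat {
      mjk <- mj[i]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[i] - x[mjk]) * (mjk - mjmjk) < (x[mjk] - x[mjmjk]) * (i - mjk)) break
      mj[i] <- mjmjk
    }
  }

  low <- 1L
  high <- n
  d_stat <- 1  # in count units; divided by 2n on return
  repeat {
    # touch points of the minorant (high -> low) and majorant (low -> high)
    gcm <- high
    i <- 1L
    while (gcm[i] > low) {
      gcm[i + 1L] <- mn[gcm[i]]
      i <- i + 1L
    }
    l_gcm <- i
    ig <- i
    ix <- i - 1L
    lcm <- low
    i <- 1L
    while (lcm[i] < high) {
      lcm[i + 1L] <- mj[lcm[i]]
      i <- i + 1L
    }
    l_lcm <- i
    ih <- i
    iv <- 2L

    # largest distance between the two fits inside [low, high]
    d <- 0
    if (l_gcm != 2L || l_lcm != 2L) {
      repeat {
        gcmix <- gcm[ix]
        lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) {
            d <- dx
            ig <- ix + 1L
            ih <- iv - 1L
          }
        } else {
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx >= d) {
            d <- dx
            ig <- ix + 1L
            ih <- iv
          }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else {
      d <- 1
    }
    if (d < d_stat) break

    # dip of the empirical CDF below the minorant (left of the modal
    # interval) and above the majorant (right of it)
    dip_l <- 0
    if (ig < l_gcm) for (jj in ig:(l_gcm - 1L)) {
      max_t <- 1
      jb <- gcm[jj + 1L]
      je <- gcm[jj]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        idx <- jb:je
        max_t <- max(max_t, (idx - jb + 1) - (x[idx] - x[jb]) * C)
      }
      dip_l <- max(dip_l, max_t)
    }
    dip_u <- 0
    if (ih < l_lcm) for (jj in ih:(l_lcm - 1L)) {
      max_t <- 1
      jb <- lcm[jj]
      je <- lcm[jj + 1L]
      if (je - jb > 1L && x[je] != x[jb]) {
        C <- (je - jb) / (x[je] - x[jb])
        idx <- jb:je
        max_t <- max(max_t, (x[idx] - x[jb]) * C - (idx - jb - 1))
      }
      dip_u <- max(dip_u, max_t)
    }
    d_stat <- max(d_stat, dip_l, dip_u)
    if (low == gcm[ig] && high == lcm[ih]) break
    low <- gcm[ig]
    high <- lcm[ih]
  }
  d_stat / (2 * n)
}

#' Monte-Carlo dip test of unimodality
#'
#' Compares the sample's dip statistic against dips of `n_sim` uniform
#' samples of the same size — the least favourable unimodal null, the same
#' reference distribution the published dip critical-value tables are
#' computed from. The p-value is `(1 + #{dip_null >= dip_obs}) /
#' (n_sim + 1)`. Small p-values reject unimodality.
#'
#' @param x numeric vector.
#' @param n_sim number of uniform null samples; default 500.
#' @param seed optional integer seed for the null simulation.
#' @return An object of class `htest` with `statistic` and `p.value`.
#' @export
dip_test <- function(x, n_sim = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  stat <- dip_statistic(x)
  null_dips <- vapply(seq_len(n_sim),
                      function(i) dip_statistic(runif(n)),
                      numeric(1L))
  p <- (1 + sum(null_dips >= stat)) / (n_sim + 1)
  structure(list(statistic = c(dip = stat),
                 p.value = p,
                 method = "Hartigan's dip test of unimodality (Monte-Carlo uniform null)",
                 data.name = deparse(substitute(x)),
                 parameter = c(n = n, n_sim = n_sim)),
            class = "htest")
}
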