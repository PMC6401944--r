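# Observables: charge fraction, radius of gyration, ion shell histograms,
# block-averaged statistics.

#' Fraction of charged monomers
#'
#' \eqn{f = N_{M^-} / (N_{M^-} + N_{MH})}.
#'
#' @param state A `wpe_state` containing at least one monomer.
#' @return f in \[0, 1\].
#' @export
charge_fraction <- function(state) {
  counts <- species_counts(state)
  n <- counts[["MH"]] + counts[["Mminus"]]
  if (n < 1) stop("state contains no monomers")
  counts[["Mminus"]] / n
}

#' Unwrap polymer coordinates across periodic images
#'
#' Walks the bond graph from bead 1, shifting each bead by the minimum
#' image of its bond vector, so the molecule is reassembled contiguously
#' regardless of how the box wrapped it.  Errors if any unwrapped bond
#' exceeds the FENE maximum `R0` (broken-molecule detection).
#'
#' @param state A `wpe_state`.
#' @param topology A `wpe_topology`.
#' @param R0 Maximum plausible bond length.
#' @return Matrix of unwrapped monomer coordinates.
#' @export
unwrap_polymer <- function(state, topology, R0 = 2) {
  n <- topology$n_monomers
  pos <- state$positions[seq_len(n), , drop = FALSE]
  box <- state$box
  adj <- vector("list", n)
  for (b in seq_len(nrow(topology$bonds))) {
    i <- topology$bonds[b, 1]; j <- topology$bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  un <- matrix(NA_real_, n, 3)
  un[1, ] <- pos[1, ]
  queue <- 1L; seen <- logical(n); seen[1] <- TRUE
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    for (j in adj[[i]]) {
      if (seen[j]) next
      d <- pos[j, ] - pos[i, ]
      d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) >= R0)
        stop("broken molecule: bond ", i, "-", j, " longer than R0 after unwrapping")
      un[j, ] <- un[i, ] + d
      seen[j] <- TRUE
      queue <- c(queue, j)
    }
  }
  un
}

#' Radius of gyration of the polymer
#'
#' \eqn{R_g = \sqrt{\langle |r_i - r_{cm}|^2 \rangle}} over the monomers
#' only (ions excluded), computed from coordinates unwrapped along the
#' bonds so the result is independent of the periodic wrapping.
#'
#' @inheritParams unwrap_polymer
#' @return \eqn{R_g} in \eqn{\sigma}.
#' @export
radius_of_gyration <- function(state, topology) {
  un <- unwrap_polymer(state, topology)
  cm <- colMeans(un)
  sqrt(mean(rowSums(sweep(un, 2, cm)^2)))
}

#' Ion counts in spherical shells around the polymer center of mass
#'
#' Counts mobile ions of each species in concentric shells of width
#' `bin_width` around the monomer center of mass (computed from unwrapped
#' coordinates); ions are assigned by minimum-image distance to the CM.
#' The cumulative count within `r < 7.5` is the standard near-polymer
#' summary for counterion-condensation comparisons.
#'
#' @inheritParams unwrap_polymer
#' @param bin_width Shell width in \eqn{\sigma}.
#' @param r_max Outermost shell radius; must be at most half the box edge.
#' @return A tibble with columns `species`, `r_lo`, `r_hi`, `count`.
#' @export
shell_histogram <- function(state, topology, bin_width = 0.5, r_max = 20) {
  if (r_max > state$box / 2)
    stop("r_max must not exceed half the box edge")
  un <- unwrap_polymer(state, topology)
  cm <- colMeans(un)
  cm <- cm - state$box * floor(cm / state$box)
  n <- topology$n_monomers
  ions <- which(state$species > 2L)
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  nb <- length(breaks) - 1L
  tab <- species_table()
  out <- list()
  for (s in 3:8) {
    rows <- ions[state$species[ions] == s]
    counts <- integer(nb)
    if (length(rows) > 0) {
      d <- sweep(state$positions[rows, , drop = FALSE], 2, cm)
      d <- d - state$box * round(d / state$box)
      r <- sqrt(rowSums(d^2))
      counts <- as.integer(table(cut(r[r < r_max], breaks,
                                     include.lowest = TRUE)))
    }
    out[[length(out) + 1]] <-
      tibble::tibble(species = tab$name[s], r_lo = breaks[-length(breaks)],
                     r_hi = breaks[-1], count = counts)
  }
  do.call(rbind, out)
}

#' Cumulative ion count near the polymer
#'
#' @inheritParams shell_histogram
#' @param r Cutoff radius (default 7.5).
#' @param species Species names to include (default the salt cations).
#' @return Named vector of counts within `r` of the polymer CM.
#' @export
near_polymer_count <- function(state, topology, r = 7.5,
                               species = c("Na+", "Mg2+")) {
  h <- shell_histogram(state, topology, bin_width = r, r_max = min(2 * r, state$box / 2))
  h <- h[h$r_lo == 0 & h$species %in% species, ]
  setNames(h$count, h$species)
}

#' Block-averaged mean and standard error
#'
#' Discards the initial `equilibration` fraction of the series, splits the
#' remainder into `blocks` contiguous blocks, and reports the grand mean
#' with the standard error of the block means (robust to autocorrelation
#' on scales shorter than a block).
#'
#' @param x Numeric series (one value per sweep).
#' @param equilibration Fraction discarded from the front.
#' @param blocks Number of blocks.
#' @return List with `mean`, `se`, `n_used`, `block_means`.
#' @export
block_average <- function(x, equilibration = 0.5, blocks = 10) {
  stopifnot(equilibration >= 0, equilibration < 1, blocks >= 2)
  x <- x[!is.na(x)]
  drop <- floor(equilibration * length(x))
  keep <- if (drop > 0) x[-seq_len(drop)] else x
  if (length(keep) < blocks)
    stop("series too short: ", length(keep), " points for ", blocks, " blocks")
  cuts <- floor(seq(0, length(keep), length.out = blocks + 1))
  bm <- vapply(seq_len(blocks),
               function(b) mean(keep[(cuts[b] + 1):cuts[b + 1]]), 0.0)
  list(mean = mean(keep), se = sd(bm) / sqrt(blocks), n_used = length(keep),
       block_means = bm)
}
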