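# Linear and star polymer architectures: FENE bond lists and seeded
# initial configurations.

#' @noRd
.new_topology <- function(n, architecture, n_arms, arm_length, bonds) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  structure(
    list(n_monomers = as.integer(n), architecture = architecture,
         n_arms = n_arms, arm_length = arm_length, bonds = bonds),
    class = "wpe_topology"
  )
}

#' @export
print.wpe_topology <- function(x, ...) {
  cat("<wpe_topology>", x$architecture, "polymer,", x$n_monomers,
      "titratable beads,", nrow(x$bonds), "FENE bonds\n")
  if (x$architecture == "star")
    cat("  ", x$n_arms, "arms of length", x$arm_length, "\n")
  invisible(x)
}

#' Build a linear bead-spring chain
#'
#' A path graph of `n` titratable monomers joined by `n - 1` FENE bonds.
#'
#' @param n Number of monomers (>= 2).
#' @return A `wpe_topology`.
#' @export
#' @examples
#' build_linear(121)
build_linear <- function(n) {
  if (!is.numeric(n) || n < 2) stop("a linear chain needs n >= 2 monomers")
  n <- as.integer(n)
  .new_topology(n, "linear", NA_integer_, NA_integer_,
                cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

#' Build a star polymer
#'
#' `n_arms` arms of `arm_length` beads each emanate from a single central
#' bead, for `N = n_arms * arm_length + 1` monomers in total and `N - 1`
#' bonds.  The central bead is titratable like every other monomer and is
#' bead 1; arm `a` occupies beads `2 + (a-1)*arm_length` onward.
#'
#' @param n_arms Number of arms (>= 2).
#' @param arm_length Beads per arm (>= 1).
#' @return A `wpe_topology`.
#' @export
#' @examples
#' build_star(10, 12)  # N = 121, same molecular weight as build_linear(121)
build_star <- function(n_arms, arm_length) {
  if (!is.numeric(n_arms) || n_arms < 2) stop("a star needs n_arms >= 2")
  if (!is.numeric(arm_length) || arm_length < 1) stop("arm_length must be >= 1")
  n_arms <- as.integer(n_arms); arm_length <- as.integer(arm_length)
  n <- n_arms * arm_length + 1L
  bonds <- matrix(0L, n - 1L, 2)
  row <- 1L
  for (a in seq_len(n_arms)) {
    first <- 2L + (a - 1L) * arm_length
    bonds[row, ] <- c(1L, first); row <- row + 1L
    if (arm_length > 1L) {
      for (k in seq_len(arm_length - 1L)) {
        bonds[row, ] <- c(first + k - 1L, first + k); row <- row + 1L
      }
    }
  }
  .new_topology(n, "star", n_arms, arm_length, bonds)
}

#' Degree sequence of a topology
#'
#' @param topology A `wpe_topology`.
#' @return Integer vector of bead degrees.
#' @export
bond_degrees <- function(topology) {
  tabulate(c(topology$bonds[, 1], topology$bonds[, 2]),
           nbins = topology$n_monomers)
}

#' Seeded initial polymer configuration
#'
#' Places the polymer in the periodic box by bond-by-bond random growth:
#' each bead is set at a random direction and unit distance from its bonded
#' predecessor, rejecting placements that put any two beads closer than
#' `min_sep` or stretch a bond to `R0 = 2` or more.  The construction is
#' deterministic per seed and always has finite FENE energy.  Residual
#' strain relaxes in the first MD sweeps.
#'
#' @param topology A `wpe_topology`.
#' @param box Box edge in \eqn{\sigma}.
#' @param seed Integer seed.
#' @param bond_length Target bond length for the growth (default 1).
#' @param min_sep Minimum allowed pair separation (default 0.8).
#' @param max_retries Retries per bead before giving up.
#' @return A `wpe_state` with all monomers in the neutral `MH` state.
#' @export
initial_configuration <- function(topology, box, seed, bond_length = 1.0,
                                  min_sep = 0.8, max_retries = 500) {
  stopifnot(inherits(topology, "wpe_topology"), box > 4)
  n <- topology$n_monomers
  .with_seed(seed, {
    # dense cores (many arms) can paint themselves into a corner; restart
    # the whole growth a bounded number of times before giving up
    for (attempt in 1:25) {
      pos <- matrix(NA_real_, n, 3)
      pos[1, ] <- rep(box / 2, 3)
      ok <- TRUE
      # bonds are listed parent-first for both architectures
      for (b in seq_len(nrow(topology$bonds))) {
        i <- topology$bonds[b, 1]; j <- topology$bonds[b, 2]
        if (anyNA(pos[i, ])) { tmp <- i; i <- j; j <- tmp }
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- pos[i, ] + bond_length * u
          d <- .min_image_dist(pos[!is.na(pos[, 1]), , drop = FALSE], cand, box)
          if (min(d) >= min_sep) { pos[j, ] <- cand; placed <- TRUE; break }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(make_state(pos, rep(1L, n), box))
    }
    stop("initial placement failed after 25 growth attempts; ",
         "increase the box or lower min_sep")
  })
}

# minimum-image distances from each row of `mat` to point `p`
#' @noRd
.min_image_dist <- function(mat, p, box) {
  d <- sweep(mat, 2, p)
  d <- d - box * round(d / box)
  sqrt(rowSums(d^2))
}

#' Add randomly placed ions to a state
#'
#' Inserts `counts` ions of the named species at uniform random positions,
#' rejecting placements closer than `min_sep` to any existing particle.
#' Used to seed salt and base before the chemostats take over.
#'
#' @param state A `wpe_state`.
#' @param counts Named integer vector, names from [species_table()]
#'   (e.g. `c("Na+" = 5, "Cl-" = 5)`).
#' @param seed Integer seed.
#' @param min_sep Minimum allowed pair separation.
#' @return The augmented `wpe_state`.
#' @export
place_ions <- function(state, counts, seed = NULL, min_sep = 0.8) {
  stopifnot(inherits(state, "wpe_state"))
  codes <- rep(.species_code(names(counts)), times = as.integer(counts))
  if (length(codes) == 0) return(state)
  if (any(codes <= 2L)) stop("place_ions is for mobile ions, not monomers")
  .with_seed(seed, {
    pos <- state$positions
    box <- state$box
    n_new <- length(codes)
    if (min_sep <= 0) {
      new <- matrix(runif(3 * n_new, 0, box), n_new, 3)
    } else {
      new <- matrix(NA_real_, n_new, 3)
      occupied <- rbind(pos, new)
      n_occ <- nrow(pos)
      for (k in seq_len(n_new)) {
        repeat {
          cand <- runif(3, 0, box)
          if (n_occ == 0 ||
              min(.min_image_dist(occupied[seq_len(n_occ), , drop = FALSE],
                                  cand, box)) >= min_sep) {
            new[k, ] <- cand
            occupied[n_occ + 1L, ] <- cand
            n_occ <- n_occ + 1L
            break
          }
        }
      }
    }
    make_state(rbind(pos, new), c(state$species, codes), box,
               rbind(state$velocities, matrix(0, length(codes), 3)))
  })
}
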