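#' Configuration for a synthetic comparative study
#'
#' Bundles every knob of the synthetic-study generator. The defaults describe
#' the study conditions the pipeline is designed for: 213 species in 38
#' families with 11 clustered GSD-to-TSD transitions, 30 years of monthly
#' climate, TSD range centroids sitting in cells about 3 degrees C warmer than
#' GSD centroids, and breeding windows placed on the warmest months.
#'
#' @param n_species number of tips / species.
#' @param n_years years of monthly climate.
#' @param grid_rows,grid_cols climate grid dimensions; rows map linearly to
#'   latitudes in \[60, -60\] degrees.
#' @param n_families number of family labels carved out of the tree.
#' @param mk_rates length-2 nonnegative vector `c(gain, loss)`: transition
#'   rates 0->1 (GSD->TSD) and 1->0 per unit branch length. `NULL` picks a
#'   gain rate aimed at `target_transitions` expected changes on the tree.
#' @param target_transitions exact number of realized state changes to
#'   condition on (rejection sampling), or `NULL` for unconditioned.
#' @param sds_temp_effect degrees C by which TSD range centroids are warmer
#'   than GSD centroids, on average.
#' @param ou_alpha,ou_sigma Ornstein-Uhlenbeck parameters for the continuous
#'   life-history traits.
#' @param range_size_cells mean number of grid cells per species range.
#' @param window_mode how breeding windows are placed: `"warmest"`,
#'   `"stablest"` or `"random"`.
#' @param window_length_probs probability over window lengths 1..12 months.
#' @param trait_obs_prob probability that each life-history trait is observed
#'   for a species (independent per trait), emulating patchy trait data.
#' @param seed RNG seed; a fixed seed makes the whole study bit-reproducible.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_species = 213, n_years = 30, grid_rows = 30,
                       grid_cols = 30, n_families = 38, mk_rates = NULL,
                       target_transitions = 11, sds_temp_effect = 3,
                       ou_alpha = 1, ou_sigma = 1, range_size_cells = 20,
                       window_mode = c("warmest", "stablest", "random"),
                       window_length_probs = rep(1 / 12, 12),
                       trait_obs_prob = 0.6, seed = 1L) {
  window_mode <- match.arg(window_mode)
  counts <- c(n_species = n_species, n_years = n_years, grid_rows = grid_rows,
              grid_cols = grid_cols, n_families = n_families)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts in sim_config must be positive integers")
  if (!is.null(mk_rates) && (length(mk_rates) != 2 || any(mk_rates < 0)))
    stop("mk_rates must be two nonnegative rates c(gain, loss)")
  if (ou_alpha < 0 || ou_sigma <= 0)
    stop("require ou_alpha >= 0 and ou_sigma > 0")
  if (length(window_length_probs) != 12 || any(window_length_probs < 0))
    stop("window_length_probs must be 12 nonnegative values")
  structure(list(
    n_species = as.integer(n_species), n_years = as.integer(n_years),
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    n_families = as.integer(n_families), mk_rates = mk_rates,
    target_transitions = target_transitions,
    sds_temp_effect = sds_temp_effect, ou_alpha = ou_alpha,
    ou_sigma = ou_sigma, range_size_cells = range_size_cells,
    window_mode = window_mode,
    window_length_probs = window_length_probs / sum(window_length_probs),
    trait_obs_prob = trait_obs_prob, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate an ultrametric birth-death phylogeny
#'
#' Thin wrapper around [ape::rphylo()] (simulation conditioned on the number
#' of extant tips) that relabels tips `sp001, sp002, ...` and validates the
#' result.
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate,death_rate birth-death rates; `birth_rate > death_rate >= 0`.
#' @param seed optional RNG seed; `NULL` uses the current RNG stream.
#' @return an object of class `phylo`.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, death_rate = 0,
                          seed = NULL) {
  if (n_species < 2) stop("n_species must be at least 2")
  if (!(birth_rate > death_rate) || death_rate < 0)
    stop("require birth_rate > death_rate >= 0")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = death_rate)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  stopifnot(all(tree$edge.length > 0))
  tree
}

# Gillespie walk of a 2-state Markov chain along one branch.
# Returns final state and number of changes.
.mk_branch <- function(state, len, rates) {
  changes <- 0L
  t <- 0
  repeat {
    rate <- if (state == 0L) rates[1] else rates[2]
    if (rate <= 0) break
    t <- t + stats::rexp(1, rate)
    if (t >= len) break
    state <- 1L - state
    changes <- changes + 1L
  }
  list(state = state, changes = changes)
}

#' Simulate a binary trait under the Mk model, tracking realized transitions
#'
#' Evolves a two-state (0 = GSD, 1 = TSD) continuous-time Markov chain along
#' every branch of `tree` (Gillespie algorithm, preorder), returning tip
#' states together with the realized number of state changes on the whole
#' tree. If `target_transitions` is given, realizations are rejection-sampled
#' until the change count matches exactly (bounded attempts).
#'
#' @param tree a `phylo` object.
#' @param rates length-2 nonnegative vector `c(rate01, rate10)`.
#' @param root_state state at the root (default 0, the ancestral GSD state).
#' @param seed optional RNG seed.
#' @param target_transitions exact realized change count to condition on.
#' @param max_attempts rejection-sampling budget (default 10000).
#' @return list with `states` (named 0/1 integer vector over tips),
#'   `n_transitions`, and `attempts`.
#' @export
simulate_binary_mk <- function(tree, rates, root_state = 0L, seed = NULL,
                               target_transitions = NULL,
                               max_attempts = 10000L) {
  if (length(rates) != 2 || any(rates < 0))
    stop("rates must be two nonnegative values c(rate01, rate10)")
  if (!root_state %in% c(0L, 1L)) stop("root_state must be 0 or 1")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # preorder: reorder edges so parents are visited before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  one_draw <- function() {
    node_state <- integer(max(tree$edge))
    node_state[root] <- as.integer(root_state)
    total <- 0L
    for (i in seq_len(nrow(ord$edge))) {
      par <- ord$edge[i, 1]
      child <- ord$edge[i, 2]
      res <- .mk_branch(node_state[par], ord$edge.length[i], rates)
      node_state[child] <- res$state
      total <- total + res$changes
    }
    states <- node_state[seq_len(n_tip)]
    names(states) <- tree$tip.label
    list(states = states, n_transitions = total)
  }
  if (is.null(target_transitions)) {
    out <- one_draw()
    out$attempts <- 1L
    return(out)
  }
  for (attempt in seq_len(max_attempts)) {
    out <- one_draw()
    if (out$n_transitions == target_transitions) {
      out$attempts <- attempt
      return(out)
    }
  }
  stop(sprintf(
    "could not realize %d transitions in %d attempts; adjust rates",
    target_transitions, max_attempts))
}

#' Simulate a seasonal monthly climate grid
#'
#' Builds temperature and precipitation arrays indexed (year, month, row,
#' col). Temperature at a cell is a latitudinal base gradient plus a seasonal
#' cosine whose amplitude grows with absolute latitude (phase flipped in the
#' southern hemisphere) plus a year-level effect shared by all months of that
#' cell-year and independent month-level noise. Precipitation is analogous
#' with a nonnegativity clamp.
#'
#' @param cfg a [sim_config()].
#' @param base_temp,lat_gradient mean temperature at the equator (deg C) and
#'   its decline per degree of absolute latitude.
#' @param amplitude_polar seasonal amplitude at |lat| = 60 (deg C); amplitude
#'   scales linearly with |lat|.
#' @param sd_year,sd_month standard deviations of the year-level effect and
#'   the month-level noise.
#' @param base_precip,precip_gradient,precip_amplitude,precip_sd_year,precip_sd_month
#'   same roles for precipitation (mm).
#' @param seed optional RNG seed.
#' @return an object of class `climate_grid`: list with `temperature` and
#'   `precipitation` arrays `(year, month, row, col)`, `lat` (per row), `lon`
#'   (per column) and `years`.
#' @export
simulate_climate_grid <- function(cfg, base_temp = 28, lat_gradient = 0.35,
                                  amplitude_polar = 12, sd_year = 0.8,
                                  sd_month = 1.2, base_precip = 180,
                                  precip_gradient = 2, precip_amplitude = 60,
                                  precip_sd_year = 15, precip_sd_month = 25,
                                  seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ny <- cfg$n_years
  nr <- cfg$grid_rows
  nc <- cfg$grid_cols
  lat <- if (nr == 1) 0 else seq(60, -60, length.out = nr)
  lon <- if (nc == 1) 0 else seq(-180, 180, length.out = nc)
  dims <- c(ny, 12L, nr, nc)
  month <- array(rep(1:12, each = ny), dims)
  alat <- array(rep(abs(lat), each = ny * 12), dims)
  peak <- array(rep(ifelse(lat >= 0, 7, 1), each = ny * 12), dims)
  seas <- cos(2 * pi * (month - peak) / 12)
  amp_t <- amplitude_polar * alat / 60
  year_eff <- array(stats::rnorm(ny * nr * nc, 0, sd_year), c(ny, nr, nc))
  year_eff <- array(rep(year_eff, times = 12), c(ny, nr, nc, 12))
  year_eff <- aperm(year_eff, c(1, 4, 2, 3))
  temperature <- base_temp - lat_gradient * alat + amp_t * seas + year_eff +
    array(stats::rnorm(prod(dims), 0, sd_month), dims)
  p_year <- array(stats::rnorm(ny * nr * nc, 0, precip_sd_year), c(ny, nr, nc))
  p_year <- aperm(array(rep(p_year, times = 12), c(ny, nr, nc, 12)),
                  c(1, 4, 2, 3))
  precipitation <- base_precip - precip_gradient * alat +
    precip_amplitude * (alat / 60) * seas + p_year +
    array(stats::rnorm(prod(dims), 0, precip_sd_month), dims)
  precipitation <- pmax(precipitation, 0)
  structure(list(temperature = temperature, precipitation = precipitation,
                 lat = lat, lon = lon, years = seq_len(ny)),
            class = "climate_grid")
}

# Mean temperature per cell over all years and months.
.cell_mean_temp <- function(grid) {
  apply(grid$temperature, c(3, 4), mean)
}

# Seeded breadth-first blob growth from a centroid cell; returns a
# (row, col) matrix of `size` contiguous cells.
.grow_blob <- function(centroid, size, nr, nc) {
  if (size > nr * nc) stop("range blob larger than the climate grid")
  in_blob <- matrix(FALSE, nr, nc)
  in_blob[centroid[1], centroid[2]] <- TRUE
  frontier <- matrix(centroid, ncol = 2)
  cells <- matrix(centroid, ncol = 2)
  while (nrow(cells) < size) {
    # neighbours of blob not yet included
    cand <- unique(do.call(rbind, lapply(seq_len(nrow(frontier)), function(i) {
      r <- frontier[i, 1]; c <- frontier[i, 2]
      rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    })))
    cand <- cand[cand[, 1] >= 1 & cand[, 1] <= nr &
                 cand[, 2] >= 1 & cand[, 2] <= nc, , drop = FALSE]
    cand <- cand[!in_blob[cand], , drop = FALSE]
    if (nrow(cand) == 0) {
      # frontier exhausted (blob boxed in); restart frontier from full blob
      frontier <- cells
      cand <- unique(do.call(rbind, lapply(seq_len(nrow(frontier)), function(i) {
        r <- frontier[i, 1]; c <- frontier[i, 2]
        rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
      })))
      cand <- cand[cand[, 1] >= 1 & cand[, 1] <= nr &
                   cand[, 2] >= 1 & cand[, 2] <= nc, , drop = FALSE]
      cand <- cand[!in_blob[cand], , drop = FALSE]
      if (nrow(cand) == 0) stop("range blob cannot grow further")
    }
    take <- cand[sample.int(nrow(cand), 1), , drop = FALSE]
    in_blob[take] <- TRUE
    cells <- rbind(cells, take)
    frontier <- rbind(frontier, take)
  }
  dimnames(cells) <- list(NULL, c("row", "col"))
  cells
}

#' Simulate species range masks and breeding windows
#'
#' Every species receives a contiguous blob of grid cells grown by seeded
#' breadth-first search from a centroid. Centroids are temperature-matched:
#' each species draws a target cell temperature equal to the grid mean plus
#' `sds_temp_effect` for TSD species (state 1) plus noise, and the centroid is
#' the unused cell closest to the target, so TSD ranges end up warmer by
#' `sds_temp_effect` on average while `sds_temp_effect = 0` gives exchangeable
#' groups. Breeding windows of sampled length are then placed on each species
#' range series: `"warmest"` maximizes mean temperature over the window,
#' `"stablest"` minimizes within-year variance, `"random"` places uniformly;
#' ties break to the earliest start month.
#'
#' @param tree a `phylo` object.
#' @param sds_states named 0/1 vector over tips.
#' @param grid a `climate_grid`.
#' @param cfg a [sim_config()]; `range_size_cells`, `sds_temp_effect`,
#'   `window_mode` and `window_length_probs` are used. Range sizes vary
#'   around `range_size_cells` (geometric-ish spread) so area weights are
#'   informative.
#' @param seed optional RNG seed.
#' @return list with `masks` (named list of (row, col) matrices), `windows`
#'   (data.frame species/start/end/length), `centroids`.
#' @export
simulate_ranges_and_windows <- function(tree, sds_states, grid, cfg,
                                        seed = NULL) {
  stopifnot(all(tree$tip.label %in% names(sds_states)))
  if (!is.null(seed)) set.seed(seed)
  nr <- dim(grid$temperature)[3]
  nc <- dim(grid$temperature)[4]
  cellT <- .cell_mean_temp(grid)
  sdT <- stats::sd(cellT)
  if (!is.finite(sdT) || sdT == 0) sdT <- 1
  species <- tree$tip.label
  masks <- vector("list", length(species))
  names(masks) <- species
  centroids <- matrix(NA_integer_, length(species), 2,
                      dimnames = list(species, c("row", "col")))
  if (min(4L, cfg$range_size_cells) > nr * nc)
    stop("range blob larger than the climate grid")
  # random range sizes (so area weights are informative), capped at the grid
  sizes <- pmin(pmax(4L, stats::rpois(length(species), cfg$range_size_cells)),
                nr * nc)
  for (i in seq_along(species)) {
    sp <- species[i]
    target <- mean(cellT) + cfg$sds_temp_effect * sds_states[[sp]] +
      stats::rnorm(1, 0, sdT)
    idx <- which.min(abs(cellT - target) + stats::runif(nr * nc, 0, 1e-9))
    centroid <- c(row(cellT)[idx], col(cellT)[idx])
    centroids[i, ] <- centroid
    masks[[sp]] <- .grow_blob(centroid, sizes[i], nr, nc)
  }
  lengths <- sample.int(12, length(species), replace = TRUE,
                        prob = cfg$window_length_probs)
  windows <- data.frame(species = species, start = NA_integer_,
                        end = NA_integer_, length = lengths,
                        stringsAsFactors = FALSE)
  for (i in seq_along(species)) {
    series <- range_series(grid, masks[[i]], "temperature")
    len <- lengths[i]
    if (cfg$window_mode == "random") {
      start <- sample.int(12, 1)
    } else {
      score <- vapply(1:12, function(s) {
        w <- breeding_window(s, ((s + len - 2) %% 12) + 1)
        if (cfg$window_mode == "warmest") {
          mean(series[, window_months(w), drop = FALSE])
        } else {
          seasonality(series, w)
        }
      }, numeric(1))
      start <- if (cfg$window_mode == "warmest") which.max(score)
               else which.min(score)
    }
    windows$start[i] <- start
    windows$end[i] <- ((start + len - 2) %% 12) + 1
  }
  list(masks = masks, windows = windows, centroids = centroids)
}

#' Simulate a continuous trait under an Ornstein-Uhlenbeck process
#'
#' Exact recursion tipward from the root: along a branch of length t the
#' trait moves from x to `theta + (x - theta) e^{-alpha t}` plus Gaussian
#' noise with variance `sigma^2 (1 - e^{-2 alpha t}) / (2 alpha)`; `alpha = 0`
#' reduces to Brownian motion. A state-dependent shift (`state_effect *
#' state`) can be added at the tips to embed a recoverable binary-trait
#' effect.
#'
#' @param tree a `phylo` object.
#' @param alpha selection strength (>= 0).
#' @param sigma diffusion (> 0).
#' @param root trait value at the root (also the OU optimum `theta`).
#' @param states optional named 0/1 vector over tips.
#' @param state_effect shift added to tips with state 1.
#' @param seed optional RNG seed.
#' @return named numeric vector over tips.
#' @export
simulate_ou_trait <- function(tree, alpha, sigma, root = 0, states = NULL,
                              state_effect = 0, seed = NULL) {
  if (alpha < 0 || sigma <= 0) stop("require alpha >= 0 and sigma > 0")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "cladewise")
  val <- numeric(max(tree$edge))
  val[n_tip + 1L] <- root
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1]; child <- ord$edge[i, 2]
    t <- ord$edge.length[i]
    if (alpha == 0) {
      m <- val[par]
      v <- sigma^2 * t
    } else {
      w <- exp(-alpha * t)
      m <- root + (val[par] - root) * w
      v <- sigma^2 * (1 - w^2) / (2 * alpha)
    }
    val[child] <- stats::rnorm(1, m, sqrt(v))
  }
  tips <- val[seq_len(n_tip)]
  names(tips) <- tree$tip.label
  if (!is.null(states) && state_effect != 0)
    tips <- tips + state_effect * as.numeric(states[names(tips)])
  tips
}

#' Generate a complete synthetic comparative study
#'
#' Ties the pieces together: an ultrametric tree, a binary sex-determination
#' trait conditioned on a target number of GSD-to-TSD transitions, a seasonal
#' climate grid, temperature-biased range blobs with breeding windows, family
#' and continent labels, range areas, a reproductive-mode trait concentrated
#' in cold-range GSD species, and three partially observed OU life-history
#' traits. The true generator parameters are recorded for recovery tests.
#'
#' @param cfg a [sim_config()].
#' @return object of class `synthetic_study`: list with `tree`, `traits`
#'   (data.frame), `grid`, `masks`, `windows`, `truth`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- simulate_tree(cfg$n_species, birth_rate = 1, death_rate = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  total_len <- sum(tree$edge.length)
  rates <- cfg$mk_rates
  if (is.null(rates)) {
    gain <- if (is.null(cfg$target_transitions)) 2 / depth
            else cfg$target_transitions / total_len
    rates <- c(gain, gain / 4)
  }
  mk <- simulate_binary_mk(tree, rates, root_state = 0L,
                           target_transitions = cfg$target_transitions)
  grid <- simulate_climate_grid(cfg)
  rw <- simulate_ranges_and_windows(tree, mk$states, grid, cfg)
  n <- cfg$n_species
  species <- tree$tip.label

  # families: cut the ultrametric tree into clades
  fam_id <- stats::cutree(stats::as.hclust(ape::multi2di(tree)),
                          k = min(cfg$n_families, n))
  family <- sprintf("fam%02d", fam_id[species])

  # continents from centroid longitude/latitude quadrant
  lonq <- cut(rw$centroids[, "col"], breaks = 3, labels = FALSE)
  latq <- as.integer(grid$lat[rw$centroids[, "row"]] < 0)
  continent <- sprintf("cont%d", lonq + 3 * latq)

  # range area: cells * nominal cell area (km^2)
  area <- vapply(rw$masks, nrow, integer(1)) * 3000

  # reproductive mode: viviparity concentrated in cold-range GSD species
  cellT <- .cell_mean_temp(grid)
  cent_temp <- cellT[rw$centroids]
  cold_z <- as.numeric(scale(-cent_temp))
  p_viv <- stats::plogis(-2.2 + 1.6 * cold_z - 2.5 * mk$states[species])
  reproductive_mode <- stats::rbinom(n, 1, p_viv)

  # life-history traits: OU with shared structure, patchy observation
  bl <- simulate_ou_trait(tree, cfg$ou_alpha, cfg$ou_sigma, root = 0)
  bm <- 0.8 * bl + simulate_ou_trait(tree, cfg$ou_alpha, cfg$ou_sigma)
  lg <- 0.5 * bl + simulate_ou_trait(tree, cfg$ou_alpha, cfg$ou_sigma)
  obs <- matrix(stats::runif(3 * n) < cfg$trait_obs_prob, n, 3)
  bl[!obs[, 1]] <- NA; bm[!obs[, 2]] <- NA; lg[!obs[, 3]] <- NA

  traits <- data.frame(
    species = species,
    sds = as.integer(mk$states[species]),
    reproductive_mode = reproductive_mode,
    breed_start = rw$windows$start,
    breed_end = rw$windows$end,
    family = family,
    continent = continent,
    range_area = as.numeric(area[species]),
    body_length = as.numeric(bl[species]),
    body_mass = as.numeric(bm[species]),
    longevity = as.numeric(lg[species]),
    stringsAsFactors = FALSE
  )
  structure(list(
    tree = tree, traits = traits, grid = grid, masks = rw$masks,
    windows = rw$windows,
    truth = list(config = cfg, mk_rates = rates,
                 n_transitions = mk$n_transitions,
                 sds_temp_effect = cfg$sds_temp_effect,
                 ou_alpha = cfg$ou_alpha, ou_sigma = cfg$ou_sigma)
  ), class = "synthetic_study")
}
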