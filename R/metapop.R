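#' Dispersal configuration for a metapopulation run
#'
#' @param mode Dispersal process: `"none"` (isolated groups), `"RM"` (random
#'   migration between neighbors), `"SM"` (selective migration: only the
#'   largest groups donate), or `"TG"` (trait-group selection: episodic
#'   pooling of all cells and uniform random redistribution).
#' @param delta_g Generations between dispersal rounds (at least 1).
#' @param propagule_shape Beta-distribution shape parameters for the propagule
#'   fraction `p`; the default `(5, 15)` has mean 0.25.
#' @param viscosity 1 restricts migration to the Moore (8-connected)
#'   neighborhood; 0 allows migration between any pair of groups.
#' @param max_events Maximum migration events per dispersal round.
#' @param sm_candidates Number of largest groups eligible as selective
#'   migration donors.
#' @return An object of class `dispersal_config`.
#' @export
dispersal_config <- function(mode = c("none", "RM", "SM", "TG"),
                             delta_g = 100L,
                             propagule_shape = c(5, 15),
                             viscosity = 1L,
                             max_events = 10L,
                             sm_candidates = 10L) {
  mode <- match.arg(mode)
  if (delta_g < 1) stop("delta_g must be at least 1")
  if (length(propagule_shape) != 2L || any(propagule_shape <= 0)) {
    stop("propagule_shape must be two positive beta shape parameters")
  }
  if (!viscosity %in% c(0L, 1L)) stop("viscosity must be 0 or 1")
  if (max_events < 1) stop("max_events must be at least 1")
  if (sm_candidates < 1) stop("sm_candidates must be at least 1")
  structure(list(mode = mode, delta_g = as.integer(delta_g),
                 propagule_shape = as.numeric(propagule_shape),
                 viscosity = as.integer(viscosity),
                 max_events = as.integer(max_events),
                 sm_candidates = as.integer(sm_candidates)),
            class = "dispersal_config")
}

#' @export
print.dispersal_config <- function(x, ...) {
  cat(sprintf(
    "Dispersal: mode %s, every %d generations, propagule Beta(%g, %g), v = %d\n",
    x$mode, x$delta_g, x$propagule_shape[1], x$propagule_shape[2],
    x$viscosity))
  invisible(x)
}

#' Metapopulation state on a rectangular grid
#'
#' Groups are stored column-major: grid index `i` maps to row
#' `(i - 1) %% nrow + 1` and column `(i - 1) %/% nrow + 1`.
#'
#' @param n_A,n_S Vectors of cell counts, one element per grid patch.
#' @param nrow,ncol Grid dimensions (default the 7 x 7, 49-group layout).
#' @param generation Global clock (generations elapsed).
#' @return An object of class `metapop_state`.
#' @export
metapop_state <- function(n_A, n_S, nrow = 7L, ncol = 7L, generation = 0L) {
  k <- nrow * ncol
  if (length(n_A) != k || length(n_S) != k) {
    stop("n_A and n_S must have one element per grid patch")
  }
  if (any(n_A < 0) || any(n_S < 0)) stop("cell counts must be non-negative")
  structure(list(n_A = as.numeric(n_A), n_S = as.numeric(n_S),
                 nrow = as.integer(nrow), ncol = as.integer(ncol),
                 generation = as.numeric(generation)),
            class = "metapop_state")
}

#' @export
print.metapop_state <- function(x, ...) {
  cat(sprintf(
    "Metapopulation: %d x %d grid, generation %g, %d A cells, %d S cells\n",
    x$nrow, x$ncol, x$generation, sum(x$n_A), sum(x$n_S)))
  invisible(x)
}

#' Neighboring patches of a grid cell
#'
#' With viscosity 1 this is the Moore (8-connected) neighborhood clipped at
#' the borders, giving 3, 5, or 8 neighbors for corner, edge, and interior
#' patches of the grid; with viscosity 0 every other patch is a neighbor.
#'
#' @param index Grid index (column-major).
#' @param nrow,ncol Grid dimensions.
#' @param viscosity 0 or 1.
#' @return Integer vector of neighboring grid indices.
#' @export
neighbors <- function(index, nrow = 7L, ncol = 7L, viscosity = 1L) {
  k <- nrow * ncol
  if (index < 1 || index > k) stop("grid index out of range")
  if (viscosity == 0L) return(setdiff(seq_len(k), index))
  r <- (index - 1L) %% nrow + 1L
  cc <- (index - 1L) %/% nrow + 1L
  rr <- max(1L, r - 1L):min(nrow, r + 1L)
  cs <- max(1L, cc - 1L):min(ncol, cc + 1L)
  cells <- as.integer(outer(rr, (cs - 1L) * nrow, "+"))
  setdiff(cells, index)
}

# Precomputed neighbor lists for every patch.
neighbor_lists <- function(nrow, ncol, viscosity) {
  lapply(seq_len(nrow * ncol), neighbors,
         nrow = nrow, ncol = ncol, viscosity = viscosity)
}

#' Move a propagule between two groups
#'
#' Transfers `round_half_up(p * n)` cells of each type from the donor patch to
#' the recipient patch. Deterministic given `p`; total cell counts are
#' conserved exactly.
#'
#' @param state A [metapop_state()].
#' @param donor,recipient Grid indices.
#' @param p Propagule fraction of the donor group.
#' @return The updated state.
#' @export
transfer_propagule <- function(state, donor, recipient, p) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  mA <- round_half_up(p * state$n_A[donor])
  mS <- round_half_up(p * state$n_S[donor])
  state$n_A[donor] <- state$n_A[donor] - mA
  state$n_S[donor] <- state$n_S[donor] - mS
  state$n_A[recipient] <- state$n_A[recipient] + mA
  state$n_S[recipient] <- state$n_S[recipient] + mS
  state
}

sample_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

#' One round of random migration
#'
#' Up to `max_events` migrations. For each event a donor is drawn uniformly
#' from the non-empty groups that have not yet played donor or recipient this
#' round, and a recipient uniformly from the donor's not-yet-used neighbors
#' (empty patches may be recolonized but never donate). If the donor has no
#' eligible neighbor the event is skipped; the donor still counts as used.
#' The propagule fraction is drawn from the configured beta distribution.
#'
#' @param state A [metapop_state()].
#' @param cfg A [dispersal_config()].
#' @param nbrs Optional precomputed neighbor lists.
#' @return The updated state, with a data frame of migration events attached
#'   as attribute `"dispersal_log"`.
#' @export
random_migration_round <- function(state, cfg, nbrs = NULL) {
  if (is.null(nbrs)) {
    nbrs <- neighbor_lists(state$nrow, state$ncol, cfg$viscosity)
  }
  used <- logical(state$nrow * state$ncol)
  log <- vector("list", cfg$max_events)
  for (e in seq_len(cfg$max_events)) {
    elig <- which(!used & (state$n_A + state$n_S) > 0)
    if (!length(elig)) break
    d <- sample_one(elig)
    used[d] <- TRUE
    rc <- nbrs[[d]]
    rc <- rc[!used[rc]]
    if (!length(rc)) next
    r <- sample_one(rc)
    used[r] <- TRUE
    p <- stats::rbeta(1, cfg$propagule_shape[1], cfg$propagule_shape[2])
    mA <- round_half_up(p * state$n_A[d])
    mS <- round_half_up(p * state$n_S[d])
    state <- transfer_propagule(state, d, r, p)
    log[[e]] <- c(donor = d, recipient = r, p = p, moved_A = mA, moved_S = mS)
  }
  attr(state, "dispersal_log") <- do.call(rbind, Filter(Negate(is.null), log))
  state
}

#' One round of selective migration
#'
#' As [random_migration_round()], but donors are drawn only from the
#' `sm_candidates` largest non-empty groups (ties at the candidacy boundary
#' broken uniformly at random), each donating at most once per round, and
#' recipients are drawn from the donor's neighbors excluding the other
#' candidate donors. Candidacy is fixed at the start of the round. Because
#' A-type groups sit at a much larger equilibrium size than S-type groups,
#' this rule effectively restricts donation to A-type groups once any exist.
#'
#' @inheritParams random_migration_round
#' @return The updated state, with attribute `"dispersal_log"`.
#' @export
selective_migration_round <- function(state, cfg, nbrs = NULL) {
  if (is.null(nbrs)) {
    nbrs <- neighbor_lists(state$nrow, state$ncol, cfg$viscosity)
  }
  sizes <- state$n_A + state$n_S
  ne <- which(sizes > 0)
  if (!length(ne)) {
    attr(state, "dispersal_log") <- NULL
    return(state)
  }
  ord <- ne[order(-sizes[ne], stats::runif(length(ne)))]
  candidates <- ord[seq_len(min(cfg$sm_candidates, length(ord)))]
  donated <- logical(state$nrow * state$ncol)
  log <- vector("list", cfg$max_events)
  for (e in seq_len(cfg$max_events)) {
    avail <- candidates[!donated[candidates] &
                          (state$n_A + state$n_S)[candidates] > 0]
    if (!length(avail)) break
    d <- sample_one(avail)
    donated[d] <- TRUE
    rc <- setdiff(nbrs[[d]], candidates)
    if (!length(rc)) next
    r <- sample_one(rc)
    p <- stats::rbeta(1, cfg$propagule_shape[1], cfg$propagule_shape[2])
    mA <- round_half_up(p * state$n_A[d])
    mS <- round_half_up(p * state$n_S[d])
    state <- transfer_propagule(state, d, r, p)
    log[[e]] <- c(donor = d, recipient = r, p = p, moved_A = mA, moved_S = mS)
  }
  attr(state, "dispersal_log") <- do.call(rbind, Filter(Negate(is.null), log))
  state
}

#' Trait-group pooling and redistribution
#'
#' Every cell in the metapopulation is independently reassigned to a patch
#' drawn uniformly from all patches (implemented as one multinomial draw per
#' type, which is equivalent). Total counts per type are conserved exactly;
#' the expected composition of every new group equals the pooled composition,
#' so between-group variance in the proportion of altruists collapses to
#' redistribution sampling noise.
#'
#' @param state A [metapop_state()].
#' @return The updated state.
#' @export
trait_group_shuffle <- function(state) {
  k <- state$nrow * state$ncol
  state$n_A <- as.numeric(stats::rmultinom(1, sum(state$n_A), rep(1, k)))
  state$n_S <- as.numeric(stats::rmultinom(1, sum(state$n_S), rep(1, k)))
  state
}

apply_dispersal <- function(state, cfg, nbrs) {
  out <- switch(cfg$mode,
                none = state,
                RM = random_migration_round(state, cfg, nbrs),
                SM = selective_migration_round(state, cfg, nbrs),
                TG = trait_group_shuffle(state))
  attr(out, "dispersal_log") <- NULL
  out
}

#' One full metapopulation iteration
#'
#' One model iteration is a dispersal round (per the configured mode)
#' followed by `delta_g` independent within-group generations, mutation
#' included. Extinct groups persist as empty patches; they can be recolonized
#' by migration but never donate.
#'
#' @param state A [metapop_state()].
#' @param params A [model_params()] object.
#' @param cfg A [dispersal_config()].
#' @param nbrs Optional precomputed neighbor lists.
#' @return The updated state, advanced by `delta_g` generations.
#' @export
step_metapopulation <- function(state, params, cfg, nbrs = NULL) {
  if (is.null(nbrs)) {
    nbrs <- neighbor_lists(state$nrow, state$ncol, cfg$viscosity)
  }
  state <- apply_dispersal(state, cfg, nbrs)
  a <- state$n_A
  s <- state$n_S
  for (g in seq_len(cfg$delta_g)) {
    ns <- step_counts(a, s, params)
    a <- ns$n_A
    s <- ns$n_S
  }
  state$n_A <- a
  state$n_S <- s
  state$generation <- state$generation + cfg$delta_g
  state
}

#' Run a metapopulation for a fixed number of generations
#'
#' Dispersal happens at iteration start: the first generation of the run is
#' preceded by a dispersal round, and another round precedes each subsequent
#' block of `delta_g` generations.
#'
#' @param state Starting [metapop_state()].
#' @param params A [model_params()] object.
#' @param cfg A [dispersal_config()].
#' @param n_gens Total generations to simulate.
#' @param record_every Interval between recorded summary rows (default:
#'   about 1000 rows over the run).
#' @param pure_threshold Group-level A-proportion above which a group counts
#'   as A-type in the recorded summaries.
#' @return A list of class `metapop_run` with `trajectory` (data frame
#'   `generation`, `total_A`, `total_S`, `n_A_groups`, `n_extinct`) and the
#'   final `state`.
#' @export
run_metapopulation <- function(state, params, cfg, n_gens,
                               record_every = NULL, pure_threshold = 0.95) {
  if (n_gens < 1) stop("n_gens must be at least 1")
  if (is.null(record_every)) record_every <- max(1L, n_gens %/% 1000L)
  nbrs <- neighbor_lists(state$nrow, state$ncol, cfg$viscosity)
  a <- state$n_A
  s <- state$n_S
  gen0 <- state$generation
  n_rec <- n_gens %/% record_every
  rec <- matrix(0, nrow = n_rec, ncol = 5L)
  ri <- 0L
  dg <- cfg$delta_g
  for (g in seq_len(n_gens)) {
    if ((g - 1L) %% dg == 0L && cfg$mode != "none") {
      state$n_A <- a
      state$n_S <- s
      state <- apply_dispersal(state, cfg, nbrs)
      a <- state$n_A
      s <- state$n_S
    }
    ns <- step_counts(a, s, params)
    a <- ns$n_A
    s <- ns$n_S
    if (g %% record_every == 0L) {
      ri <- ri + 1L
      tot <- a + s
      live <- tot > 0
      rec[ri, ] <- c(gen0 + g, sum(a), sum(s),
                     sum(live & (a / pmax(tot, 1)) > pure_threshold),
                     sum(!live))
    }
  }
  state$n_A <- a
  state$n_S <- s
  state$generation <- gen0 + n_gens
  structure(list(
    trajectory = data.frame(generation = rec[, 1], total_A = rec[, 2],
                            total_S = rec[, 3], n_A_groups = rec[, 4],
                            n_extinct = rec[, 5]),
    state = state, params = params, cfg = cfg),
    class = "metapop_run")
}

#' Summarize a metapopulation state
#'
#' @param state A [metapop_state()].
#' @param pure_threshold Group-level A-proportion above which a non-empty
#'   group counts as A-type.
#' @return A list with `pi` (metapopulation A-cell proportion; `NA` with a
#'   warning when every group is extinct), `F_A` (fraction of non-empty
#'   groups that are A-type), `group_sizes`, and `n_extinct`.
#' @export
metapop_summary <- function(state, pure_threshold = 0.95) {
  tot <- state$n_A + state$n_S
  live <- tot > 0
  if (!any(live)) {
    warning("metapopulation fully extinct: pi undefined")
    pi <- NA_real_
    F_A <- NA_real_
  } else {
    pi <- sum(state$n_A) / sum(tot)
    F_A <- mean(state$n_A[live] / tot[live] > pure_threshold)
  }
  list(pi = pi, F_A = F_A, group_sizes = tot, n_extinct = sum(!live))
}

#' Flatten a metapopulation state to a tabular grid snapshot
#'
#' @param state A [metapop_state()].
#' @return A data frame with columns `generation`, `row`, `col`, `n_A`,
#'   `n_S`, one row per patch, suitable for bubble-grid plotting.
#' @export
metapop_to_table <- function(state) {
  k <- state$nrow * state$ncol
  i <- seq_len(k)
  data.frame(generation = state$generation,
             row = (i - 1L) %% state$nrow + 1L,
             col = (i - 1L) %/% state$nrow + 1L,
             n_A = state$n_A, n_S = state$n_S)
}
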