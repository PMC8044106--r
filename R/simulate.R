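#' Parameters for the serial-transfer sporulation-bottleneck simulator
#'
#' Encodes one cycle of the wet-lab regime: growth in fresh medium, partial
#' sporulation by harvest time, heat treatment killing vegetative cells, and
#' a 1/20 volumetric transfer of the surviving suspension into the next
#' culture. Per-strain vectors are recycled to \code{n_strains}.
#'
#' @param n_strains number of competing strains.
#' @param growth_yield expected fold-increase of vegetative cells per cycle
#'   (per strain, recycled). Default 20: a culture diluted 1/20 regrows to the
#'   same stationary density.
#' @param sporulation_fraction probability that a cell is a mature spore at
#'   harvest (per strain, recycled), in [0,1].
#' @param heat_kill_survival_vegetative probability a vegetative cell survives
#'   the 80 degC / 20 min treatment. Default 0 (all die).
#' @param dilution_fraction proportion of the culture transferred; default
#'   1/20 (0.5 ml into 9.5 ml, or 100 ul into 1900 ul).
#' @param n_cycles number of reinoculation cycles; the study used 9.
#' @param carrying_capacity maximum total cells after growth; exceeding
#'   totals are rescaled proportionally (composition-preserving).
#' @param error_rate per-base substitution probability for synthetic reads.
#' @param depth read pairs per rendered sample.
#' @param initial_cells total cells in the equal-ratio inoculum.
#' @param seed root seed; per-cycle streams are derived via [derive_seed()].
#' @param fitness_modifier optional \code{function(cycle)} returning a
#'   multiplicative per-strain adjustment to \code{growth_yield} at that
#'   cycle; a scalar stand-in for mutations acquired during the experiment.
#' @return a validated \code{simulation_params} list.
#' @export
simulation_params <- function(n_strains,
                              growth_yield = 20,
                              sporulation_fraction = 0.5,
                              heat_kill_survival_vegetative = 0,
                              dilution_fraction = 1 / 20,
                              n_cycles = 9L,
                              carrying_capacity = 1e9,
                              error_rate = 0.001,
                              depth = 1e5,
                              initial_cells = 1e6,
                              seed = 1L,
                              fitness_modifier = NULL) {
  p <- list(
    n_strains = as.integer(n_strains),
    growth_yield = rep_len(growth_yield, n_strains),
    sporulation_fraction = rep_len(sporulation_fraction, n_strains),
    heat_kill_survival_vegetative = heat_kill_survival_vegetative,
    dilution_fraction = dilution_fraction,
    n_cycles = as.integer(n_cycles),
    carrying_capacity = carrying_capacity,
    error_rate = error_rate,
    depth = depth,
    initial_cells = initial_cells,
    seed = as.integer(seed),
    fitness_modifier = fitness_modifier)
  stopifnot(
    all(p$sporulation_fraction >= 0 & p$sporulation_fraction <= 1),
    p$heat_kill_survival_vegetative >= 0,
    p$heat_kill_survival_vegetative <= 1,
    p$dilution_fraction > 0, p$dilution_fraction <= 1,
    p$n_cycles >= 0, p$depth >= 0,
    p$error_rate >= 0, p$error_rate <= 1,
    all(p$growth_yield >= 0), p$carrying_capacity > 0)
  class(p) <- "simulation_params"
  p
}

#' Scenario presets for the simulator
#'
#' Qualitative regimes mirroring the selection outcomes described for the
#' competition: \code{"neutral"} (identical strains), \code{"early_sporulator"}
#' (one focal strain sporulates well before harvest), \code{"late_sporulator"}
#' (the focal strain delays sporulation, trading spores for extra divisions),
#' and \code{"growth_deficient"} (the focal strain grows poorly). The focal
#' strain is the first one.
#'
#' @param scenario preset name.
#' @param n_strains panel size.
#' @param ... overrides passed on to [simulation_params()].
#' @export
scenario_params <- function(scenario = c("neutral", "early_sporulator",
                                         "late_sporulator", "growth_deficient"),
                            n_strains = 79L, ...) {
  scenario <- match.arg(scenario)
  spo <- rep(0.5, n_strains)
  yld <- rep(20, n_strains)
  if (scenario == "early_sporulator") {
    spo[] <- 0.3
    spo[1] <- 0.9
  } else if (scenario == "late_sporulator") {
    spo[] <- 0.5
    spo[1] <- 0.2
    yld[1] <- 30       # extra divisions before committing to sporulation
  } else if (scenario == "growth_deficient") {
    yld[1] <- 5
  }
  simulation_params(n_strains, growth_yield = yld, sporulation_fraction = spo,
                    ...)
}

#' Construct a population state
#'
#' @param vegetative,spores named non-negative integer vectors (same names).
#' @param cycle_index which cycle this state precedes.
#' @export
population_state <- function(vegetative, spores = NULL, cycle_index = 0L) {
  if (is.null(spores)) spores <- setNames(rep(0, length(vegetative)),
                                          names(vegetative))
  stopifnot(length(vegetative) == length(spores),
            all(vegetative >= 0), all(spores >= 0))
  st <- list(vegetative = vegetative, spores = spores,
             cycle_index = as.integer(cycle_index), extinct = FALSE)
  class(st) <- "population_state"
  st
}

#' Simulate one growth / sporulation / heat-kill / bottleneck cycle
#'
#' Applies, in order: (1) deterministic growth with composition-preserving
#' rescaling at carrying capacity; (2) binomial sporulation per strain;
#' (3) binomial heat-kill survival of vegetative cells (default: none
#' survive); (4) a multinomial bottleneck of size Binomial(survivors,
#' dilution_fraction), modelling volume transfer of a well-mixed suspension.
#' Sampled spores germinate and seed the next cycle as vegetative cells.
#'
#' Uses the current RNG state; seed management is the caller's concern
#' (see [simulate_experiment()]).
#'
#' @param state a \code{population_state}.
#' @param params a \code{simulation_params}.
#' @param yield_multiplier optional per-strain multiplier on growth_yield for
#'   this cycle (the acquired-mutation hook).
#' @return the next \code{population_state}; attribute \code{post_growth}
#'   holds the per-strain cell counts after growth (the composition sampled
#'   for sequencing, before heat treatment) and attribute \code{generations}
#'   the log2 fold-expansion realised during growth. Extinction sets
#'   \code{$extinct} rather than raising an error.
#' @export
simulate_cycle <- function(state, params, yield_multiplier = NULL) {
  v <- state$vegetative
  s <- state$spores
  yield <- params$growth_yield
  if (!is.null(yield_multiplier)) yield <- yield * yield_multiplier

  # (1) growth of vegetative cells; spores carried through inert
  grown <- v * yield
  tot <- sum(grown) + sum(s)
  if (is.finite(params$carrying_capacity) && tot > params$carrying_capacity) {
    f <- params$carrying_capacity / tot
    grown <- grown * f
    s <- s * f
  }
  grown <- round(grown)
  s <- round(s)
  post_growth <- grown + s
  gens <- if (sum(v) > 0) log2(sum(post_growth) / (sum(v) + sum(state$spores)))
          else NA_real_

  # (2) sporulation at harvest
  new_spores <- rbinom(length(grown), size = grown,
                       prob = params$sporulation_fraction)
  veg_left <- grown - new_spores
  spores_harvest <- new_spores + s

  # (3) heat-kill of vegetative cells
  veg_surv <- rbinom(length(veg_left), size = veg_left,
                     prob = params$heat_kill_survival_vegetative)
  survivors <- spores_harvest + veg_surv
  total_surv <- sum(survivors)

  # (4) volumetric bottleneck: one multinomial draw
  if (total_surv == 0) {
    nxt <- population_state(setNames(rep(0, length(v)), names(v)),
                            cycle_index = state$cycle_index + 1L)
    nxt$extinct <- TRUE
  } else {
    n_transfer <- rbinom(1, size = total_surv, prob = params$dilution_fraction)
    if (n_transfer == 0) {
      sampled <- rep(0, length(survivors))
    } else if (n_transfer == total_surv) {
      # whole volume transferred: identity, no resampling noise
      sampled <- survivors
    } else {
      sampled <- as.vector(rmultinom(1, size = n_transfer,
                                     prob = survivors / total_surv))
    }
    nxt <- population_state(setNames(sampled, names(v)),
                            cycle_index = state$cycle_index + 1L)
    nxt$extinct <- sum(sampled) == 0
  }
  attr(nxt, "post_growth") <- setNames(post_growth, names(v))
  attr(nxt, "generations") <- gens
  nxt
}

#' Simulate the full serial-transfer competition for one replicate population
#'
#' Starts from an equal-ratio inoculum of \code{initial_cells} and runs
#' \code{n_cycles} of [simulate_cycle()]. The recorded composition after each
#' cycle is the post-growth, pre-heat-treatment state, matching when DNA was
#' sampled for sequencing.
#'
#' @param panel a \code{strain_panel}.
#' @param params a \code{simulation_params} with
#'   \code{n_strains == nrow(panel)}.
#' @param mix,replicate integer stream indices; together with
#'   \code{params$seed} they determine every random draw (per-cycle streams
#'   derived with [derive_seed()]).
#' @return a \code{competition_trajectory}: list with \code{frequencies}
#'   (matrix, rows t0..t{n_cycles}, columns strains; t0 is the inoculum),
#'   \code{counts} (post-growth cell counts per cycle), \code{generations}
#'   (per-cycle log2 fold-expansion), \code{final_state}, and
#'   \code{extinct} flag.
#' @export
simulate_experiment <- function(panel, params, mix = 1L, replicate = 1L) {
  n <- nrow(panel)
  if (n < 1) stop("simulate_experiment(): empty panel")
  if (params$n_strains != n)
    stop("simulate_experiment(): params built for ", params$n_strains,
         " strains, panel has ", n)
  inoc <- setNames(rep(round(params$initial_cells / n), n), panel$strain_id)
  state <- population_state(inoc, cycle_index = 0L)

  freqs <- matrix(NA_real_, nrow = params$n_cycles + 1L, ncol = n,
                  dimnames = list(paste0("t", 0:params$n_cycles),
                                  panel$strain_id))
  counts <- freqs
  freqs[1, ] <- inoc / sum(inoc)
  counts[1, ] <- inoc
  gens <- numeric(params$n_cycles)
  extinct <- FALSE

  for (cy in seq_len(params$n_cycles)) {
    set.seed(derive_seed(params$seed, mix, replicate, cy))
    mult <- if (!is.null(params$fitness_modifier))
      rep_len(params$fitness_modifier(cy), n) else NULL
    state <- simulate_cycle(state, params, yield_multiplier = mult)
    pg <- attr(state, "post_growth")
    counts[cy + 1L, ] <- pg
    freqs[cy + 1L, ] <- if (sum(pg) > 0) pg / sum(pg) else NA_real_
    gens[cy] <- attr(state, "generations")
    if (state$extinct) {
      extinct <- TRUE
      break
    }
  }
  structure(list(frequencies = freqs, counts = counts, generations = gens,
                 final_state = state, extinct = extinct),
            class = "competition_trajectory")
}

#' @export
print.competition_trajectory <- function(x, ...) {
  cat("competition_trajectory:", ncol(x$frequencies), "strains,",
      nrow(x$frequencies) - 1L, "cycles",
      if (x$extinct) "(EXTINCT)" else "", "\n")
  cat("total generations (log2 fold-expansion):",
      round(sum(x$generations, na.rm = TRUE), 1), "\n")
  invisible(x)
}

#' Simulate CFU records for a pairwise competition
#'
#' Generates one replicate of a two-strain competition using the same
#' growth / sporulation mechanics as [simulate_cycle()]: both strains grow by
#' their yield, then each cell sporulates with its strain-specific
#' probability. Returns the plate-count quantities a wet-lab competition
#' would report, for feeding the fitness estimators.
#'
#' @param start_a,start_b inoculated CFU of strains A and B.
#' @param yield_a,yield_b per-cycle fold-increase (default 20).
#' @param spo_a,spo_b sporulation fractions.
#' @param seed optional seed.
#' @return one-row data.frame with cfu_a_start, cfu_b_start, cfu_a_48h,
#'   cfu_b_48h, spores_a_48h, spores_b_48h.
#' @export
simulate_competition <- function(start_a, start_b, yield_a = 20, yield_b = 20,
                                 spo_a = 0.5, spo_b = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grown_a <- round(start_a * yield_a)
  grown_b <- round(start_b * yield_b)
  spores_a <- rbinom(1, grown_a, spo_a)
  spores_b <- rbinom(1, grown_b, spo_b)
  data.frame(cfu_a_start = start_a, cfu_b_start = start_b,
             cfu_a_48h = grown_a, cfu_b_48h = grown_b,
             spores_a_48h = spores_a, spores_b_48h = spores_b)
}
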