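#' @include kinetics.R
NULL

#' Pulsatile insertion interval matching continuous delivery
#'
#' The interval between pulses of size \code{PH} that reproduces the
#' continuous model's maximal insertion flux \code{k_ins * M_F0}:
#' \deqn{t_{int0} = PH / (k_{ins} M_{F0})}
#' With the default pools (single insertions of 10\% of the maximum docking
#' concentration) this gives 25.9 s for pool X and 2.6 s for pool D.
#'
#' @param PH single-insertion amount (nM), > 0.
#' @param k_ins continuous insertion rate constant (1/s), > 0.
#' @param M_F0 maximum docking-site concentration (nM), > 0.
#' @return interval t_int0 (s).
#' @examples
#' pulseInterval(0.3, 1 / 259, 3)  # 25.9 s
#' pulseInterval(0.7, 1 / 26.0, 7) # 2.6 s
#' @export
pulseInterval <- function(PH, k_ins, M_F0) {
  if (!all(is.finite(c(PH, k_ins, M_F0))) || any(c(PH, k_ins, M_F0) <= 0))
    stop("PH, k_ins and M_F0 must all be finite and > 0")
  PH / (k_ins * M_F0)
}

#' Construct an insertion schedule
#'
#' @param mode \code{"continuous"} or \code{"pulsatile"}.
#' @param interval_mode \code{"regular"} or \code{"random"}.
#' @param amount_mode \code{"regular"} or \code{"random"}.
#' @param PH named single-insertion amounts per pool (nM); defaults to 10\%
#'   of each pool's maximum docking concentration.
#' @param freq_fold,conc_fold fold changes relative to the control regimen;
#'   keep \code{freq_fold * conc_fold = 1} to conserve time-averaged
#'   delivery.
#' @param seed RNG seed (required semantics when any mode is random).
#' @return An \linkS4class{InsertionSchedule}.
#' @export
insertionSchedule <- function(mode = c("pulsatile", "continuous"),
                              interval_mode = c("regular", "random"),
                              amount_mode = c("regular", "random"),
                              PH = c(X = 0.3, D = 0.7),
                              freq_fold = 1, conc_fold = 1, seed = 1L) {
  methods::new("InsertionSchedule", mode = match.arg(mode),
               interval_mode = match.arg(interval_mode),
               amount_mode = match.arg(amount_mode), PH = PH,
               freq_fold = freq_fold, conc_fold = conc_fold,
               seed = as.integer(seed))
}

#' Realize a pulse-event list from a schedule
#'
#' Regular mode emits pulses at 0, t_int0, 2 t_int0, ... per pool (interval
#' divided by \code{freq_fold}); random-interval mode draws exponential
#' waiting times with the same mean; random-amount mode draws amounts
#' uniformly on [0, 2 PH] (mean PH * conc_fold).  The realized schedule's
#' expected time-averaged delivery equals the regular schedule's.  The same
#' seed always yields the same schedule.
#'
#' @param sched an \linkS4class{InsertionSchedule}.
#' @param t_end horizon (s).
#' @param pools named list of \linkS4class{PoolConfig}s.
#' @return \code{data.frame(time, pool, amount)} sorted by time.
#' @examples
#' ev <- generateSchedule(insertionSchedule(), 51.8)
#' table(ev$pool)  # 3 X pulses, 20 D pulses
#' @export
generateSchedule <- function(sched, t_end,
                             pools = list(X = poolConfig("X"),
                                          D = poolConfig("D"))) {
  stopifnot(methods::is(sched, "InsertionSchedule"))
  if (sched@mode != "pulsatile") stop("schedule mode is not pulsatile")
  random <- sched@interval_mode == "random" || sched@amount_mode == "random"
  if (random) set.seed(sched@seed)
  out <- list()
  for (pl in names(pools)) {
    pc <- pools[[pl]]
    ph <- sched@PH[[pl]]
    t_int <- pulseInterval(ph, pc@k_ins, pc@M_F0) / sched@freq_fold
    amount <- ph * sched@conc_fold
    times <- if (sched@interval_mode == "regular") {
      seq(0, t_end, by = t_int)
    } else {
      tt <- 0
      acc <- numeric(0)
      repeat {
        acc <- c(acc, tt)
        tt <- tt + stats::rexp(1, rate = 1 / t_int)
        if (tt > t_end) break
      }
      acc
    }
    amounts <- if (sched@amount_mode == "regular") rep(amount, length(times))
               else stats::runif(length(times), 0, 2 * amount)
    out[[pl]] <- data.frame(time = times, pool = pl, amount = amounts,
                            stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$time, ev$pool), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Apply a single insertion pulse to a state vector
#'
#' Adds \code{min(amount, M_F0 - occupancy)} of free MT1-MMP monomer to the
#' pool; no insertion occurs beyond full docking-site occupancy.  A complex
#' occupies sites equal to its MT1-MMP monomer count.
#'
#' @param state named numeric concentrations (nM).
#' @param pool a \linkS4class{PoolConfig}.
#' @param amount requested amount (nM), >= 0.
#' @param species species table (from \code{\link{speciesTable}}).
#' @return Modified state vector.
#' @export
applyPulse <- function(state, pool, amount, species) {
  stopifnot(amount >= 0)
  loc <- paste0("membrane_", pool@pool_id)
  mem <- species$name[species$location == loc & species$m14 > 0]
  occ <- sum(state[mem] * species$m14[match(mem, species$name)], na.rm = TRUE)
  add <- min(amount, max(pool@M_F0 - occ, 0))
  tgt <- paste0("M14", pool@pool_id)
  state[tgt] <- state[tgt] + add
  state
}

#' Continuous turnover reactions for one pool
#'
#' Insertion of free MT1-MMP at rate \code{k_ins * M_F} (M_F = free docking
#' sites), and first-order internalization of every membrane species of the
#' pool.  Internalization removes the MT1-MMP enzyme without recycling it,
#' but releases its cargo back to the extracellular space: bound ECM
#' returns to the matrix, TIMP-2 / proMMP-2 return to solution (as the
#' T2.M2 complex where they were paired and that species exists, else as
#' free monomers), so solution totals are conserved by turnover.
#'
#' @param pool a \linkS4class{PoolConfig}.
#' @param species species table of the target network.
#' @return Reaction \code{data.frame} rows (see
#'   \linkS4class{ReactionNetwork}).
#' @export
continuousTurnoverReactions <- function(pool, species) {
  pl <- pool@pool_id
  loc <- paste0("membrane_", pl)
  has_t2m2 <- "T2.M2" %in% species$name
  b <- .rxn_builder()
  b$add(NA_character_, products = numeric(0), k = pool@k_ins,
        tag = "insertion", type = "insertion", pool = pl, mf0 = pool@M_F0,
        dist = stats::setNames(1, paste0("M14", pl)))
  mem <- species[species$location == loc, , drop = FALSE]
  for (i in seq_len(nrow(mem))) {
    pr <- c(ECM = mem$ecm[i])
    if (has_t2m2) {
      pr <- c(pr, "T2.M2" = mem$m2[i], T2 = mem$t2[i] - mem$m2[i])
    } else {
      pr <- c(pr, T2 = mem$t2[i], M2 = mem$m2[i])
    }
    pr <- pr[pr > 0]
    b$add(mem$name[i], products = pr, k = pool@k_int,
          tag = "internalization")
  }
  b$build()
}

#' Add continuous membrane turnover to a pools network
#'
#' @param net a \linkS4class{ReactionNetwork} built with
#'   \code{pools = "XD"}.
#' @param pools named list of \linkS4class{PoolConfig}s.
#' @param insertion \code{"free"} (fresh TIMP-free monomer; the normal
#'   model) or \code{"none"} (internalization only; used with pulsatile
#'   schedules).
#' @param distribute named list by pool of steady-state fractions for
#'   transient-eliminated continuous insertion (overrides \code{insertion}).
#' @return A new \linkS4class{ReactionNetwork} with turnover reactions and
#'   registered pool configurations.
#' @export
addContinuousTurnover <- function(net, pools = list(X = poolConfig("X"),
                                                    D = poolConfig("D")),
                                  insertion = c("free", "none"),
                                  distribute = NULL) {
  insertion <- match.arg(insertion)
  if (!identical(net@metadata$options$pools, "XD"))
    stop("turnover requires a pools='XD' network")
  rx <- net@reactions
  for (pl in names(pools)) {
    rows <- continuousTurnoverReactions(pools[[pl]], net@species)
    if (insertion == "none" && is.null(distribute))
      rows <- rows[rows$type != "insertion", , drop = FALSE]
    if (!is.null(distribute)) {
      ins <- rows$type == "insertion"
      rows$dist[ins] <- list(.distribution_delta(net@species,
                                                 distribute[[pl]]))
    }
    rx <- rbind(rx, rows)
  }
  md <- net@metadata
  md$pool_configs <- pools
  md$options$turnover <- if (insertion == "none" && is.null(distribute))
    "internalization_only" else if (is.null(distribute)) "continuous"
    else "continuous_distributed"
  methods::new("ReactionNetwork", species = net@species, reactions = rx,
               metadata = md)
}

#' Register pool configurations without adding reactions
#'
#' Needed when pulses are the only delivery route but occupancy clamping
#' must still know each pool's capacity.
#'
#' @inheritParams addContinuousTurnover
#' @export
registerPools <- function(net, pools = list(X = poolConfig("X"),
                                            D = poolConfig("D"))) {
  md <- net@metadata
  md$pool_configs <- pools
  methods::new("ReactionNetwork", species = net@species,
               reactions = net@reactions, metadata = md)
}

#' Steady-state composition fractions of a membrane pool
#'
#' Runs the continuous-turnover model to steady state and returns, for the
#' requested pool, the fraction of MT1-MMP monomer equivalents held by each
#' membrane species.  These fractions drive transient-eliminated insertion:
#' newly delivered MT1-MMP apportioned in steady-state proportions produces
#' no activity transient.
#'
#' @param net a turnover-enabled \linkS4class{ReactionNetwork}.
#' @param pool_id \code{"X"} or \code{"D"}.
#' @param y0 named initial concentrations (nM).
#' @param t_max,dt integration horizon and step (s).
#' @param rel_tol,window steady-state criterion
#'   (\code{\link{detectSteadyState}}).
#' @param clamp species held at bulk concentration during the run.
#' @return Named numeric fractions (sum 1) over the pool's membrane species.
#' @export
steadyStateFractions <- function(net, pool_id, y0, t_max = 20000, dt = 0.05,
                                 rel_tol = 1e-5, window = 500,
                                 clamp = c("T2", "M2")) {
  clamp <- intersect(clamp, net@species$name[net@species$name %in% names(y0)])
  traj <- integrateRK4(net, y0, t_end = t_max, dt = dt,
                       out_stride = max(1L, floor(10 / dt)), clamp = clamp)
  loc <- paste0("membrane_", pool_id)
  sp <- net@species
  mem <- sp$name[sp$location == loc & sp$m14 > 0]
  occ_series <- as.numeric(concentrations(traj, mem) %*%
                             sp$m14[match(mem, sp$name)])
  ss <- detectSteadyState(traj, occ_series, rel_tol = rel_tol,
                          window = window)
  if (!ss$converged)
    stop("steady state not reached within t_max = ", t_max, " s")
  i <- which.min(abs(traj@times - ss$reached_at))
  w <- traj@states[i, mem] * sp$m14[match(mem, sp$name)]
  if (sum(w) <= 0) stop("empty pool at steady state")
  fr <- w / sum(w)
  fr[fr < 1e-12] <- 0
  fr / sum(fr)
}

#' Distribute an insertion amount across complexes
#'
#' Apportions a pulse across the pool's membrane species proportionally to
#' steady-state fractions, conserving inserted MT1-MMP monomer equivalents;
#' TIMP-2 and proMMP-2 contained in inserted complexes are drawn from the
#' bulk solution species.
#'
#' @inheritParams applyPulse
#' @param fractions named fractions from \code{\link{steadyStateFractions}}.
#' @return Modified state vector.
#' @export
distributeInsertion <- function(state, pool, amount, fractions, species) {
  stopifnot(amount >= 0)
  loc <- paste0("membrane_", pool@pool_id)
  mem <- species$name[species$location == loc & species$m14 > 0]
  occ <- sum(state[mem] * species$m14[match(mem, species$name)], na.rm = TRUE)
  add <- min(amount, max(pool@M_F0 - occ, 0))
  delta <- .distribution_delta(species, fractions)
  state[names(delta)] <- state[names(delta)] + add * delta
  state
}
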