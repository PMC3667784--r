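#' @include ecm.R
NULL

#' M14a activity weights
#'
#' M14a is the weighted sum of ECM-degradation-competent MT1-MMP complexes:
#' the free monomer (weight 1), the dimer (weight 2, both catalytic sites
#' free) and the two half-inhibited dimer forms M14.M14.T2 and
#' M14.M14.T2.M2 (weight 1 each, one catalytic site blocked), summed over
#' pools.
#'
#' @param species species table (or a \linkS4class{ReactionNetwork} /
#'   \linkS4class{Trajectory}).
#' @return Named numeric weights over the active species.
#' @export
m14aDefinition <- function(species) {
  if (methods::is(species, "ReactionNetwork") ||
      methods::is(species, "Trajectory"))
    species <- speciesTable(species)
  w <- species$activity_weight
  stats::setNames(w[w > 0], species$name[w > 0])
}

#' M14a activity series
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param def named weights (default \code{\link{m14aDefinition}} of the
#'   trajectory's species).
#' @return Numeric series (nM) on the trajectory time grid.
#' @examples
#' # a pure dimer concentration of 1 nM gives M14a = 2 nM
#' @export
computeM14a <- function(traj, def = m14aDefinition(traj)) {
  present <- intersect(names(def), colnames(traj@states))
  if (!length(present)) return(numeric(length(traj@times)))
  as.numeric(concentrations(traj, present) %*% def[present])
}

#' Half-width of a transient peak above its steady level
#'
#' Full width of the interval where the series is at or above
#' steady + (peak - steady)/2, from the first rise to the last fall,
#' linearly interpolated.  A series with no peak above the steady level has
#' width 0.  The baseline is the steady level, not zero: with a nonzero
#' plateau the half-width is otherwise ill-defined.
#'
#' @param times time grid (s).
#' @param series observable series (same length).
#' @param steady steady (plateau) level.
#' @return t_transient (s).
#' @examples
#' t <- seq(0, 10, 0.01)
#' tri <- pmax(0, 1 - abs(t - 5) / 5)     # triangular pulse, base 10 s
#' halfWidth(t, tri, 0)                    # 5 s
#' @export
halfWidth <- function(times, series, steady) {
  peak <- max(series)
  if (peak <= steady || !is.finite(steady)) return(0)
  level <- steady + (peak - steady) / 2
  above <- series >= level
  if (!any(above)) return(0)
  i1 <- which(above)[1]
  i2 <- which(above)[length(which(above))]
  t_start <- if (i1 == 1) times[1] else {
    y1 <- series[i1 - 1]; y2 <- series[i1]
    times[i1 - 1] + (level - y1) / (y2 - y1) * (times[i1] - times[i1 - 1])
  }
  t_end <- if (i2 == length(series)) times[length(times)] else {
    y1 <- series[i2]; y2 <- series[i2 + 1]
    times[i2] + (y1 - level) / (y1 - y2) * (times[i2 + 1] - times[i2])
  }
  t_end - t_start
}

#' Transient-activity metrics of a trajectory
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param observable as in \code{\link{detectSteadyState}} (default M14a).
#' @param rel_tol,window steady-state criterion.
#' @return list with \code{peak}, \code{steady} (M14a_steady),
#'   \code{t_transient} (s) and \code{steady_reached_at}.
#' @export
transientMetrics <- function(traj, observable = computeM14a,
                             rel_tol = 5e-3, window = 50) {
  series <- if (is.function(observable)) observable(traj)
            else if (is.character(observable))
              concentrations(traj, observable)[, 1]
            else as.numeric(observable)
  ss <- detectSteadyState(traj, series, rel_tol = rel_tol, window = window)
  if (!ss$converged)
    stop("no steady state within the trajectory; extend the horizon")
  list(peak = max(series), steady = ss$value,
       t_transient = halfWidth(traj@times, series, ss$value),
       steady_reached_at = ss$reached_at)
}

## ------- model drivers -------

#' Closed single-membrane model run
#'
#' The complex-formation model without turnover or ECM: surface MT1-MMP
#' expressed at t = 0 against solution TIMP-2 and proMMP-2; fully closed
#' (monomer equivalents conserved).
#'
#' @param params kinetic parameters.
#' @param T2 initial TIMP-2 (nM); overrides \code{params$T2_0}.
#' @param M2 initial proMMP-2 (nM); overrides \code{params$M2_0}.
#' @param t_end,dt,out_stride integration control.
#' @param net optional prebuilt network (e.g. with path deletions).
#' @return A \linkS4class{Trajectory}.
#' @export
runClosedModel <- function(params = defaultKineticParameters(),
                           T2 = params$T2_0, M2 = params$M2_0,
                           t_end = 300, dt = 0.005, out_stride = 10L,
                           net = NULL) {
  if (is.null(net)) net <- buildCoreNetwork(params)
  y0 <- c(M14 = params$M14_0, T2 = T2, M2 = M2)
  y0 <- y0[intersect(names(y0), net@species$name)]
  integrateRK4(net, y0, t_end = t_end, dt = dt, out_stride = out_stride)
}

#' Assemble the two-pool turnover network
#'
#' @param params kinetic parameters.
#' @param ecm include ECM degradation.
#' @param pools named list of \linkS4class{PoolConfig}s.
#' @param regimen \code{"continuous"} or \code{"pulsatile"} (pulsatile
#'   keeps internalization but delivers MT1-MMP through pulse events).
#' @param distribute steady-state fractions for transient-eliminated
#'   continuous insertion (named list by pool), or NULL.
#' @param turnover_scale joint scale factor on k_ins and k_int (turnover
#'   rate sweeps; 0 switches turnover off).
#' @param preassembled passed to \code{\link{buildCoreNetwork}}.
#' @return A \linkS4class{ReactionNetwork}.
#' @export
buildPoolsNetwork <- function(params = defaultKineticParameters(),
                              ecm = FALSE,
                              pools = list(X = poolConfig("X"),
                                           D = poolConfig("D")),
                              regimen = c("continuous", "pulsatile"),
                              distribute = NULL, turnover_scale = 1,
                              preassembled = TRUE) {
  regimen <- match.arg(regimen)
  if (turnover_scale != 1)
    pools <- lapply(pools, function(pc)
      poolConfig(pc@pool_id, M_F0 = pc@M_F0,
                 k_ins = pc@k_ins * turnover_scale,
                 k_int = pc@k_int * turnover_scale))
  net <- buildCoreNetwork(params, include_ecm = ecm, pools = "XD",
                          preassembled = preassembled)
  if (turnover_scale == 0) return(registerPools(net, pools))
  addContinuousTurnover(net, pools,
                        insertion = if (regimen == "continuous") "free"
                                    else "none",
                        distribute = distribute)
}

#' Membrane steady-occupancy initial state
#'
#' The membrane carries its steady MT1-MMP complement, all TIMP-free, at
#' t = 0: free M14 per pool at the turnover fixed point
#' \code{M_F0 k_ins / (k_ins + k_int)}.
#'
#' @param pools named list of \linkS4class{PoolConfig}s.
#' @return Named numeric vector (nM).
#' @export
steadyOccupancyInit <- function(pools = list(X = poolConfig("X"),
                                             D = poolConfig("D"))) {
  vapply(pools, function(pc)
    pc@M_F0 * pc@k_ins / (pc@k_ins + pc@k_int), numeric(1)) |>
    stats::setNames(paste0("M14", names(pools)))
}

#' Run the two-pool turnover model
#'
#' The workhorse for turnover / ECM experiments.  Continuous runs with the
#' transient present start from the steady-occupancy membrane state (fresh
#' TIMP-free MT1-MMP); transient-eliminated runs compute (or accept)
#' steady-state fractions and start from the relaxed composition.
#' Pulsatile runs start from an empty membrane with the first pulse at
#' t = 0.  The solution is a closed, finite reservoir: free TIMP-2,
#' proMMP-2 and their complex start at binding equilibrium for the given
#' totals, and internalization recycles cargo back to solution
#' (\code{\link{continuousTurnoverReactions}}), so solution totals are
#' conserved.  A constant-concentration bath is available through
#' \code{clamp}.
#'
#' @param params kinetic parameters.
#' @param T2 bulk TIMP-2 (nM).
#' @param regimen \code{"continuous"} or \code{"pulsatile"}.
#' @param transient \code{"present"} or \code{"eliminated"}.
#' @param sched an \linkS4class{InsertionSchedule} for pulsatile runs.
#' @param ecm include ECM degradation.
#' @param t_end,dt,out_stride integration control.
#' @param pools pool configurations.
#' @param turnover_scale joint k_ins/k_int scale.
#' @param fractions optional precomputed steady-state fractions (list by
#'   pool) for eliminated runs.
#' @param clamp species held at their initial concentrations (default
#'   none; pass e.g. \code{c("T2", "M2")} for an open-bath variant).
#' @return A \linkS4class{Trajectory}.
#' @export
runPoolsModel <- function(params = defaultKineticParameters(), T2 = params$T2_0,
                          regimen = c("continuous", "pulsatile"),
                          transient = c("present", "eliminated"),
                          sched = insertionSchedule(), ecm = FALSE,
                          t_end = 2000, dt = 0.02, out_stride = 25L,
                          pools = list(X = poolConfig("X"),
                                       D = poolConfig("D")),
                          turnover_scale = 1, fractions = NULL,
                          clamp = character()) {
  regimen <- match.arg(regimen)
  transient <- match.arg(transient)
  if (transient == "eliminated" && is.null(fractions))
    fractions <- poolSteadyFractions(params, T2, pools = pools,
                                     turnover_scale = turnover_scale,
                                     eliminate = TRUE)
  net <- buildPoolsNetwork(params, ecm = ecm, pools = pools,
                           regimen = regimen,
                           distribute = if (regimen == "continuous")
                             fractions else NULL,
                           turnover_scale = turnover_scale)
  ## solution pre-equilibrated: free T2 / M2 and the preassembled complex
  ## at binding equilibrium for the requested totals
  y0 <- .bath_equilibrium(T2, params$M2_0, params)
  if (ecm) y0 <- c(y0, ECM = params$ECM_0)
  events <- NULL
  distribute <- NULL
  if (regimen == "continuous") {
    if (transient == "present") y0 <- c(y0, steadyOccupancyInit(pools))
    else y0 <- c(y0, .fractions_init(net, fractions, pools))
  } else {
    events <- generateSchedule(sched, t_end, pools)
    if (transient == "eliminated") {
      distribute <- fractions
      y0 <- c(y0, .fractions_init(net, fractions, pools))
    }
  }
  integrateRK4(net, y0, t_end = t_end, dt = dt, events = events,
               distribute = distribute, out_stride = out_stride,
               clamp = intersect(clamp, names(y0)[y0 > 0]))
}

## Pre-equilibrated bulk solution: free TIMP-2, free proMMP-2 and their
## complex at binding equilibrium for the given totals (quadratic root).
.bath_equilibrium <- function(T2_tot, M2_tot, params) {
  Kd <- params$koff_m2 / params$kon_m2
  if (T2_tot <= 0 || M2_tot <= 0)
    return(c(T2 = T2_tot, M2 = M2_tot, T2.M2 = 0))
  b <- T2_tot + M2_tot + Kd
  x <- (b - sqrt(b^2 - 4 * T2_tot * M2_tot)) / 2
  c(T2 = T2_tot - x, M2 = M2_tot - x, T2.M2 = x)
}

## initial membrane composition matching steady fractions (eliminated runs)
.fractions_init <- function(net, fractions, pools) {
  out <- numeric(0)
  sp <- net@species
  for (pl in names(fractions)) {
    occ <- pools[[pl]]@M_F0 * pools[[pl]]@k_ins /
      (pools[[pl]]@k_ins + pools[[pl]]@k_int)
    fr <- fractions[[pl]]
    m14 <- sp$m14[match(names(fr), sp$name)]
    out <- c(out, stats::setNames(occ * fr / m14, names(fr)))
  }
  out[out > 0]
}

#' Steady-state fractions of the continuous-turnover model
#'
#' Builds the continuous two-pool model at the given bulk TIMP-2, runs it
#' to steady state and returns the per-pool M14-weighted composition
#' fractions.  With \code{eliminate = TRUE} the fractions are iterated to
#' the fixed point of the transient-eliminated dynamics (insertion
#' distributed by the returned fractions reproduces exactly these
#' fractions), which is what makes eliminated-mode M14a traces flat.
#'
#' @inheritParams runPoolsModel
#' @param t_max,dt steady-state run control.
#' @param eliminate iterate to the self-consistent eliminated-mode
#'   fractions.
#' @param tol,maxit iteration control for \code{eliminate}.
#' @return Named list \code{list(X = ..., D = ...)}.
#' @export
poolSteadyFractions <- function(params = defaultKineticParameters(),
                                T2 = params$T2_0,
                                pools = list(X = poolConfig("X"),
                                             D = poolConfig("D")),
                                turnover_scale = 1, t_max = 20000, dt = 0.05,
                                eliminate = FALSE, tol = 0.005, maxit = 10) {
  if (turnover_scale == 0)
    stop("steady fractions undefined without turnover")
  bath <- .bath_equilibrium(T2, params$M2_0, params)
  one_pass <- function(fractions) {
    net <- buildPoolsNetwork(params, ecm = FALSE, pools = pools,
                             regimen = "continuous",
                             distribute = fractions,
                             turnover_scale = turnover_scale)
    y0 <- c(bath, if (is.null(fractions)) steadyOccupancyInit(pools)
            else .fractions_init(net, fractions, pools))
    traj <- integrateRK4(net, y0, t_end = t_max, dt = dt,
                         out_stride = max(1L, floor(10 / dt)))
    sp <- net@species
    i <- nrow(traj@states)
    mem_all <- sp$name[sp$location != "solution"]
    j <- which.min(abs(traj@times - (t_max - 500)))
    drift <- abs(traj@states[i, mem_all] - traj@states[j, mem_all])
    if (max(drift / pmax(abs(traj@states[i, mem_all]), 1e-9)) > 0.05 &&
        max(drift) > 1e-6)
      stop("steady state not reached within t_max = ", t_max, " s")
    lapply(stats::setNames(names(pools), names(pools)), function(pl) {
      mem <- sp$name[sp$location == paste0("membrane_", pl) & sp$m14 > 0]
      w <- traj@states[i, mem] * sp$m14[match(mem, sp$name)]
      fr <- w / sum(w)
      fr[fr < 1e-12] <- 0
      fr / sum(fr)
    })
  }
  fr <- one_pass(NULL)
  if (eliminate) {
    for (it in seq_len(maxit)) {
      fr2 <- one_pass(fr)
      dmax <- max(vapply(names(fr), function(pl)
        max(abs(fr2[[pl]] - fr[[pl]])), numeric(1)))
      fr <- fr2
      if (dmax < tol) break
    }
  }
  fr
}

## ------- sweeps and ensembles -------

#' TIMP-2 titration sweep
#'
#' One full simulation per TIMP-2 value; returns M14a_steady, the transient
#' half-width and (for ECM variants) tau_H.  Deterministic given the
#' configuration.
#'
#' M14a_steady is the post-transient plateau
#' (\code{\link{transientMetrics}}); for the closed variant both metrics
#' come from one fine-step run that resolves the seconds-wide transient.
#'
#' @param values TIMP-2 concentrations (nM), >= 0.
#' @param variant \code{"closed"} (surface-expression model) or
#'   \code{"pools"} (continuous turnover).
#' @param params kinetic parameters.
#' @param ecm include ECM degradation and report tau_H (pools variant).
#' @param t_end,dt,out_stride integration control.
#' @param ... passed to the model driver.
#' @return \code{data.frame(T2, M14a_steady, t_transient, tau_H)}.
#' @export
sweepTimp2 <- function(values = c(0, 20, 40, 60, 80, 100, 120, 200, 300,
                                  400, 500),
                       variant = c("closed", "pools"),
                       params = defaultKineticParameters(), ecm = FALSE,
                       t_end = if (variant[1] == "closed") 600 else 3000,
                       dt = if (variant[1] == "closed") 0.005 else 0.05,
                       out_stride = if (variant[1] == "closed") 10L else 50L,
                       ...) {
  stopifnot(all(values >= 0))
  variant <- match.arg(variant)
  rows <- lapply(values, function(v) {
    if (variant == "closed") {
      traj <- runClosedModel(params, T2 = v, t_end = t_end, dt = dt,
                             out_stride = out_stride, ...)
      tm <- transientMetrics(traj)
      data.frame(T2 = v, M14a_steady = tm$steady,
                 t_transient = tm$t_transient, tau_H = NA_real_)
    } else {
      traj <- runPoolsModel(params, T2 = v, ecm = ecm, t_end = t_end,
                            dt = dt, out_stride = out_stride, ...)
      m14a <- computeM14a(traj)
      ss <- detectSteadyState(traj, m14a, rel_tol = 1e-3, window = 100)
      data.frame(T2 = v, M14a_steady = ss$value,
                 t_transient = if (ss$converged)
                   halfWidth(traj@times, m14a, ss$value) else NA_real_,
                 tau_H = if (ecm) tauHalf(traj) else NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' Ensemble of stochastic insertion schedules
#'
#' Runs the pulsatile ECM-degradation model across seeds and TIMP-2 values
#' and summarizes tau_H.
#'
#' @param T2_values bulk TIMP-2 concentrations (nM).
#' @param n_runs seeds per condition (>= 2).
#' @param seeds integer seeds (default 1..n_runs).
#' @param interval_mode,amount_mode randomness switches (see
#'   \code{\link{insertionSchedule}}).
#' @param params kinetic parameters.
#' @param t_end,dt integration control (the horizon should comfortably
#'   exceed tau_H).
#' @param ... passed to \code{\link{runPoolsModel}}.
#' @return list with \code{summary} (per-T2 mean, sd, cv of tau_H) and
#'   \code{raw} (per-run values).
#' @export
runEnsemble <- function(T2_values = c(0, 200, 400), n_runs = 30,
                        seeds = seq_len(n_runs),
                        interval_mode = "random", amount_mode = "regular",
                        params = defaultKineticParameters(),
                        t_end = 12000, dt = 0.1, ...) {
  stopifnot(n_runs >= 2)
  raw <- do.call(rbind, lapply(T2_values, function(v) {
    th <- vapply(seeds, function(s) {
      sched <- insertionSchedule(interval_mode = interval_mode,
                                 amount_mode = amount_mode, seed = s)
      traj <- runPoolsModel(params, T2 = v, regimen = "pulsatile",
                            sched = sched, ecm = TRUE, t_end = t_end,
                            dt = dt, out_stride = 50L, ...)
      tauHalf(traj, params$ECM_0)
    }, numeric(1))
    data.frame(T2 = v, seed = seeds, tau_H = th)
  }))
  summ <- do.call(rbind, lapply(split(raw, raw$T2), function(d)
    data.frame(T2 = d$T2[1], n = nrow(d), mean = mean(d$tau_H),
               sd = stats::sd(d$tau_H),
               cv = stats::sd(d$tau_H) / mean(d$tau_H))))
  rownames(summ) <- NULL
  list(summary = summ, raw = raw)
}
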