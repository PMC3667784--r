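#' @include network.R
NULL

## Compile a ReactionNetwork into flat arrays for the C++ core.
## Stoichiometry: each reactant occurrence consumes one copy (identical
## reactants therefore consume two), products add their stoichiometry; a
## reaction with a `dist` entry uses that named delta vector verbatim
## (per unit flux), which is how distributed insertion and internalization
## with ECM release are encoded.
.compile_network <- function(net) {
  sp <- net@species
  rx <- net@reactions
  ns <- nrow(sp)
  idx <- stats::setNames(seq_len(ns) - 1L, sp$name)
  nr <- nrow(rx)
  k <- rx$k
  r1 <- ifelse(is.na(rx$r1), -1L, idx[rx$r1])
  r2 <- ifelse(is.na(rx$r2), -1L, idx[rx$r2])
  type <- ifelse(rx$type == "insertion", 1L, 0L)
  s_idx <- integer(0); s_del <- numeric(0); s_off <- integer(nr + 1)
  o_idx <- integer(0); o_w <- numeric(0); o_off <- integer(nr + 1)
  mf0 <- numeric(nr)
  membrane <- sp$location != "solution"
  embed <- integer(nr)
  for (i in seq_len(nr)) {
    delta <- numeric(ns)
    di <- rx$dist[[i]]
    if (!is.null(di)) {
      delta[idx[names(di)] + 1L] <- delta[idx[names(di)] + 1L] + unname(di)
    } else {
      if (!is.na(rx$r1[i])) delta[idx[rx$r1[i]] + 1L] <- delta[idx[rx$r1[i]] + 1L] - 1
      if (!is.na(rx$r2[i])) delta[idx[rx$r2[i]] + 1L] <- delta[idx[rx$r2[i]] + 1L] - 1
      for (p in 1:3) {
        nm <- rx[[paste0("p", p)]][i]
        if (!is.na(nm))
          delta[idx[nm] + 1L] <- delta[idx[nm] + 1L] + rx[[paste0("n", p)]][i]
      }
    }
    if (type[i] == 1L) {
      ## insertion also consumes reactant side implicitly: none; delta from
      ## dist covers targets (and solution draws for distributed insertion)
      pool <- rx$pool[i]
      sel <- if (is.na(pool)) membrane else sp$location == paste0("membrane_", pool)
      occ <- which(sel & sp$m14 > 0)
      o_idx <- c(o_idx, occ - 1L)
      o_w <- c(o_w, sp$m14[occ])
      mf0[i] <- rx$mf0[i]
    }
    touched <- unique(c(which(delta != 0), r1[i] + 1L, r2[i] + 1L))
    touched <- touched[touched >= 1]
    embed[i] <- if (any(membrane[touched]) || type[i] == 1L) 1L else 0L
    nz <- which(delta != 0)
    s_idx <- c(s_idx, nz - 1L)
    s_del <- c(s_del, delta[nz])
    s_off[i + 1] <- length(s_idx)
    o_off[i + 1] <- length(o_idx)
  }
  list(n_species = ns, k = as.numeric(k), r1 = as.integer(r1),
       r2 = as.integer(r2), type = as.integer(type), embed = embed,
       s_off = as.integer(s_off), s_idx = as.integer(s_idx),
       s_del = as.numeric(s_del), o_off = as.integer(o_off),
       o_idx = as.integer(o_idx), o_w = as.numeric(o_w),
       mf0 = as.numeric(mf0), index = idx)
}

## Build the flat event arrays used by the C++ cores.
## events: data.frame(time, pool, amount); distribute: named list by pool of
## M14-weighted steady-state fractions (NULL -> plain free-M14 pulse).
.compile_events <- function(net, events, distribute = NULL) {
  empty <- list(e_time = numeric(0), e_amount = numeric(0), e_mf0 = numeric(0),
                e_ooff = 0L, e_oidx = integer(0), e_ow = numeric(0),
                e_doff = 0L, e_didx = integer(0), e_ddel = numeric(0))
  if (is.null(events) || nrow(events) == 0) return(empty)
  sp <- net@species
  idx <- stats::setNames(seq_len(nrow(sp)) - 1L, sp$name)
  pools <- net@metadata$pool_configs
  events <- events[order(events$time), , drop = FALSE]
  nE <- nrow(events)
  ## one template per pool, then replicated over the event list
  tmpl <- lapply(stats::setNames(unique(events$pool), unique(events$pool)),
                 function(pl) {
    pc <- pools[[pl]]
    if (is.null(pc)) stop("no PoolConfig registered for pool ", pl)
    sel <- which(sp$location == paste0("membrane_", pl) & sp$m14 > 0)
    fr <- distribute[[pl]]
    tgt <- if (is.null(fr)) stats::setNames(1, paste0("M14", pl))
           else .distribution_delta(sp, fr)
    list(oidx = unname(idx[sp$name[sel]]), ow = sp$m14[sel], mf0 = pc@M_F0,
         didx = unname(idx[names(tgt)]), ddel = unname(tgt))
  })
  tm <- tmpl[events$pool]
  on <- vapply(tm, function(t) length(t$oidx), integer(1))
  dn <- vapply(tm, function(t) length(t$didx), integer(1))
  list(e_time = events$time, e_amount = events$amount,
       e_mf0 = vapply(tm, function(t) t$mf0, numeric(1)),
       e_ooff = as.integer(c(0, cumsum(on))),
       e_oidx = as.integer(unlist(lapply(tm, function(t) t$oidx),
                                  use.names = FALSE)),
       e_ow = as.numeric(unlist(lapply(tm, function(t) t$ow),
                                use.names = FALSE)),
       e_doff = as.integer(c(0, cumsum(dn))),
       e_didx = as.integer(unlist(lapply(tm, function(t) t$didx),
                                  use.names = FALSE)),
       e_ddel = as.numeric(unlist(lapply(tm, function(t) t$ddel),
                                  use.names = FALSE)))
}

## Per-unit-M14 delta vector for steady-fraction (transient-eliminated)
## insertion: fractions f_j of inserted M14 monomer equivalents go to
## complex j (so the complex concentration rises by f_j / m14_j), and the
## TIMP-2 / proMMP-2 carried inside those complexes is drawn from the bulk
## solution species so that solution totals stay physical.
.distribution_delta <- function(sp, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-6)
  rows <- match(names(fractions), sp$name)
  if (anyNA(rows)) stop("unknown species in fractions")
  m14 <- sp$m14[rows]
  if (any(m14 <= 0)) stop("fractions must target MT1-containing species")
  delta <- stats::setNames(fractions / m14, names(fractions))
  t2_draw <- sum(fractions * sp$t2[rows] / m14)
  m2_draw <- sum(fractions * sp$m2[rows] / m14)
  if (t2_draw > 0) delta <- c(delta, T2 = -t2_draw)
  if (m2_draw > 0) delta <- c(delta, M2 = -m2_draw)
  delta[delta != 0]
}

#' Mass-action right-hand side
#'
#' Evaluates d[X]/dt for every species from the reaction table:
#' \code{k [A]} for unimolecular, \code{k [A][B]} for bimolecular reactions
#' (\code{k [A]^2} for identical reactants, both copies consumed), plus the
#' saturating insertion terms \code{k_ins max(M_F0 - occupancy, 0)}
#' contributed by membrane turnover.  Pure function; used by the fixed-step
#' integrator and directly useful for inspection and cross-checks.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param state named numeric vector of concentrations (nM); species not
#'   named are taken as 0.
#' @return Named numeric vector of derivatives (nM/s) over all species.
#' @examples
#' net <- buildCoreNetwork()
#' v <- massActionRHS(net, c(M14 = 100, T2 = 100, M2 = 100))
#' v["M14"] < 0
#' @export
massActionRHS <- function(net, state) {
  cn <- .compile_network(net)
  y <- numeric(cn$n_species)
  names(y) <- net@species$name
  if (length(state)) y[names(state)] <- state
  dy <- numeric(cn$n_species)
  for (j in seq_along(cn$k)) {
    if (cn$type[j] == 1L) {
      rng <- if (cn$o_off[j] < cn$o_off[j + 1])
        (cn$o_off[j] + 1):cn$o_off[j + 1] else integer(0)
      occ <- sum(cn$o_w[rng] * y[cn$o_idx[rng] + 1L])
      v <- cn$k[j] * max(cn$mf0[j] - occ, 0)
    } else {
      v <- cn$k[j]
      if (cn$r1[j] >= 0) v <- v * y[cn$r1[j] + 1L]
      if (cn$r2[j] >= 0) v <- v * y[cn$r2[j] + 1L]
    }
    rng <- if (cn$s_off[j] < cn$s_off[j + 1])
      (cn$s_off[j] + 1):cn$s_off[j + 1] else integer(0)
    dy[cn$s_idx[rng] + 1L] <- dy[cn$s_idx[rng] + 1L] + cn$s_del[rng] * v
  }
  stats::setNames(dy, net@species$name)
}

#' Integrate the network ODEs with fixed-step RK4
#'
#' Classic fourth-order Runge-Kutta with fixed step \code{dt}.  Insertion
#' pulses are instantaneous state jumps applied between steps on an
#' event-aligned grid (the integrator lands exactly on each event time);
#' pulse amounts are clamped to the free docking sites of the target pool.
#' Output is sampled every \code{out_stride} steps.  Species listed in
#' \code{clamp} are held at their initial concentrations (constant-bath
#' boundary condition for bulk solution species).
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param y0 named numeric initial concentrations (nM); unnamed species
#'   start at 0.
#' @param t_end end time (s).
#' @param dt step size (s); default 1e-3 resolves the stiff initial
#'   transient (see \code{\link{auditStepSize}} for an on-demand audit).
#' @param events \code{data.frame(time, pool, amount)} of insertion pulses,
#'   or NULL.
#' @param distribute named list by pool of steady-state fractions for
#'   transient-eliminated insertion (see
#'   \code{\link{steadyStateFractions}}); NULL inserts free M14.
#' @param out_stride record every \code{out_stride}-th step.
#' @param clamp character vector of species held constant.
#' @param t0 start time (s).
#' @return A \linkS4class{Trajectory}.
#' @examples
#' net <- buildCoreNetwork()
#' tr <- integrateRK4(net, c(M14 = 100, T2 = 100, M2 = 100),
#'                    t_end = 10, dt = 0.01)
#' tr
#' @export
integrateRK4 <- function(net, y0, t_end, dt = 1e-3, events = NULL,
                         distribute = NULL, out_stride = 1L,
                         clamp = character(), t0 = 0) {
  stopifnot(dt > 0, t_end > t0)
  cn <- .compile_network(net)
  y <- numeric(cn$n_species)
  names(y) <- net@species$name
  if (length(y0)) {
    bad <- setdiff(names(y0), names(y))
    if (length(bad)) stop("unknown species in y0: ", paste(bad, collapse = ", "))
    y[names(y0)] <- y0
  }
  ev <- .compile_events(net, events, distribute)
  clamp_idx <- integer(0); clamp_val <- numeric(0)
  if (length(clamp)) {
    clamp_idx <- cn$index[clamp]
    if (anyNA(clamp_idx)) stop("unknown species in clamp")
    clamp_val <- unname(y[clamp])
  }
  res <- .rk4_core(unname(y), t0, t_end, dt, as.integer(out_stride), cn,
                   net@species$name,
                   ev$e_time, ev$e_amount, ev$e_mf0, ev$e_ooff, ev$e_oidx,
                   ev$e_ow, ev$e_doff, ev$e_didx, ev$e_ddel,
                   as.integer(unname(clamp_idx)), clamp_val)
  states <- res$states
  colnames(states) <- net@species$name
  evdf <- if (length(ev$e_time))
    data.frame(time = ev$e_time,
               pool = events[order(events$time), "pool"],
               requested = ev$e_amount, applied = res$applied,
               stringsAsFactors = FALSE)
  else data.frame(time = numeric(0), pool = character(0),
                  requested = numeric(0), applied = numeric(0))
  methods::new("Trajectory", times = res$times, states = states,
               species = net@species, events = evdf,
               metadata = list(dt = dt, out_stride = out_stride,
                               clamp = clamp, t0 = t0,
                               network = net@metadata$options,
                               deletions = net@metadata$deletions))
}

#' Step-size audit by halving
#'
#' Re-runs an integration at dt/2 and reports the maximum relative
#' difference over species at the final time, as a practical check that the
#' chosen fixed step resolves the dynamics.
#'
#' @inheritParams integrateRK4
#' @return max relative end-state difference between dt and dt/2.
#' @export
auditStepSize <- function(net, y0, t_end, dt, ...) {
  a <- integrateRK4(net, y0, t_end, dt, out_stride = 1e9, ...)
  b <- integrateRK4(net, y0, t_end, dt / 2, out_stride = 1e9, ...)
  ya <- a@states[nrow(a@states), ]
  yb <- b@states[nrow(b@states), ]
  sc <- max(abs(yb), 1e-12)
  max(abs(ya - yb) / sc)
}

#' Detect a steady state of an observable
#'
#' Returns the observable's value once its relative spread over a trailing
#' window falls below \code{rel_tol}.  Non-convergence is reported
#' explicitly, never silently replaced by the last value.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param observable a species name, a numeric series on the trajectory
#'   grid, or a function of the trajectory returning such a series
#'   (default: M14a, \code{\link{computeM14a}}).
#' @param rel_tol relative spread tolerance (default 1e-4).
#' @param window trailing window length (s, default 500).
#' @return list with \code{value} (window mean), \code{reached_at} (s) and
#'   \code{converged} (logical; when FALSE, value and reached_at are NA).
#' @export
detectSteadyState <- function(traj, observable = computeM14a,
                              rel_tol = 1e-4, window = 500) {
  tt <- traj@times
  if (tt[length(tt)] - tt[1] <= window)
    stop("trajectory shorter than the steady-state window")
  series <- if (is.character(observable)) {
    concentrations(traj, observable)[, 1]
  } else if (is.function(observable)) {
    observable(traj)
  } else as.numeric(observable)
  if (length(series) != length(tt)) stop("observable length mismatch")
  start <- which(tt >= tt[1] + window)[1]
  for (i in start:length(tt)) {
    in_win <- tt > tt[i] - window & tt <= tt[i]
    s <- series[in_win]
    m <- mean(s)
    spread <- (max(s) - min(s)) / max(abs(m), 1e-12)
    if (spread < rel_tol)
      return(list(value = m, reached_at = tt[i], converged = TRUE))
  }
  list(value = NA_real_, reached_at = NA_real_, converged = FALSE)
}

#' Monomer-equivalent conservation totals
#'
#' Total MT1-MMP, TIMP-2 and (pro+active) MMP-2 monomer equivalents per
#' time point; conserved along any closed-system trajectory to integrator
#' tolerance.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @return matrix (time by \code{m14}, \code{t2}, \code{m2tot}).
#' @export
conservationTotals <- function(traj) {
  sp <- traj@species
  st <- traj@states
  cbind(m14 = as.numeric(st %*% sp$m14),
        t2 = as.numeric(st %*% sp$t2),
        m2tot = as.numeric(st %*% (sp$m2 + sp$m2act)))
}
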