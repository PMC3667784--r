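#' @include io.R
NULL

.preset_names <- c("fig1", "fig2", "fig3", "fig4", "fig5", "fig6", "fig7",
                   "s5", "s10", "s11", "s12", "s13")

.save_csv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(out_dir, paste0(name, ".csv"))
  utils::write.csv(df, p, row.names = FALSE)
  invisible(p)
}

.save_plot <- function(p, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(out_dir, paste0(name, ".png"))
  ggplot2::ggsave(f, p, width = 6, height = 4, dpi = 150)
  invisible(f)
}

.m14a_df <- function(traj, label) {
  data.frame(time = traj@times, M14a = computeM14a(traj), run = label,
             stringsAsFactors = FALSE)
}

#' Run a figure-style experiment preset
#'
#' Each preset reproduces one of the package's canonical computational
#' experiments at a documented (scaled-down) problem size and writes its
#' metrics as CSV plus a summary plot when \code{out_dir} is given:
#' \describe{
#'   \item{fig1}{closed-model M14a time course and the TIMP-2 titration of
#'     M14a_steady and t_transient.}
#'   \item{fig2}{complex-resolved time courses and the path-deletion
#'     ladder of M14a_steady.}
#'   \item{fig3}{M14a_steady against TIMP-2 for joint turnover-rate scale
#'     factors 1, 0.3, 0.1, 0.03, 0.}
#'   \item{fig4}{tau_H with the transient present vs eliminated across
#'     TIMP-2.}
#'   \item{fig5}{regular vs random pulsatile insertion: M14a, ECM and the
#'     integrated M14a.ECM complex.}
#'   \item{fig6}{frequency/concentration trade-off at fixed time-averaged
#'     insertion: tau_H and initial degradation rate over the 13
#'     fold-pairs.}
#'   \item{fig7}{spatial focal degradation at TIMP-2 = 200 nM: continuous
#'     vs pulsatile, transient present vs eliminated, plus line scans.}
#'   \item{s5}{closed model with and without proMMP-2.}
#'   \item{s10}{pulsatile insertion with random amounts: tau_H spread.}
#'   \item{s11}{abrupt 5/10/20-fold insertion at tau_H.}
#'   \item{s12}{TIMP-2 spatial gradients and transient persistence across
#'     diffusion coefficients, 1 and 5 invadopodia.}
#'   \item{s13}{ectodomain shedding on/off.}
#' }
#'
#' @param name preset name.
#' @param out_dir output directory (NULL: return results only).
#' @param seed RNG seed for stochastic schedules.
#' @param params kinetic parameters.
#' @return list with \code{metrics} (data.frame) and preset-specific
#'   \code{data}.
#' @export
runFigurePreset <- function(name = .preset_names, out_dir = NULL, seed = 1,
                            params = defaultKineticParameters()) {
  name <- match.arg(name)
  fun <- switch(name,
    fig1 = .preset_fig1, fig2 = .preset_fig2, fig3 = .preset_fig3,
    fig4 = .preset_fig4, fig5 = .preset_fig5, fig6 = .preset_fig6,
    fig7 = .preset_fig7, s5 = .preset_s5, s10 = .preset_s10,
    s11 = .preset_s11, s12 = .preset_s12, s13 = .preset_s13)
  res <- fun(params, seed = seed, out_dir = out_dir)
  .save_csv(res$metrics, out_dir, paste0(name, "_metrics"))
  res
}

.preset_fig1 <- function(params, seed, out_dir) {
  traj <- runClosedModel(params, T2 = 100, t_end = 300, dt = 0.005,
                         out_stride = 10L)
  sweep <- sweepTimp2(variant = "closed", params = params)
  p <- ggplot2::ggplot(.m14a_df(traj, "T2=100"),
                       ggplot2::aes(time, M14a)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "M14a (nM)")
  .save_plot(p, out_dir, "fig1_timecourse")
  p2 <- ggplot2::ggplot(sweep, ggplot2::aes(T2, M14a_steady)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "TIMP-2 (nM)", y = "M14a_steady (nM)")
  .save_plot(p2, out_dir, "fig1_titration")
  list(metrics = sweep, data = list(trajectory = traj))
}

.preset_fig2 <- function(params, seed, out_dir) {
  net <- buildCoreNetwork(params)
  traj <- runClosedModel(params, T2 = 100, t_end = 300, dt = 0.005,
                         out_stride = 10L, net = net)
  cumdel <- list(integer(0), 1, c(1, 2), c(1, 2, 3), c(1, 2, 3, 4),
                 c(1, 2, 3, 4, 5))
  ladder <- do.call(rbind, lapply(cumdel, function(d) {
    nd <- applyPathDeletions(net, d)
    tr <- runClosedModel(params, T2 = 100, t_end = 600, dt = 0.005,
                         out_stride = 10L, net = nd)
    data.frame(n_deleted = length(d), M14a_steady = transientMetrics(tr)$steady)
  }))
  df <- data.frame(time = rep(traj@times, ncol(traj@states)),
                   species = rep(colnames(traj@states), each = nrow(traj@states)),
                   concentration = as.vector(traj@states))
  df <- df[df$species %in% speciesTable(net)$name[
    speciesTable(net)$location != "solution"], ]
  p <- ggplot2::ggplot(df, ggplot2::aes(time, concentration,
                                        colour = species)) +
    ggplot2::geom_line() + ggplot2::labs(x = "time (s)", y = "nM")
  .save_plot(p, out_dir, "fig2_complexes")
  list(metrics = ladder, data = list(trajectory = traj))
}

.preset_fig3 <- function(params, seed, out_dir) {
  scales <- c(1, 0.3, 0.1, 0.03, 0)
  t2s <- c(0, 20, 60, 100, 200, 500)
  rows <- do.call(rbind, lapply(scales, function(sc)
    do.call(rbind, lapply(t2s, function(v) {
      traj <- if (sc == 0) {
        net <- buildPoolsNetwork(params, turnover_scale = 0)
        integrateRK4(net, c(invadosim:::.bath_equilibrium(v, params$M2_0,
                                                          params),
                            steadyOccupancyInit()),
                     t_end = 3000, dt = 0.05, out_stride = 50L)
      } else {
        runPoolsModel(params, T2 = v, turnover_scale = sc, t_end = 3000,
                      dt = 0.05, out_stride = 50L)
      }
      ss <- detectSteadyState(traj, computeM14a, rel_tol = 1e-3, window = 100)
      data.frame(turnover_scale = sc, T2 = v, M14a_steady = ss$value)
    }))))
  p <- ggplot2::ggplot(rows, ggplot2::aes(T2, M14a_steady,
                                          colour = factor(turnover_scale))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "TIMP-2 (nM)", colour = "turnover scale")
  .save_plot(p, out_dir, "fig3_turnover")
  list(metrics = rows, data = NULL)
}

.preset_fig4 <- function(params, seed, out_dir) {
  t2s <- c(0, 100, 300, 500)
  rows <- do.call(rbind, lapply(t2s, function(v) {
    frc <- if (v > 0) poolSteadyFractions(params, v, eliminate = TRUE) else NULL
    pres <- runPoolsModel(params, T2 = v, ecm = TRUE, t_end = 30000,
                          dt = 0.1, out_stride = 100L)
    tp <- tauHalf(pres, params$ECM_0)
    te <- if (v > 0) {
      elim <- runPoolsModel(params, T2 = v, ecm = TRUE,
                            transient = "eliminated", fractions = frc,
                            t_end = 200000, dt = 0.1, out_stride = 1000L)
      tauHalf(elim, params$ECM_0)
    } else tp
    data.frame(T2 = v, tau_present = tp, tau_eliminated = te)
  }))
  p <- ggplot2::ggplot(rows, ggplot2::aes(T2, tau_present)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = tau_eliminated), linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "TIMP-2 (nM)", y = "tau_H (s)")
  .save_plot(p, out_dir, "fig4_tauH")
  list(metrics = rows, data = NULL)
}

.preset_fig5 <- function(params, seed, out_dir) {
  reg <- runPoolsModel(params, T2 = 100, regimen = "pulsatile",
                       sched = insertionSchedule(seed = seed), ecm = TRUE,
                       t_end = 1500, dt = 0.02, out_stride = 25L)
  rnd <- runPoolsModel(params, T2 = 100, regimen = "pulsatile",
                       sched = insertionSchedule(interval_mode = "random",
                                                 seed = seed), ecm = TRUE,
                       t_end = 1500, dt = 0.02, out_stride = 25L)
  df <- rbind(.m14a_df(reg, "regular"), .m14a_df(rnd, "random"))
  p <- ggplot2::ggplot(df, ggplot2::aes(time, M14a, colour = run)) +
    ggplot2::geom_line() + ggplot2::labs(x = "time (s)", y = "M14a (nM)")
  .save_plot(p, out_dir, "fig5_m14a")
  metrics <- data.frame(
    run = c("regular", "random"),
    tau_H = c(tauHalf(reg, params$ECM_0), tauHalf(rnd, params$ECM_0)),
    integrated_m14a_ecm = c(max(integratedActiveEcmComplex(reg)),
                            max(integratedActiveEcmComplex(rnd))))
  list(metrics = metrics,
       data = list(regular = reg, random = rnd))
}

.fig6_folds <- c(100, 50, 20, 10, 5, 2, 1, 0.5, 0.2, 0.1, 0.05, 0.02, 0.01)

.preset_fig6 <- function(params, seed, out_dir) {
  rows <- do.call(rbind, lapply(.fig6_folds, function(f) {
    sched <- insertionSchedule(freq_fold = f, conc_fold = 1 / f, seed = seed)
    traj <- runPoolsModel(params, T2 = 100, regimen = "pulsatile",
                          sched = sched, ecm = TRUE, t_end = 4000,
                          dt = 0.05, out_stride = 20L)
    data.frame(freq_fold = f, conc_fold = 1 / f,
               tau_H = tauHalf(traj, params$ECM_0),
               initial_rate = initialDegradationRate(traj, window = 60))
  }))
  p <- ggplot2::ggplot(rows, ggplot2::aes(conc_fold, tau_H)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration fold", y = "tau_H (s)")
  .save_plot(p, out_dir, "fig6_folds")
  list(metrics = rows, data = NULL)
}

.preset_fig7 <- function(params, seed, out_dir) {
  grid <- buildGrid(D = 2e-12)
  frc <- poolSteadyFractions(params, 200, eliminate = TRUE)
  runs <- list(
    cont_present = runFocalDegradation(params, 200, "continuous", "present",
                                       grid, t_end = 60, snap_times = c(30, 60)),
    puls_present = runFocalDegradation(params, 200, "pulsatile", "present",
                                       grid, t_end = 60, snap_times = c(30, 60)),
    cont_elim = runFocalDegradation(params, 200, "continuous", "eliminated",
                                    grid, t_end = 60, fractions = frc),
    puls_elim = runFocalDegradation(params, 200, "pulsatile", "eliminated",
                                    grid, t_end = 60, fractions = frc))
  metrics <- do.call(rbind, lapply(names(runs), function(nm) {
    fs <- runs[[nm]]
    data.frame(run = nm,
               degraded_frac = 1 - fs@trace[nrow(fs@trace), "ECM"] /
                 fs@trace[1, "ECM"])
  }))
  scan <- lineScan(runs$cont_present)
  df <- do.call(rbind, lapply(names(runs), function(nm)
    data.frame(time = runs[[nm]]@times,
               ECM = runs[[nm]]@trace[, "ECM"], run = nm)))
  p <- ggplot2::ggplot(df, ggplot2::aes(time, ECM, colour = run)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "invadopodium ECM (nM)")
  .save_plot(p, out_dir, "fig7_spatial")
  list(metrics = metrics, data = list(runs = runs, line_scan = scan))
}

.preset_s5 <- function(params, seed, out_dir) {
  t2s <- c(0, 100, 200, 500)
  rows <- do.call(rbind, lapply(t2s, function(v) {
    with_m2 <- runClosedModel(params, T2 = v, t_end = 600, dt = 0.005,
                              out_stride = 10L)
    no_m2 <- runClosedModel(params, T2 = v, M2 = 0, t_end = 600, dt = 0.005,
                            out_stride = 10L)
    data.frame(
      T2 = v,
      M14a_steady_with_M2 = transientMetrics(with_m2)$steady,
      M14a_steady_no_M2 = transientMetrics(no_m2)$steady)
  }))
  list(metrics = rows, data = NULL)
}

.preset_s10 <- function(params, seed, out_dir) {
  ens <- runEnsemble(T2_values = c(0, 200), n_runs = 10,
                     seeds = seed + seq_len(10) - 1,
                     interval_mode = "regular", amount_mode = "random",
                     params = params, t_end = 8000)
  list(metrics = ens$summary, data = ens$raw)
}

.preset_s11 <- function(params, seed, out_dir) {
  base <- runPoolsModel(params, T2 = 100, regimen = "pulsatile",
                        sched = insertionSchedule(seed = seed), ecm = TRUE,
                        t_end = 3000, dt = 0.05, out_stride = 20L)
  th <- tauHalf(base, params$ECM_0)
  rows <- do.call(rbind, lapply(c(1, 5, 10, 20), function(f) {
    sched <- insertionSchedule(seed = seed)
    ev <- generateSchedule(sched, 3000)
    if (f > 1)
      ev <- rbind(ev, data.frame(time = th, pool = c("X", "D"),
                                 amount = f * c(0.3, 0.7)))
    net <- buildPoolsNetwork(params, ecm = TRUE, regimen = "pulsatile")
    traj <- integrateRK4(net, c(invadosim:::.bath_equilibrium(100,
                                  params$M2_0, params),
                                ECM = params$ECM_0),
                         t_end = 3000, dt = 0.05, events = ev,
                         out_stride = 20L)
    data.frame(fold = f, tau_H = tauHalf(traj, params$ECM_0),
               ecm_final = concentrations(traj, "ECM")[nrow(traj@states), 1])
  }))
  list(metrics = rows, data = NULL)
}

.preset_s12 <- function(params, seed, out_dir) {
  Ds <- c(2e-11, 2e-13, 2e-15, 2e-17, 2e-19)
  rows <- do.call(rbind, lapply(c(1, 5), function(ninv)
    do.call(rbind, lapply(Ds, function(D) {
      grid <- buildGrid(n_invadopodia = ninv, D = D)
      fs <- runFocalDegradation(params, T2 = 20, "continuous", "present",
                                grid, t_end = 30, dt = 0.01,
                                trace_stride = 10L)
      m14a <- as.numeric(fs@trace[, names(m14aDefinition(fs@species))] %*%
                           m14aDefinition(fs@species))
      tail_lvl <- mean(m14a[fs@times > max(fs@times) - 5])
      data.frame(n_invadopodia = ninv, D = D, peak = max(m14a),
                 steady = tail_lvl, peak_ratio = max(m14a) / tail_lvl)
    }))))
  ## TIMP-2 gradient growth at the default diffusion coefficient
  grid <- buildGrid(D = 2e-12)
  fs <- runFocalDegradation(params, T2 = 20, "continuous", "present", grid,
                            t_end = 60, dt = 0.01,
                            snap_times = c(15, 30, 60))
  t2row <- match("T2", fs@species$name)
  grad <- vapply(fs@snaps, function(sn) {
    v <- sn[t2row, ]
    max(v) / max(min(v), 1e-12)
  }, numeric(1))
  list(metrics = rows,
       data = list(t2_gradient = data.frame(time = fs@snap_times,
                                            maxmin_ratio = grad)))
}

.preset_s13 <- function(params, seed, out_dir) {
  base <- buildCoreNetwork(params)
  shed <- addEctodomainShedding(base, params$k_shed)
  t_no <- runClosedModel(params, T2 = 100, t_end = 300, dt = 0.005,
                         out_stride = 10L, net = base)
  t_sh <- runClosedModel(params, T2 = 100, t_end = 300, dt = 0.005,
                         out_stride = 10L, net = shed)
  m_no <- computeM14a(t_no); m_sh <- computeM14a(t_sh)
  metrics <- data.frame(
    variant = c("no_shedding", "shedding"),
    M14a_final = c(m_no[length(m_no)], m_sh[length(m_sh)]),
    M14a_peak = c(max(m_no), max(m_sh)))
  list(metrics = metrics, data = list(no_shedding = t_no, shedding = t_sh))
}
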