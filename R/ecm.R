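#' @include turnover.R
NULL

#' Add ECM degradation reactions
#'
#' ECM is degraded through explicit enzyme-substrate complexes,
#' \code{E + ECM <-> E.ECM -> E} (one ECM unit consumed), for each of the
#' five enzyme classes: the four active MT1-MMP forms (monomer, dimer and
#' the two half-inhibited dimer forms, per pool) and active MMP-2.
#' MT1-ECM complexes remain pool-resident (and internalizable); the
#' M2act.ECM complex lives in solution.
#'
#' @param net a \linkS4class{ReactionNetwork} whose species include the ECM
#'   set (build with \code{include_ecm = TRUE}).
#' @param params kinetic parameter list (\code{kon_ecm}, \code{koff_ecm},
#'   \code{kcat_ecm}, \code{kon_ecm_m2a}, \code{koff_ecm_m2a},
#'   \code{kcat_ecm_m2a}).
#' @return A new \linkS4class{ReactionNetwork}.
#' @export
addEcmReactions <- function(net, params = net@metadata$params) {
  .check_params(params, c("kon_ecm", "koff_ecm", "kcat_ecm", "kon_ecm_m2a",
                          "koff_ecm_m2a", "kcat_ecm_m2a"))
  sp <- net@species
  if (!"ECM" %in% sp$name)
    stop("network does not include ECM species; build with include_ecm = TRUE")
  b <- .rxn_builder()
  ## membrane enzyme classes: active (weighted) MT1 forms with a .ECM partner
  act <- sp[sp$location != "solution" & sp$ecm == 0 & sp$activity_weight > 0, ]
  for (i in seq_len(nrow(act))) {
    e <- act$name[i]; ec <- paste0(e, ".ECM")
    if (!ec %in% sp$name) next
    b$add(e, "ECM", stats::setNames(1, ec), params$kon_ecm, "ecm_binding")
    b$add(ec, products = c(stats::setNames(1, e), ECM = 1),
          k = params$koff_ecm, tag = "dissociation")
    b$add(ec, products = stats::setNames(1, e), k = params$kcat_ecm,
          tag = "ecm_cleavage")
  }
  b$add("M2act", "ECM", c("M2act.ECM" = 1), params$kon_ecm_m2a, "ecm_binding")
  b$add("M2act.ECM", products = c("M2act" = 1, ECM = 1),
        k = params$koff_ecm_m2a, tag = "dissociation")
  b$add("M2act.ECM", products = c("M2act" = 1), k = params$kcat_ecm_m2a,
        tag = "ecm_cleavage")
  methods::new("ReactionNetwork", species = sp,
               reactions = rbind(net@reactions, b$build()),
               metadata = net@metadata)
}

#' Time to half-degradation of ECM
#'
#' First crossing time of ECM(t) = ECM_0 / 2, linearly interpolated between
#' output samples.  If ECM never falls below half within the trajectory,
#' the result is \code{NA} (an explicit not-reached marker).
#'
#' @param traj a \linkS4class{Trajectory} containing the ECM species.
#' @param ECM_0 reference initial ECM (nM); defaults to ECM at the first
#'   time point.
#' @return tau_H (s), or NA if not reached.
#' @examples
#' # exponential decay: tau_H = ln(2) / lambda
#' @export
tauHalf <- function(traj, ECM_0 = NULL) {
  ecm <- concentrations(traj, "ECM")[, 1]
  if (is.null(ECM_0)) ECM_0 <- ecm[1]
  half <- ECM_0 / 2
  below <- which(ecm <= half)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(traj@times[1])
  t1 <- traj@times[i - 1]; t2 <- traj@times[i]
  y1 <- ecm[i - 1]; y2 <- ecm[i]
  t1 + (y1 - half) / (y1 - y2) * (t2 - t1)
}

#' Integrated concentration of active MT1-ECM complexes
#'
#' Cumulative trapezoidal integral over time of the summed M14a.ECM
#' complexes (M14.ECM + M14.M14.ECM + M14.M14.T2.ECM + M14.M14.T2.M2.ECM,
#' over pools), the quantity directly related to the amount of degraded
#' ECM.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @return Numeric series (nM s) on the trajectory time grid.
#' @export
integratedActiveEcmComplex <- function(traj) {
  sp <- traj@species
  cs <- sp$name[sp$location != "solution" & sp$ecm > 0 & sp$m14 > 0]
  if (!length(cs)) stop("no membrane MT1-ECM complexes in trajectory")
  series <- rowSums(concentrations(traj, cs))
  tt <- traj@times
  n <- length(tt)
  out <- numeric(n)
  if (n > 1)
    out[-1] <- cumsum(0.5 * (series[-n] + series[-1]) * diff(tt))
  out
}

#' Initial rate of ECM degradation
#'
#' Least-squares slope of -ECM(t) over the window [0, window].
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param window fit window (s); must contain at least 2 samples.
#' @return rate (nM/s).
#' @export
initialDegradationRate <- function(traj, window = 10) {
  sel <- traj@times <= traj@times[1] + window
  if (sum(sel) < 2) stop("window must contain at least 2 samples")
  tt <- traj@times[sel]
  y <- -concentrations(traj, "ECM")[sel, 1]
  unname(stats::coef(stats::lm(y ~ tt))[2])
}
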