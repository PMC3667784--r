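#' @include experiments.R
NULL

#' Compartmental reaction-diffusion field series
#'
#' @slot times trace time grid (s).
#' @slot trace matrix (time by species): invadopodium-mask mean
#'   concentrations (nM).
#' @slot snap_times times of full-field snapshots (s).
#' @slot snaps list of species-by-compartment matrices.
#' @slot grid the \linkS4class{SpatialGrid}.
#' @slot species species table.
#' @slot events applied pulse events (mask-mean amounts).
#' @slot metadata list (dt, substeps, variant).
#' @export
setClass("FieldSeries",
  representation(times = "numeric", trace = "matrix", snap_times = "numeric",
                 snaps = "list", grid = "SpatialGrid", species = "data.frame",
                 events = "data.frame", metadata = "list"))

setMethod("show", "FieldSeries", function(object) {
  cat("FieldSeries:", length(object@times), "trace points,",
      length(object@snaps), "field snapshots on a",
      paste(object@grid@divisions, collapse = " x "), "lattice\n")
})

#' Build the compartment lattice
#'
#' A cuboid extracellular space (default 5 x 5 x 3 um) divided into
#' 51 x 51 x 1 identical compartments, with a central invadopodium disc of
#' 49 compartments (diameter about 0.9 um); ECM is present in every
#' compartment, membrane reactions only inside the mask.  proMMP-2, active
#' MMP-2, TIMP-2 and the TIMP-2.MMP-2 complex diffuse.
#'
#' @param extent physical extent (m), length 3.
#' @param divisions lattice divisions, length 3; x and y must be odd so a
#'   central compartment exists (z is a single layer, so diffusion is
#'   effectively two-dimensional).
#' @param n_invadopodia 1 (central disc) or 5 (centre plus four diagonal
#'   discs).
#' @param mask_radius disc radius in compartments (default 4, giving the
#'   49-compartment disc at default geometry).
#' @param diffusing names of diffusing species.
#' @param D diffusion coefficients (m^2/s), recycled over
#'   \code{diffusing}; default 2e-11.
#' @return A \linkS4class{SpatialGrid}.
#' @examples
#' g <- buildGrid()
#' length(g@mask)  # 49
#' @export
buildGrid <- function(extent = c(5e-6, 5e-6, 3e-6),
                      divisions = c(51L, 51L, 1L), n_invadopodia = 1,
                      mask_radius = 4L,
                      diffusing = c("T2", "M2", "M2act", "T2.M2act"),
                      D = 2e-11) {
  divisions <- as.integer(divisions)
  if (divisions[1] %% 2 == 0 || divisions[2] %% 2 == 0)
    stop("x and y divisions must be odd so a central compartment exists")
  nx <- divisions[1]; ny <- divisions[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  centers <- if (n_invadopodia == 1) list(c(cx, cy)) else if (n_invadopodia == 5) {
    off <- 13
    list(c(cx, cy), c(cx - off, cy - off), c(cx - off, cy + off),
         c(cx + off, cy - off), c(cx + off, cy + off))
  } else stop("n_invadopodia must be 1 or 5")
  disc <- function(ct) {
    ix <- rep(seq_len(nx), times = ny); iy <- rep(seq_len(ny), each = nx)
    sel <- (ix - ct[1])^2 + (iy - ct[2])^2 <= mask_radius^2
    if (any(sel & (ix == 1 | ix == nx | iy == 1 | iy == ny)))
      stop("invadopodium disc clipped by the lattice boundary; ",
           "enlarge divisions or reduce mask_radius")
    which(sel)
  }
  masks <- lapply(centers, disc)
  if (length(masks) > 1 && any(duplicated(unlist(masks))))
    stop("invadopodium discs overlap")
  mask <- sort(unique(unlist(masks)))
  D <- rep_len(D, length(diffusing))
  methods::new("SpatialGrid", extent = extent, divisions = divisions,
               mask = as.integer(mask), diffusing = diffusing,
               D = stats::setNames(D, diffusing))
}

## diffusion substep count satisfying the explicit FTCS stability bound
## dt_sub < h^2 / (2 d D) for lattice dimension d = 2 (single z layer)
.diffusion_substeps <- function(grid, dt) {
  dmax <- max(grid@D, 0)
  if (dmax == 0) return(1L)
  h <- grid@extent[1] / grid@divisions[1]
  dt_limit <- h^2 / (4 * dmax)
  max(1L, as.integer(ceiling(dt / (0.9 * dt_limit))))
}

#' Advance a field by one reaction-diffusion step
#'
#' Operator-split step: fixed-step RK4 chemistry per compartment (the full
#' reaction set inside the invadopodium mask, solution-phase reactions
#' everywhere), then explicit finite-difference diffusion with zero-flux
#' boundaries.  Diffusion is automatically sub-stepped to satisfy the
#' explicit stability bound \code{dt < h^2/(2 d D)}; an error names the
#' suggested step if even one substep cannot satisfy it.
#'
#' @param grid a \linkS4class{SpatialGrid}.
#' @param field species-by-compartment matrix (nM); rows in network
#'   species order.
#' @param net the \linkS4class{ReactionNetwork}.
#' @param dt chemistry step (s).
#' @return Updated field matrix.
#' @export
stepReactionDiffusion <- function(grid, field, net, dt) {
  fs <- .run_spatial(net, grid, field, t_end = dt, dt = dt,
                     trace_stride = 1L, snap_times = dt)
  fs@snaps[[length(fs@snaps)]]
}

## core spatial driver
.run_spatial <- function(net, grid, field, t_end, dt, events = NULL,
                         distribute = NULL, trace_stride = 10L,
                         snap_times = numeric(0)) {
  cn <- .compile_network(net)
  sp <- net@species
  nx <- grid@divisions[1]; ny <- grid@divisions[2]
  ncomp <- nx * ny
  if (is.null(dim(field))) {
    y <- numeric(nrow(sp)); names(y) <- sp$name
    y[names(field)] <- field
    field <- matrix(y, nrow = nrow(sp), ncol = ncomp)
  }
  stopifnot(nrow(field) == nrow(sp), ncol(field) == ncomp)
  diff_idx <- match(grid@diffusing, sp$name)
  if (anyNA(diff_idx)) stop("diffusing species missing from network")
  h <- grid@extent[1] / nx
  nsub <- .diffusion_substeps(grid, dt)
  ev <- .compile_events(net, events, distribute)
  snap_steps <- sort(unique(as.integer(round(snap_times / dt))))
  res <- .spatial_core(field, nx, ny, as.integer(grid@mask - 1L), cn,
                       sp$name, as.integer(diff_idx - 1L),
                       unname(grid@D), h, dt, nsub, t_end,
                       as.integer(trace_stride), snap_steps,
                       ev$e_time, ev$e_amount, ev$e_mf0, ev$e_ooff,
                       ev$e_oidx, ev$e_ow, ev$e_doff, ev$e_didx, ev$e_ddel)
  trace <- res$trace
  colnames(trace) <- sp$name
  evdf <- if (length(ev$e_time))
    data.frame(time = ev$e_time, pool = events[order(events$time), "pool"],
               requested = ev$e_amount, applied = res$applied,
               stringsAsFactors = FALSE)
  else data.frame(time = numeric(0), pool = character(0),
                  requested = numeric(0), applied = numeric(0))
  methods::new("FieldSeries", times = res$trace_times, trace = trace,
               snap_times = res$snap_times, snaps = res$snaps, grid = grid,
               species = sp, events = evdf,
               metadata = list(dt = dt, nsub = nsub,
                               network = net@metadata$options))
}

#' Focal ECM degradation at an invadopodium
#'
#' Runs the spatially distributed model: the two-pool MT1-MMP machinery,
#' proMMP-2 activation and MT1-driven ECM degradation embedded in the
#' invadopodium mask; MMP-2-driven ECM degradation and TIMP-2 inhibition of
#' MMP-2 everywhere; TIMP-2, proMMP-2, active MMP-2 and TIMP-2.MMP-2
#' diffusing; closed (zero-flux) boundaries.  The docking route through
#' the preassembled T2.M2 complex is switched off here so the diffusing
#' species are exactly the four transported ones.
#'
#' @param params kinetic parameters.
#' @param T2 initial (uniform) TIMP-2 (nM).
#' @param regimen \code{"continuous"} or \code{"pulsatile"} (regular).
#' @param transient \code{"present"} or \code{"eliminated"}
#'   (steady-fraction insertion).
#' @param grid a \linkS4class{SpatialGrid}.
#' @param t_end,dt horizon and chemistry step (s).
#' @param pools pool configurations.
#' @param fractions precomputed steady-state fractions for eliminated runs
#'   (else computed from the well-mixed model at the same TIMP-2).
#' @param trace_stride,snap_times output control.
#' @return A \linkS4class{FieldSeries}; the invadopodium ECM time course is
#'   \code{trace[, "ECM"]}.
#' @export
runFocalDegradation <- function(params = defaultKineticParameters(),
                                T2 = 200,
                                regimen = c("continuous", "pulsatile"),
                                transient = c("present", "eliminated"),
                                grid = buildGrid(), t_end = 60, dt = 0.01,
                                pools = list(X = poolConfig("X"),
                                             D = poolConfig("D")),
                                fractions = NULL, trace_stride = 25L,
                                snap_times = numeric(0)) {
  regimen <- match.arg(regimen)
  transient <- match.arg(transient)
  if (transient == "eliminated" && is.null(fractions))
    fractions <- poolSteadyFractions(params, T2, pools = pools,
                                     eliminate = TRUE)
  net <- buildPoolsNetwork(params, ecm = TRUE, pools = pools,
                           regimen = regimen,
                           distribute = if (regimen == "continuous")
                             fractions else NULL,
                           preassembled = FALSE)
  sp <- net@species
  ncomp <- prod(grid@divisions[1:2])
  y <- numeric(nrow(sp)); names(y) <- sp$name
  y["T2"] <- T2; y["M2"] <- params$M2_0; y["ECM"] <- params$ECM_0
  field <- matrix(y, nrow = nrow(sp), ncol = ncomp)
  rownames(field) <- sp$name
  init <- if (transient == "present") steadyOccupancyInit(pools)
          else .fractions_init(net, fractions, pools)
  for (nm in names(init)) field[nm, grid@mask] <- init[[nm]]
  events <- NULL; distribute <- NULL
  if (regimen == "pulsatile") {
    events <- generateSchedule(insertionSchedule(), t_end, pools)
    if (transient == "eliminated") distribute <- fractions
  }
  .run_spatial(net, grid, field, t_end = t_end, dt = dt, events = events,
               distribute = distribute, trace_stride = trace_stride,
               snap_times = snap_times)
}

#' Line scan through field snapshots
#'
#' ECM (or any species) sampled along a grid row or column at each
#' snapshot time.
#'
#' @param fs a \linkS4class{FieldSeries} with snapshots.
#' @param species species name (default "ECM").
#' @param axis \code{"row"} (scan along x at fixed y) or \code{"col"}.
#' @param index row/column index (default: through the centre).
#' @return Matrix (position by time); positions in compartments.
#' @export
lineScan <- function(fs, species = "ECM", axis = c("row", "col"),
                     index = NULL) {
  axis <- match.arg(axis)
  if (!length(fs@snaps)) stop("no snapshots recorded")
  nx <- fs@grid@divisions[1]; ny <- fs@grid@divisions[2]
  if (is.null(index)) index <- if (axis == "row") (ny + 1) %/% 2 else (nx + 1) %/% 2
  srow <- match(species, fs@species$name)
  if (is.na(srow)) stop("unknown species")
  cells <- if (axis == "row") (index - 1) * nx + seq_len(nx)
           else index + nx * (seq_len(ny) - 1)
  out <- vapply(fs@snaps, function(sn) sn[srow, cells],
                numeric(length(cells)))
  dimnames(out) <- list(position = NULL, time = signif(fs@snap_times, 6))
  out
}
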