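#' @include spatial.R
NULL

#' Default configuration
#'
#' The single-file configuration (YAML dialect) covering kinetic
#' parameters, network variant options, pool properties, the insertion
#' schedule and the spatial geometry.
#'
#' @return Nested list.
#' @export
defaultConfig <- function() {
  list(
    params = defaultKineticParameters(),
    network = list(pools = "XD", include_ecm = TRUE,
                   include_shedding = FALSE, preassembled = TRUE,
                   deletions = integer()),
    pools = list(X = list(M_F0 = 3, tau = 259),
                 D = list(M_F0 = 7, tau = 26.0)),
    schedule = list(mode = "pulsatile", interval_mode = "regular",
                    amount_mode = "regular", PH = list(X = 0.3, D = 0.7),
                    freq_fold = 1, conc_fold = 1, seed = 1),
    spatial = list(extent_um = c(5, 5, 3), divisions = c(51, 51, 1),
                   n_invadopodia = 1, mask_radius = 4,
                   D_timp2 = 2e-11))
}

#' Read / write a configuration file
#'
#' @param path YAML file path.
#' @return \code{readConfig}: nested list merged over
#'   \code{\link{defaultConfig}}.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultConfig()
  merge2 <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge2(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  merge2(base, cfg)
}

#' @rdname readConfig
#' @param cfg configuration list.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Instantiate model objects from a configuration
#'
#' @param cfg configuration list (\code{\link{readConfig}}).
#' @return list with \code{network}, \code{pools}, \code{schedule},
#'   \code{grid} and \code{params}.
#' @export
fromConfig <- function(cfg) {
  p <- cfg$params
  net <- buildCoreNetwork(p, include_ecm = isTRUE(cfg$network$include_ecm),
                          include_shedding = isTRUE(cfg$network$include_shedding),
                          pools = cfg$network$pools,
                          preassembled = isTRUE(cfg$network$preassembled))
  if (length(cfg$network$deletions))
    net <- applyPathDeletions(net, cfg$network$deletions)
  pools <- lapply(names(cfg$pools), function(pl)
    poolConfig(pl, M_F0 = cfg$pools[[pl]]$M_F0, tau = cfg$pools[[pl]]$tau))
  names(pools) <- names(cfg$pools)
  sch <- cfg$schedule
  sched <- insertionSchedule(mode = sch$mode,
                             interval_mode = sch$interval_mode,
                             amount_mode = sch$amount_mode,
                             PH = unlist(sch$PH), freq_fold = sch$freq_fold,
                             conc_fold = sch$conc_fold, seed = sch$seed)
  gg <- cfg$spatial
  grid <- buildGrid(extent = gg$extent_um * 1e-6,
                    divisions = gg$divisions,
                    n_invadopodia = gg$n_invadopodia,
                    mask_radius = gg$mask_radius, D = gg$D_timp2)
  list(network = net, pools = pools, schedule = sched, grid = grid,
       params = p)
}

#' Export the reaction list as a reviewable plain-text table
#'
#' One reaction per row: reactants, products, rate constant, tag.  The
#' table is the auditable record of the generated network and, re-read
#' with \code{\link{readReactionTable}}, the hand-curated override path.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param path TSV output path.
#' @return The exported \code{data.frame}, invisibly.
#' @export
exportReactionTable <- function(net, path) {
  rx <- net@reactions
  fmt_side <- function(nm, n) {
    keep <- !is.na(nm)
    if (!any(keep)) return("")
    paste(ifelse(n[keep] == 1, nm[keep], paste0(n[keep], " ", nm[keep])),
          collapse = " + ")
  }
  rows <- lapply(seq_len(nrow(rx)), function(i) {
    data.frame(
      reactants = fmt_side(c(rx$r1[i], rx$r2[i]), c(1, 1)),
      products = if (!is.null(rx$dist[[i]]))
        fmt_side(names(rx$dist[[i]]), unname(rx$dist[[i]]))
      else fmt_side(c(rx$p1[i], rx$p2[i], rx$p3[i]),
                    c(rx$n1[i], rx$n2[i], rx$n3[i])),
      k = rx$k[i], tag = rx$tag[i], type = rx$type[i],
      pool = rx$pool[i], mf0 = rx$mf0[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a hand-curated reaction table
#'
#' Rebuilds a \linkS4class{ReactionNetwork} from a TSV in the
#' \code{\link{exportReactionTable}} format over a given species set,
#' allowing a reviewed or edited reaction list to replace the generated
#' one.
#'
#' @param path TSV path.
#' @param species species table (e.g. \code{\link{enumerateSpecies}}).
#' @param metadata optional metadata list.
#' @return A \linkS4class{ReactionNetwork}.
#' @export
readReactionTable <- function(path, species, metadata = list()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  b <- .rxn_builder()
  parse_side <- function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    parts <- strsplit(s, " \\+ ")[[1]]
    out <- vapply(parts, function(p) {
      toks <- strsplit(trimws(p), " ")[[1]]
      if (length(toks) == 2) stats::setNames(as.numeric(toks[1]), toks[2])
      else stats::setNames(1, toks[1])
    }, numeric(1))
    names(out) <- vapply(parts, function(p) {
      toks <- strsplit(trimws(p), " ")[[1]]
      toks[length(toks)]
    }, character(1))
    out
  }
  for (i in seq_len(nrow(tab))) {
    re <- parse_side(tab$reactants[i])
    pr <- parse_side(tab$products[i])
    rn <- rep(names(re), times = re)
    if (length(rn) > 2) stop("at most bimolecular reactions are supported")
    if (identical(tab$type[i], "insertion")) {
      b$add(NA_character_, products = numeric(0), k = tab$k[i],
            tag = tab$tag[i], type = "insertion", pool = tab$pool[i],
            mf0 = tab$mf0[i], dist = pr)
    } else {
      b$add(if (length(rn) >= 1) rn[1] else NA_character_,
            if (length(rn) >= 2) rn[2] else NA_character_,
            products = pr, k = tab$k[i], tag = tab$tag[i])
    }
  }
  methods::new("ReactionNetwork", species = species, reactions = b$build(),
               metadata = c(metadata, list(source = path,
                                           deletions = integer())))
}

#' Write a trajectory as CSV
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path CSV output path.
#' @param format \code{"tidy"} (time, species, concentration) or
#'   \code{"wide"} (one column per species).
#' @return \code{path}, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path, format = c("tidy", "wide")) {
  format <- match.arg(format)
  st <- traj@states
  if (format == "wide") {
    df <- data.frame(time = traj@times, st, check.names = FALSE)
  } else {
    df <- data.frame(
      time = rep(traj@times, times = ncol(st)),
      species = rep(colnames(st), each = nrow(st)),
      concentration = as.vector(st))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run-manifest JSON sidecar
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path JSON output path.
#' @param extra additional fields.
#' @export
writeRunManifest <- function(traj, path, extra = list()) {
  md <- traj@metadata
  manifest <- c(list(dt = md$dt, out_stride = md$out_stride,
                     t_range = range(traj@times),
                     n_species = ncol(traj@states),
                     network = md$network, clamp = md$clamp,
                     n_events = nrow(traj@events)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
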