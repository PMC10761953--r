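#' @include fixtures.R
NULL

.fmt6 <- function(x) formatC(signif(x, 6), format = "g", digits = 6)

.write_matrix_tsv <- function(M, path) {
  out <- apply(M, 1, function(row) paste(.fmt6(row), collapse = "\t"))
  writeLines(out, path)
  invisible(path)
}

.write_profile_tsv <- function(values, path, valueName = "score") {
  writeLines(c(paste("residue_index", valueName, sep = "\t"),
               paste(seq_along(values), .fmt6(values), sep = "\t")), path)
  invisible(path)
}

#' Write PRS matrices, profiles and key residues to a directory
#'
#' Emits response.tsv and normalized.tsv (both raw and normalized views,
#' since published heatmaps rarely state their scaling), two-column
#' profile TSVs, and key_residues.json.
#'
#' @param prs \linkS4class{PRSResult}.
#' @param dir output directory (created if needed).
#' @param zThreshold key-residue z-score cutoff.
#' @return invisible vector of files written
#' @export
writePRSOutputs <- function(prs, dir, zThreshold = 1.0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("response.tsv", "normalized.tsv",
                        "effector_profile.tsv", "sensor_profile.tsv",
                        "key_residues.json"))
  .write_matrix_tsv(prs@response, f[1])
  .write_matrix_tsv(prs@normalized, f[2])
  .write_profile_tsv(prs@effectorProfile, f[3], "effector")
  .write_profile_tsv(prs@sensorProfile, f[4], "sensor")
  kr <- withCallingHandlers(keyResidues(prs, zThreshold),
                            warning = function(w) invokeRestart("muffleWarning"))
  jsonlite::write_json(kr, f[5], dataframe = "rows", digits = NA)
  invisible(f)
}

#' PyMOL-style selection string for a path
#'
#' @param path \linkS4class{AllostericPath}.
#' @return e.g. "resi 1+5+9"
#' @export
pymolSelection <- function(path) {
  paste0("resi ", paste(path@nodes, collapse = "+"))
}

#' Write allosteric paths and the mediation profile to a directory
#'
#' paths.json carries source, sink, nodes (with residue names when a
#' model is supplied), total weight and a PyMOL selection per path;
#' paths.tsv is a flat one-row-per-path table; mediation.tsv the
#' interior-node counts.
#'
#' @param paths named list of \linkS4class{AllostericPath} from
#'   \code{allPairsPaths}.
#' @param nNodes residue count of the underlying graph.
#' @param dir output directory.
#' @param model optional \linkS4class{StructureModel} for residue names.
#' @return invisible vector of files written
#' @export
writePathOutputs <- function(paths, nNodes, dir, model = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("paths.json", "paths.tsv", "mediation.tsv"))
  recs <- lapply(names(paths), function(nm) {
    p <- paths[[nm]]
    rec <- list(source = p@nodes[1], sink = p@nodes[length(p@nodes)],
                nodes = p@nodes, total_weight = p@totalWeight,
                pymol = pymolSelection(p))
    if (!is.null(model)) {
      a <- model@atoms
      rec$residue_names <- a$resname[match(p@nodes, a$resid)]
    }
    rec
  })
  jsonlite::write_json(recs, f[1], auto_unbox = TRUE, digits = NA)
  writeLines(c("source\tsink\ttotal_weight\tnodes",
               vapply(paths, function(p)
                 paste(p@nodes[1], p@nodes[length(p@nodes)],
                       .fmt6(p@totalWeight),
                       paste(p@nodes, collapse = ","), sep = "\t"),
                 character(1))), f[2])
  med <- mediationProfile(paths, nNodes)
  writeLines(c("residue_index\tcount",
               paste(seq_len(nNodes), med@counts, sep = "\t")), f[3])
  invisible(f)
}

.write_series_tsv <- function(series, dir, nBins = 50L) {
  base <- file.path(dir, series@name)
  writeLines(c("frame\tvalue",
               paste(seq_along(series@values), .fmt6(series@values),
                     sep = "\t")), paste0(base, ".tsv"))
  h <- metricHistogram(series, nBins)@histogram
  writeLines(c("bin_left\tbin_right\trel_freq",
               paste(.fmt6(h$edges[-length(h$edges)]),
                     .fmt6(h$edges[-1]), .fmt6(h$freq), sep = "\t")),
             paste0(base, "_hist.tsv"))
}

.default_config <- function() {
  list(mode = "anm", cutoff = 13, gamma = 1, nforces = 100L,
       scheme = "fibonacci", contactCutoff = 10, epsilon = 1e-6,
       k = 10L, seed = 1L, hbDist = 3.0, hbAngle = 135, probe = 1.4,
       spherePoints = 960L, nbins = 50L, zThreshold = 1.0, stride = 1L,
       referenceFrame = 1L)
}

.covariance_from_config <- function(cfg) {
  if (cfg$mode == "ensemble") {
    if (is.null(cfg$traj)) stop("mode 'ensemble' needs a trajectory (traj)")
    ens <- readEnsemble(cfg$traj)
    ca <- selectCA(topology(ens))
    ## restrict frames to the CA subset
    idx <- match(paste(ca@atoms$chain, ca@atoms$resid, ca@atoms$name),
                 paste(topology(ens)@atoms$chain, topology(ens)@atoms$resid,
                       topology(ens)@atoms$name))
    ens <- CoordinateEnsemble(ca, lapply(frames(ens), function(f)
      f[idx, , drop = FALSE]))
    list(cov = ensembleCovariance(ens), ca = ca)
  } else {
    if (is.null(cfg$pdb)) stop("mode 'anm' needs a structure (pdb)")
    ca <- selectCA(readStructure(cfg$pdb))
    if (cfg$stride > 1L) ca <- subsampleResidues(ca, cfg$stride)
    net <- buildANMHessian(ca, cutoff = cfg$cutoff, gamma = cfg$gamma)
    list(cov = anmCovariance(net), ca = ca)
  }
}

#' Run one pipeline subcommand
#'
#' The programmatic entry point behind the command-line wrapper. Writes
#' all artifacts plus a config echo (config.json) and a run log to the
#' output directory; outputs are staged and only published on success, so
#' a failing run leaves no partial files.
#'
#' Subcommands: \code{prs} (response/normalized TSVs, profiles, key
#' residues), \code{paths} (path JSON/TSV and mediation profile),
#' \code{metrics} (RMSD/Rg/SASA/H-bond series with histograms, RMSF,
#' cluster representatives PDB), \code{energy} (MM-PBSA summary JSON with
#' consistency audit), \code{fixtures} (synthetic PDB plus ground-truth
#' sidecar).
#'
#' @param subcommand one of "prs", "paths", "metrics", "energy", "fixtures".
#' @param config named list of parameters; unset entries take the
#'   documented module defaults.
#' @param outDir output directory.
#' @return invisible list of artifact paths
#' @export
runPipeline <- function(subcommand = c("prs", "paths", "metrics", "energy",
                                       "fixtures"),
                        config = list(), outDir = ".") {
  subcommand <- match.arg(subcommand)
  cfg <- utils::modifyList(.default_config(), config)
  stage <- tempfile("allopath_stage_")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  if (subcommand == "prs") {
    cc <- .covariance_from_config(cfg)
    forces <- if (cfg$scheme == "analytic") analyticForceSet()
              else fibonacciForceSet(cfg$nforces)
    res <- prsScan(cc$cov, forces)
    writePRSOutputs(res, stage, zThreshold = cfg$zThreshold)
  } else if (subcommand == "paths") {
    if (is.null(cfg$sources) || is.null(cfg$sinks))
      stop("paths needs sources and sinks")
    cc <- .covariance_from_config(cfg)
    forces <- if (cfg$scheme == "analytic") analyticForceSet()
              else fibonacciForceSet(cfg$nforces)
    res <- prsScan(cc$cov, forces)
    g <- buildContactGraph(cc$ca, contactCutoff = cfg$contactCutoff)
    g <- assignEdgeWeights(g, res, epsilon = cfg$epsilon)
    paths <- allPairsPaths(g, cfg$sources, cfg$sinks)
    if (length(paths) == 0) stop("no (source, sink) pair was reachable")
    writePathOutputs(paths, g@nNodes, stage, model = cc$ca)
  } else if (subcommand == "metrics") {
    if (is.null(cfg$traj)) stop("metrics needs a trajectory (traj)")
    ens <- readEnsemble(cfg$traj)
    sel <- which(topology(ens)@atoms$name == "CA")
    if (length(sel) == 0) sel <- seq_len(nAtoms(ens))
    .write_series_tsv(rmsdSeries(ens, cfg$referenceFrame, sel), stage,
                      cfg$nbins)
    .write_series_tsv(rgSeries(ens), stage, cfg$nbins)
    .write_series_tsv(sasaSeries(ens, cfg$probe, cfg$spherePoints), stage,
                      cfg$nbins)
    if (!is.null(cfg$donors) && !is.null(cfg$acceptors)) {
      .write_series_tsv(
        hbondSeries(ens, parseResidueSelection(cfg$donors),
                    parseResidueSelection(cfg$acceptors),
                    hbondCriteria(cfg$hbDist, cfg$hbAngle)),
        stage, cfg$nbins)
    }
    if (nFrames(ens) >= 2)
      .write_profile_tsv(rmsfProfile(ens, sel),
                         file.path(stage, "rmsf.tsv"), "rmsf")
    if (cfg$k <= nFrames(ens)) {
      cl <- clusterFrames(ens, k = cfg$k, seed = cfg$seed)
      writeRepresentatives(ens, cl, file.path(stage, "representatives.pdb"))
      writeLines(c("frame\tcluster",
                   paste(seq_along(cl@labels), cl@labels, sep = "\t")),
                 file.path(stage, "clusters.tsv"))
    }
  } else if (subcommand == "energy") {
    if (!is.null(cfg$components)) {
      summ <- snapshotSummary(cfg$components)
    } else {
      if (is.null(cfg$eEle) || is.null(cfg$eVdw) || is.null(cfg$gPb))
        stop("energy needs a components table or eEle/eVdw/gPb[/gSa]")
      gSa <- if (is.null(cfg$gSa)) 0 else cfg$gSa
      summ <- list(mean = combineComponents(cfg$eEle, cfg$eVdw, cfg$gPb, gSa),
                   n = 1L)
    }
    audit <- NULL
    if (!is.null(cfg$printedGGas)) {
      ee <- if (!is.null(cfg$eEle)) cfg$eEle else
        summ$components$mean[summ$components$term == "e_ele"]
      ev <- if (!is.null(cfg$eVdw)) cfg$eVdw else
        summ$components$mean[summ$components$term == "e_vdw"]
      audit <- auditComponents(ee, ev, cfg$printedGGas,
                               gSolv = cfg$printedGSolv %||% NA,
                               gTotal = cfg$printedGTotal %||% NA)
    }
    jsonlite::write_json(list(summary = summ$mean, n_snapshots = summ$n,
                              audit = audit),
                         file.path(stage, "energy.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else if (subcommand == "fixtures") {
    kind <- cfg$kind %||% "helix"
    n <- cfg$n %||% 20L
    if (kind == "helix") {
      fx <- makeHelix(n); sidecar <- list(kind = "helix", n = n)
    } else if (kind == "chain") {
      fx <- makeChain(n); sidecar <- list(kind = "chain", n = n)
    } else if (kind == "dumbbell") {
      db <- makeDumbbell(n, cfg$channel %||% 3L, seed = cfg$seed,
                         cutoff = cfg$contactCutoff)
      fx <- db$model
      sidecar <- list(kind = "dumbbell", n_per_domain = n,
                      channel = db$channel, seed = cfg$seed)
    } else stop("unknown fixture kind: ", kind)
    writeStructure(fx, file.path(stage, "fixture.pdb"))
    jsonlite::write_json(sidecar, file.path(stage, "fixture.json"),
                         auto_unbox = TRUE)
  }

  ## config echo + run log, then publish atomically
  jsonlite::write_json(c(list(subcommand = subcommand), cfg),
                       file.path(stage, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(c(sprintf("allopath %s",
                       as.character(utils::packageVersion("allopath"))),
               sprintf("subcommand: %s", subcommand),
               sprintf("seed: %s", cfg$seed),
               paste0(names(cfg), " = ",
                      vapply(cfg, function(v) paste(format(v), collapse = ","),
                             character(1)))),
             file.path(stage, "run.log"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  arts <- list.files(stage, full.names = TRUE)
  file.copy(arts, outDir, overwrite = TRUE)
  invisible(file.path(outDir, basename(arts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
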