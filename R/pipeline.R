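## Orchestration: the size-assay driver and the end-to-end report that
## ties geometry, burial and (optionally) SAXS fitting together. Every
## stochastic stage's seed is recorded so deterministic sections of a
## report are bit-reproducible.

#' Size assay: shape metrics across sequence lengths
#'
#' Sweeps structure sizes (default 100, 200, 400 residues), generating
#' `replicates` synthetic structures per length and recording the full
#' metric set and shape class of each; reports per-length class votes
#' and the first length at which the modal class stops being
#' spherical, i.e. where elongated (tube-like) geometry begins to
#' dominate.
#'
#' @param lengths residue counts to sweep.
#' @param generator `function(n, seed)` returning a
#'   `list(chain = BeadChain, ...)` (any of the synthetic generators
#'   partially applied, or your own).
#' @param replicates structures per length.
#' @param seed master seed; per-run seeds are derived deterministically
#'   from it and recorded in the result.
#' @param window,step axis parameters (chains shorter than the window
#'   simply get `NA` axis metrics).
#' @param calibration optional shape calibration, see
#'   [classifyShape()].
#' @return `list(results, class_votes, first_nonspherical)`; `results`
#'   is a data.frame with one row per structure.
#' @export
runSizeAssay <- function(lengths = c(100L, 200L, 400L),
                         generator = function(n, seed)
                           makeTube(n, axisLength = max(3, n / 60),
                                    tubeRadius = 2, seed = seed),
                         replicates = 5L, seed = 1L,
                         window = 150L, step = 10L, calibration = NULL) {
  rows <- list()
  runSeed <- function(i) (seed + 7919L * i) %% 2147483647L
  i <- 0L
  for (n in lengths) {
    for (r in seq_len(replicates)) {
      i <- i + 1L
      s <- runSeed(i)
      chain <- generator(n, s)$chain
      m <- shapeMetrics(chain, window = window, step = step,
                        calibration = calibration)
      rows[[i]] <- cbind(data.frame(length = n, replicate = r, seed = s),
                         as.data.frame(m))
    }
  }
  results <- do.call(rbind, rows)
  votes <- table(results$length, results$shape_class)
  modal <- apply(votes, 1, function(v) colnames(votes)[which.max(v)])
  nonsph <- names(modal)[modal != "spherical"]
  list(results = results, class_votes = votes,
       first_nonspherical = if (length(nonsph))
         as.integer(nonsph[1]) else NA_integer_)
}

#' Run the full analysis report
#'
#' Executes geometry -> burial -> (optional) SAXS ensemble fit on one
#' structure and writes a self-contained JSON report (plus a TSV burial
#' table). The report embeds the package version, the full
#' configuration echo, its MD5 hash and every seed used, so
#' deterministic stages reproduce bit-for-bit under the same config.
#' Stage errors are collected into an `errors` section of the partial
#' report before the function itself fails.
#'
#' @param config a list (or path to a JSON file) with entries:
#'   * `input`: PDB path, or alternatively `chain`: a [BeadChain-class];
#'   * `window`, `step`, `percentile`: axis/metric parameters;
#'   * `sasa`: optional list(`bead_radius`, `probe_radius`, `n_points`);
#'   * `saxs`: optional list(`exp` = experimental .dat path,
#'     `pool_dir` = directory of PDB conformers, `q_min`, `q_max`,
#'     `n_q`, `ga` = [gaParams()] overrides);
#'   * `out`: output stem (writes `<out>.json` and `<out>_burial.tsv`).
#' @return The report list, invisibly.
#' @export
runFullReport <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- modifyList(list(window = 150L, step = 10L, percentile = 90,
                         sasa = list(bead_radius = 0.30,
                                     probe_radius = 0.14, n_points = 960L),
                         out = NULL), config)
  errors <- list()
  report <- list(
    tool = "silktube",
    version = as.character(utils::packageVersion("silktube")),
    config = cfg[setdiff(names(cfg), "chain")],
    config_hash = hashConfig(cfg[setdiff(names(cfg), "chain")]))

  chain <- tryCatch({
    if (!is.null(cfg$chain)) cfg$chain
    else {
      if (is.null(cfg$input) || !file.exists(cfg$input))
        stop("input file not found: ", cfg$input)
      readBeadPDB(cfg$input)[[1]]
    }
  }, error = function(e) { errors$input <<- conditionMessage(e); NULL })

  if (!is.null(chain)) {
    report$n_beads <- nBeads(chain)
    report$metrics <- tryCatch(
      unclass(shapeMetrics(chain, cfg$window, cfg$step, cfg$percentile)),
      error = function(e) { errors$metrics <<- conditionMessage(e); NULL })
    report$burial <- tryCatch({
      areas <- beadSASA(chain, cfg$sasa$bead_radius, cfg$sasa$probe_radius,
                        cfg$sasa$n_points)
      cls <- classifyBurial(areas, chain,
                            beadRadius = cfg$sasa$bead_radius,
                            probeRadius = cfg$sasa$probe_radius,
                            nSpherePoints = cfg$sasa$n_points)
      burialTable(cls, chain)
    }, error = function(e) { errors$burial <<- conditionMessage(e); NULL })
  }

  if (!is.null(cfg$saxs)) {
    report$saxs <- tryCatch({
      sx <- cfg$saxs
      expCurve <- readSAXS(sx$exp)
      q <- seq(sx$q_min %||% min(qValues(expCurve)),
               sx$q_max %||% max(qValues(expCurve)),
               length.out = sx$n_q %||% 101L)
      pool <- assemblePool(sx$pool_dir, q)
      ga <- do.call(gaParams, as.list(sx$ga %||% list()))
      fit <- gaEnsembleFit(pool, expCurve, ga)
      gf <- tryCatch(guinierFit(fittedCurve(fit)),
                     error = function(e) NULL)
      list(chi2 = fitChi2(fit), scale = fit@scale,
           weights = as.list(ensembleWeights(fit)),
           guinier_rg = if (is.null(gf)) NA else gf$rg,
           ga_seed = ga$seed)
    }, error = function(e) { errors$saxs <<- conditionMessage(e); NULL })
  }

  if (length(errors)) report$errors <- errors
  if (!is.null(cfg$out)) {
    jsonlite::write_json(reportForJson(report), paste0(cfg$out, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(report$burial))
      write.table(report$burial, paste0(cfg$out, "_burial.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(errors))
    stop("report finished with stage error(s): ",
         paste(names(errors), collapse = ", "))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reportForJson <- function(report) {
  if (!is.null(report$burial)) report$burial <- as.list(report$burial)
  report
}

hashConfig <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
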