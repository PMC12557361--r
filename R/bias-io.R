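# PLUMED-dialect text I/O. COLVAR files: a "#! FIELDS <name> ..." header
# followed by whitespace-separated numeric rows; "#" lines are comments.
# Restart appends can duplicate or rewind the time column; the reader keeps
# the last occurrence of each time (the appended rows supersede the originals).

.readPlumedTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^#!\\s*FIELDS\\s+", lines[1L]))
    stop("format error: first line must be a '#! FIELDS ...' header: ", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", lines[1L]), "\\s+")[[1L]]
  body <- lines[-1L]
  body <- body[!grepl("^\\s*#", body) & nzchar(trimws(body))]
  if (!length(body)) {
    tab <- as.data.frame(matrix(numeric(), 0L, length(fields)))
    names(tab) <- fields
    return(tab)
  }
  tab <- read.table(text = body, col.names = fields, colClasses = "numeric",
                    check.names = FALSE)
  names(tab) <- fields
  tab
}

# Keep rows forming a strictly increasing time sequence, scanning from the
# end (PLUMED append-on-restart semantics: later rows win).
.dedupRestart <- function(tab, timeField) {
  tt <- tab[[timeField]]
  n <- length(tt)
  if (n <= 1L) return(tab)
  suffixMin <- rev(cummin(rev(tt)))
  keep <- c(tt[-n] < suffixMin[-1L], TRUE)
  tab[keep, , drop = FALSE]
}

#' Read a PLUMED COLVAR-style file into a BiasTrajectory
#'
#' Parses a whitespace table with a `#! FIELDS` header, keeping the named
#' time and bias columns (and optionally a CV column). Duplicated or
#' backward time rows from restarts are resolved by keeping the last
#' occurrence of each time.
#'
#' @param path file path.
#' @param timeField,biasField column names as given in the FIELDS header.
#' @param cvField optional CV column name (NULL to skip).
#' @param label run identifier; defaults to the file name.
#' @return A \linkS4class{BiasTrajectory} (censored; assign transition status
#'   with \code{\link{assembleEnsemble}}).
#' @export
readColvar <- function(path, timeField = "time", biasField = "metad.bias",
                       cvField = NULL, label = basename(path)) {
  tab <- .readPlumedTable(path)
  for (f in c(timeField, biasField, cvField))
    if (!f %in% names(tab))
      stop("field error: column '", f, "' not present in ", path)
  tab <- .dedupRestart(tab, timeField)
  if (nrow(tab) < 2L)
    stop("data error: fewer than 2 usable rows in ", path)
  biasTrajectory(time = tab[[timeField]], bias = tab[[biasField]],
                 cv = if (is.null(cvField)) numeric() else tab[[cvField]],
                 label = label)
}

#' Write a BiasTrajectory as a COLVAR-dialect file
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the arrays exactly.
#'
#' @param traj a \linkS4class{BiasTrajectory}.
#' @param path output path.
#' @param timeField,biasField,cvField column names to use in the header.
#' @return \code{path}, invisibly.
#' @export
writeColvar <- function(traj, path, timeField = "time",
                        biasField = "metad.bias", cvField = "cv") {
  hasCV <- length(traj@cv) > 0L
  fields <- c(timeField, if (hasCV) cvField, biasField)
  cols <- cbind(traj@time, if (hasCV) traj@cv, traj@bias)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(fields, collapse = " ")), con)
  writeLines(apply(cols, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Read a PLUMED HILLS-style file
#'
#' Accepts the dialect `#! FIELDS time <cv> sigma_<cv> height [biasf]`; the
#' biasf column is optional and ignored. An empty body yields a length-zero
#' schedule (no bias deposited yet).
#'
#' @param path file path.
#' @return A \linkS4class{HillSchedule}.
#' @export
readHills <- function(path) {
  tab <- .readPlumedTable(path)
  nm <- names(tab)
  timeF <- nm[nm == "time"][1L]
  sigmaF <- nm[startsWith(nm, "sigma")][1L]
  heightF <- nm[nm == "height"][1L]
  centerF <- setdiff(nm, c(timeF, sigmaF, heightF, "biasf"))[1L]
  if (anyNA(c(timeF, sigmaF, heightF, centerF)))
    stop("field error: HILLS file needs time, <cv>, sigma_<cv>, height: ",
         path)
  if (!nrow(tab))
    return(hillSchedule())
  if (any(tab[[sigmaF]] <= 0))
    stop("data error: non-positive sigma in ", path)
  tab <- .dedupRestart(tab, timeF)
  hillSchedule(centers = tab[[centerF]], heights = tab[[heightF]],
               widths = tab[[sigmaF]], times = tab[[timeF]])
}

#' Write a HillSchedule as a HILLS-dialect file
#' @param hills a \linkS4class{HillSchedule}.
#' @param path output path.
#' @param cvName CV name used for the center and sigma columns.
#' @return \code{path}, invisibly.
#' @export
writeHills <- function(hills, path, cvName = "cv") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#! FIELDS time %s sigma_%s height", cvName, cvName), con)
  if (length(hills@times))
    writeLines(sprintf("%.17g %.17g %.17g %.17g", hills@times, hills@centers,
                       hills@widths, hills@heights), con)
  invisible(path)
}

# First time the CV crosses the threshold, linearly interpolated between the
# bracketing frames so grid resolution does not quantize transition times.
.firstCrossing <- function(time, cv, threshold, direction) {
  hit <- if (direction == "above") cv >= threshold else cv <= threshold
  if (hit[1L]) return(time[1L])
  i <- which(hit)[1L]
  if (is.na(i)) return(NA_real_)
  frac <- (threshold - cv[i - 1L]) / (cv[i] - cv[i - 1L])
  time[i - 1L] + frac * (time[i] - time[i - 1L])
}

#' Assemble a TrajectoryEnsemble, assigning transition status
#'
#' Transition times are assigned either explicitly (one per trajectory, NA
#' meaning censored) or by a CV-threshold rule with first-passage semantics:
#' the transition time is the first crossing of the threshold, linearly
#' interpolated between the bracketing grid points. Runs whose CV never
#' crosses are right-censored at their final recorded time; censored runs
#' are first-class citizens of every downstream fit.
#'
#' @param trajectories list of \linkS4class{BiasTrajectory}.
#' @param beta inverse thermal energy matching the bias units.
#' @param transitionTimes explicit per-trajectory times (NA = censored), or
#'   NULL to use the threshold rule.
#' @param threshold CV threshold for the crossing rule.
#' @param direction "above" (first time cv >= threshold) or "below".
#' @param iterationLabel,pace,timeUnit,energyUnit ensemble metadata.
#' @return A \linkS4class{TrajectoryEnsemble}.
#' @export
assembleEnsemble <- function(trajectories, beta, transitionTimes = NULL,
                             threshold = NULL,
                             direction = c("above", "below"),
                             iterationLabel = "", pace = NA_real_,
                             timeUnit = "arbitrary",
                             energyUnit = "arbitrary") {
  direction <- match.arg(direction)
  if (is.null(transitionTimes) && is.null(threshold))
    stop("supply either explicit transitionTimes or a CV threshold")
  if (!is.null(transitionTimes) &&
      length(transitionTimes) != length(trajectories))
    stop("transitionTimes must have one entry per trajectory")
  out <- vector("list", length(trajectories))
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    tt <- if (!is.null(transitionTimes)) {
      transitionTimes[[i]]
    } else {
      if (!length(tr@cv))
        stop("trajectory '", tr@label, "' has no CV column for the ",
             "threshold rule")
      .firstCrossing(tr@time, tr@cv, threshold, direction)
    }
    # explicit times from rounded manifests may overshoot the final recorded
    # time by round-off; clamp within a tight relative tolerance
    if (!is.na(tt) && tt > tr@tMax &&
        tt <= tr@tMax + 1e-6 * max(tr@tMax, 1))
      tt <- tr@tMax
    tr@transitionTime <- if (is.na(tt)) numeric() else as.numeric(tt)
    validObject(tr)
    out[[i]] <- tr
  }
  trajectoryEnsemble(out, beta = beta, iterationLabel = iterationLabel,
                     pace = pace, timeUnit = timeUnit,
                     energyUnit = energyUnit)
}

#' Read an ensemble manifest
#'
#' A manifest is a small YAML file tying an ensemble together: trajectory
#' file paths (relative to the manifest), beta, field names, the transition
#' rule, and optional metadata. Layout:
#' \preformatted{
#' beta: 2.5
#' iteration_label: iter3
#' time_field: time
#' bias_field: metad.bias
#' cv_field: cv          # optional
#' time_unit: ps         # optional, must agree across merged manifests
#' energy_unit: kJ/mol
#' transition:
#'   type: threshold      # or "explicit" or "none"
#'   threshold: 1.0
#'   direction: above
#'   times: [12.5, .na]   # for type: explicit
#' trajectories: [run1.colvar, run2.colvar]
#' }
#'
#' @param path manifest path.
#' @return A \linkS4class{TrajectoryEnsemble}.
#' @export
readEnsembleManifest <- function(path) {
  m <- yaml::read_yaml(path)
  base <- dirname(path)
  if (is.null(m$trajectories) || !length(m$trajectories))
    stop("manifest lists no trajectories: ", path)
  if (is.null(m$beta)) stop("manifest must declare beta: ", path)
  cvField <- m$cv_field
  trajs <- lapply(m$trajectories, function(f) {
    p <- if (file.exists(f)) f else file.path(base, f)
    readColvar(p, timeField = m$time_field %||% "time",
               biasField = m$bias_field %||% "metad.bias",
               cvField = cvField)
  })
  tr <- m$transition
  type <- tr$type %||% "none"
  ens <- switch(type,
    threshold = assembleEnsemble(trajs, beta = m$beta,
                                 threshold = tr$threshold,
                                 direction = tr$direction %||% "above",
                                 iterationLabel = m$iteration_label %||% "",
                                 pace = m$pace %||% NA_real_,
                                 timeUnit = m$time_unit %||% "arbitrary",
                                 energyUnit = m$energy_unit %||% "arbitrary"),
    explicit = assembleEnsemble(trajs, beta = m$beta,
                                transitionTimes =
                                  vapply(tr$times, function(x)
                                    if (is.null(x) || is.na(x)) NA_real_
                                    else as.numeric(x), numeric(1)),
                                iterationLabel = m$iteration_label %||% "",
                                pace = m$pace %||% NA_real_,
                                timeUnit = m$time_unit %||% "arbitrary",
                                energyUnit = m$energy_unit %||% "arbitrary"),
    none = trajectoryEnsemble(trajs, beta = m$beta,
                              iterationLabel = m$iteration_label %||% "",
                              pace = m$pace %||% NA_real_,
                              timeUnit = m$time_unit %||% "arbitrary",
                              energyUnit = m$energy_unit %||% "arbitrary"),
    stop("unknown transition type in manifest: ", type))
  ens
}

#' Merge ensembles, enforcing consistent unit declarations
#'
#' @param ensembles list of \linkS4class{TrajectoryEnsemble}.
#' @return A single merged \linkS4class{TrajectoryEnsemble}.
#' @export
mergeEnsembles <- function(ensembles) {
  units <- unique(vapply(ensembles, function(e)
    paste(e@timeUnit, e@energyUnit, e@beta), character(1)))
  if (length(units) > 1L)
    stop("unit error: ensembles declare different time/energy units or beta")
  trajectoryEnsemble(
    unlist(lapply(ensembles, trajectories), recursive = FALSE),
    beta = ensembles[[1L]]@beta,
    iterationLabel = ensembles[[1L]]@iterationLabel,
    pace = ensembles[[1L]]@pace,
    timeUnit = ensembles[[1L]]@timeUnit,
    energyUnit = ensembles[[1L]]@energyUnit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
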