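#' @include AllClasses.R
NULL

# Trace file format: '#'-prefixed header lines (key: value), then one integer
# count per line. Plain text, diffable, one file per molecule.

#' Write / read a blinking trace
#'
#' Traces are stored as plain text: comment header lines carrying
#' `bin_time_s`, `molecule_id`, `class_label` (and any extra metadata),
#' followed by one integer count per line.
#'
#' @param trace a [BlinkingTrace-class].
#' @param path file path.
#' @param extra named character vector of additional header fields (e.g.
#'   `c(seed = "7")`).
#' @return `writeTrace` returns `path` invisibly; `readTrace` returns a
#'   [BlinkingTrace-class].
#' @export
writeTrace <- function(trace, path, extra = character(0)) {
  hdr <- c(bin_time_s = format(binTime(trace), digits = 17),
           molecule_id = moleculeId(trace),
           class_label = classLabel(trace), extra)
  lines <- c(sprintf("# %s: %s", names(hdr), hdr),
             as.character(counts(trace)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path)
  isHdr <- grepl("^#", lines)
  hdr <- lines[isHdr]
  keyval <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  meta <- setNames(vapply(keyval, `[`, character(1), 3L),
                   trimws(vapply(keyval, `[`, character(1), 2L)))
  body <- trimws(lines[!isHdr])
  body <- body[nzchar(body)]
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(is.na(vals) | vals < 0 | abs(vals - round(vals)) > 1e-8)
  if (length(bad)) {
    lineNo <- which(!isHdr & nzchar(trimws(lines)))[bad[1L]]
    stop(sprintf("invalid count in %s at line %d: '%s'",
                 path, lineNo, body[bad[1L]]))
  }
  BlinkingTrace(vals,
                binTime = as.numeric(meta[["bin_time_s"]]),
                moleculeId = meta[["molecule_id"]] %||% basename(path),
                classLabel = if ("class_label" %in% names(meta))
                  meta[["class_label"]] else NA_character_)
}

#' Write / load a trace population
#'
#' A population is a directory of per-molecule trace files plus a tab-
#' delimited manifest (`molecule_id`, `class_label`, `file`). Loading
#' validates every referenced file and reports offending files and line
#' numbers; mixed bin times across one population are an error.
#'
#' @param population list of [BlinkingTrace-class] objects.
#' @param dir output directory (created if needed).
#' @param manifest manifest file name within `dir`.
#' @return `writePopulation` returns the manifest path invisibly;
#'   `loadPopulation` returns a named list of traces.
#' @export
writePopulation <- function(population, dir, manifest = "manifest.tsv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(population, function(tr) {
    fn <- paste0(moleculeId(tr), ".txt")
    writeTrace(tr, file.path(dir, fn))
    data.frame(molecule_id = moleculeId(tr),
               class_label = classLabel(tr),
               file = fn, stringsAsFactors = FALSE)
  })
  mpath <- file.path(dir, manifest)
  write.table(do.call(rbind, rows), mpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(mpath)
}

#' @rdname writePopulation
#' @param manifestPath path to a manifest file.
#' @export
loadPopulation <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stop("manifest not found: ", manifestPath)
  man <- read.table(manifestPath, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!nrow(man)) stop("empty population: manifest lists no traces")
  need <- c("molecule_id", "class_label", "file")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifestPath)
  traces <- list()
  for (i in seq_len(nrow(man))) {
    p <- file.path(base, man$file[i])
    tr <- tryCatch(readTrace(p), error = function(e)
      stop(sprintf("manifest row %d (%s): %s", i, man$molecule_id[i],
                   conditionMessage(e)), call. = FALSE))
    tr@moleculeId <- man$molecule_id[i]
    tr@classLabel <- as.character(man$class_label[i])
    traces[[man$molecule_id[i]]] <- tr
  }
  bts <- vapply(traces, binTime, numeric(1))
  if (diff(range(bts)) > 1e-12)
    stop("inconsistent bin_time across the population: ",
         paste(unique(signif(bts, 6)), collapse = ", "))
  traces
}

#' Read mechanism specifications from a YAML configuration file
#'
#' The file maps class labels to mechanism fields, e.g.
#' \preformatted{
#' R6G:
#'   onFamily: lognormal
#'   onParams: {mu: 0.01, sigma: 1.9}
#'   offFamily: lognormal
#'   offParams: {mu: -1.27, sigma: 2.07}
#'   bleachMean: 25
#' }
#' Missing fields take the [mechanismSpec()] defaults; `preset: <name>`
#' pulls a [presetSpec()] and applies any overrides on top.
#'
#' @param path YAML file path.
#' @return Named list of [MechanismSpec-class] objects.
#' @export
readMechanismSpecs <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg)) stop("no mechanism specs in ", path)
  out <- lapply(names(cfg), function(lab) {
    fields <- cfg[[lab]]
    if (!is.null(fields$preset)) {
      spec <- presetSpec(fields$preset)
      spec@classLabel <- lab
      for (nm in setdiff(names(fields), "preset"))
        slot(spec, nm) <- if (nm %in% c("onParams", "offParams"))
          fields[[nm]] else as.numeric(fields[[nm]])
      validObject(spec)
      spec
    } else {
      args <- c(list(classLabel = lab), fields)
      do.call(mechanismSpec, args)
    }
  })
  names(out) <- names(cfg)
  out
}

#' Write / read a statistics table
#'
#' Tab-delimited, one row per molecule, columns `molecule_id`,
#' `class_label`, the ten statistics in [statNames()] order and the
#' degeneracy flags.
#'
#' @param stats data.frame from [computeStatTable()].
#' @param path file path.
#' @return `writeStatTable` returns `path` invisibly.
#' @export
writeStatTable <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStatTable
#' @export
readStatTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Serialize duration fits to JSON
#'
#' One record per (class, event kind, family): parameters, log-likelihood,
#' KS statistics, sample size and censoring policy.
#'
#' @param fits nested list of [DistFit-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFitReport <- function(fits, path) {
  rec <- rapply(fits, how = "replace", function(f) {
    if (!is(f, "DistFit")) return(f)
    list(family = f@family, params = as.list(f@params),
         log_likelihood = f@logLik, ks_D = f@ksD, ks_p = f@ksP,
         n = f@n, fit_floor = f@fitFloor)
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize / restore an MLR model
#'
#' Stores class labels, coefficients and the z-score normalization record as
#' JSON, restoring them to full double precision.
#'
#' @param model an [MLRModel-class].
#' @param path file path.
#' @return `writeModel` returns `path` invisibly; `readModel` an
#'   [MLRModel-class].
#' @export
writeModel <- function(model, path) {
  jsonlite::write_json(list(
    class_labels = model@classLabels,
    coefficients = model@coefficients,
    coef_colnames = colnames(model@coefficients),
    center = as.list(model@center),
    scale = as.list(model@scale),
    dropped = model@dropped,
    lambda = model@lambda
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  B <- matrix(as.numeric(rec$coefficients),
              nrow = length(rec$class_labels) - 1L,
              dimnames = list(rec$class_labels[-length(rec$class_labels)],
                              rec$coef_colnames))
  new("MLRModel", classLabels = rec$class_labels, coefficients = B,
      center = unlist(rec$center) %||% numeric(0),
      scale = unlist(rec$scale) %||% numeric(0),
      dropped = as.character(unlist(rec$dropped)),
      lambda = rec$lambda %||% 0, converged = TRUE)
}
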