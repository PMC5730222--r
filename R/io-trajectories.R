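#' Write trajectory records and a run manifest to a directory
#'
#' One TSV per trajectory (`trajectory_00001.tsv`, ...: column 1 the time
#' grid, one column per species with species ids as header) plus a
#' `manifest.json` recording the method, master seed, number of
#' trajectories, time grid and a hash of the model file content, so any
#' run is reproducible from its output directory alone.
#'
#' @param records List of [TrajectoryRecord-class] objects (a single
#'   record is accepted).
#' @param outdir Output directory (created if missing).
#' @param net Optional [ReactionNetwork-class]; when given it is saved as
#'   `model.txt` alongside the trajectories and hashed into the manifest.
#' @param config Optional named list echoed verbatim into the manifest
#'   (CLI flags, provenance).
#' @return `outdir`, invisibly.
#' @export
writeTrajectories <- function(records, outdir, net = NULL, config = list()) {
  if (is(records, "TrajectoryRecord")) records <- list(records)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(records)) {
    tr <- records[[i]]
    df <- data.frame(time = tr@times, tr@counts, check.names = FALSE)
    utils::write.table(df, file.path(outdir, sprintf("trajectory_%05d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  modelHash <- NA_character_
  if (!is.null(net)) {
    saveModel(net, file.path(outdir, "model.txt"))
    modelHash <- unname(tools::md5sum(file.path(outdir, "model.txt")))
  }
  manifest <- c(list(
    method = records[[1]]@method,
    seed = records[[1]]@seed,
    nTrajectories = length(records),
    species = records[[1]]@species,
    tEnd = max(records[[1]]@times),
    dt = if (length(records[[1]]@times) > 1)
      records[[1]]@times[2] - records[[1]]@times[1] else NA,
    modelHash = modelHash), config)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Read trajectories written by [writeTrajectories()]
#'
#' @param outdir Directory containing `trajectory_*.tsv` and
#'   `manifest.json`.
#' @param n Maximum number of trajectories to read (`Inf` = all).
#' @return List with `records` (list of [TrajectoryRecord-class]) and
#'   `manifest` (named list).
#' @export
readTrajectories <- function(outdir, n = Inf) {
  mf <- file.path(outdir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", outdir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  files <- sort(list.files(outdir, pattern = "^trajectory_[0-9]+\\.tsv$",
                           full.names = TRUE))
  files <- utils::head(files, n)
  records <- lapply(files, function(f) {
    df <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(counts) <- "integer"
    new("TrajectoryRecord", times = df$time, counts = counts,
        species = colnames(counts), method = manifest$method,
        seed = as.integer(manifest$seed), events = NA_real_)
  })
  list(records = records, manifest = manifest)
}
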