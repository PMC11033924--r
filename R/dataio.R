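#' Read a cohort from a manifest and a directory of time-series files
#'
#' The manifest is tab-delimited with a header; each subject `<id>` has a
#' matching `ts_<id>.tsv` (parcels x timepoints, no header) in
#' `timeseries_dir`. Missing optional clinical fields stay `NA`. A missing
#' time-series file flags the subject (column `missing_file`) rather than
#' silently dropping it; a parcel-count mismatch between subjects is a hard
#' error naming the subject.
#'
#' @param manifest_path path to the manifest TSV.
#' @param timeseries_dir directory containing `ts_<id>.tsv` files.
#' @param tr sampling interval in seconds attached to each series.
#' @return list with `manifest` (data.frame, plus logical `missing_file`) and
#'   `ts` (named list of [parcel_timeseries()] for the subjects with files).
#' @export
read_cohort <- function(manifest_path, timeseries_dir, tr = 1.5) {
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(manifest)) stop("manifest lacks subject_id column")
  if (anyDuplicated(manifest$subject_id))
    stop("duplicate subject ids in manifest")
  files <- file.path(timeseries_dir, paste0("ts_", manifest$subject_id, ".tsv"))
  manifest$missing_file <- !file.exists(files)
  ts <- list()
  P <- NULL; first_subj <- NULL
  for (i in which(!manifest$missing_file)) {
    m <- as.matrix(utils::read.delim(files[i], header = FALSE))
    dimnames(m) <- NULL
    if (is.null(P)) { P <- nrow(m); first_subj <- manifest$subject_id[i] }
    if (nrow(m) != P)
      stop("subject ", manifest$subject_id[i], " has ", nrow(m),
           " parcels; expected ", P, " (as for subject ", first_subj, ")")
    ts[[manifest$subject_id[i]]] <-
      parcel_timeseries(m, tr = tr, subject_id = manifest$subject_id[i])
  }
  list(manifest = manifest, ts = ts)
}

#' Read a parcel-to-network lookup table
#'
#' Two tab-delimited columns (`parcel_id`, `network`), one row per parcel,
#' 1-based parcel ids. Network levels are taken in first-appearance order.
#' A lookup using fewer than the declared number of labels is accepted with a
#' warning.
#'
#' @param path path to the lookup TSV.
#' @param P expected number of parcels.
#' @param K declared number of network labels (default 7); fewer observed
#'   labels trigger a warning.
#' @return A [network_assignment()].
#' @export
read_network_lookup <- function(path, P, K = 7L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("parcel_id", "network")
  if (nrow(df) != P) stop("lookup has ", nrow(df), " rows; expected ", P)
  out <- network_assignment(df)
  if (nlevels(out$network) < K)
    warning("lookup uses ", nlevels(out$network), " of ", K, " declared labels")
  out
}

#' Write result tables to a directory
#'
#' Writes each named table as a TSV with deterministic row/column order and
#' fixed-precision floats (15 significant digits), so repeated writes of the
#' same table are byte-identical and rereads reproduce values to serialized
#' precision.
#'
#' @param tables named list of data.frames or matrices.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, outdir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(outdir, paste0(nm, ".tsv"))
    tab <- tables[[nm]]
    if (is.matrix(tab)) {
      write_matrix_tsv(tab, path)
    } else {
      tab <- as.data.frame(tab)
      num <- vapply(tab, is.numeric, TRUE)
      tab[num] <- lapply(tab[num], function(x) sprintf("%.15g", x))
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write a numeric matrix as headerless TSV
#'
#' @param m numeric matrix.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(m, 1, function(r) paste(sprintf("%.15g", r), collapse = "\t")),
             con)
  invisible(path)
}

#' Read a numeric matrix from headerless TSV
#'
#' @param path input file.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Write a synthetic cohort to disk
#'
#' Writes `manifest.tsv`, `lookup.tsv`, `ground_truth.tsv` and one
#' `ts_<id>.tsv` per subject, in the formats [read_cohort()] and
#' [read_network_lookup()] consume.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param outdir output directory.
#' @return invisibly, `outdir`.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(parcel_id = cohort$lookup$parcel_id,
                                network = as.character(cohort$lookup$network)),
                     file.path(outdir, "lookup.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$ground_truth, file.path(outdir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sid in names(cohort$ts))
    write_matrix_tsv(cohort$ts[[sid]]$matrix,
                     file.path(outdir, paste0("ts_", sid, ".tsv")))
  invisible(outdir)
}
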