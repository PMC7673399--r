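#' @include gait-pipeline.R
NULL

skeletonHeader <- function() {
  c("subject_id", "frame_index",
    as.vector(t(outer(0:24, c("x", "y", "z"),
                      function(j, a) paste0(a, j)))))
}

#' Write a skeleton record as CSV or JSON-lines
#'
#' One row (or JSON object) per frame: `subject_id`, `frame_index`, then 75
#' coordinate columns `x0,y0,z0,...,x24,y24,z24` in meters, written with 6
#' decimals. Reading a written file reproduces the record to that
#' precision.
#'
#' @param record a [SkeletonRecord-class].
#' @param path output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @param digits decimal places (default 6).
#' @export
writeSkeletonRecord <- function(record, path, format = c("csv", "jsonl"),
                                digits = 6L) {
  format <- match.arg(format)
  t <- nFrames(record)
  v <- nJoints(record)
  coordRows <- matrix(aperm(record@coords, c(1L, 2L, 3L)), 3L * v, t)
  num <- formatC(t(coordRows), format = "f", digits = digits)
  if (format == "csv") {
    lines <- c(paste(skeletonHeader(), collapse = ","),
               paste(record@subjectId, record@frameIndex,
                     apply(num, 1L, paste, collapse = ","), sep = ","))
    writeLines(lines, path)
  } else {
    hdr <- skeletonHeader()[-(1:2)]
    lines <- vapply(seq_len(t), function(i) {
      vals <- paste0('"', hdr, '":', num[i, ], collapse = ",")
      sprintf('{"subject_id":"%s","frame_index":%d,%s}',
              record@subjectId, record@frameIndex[i], vals)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read one skeleton record file
#'
#' Accepts the CSV dialect or the JSON-lines dialect written by
#' [writeSkeletonRecord()]. The file is validated (column count, finite
#' values, single subject); malformed files raise an error with a per-file
#' report.
#'
#' @param path file path (`.csv` or `.jsonl`).
#' @param view view tag to attach (the dialect stores front-view records).
#' @return a [SkeletonRecord-class].
#' @export
readSkeletonRecord <- function(path, view = "front") {
  isJson <- grepl("\\.jsonl?$", path)
  if (isJson) {
    rows <- lapply(readLines(path), jsonlite::fromJSON)
    hdr <- skeletonHeader()
    bad <- which(vapply(rows, function(r)
      !all(hdr %in% names(r)), logical(1)))
    if (length(bad))
      stop("file '", path, "': malformed JSON rows: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r[hdr], check.names = FALSE)))
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = c(subject_id = "character"))
    if (!identical(names(df), skeletonHeader()))
      stop("file '", path, "': expected ", length(skeletonHeader()),
           " columns (", paste(utils::head(skeletonHeader(), 3L),
                               collapse = ","),
           ", ...); got ", ncol(df))
  }
  subj <- unique(df$subject_id)
  if (length(subj) != 1L)
    stop("file '", path, "': multiple subject ids")
  coords <- t(as.matrix(df[, -(1:2)]))
  if (!all(is.finite(coords)))
    stop("file '", path, "': non-finite coordinates")
  dim(coords) <- c(3L, 25L, nrow(df))
  skeletonRecord(subj, coords, view = view,
                 frameIndex = as.integer(df$frame_index))
}

#' Write/read the dataset manifest
#'
#' Tab-delimited text mapping `subject_id` to its diagnostic `label`
#' (HC/MCI/AD) and `has_eeg` flag.
#'
#' @param manifest data.frame with columns `subject_id`, `label`,
#'   `has_eeg`.
#' @param path file path.
#' @return `readManifest` returns the manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  df <- utils::read.delim(path, colClasses = c(subject_id = "character"))
  need <- c("subject_id", "label")
  if (!all(need %in% names(df)))
    stop("manifest '", path, "' lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$has_eeg)) df$has_eeg <- df$label %in% c("MCI", "AD")
  df
}

#' Write a directory of skeleton records plus manifest
#'
#' @param records list of [SkeletonRecord-class] objects.
#' @param labels character labels parallel to `records`.
#' @param root output directory (created if needed).
#' @param format `"csv"` or `"jsonl"`.
#' @return the root path, invisibly.
#' @export
writeSkeletonDataset <- function(records, labels, root, format = "csv") {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(records, subjectId, character(1))
  ext <- if (format == "csv") ".csv" else ".jsonl"
  for (i in seq_along(records)) {
    writeSkeletonRecord(records[[i]], file.path(root, paste0(ids[i], ext)),
                        format = format)
  }
  writeManifest(data.frame(subject_id = ids, label = labels,
                           has_eeg = labels %in% c("MCI", "AD")),
                file.path(root, "manifest.tsv"))
  invisible(root)
}

#' Read a skeleton dataset directory
#'
#' Reads every `.csv`/`.jsonl` record under `root` and the `manifest.tsv`
#' mapping. Files that fail validation are skipped with a warning naming
#' the file and cause; an empty directory yields an empty dataset with a
#' warning. Only front-view records enter the pipeline (the stored dialect
#' carries front-view data).
#'
#' @param root dataset directory.
#' @return list with `records` (list of [SkeletonRecord-class]) and
#'   `manifest` (data.frame; `NULL` when absent).
#' @export
readSkeletonDataset <- function(root) {
  files <- list.files(root, pattern = "\\.(csv|jsonl)$", full.names = TRUE)
  manifestPath <- file.path(root, "manifest.tsv")
  manifest <- if (file.exists(manifestPath)) readManifest(manifestPath)
              else NULL
  if (length(files) == 0L) {
    warning("no skeleton record files under '", root, "'")
    return(list(records = list(), manifest = manifest))
  }
  records <- list()
  for (f in files) {
    rec <- tryCatch(readSkeletonRecord(f), error = function(e) {
      warning("skipping '", basename(f), "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  list(records = records, manifest = manifest)
}
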