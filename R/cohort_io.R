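# Cohort serialization. The container is HDF5 (/subjects/<id>/data,
# /subjects/<id>/fs) when rhdf5 is available, with a plain-text TSV
# fallback that round-trips doubles exactly (%.17g). Electrode and subject
# tables are TSV/CSV; ground truth is JSON.

#' Write a cohort to disk
#'
#' Emits one recording container per subject plus `electrodes.tsv`,
#' `subjects.csv` and `ground_truth.json`.
#'
#' @param cohort an `ndp_cohort` from [generate_cohort()].
#' @param out_dir output directory (created if missing).
#' @param format `"hdf5"` (one `.h5` file per subject, requires rhdf5) or
#'   `"text"` (one `.tsv` matrix per subject, full double precision).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, out_dir,
                         format = c("hdf5", "text")) {
  format <- match.arg(format)
  if (format == "hdf5" && !requireNamespace("rhdf5", quietly = TRUE)) {
    stop("rhdf5 not available; use format = \"text\"")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sid in names(cohort$recordings)) {
    x <- cohort$recordings[[sid]]
    if (format == "hdf5") {
      path <- file.path(out_dir, paste0(sid, ".h5"))
      if (file.exists(path)) file.remove(path)
      rhdf5::h5createFile(path)
      rhdf5::h5createGroup(path, "subjects")
      grp <- paste0("subjects/", sid)
      rhdf5::h5createGroup(path, grp)
      rhdf5::h5write(x, path, paste0(grp, "/data"))
      rhdf5::h5write(cohort$fs, path, paste0(grp, "/fs"))
      rhdf5::h5write(rownames(x), path, paste0(grp, "/electrode_ids"))
      rhdf5::h5write(cohort$start_time %||% "08:00:00", path,
                     paste0(grp, "/start_time"))
      rhdf5::h5closeAll()
    } else {
      path <- file.path(out_dir, paste0(sid, ".tsv"))
      con <- file(path, "w")
      writeLines(paste0("# fs=", cohort$fs, " start_time=",
                        cohort$start_time %||% "08:00:00"), con)
      writeLines(paste(rownames(x), collapse = "\t"), con)
      # rows = samples, columns = electrodes; %.17g round-trips exactly
      body <- apply(t(x), 1, function(row)
        paste(sprintf("%.17g", row), collapse = "\t"))
      writeLines(body, con)
      close(con)
    }
    files <- c(files, path)
  }
  f_el <- file.path(out_dir, "electrodes.tsv")
  utils::write.table(cohort$electrodes, f_el, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  f_su <- file.path(out_dir, "subjects.csv")
  utils::write.csv(cohort$subjects, f_su, row.names = FALSE)
  f_gt <- file.path(out_dir, "ground_truth.json")
  gt <- cohort$ground_truth
  gt$coords <- NULL  # stored in electrodes.tsv
  jsonlite::write_json(gt, f_gt, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(files, f_el, f_su, f_gt))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param in_dir directory produced by [write_cohort()].
#' @return A list with `recordings`, `fs`, `electrodes`, `subjects`,
#'   `start_time` (ground truth is reloaded from JSON when present).
#' @export
read_cohort <- function(in_dir) {
  electrodes <- utils::read.table(file.path(in_dir, "electrodes.tsv"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  subjects <- utils::read.csv(file.path(in_dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  h5 <- sort(list.files(in_dir, pattern = "\\.h5$", full.names = TRUE))
  txt <- sort(setdiff(list.files(in_dir, pattern = "\\.tsv$",
                                 full.names = TRUE),
                      file.path(in_dir, "electrodes.tsv")))
  recordings <- list(); fs <- NULL; start_time <- "08:00:00"
  if (length(h5) > 0) {
    for (path in h5) {
      sid <- sub("\\.h5$", "", basename(path))
      grp <- paste0("subjects/", sid)
      x <- rhdf5::h5read(path, paste0(grp, "/data"))
      rownames(x) <- as.character(rhdf5::h5read(path, paste0(grp, "/electrode_ids")))
      fs <- as.numeric(rhdf5::h5read(path, paste0(grp, "/fs")))
      start_time <- as.character(rhdf5::h5read(path, paste0(grp, "/start_time")))
      rhdf5::h5closeAll()
      recordings[[sid]] <- x
    }
  } else {
    for (path in txt) {
      sid <- sub("\\.tsv$", "", basename(path))
      hdr <- readLines(path, n = 2)
      meta <- regmatches(hdr[1], regexec("fs=([0-9.]+) start_time=(\\S+)", hdr[1]))[[1]]
      fs <- as.numeric(meta[2]); start_time <- meta[3]
      ids <- strsplit(hdr[2], "\t")[[1]]
      body <- utils::read.table(path, skip = 2, sep = "\t")
      x <- t(as.matrix(body))
      rownames(x) <- ids
      dimnames(x)[[2]] <- NULL
      recordings[[sid]] <- x
    }
  }
  gt_path <- file.path(in_dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  list(recordings = recordings, fs = fs, electrodes = electrodes,
       subjects = subjects, ground_truth = gt, start_time = start_time)
}
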