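# Plain-text serialization. Recordings travel as a TSV data matrix plus a
# channel table and a small header; events use the sidecar TSV contract
# `onset_s  duration_s  label`.

#' Write a recording (or envelope series) to plain-text files
#'
#' Creates `<prefix>_data.tsv` (samples x channels, named columns),
#' `<prefix>_channels.tsv` and `<prefix>_meta.tsv` (`fs`, `session_id`,
#' `kind`).
#'
#' @param rec a `recording` or `envelope_series`.
#' @param prefix file path prefix.
#' @return invisibly, the paths written.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, c("recording", "envelope_series")))
  paths <- paste0(prefix, c("_data.tsv", "_channels.tsv", "_meta.tsv"))
  dat <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dat, rec$channels$name)
  data.table::fwrite(dat, paths[1], sep = "\t")
  data.table::fwrite(rec$channels, paths[2], sep = "\t")
  meta <- data.frame(key = c("fs", "session_id", "kind"),
                     value = c(format(rec$fs, digits = 12), rec$session_id,
                               class(rec)[1]))
  data.table::fwrite(meta, paths[3], sep = "\t")
  invisible(paths)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix file path prefix used at write time.
#' @return a `recording` or `envelope_series`, per the stored `kind`.
#' @export
read_recording <- function(prefix) {
  dat <- data.table::fread(paste0(prefix, "_data.tsv"), sep = "\t")
  channels <- as.data.frame(data.table::fread(paste0(prefix, "_channels.tsv"),
                                              sep = "\t"))
  meta <- data.table::fread(paste0(prefix, "_meta.tsv"), sep = "\t")
  kv <- stats::setNames(as.character(meta$value), meta$key)
  structure(list(data = t(as.matrix(dat)),
                 fs = as.numeric(kv[["fs"]]),
                 channels = channels,
                 session_id = kv[["session_id"]]),
            class = kv[["kind"]])
}

#' Write an event table as sidecar TSV
#'
#' Header: `onset_s  duration_s  label`.
#'
#' @param events data.frame with `onset`, `duration`, `label`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_events <- function(events, path) {
  out <- data.frame(onset_s = events$onset, duration_s = events$duration,
                    label = events$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event table written by [write_events()]
#'
#' @param path TSV path.
#' @return data.frame with `onset`, `duration`, `label`.
#' @export
read_events <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(onset = x$onset_s, duration = x$duration_s, label = x$label,
             stringsAsFactors = FALSE)
}

#' Write report tables to disk
#'
#' Writes accuracies, confusion and consensus matrices, channel
#' importances, comparison statistics and the provenance block (JSON +
#' TSV), records MD5 checksums of every file in the report's provenance,
#' and returns the updated report.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if missing).
#' @return the report with `provenance$files` filled in.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  files <- character(0)
  wr_tsv <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[length(files) + 1L]] <<- p(f)
  }
  acc <- data.frame(modality = names(report$accuracy),
                    accuracy = unlist(report$accuracy))
  wr_tsv(acc, "accuracy.tsv")
  for (mod in names(report$confusion)) {
    cm <- as.data.frame.matrix(report$confusion[[mod]])
    cm <- cbind(true = rownames(cm), cm)
    wr_tsv(cm, sprintf("confusion_%s.tsv", mod))
    wr_tsv(report$importance[[mod]], sprintf("importance_%s.tsv", mod))
  }
  cons <- as.data.frame.matrix(report$agreement$consensus)
  cons <- cbind(EMG = rownames(cons), cons)
  wr_tsv(cons, "consensus.tsv")
  stats_json <- list(
    accuracy = report$accuracy,
    agreement = list(percent = report$agreement$percent,
                     kappa = report$agreement$kappa),
    mcnemar = report$mcnemar[c("b", "c", "chi2", "df", "p", "g")],
    five_by_two = if (!is.null(report$five_by_two))
      report$five_by_two[c("f", "df", "p")],
    permutation = if (!isTRUE(report$permutation$skipped)) list(
      p = lapply(report$permutation$p, function(x) x[c("p", "display")]),
      d = report$permutation$d,
      null_mean = lapply(report$permutation$null,
                         function(x) mean(x$values))
    ) else list(skipped = TRUE)
  )
  jsonlite::write_json(stats_json, p("statistics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files[[length(files) + 1L]] <- p("statistics.json")
  report$provenance$files <- data.frame(
    path = unlist(files),
    md5 = unname(tools::md5sum(unlist(files))),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(report$provenance, p("provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report
}

#' Verify checksums of a written report
#'
#' Recomputes MD5 sums of the files recorded in the report's provenance and
#' fails on any mismatch (tamper/corruption detection).
#'
#' @param report a `run_report` returned by [write_report()] (or
#'   [run_full_analysis()] with `out_dir`).
#' @return invisibly `TRUE` if all checksums match.
#' @export
verify_report_files <- function(report) {
  fl <- report$provenance$files
  if (is.null(fl)) stopf("report has no recorded files")
  now <- unname(tools::md5sum(fl$path))
  bad <- which(is.na(now) | now != fl$md5)
  if (length(bad))
    stopf("checksum mismatch for: %s", paste(fl$path[bad], collapse = ", "))
  invisible(TRUE)
}
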