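#' @include AllClasses.R
NULL

#' Write / read a SourceDataset as delimited text
#'
#' A dataset directory holds one tab-delimited ROIs x time matrix per
#' subject (\code{signal_<id>.tsv}, no header), a \code{subjects.tsv}
#' table (id, group, age) and a \code{meta.json} sidecar (fs, carrier
#' band, seed).
#'
#' @param dataset a [SourceDataset-class].
#' @param dir directory to create/read.
#' @return \code{writeSourceDataset} returns \code{dir} invisibly;
#'   \code{readSourceDataset} returns a [SourceDataset-class].
#' @export
writeSourceDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subj <- as.data.frame(subjectInfo(dataset))
  utils::write.table(subj, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_len(nSubjects(dataset)))
    utils::write.table(signalMatrix(dataset, i),
                       file.path(dir, sprintf("signal_%s.tsv", subj$id[i])),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  meta <- list(fs = samplingRate(dataset))
  md <- dataset@metadata
  if (!is.null(md$carrierBand)) meta$carrier_band <- as.list(md$carrierBand)
  if (!is.null(md$seed)) meta$seed <- md$seed
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeSourceDataset
#' @export
readSourceDataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  subj <- utils::read.table(file.path(dir, "subjects.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  signals <- lapply(subj$id, function(id) {
    m <- as.matrix(utils::read.table(
      file.path(dir, sprintf("signal_%s.tsv", id)), sep = "\t"))
    dimnames(m) <- list(paste0("ROI", seq_len(nrow(m))), NULL)
    m
  })
  methods::new("SourceDataset", signals = signals, fs = meta$fs,
               subjects = S4Vectors::DataFrame(
                 id = subj$id, group = factor(subj$group), age = subj$age),
               metadata = meta[setdiff(names(meta), "fs")])
}

#' Write per-subject DFA tables or NBS component reports as TSV
#'
#' @param x a data.frame (e.g. from [runSubject]) or an
#'   [NBSResult-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(x, path) {
  if (methods::is(x, "NBSResult")) {
    comp <- nbsComponents(x)
    x <- data.frame(
      component = seq_len(nrow(comp)),
      extent = comp$extent, intensity = comp$intensity,
      pFwer = comp$pFwer,
      edges = vapply(comp$edges, function(e)
        paste(pairLabels(e), collapse = ","), character(1)))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
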