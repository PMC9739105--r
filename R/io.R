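# Strict CSV/FASTA readers and writers for the pipeline's interchange
# formats. All CSVs are UTF-8 with "." decimals and a required header:
#   tracks:    track_id,time_s,length_um,condition
#   turbidity: time_s,a350,condition
#   itc:       injection_index,volume_uL,heat        (heats in uJ)
#   peaks:     mz,intensity
# FASTA description lines may carry an "n_disulfides=<k>" key.

.check_columns <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", file,
                 paste(missing, collapse = ", ")))
}

.check_numeric <- function(df, cols, file) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop(sprintf("%s: column '%s' is not numeric (first bad entry at data line %d)",
                   file, col, if (length(bad)) bad[1L] else NA_integer_))
    }
  }
}

.read_csv_strict <- function(file, required, numeric_cols) {
  if (!file.exists(file)) stop(sprintf("file not found: %s", file))
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  .check_columns(df, required, file)
  .check_numeric(df, numeric_cols, file)
  df
}

#' Read / write microtubule tracks CSV
#'
#' @param file Path to a CSV with columns `track_id`, `time_s`,
#'   `length_um`, `condition`.
#' @return data.frame with those columns.
#' @export
read_tracks <- function(file) {
  .read_csv_strict(file, c("track_id", "time_s", "length_um", "condition"),
                   c("time_s", "length_um"))
}

#' @rdname read_tracks
#' @param x Tracks data.frame or `mt_trackset`.
#' @export
write_tracks <- function(x, file) {
  if (inherits(x, "mt_trackset")) x <- x$tracks
  utils::write.csv(x[c("track_id", "time_s", "length_um", "condition")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read / write turbidity curves CSV
#'
#' @param file Path to a CSV with columns `time_s`, `a350`, `condition`.
#' @return data.frame with those columns.
#' @export
read_turbidity <- function(file) {
  .read_csv_strict(file, c("time_s", "a350", "condition"),
                   c("time_s", "a350"))
}

#' @rdname read_turbidity
#' @param x Turbidity data.frame (possibly several conditions stacked).
#' @export
write_turbidity <- function(x, file) {
  utils::write.csv(as.data.frame(x)[c("time_s", "a350", "condition")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read / write ITC injection tables CSV
#'
#' The CSV holds per-injection volumes and integrated heats; cell/syringe
#' concentrations travel in the run configuration or manifest, so
#' [as_titration()] combines the table with an [itc_schedule()].
#'
#' @param file Path to a CSV with columns `injection_index`, `volume_uL`,
#'   `heat`.
#' @return data.frame with those columns.
#' @export
read_itc <- function(file) {
  .read_csv_strict(file, c("injection_index", "volume_uL", "heat"),
                   c("injection_index", "volume_uL", "heat"))
}

#' @rdname read_itc
#' @param x An `itc_titration` or data.frame with the ITC columns.
#' @export
write_itc <- function(x, file) {
  if (inherits(x, "itc_titration"))
    x <- data.frame(injection_index = seq_along(x$heats),
                    volume_uL = x$schedule$inj_volumes,
                    heat = x$heats)
  utils::write.csv(x[c("injection_index", "volume_uL", "heat")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Combine an ITC injection table with a schedule
#'
#' @param df data.frame from [read_itc()].
#' @param schedule An [itc_schedule()] whose injection volumes are replaced
#'   by the table's.
#' @param blank Optional data.frame of blank (dilution) injections with the
#'   same layout.
#' @return An [itc_titration()].
#' @export
as_titration <- function(df, schedule, blank = NULL) {
  sch <- itc_schedule(cell_conc = schedule$cell_conc,
                      syringe_conc = schedule$syringe_conc,
                      inj_volumes = df$volume_uL,
                      cell_volume = schedule$cell_volume,
                      temperature = schedule$temperature)
  itc_titration(sch, df$heat,
                blank_heats = if (!is.null(blank)) blank$heat else NULL)
}

#' Read / write mass peak lists CSV
#'
#' @param file Path to a CSV with columns `mz`, `intensity`.
#' @return data.frame of class `peak_list`.
#' @export
read_peaks <- function(file) {
  df <- .read_csv_strict(file, c("mz", "intensity"), c("mz", "intensity"))
  class(df) <- c("peak_list", "data.frame")
  df
}

#' @rdname read_peaks
#' @param x Peak-list data.frame.
#' @export
write_peaks <- function(x, file) {
  utils::write.csv(as.data.frame(x)[c("mz", "intensity")], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read / write peptide FASTA
#'
#' Sequences are wrapped at 60 columns; the description line may carry an
#' `n_disulfides=<k>` key which is parsed into the peptide's disulfide
#' count.
#'
#' @param file Path to a FASTA file.
#' @return List of [peptide()] objects, named by FASTA identifier.
#' @export
read_fasta_peptides <- function(file) {
  if (!file.exists(file)) stop(sprintf("file not found: %s", file))
  set <- Biostrings::readAAStringSet(file)
  out <- lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    nd <- 0L
    m <- regmatches(header, regexpr("n_disulfides=\\d+", header))
    if (length(m) && nzchar(m))
      nd <- as.integer(sub("n_disulfides=", "", m))
    peptide(as.character(set[[i]]), n_disulfides = nd,
            name = strsplit(header, "\\s+")[[1L]][1L])
  })
  names(out) <- vapply(out, function(p) p$name, character(1))
  out
}

#' @rdname read_fasta_peptides
#' @param peptides List of [peptide()] objects (or a single one).
#' @export
write_fasta_peptides <- function(peptides, file) {
  if (inherits(peptides, "peptide")) peptides <- list(peptides)
  seqs <- Biostrings::AAStringSet(vapply(peptides, function(p) p$sequence,
                                         character(1)))
  names(seqs) <- vapply(peptides, function(p) {
    nm <- if (nzchar(p$name)) gsub("\\s+", "_", p$name) else "peptide"
    sprintf("%s n_disulfides=%d", nm, p$n_disulfides)
  }, character(1))
  Biostrings::writeXStringSet(seqs, file, width = 60L)
  invisible(file)
}

#' Typed dataset reader dispatching on schema
#'
#' @param file Input path.
#' @param schema One of `"tracks"`, `"turbidity"`, `"itc"`, `"peaks"`,
#'   `"fasta"`.
#' @return The schema's native object (data.frame or peptide list).
#' @export
read_dataset <- function(file, schema = c("tracks", "turbidity", "itc",
                                          "peaks", "fasta")) {
  schema <- match.arg(schema)
  switch(schema,
         tracks = read_tracks(file),
         turbidity = read_turbidity(file),
         itc = read_itc(file),
         peaks = read_peaks(file),
         fasta = read_fasta_peptides(file))
}

#' Published reference set of dynamic-instability parameters
#'
#' The MCF-7 dynamic-instability measurements under increasing myotoxin-3
#' concentrations (control, 1, 5, 25 uM), as mean, SEM and n per
#' parameter, shipped as a plain-text table with the package. These are the
#' numbers behind the reported percent changes (e.g. dynamicity
#' 14.4 -> 8.65 um/min, i.e. -40% at 25 uM).
#'
#' @return data.frame with columns `condition`, `parameter`, `mean`,
#'   `sem`, `n`, `code`.
#' @examples
#' ref <- reference_dynamics()
#' subset(ref, parameter == "dynamicity")
#' @export
reference_dynamics <- function() {
  file <- system.file("extdata", "mcf7_dynamics_reference.tsv",
                      package = "mtxkit", mustWork = TRUE)
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' A reference condition as a named parameter vector
#'
#' Convenience accessor pulling one condition column of
#' [reference_dynamics()] into the named-vector form accepted by
#' [compare_conditions()].
#'
#' @param condition One of `"control"`, `"1uM"`, `"5uM"`, `"25uM"`.
#' @return Named numeric vector of parameter means.
#' @export
reference_condition <- function(condition = c("control", "1uM", "5uM",
                                              "25uM")) {
  condition <- match.arg(condition)
  ref <- reference_dynamics()
  sub <- ref[ref$condition == condition, ]
  stats::setNames(sub$mean, sub$parameter)
}
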