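# One call writes every fixture input the pipeline consumes, with the
# generating ground truth recorded in a JSON manifest. Per-stage seeds are
# derived deterministically from the master seed so the whole bundle is a
# pure function of (parameters, seed).

# dose-dependent track parameters for the fixture conditions: speeds and
# growth persistence fall with dose, pause occupancy rises — the direction
# of the measured MCF-7 response. Values are fixture conventions.
.fixture_di_params <- function(condition) {
  switch(condition,
    control = di_params(),
    "1uM"  = di_params(v_g = 26.5, v_s = 32,
                       k_GS = 6.5, k_GP = 8.2, k_PG = 3.8, k_PS = 3.1,
                       k_SG = 12.5, k_SP = 7.2),
    "5uM"  = di_params(v_g = 26.5, v_s = 31,
                       k_GS = 6.5, k_GP = 9.5, k_PG = 3.1, k_PS = 2.9,
                       k_SG = 12.5, k_SP = 7.5),
    "25uM" = di_params(v_g = 20.5, v_s = 24.5,
                       k_GS = 8.0, k_GP = 11.5, k_PG = 2.6, k_PS = 2.6,
                       k_SG = 13.5, k_SP = 9.0),
    stop(sprintf("unknown fixture condition '%s'", condition))
  )
}

.fixture_track_n <- c(control = 54L, "1uM" = 44L, "5uM" = 44L, "25uM" = 68L)

#' Write the full synthetic fixture bundle
#'
#' Generates and writes, under `outdir`: microtubule tracks for a control
#' and three peptide doses (sample sizes 54/44/44/68 tracks, 2-s sampling
#' for 1 min), a control/peptide pair of turbidity curves (the peptide
#' curve with shorter lag and higher plateau), a one-site ITC isotherm at
#' the tubulin schedule (55 uM cell, 2.2 mM syringe, 2 uL injections;
#' generating values N = 2, Kd = 5.3 uM, dH = -40 kJ/mol) with its blank,
#' an in-source-decay spectrum of the 45-residue peptide, the four isoform
#' sequences as FASTA, and a `manifest.json` holding every generating
#' parameter. Byte-identical output under identical seeds.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param n_tracks Optional named vector overriding tracks per condition.
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(outdir, seed = 1L, n_tracks = NULL) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  nt <- .fixture_track_n
  if (!is.null(n_tracks)) nt[names(n_tracks)] <- n_tracks

  manifest <- list(seed = seed, files = list(), truth = list())

  # tracks: one CSV, all conditions stacked
  conditions <- names(nt)
  all_tracks <- vector("list", length(conditions))
  truth_tracks <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    p <- .fixture_di_params(cond)
    ts <- simulate_tracks(p, n_tracks = nt[[cond]], duration = 60, dt = 2,
                          condition = cond, seed = seed + 1000L + i)
    all_tracks[[i]] <- ts$tracks
    truth_tracks[[cond]] <- c(unclass(p), n_tracks = nt[[cond]])
  }
  tracks_file <- file.path(outdir, "tracks.csv")
  write_tracks(do.call(rbind, all_tracks), tracks_file)
  manifest$files$tracks <- "tracks.csv"
  manifest$truth$tracks <- truth_tracks

  # turbidity: control vs peptide, peptide has shorter lag, higher plateau
  turb_truth <- list(
    control = list(plateau = 0.20, lag = 300, rate = 0.008,
                   baseline = 0.05, noise_sd = 0.002),
    peptide = list(plateau = 0.38, lag = 120, rate = 0.012,
                   baseline = 0.05, noise_sd = 0.002)
  )
  curves <- mapply(function(tr, cond, s) {
    simulate_turbidity(plateau = tr$plateau, lag = tr$lag, rate = tr$rate,
                       baseline = tr$baseline, noise_sd = tr$noise_sd,
                       n_points = 181, dt = 10, condition = cond, seed = s)
  }, turb_truth, names(turb_truth),
  seed + 2000L + seq_along(turb_truth), SIMPLIFY = FALSE)
  turb_file <- file.path(outdir, "turbidity.csv")
  write_turbidity(do.call(rbind, lapply(curves, as.data.frame)), turb_file)
  manifest$files$turbidity <- "turbidity.csv"
  manifest$truth$turbidity <- turb_truth

  # ITC: the tubulin schedule with N = 2, Kd = 5.3 uM
  sch <- itc_schedule()
  truth <- binding_params(N = 2, Ka = 1 / 5.3e-6, dH = -40,
                          T = sch$temperature)
  tit <- simulate_itc(truth, sch, noise_sd = 2, dilution_offset = -5,
                      seed = seed + 3000L)
  itc_file <- file.path(outdir, "itc.csv")
  write_itc(tit, itc_file)
  blank_file <- file.path(outdir, "itc_blank.csv")
  write_itc(data.frame(injection_index = seq_along(tit$heats),
                       volume_uL = sch$inj_volumes,
                       heat = tit$blank_heats), blank_file)
  manifest$files$itc <- "itc.csv"
  manifest$files$itc_blank <- "itc_blank.csv"
  manifest$truth$itc <- list(N = truth$N, Ka = truth$Ka, Kd = truth$Kd,
                             dH = truth$dH, noise_sd = 2,
                             dilution_offset = -5,
                             schedule = unclass(sch))

  # ISD spectrum of the 45-residue peptide
  pep <- myotoxin3_peptide("45H")
  peaks <- simulate_isd_peaks(pep, dropout = 0.15, mz_noise_sd = 0.02,
                              seed = seed + 4000L)
  peaks_file <- file.path(outdir, "isd_peaks.csv")
  write_peaks(peaks, peaks_file)
  manifest$files$peaks <- "isd_peaks.csv"
  manifest$truth$peaks <- list(sequence = pep$sequence, dropout = 0.15,
                               mz_noise_sd = 0.02, window = c(1000, 5000))

  # isoform FASTA
  fasta_file <- file.path(outdir, "myotoxin3.fasta")
  write_fasta_peptides(lapply(c("45H", "45L", "43H", "43L"),
                              myotoxin3_peptide), fasta_file)
  manifest$files$fasta <- "myotoxin3.fasta"

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
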