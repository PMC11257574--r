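#' Beta-galactosidase specific activity (protein-normalized)
#'
#' The ONPG liquid assay normalized by total protein:
#' `activity (nmol/min/mg) = OD420 * 1.7 /
#'  (0.0045 * protein * extract_volume * time)`.
#' The constants 1.7 and 0.0045 are used verbatim as printed in the
#' protocol.
#'
#' @param od420 absorbance of the stopped reaction at 420 nm.
#' @param protein_mg_ml protein concentration of the extract (mg/ml).
#' @param extract_volume_ml extract volume in the reaction (ml).
#' @param time_min elapsed reaction time (min).
#' @return activity in nmol/min/mg.
#' @export
beta_gal_activity_amberg <- function(od420, protein_mg_ml,
                                     extract_volume_ml, time_min) {
  if (any(od420 < 0)) stop("od420 must be >= 0")
  if (any(protein_mg_ml <= 0) || any(extract_volume_ml <= 0) ||
      any(time_min <= 0)) {
    stop("protein, volume and time must be > 0")
  }
  od420 * 1.7 / (0.0045 * protein_mg_ml * extract_volume_ml * time_min)
}

#' Beta-galactosidase units (culture-density normalized)
#'
#' The Miller-style unit formula normalized by culture density:
#' `units = 1000 * OD420 / (T * V * OD595)`.
#'
#' @param od420 absorbance of the stopped reaction at 420 nm.
#' @param time_min elapsed reaction time T (min).
#' @param volume_ml culture volume V used (ml).
#' @param od595 optical density of the culture at 595 nm.
#' @return activity units.
#' @export
beta_gal_units_miller <- function(od420, time_min, volume_ml, od595) {
  if (any(od420 < 0)) stop("od420 must be >= 0")
  if (any(time_min <= 0) || any(volume_ml <= 0) || any(od595 <= 0)) {
    stop("time, volume and od595 must be > 0")
  }
  1000 * od420 / (time_min * volume_ml * od595)
}

#' Append beta-galactosidase activities to a measurement table
#'
#' Reads a CSV of ONPG measurements, computes the activity with the
#' formula named in each row's `method` column (`"amberg"` needs
#' `protein_mg_ml` and `extract_volume_ml`; `"miller"` needs
#' `volume_ml` and `od595`) and writes the table back with an
#' `activity` column appended.
#'
#' @param infile,outfile CSV paths.
#' @return the augmented data.frame, invisibly.
#' @export
beta_gal_table <- function(infile, outfile = NULL) {
  df <- utils::read.csv(infile)
  df$activity <- vapply(seq_len(nrow(df)), function(i) {
    if (identical(df$method[i], "miller")) {
      beta_gal_units_miller(df$od420[i], df$time_min[i], df$volume_ml[i],
                            df$od595[i])
    } else {
      beta_gal_activity_amberg(df$od420[i], df$protein_mg_ml[i],
                               df$extract_volume_ml[i], df$time_min[i])
    }
  }, numeric(1))
  if (!is.null(outfile)) utils::write.csv(df, outfile, row.names = FALSE)
  invisible(df)
}
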