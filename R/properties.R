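# Amino-acid physicochemical property tables and per-sequence averages.
# Scales are typed in from the published sources named below; no value is
# derived at run time.

#' Amino-acid physicochemical property table
#'
#' Per-residue values for the ten Kidera factors and seven additional
#' scales. Provenance:
#' * `kf1`..`kf10`: Kidera et al. (1985) orthogonal factors (KF1
#'   helix/bend preference, KF3 extended-structure preference, KF5
#'   double-bend preference, KF6 partial specific volume, KF7 flat
#'   extended preference, KF10 surrounding hydrophobicity).
#' * `charge`: side-chain charge at neutral pH (+1 for R/K, -1 for D/E,
#'   0 for H and the rest).
#' * `hydropathy`: Kyte-Doolittle (1982).
#' * `volume`: Zamyatnin (1972) residue volume, cubic angstroms.
#' * `polarity`: Grantham (1974).
#' * `mjenergy`: Miyazawa-Jernigan contact-energy hydrophobicity scale.
#' * `disorder`: TOP-IDP intrinsic-disorder propensity (Campen et al. 2008,
#'   approximate transcription).
#' * `core`: residue burial propensity (fraction buried, approximate
#'   transcription of the Chothia-style scale).
#'
#' @return tibble with a `residue` column and one column per property.
#' @export
aa_property_table <- function() {
  m <- rbind(
    #     kf1    kf2    kf3    kf4    kf5    kf6    kf7    kf8    kf9   kf10 charge hydro  volume polar  mj    disorder core
    A = c(-1.56, -1.67, -0.97, -0.27, -0.93, -0.78, -0.20, -0.08,  0.21, -0.48, 0,  1.8,  88.6,  8.1, 5.33,  0.060, 0.38),
    R = c( 0.22,  1.27,  1.37,  1.87, -1.70,  0.46,  0.92, -0.39,  0.23,  0.93, 1, -4.5, 173.4, 10.5, 4.18,  0.180, 0.01),
    N = c( 1.14, -0.07, -0.12,  0.81,  0.18,  0.37, -0.09,  1.23,  1.10, -1.73, 0, -3.5, 114.1, 11.6, 3.71,  0.007, 0.12),
    D = c( 0.58, -0.22, -1.58,  0.81, -0.92,  0.15, -1.52,  0.47,  0.76,  0.70, -1, -3.5, 111.1, 13.0, 3.59,  0.192, 0.15),
    C = c( 0.12, -0.89,  0.45, -1.05, -0.71,  2.41,  1.52, -0.69,  1.13,  1.10, 0,  2.5, 108.5,  5.5, 7.93,  0.020, 0.50),
    Q = c(-0.47,  0.24,  0.07,  1.10,  1.10,  0.59,  0.84, -0.71, -0.03, -2.33, 0, -3.5, 143.8, 10.5, 3.87,  0.318, 0.07),
    E = c(-1.45,  0.19, -1.61,  1.17, -1.31,  0.40,  0.04,  0.38, -0.35, -0.12, -1, -3.5, 138.4, 12.3, 3.65,  0.736, 0.18),
    G = c( 1.46, -1.96, -0.23, -0.16,  0.10, -0.11,  1.32,  2.36, -1.66,  0.46, 0, -0.4,  60.1,  9.0, 4.48,  0.166, 0.36),
    H = c(-0.41,  0.52, -0.28,  0.28,  1.61,  1.01, -1.85,  0.47,  1.13,  1.63, 0, -3.2, 153.2, 10.4, 5.10,  0.303, 0.17),
    I = c(-0.73, -0.16,  1.79, -0.77, -0.54,  0.03, -0.83,  0.51,  0.66, -1.78, 0,  4.5, 166.7,  5.2, 8.83, -0.486, 0.60),
    L = c(-1.04,  0.00, -0.24, -1.10, -0.55, -2.05,  0.96, -0.76,  0.45,  0.93, 0,  3.8, 166.7,  4.9, 8.47, -0.326, 0.45),
    K = c(-0.34,  0.82, -0.23,  1.70,  1.54, -1.62,  1.15, -0.08, -0.48,  0.60, 1, -3.9, 168.6, 11.3, 2.95,  0.586, 0.03),
    M = c(-1.40,  0.18, -0.42, -0.73,  2.00,  1.52,  0.26,  0.11, -1.27,  0.27, 0,  1.9, 162.9,  5.7, 8.95, -0.397, 0.40),
    F = c(-0.21,  0.98, -0.36, -1.43,  0.22, -0.81,  0.67,  1.10,  1.71, -0.44, 0,  2.8, 189.9,  5.2, 9.03, -0.697, 0.50),
    P = c( 2.06, -0.33, -1.15, -0.75,  0.88, -0.45,  0.30, -2.30,  0.74, -0.28, 0, -1.6, 112.7,  8.0, 3.87,  0.987, 0.18),
    S = c( 0.81, -1.08,  0.16,  0.42, -0.21, -0.43, -1.89, -1.15, -0.97, -0.23, 0, -0.8,  89.0,  9.2, 4.09,  0.341, 0.22),
    T = c( 0.26, -0.70,  1.21,  0.63, -0.10,  0.21,  0.24, -1.15, -0.56,  0.19, 0, -0.7, 116.1,  8.6, 4.49,  0.059, 0.23),
    W = c( 0.30,  2.10, -0.72, -1.57, -1.16,  0.57, -0.48, -0.40, -2.30, -0.60, 0, -0.9, 227.8,  5.4, 7.66, -0.884, 0.27),
    Y = c( 1.38,  1.48,  0.80, -0.56,  0.00, -0.68, -0.31,  1.03, -0.05,  0.53, 0, -1.3, 193.6,  6.2, 5.89, -0.510, 0.15),
    V = c(-0.74, -0.71,  2.04, -0.40,  0.50, -0.81, -1.07,  0.06, -0.46,  0.65, 0,  4.2, 140.0,  5.9, 7.63, -0.121, 0.54)
  )
  colnames(m) <- c(paste0("kf", 1:10), "charge", "hydropathy", "volume",
                   "polarity", "mjenergy", "disorder", "core")
  as_tibble(m, rownames = "residue")
}

#' Names of the available amino-acid properties
#' @return character vector of property column names.
#' @export
aa_property_names <- function() setdiff(names(aa_property_table()), "residue")

property_lookup <- function(property, table = aa_property_table()) {
  if (!property %in% names(table)) {
    abort(sprintf("unknown property '%s'", property))
  }
  setNames(table[[property]], table$residue)
}

#' Mean per-residue property value of one sequence
#'
#' @param seq an amino-acid string.
#' @param property a property name, see [aa_property_names()].
#' @param table property table (default [aa_property_table()]).
#' @return mean of the per-residue values; order-invariant by construction.
#' @export
sequence_property_mean <- function(seq, property, table = aa_property_table()) {
  lk <- property_lookup(property, table)
  res <- strsplit(seq, "")[[1]]
  vals <- lk[res]
  if (anyNA(vals)) {
    abort(sprintf("residue(s) %s absent from property table",
                  paste(unique(res[is.na(vals)]), collapse = ", ")))
  }
  mean(vals)
}

#' Unweighted group mean of a sequence property
#'
#' Mean over sequences of [sequence_property_mean()] (each clonotype counts
#' once, unweighted by abundance).
#'
#' @param group character vector of sequences (non-empty).
#' @inheritParams sequence_property_mean
#' @return the group mean.
#' @export
group_property_mean <- function(group, property, table = aa_property_table()) {
  if (length(group) == 0) abort("empty group")
  mean(vapply(group, sequence_property_mean, numeric(1),
              property = property, table = table, USE.NAMES = FALSE))
}
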