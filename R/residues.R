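# Per-residue coarse-grained parameters.
#
# Charges follow titration states at neutral pH: Arg/Lys +1, Asp/Glu -1,
# His neutral, everything else (and both termini) uncharged.
# Hydrophobicity is the Kyte-Doolittle scale min-max normalized to [0, 1].
# Bead radii derive from amino-acid van der Waals volumes (sphere of equal
# volume); masses are average residue masses (amino acid minus water).

.aa_codes <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.aa_mass <- c(A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14,
              Q = 128.13, E = 129.12, G = 57.05, H = 137.14, I = 113.16,
              L = 113.16, K = 128.17, M = 131.19, F = 147.18, P = 97.12,
              S = 87.08, T = 101.10, W = 186.21, Y = 163.18, V = 99.13)

# van der Waals volumes, A^3 (Richards-type consensus values)
.aa_vdw_vol <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
                 Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
                 L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
                 S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

.aa_kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
            Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
            L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
            S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.aa_charge <- c(A = 0L, R = 1L, N = 0L, D = -1L, C = 0L,
                Q = 0L, E = -1L, G = 0L, H = 0L, I = 0L,
                L = 0L, K = 1L, M = 0L, F = 0L, P = 0L,
                S = 0L, T = 0L, W = 0L, Y = 0L, V = 0L)

#' Coarse-grained residue parameter table
#'
#' One row per canonical amino acid: titration-state side-chain charge
#' (Arg/Lys +1, Asp/Glu -1, His neutral), min-max normalized Kyte-Doolittle
#' hydrophobicity in \[0, 1\], bead radius from the van der Waals volume
#' (radius of the equal-volume sphere, Angstrom) and average residue mass
#' (Dalton).
#'
#' @return A data.frame with columns `code`, `charge`, `hydrophobicity`,
#'   `radius`, `mass`, keyed by 1-letter code.
#' @examples
#' residue_params()["K", ]
#' @export
residue_params <- function() {
  kd <- (.aa_kd - min(.aa_kd)) / (max(.aa_kd) - min(.aa_kd))
  data.frame(
    code = .aa_codes,
    charge = .aa_charge[.aa_codes],
    hydrophobicity = unname(kd[.aa_codes]),
    radius = unname((3 * .aa_vdw_vol[.aa_codes] / (4 * pi))^(1 / 3)),
    mass = unname(.aa_mass[.aa_codes]),
    row.names = .aa_codes,
    stringsAsFactors = FALSE
  )
}

.check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(res %in% .aa_codes))
  if (length(bad) > 0L) {
    stop(sprintf("invalid amino-acid code '%s' at position %d",
                 res[bad[1]], bad[1]), call. = FALSE)
  }
  res
}

#' Net side-chain charge of a sequence
#'
#' Sums titration-state side-chain charges (Arg/Lys +1, Asp/Glu -1, His and
#' all other residues 0). Termini are treated as uncharged; the N-terminal
#' +1 and C-terminal -1 of a free peptide would cancel in any case.
#'
#' @param sequence single string of 1-letter amino-acid codes.
#' @return Integer net charge in units of e.
#' @examples
#' net_charge("KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY") # amylin, +2
#' net_charge("KRDE") # 0
#' @export
net_charge <- function(sequence) {
  res <- .check_sequence(sequence)
  if (length(res) == 0L) return(0L)
  sum(.aa_charge[res])
}

#' Counterions needed to neutralize a system
#'
#' Chloride neutralizes positive net charge, sodium negative; a neutral
#' system needs none.
#'
#' @param total_charge integer net charge of the solute content, in e.
#' @return list with `species` ("Cl-", "Na+" or "none") and integer `count`.
#' @examples
#' counterions_for(2)   # 2 Cl-
#' counterions_for(-7)  # 7 Na+
#' @export
counterions_for <- function(total_charge) {
  stopifnot(length(total_charge) == 1L, total_charge == round(total_charge))
  total_charge <- as.integer(total_charge)
  if (total_charge > 0L) {
    list(species = "Cl-", count = total_charge)
  } else if (total_charge < 0L) {
    list(species = "Na+", count = -total_charge)
  } else {
    list(species = "none", count = 0L)
  }
}

#' Built-in amylin (IAPP) fixture
#'
#' The 37-residue human islet amyloid polypeptide: primary sequence,
#' intramolecular disulfide bridge between residues 2 and 7, nominal
#' molecular weight of the peptide reagent, and the net side-chain charge
#' under the titration rules of [net_charge()]. The mass computed from
#' residue masses plus one water is also returned; it differs slightly from
#' the nominal MW (the amidation state of the reagent is not modelled).
#'
#' @return list with `sequence`, `disulfide` (integer pair), `nominal_mw`,
#'   `computed_mw` and `net_charge`.
#' @export
iapp_fixture <- function() {
  seq <- "KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY"
  res <- .check_sequence(seq)
  list(
    sequence = seq,
    disulfide = c(2L, 7L),
    nominal_mw = 3906,
    computed_mw = sum(.aa_mass[res]) + 18.02,
    net_charge = net_charge(seq)
  )
}
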