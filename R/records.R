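#' @keywords internal
"_PACKAGE"

## Canonical 20-letter amino-acid alphabet, alphabetical order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Secondary-structure states: alpha helix, beta strand, random coil.
SS_STATES <- c("H", "E", "C")

#' A validated protein sequence record
#'
#' Couples an identifier with an amino-acid sequence restricted to the 20
#' standard residues. All encoders in the package consume this type, so the
#' alphabet check happens exactly once, at construction.
#'
#' @param id Identifier token (non-empty, no whitespace).
#' @param sequence Amino-acid sequence over `ACDEFGHIKLMNPQRSTVWY`;
#'   lower-case input is upper-cased.
#' @return An object of class `protein_record` with elements `id` and
#'   `sequence`.
#' @examples
#' protein_record("p1", "ACDEFG")
#' @export
protein_record <- function(id, sequence) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id)) {
    stop("protein id must be a single non-empty token without whitespace", call. = FALSE)
  }
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop(sprintf("record '%s': empty sequence", id), call. = FALSE)
  }
  bad <- residue_violations(sequence)
  if (length(bad) > 0L) {
    stop(sprintf(
      "record '%s': illegal residue '%s' at position %d (alphabet is the 20 standard amino acids)",
      id, substr(sequence, bad[1L], bad[1L]), bad[1L]
    ), call. = FALSE)
  }
  structure(list(id = id, sequence = sequence), class = "protein_record")
}

## Positions of characters outside the 20-letter alphabet (0-length if clean).
residue_violations <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  which(!chars %in% AA_ALPHABET)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

seq_chars <- function(record) {
  strsplit(record$sequence, "", fixed = TRUE)[[1L]]
}

#' Side-chain functional-group scheme
#'
#' The ten functional groups that partition the 20 amino acids by side-chain
#' chemistry: phenyl (F/W/Y), carboxyl (D/E), imidazole (H), primary amine
#' (K), guanidino (R), thiol (C), sulfur (M), amido (Q/N), hydroxyl (S/T)
#' and non-polar (A/G/I/L/V/P). The order of this list is the canonical
#' group order used by the frequency, transition and secondary-structure
#' encoders.
#'
#' @return Named list of character vectors, one per group, jointly
#'   partitioning the amino-acid alphabet.
#' @export
functional_group_scheme <- function() {
  list(
    phenyl        = c("F", "W", "Y"),
    carboxyl      = c("D", "E"),
    imidazole     = "H",
    primary_amine = "K",
    guanidino     = "R",
    thiol         = "C",
    sulfur        = "M",
    amido         = c("Q", "N"),
    hydroxyl      = c("S", "T"),
    non_polar     = c("A", "G", "I", "L", "V", "P")
  )
}

## Residue -> group name lookup vector for the canonical scheme.
group_of_residue <- function(scheme = functional_group_scheme()) {
  map <- character(0)
  for (g in names(scheme)) {
    map[scheme[[g]]] <- g
  }
  map[AA_ALPHABET]
}

#' Physicochemical property scales
#'
#' Per-amino-acid numeric scales used by the pseudo amino-acid composition
#' and wavelet encoders: Kyte-Doolittle hydrophobicity, average flexibility
#' index, net side-chain charge at physiological pH, and accessible surface
#' area of the residue in an extended tripeptide (A^2). Scales are
#' standardized to zero mean and unit population standard deviation over the
#' 20 amino acids before use, so only relative values matter; alternative
#' tables can be supplied as a replacement matrix of the same shape.
#'
#' @param standardize Standardize each scale to mean 0 / population SD 1
#'   over the 20 amino acids (the form all encoders consume). Default `TRUE`.
#' @return A 20 x 4 numeric matrix, rows named by amino acid, columns
#'   `hydrophobicity`, `flexibility`, `charge`, `asa`.
#' @export
property_scales <- function(standardize = TRUE) {
  hydro <- c(A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
             G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
             M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
             S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)
  flex  <- c(A = 0.357, C = 0.346, D = 0.511, E = 0.497, F = 0.314,
             G = 0.544, H = 0.323, I = 0.462, K = 0.466, L = 0.365,
             M = 0.295, N = 0.463, P = 0.509, Q = 0.493, R = 0.529,
             S = 0.507, T = 0.444, V = 0.386, W = 0.305, Y = 0.420)
  charge <- c(A = 0, C = 0, D = -1, E = -1, F = 0,
              G = 0, H = 0.1, I = 0, K = 1, L = 0,
              M = 0, N = 0, P = 0, Q = 0, R = 1,
              S = 0, T = 0, V = 0, W = 0, Y = 0)
  asa   <- c(A = 115, C = 135, D = 150, E = 190, F = 210,
             G =  75, H = 195, I = 175, K = 200, L = 170,
             M = 185, N = 160, P = 145, Q = 180, R = 225,
             S = 115, T = 140, V = 155, W = 255, Y = 230)
  m <- cbind(hydrophobicity = hydro[AA_ALPHABET],
             flexibility    = flex[AA_ALPHABET],
             charge         = charge[AA_ALPHABET],
             asa            = asa[AA_ALPHABET])
  rownames(m) <- AA_ALPHABET
  if (standardize) m <- apply(m, 2L, standardize_scale)
  m
}

## Zero mean, unit population SD over the 20 amino acids.
standardize_scale <- function(v) {
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  if (sd_pop == 0) stop("constant property scale cannot be standardized", call. = FALSE)
  (v - mu) / sd_pop
}

## Population (denominator n) variance / SD; 0 for length-1 input.
pop_var <- function(x) {
  if (length(x) == 0L) return(0)
  mean((x - mean(x))^2)
}
pop_sd <- function(x) sqrt(pop_var(x))

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards. All stochastic package code funnels through
## this so a single integer seed pins every result.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
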