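#' Functional-group frequencies
#'
#' Fraction of residues falling in each of the ten side-chain functional
#' groups (see [functional_group_scheme()]). Because the groups partition
#' the alphabet the ten components sum to exactly 1.
#'
#' @param record A [protein_record()].
#' @param scheme Functional-group scheme; default the canonical ten groups.
#' @return Named 10-vector `ffg.<group>`.
#' @export
ffg_frequencies <- function(record, scheme = functional_group_scheme()) {
  chars <- seq_chars(record)
  out <- vapply(scheme, function(members) sum(chars %in% members), numeric(1L))
  out <- out / length(chars)
  names(out) <- paste0("ffg.", names(scheme))
  out
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropies of amino-acid and dipeptide composition
#'
#' `H(x) = -sum(P_i * log2(P_i))` over the frequencies of the 20 amino
#' acids, and over the 400 dipeptides formed by the L-1 overlapping residue
#' pairs. Zero-frequency terms contribute 0.
#'
#' @param record A [protein_record()] of length >= 2.
#' @return Named 2-vector `entropy.aac`, `entropy.dipeptide`;
#'   `entropy.aac` lies in \[0, log2(20)\] and `entropy.dipeptide` in
#'   \[0, log2(400)\].
#' @export
shannon_entropies <- function(record) {
  chars <- seq_chars(record)
  L <- length(chars)
  if (L < 2L) {
    stop(sprintf("record '%s': dipeptide entropy needs length >= 2", record$id),
         call. = FALSE)
  }
  aac <- table(factor(chars, levels = AA_ALPHABET)) / L
  dipep <- paste0(chars[-L], chars[-1L])
  dp <- table(dipep) / (L - 1L)
  c(entropy.aac = shannon(as.numeric(aac)),
    entropy.dipeptide = shannon(as.numeric(dp)))
}

#' Positional distribution descriptor
#'
#' For each amino acid, the population variance of the distances from each
#' of its occurrences to its first occurrence. Amino acids occurring at most
#' once contribute 0.
#'
#' @param record A [protein_record()].
#' @return Named 20-vector `dist.<aa>` in alphabet order.
#' @export
distribution_descriptor <- function(record) {
  chars <- seq_chars(record)
  out <- vapply(AA_ALPHABET, function(aa) {
    pos <- which(chars == aa)
    if (length(pos) <= 1L) return(0)
    d <- pos - pos[1L]
    pop_var(d)
  }, numeric(1L))
  names(out) <- paste0("dist.", AA_ALPHABET)
  out
}

#' Functional-group transition descriptor
#'
#' For each unordered pair of distinct functional groups \{g_i, g_j\}, the
#' number of adjacent residue pairs crossing between the two groups (in
#' either direction) divided by the sequence length L. The 45 components
#' are ordered lexicographically over (i, j), i < j, in scheme order.
#'
#' @param record A [protein_record()].
#' @param scheme Functional-group scheme.
#' @return Named 45-vector `trans.<gi>.<gj>`; each component lies in
#'   \[0, (L-1)/L\].
#' @export
transition_descriptor <- function(record, scheme = functional_group_scheme()) {
  chars <- seq_chars(record)
  L <- length(chars)
  gmap <- group_of_residue(scheme)
  names(gmap) <- AA_ALPHABET
  groups <- gmap[chars]
  gnames <- names(scheme)
  n_g <- length(gnames)
  counts <- matrix(0, n_g, n_g, dimnames = list(gnames, gnames))
  if (L >= 2L) {
    from <- groups[-L]
    to <- groups[-1L]
    tab <- table(factor(from, levels = gnames), factor(to, levels = gnames))
    counts <- counts + as.matrix(tab)
  }
  out <- numeric(0)
  for (i in seq_len(n_g - 1L)) {
    for (j in (i + 1L):n_g) {
      v <- (counts[i, j] + counts[j, i]) / L
      names(v) <- paste0("trans.", gnames[i], ".", gnames[j])
      out <- c(out, v)
    }
  }
  out
}

#' Pseudo amino-acid composition parameters
#'
#' @param eta Number of sequence-order correlation tiers (default 20).
#' @param w Weight of the correlation block relative to composition
#'   (default 0.05).
#' @return An object of class `pseaac_params`.
#' @export
pseaac_params <- function(eta = 20L, w = 0.05) {
  stopifnot(eta >= 1L, w > 0)
  structure(list(eta = as.integer(eta), w = w), class = "pseaac_params")
}

#' Type-I pseudo amino-acid composition
#'
#' Classic PseAAC with `eta` correlation tiers over the four standardized
#' physicochemical property scales (hydrophobicity, flexibility, net
#' charge, accessible surface area). The tier-k correlation factor is the
#' mean over positions j of `Theta(R_j, R_{j+k})`, where `Theta(a, b)` is
#' the mean squared difference of the four property values of a and b. The
#' first 20 components are the weighted amino-acid frequencies, the last
#' `eta` the weighted correlation factors; all components sum to 1.
#'
#' @param record A [protein_record()] with length > `eta`.
#' @param params A [pseaac_params()].
#' @param scales Standardized property matrix from [property_scales()];
#'   PseAAC uses all four columns.
#' @return Named (20 + eta)-vector `pseaac.f.<aa>`, `pseaac.theta.<k>`.
#' @export
pseaac <- function(record, params = pseaac_params(), scales = property_scales()) {
  chars <- seq_chars(record)
  L <- length(chars)
  eta <- params$eta
  if (L <= eta) {
    stop(sprintf("record '%s': PseAAC with eta=%d needs length > %d (got %d)",
                 record$id, eta, eta, L), call. = FALSE)
  }
  props <- scales[chars, , drop = FALSE]   # L x 4
  theta <- vapply(seq_len(eta), function(k) {
    d <- props[1:(L - k), , drop = FALSE] - props[(1 + k):L, , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1L))
  f <- as.numeric(table(factor(chars, levels = AA_ALPHABET))) / L
  denom <- 1 + params$w * sum(theta)
  out <- c(f / denom, params$w * theta / denom)
  names(out) <- c(paste0("pseaac.f.", AA_ALPHABET),
                  paste0("pseaac.theta.", seq_len(eta)))
  out
}

#' Wavelet feature parameters
#'
#' @param wavelet Wavelet name; only `"db4"` is built in.
#' @param level Decomposition depth (default 4).
#' @param subbands Which coefficient bands are summarized. Default the
#'   three coarsest of the level-4 decomposition: the final approximation
#'   `cA4` and the two coarsest detail bands `cD4`, `cD3`. With three bands
#'   each property contributes 2 raw-signal statistics + 4 statistics per
#'   band = 14 features, giving 42 over the three property signals.
#' @return An object of class `dwt_params`.
#' @export
dwt_params <- function(wavelet = "db4", level = 4L,
                       subbands = c("cA4", "cD4", "cD3")) {
  stopifnot(level >= 1L)
  if (wavelet != "db4") stop("only the db4 wavelet is available", call. = FALSE)
  ok <- c(paste0("cA", level), paste0("cD", seq_len(level)))
  if (!all(subbands %in% ok)) {
    stop(sprintf("subbands must be among %s", paste(ok, collapse = ", ")), call. = FALSE)
  }
  structure(list(wavelet = wavelet, level = as.integer(level), subbands = subbands),
            class = "dwt_params")
}

#' Discrete-wavelet-transform statistics of property signals
#'
#' Maps the sequence to three per-residue numeric signals (standardized
#' hydrophobicity, flexibility and accessible surface area), decomposes
#' each with a level-4 db4 wavelet transform under symmetric boundary
#' extension, and summarizes: mean and population SD of the raw signal,
#' plus max, min, mean and population SD of the coefficients in each
#' selected sub-band. With the default three sub-bands this yields 14
#' features per property, 42 in total.
#'
#' @param record A [protein_record()] with length >= `2^level` (16 for the
#'   default level 4).
#' @param params A [dwt_params()].
#' @param scales Standardized property matrix from [property_scales()]; the
#'   `hydrophobicity`, `flexibility` and `asa` columns are used.
#' @return Named 42-vector `dwt.<property>.<stat>`.
#' @export
dwt_features <- function(record, params = dwt_params(), scales = property_scales()) {
  chars <- seq_chars(record)
  props <- c("hydrophobicity", "flexibility", "asa")
  out <- numeric(0)
  for (p in props) {
    sig <- scales[chars, p]
    dec <- dwt_decompose(sig, params$level)
    stats <- c(raw.mean = mean(sig), raw.sd = pop_sd(sig))
    for (band in params$subbands) {
      coefs <- if (grepl("^cA", band)) {
        dec$approximation
      } else {
        dec$details[[as.integer(sub("cD", "", band))]]
      }
      s <- c(max = max(coefs), min = min(coefs), mean = mean(coefs),
             sd = pop_sd(coefs))
      names(s) <- paste0(band, ".", names(s))
      stats <- c(stats, s)
    }
    names(stats) <- paste0("dwt.", p, ".", names(stats))
    out <- c(out, stats)
  }
  out
}
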